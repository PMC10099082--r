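#' Acoustic scene description
#'
#' A scene is a homogeneous background plus an ordered list of regions painted
#' on top of it (later regions override earlier ones where they overlap).
#'
#' @param background_speed background speed of sound (m/s), e.g. 1490 for
#'   coupling water.
#' @param background_density background density (kg/m^3).
#' @param regions list of regions from \code{region_circle()} /
#'   \code{region_annulus()}.
#' @return an object of class \code{acoustic_scene}.
#' @export
acoustic_scene <- function(background_speed = 1490, background_density = 1000,
                           regions = list()) {
  if (background_speed <= 0 || background_density <= 0)
    stop("background speed and density must be positive")
  structure(list(background_speed = background_speed,
                 background_density = background_density,
                 regions = regions),
            class = "acoustic_scene")
}

#' @rdname acoustic_scene
#' @param center region centre (mm).
#' @param radius circle radius (mm).
#' @param speed,density acoustic properties of the region.
#' @export
region_circle <- function(center, radius, speed, density) {
  if (radius <= 0) stop("radius must be positive")
  if (speed <= 0 || density <= 0) stop("speed and density must be positive")
  list(shape = "circle", center = center, radius = radius,
       speed = speed, density = density)
}

#' @rdname acoustic_scene
#' @param r_in,r_out inner and outer radii of the annulus (mm), r_out > r_in >= 0.
#' @export
region_annulus <- function(center, r_in, r_out, speed, density) {
  if (!(r_out > r_in && r_in >= 0)) stop("need r_out > r_in >= 0")
  if (speed <= 0 || density <= 0) stop("speed and density must be positive")
  list(shape = "annulus", center = center, r_in = r_in, r_out = r_out,
       speed = speed, density = density)
}

# evaluate the scene at arbitrary points (painter's order)
scene_at <- function(scene, points) {
  points <- rbind(points)
  speed <- rep(scene$background_speed, nrow(points))
  dens <- rep(scene$background_density, nrow(points))
  for (rg in scene$regions) {
    d <- sqrt((points[, 1] - rg$center[1])^2 + (points[, 2] - rg$center[2])^2)
    inside <- if (rg$shape == "circle") d <= rg$radius
              else d >= rg$r_in & d <= rg$r_out
    speed[inside] <- rg$speed
    dens[inside] <- rg$density
  }
  list(speed = speed, density = dens)
}

#' Rasterize a scene onto a grid
#'
#' Paints per-pixel speed (and density) by point-in-shape tests in painter's
#' order; pixels outside all regions keep the background values.
#'
#' @param scene an \code{acoustic_scene}.
#' @param grid an \code{imaging_grid}.
#' @return a \code{sos_map} whose \code{density} field holds the matching
#'   density map.
#' @export
rasterize_scene <- function(scene, grid) {
  stopifnot(inherits(scene, "acoustic_scene"), inherits(grid, "imaging_grid"))
  co <- grid_coordinates(grid)
  xmin <- min(co$x); xmax <- max(co$x); ymin <- min(co$y); ymax <- max(co$y)
  for (rg in scene$regions) {
    r <- if (rg$shape == "circle") rg$radius else rg$r_out
    if (rg$center[1] - r < xmin - grid$spacing / 2 ||
        rg$center[1] + r > xmax + grid$spacing / 2 ||
        rg$center[2] - r < ymin - grid$spacing / 2 ||
        rg$center[2] + r > ymax + grid$spacing / 2)
      warning("region extends outside the grid; it is clipped")
  }
  v <- scene_at(scene, co$points)
  sos_map(matrix(v$speed, grid$shape[1], grid$shape[2]), grid,
          density = matrix(v$density, grid$shape[1], grid$shape[2]),
          background_speed = scene$background_speed)
}

#' Gaussian-modulated excitation pulse
#'
#' A Gaussian-enveloped sinusoid with the stated -6 dB fractional bandwidth,
#' sampled at \code{fs}. The waveform is causal: sample 1 is the pulse onset
#' (envelope truncated at 3.5 envelope standard deviations before the peak),
#' and \code{peak_offset} gives the envelope-peak time relative to onset in
#' microseconds. The mean is removed so the pulse carries no DC.
#'
#' @param f0 centre frequency (Hz).
#' @param fractional_bandwidth -6 dB fractional bandwidth.
#' @param fs sampling rate (Hz).
#' @param amplitude peak envelope amplitude (a.u.).
#' @return an object of class \code{pulse_model} with the sampled
#'   \code{waveform}.
#' @export
pulse_model <- function(f0, fractional_bandwidth = 0.9, fs,
                        amplitude = 1) {
  sigma_f <- fractional_bandwidth * f0 / (2 * sqrt(2 * log(2)))
  sigma_t <- 1 / (2 * pi * sigma_f) * 1e6        # us
  tc <- 3.5 * sigma_t
  t <- seq(0, 2 * tc, by = 1e6 / fs)             # us
  w <- amplitude * exp(-(t - tc)^2 / (2 * sigma_t^2)) *
    sin(2 * pi * f0 * 1e-6 * (t - tc))
  w <- w - mean(w)
  structure(list(center_frequency = f0,
                 fractional_bandwidth = fractional_bandwidth,
                 amplitude = amplitude, fs = fs,
                 waveform = w, peak_offset = tc, sigma_t = sigma_t),
            class = "pulse_model")
}

# Eikonal forward solution on a fine grid covering the whole ring:
# one travel-time map (matrix, us) per element, plus the fine grid.
forward_solution <- function(scene, geometry, spacing, order = 2, margin = 2,
                             elements = seq_len(geometry$n_elements)) {
  extent <- 2 * (geometry$ring_radius + margin)
  fine <- imaging_grid(extent = extent, spacing = spacing, center = c(0, 0))
  sos <- rasterize_scene(scene, fine)
  maps <- lapply(elements, function(e)
    solve_eikonal(sos, geometry$element_positions[e, ], order = order)$times)
  list(maps = maps, grid = fine, sos = sos, elements = elements)
}

#' Simulate transmission times of flight
#'
#' First-arrival (bent-ray) times for every transmitter-receiver pair, obtained
#' by running the fast-marching Eikonal solver on a fine rasterization of the
#' scene and sampling each element's travel-time field at the other elements'
#' positions. Optional additive Gaussian noise models picking jitter. The
#' forward grid should be at least twice as fine as any grid later used for
#' reconstruction, so that the inversion is not tested on its own
#' discretization.
#'
#' @param scene an \code{acoustic_scene}.
#' @param geometry a \code{ring_geometry}.
#' @param forward_grid_spacing fine-grid pixel size (mm).
#' @param noise_sd standard deviation of additive time noise (us).
#' @param seed optional RNG seed for reproducible noise.
#' @param order upwind order of the Eikonal solver.
#' @param forward optional precomputed result of the internal forward solve
#'   (shared with the reflection simulator).
#' @return a \code{tof_matrix}; the diagonal (tx == rx) is marked invalid.
#' @export
simulate_transmission_tofs <- function(scene, geometry,
                                       forward_grid_spacing = 0.2,
                                       noise_sd = 0.02, seed = NULL,
                                       order = 2, forward = NULL) {
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (is.null(forward))
    forward <- forward_solution(scene, geometry, forward_grid_spacing, order)
  ne <- geometry$n_elements
  times <- matrix(NA_real_, ne, ne)
  for (k in seq_along(forward$elements)) {
    e <- forward$elements[k]
    times[e, ] <- interp_grid(forward$maps[[k]], forward$grid,
                              geometry$element_positions)
  }
  if (!is.null(seed)) set.seed(seed)
  if (noise_sd > 0) times <- times + matrix(stats::rnorm(ne * ne, 0, noise_sd), ne, ne)
  valid <- matrix(TRUE, ne, ne); diag(valid) <- FALSE
  tof_matrix(times, valid, method = "synthetic")
}

# scatterers equally spaced along every region boundary, with
# impedance-contrast reflectivity of the local interface
boundary_scatterers <- function(scene, n_total, phase = 0) {
  if (length(scene$regions) == 0 || n_total == 0)
    return(list(points = matrix(numeric(0), 0, 2), reflectivity = numeric(0)))
  circles <- list()
  for (rg in scene$regions) {
    if (rg$shape == "circle")
      circles[[length(circles) + 1]] <- list(center = rg$center, r = rg$radius)
    else {
      circles[[length(circles) + 1]] <- list(center = rg$center, r = rg$r_out)
      if (rg$r_in > 0)
        circles[[length(circles) + 1]] <- list(center = rg$center, r = rg$r_in)
    }
  }
  per <- vapply(circles, function(cc) 2 * pi * cc$r, 0)
  counts <- pmax(1L, round(n_total * per / sum(per)))
  pts <- NULL; refl <- NULL
  eps <- 1e-4
  for (k in seq_along(circles)) {
    cc <- circles[[k]]
    ang <- 2 * pi * (seq_len(counts[k]) - 1) / counts[k] + phase
    u <- cbind(cos(ang), sin(ang))
    p <- sweep(cc$r * u, 2, cc$center, "+")
    a_in <- scene_at(scene, sweep((cc$r - eps) * u, 2, cc$center, "+"))
    a_out <- scene_at(scene, sweep((cc$r + eps) * u, 2, cc$center, "+"))
    z1 <- a_in$speed * a_in$density
    z2 <- a_out$speed * a_out$density
    pts <- rbind(pts, p)
    refl <- c(refl, abs(z2 - z1) / (z2 + z1))
  }
  keep <- refl > 0
  list(points = pts[keep, , drop = FALSE], reflectivity = refl[keep])
}

#' Simulate reflection channel data
#'
#' Synthesizes ring-array pulse-echo data: scatterers are placed uniformly
#' along every region boundary, and for each transmit event an echo is added
#' on each receiver, delayed by the bent-ray (Eikonal) transmit + receive
#' travel times, with amplitude proportional to the normal-incidence
#' impedance-contrast reflectivity |Z2-Z1|/(Z2+Z1), geometric spreading
#' 1/sqrt(r_tx r_rx), and the transmit/receive reception-cone apodization.
#'
#' @inheritParams simulate_transmission_tofs
#' @param n_boundary_scatterers total number of boundary scatterers.
#' @param noise_sd additive Gaussian noise on the samples (a.u.).
#' @param n_time number of time samples; default
#'   \code{ceiling(2.4 * 2R/c_min * fs)} so diametric echoes fit.
#' @param t0 recording start time (us).
#' @param include_direct also add the directly transmitted (through-target)
#'   arrival on every receiver, as acquired in a combined
#'   transmission-reflection sequence.
#' @param extra_scatterers optional list(points, reflectivity) of additional
#'   point scatterers.
#' @return a \code{channel_data} object with samples
#'   [events x receivers x time].
#' @export
simulate_reflection_channels <- function(scene, geometry,
                                         n_boundary_scatterers = 256,
                                         noise_sd = 0, seed = NULL,
                                         forward_grid_spacing = 0.2,
                                         n_time = NULL, t0 = 0,
                                         include_direct = FALSE,
                                         order = 2, forward = NULL,
                                         extra_scatterers = NULL) {
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  ne <- geometry$n_elements
  fs <- geometry$sampling_rate
  pulse <- pulse_model(geometry$center_frequency,
                       geometry$fractional_bandwidth, fs)
  v <- scene_at(scene, rbind(c(0, 0)))
  c_min <- min(scene$background_speed,
               vapply(scene$regions, `[[`, 0, "speed"), 1e9)
  if (length(scene$regions) == 0) c_min <- scene$background_speed
  if (is.null(n_time))
    n_time <- as.integer(ceiling(2.4 * (2 * geometry$ring_radius /
                                          (c_min / 1000)) * fs / 1e6))

  sc <- boundary_scatterers(scene, n_boundary_scatterers)
  if (!is.null(extra_scatterers)) {
    sc$points <- rbind(sc$points, extra_scatterers$points)
    sc$reflectivity <- c(sc$reflectivity, extra_scatterers$reflectivity)
  }
  nq <- nrow(sc$points)

  samples <- array(0, dim = c(ne, ne, n_time))
  need_forward <- (nq > 0 || include_direct) && length(scene$regions) > 0
  if (need_forward && is.null(forward))
    forward <- forward_solution(scene, geometry, forward_grid_spacing, order)

  if (nq > 0 || include_direct) {
    # one-way element -> scatterer travel times (us) and geometry factors
    if (nq > 0) {
      Tq <- matrix(0, nq, ne)
      D <- matrix(0, nq, ne)
      Wc <- matrix(0, nq, ne)
      for (e in seq_len(ne)) {
        D[, e] <- pmax(sqrt((sc$points[, 1] - geometry$element_positions[e, 1])^2 +
                            (sc$points[, 2] - geometry$element_positions[e, 2])^2), 0.5)
        Wc[, e] <- apodization_weight(e, sc$points, geometry)
        Tq[, e] <- if (need_forward)
          interp_grid(forward$maps[[e]], forward$grid, sc$points)
        else D[, e] / (scene$background_speed / 1000)
      }
    }
    if (include_direct) {
      Tdir <- if (need_forward) {
        td <- matrix(0, ne, ne)
        for (e in seq_len(ne))
          td[e, ] <- interp_grid(forward$maps[[e]], forward$grid,
                                 geometry$element_positions)
        td
      } else {
        dd <- as.matrix(stats::dist(geometry$element_positions))
        dd / (scene$background_speed / 1000)
      }
      Ddir <- pmax(as.matrix(stats::dist(geometry$element_positions)), 0.5)
    }
    for (a in seq_len(ne)) {
      if (nq > 0) {
        delay <- Tq[, a] + Tq                       # nq x ne
        amp <- (sc$reflectivity * Wc[, a] / sqrt(D[, a])) * Wc / sqrt(D)
      } else {
        delay <- matrix(numeric(0), 0, ne); amp <- delay
      }
      if (include_direct) {
        delay <- rbind(delay, Tdir[a, ])
        wdir <- rep(0, ne); wdir[-a] <- 1 / sqrt(Ddir[a, -a])
        amp <- rbind(amp, wdir)
      }
      if (nrow(delay) > 0)
        samples[a, , ] <- t(.synth_echoes_cpp(n_time, fs / 1e6, t0,
                                              delay, amp, pulse$waveform))
    }
  }
  if (noise_sd > 0)
    samples <- samples + array(stats::rnorm(length(samples), 0, noise_sd),
                               dim = dim(samples))
  channel_data(samples, geometry, t0 = t0, pulse = pulse)
}

#' Channel data container
#'
#' @param samples numeric array [n_events x n_receivers x n_time].
#' @param geometry the \code{ring_geometry} used for acquisition.
#' @param t0 recording start time (us).
#' @param pulse the \code{pulse_model} used for excitation.
#' @param events transmit element index per event (defaults to element order).
#' @export
channel_data <- function(samples, geometry, t0 = 0, pulse = NULL,
                         events = seq_len(dim(samples)[1])) {
  stopifnot(length(dim(samples)) == 3)
  structure(list(samples = samples, geometry = geometry, t0 = t0,
                 pulse = pulse, events = events),
            class = "channel_data")
}

#' @export
print.channel_data <- function(x, ...) {
  d <- dim(x$samples)
  cat(sprintf("Channel data: %d events x %d receivers x %d samples (t0 = %.2f us, fs = %.3f MHz)\n",
              d[1], d[2], d[3], x$t0, x$geometry$sampling_rate / 1e6))
  invisible(x)
}

#' Full-view acquisition sequence
#'
#' Runs the complete emission-reception cycle: every element transmits in
#' turn and all elements receive, yielding reflection channel data (with the
#' direct transmission arrivals included), the matrix of first-arrival times,
#' and the ground-truth speed map on the requested grid.
#'
#' @param scene an \code{acoustic_scene}.
#' @param geometry a \code{ring_geometry}.
#' @param config list of options: \code{grid} (truth-map grid, default the
#'   20 x 20 mm field of view at 0.1 mm), \code{n_scatterers},
#'   \code{noise_sd_tof} (us), \code{noise_sd_channel},
#'   \code{forward_grid_spacing} (mm), \code{n_time}, \code{seed},
#'   \code{include_direct}.
#' @return list with \code{channels}, \code{tofs} and \code{truth}.
#' @export
full_view_sequence <- function(scene, geometry, config = list()) {
  cfg <- utils::modifyList(list(
    grid = imaging_grid(extent = 20, spacing = 0.1),
    n_scatterers = 256, noise_sd_tof = 0.02, noise_sd_channel = 0,
    forward_grid_spacing = 0.2, n_time = NULL, seed = NULL,
    include_direct = TRUE, order = 2
  ), config)
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  forward <- if (length(scene$regions) > 0)
    forward_solution(scene, geometry, cfg$forward_grid_spacing, cfg$order)
  else NULL
  tofs <- simulate_transmission_tofs(scene, geometry,
                                     cfg$forward_grid_spacing,
                                     noise_sd = cfg$noise_sd_tof,
                                     order = cfg$order,
                                     forward = forward)
  channels <- simulate_reflection_channels(scene, geometry,
                                           n_boundary_scatterers = cfg$n_scatterers,
                                           noise_sd = cfg$noise_sd_channel,
                                           forward_grid_spacing = cfg$forward_grid_spacing,
                                           n_time = cfg$n_time,
                                           include_direct = cfg$include_direct,
                                           order = cfg$order,
                                           forward = forward)
  list(channels = channels, tofs = tofs,
       truth = rasterize_scene(scene, cfg$grid))
}

#' The high-contrast circular-target study scene
#'
#' An 18.00 mm diameter circle of steel-like material (5300 m/s) centred in
#' 1490 m/s coupling water — the dominant-refraction test case.
#' @param speed,density target properties.
#' @export
scene_steel_circle <- function(speed = 5300, density = 7850) {
  acoustic_scene(1490, 1000,
                 list(region_circle(c(0, 0), 9, speed, density)))
}

#' A multi-layer multi-target study scene
#'
#' A layered soft-tissue-like phantom: a 30 mm outer disc (1540 m/s) carrying
#' a higher-speed annulus (1580 m/s) and two 6 mm inclusions at 1460 and
#' 1600 m/s. The layer values are a configurable synthetic stand-in for a
#' layered phantom whose exact properties are not published.
#' @export
scene_multilayer <- function() {
  acoustic_scene(1490, 1000, list(
    region_circle(c(0, 0), 15, 1540, 1020),
    region_annulus(c(0, 0), 10, 12, 1580, 1060),
    region_circle(c(-4, -3), 3, 1460, 980),
    region_circle(c(4, 3), 3, 1600, 1080)
  ))
}

#' water-only scene helper
#' @rdname scene_steel_circle
#' @export
scene_water <- function() acoustic_scene(1490, 1000, list())
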