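#' Reception-cone apodization model
#'
#' Elements only sense a finite cone around their inward normal (about a 30
#' degree full reception angle for the modelled ring probe). The weight for a
#' pixel is a raised-cosine taper of the angle theta between the element's
#' normal and the element-to-pixel direction: \code{cos(pi/2 * theta/theta_half)^taper}
#' inside the cone and 0 outside. By the acoustic reciprocity of transmit and
#' receive sensitivity, the same cone is applied to both legs.
#'
#' @param reception_half_angle cone half-angle in degrees.
#' @param taper raised-cosine exponent.
#' @param min_weight floor applied inside the cone.
#' @export
apodization_model <- function(reception_half_angle = 15, taper = 1,
                              min_weight = 0) {
  structure(list(reception_half_angle = reception_half_angle,
                 taper = taper, min_weight = min_weight),
            class = "apodization_model")
}

#' Apodization weight of an element at pixels
#'
#' @param element element index.
#' @param points npix x 2 matrix of physical points (mm).
#' @param geometry a \code{ring_geometry}.
#' @param apod an \code{apodization_model}; default uses the geometry's
#'   reception half-angle.
#' @return weights in [0, 1].
#' @export
apodization_weight <- function(element, points, geometry, apod = NULL) {
  if (is.null(apod))
    apod <- apodization_model(geometry$reception_half_angle)
  points <- rbind(points)
  p <- geometry$element_positions[element, ]
  nv <- geometry$element_normals[element, ]
  dx <- points[, 1] - p[1]; dy <- points[, 2] - p[2]
  r <- sqrt(dx^2 + dy^2)
  cosang <- ifelse(r > 0, (dx * nv[1] + dy * nv[2]) / r, 1)
  theta <- acos(pmin(pmax(cosang, -1), 1))
  th <- apod$reception_half_angle * pi / 180
  w <- ifelse(theta <= th, cos(pi / 2 * theta / th)^apod$taper, 0)
  pmax(w, ifelse(theta <= th, apod$min_weight, 0))
}

#' Constant-speed delay maps
#'
#' One-way delay from every element to every pixel assuming a homogeneous
#' medium: |p_k - x_mn| / c.
#'
#' @param geometry a \code{ring_geometry}.
#' @param grid an \code{imaging_grid}.
#' @param c speed of sound (m/s).
#' @return npix x n_elements matrix of delays (us), pixels in column-major
#'   order.
#' @export
constant_delay <- function(geometry, grid, c) {
  if (c <= 0) stop("speed must be positive")
  pts <- grid_coordinates(grid)$points
  p <- geometry$element_positions
  d <- sqrt(outer(pts[, 1], p[, 1], "-")^2 + outer(pts[, 2], p[, 2], "-")^2)
  d / (c / 1000)
}

# analytic signal (FFT construction): x + i * Hilbert(x), column-wise
analytic_signal <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::mvfft(stats::mvfft(x) * h, inverse = TRUE) / n
}

#' Delay-and-sum beamforming with full-angle spatial compounding
#'
#' For every transmit event, the echoes of the K receive channels adjacent to
#' the transmitter are delayed by the two-way travel time to each pixel
#' (transmit leg + receive leg, linear interpolation in fast time on the
#' analytic signal), weighted by the transmit-cone x receive-cone apodization,
#' and accumulated over all events around the ring. The delay maps may come
#' from a constant speed (\code{\link{constant_delay}}) or from the Eikonal
#' solver through a heterogeneous speed map
#' (\code{\link{delay_maps_for_all_elements}}) — the delay source is the only
#' difference between the two modes. The envelope is the magnitude of the
#' compounded analytic sum (coherent compounding); with
#' \code{compounding = "incoherent"} each event is envelope-detected before
#' summation.
#'
#' @param channels a \code{channel_data}.
#' @param delays either an npix x n_elements matrix of one-way delays (us) or
#'   a list of \code{travel_time_map}s (one per element).
#' @param grid the imaging grid (required when \code{delays} is a matrix).
#' @param apod an \code{apodization_model}.
#' @param K number of adjacent receive channels centred on the transmitter.
#' @param compounding "coherent" or "incoherent".
#' @param dynamic_range display dynamic range in dB.
#' @param mode label stored in the result ("constant" or "adaptive").
#' @param peak_offset pulse envelope-peak delay compensated when sampling (us);
#'   defaults to the channel data's pulse model.
#' @return object of class \code{bf_image} with \code{rf_sum} (complex),
#'   \code{envelope} and \code{log_image} (dB, max 0).
#' @export
das <- function(channels, delays, grid = NULL, apod = NULL,
                K = NULL, compounding = c("coherent", "incoherent"),
                dynamic_range = 50, mode = NULL, peak_offset = NULL) {
  stopifnot(inherits(channels, "channel_data"))
  compounding <- match.arg(compounding)
  geom <- channels$geometry
  ne <- geom$n_elements
  if (is.null(K)) K <- max(2L, ne %/% 4L)
  if (K > ne) stop("K cannot exceed the number of elements")
  if (is.list(delays) && inherits(delays[[1]], "travel_time_map")) {
    if (is.null(grid)) grid <- delays[[1]]$grid
    if (is.null(mode)) mode <- "adaptive"
    delays <- vapply(delays, function(tt) as.vector(tt$times),
                     numeric(prod(grid$shape)))
  } else if (is.null(mode)) mode <- "constant"
  if (is.null(grid)) stop("grid is required with a plain delay matrix")
  npix <- prod(grid$shape)
  if (nrow(delays) != npix || ncol(delays) != ne)
    stop("delay maps do not cover the grid for every element")
  if (is.null(apod)) apod <- apodization_model(geom$reception_half_angle)
  if (is.null(peak_offset))
    peak_offset <- if (!is.null(channels$pulse)) channels$pulse$peak_offset else 0

  pts <- grid_coordinates(grid)$points
  apw <- vapply(seq_len(ne),
                function(e) apodization_weight(e, pts, geom, apod),
                numeric(npix))

  sam <- aperm(channels$samples, c(3, 2, 1))     # time x rx x ev
  an <- analytic_signal(matrix(sam, nrow = dim(sam)[1]))
  offs <- as.integer(seq.int(-(K %/% 2) + 1L, length.out = K))
  res <- .das_cpp(Re(an), Im(an), dim(sam), as.integer(channels$events),
                  delays, apw, offs, channels$t0, geom$sampling_rate / 1e6,
                  peak_offset, compounding == "incoherent")
  if (res$total > 0 && res$clipped / res$total > 0.10)
    warning(sprintf("%.1f%% of delay samples fall outside the recording",
                    100 * res$clipped / res$total))
  m <- grid$shape[1]; n <- grid$shape[2]
  rf <- matrix(complex(real = res$re, imaginary = res$im), m, n)
  env <- if (compounding == "incoherent") matrix(res$env, m, n) else Mod(rf)
  mx <- max(env)
  logim <- if (mx > 0) 20 * log10(pmax(env / mx, 10^(-dynamic_range / 20 - 2)))
           else matrix(-Inf, m, n)
  structure(list(rf_sum = rf, envelope = env, log_image = logim,
                 grid = grid, mode = mode, aperture_K = K,
                 dynamic_range = dynamic_range,
                 compounding = compounding),
            class = "bf_image")
}

#' @export
print.bf_image <- function(x, ...) {
  cat(sprintf("Beamformed image (%s, %s compounding, K = %d): %d x %d, peak envelope %.3g\n",
              x$mode, x$compounding, x$aperture_K,
              x$grid$shape[1], x$grid$shape[2], max(x$envelope)))
  invisible(x)
}

#' Plot a beamformed image (log-compressed)
#' @param x a \code{bf_image}.
#' @param main title.
#' @param ... passed to \code{image()}.
#' @export
plot.bf_image <- function(x, main = NULL, ...) {
  if (is.null(main)) main <- sprintf("%s DAS (dB)", x$mode)
  co <- grid_coordinates(x$grid)
  z <- pmax(x$log_image, -x$dynamic_range)
  graphics::image(co$x[1, ], co$y[, 1], t(z), asp = 1, col = grDevices::gray.colors(256),
                  xlab = "x (mm)", ylab = "y (mm)", main = main,
                  zlim = c(-x$dynamic_range, 0), useRaster = TRUE, ...)
  invisible(x)
}

#' Apparent diameter of a closed bright boundary
#'
#' Casts 360 radial profiles of the envelope from the detected centroid (or a
#' supplied centre); on each profile the boundary radius is the outermost
#' local envelope maximum above the threshold, and the apparent diameter is
#' twice the median boundary radius.
#'
#' @param image a \code{bf_image} (or an envelope matrix with \code{grid}).
#' @param center_hint optional centre (mm); default is the intensity-weighted
#'   centroid of the supra-threshold envelope.
#' @param threshold_db peak acceptance threshold relative to the image
#'   maximum (dB).
#' @param grid required when \code{image} is a plain matrix.
#' @param n_angles number of radial profiles.
#' @return list(diameter (mm), radii (per angle, mm), center, frac_detected,
#'   failed).
#' @export
measure_apparent_diameter <- function(image, center_hint = NULL,
                                      threshold_db = -12, grid = NULL,
                                      n_angles = 360) {
  if (inherits(image, "bf_image")) { env <- image$envelope; grid <- image$grid }
  else env <- image
  stopifnot(inherits(grid, "imaging_grid"))
  mx <- max(env)
  if (mx <= 0) return(list(diameter = NA_real_, radii = rep(NA_real_, n_angles),
                           center = c(NA, NA), frac_detected = 0, failed = TRUE))
  thr <- mx * 10^(threshold_db / 20)
  co <- grid_coordinates(grid)
  if (is.null(center_hint)) {
    w <- pmax(env - thr, 0)
    center_hint <- c(sum(w * co$x), sum(w * co$y)) / sum(w)
  }
  h <- grid$spacing
  rmax <- max(grid$extent) / 2
  rs <- seq(h, rmax, by = h / 2)
  ang <- 2 * pi * (seq_len(n_angles) - 1) / n_angles
  radii <- rep(NA_real_, n_angles)
  for (k in seq_len(n_angles)) {
    pts <- cbind(center_hint[1] + rs * cos(ang[k]),
                 center_hint[2] + rs * sin(ang[k]))
    inside <- pts[, 1] >= min(co$x) & pts[, 1] <= max(co$x) &
              pts[, 2] >= min(co$y) & pts[, 2] <= max(co$y)
    if (sum(inside) < 3) next
    prof <- interp_grid(env, grid, pts[inside, , drop = FALSE])
    rr <- rs[inside]
    np <- length(prof)
    is_peak <- prof >= thr &
      prof >= c(-Inf, prof[-np]) & prof >= c(prof[-1], -Inf)
    if (any(is_peak)) radii[k] <- rr[max(which(is_peak))]
  }
  frac <- mean(!is.na(radii))
  list(diameter = 2 * stats::median(radii, na.rm = TRUE),
       radii = radii, center = center_hint,
       frac_detected = frac, failed = frac < 0.75)
}
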