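#' Default pipeline configuration
#'
#' Builds the full configuration for \code{\link{run_pipeline}}; any field can
#' be overridden through \code{...} (nested lists are merged). A run is
#' reproducible from the configuration and seed alone.
#'
#' @param ... overrides, e.g. \code{geometry = list(n_elements = 64)}.
#' @return a nested list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(...) {
  base <- list(
    seed = 1L,
    geometry = list(n_elements = 128L, ring_radius = 40, f0 = 7.5e6,
                    fs = 31.25e6, fractional_bandwidth = 0.9,
                    reception_half_angle = 15),
    scene = list(background_speed = 1490, background_density = 1000,
                 regions = list()),
    sim = list(n_scatterers = 256L, noise_sd_tof = 0.02,
               noise_sd_channel = 0, forward_grid_spacing = 0.2,
               include_direct = TRUE),
    gate = list(c_min = 1400, c_max = 1700, pad = 1,
                crosstalk_exclude = 2),
    sart = list(lambda = 0.25, n_iter = 50, init_speed = 1490,
                bounds = c(1300, 6000), spacing = 0.4, tol = 1e-4),
    msfm = list(order = 2L),
    beamform = list(speeds = c(1490, 1540), K = NULL, dynamic_range = 50,
                    compounding = "coherent", grid_extent = 20,
                    grid_spacing = 0.1, adaptive = TRUE,
                    adaptive_truth = FALSE),
    metrics = list(true_diameter = NA_real_),
    output_dir = NULL
  )
  ov <- list(...)
  structure(merge_config(base, ov), class = "pipeline_config")
}

# recursive config merge: named lists merge element-wise, anything else —
# including unnamed lists such as scene$regions — replaces the default
# (utils::modifyList silently drops unnamed list elements)
merge_config <- function(base, ov) {
  for (nm in names(ov)) {
    if (is.list(ov[[nm]]) && is.list(base[[nm]]) &&
        length(ov[[nm]]) > 0 &&
        !is.null(names(ov[[nm]])) && all(names(ov[[nm]]) != ""))
      base[[nm]] <- merge_config(base[[nm]], ov[[nm]])
    else
      base[[nm]] <- ov[[nm]]
  }
  base
}

scene_from_config <- function(sc) {
  regs <- lapply(sc$regions, function(r) {
    if (identical(r$shape, "annulus"))
      region_annulus(unlist(r$center), r$r_in, r$r_out, r$speed, r$density)
    else region_circle(unlist(r$center), r$radius, r$speed, r$density)
  })
  acoustic_scene(sc$background_speed, sc$background_density, regs)
}

# resample a sos map onto another grid (bilinear)
resample_sos <- function(sos, grid) {
  pts <- grid_coordinates(grid)$points
  v <- interp_grid(sos$values, sos$grid, pts)
  sos_map(matrix(v, grid$shape[1], grid$shape[2]), grid,
          background_speed = sos$background_speed)
}

#' Run the full transmission-reflection pipeline
#'
#' Simulate (or load) ring-array channel data, pick first arrivals, reconstruct
#' the speed map by SART, compute per-element Eikonal delay maps through it,
#' and beamform both constant-speed and speed-adaptive reflection images, with
#' apparent-size metrics. All stages log their parameters; the same
#' configuration and seed reproduce the same bundle.
#'
#' @param config a \code{pipeline_config} (or a YAML file path, or a plain
#'   list of overrides).
#' @param channels optional pre-acquired \code{channel_data}; skips simulation
#'   (the scene is then only used for the optional truth map).
#' @param quiet suppress progress messages.
#' @return list with the stage outputs (\code{channels}, \code{tofs_picked},
#'   \code{sos}, \code{images}, \code{metrics}, \code{config}, \code{log}).
#' @export
run_pipeline <- function(config = pipeline_config(), channels = NULL,
                         quiet = FALSE) {
  if (is.character(config)) config <- pipeline_config_from_yaml(config)
  if (!inherits(config, "pipeline_config"))
    config <- do.call(pipeline_config, config)
  cfg <- config
  log <- character(0)
  say <- function(fmt, ...) {
    msg <- sprintf(paste0("[%s] ", fmt), format(Sys.time(), "%H:%M:%S"), ...)
    log <<- c(log, msg)
    if (!quiet) message(msg)
  }
  stage <- function(name, expr) {
    t0 <- proc.time()[3]
    out <- tryCatch(force(expr), error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    say("%s done in %.1f s", name, proc.time()[3] - t0)
    out
  }

  set.seed(cfg$seed)
  geom <- do.call(ring_geometry, cfg$geometry)
  scene <- scene_from_config(cfg$scene)
  fov <- imaging_grid(extent = cfg$beamform$grid_extent,
                      spacing = cfg$beamform$grid_spacing)
  say("pipeline start: %d elements, seed %d", geom$n_elements, cfg$seed)

  sim <- NULL
  if (is.null(channels)) {
    sim <- stage("simulate", full_view_sequence(scene, geom, c(
      cfg$sim, list(grid = fov, seed = cfg$seed, order = cfg$msfm$order))))
    channels <- sim$channels
  }
  truth <- if (!is.null(sim)) sim$truth else rasterize_scene(scene, fov)

  gate <- gate_config(cfg$gate$c_min, cfg$gate$c_max, cfg$gate$pad)
  tofs <- stage("pick", pick_all(channels, gate,
                                 crosstalk_exclude = cfg$gate$crosstalk_exclude))
  say("picked %d/%d valid first arrivals", sum(tofs$valid), length(tofs$valid))

  sart_grid <- imaging_grid(extent = 2 * geom$ring_radius + 2,
                            spacing = cfg$sart$spacing)
  system <- stage("rays", build_ray_system(tofs, geom, sart_grid))
  sos_coarse <- stage("sart", sart_reconstruct(
    system, init = cfg$sart$init_speed, lambda = cfg$sart$lambda,
    n_iter = cfg$sart$n_iter, bounds = cfg$sart$bounds, tol = cfg$sart$tol))
  say("SART: %d iterations, residual %.4g us", sos_coarse$iteration_count,
      utils::tail(sos_coarse$residual_history, 1))
  sos_coarse$background_speed <- scene$background_speed
  sos <- resample_sos(sos_coarse, fov)

  images <- list()
  for (c0 in cfg$beamform$speeds) {
    img <- stage(sprintf("beamform constant %.0f", c0),
                 das(channels, constant_delay(geom, fov, c0), grid = fov,
                     K = cfg$beamform$K,
                     compounding = cfg$beamform$compounding,
                     dynamic_range = cfg$beamform$dynamic_range,
                     mode = sprintf("constant-%.0f", c0)))
    images[[sprintf("constant_%.0f", c0)]] <- img
  }
  if (isTRUE(cfg$beamform$adaptive)) {
    dmaps <- stage("delay maps",
                   delay_maps_for_all_elements(sos, geom,
                                               order = cfg$msfm$order,
                                               pad_speed = scene$background_speed))
    images$adaptive <- stage("beamform adaptive",
                             das(channels, dmaps,
                                 K = cfg$beamform$K,
                                 compounding = cfg$beamform$compounding,
                                 dynamic_range = cfg$beamform$dynamic_range,
                                 mode = "adaptive"))
  }
  if (isTRUE(cfg$beamform$adaptive_truth)) {
    dmaps_t <- stage("delay maps (truth)",
                     delay_maps_for_all_elements(truth, geom,
                                                 order = cfg$msfm$order,
                                                 pad_speed = scene$background_speed))
    images$adaptive_truth <- stage("beamform adaptive (truth map)",
                                   das(channels, dmaps_t,
                                       K = cfg$beamform$K,
                                       compounding = cfg$beamform$compounding,
                                       dynamic_range = cfg$beamform$dynamic_range,
                                       mode = "adaptive-truth"))
  }

  met <- data.frame(image = names(images),
                    diameter_mm = NA_real_, cnr_db = NA_real_)
  for (k in seq_along(images)) {
    dm <- measure_apparent_diameter(images[[k]])
    met$diameter_mm[k] <- dm$diameter
    rg <- default_cnr_regions(images[[k]], dm)
    if (!is.null(rg)) {
      cv <- cnr(images[[k]], rg$target, rg$background)
      met$cnr_db[k] <- cv$cnr_db
    }
    say("%s: apparent diameter %.2f mm, CNR %.2f dB",
        names(images)[k], met$diameter_mm[k], met$cnr_db[k])
  }

  res <- list(channels = channels, tofs_picked = tofs, sos = sos,
              sos_coarse = sos_coarse, truth = truth, images = images,
              metrics = met, config = cfg, log = log)
  if (!is.null(cfg$output_dir)) write_bundle(res, cfg$output_dir)
  res
}

# annular target region on the detected boundary, square background patch in
# the upper-left corner
default_cnr_regions <- function(image, dm) {
  if (!is.finite(dm$diameter)) return(NULL)
  g <- image$grid
  co <- grid_coordinates(g)
  r <- sqrt((co$x - dm$center[1])^2 + (co$y - dm$center[2])^2)
  band <- 3 * g$spacing
  target <- r >= dm$diameter / 2 - band & r <= dm$diameter / 2 + band
  m <- g$shape[1]; n <- g$shape[2]
  k <- max(4L, round(m / 10))
  background <- matrix(FALSE, m, n)
  background[(m - k + 1):m, 1:k] <- TRUE      # upper-left in plot orientation
  background <- background & !target
  if (sum(target) < 2 || sum(background) < 2) return(NULL)
  list(target = target, background = background)
}

#' Constant-speed calibration sweep
#'
#' Beamforms the channel data at every candidate speed and measures the
#' apparent target size; when the true size is known the optimal speed is the
#' one minimizing the absolute size error.
#'
#' @param channels a \code{channel_data}.
#' @param grid imaging grid.
#' @param c_range c(lo, hi, step) in m/s (e.g. c(1420, 1620, 5)).
#' @param true_diameter optional true size (mm).
#' @param ... passed to \code{\link{das}}.
#' @return data.frame(speed, diameter_mm, peak) with attribute
#'   \code{optimal_speed} when \code{true_diameter} is given.
#' @export
speed_sweep <- function(channels, grid, c_range, true_diameter = NULL, ...) {
  if (!(c_range[1] < c_range[2] && c_range[3] > 0))
    stop("need lo < hi and step > 0")
  speeds <- seq(c_range[1], c_range[2], by = c_range[3])
  geom <- channels$geometry
  out <- data.frame(speed = speeds, diameter_mm = NA_real_, peak = NA_real_)
  for (k in seq_along(speeds)) {
    img <- das(channels, constant_delay(geom, grid, speeds[k]), grid = grid, ...)
    out$diameter_mm[k] <- measure_apparent_diameter(img)$diameter
    out$peak[k] <- max(img$envelope)
  }
  if (!is.null(true_diameter)) {
    err <- abs(out$diameter_mm - true_diameter)
    attr(out, "optimal_speed") <- out$speed[which.min(err)]
  }
  out
}

#' Read a pipeline configuration from YAML
#' @param path YAML file.
#' @return a \code{pipeline_config}.
#' @export
pipeline_config_from_yaml <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' Save / load a result bundle
#'
#' Writes the pipeline outputs to a directory: the serialized data container
#' (channel samples, picked times, speed maps, geometry metadata), a PNG of
#' every log-compressed image and of the speed map, the metrics CSV and the
#' run log. The container carries enough metadata (configuration echo, seed)
#' to re-run the pipeline.
#'
#' @param result value of \code{\link{run_pipeline}}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_bundle <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  saveRDS(list(samples = result$channels$samples,
               t0 = result$channels$t0,
               pulse = result$channels$pulse,
               geometry = result$channels$geometry,
               tof = result$tofs_picked$times,
               tof_valid = result$tofs_picked$valid,
               recon_sos = result$sos$values,
               truth_sos = result$truth$values,
               config = result$config),
          file.path(dir, "usct_data.rds"))
  for (nm in names(result$images)) {
    grDevices::png(file.path(dir, paste0(nm, ".png")), 640, 640)
    plot(result$images[[nm]])
    grDevices::dev.off()
  }
  grDevices::png(file.path(dir, "sos_map.png"), 640, 640)
  plot(result$sos)
  grDevices::dev.off()
  utils::write.csv(result$metrics, file.path(dir, "metrics.csv"),
                   row.names = FALSE)
  writeLines(result$log, file.path(dir, "run.log"))
  invisible(dir)
}

#' @rdname write_bundle
#' @param path the \code{usct_data.rds} file (or its directory).
#' @export
read_bundle <- function(path) {
  if (dir.exists(path)) path <- file.path(path, "usct_data.rds")
  b <- readRDS(path)
  b$channels <- channel_data(b$samples, b$geometry, t0 = b$t0, pulse = b$pulse)
  b
}
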