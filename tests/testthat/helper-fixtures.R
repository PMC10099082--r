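# Shared fixtures, computed lazily and cached for the whole test run.
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- force(expr)
  .fixtures[[name]]
}

# small ring used across unit tests (reduced frequency keeps traces short)
test_geometry <- function(n = 32L) ring_geometry(n, 40, 2.5e6, 12.5e6)

# water channels with a single point scatterer at (3, -2), no noise
fix_point_channels <- function() fixture("point_channels", {
  sc <- list(points = matrix(c(3, -2), 1, 2), reflectivity = 1)
  simulate_reflection_channels(scene_water(), test_geometry(64L),
                               n_boundary_scatterers = 0,
                               extra_scatterers = sc)
})

fix_fov <- function(spacing = 0.1) {
  imaging_grid(extent = 20, spacing = spacing)
}

# low-contrast (+/-5%) smooth phantom reconstructed by SART from noiseless
# bent-ray (Eikonal) first arrivals; shared by the SART and acceptance suites
fix_lowcontrast_sart <- function() fixture("lowcontrast_sart", {
  geom <- ring_geometry(128, 40, 7.5e6, 31.25e6)
  fine <- imaging_grid(extent = 84, spacing = 0.25)
  co <- grid_coordinates(fine)
  pert <- function(x, y) {
    0.05 * exp(-((x - 2)^2 + (y - 1)^2) / (2 * 3^2)) -
    0.05 * exp(-((x + 4)^2 + (y + 3)^2) / (2 * 2.5^2))
  }
  sosf <- sos_map(1490 * (1 + pert(co$x, co$y)), fine, background_speed = 1490)
  ne <- 128L
  times <- matrix(NA_real_, ne, ne)
  for (e in seq_len(ne)) {
    tt <- solve_eikonal(sosf, geom$element_positions[e, ])
    times[e, ] <- ringusct:::interp_grid(tt$times, fine,
                                         geom$element_positions)
  }
  valid <- matrix(TRUE, ne, ne)
  for (a in seq_len(ne)) for (k in seq_len(ne))
    if (min(abs(a - k), ne - abs(a - k)) <= 2) valid[a, k] <- FALSE
  tofs <- tof_matrix(times, valid, method = "synthetic")
  sgrid <- imaging_grid(extent = 82, spacing = 0.5)
  sys <- build_ray_system(tofs, geom, sgrid)
  rec <- sart_reconstruct(sys, init = 1490, lambda = 0.25, n_iter = 100,
                          tol = 0)
  co2 <- grid_coordinates(sgrid)
  truth <- 1490 * (1 + pert(co2$x, co2$y))
  sel <- sqrt(co2$x^2 + co2$y^2) <= 10
  list(rec = rec, truth = truth, sel = sel,
       rmse_rel = sqrt(mean((rec$values[sel] - truth[sel])^2)) / 1490)
})

# the scaled circular-target dataset (64 elements, 2.5 MHz) shared between
# the beamforming tests and the acceptance suite
fix_steel_pipeline <- function() fixture("steel_pipeline", {
  cfg <- pipeline_config(
    seed = 1L,
    geometry = list(n_elements = 64L, ring_radius = 40,
                    f0 = 2.5e6, fs = 12.5e6),
    scene = list(regions = list(list(shape = "circle", center = c(0, 0),
                                     radius = 9, speed = 5300,
                                     density = 7850))),
    sim = list(n_scatterers = 240L),
    beamform = list(adaptive = TRUE, adaptive_truth = TRUE),
    metrics = list(true_diameter = 18))
  run_pipeline(cfg, quiet = TRUE)
})
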