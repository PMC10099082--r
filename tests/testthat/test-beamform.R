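wavelength_mm <- 1.49 / 2.5                       # 1490 m/s at 2.5 MHz

test_that("constant delays reproduce distance over speed", {
  geom <- ring_geometry(128, 40, 7.5e6, 31.25e6)
  grid <- imaging_grid(spacing = 0.1, shape = c(201, 201), center = c(0, 0))
  idx0 <- point_to_grid_index(grid, rbind(c(0, 0)))
  k0 <- (idx0$j - 1) * grid$shape[1] + idx0$i     # column-major pixel index
  d1490 <- constant_delay(geom, grid, 1490)
  d1540 <- constant_delay(geom, grid, 1540)
  expect_equal(d1490[k0, 1], 40 / 1.49)           # = 26.846 us
  expect_equal(d1540[k0, 1], 40 / 1.54)           # = 25.974 us
  expect_error(constant_delay(geom, grid, 0), "positive")
})

test_that("Eikonal delays on a uniform map equal the constant-speed delays", {
  geom <- test_geometry(16L)
  grid <- imaging_grid(extent = 20, spacing = 0.2)
  sos <- sos_map(matrix(1490, grid$shape[1], grid$shape[2]), grid,
                 background_speed = 1490)
  maps <- delay_maps_for_all_elements(sos, geom)
  dc <- constant_delay(geom, grid, 1490)
  de <- vapply(maps, function(tt) as.vector(tt$times), numeric(nrow(dc)))
  expect_lt(max(abs(de - dc) / dc), 1e-6)
})

test_that("apodization is 1 on the normal, 0 at the cone edge and beyond", {
  geom <- test_geometry(16L)
  e <- 1L
  p <- geom$element_positions[e, ]                # (40, 0), normal (-1, 0)
  expect_equal(apodization_weight(e, rbind(c(0, 0)), geom), 1,
               ignore_attr = TRUE)
  th <- geom$reception_half_angle * pi / 180
  edge <- p + 10 * c(cos(pi + th), sin(pi + th)) # exactly on the cone edge
  expect_equal(apodization_weight(e, rbind(edge), geom), 0, tolerance = 1e-8,
               ignore_attr = TRUE)
  side <- p + 10 * c(0, 1)                        # 90 degrees off the normal
  expect_equal(apodization_weight(e, rbind(side), geom), 0, ignore_attr = TRUE)
  set.seed(2)
  pts <- cbind(runif(200, -20, 20), runif(200, -20, 20))
  w <- apodization_weight(e, pts, geom)
  expect_true(all(w >= 0 & w <= 1))
})

test_that("analytic signal has the original real part and a flat envelope", {
  set.seed(6)
  for (n in c(256L, 255L)) {                      # even and odd lengths
    x <- rnorm(n)
    a <- ringusct:::analytic_signal(x)
    expect_equal(Re(a[, 1]), x, tolerance = 1e-10)
  }
  t <- seq(0, 10, by = 0.01)
  a <- ringusct:::analytic_signal(cos(2 * pi * 2 * t))
  mid <- seq(100, 900)
  expect_lt(max(abs(Mod(a[mid, 1]) - 1)), 0.01)
})

test_that("silent channels beamform to an all-zero image", {
  geom <- test_geometry(16L)
  ch <- simulate_reflection_channels(scene_water(), geom,
                                     n_boundary_scatterers = 0,
                                     include_direct = FALSE)
  grid <- fix_fov(0.25)
  img <- das(ch, constant_delay(geom, grid, 1490), grid)
  expect_true(all(img$envelope == 0))
  expect_true(all(img$log_image == -Inf))
})

test_that("a point scatterer is localized to within one wavelength", {
  ch <- fix_point_channels()
  grid <- fix_fov()
  img <- das(ch, constant_delay(ch$geometry, grid, 1490), grid)
  le <- localization_error(img, c(3, -2))
  expect_false(le$flagged[1])
  expect_lt(le$errors[1], wavelength_mm)
})

test_that("the beamformer is linear in the channel data", {
  ch <- fix_point_channels()
  grid <- fix_fov(0.25)
  d <- constant_delay(ch$geometry, grid, 1490)
  b1 <- das(ch, d, grid)
  ch2 <- ch
  ch2$samples <- 2 * ch$samples
  b2 <- das(ch2, d, grid)
  expect_equal(b2$rf_sum, 2 * b1$rf_sum)
})

test_that("compounding does not depend on the order of transmit events", {
  ch <- fix_point_channels()
  grid <- fix_fov(0.25)
  d <- constant_delay(ch$geometry, grid, 1490)
  b1 <- das(ch, d, grid)
  set.seed(8)
  perm <- sample(length(ch$events))
  chp <- ch
  chp$events <- ch$events[perm]
  chp$samples <- ch$samples[perm, , , drop = FALSE]
  b2 <- das(chp, d, grid)
  expect_equal(b2$rf_sum, b1$rf_sum, tolerance = 1e-12)
})

test_that("a scatterer behind the steel circle only localizes with adaptive delays", {
  geom <- test_geometry(64L)
  scene <- scene_steel_circle()
  ch <- fixture("behind_disc_channels", simulate_reflection_channels(
    scene, geom, n_boundary_scatterers = 0,
    extra_scatterers = list(points = matrix(c(0, 0), 1, 2), reflectivity = 1),
    forward_grid_spacing = 0.2))
  grid <- fix_fov()
  img_c <- das(ch, constant_delay(geom, grid, 1490), grid)
  le_c <- localization_error(img_c, c(0, 0))
  # constant 1490 m/s ignores the 5300 m/s interior: the echo is mapped far
  # from the true position (a ring at roughly 9 - 9 * 1490/5300 mm radius)
  expect_gt(le_c$errors[1], 5)
  sos <- rasterize_scene(scene, grid)
  img_a <- das(ch, delay_maps_for_all_elements(sos, geom), mode = "adaptive")
  le_a <- localization_error(img_a, c(0, 0))
  expect_false(le_a$flagged[1])
  expect_lt(le_a$errors[1], wavelength_mm)
  expect_lt(le_a$errors[1], le_c$errors[1])
})

test_that("a grid of water scatterers localizes with sub-0.2 mm median error", {
  geom <- test_geometry(64L)
  pts <- as.matrix(expand.grid(x = c(-6, 0, 6), y = c(-6, 0, 6)))
  ch <- simulate_reflection_channels(
    scene_water(), geom, n_boundary_scatterers = 0,
    extra_scatterers = list(points = pts, reflectivity = rep(1, nrow(pts))))
  grid <- fix_fov()
  img <- das(ch, constant_delay(geom, grid, 1490), grid)
  le <- localization_error(img, pts, threshold_db = -30)
  expect_true(all(!le$flagged))
  expect_lt(median(le$errors), 0.2)
})

test_that("delays that fall mostly outside the recording trigger a warning", {
  geom <- test_geometry(16L)
  sc <- list(points = matrix(c(3, -2), 1, 2), reflectivity = 1)
  ch <- simulate_reflection_channels(scene_water(), geom,
                                     n_boundary_scatterers = 0,
                                     extra_scatterers = sc, n_time = 120L)
  grid <- fix_fov(0.25)
  expect_warning(das(ch, constant_delay(geom, grid, 1490), grid),
                 "outside the recording")
})

test_that("apparent diameter of a painted ring is recovered exactly", {
  grid <- fix_fov(0.1)
  co <- grid_coordinates(grid)
  r <- sqrt(co$x^2 + co$y^2)
  env <- exp(-(r - 9)^2 / (2 * 0.3^2))
  m <- measure_apparent_diameter(env, grid = grid)
  expect_false(m$failed)
  expect_equal(m$frac_detected, 1)
  expect_equal(m$diameter, 18, tolerance = 0.01)
  expect_equal(m$center, c(0, 0), tolerance = 1e-6)
  # blank image is flagged as failed
  expect_true(measure_apparent_diameter(0 * env, grid = grid)$failed)
})

test_that("incoherent compounding produces a valid envelope", {
  ch <- fix_point_channels()
  grid <- fix_fov(0.25)
  img <- das(ch, constant_delay(ch$geometry, grid, 1490), grid,
             compounding = "incoherent")
  expect_true(all(is.finite(img$envelope)) && all(img$envelope >= 0))
  le <- localization_error(img, c(3, -2))
  expect_lt(le$errors[1], wavelength_mm)
})
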