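# small helper: a consistent toy system on a 3x3 grid with full column rank
toy_system <- function() {
  fixture("toy_system", {
    grid <- imaging_grid(spacing = 2, shape = c(3, 3), center = c(0, 0))
    geom <- ring_geometry(8, 2.9, 2.5e6, 12.5e6)
    valid <- matrix(TRUE, 8, 8)
    for (a in 1:8) for (k in 1:8)
      if (min(abs(a - k), 8 - abs(a - k)) <= 1) valid[a, k] <- FALSE
    set.seed(7)
    s_true <- 1000 / (1490 + 60 * matrix(runif(9), 3, 3))
    sys0 <- build_ray_system(tof_matrix(matrix(1, 8, 8), valid,
                                        method = "synthetic"), geom, grid)
    t_true <- as.vector(sys0$W %*% as.vector(s_true))
    times <- matrix(NA_real_, 8, 8)
    times[cbind(sys0$tx, sys0$rx)] <- t_true
    sys <- build_ray_system(tof_matrix(times, valid, method = "synthetic"),
                            geom, grid)
    list(sys = sys, s_true = s_true, grid = grid)
  })
}

test_that("Siddon weights are exact pixel intersection lengths", {
  # horizontal ray through a row of five 1 mm pixels
  grid <- imaging_grid(spacing = 1, shape = c(5, 5), center = c(0, 0))
  tofs <- tof_matrix(matrix(c(NA, 1, 1, NA), 2, 2),
                     matrix(c(FALSE, TRUE, TRUE, FALSE), 2, 2),
                     method = "synthetic")
  geom <- list(n_elements = 2L,
               element_positions = rbind(c(-2.5, 0), c(2.5, 0)),
               ring_radius = 2.5)
  class(geom) <- "ring_geometry"
  sys <- build_ray_system(tofs, geom, grid)
  w <- as.matrix(sys$W)
  expect_equal(sort(w[1, w[1, ] > 0]), rep(1, 5))
  expect_equal(Matrix::rowSums(sys$W), rep(5, 2), ignore_attr = TRUE)

  # 45-degree ray through one pixel's diagonal
  grid1 <- imaging_grid(spacing = 1, shape = c(1, 1), center = c(0, 0))
  geom2 <- geom
  geom2$element_positions <- rbind(c(-0.5, -0.5), c(0.5, 0.5))
  sys2 <- build_ray_system(tofs, geom2, grid1)
  expect_equal(as.vector(sys2$W[1, ]), sqrt(2))
})

test_that("ray row sums equal chord lengths for random pairs", {
  geom <- test_geometry(32L)
  grid <- imaging_grid(extent = 82, spacing = 1)
  valid <- matrix(FALSE, 32, 32)
  set.seed(3)
  valid[cbind(sample(32, 40, TRUE), sample(32, 40, TRUE))] <- TRUE
  diag(valid) <- FALSE
  tofs <- tof_matrix(matrix(1, 32, 32), valid, method = "synthetic")
  sys <- build_ray_system(tofs, geom, grid)
  p <- geom$element_positions
  chord <- sqrt(rowSums((p[sys$tx, ] - p[sys$rx, ])^2))
  expect_lt(max(abs(Matrix::rowSums(sys$W) - chord)), 1e-6)
})

test_that("a grid that does not cover the chords is rejected", {
  geom <- test_geometry(16L)
  tofs <- tof_matrix(matrix(1, 16, 16), method = "synthetic")
  expect_error(build_ray_system(tofs, geom, imaging_grid(extent = 20, spacing = 1)),
               "cover")
})

test_that("SART leaves a consistent truth untouched (fixed point)", {
  ts <- toy_system()
  init <- sos_map(matrix(1000 / as.vector(ts$s_true), 3, 3), ts$grid)
  rec <- sart_reconstruct(ts$sys, init = init, n_iter = 3, tol = 0)
  expect_lt(max(abs(rec$values - init$values) / init$values), 1e-12)
  expect_lt(residual_norm(ts$sys, init), 1e-12)
})

test_that("SART converges to the dense least-squares solution on the toy system", {
  ts <- toy_system()
  # full column rank -> unique LS solution
  expect_equal(qr(as.matrix(ts$sys$W))$rank, 9L)
  x_ls <- as.vector(MASS::ginv(as.matrix(ts$sys$W)) %*% ts$sys$t)
  rec <- sart_reconstruct(ts$sys, init = 1490, lambda = 0.25,
                          n_iter = 400, tol = 0)
  x_sart <- as.vector(1000 / rec$values)
  expect_lt(sqrt(mean((x_sart - x_ls)^2)) / mean(x_ls), 1e-3)
  expect_lt(sqrt(mean((x_sart - as.vector(ts$s_true))^2)) / mean(ts$s_true), 1e-3)
})

test_that("residuals decrease monotonically on consistent systems", {
  ts <- toy_system()
  rec <- sart_reconstruct(ts$sys, init = 1490, lambda = 0.25,
                          n_iter = 40, tol = 0)
  expect_true(all(diff(rec$residual_history) <= 1e-12))
  expect_equal(rec$iteration_count, 40L)
})

test_that("SART validates its inputs and respects bounds", {
  ts <- toy_system()
  expect_error(sart_reconstruct(ts$sys, lambda = 0), "lambda")
  expect_error(sart_reconstruct(ts$sys, lambda = 1.5), "lambda")
  rec <- sart_reconstruct(ts$sys, bounds = c(1480, 1500), n_iter = 10)
  expect_true(all(rec$values >= 1480 - 1e-9 & rec$values <= 1500 + 1e-9))
  expect_error(residual_norm(ts$sys,
                             sos_map(matrix(1490, 4, 4),
                                     imaging_grid(spacing = 2, shape = c(4, 4)))),
               "shapes")
})

test_that("low-contrast smooth phantom is recovered to < 1% of background", {
  lc <- fix_lowcontrast_sart()
  expect_lt(lc$rmse_rel, 0.01)
  # the recovered field tracks the truth, not just its norm
  expect_gt(cor(as.vector(lc$rec$values[lc$sel]),
                as.vector(lc$truth[lc$sel])), 0.9)
})

test_that("high-contrast circle is recovered qualitatively (location, not value)", {
  geom <- test_geometry(64L)
  tofs <- simulate_transmission_tofs(scene_steel_circle(), geom,
                                     forward_grid_spacing = 0.25, noise_sd = 0)
  for (a in 1:64) for (k in 1:64)
    if (min(abs(a - k), 64 - abs(a - k)) <= 2) tofs$valid[a, k] <- FALSE
  sgrid <- imaging_grid(extent = 82, spacing = 0.5)
  rec <- sart_reconstruct(build_ray_system(tofs, geom, sgrid))
  co <- grid_coordinates(sgrid)
  r <- sqrt(co$x^2 + co$y^2)
  expect_gt(mean(rec$values[r <= 7]), mean(rec$values[r >= 12 & r <= 20]))
  w <- pmax(rec$values - 1490, 0) * (r <= 15)
  centroid <- c(sum(w * co$x), sum(w * co$y)) / sum(w)
  expect_lt(sqrt(sum(centroid^2)), 1)
})
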