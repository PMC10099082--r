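#' Build the straight-ray system for travel-time tomography
#'
#' For every valid pick, traces the straight ray between the transmit and
#' receive element positions through the reconstruction grid (Siddon
#' traversal) and stores the exact pixel-intersection lengths as a sparse
#' weight matrix. Row sums equal the transmitter-receiver chord lengths, so a
#' row dotted with the slowness vector (us/mm) is the modelled time of flight.
#' The grid must cover every chord; rays are grouped by transmit channel for
#' the SART update.
#'
#' @param tofs a \code{tof_matrix}.
#' @param geometry a \code{ring_geometry}.
#' @param grid reconstruction \code{imaging_grid}; must cover the ring chords.
#' @return object of class \code{ray_system} with fields \code{W} (sparse,
#'   rays x pixels, mm), \code{t} (us), \code{tx}, \code{rx}, \code{grid}.
#' @export
build_ray_system <- function(tofs, geometry, grid) {
  stopifnot(inherits(tofs, "tof_matrix"), inherits(geometry, "ring_geometry"),
            inherits(grid, "imaging_grid"))
  idx <- which(tofs$valid, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("no valid times of flight")
  p <- geometry$element_positions
  p0 <- p[idx[, 1], , drop = FALSE]
  p1 <- p[idx[, 2], , drop = FALSE]
  half <- grid$spacing / 2
  xr <- range(grid_coordinates(grid)$x) + c(-half, half)
  yr <- range(grid_coordinates(grid)$y) + c(-half, half)
  if (any(p0[, 1] < xr[1] | p0[, 1] > xr[2] | p0[, 2] < yr[1] | p0[, 2] > yr[2]) ||
      any(p1[, 1] < xr[1] | p1[, 1] > xr[2] | p1[, 2] < yr[1] | p1[, 2] > yr[2]))
    stop("reconstruction grid does not cover the ring chords")
  tr <- .siddon_rays_cpp(p0, p1, grid$origin[1], grid$origin[2],
                         grid$spacing, grid$shape[1], grid$shape[2])
  W <- Matrix::sparseMatrix(i = tr$ray, j = tr$pixel, x = tr$length,
                            dims = c(nrow(idx), prod(grid$shape)))
  structure(list(W = W, t = tofs$times[idx],
                 tx = idx[, 1], rx = idx[, 2], grid = grid),
            class = "ray_system")
}

#' @export
print.ray_system <- function(x, ...) {
  cat(sprintf("Ray system: %d rays x %d pixels (%.2f%% non-zero), %d transmit groups\n",
              nrow(x$W), ncol(x$W),
              100 * length(x$W@x) / prod(dim(x$W)), length(unique(x$tx))))
  invisible(x)
}

#' Simultaneous algebraic reconstruction of the speed map
#'
#' Iterative tomographic inversion of the picked times of flight. The internal
#' unknown is slowness (travel time is linear in slowness); results are
#' displayed as speed. One iteration is a full pass over the transmit groups
#' in element order: for group phi, each ray's correction is
#' \code{c_i = (t_i - sum_n w_in x_n) / sum_n w_in^2} and pixel j is updated by
#' \code{lambda * sum_{i in T_phi} c_i w_ij / sum_{i in T_phi} w_ij} — the
#' Andersen-Kak update. Values are clipped to physical speed bounds after every
#' sweep and the RMS time residual is recorded per iteration.
#'
#' @param system a \code{ray_system}.
#' @param init initial \code{sos_map}, or a single speed (m/s) used uniformly
#'   (default 1490, water).
#' @param lambda relaxation factor in (0, 1].
#' @param n_iter maximum number of full sweeps.
#' @param bounds c(c_lo, c_hi) physical speed bounds (m/s).
#' @param tol stop early when the relative residual change drops below this.
#' @param median_smooth apply a 3 x 3 median filter between sweeps (for noisy
#'   picks; default off).
#' @return a \code{sos_map} with \code{iteration_count} and
#'   \code{residual_history} (us).
#' @export
sart_reconstruct <- function(system, init = 1490, lambda = 0.25, n_iter = 50,
                             bounds = c(1300, 6000), tol = 1e-4,
                             median_smooth = FALSE) {
  stopifnot(inherits(system, "ray_system"))
  if (!(lambda > 0 && lambda <= 1)) stop("lambda must be in (0, 1]")
  if (nrow(system$W) == 0) stop("empty ray system")
  grid <- system$grid
  npix <- prod(grid$shape)
  x <- if (inherits(init, "sos_map")) {
    stopifnot(all(init$grid$shape == grid$shape))
    as.vector(1000 / init$values)
  } else rep(1000 / init, npix)                  # slowness, us/mm
  s_lo <- 1000 / bounds[2]; s_hi <- 1000 / bounds[1]

  W <- system$W
  rn2 <- Matrix::rowSums(W^2)
  groups <- split(seq_along(system$tx), system$tx)
  Wg <- lapply(groups, function(i) W[i, , drop = FALSE])
  colsum_g <- lapply(Wg, Matrix::colSums)
  t_g <- lapply(groups, function(i) system$t[i])
  rn2_g <- lapply(groups, function(i) rn2[i])

  resid_hist <- numeric(0)
  prev <- Inf
  it_done <- 0L
  for (it in seq_len(n_iter)) {
    for (g in seq_along(Wg)) {
      ci <- (t_g[[g]] - as.vector(Wg[[g]] %*% x)) / rn2_g[[g]]
      num <- as.vector(Matrix::crossprod(Wg[[g]], ci))
      den <- colsum_g[[g]]
      upd <- num / ifelse(den > 0, den, 1)
      upd[den == 0] <- 0
      x <- x + lambda * upd
      if (any(!is.finite(x))) stop("non-finite SART update (diverging system)")
      x <- pmin(pmax(x, s_lo), s_hi)
    }
    if (median_smooth)
      x <- as.vector(median_filter3(matrix(x, grid$shape[1], grid$shape[2])))
    r <- sqrt(mean((system$t - as.vector(W %*% x))^2))
    resid_hist <- c(resid_hist, r)
    it_done <- it
    if (is.finite(prev) && abs(prev - r) < tol * max(prev, .Machine$double.eps))
      break
    prev <- r
  }
  sos_map(matrix(1000 / x, grid$shape[1], grid$shape[2]), grid,
          iteration_count = it_done, residual_history = resid_hist)
}

# 3x3 median filter with edge replication
median_filter3 <- function(v) {
  m <- nrow(v); n <- ncol(v)
  vp <- v[c(1, 1:m, m), c(1, 1:n, n)]
  stack <- vapply(1:9, function(k) {
    di <- (k - 1) %% 3; dj <- (k - 1) %/% 3
    as.vector(vp[di + 1:m, dj + 1:n])
  }, numeric(m * n))
  matrix(apply(stack, 1, stats::median), m, n)
}

#' RMS time-of-flight residual of a speed map
#'
#' @param system a \code{ray_system}.
#' @param map a \code{sos_map} on the system's grid.
#' @return RMS of \code{t_i - sum_n w_in x_n} over rays (us).
#' @export
residual_norm <- function(system, map) {
  stopifnot(inherits(system, "ray_system"), inherits(map, "sos_map"))
  if (nrow(system$W) == 0) stop("empty ray system")
  if (!all(map$grid$shape == system$grid$shape)) stop("incompatible shapes")
  x <- as.vector(1000 / map$values)
  sqrt(mean((system$t - as.vector(system$W %*% x))^2))
}
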