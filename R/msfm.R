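#' Speed-of-sound map
#'
#' @param values m x n matrix of speeds (m/s).
#' @param grid the \code{imaging_grid} the values live on.
#' @param ... extra fields (e.g. \code{density}, \code{iteration_count},
#'   \code{residual_history}, \code{background_speed}).
#' @return object of class \code{sos_map}.
#' @export
sos_map <- function(values, grid, ...) {
  stopifnot(inherits(grid, "imaging_grid"),
            all(dim(values) == grid$shape))
  structure(c(list(values = values, grid = grid), list(...)),
            class = "sos_map")
}

#' @export
print.sos_map <- function(x, ...) {
  cat(sprintf("SoS map: %d x %d pixels, %.3f mm spacing, speeds %.0f-%.0f m/s\n",
              x$grid$shape[1], x$grid$shape[2], x$grid$spacing,
              min(x$values), max(x$values)))
  if (!is.null(x$iteration_count))
    cat(sprintf("  (%d SART iterations, final residual %.4g us)\n",
                x$iteration_count, utils::tail(x$residual_history, 1)))
  invisible(x)
}

#' Plot a speed-of-sound map
#' @param x a \code{sos_map}.
#' @param main plot title.
#' @param ... passed to \code{image()}.
#' @export
plot.sos_map <- function(x, main = "speed of sound (m/s)", ...) {
  co <- grid_coordinates(x$grid)
  graphics::image(co$x[1, ], co$y[, 1], t(x$values),
                  asp = 1, xlab = "x (mm)", ylab = "y (mm)",
                  main = main, useRaster = TRUE, ...)
  invisible(x)
}

# pad a sos map with a constant speed so its grid covers the requested box,
# keeping pixel alignment; returns the padded map and the crop offsets
extend_sos_map <- function(sos, xmin, xmax, ymin, ymax, pad_speed) {
  g <- sos$grid; h <- g$spacing
  m <- g$shape[1]; n <- g$shape[2]
  lo_x <- max(0L, as.integer(ceiling((g$origin[1] - xmin) / h)))
  lo_y <- max(0L, as.integer(ceiling((g$origin[2] - ymin) / h)))
  hi_x <- max(0L, as.integer(ceiling((xmax - (g$origin[1] + (n - 1) * h)) / h)))
  hi_y <- max(0L, as.integer(ceiling((ymax - (g$origin[2] + (m - 1) * h)) / h)))
  M <- m + lo_y + hi_y; N <- n + lo_x + hi_x
  vals <- matrix(pad_speed, M, N)
  vals[lo_y + seq_len(m), lo_x + seq_len(n)] <- sos$values
  grid2 <- imaging_grid(spacing = h, shape = c(M, N),
                        center = c(g$origin[1] + (lo_x * -1 + (N - 1) / 2) * h,
                                   g$origin[2] + (lo_y * -1 + (M - 1) / 2) * h))
  list(sos = sos_map(vals, grid2), oi = lo_y, oj = lo_x)
}

#' Solve the Eikonal equation through a heterogeneous speed map
#'
#' First-arrival travel times |grad T| = 1/c from a point source by
#' multi-stencils fast marching: the front is propagated along the grid axes
#' and along the diagonals (spacing h*sqrt(2)), keeping the causal minimum
#' over the two stencils, with second-order upwind differences where two
#' accepted upwind neighbours exist. The source may lie between grid nodes:
#' all nodes within \code{seed_radius} pixels of the source are initialized
#' with their exact straight-line times at the local speed and kept fixed —
#' the front curvature in the first few pixels is far too strong for the
#' upwind stencils, and seeding a small exact disc removes the dominant
#' near-source discretization error.
#'
#' @param sos a \code{sos_map} (speeds in m/s).
#' @param source 2-D physical point (mm); must be inside the grid bounding box.
#' @param order upwind accuracy, 1 or 2.
#' @param source_index optional element index stored in the result.
#' @param seed_radius minimum exact-initialization radius in pixels.
#' @param adaptive_seed grow the exact disc while the medium around the source
#'   is uniform: if the nearest pixel whose speed differs from the source
#'   speed lies d pixels away, straight-line times are provably first arrivals
#'   out to 0.6 d (any detour touching the heterogeneity travels at least
#'   2d - r > r pixels in the background medium), so the disc is extended to
#'   that radius. On a fully uniform map the whole solution is exact.
#' @return object of class \code{travel_time_map} with \code{times} in us.
#' @export
solve_eikonal <- function(sos, source, order = 2, source_index = NA_integer_,
                          seed_radius = 6, adaptive_seed = TRUE) {
  stopifnot(inherits(sos, "sos_map"))
  if (any(sos$values <= 0)) stop("speed map contains non-positive values")
  g <- sos$grid; h <- g$spacing
  m <- g$shape[1]; n <- g$shape[2]
  half <- h / 2
  if (source[1] < g$origin[1] - half || source[1] > g$origin[1] + (n - 1) * h + half ||
      source[2] < g$origin[2] - half || source[2] > g$origin[2] + (m - 1) * h + half)
    stop("source lies outside the grid bounding box")
  slow <- 1000 / sos$values                     # us/mm
  fj <- (source[1] - g$origin[1]) / h
  fi <- (source[2] - g$origin[2]) / h
  rad <- max(seed_radius, 1)
  if (adaptive_seed) {
    c0 <- sos$values[min(max(round(fi) + 1, 1), m), min(max(round(fj) + 1, 1), n)]
    het <- which(abs(sos$values - c0) > 1e-9 * c0)
    if (length(het) == 0L) {
      rad <- ceiling(sqrt(m * m + n * n)) + 1     # uniform map: seed everything
    } else {
      ii <- (het - 1L) %% m
      jj <- (het - 1L) %/% m
      d_het <- sqrt(min((ii - fi)^2 + (jj - fj)^2))
      rad <- max(rad, 0.6 * d_het)
    }
  }
  is <- max(0, floor(fi - rad)):min(m - 1, ceiling(fi + rad))
  js <- max(0, floor(fj - rad)):min(n - 1, ceiling(fj + rad))
  seeds <- expand.grid(i = is, j = js)
  dpx <- sqrt((seeds$i - fi)^2 + (seeds$j - fj)^2)
  keep <- dpx <= rad
  if (!any(keep)) keep <- dpx <= min(dpx) + 1.5  # source just outside: nearest nodes
  seeds <- seeds[keep, ]; dpx <- dpx[keep]
  t0 <- dpx * h * slow[cbind(seeds$i + 1, seeds$j + 1)]
  times <- .fm_solve_cpp(slow, h, as.integer(seeds$i + 1),
                         as.integer(seeds$j + 1), t0, as.integer(order))
  structure(list(times = times, source = source,
                 source_index = source_index, grid = g,
                 order = as.integer(order)),
            class = "travel_time_map")
}

#' @export
print.travel_time_map <- function(x, ...) {
  cat(sprintf("Travel-time map (order %d): %d x %d, source (%.2f, %.2f) mm, max %.2f us\n",
              x$order, x$grid$shape[1], x$grid$shape[2],
              x$source[1], x$source[2], max(x$times)))
  invisible(x)
}

#' Per-element delay maps through a speed map
#'
#' Computes one first-arrival travel-time map per transducer element. Element
#' positions generally lie outside the imaging field of view, so the solve
#' runs on an extended grid that covers the full ring (padded with a constant
#' background speed, by default the map's recorded background or its border
#' median) and the result is cropped back to the map's grid.
#'
#' @param sos a \code{sos_map} on the imaging grid.
#' @param geometry a \code{ring_geometry}.
#' @param order upwind order (1 or 2).
#' @param pad_speed speed (m/s) used outside the field of view.
#' @param margin extra padding beyond the ring radius (mm).
#' @param elements element indices to solve for (default all).
#' @return list of \code{travel_time_map}s on the \code{sos} grid.
#' @export
delay_maps_for_all_elements <- function(sos, geometry, order = 2,
                                        pad_speed = NULL, margin = 2,
                                        elements = seq_len(geometry$n_elements)) {
  stopifnot(inherits(sos, "sos_map"), inherits(geometry, "ring_geometry"))
  if (is.null(pad_speed)) {
    pad_speed <- sos$background_speed
    if (is.null(pad_speed)) {
      v <- sos$values
      pad_speed <- stats::median(c(v[1, ], v[nrow(v), ], v[, 1], v[, ncol(v)]))
    }
  }
  R <- geometry$ring_radius + margin
  ext <- extend_sos_map(sos, -R, R, -R, R, pad_speed)
  m <- sos$grid$shape[1]; n <- sos$grid$shape[2]
  lapply(elements, function(e) {
    tt <- solve_eikonal(ext$sos, geometry$element_positions[e, ],
                        order = order, source_index = e)
    tt$times <- tt$times[ext$oi + seq_len(m), ext$oj + seq_len(n)]
    tt$grid <- sos$grid
    tt
  })
}
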