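#' Ring-array transducer geometry
#'
#' Builds the description of a circular (ring) transducer array: element
#' positions on the circle, inward-pointing normals, pitch, and the pulse and
#' sampling parameters shared by the simulation, picking, tomography and
#' beamforming stages. Element 1 sits at angle 0 and elements are ordered
#' counter-clockwise; the ring centre is the coordinate origin. Lengths are in
#' mm, times in microseconds, speeds in m/s throughout the package.
#'
#' @param n_elements number of elements on the ring (>= 3).
#' @param ring_radius ring radius in mm.
#' @param f0 pulse centre frequency in Hz.
#' @param fs sampling rate in Hz.
#' @param fractional_bandwidth -6 dB fractional bandwidth of the pulse.
#' @param reception_half_angle half-angle of the element reception cone in
#'   degrees (the full reception angle of the modelled probe is about 30
#'   degrees, so the default half-angle is 15).
#' @param kerf element spacing in mm; metadata only in this 2-D point-element
#'   model.
#' @return an object of class \code{ring_geometry}.
#' @examples
#' g <- ring_geometry(128, 40, 7.5e6, 31.25e6)
#' round(g$pitch, 2)  # 1.96 mm
#' @export
ring_geometry <- function(n_elements, ring_radius, f0, fs,
                          fractional_bandwidth = 0.9,
                          reception_half_angle = 15,
                          kerf = 0.1) {
  if (!is.numeric(n_elements) || n_elements < 3 || n_elements != round(n_elements))
    stop("invalid geometry: n_elements must be an integer >= 3")
  if (!is.numeric(ring_radius) || ring_radius <= 0)
    stop("invalid geometry: ring_radius must be positive")
  n_elements <- as.integer(n_elements)
  ang <- 2 * pi * (seq_len(n_elements) - 1L) / n_elements
  pos <- cbind(x = ring_radius * cos(ang), y = ring_radius * sin(ang))
  structure(list(
    n_elements = n_elements,
    ring_radius = ring_radius,
    element_positions = pos,
    element_normals = -pos / ring_radius,
    pitch = 2 * pi * ring_radius / n_elements,
    center_frequency = f0,
    fractional_bandwidth = fractional_bandwidth,
    sampling_rate = fs,
    reception_half_angle = reception_half_angle,
    kerf = kerf
  ), class = "ring_geometry")
}

#' @export
print.ring_geometry <- function(x, ...) {
  cat(sprintf("Ring array: %d elements, radius %.2f mm, pitch %.3f mm\n",
              x$n_elements, x$ring_radius, x$pitch))
  cat(sprintf("Pulse: %.2f MHz (%.0f%% bandwidth), fs %.3f MHz, reception half-angle %.1f deg\n",
              x$center_frequency / 1e6, 100 * x$fractional_bandwidth,
              x$sampling_rate / 1e6, x$reception_half_angle))
  invisible(x)
}

#' Regular imaging grid
#'
#' A square-pixel grid centred on a given point (by default the ring centre).
#' Row index i maps to y and column index j to x; pixel (i, j) is centred at
#' \code{center + spacing * (j - (n+1)/2, i - (m+1)/2)}.
#'
#' @param extent side length(s) of the field of view in mm (scalar or
#'   c(height, width)); ignored when \code{shape} is given.
#' @param spacing pixel size in mm (isotropic).
#' @param center physical centre of the grid (mm).
#' @param shape optional integer c(m, n) overriding \code{extent}.
#' @return an object of class \code{imaging_grid}.
#' @examples
#' gr <- imaging_grid(extent = 20, spacing = 0.1)
#' gr$shape  # 200 x 200
#' @export
imaging_grid <- function(extent = 20, spacing = 0.1, center = c(0, 0),
                         shape = NULL) {
  if (spacing <= 0) stop("spacing must be positive")
  if (is.null(shape)) {
    extent <- rep_len(extent, 2)
    shape <- as.integer(round(extent / spacing))
  } else shape <- as.integer(rep_len(shape, 2))
  if (any(shape < 1)) stop("grid shape must be at least 1 x 1")
  m <- shape[1]; n <- shape[2]
  origin <- c(center[1] - spacing * (n - 1) / 2,
              center[2] - spacing * (m - 1) / 2)  # centre of pixel (1, 1)
  structure(list(origin = origin, spacing = spacing, shape = c(m, n),
                 center = center, extent = c(m, n) * spacing),
            class = "imaging_grid")
}

#' @export
print.imaging_grid <- function(x, ...) {
  cat(sprintf("Imaging grid: %d x %d pixels, %.3f mm spacing, extent %.1f x %.1f mm, centre (%.1f, %.1f)\n",
              x$shape[1], x$shape[2], x$spacing, x$extent[1], x$extent[2],
              x$center[1], x$center[2]))
  invisible(x)
}

#' Physical coordinates of all pixel centres
#'
#' @param grid an \code{imaging_grid}.
#' @return list with matrices \code{x} and \code{y} (shape m x n) and the
#'   flattened (column-major) coordinate matrix \code{points} (npix x 2, mm).
#' @export
grid_coordinates <- function(grid) {
  stopifnot(inherits(grid, "imaging_grid"))
  m <- grid$shape[1]; n <- grid$shape[2]
  xs <- grid$origin[1] + grid$spacing * (seq_len(n) - 1)
  ys <- grid$origin[2] + grid$spacing * (seq_len(m) - 1)
  x <- matrix(xs, m, n, byrow = TRUE)
  y <- matrix(ys, m, n)
  list(x = x, y = y, points = cbind(x = as.vector(x), y = as.vector(y)))
}

#' Map pixel indices to physical points
#' @param grid an \code{imaging_grid}.
#' @param i,j row and column indices (1-based, vectorised).
#' @return npix x 2 matrix of points (mm).
#' @export
grid_index_to_point <- function(grid, i, j) {
  cbind(x = grid$origin[1] + grid$spacing * (j - 1),
        y = grid$origin[2] + grid$spacing * (i - 1))
}

#' Map physical points to the nearest pixel indices
#' @param grid an \code{imaging_grid}.
#' @param points npix x 2 matrix (mm).
#' @return data.frame with columns i, j (1-based; may fall outside the grid).
#' @export
point_to_grid_index <- function(grid, points) {
  points <- rbind(points)
  data.frame(i = round((points[, 2] - grid$origin[2]) / grid$spacing) + 1,
             j = round((points[, 1] - grid$origin[1]) / grid$spacing) + 1)
}

# bilinear interpolation of a gridded field at arbitrary points; points
# outside the grid are clamped to the border
interp_grid <- function(values, grid, points) {
  points <- rbind(points)
  m <- grid$shape[1]; n <- grid$shape[2]
  fj <- (points[, 1] - grid$origin[1]) / grid$spacing
  fi <- (points[, 2] - grid$origin[2]) / grid$spacing
  fi <- pmin(pmax(fi, 0), m - 1)
  fj <- pmin(pmax(fj, 0), n - 1)
  i0 <- pmin(floor(fi), m - 2); j0 <- pmin(floor(fj), n - 2)
  if (m == 1) i0 <- rep(0, length(fi))
  if (n == 1) j0 <- rep(0, length(fj))
  di <- fi - i0; dj <- fj - j0
  v00 <- values[cbind(i0 + 1, j0 + 1)]
  v10 <- values[cbind(pmin(i0 + 2, m), j0 + 1)]
  v01 <- values[cbind(i0 + 1, pmin(j0 + 2, n))]
  v11 <- values[cbind(pmin(i0 + 2, m), pmin(j0 + 2, n))]
  v00 * (1 - di) * (1 - dj) + v10 * di * (1 - dj) +
    v01 * (1 - di) * dj + v11 * di * dj
}
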