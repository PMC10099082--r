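#' First-arrival time matrix
#'
#' @param times n_events x n_receivers matrix of times (us).
#' @param valid logical mask of usable picks.
#' @param method "picked" or "synthetic".
#' @export
tof_matrix <- function(times, valid = is.finite(times),
                       method = c("picked", "synthetic")) {
  method <- match.arg(method)
  stopifnot(all(dim(times) == dim(valid)))
  if (any(valid & (!is.finite(times) | times <= 0)))
    stop("valid picks must be positive and finite")
  structure(list(times = times, valid = valid, method = method),
            class = "tof_matrix")
}

#' @export
print.tof_matrix <- function(x, ...) {
  cat(sprintf("ToF matrix (%s): %d x %d, %d valid picks (%.1f%%)\n",
              x$method, nrow(x$times), ncol(x$times), sum(x$valid),
              100 * mean(x$valid)))
  invisible(x)
}

#' Gate configuration for first-arrival picking
#'
#' The pick for a transmitter-receiver pair is only searched within the time
#' window implied by the geometric distance and a plausible speed range.
#'
#' @param c_min,c_max slowest/fastest plausible medium speed (m/s).
#' @param pad extra time padding added on both sides (us).
#' @export
gate_config <- function(c_min = 1400, c_max = 1700, pad = 1) {
  if (!(c_min > 0 && c_max > c_min)) stop("need 0 < c_min < c_max")
  if (pad < 0) stop("pad must be non-negative")
  structure(list(c_min = c_min, c_max = c_max, pad = pad),
            class = "gate_config")
}

#' Geometric search gate for one transmitter-receiver pair
#'
#' @param geometry a \code{ring_geometry}.
#' @param tx,rx element indices.
#' @param gate a \code{gate_config}.
#' @return c(t_lo, t_hi) in us; both NA for a degenerate (zero-distance) pair.
#' @examples
#' g <- ring_geometry(128, 40, 7.5e6, 31.25e6)
#' geometric_gate(g, 1, 65, gate_config(1400, 1700, 1))
#' @export
geometric_gate <- function(geometry, tx, rx, gate = gate_config()) {
  p <- geometry$element_positions
  d <- sqrt(sum((p[tx, ] - p[rx, ])^2))
  if (d == 0) return(c(NA_real_, NA_real_))
  c(d / (gate$c_max / 1000) - gate$pad, d / (gate$c_min / 1000) + gate$pad)
}

# AIC of a variance changepoint at each split of x (characteristic function)
aic_curve <- function(x) {
  n <- length(x)
  cs <- cumsum(x); cs2 <- cumsum(x^2)
  k <- seq_len(n - 1)
  v1 <- pmax(cs2[k] / k - (cs[k] / k)^2, 0)
  v2 <- pmax((cs2[n] - cs2[k]) / (n - k) - ((cs[n] - cs[k]) / (n - k))^2, 0)
  eps <- .Machine$double.xmin
  k * log(v1 + eps) + (n - k) * log(v2 + eps)
}

#' Pick the first arrival on one trace
#'
#' Within the geometric gate, the pick is the Akaike-information-criterion
#' variance changepoint of the squared-amplitude characteristic function:
#' \code{argmin_k [k log var(x[1..k]) + (N-k) log var(x[k+1..N])]}. Two
#' standard robustness refinements are applied: the analysis window is
#' truncated a few samples after its strongest sample (the onset always
#' precedes the pulse peak, and a long quiet tail otherwise biases the
#' changepoint late), and changepoints within \code{margin} samples of either
#' window edge are excluded (a one-sample segment has zero variance, which
#' makes the edge AIC spuriously minimal on noisy traces). A pick is invalid
#' when the gate lies outside the recording, is degenerate, or the windowed
#' peak amplitude is below \code{noise_factor} times the median absolute
#' deviation of the pre-gate segment (noise floor).
#'
#' @param trace numeric vector of samples.
#' @param gate c(t_lo, t_hi) in us.
#' @param fs sampling rate (Hz).
#' @param t0 time of the first sample (us).
#' @param noise_factor validity threshold relative to the pre-gate MAD.
#' @param margin samples excluded at both window edges.
#' @return list(time = us or NA, valid = logical).
#' @export
pick_first_arrival <- function(trace, gate, fs, t0 = 0, noise_factor = 5,
                               margin = 4L) {
  invalid <- list(time = NA_real_, valid = FALSE)
  if (anyNA(gate)) return(invalid)
  n <- length(trace)
  i_lo <- max(1L, as.integer(floor((gate[1] - t0) * fs / 1e6)) + 1L)
  i_hi <- min(n, as.integer(ceiling((gate[2] - t0) * fs / 1e6)) + 1L)
  if (i_hi - i_lo < 4L) return(invalid)
  w <- trace[i_lo:i_hi]
  pre <- trace[seq_len(max(i_lo - 1L, 0L))]
  floor_level <- if (length(pre) >= 8) noise_factor * stats::mad(pre) else 0
  if (max(abs(w)) <= max(floor_level, .Machine$double.eps)) return(invalid)
  ip <- which.max(abs(w))
  w <- w[seq_len(min(length(w), ip + margin))]
  if (length(w) < 2L * margin + 2L) return(invalid)
  a <- aic_curve(w^2)
  ks <- seq.int(margin, length(a) - margin + 1L)
  k <- ks[which.min(a[ks])]
  list(time = t0 + (i_lo + k - 1) * 1e6 / fs, valid = TRUE)
}

#' Pick first arrivals for all transmitter-receiver pairs
#'
#' Applies \code{\link{pick_first_arrival}} per (event, receiver) with per-pair
#' geometric gates. Pairs closer than \code{crosstalk_exclude} positions on the
#' ring are marked invalid (transmit cross-talk; such rays also carry no
#' tomographic information through the centre).
#'
#' @param channels a \code{channel_data}.
#' @param gate a \code{gate_config}.
#' @param crosstalk_exclude exclude pairs with ring distance <= this value.
#' @param noise_factor see \code{\link{pick_first_arrival}}.
#' @return a \code{tof_matrix}.
#' @export
pick_all <- function(channels, gate = gate_config(), crosstalk_exclude = 2,
                     noise_factor = 5) {
  stopifnot(inherits(channels, "channel_data"))
  geom <- channels$geometry
  ne <- geom$n_elements
  n_ev <- dim(channels$samples)[1]
  times <- matrix(NA_real_, n_ev, ne)
  valid <- matrix(FALSE, n_ev, ne)
  fs <- geom$sampling_rate
  for (a in seq_len(n_ev)) {
    tx <- channels$events[a]
    for (k in seq_len(ne)) {
      ring_d <- min(abs(tx - k), ne - abs(tx - k))
      if (ring_d <= crosstalk_exclude) next
      g <- geometric_gate(geom, tx, k, gate)
      p <- pick_first_arrival(channels$samples[a, k, ], g, fs,
                              t0 = channels$t0, noise_factor = noise_factor)
      times[a, k] <- p$time
      valid[a, k] <- p$valid
    }
  }
  tof_matrix(times, valid, method = "picked")
}
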