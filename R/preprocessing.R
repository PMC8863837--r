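#' Hip joint centers from the inter-ASIS distance
#'
#' Locates the right and left hip joint centers from the distance between
#' the anterior superior iliac spine markers using the standard regression
#' coefficients: RHJC = (0.36 d, -0.19 d, -0.30 d) and
#' LHJC = (-0.36 d, -0.19 d, -0.30 d), in the marker coordinate units of d.
#'
#' @param asis_distance inter-ASIS distance, >= 0, marker units.
#' @return List with numeric 3-vectors `rhjc` and `lhjc`.
#' @examples
#' hip_joint_centers(100)  # rhjc = (36, -19, -30)
#' @export
hip_joint_centers <- function(asis_distance) {
  if (length(asis_distance) != 1L || !is.finite(asis_distance))
    stop("asis_distance: must be a single finite value")
  if (asis_distance < 0)
    stop("asis_distance: must be >= 0")
  d <- as.numeric(asis_distance)
  list(rhjc = c(0.36 * d, -0.19 * d, -0.30 * d),
       lhjc = c(-0.36 * d, -0.19 * d, -0.30 * d))
}

#' Detect the stance phase in a vertical ground reaction force series
#'
#' Stance begins at the first sample where the vertical GRF exceeds the
#' threshold (default 10 N, the conventional contact criterion) and ends at
#' the first subsequent sample where it falls back to or below the
#' threshold. The same threshold is used for toe-off as for contact, since a
#' literal return to zero is not realizable on noisy force-plate data. If
#' the force never drops back below threshold, stance extends to the end of
#' the series.
#'
#' @param force numeric vector of vertical GRF samples (newtons).
#' @param threshold contact threshold in newtons (default 10).
#' @return List with 1-based half-open sample interval `start`, `end`
#'   (stance samples are `start, ..., end - 1`), or `NULL` if no sample
#'   exceeds the threshold.
#' @examples
#' detect_stance(c(0, 5, 12, 300, 200, 8, 0))  # start 3, end 6
#' @export
detect_stance <- function(force, threshold = 10) {
  if (length(force) == 0L) stop("force: empty series")
  if (!all(is.finite(force))) stop("force: non-finite values")
  above <- force > threshold
  if (!any(above)) return(NULL)
  start <- which(above)[1L]
  after <- which(!above & seq_along(force) > start)
  end <- if (length(after)) after[1L] else length(force) + 1L
  list(start = start, end = end)
}

# Direct-form-II-transposed IIR filter with explicit initial state.
iir_filter <- function(b, a, x, zi) {
  n <- max(length(a), length(b))
  b <- c(b, rep(0, n - length(b))) / a[1]
  a <- c(a, rep(0, n - length(a))) / a[1]
  z <- c(zi, 0)
  y <- numeric(length(x))
  for (i in seq_along(x)) {
    yi <- b[1] * x[i] + z[1]
    for (k in seq_len(n - 1))
      z[k] <- b[k + 1] * x[i] + z[k + 1] - a[k + 1] * yi
    y[i] <- yi
  }
  y
}

# Steady-state filter state for a unit-step input: with zi * x[1] as the
# initial state, a constant series passes through unchanged, removing the
# startup transient.
iir_steady_state <- function(b, a) {
  b <- b / a[1]; a <- a / a[1]
  n <- max(length(a), length(b))
  a <- c(a, rep(0, n - length(a)))
  b <- c(b, rep(0, n - length(b)))
  comp <- rbind(-a[-1], cbind(diag(n - 2), 0))
  B <- b[-1] - a[-1] * b[1]
  solve(diag(n - 1) - t(comp), B)
}

#' Zero-phase low-pass Butterworth filter
#'
#' Forward-backward application of a Butterworth low-pass filter, the
#' standard zero-phase-lag smoothing for biomechanical signals. The default
#' applies a second-order filter in each direction, giving a net
#' fourth-order response with no phase distortion; `order` is the per-pass
#' order and may be raised to 4 for a net eighth-order response. Edges are
#' handled by odd (point-reflected) padding of at least three times the
#' filter length before filtering.
#'
#' @param x numeric series.
#' @param cutoff low-pass cutoff frequency, Hz (e.g. 10 for joint angles,
#'   20 for joint moments).
#' @param rate sampling rate, Hz; `cutoff` must be below the Nyquist
#'   frequency `rate/2`.
#' @param order per-pass Butterworth order (default 2; net order is twice
#'   this).
#' @return Filtered series, same length as `x`.
#' @export
lowpass_filter <- function(x, cutoff, rate, order = 2L) {
  if (!is.numeric(x) || !all(is.finite(x))) stop("x: non-finite values")
  if (cutoff <= 0 || rate <= 0) stop("cutoff and rate must be > 0")
  if (cutoff >= rate / 2) stop("cutoff: must be below the Nyquist frequency")
  n <- length(x)
  padlen <- min(n - 1L, max(12L, 3L * (3L * order + 1L)))
  if (padlen < 1L) stop("x: series too short to filter")
  bf <- signal::butter(order, cutoff / (rate / 2), type = "low")
  b <- as.numeric(bf$b); a <- as.numeric(bf$a)
  zi <- iir_steady_state(b, a)
  # odd reflection about the end samples keeps the padded signal continuous
  # in value and slope; steady-state initialization removes the startup
  # transient of each pass
  pre <- 2 * x[1L] - x[seq.int(padlen + 1L, 2L)]
  post <- 2 * x[n] - x[seq.int(n - 1L, n - padlen)]
  xp <- c(pre, x, post)
  y <- iir_filter(b, a, xp, zi * xp[1L])
  y <- rev(y)
  y <- rev(iir_filter(b, a, y, zi * y[1L]))
  y[seq.int(padlen + 1L, padlen + n)]
}

#' Time-normalize a series to a fixed number of stance points
#'
#' Resamples a series onto `n_out` equally spaced points spanning its full
#' extent, preserving both endpoints. Cubic (natural spline) interpolation
#' is the default since gait waveforms are smooth; linear interpolation is
#' available.
#'
#' @param x numeric series of length >= 2.
#' @param n_out number of output points (default 100).
#' @param method `"cubic"` (default) or `"linear"`.
#' @return Numeric series of length `n_out`.
#' @export
time_normalize <- function(x, n_out = 100L, method = c("cubic", "linear")) {
  method <- match.arg(method)
  n <- length(x)
  if (n < 2L) stop("x: need at least 2 samples")
  if (n_out < 2L) stop("n_out: must be >= 2")
  t_in <- seq(0, 1, length.out = n)
  t_out <- seq(0, 1, length.out = n_out)
  if (method == "linear")
    stats::approx(t_in, x, xout = t_out)$y
  else
    stats::spline(t_in, x, xout = t_out, method = "natural")$y
}
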