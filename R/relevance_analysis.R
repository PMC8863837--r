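smooth_121 <- function(x) {
  n <- length(x)
  if (n == 1L) return(x)
  out <- numeric(n)
  out[1L] <- (0.5 * x[1L] + 0.25 * x[2L]) / 0.75
  out[n] <- (0.25 * x[n - 1L] + 0.5 * x[n]) / 0.75
  if (n > 2L) {
    i <- 2:(n - 1L)
    out[i] <- 0.25 * x[i - 1L] + 0.5 * x[i] + 0.25 * x[i + 1L]
  }
  out
}

#' Aggregate per-sample relevance into a processed contribution map
#'
#' Turns raw signed per-sample relevance vectors into one interpretable
#' score per (trajectory, timepoint), in five steps applied in order:
#' \enumerate{
#'   \item normalize each sample's relevance vector to its own maximum
#'     absolute value, so every sample contributes on a comparable scale;
#'   \item average across samples;
#'   \item rectify (absolute value);
#'   \item smooth along the timepoint axis within each trajectory with the
#'     kernel (0.25, 0.5, 0.25) — present point weighted 50%, neighbours
#'     25% — repeated `passes` times (default 3, approximating a Gaussian);
#'     at trajectory endpoints the in-range kernel weights are renormalized
#'     so no relevance leaks across trajectory boundaries;
#'   \item rescale the result to the unit interval, 0 = no relevance,
#'     1 = the highest.
#' }
#'
#' @param relevance samples x features matrix of raw relevance (e.g.
#'   `batch_relevance()$relevance`).
#' @param columns the column registry of the feature matrix the relevance
#'   refers to (`feature_matrix$columns`).
#' @param passes number of smoothing passes (default 3).
#' @param rectify_before_average rectify each sample before averaging
#'   instead of rectifying the average (default FALSE).
#' @return An object of class `"relevance_map"`: data.frame with columns
#'   `name`, `joint`, `plane`, `modality`, `timepoint`, `trajectory`,
#'   `score` (in [0, 1]); processing provenance in attributes.
#' @export
aggregate_relevance <- function(relevance, columns, passes = 3L,
                                rectify_before_average = FALSE) {
  if (is.vector(relevance)) relevance <- matrix(relevance, nrow = 1L)
  if (nrow(relevance) == 0L) stop("relevance: no samples")
  if (ncol(relevance) != nrow(columns))
    stop("relevance columns do not match the column registry")
  maxabs <- apply(abs(relevance), 1, max)
  if (all(maxabs == 0)) stop("all-zero relevance; rescaling undefined")
  maxabs[maxabs == 0] <- 1
  normed <- relevance / maxabs
  if (rectify_before_average) normed <- abs(normed)
  avg <- colMeans(normed)
  avg <- abs(avg)
  for (tr in unique(columns$trajectory)) {
    idx <- which(columns$trajectory == tr)
    idx <- idx[order(columns$timepoint[idx])]
    s <- avg[idx]
    for (p in seq_len(passes)) s <- smooth_121(s)
    avg[idx] <- s
  }
  lo <- min(avg); hi <- max(avg)
  score <- if (hi > lo) (avg - lo) / (hi - lo) else rep(0, length(avg))
  out <- cbind(columns, score = as.numeric(score))
  class(out) <- c("relevance_map", "data.frame")
  attr(out, "provenance") <- list(
    n_samples = nrow(relevance), passes = passes,
    rectify_before_average = rectify_before_average,
    rescale_bounds = c(lo, hi))
  out
}

#' Top-k most relevant variables
#'
#' The k (trajectory, timepoint) variables with the highest processed
#' relevance scores, in descending order; ties are broken by canonical
#' feature order (the registry order), making the selection deterministic.
#'
#' @param map a `relevance_map`.
#' @param k number of variables (default 200).
#' @return The map rows of the selected variables, ranked; attribute
#'   `min_score` records the lowest score in the set.
#' @export
top_k <- function(map, k = 200L) {
  if (!inherits(map, "relevance_map")) stop("map: not a relevance_map")
  if (k > nrow(map)) stop("k (", k, ") exceeds number of variables (",
                          nrow(map), ")")
  ord <- order(-map$score, seq_len(nrow(map)))[seq_len(k)]
  out <- map[ord, , drop = FALSE]
  rownames(out) <- NULL
  out <- as.data.frame(out)
  attr(out, "min_score") <- min(out$score)
  out
}

#' Contribution percentages by joint, plane, trajectory and stance window
#'
#' Sums the processed relevance map within each group of a partition and
#' expresses it as a percentage of the total, for four partitions: joints,
#' planes, the 18 individual trajectories, and stance-phase windows.
#' Timepoints are indexed 0-99 internally and reported as 1%-100% of
#' stance; the default windows contrast early (1-47%) with late (48-100%)
#' stance.
#'
#' @param map a `relevance_map`.
#' @param windows named list of inclusive percent ranges `c(from, to)`
#'   that must partition 1-100%.
#' @return List of data.frames `joint`, `plane`, `trajectory`, `window`,
#'   each with a `percent` column summing to 100.
#' @export
contributions <- function(map,
                          windows = list(early = c(1, 47),
                                         late = c(48, 100))) {
  if (!inherits(map, "relevance_map")) stop("map: not a relevance_map")
  pct_max <- max(map$timepoint) + 1L
  covered <- integer(0)
  for (w in windows) {
    if (length(w) != 2L || w[1] > w[2])
      stop("windows: each must be an inclusive c(from, to) percent range")
    covered <- c(covered, seq.int(w[1], w[2]))
  }
  if (length(covered) != pct_max || anyDuplicated(covered) ||
      !setequal(covered, seq_len(pct_max)))
    stop("windows must partition 1-", pct_max, "% of stance")
  total <- sum(map$score)
  if (total == 0) stop("all-zero map; contributions undefined")
  tab <- function(key) {
    s <- tapply(map$score, key, sum)
    data.frame(group = names(s), percent = 100 * as.numeric(s) / total,
               stringsAsFactors = FALSE)
  }
  pct <- map$timepoint + 1L
  wkey <- rep(NA_character_, nrow(map))
  for (nm in names(windows))
    wkey[pct >= windows[[nm]][1] & pct <= windows[[nm]][2]] <- nm
  win <- tab(factor(wkey, levels = names(windows)))
  list(joint = tab(factor(map$joint, levels = JOINTS)),
       plane = tab(factor(map$plane, levels = PLANES)),
       trajectory = tab(factor(map$trajectory,
                               levels = unique(map$trajectory))),
       window = win)
}
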