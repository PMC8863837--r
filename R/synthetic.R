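#' Specify a class-discriminative effect for the cohort simulator
#'
#' An effect is a mean offset added to one trajectory of every positive-class
#' (higher-mileage) trial, confined to a half-open window of stance
#' timepoints. Effects are the simulator's ground truth: a relevance method
#' applied to a cohort built with one effect should concentrate its map
#' inside that window.
#'
#' @param trajectory trajectory name, e.g. `"knee_transverse_angle"`
#'   (see [trajectory_names()]).
#' @param window half-open integer interval `c(from, to)` of 0-based
#'   timepoints, `0 <= from < to <= n_timepoints`; the effect covers
#'   timepoints `from, ..., to - 1`.
#' @param amplitude peak offset in waveform units; must be finite.
#' @param shape `"boxcar"` (constant inside the window) or
#'   `"raised_cosine"` (smooth bump, zero at the window edges, peak
#'   `amplitude` at its centre).
#' @return An object of class `"gait_effect"`.
#' @export
gait_effect <- function(trajectory, window, amplitude,
                        shape = c("boxcar", "raised_cosine")) {
  parse_trajectory(trajectory)
  shape <- match.arg(shape)
  if (length(window) != 2L || !all(is.finite(window)))
    stop("window: must be a finite length-2 vector")
  window <- as.integer(window)
  if (window[1] < 0L || window[2] <= window[1])
    stop("window: need 0 <= from < to")
  if (!is.finite(amplitude))
    stop("amplitude: must be finite")
  structure(list(trajectory = trajectory, window = window,
                 amplitude = amplitude, shape = shape),
            class = "gait_effect")
}

effect_curve <- function(effect, n_timepoints) {
  if (effect$window[2] > n_timepoints)
    stop("window: exceeds n_timepoints")
  curve <- numeric(n_timepoints)
  idx <- seq.int(effect$window[1] + 1L, effect$window[2])
  if (effect$shape == "boxcar") {
    curve[idx] <- effect$amplitude
  } else {
    u <- (seq_along(idx) - 0.5) / length(idx)   # (0,1) across the window
    curve[idx] <- effect$amplitude * 0.5 * (1 - cos(2 * pi * u))
  }
  curve
}

#' Specify a synthetic two-class gait cohort
#'
#' Describes the hierarchical structure of a simulated cohort: two classes
#' of subjects (positive = higher-mileage), several trials per subject, and
#' per trial the 18 stance-phase trajectories (3 joints x 3 planes x
#' angle/moment), each time-normalized to `n_timepoints` points. The defaults
#' mirror the study design the simulator emulates: 40 subjects per class,
#' 10 trials each, 100 stance points.
#'
#' Each trajectory is built as a fixed smooth class-independent template plus
#' a subject-level random smooth offset curve (shared across that subject's
#' trials, marginal sd `subject_sd`), plus trial-level smooth noise (marginal
#' sd `trial_sd`), plus the class effects for positive-class trials. Noise
#' curves are Gaussian processes realized by convolving white noise with a
#' raised-cosine kernel of half-width `noise_smoothness` timepoints.
#'
#' @param n_subjects_per_class subjects in each class (default 40).
#' @param n_trials trials per subject (default 10).
#' @param n_timepoints stance points per trajectory (default 100).
#' @param subject_sd sd of the between-subject offset curves, waveform units.
#' @param trial_sd sd of the within-subject (trial) noise, waveform units.
#' @param noise_smoothness correlation half-width of the noise kernel,
#'   in timepoints.
#' @param effects list of [gait_effect()] objects (possibly empty).
#' @param seed integer; fully determines the generated dataset.
#' @return An object of class `"cohort_spec"`.
#' @seealso [generate_cohort()]
#' @export
cohort_spec <- function(n_subjects_per_class = 40L, n_trials = 10L,
                        n_timepoints = 100L, subject_sd = 0.5,
                        trial_sd = 0.25, noise_smoothness = 10L,
                        effects = list(), seed = 1L) {
  chk_count <- function(x, nm) {
    if (length(x) != 1L || !is.finite(x) || x < 1 || x != round(x))
      stop(nm, ": must be a single integer >= 1")
    as.integer(x)
  }
  chk_sd <- function(x, nm) {
    if (length(x) != 1L || !is.finite(x) || x < 0)
      stop(nm, ": must be a single finite value >= 0")
    as.numeric(x)
  }
  if (!is.list(effects) || (length(effects) &&
      !all(vapply(effects, inherits, TRUE, "gait_effect"))))
    stop("effects: must be a list of gait_effect objects")
  if (length(seed) != 1L || !is.finite(seed) || seed != round(seed))
    stop("seed: must be a single integer")
  spec <- structure(list(
    n_subjects_per_class = chk_count(n_subjects_per_class,
                                     "n_subjects_per_class"),
    n_trials = chk_count(n_trials, "n_trials"),
    n_timepoints = chk_count(n_timepoints, "n_timepoints"),
    subject_sd = chk_sd(subject_sd, "subject_sd"),
    trial_sd = chk_sd(trial_sd, "trial_sd"),
    noise_smoothness = chk_count(noise_smoothness, "noise_smoothness"),
    effects = effects,
    seed = as.integer(seed)), class = "cohort_spec")
  for (e in effects) effect_curve(e, spec$n_timepoints)  # window fits
  spec
}

# Fixed deterministic template per trajectory: a low-order mixture of
# periodic basis functions over the stance phase, loosely shaped like
# published stance-phase angle/moment curves (unimodal or bimodal smooth
# arcs). Coefficients depend only on the trajectory's canonical index, not
# on the RNG, so templates are identical across cohorts.
trajectory_template <- function(name, n_timepoints) {
  k <- match(name, trajectory_names())
  if (is.na(k)) stop("unknown trajectory: ", name)
  t <- (seq_len(n_timepoints) - 0.5) / n_timepoints   # (0,1)
  a1 <- cos(0.7 * k); a2 <- 0.6 * sin(1.3 * k); a3 <- 0.3 * cos(2.1 * k + 1)
  ph <- 0.4 * k
  a1 * sin(pi * t + ph) + a2 * sin(2 * pi * t + 0.5 * ph) +
    a3 * (1 - cos(2 * pi * t)) / 2
}

# Smooth unit-variance noise curve: white Gaussian noise convolved with a
# raised-cosine kernel of half-width L, kernel normalized to unit l2 norm so
# the marginal variance of the output equals that of the input.
smooth_noise <- function(n, L) {
  if (L <= 1L) return(stats::rnorm(n))
  tk <- seq.int(-L, L)
  kern <- 0.5 * (1 + cos(pi * tk / L))
  kern <- kern / sqrt(sum(kern^2))
  w <- stats::rnorm(n + 2L * L)
  as.numeric(stats::convolve(w, rev(kern), type = "filter"))
}

#' Generate a synthetic two-class gait cohort
#'
#' Simulates the full hierarchy described by a [cohort_spec()]: for every
#' subject a class label and one random smooth offset curve per trajectory
#' (shared by all that subject's trials), and for every trial the 18
#' trajectories = template + subject offset + smooth trial noise
#' (+ class effects inside their windows, positive class only).
#' The same spec (including its seed) always yields a bit-identical dataset.
#'
#' @param spec a [cohort_spec()].
#' @return An object of class `"gait_dataset"`: a list with
#' \describe{
#'   \item{values}{numeric array `trials x 18 trajectories x timepoints`}
#'   \item{trials}{data.frame `subject_id`, `trial_id`, `label` per row of
#'     `values` (label `"high"` = positive / higher-mileage, `"low"` =
#'     negative)}
#'   \item{subjects}{data.frame `subject_id`, `label`}
#'   \item{trajectories}{the 18 trajectory names, canonical order}
#'   \item{spec}{the generating spec (provenance)}
#' }
#' @examples
#' ds <- generate_cohort(cohort_spec(n_subjects_per_class = 2, n_trials = 3,
#'                                   seed = 7))
#' dim(ds$values)  # 12 trials x 18 trajectories x 100 points
#' @export
generate_cohort <- function(spec) {
  if (!inherits(spec, "cohort_spec")) stop("spec: must be a cohort_spec")
  trajs <- trajectory_names()
  nt <- spec$n_timepoints
  n_subj <- 2L * spec$n_subjects_per_class
  n_rows <- n_subj * spec$n_trials

  subjects <- data.frame(
    subject_id = sprintf("S%03d", seq_len(n_subj)),
    label = rep(c("high", "low"), each = spec$n_subjects_per_class),
    stringsAsFactors = FALSE)

  templates <- vapply(trajs, trajectory_template, numeric(nt),
                      n_timepoints = nt)                # nt x 18
  eff <- matrix(0, nt, length(trajs), dimnames = list(NULL, trajs))
  for (e in spec$effects)
    eff[, e$trajectory] <- eff[, e$trajectory] + effect_curve(e, nt)

  values <- array(NA_real_, dim = c(n_rows, length(trajs), nt),
                  dimnames = list(NULL, trajs, NULL))
  trials <- data.frame(subject_id = rep(subjects$subject_id,
                                        each = spec$n_trials),
                       trial_id = rep(seq_len(spec$n_trials), n_subj),
                       label = rep(subjects$label, each = spec$n_trials),
                       stringsAsFactors = FALSE)

  with_seed(spec$seed, {
    row <- 0L
    for (s in seq_len(n_subj)) {
      subj_off <- matrix(0, nt, length(trajs))
      if (spec$subject_sd > 0)
        for (j in seq_along(trajs))
          subj_off[, j] <- spec$subject_sd *
            smooth_noise(nt, spec$noise_smoothness)
      positive <- subjects$label[s] == "high"
      for (tr in seq_len(spec$n_trials)) {
        row <- row + 1L
        for (j in seq_along(trajs)) {
          curve <- templates[, j] + subj_off[, j]
          if (spec$trial_sd > 0)
            curve <- curve + spec$trial_sd *
              smooth_noise(nt, spec$noise_smoothness)
          if (positive) curve <- curve + eff[, j]
          values[row, j, ] <- curve
        }
      }
    }
  })

  structure(list(values = values, trials = trials, subjects = subjects,
                 trajectories = trajs, spec = spec),
            class = "gait_dataset")
}

#' @export
print.gait_dataset <- function(x, ...) {
  cat("gait_dataset:", nrow(x$trials), "trials,",
      nrow(x$subjects), "subjects (",
      sum(x$subjects$label == "high"), "high /",
      sum(x$subjects$label == "low"), "low ),",
      length(x$trajectories), "trajectories x",
      dim(x$values)[3], "timepoints\n")
  invisible(x)
}

#' Write a cohort to disk as a trial table with a metadata sidecar
#'
#' Writes `trials.csv` (the delimited-text trial table of the combined
#' feature matrix, see [write_trial_table()]) and `cohort.json`, a
#' structured record of the generating [cohort_spec()] including the
#' ground-truth effect windows — so a simulated cohort on disk always
#' carries its own provenance.
#'
#' @param dataset a `gait_dataset` with a synthetic provenance spec.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(dataset, dir) {
  if (!inherits(dataset, "gait_dataset")) stop("dataset: not a gait_dataset")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_trial_table(assemble(dataset, "combined"),
                    file.path(dir, "trials.csv"))
  spec <- dataset$spec
  meta <- list(
    n_subjects_per_class = spec$n_subjects_per_class,
    n_trials = spec$n_trials,
    n_timepoints = spec$n_timepoints,
    subject_sd = spec$subject_sd,
    trial_sd = spec$trial_sd,
    noise_smoothness = spec$noise_smoothness,
    seed = spec$seed,
    effects = lapply(spec$effects, function(e)
      list(trajectory = e$trajectory, window = e$window,
           amplitude = e$amplitude, shape = e$shape)))
  jsonlite::write_json(meta, file.path(dir, "cohort.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' @rdname write_cohort
#' @param dir directory written by `write_cohort`.
#' @return `read_cohort_metadata` returns the metadata list with effects
#'   restored as [gait_effect()] objects.
#' @export
read_cohort_metadata <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "cohort.json"),
                              simplifyVector = TRUE)
  effs <- meta$effects
  meta$effects <- lapply(seq_len(NROW(effs)), function(i)
    gait_effect(effs$trajectory[i], unlist(effs$window[i]),
                effs$amplitude[i], effs$shape[i]))
  meta
}

#' Per-timepoint class mean difference of one trajectory
#'
#' Positive-class (higher-mileage) mean minus negative-class mean at every
#' timepoint, averaging over all trials of each class. Serves as the
#' ground-truth oracle when testing whether relevance maps recover injected
#' discriminative windows.
#'
#' @param dataset a `gait_dataset` containing both classes.
#' @param trajectory trajectory name.
#' @return Numeric vector of length `n_timepoints`.
#' @export
class_mean_difference <- function(dataset, trajectory) {
  if (!inherits(dataset, "gait_dataset")) stop("dataset: not a gait_dataset")
  j <- match(trajectory, dataset$trajectories)
  if (is.na(j)) stop("unknown trajectory: ", trajectory)
  pos <- dataset$trials$label == "high"
  if (!any(pos) || all(pos))
    stop("dataset must contain trials of both classes")
  apply(dataset$values[pos, j, , drop = FALSE], 3, mean) -
    apply(dataset$values[!pos, j, , drop = FALSE], 3, mean)
}
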