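#' Assemble a flat feature matrix from a gait dataset
#'
#' Flattens a hierarchical `gait_dataset` into a trials-by-features numeric
#' matrix. With the default cohort (80 subjects x 10 trials, 100 stance
#' points) the kinematics and kinetics scopes each give an 800 x 900 matrix
#' (3 joints x 3 planes x 100 points) and the combined scope an 800 x 1800
#' matrix with the kinematics block first. Rows are ordered by (subject,
#' trial); columns follow the frozen canonical order joint (ankle, knee,
#' hip) x plane (sagittal, frontal, transverse) x timepoint, and are named
#' `<joint>_<plane>_<modality>_t<NN>` with NN = 00..99.
#'
#' @param dataset a `gait_dataset` (see [generate_cohort()]).
#' @param scope `"kinematics"` (joint angles), `"kinetics"` (joint moments)
#'   or `"combined"`.
#' @return An object of class `"feature_matrix"`: list with `values`
#'   (numeric matrix), `rows` (data.frame `subject_id`, `trial_id`,
#'   `label`), `columns` (data.frame `name`, `joint`, `plane`, `modality`,
#'   `timepoint` with 0-based timepoints), and `scope`.
#' @export
assemble <- function(dataset,
                     scope = c("kinematics", "kinetics", "combined")) {
  if (!inherits(dataset, "gait_dataset")) stop("dataset: not a gait_dataset")
  scope <- match.arg(scope)
  mods <- switch(scope, kinematics = "angle", kinetics = "moment",
                 combined = c("angle", "moment"))
  trajs <- trajectory_names()
  trajs <- trajs[parse_trajectory(trajs)$modality %in% mods]
  missing <- setdiff(trajs, dataset$trajectories)
  if (length(missing))
    stop("dataset lacks trajectories: ", paste(missing, collapse = ", "))
  if (anyNA(dataset$values))
    stop("trial with missing trajectory values: row ",
         which(apply(is.na(dataset$values), 1, any))[1L])

  nt <- dim(dataset$values)[3]
  ord <- order(dataset$trials$subject_id, dataset$trials$trial_id)
  rows <- dataset$trials[ord, , drop = FALSE]
  rownames(rows) <- NULL

  blocks <- lapply(trajs, function(tr)
    dataset$values[ord, match(tr, dataset$trajectories), , drop = FALSE][, 1, ,
                                                                drop = TRUE])
  values <- do.call(cbind, lapply(blocks, function(b)
    matrix(b, nrow = nrow(rows), ncol = nt)))

  cols <- do.call(rbind, lapply(trajs, function(tr) {
    info <- parse_trajectory(tr)
    data.frame(name = sprintf("%s_t%02d", tr, seq_len(nt) - 1L),
               joint = info$joint, plane = info$plane,
               modality = info$modality, timepoint = seq_len(nt) - 1L,
               trajectory = tr, stringsAsFactors = FALSE)
  }))
  colnames(values) <- cols$name
  structure(list(values = values, rows = rows, columns = cols,
                 scope = scope), class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat("feature_matrix (", x$scope, "): ", nrow(x$values), " trials x ",
      ncol(x$values), " features\n", sep = "")
  invisible(x)
}

subset_rows <- function(fm, idx) {
  out <- fm
  out$values <- fm$values[idx, , drop = FALSE]
  out$rows <- fm$rows[idx, , drop = FALSE]
  rownames(out$rows) <- NULL
  out
}

#' Subject-grouped, class-stratified train/test split
#'
#' Randomly assigns whole subjects (all their trials together) to the
#' training or the test side, keeping the classes balanced. The split ratio
#' is 32 train : 8 test subjects per class at the reference cohort size of
#' 40 per class, i.e. 80% of each class's subjects train; smaller cohorts
#' must be divisible so the same ratio gives whole subjects. With the
#' reference cohort this yields 640 training and 160 test rows. Grouping by
#' subject prevents leakage of within-subject correlation across the split.
#'
#' @param matrix a `feature_matrix`.
#' @param seed integer seed determining the subject assignment.
#' @param train_frac fraction of each class's subjects assigned to training
#'   (default 0.8 = 32/40).
#' @return List with `train` and `test` feature matrices and `plan`
#'   (data.frame `subject_id`, `label`, `role`, plus the seed as an
#'   attribute).
#' @export
split_matrix <- function(matrix, seed, train_frac = 0.8) {
  if (!inherits(matrix, "feature_matrix")) stop("matrix: not a feature_matrix")
  subj <- unique(matrix$rows[, c("subject_id", "label")])
  plan <- NULL
  for (cl in sort(unique(subj$label))) {
    ids <- sort(subj$subject_id[subj$label == cl])
    n_train <- train_frac * length(ids)
    if (abs(n_train - round(n_train)) > 1e-9 || round(n_train) < 1 ||
        round(n_train) >= length(ids))
      stop("cannot split ", length(ids), " subjects of class '", cl,
           "' at train fraction ", train_frac,
           ": need a whole number of train and >= 1 test subjects")
    n_train <- as.integer(round(n_train))
    picked <- with_seed(seed + match(cl, sort(unique(subj$label))),
                        sample(ids, n_train))
    plan <- rbind(plan, data.frame(
      subject_id = ids, label = cl,
      role = ifelse(ids %in% picked, "train", "test"),
      stringsAsFactors = FALSE))
  }
  attr(plan, "seed") <- as.integer(seed)
  train_ids <- plan$subject_id[plan$role == "train"]
  list(train = subset_rows(matrix, matrix$rows$subject_id %in% train_ids),
       test = subset_rows(matrix, !matrix$rows$subject_id %in% train_ids),
       plan = plan)
}

#' Per-feature standardization fitted on the training matrix
#'
#' Centers and scales every feature to zero mean and unit variance using
#' statistics of the training matrix only, then applies the same affine map
#' to any further matrices (e.g. the test set). Standardization keeps the
#' tanh units of the downstream network out of saturation on raw
#' degree/moment scales; it can be skipped by not calling this function.
#' Zero-variance features are left at unit scale with a warning.
#'
#' @param train a `feature_matrix` to fit on.
#' @param ... further `feature_matrix` objects to transform with the
#'   training statistics.
#' @return List with `train`, the transformed extra matrices (in order,
#'   named as passed), and `scaling` (list of `center` and `scale`
#'   vectors).
#' @export
standardize <- function(train, ...) {
  if (!inherits(train, "feature_matrix")) stop("train: not a feature_matrix")
  if (nrow(train$values) == 0L) stop("train: empty matrix")
  center <- colMeans(train$values)
  scale <- apply(train$values, 2, stats::sd)
  zero <- !is.finite(scale) | scale == 0
  if (any(zero)) {
    warning(sum(zero), " zero-variance feature(s) left at unit scale")
    scale[zero] <- 1
  }
  tf <- function(fm) {
    fm$values <- sweep(sweep(fm$values, 2, center), 2, scale, "/")
    fm
  }
  extras <- lapply(list(...), function(fm) {
    if (!inherits(fm, "feature_matrix")) stop("...: not a feature_matrix")
    tf(fm)
  })
  c(list(train = tf(train)), extras,
    list(scaling = list(center = center, scale = scale)))
}

#' Invert a standardization
#'
#' @param matrix a standardized `feature_matrix`.
#' @param scaling the `scaling` record returned by [standardize()].
#' @return The feature matrix on its original scale.
#' @export
unstandardize <- function(matrix, scaling) {
  matrix$values <- sweep(sweep(matrix$values, 2, scaling$scale, "*"),
                         2, scaling$center, "+")
  matrix
}

#' Write / read the delimited-text trial table
#'
#' The interchange format is a plain CSV with one row per trial: columns
#' `subject_id`, `trial_id`, `label`, then the features in canonical order
#' named `<joint>_<plane>_<modality>_t<NN>`.
#'
#' @param matrix a `feature_matrix`.
#' @param path file path.
#' @return `write_trial_table` returns `path` invisibly; `read_trial_table`
#'   returns a `feature_matrix`.
#' @export
write_trial_table <- function(matrix, path) {
  if (!inherits(matrix, "feature_matrix")) stop("matrix: not a feature_matrix")
  df <- cbind(matrix$rows, as.data.frame(matrix$values))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trial_table
#' @export
read_trial_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  meta_cols <- c("subject_id", "trial_id", "label")
  if (!all(meta_cols %in% names(df)))
    stop("trial table must have subject_id, trial_id, label columns")
  feat <- setdiff(names(df), meta_cols)
  info <- parse_trajectory(sub("_t[0-9]+$", "", feat))
  timepoint <- as.integer(sub("^.*_t", "", feat))
  mods <- sort(unique(info$modality))
  scope <- if (identical(mods, "angle")) "kinematics"
           else if (identical(mods, "moment")) "kinetics" else "combined"
  structure(list(
    values = as.matrix(df[, feat, drop = FALSE]),
    rows = df[, meta_cols],
    columns = data.frame(name = feat, joint = info$joint,
                         plane = info$plane, modality = info$modality,
                         timepoint = timepoint,
                         trajectory = info$name, stringsAsFactors = FALSE),
    scope = scope), class = "feature_matrix")
}
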