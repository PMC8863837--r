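#' Configure an end-to-end gait-classification experiment
#'
#' Bundles every stage's parameters: the synthetic cohort, the input scopes
#' to compare (kinematics, kinetics, and/or the combined matrix), the
#' network, relevance propagation and post-processing. All stage seeds are
#' derived deterministically from one master seed, so a config reproduces
#' an experiment exactly.
#'
#' @param cohort a [cohort_spec()].
#' @param scopes character vector of scopes to run (default all three).
#' @param n_hidden_layers,hidden_width,batch_size,max_epochs,learning_rate
#'   network settings (see [network_config()]); `hidden_width = NULL`
#'   keeps the reference width of twice the input size.
#' @param train_frac fraction of each class's subjects assigned to training
#'   (default 0.8, the reference 32/40; see [split_matrix()]).
#' @param lrp an [lrp_options()].
#' @param relevance_on which rows to explain: `"test"` (default) or
#'   `"all"` correctly classified rows.
#' @param k top-k size for variable selection (default 200).
#' @param windows stance windows for the contribution report.
#' @param standardize_inputs standardize features on training statistics
#'   before fitting (default TRUE).
#' @param seed master seed.
#' @return List of class `"experiment_config"`.
#' @export
experiment_config <- function(cohort = cohort_spec(),
                              scopes = c("kinematics", "kinetics",
                                         "combined"),
                              n_hidden_layers = 10L, hidden_width = NULL,
                              batch_size = 25L, max_epochs = 3000L,
                              learning_rate = 1e-3, weight_decay = 0,
                              train_frac = 0.8,
                              lrp = lrp_options(),
                              relevance_on = c("test", "all"),
                              k = 200L,
                              windows = list(early = c(1, 47),
                                             late = c(48, 100)),
                              standardize_inputs = TRUE,
                              seed = 1L) {
  scopes <- match.arg(scopes, several.ok = TRUE)
  relevance_on <- match.arg(relevance_on)
  if (!inherits(cohort, "cohort_spec")) stop("cohort: not a cohort_spec")
  if (!inherits(lrp, "lrp_options")) stop("lrp: not lrp_options")
  structure(list(cohort = cohort, scopes = scopes,
                 n_hidden_layers = as.integer(n_hidden_layers),
                 hidden_width = hidden_width,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 learning_rate = learning_rate,
                 weight_decay = weight_decay, train_frac = train_frac,
                 lrp = lrp,
                 relevance_on = relevance_on, k = as.integer(k),
                 windows = windows,
                 standardize_inputs = isTRUE(standardize_inputs),
                 seed = as.integer(seed)),
            class = "experiment_config")
}

derive_seed <- function(master, offset) {
  as.integer((as.numeric(master) * 7919 + offset * 104729) %% 2147483647)
}

#' Run the full experiment
#'
#' Executes simulate, assemble, split, (standardize,) train, evaluate,
#' explain for every requested scope. The cohort is generated once from
#' the cohort spec; the train/test split (by subject, class-stratified)
#' and every network initialization are seeded from the master seed, so
#' rerunning the same config reproduces identical numeric outputs.
#'
#' @param config an [experiment_config()].
#' @param out optional directory; when given, per-scope metric tables, the
#'   processed relevance maps, contribution tables and a JSON manifest of
#'   the config and seeds are written there.
#' @return List of class `"experiment_result"` with the dataset, the split
#'   plan, and per scope: the trained network log, confusion matrix,
#'   `metrics` (including `auc_trapezoid` from the test-set ROC),
#'   relevance map, top-k set and contribution tables.
#' @export
run_experiment <- function(config, out = NULL) {
  if (!inherits(config, "experiment_config"))
    stop("config: not an experiment_config")
  dataset <- generate_cohort(config$cohort)
  split_seed <- derive_seed(config$seed, 1L)
  results <- list()
  for (scope in config$scopes) {
    fm <- assemble(dataset, scope)
    sp <- split_matrix(fm, seed = split_seed,
                       train_frac = config$train_frac)
    train_fm <- sp$train; test_fm <- sp$test
    if (config$standardize_inputs) {
      st <- standardize(train_fm, test = test_fm)
      train_fm <- st$train; test_fm <- st$test
    }
    width <- if (is.null(config$hidden_width)) 2L * ncol(fm$values)
             else config$hidden_width
    net_cfg <- network_config(
      n_inputs = ncol(fm$values),
      n_hidden_layers = config$n_hidden_layers,
      hidden_width = width, batch_size = config$batch_size,
      max_epochs = config$max_epochs,
      learning_rate = config$learning_rate,
      weight_decay = config$weight_decay,
      seed = derive_seed(config$seed, 10L + match(scope, config$scopes)))
    params <- train_network(net_cfg, train_fm)
    pred <- predict_network(params, test_fm)
    cm <- confusion_matrix(test_fm$rows$label, pred$labels)
    metrics <- classifier_metrics(cm)
    roc <- roc_curve(test_fm$rows$label, pred$probabilities[, "high"])
    metrics$auc_trapezoid <- roc$auc
    expl_fm <- if (config$relevance_on == "test") test_fm else {
      both <- train_fm
      both$values <- rbind(train_fm$values, test_fm$values)
      both$rows <- rbind(train_fm$rows, test_fm$rows)
      both
    }
    rel <- batch_relevance(params, expl_fm, options = config$lrp)
    map <- aggregate_relevance(rel$relevance, expl_fm$columns)
    results[[scope]] <- list(
      scope = scope, network_log = params$log, params = params,
      confusion = cm, metrics = metrics, roc = roc,
      relevance_n_kept = rel$n_kept, relevance_map = map,
      top_k = top_k(map, min(config$k, nrow(map))),
      contributions = contributions(map, config$windows))
  }
  res <- structure(list(config = config, dataset = dataset,
                        split_plan_seed = split_seed,
                        scopes = results),
                   class = "experiment_result")
  if (!is.null(out)) write_experiment(res, out)
  res
}

write_experiment <- function(res, out) {
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    seed = res$config$seed,
    split_seed = res$split_plan_seed,
    scopes = res$config$scopes,
    cohort = unclass(res$config$cohort)[
      c("n_subjects_per_class", "n_trials", "n_timepoints",
        "subject_sd", "trial_sd", "noise_smoothness", "seed")],
    n_effects = length(res$config$cohort$effects),
    timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  for (scope in names(res$scopes)) {
    r <- res$scopes[[scope]]
    utils::write.csv(as.data.frame(r$relevance_map),
                     file.path(out, paste0("relevance_", scope, ".csv")),
                     row.names = FALSE)
    met <- r$metrics
    utils::write.csv(
      data.frame(metric = names(unclass(met)),
                 value = as.numeric(unlist(unclass(met)))),
      file.path(out, paste0("metrics_", scope, ".csv")),
      row.names = FALSE)
    for (part in names(r$contributions))
      utils::write.csv(r$contributions[[part]],
                       file.path(out, paste0("contributions_", scope, "_",
                                             part, ".csv")),
                       row.names = FALSE)
  }
  invisible(out)
}

#' @export
print.experiment_result <- function(x, ...) {
  cat("experiment_result (master seed ", x$config$seed, ")\n", sep = "")
  for (scope in names(x$scopes)) {
    m <- x$scopes[[scope]]$metrics
    cat(sprintf(
      "  %-10s accuracy %.2f%%  F1 %.4f  MCC %.4f  AUC(trap) %.4f\n",
      scope, 100 * m$accuracy, m$f1, m$mcc, m$auc_trapezoid))
  }
  invisible(x)
}
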