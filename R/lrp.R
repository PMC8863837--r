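#' Options for layer-wise relevance propagation
#'
#' Relevance is redistributed with the z-rule: the message from an upper
#' neuron j to a lower neuron i is R_{i<-j} = z_ij / z_j * R_j, where
#' z_ij = w_ij x_i is the local pre-activation and z_j = sum_i z_ij + b_j
#' the global one. A small stabilizer epsilon (added to z_j with the sign
#' of z_j) keeps the rule defined near z_j = 0; `epsilon` is expressed
#' relative to each layer's pre-activation dynamic range, so the default
#' 1e-6 perturbs z_j by at most one millionth of the layer's largest |z|.
#'
#' @param epsilon relative stabilizer, >= 0. With `epsilon = 0` the raw
#'   rule is used and propagation fails with an instructive error if any
#'   z_j is exactly 0.
#' @param target which output neuron seeds the propagation: the predicted
#'   class (`"predicted"`, default), always the positive-class neuron
#'   (`"positive"`), or an explicit unit index via `target_index`.
#' @param target_index output unit (1 = negative, 2 = positive) when
#'   `target = "index"`.
#' @return An object of class `"lrp_options"`.
#' @export
lrp_options <- function(epsilon = 1e-6,
                        target = c("predicted", "positive", "index"),
                        target_index = NULL) {
  target <- match.arg(target)
  if (epsilon < 0) stop("epsilon: must be >= 0")
  if (target == "index") {
    if (is.null(target_index) || !target_index %in% 1:2)
      stop("target_index: must be 1 or 2")
    target_index <- as.integer(target_index)
  }
  structure(list(epsilon = epsilon, target = target,
                 target_index = target_index), class = "lrp_options")
}

#' Propagate relevance from the output to the input layer
#'
#' Seeds the selected output neuron with its raw (pre-softmax) score f(x)
#' and redistributes it backwards layer by layer with the epsilon-stabilized
#' z-rule; each lower neuron's relevance is the sum of its incoming
#' messages. The tanh nonlinearity is relevance-transparent: redistribution
#' uses only the linear pre-activations, the rule for tanh networks. Bias
#' terms absorb the share b_j / z_j of each neuron's relevance, so with
#' nonzero biases the input-layer total is less than f(x) by exactly the
#' absorbed amount.
#'
#' @param trace a `forward_trace` for a single input row (see [forward()]).
#' @param params the `network_params` the trace was computed from.
#' @param options an [lrp_options()].
#' @return Numeric vector of per-input-feature relevance R^(1), named like
#'   the input features when the trace input had column names. Attributes
#'   `fx` (the seeded output score) and `target_unit`.
#' @export
lrp_propagate <- function(trace, params, options = lrp_options()) {
  if (!inherits(trace, "forward_trace")) stop("trace: not a forward_trace")
  if (nrow(trace$output) != 1L)
    stop("trace must be for a single input row")
  nl <- length(params$layers)
  unit <- switch(options$target,
                 predicted = if (trace$output[1, 2] > trace$output[1, 1]) 2L
                             else 1L,
                 positive = 2L,
                 index = options$target_index)
  R <- numeric(params$sizes[nl + 1L])
  R[unit] <- trace$output[1, unit]
  for (l in seq.int(nl, 1L)) {
    W <- params$layers[[l]]$W
    x <- as.numeric(trace$activations[[l]][1, ])
    z <- as.numeric(trace$preactivations[[l]][1, ])
    if (options$epsilon == 0) {
      if (any(z == 0 & R != 0))
        stop("zero pre-activation with epsilon = 0; use a positive ",
             "stabilizer (see lrp_options)")
      denom <- z
      denom[denom == 0] <- 1  # no relevance flows through these units
    } else {
      eps <- options$epsilon * max(abs(z), .Machine$double.eps)
      denom <- z + eps * ifelse(z >= 0, 1, -1)
    }
    R <- x * as.numeric(W %*% (R / denom))
  }
  names(R) <- colnames(trace$activations[[1L]])
  attr(R, "fx") <- trace$output[1, unit]
  attr(R, "target_unit") <- unit
  R
}

#' Relevance for every correctly classified row of a matrix
#'
#' Runs a forward pass and relevance propagation for each row, keeping only
#' rows whose predicted hard label equals the true label — relevance maps
#' explain classification decisions, which is only meaningful where the
#' decision is right.
#'
#' @param params trained `network_params`.
#' @param matrix a `feature_matrix` or plain matrix.
#' @param labels true labels; default the feature matrix's own.
#' @param options an [lrp_options()].
#' @return List with `relevance` (kept rows x features matrix), `kept`
#'   (logical per input row), `n_kept`, `n_dropped`.
#' @export
batch_relevance <- function(params, matrix, labels = NULL,
                            options = lrp_options()) {
  if (inherits(matrix, "feature_matrix")) {
    if (is.null(labels)) labels <- matrix$rows$label
    x <- matrix$values
  } else x <- matrix
  if (is.null(labels)) stop("labels required")
  if (length(labels) != nrow(x)) stop("labels/rows length mismatch")
  pred <- predict_network(params, x)$labels
  truth <- ifelse(encode_labels(labels) == 1, "high", "low")
  kept <- pred == truth
  if (!any(kept))
    stop("no correctly classified rows; relevance aggregation undefined")
  keep_idx <- which(kept)
  rel <- matrix(NA_real_, length(keep_idx), ncol(x),
                dimnames = list(NULL, colnames(x)))
  for (k in seq_along(keep_idx)) {
    tr <- forward(params, x[keep_idx[k], , drop = FALSE])
    rel[k, ] <- lrp_propagate(tr, params, options)
  }
  list(relevance = rel, kept = kept, n_kept = sum(kept),
       n_dropped = sum(!kept))
}
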