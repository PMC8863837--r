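#' Configure a fully-connected tanh classifier
#'
#' The classifier is a deep fully-connected network: an input layer of
#' `n_inputs` features, `n_hidden_layers` hidden layers of `hidden_width`
#' tanh units each, and a 2-unit linear output layer (one score per class;
#' positive = higher-mileage). Each unit computes the linear pre-activation
#' z = sum_i w_i x_i + b followed, in hidden layers, by the hyperbolic
#' tangent g(z) = (e^z - e^-z)/(e^z + e^-z). The reference architecture is
#' 10 hidden layers of twice the input width (1800 units for 900 inputs,
#' 3600 for 1800); desk-scale work usually uses a reduced net such as
#' 3 x 64.
#'
#' Training is mini-batch gradient descent (Adam) on the softmax
#' cross-entropy of the two output scores, batch size 25, with an epoch cap
#' of 3000 and optional early stopping on a training-loss plateau.
#'
#' @param n_inputs number of input features (900 or 1800 for the reference
#'   matrices).
#' @param n_hidden_layers number of hidden layers (reference 10).
#' @param hidden_width units per hidden layer; default `2 * n_inputs`, the
#'   reference width.
#' @param batch_size mini-batch size (default 25).
#' @param max_epochs epoch cap (default 3000).
#' @param learning_rate Adam step size.
#' @param weight_decay decoupled L2 weight decay per update (AdamW style);
#'   0 disables it. Useful for small cohorts where the network would
#'   otherwise memorize subject-level noise.
#' @param early_stop_tol,early_stop_patience stop when the epoch training
#'   loss has improved by less than `early_stop_tol` (relative) for
#'   `early_stop_patience` consecutive epochs; set patience to `Inf` to
#'   always run to `max_epochs`.
#' @param seed integer seed for weight initialization and batch shuffling.
#' @return An object of class `"network_config"`.
#' @export
network_config <- function(n_inputs, n_hidden_layers = 10L,
                           hidden_width = NULL, batch_size = 25L,
                           max_epochs = 3000L, learning_rate = 1e-3,
                           weight_decay = 0,
                           early_stop_tol = 1e-5,
                           early_stop_patience = 25L, seed = 1L) {
  if (is.null(hidden_width)) hidden_width <- 2L * as.integer(n_inputs)
  stopifnot(n_inputs >= 1, n_hidden_layers >= 1, hidden_width >= 1,
            batch_size >= 1, max_epochs >= 1, learning_rate > 0,
            weight_decay >= 0)
  structure(list(n_inputs = as.integer(n_inputs),
                 n_hidden_layers = as.integer(n_hidden_layers),
                 hidden_width = as.integer(hidden_width),
                 n_outputs = 2L,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 learning_rate = learning_rate,
                 weight_decay = weight_decay,
                 early_stop_tol = early_stop_tol,
                 early_stop_patience = early_stop_patience,
                 seed = as.integer(seed)),
            class = "network_config")
}

#' Initialize network parameters
#'
#' Symmetric uniform fan-in-scaled initialization: weights of a layer with
#' `n_in` inputs are drawn from U(-1/sqrt(n_in), 1/sqrt(n_in)); biases
#' start at zero. Fully determined by the config seed.
#'
#' @param config a [network_config()].
#' @return An object of class `"network_params"`: list of layers, each with
#'   weight matrix `W` (inputs x outputs) and bias vector `b`; the output
#'   layer is last. Output unit 1 scores the negative (lower-mileage)
#'   class, unit 2 the positive (higher-mileage) class.
#' @export
init_network <- function(config) {
  sizes <- c(config$n_inputs,
             rep(config$hidden_width, config$n_hidden_layers),
             config$n_outputs)
  layers <- with_seed(config$seed, lapply(seq_len(length(sizes) - 1L),
    function(l) {
      lim <- 1 / sqrt(sizes[l])
      list(W = matrix(stats::runif(sizes[l] * sizes[l + 1L], -lim, lim),
                      sizes[l], sizes[l + 1L]),
           b = numeric(sizes[l + 1L]))
    }))
  structure(list(layers = layers, sizes = sizes, config = config),
            class = "network_params")
}

#' Forward pass with full activation trace
#'
#' Propagates one or more input rows through the network, recording every
#' layer's pre-activations z = W'x + b and activations. Hidden layers apply
#' tanh; the output layer is linear, so `output` holds the raw two scores
#' f(x) per row (the quantities relevance propagation decomposes), with
#' softmax probabilities available via [predict_network()].
#'
#' @param params a `network_params`.
#' @param x numeric vector of length `n_inputs`, or a matrix with that many
#'   columns (rows are samples).
#' @return An object of class `"forward_trace"`: list with `activations`
#'   (list of matrices, input first, post-tanh layer outputs after),
#'   `preactivations` (list of z matrices per layer) and `output`
#'   (rows x 2 score matrix).
#' @export
forward <- function(params, x) {
  if (!inherits(params, "network_params")) stop("params: not network_params")
  if (is.vector(x)) x <- matrix(x, nrow = 1L)
  if (ncol(x) != params$sizes[1L])
    stop("input has ", ncol(x), " features; network expects ",
         params$sizes[1L])
  nl <- length(params$layers)
  acts <- vector("list", nl + 1L)
  pres <- vector("list", nl)
  acts[[1L]] <- x
  for (l in seq_len(nl)) {
    z <- sweep(acts[[l]] %*% params$layers[[l]]$W, 2,
               params$layers[[l]]$b, "+")
    pres[[l]] <- z
    acts[[l + 1L]] <- if (l < nl) tanh(z) else z
  }
  structure(list(activations = acts, preactivations = pres,
                 output = acts[[nl + 1L]]),
            class = "forward_trace")
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  ez <- exp(z)
  ez / rowSums(ez)
}

label_to_onehot <- function(labels) {
  y <- encode_labels(labels)
  cbind(1 - y, y)  # column 1 = negative, column 2 = positive
}

# Softmax cross-entropy loss and parameter gradients for one batch.
# Returns per-layer weight/bias gradients (mean over the batch), the summed
# loss and the number of correct hard predictions. Backprop through the
# linear layers and tanh units; used by train_network and validated against
# central finite differences in the test suite.
network_gradients <- function(params, xb, yb) {
  nl <- length(params$layers)
  tr <- forward(params, xb)
  p <- softmax_rows(tr$output)
  loss <- -sum(yb * log(pmax(p, 1e-12)))
  correct <- sum((p[, 2] > p[, 1]) == (yb[, 2] == 1))
  delta <- (p - yb) / nrow(xb)
  gW <- vector("list", nl); gb <- vector("list", nl)
  for (l in seq.int(nl, 1L)) {
    gW[[l]] <- crossprod(tr$activations[[l]], delta)
    gb[[l]] <- colSums(delta)
    if (l > 1L)
      delta <- (delta %*% t(params$layers[[l]]$W)) *
        (1 - tr$activations[[l]]^2)
  }
  list(gW = gW, gb = gb, loss = loss, correct = correct)
}

# positive (higher-mileage) class -> 1, negative -> 0
encode_labels <- function(labels) {
  if (is.factor(labels)) labels <- as.character(labels)
  if (is.numeric(labels)) {
    u <- sort(unique(labels))
    if (!all(labels %in% c(0, 1)))
      stop("numeric labels must be 0/1 (1 = positive class)")
    return(as.numeric(labels))
  }
  u <- sort(unique(labels))
  if (!all(labels %in% c("high", "low")))
    stop("labels must be 'high'/'low' or 0/1")
  as.numeric(labels == "high")
}

#' Train the classifier
#'
#' Mini-batch Adam on softmax cross-entropy. Batches are reshuffled every
#' epoch; initialization and shuffling are both driven by the config seed,
#' so identical config + data reproduce identical parameters. Training
#' stops at the epoch cap or earlier when the epoch-mean loss has stopped
#' improving (relative improvement below `early_stop_tol` for
#' `early_stop_patience` consecutive epochs).
#'
#' @param config a [network_config()].
#' @param x training matrix (rows x `n_inputs`), or a `feature_matrix`.
#' @param labels class labels, `"high"`/`"low"` or 1/0 (positive =
#'   higher-mileage); defaults to the feature matrix's own labels.
#' @return A `network_params` with a `log` element: data.frame of epoch,
#'   mean loss and training accuracy, plus the stopping reason.
#' @export
train_network <- function(config, x, labels = NULL) {
  if (inherits(x, "feature_matrix")) {
    if (is.null(labels)) labels <- x$rows$label
    x <- x$values
  }
  if (is.null(labels)) stop("labels required")
  if (nrow(x) < config$batch_size)
    stop("fewer rows (", nrow(x), ") than batch size (", config$batch_size,
         ")")
  if (ncol(x) != config$n_inputs)
    stop("x has ", ncol(x), " features; config expects ", config$n_inputs)
  y <- label_to_onehot(labels)
  params <- init_network(config)
  nl <- length(params$layers)

  m <- lapply(params$layers, function(l)
    list(W = 0 * l$W, b = 0 * l$b))
  v <- m
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  step <- 0L
  n <- nrow(x)
  log_epoch <- integer(0); log_loss <- numeric(0); log_acc <- numeric(0)
  best <- Inf; stall <- 0L; reason <- "epoch limit"

  with_seed(config$seed + 1L, {
    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0; ep_correct <- 0L
      for (start in seq.int(1L, n, by = config$batch_size)) {
        idx <- ord[seq.int(start, min(start + config$batch_size - 1L, n))]
        xb <- x[idx, , drop = FALSE]
        yb <- y[idx, , drop = FALSE]
        g <- network_gradients(params, xb, yb)
        ep_loss <- ep_loss + g$loss
        ep_correct <- ep_correct + g$correct
        if (!all(vapply(g$gW, function(w) all(is.finite(w)), TRUE)))
          stop("non-finite loss gradient at epoch ", epoch,
               "; lower the learning rate")
        step <- step + 1L
        for (l in seq.int(nl, 1L)) {
          gW <- g$gW[[l]]
          gb <- g$gb[[l]]
          m[[l]]$W <- beta1 * m[[l]]$W + (1 - beta1) * gW
          m[[l]]$b <- beta1 * m[[l]]$b + (1 - beta1) * gb
          v[[l]]$W <- beta2 * v[[l]]$W + (1 - beta2) * gW^2
          v[[l]]$b <- beta2 * v[[l]]$b + (1 - beta2) * gb^2
          corr1 <- 1 - beta1^step; corr2 <- 1 - beta2^step
          params$layers[[l]]$W <- params$layers[[l]]$W -
            config$learning_rate * ((m[[l]]$W / corr1) /
            (sqrt(v[[l]]$W / corr2) + eps) +
            config$weight_decay * params$layers[[l]]$W)
          params$layers[[l]]$b <- params$layers[[l]]$b -
            config$learning_rate * (m[[l]]$b / corr1) /
            (sqrt(v[[l]]$b / corr2) + eps)
        }
      }
      ep_loss <- ep_loss / n
      log_epoch <- c(log_epoch, epoch)
      log_loss <- c(log_loss, ep_loss)
      log_acc <- c(log_acc, ep_correct / n)
      if (!is.finite(ep_loss))
        stop("non-finite training loss at epoch ", epoch)
      if (ep_loss < best * (1 - config$early_stop_tol)) {
        best <- ep_loss; stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= config$early_stop_patience) {
          reason <- "loss plateau"
          break
        }
      }
    }
  })
  params$log <- data.frame(epoch = log_epoch, loss = log_loss,
                           accuracy = log_acc)
  attr(params$log, "stopped") <- reason
  params
}

#' Predict class scores, probabilities and labels
#'
#' @param params a trained `network_params`.
#' @param x matrix of rows to classify, or a `feature_matrix`.
#' @return List with `scores` (raw two-column output f(x)), `probabilities`
#'   (softmax over the scores; column `"high"` is the positive class),
#'   and `labels` (`"high"`/`"low"`; a tied score is resolved to the
#'   negative class).
#' @export
predict_network <- function(params, x) {
  if (inherits(x, "feature_matrix")) x <- x$values
  scores <- forward(params, x)$output
  p <- softmax_rows(scores)
  colnames(scores) <- colnames(p) <- c("low", "high")
  list(scores = scores, probabilities = p,
       labels = unname(ifelse(scores[, "high"] > scores[, "low"],
                              "high", "low")))
}
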