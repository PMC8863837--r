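# Independent brute-force oracles used across the suite. These deliberately
# use naive loops and closed forms, never the package's own vectorized
# implementations.

# One pass of the 25/50/25 smoothing kernel by explicit convolution, with
# endpoint weights renormalized over the in-range support.
oracle_smooth_once <- function(x) {
  n <- length(x)
  out <- numeric(n)
  for (i in seq_len(n)) {
    if (i == 1 && n > 1) {
      out[i] <- (0.5 * x[1] + 0.25 * x[2]) / 0.75
    } else if (i == n && n > 1) {
      out[i] <- (0.25 * x[n - 1] + 0.5 * x[n]) / 0.75
    } else if (n == 1) {
      out[i] <- x[i]
    } else {
      out[i] <- 0.25 * x[i - 1] + 0.5 * x[i] + 0.25 * x[i + 1]
    }
  }
  out
}

# LRP by message-by-message enumeration with scalar loops (z-rule with the
# same epsilon stabilization contract as the package).
oracle_lrp <- function(params, x, unit, epsilon = 0) {
  nl <- length(params$layers)
  acts <- list(as.numeric(x))
  zs <- list()
  for (l in seq_len(nl)) {
    z <- as.numeric(t(params$layers[[l]]$W) %*% acts[[l]] +
                      params$layers[[l]]$b)
    zs[[l]] <- z
    acts[[l + 1]] <- if (l < nl) tanh(z) else z
  }
  R_upper <- numeric(length(acts[[nl + 1]]))
  R_upper[unit] <- acts[[nl + 1]][unit]
  layer_sums <- numeric(nl + 1)
  layer_sums[nl + 1] <- sum(R_upper)
  for (l in nl:1) {
    W <- params$layers[[l]]$W
    R_lower <- numeric(length(acts[[l]]))
    for (j in seq_along(R_upper)) {
      zj <- zs[[l]][j]
      denom <- if (epsilon == 0) zj else
        zj + epsilon * max(abs(zs[[l]]), .Machine$double.eps) *
          (if (zj >= 0) 1 else -1)
      for (i in seq_along(R_lower)) {
        zij <- W[i, j] * acts[[l]][i]
        R_lower[i] <- R_lower[i] + zij / denom * R_upper[j]
      }
    }
    layer_sums[l] <- sum(R_lower)
    R_upper <- R_lower
  }
  list(R = R_upper, layer_sums = layer_sums, zs = zs,
       fx = acts[[nl + 1]][unit])
}

# Mann-Whitney pair-counting AUC (ties count one half).
oracle_auc_pairs <- function(y, s) {
  pos <- s[y == 1]; neg <- s[y == 0]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + (p > q) + 0.5 * (p == q)
  total / (length(pos) * length(neg))
}

# Hand-built network_params for arbitrary layer sizes.
make_params <- function(Ws, bs) {
  sizes <- c(nrow(Ws[[1]]), vapply(Ws, ncol, 1L))
  structure(list(
    layers = Map(function(W, b) list(W = W, b = b), Ws, bs),
    sizes = sizes,
    config = NULL), class = "network_params")
}

# Random small net with controllable bias.
random_params <- function(sizes, seed, bias = TRUE) {
  set.seed(seed)
  Ws <- list(); bs <- list()
  for (l in seq_len(length(sizes) - 1)) {
    Ws[[l]] <- matrix(rnorm(sizes[l] * sizes[l + 1], sd = 0.7),
                      sizes[l], sizes[l + 1])
    bs[[l]] <- if (bias) rnorm(sizes[l + 1], sd = 0.3)
               else numeric(sizes[l + 1])
  }
  make_params(Ws, bs)
}

# Small recovery cohort shared by the stochastic relevance tests.
recovery_cohort_spec <- function(seed, amplitude = 0.75,
                                 trajectory = "knee_transverse_angle",
                                 window = c(10, 35),
                                 n_subjects_per_class = 16L) {
  cohort_spec(n_subjects_per_class = n_subjects_per_class, n_trials = 10L,
              subject_sd = 0.05, trial_sd = 0.25, noise_smoothness = 10L,
              effects = list(gait_effect(trajectory, window, amplitude)),
              seed = seed)
}
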