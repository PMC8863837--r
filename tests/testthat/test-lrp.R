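test_that("a single linear layer decomposes into z_ij exactly", {
  # f(x) = 1*3 + 2*4 = 11 at output unit 1; relevance = (3, 8)
  p <- make_params(list(matrix(c(1, 2, 0, 0), 2, 2)),
                   list(c(0, 0)))
  tr <- forward(p, c(3, 4))
  R <- lrp_propagate(tr, p, lrp_options(epsilon = 0, target = "index",
                                        target_index = 1))
  expect_equal(as.numeric(R), c(3, 8))
  expect_equal(attr(R, "fx"), 11)
  expect_equal(sum(R), 11)
})

test_that("linear-model equivalence holds for every input", {
  set.seed(41)
  w <- rnorm(6)
  p <- make_params(list(cbind(w, rnorm(6))), list(c(0, 0)))
  for (i in 1:5) {
    x <- rnorm(6)
    tr <- forward(p, x)
    R <- lrp_propagate(tr, p, lrp_options(epsilon = 0, target = "index",
                                          target_index = 1))
    expect_equal(as.numeric(R), w * x)
  }
})

test_that("relevance is conserved through bias-free networks", {
  shapes <- list(c(6, 8, 2), c(5, 16, 16, 2), c(10, 32, 24, 8, 2))
  for (k in seq_along(shapes)) {
    p <- random_params(shapes[[k]], seed = 100 + k, bias = FALSE)
    set.seed(200 + k)
    for (rep in 1:3) {
      x <- rnorm(shapes[[k]][1])
      tr <- forward(p, x)
      R <- lrp_propagate(tr, p, lrp_options(epsilon = 1e-9))
      fx <- attr(R, "fx")
      expect_lt(abs(sum(R) - fx) / max(abs(fx), 1e-12), 1e-6)
    }
  }
})

test_that("bias absorption follows the (1 - b_j/z_j) multiplier", {
  p <- random_params(c(4, 6, 5, 2), seed = 55, bias = TRUE)
  set.seed(56)
  x <- rnorm(4)
  tr <- forward(p, x)
  unit <- if (tr$output[1, 2] > tr$output[1, 1]) 2L else 1L
  oracle <- oracle_lrp(p, x, unit, epsilon = 0)
  R <- lrp_propagate(tr, p, lrp_options(epsilon = 0))
  expect_equal(as.numeric(R), oracle$R, tolerance = 1e-10)
  # per-layer deficit audit: relevance lost between layer l+1 and l equals
  # sum_j R_j * b_j / z_j, recomputed message by message
  nl <- length(p$layers)
  R_upper <- numeric(p$sizes[nl + 1]); R_upper[unit] <- oracle$fx
  for (l in nl:1) {
    zj <- oracle$zs[[l]]
    bj <- p$layers[[l]]$b
    deficit_expected <- sum(R_upper * bj / zj)
    R_lower <- numeric(p$sizes[l])
    for (j in seq_along(R_upper)) {
      acts_l <- if (l == 1) x else tanh(oracle$zs[[l - 1]])
      for (i in seq_along(R_lower))
        R_lower[i] <- R_lower[i] +
          p$layers[[l]]$W[i, j] * acts_l[i] / zj[j] * R_upper[j]
    }
    expect_equal(sum(R_upper) - sum(R_lower), deficit_expected,
                 tolerance = 1e-8)
    R_upper <- R_lower
  }
  expect_equal(R_upper, oracle$R, tolerance = 1e-10)
})

test_that("epsilon-stabilized propagation matches enumeration on deep nets", {
  for (seed in 1:4) {
    p <- random_params(c(5, 12, 10, 6, 2), seed = 300 + seed)
    set.seed(400 + seed)
    x <- rnorm(5)
    tr <- forward(p, x)
    unit <- if (tr$output[1, 2] > tr$output[1, 1]) 2L else 1L
    R <- lrp_propagate(tr, p, lrp_options(epsilon = 1e-6))
    oracle <- oracle_lrp(p, x, unit, epsilon = 1e-6)
    expect_equal(as.numeric(R), oracle$R, tolerance = 1e-10)
  }
})

test_that("zero pre-activations absorb relevance or raise with epsilon 0", {
  # a unit with z = 0 necessarily carries zero relevance in a consistent
  # trace (tanh(0) = 0), so propagation stays finite and absorbs nothing
  p <- make_params(list(matrix(c(1, -1), 2, 1), matrix(1, 1, 2)),
                   list(0, c(0.5, 0)))
  tr <- forward(p, c(1, 1))   # hidden z = 0
  R <- lrp_propagate(tr, p, lrp_options(epsilon = 0, target = "index",
                                        target_index = 1))
  expect_true(all(is.finite(R)))
  expect_equal(as.numeric(R), c(0, 0))
  # relevance seeded onto a zero pre-activation (an inconsistent trace)
  # must be rejected, not silently divided through
  tr2 <- tr
  tr2$output[1, 2] <- 1   # output unit 2 has pre-activation exactly 0
  expect_error(
    lrp_propagate(tr2, p, lrp_options(epsilon = 0, target = "index",
                                      target_index = 2)),
    "stabilizer")
})

test_that("batch relevance keeps exactly the correctly classified rows", {
  set.seed(61)
  n <- 40
  x <- rbind(matrix(rnorm(n, 1.5, 0.5), n / 2, 2),
             matrix(rnorm(n, -1.5, 0.5), n / 2, 2))
  labels <- rep(c("high", "low"), each = n / 2)
  cfg <- network_config(2, 1, 8, batch_size = 10, max_epochs = 200,
                        learning_rate = 5e-3, seed = 6)
  net <- train_network(cfg, x, labels)
  # perfectly classified: everything kept
  br <- batch_relevance(net, x, labels)
  expect_equal(br$n_kept, n)
  expect_equal(br$n_dropped, 0)
  expect_identical(dim(br$relevance), c(as.integer(n), 2L))
  # deliberately wrong labels: nothing kept -> error
  flipped <- ifelse(labels == "high", "low", "high")
  expect_error(batch_relevance(net, x, flipped), "no correctly classified")
  # mixed case: kept count equals TP + TN from the confusion matrix
  mixed <- labels
  mixed[c(1:5, 25:30)] <- ifelse(mixed[c(1:5, 25:30)] == "high",
                                 "low", "high")
  pred <- predict_network(net, x)$labels
  cm <- confusion_matrix(mixed, pred)
  br2 <- batch_relevance(net, x, mixed)
  expect_equal(br2$n_kept, cm$tp + cm$tn)
})

test_that("relevance seeding follows the selected target unit", {
  p <- random_params(c(3, 5, 2), seed = 91)
  x <- c(0.3, -0.2, 0.8)
  tr <- forward(p, x)
  R_pos <- lrp_propagate(tr, p, lrp_options(target = "positive"))
  expect_equal(attr(R_pos, "target_unit"), 2L)
  expect_equal(attr(R_pos, "fx"), tr$output[1, 2])
  R_idx <- lrp_propagate(tr, p, lrp_options(target = "index",
                                            target_index = 1))
  expect_equal(attr(R_idx, "target_unit"), 1L)
})
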