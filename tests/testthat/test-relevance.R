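# column registry for a compact 18-trajectory map with nt timepoints
tiny_columns <- function(nt = 10) {
  do.call(rbind, lapply(trajectory_names(), function(tr) {
    info <- parse_trajectory(tr)
    data.frame(name = sprintf("%s_t%02d", tr, seq_len(nt) - 1L),
               joint = info$joint, plane = info$plane,
               modality = info$modality, timepoint = seq_len(nt) - 1L,
               trajectory = tr, stringsAsFactors = FALSE)
  }))
}

test_that("one smoothing pass spreads an impulse as 25/50/25", {
  x <- numeric(11); x[6] <- 1
  s <- gaitlrp:::smooth_121(x)
  expect_equal(s[5:7], c(0.25, 0.5, 0.25))
  expect_equal(sum(s), 1)  # interior mass is conserved exactly
  expect_equal(s[-(5:7)], numeric(8))
})

test_that("repeated smoothing matches the direct-convolution oracle", {
  set.seed(9)
  for (rep in 1:5) {
    x <- abs(rnorm(17))
    got <- x; want <- x
    for (p in 1:3) {
      got <- gaitlrp:::smooth_121(got)
      want <- oracle_smooth_once(want)
    }
    expect_identical(got, want)
  }
  # boundary rule: endpoint weights renormalized over in-range support
  e <- c(1, numeric(7))
  expect_identical(gaitlrp:::smooth_121(e),
                   c(0.5 / 0.75, 0.25, numeric(6)))
})

test_that("aggregate pipeline normalizes, rectifies, smooths and rescales", {
  cols <- tiny_columns(10)
  n_feat <- nrow(cols)
  # single sample, one trajectory at a constant level, rest zero:
  # the nonzero trajectory must map to 1, everything else to 0
  r <- numeric(n_feat)
  r[cols$trajectory == "knee_sagittal_angle"] <- 4
  map <- aggregate_relevance(r, cols)
  expect_true(all(map$score[cols$trajectory == "knee_sagittal_angle"] == 1))
  expect_true(all(map$score[cols$trajectory != "knee_sagittal_angle"] == 0))
  expect_s3_class(map, "relevance_map")
  # per-sample normalization: scaling any sample must not change the map
  set.seed(15)
  rel <- matrix(rnorm(3 * n_feat), 3)
  map1 <- aggregate_relevance(rel, cols)
  rel2 <- rel * c(10, 0.1, 3)
  map2 <- aggregate_relevance(rel2, cols)
  expect_equal(map1$score, map2$score, tolerance = 1e-12)
  # sample order invariance
  map3 <- aggregate_relevance(rel[c(3, 1, 2), ], cols)
  expect_equal(map1$score, map3$score, tolerance = 1e-12)
  # signed relevance is rectified: sign-flipping every sample changes nothing
  map4 <- aggregate_relevance(-rel, cols)
  expect_equal(map1$score, map4$score, tolerance = 1e-12)
  expect_error(aggregate_relevance(matrix(0, 2, n_feat), cols),
               "all-zero")
})

test_that("smoothing stays within trajectories (no cross-boundary leak)", {
  cols <- tiny_columns(10)
  r <- numeric(nrow(cols))
  # impulse at the last timepoint of the first trajectory
  r[cols$trajectory == "ankle_sagittal_angle" & cols$timepoint == 9] <- 1
  map <- aggregate_relevance(r, cols)
  second <- map$score[cols$trajectory == "ankle_frontal_angle"]
  expect_true(all(second == 0))
})

test_that("top_k ranks by score with canonical tie-breaking", {
  cols <- tiny_columns(10)
  n_feat <- nrow(cols)
  set.seed(33)
  rel <- matrix(abs(rnorm(2 * n_feat)) + 0.1, 2)
  map <- aggregate_relevance(rel, cols)
  got <- top_k(map, 20)
  # full-sort oracle
  ord <- order(-map$score)[1:20]
  expect_equal(got$score, map$score[ord])
  expect_equal(got$name, map$name[ord])
  expect_equal(attr(got, "min_score"), min(map$score[ord]))
  expect_true(all(diff(got$score) <= 0))
  # all-equal scores: first k in canonical registry order
  map_eq <- map; map_eq$score <- rep(1, n_feat)
  expect_identical(top_k(map_eq, 5)$name, cols$name[1:5])
  expect_error(top_k(map, n_feat + 1), "exceeds")
})

test_that("contribution percentages partition to 100 in every grouping", {
  cols <- tiny_columns(10)
  set.seed(44)
  rel <- matrix(abs(rnorm(nrow(cols))), 1)
  map <- aggregate_relevance(rel, cols)
  co <- contributions(map, windows = list(early = c(1, 5), late = c(6, 10)))
  for (part in co)
    expect_equal(sum(part$percent), 100, tolerance = 1e-9)
  expect_error(contributions(map, windows = list(a = c(1, 4), b = c(6, 10))),
               "partition")
})

test_that("contributions localize to the carrying groups and windows", {
  cols <- tiny_columns(10)
  r <- numeric(nrow(cols))
  # three smoothing passes spread mass at most 3 timepoints, so an
  # impulse at timepoints 0-1 stays inside the 5-point early window
  sel <- cols$trajectory == "knee_transverse_angle" & cols$timepoint < 2
  r[sel] <- 1
  map <- aggregate_relevance(r, cols)
  co <- contributions(map, windows = list(early = c(1, 5), late = c(6, 10)))
  expect_equal(co$trajectory$percent[
    co$trajectory$group == "knee_transverse_angle"], 100)
  expect_equal(co$joint$percent[co$joint$group == "knee"], 100)
  expect_equal(co$plane$percent[co$plane$group == "transverse"], 100)
  expect_gt(co$window$percent[co$window$group == "early"], 99.999)
})

test_that("a uniform map splits between windows by width", {
  cols <- tiny_columns(100)
  map <- cbind(cols, score = 1)
  class(map) <- c("relevance_map", "data.frame")
  co <- contributions(map)
  expect_equal(co$window$percent[co$window$group == "early"], 47)
  expect_equal(co$window$percent[co$window$group == "late"], 53)
  # each joint carries a third of a uniform map
  expect_equal(co$joint$percent, rep(100 / 3, 3), tolerance = 1e-9)
})

test_that("relevance inside an injected window grows with amplitude", {
  # 3-step amplitude ladder x 5 seeds; seed-averaged in-window relevance
  # must be non-decreasing
  amps <- c(0.2, 0.6, 1.2)
  mean_inside <- sapply(amps, function(a) {
    mean(sapply(1:5, function(seed) {
      spec <- recovery_cohort_spec(seed, amplitude = a,
                                   n_subjects_per_class = 8L)
      ds <- generate_cohort(spec)
      fm <- assemble(ds, "kinematics")
      sp <- split_matrix(fm, seed = seed, train_frac = 0.75)
      st <- standardize(sp$train, test = sp$test)
      cfg <- network_config(900, 2, 32, max_epochs = 40,
                            learning_rate = 2e-3, weight_decay = 1e-2,
                            seed = seed + 50)
      net <- train_network(cfg, st$train)
      rel <- batch_relevance(net, st$test)
      map <- aggregate_relevance(rel$relevance, st$test$columns)
      inside <- map$trajectory == "knee_transverse_angle" &
        map$timepoint %in% 10:34
      mean(map$score[inside])
    }))
  })
  expect_true(all(diff(mean_inside) >= 0))
})
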