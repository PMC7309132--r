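test_that("entropy confidence spans [0, 1] with the documented anchors", {
  expect_equal(entropy_confidence(rep(1 / 7, 7)), 0, tolerance = 1e-12)
  expect_equal(entropy_confidence(c(1, rep(0, 6))), 1)
  expect_equal(entropy_confidence(c(0.5, 0.5, rep(0, 5))),
               1 - log(2) / log(7), tolerance = 1e-12)
})

test_that("weight update is the confidence-weighted Bayes rule", {
  onehot <- c(1, rep(0, 6))
  unif <- rep(1 / 7, 7)
  # a decisive classifier against two uncertain ones takes all the weight
  w <- update_weights(rep(1 / 3, 3), list(onehot, unif, unif))
  expect_equal(w, c(1, 0, 0))
  # identical posteriors leave the weights unchanged
  p <- c(0.6, 0.3, 0.1, rep(0, 4))
  expect_equal(update_weights(c(0.2, 0.8), list(p, p)), c(0.2, 0.8))
  # all-zero confidences carry the weights over
  expect_equal(update_weights(c(0.3, 0.7), list(unif, unif)), c(0.3, 0.7))
  # general case: proportional to confidence x previous weight
  set.seed(1)
  ps <- list(rand_posterior(1, 7)[1, ], rand_posterior(1, 7)[1, ])
  conf <- vapply(ps, entropy_confidence, 0)
  prev <- c(0.5, 0.5)
  expect_equal(update_weights(prev, ps),
               conf * prev / sum(conf * prev), tolerance = 1e-12)
})

test_that("a single step reduces and fixes correctly", {
  p <- c(0.7, 0.2, 0.1)
  # N = 1 at t = 1: the uniform prior cancels
  expect_equal(dbmm_step(list(p), 1), p, tolerance = 1e-12)
  # all-uniform bases keep the uniform posterior as a fixed point
  u <- rep(1 / 7, 7)
  expect_equal(dbmm_step(list(u, u), c(0.5, 0.5), prev_posterior = u), u)
  # explicit transition matrix replaces the posterior-as-prior rule
  Tm <- matrix(c(0.9, 0.1, 0.2, 0.8), 2, 2, byrow = TRUE)
  prev <- c(1, 0)
  out <- dbmm_step(list(c(0.5, 0.5)), 1, prev_posterior = prev,
                   transition = Tm)
  expect_equal(out, c(0.9, 0.1) * 0.5 / sum(c(0.9, 0.1) * 0.5))
})

test_that("the recursion matches the scalar brute-force oracle", {
  # tiny hand-checkable case: 2 classes, 2 frames, 2 classifiers
  b1 <- rbind(c(0.9, 0.1), c(0.8, 0.2))
  b2 <- rbind(c(0.6, 0.4), c(0.3, 0.7))
  model <- dbmm_shell(2, c("walking", "running"))
  tr <- classify_sequence(model, list(b1, b2))
  expect_equal(tr$posterior, oracle_dbmm(list(b1, b2), c(0.5, 0.5)),
               ignore_attr = TRUE, tolerance = 1e-12)

  # random 3-class, 5-frame instances
  set.seed(42)
  for (rep in 1:25) {
    bs <- list(rand_posterior(5, 3), rand_posterior(5, 3),
               rand_posterior(5, 3))
    w0 <- c(0.2, 0.5, 0.3)
    model3 <- dbmm_shell(3, c("walking", "running", "passing"), w0)
    tr3 <- classify_sequence(model3, bs)
    expect_equal(tr3$posterior, oracle_dbmm(bs, w0),
                 ignore_attr = TRUE, tolerance = 1e-12)
  }
})

test_that("beta-normalisation and the weight simplex hold on random instances", {
  set.seed(7)
  for (rep in 1:200) {
    cc <- sample(2:7, 1)
    Tn <- sample(1:6, 1)
    N <- sample(1:3, 1)
    bs <- replicate(N, rand_posterior(Tn, cc), simplify = FALSE)
    model <- dbmm_shell(N, futsal_actions()[1:cc])
    tr <- classify_sequence(model, bs)
    expect_equal(rowSums(tr$posterior), rep(1, Tn), tolerance = 1e-9)
    expect_equal(rowSums(tr$weights), rep(1, Tn), tolerance = 1e-12)
    expect_true(all(tr$posterior >= 0))
    # beta equals the explicit renormaliser of prior * mixture
    expect_true(all(is.finite(tr$beta) & tr$beta > 0))
  }
})

test_that("single-classifier reduction follows the Markov-weighted base", {
  set.seed(9)
  b <- rand_posterior(5, 3)
  model <- dbmm_shell(1, c("walking", "running", "passing"), 1)
  tr <- classify_sequence(model, list(b))
  # brute force: prior(t) = fused(t-1), fused ~ prior * base
  prior <- rep(1 / 3, 3)
  for (t in 1:5) {
    f <- prior * b[t, ]
    f <- f / sum(f)
    expect_equal(tr$posterior[t, ], f, ignore_attr = TRUE,
                 tolerance = 1e-12)
    prior <- f
  }
})

test_that("classifier order does not change the fused posterior", {
  set.seed(13)
  bs <- list(rand_posterior(4, 3), rand_posterior(4, 3),
             rand_posterior(4, 3))
  w0 <- c(0.5, 0.3, 0.2)
  cls <- c("walking", "running", "passing")
  tr1 <- classify_sequence(dbmm_shell(3, cls, w0), bs)
  perm <- c(3, 1, 2)
  tr2 <- classify_sequence(dbmm_shell(3, cls, w0[perm]), bs[perm])
  expect_equal(tr1$posterior, tr2$posterior, tolerance = 1e-12)
})

test_that("agreeing bases reinforce monotonically to the shared label", {
  p <- c(0.6, 0.25, 0.15)
  b <- matrix(rep(p, each = 8), 8, 3)
  model <- dbmm_shell(2, c("walking", "running", "passing"))
  tr <- classify_sequence(model, list(b, b))
  expect_equal(tr$action, "walking")
  expect_true(all(diff(tr$posterior[, 1]) > -1e-12))   # sharpening
  # one-frame trial: argmax of the weighted mixture
  tr1 <- classify_sequence(model, list(b[1, , drop = FALSE],
                                       b[1, , drop = FALSE]))
  expect_equal(tr1$action, "walking")
})

test_that("ensemble fitting assigns confidence-based initial weights", {
  ds <- make_cluster_dataset(n_per_class = 40, sep = 3, seed = 10)
  m1 <- fit_dbmm(ds, bases = "nb", seed = 2)
  expect_equal(m1$init_weights, 1)
  m2 <- fit_dbmm(ds, bases = c("nb", "nb"), seed = 2)
  expect_equal(unname(m2$init_weights), c(0.5, 0.5))
  m3 <- fit_dbmm(ds, seed = 2)
  expect_equal(sum(m3$init_weights), 1)
  expect_length(m3$models, 3)
})

test_that("training on shuffled labels lowers held-out entropy confidence", {
  # the mechanism behind the initial weights: a corrupted base is less decisive
  set.seed(15)
  ds <- make_cluster_dataset(n_per_class = 60, sep = 3, seed = 11)
  hold <- make_cluster_dataset(n_per_class = 30, sep = 3, seed = 12)
  shuf <- ds
  shuf$action <- sample(shuf$action)
  attr(shuf, "features") <- attr(ds, "features")
  conf_true <- mean(entropy_confidence(posterior_matrix(fit_nb(ds), hold)))
  conf_shuf <- mean(entropy_confidence(posterior_matrix(fit_nb(shuf), hold)))
  expect_gt(conf_true, conf_shuf)
})

ensemble_vs_bases <- function(features, seed) {
  ds <- assemble_dataset(features, "frame")
  sp <- train_test_split(ds, seed = seed)
  model <- fit_dbmm(sp$train, seed = seed)
  pred_d <- predict(model, sp$test)
  base_acc <- vapply(model$models, function(m) {
    p <- classify_trials_framewise(m, sp$test)
    mean(p$pred == p$truth)
  }, 0)
  tibble::tibble(seed = seed, dbmm = mean(pred_d$pred == pred_d$truth),
                 best_base = max(base_acc), worst_base = min(base_acc),
                 mean_base = mean(base_acc), ann_base = base_acc[["ann"]])
}

test_that("the fused ensemble improves on the typical base classifier", {
  accs <- purrr::map_dfr(1:5, function(seed) {
    f <- corpus_features(duration_s = 950, seed = 100 + seed)
    ensemble_vs_bases(f, seed)
  })
  # better than the average of its bases on every seed, never below the
  # weakest base, and better than the frame-wise network overall
  expect_true(all(accs$dbmm > accs$mean_base))
  expect_true(all(accs$dbmm >= accs$worst_base))
  expect_gt(mean(accs$dbmm), mean(accs$ann_base))
})
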