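test_that("naive Bayes fits per-class Gaussians with a variance floor", {
  ds <- tibble::tibble(trial_id = c("a", "a", "b", "b"),
                       action = c("walking", "walking", "running", "running"),
                       frame = c(1, 2, 1, 2),
                       v = c(0, 0, 1, 1))
  attr(ds, "features") <- "v"
  m <- fit_nb(ds)
  expect_equal(as.vector(m$mu[, "v"]), c(1, 0))   # canonical class order
  expect_equal(as.vector(m$var[, "v"]), c(1e-9, 1e-9))
  expect_equal(sum(m$prior), 1)
})

test_that("naive Bayes posterior matches the closed-form Gaussian ratio", {
  m <- structure(list(classes = c("running", "walking"), features = "v",
                      prior = c(0.5, 0.5),
                      mu = matrix(c(0, 2), 2, 1,
                                  dimnames = list(c("running", "walking"), "v")),
                      var = matrix(1, 2, 1,
                                   dimnames = list(c("running", "walking"), "v"))),
                 class = "nb_model")
  P <- posterior_matrix(m, matrix(c(1, 0), 2, 1))
  expect_equal(P[1, ], c(running = 0.5, walking = 0.5), tolerance = 1e-9)
  expect_equal(unname(P[2, "running"]), stats::plogis(2), tolerance = 1e-6)

  # log-domain survives extreme frames and stays a distribution
  Pfar <- posterior_matrix(m, matrix(1e6, 1, 1))
  expect_equal(sum(Pfar), 1, tolerance = 1e-9)
  expect_true(all(Pfar > 0))
})

test_that("naive Bayes log-posterior equals the direct product on small cases", {
  set.seed(4)
  ds <- make_cluster_dataset(n_per_class = 20, sep = 1.5)
  m <- fit_nb(ds)
  x <- c(v = 0.45, d = 0.75, theta = 0.05)
  P <- posterior_matrix(m, matrix(x, 1, 3, dimnames = list(NULL, m$features)))
  # brute-force: direct product of densities, no log domain
  direct <- vapply(seq_along(m$classes), function(j) {
    m$prior[j] * prod(stats::dnorm(x, m$mu[j, ], sqrt(m$var[j, ])))
  }, 0)
  direct <- direct / sum(direct)
  expect_equal(as.vector(P), direct, tolerance = 1e-9)
})

test_that("naive Bayes separates well-separated synthetic classes", {
  ds <- make_cluster_dataset(n_per_class = 100, sep = 4, sd = 0.5, seed = 2)
  hold <- make_cluster_dataset(n_per_class = 50, sep = 4, sd = 0.5, seed = 3)
  m <- fit_nb(ds)
  P <- posterior_matrix(m, hold)
  acc <- mean(m$classes[max.col(P)] == hold$action)
  expect_gt(acc, 0.95)
})

test_that("k-NN posteriors are neighbour vote proportions", {
  ds <- make_cluster_dataset(n_per_class = 10, frames_per_trial = 5)
  m1 <- fit_knn(ds, k = 1)
  P <- posterior_matrix(m1, ds[3, ])
  expect_gt(P[1, ds$action[3]], 0.99)              # own frame wins at k = 1

  # hand-built 3-neighbour vote: 2 walking, 1 running
  tr <- tibble::tibble(trial_id = c("a", "a", "b"),
                       action = c("walking", "walking", "running"),
                       frame = 1:3, v = c(0, 0.1, 0.2), d = 0, theta = 0)
  attr(tr, "features") <- c("v", "d", "theta")
  m3 <- fit_knn(tr, k = 3)
  P3 <- posterior_matrix(m3, tr[1, ])
  expect_equal(unname(P3[1, "walking"]), 2 / 3, tolerance = 1e-5)
  expect_equal(unname(P3[1, "running"]), 1 / 3, tolerance = 1e-5)
})

test_that("k-NN matches a brute-force all-pairs scan", {
  set.seed(11)
  ds <- make_cluster_dataset(n_per_class = 50, frames_per_trial = 5,
                             sep = 1, sd = 1)
  m <- fit_knn(ds, k = 5)
  qx <- matrix(rnorm(50 * 3, 1, 2), 50, 3,
               dimnames = list(NULL, m$features))
  P <- posterior_matrix(m, qx)
  X <- m$X
  for (i in seq_len(nrow(qx))) {
    d2 <- rowSums(sweep(X, 2, qx[i, ])^2)
    nb <- order(d2)[1:5]                           # stable: earlier index wins
    votes <- table(factor(m$y[nb], m$classes)) / 5
    expect_equal(as.vector(P[i, ]), as.vector(votes), tolerance = 1e-5)
  }
})

test_that("ANN with zero weights emits the uniform posterior", {
  cls <- futsal_actions()
  m <- structure(list(classes = cls, features = c("v", "d", "theta"),
                      W1 = matrix(0, 3, 4), b1 = numeric(4),
                      W2 = matrix(0, 4, 7), b2 = numeric(7)),
                 class = "ann_model")
  P <- posterior_matrix(m, matrix(rnorm(6), 2, 3))
  expect_equal(as.vector(P), rep(1 / 7, 14), tolerance = 1e-12)
})

test_that("ANN gradient descent moves the output toward the target", {
  ds <- make_cluster_dataset(n_per_class = 10, frames_per_trial = 5)
  m0 <- fit_ann(ds, hidden = 5, epochs = 1, lr = 0, seed = 1)   # = init
  m1 <- fit_ann(ds, hidden = 5, epochs = 2, lr = 0.5, seed = 1)
  p0 <- posterior_matrix(m0, ds[1, ])[1, ds$action[1]]
  p1 <- posterior_matrix(m1, ds[1, ])[1, ds$action[1]]
  expect_gt(p1, p0)
  # loss decreases monotonically at a sane rate on separable data
  m <- fit_ann(ds, hidden = 5, epochs = 50, lr = 0.3, seed = 1)
  expect_lt(m$loss_trace[50], m$loss_trace[1])
})

test_that("ANN reaches full training accuracy on a separable toy", {
  ds <- make_cluster_dataset(n_per_class = 50, sep = 3, sd = 0.4, seed = 5)
  m <- fit_ann(ds, hidden = 10, epochs = 200, lr = 0.3, seed = 2)
  P <- posterior_matrix(m, ds)
  expect_equal(mean(m$classes[max.col(P)] == ds$action), 1.0)
})

test_that("base classifiers always emit floored probability simplices", {
  set.seed(21)
  ds <- make_cluster_dataset(n_per_class = 30, sep = 2)
  q <- matrix(rnorm(60, 0, 5), 20, 3)
  for (m in list(fit_nb(ds), fit_knn(ds, k = 5),
                 fit_ann(ds, hidden = 4, epochs = 20, seed = 3))) {
    P <- posterior_matrix(m, q)
    expect_true(all(P >= 1e-7))
    expect_equal(rowSums(P), rep(1, 20), tolerance = 1e-9)
  }
})

test_that("trial labels come from the mean frame posterior", {
  ds <- make_cluster_dataset(n_per_class = 20, sep = 4, seed = 6)
  m <- fit_nb(ds)
  pred <- classify_trials_framewise(m, ds)
  expect_setequal(pred$trial_id, unique(ds$trial_id))
  expect_equal(pred$truth, pred$pred)              # separable: all correct
})
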