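rand_params <- function(H, I, C, seed = 1) {
  with_seed <- function(code) { set.seed(seed); code }
  with_seed(list(W = matrix(rnorm(4 * H * (H + I), 0, 0.5), 4 * H, H + I),
                 b = rnorm(4 * H, 0, 0.5),
                 Wy = matrix(rnorm(C * H, 0, 0.5), C, H),
                 by = rnorm(C, 0, 0.5)))
}

test_that("Glorot initialisation has the stated moments and is seedable", {
  H <- 5; I <- 9
  n_draw <- 1e5
  W <- glorot_init(1000, 100, input_size = I + H, num_hidden = H, seed = 4)
  draws <- as.vector(W)[1:n_draw]
  v_target <- 2 / ((I + H) + 4 * H)
  se <- sqrt(v_target / n_draw)
  expect_lt(abs(mean(draws)), 3 * se)
  expect_lt(abs(var(draws) - v_target) / v_target, 0.05)
  expect_identical(glorot_init(10, 10, 14, 5, seed = 1),
                   glorot_init(10, 10, 14, 5, seed = 1))
})

test_that("unit-forget-gate bias stacks ones then zeros", {
  expect_equal(unit_forget_bias_init(1), c(1, 0, 0, 0))
  expect_equal(unit_forget_bias_init(3)[1:3], c(1, 1, 1))
  expect_equal(sum(unit_forget_bias_init(8)), 8)
  # flatten/unflatten round-trips the documented block ordering
  p <- init_lstm_params(9, 3, 7, seed = 2)
  expect_equal(futsalr:::unflatten_params(futsalr:::flatten_params(p), p), p,
               ignore_attr = TRUE)
  expect_equal(p$b, unit_forget_bias_init(3))
})

test_that("the zero-parameter cell halves state and gates at 0.5", {
  H <- 4
  params <- list(W = matrix(0, 4 * H, H + 2), b = rep(0, 4 * H))
  st <- list(h = rep(0.3, H), C = rep(1, H))
  out <- lstm_cell_step(params, st, c(5, -2))
  expect_equal(out$f, rep(0.5, H))
  expect_equal(out$i, rep(0.5, H))
  expect_equal(out$o, rep(0.5, H))
  expect_equal(out$g, rep(0, H))
  expect_equal(out$C, 0.5 * st$C)
  expect_equal(out$h, 0.5 * tanh(out$C))
})

test_that("a saturated forget gate gives perfect memory", {
  H <- 3
  params <- rand_params(H, 2, 2, seed = 8)
  params$b[1:H] <- 50                           # forget-gate block
  st <- list(h = rnorm(H), C = rnorm(H))
  x <- rnorm(2)
  out <- lstm_cell_step(params, st, x)
  expect_equal(out$C, st$C + out$i * out$g, tolerance = 1e-12)
})

test_that("cell step matches an independent scalar re-evaluation", {
  H <- 3; I <- 2
  params <- rand_params(H, I, 2, seed = 5)
  st <- list(h = rnorm(H), C = rnorm(H))
  x <- rnorm(I)
  out <- lstm_cell_step(params, st, x)
  # scalar-by-scalar: no vector ops at all
  hx <- c(st$h, x)
  for (u in 1:H) {
    af <- params$b[u];         for (j in 1:(H + I)) af <- af + params$W[u, j] * hx[j]
    ai <- params$b[H + u];     for (j in 1:(H + I)) ai <- ai + params$W[H + u, j] * hx[j]
    ag <- params$b[2 * H + u]; for (j in 1:(H + I)) ag <- ag + params$W[2 * H + u, j] * hx[j]
    ao <- params$b[3 * H + u]; for (j in 1:(H + I)) ao <- ao + params$W[3 * H + u, j] * hx[j]
    f <- 1 / (1 + exp(-af)); i <- 1 / (1 + exp(-ai))
    g <- tanh(ag);           o <- 1 / (1 + exp(-ao))
    C <- f * st$C[u] + i * g
    expect_equal(out$C[u], C, tolerance = 1e-12)
    expect_equal(out$h[u], o * tanh(C), tolerance = 1e-12)
  }
  # gate ranges
  expect_true(all(out$f > 0 & out$f < 1))
  expect_true(all(out$o > 0 & out$o < 1))
  expect_true(all(abs(out$h) < 1))
})

test_that("compiled forward pass equals composed R cell steps", {
  H <- 4; I <- 3; Tn <- 6
  params <- rand_params(H, I, 3, seed = 6)
  X <- matrix(rnorm(I * Tn), I, Tn)
  st <- list(h = numeric(H), C = numeric(H))
  for (t in seq_len(Tn)) st <- lstm_cell_step(params, st, X[, t])
  fw <- futsalr:::lstm_forward_cpp(params$W, params$b, params$Wy, params$by,
                                   X, 0L)
  expect_equal(fw$h[, Tn], st$h, tolerance = 1e-12)
  expect_equal(fw$C[, Tn], st$C, tolerance = 1e-12)
  expect_equal(sum(fw$prob), 1, tolerance = 1e-12)
})

test_that("analytic BPTT gradient matches central finite differences", {
  H <- 2; I <- 3; Tn <- 3; C <- 3
  params <- rand_params(H, I, C, seed = 7)
  X <- matrix(rnorm(I * Tn), I, Tn)
  for (rd in c(0L, 1L)) {
    g <- futsalr:::lstm_grad_cpp(params$W, params$b, params$Wy, params$by,
                                 X, 1L, rd)
    ga <- c(as.vector(g$dW), g$db, as.vector(g$dWy), g$dby)
    th <- futsalr:::flatten_params(params)
    lossf <- function(v) {
      q <- futsalr:::unflatten_params(v, params)
      futsalr:::lstm_grad_cpp(q$W, q$b, q$Wy, q$by, X, 1L, rd)$loss
    }
    gn <- vapply(seq_along(th), function(j) {
      e <- 1e-6
      tp <- th; tp[j] <- tp[j] + e
      tm <- th; tm[j] <- tm[j] - e
      (lossf(tp) - lossf(tm)) / (2 * e)
    }, 0)
    expect_lt(sqrt(sum((ga - gn)^2)) / sqrt(sum(gn^2)), 1e-5)
  }
})

test_that("training separates two constant distinct sequences", {
  mk <- function(id, action, value) {
    tibble::tibble(trial_id = id, action = action,
                   seq = list(matrix(value, 1, 30)))
  }
  ds <- dplyr::bind_rows(
    purrr::map(1:4, ~mk(paste0("w", .x), "walking", 0.1)),
    purrr::map(1:4, ~mk(paste0("r", .x), "running", 0.9)))
  m <- fit_lstm(ds, hidden = 4, epochs = 150, batch = 4, lr = 0.02, seed = 1)
  pred <- predict(m, ds)
  expect_equal(pred$pred, pred$truth)
  expect_lt(m$loss_trace[length(m$loss_trace)], m$loss_trace[1])
})

test_that("LSTM training is deterministic under a fixed seed", {
  f <- corpus_features(duration_s = 120, seed = 31)
  ds <- assemble_dataset(f, "sequence")
  m1 <- fit_lstm(ds, hidden = 4, epochs = 2, seed = 3)
  m2 <- fit_lstm(ds, hidden = 4, epochs = 2, seed = 3)
  expect_identical(m1$params, m2$params)
  expect_identical(predict(m1, ds), predict(m2, ds))
})
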