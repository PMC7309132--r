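emg_stream <- function(time, value = 1) {
  chans <- stats::setNames(rep(list(rep_len(value, length(time))), 6),
                           c("r_quad", "l_quad", "r_hams", "l_hams",
                             "r_gluteo", "l_gluteo"))
  out <- tibble::as_tibble(chans)
  out$time <- time
  out
}

test_that("EMG regularisation reproduces constants and fills dropped seconds", {
  st <- emg_stream(seq(0, 9.96, by = 0.04), value = 7)
  out <- regularize_emg(st)
  expect_equal(nrow(out), 250)
  expect_equal(diff(out$time), rep(0.04, 249))
  expect_equal(out$r_quad, rep(7, 250), tolerance = 1e-9)

  # drop one interior second entirely: the uniform grid is still complete
  keep <- !(st$time >= 4 & st$time < 5)
  out2 <- regularize_emg(st[keep, ])
  expect_equal(nrow(out2), 250)

  expect_error(regularize_emg(st[1:3, ]), "4")
})

test_that("near-interpolating spline recovers a thinned linear ramp", {
  set.seed(7)
  t_full <- seq(0, 9.96, by = 0.04)
  keep <- sort(sample(seq_along(t_full), round(0.8 * length(t_full))))
  keep[1] <- 1; keep[length(keep)] <- length(t_full)
  st <- emg_stream(t_full[keep])
  for (ch in c("r_quad", "l_quad", "r_hams", "l_hams", "r_gluteo",
               "l_gluteo")) {
    st[[ch]] <- 2 * st$time + 1
  }
  out <- regularize_emg(st, smoothing = 1 - 1e-12)
  expect_lt(max(abs(out$r_quad - (2 * out$time + 1))), 1e-6)
})

test_that("positional resampling is rate-exact, DC-exact and delay-free", {
  n <- 1800
  t30 <- (0:(n - 1)) / 30
  st <- tibble::tibble(idx = 1:n, x = rep(3.3, n), y = sin(2 * pi * 1 * t30),
                       w = rep(90, n))
  out <- resample_positional(st)
  expect_equal(nrow(out), 1500)                    # 5/6 of 1800
  expect_equal(attr(out, "rate_hz"), 25)
  expect_lt(max(abs(out$x - 3.3)), 0.05)           # DC gain 1 (edge-padded)
  # 1 Hz sits in the passband: amplitude within 1%, no residual group delay
  t25 <- (out$idx - 1) / 25
  interior <- out$idx > 50 & out$idx < 1450
  err <- out$y[interior] - sin(2 * pi * 1 * t25[interior])
  expect_lt(max(abs(err)), 0.01)

  expect_error(resample_positional(st[c(1:5, 7:10), ]), "regularise")
})

test_that("angular channel resamples across the 360-degree wrap", {
  n <- 600
  # heading oscillating around north: +/- 5 degrees about 0/360
  w <- (5 * sin(2 * pi * (0:(n - 1)) / 300)) %% 360
  st <- tibble::tibble(idx = 1:n, x = 0, y = 0, w = w)
  out <- resample_positional(st)
  dev <- pmin(out$w, 360 - out$w)
  expect_lt(max(dev), 5.5)                          # no wrap tearing
})

test_that("segmentation yields one trial per constant-label run", {
  fr <- make_frames(rep("walking", 100))
  tr <- segment_trials(fr)
  expect_equal(length(unique(tr$trial_id)), 1)
  expect_equal(nrow(tr), 100)

  fr2 <- make_frames(c("walking", "walking", "passing", "passing", "passing"))
  tr2 <- segment_trials(fr2)
  lens <- table(tr2$trial_id)
  expect_equal(as.vector(lens), c(2, 3))
  expect_equal(sum(lens), nrow(fr2))                # frame mass conserved
})

test_that("aligned session keeps one label per frame and segment bookkeeping", {
  s <- sim_session(session_config(duration_s = 60, rng_seed = 21))
  fr <- align_session(s)
  expect_equal(nrow(fr), 1500)                      # 60 s at 25 Hz
  expect_true(all(fr$action %in% futsal_actions()))
  tr <- segment_trials(fr)
  expect_equal(length(unique(tr$trial_id)), nrow(s$script))
  expect_equal(rle(fr$action)$values, s$script$action)
})

test_that("short-trial filter applies the threshold and the class rescue", {
  fr <- make_frames(c(rep("walking", 24), rep("passing", 30),
                      rep("walking", 25), rep("passing", 40),
                      rep("walking", 26)))
  tr <- segment_trials(fr)
  kept <- filter_short_trials(tr)
  lens <- table(kept$trial_id)
  expect_setequal(as.vector(lens), c(30, 25, 40, 26))

  # all trials >= 25: identity
  expect_equal(filter_short_trials(kept), kept)

  # a class whose trials are all short keeps its longest, with a warning
  fr2 <- make_frames(c(rep("shooting", 10), rep("walking", 30),
                       rep("shooting", 15), rep("walking", 40)))
  tr2 <- segment_trials(fr2)
  expect_warning(kept2 <- filter_short_trials(tr2), "shooting")
  sh <- kept2[kept2$action == "shooting", ]
  expect_equal(nrow(sh), 15)
})

test_that("long-trial splitting follows the chunk-and-merge rule", {
  lens_after <- function(n, max_frames) {
    fr <- make_frames(rep("walking", n))
    tr <- split_long_trials(segment_trials(fr), max_frames = max_frames)
    as.vector(table(factor(tr$trial_id, unique(tr$trial_id))))
  }
  expect_equal(lens_after(300, 100), c(100, 100, 100))
  expect_equal(lens_after(90, 100), 90)
  expect_equal(lens_after(230, 100), c(100, 100, 30))   # 30 >= 25 stands
  expect_equal(lens_after(210, 100), c(100, 110))       # 10 < 25 merges back
  expect_equal(sum(lens_after(230, 100)), 230)          # mass conserved
})

test_that("preprocessing is deterministic given its inputs", {
  s <- sim_session(session_config(duration_s = 30, rng_seed = 8))
  expect_identical(suppressWarnings(preprocess_session(s)),
                   suppressWarnings(preprocess_session(s)))
})
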