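# Shared fixtures, built once per test run and cached.
.fixture_cache <- new.env(parent = emptyenv())

# Normalised feature table for a simulated session of the given length.
corpus_features <- function(duration_s = 600, seed = 42) {
  key <- sprintf("corpus_%d_%d", duration_s, seed)
  if (is.null(.fixture_cache[[key]])) {
    s <- sim_session(session_config(duration_s = duration_s, rng_seed = seed))
    tr <- suppressWarnings(preprocess_session(s))
    .fixture_cache[[key]] <- normalize_emg(compute_features(tr))
  }
  .fixture_cache[[key]]
}

cache_put <- function(key, value) assign(key, value, envir = .fixture_cache)
cache_get <- function(key) .fixture_cache[[key]]

# A minimal frames tibble (aligned-stream shape) built from vectors.
make_frames <- function(action, x = NULL, y = NULL, w = 0) {
  n <- length(action)
  if (is.null(x)) x <- seq(0, 1, length.out = n)
  if (is.null(y)) y <- rep(0, n)
  df <- tibble::tibble(t = (seq_len(n) - 1) / 25, x = x, y = y,
                       w = rep_len(w, n))
  for (ch in c("r_quad", "l_quad", "r_hams", "l_hams", "r_gluteo",
               "l_gluteo")) {
    df[[ch]] <- seq_len(n) / n * 10
  }
  df$action <- action
  df
}

# Frame-major dataset with gaussian class clusters, for classifier tests.
make_cluster_dataset <- function(n_per_class = 30, classes = c("walking", "running"),
                                 sep = 4, sd = 0.5, frames_per_trial = 5,
                                 seed = 1) {
  stopifnot(n_per_class %% frames_per_trial == 0)
  withr_seed <- function(code) { set.seed(seed); code }
  withr_seed({
    rows <- lapply(seq_along(classes), function(i) {
      n <- n_per_class
      tibble::tibble(
        trial_id = rep(sprintf("%s_%02d", classes[i],
                               seq_len(n / frames_per_trial)),
                       each = frames_per_trial),
        action = classes[i],
        frame = rep(seq_len(frames_per_trial), n / frames_per_trial),
        v = stats::rnorm(n, i * sep / 5, sd / 5),
        d = stats::rnorm(n, (4 - i) * sep / 5, sd / 5),
        theta = stats::rnorm(n, 0, sd / 5)
      )
    })
    out <- dplyr::bind_rows(rows)
    attr(out, "features") <- c("v", "d", "theta")
    out
  })
}
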