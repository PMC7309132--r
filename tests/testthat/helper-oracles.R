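# Independent brute-force oracles used by the unit and acceptance tests.

# Scalar evaluation of the entropy-weighted fused recursion: plain loops,
# no shared code with the package implementation.
oracle_dbmm <- function(base_seq, w0) {
  Tn <- nrow(base_seq[[1]]); cc <- ncol(base_seq[[1]]); N <- length(base_seq)
  w <- w0
  prior <- rep(1 / cc, cc)
  fused <- matrix(0, Tn, cc)
  for (t in seq_len(Tn)) {
    if (t > 1) {
      conf <- numeric(N)
      for (i in 1:N) {
        h <- 0
        for (j in 1:cc) {
          p <- base_seq[[i]][t, j]
          if (p > 0) h <- h - p * log(p)
        }
        conf[i] <- 1 - h / log(cc)
      }
      z <- numeric(N)
      for (i in 1:N) z[i] <- conf[i] * w[i]
      if (sum(z) > 0) w <- z / sum(z)
    }
    mix <- numeric(cc)
    for (j in 1:cc) {
      for (i in 1:N) mix[j] <- mix[j] + w[i] * base_seq[[i]][t, j]
    }
    unnorm <- prior * mix
    beta <- 1 / sum(unnorm)
    for (j in 1:cc) fused[t, j] <- unnorm[j] * beta
    prior <- fused[t, ]
  }
  fused
}

# A dbmm_model skeleton around externally supplied posterior sequences.
dbmm_shell <- function(N, classes, w0 = rep(1 / N, N)) {
  structure(list(models = vector("list", N), bases = paste0("b", 1:N),
                 classes = classes, init_weights = w0, transition = NULL),
            class = "dbmm_model")
}

rand_posterior <- function(n, cc) {
  p <- matrix(stats::rexp(n * cc), n, cc)
  p / rowSums(p)
}
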