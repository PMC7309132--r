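#' @importFrom Rcpp sourceCpp
#' @importFrom rlang .data
#' @importFrom utils head tail
#' @useDynLib futsalr, .registration = TRUE
NULL

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

# Numerically stable softmax over rows of a matrix (or a single vector).
softmax <- function(z) {
  if (is.null(dim(z))) z <- matrix(z, nrow = 1)
  m <- apply(z, 1, max)
  e <- exp(z - m)
  e / rowSums(e)
}

# log(sum(exp(x))) without overflow
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Floor a probability vector (or matrix, row-wise) at eps and renormalize.
# Classifier posteriors must never carry exact zeros: the DBMM temporal
# product would annihilate a class permanently.
floor_posterior <- function(p, eps = 1e-6) {
  if (is.null(dim(p))) {
    p <- pmax(p, eps)
    return(p / sum(p))
  }
  p <- pmax(p, eps)
  p / rowSums(p)
}

# Round-half-up: round(10.5) in base R goes to 10 (banker's rounding) but the
# stratified 70% allocation requires 15 -> 11.
round_half_up <- function(x) floor(x + 0.5)

# Wrap angles (radians) into (-pi, pi].
wrap_angle <- function(a) {
  w <- (a + pi) %% (2 * pi) - pi
  ifelse(w == -pi, pi, w)
}

# Deterministic per-stage seed fan-out: one top-level seed yields
# independent, reproducible sub-seeds for each named stage/repeat.
derive_seed <- function(seed, stage, index = 0L) {
  offsets <- c(simulate = 11L, split = 23L, ann = 37L, lstm = 41L,
               dbmm = 53L, benchmark = 67L, other = 71L)
  off <- offsets[[match.arg(stage, names(offsets))]]
  as.integer((as.numeric(seed) * 1009 + off * 97 + as.numeric(index) * 131) %%
               2147483629)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
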