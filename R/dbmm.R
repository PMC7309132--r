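#' Entropy-based confidence of a posterior
#'
#' One minus the Shannon entropy of the posterior normalised by its maximum
#' `log(c)`: 0 for a uniform (maximally uncertain) posterior, 1 for a
#' one-hot (fully decisive) one. This is the uncertainty measure the
#' ensemble uses to weight its base classifiers online.
#'
#' @param posterior Probability vector (or matrix, row-wise).
#' @param c Number of classes; defaults to the posterior length.
#' @return Confidence value(s) in `[0, 1]`.
#' @export
#' @examples
#' entropy_confidence(rep(1 / 7, 7))   # 0
#' entropy_confidence(c(1, 0, 0, 0, 0, 0, 0))   # 1
entropy_confidence <- function(posterior, c = NULL) {
  if (is.null(dim(posterior))) posterior <- matrix(posterior, nrow = 1)
  if (is.null(c)) c <- ncol(posterior)
  pl <- posterior * log(posterior)
  pl[posterior == 0] <- 0
  h <- -rowSums(pl)
  conf <- 1 - h / log(c)
  if (length(conf) == 1) conf[[1]] else conf
}

#' Bayesian update of the base-classifier weights
#'
#' Each classifier's weight is multiplied by its current entropy-confidence
#' and the set is renormalised; the previous weights act as the prior. If
#' every classifier is maximally uncertain (all confidences zero) the
#' weights are carried over unchanged.
#'
#' @param prev_weights Weight vector from the previous frame (simplex).
#' @param base_posteriors List of per-classifier posterior vectors for the
#'   current frame.
#' @param c Number of classes (for the entropy normalisation).
#' @return Updated weight vector on the simplex.
#' @export
update_weights <- function(prev_weights, base_posteriors, c = NULL) {
  conf <- vapply(base_posteriors, entropy_confidence, 0, c = c)
  z <- conf * prev_weights
  s <- sum(z)
  if (s <= 0) return(prev_weights)
  z / s
}

#' One step of the dynamic Bayesian mixture recursion
#'
#' The fused posterior is the elementwise product of the temporal prior
#' with the weighted mixture of base posteriors, renormalised by the factor
#' `beta`:
#' `P(C_t | A)  =  beta * P(C_t | C_{t-1}) * sum_i w_i,t P_i(A | C_t)`.
#' The prior is uniform at the first frame and the previous fused
#' posterior afterwards, unless an explicit class-transition matrix is
#' supplied (then `prior = t(P) %*% prev`).
#'
#' @param base_posteriors List of per-classifier posterior vectors.
#' @param weights Current classifier weights (simplex).
#' @param prev_posterior Fused posterior of the previous frame, or `NULL`
#'   at `t = 1`.
#' @param transition Optional row-stochastic class-transition matrix.
#' @return The fused posterior vector.
#' @export
dbmm_step <- function(base_posteriors, weights, prev_posterior = NULL,
                      transition = NULL) {
  mix <- Reduce(`+`, Map(`*`, base_posteriors, weights))
  c <- length(mix)
  prior <- if (is.null(prev_posterior)) {
    rep(1 / c, c)
  } else if (is.null(transition)) {
    prev_posterior
  } else {
    as.numeric(crossprod(transition, prev_posterior))
  }
  fused <- prior * mix
  fused / sum(fused)
}

#' Fit the Dynamic Bayesian Mixture Model ensemble
#'
#' Fits the base classifiers (by default naive Bayes, the frame-wise ANN
#' and k-NN) on 90% of the training trials and sets the initial classifier
#' weights from each base's mean entropy-confidence on the held-out 10%
#' fold, normalised to the simplex. Optionally estimates an empirical
#' class-transition matrix from row-normalised bigram counts of the
#' training frame labels.
#'
#' @param train Frame-major dataset tibble.
#' @param bases Character vector naming the base learners, a subset of
#'   `c("nb", "ann", "knn")`.
#' @param use_transition Estimate and use the empirical transition matrix
#'   instead of the posterior-as-prior rule.
#' @param seed Integer seed (fold selection and ANN initialisation).
#' @param ann_args,knn_args,nb_args Extra arguments for the base fitters.
#' @return An object of class `dbmm_model`.
#' @export
fit_dbmm <- function(train, bases = c("nb", "ann", "knn"),
                     use_transition = FALSE, seed = 1,
                     ann_args = list(), knn_args = list(), nb_args = list()) {
  stopifnot(length(bases) >= 1, all(bases %in% c("nb", "ann", "knn")))
  ids <- unique(train$trial_id)
  hold <- with_local_seed(derive_seed(seed, "dbmm"),
                          sample(ids, max(1, round(0.1 * length(ids)))))
  fit_part <- train[!train$trial_id %in% hold, , drop = FALSE]
  hold_part <- train[train$trial_id %in% hold, , drop = FALSE]
  if (length(unique(fit_part$action)) < length(unique(train$action))) {
    fit_part <- train                      # unlucky fold: fit on everything
    hold_part <- train
  }
  for (a in c("features", "layout", "mask")) {
    attr(fit_part, a) <- attr(train, a)
    attr(hold_part, a) <- attr(train, a)
  }
  fitters <- list(
    nb  = function() do.call(fit_nb, c(list(fit_part), nb_args)),
    ann = function() do.call(fit_ann, c(list(fit_part),
                                        ann_args,
                                        if (is.null(ann_args$seed))
                                          list(seed = derive_seed(seed, "ann")))),
    knn = function() do.call(fit_knn, c(list(fit_part), knn_args))
  )
  models <- lapply(bases, function(b) fitters[[b]]())
  names(models) <- bases
  classes <- dataset_classes(train)
  conf <- vapply(models, function(m) {
    P <- posterior_matrix(m, hold_part)
    mean(entropy_confidence(P))
  }, 0)
  w0 <- if (sum(conf) > 0) unname(conf / sum(conf))
        else rep(1 / length(conf), length(conf))
  transition <- if (use_transition) {
    estimate_transition(train$action, classes)
  } else NULL
  structure(list(models = models, bases = bases, classes = classes,
                 init_weights = w0, transition = transition,
                 features = models[[1]]$features),
            class = "dbmm_model")
}

# Row-normalised bigram counts of consecutive frame labels.
estimate_transition <- function(labels, classes) {
  f <- factor(labels, classes)
  tab <- table(utils::head(f, -1), utils::tail(f, -1))
  tab <- tab + 1e-9                            # keep rows stochastic
  m <- as.matrix(tab / rowSums(tab))
  dimnames(m) <- list(classes, classes)
  m
}

#' Run the DBMM recursion over one trial
#'
#' Applies [dbmm_step()] frame by frame, updating the classifier weights
#' with [update_weights()] from the second frame on. The trial label is
#' the argmax of the final-frame fused posterior (the temporal loop has by
#' then accumulated the whole trial's evidence); majority vote over frame
#' argmaxes is available as an alternative decision rule.
#'
#' @param model A fitted `dbmm_model`.
#' @param trial_frames Frame-major tibble of one trial (or a list of
#'   precomputed base posterior matrices).
#' @param decision `"final"` or `"vote"`.
#' @return A list of class `dbmm_trace`: `action` (predicted label),
#'   `posterior` (T x c fused posteriors), `weights` (T x N), `beta`
#'   (length T normalisers), `confidence` (T x N base confidences).
#' @export
classify_sequence <- function(model, trial_frames,
                              decision = c("final", "vote")) {
  decision <- match.arg(decision)
  base_P <- if (is.list(trial_frames) && !is.data.frame(trial_frames)) {
    trial_frames
  } else {
    lapply(model$models, posterior_matrix, newdata = trial_frames)
  }
  n <- nrow(base_P[[1]])
  c <- length(model$classes)
  N <- length(base_P)
  fused <- matrix(0, n, c, dimnames = list(NULL, model$classes))
  wts <- matrix(0, n, N)
  beta <- numeric(n)
  # per-frame base confidences, vectorised over frames
  confs <- matrix(vapply(base_P, function(P) entropy_confidence(P, c = c),
                         numeric(n)), n, N)
  w <- model$init_weights
  prev <- rep(1 / c, c)
  for (t in seq_len(n)) {
    if (t > 1) {
      z <- confs[t, ] * w
      s <- sum(z)
      if (s > 0) w <- z / s
    }
    mix <- base_P[[1]][t, ] * w[1]
    if (N > 1) for (i in 2:N) mix <- mix + base_P[[i]][t, ] * w[i]
    prior <- if (t == 1) rep(1 / c, c)
             else if (is.null(model$transition)) prev
             else as.numeric(crossprod(model$transition, prev))
    unnorm <- prior * mix
    beta[t] <- 1 / sum(unnorm)
    prev <- unnorm * beta[t]
    fused[t, ] <- prev
    wts[t, ] <- w
  }
  pred <- if (decision == "final" || n == 1) {
    model$classes[which.max(fused[n, ])]
  } else {
    votes <- model$classes[max.col(fused, ties.method = "first")]
    names(sort(table(votes), decreasing = TRUE))[1]
  }
  structure(list(action = pred, posterior = fused, weights = wts,
                 beta = beta, confidence = confs),
            class = "dbmm_trace")
}

#' Classify every trial of a dataset with the DBMM
#'
#' @param object A fitted `dbmm_model`.
#' @param newdata Frame-major dataset tibble.
#' @param decision Decision rule, see [classify_sequence()].
#' @param ... Unused.
#' @return A tibble `trial_id`, `truth`, `pred`.
#' @export
predict.dbmm_model <- function(object, newdata,
                               decision = c("final", "vote"), ...) {
  decision <- match.arg(decision)
  # Base posteriors for all frames at once (k-NN etc. are batch-efficient),
  # then the temporal recursion per trial.
  base_P <- lapply(object$models, posterior_matrix, newdata = newdata)
  split_idx <- split(seq_len(nrow(newdata)), newdata$trial_id)
  res <- purrr::imap(split_idx, function(ix, id) {
    tr <- classify_sequence(object,
                            lapply(base_P, function(P) P[ix, , drop = FALSE]),
                            decision = decision)
    tibble::tibble(trial_id = id, truth = newdata$action[ix[1]],
                   pred = tr$action)
  })
  dplyr::bind_rows(res)
}

#' @export
tidy.dbmm_model <- function(x, ...) {
  tibble::tibble(base = x$bases, init_weight = x$init_weights)
}

#' @export
glance.dbmm_model <- function(x, ...) {
  tibble::tibble(n_bases = length(x$bases),
                 n_classes = length(x$classes),
                 uses_transition = !is.null(x$transition))
}

#' @export
print.dbmm_model <- function(x, ...) {
  cat("<dbmm_model> bases:", paste(x$bases, collapse = ", "),
      "| init weights:", paste(sprintf("%.3f", x$init_weights), collapse = ", "),
      "\n")
  invisible(x)
}
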