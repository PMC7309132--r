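#' Class posterior probabilities from a fitted base classifier
#'
#' Every base learner of the ensemble emits a proper posterior per frame:
#' nonnegative, summing to one, floored at `eps` and renormalised so no
#' class probability is ever exactly zero (the temporal product of the
#' ensemble must not annihilate a class).
#'
#' @param model A fitted `nb_model`, `knn_model` or `ann_model`.
#' @param newdata Frame-major dataset tibble (or bare feature matrix).
#' @param ... Unused.
#' @return Numeric matrix, one row per frame, one column per class (column
#'   names are the class ids).
#' @export
posterior_matrix <- function(model, newdata, ...) {
  UseMethod("posterior_matrix")
}

dataset_matrix <- function(model, newdata) {
  if (is.matrix(newdata)) {
    m <- newdata
  } else {
    m <- as.matrix(newdata[, model$features, drop = FALSE])
  }
  storage.mode(m) <- "double"
  m
}

dataset_classes <- function(train) {
  futsal_actions()[futsal_actions() %in% unique(train$action)]
}

# ---------------------------------------------------------------- naive Bayes

#' Fit a Gaussian naive Bayes base classifier
#'
#' Per class and per feature a univariate Gaussian density is fitted
#' (features treated as independent given the class); class priors are the
#' class frame frequencies. Variances are floored at `var_floor` so
#' single-frame or constant classes stay proper.
#'
#' @param train Frame-major dataset tibble (`trial_id`, `action`, features).
#' @param var_floor Minimum per-feature variance.
#' @return An object of class `nb_model`.
#' @export
fit_nb <- function(train, var_floor = 1e-9) {
  feats <- attr(train, "features") %||%
    intersect(feature_names(), names(train))
  classes <- dataset_classes(train)
  X <- as.matrix(train[, feats, drop = FALSE])
  y <- train$action
  mu <- matrix(0, length(classes), length(feats),
               dimnames = list(classes, feats))
  va <- mu
  for (cl in classes) {
    Xc <- X[y == cl, , drop = FALSE]
    mu[cl, ] <- colMeans(Xc)
    v <- apply(Xc, 2, stats::var)
    v[!is.finite(v)] <- 0
    va[cl, ] <- pmax(v, var_floor)
  }
  structure(list(classes = classes, features = feats,
                 prior = as.numeric(table(factor(y, classes)) / length(y)),
                 mu = mu, var = va),
            class = "nb_model")
}

#' @rdname posterior_matrix
#' @param eps Posterior floor.
#' @export
posterior_matrix.nb_model <- function(model, newdata, eps = 1e-6, ...) {
  X <- dataset_matrix(model, newdata)
  n <- nrow(X)
  ll <- matrix(0, n, length(model$classes),
               dimnames = list(NULL, model$classes))
  logp <- log(pmax(model$prior, 1e-300))
  for (j in seq_along(model$classes)) {
    sd_j <- sqrt(model$var[j, ])
    lj <- stats::dnorm(X, rep(model$mu[j, ], each = n),
                       rep(sd_j, each = n), log = TRUE)
    ll[, j] <- rowSums(lj) + logp[j]
  }
  floor_posterior(softmax(ll), eps)
}

#' @export
tidy.nb_model <- function(x, ...) {
  out <- tidyr::pivot_longer(
    dplyr::bind_cols(tibble::tibble(action = x$classes),
                     tibble::as_tibble(x$mu)),
    -"action", names_to = "feature", values_to = "mean")
  out$variance <- as.vector(t(x$var))
  out$prior <- rep(x$prior, each = length(x$features))
  out
}

# ------------------------------------------------------------------------ kNN

#' Fit a k-nearest-neighbour base classifier
#'
#' Stores the training frames; the posterior for a query frame is the vote
#' proportion among its `k` Euclidean nearest training frames (distance
#' ties broken by training order), floored and renormalised.
#'
#' @param train Frame-major dataset tibble.
#' @param k Number of neighbours (odd by default).
#' @return An object of class `knn_model`.
#' @export
fit_knn <- function(train, k = 5) {
  stopifnot(k >= 1)
  feats <- attr(train, "features") %||%
    intersect(feature_names(), names(train))
  X <- as.matrix(train[, feats, drop = FALSE])
  storage.mode(X) <- "double"
  structure(list(classes = dataset_classes(train), features = feats,
                 X = X, y = train$action, k = as.integer(k)),
            class = "knn_model")
}

#' @rdname posterior_matrix
#' @export
posterior_matrix.knn_model <- function(model, newdata, eps = 1e-6, ...) {
  Xq <- dataset_matrix(model, newdata)
  k <- min(model$k, nrow(model$X))
  idx <- knn_neighbors_cpp(model$X, Xq, k)      # m x k, 1-based, stable ties
  votes <- matrix(model$y[idx], nrow(Xq), k)
  P <- matrix(0, nrow(Xq), length(model$classes),
              dimnames = list(NULL, model$classes))
  for (j in seq_along(model$classes)) {
    P[, j] <- rowSums(votes == model$classes[j]) / k
  }
  floor_posterior(P, eps)
}

#' @export
glance.knn_model <- function(x, ...) {
  tibble::tibble(n_train = nrow(x$X), k = x$k,
                 n_classes = length(x$classes))
}

# ------------------------------------------------------------------------ ANN

#' Fit the frame-wise artificial neural network
#'
#' One hidden layer with hyperbolic-tangent-sigmoid activation and a
#' normalised-exponential (softmax) output, trained frame-wise by
#' full-batch gradient descent on the cross-entropy (the delta rule
#' generalised through backpropagation). Deterministic given `seed`.
#'
#' @param train Frame-major dataset tibble.
#' @param hidden Hidden-layer width.
#' @param epochs Gradient-descent epochs.
#' @param lr Learning rate.
#' @param seed Integer seed for the weight initialisation.
#' @return An object of class `ann_model` with the loss trace in
#'   `$loss_trace`.
#' @export
fit_ann <- function(train, hidden = 20, epochs = 100, lr = 0.01, seed = 1) {
  feats <- attr(train, "features") %||%
    intersect(feature_names(), names(train))
  classes <- dataset_classes(train)
  X <- as.matrix(train[, feats, drop = FALSE])
  n <- nrow(X); p <- ncol(X); C <- length(classes)
  Y <- outer(train$action, classes, `==`) * 1
  with_local_seed(seed, {
    lim1 <- sqrt(6 / (p + hidden)); lim2 <- sqrt(6 / (hidden + C))
    W1 <- matrix(stats::runif(p * hidden, -lim1, lim1), p, hidden)
    b1 <- numeric(hidden)
    W2 <- matrix(stats::runif(hidden * C, -lim2, lim2), hidden, C)
    b2 <- numeric(C)
    loss_trace <- numeric(epochs)
    for (ep in seq_len(epochs)) {
      H <- tanh(sweep(X %*% W1, 2, b1, `+`))
      P <- softmax(sweep(H %*% W2, 2, b2, `+`))
      loss <- -mean(rowSums(Y * log(pmax(P, 1e-300))))
      if (!is.finite(loss)) {
        stop("ANN training diverged (non-finite loss) at epoch ", ep,
             call. = FALSE)
      }
      loss_trace[ep] <- loss
      dZ2 <- (P - Y) / n
      dW2 <- crossprod(H, dZ2); db2 <- colSums(dZ2)
      dH <- tcrossprod(dZ2, W2) * (1 - H^2)
      dW1 <- crossprod(X, dH); db1 <- colSums(dH)
      W1 <- W1 - lr * dW1; b1 <- b1 - lr * db1
      W2 <- W2 - lr * dW2; b2 <- b2 - lr * db2
    }
    structure(list(classes = classes, features = feats,
                   W1 = W1, b1 = b1, W2 = W2, b2 = b2,
                   lr = lr, epochs = epochs, loss_trace = loss_trace),
              class = "ann_model")
  })
}

#' @rdname posterior_matrix
#' @export
posterior_matrix.ann_model <- function(model, newdata, eps = 1e-6, ...) {
  X <- dataset_matrix(model, newdata)
  H <- tanh(sweep(X %*% model$W1, 2, model$b1, `+`))
  P <- softmax(sweep(H %*% model$W2, 2, model$b2, `+`))
  colnames(P) <- model$classes
  floor_posterior(P, eps)
}

#' @export
glance.ann_model <- function(x, ...) {
  tibble::tibble(hidden = ncol(x$W1), epochs = x$epochs, lr = x$lr,
                 final_loss = x$loss_trace[length(x$loss_trace)])
}

# --------------------------------------------------------- trial-level labels

#' Classify trials with a frame-wise base classifier
#'
#' The trial label is the argmax of the mean frame posterior (the rule used
#' when the frame-wise ANN stands alone).
#'
#' @param model A fitted base classifier.
#' @param dataset Frame-major dataset tibble.
#' @return A tibble `trial_id`, `truth`, `pred`.
#' @export
classify_trials_framewise <- function(model, dataset) {
  P <- posterior_matrix(model, dataset)
  df <- tibble::tibble(trial_id = dataset$trial_id, truth = dataset$action)
  means <- rowsum(P, df$trial_id)              # rows sorted by trial_id
  means <- means / as.vector(table(df$trial_id))
  pred <- model$classes[max.col(means, ties.method = "first")]
  truth <- df$truth[!duplicated(df$trial_id)]
  names(truth) <- df$trial_id[!duplicated(df$trial_id)]
  tibble::tibble(trial_id = rownames(means),
                 truth = unname(truth[rownames(means)]),
                 pred = pred)
}
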