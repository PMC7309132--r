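#' Glorot (uniform) weight initialisation
#'
#' Zero-mean uniform draw on `[-sqrt(6/(in+out)), +sqrt(6/(in+out))]`, so
#' the variance is `2 / (in + out)`. For LSTM input weights the fan-out is
#' `4 * num_hidden` (the four stacked gate blocks).
#'
#' @param nrow,ncol Shape of the weight matrix.
#' @param input_size Fan-in.
#' @param num_hidden Hidden units; fan-out is `4 * num_hidden`.
#' @param seed Optional integer seed (draws are then reproducible).
#' @return `nrow x ncol` weight matrix.
#' @export
glorot_init <- function(nrow, ncol, input_size, num_hidden, seed = NULL) {
  lim <- sqrt(6 / (input_size + 4 * num_hidden))
  with_local_seed(seed,
    matrix(stats::runif(nrow * ncol, -lim, lim), nrow, ncol))
}

#' Unit-forget-gate bias initialisation
#'
#' The concatenated 4H bias vector with the forget-gate block set to one
#' and the input, candidate and output blocks set to zero. Block order
#' (here and in all LSTM parameter stacks): forget, input, candidate,
#' output.
#'
#' @param num_hidden Hidden units H.
#' @return Numeric vector of length `4 * num_hidden`.
#' @export
#' @examples
#' unit_forget_bias_init(1)   # c(1, 0, 0, 0)
unit_forget_bias_init <- function(num_hidden) {
  c(rep(1, num_hidden), rep(0, 3 * num_hidden))
}

#' One LSTM cell step
#'
#' Reference (pure-R) evaluation of the cell equations: sigmoid forget,
#' input and output gates and a tanh candidate, all affine in
#' `[h_prev, x]`; `C = f * C_prev + i * g`; `h = o * tanh(C)`.
#'
#' @param params List with `W` (4H x (H+I), gate blocks in forget, input,
#'   candidate, output order, acting on `[h; x]`) and `b` (length 4H).
#' @param state List with `h` and `C` (length-H vectors).
#' @param x Input vector (length I).
#' @return Updated state: list with `h`, `C` and the gate activations
#'   `f`, `i`, `g`, `o`.
#' @export
lstm_cell_step <- function(params, state, x) {
  H <- length(state$h)
  a <- as.numeric(params$W %*% c(state$h, x)) + params$b
  sig <- function(z) 1 / (1 + exp(-z))
  f <- sig(a[seq_len(H)])
  i <- sig(a[H + seq_len(H)])
  g <- tanh(a[2 * H + seq_len(H)])
  o <- sig(a[3 * H + seq_len(H)])
  C <- f * state$C + i * g
  h <- o * tanh(C)
  list(h = h, C = C, f = f, i = i, g = g, o = o)
}

#' Initialise LSTM parameters
#'
#' Input weights by Glorot uniform (fan-out `4H`), biases by
#' unit-forget-gate, softmax readout by Glorot uniform with fan-out equal
#' to the class count.
#'
#' @param input_size Features per frame I.
#' @param num_hidden Hidden units H.
#' @param n_classes Output classes.
#' @param seed Integer seed.
#' @return List with `W` (4H x (H+I)), `b` (4H), `Wy` (classes x H),
#'   `by` (classes).
#' @export
init_lstm_params <- function(input_size, num_hidden, n_classes, seed = 1) {
  with_local_seed(seed, {
    W <- glorot_init(4 * num_hidden, num_hidden + input_size,
                     input_size = num_hidden + input_size,
                     num_hidden = num_hidden)
    limy <- sqrt(6 / (num_hidden + n_classes))
    Wy <- matrix(stats::runif(n_classes * num_hidden, -limy, limy),
                 n_classes, num_hidden)
    list(W = W, b = unit_forget_bias_init(num_hidden),
         Wy = Wy, by = numeric(n_classes))
  })
}

flatten_params <- function(p) c(as.vector(p$W), p$b, as.vector(p$Wy), p$by)

unflatten_params <- function(v, tmpl) {
  nW <- length(tmpl$W); nb <- length(tmpl$b); nWy <- length(tmpl$Wy)
  list(W = matrix(v[seq_len(nW)], nrow(tmpl$W)),
       b = v[nW + seq_len(nb)],
       Wy = matrix(v[nW + nb + seq_len(nWy)], nrow(tmpl$Wy)),
       by = v[(nW + nb + nWy + 1):length(v)])
}

#' Train the LSTM sequence classifier
#'
#' Sequence-to-label training by backpropagation through time with Adam on
#' the softmax cross-entropy; sequences are processed one at a time (no
#' padding), gradients accumulated over shuffled mini-batches. The readout
#' is the final frame's hidden state by default (`"last"`), or the mean
#' over frames (`"mean"`). Deterministic given `seed`. If the loss turns
#' non-finite, training aborts and returns the last finite checkpoint.
#'
#' @param train Sequence-major dataset from
#'   `assemble_dataset(..., layout = "sequence")`.
#' @param hidden Hidden units.
#' @param epochs Training epochs.
#' @param batch Mini-batch size (sequences per Adam update).
#' @param lr Adam learning rate.
#' @param readout `"last"` or `"mean"`.
#' @param seed Integer seed.
#' @return An object of class `lstm_model` with the per-epoch mean loss in
#'   `$loss_trace`.
#' @export
fit_lstm <- function(train, hidden = 32, epochs = 20, batch = 16,
                     lr = 1e-3, readout = c("last", "mean"), seed = 1) {
  readout <- match.arg(readout)
  rd <- if (readout == "mean") 1L else 0L
  stopifnot("seq" %in% names(train))
  classes <- dataset_classes(train)
  y0 <- match(train$action, classes) - 1L
  I <- nrow(train$seq[[1]])
  params <- init_lstm_params(I, hidden, length(classes), seed = seed)
  theta <- flatten_params(params)
  m <- numeric(length(theta)); v <- numeric(length(theta))
  b1 <- 0.9; b2 <- 0.999; epsa <- 1e-8; step <- 0
  loss_trace <- numeric(epochs)
  n <- nrow(train)
  aborted <- FALSE
  with_local_seed(derive_seed(seed, "lstm"), {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0
      for (start in seq(1, n, by = batch)) {
        ix <- ord[start:min(start + batch - 1, n)]
        g <- numeric(length(theta))
        bl <- 0
        p <- unflatten_params(theta, params)
        for (ii in ix) {
          res <- lstm_grad_cpp(p$W, p$b, p$Wy, p$by,
                               train$seq[[ii]], y0[ii], rd)
          g <- g + c(as.vector(res$dW), res$db,
                     as.vector(res$dWy), res$dby)
          bl <- bl + res$loss
        }
        if (!is.finite(bl)) {
          warning("LSTM loss became non-finite; returning last finite checkpoint",
                  call. = FALSE)
          loss_trace <- loss_trace[seq_len(max(ep - 1, 0))]
          aborted <- TRUE
          break
        }
        g <- g / length(ix)
        ep_loss <- ep_loss + bl
        step <- step + 1
        m <- b1 * m + (1 - b1) * g
        v <- b2 * v + (1 - b2) * g^2
        mhat <- m / (1 - b1^step)
        vhat <- v / (1 - b2^step)
        theta <- theta - lr * mhat / (sqrt(vhat) + epsa)
      }
      if (aborted) break
      loss_trace[ep] <- ep_loss / n
    }
  })
  new_lstm_model(unflatten_params(theta, params), classes, readout,
                 hidden, loss_trace, seed)
}

new_lstm_model <- function(params, classes, readout, hidden, loss_trace,
                           seed) {
  structure(list(params = params, classes = classes, readout = readout,
                 hidden = hidden, loss_trace = loss_trace, seed = seed),
            class = "lstm_model")
}

#' Predict trial labels with a fitted LSTM
#'
#' @param object An `lstm_model`.
#' @param newdata Sequence-major dataset tibble.
#' @param ... Unused.
#' @return A tibble `trial_id`, `truth`, `pred`.
#' @export
predict.lstm_model <- function(object, newdata, ...) {
  rd <- if (object$readout == "mean") 1L else 0L
  p <- object$params
  pred <- vapply(newdata$seq, function(X) {
    out <- lstm_forward_cpp(p$W, p$b, p$Wy, p$by, X, rd)
    object$classes[which.max(out$prob)]
  }, character(1))
  tibble::tibble(trial_id = newdata$trial_id, truth = newdata$action,
                 pred = pred)
}

#' @export
glance.lstm_model <- function(x, ...) {
  tibble::tibble(hidden = x$hidden, readout = x$readout,
                 epochs = length(x$loss_trace),
                 final_loss = x$loss_trace[length(x$loss_trace)])
}

#' @export
print.lstm_model <- function(x, ...) {
  cat(sprintf("<lstm_model> %d hidden units, %s readout, %d epochs (final loss %.4f)\n",
              x$hidden, x$readout, length(x$loss_trace),
              x$loss_trace[length(x$loss_trace)]))
  invisible(x)
}
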