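#' Regularise an irregular EMG stream onto a uniform clock
#'
#' The EMG garment targets a nominal rate but drops samples, so the raw
#' stream is irregular. A smoothing spline is fitted per channel and
#' evaluated on a strictly uniform `target_hz` grid spanning the recorded
#' time range, guaranteeing the nominal sample count every second. Long
#' streams are fitted in overlapping time windows so knot density stays at
#' the sample level throughout.
#'
#' @param stream EMG tibble (six channels + `time`), see [read_mbody3()].
#' @param target_hz Output rate in Hz.
#' @param smoothing Fidelity parameter `p` in (0, 1]: the spline penalty is
#'   `lambda = (1 - p) / p * h^3 / 6` with `h` the mean sample spacing
#'   (the cubic-spline balance-point convention), so `p -> 1` approaches an
#'   interpolating spline. Default 0.99: heavy fidelity, light smoothing.
#' @return An EMG tibble on the uniform grid, with attribute `rate_hz`.
#' @export
regularize_emg <- function(stream, target_hz = 25, smoothing = 0.99) {
  stopifnot(all(c(emg_channels(), "time") %in% names(stream)),
            smoothing > 0, smoothing <= 1)
  tt <- stream$time
  if (length(unique(tt)) < 4) {
    stop("regularize_emg needs at least 4 distinct samples", call. = FALSE)
  }
  n_out <- floor((tt[length(tt)] - tt[1]) * target_hz) + 1L
  t_out <- tt[1] + (seq_len(n_out) - 1) / target_hz
  out <- lapply(emg_channels(), function(ch) {
    spline_eval_windowed(tt, stream[[ch]], t_out, smoothing)
  })
  names(out) <- emg_channels()
  out <- tibble::as_tibble(out)
  out$time <- t_out
  attr(out, "rate_hz") <- target_hz
  out
}

# Fit smoothing splines in overlapping windows and evaluate at t_out.
spline_eval_windowed <- function(t_in, y, t_out, smoothing,
                                 win_s = 10, margin_s = 1) {
  span <- t_in[length(t_in)] - t_in[1]
  edges <- if (span <= win_s * 1.5) c(t_in[1], t_in[length(t_in)] + 1e-9)
           else c(seq(t_in[1], t_in[length(t_in)], by = win_s),
                  t_in[length(t_in)] + 1e-9)
  if (length(edges) < 2) edges <- c(t_in[1], t_in[length(t_in)] + 1e-9)
  res <- numeric(length(t_out))
  for (i in seq_len(length(edges) - 1)) {
    a <- edges[i]; b <- edges[i + 1]
    oi <- which(t_out >= a - 1e-12 & t_out < b)
    if (length(oi) == 0) next
    ii <- which(t_in >= a - margin_s & t_in <= b + margin_s)
    if (length(unique(t_in[ii])) < 4) ii <- seq_along(t_in)
    h <- mean(diff(sort(unique(t_in[ii])))) / diff(range(t_in[ii]))
    lambda <- (1 - smoothing) / smoothing * h^3 / 6
    fit <- stats::smooth.spline(t_in[ii], y[ii], lambda = max(lambda, 1e-12),
                                all.knots = TRUE, keep.data = FALSE)
    res[oi] <- stats::predict(fit, t_out[oi])$y
  }
  res
}

#' Resample a uniform positional stream to a new rate
#'
#' Rational-ratio polyphase resampling with an FIR antialiasing lowpass
#' filter and group-delay compensation (via [signal::resample()]). The
#' stream is padded by edge replication before filtering so boundary
#' transients do not leak into the output. The angular-position channel is
#' resampled on the unit circle (cos/sin) to respect its 360-degree wrap.
#'
#' @param stream Positional tibble (`idx`, `x`, `y`, `w`), uniformly
#'   sampled at `from_hz`.
#' @param from_hz Input rate (Hz).
#' @param to_hz Output rate (Hz).
#' @return A positional tibble at `to_hz` with attribute `rate_hz`.
#' @export
resample_positional <- function(stream, from_hz = 30, to_hz = 25) {
  stopifnot(all(c("idx", "x", "y", "w") %in% names(stream)))
  n <- nrow(stream)
  if (n < 2) stop("resample_positional needs at least 2 frames", call. = FALSE)
  didx <- diff(stream$idx)
  if (length(unique(didx)) != 1) {
    stop("positional stream is not uniformly sampled; regularise it first",
         call. = FALSE)
  }
  g <- gcd_int(round(to_hz), round(from_hz))
  p <- round(to_hz) / g
  q <- round(from_hz) / g
  n_out <- floor((n - 1) * p / q) + 1L
  rs <- function(v) fir_resample(v, p, q, n_out)
  w_rad <- stream$w * pi / 180
  wc <- rs(cos(w_rad)); ws <- rs(sin(w_rad))
  out <- tibble::tibble(idx = seq_len(n_out),
                        x = rs(stream$x),
                        y = rs(stream$y),
                        w = (atan2(ws, wc) * 180 / pi) %% 360)
  attr(out, "rate_hz") <- to_hz
  out
}

gcd_int <- function(a, b) if (b == 0) a else gcd_int(b, a %% b)

# Edge-padded rational FIR resampling of one numeric channel: zero-stuff
# by p, Kaiser-windowed linear-phase lowpass of order 10*max(p,q) at the
# tighter Nyquist cutoff, pick every q-th sample with the group delay
# (N/2) removed so the output has zero net delay.
fir_resample <- function(v, p, q, n_out) {
  N <- 10 * max(p, q)
  if (N %% 2 == 1) N <- N + 1
  h <- p * signal::fir1(N, 1 / max(p, q),
                        window = signal::kaiser(N + 1, 5))
  pad <- N
  vp <- c(rep(v[1], pad), v, rep(v[length(v)], pad))
  xup <- numeric(length(vp) * p)
  xup[seq(1, length(xup), by = p)] <- vp
  yf <- stats::filter(xup, h, method = "convolution", sides = 1)
  idx <- pad * p + 1 + (seq_len(n_out) - 1) * q + N / 2
  as.numeric(yf[idx])
}

#' Align a sensor session on the common 25 Hz clock
#'
#' Runs the full stream regularisation: the EMG stream through
#' [regularize_emg()], the positional stream through
#' [resample_positional()], then pairs each positional frame with the
#' nearest EMG sample in time (ties to the earlier sample) and carries the
#' per-frame action label over from the original positional clock.
#'
#' @param session A `sensor_session` from [sim_session()], or any list with
#'   `positional`, `emg`, `labels` and `config` entries.
#' @param target_hz Common output clock (Hz).
#' @param smoothing Spline fidelity parameter for [regularize_emg()].
#' @return A frames tibble: `t`, `x`, `y`, `w`, the six EMG channels, and
#'   `action`; one row per frame of the common clock.
#' @export
align_session <- function(session, target_hz = 25, smoothing = 0.99) {
  cfg <- session$config
  pos25 <- resample_positional(session$positional,
                               from_hz = cfg$pos_rate_hz, to_hz = target_hz)
  emg25 <- regularize_emg(session$emg, target_hz = target_hz,
                          smoothing = smoothing)
  t_pos <- (pos25$idx - 1) / target_hz
  # nearest EMG sample, ties to the earlier one
  ei <- findInterval(t_pos, emg25$time)
  ei[ei < 1] <- 1L
  lo <- pmax(ei, 1L)
  hi <- pmin(ei + 1L, nrow(emg25))
  pick_hi <- (emg25$time[hi] - t_pos) < (t_pos - emg25$time[lo])
  ei <- ifelse(pick_hi, hi, lo)
  # label of the nearest original positional frame
  src <- pmin(pmax(round(t_pos * cfg$pos_rate_hz) + 1L, 1L),
              length(session$labels))
  frames <- tibble::tibble(t = t_pos, x = pos25$x, y = pos25$y, w = pos25$w)
  for (ch in emg_channels()) frames[[ch]] <- emg25[[ch]][ei]
  frames$action <- session$labels[src]
  attr(frames, "rate_hz") <- target_hz
  frames
}

#' Cut an aligned frame stream into single-action trials
#'
#' Each maximal run of frames sharing one action label becomes one trial,
#' the unit of classification.
#'
#' @param frames Aligned frames tibble from [align_session()].
#' @return A trials tibble: `trial_id`, `action`, `frame` (1-based within
#'   trial), plus all frame columns.
#' @export
segment_trials <- function(frames) {
  if (nrow(frames) == 0) {
    return(dplyr::mutate(frames, trial_id = character(), frame = integer()))
  }
  r <- rle(frames$action)
  trial_id <- rep(sprintf("T%04d", seq_along(r$values)), r$lengths)
  out <- dplyr::mutate(frames,
                       trial_id = trial_id,
                       frame = stats::ave(seq_len(nrow(frames)), trial_id,
                                          FUN = seq_along))
  dplyr::relocate(out, "trial_id", "action", "frame")
}

#' Drop trials shorter than the minimum usable length
#'
#' Trials below `min_frames` (one second at 25 Hz by default) are too short
#' for the sequential classifiers to converge and are removed. If that
#' would eliminate an action class entirely, its single longest trial is
#' kept instead (with a warning), preserving class representativeness.
#'
#' @param trials Trials tibble from [segment_trials()].
#' @param min_frames Minimum trial length in frames.
#' @return Filtered trials tibble.
#' @export
filter_short_trials <- function(trials, min_frames = 25) {
  len <- dplyr::summarise(dplyr::group_by(trials, .data$trial_id,
                                          .data$action),
                          n = dplyr::n(), .groups = "drop")
  keep <- len$trial_id[len$n >= min_frames]
  lost <- setdiff(unique(len$action), unique(len$action[len$n >= min_frames]))
  if (length(lost) > 0) {
    rescue <- vapply(lost, function(a) {
      sub <- len[len$action == a, ]
      sub$trial_id[which.max(sub$n)]
    }, character(1))
    warning(sprintf(
      "all trials of class(es) %s are shorter than %d frames; keeping the longest trial of each",
      paste(lost, collapse = ", "), min_frames), call. = FALSE)
    keep <- c(keep, rescue)
  }
  dplyr::filter(trials, .data$trial_id %in% keep)
}

#' Split over-long trials into chunks of comparable duration
#'
#' Trials longer than `max_frames` are divided into consecutive chunks of
#' at most `max_frames` frames; a final remainder shorter than `min_frames`
#' is merged into the preceding chunk so every output trial stays usable.
#' Labels are inherited.
#'
#' @param trials Trials tibble.
#' @param max_frames Maximum trial length; defaults to the 75th percentile
#'   of the input trial lengths, which keeps average trial duration similar
#'   across actions.
#' @param min_frames Minimum chunk length (see [filter_short_trials()]).
#' @return Trials tibble with re-numbered chunk trial ids (`<id>.1`, ...).
#' @export
split_long_trials <- function(trials, max_frames = NULL, min_frames = 25) {
  if (nrow(trials) == 0) return(trials)
  lens <- table(trials$trial_id)
  if (is.null(max_frames)) {
    max_frames <- max(ceiling(stats::quantile(as.numeric(lens), 0.75)),
                      min_frames)
  }
  chunk_of <- function(n) {
    if (n <= max_frames) return(rep(1L, n))
    k <- n %/% max_frames
    r <- n %% max_frames
    sizes <- rep(max_frames, k)
    if (r >= min_frames) sizes <- c(sizes, r)
    else if (r > 0) sizes[k] <- sizes[k] + r
    rep(seq_along(sizes), sizes)
  }
  out <- dplyr::group_modify(
    dplyr::group_by(trials, .data$trial_id),
    function(df, key) {
      ck <- chunk_of(nrow(df))
      df$chunk <- ck
      df$frame <- stats::ave(seq_len(nrow(df)), ck, FUN = seq_along)
      df
    })
  out <- dplyr::ungroup(out)
  out$trial_id <- paste0(out$trial_id, ".", out$chunk)
  out$chunk <- NULL
  dplyr::relocate(out, "trial_id", "action", "frame")
}

#' Full preprocessing: session to classified-ready trials
#'
#' Convenience composition of [align_session()], [segment_trials()],
#' [filter_short_trials()] and [split_long_trials()].
#'
#' @inheritParams align_session
#' @inheritParams filter_short_trials
#' @param max_frames Passed to [split_long_trials()].
#' @return Trials tibble.
#' @export
preprocess_session <- function(session, target_hz = 25, smoothing = 0.99,
                               min_frames = 25, max_frames = NULL) {
  frames <- align_session(session, target_hz = target_hz,
                          smoothing = smoothing)
  trials <- segment_trials(frames)
  trials <- filter_short_trials(trials, min_frames = min_frames)
  split_long_trials(trials, max_frames = max_frames, min_frames = min_frames)
}
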