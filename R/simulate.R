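#' Default action profiles for the futsal session simulator
#'
#' One profile per target action, describing how the simulator renders it:
#' dwell-time distribution (seconds), ground-speed range (m/s), mean EMG
#' envelope level and burst amplitude per muscle channel (arbitrary EMG
#' units, channel order R.Quad, L.Quad, R.Hams, L.Hams, R.Gluteo, L.Gluteo),
#' turn-rate noise (rad/s) and the sampling prior weight.
#'
#' Defaults encode futsal-plausible signatures: with-ball variants are ~10%
#' slower than their base gait with an asymmetric (dominant-leg) EMG
#' elevation; shooting and jumping are short (0.5-1.5 s) bursts dominated by
#' quadriceps/gluteus activity; prior weights are proportional to the
#' per-class trial counts of the reference corpus
#' (see [futsal_trial_counts()]), so simulated corpora inherit its class
#' imbalance.
#'
#' @return A tibble with one row per action and columns `action`,
#'   `dwell_mean`, `dwell_sd`, `speed_min`, `speed_max`, `emg_level`
#'   (list of 6-vectors), `emg_burst_amp` (list of 6-vectors),
#'   `heading_noise_sd`, `prior_weight`.
#' @export
#' @examples
#' default_action_profiles()
default_action_profiles <- function() {
  tibble::tibble(
    action     = futsal_actions(),
    dwell_mean = c(3.0, 2.5, 1.5, 3.5, 3.0, 1.0, 1.0),
    dwell_sd   = c(1.2, 1.0, 0.5, 1.5, 1.2, 0.25, 0.25),
    speed_min  = c(3.0, 2.7, 0.5, 0.5, 0.45, 0.5, 0.3),
    speed_max  = c(6.0, 5.4, 2.5, 2.0, 1.8, 2.0, 1.5),
    emg_level = list(
      c(40, 40, 30, 30, 25, 25),   # running: high, symmetric
      c(50, 32, 38, 24, 30, 20),   # running w/ball: elevated, asymmetric
      c(30, 15, 20, 10, 15, 8),    # passing: one-legged kick
      c(12, 12, 8, 8, 6, 6),       # walking: low, symmetric
      c(18, 10, 12, 7, 8, 5),      # walking w/ball: low, asymmetric
      c(45, 20, 15, 10, 35, 15),   # shooting: quad + gluteus dominant
      c(40, 40, 20, 20, 35, 35)    # jumping: bilateral quad + gluteus
    ),
    emg_burst_amp = list(
      c(15, 15, 12, 12, 10, 10),
      c(20, 12, 15, 10, 12, 8),
      c(40, 10, 20, 8, 10, 5),
      c(5, 5, 4, 4, 3, 3),
      c(8, 5, 5, 4, 4, 3),
      c(50, 15, 10, 8, 40, 12),
      c(45, 45, 15, 15, 35, 35)
    ),
    heading_noise_sd = c(0.5, 0.6, 0.8, 0.8, 0.8, 0.6, 0.4),
    prior_weight = c(183, 57, 80, 690, 27, 15, 24)
  )
}

#' Session simulator configuration
#'
#' @param duration_s Session length in seconds.
#' @param pos_rate_hz Positional sampling rate (Hz); the tracker emits 30 Hz.
#' @param emg_nominal_rate_hz Nominal EMG sampling rate (Hz); the garment
#'   targets 25 Hz but drops samples.
#' @param emg_dropout_prob Probability that any individual EMG sample is
#'   dropped (binomial thinning, so per-second counts are at most nominal).
#' @param field_length_m,field_width_m Pitch dimensions; default 40 x 20 m
#'   (standard futsal), origin at pitch centre.
#' @param goal_x,goal_y Opponent goal-line midpoint, on the field boundary.
#' @param speed_noise_sd Within-action speed fluctuation (m/s, AR(1)).
#' @param emg_noise_sd Additive Gaussian noise on EMG envelopes (EMG units).
#' @param burst_rate_hz Rate of EMG activation bursts within an action.
#' @param burst_dur_s Duration of one raised-cosine EMG burst.
#' @param rng_seed Integer seed; fixing it makes the session bit-reproducible.
#' @return A list of class `session_config`.
#' @export
session_config <- function(duration_s = 60,
                           pos_rate_hz = 30,
                           emg_nominal_rate_hz = 25,
                           emg_dropout_prob = 0.1,
                           field_length_m = 40,
                           field_width_m = 20,
                           goal_x = 20,
                           goal_y = 0,
                           speed_noise_sd = 0.15,
                           emg_noise_sd = 6,
                           burst_rate_hz = 1.5,
                           burst_dur_s = 0.3,
                           rng_seed = NULL) {
  stopifnot(duration_s >= 0, pos_rate_hz > 0, emg_nominal_rate_hz > 0,
            emg_dropout_prob >= 0, emg_dropout_prob < 1,
            field_length_m > 0, field_width_m > 0)
  on_boundary <-
    isTRUE(all.equal(abs(goal_x), field_length_m / 2)) && abs(goal_y) <= field_width_m / 2 ||
    isTRUE(all.equal(abs(goal_y), field_width_m / 2)) && abs(goal_x) <= field_length_m / 2
  if (!on_boundary) {
    stop("goal midpoint (goal_x, goal_y) must lie on the field boundary",
         call. = FALSE)
  }
  structure(as.list(environment())[c(
    "duration_s", "pos_rate_hz", "emg_nominal_rate_hz", "emg_dropout_prob",
    "field_length_m", "field_width_m", "goal_x", "goal_y",
    "speed_noise_sd", "emg_noise_sd", "burst_rate_hz", "burst_dur_s",
    "rng_seed"
  )], class = "session_config")
}

check_profiles <- function(profiles) {
  stopifnot(is.data.frame(profiles))
  need <- c("action", "dwell_mean", "dwell_sd", "speed_min", "speed_max",
            "emg_level", "emg_burst_amp", "heading_noise_sd", "prior_weight")
  miss <- setdiff(need, names(profiles))
  if (length(miss) > 0) {
    stop("profiles missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(profiles) != 7 || !setequal(profiles$action, futsal_actions())) {
    stop("profiles must contain exactly one row per target action",
         call. = FALSE)
  }
  stopifnot(all(profiles$dwell_mean > 0),
            all(profiles$speed_min >= 0),
            all(profiles$speed_max >= profiles$speed_min),
            all(profiles$prior_weight >= 0))
  invisible(profiles)
}

# Run code with a local, restorable RNG state when seed is non-NULL.
with_local_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed) %% 2147483629L)
  code
}

#' Draw a semi-Markov action script for a simulated session
#'
#' Actions are drawn independently in proportion to their prior weights and
#' dwell times from a truncated normal floored at two positional frames;
#' adjacent draws of the same action are merged, so each script row is a
#' maximal single-action segment. The final segment is trimmed so the script
#' covers `duration_s` exactly whenever the trim leaves at least two frames.
#'
#' @param config A [session_config()].
#' @param profiles Action profile tibble, see [default_action_profiles()].
#' @return A tibble with columns `action`, `duration_s`.
#' @export
#' @examples
#' sim_action_script(session_config(duration_s = 30, rng_seed = 1))
sim_action_script <- function(config = session_config(),
                              profiles = default_action_profiles()) {
  check_profiles(profiles)
  if (sum(profiles$prior_weight) <= 0) {
    stop("at least one action must have a positive prior_weight",
         call. = FALSE)
  }
  if (config$duration_s == 0) {
    return(tibble::tibble(action = character(), duration_s = numeric()))
  }
  floor_s <- 2 / config$pos_rate_hz
  with_local_seed(config$rng_seed, {
    p <- profiles$prior_weight / sum(profiles$prior_weight)
    # Expected draws needed, padded; extend if the tail falls short.
    acts <- character(0); durs <- numeric(0); total <- 0
    while (total < config$duration_s) {
      n_more <- max(16L, ceiling((config$duration_s - total) /
                                   max(weighted.mean(profiles$dwell_mean, p), floor_s)))
      idx <- sample.int(7L, n_more, replace = TRUE, prob = p)
      d <- pmax(stats::rnorm(n_more, profiles$dwell_mean[idx],
                             profiles$dwell_sd[idx]), floor_s)
      keep <- cumsum(d) + total
      cut <- which(keep >= config$duration_s)
      if (length(cut) > 0) {
        idx <- idx[seq_len(cut[1])]
        d <- d[seq_len(cut[1])]
      }
      acts <- c(acts, profiles$action[idx])
      durs <- c(durs, d)
      total <- sum(durs)
    }
    # trim tail to land exactly on duration_s when feasible
    excess <- total - config$duration_s
    if (excess > 0 && durs[length(durs)] - excess >= floor_s) {
      durs[length(durs)] <- durs[length(durs)] - excess
    }
    # merge adjacent duplicates into maximal single-action segments
    r <- rle(acts)
    seg_end <- cumsum(r$lengths)
    seg_start <- seg_end - r$lengths + 1
    merged <- vapply(seq_along(r$values),
                     function(i) sum(durs[seg_start[i]:seg_end[i]]), 0)
    tibble::tibble(action = r$values, duration_s = merged)
  })
}

# Locate the active script segment for each time point.
segment_at <- function(times, script) {
  breaks <- c(0, cumsum(script$duration_s))
  i <- findInterval(times, breaks, rightmost.closed = TRUE)
  pmin(pmax(i, 1L), nrow(script))
}

# Raised-cosine burst envelope in [0, 1] for times within a segment.
burst_envelope <- function(t_local, seg_dur, rate_hz, dur_s, phase) {
  if (rate_hz <= 0 || dur_s <= 0 || phase > seg_dur) {
    return(numeric(length(t_local)))
  }
  centres <- seq(phase, seg_dur, by = 1 / rate_hz)
  env <- numeric(length(t_local))
  for (ct in centres) {
    d <- abs(t_local - ct)
    in_b <- d < dur_s / 2
    env[in_b] <- pmax(env[in_b], 0.5 * (1 + cos(2 * pi * d[in_b] / dur_s)))
  }
  env
}

#' Synthesise a labelled sensor session
#'
#' Renders an action script into the two wearable streams: a positional
#' stream at `pos_rate_hz` (player position in metres, body orientation in
#' degrees) simulated as a bounded random walk with action-dependent speed,
#' and a six-channel EMG envelope stream at the nominal EMG rate with
#' binomial sample dropout. A per-positional-frame label track records the
#' active action.
#'
#' @param config A [session_config()].
#' @param profiles Action profile tibble.
#' @param script Optional pre-drawn script from [sim_action_script()]; drawn
#'   from `config`/`profiles` when `NULL`.
#' @return A `sensor_session`: list with `positional` (tibble `idx`, `x`,
#'   `y`, `w`), `emg` (tibble of the six channels plus `time`), `labels`
#'   (character, one per positional frame), `script`, and `config`.
#' @export
#' @examples
#' s <- sim_session(session_config(duration_s = 10, rng_seed = 1))
#' nrow(s$positional)
sim_session <- function(config = session_config(),
                        profiles = default_action_profiles(),
                        script = NULL) {
  check_profiles(profiles)
  dt <- 1 / config$pos_rate_hz
  if (max(profiles$speed_max) * dt > min(config$field_length_m,
                                         config$field_width_m) / 2) {
    stop("speed_range infeasible for this field size", call. = FALSE)
  }
  with_local_seed(config$rng_seed, {
    if (is.null(script)) {
      cfg2 <- config; cfg2$rng_seed <- NULL   # already inside seeded scope
      script <- sim_action_script(cfg2, profiles)
    }
    n_pos <- round(config$duration_s * config$pos_rate_hz)
    if (nrow(script) == 0 || n_pos == 0) {
      return(empty_session(script, config))
    }
    prof_of <- match(script$action, profiles$action)
    t_pos <- (seq_len(n_pos) - 1) * dt
    seg <- segment_at(t_pos, script)

    # per-segment target speed and burst phase
    tgt_speed <- stats::runif(nrow(script),
                              profiles$speed_min[prof_of],
                              profiles$speed_max[prof_of])
    burst_phase <- stats::runif(nrow(script), 0, 1 / config$burst_rate_hz)

    # AR(1) speed fluctuation around the segment target
    eps <- stats::rnorm(n_pos, 0, config$speed_noise_sd)
    ar <- numeric(n_pos)
    if (n_pos >= 2) for (t in 2:n_pos) ar[t] <- 0.9 * ar[t - 1] + eps[t]
    v <- pmax(tgt_speed[seg] + ar, 0)

    hx <- config$field_length_m / 2
    hy <- config$field_width_m / 2
    x <- numeric(n_pos); y <- numeric(n_pos); h <- numeric(n_pos)
    x[1] <- stats::runif(1, -hx / 2, hx / 2)
    y[1] <- stats::runif(1, -hy / 2, hy / 2)
    h[1] <- stats::runif(1, -pi, pi)
    turn <- stats::rnorm(n_pos, 0,
                         profiles$heading_noise_sd[prof_of[seg]] * sqrt(dt))
    for (t in seq_len(n_pos)[-1]) {
      hd <- h[t - 1] + turn[t]
      nx <- x[t - 1] + v[t] * dt * cos(hd)
      ny <- y[t - 1] + v[t] * dt * sin(hd)
      if (nx > hx || nx < -hx) {         # reflect off end walls
        hd <- wrap_angle(pi - hd)
        nx <- x[t - 1] + v[t] * dt * cos(hd)
      }
      if (ny > hy || ny < -hy) {         # reflect off side walls
        hd <- wrap_angle(-hd)
        ny <- y[t - 1] + v[t] * dt * sin(hd)
      }
      x[t] <- min(max(nx, -hx), hx)
      y[t] <- min(max(ny, -hy), hy)
      h[t] <- wrap_angle(hd)
    }
    w_deg <- (h * 180 / pi) %% 360

    positional <- tibble::tibble(idx = seq_len(n_pos), x = x, y = y, w = w_deg)
    labels <- script$action[seg]

    # EMG on the nominal grid, then binomial thinning
    n_emg <- round(config$duration_s * config$emg_nominal_rate_hz)
    t_emg <- (seq_len(n_emg) - 1) / config$emg_nominal_rate_hz
    seg_e <- segment_at(t_emg, script)
    seg_t0 <- c(0, cumsum(script$duration_s))[seg_e]
    env <- numeric(n_emg)
    for (s in unique(seg_e)) {
      ii <- which(seg_e == s)
      env[ii] <- burst_envelope(t_emg[ii] - seg_t0[ii][1],
                                script$duration_s[s],
                                config$burst_rate_hz, config$burst_dur_s,
                                burst_phase[s])
    }
    lev <- do.call(rbind, profiles$emg_level)[prof_of[seg_e], , drop = FALSE]
    amp <- do.call(rbind, profiles$emg_burst_amp)[prof_of[seg_e], , drop = FALSE]
    noise <- matrix(stats::rnorm(n_emg * 6, 0, config$emg_noise_sd), n_emg, 6)
    e <- pmax(lev + amp * env + noise, 0)
    keep <- stats::runif(n_emg) >= config$emg_dropout_prob
    if (sum(keep) < 4) keep[seq_len(min(4, n_emg))] <- TRUE
    emg <- tibble::as_tibble(as.data.frame(e[keep, , drop = FALSE]))
    names(emg) <- emg_channels()
    emg$time <- t_emg[keep]

    structure(list(positional = positional, emg = emg, labels = labels,
                   script = script, config = config),
              class = "sensor_session")
  })
}

empty_session <- function(script, config) {
  emg <- tibble::as_tibble(stats::setNames(
    rep(list(numeric()), 7), c(emg_channels(), "time")))
  structure(list(
    positional = tibble::tibble(idx = integer(), x = numeric(),
                                y = numeric(), w = numeric()),
    emg = emg, labels = character(), script = script, config = config),
    class = "sensor_session")
}

#' @export
print.sensor_session <- function(x, ...) {
  cat(sprintf(
    "<sensor_session> %.1f s | %d positional frames @ %g Hz | %d EMG samples | %d segments\n",
    x$config$duration_s, nrow(x$positional), x$config$pos_rate_hz,
    nrow(x$emg), nrow(x$script)))
  invisible(x)
}

# Canonical EMG channel names (muscle order of the garment).
emg_channels <- function() {
  c("r_quad", "l_quad", "r_hams", "l_hams", "r_gluteo", "l_gluteo")
}
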