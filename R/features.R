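#' Per-frame speed of a trial
#'
#' Euclidean displacement between consecutive positions divided by the
#' frame interval. The first frame copies the second so the output has one
#' value per frame.
#'
#' @param trial Data frame with `x`, `y` columns (metres), one row per
#'   frame on the common clock.
#' @param dt Frame interval in seconds (1/25 s after resampling).
#' @return Numeric vector of speeds (m/s), same length as `nrow(trial)`.
#' @export
velocity <- function(trial, dt = 1 / 25) {
  n <- nrow(trial)
  if (n < 2) stop("velocity needs at least 2 frames", call. = FALSE)
  v <- sqrt(diff(trial$x)^2 + diff(trial$y)^2) / dt
  c(v[1], v)
}

#' Per-frame distance to the opponent goal midpoint
#'
#' @param trial Data frame with `x`, `y` columns (metres).
#' @param goal_x,goal_y Goal-line midpoint coordinates (metres).
#' @return Numeric vector of distances (m).
#' @export
distance_to_goal <- function(trial, goal_x = 20, goal_y = 0) {
  sqrt((trial$x - goal_x)^2 + (trial$y - goal_y)^2)
}

#' Per-frame orientation towards the opponent goal
#'
#' Difference between the player's angular position `w` (recorded in
#' degrees, converted to radians) and the bearing of the goal midpoint from
#' the player, wrapped into (-pi, pi]. Zero means facing the goal.
#'
#' @param trial Data frame with `x`, `y`, `w` columns (`w` in degrees).
#' @param goal_x,goal_y Goal-line midpoint coordinates (metres).
#' @return Numeric vector of angles in radians, in (-pi, pi].
#' @export
orientation_to_goal <- function(trial, goal_x = 20, goal_y = 0) {
  at_goal <- trial$x == goal_x & trial$y == goal_y
  if (any(at_goal)) {
    warning("player exactly at the goal midpoint; orientation defaults to the wrapped angular position",
            call. = FALSE)
  }
  bearing <- atan2(goal_y - trial$y, goal_x - trial$x)
  bearing[at_goal] <- 0
  wrap_angle(trial$w * pi / 180 - bearing)
}

#' Feature column order of the nine-feature frame vector
#' @return Character vector: six EMG channels, `v`, `d`, `theta`.
#' @export
feature_names <- function() c(emg_channels(), "v", "d", "theta")

feature_mask_columns <- function(mask) {
  masks <- list(
    "emg"   = emg_channels(),
    "emg+v" = c(emg_channels(), "v"),
    "emg+d" = c(emg_channels(), "d"),
    "emg+o" = c(emg_channels(), "theta"),
    "all"   = feature_names()
  )
  if (!mask %in% names(masks)) {
    stop("unknown feature mask '", mask, "'; use one of: ",
         paste(names(masks), collapse = ", "), call. = FALSE)
  }
  masks[[mask]]
}

#' Compute the nine sequential features for every trial
#'
#' Adds speed (`v`), distance to goal (`d`) and orientation to goal
#' (`theta`) to the six EMG channels, per frame and per trial. EMG values
#' are carried through unchanged; normalise them with [normalize_emg()].
#'
#' @param trials Trials tibble from [segment_trials()] /
#'   [preprocess_session()].
#' @param goal_x,goal_y Opponent goal midpoint (metres).
#' @param dt Frame interval (seconds).
#' @return A features tibble: `trial_id`, `action`, `frame`, the six EMG
#'   channels, `v`, `d`, `theta`.
#' @export
compute_features <- function(trials, goal_x = 20, goal_y = 0, dt = 1 / 25) {
  out <- dplyr::ungroup(dplyr::mutate(
    dplyr::group_by(trials, .data$trial_id),
    v = velocity(dplyr::pick("x", "y"), dt = dt),
    d = distance_to_goal(dplyr::pick("x", "y"),
                         goal_x = goal_x, goal_y = goal_y),
    theta = orientation_to_goal(dplyr::pick("x", "y", "w"),
                                goal_x = goal_x, goal_y = goal_y)
  ))
  dplyr::select(out, "trial_id", "action", "frame",
                dplyr::all_of(feature_names()))
}

#' Min-max normalise the EMG channels of a feature table
#'
#' Each channel is mapped to `[0, 1]` by `(e - min(e)) / (max(e) - min(e))`
#' with the extrema taken over all values of that channel. By default the
#' statistics come from the whole table (the convention of the original
#' analysis, which normalises before splitting); pass `stats` computed on a
#' training set to normalise held-out data instead, in which case values
#' are clipped to `[0, 1]`. A constant channel maps to 0.5.
#'
#' @param features Features tibble from [compute_features()].
#' @param stats Optional tibble (`channel`, `min`, `max`) from a previous
#'   call (stored in attribute `emg_stats`).
#' @return The features tibble with normalised EMG channels and an
#'   `emg_stats` attribute.
#' @export
normalize_emg <- function(features, stats = NULL) {
  own <- is.null(stats)
  if (own) {
    stats <- tibble::tibble(
      channel = emg_channels(),
      min = vapply(emg_channels(), function(ch) min(features[[ch]]), 0),
      max = vapply(emg_channels(), function(ch) max(features[[ch]]), 0)
    )
  }
  for (i in seq_len(nrow(stats))) {
    ch <- stats$channel[i]
    rng <- stats$max[i] - stats$min[i]
    if (rng <= 0) {
      warning(sprintf("EMG channel '%s' is constant; normalised to 0.5", ch),
              call. = FALSE)
      features[[ch]] <- rep(0.5, nrow(features))
    } else {
      z <- (features[[ch]] - stats$min[i]) / rng
      if (!own) z <- pmin(pmax(z, 0), 1)
      features[[ch]] <- z
    }
  }
  attr(features, "emg_stats") <- stats
  features
}

#' Assemble a classification dataset in frame- or sequence-major layout
#'
#' Frame-major (one row per frame, one column per feature) feeds the
#' frame-wise classifiers (ANN, and the DBMM bases); sequence-major (one
#' feature-by-frames matrix per trial) feeds the LSTM. An ablation mask
#' selects feature subsets: `"emg"`, `"emg+v"`, `"emg+d"`, `"emg+o"` or
#' `"all"`.
#'
#' @param features Normalised features tibble.
#' @param layout `"frame"` or `"sequence"`.
#' @param mask Feature mask name.
#' @return For `"frame"`: a tibble `trial_id`, `action`, `frame`, selected
#'   features. For `"sequence"`: a tibble `trial_id`, `action`, `seq`
#'   (list of p x T matrices). Both carry attributes `layout`, `mask` and
#'   `features`.
#' @export
assemble_dataset <- function(features, layout = c("frame", "sequence"),
                             mask = "all") {
  layout <- match.arg(layout)
  cols <- feature_mask_columns(mask)
  if (layout == "frame") {
    out <- dplyr::select(features, "trial_id", "action", "frame",
                         dplyr::all_of(cols))
  } else {
    out <- dplyr::summarise(
      dplyr::group_by(features, .data$trial_id, .data$action),
      seq = list(t(as.matrix(dplyr::pick(dplyr::all_of(cols))))),
      .groups = "drop")
  }
  attr(out, "layout") <- layout
  attr(out, "mask") <- mask
  attr(out, "features") <- cols
  out
}

#' Stratified train/test split at trial level
#'
#' Each action class is split independently: `round-half-up(train_frac * N)`
#' trials to training, the remainder to test. This is the allocation that
#' reproduces the published per-class 70/30 counts of the reference corpus
#' exactly (e.g. 15 trials split 11/4).
#'
#' @param dataset A frame- or sequence-major dataset (any tibble with
#'   `trial_id` and `action`).
#' @param train_frac Training fraction.
#' @param seed Integer seed for the per-class sampling.
#' @return A list with elements `train` and `test` (disjoint subsets of
#'   `dataset`, attributes preserved).
#' @export
train_test_split <- function(dataset, train_frac = 0.7, seed = 1) {
  ids <- dplyr::distinct(tibble::as_tibble(dataset[, c("trial_id", "action")]))
  train_ids <- with_local_seed(seed, {
    unlist(lapply(split(ids$trial_id, ids$action), function(tr) {
      n_tr <- round_half_up(train_frac * length(tr))
      if (length(tr) == 1) {
        if (n_tr >= 1) tr else character(0)
      } else {
        sample(tr, n_tr)
      }
    }), use.names = FALSE)
  })
  subset_keep <- function(keep) {
    out <- dataset[dataset$trial_id %in% keep, , drop = FALSE]
    for (a in c("layout", "mask", "features", "emg_stats")) {
      attr(out, a) <- attr(dataset, a)
    }
    out
  }
  list(train = subset_keep(train_ids),
       test = subset_keep(setdiff(ids$trial_id, train_ids)))
}
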