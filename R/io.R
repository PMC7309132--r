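#' Read a TraXports positional CSV
#'
#' The tracker export is a comma-separated file with a header row
#' `idx, posX1, posY1, posW1, ...` (one `posX/posY/posW` triple per tracked
#' player): frame index, X/Y position in metres, angular position in
#' degrees. Unknown extra columns are preserved.
#'
#' @param path Path to the CSV file.
#' @param player Which player's triple to extract into the canonical
#'   `x`/`y`/`w` columns.
#' @param rate_hz Sampling rate recorded with the stream (Hz).
#' @return A tibble with columns `idx`, `x`, `y`, `w` plus any extra
#'   columns, and attributes `rate_hz` and `player`.
#' @export
read_traxports <- function(path, player = 1, rate_hz = 30) {
  df <- readr::read_csv(path, show_col_types = FALSE,
                        name_repair = "minimal")
  names(df) <- trimws(names(df))
  need <- c("idx", paste0(c("posX", "posY", "posW"), player))
  for (col in need) {
    if (!col %in% names(df)) {
      stop(sprintf("TraXports file '%s' is missing mandatory column '%s'",
                   path, col), call. = FALSE)
    }
  }
  if (nrow(df) > 0 && any(diff(df$idx) <= 0)) {
    stop("TraXports column 'idx' must be strictly increasing", call. = FALSE)
  }
  out <- tibble::tibble(idx = df$idx,
                        x = df[[paste0("posX", player)]],
                        y = df[[paste0("posY", player)]],
                        w = df[[paste0("posW", player)]])
  extra <- setdiff(names(df), need)
  for (col in extra) out[[col]] <- df[[col]]
  attr(out, "rate_hz") <- rate_hz
  attr(out, "player") <- player
  out
}

#' Write a positional stream as a TraXports CSV
#'
#' @param stream Tibble with columns `idx`, `x`, `y`, `w` (see
#'   [read_traxports()]); any extra columns are written unchanged.
#' @param path Output path.
#' @param player Player number used for the column suffix.
#' @return `path`, invisibly.
#' @export
write_traxports <- function(stream, path, player = attr(stream, "player") %||% 1) {
  stopifnot(all(c("idx", "x", "y", "w") %in% names(stream)))
  out <- tibble::tibble(idx = stream$idx)
  out[[paste0("posX", player)]] <- stream$x
  out[[paste0("posY", player)]] <- stream$y
  out[[paste0("posW", player)]] <- stream$w
  extra <- setdiff(names(stream), c("idx", "x", "y", "w"))
  for (col in extra) out[[col]] <- stream[[col]]
  readr::write_csv(out, path)
  invisible(path)
}

# Header names of the EMG garment export, in muscle order.
mbody3_header <- function() {
  c("R.Quad", "L.Quad", "R.Hams", "L.Hams", "R.Gluteo", "L.Gluteo", "Time(s)")
}

#' Read an MBody3 EMG CSV
#'
#' Seven columns: six muscle channels (right/left quadriceps, hamstrings,
#' gluteus; pre-rectified, smoothed envelope values in arbitrary EMG units)
#' followed by the sample time in seconds. Time must be nondecreasing.
#'
#' @param path Path to the CSV file.
#' @return A tibble with columns `r_quad`, `l_quad`, `r_hams`, `l_hams`,
#'   `r_gluteo`, `l_gluteo`, `time`.
#' @export
read_mbody3 <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE,
                        name_repair = "minimal")
  names(df) <- trimws(names(df))
  if (ncol(df) != 7 || !identical(names(df), mbody3_header())) {
    stop(sprintf(
      "MBody3 file '%s' must have exactly the 7 columns: %s",
      path, paste(mbody3_header(), collapse = ", ")), call. = FALSE)
  }
  names(df) <- c(emg_channels(), "time")
  if (nrow(df) > 1) {
    bad <- which(diff(df$time) < 0)
    if (length(bad) > 0) {
      stop(sprintf("MBody3 time must be nondecreasing; first violation at row %d",
                   bad[1] + 1L), call. = FALSE)
    }
  }
  tibble::as_tibble(df)
}

#' Write an EMG stream as an MBody3 CSV
#'
#' @param stream Tibble with the six channel columns and `time` (see
#'   [read_mbody3()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mbody3 <- function(stream, path) {
  stopifnot(all(c(emg_channels(), "time") %in% names(stream)))
  out <- stream[, c(emg_channels(), "time")]
  names(out) <- mbody3_header()
  readr::write_csv(out, path)
  invisible(path)
}

#' Read a frame-interval label track
#'
#' Rows are `frame_start, frame_end, action` with 0-based half-open
#' intervals in positional-frame units. Intervals must not overlap and
#' every action must belong to the seven-class taxonomy.
#'
#' @param path Path to the CSV file.
#' @return A tibble with columns `frame_start`, `frame_end`, `action`,
#'   sorted by `frame_start`.
#' @export
read_labels <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  if (nrow(df) == 0) {
    return(tibble::tibble(frame_start = integer(), frame_end = integer(),
                          action = character()))
  }
  stopifnot(all(c("frame_start", "frame_end", "action") %in% names(df)))
  validate_labels(tibble::as_tibble(df[, c("frame_start", "frame_end", "action")]))
}

validate_labels <- function(track) {
  check_actions(track$action)
  if (any(track$frame_end <= track$frame_start)) {
    stop("label intervals must satisfy frame_end > frame_start", call. = FALSE)
  }
  track <- track[order(track$frame_start), ]
  if (nrow(track) > 1 &&
      any(track$frame_start[-1] < track$frame_end[-nrow(track)])) {
    stop("label intervals overlap", call. = FALSE)
  }
  track
}

#' Write a label track CSV
#' @param track Tibble with `frame_start`, `frame_end`, `action`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(track, path) {
  readr::write_csv(validate_labels(track), path)
  invisible(path)
}

#' Expand a label track to one action id per frame
#'
#' @param track Label intervals as returned by [read_labels()].
#' @param n_frames Number of positional frames; unlabelled frames get `NA`.
#' @return Character vector of length `n_frames`.
#' @export
labels_to_frames <- function(track, n_frames) {
  out <- rep(NA_character_, n_frames)
  for (i in seq_len(nrow(track))) {
    a <- max(track$frame_start[i] + 1L, 1L)
    b <- min(track$frame_end[i], n_frames)
    if (b >= a) out[a:b] <- track$action[i]
  }
  out
}

#' Collapse a per-frame label vector to interval form
#'
#' Inverse of [labels_to_frames()] for fully labelled tracks.
#'
#' @param labels Character vector of per-frame action ids.
#' @return A tibble with `frame_start`, `frame_end`, `action` (0-based,
#'   half-open).
#' @export
frames_to_labels <- function(labels) {
  if (length(labels) == 0) {
    return(tibble::tibble(frame_start = integer(), frame_end = integer(),
                          action = character()))
  }
  r <- rle(labels)
  end <- cumsum(r$lengths)
  tibble::tibble(frame_start = end - r$lengths, frame_end = end,
                 action = r$values)
}
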