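#' Two-pulse canceller (first-order MTI clutter filter)
#'
#' Subtracts each radar frame from its successor, `R_out[i] = R[i+1] - R[i]`,
#' which annihilates any frame-invariant (static clutter) component exactly.
#' The output has one row fewer than the input; no zero-padded first frame is
#' inserted, so downstream statistics never see a synthetic all-zero row.
#'
#' @param rg A [radargram()] with at least 2 frames.
#' @return A [radargram()] with `n_frames - 1` rows.
#' @export
two_pulse_cancel <- function(rg) {
  stopifnot(inherits(rg, "radargram"))
  v <- rg$values
  if (nrow(v) < 2)
    abort_config("two-pulse canceller needs >= 2 frames, got %d", nrow(v))
  out <- v[-1L, , drop = FALSE] - v[-nrow(v), , drop = FALSE]
  radargram(out, frame_rate_hz = rg$frame_rate_hz, source_id = rg$source_id,
            label = rg$label, min_frames = 1L)
}

#' Crop a radar-gram to the region-of-interest columns
#'
#' Keeps the verbatim sub-block of fast-time columns
#' `geometry$roi_start_col .. geometry$roi_end_col` (62 columns for the
#' default 259--320 ROI).
#'
#' @param rg A [radargram()].
#' @param geometry A [radar_geometry()]; its ROI must lie inside the matrix.
#' @return A cropped [radargram()].
#' @export
crop_roi <- function(rg, geometry) {
  stopifnot(inherits(rg, "radargram"), inherits(geometry, "radar_geometry"))
  if (geometry$roi_end_col > ncol(rg$values))
    abort_config("ROI end column %d exceeds matrix width %d",
                 geometry$roi_end_col, ncol(rg$values))
  out <- rg$values[, geometry$roi_start_col:geometry$roi_end_col,
                   drop = FALSE]
  radargram(out, frame_rate_hz = rg$frame_rate_hz, source_id = rg$source_id,
            label = rg$label, min_frames = 1L)
}

#' Peak detection configuration
#'
#' @param threshold Minimum absolute amplitude for a peak. The study uses
#'   0.4e4 on the clutter-removed signal.
#' @param require_local_max If `TRUE`, a peak's absolute value must strictly
#'   exceed both neighbours (edge bins compare to their single neighbour).
#' @param min_separation_bins Peaks closer than this keep only the larger
#'   absolute value.
#' @return A `peak_config` object.
#' @export
peak_config <- function(threshold = 4000, require_local_max = TRUE,
                        min_separation_bins = 1L) {
  if (!is.numeric(threshold) || threshold < 0)
    abort_config("threshold must be >= 0")
  if (!is_count(min_separation_bins) || min_separation_bins < 1)
    abort_config("min_separation_bins must be a positive integer")
  structure(list(threshold = as.numeric(threshold),
                 require_local_max = isTRUE(require_local_max),
                 min_separation_bins = as.integer(min_separation_bins)),
            class = "peak_config")
}

#' Detect significant peaks in one fast-time frame
#'
#' Applied to the clutter-removed signal, whose values are signed, so the
#' threshold and the local-maximum test act on absolute values. Indices are
#' returned ascending; when two surviving peaks are closer than
#' `min_separation_bins`, the one with the larger absolute value wins.
#'
#' @param frame Numeric vector of amplitudes (one slow-time row).
#' @param cfg A [peak_config()].
#' @return Integer vector of 1-based bin indices (possibly empty).
#' @export
detect_peaks <- function(frame, cfg = peak_config()) {
  stopifnot(inherits(cfg, "peak_config"))
  if (length(frame) == 0) abort_config("empty frame")
  a <- abs(frame)
  cand <- which(a >= cfg$threshold)
  if (cfg$require_local_max && length(cand)) {
    n <- length(a)
    keep <- vapply(cand, function(i) {
      left_ok <- i == 1L || a[i] > a[i - 1L]
      right_ok <- i == n || a[i] > a[i + 1L]
      left_ok && right_ok
    }, logical(1))
    cand <- cand[keep]
  }
  if (cfg$min_separation_bins > 1L && length(cand) > 1L) {
    ord <- cand[order(a[cand], decreasing = TRUE)]
    kept <- integer(0)
    for (i in ord) {
      if (!length(kept) || all(abs(kept - i) >= cfg$min_separation_bins))
        kept <- c(kept, i)
    }
    cand <- sort(kept)
  }
  as.integer(cand)
}

#' Extract a fixed-length physiological window around a peak
#'
#' The nominal span is the half-open interval
#' `[peak_col - window_size/2, peak_col + window_size/2)`; a window that
#' would exit the frame is shifted (never shrunk) to fit, so every window
#' has exactly `window_size` samples.
#'
#' @param frame Numeric vector (one clutter-removed, ROI-cropped row).
#' @param peak_col 1-based peak index inside `frame`.
#' @param window_size Window length in bins (study value 10).
#' @return List with `start_col`, `peak_col`, and `values`
#'   (length `window_size`).
#' @export
extract_window <- function(frame, peak_col, window_size = 10L) {
  n <- length(frame)
  if (!is_count(window_size) || window_size < 1)
    abort_config("window_size must be a positive integer")
  if (window_size > n)
    abort_config("window_size %d exceeds frame length %d", window_size, n)
  if (!is_count(peak_col) || peak_col < 1 || peak_col > n)
    abort_domain("peak_col %s outside frame of length %d", format(peak_col), n)
  start <- peak_col - floor_eps(window_size / 2)
  start <- max(1L, min(as.integer(start), n - as.integer(window_size) + 1L))
  list(start_col = start, peak_col = as.integer(peak_col),
       values = frame[start:(start + window_size - 1L)])
}

#' Segment a recording into physiological windows
#'
#' Pipeline composition: two-pulse cancel, crop to the ROI, detect peaks in
#' every cancelled frame, and extract one fixed-length window per peak.
#' Column indices in the result are relative to the cropped ROI (1-based);
#' `frame_index` indexes cancelled frames (frame i is scan i+1 minus scan i).
#'
#' @param rg A [radargram()].
#' @param geometry A [radar_geometry()].
#' @param cfg A [peak_config()].
#' @param window_size Window length in bins.
#' @return A `physio_windows` data.frame with columns `source_id`,
#'   `frame_index`, `peak_col`, `start_col`, `label`, and `v1..v<window_size>`
#'   (the verbatim window samples). Zero rows when no peak is detected.
#' @export
segment_recording <- function(rg, geometry = radar_geometry(),
                              cfg = peak_config(), window_size = 10L) {
  cancelled <- crop_roi(two_pulse_cancel(rg), geometry)
  v <- cancelled$values
  rows <- vector("list", nrow(v))
  for (i in seq_len(nrow(v))) {
    peaks <- detect_peaks(v[i, ], cfg)
    if (!length(peaks)) next
    rows[[i]] <- lapply(peaks, function(p) {
      w <- extract_window(v[i, ], p, window_size)
      c(list(frame_index = i, peak_col = w$peak_col,
             start_col = w$start_col), as.list(w$values))
    })
  }
  rows <- unlist(rows, recursive = FALSE)
  vcols <- paste0("v", seq_len(window_size))
  if (!length(rows)) {
    out <- as.data.frame(matrix(numeric(0), 0, 3 + window_size))
    names(out) <- c("frame_index", "peak_col", "start_col", vcols)
  } else {
    out <- do.call(rbind, lapply(rows, function(r)
      as.data.frame(stats::setNames(r, c("frame_index", "peak_col",
                                         "start_col", vcols)))))
  }
  out <- cbind(source_id = rep(rg$source_id, nrow(out)),
               out,
               label = rep(if (is.null(rg$label)) NA_integer_ else rg$label,
                           nrow(out)))
  attr(out, "window_size") <- as.integer(window_size)
  class(out) <- c("physio_windows", "data.frame")
  out
}
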