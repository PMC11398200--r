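#' Radar-gram: slow-time x fast-time return matrix
#'
#' A radar-gram holds one recording: rows are successive radar scans (slow
#' time, one frame every `1/frame_rate_hz` seconds) and columns are range
#' bins (fast time). The study layout is 120 rows x 1440 columns per
#' recording. An optional integer label 1--5 encodes the exercise class
#' (1 = LSA left shoulder abduction, 2 = BSA bilateral shoulder abduction,
#' 3 = SFU shoulder flexion up, 4 = SFD shoulder flexion down,
#' 5 = BS breaststroke).
#'
#' @param values Numeric matrix, frames x bins; all entries finite.
#' @param frame_rate_hz Scan rate in frames per second.
#' @param source_id Identifier carried through to windows and feature rows.
#' @param label Optional exercise class in 1..5.
#' @param min_frames Minimum number of rows accepted (internal stages that
#'   consume differenced matrices relax this to 1).
#' @return A `radargram` object.
#' @export
radargram <- function(values, frame_rate_hz = 20, source_id = "",
                      label = NULL, min_frames = 2L) {
  if (!is.matrix(values) || !is.numeric(values))
    abort_config("values must be a numeric matrix")
  if (nrow(values) < min_frames || ncol(values) < 2)
    abort_config("radargram needs >= %d frames and >= 2 bins, got %d x %d",
                 min_frames, nrow(values), ncol(values))
  if (!all(is.finite(values)))
    abort_data("radargram contains non-finite entries")
  if (!is.null(label)) {
    if (!is_count(label) || !(label %in% 1:5))
      abort_config("label must be an integer in 1..5, got %s", format(label))
    label <- as.integer(label)
  }
  if (!is.numeric(frame_rate_hz) || frame_rate_hz <= 0)
    abort_config("frame_rate_hz must be positive")
  structure(list(values = unname(values),
                 frame_rate_hz = as.numeric(frame_rate_hz),
                 source_id = as.character(source_id),
                 label = label),
            class = "radargram")
}

#' @export
print.radargram <- function(x, ...) {
  cat(sprintf("<radargram> %d frames x %d bins @ %g Hz%s%s\n",
              nrow(x$values), ncol(x$values), x$frame_rate_hz,
              if (nzchar(x$source_id)) paste0(" [", x$source_id, "]") else "",
              if (!is.null(x$label)) paste0(" label=", x$label) else ""))
  invisible(x)
}

#' @export
dim.radargram <- function(x) dim(x$values)

#' Read a radar-gram from a headerless numeric CSV
#'
#' One row per slow-time frame, one column per range bin, no header — the
#' raw acquisition layout. Ragged rows or non-numeric cells raise a parse
#' error naming the first offending row.
#'
#' @param path CSV file path.
#' @param frame_rate_hz Scan rate to attach (not stored in the CSV).
#' @param source_id Identifier; defaults to the file name.
#' @param label Optional exercise class in 1..5.
#' @return A [radargram()].
#' @export
read_radargram <- function(path, frame_rate_hz = 20,
                           source_id = basename(path), label = NULL) {
  if (!file.exists(path)) abort_data("no such file: %s", path)
  nf <- utils::count.fields(path, sep = ",", quote = "")
  if (length(nf) == 0) abort_parse("empty radar-gram file: %s", path)
  if (length(unique(nf)) != 1) {
    bad <- which(nf != nf[1])[1]
    abort_parse("ragged CSV %s: row %d has %d fields, expected %d",
                path, bad, nf[bad], nf[1])
  }
  dt <- tryCatch(
    suppressWarnings(data.table::fread(path, header = FALSE, sep = ",",
                                       colClasses = "numeric",
                                       showProgress = FALSE,
                                       data.table = FALSE)),
    error = function(e) abort_parse("cannot parse %s as numeric CSV: %s",
                                    path, conditionMessage(e)))
  m <- suppressWarnings(
    matrix(as.numeric(as.matrix(dt)), nrow(dt), ncol(dt)))
  if (!is.numeric(m) || anyNA(m)) {
    bad <- which(apply(is.na(m), 1, any))[1]
    abort_parse("non-numeric cell in %s at row %d", path, bad)
  }
  radargram(m, frame_rate_hz = frame_rate_hz, source_id = source_id,
            label = label)
}

#' Write a radar-gram as a headerless numeric CSV
#'
#' Full double precision (round-trips losslessly through [read_radargram()]).
#'
#' @param rg A [radargram()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_radargram <- function(rg, path) {
  stopifnot(inherits(rg, "radargram"))
  # %.17g round-trips IEEE doubles exactly
  txt <- sprintf("%.17g", rg$values)
  dim(txt) <- dim(rg$values)
  writeLines(apply(txt, 1, paste, collapse = ","), path)
  invisible(path)
}
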