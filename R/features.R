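#' Names of the 19 window descriptors, in table column order
#'
#' Eight amplitude/phase statistics followed by eleven spectral descriptors
#' computed from the one-sided DFT of the window's fast-time samples.
#'
#' @export
feature_names <- c(
  "amplitude", "amplitude_mean", "amplitude_sd", "amplitude_range",
  "phase", "phase_mean", "phase_sd", "phase_range",
  "spectral_centroid", "spectral_spread", "spectral_skewness",
  "spectral_kurtosis", "spectral_entropy", "spectral_flatness",
  "spectral_crest", "spectral_flux", "spectral_slope",
  "spectral_decrease", "spectral_rolloff")

#' Discrete Fourier spectrum of a physiological window
#'
#' Magnitudes and phases of the DFT of the window's fast-time samples, with
#' no tapering and no zero-padding. Frequencies are normalized bin fractions
#' `k/N` (dimensionless).
#'
#' @param values Numeric vector of window samples (length >= 2).
#' @return List with `magnitudes`, `phases` (radians in (-pi, pi]) and
#'   `bin_freqs`, each of length `N`.
#' @export
compute_spectrum <- function(values) {
  n <- length(values)
  if (n < 2) abort_config("window must have >= 2 samples")
  x <- stats::fft(values)
  list(magnitudes = Mod(x), phases = Arg(x), bin_freqs = (seq_len(n) - 1) / n)
}

# One-sided view (bins 0..floor(N/2)) used by all descriptors, to avoid
# double-counting conjugate bins.
one_sided <- function(spec) {
  m <- floor(length(spec$magnitudes) / 2) + 1L
  list(magnitudes = spec$magnitudes[seq_len(m)],
       phases = spec$phases[seq_len(m)],
       bin_freqs = spec$bin_freqs[seq_len(m)])
}

#' Eleven spectral descriptors of a window spectrum
#'
#' Computed over the one-sided spectrum with weights `w_k = |X_k|` and the
#' normalized distribution `p_k = w_k / sum(w)`:
#' centroid `sum(f p)`; spread `sqrt(sum((f-c)^2 p))`; skewness and kurtosis
#' as third/fourth standardized moments of `p` (0 when the spread is 0);
#' entropy `-sum(p log p) / log(n_bins)` (in `[0, 1]`); flatness
#' geometric-over-arithmetic mean of `w` (0 if any `w` is 0); crest
#' `max(w)/mean(w)`; flux, the squared distance to a previous window's
#' one-sided magnitudes (0 when there is none); slope, the least-squares
#' slope of `w` on `f`; decrease `sum_{k>=1}((w_k - w_0)/k) / sum_{k>=1} w_k`;
#' rolloff, the smallest `f` below which 85% of total magnitude lies.
#' An all-zero spectrum returns every descriptor as 0 by convention.
#'
#' @param spec Output of [compute_spectrum()].
#' @param prev_spec Optional previous-window spectrum for flux.
#' @param rolloff_prop Cumulative-magnitude proportion for rolloff.
#' @return Named numeric vector of the 11 `spectral_*` descriptors.
#' @export
spectral_descriptors <- function(spec, prev_spec = NULL,
                                 rolloff_prop = 0.85) {
  os <- one_sided(spec)
  w <- os$magnitudes
  f <- os$bin_freqs
  nb <- length(w)
  out <- stats::setNames(numeric(11), feature_names[9:19])
  tot <- sum(w)
  if (tot <= 0) return(out)

  p <- w / tot
  centroid <- sum(f * p)
  spread <- sqrt(max(sum((f - centroid)^2 * p), 0))
  if (spread > 0) {
    skew <- sum((f - centroid)^3 * p) / spread^3
    kurt <- sum((f - centroid)^4 * p) / spread^4
  } else skew <- kurt <- 0
  pz <- p[p > 0]
  entropy <- -sum(pz * log(pz)) / log(nb)
  flatness <- if (any(w == 0)) 0 else exp(mean(log(w))) / mean(w)
  crest <- max(w) / mean(w)
  flux <- if (is.null(prev_spec)) 0 else {
    wp <- one_sided(prev_spec)$magnitudes
    sum((w - wp)^2)
  }
  fb <- mean(f)
  slope <- sum((f - fb) * (w - mean(w))) / sum((f - fb)^2)
  denom <- sum(w[-1])
  decrease <- if (denom > 0)
    sum((w[-1] - w[1]) / seq_len(nb - 1)) / denom else 0
  rolloff <- f[which(cumsum(w) >= rolloff_prop * tot - 1e-12)[1]]

  out[] <- c(centroid, spread, skew, kurt, entropy, flatness, crest, flux,
             slope, decrease, rolloff)
  out
}

#' Amplitude and phase statistics of a window
#'
#' Amplitude statistics are taken over the absolute window samples:
#' `amplitude` is the maximum, plus mean, standard deviation and range
#' (max - min). Phase statistics are taken over the one-sided DFT phases;
#' `phase` is the phase at the bin with the largest magnitude.
#'
#' @param values Window samples.
#' @param spec Output of [compute_spectrum()] for the same window.
#' @return Named numeric vector of the 8 amplitude/phase descriptors.
#' @export
amplitude_phase_stats <- function(values, spec = compute_spectrum(values)) {
  a <- abs(values)
  os <- one_sided(spec)
  ph <- os$phases
  stats::setNames(
    c(max(a), mean(a), stats::sd(a), max(a) - min(a),
      ph[which.max(os$magnitudes)], mean(ph), stats::sd(ph),
      max(ph) - min(ph)),
    feature_names[1:8])
}

#' Build the descriptor table from physiological windows
#'
#' One row of 19 descriptors plus `label` per window. Spectral flux pairs
#' each window with the window of the previous cancelled frame (within the
#' same recording) whose peak column is nearest; if the previous frame
#' produced no window within `max_track_gap_bins`, flux is 0.
#'
#' @param windows A `physio_windows` data.frame from [segment_recording()]
#'   (possibly several recordings row-bound together; recordings are
#'   distinguished by `source_id`).
#' @param max_track_gap_bins Largest peak-column jump still treated as the
#'   same target track when pairing consecutive frames for flux.
#' @param per_recording If `TRUE`, average the descriptor rows of each
#'   recording into a single row (an alternative reading of
#'   "averaged over the physiological windows"; the default keeps one
#'   row per window, the reading consistent with window-level sample
#'   counts).
#' @return A `feature_table` data.frame: `source_id`, the 19 descriptor
#'   columns of [feature_names], and `label`.
#' @export
featurize <- function(windows, max_track_gap_bins = 10L,
                      per_recording = FALSE) {
  stopifnot(is.data.frame(windows))
  if (nrow(windows) == 0) abort_config("no windows to featurize")
  vcols <- grep("^v\\d+$", names(windows), value = TRUE)
  vcols <- vcols[order(as.integer(sub("^v", "", vcols)))]
  if (length(vcols) < 2) abort_config("windows table has no sample columns")
  vals <- as.matrix(windows[, vcols])

  specs <- lapply(seq_len(nrow(vals)), function(i) compute_spectrum(vals[i, ]))
  feats <- matrix(0, nrow(vals), 19, dimnames = list(NULL, feature_names))
  for (g in split(seq_len(nrow(windows)), windows$source_id)) {
    g <- g[order(windows$frame_index[g], windows$peak_col[g])]
    for (i in g) {
      prev <- g[windows$frame_index[g] == windows$frame_index[i] - 1L]
      prev_spec <- NULL
      if (length(prev)) {
        d <- abs(windows$peak_col[prev] - windows$peak_col[i])
        j <- prev[which.min(d)]
        if (min(d) <= max_track_gap_bins) prev_spec <- specs[[j]]
      }
      feats[i, 1:8] <- amplitude_phase_stats(vals[i, ], specs[[i]])
      feats[i, 9:19] <- spectral_descriptors(specs[[i]], prev_spec)
    }
  }
  out <- data.frame(source_id = windows$source_id, feats,
                    label = windows$label, check.names = FALSE)
  if (per_recording) {
    agg <- stats::aggregate(out[feature_names],
                            by = list(source_id = out$source_id), mean)
    lab <- vapply(split(out$label, out$source_id), function(x) x[1],
                  out$label[1])
    agg$label <- lab[agg$source_id]
    out <- agg[, c("source_id", feature_names, "label")]
  }
  class(out) <- c("feature_table", "data.frame")
  out
}

#' Min--max feature normalizer
#'
#' Fits per-descriptor minima and maxima on a training table only;
#' [apply_normalizer()] rescales any table with
#' `(x - min) / (max - min)` so training columns span `[0, 1]`
#' (held-out rows may fall outside). Constant columns map to 0.
#'
#' @param train A `feature_table` with at least one row.
#' @return A `minmax_normalizer` object.
#' @export
fit_normalizer <- function(train) {
  stopifnot(is.data.frame(train))
  if (nrow(train) == 0) abort_config("cannot fit a normalizer on 0 rows")
  cols <- intersect(feature_names, names(train))
  if (!length(cols)) abort_schema("table has no descriptor columns")
  structure(list(columns = cols,
                 min = vapply(train[cols], min, numeric(1)),
                 max = vapply(train[cols], max, numeric(1))),
            class = "minmax_normalizer")
}

#' @rdname fit_normalizer
#' @param norm A fitted `minmax_normalizer`.
#' @param table A `feature_table` to rescale.
#' @export
apply_normalizer <- function(norm, table) {
  if (!inherits(norm, "minmax_normalizer"))
    abort_state("apply_normalizer() needs a fitted normalizer")
  missing <- setdiff(norm$columns, names(table))
  if (length(missing))
    abort_schema("table lacks descriptor columns: %s",
                 paste(missing, collapse = ", "))
  for (cn in norm$columns) {
    span <- norm$max[[cn]] - norm$min[[cn]]
    table[[cn]] <- if (span > 0) (table[[cn]] - norm$min[[cn]]) / span
                   else rep(0, nrow(table))
  }
  table
}
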