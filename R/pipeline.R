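#' Feature table from a set of recordings
#'
#' Segments every recording (cancel, crop, detect, window) and computes the
#' 19 descriptors per window. Accepts a list of [radargram()]s or a
#' directory containing `manifest.csv` plus per-recording CSVs (the layout
#' written by [generate_dataset()]).
#'
#' @param recordings List of [radargram()]s, or a directory path.
#' @param geometry A [radar_geometry()].
#' @param cfg A [peak_config()].
#' @param window_size Window length in bins.
#' @param frame_rate_hz Frame rate used when reading from disk.
#' @param verbose Log per-stage row counts via `message()`.
#' @return A labelled `feature_table`.
#' @export
build_feature_table <- function(recordings, geometry = radar_geometry(),
                                cfg = peak_config(), window_size = 10L,
                                frame_rate_hz = 20, verbose = FALSE) {
  if (is.character(recordings)) {
    manifest_path <- file.path(recordings, "manifest.csv")
    if (!file.exists(manifest_path))
      abort_data("no manifest.csv in %s", recordings)
    manifest <- utils::read.csv(manifest_path)
    recordings <- lapply(seq_len(nrow(manifest)), function(i)
      read_radargram(file.path(dirname(manifest_path), manifest$file[i]),
                     frame_rate_hz = frame_rate_hz,
                     label = manifest$label[i]))
  }
  wins <- lapply(recordings, segment_recording, geometry = geometry,
                 cfg = cfg, window_size = window_size)
  wins <- wins[vapply(wins, nrow, integer(1)) > 0]
  if (!length(wins))
    abort_data("no peaks detected in any recording")
  windows <- do.call(rbind, wins)
  if (verbose)
    message(sprintf("segmented %d recordings into %d windows",
                    length(recordings), nrow(windows)))
  out <- featurize(windows)
  if (verbose)
    message(sprintf("featurized %d rows x %d descriptors", nrow(out),
                    length(feature_names)))
  out
}

#' End-to-end synthetic benchmark run
#'
#' Generates a labelled synthetic dataset, builds the feature table, makes
#' one stratified 70/30 split, fits normalization and fusion on the
#' training rows, and trains/evaluates the requested classifiers on both
#' raw and fused features.
#'
#' @param preset `"easy"` or `"hard"` (see [scenario_presets()]).
#' @param n_per_class Recordings per class.
#' @param specs List of [model_spec()]s.
#' @param seed Master seed (dataset, split, fold assignment).
#' @param train_frac Training fraction.
#' @param fusion_cfg A [fusion_config()].
#' @param verbose Log stage progress.
#' @return The [compare_raw_vs_fused()] result plus `features`.
#' @export
run_benchmark <- function(preset = "easy", n_per_class = 40L,
                          specs = list(model_spec("ensemble_rrgraboost")),
                          seed = 123L, train_frac = 0.7,
                          fusion_cfg = fusion_config(),
                          verbose = FALSE) {
  scenarios <- scenario_presets(preset)
  ds <- generate_dataset(scenarios, n_per_class, seed)
  if (verbose)
    message(sprintf("simulated %d recordings (%s preset)",
                    length(ds$radargrams), preset))
  features <- build_feature_table(ds$radargrams, verbose = verbose)
  res <- compare_raw_vs_fused(features, specs, train_frac = train_frac,
                              seed = seed, fusion_cfg = fusion_cfg)
  res$features <- features
  res
}
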