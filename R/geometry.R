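#' Radar acquisition geometry
#'
#' Describes how fast-time columns of a radar scan map onto radial distance,
#' and which column range (region of interest, ROI) contains the subject's
#' upper-limb motion. Defaults reproduce the study setup: a 950 cm total
#' scanned range digitized into 1440 range bins (0.659 cm per bin), a subject
#' standing at roughly 2 m, and an ROI of columns 259--320 (62 columns).
#'
#' Columns are 1-based and `roi_end_col` is inclusive, so the ROI width is
#' `roi_end_col - roi_start_col + 1`. The ROI is configuration, not derived
#' from `subject_distance_cm`: the asserted column range is kept verbatim and
#' [bin_of()] is offered as a helper for cross-checking distances.
#'
#' @param total_range_cm Total scanned radial distance in cm.
#' @param n_bins Number of fast-time range bins (columns).
#' @param subject_distance_cm Nominal subject distance in cm (metadata only).
#' @param roi_start_col,roi_end_col 1-based inclusive ROI column bounds.
#' @return A `radar_geometry` object (a validated list).
#' @examples
#' geom <- radar_geometry()
#' bin_width_cm(geom)          # 0.6597...
#' bin_of(200, geom)           # 303
#' @export
radar_geometry <- function(total_range_cm = 950, n_bins = 1440,
                           subject_distance_cm = 200,
                           roi_start_col = 259, roi_end_col = 320) {
  if (!is.numeric(total_range_cm) || total_range_cm <= 0)
    abort_config("total_range_cm must be positive, got %s",
                 format(total_range_cm))
  if (!is_count(n_bins) || n_bins < 1)
    abort_config("n_bins must be a positive integer")
  if (!is_count(roi_start_col) || !is_count(roi_end_col) ||
      roi_start_col < 1 || roi_end_col < roi_start_col || roi_end_col > n_bins)
    abort_config("ROI [%s, %s] must satisfy 1 <= start <= end <= n_bins (%d)",
                 format(roi_start_col), format(roi_end_col), n_bins)
  structure(list(total_range_cm = as.numeric(total_range_cm),
                 n_bins = as.integer(n_bins),
                 subject_distance_cm = as.numeric(subject_distance_cm),
                 roi_start_col = as.integer(roi_start_col),
                 roi_end_col = as.integer(roi_end_col)),
            class = "radar_geometry")
}

#' @export
print.radar_geometry <- function(x, ...) {
  cat(sprintf(
    "<radar_geometry> %g cm over %d bins (%.3f cm/bin), ROI cols %d-%d (%d)\n",
    x$total_range_cm, x$n_bins, bin_width_cm(x),
    x$roi_start_col, x$roi_end_col, x$roi_end_col - x$roi_start_col + 1L))
  invisible(x)
}

#' Width of one range bin in centimetres
#'
#' `total_range_cm / n_bins`, at full double precision. The study quotes this
#' value truncated to three decimals (950/1440 -> 0.659 cm).
#'
#' @param geometry A [radar_geometry()].
#' @return Bin width in cm.
#' @export
bin_width_cm <- function(geometry) {
  stopifnot(inherits(geometry, "radar_geometry"))
  geometry$total_range_cm / geometry$n_bins
}

#' Map a radial distance to its 1-based range-bin column
#'
#' Rounds `distance_cm / bin_width_cm(geometry)` half away from zero and
#' clamps the result into `[1, n_bins]`. Distances must lie inside the
#' scanned range.
#'
#' @param distance_cm Radial distance in cm, in `[0, total_range_cm]`.
#' @param geometry A [radar_geometry()].
#' @return Integer column index (vectorized over `distance_cm`).
#' @export
bin_of <- function(distance_cm, geometry) {
  stopifnot(inherits(geometry, "radar_geometry"))
  if (any(!is.finite(distance_cm)) ||
      any(distance_cm < 0 | distance_cm > geometry$total_range_cm))
    abort_domain("distance_cm must lie in [0, %g] cm",
                 geometry$total_range_cm)
  col <- round_half_away(distance_cm / bin_width_cm(geometry))
  as.integer(pmin(pmax(col, 1), geometry$n_bins))
}
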