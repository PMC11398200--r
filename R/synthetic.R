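#' Exercise scenario for the synthetic radar-gram simulator
#'
#' A scenario describes one exercise class as one or two oscillating point
#' scatterers in front of the radar: each scatterer s follows the range
#' trajectory
#' `r_s(t) = center_range_cm + osc_amplitude_cm * sin(2*pi*osc_freq_hz*t
#'           + phase_offsets[s]) + drift_cm_per_s * t
#'           (+ osc_amplitude2_cm * sin(2*pi*osc_freq2_hz*t))`,
#' rendered as a Gaussian pulse in fast time of width `pulse_width_bins`
#' scaled by `return_amplitude`, on top of a per-bin static clutter offset
#' (drawn once per recording) and white Gaussian noise. Scatterer 2, when
#' present, is displaced by `scatterer_sep_cm`.
#'
#' Label encoding is 1 = LSA, 2 = BSA, 3 = SFU, 4 = SFD, 5 = BS.
#'
#' @param class_label Integer exercise class in 1..5.
#' @param n_scatterers 1 or 2 oscillating point scatterers.
#' @param center_range_cm Mean scatterer distance from the radar in cm.
#' @param osc_amplitude_cm Oscillation amplitude in cm.
#' @param osc_freq_hz Oscillation frequency in Hz.
#' @param phase_offsets Radians, one per scatterer.
#' @param drift_cm_per_s Linear range drift superposed on the oscillation
#'   (approaching < 0 < receding).
#' @param osc_freq2_hz,osc_amplitude2_cm Optional second oscillation
#'   component (used for the breaststroke preset).
#' @param scatterer_sep_cm Range offset of the second scatterer.
#' @param return_amplitude Peak return amplitude (dimensionless counts). The
#'   default keeps clutter-removed peaks above the study's 0.4e4 detection
#'   threshold at typical limb speeds.
#' @param clutter_amplitude Scale of the static per-bin clutter offsets.
#' @param noise_sd Standard deviation of the additive white noise.
#' @param frame_rate_hz,n_frames,n_bins Acquisition layout (defaults
#'   20 Hz, 120 frames, 1440 bins).
#' @param pulse_width_bins Gaussian pulse standard deviation in bins.
#' @param geometry A [radar_geometry()] used to map cm to bins.
#' @return An `exercise_scenario` object.
#' @export
exercise_scenario <- function(class_label,
                              n_scatterers = 1L,
                              center_range_cm = 200,
                              osc_amplitude_cm = 2,
                              osc_freq_hz = 2,
                              phase_offsets = rep(0.6, n_scatterers),
                              drift_cm_per_s = 0,
                              osc_freq2_hz = 0,
                              osc_amplitude2_cm = 0,
                              scatterer_sep_cm = 0,
                              return_amplitude = 6000,
                              clutter_amplitude = 2000,
                              noise_sd = 50,
                              frame_rate_hz = 20,
                              n_frames = 120L,
                              n_bins = 1440L,
                              pulse_width_bins = 1,
                              geometry = radar_geometry(n_bins = n_bins)) {
  if (!is_count(class_label) || !(class_label %in% 1:5))
    abort_config("class_label must be an integer in 1..5")
  if (!is_count(n_scatterers) || n_scatterers < 1)
    abort_config("n_scatterers must be >= 1")
  if (!is_count(n_frames) || n_frames < 2)
    abort_config("n_frames must be >= 2 (the pulse canceller needs 2 frames)")
  if (length(phase_offsets) != n_scatterers)
    abort_config("need one phase offset per scatterer (%d != %d)",
                 length(phase_offsets), n_scatterers)
  if (return_amplitude < 0 || clutter_amplitude < 0 || noise_sd < 0)
    abort_config("amplitudes and noise_sd must be >= 0")
  if (pulse_width_bins <= 0)
    abort_config("pulse_width_bins must be positive")
  duration <- (n_frames - 1) / frame_rate_hz
  excursion <- abs(osc_amplitude_cm) + abs(osc_amplitude2_cm) +
    abs(drift_cm_per_s) * duration + max(0, scatterer_sep_cm)
  if (center_range_cm - excursion < 0 ||
      center_range_cm + excursion > geometry$total_range_cm)
    abort_config(paste0("trajectory [%g, %g] cm leaves the scanned range ",
                        "[0, %g] cm"),
                 center_range_cm - excursion, center_range_cm + excursion,
                 geometry$total_range_cm)
  structure(list(class_label = as.integer(class_label),
                 n_scatterers = as.integer(n_scatterers),
                 center_range_cm = center_range_cm,
                 osc_amplitude_cm = osc_amplitude_cm,
                 osc_freq_hz = osc_freq_hz,
                 phase_offsets = phase_offsets,
                 drift_cm_per_s = drift_cm_per_s,
                 osc_freq2_hz = osc_freq2_hz,
                 osc_amplitude2_cm = osc_amplitude2_cm,
                 scatterer_sep_cm = scatterer_sep_cm,
                 return_amplitude = return_amplitude,
                 clutter_amplitude = clutter_amplitude,
                 noise_sd = noise_sd,
                 frame_rate_hz = frame_rate_hz,
                 n_frames = as.integer(n_frames),
                 n_bins = as.integer(n_bins),
                 pulse_width_bins = pulse_width_bins,
                 geometry = geometry),
            class = "exercise_scenario")
}

#' Scenario presets for the five exercise classes
#'
#' Presets are read from the packaged YAML config
#' (`inst/extdata/scenario_presets.yaml`); [scenarios_from_yaml()] loads
#' the same format from any path, so alternative preset files can be
#' supplied without touching code.
#'
#' Two benchmark difficulty levels. `"easy"` gives each class a distinct
#' combination of oscillation frequency, scatterer count and pulse width
#' at high signal-to-noise ratio, so the classes separate in the
#' descriptor space; `"hard"` shares the pulse width across classes,
#' narrows the oscillation differences, and adds strong noise, so raw
#' descriptors overlap and the probability-fusion stage has headroom.
#'
#' Class motion mapping (mirroring the exercise descriptions): LSA one
#' scatterer; BSA two in-phase scatterers at slightly different ranges
#' (both arms); SFU/SFD one scatterer with a receding/approaching linear
#' drift superposed; BS one scatterer with two superposed oscillation
#' frequencies (circular stroke).
#'
#' @param preset `"easy"` or `"hard"`.
#' @return Named list of five [exercise_scenario()] objects
#'   (`LSA`, `BSA`, `SFU`, `SFD`, `BS`).
#' @export
scenario_presets <- function(preset = c("easy", "hard")) {
  preset <- match.arg(preset)
  path <- system.file("extdata", "scenario_presets.yaml",
                      package = "radrehab", mustWork = TRUE)
  scenarios_from_yaml(path, preset)
}

#' Load exercise scenarios from a YAML config
#'
#' The file maps preset names to named scenario blocks whose fields are
#' the arguments of [exercise_scenario()].
#'
#' @param path YAML file path.
#' @param preset Top-level key to read.
#' @return Named list of [exercise_scenario()] objects.
#' @export
scenarios_from_yaml <- function(path, preset) {
  if (!file.exists(path)) abort_config("no such preset file: %s", path)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg[[preset]]))
    abort_config("preset '%s' not found in %s (has: %s)", preset, path,
                 paste(names(cfg), collapse = ", "))
  lapply(cfg[[preset]], function(fields) {
    fields$class_label <- as.integer(fields$class_label)
    if (!is.null(fields$n_scatterers))
      fields$n_scatterers <- as.integer(fields$n_scatterers)
    do.call(exercise_scenario, fields)
  })
}

# Continuous range trajectory of scatterer s at times t (seconds).
scenario_trajectory <- function(scenario, t, s = 1L) {
  r <- scenario$center_range_cm +
    scenario$osc_amplitude_cm *
      sin(2 * pi * scenario$osc_freq_hz * t + scenario$phase_offsets[s]) +
    scenario$drift_cm_per_s * t
  if (scenario$osc_amplitude2_cm != 0)
    r <- r + scenario$osc_amplitude2_cm *
      sin(2 * pi * scenario$osc_freq2_hz * t)
  if (s > 1L) r <- r + scenario$scatterer_sep_cm
  r
}

#' Generate one synthetic radar-gram
#'
#' Renders `clutter(bin) + sum_s pulse(bin - bin(r_s(t))) * return_amplitude
#' + noise` on the scenario's frame/bin grid. Clutter is a per-bin constant
#' drawn once per recording (frame-invariant, so the two-pulse canceller
#' removes it exactly); the pulse is a unit-height Gaussian of width
#' `pulse_width_bins`. Identical `(scenario, seed)` give bit-identical
#' output.
#'
#' @param scenario An [exercise_scenario()].
#' @param seed Integer seed.
#' @param source_id Identifier stored on the radar-gram.
#' @return A labelled [radargram()].
#' @export
generate_radargram <- function(scenario, seed,
                               source_id = sprintf("sim_c%d_s%d",
                                                   scenario$class_label,
                                                   seed)) {
  stopifnot(inherits(scenario, "exercise_scenario"))
  bw <- bin_width_cm(scenario$geometry)
  t <- (seq_len(scenario$n_frames) - 1) / scenario$frame_rate_hz
  bins <- seq_len(scenario$n_bins)
  with_seed(seed, {
    clutter <- stats::runif(scenario$n_bins, 0, scenario$clutter_amplitude)
    v <- matrix(rep(clutter, each = scenario$n_frames),
                scenario$n_frames, scenario$n_bins)
    for (s in seq_len(scenario$n_scatterers)) {
      pos <- scenario_trajectory(scenario, t, s) / bw
      dev <- outer(pos, bins, function(p, b) b - p)
      v <- v + scenario$return_amplitude *
        exp(-0.5 * (dev / scenario$pulse_width_bins)^2)
    }
    if (scenario$noise_sd > 0)
      v <- v + matrix(stats::rnorm(length(v), 0, scenario$noise_sd),
                      nrow(v), ncol(v))
    radargram(v, frame_rate_hz = scenario$frame_rate_hz,
              source_id = source_id, label = scenario$class_label)
  })
}

#' Generate a labelled synthetic dataset
#'
#' `n_per_class` recordings per scenario, each with a seed derived
#' reproducibly from the master seed. When `dir` is given, every recording
#' is written as a headerless CSV plus a `manifest.csv` with columns
#' `file,label,seed,scenario_id`.
#'
#' @param scenarios List of [exercise_scenario()]s covering every class
#'   label present, e.g. [scenario_presets()].
#' @param n_per_class Recordings per scenario.
#' @param seed Master seed.
#' @param dir Optional output directory (created if missing).
#' @return Invisible list with `radargrams` (list of [radargram()]) and
#'   `manifest` (data.frame).
#' @export
generate_dataset <- function(scenarios, n_per_class, seed, dir = NULL) {
  if (!length(scenarios)) abort_config("no scenarios given")
  labels <- vapply(scenarios, function(s) s$class_label, integer(1))
  if (!all(1:5 %in% labels))
    abort_config("missing scenario for class(es): %s",
                 paste(setdiff(1:5, labels), collapse = ", "))
  ids <- names(scenarios) %||% paste0("scenario", seq_along(scenarios))
  rgs <- list()
  manifest <- list()
  k <- 0L
  for (i in seq_along(scenarios)) {
    for (j in seq_len(n_per_class)) {
      k <- k + 1L
      rec_seed <- derive_seed(seed, k)
      sid <- sprintf("rec_%s_%03d", ids[i], j)
      rg <- generate_radargram(scenarios[[i]], rec_seed, source_id = sid)
      rgs[[sid]] <- rg
      manifest[[k]] <- data.frame(file = paste0(sid, ".csv"),
                                  label = labels[i], seed = rec_seed,
                                  scenario_id = ids[i])
    }
  }
  manifest <- do.call(rbind, manifest)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    for (sid in names(rgs))
      write_radargram(rgs[[sid]], file.path(dir, paste0(sid, ".csv")))
    utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  invisible(list(radargrams = rgs, manifest = manifest))
}
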