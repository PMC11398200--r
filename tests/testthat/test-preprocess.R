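test_that("two-pulse canceller implements successive-frame differencing", {
  rg <- radargram(matrix(c(1, 2, 4, 6, 5, 3), 3, 2, byrow = TRUE))
  out <- two_pulse_cancel(rg)
  expect_equal(out$values, matrix(c(3, 4, 1, -3), 2, 2, byrow = TRUE))

  # brute-force elementwise oracle on a random matrix
  m <- withr_seed(4, matrix(stats::rnorm(20 * 30), 20, 30))
  got <- two_pulse_cancel(radargram(m))$values
  want <- matrix(0, 19, 30)
  for (i in 1:19) for (j in 1:30) want[i, j] <- m[i + 1, j] - m[i, j]
  expect_identical(got, want)

  # static scene cancels exactly; frame-constant offsets are annihilated
  static <- radargram(matrix(7, 5, 8))
  expect_true(all(two_pulse_cancel(static)$values == 0))
  offs <- m + matrix(rep(stats::runif(30, -5, 5), each = 20), 20, 30)
  expect_equal(two_pulse_cancel(radargram(offs))$values, got,
               tolerance = 1e-12)

  # a single cancelled frame cannot be cancelled again
  once <- two_pulse_cancel(radargram(matrix(1:6, 2, 3)))
  expect_error(two_pulse_cancel(once), class = "radrehab_config_error")
})

test_that("ROI cropping keeps the verbatim sub-block", {
  m <- withr_seed(5, matrix(stats::rnorm(10 * 1440), 10, 1440))
  geom <- radar_geometry()
  out <- crop_roi(radargram(m), geom)
  expect_identical(ncol(out$values), 62L)
  for (j in seq_len(62))
    expect_identical(out$values[, j], m[, j + geom$roi_start_col - 1L])
  # full-extent ROI is the identity
  g_full <- radar_geometry(n_bins = 1440, roi_start_col = 1,
                           roi_end_col = 1440)
  expect_identical(crop_roi(radargram(m), g_full)$values, m)
  # out-of-bounds ROI is a configuration error
  expect_error(crop_roi(radargram(m[, 1:100]), geom),
               class = "radrehab_config_error")
})

test_that("peak detection applies threshold, local-max and separation rules", {
  cfg <- peak_config()
  expect_identical(detect_peaks(rep(3999, 62), cfg), integer(0))
  frame <- numeric(62); frame[30] <- 5000
  expect_identical(detect_peaks(frame, cfg), 30L)
  # threshold acts on absolute value of the signed cancelled signal
  frame[30] <- -5000
  expect_identical(detect_peaks(frame, cfg), 30L)

  # exhaustive scan oracle on random multi-modal frames
  oracle_detect <- function(x, thr, sep) {
    a <- abs(x)
    cand <- integer(0)
    for (i in seq_along(a)) {
      if (a[i] < thr) next
      left <- if (i == 1) TRUE else a[i] > a[i - 1]
      right <- if (i == length(a)) TRUE else a[i] > a[i + 1]
      if (left && right) cand <- c(cand, i)
    }
    if (sep > 1 && length(cand) > 1) {
      kept <- integer(0)
      for (i in cand[order(a[cand], decreasing = TRUE)])
        if (!length(kept) || all(abs(kept - i) >= sep)) kept <- c(kept, i)
      cand <- sort(kept)
    }
    cand
  }
  withr_seed(6, {
    for (rep_i in 1:50) {
      x <- stats::rnorm(62, sd = 3000)
      for (sep in c(1L, 4L, 10L)) {
        cfg_i <- peak_config(threshold = 2000, min_separation_bins = sep)
        expect_identical(detect_peaks(x, cfg_i),
                         as.integer(oracle_detect(x, 2000, sep)))
      }
    }
  })
})

test_that("raising the threshold never increases the peak count", {
  withr_seed(8, {
    for (rep_i in 1:20) {
      x <- stats::rnorm(62, sd = 4000)
      counts <- vapply(c(0, 1000, 2000, 4000, 8000), function(thr)
        length(detect_peaks(x, peak_config(threshold = thr))), integer(1))
      expect_true(all(diff(counts) <= 0))
    }
  })
})

test_that("window extraction is half-open, fixed-length, and edge-shifted", {
  frame <- seq_len(62)
  w <- extract_window(frame, 50L, 10L)
  expect_identical(w$start_col, 45L)
  expect_identical(w$values, 45:54)      # [p-5, p+5)
  w_lo <- extract_window(frame, 3L, 10L)
  expect_identical(w_lo$values, 1:10)    # shifted, not shrunk
  w_hi <- extract_window(frame, 60L, 10L)
  expect_identical(w_hi$values, 53:62)
  expect_error(extract_window(1:5, 3L, 10L),
               class = "radrehab_config_error")
  expect_error(extract_window(frame, 70L), class = "radrehab_domain_error")
})

test_that("a static synthetic scene yields zero windows", {
  sc <- exercise_scenario(1L, osc_amplitude_cm = 0, noise_sd = 0)
  rg <- generate_radargram(sc, 1)
  expect_true(all(two_pulse_cancel(rg)$values == 0))
  expect_identical(nrow(segment_recording(rg)), 0L)
})

test_that("a noiseless moving scatterer yields one tracked window per frame", {
  sc <- noiseless_scenario()
  rg <- generate_radargram(sc, 42)
  # near-zero threshold + wide suppression: exactly the strongest return
  # per cancelled frame survives
  cfg <- peak_config(threshold = 1e-6, min_separation_bins = 62L)
  wins <- segment_recording(rg, cfg = cfg)
  expect_identical(nrow(wins), sc$n_frames - 1L)
  expect_identical(wins$frame_index, seq_len(119L))
  # the kept peak sits within 2 bins of the nearer of the two frame
  # positions bounding each difference (derivative-lobe geometry of the
  # Gaussian pulse allows up to ~pulse_width offset)
  geom <- sc$geometry
  t <- (seq_len(sc$n_frames) - 1) / sc$frame_rate_hz
  traj_bins <- radrehab:::scenario_trajectory(sc, t) / bin_width_cm(geom)
  for (i in seq_len(nrow(wins))) {
    abs_col <- wins$peak_col[i] + geom$roi_start_col - 1L
    d <- min(abs(abs_col - traj_bins[i]), abs(abs_col - traj_bins[i + 1]))
    expect_lt(d, 2.5)
  }
  expect_identical(unique(wins$label), 1L)
})

test_that("segmentation commutes with frame order up to bookkeeping", {
  sc <- noiseless_scenario(n_frames = 40L)
  rg <- generate_radargram(sc, 9)
  cfg <- peak_config(threshold = 1e-6, min_separation_bins = 62L)
  wins <- segment_recording(rg, cfg = cfg)
  vcols <- paste0("v", 1:10)
  key <- function(df) sort(unname(apply(df[, vcols], 1, paste,
                                        collapse = ",")))
  # windows are verbatim slices of the cancelled, cropped matrix
  cc <- crop_roi(two_pulse_cancel(rg), radar_geometry())$values
  for (i in seq_len(nrow(wins))) {
    expect_identical(as.numeric(wins[i, vcols]),
                     cc[wins$frame_index[i],
                        wins$start_col[i]:(wins$start_col[i] + 9L)])
  }
  # shuffling whole frames (and re-segmenting each in isolation) leaves the
  # multiset of window value-vectors of those frames unchanged
  pick <- c(5L, 17L, 30L)
  sub_direct <- wins[wins$frame_index %in% pick, ]
  sub_resegment <- do.call(rbind, lapply(rev(pick), function(i) {
    rg_i <- radargram(rbind(rg$values[i, ], rg$values[i + 1L, ]),
                      source_id = rg$source_id, label = rg$label)
    segment_recording(rg_i, cfg = cfg)
  }))
  expect_identical(key(sub_direct), key(sub_resegment))
})
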