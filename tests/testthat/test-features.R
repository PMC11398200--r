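test_that("window spectra match closed forms and an O(N^2) DFT oracle", {
  # DC-only: constant window
  sp <- compute_spectrum(rep(3, 10))
  expect_equal(sp$magnitudes[1], 30)
  expect_equal(sp$magnitudes[-1], rep(0, 9), tolerance = 1e-9)
  # single tone at k = 2 concentrates at bins 2 and N-2 (0-based)
  tone <- cos(2 * pi * 2 * (0:9) / 10)
  spt <- compute_spectrum(tone)
  expect_equal(order(spt$magnitudes, decreasing = TRUE)[1:2],
               c(3L, 9L), ignore_attr = TRUE)
  # random vectors vs direct double-sum DFT
  withr_seed(21, {
    for (rep_i in 1:20) {
      x <- stats::rnorm(10)
      got <- compute_spectrum(x)
      m <- length(x)
      want <- vapply(0:(m - 1), function(k)
        Mod(sum(x * exp(-2i * pi * k * (0:(m - 1)) / m))), numeric(1))
      expect_equal(got$magnitudes, want, tolerance = 1e-9)
      # Parseval
      expect_equal(sum(x^2), sum(got$magnitudes^2) / m, tolerance = 1e-9)
    }
  })
})

test_that("degenerate spectra hit their closed-form descriptor values", {
  # all mass at one bin: the one-sided spectrum is a delta
  delta_vals <- rep(5, 10)  # DC only -> delta at f = 0
  d <- spectral_descriptors(compute_spectrum(delta_vals))
  expect_equal(d[["spectral_centroid"]], 0)
  expect_equal(d[["spectral_spread"]], 0)
  expect_equal(d[["spectral_entropy"]], 0)
  expect_equal(d[["spectral_flatness"]], 0)
  expect_equal(d[["spectral_crest"]], 6)  # n_bins one-sided
  expect_equal(d[["spectral_rolloff"]], 0)
  # uniform one-sided magnitudes: a unit impulse has a flat spectrum
  u <- spectral_descriptors(compute_spectrum(c(1, rep(0, 9))))
  expect_equal(u[["spectral_entropy"]], 1)
  expect_equal(u[["spectral_flatness"]], 1)
  expect_equal(u[["spectral_crest"]], 1)
  expect_equal(u[["spectral_slope"]], 0)
  # all-zero spectrum: every descriptor is 0 by convention
  z <- spectral_descriptors(compute_spectrum(rep(0, 10)))
  expect_true(all(z == 0))
})

test_that("descriptors match an independent scalar formula oracle", {
  withr_seed(22, {
    for (rep_i in 1:200) {
      x <- stats::rnorm(10, sd = stats::runif(1, 0.1, 5000))
      prev <- if (rep_i %% 3 == 0) stats::rnorm(10) else NULL
      got <- spectral_descriptors(compute_spectrum(x),
                                  if (!is.null(prev)) compute_spectrum(prev))
      want <- oracle_spectral(x, prev)
      expect_equal(got, want, tolerance = 1e-9)
    }
  })
})

test_that("amplitude and phase statistics match direct recomputation", {
  s7 <- amplitude_phase_stats(rep(7, 10))
  expect_equal(s7[["amplitude"]], 7)
  expect_equal(s7[["amplitude_sd"]], 0)
  expect_equal(s7[["amplitude_range"]], 0)
  spike <- c(rep(0, 4), 5000, rep(0, 5))
  ss <- amplitude_phase_stats(spike)
  expect_equal(ss[["amplitude"]], 5000)
  expect_equal(ss[["amplitude_range"]], 5000)
  withr_seed(23, {
    for (rep_i in 1:30) {
      x <- stats::rnorm(10, sd = 100)
      got <- amplitude_phase_stats(x)
      a <- abs(x)
      X <- stats::fft(x)[1:6]
      ph <- Arg(X)
      expect_equal(got[["amplitude"]], max(a))
      expect_equal(got[["amplitude_mean"]], mean(a))
      expect_equal(got[["amplitude_sd"]], stats::sd(a))
      expect_equal(got[["amplitude_range"]], max(a) - min(a))
      expect_equal(got[["phase"]], ph[which.max(Mod(X))])
      expect_equal(got[["phase_mean"]], mean(ph))
      expect_equal(got[["phase_sd"]], stats::sd(ph))
      expect_equal(got[["phase_range"]], max(ph) - min(ph))
    }
  })
})

test_that("positive rescaling of a window moves only the scale-carrying
           descriptors", {
  invariant <- c("spectral_entropy", "spectral_flatness", "spectral_crest",
                 "spectral_centroid", "spectral_spread",
                 "spectral_skewness", "spectral_kurtosis",
                 "spectral_rolloff")
  withr_seed(24, {
    for (rep_i in 1:20) {
      x <- stats::rnorm(10)
      lam <- stats::runif(1, 0.2, 50)
      d1 <- spectral_descriptors(compute_spectrum(x))
      d2 <- spectral_descriptors(compute_spectrum(lam * x))
      expect_equal(d1[invariant], d2[invariant], tolerance = 1e-9)
      a1 <- amplitude_phase_stats(x)
      a2 <- amplitude_phase_stats(lam * x)
      amp <- c("amplitude", "amplitude_mean", "amplitude_sd",
               "amplitude_range")
      expect_equal(lam * a1[amp], a2[amp], tolerance = 1e-9)
    }
  })
})

test_that("featurize emits one labelled 19-descriptor row per window", {
  sc <- noiseless_scenario(n_frames = 30L)
  rg <- generate_radargram(sc, 3)
  wins <- segment_recording(rg, cfg = peak_config(threshold = 1e-6,
                                                  min_separation_bins = 62L))
  ft <- featurize(wins)
  expect_identical(nrow(ft), nrow(wins))
  expect_identical(setdiff(names(ft), "source_id"),
                   c(feature_names, "label"))
  expect_true(all(ft$label == 1L))
  expect_true(all(is.finite(as.matrix(ft[, feature_names]))))
  # permuting windows permutes rows only
  perm <- rev(seq_len(nrow(wins)))
  ft2 <- featurize(wins[perm, ])
  expect_equal(ft2[order(perm), feature_names], ft[, feature_names],
               ignore_attr = TRUE)
})

test_that("flux tracks the previous frame's nearest-peak window", {
  sc <- noiseless_scenario(n_frames = 30L)
  rg <- generate_radargram(sc, 3)
  wins <- segment_recording(rg, cfg = peak_config(threshold = 1e-6,
                                                  min_separation_bins = 62L))
  ft <- featurize(wins)
  vcols <- paste0("v", 1:10)
  expect_equal(ft$spectral_flux[1], 0)  # no previous frame
  for (i in 2:5) {
    w_now <- oracle_magnitudes(as.numeric(wins[i, vcols]))
    w_prev <- oracle_magnitudes(as.numeric(wins[i - 1, vcols]))
    expect_equal(ft$spectral_flux[i], sum((w_now - w_prev)^2),
                 tolerance = 1e-6)
  }
})

test_that("min-max normalization is fit on train and applied elsewhere", {
  tab <- toy_feature_table(15)
  tab$spectral_flux <- 5  # constant column maps to 0
  norm <- fit_normalizer(tab)
  scaled <- apply_normalizer(norm, tab)
  for (cn in setdiff(feature_names, "spectral_flux")) {
    expect_equal(min(scaled[[cn]]), 0)
    expect_equal(max(scaled[[cn]]), 1)
  }
  expect_true(all(scaled$spectral_flux == 0))
  # held-out rows use the train min/max and may leave [0, 1]
  test_tab <- toy_feature_table(5, seed = 99)
  got <- apply_normalizer(norm, test_tab)
  for (cn in c("amplitude", "phase")) {
    want <- (test_tab[[cn]] - norm$min[[cn]]) /
      (norm$max[[cn]] - norm$min[[cn]])
    expect_equal(got[[cn]], want)
  }
  expect_error(apply_normalizer(structure(list(), class = "list"), tab),
               class = "radrehab_state_error")
  expect_error(apply_normalizer(norm, data.frame(a = 1)),
               class = "radrehab_schema_error")
})
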