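# Shared fixtures, built in code at test time.

# A tiny, well-separated 2-class descriptor table: class 1 clusters low,
# class 2 clusters high on the first two descriptors.
toy_feature_table <- function(n_per_class = 20, seed = 7, labels = c(1L, 2L)) {
  stopifnot(length(labels) >= 2)
  rows <- withr_seed(seed, {
    do.call(rbind, lapply(seq_along(labels), function(i) {
      m <- matrix(stats::rnorm(n_per_class * 19, mean = 3 * (i - 1), sd = 0.3),
                  n_per_class, 19)
      m
    }))
  })
  colnames(rows) <- feature_names
  out <- data.frame(source_id = "toy", rows,
                    label = rep(labels, each = n_per_class),
                    check.names = FALSE)
  class(out) <- c("feature_table", "data.frame")
  out
}

# Local stand-in for withr::with_seed (withr not assumed at test run time).
withr_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}

# A noiseless single-scatterer scene whose ground-truth trajectory is known.
noiseless_scenario <- function(...) {
  exercise_scenario(1L, center_range_cm = 195, osc_amplitude_cm = 12,
                    osc_freq_hz = 0.43, noise_sd = 0, clutter_amplitude = 1500,
                    pulse_width_bins = 1, ...)
}

# Independent scalar reimplementation of the 11 spectral descriptors,
# written directly from their formulas (loops, no vectorized reuse of the
# package code).
oracle_spectral <- function(values, prev_values = NULL, rolloff_prop = 0.85) {
  n <- length(values)
  m <- floor(n / 2) + 1
  X <- complex(real = numeric(m), imaginary = numeric(m))
  for (k in 0:(m - 1)) {
    acc <- 0 + 0i
    for (j in 0:(n - 1))
      acc <- acc + values[j + 1] * exp(-2i * pi * k * j / n)
    X[k + 1] <- acc
  }
  w <- Mod(X)
  f <- (0:(m - 1)) / n
  out <- stats::setNames(numeric(11), feature_names[9:19])
  tot <- sum(w)
  if (tot <= 0) return(out)
  p <- w / tot
  cen <- 0
  for (k in 1:m) cen <- cen + f[k] * p[k]
  spr2 <- 0
  for (k in 1:m) spr2 <- spr2 + (f[k] - cen)^2 * p[k]
  spr <- sqrt(spr2)
  skw <- krt <- 0
  if (spr > 0) {
    for (k in 1:m) {
      skw <- skw + (f[k] - cen)^3 * p[k]
      krt <- krt + (f[k] - cen)^4 * p[k]
    }
    skw <- skw / spr^3
    krt <- krt / spr^4
  }
  ent <- 0
  for (k in 1:m) if (p[k] > 0) ent <- ent - p[k] * log(p[k])
  ent <- ent / log(m)
  flat <- if (any(w == 0)) 0 else {
    lg <- 0
    for (k in 1:m) lg <- lg + log(w[k])
    exp(lg / m) / (tot / m)
  }
  crest <- max(w) / (tot / m)
  flux <- 0
  if (!is.null(prev_values)) {
    wp <- oracle_magnitudes(prev_values)
    for (k in 1:m) flux <- flux + (w[k] - wp[k])^2
  }
  fb <- mean(f)
  num <- den <- 0
  for (k in 1:m) {
    num <- num + (f[k] - fb) * (w[k] - mean(w))
    den <- den + (f[k] - fb)^2
  }
  slope <- num / den
  dn <- dd <- 0
  for (k in 2:m) {
    dn <- dn + (w[k] - w[1]) / (k - 1)
    dd <- dd + w[k]
  }
  dec <- if (dd > 0) dn / dd else 0
  cum <- 0
  roll <- f[m]
  for (k in 1:m) {
    cum <- cum + w[k]
    if (cum >= rolloff_prop * tot - 1e-12) { roll <- f[k]; break }
  }
  out[] <- c(cen, spr, skw, krt, ent, flat, crest, flux, slope, dec, roll)
  out
}

oracle_magnitudes <- function(values) {
  n <- length(values)
  m <- floor(n / 2) + 1
  w <- numeric(m)
  for (k in 0:(m - 1)) {
    acc <- 0 + 0i
    for (j in 0:(n - 1))
      acc <- acc + values[j + 1] * exp(-2i * pi * k * j / n)
    w[k + 1] <- Mod(acc)
  }
  w
}
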