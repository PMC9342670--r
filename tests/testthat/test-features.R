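make_sine_dataset <- function(freq, fs = 10, dur = 60, p = 1L, channels = 1L) {
  tt <- seq(0, dur - 1 / fs, by = 1 / fs)
  sig <- array(rep(sin(2 * pi * freq * tt), each = p * channels),
               dim = c(p, channels, length(tt)))
  fnirs_dataset(sig, fs, rep_len(c(1L, 0L), p))
}

test_that("low-pass filter passes DC and matches its frequency-response oracle", {
  ds <- tiny_dataset(p = 2L, channels = 2L, s = 200L)
  ds$signals[] <- 3.7
  out <- lowpass_filter(ds, 0.6)
  expect_equal(out$signals, ds$signals, tolerance = 1e-6)

  # oracle: squared magnitude of the digital Butterworth response
  # (forward-backward filtering doubles the attenuation in dB)
  bf <- signal::butter(4, 0.6 / 5, type = "low")
  gain2 <- function(f, fs = 10) {
    w <- 2 * pi * f / fs
    z <- exp(1i * w)
    Mod(sum(bf$b * z^-(seq_along(bf$b) - 1)) /
          sum(bf$a * z^-(seq_along(bf$a) - 1)))^2
  }

  hi <- make_sine_dataset(2)
  amp_hi <- sine_amplitude(lowpass_filter(hi, 0.6)$signals[1, 1, 100:500], 2, 10)
  expect_lt(amp_hi, 0.05)               # < 5% of unit input amplitude
  expect_equal(amp_hi, gain2(2), tolerance = 0.5 * gain2(2) + 1e-4)

  lo <- make_sine_dataset(0.1)
  amp_lo <- sine_amplitude(lowpass_filter(lo, 0.6)$signals[1, 1, 100:500], 0.1, 10)
  expect_equal(amp_lo, 1, tolerance = 0.05)
  expect_equal(amp_lo, gain2(0.1), tolerance = 0.01)

  expect_error(lowpass_filter(ds, 5), "Nyquist")
})

test_that("time-mean features z-normalize per channel across participants", {
  sig <- array(c(1, 3), dim = c(2, 1, 5))  # constant signals 1 and 3
  ds <- fnirs_dataset(sig, 10, c(0L, 1L))
  fm <- extract_time_mean(ds)
  expect_equal(unname(fm$values[, 1]), c(-1, 1))  # population-SD two-point z

  ds2 <- tiny_dataset(p = 10L, channels = 4L, s = 30L, seed = 9L)
  z <- extract_time_mean(ds2)$values
  expect_lt(max(abs(colMeans(z))), 1e-9)
  expect_equal(unname(apply(z, 2, function(v) sqrt(mean((v - mean(v))^2)))),
               rep(1, 4), tolerance = 1e-9)

  # re-normalizing normalized columns is a no-op
  z2 <- fnirsopt:::znorm_columns(z, "population")
  expect_equal(z2, z, tolerance = 1e-12)

  # zero across-participant variance is a named error
  ds2$signals[, 3, ] <- 5
  expect_error(extract_time_mean(ds2), "channel c3")
})

test_that("FC features are pairwise Pearson correlations in lexicographic order", {
  withr::with_seed(3, {
    base <- rnorm(50)
    sig <- array(0, dim = c(2, 3, 50))
    sig[1, 1, ] <- base; sig[1, 2, ] <- base; sig[1, 3, ] <- -base
    sig[2, , ] <- rnorm(150)
  })
  ds <- fnirs_dataset(sig, 10, c(1L, 0L))
  fm <- extract_fc(ds)
  expect_identical(colnames(fm$values), c("c1-c2", "c1-c3", "c2-c3"))
  expect_equal(unname(fm$values[1, ]), c(1, -1, -1))
  expect_true(all(fm$values >= -1 & fm$values <= 1))

  # reshapes to a symmetric unit-diagonal matrix
  m <- fc_to_matrix(fm$values[2, ], 3)
  expect_equal(m, t(m))
  expect_equal(diag(m), rep(1, 3))

  # 52 channels give the full C(52,2) pair count
  ds52 <- tiny_dataset(p = 2L, channels = 52L, s = 12L, seed = 4L)
  expect_equal(ncol(extract_fc(ds52)$values), 1326L)

  sigz <- sig; sigz[2, 2, ] <- 0
  expect_error(extract_fc(fnirs_dataset(sigz, 10, c(1L, 0L))),
               "participant 2, channel 2")
})

test_that("periodized db5 decomposition partitions energy exactly", {
  withr::with_seed(11, x <- rnorm(600))
  dec <- wavelet_decompose(x, 3)
  e <- wavelet_band_energies(dec)
  expect_named(e, c("a3", "d3", "d2", "d1"))
  expect_equal(sum(e), sum(x^2), tolerance = 1e-6)

  # independent oracle: one analysis step as an explicit orthogonal matrix
  h <- fnirsopt:::DB5_DEC_LO
  g <- fnirsopt:::db5_dec_hi()
  L <- 32L
  withr::with_seed(2, y <- rnorm(L))
  Wa <- t(vapply(seq_len(L / 2), function(k) {
    row <- numeric(L)
    idx <- (2 * (k - 1) + seq_along(h) - 1) %% L + 1
    for (n in seq_along(h)) row[idx[n]] <- row[idx[n]] + h[n]
    row
  }, numeric(L)))
  st <- fnirsopt:::dwt_step(y)
  expect_equal(st$a, as.numeric(Wa %*% y), tolerance = 1e-12)
  expect_equal(sum(st$a^2) + sum(st$d^2), sum(y^2), tolerance = 1e-12)

  expect_equal(approximation_band(10, 3), c(0, 0.625))
  expect_error(wavelet_decompose(rnorm(4), 3), "too short")
})

test_that("wavelet energy features behave on degenerate and standard input", {
  sig <- array(0, dim = c(2, 1, 64))
  sig[2, 1, ] <- rnorm(64)
  ds <- fnirs_dataset(sig, 10, c(1L, 0L))
  raw <- extract_wavelet_energy(ds, normalize = FALSE)
  expect_equal(unname(raw$values[1, 1]), 0)  # all-zero signal: zero energy
  expect_gt(raw$values[2, 1], 0)

  ds2 <- tiny_dataset(p = 6L, channels = 3L, s = 80L, seed = 8L)
  z <- extract_wavelet_energy(ds2)$values
  expect_lt(max(abs(colMeans(z))), 1e-9)
  rel <- extract_wavelet_energy(ds2, relative = TRUE, normalize = FALSE)$values
  expect_true(all(rel >= 0 & rel <= 1))
})

test_that("feature matrices round-trip through delimited text", {
  ds <- tiny_dataset(p = 5L, channels = 3L, s = 20L, seed = 6L)
  for (fm in list(extract_time_mean(ds), extract_fc(ds))) {
    f <- withr::local_tempfile(fileext = ".tsv")
    write_feature_matrix(fm, f)
    back <- read_feature_matrix(f)
    expect_equal(back$values, fm$values, tolerance = 1e-12,
                 ignore_attr = FALSE)
    expect_identical(back$kind, fm$kind)
    expect_identical(back$normalized, fm$normalized)
  }
})
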