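# Periodic spectral averaging, FRF, coherence, nonlinearity screen.

make_tone <- function(f, fs, duration, amplitude = 1, phase = 0) {
  t <- seq(0, duration - 1 / fs, by = 1 / fs)
  amplitude * cos(2 * pi * f * t + phase)
}

test_that("periodic signals give identical per-block coefficients", {
  fs <- 40; period <- 20
  y <- make_tone(0.05, fs, 6 * period)
  sp <- segment_spectra(y, fs, period, 6)
  idx <- which(abs(sp$freq_hz - 0.05) < 1e-12)
  expect_equal(Mod(sp$coef[, idx]), rep(0.5, 6), tolerance = 1e-9)
  expect_equal(sp$mean_coef[idx], sp$coef[1, idx], tolerance = 1e-12)
})

test_that("a constant record has power only at DC", {
  sp <- segment_spectra(rep(3.2, 6 * 20 * 25), 25, 20, 6)
  expect_equal(Mod(sp$mean_coef[1]), 3.2, tolerance = 1e-9)
  expect_lt(max(Mod(sp$mean_coef[-1])), 1e-9)
})

test_that("record length must be an exact multiple of the block length", {
  expect_error(segment_spectra(rnorm(100), 25, 20, 6), "2999|3000")
})

test_that("coefficient averaging shrinks white noise like sqrt(n_blocks)", {
  withr::local_seed(2)
  ratios <- replicate(500, {
    y <- rnorm(6 * 200)
    sp <- segment_spectra(y, 10, 20, 6)
    mean(Mod(sp$mean_coef[-1])) / mean(Mod(sp$coef[, -1]))
  })
  # complex-mean magnitude of 6 independent coefficients: 1/sqrt(6)
  expect_equal(mean(ratios), 1 / sqrt(6), tolerance = 0.05)
})

test_that("the FRF of identity, gain and delay systems is exact", {
  fs <- 40; period <- 20
  sig <- prts_rotation(prts_states(4), 1, fs = fs)
  ss <- rep(sig$position_deg, 6)
  frf_id <- estimate_frf(ss = ss, bs = ss, fs = fs, period = period)
  expect_equal(frf_id$response, rep(complex(real = 1), 21), tolerance = 1e-9)
  frf_gain <- estimate_frf(ss = ss, bs = 3.7 * ss, fs = fs, period = period)
  expect_equal(frf_gain$response, rep(complex(real = 3.7), 21), tolerance = 1e-9)
  # circular 1 s delay of a periodic signal
  d <- fs * 1
  bs <- c(ss[(length(ss) - d + 1):length(ss)], ss[1:(length(ss) - d)])
  frf_del <- estimate_frf(ss = ss, bs = bs, fs = fs, period = period)
  expect_equal(Mod(frf_del$response), rep(1, 21), tolerance = 1e-9)
  phase <- Arg(frf_del$response)
  expected <- -2 * pi * frf_del$freq_hz * 1
  expect_equal(exp(1i * phase), exp(1i * expected), tolerance = 1e-9)
})

test_that("perfectly related records have unit coherence", {
  fs <- 40
  ss <- rep(prts_rotation(prts_states(4), 1, fs = fs)$position_deg, 6)
  coh <- coherence(ss = ss, bs = 2 * ss, fs = fs, period = 20)
  expect_equal(coh$coherence, rep(1, 21), tolerance = 1e-12)
})

test_that("coherence of independent records averages about 1/n_blocks", {
  withr::local_seed(31)
  fs <- 25; period <- 20
  means <- replicate(300, {
    ss <- rnorm(6 * period * fs)
    bs <- rnorm(6 * period * fs)
    mean(coherence(ss = ss, bs = bs, fs = fs, period = period)$coherence)
  })
  expect_equal(mean(means), 1 / 6, tolerance = 0.03)
})

test_that("coherence never exceeds one on arbitrary records", {
  withr::local_seed(5)
  for (i in 1:25) {
    fs <- sample(c(10, 25, 50), 1)
    n <- 6 * 20 * fs
    ss <- rnorm(n) + rep(sin(2 * pi * 0.05 * (1:(20 * fs)) / fs), 6)
    bs <- 0.5 * ss + rnorm(n) * runif(1, 0, 2)
    coh <- coherence(ss = ss, bs = bs, fs = fs, period = 20)$coherence
    expect_lte(max(coh), 1 + 1e-12)
    expect_gte(min(coh), 0)
  }
})

test_that("coherence needs at least two blocks and flags dead output lines", {
  fs <- 20
  ss <- prts_rotation(prts_states(4), 1, fs = fs)$position_deg
  expect_error(coherence(ss = ss, bs = ss, fs = fs, period = 20), "2 blocks")
  # sway with power at a single excited line: other lines undefined, not 0
  ss6 <- rep(ss, 6)
  bs6 <- rep(make_tone(0.05, fs, 20), 6)
  coh <- coherence(ss = ss6, bs = bs6, fs = fs, period = 20)
  expect_true(is.na(coh$coherence[coh$freq_hz == 0.15]))
  expect_false(is.na(coh$coherence[coh$freq_hz == 0.05]))
})

test_that("block spectra satisfy Parseval's identity", {
  withr::local_seed(8)
  fs <- 25; period <- 20; L <- fs * period
  y <- rnorm(L)
  # full two-sided power from the one-sided harmonic table
  co <- stats::fft(y) / L
  expect_equal(sum(Mod(co)^2), mean(y^2), tolerance = 1e-9)
  sp <- segment_spectra(rep(y, 6), fs, period, 6)
  one_sided <- Mod(sp$coef[1, ])^2
  two_sided <- one_sided[1] + 2 * sum(one_sided[-c(1, length(one_sided))]) +
    one_sided[length(one_sided)]
  expect_equal(two_sided, mean(y^2), tolerance = 1e-9)
})

test_that("even-harmonic fraction separates odd and even content", {
  fs <- 25; dur <- 6 * 20
  odd_tone <- make_tone(0.05, fs, dur)
  even_tone <- make_tone(0.10, fs, dur)
  expect_equal(even_harmonic_fraction(bs = odd_tone, fs = fs, period = 20), 0,
               tolerance = 1e-10)
  expect_equal(even_harmonic_fraction(bs = even_tone, fs = fs, period = 20), 100,
               tolerance = 1e-10)
  expect_equal(even_harmonic_fraction(bs = odd_tone + even_tone, fs = fs,
                                      period = 20), 50, tolerance = 1e-9)
  # any signal built purely from odd harmonics stays below numerical dust
  mix <- make_tone(0.05, fs, dur) + 0.4 * make_tone(0.75, fs, dur) +
    0.1 * make_tone(2.05, fs, dur)
  expect_lt(even_harmonic_fraction(bs = mix, fs = fs, period = 20), 1e-10)
  expect_error(even_harmonic_fraction(bs = rep(0, 6 * 20 * 25), fs = 25,
                                      period = 20), "zero power")
})

test_that("a dead perturbation line is reported by name", {
  fs <- 25
  ss <- rep(make_tone(0.05, fs, 20), 6)  # power only at 0.05 Hz
  bs <- rnorm(length(ss))
  expect_error(estimate_frf(ss = ss, bs = bs, fs = fs, period = 20), "0.15")
})
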