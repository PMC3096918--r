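test_that("stimulus components are exact record-periodic Fourier bins", {
  s <- synthesize_pseudorandom_stimulus(1, duration = 6, sample_rate = 256,
                                        amplitudes = 1, phases = 0)
  co <- dft_coefficients(s$signal, 256, s$frequencies)
  expect_equal(Mod(co), 0.5, tolerance = 1e-12)
  # all other default stimulus bins empty
  others <- setdiff(default_stimulus_frequencies(), 1)
  expect_lt(max(Mod(dft_coefficients(s$signal, 256, others))), 1e-12)
  expect_error(synthesize_pseudorandom_stimulus(1.05, duration = 6),
               "integer multiple")
  expect_error(synthesize_pseudorandom_stimulus(20, sample_rate = 30),
               "twice")
})

test_that("stimulus synthesis is deterministic given a seed", {
  f <- default_stimulus_frequencies()
  s1 <- synthesize_pseudorandom_stimulus(f, seed = 9)
  s2 <- synthesize_pseudorandom_stimulus(f, seed = 9)
  s3 <- synthesize_pseudorandom_stimulus(f, seed = 10)
  expect_identical(s1$signal, s2$signal)
  expect_false(identical(s1$signal, s3$signal))
})

test_that("default component set avoids mutual harmonics and spans the band", {
  f <- default_stimulus_frequencies()
  expect_length(f, 16)
  expect_true(all(f >= 0.5 & f <= 21))
  k <- round(f * 6)
  for (i in seq_along(k)) for (j in seq_along(k)) {
    if (i != j) expect_true(k[j] %% k[i] != 0)
  }
})

test_that("crest factor of the default stimulus is stable across seeds", {
  f <- default_stimulus_frequencies()
  cf <- vapply(1:100, function(s) {
    crest_factor(synthesize_pseudorandom_stimulus(f, seed = s)$signal)
  }, numeric(1))
  # random-phase multisine with 16 components: comfortably below the
  # coherent-phase worst case of sqrt(2 * 16)
  expect_true(all(cf > 1.5 & cf < 4.5))
  expect_lt(diff(range(cf)), 2.5)
})

test_that("transfer estimate is exact for identity and periodic delay", {
  f <- c(1, 3, 5)
  s <- synthesize_pseudorandom_stimulus(f, duration = 6, sample_rate = 240,
                                        seed = 1)
  fr <- pressure_frames(240, s$signal, s$signal, f)
  expect_equal(estimate_transfer_function(fr)[1:3],
               rep(complex(real = 1), 3), tolerance = 1e-10)
  # delay by one full period of a single-component signal
  s1 <- synthesize_pseudorandom_stimulus(1, duration = 6, sample_rate = 240,
                                         phases = 0.3)
  delayed <- c(tail(s1$signal, 240), head(s1$signal, -240))
  fr2 <- pressure_frames(240, s1$signal, delayed, 1)
  expect_equal(estimate_transfer_function(fr2)[1], complex(real = 1),
               tolerance = 1e-10)
})

test_that("a known per-bin complex ratio is recovered from synthesis", {
  f <- default_stimulus_frequencies()
  set.seed(3)
  ratio <- complex(real = runif(16, 0.5, 2), imaginary = runif(16, -1, 1))
  s <- synthesize_pseudorandom_stimulus(f, seed = 4)
  p1 <- numeric(length(s$t))
  for (i in seq_along(f)) {
    p1 <- p1 + s$amplitudes[i] * Mod(ratio[i]) *
      cos(2 * pi * f[i] * s$t + s$phases[i] + Arg(ratio[i]))
  }
  fr <- pressure_frames(s$sample_rate, p1, s$signal, f)
  tf <- estimate_transfer_function(fr)
  expect_lt(max(Mod(tf - ratio)), 1e-10)
})

test_that("matched load gives exp(gamma*L) and feeds back to Z0", {
  wt <- wave_tube_spec()
  f <- default_stimulus_frequencies()
  cons <- fotmech:::wavetube_constants(wt, f)
  z0_spec <- impedance_spectrum(f, cons$z0)
  fr <- simulate_pressures_from_load(z0_spec, wt, seed = 5)
  tf <- estimate_transfer_function(fr)
  expect_lt(max(Mod(tf - exp(cons$gl))), 1e-9)
  zl <- load_impedance_from_transfer(tf, wt)
  expect_lt(max(Mod(zl$values - cons$z0) / Mod(cons$z0)), 1e-8)
})

test_that("near-closed-end bins are flagged singular, not propagated", {
  wt <- wave_tube_spec()
  f <- c(2, 5, 10)
  cons <- fotmech:::wavetube_constants(wt, f)
  tf <- cosh(cons$gl)
  tf[2] <- tf[2] + 1e-15 # essentially singular
  tf[c(1, 3)] <- tf[c(1, 3)] + 0.5
  attr(tf, "frequencies") <- f
  zl <- load_impedance_from_transfer(tf, wt)
  expect_equal(attr(zl, "singular_bins"), 2L)
  expect_true(is.na(zl$values[2]))
  expect_true(all(is.finite(Mod(zl$values[c(1, 3)]))))
})

test_that("simulate -> transfer -> load is the identity on impedance", {
  wt <- wave_tube_spec()
  f <- default_stimulus_frequencies()
  set.seed(6)
  for (i in 1:10) {
    p <- random_rat_params()
    load <- forward_impedance(p, f)
    fr <- simulate_pressures_from_load(load, wt, seed = i)
    zl <- load_impedance_from_transfer(estimate_transfer_function(fr), wt)
    expect_lt(max(Mod(zl$values - load$values) / Mod(load$values)), 1e-8)
  }
})

test_that("averaging noisy frames reduces impedance error roughly as 1/sqrt(K)", {
  wt <- wave_tube_spec()
  f <- default_stimulus_frequencies()
  p <- constant_phase_params(30, 0.1, 800, 2900)
  load <- forward_impedance(p, f)
  rmse <- sapply(c(1, 4, 6), function(K) {
    errs <- vapply(1:50, function(s) {
      fr <- simulate_pressures_from_load(load, wt, noise_sd = 0.002,
                                         n_frames = K, seed = 1000 + s)
      zl <- load_impedance_from_transfer(estimate_transfer_function(fr), wt)
      sqrt(mean(Mod(zl$values - load$values)^2))
    }, numeric(1))
    sqrt(mean(errs^2))
  })
  expect_true(all(diff(rmse) < 0))
  # ~1/sqrt(K) decay: allow a factor-of-1.5 band around the ideal ratios
  expect_equal(rmse[1] / rmse[2], 2, tolerance = 0.5)
  expect_equal(rmse[1] / rmse[3], sqrt(6), tolerance = 0.5 * sqrt(6) / 2)
})
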