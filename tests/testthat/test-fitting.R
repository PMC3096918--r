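test_that("noiseless spectra are recovered exactly (self-consistency)", {
  f <- seq(0.5, 21, length.out = 16)
  truth <- constant_phase_params(30, 0.1, 800, 2900)
  sp <- forward_impedance(truth, f)
  fit <- fit_constant_phase(sp, seed = 1)
  expect_true(fit$converged)
  for (nm in c("raw", "iaw", "g", "h")) {
    expect_equal(fit$params[[nm]], truth[[nm]], tolerance = 1e-6)
  }
  expect_lt(fit$residual_norm, 1e-8)
})

test_that("recovery holds across random draws spanning the rat range", {
  f <- seq(0.5, 21, length.out = 16)
  set.seed(21)
  for (i in 1:30) {
    truth <- random_rat_params()
    fit <- fit_constant_phase(forward_impedance(truth, f), seed = i)
    for (nm in c("raw", "iaw", "g", "h")) {
      expect_equal(fit$params[[nm]], truth[[nm]], tolerance = 1e-5)
    }
  }
})

test_that("purely resistive spectra drive the tissue terms to the bound", {
  sp <- impedance_spectrum(c(0.5, 2, 8, 15, 21),
                           rep(complex(real = 5), 5))
  fit <- fit_constant_phase(sp, seed = 1)
  expect_equal(fit$params$raw, 5, tolerance = 1e-4)
  expect_lt(fit$params$g, 1e-3)
  expect_lt(fit$params$h, 1e-3)
  expect_lt(fit$residual_norm, 1e-6)
})

test_that("noisy replicates are unbiased within Monte-Carlo error", {
  f <- seq(0.5, 21, length.out = 16)
  truth <- constant_phase_params(30, 0.1, 800, 2900)
  clean <- forward_impedance(truth, f)
  est <- t(vapply(1:200, function(s) {
    set.seed(3000 + s)
    sp <- impedance_spectrum(f, clean$values +
                               complex(real = rnorm(16), imaginary = rnorm(16)))
    fit <- fit_constant_phase(sp, seed = 1)
    unlist(fit$params[c("raw", "iaw", "g", "h")])
  }, numeric(4)))
  tv <- unlist(truth[c("raw", "iaw", "g", "h")])
  for (j in 1:4) {
    mc_se <- sd(est[, j]) / sqrt(nrow(est))
    expect_lt(abs(mean(est[, j]) - tv[j]), 4 * mc_se + 1e-8)
  }
  # empirical dispersion stays in a sane regression band at noise sd 1
  expect_lt(sd(est[, "raw"]), 2)
  expect_lt(sd(est[, "g"]), 60)
})

test_that("objective never exceeds the heuristic start (descent)", {
  f <- seq(0.5, 21, length.out = 16)
  set.seed(31)
  w <- 2 * pi * f
  for (i in 1:10) {
    truth <- random_rat_params()
    sp <- forward_impedance(truth, f)
    sp$values <- sp$values + complex(real = rnorm(16, 0, 3),
                                    imaginary = rnorm(16, 0, 3))
    init <- heuristic_init(sp)
    obj0 <- sum(fotmech:::fit_residuals(
      c(init$raw, init$iaw, init$g, init$h), w, sp$values)^2)
    fit <- fit_constant_phase(sp, seed = i)
    expect_lte(fit$objective, obj0 + 1e-9)
  }
})

test_that("fit is invariant to frequency ordering", {
  f <- seq(0.5, 21, length.out = 16)
  truth <- constant_phase_params(42, 0.2, 1200, 4100)
  sp <- forward_impedance(truth, f)
  perm <- c(9, 3, 16, 1, 12, 5, 14, 7, 2, 11, 4, 13, 6, 15, 8, 10)
  sp_perm <- list(frequencies = sp$frequencies[perm],
                  values = sp$values[perm], recording_id = NULL,
                  duration = NA_real_)
  class(sp_perm) <- "impedance_spectrum"
  f1 <- fit_constant_phase(sp, seed = 2)
  f2 <- fit_constant_phase(sp_perm, seed = 2)
  expect_equal(unlist(f1$params), unlist(f2$params), tolerance = 1e-10)
})

test_that("heuristic start is deterministic and lands near the truth", {
  f <- seq(0.5, 21, length.out = 16)
  set.seed(41)
  within3 <- 0
  n_draw <- 200
  for (i in seq_len(n_draw)) {
    truth <- random_rat_params()
    sp <- forward_impedance(truth, f)
    init <- heuristic_init(sp)
    expect_identical(unlist(init), unlist(heuristic_init(sp)))
    ratios <- unlist(init) / unlist(truth[c("raw", "iaw", "g", "h")])
    if (all(ratios > 1 / 3 & ratios < 3)) within3 <- within3 + 1
  }
  # the start need not always be within 3x, but must be for the large majority
  expect_gt(within3 / n_draw, 0.8)
  # purely resistive input
  spr <- impedance_spectrum(c(0.5, 2, 8, 21), rep(complex(real = 7), 4))
  ir <- heuristic_init(spr)
  expect_equal(ir$raw, 7, tolerance = 1e-9)
  expect_lte(ir$g, 0.1)
  expect_lte(ir$h, 0.1)
})

test_that("fewer than four frequencies is under-determined", {
  sp <- impedance_spectrum(c(1, 2, 3), rep(complex(real = 5), 3))
  expect_error(fit_constant_phase(sp), "under-determined")
})

test_that("aggregation averages accepted fits and filters outliers", {
  f <- seq(0.5, 21, length.out = 16)
  truth <- constant_phase_params(30, 0.1, 800, 2900)
  sp <- forward_impedance(truth, f)
  fit <- fit_constant_phase(sp, seed = 1)
  # identical fits: mean equals the fit, SE = 0
  agg <- aggregate_recordings(list(fit, fit, fit))
  expect_equal(unlist(agg$params), unlist(fit$params))
  expect_equal(unname(agg$se), rep(0, 4))
  expect_equal(agg$n_accepted, 3)
  # one high-residual outlier among five is excluded
  bad <- fit
  bad$residual_norm <- 50
  bad$params <- constant_phase_params(1000, 1, 1, 1)
  agg2 <- aggregate_recordings(list(fit, fit, bad, fit, fit),
                               residual_threshold = 5)
  expect_equal(agg2$n_accepted, 4)
  expect_equal(agg2$params$raw, fit$params$raw)
  expect_false(agg2$accepted[3])
  expect_error(aggregate_recordings(list(bad), residual_threshold = 5),
               "rejected")
})

test_that("aggregating noisy replicates beats single recordings", {
  f <- seq(0.5, 21, length.out = 16)
  truth <- constant_phase_params(30, 0.1, 800, 2900)
  clean <- forward_impedance(truth, f)
  tv <- unlist(truth[c("raw", "iaw", "g", "h")])
  err_single <- err_agg <- numeric(50)
  for (s in 1:50) {
    set.seed(5000 + s)
    fits <- lapply(1:4, function(k) {
      sp <- impedance_spectrum(f, clean$values +
                                 complex(real = rnorm(16), imaginary = rnorm(16)))
      fit_constant_phase(sp, seed = 1)
    })
    est1 <- unlist(fits[[1]]$params[c("raw", "iaw", "g", "h")])
    esta <- unlist(aggregate_recordings(fits)$params)
    err_single[s] <- sqrt(mean(((est1 - tv) / tv)^2))
    err_agg[s] <- sqrt(mean(((esta - tv) / tv)^2))
  }
  expect_lt(sqrt(mean(err_agg^2)), sqrt(mean(err_single^2)))
})
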