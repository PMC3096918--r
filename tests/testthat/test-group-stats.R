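test_that("Lilliefors statistic matches the brute-force enumeration", {
  set.seed(51)
  for (i in 1:20) {
    x <- rnorm(sample(8:40, 1), mean = runif(1, -5, 5), sd = runif(1, 0.5, 4))
    res <- ks_normality(x)
    expect_equal(res$statistic, oracle_lilliefors_D(x), tolerance = 1e-12)
  }
})

test_that("normality test accepts constructed normal-quantile samples", {
  # a sample sitting exactly on fitted-normal quantiles at plotting positions
  x <- qnorm((1:20 - 0.5) / 20, mean = 3, sd = 2)
  res <- ks_normality(x)
  expect_lt(res$statistic, 0.06)
  expect_gt(res$p_value, 0.5)
  expect_error(ks_normality(rep(1, 10)), "zero variance")
  expect_error(ks_normality(c(1, 2, 3)), "at least 4")
})

test_that("normality test rejects exponential samples with high power", {
  rejections <- sum(vapply(1:100, function(s) {
    set.seed(8000 + s)
    ks_normality(rexp(100))$p_value < 0.05
  }, logical(1)))
  expect_gte(rejections, 95)
})

test_that("one-way ANOVA matches the definitional sums of squares", {
  # identical groups: F = 0, p = 1
  res0 <- oneway_anova(list(a = c(1, 2, 3), b = c(1, 2, 3)))
  expect_equal(res0$statistic, 0)
  expect_equal(res0$p_value, 1)
  set.seed(52)
  for (i in 1:20) {
    samples <- lapply(1:3, function(g) rnorm(sample(3:15, 1), mean = g))
    names(samples) <- c("a", "b", "c")
    res <- oneway_anova(samples)
    expect_equal(res$statistic, oracle_oneway_F(samples), tolerance = 1e-10)
    # location invariance
    shifted <- lapply(samples, `+`, 100)
    expect_equal(oneway_anova(shifted)$statistic, res$statistic,
                 tolerance = 1e-10)
  }
  expect_error(oneway_anova(list(a = 1, b = c(1, 2))), "n >= 2")
})

test_that("one-way ANOVA holds its nominal type-I error", {
  pvals <- vapply(1:2000, function(s) {
    set.seed(s)
    oneway_anova(list(a = rnorm(10), b = rnorm(10), c = rnorm(10)))$p_value
  }, numeric(1))
  # binomial SE at n = 2000 is ~0.005; the wider acceptance run lives in
  # the acceptance suite
  expect_gt(mean(pvals < 0.05), 0.035)
  expect_lt(mean(pvals < 0.05), 0.065)
})

make_rm_dataset <- function(n_groups = 2, n_per_group = 4, doses = 3,
                            effect = 0) {
  subj <- paste0("s", seq_len(n_groups * n_per_group))
  grp <- rep(paste0("g", seq_len(n_groups)), each = n_per_group)
  d <- expand.grid(animal = subj, dose = paste0("d", seq_len(doses)),
                   stringsAsFactors = FALSE)
  d$group <- grp[match(d$animal, subj)]
  subj_eff <- rnorm(length(subj))
  d$response <- rnorm(nrow(d)) + subj_eff[match(d$animal, subj)] +
    effect * (d$group == "g2") * as.integer(factor(d$dose))
  d
}

test_that("mixed-design RM-ANOVA matches the definitional decomposition", {
  set.seed(53)
  for (i in 1:15) {
    d <- make_rm_dataset(n_groups = sample(2:3, 1),
                         n_per_group = sample(3:6, 1),
                         doses = sample(3:5, 1), effect = runif(1, 0, 1))
    res <- rm_anova_two_way(d)
    oracle <- oracle_rm_anova_F(d)
    expect_equal(res$treatment$statistic, unname(oracle["treatment"]),
                 tolerance = 1e-10)
    expect_equal(res$dose$statistic, unname(oracle["dose"]),
                 tolerance = 1e-10)
    expect_equal(res$interaction$statistic, unname(oracle["interaction"]),
                 tolerance = 1e-10)
  }
})

test_that("RM-ANOVA handles degenerate and malformed input", {
  d <- make_rm_dataset()
  d$response <- 1
  res <- rm_anova_two_way(d)
  expect_equal(res$treatment$statistic, 0, tolerance = 1e-20)
  expect_equal(res$dose$statistic, 0, tolerance = 1e-20)
  # missing cell is named in the error
  d2 <- make_rm_dataset()
  d2 <- d2[!(d2$animal == "s1" & d2$dose == "d2"), ]
  expect_error(rm_anova_two_way(d2), "s1.*d2|animal 's1'")
})

test_that("treatment effect ignores within-subject permutation of dose labels", {
  set.seed(54)
  d <- make_rm_dataset(effect = 0.8)
  res1 <- rm_anova_two_way(d)
  perm <- c(d2 = "d3", d3 = "d1", d1 = "d2")
  d2 <- d
  d2$dose <- unname(perm[d2$dose])
  res2 <- rm_anova_two_way(d2)
  expect_equal(res2$treatment$statistic, res1$treatment$statistic,
               tolerance = 1e-10)
})

test_that("SNK agrees with exhaustive span enumeration", {
  set.seed(55)
  for (i in 1:30) {
    k <- sample(3:5, 1)
    samples <- lapply(seq_len(k), function(g) {
      rnorm(sample(5:12, 1), mean = runif(1, 0, 3))
    })
    names(samples) <- paste0("g", seq_len(k))
    dec <- snk_posthoc(samples, require_significant_anova = FALSE)
    oracle <- oracle_snk_decisions(samples)
    for (r in seq_len(nrow(dec))) {
      expect_identical(
        dec$significant[r],
        unname(oracle[dec$group1[r], dec$group2[r]]),
        info = sprintf("draw %d pair %s-%s", i, dec$group1[r], dec$group2[r]))
    }
    # containment: every span enclosing a significant pair is significant
    means <- vapply(samples, mean, numeric(1))
    pos <- match(names(sort(means)), names(samples))
    at <- function(g) which(pos == match(g, names(samples)))
    lohi <- cbind(mapply(function(a, b) min(at(a), at(b)),
                         dec$group1, dec$group2),
                  mapply(function(a, b) max(at(a), at(b)),
                         dec$group1, dec$group2))
    for (r in which(dec$significant)) {
      encl <- lohi[, 1] <= lohi[r, 1] & lohi[, 2] >= lohi[r, 2]
      expect_true(all(dec$significant[encl]))
    }
  }
})

test_that("SNK base cases: equal means, two groups, one outlier", {
  set.seed(56)
  eq <- lapply(1:4, function(i) rnorm(10) + 0)
  names(eq) <- paste0("g", 1:4)
  eq <- lapply(eq, function(x) x - mean(x)) # all group means exactly 0
  expect_false(any(snk_posthoc(eq, require_significant_anova = FALSE)$significant))
  # two groups: SNK decision equals the studentized-range test with q = sqrt(2)*|t|
  a <- rnorm(10); b <- rnorm(10) + 2
  dec2 <- snk_posthoc(list(a = a, b = b), require_significant_anova = FALSE)
  tt <- t.test(a, b, var.equal = TRUE)
  expect_equal(abs(dec2$q), sqrt(2) * abs(unname(tt$statistic)),
               tolerance = 1e-10)
  expect_identical(dec2$significant,
                   qtukey(0.95, 2, 18) < abs(dec2$q))
  # 4 groups, one mean 10 pooled sds away: exactly its 3 pairs flagged
  sep <- lapply(1:4, function(i) rnorm(10, mean = if (i == 4) 10 else 0))
  names(sep) <- paste0("g", 1:4)
  dec4 <- snk_posthoc(sep, require_significant_anova = FALSE)
  flagged <- dec4[dec4$significant, ]
  expect_equal(nrow(flagged), 3)
  expect_true(all(flagged$group1 == "g4" | flagged$group2 == "g4"))
})

test_that("SNK runs only after a significant ANOVA when required", {
  set.seed(57)
  null_groups <- lapply(1:3, function(i) rnorm(8))
  names(null_groups) <- paste0("g", 1:3)
  # force a clearly non-significant ANOVA
  null_groups <- lapply(null_groups, function(x) x - mean(x))
  dec <- snk_posthoc(null_groups, require_significant_anova = TRUE)
  expect_false(any(dec$significant))
  expect_true(all(is.na(dec$q)))
})

test_that("grouped Pearson correlation: exact, invariant, pairwise-complete", {
  x <- 1:10
  res <- pearson_with_groups(x, 2 * x + 1, rep(c("a", "b"), 5))
  expect_equal(res$pooled$r, 1, tolerance = 1e-12)
  expect_equal(res$pooled$slope, 2, tolerance = 1e-12)
  # affine invariance with positive slopes
  set.seed(58)
  x2 <- rnorm(20); y2 <- 0.5 * x2 + rnorm(20)
  g2 <- rep(c("a", "b"), 10)
  r1 <- pearson_with_groups(x2, y2, g2)$pooled$r
  r2 <- pearson_with_groups(3 * x2 + 5, 0.2 * y2 - 4, g2)$pooled$r
  expect_equal(r1, r2, tolerance = 1e-12)
  # missing pairs dropped pairwise
  x3 <- c(x2, NA); y3 <- c(y2, 1); g3 <- c(g2, "a")
  expect_equal(pearson_with_groups(x3, y3, g3)$pooled$n, 20)
  expect_error(pearson_with_groups(rep(1, 5), rnorm(5), rep("a", 5)),
               "zero variance")
})

test_that("t-based correlation p agrees with a permutation cross-check", {
  # at n = 17, |R| >= 0.59 should occur with probability ~= the two-sided
  # t-based p for R = 0.59 (0.0127) under independence
  n <- 17
  r_obs <- 0.59
  t_p <- 2 * pt(-abs(r_obs * sqrt((n - 2) / (1 - r_obs^2))), n - 2)
  set.seed(59)
  x <- rnorm(n)
  y <- rnorm(n)
  exceed <- mean(vapply(1:10000, function(i) {
    abs(cor(x, sample(y))) >= r_obs
  }, logical(1)))
  expect_lt(abs(exceed - t_p), 0.006)
})
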