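# Independent oracles used across the suite. Each is a deliberately plain,
# per-element implementation kept separate from the package's vectorised or
# library-backed code paths.

# scalar straight-line evaluation of the constant-phase model at one frequency
oracle_impedance_scalar <- function(raw, iaw, g, h, f_hz) {
  w <- 2 * pi * f_hz
  alpha <- (2 / pi) * atan(h / g)
  re <- raw + g / w^alpha
  im <- w * iaw - h / w^alpha
  complex(real = re, imaginary = im)
}

# ED50 by dense numeric scan of the piecewise-linear dose-response
oracle_ed50_dense_scan <- function(doses, baseline, raw, n_grid = 200000) {
  d <- c(0, doses)
  r <- c(baseline, raw)
  target <- 1.5 * baseline
  grid <- seq(0, max(d), length.out = n_grid)
  vals <- approx(d, r, xout = grid)$y
  hit <- which(vals[-1] >= target & vals[-length(vals)] < target)
  if (length(hit) == 0) return(NA_real_)
  i <- hit[1]
  # refine linearly inside the grid cell
  x0 <- grid[i]; x1 <- grid[i + 1]
  y0 <- vals[i]; y1 <- vals[i + 1]
  x0 + (target - y0) / (y1 - y0) * (x1 - x0)
}

# definitional one-way ANOVA F from textbook sums of squares
oracle_oneway_F <- function(samples) {
  all <- unlist(samples)
  gm <- mean(all)
  ssb <- sum(vapply(samples, function(s) length(s) * (mean(s) - gm)^2,
                    numeric(1)))
  ssw <- sum(vapply(samples, function(s) sum((s - mean(s))^2), numeric(1)))
  dfb <- length(samples) - 1
  dfw <- length(all) - length(samples)
  (ssb / dfb) / (ssw / dfw)
}

# definitional mixed-design (one between, one within factor) sums of squares,
# for balanced groups; returns the three F statistics
oracle_rm_anova_F <- function(df) {
  # df: animal, group, dose, response; complete and balanced
  df$animal <- as.character(df$animal)
  df$group <- as.character(df$group)
  df$dose <- as.character(df$dose)
  gm <- mean(df$response)
  subj <- unique(df[c("animal", "group")])
  a <- length(unique(df$dose))
  subj_means <- tapply(df$response, df$animal, mean)
  grp_means <- tapply(df$response, df$group, mean)
  dose_means <- tapply(df$response, df$dose, mean)
  cell_means <- tapply(df$response, list(df$group, df$dose), mean)
  n_per_grp <- table(subj$group)
  ss_group <- a * sum(n_per_grp[names(grp_means)] * (grp_means - gm)^2)
  ss_subj_within <- a * sum((subj_means[subj$animal] -
                               grp_means[subj$group])^2)
  n_tot <- nrow(subj)
  ss_dose <- n_tot * sum((dose_means - gm)^2)
  ss_cells <- 0
  for (g in rownames(cell_means)) for (d in colnames(cell_means)) {
    ss_cells <- ss_cells + n_per_grp[[g]] *
      (cell_means[g, d] - grp_means[[g]] - dose_means[[d]] + gm)^2
  }
  ss_int <- ss_cells
  ss_tot <- sum((df$response - gm)^2)
  ss_err <- ss_tot - ss_group - ss_subj_within - ss_dose - ss_int
  k <- length(unique(df$group))
  df_group <- k - 1
  df_subj <- n_tot - k
  df_dose <- a - 1
  df_int <- (a - 1) * (k - 1)
  df_err <- (a - 1) * (n_tot - k)
  c(treatment = (ss_group / df_group) / (ss_subj_within / df_subj),
    dose = (ss_dose / df_dose) / (ss_err / df_err),
    interaction = (ss_int / df_int) / (ss_err / df_err))
}

# brute-force Lilliefors D statistic (max deviation of the empirical CDF
# from the normal fitted by moments, checked on both sides of each step)
oracle_lilliefors_D <- function(x) {
  x <- sort(x)
  n <- length(x)
  p <- pnorm(x, mean(x), sd(x))
  d_plus <- max(seq_len(n) / n - p)
  d_minus <- max(p - (seq_len(n) - 1) / n)
  max(d_plus, d_minus)
}

# exhaustive SNK evaluation: for each pair, significant iff every enclosing
# span (including its own) exceeds its studentized-range critical value
oracle_snk_decisions <- function(samples, alpha = 0.05) {
  k <- length(samples)
  means <- vapply(samples, mean, numeric(1))
  ns <- lengths(samples)
  dfe <- sum(ns) - k
  mse <- sum(unlist(lapply(samples, function(s) (s - mean(s))^2))) / dfe
  o <- order(means)
  means <- means[o]; ns <- ns[o]
  qstat <- function(i, j) {
    (means[j] - means[i]) / sqrt(mse / 2 * (1 / ns[i] + 1 / ns[j]))
  }
  raw_sig <- matrix(FALSE, k, k)
  for (i in 1:(k - 1)) for (j in (i + 1):k) {
    raw_sig[i, j] <- qstat(i, j) > qtukey(1 - alpha, j - i + 1, dfe)
  }
  dec <- matrix(FALSE, k, k)
  for (i in 1:(k - 1)) for (j in (i + 1):k) {
    enclosing <- TRUE
    for (a in 1:i) for (b in j:k) {
      if (!raw_sig[a, b]) enclosing <- FALSE
    }
    dec[i, j] <- enclosing
  }
  dimnames(dec) <- list(names(samples)[o], names(samples)[o])
  dec
}

# small random spectrum in the rat parameter range
random_rat_params <- function() {
  constant_phase_params(raw = runif(1, 10, 100),
                        iaw = runif(1, 0.02, 0.5),
                        g = runif(1, 200, 3000),
                        h = runif(1, 800, 10000))
}
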