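stat_result <- function(test, statistic, df, p_value, grouping = NULL) {
  structure(list(test = test, statistic = statistic, df = df,
                 p_value = p_value, grouping = grouping),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, df = %s, p = %.4g\n", x$test,
              x$statistic, paste(signif(x$df, 6), collapse = ", "),
              x$p_value))
  invisible(x)
}

#' Kolmogorov-Smirnov normality test (Lilliefors)
#'
#' One-sample KS test of normality with mean and standard deviation estimated
#' from the sample (Lilliefors correction), the appropriate form when no
#' normal is prespecified. Computed via \pkg{nortest}.
#'
#' @param x Numeric sample, n >= 4, non-degenerate.
#' @return A `stat_result` with the D statistic and p-value.
#' @export
ks_normality <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 4L) stop("need at least 4 observations", call. = FALSE)
  if (stats::sd(x) == 0) stop("degenerate sample: zero variance", call. = FALSE)
  t <- nortest::lillie.test(x)
  stat_result("Kolmogorov-Smirnov (Lilliefors)", unname(t$statistic),
              length(x), t$p.value)
}

as_group_df <- function(groups) {
  if (is.data.frame(groups)) {
    stopifnot(all(c("value", "group") %in% names(groups)))
    return(data.frame(value = groups$value, group = factor(groups$group)))
  }
  stopifnot(is.list(groups), !is.null(names(groups)))
  data.frame(value = unlist(groups, use.names = FALSE),
             group = factor(rep(names(groups), lengths(groups)),
                            levels = names(groups)))
}

#' One-way analysis of variance
#'
#' Standard between/within variance decomposition across independent groups,
#' as used to compare baseline parameters and ED50 among protocol groups.
#'
#' @param groups A named list of numeric samples, or a data frame with columns
#'   `value` and `group`. Every group needs n >= 2; at least 2 groups.
#' @return A `stat_result` with the F statistic, `df = c(between, within)` and
#'   p-value; the fitted `aov` object is attached as attribute `fit` for
#'   post-hoc use.
#' @export
oneway_anova <- function(groups) {
  d <- as_group_df(groups)
  d <- d[is.finite(d$value), ]
  d$group <- droplevels(d$group)
  cnt <- table(d$group)
  if (length(cnt) < 2L) stop("need at least 2 groups", call. = FALSE)
  if (any(cnt < 2L)) {
    stop(sprintf("every group needs n >= 2 (violated by: %s)",
                 paste(names(cnt)[cnt < 2], collapse = ", ")), call. = FALSE)
  }
  fit <- stats::aov(value ~ group, data = d)
  s <- summary(fit)[[1]]
  res <- stat_result("one-way ANOVA", s[["F value"]][1],
                     c(s[["Df"]][1], s[["Df"]][2]), s[["Pr(>F)"]][1],
                     grouping = levels(d$group))
  attr(res, "fit") <- fit
  res
}

#' Two-way repeated-measures ANOVA (mixed design)
#'
#' Mixed-design decomposition for a between-subject treatment factor and a
#' within-subject dose factor with subjects nested in treatment: main effects
#' of treatment (tested against subjects-within-groups) and of dose, and the
#' treatment x dose interaction (both tested against the within-subject
#' residual). Uses the unadjusted univariate F statistics.
#'
#' @param table Data frame with columns `animal` (subject id), `group`
#'   (treatment), `dose` (within-subject level) and `response`. Every animal
#'   must have exactly one response at every dose level; missing cells are an
#'   error (no imputation).
#' @return A named list of three `stat_result`s: `treatment`, `dose`,
#'   `interaction`.
#' @export
rm_anova_two_way <- function(table) {
  stopifnot(is.data.frame(table),
            all(c("animal", "group", "dose", "response") %in% names(table)))
  d <- data.frame(animal = factor(table$animal),
                  group = factor(table$group),
                  dose = factor(table$dose),
                  response = table$response)
  if (nlevels(d$group) < 2L) stop("need at least 2 groups", call. = FALSE)
  tab <- table(d$animal, d$dose)
  if (any(tab != 1L)) {
    bad <- which(tab != 1L, arr.ind = TRUE)[1, ]
    stop(sprintf("incomplete design: animal '%s' has %d responses at dose '%s'",
                 rownames(tab)[bad[1]], tab[bad[1], bad[2]],
                 colnames(tab)[bad[2]]), call. = FALSE)
  }
  # an exactly flat response has no variance to partition: all F = 0
  if (stats::var(d$response) <=
      (1e-10 * (1 + mean(abs(d$response))))^2) {
    zero <- function(label, df) stat_result(label, 0, df, 1)
    k <- nlevels(d$group); a <- nlevels(d$dose); n <- nlevels(d$animal)
    return(list(
      treatment = zero("RM-ANOVA treatment effect", c(k - 1, n - k)),
      dose = zero("RM-ANOVA dose effect", c(a - 1, (a - 1) * (n - k))),
      interaction = zero("RM-ANOVA treatment x dose interaction",
                         c((a - 1) * (k - 1), (a - 1) * (n - k)))))
  }
  fit <- stats::aov(response ~ group * dose + Error(animal), data = d)
  s <- summary(fit)
  between <- s[["Error: animal"]][[1]]
  within <- s[["Error: Within"]][[1]]
  rn <- function(x) trimws(rownames(x))
  pick <- function(tab, term, label) {
    i <- match(term, rn(tab))
    f <- tab[["F value"]][i]
    p <- tab[["Pr(>F)"]][i]
    if (tab[["Sum Sq"]][i] == 0) { # no effect variance at all: F := 0
      f <- 0; p <- 1
    }
    stat_result(label, f, c(tab[["Df"]][i],
                            tab[["Df"]][rn(tab) == "Residuals"]), p)
  }
  list(
    treatment = pick(between, "group", "RM-ANOVA treatment effect"),
    dose = pick(within, "dose", "RM-ANOVA dose effect"),
    interaction = pick(within, "group:dose",
                       "RM-ANOVA treatment x dose interaction"))
}

#' Student-Newman-Keuls post-hoc comparisons
#'
#' Stepwise studentized-range multiple comparisons following a one-way ANOVA.
#' Group means are ordered; each pair is compared with the critical value
#' `qtukey(1 - alpha, p, df_error)` where `p` is the number of ordered means
#' the pair spans, working from the widest span inwards. The containment rule
#' is enforced: no pair inside a non-significant span is ever declared
#' significant. Unequal group sizes use the harmonic-mean (Tukey-Kramer)
#' standard error.
#'
#' @param groups As in [oneway_anova()].
#' @param alpha Familywise significance level.
#' @param require_significant_anova If `TRUE` (default), the procedure runs
#'   only after the one-way ANOVA is significant at `alpha`; otherwise an
#'   empty decision set is returned with the ANOVA attached.
#' @return A data frame with one row per pair: `group1`, `group2`, `span`,
#'   `q` (studentized-range statistic, NA for pairs blocked by containment),
#'   `q_crit`, and `significant`. The one-way ANOVA `stat_result` is attached
#'   as attribute `anova`.
#' @export
snk_posthoc <- function(groups, alpha = 0.05,
                        require_significant_anova = TRUE) {
  d <- as_group_df(groups)
  d <- d[is.finite(d$value), ]
  d$group <- droplevels(d$group)
  k <- nlevels(d$group)
  stopifnot(k >= 2L)
  av <- oneway_anova(d)
  means <- tapply(d$value, d$group, mean)
  ns <- tapply(d$value, d$group, length)
  dfe <- av$df[2]
  mse <- sum(stats::resid(attr(av, "fit"))^2) / dfe
  ord <- order(means)
  means <- means[ord]; ns <- ns[ord]
  gnames <- names(means)
  pairs <- expand.grid(i = seq_len(k), j = seq_len(k))
  pairs <- pairs[pairs$i < pairs$j, ]
  pairs$span <- pairs$j - pairs$i + 1L
  pairs <- pairs[order(-pairs$span, pairs$i), ]
  skip_all <- require_significant_anova && !(is.finite(av$p_value) &&
                                             av$p_value < alpha)
  blocked <- matrix(FALSE, k, k)
  out <- data.frame(group1 = character(0), group2 = character(0),
                    span = integer(0), q = numeric(0), q_crit = numeric(0),
                    significant = logical(0))
  for (r in seq_len(nrow(pairs))) {
    i <- pairs$i[r]; j <- pairs$j[r]; p <- pairs$span[r]
    qcrit <- stats::qtukey(1 - alpha, p, dfe)
    if (!is.finite(qcrit)) {
      stop(sprintf("studentized-range quantile unavailable (p = %d, df = %g)",
                   p, dfe), call. = FALSE)
    }
    if (skip_all || blocked[i, j]) {
      out[nrow(out) + 1L, ] <- list(gnames[i], gnames[j], p, NA_real_,
                                    qcrit, FALSE)
      next
    }
    se <- sqrt(mse / 2 * (1 / ns[i] + 1 / ns[j]))
    q <- (means[j] - means[i]) / se
    sig <- q > qcrit
    if (!sig) for (a in i:j) for (b in i:j) if (a < b) blocked[a, b] <- TRUE
    out[nrow(out) + 1L, ] <- list(gnames[i], gnames[j], p, q, qcrit, sig)
  }
  attr(out, "anova") <- av
  out
}

#' Pearson correlation with per-group and pooled regressions
#'
#' Pooled Pearson correlation with its t-based p-value, plus the per-group
#' correlation coefficients and least-squares lines for every group with at
#' least 3 complete pairs. Pairs with a missing value in either variable are
#' dropped pairwise (e.g. animals without a technically acceptable pressure
#' recording).
#'
#' @param x,y Numeric vectors of equal length.
#' @param group Group labels, same length.
#' @return A list with `pooled` (`r`, `p`, `n`, `intercept`, `slope`) and
#'   `by_group` (data frame `group`, `n`, `r`, `intercept`, `slope`).
#' @export
pearson_with_groups <- function(x, y, group) {
  stopifnot(length(x) == length(y), length(x) == length(group))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]; group <- factor(group[ok])
  if (length(x) < 3L) stop("need at least 3 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined: zero variance", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  cf <- stats::coef(stats::lm(y ~ x))
  pooled <- list(r = unname(ct$estimate), p = ct$p.value, n = length(x),
                 intercept = unname(cf[1]), slope = unname(cf[2]))
  rows <- lapply(levels(group), function(g) {
    i <- group == g
    if (sum(i) < 3L || stats::sd(x[i]) == 0 || stats::sd(y[i]) == 0) {
      return(NULL)
    }
    cfg <- stats::coef(stats::lm(y[i] ~ x[i]))
    data.frame(group = g, n = sum(i), r = stats::cor(x[i], y[i]),
               intercept = unname(cfg[1]), slope = unname(cfg[2]))
  })
  list(pooled = pooled, by_group = do.call(rbind, rows))
}
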