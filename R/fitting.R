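#' Heuristic starting point for the constant-phase fit
#'
#' A deterministic initial guess obtained by linearising the model at a fixed
#' tissue exponent: with `u = omega^-alpha`, `Re Z = Raw + G*u` and
#' `Im Z = omega*Iaw - H*u` are linear in the parameters, so Raw and G come
#' from a least-squares line of the real part on `u`, and Iaw and H from a
#' two-regressor fit of the imaginary part on `(omega, u)`. Starting from
#' `alpha = 0.9`, the exponent is refreshed from the current G and H estimates
#' and the linear fits repeated a few times (separable least squares over
#' alpha). All components are clipped into the optimisation bounds.
#'
#' @param spectrum An [impedance_spectrum()] with at least 4 frequencies.
#' @param lower,upper Bounds as in [fit_constant_phase()].
#' @return A [constant_phase_params()] start point.
#' @export
heuristic_init <- function(spectrum, lower = c(0, 0, 0, 0),
                           upper = rep(Inf, 4)) {
  stopifnot(inherits(spectrum, "impedance_spectrum"))
  f <- spectrum$frequencies
  z <- spectrum$values
  if (length(f) < 4L) stop("need at least 4 frequencies", call. = FALSE)
  o <- order(f)
  z <- z[o]
  w <- 2 * pi * f[o]
  alpha <- 0.9
  for (it in 1:4) {
    u <- w^-alpha
    cre <- stats::lm.fit(cbind(1, u), Re(z))$coefficients
    cim <- stats::lm.fit(cbind(w, u), Im(z))$coefficients
    alpha <- (2 / pi) * atan(max(-cim[2], 1e-2) / max(cre[2], 1e-2))
  }
  par <- c(cre[1], cim[1], cre[2], -cim[2])
  par <- pmin(pmax(par, lower + 1e-12), upper)
  # keep a usable strictly-positive floor for multiplicative perturbation
  par <- pmax(par, c(1e-3, 1e-5, 1e-2, 1e-2))
  constant_phase_params(par[1], par[2], par[3], par[4])
}

fit_residuals <- function(par, w, z) {
  m <- complex(real = par[1], imaginary = w * par[2])
  if (par[3] > 0 || par[4] > 0) {
    a <- (2 / pi) * atan(par[4] / par[3])
    m <- m + complex(real = par[3], imaginary = -par[4]) / w^a
  }
  d <- m - z
  c(Re(d), Im(d))
}

#' Fit the constant-phase model to an impedance spectrum
#'
#' Complex nonlinear least squares: minimises the sum over frequencies of
#' `(Re Zhat - Re Z)^2 + (Im Zhat - Im Z)^2` over `(Raw, Iaw, G, H)`, with the
#' tissue exponent tied to G and H via [tissue_alpha()] so the search is
#' 4-dimensional, and all parameters bounded below by zero. Levenberg-Marquardt
#' steps (via \pkg{minpack.lm}) are started from the deterministic
#' [heuristic_init()] plus seeded log-uniform multiplicative perturbations; the
#' best local optimum is returned.
#'
#' @param spectrum An [impedance_spectrum()] with >= 4 frequencies.
#' @param init Optional [constant_phase_params()] start; default
#'   [heuristic_init()].
#' @param lower,upper Length-4 bounds on `(raw, iaw, g, h)`.
#' @param multistart Total number of starts (1 heuristic + the rest perturbed).
#' @param seed Optional integer seed for the perturbed starts.
#' @return An object of class `fot_fit`: a list with `params`
#'   ([constant_phase_params()]), `residual_norm` (root-mean-square modulus of
#'   the complex residuals, cmH2O.s/l), `per_frequency_residuals` (complex),
#'   `converged`, `n_iterations`, and `objective` (sum of squares).
#' @examples
#' truth <- constant_phase_params(30, 0.1, 800, 2900)
#' sp <- forward_impedance(truth, seq(0.5, 20.5, length.out = 16))
#' fit_constant_phase(sp)$params
#' @export
fit_constant_phase <- function(spectrum, init = NULL,
                               lower = c(0, 0, 0, 0), upper = rep(Inf, 4),
                               multistart = 5, seed = NULL) {
  stopifnot(inherits(spectrum, "impedance_spectrum"))
  f <- spectrum$frequencies
  if (length(f) < 4L) {
    stop("under-determined: need >= 4 frequencies for 4 parameters",
         call. = FALSE)
  }
  o <- order(f)
  w <- 2 * pi * f[o]
  z <- spectrum$values[o]
  if (is.null(init)) init <- heuristic_init(spectrum, lower, upper)
  stopifnot(inherits(init, "constant_phase_params"))
  p0 <- c(init$raw, init$iaw, init$g, init$h)
  starts <- list(p0)
  if (multistart > 1) {
    perturb <- with_seed(seed, {
      lapply(seq_len(multistart - 1), function(i) {
        fac <- exp(stats::runif(4, log(1 / 3), log(3)))
        pmin(pmax(p0 * fac, lower + 1e-12), upper)
      })
    })
    starts <- c(starts, perturb)
  }
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = s, lower = lower, upper = upper,
                         fn = fit_residuals, w = w, z = z,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 200, ftol = 1e-14, ptol = 1e-14)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) {
    return(structure(list(params = init, residual_norm = NA_real_,
                          per_frequency_residuals = NULL, converged = FALSE,
                          n_iterations = 0L, objective = NA_real_),
                     class = "fot_fit"))
  }
  resid <- fit_residuals(best$par, w, z)
  cplx <- complex(real = resid[seq_along(w)],
                  imaginary = resid[seq_along(w) + length(w)])
  structure(list(
    params = constant_phase_params(best$par[1], best$par[2],
                                   best$par[3], best$par[4]),
    residual_norm = sqrt(mean(Mod(cplx)^2)),
    per_frequency_residuals = cplx,
    converged = best$info %in% 1:4,
    n_iterations = best$niter,
    objective = best$deviance), class = "fot_fit")
}

#' @export
print.fot_fit <- function(x, ...) {
  cat(sprintf("Constant-phase fit (%s, %d iterations)\n",
              if (x$converged) "converged" else "NOT converged",
              x$n_iterations))
  print(x$params)
  cat(sprintf("  residual RMS = %g cmH2O.s/l\n", x$residual_norm))
  invisible(x)
}

#' Aggregate replicate recording fits
#'
#' Protocols record several impedance spectra per condition; each is fitted
#' independently and the accepted fits are averaged. Fits whose residual RMS
#' exceeds `residual_threshold` are rejected as technically unacceptable.
#'
#' @param fits A list of `fot_fit` objects (one per recording).
#' @param residual_threshold Maximum accepted residual RMS, cmH2O.s/l. The
#'   default of 5 corresponds to several times the residual level seen at the
#'   package's default measurement-noise calibration.
#' @return A list with `params` (mean [constant_phase_params()]), `se`
#'   (named standard errors of the four parameters), `n_accepted`, and
#'   `accepted` (logical per input fit).
#' @export
aggregate_recordings <- function(fits, residual_threshold = 5) {
  stopifnot(length(fits) >= 1L,
            all(vapply(fits, inherits, logical(1), "fot_fit")))
  rn <- vapply(fits, function(f) f$residual_norm, numeric(1))
  ok <- is.finite(rn) & rn <= residual_threshold &
    vapply(fits, function(f) isTRUE(f$converged), logical(1))
  if (!any(ok)) {
    stop(sprintf(
      "all %d recording fits rejected (residual RMS threshold %g cmH2O.s/l)",
      length(fits), residual_threshold), call. = FALSE)
  }
  m <- t(vapply(fits[ok], function(f) {
    unlist(f$params[c("raw", "iaw", "g", "h")])
  }, numeric(4)))
  mu <- colMeans(m)
  se <- apply(m, 2, function(v) stats::sd(v) / sqrt(length(v)))
  if (sum(ok) == 1L) se <- rep(0, 4)
  names(se) <- c("raw", "iaw", "g", "h")
  list(params = constant_phase_params(mu[1], mu[2], mu[3], mu[4]),
       se = se, n_accepted = sum(ok), accepted = ok)
}
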