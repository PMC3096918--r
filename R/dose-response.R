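#' Per-animal methacholine dose-response curve
#'
#' Airway resistance (and optionally tissue damping and elastance) measured at
#' baseline and during steady-state bronchoconstriction at each methacholine
#' (MCh) infusion rate.
#'
#' @param doses MCh infusion rates, ug/kg/min, strictly increasing and > 0;
#'   default schedule `c(2, 4, 8, 12, 24)`.
#' @param baseline_raw Baseline airway resistance, cmH2O.s/l (> 0).
#' @param raw Airway resistance at each dose, cmH2O.s/l (NA for missing).
#' @param g,h Optional tissue damping / elastance at each dose, cmH2O/l.
#' @param baseline_g,baseline_h Optional baseline tissue parameters.
#' @return An object of class `dose_response_curve`.
#' @export
dose_response_curve <- function(doses = c(2, 4, 8, 12, 24), baseline_raw, raw,
                                g = NULL, h = NULL,
                                baseline_g = NA_real_, baseline_h = NA_real_) {
  doses <- as.numeric(doses)
  if (any(doses <= 0) || is.unsorted(doses, strictly = TRUE)) {
    stop("doses must be positive and strictly increasing", call. = FALSE)
  }
  if (!is.finite(baseline_raw) || baseline_raw <= 0) {
    stop("baseline_raw must be > 0", call. = FALSE)
  }
  if (length(raw) != length(doses)) {
    stop("'raw' must have one value per dose", call. = FALSE)
  }
  structure(list(doses = doses, baseline_raw = baseline_raw, raw = raw,
                 g = g, h = h, baseline_g = baseline_g,
                 baseline_h = baseline_h),
            class = "dose_response_curve")
}

#' ED50: equivalent dose causing a 50% increase in airway resistance
#'
#' The target is `T = 1.5 * baseline_raw`. Treating baseline as dose 0, the
#' first dose interval over which Raw crosses T is found and the crossing dose
#' obtained by linear interpolation; if the first measured dose already
#' exceeds T the interpolation runs on `[0, d1]`. When T is never reached
#' within the schedule, the behaviour depends on `policy`:
#' `"extrapolate"` (default) continues the last dose segment's line beyond the
#' schedule and flags the result as extrapolated (falling back to censoring at
#' the top dose if the final segment is non-increasing), while `"censor"`
#' returns the top dose flagged as censored above.
#'
#' Non-monotone curves (measurement noise) are handled by the first-crossing
#' rule. ED50 is invariant to rescaling baseline and all Raw values by a
#' common positive factor.
#'
#' @param curve A [dose_response_curve()]; missing Raw values are dropped.
#' @param policy Handling of curves that never reach the target within the
#'   dose schedule; see Details.
#' @return A list with `ed50` (ug/kg), `censored` and `extrapolated` flags.
#' @examples
#' cv <- dose_response_curve(c(2, 4), baseline_raw = 20, raw = c(25, 35))
#' compute_ed50(cv)$ed50  # 3.0
#' @export
compute_ed50 <- function(curve, policy = c("extrapolate", "censor")) {
  stopifnot(inherits(curve, "dose_response_curve"))
  policy <- match.arg(policy)
  keep <- is.finite(curve$raw)
  if (!any(keep)) stop("all Raw values missing", call. = FALSE)
  d <- c(0, curve$doses[keep])
  r <- c(curve$baseline_raw, curve$raw[keep])
  target <- 1.5 * curve$baseline_raw
  for (i in seq_len(length(d) - 1L)) {
    if (r[i] < target && r[i + 1L] >= target) {
      ed <- d[i] + (target - r[i]) / (r[i + 1L] - r[i]) * (d[i + 1L] - d[i])
      return(list(ed50 = ed, censored = FALSE, extrapolated = FALSE))
    }
  }
  n <- length(d)
  if (policy == "extrapolate" && n >= 2L) {
    slope <- (r[n] - r[n - 1L]) / (d[n] - d[n - 1L])
    if (slope > 0) {
      return(list(ed50 = d[n] + (target - r[n]) / slope,
                  censored = FALSE, extrapolated = TRUE))
    }
  }
  list(ed50 = d[n], censored = TRUE, extrapolated = FALSE)
}

#' Percentage change from baseline
#'
#' `100 * (value - baseline) / baseline`; used for the MCh-induced changes in
#' the tissue parameters.
#'
#' @param baseline Baseline value (> 0).
#' @param value Value under the challenge condition.
#' @return Percentage change. Vectorised.
#' @examples
#' percent_change(866, 1150) # ~32.8
#' @export
percent_change <- function(baseline, value) {
  if (any(!is.finite(baseline)) || any(baseline <= 0)) {
    stop("baseline must be finite and > 0", call. = FALSE)
  }
  100 * (value - baseline) / baseline
}

#' Specific airway resistance
#'
#' Airway resistance normalised to the absolute lung volume:
#' `sRaw = Raw * EELV` (cmH2O.s). Normalising Raw by the lung volume can
#' reveal airway narrowing that basal Raw alone does not, because Raw and lung
#' volume covary.
#'
#' @param raw Airway resistance, cmH2O.s/l.
#' @param eelv End-expiratory lung volume, l (> 0).
#' @return Specific resistance, cmH2O.s. Vectorised.
#' @export
specific_raw <- function(raw, eelv) {
  if (any(!is.finite(eelv)) || any(eelv <= 0)) {
    stop("eelv must be finite and > 0", call. = FALSE)
  }
  raw * eelv
}
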