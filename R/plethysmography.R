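#' Occluded-airway manoeuvre recording
#'
#' Tracheal- and box-pressure traces recorded while the airway is occluded at
#' end expiration and the animal makes spontaneous inspiratory efforts inside a
#' closed body plethysmograph. End-expiratory lung volume (EELV) follows from
#' Boyle's law applied to the relation between the two pressures.
#'
#' @param sample_rate Sampling rate, Hz.
#' @param tracheal_pressure Tracheal pressure during occlusion, cmH2O.
#' @param box_pressure Plethysmograph box pressure, cmH2O (as measured, i.e.
#'   possibly distorted by the box's own dynamics).
#' @param n_efforts Number of inspiratory efforts in the trace (typically 3-4).
#' @param barometric_pressure Barometric pressure, cmH2O.
#' @param water_vapor_pressure Saturated water vapour pressure at body
#'   temperature, cmH2O. Must satisfy
#'   `barometric_pressure > water_vapor_pressure > 0`.
#' @param box_calibration Box volume-displacement calibration, l per cmH2O of
#'   (corrected) box pressure.
#' @param box_gain,box_time_constant First-order model of the box's pressure
#'   response: static gain and time constant (s). `box_gain = 1`,
#'   `box_time_constant = 0` is the identity (ideal box).
#' @param effort_id Optional integer vector, one per sample, assigning samples
#'   to efforts; if `NULL`, the trace is split into `n_efforts` equal segments.
#' @return An object of class `occlusion_manoeuvre`.
#' @export
occlusion_manoeuvre <- function(sample_rate, tracheal_pressure, box_pressure,
                                n_efforts, barometric_pressure = 1003,
                                water_vapor_pressure = 33,
                                box_calibration = 1e-4,
                                box_gain = 1, box_time_constant = 0,
                                effort_id = NULL) {
  if (length(tracheal_pressure) != length(box_pressure)) {
    stop("pressure traces must have the same length", call. = FALSE)
  }
  stopifnot(n_efforts >= 1,
            barometric_pressure > water_vapor_pressure,
            water_vapor_pressure > 0,
            box_calibration > 0, box_gain > 0)
  if (box_time_constant < 0) {
    stop("box time constant must be >= 0", call. = FALSE)
  }
  if (!is.null(effort_id)) {
    stopifnot(length(effort_id) == length(tracheal_pressure))
  }
  structure(list(sample_rate = sample_rate,
                 tracheal_pressure = tracheal_pressure,
                 box_pressure = box_pressure,
                 n_efforts = n_efforts,
                 barometric_pressure = barometric_pressure,
                 water_vapor_pressure = water_vapor_pressure,
                 box_calibration = box_calibration,
                 box_gain = box_gain,
                 box_time_constant = box_time_constant,
                 effort_id = effort_id),
            class = "occlusion_manoeuvre")
}

#' Correct a box-pressure trace for the box's own dynamics
#'
#' The plethysmograph box is modelled as a first-order system with static gain
#' and time constant: measured = gain * lowpass(true). The correction inverts
#' that model in the frequency domain, multiplying each Fourier component by
#' `(1 + j*omega*tau) / gain`. Gain 1 and time constant 0 give the identity.
#'
#' @param box_pressure Measured box-pressure samples, cmH2O.
#' @param sample_rate Sampling rate, Hz.
#' @param gain Static gain of the box response (> 0).
#' @param time_constant Time constant tau of the box response, s (>= 0).
#' @return The corrected box-pressure samples.
#' @export
correct_box_pressure <- function(box_pressure, sample_rate, gain = 1,
                                 time_constant = 0) {
  if (!is.finite(gain) || gain <= 0 || !is.finite(time_constant)) {
    stop("box correction parameters must be finite and gain > 0", call. = FALSE)
  }
  if (time_constant < 0) {
    stop("box time constant must be >= 0", call. = FALSE)
  }
  if (gain == 1 && time_constant == 0) return(box_pressure)
  n <- length(box_pressure)
  freq <- c(0:(floor(n / 2)), -((ceiling(n / 2) - 1):1)) * sample_rate / n
  hinv <- (1 + 1i * 2 * pi * freq * time_constant) / gain
  Re(stats::fft(stats::fft(box_pressure) * hinv, inverse = TRUE)) / n
}

# forward first-order box distortion (used by the synthetic generator)
apply_box_distortion <- function(box_pressure, sample_rate, gain = 1,
                                 time_constant = 0) {
  if (gain == 1 && time_constant == 0) return(box_pressure)
  n <- length(box_pressure)
  freq <- c(0:(floor(n / 2)), -((ceiling(n / 2) - 1):1)) * sample_rate / n
  h <- gain / (1 + 1i * 2 * pi * freq * time_constant)
  Re(stats::fft(stats::fft(box_pressure) * h, inverse = TRUE)) / n
}

#' End-expiratory lung volume by Boyle's law
#'
#' For each inspiratory effort against the occlusion: (1) the box pressure is
#' corrected for the box dynamics ([correct_box_pressure()]); (2) the corrected
#' box pressure is converted to thoracic volume change via the box calibration;
#' (3) the volume change is regressed on the tracheal-pressure change over the
#' effort; (4) Boyle's law gives
#' `EELV = (Pb - PH2O) * dV/dPtr`. The manoeuvre's EELV is the mean over
#' accepted efforts.
#'
#' @param m An [occlusion_manoeuvre()].
#' @param min_swing Minimum peak-to-peak tracheal-pressure swing, cmH2O, for an
#'   effort to be accepted (default 5).
#' @param method `"regression"` (least-squares slope of dV on dPtr over the
#'   whole effort; default) or `"peak"` (peak-to-peak amplitude ratio).
#' @return EELV in litres, with attribute `per_effort` (the per-effort values).
#' @examples
#' t <- seq(0, 1, by = 1 / 200)[-201]
#' ptr <- 10 * sin(2 * pi * t)          # 20 cmH2O peak-to-peak
#' pbox <- 0.5e-4 * sin(2 * pi * t)     # 1.0e-4 l swing at calibration 1e-3
#' m <- occlusion_manoeuvre(200, ptr, pbox, n_efforts = 1,
#'                          box_calibration = 1e-3)
#' compute_eelv(m)  # 970 * (1e-4 / 20) = 4.85e-3 l
#' @export
compute_eelv <- function(m, min_swing = 5,
                         method = c("regression", "peak")) {
  stopifnot(inherits(m, "occlusion_manoeuvre"))
  method <- match.arg(method)
  pbox <- correct_box_pressure(m$box_pressure, m$sample_rate,
                               m$box_gain, m$box_time_constant)
  dv <- pbox * m$box_calibration
  ptr <- m$tracheal_pressure
  n <- length(ptr)
  eff <- m$effort_id
  if (is.null(eff)) {
    eff <- rep(seq_len(m$n_efforts), each = ceiling(n / m$n_efforts),
               length.out = n)
  }
  vals <- c()
  for (e in unique(eff)) {
    i <- which(eff == e)
    swing <- diff(range(ptr[i]))
    if (swing < min_swing) next
    slope <- if (method == "regression") {
      stats::cov(dv[i], ptr[i]) / stats::var(ptr[i])
    } else {
      # peak-to-peak ratio, signed by the regression direction
      sign(stats::cov(dv[i], ptr[i])) * diff(range(dv[i])) / swing
    }
    if (!is.finite(slope) || slope <= 0) {
      stop(sprintf(
        "invalid manoeuvre: non-positive dV/dPtr slope (%g) in effort %s",
        slope, e), call. = FALSE)
    }
    vals <- c(vals, (m$barometric_pressure - m$water_vapor_pressure) * slope)
  }
  if (length(vals) == 0L) {
    stop(sprintf(
      "no effort with tracheal-pressure swing >= %g cmH2O", min_swing),
      call. = FALSE)
  }
  structure(mean(vals), per_effort = vals)
}
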