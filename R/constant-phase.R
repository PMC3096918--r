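#' Constant-phase model parameters
#'
#' Container for the four mechanical parameters of the constant-phase model of
#' respiratory input impedance: a frequency-independent Newtonian airway
#' resistance `raw` and airway inertance `iaw` in series with a constant-phase
#' tissue compartment described by tissue damping `g` and tissue elastance `h`.
#' The tissue exponent alpha is not free: it is tied to G and H through
#' [tissue_alpha()].
#'
#' @param raw Newtonian (airway) resistance, cmH2O.s/l. Must be >= 0.
#' @param iaw Airway inertance, cmH2O.s^2/l. Must be >= 0.
#' @param g Tissue damping, cmH2O/l. Must be >= 0.
#' @param h Tissue elastance, cmH2O/l. Must be >= 0.
#'
#' @return An object of class `constant_phase_params`: a list with elements
#'   `raw`, `iaw`, `g`, `h`.
#'
#' @examples
#' p <- constant_phase_params(raw = 30, iaw = 0.1, g = 800, h = 2900)
#' tissue_alpha(p$g, p$h)
#' @export
constant_phase_params <- function(raw, iaw, g, h) {
  for (nm in c("raw", "iaw", "g", "h")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop(sprintf("'%s' must be a single finite number", nm), call. = FALSE)
    }
    if (v < 0) stop(sprintf("'%s' must be >= 0 (got %g)", nm, v), call. = FALSE)
  }
  structure(list(raw = unname(raw), iaw = unname(iaw),
                 g = unname(g), h = unname(h)),
            class = "constant_phase_params")
}

#' @export
print.constant_phase_params <- function(x, ...) {
  cat("Constant-phase model parameters:\n")
  cat(sprintf("  Raw = %g cmH2O.s/l\n  Iaw = %g cmH2O.s^2/l\n", x$raw, x$iaw))
  cat(sprintf("  G   = %g cmH2O/l\n  H   = %g cmH2O/l\n", x$g, x$h))
  if (x$g > 0 || x$h > 0) {
    cat(sprintf("  alpha = %.4f", tissue_alpha(x$g, x$h)))
    if (x$h > 0) cat(sprintf(", eta (G/H) = %.4f", hysteresivity(x$g, x$h)))
    cat("\n")
  }
  invisible(x)
}

#' Constant-phase tissue exponent
#'
#' The exponent of the tissue compartment, `alpha = (2/pi) * atan(h/g)`. It
#' lies in `[0, 1]`, equals 0.5 exactly when `g == h > 0`, and tends to 1 for a
#' purely elastic tissue (`g = 0`).
#'
#' @param g Tissue damping, cmH2O/l, >= 0.
#' @param h Tissue elastance, cmH2O/l, >= 0. `g` and `h` must not both be zero.
#' @return The dimensionless exponent in `[0, 1]`. Vectorised over `g` and `h`.
#' @examples
#' tissue_alpha(1, 1)      # 0.5
#' tissue_alpha(866, 2927) # ~0.817
#' @export
tissue_alpha <- function(g, h) {
  if (any(g < 0) || any(h < 0)) stop("'g' and 'h' must be >= 0", call. = FALSE)
  if (any(g == 0 & h == 0)) {
    stop("tissue exponent undefined when g and h are both zero", call. = FALSE)
  }
  # atan(Inf) = pi/2 gives the g = 0 limit (alpha = 1) automatically
  (2 / pi) * atan(h / g)
}

#' Tissue hysteresivity
#'
#' The ratio `eta = g/h` of tissue damping to tissue elastance, a dimensionless
#' index of the coupling between dissipative and elastic tissue processes.
#'
#' @inheritParams tissue_alpha
#' @return `g/h`; defined only for `h > 0`.
#' @export
hysteresivity <- function(g, h) {
  if (any(h <= 0)) stop("hysteresivity requires h > 0", call. = FALSE)
  g / h
}

#' Impedance spectrum
#'
#' A respiratory input impedance spectrum: complex impedance values on a
#' strictly increasing grid of positive oscillation frequencies, with optional
#' recording metadata. This is the exchange format between the wave-tube
#' estimator, the model fitter, and forward simulation.
#'
#' @param frequencies Oscillation frequencies in Hz; strictly increasing, > 0.
#' @param values Complex impedance at each frequency, cmH2O.s/l.
#' @param recording_id Optional identifier for the recording.
#' @param duration Optional recording length, s.
#' @return An object of class `impedance_spectrum`.
#' @export
impedance_spectrum <- function(frequencies, values, recording_id = NULL,
                               duration = NA_real_) {
  frequencies <- as.numeric(frequencies)
  values <- as.complex(values)
  if (length(frequencies) == 0L) stop("empty frequency grid", call. = FALSE)
  if (length(frequencies) != length(values)) {
    stop("'frequencies' and 'values' must have the same length", call. = FALSE)
  }
  if (any(!is.finite(frequencies)) || any(frequencies <= 0)) {
    stop("all frequencies must be finite and > 0", call. = FALSE)
  }
  if (is.unsorted(frequencies, strictly = TRUE)) {
    stop("frequencies must be strictly increasing", call. = FALSE)
  }
  structure(list(frequencies = frequencies, values = values,
                 recording_id = recording_id, duration = duration),
            class = "impedance_spectrum")
}

#' @export
print.impedance_spectrum <- function(x, ...) {
  cat(sprintf("Impedance spectrum: %d frequencies, %.3g-%.3g Hz",
              length(x$frequencies), min(x$frequencies), max(x$frequencies)))
  if (!is.null(x$recording_id)) cat(sprintf(" [%s]", x$recording_id))
  cat("\n")
  invisible(x)
}

#' @export
as.data.frame.impedance_spectrum <- function(x, ...) {
  data.frame(frequency_hz = x$frequencies,
             z_real = Re(x$values),
             z_imag = Im(x$values))
}

#' Forward evaluation of the constant-phase model
#'
#' Evaluates `Zrs(omega) = Raw + j*omega*Iaw + (G - jH) / omega^alpha` with
#' `omega = 2*pi*f` in rad/s and `alpha = (2/pi)*atan(H/G)`, so that
#' `Re Z = Raw + G/omega^alpha` and `Im Z = omega*Iaw - H/omega^alpha`.
#'
#' @param params A [constant_phase_params()] object.
#' @param frequencies Frequencies in Hz, all > 0.
#' @param recording_id,duration Optional metadata passed to the result.
#' @return An [impedance_spectrum()] on the given grid.
#' @details When `g = h = 0` the tissue compartment is absent and the tissue
#'   term is zero at all frequencies (a purely resistive-inertive model); this
#'   degenerate case is permitted so that resistive fixtures are expressible.
#' @examples
#' p <- constant_phase_params(30, 0.1, 800, 2900)
#' forward_impedance(p, seq(0.5, 20.5, by = 2))
#' @export
forward_impedance <- function(params, frequencies, recording_id = NULL,
                              duration = NA_real_) {
  stopifnot(inherits(params, "constant_phase_params"))
  frequencies <- as.numeric(frequencies)
  if (length(frequencies) == 0L) stop("empty frequency grid", call. = FALSE)
  if (any(frequencies <= 0)) stop("frequencies must be > 0", call. = FALSE)
  omega <- 2 * pi * frequencies
  z <- complex(real = params$raw, imaginary = omega * params$iaw)
  if (params$g > 0 || params$h > 0) {
    alpha <- tissue_alpha(params$g, params$h)
    z <- z + complex(real = params$g, imaginary = -params$h) / omega^alpha
  }
  o <- order(frequencies)
  impedance_spectrum(frequencies[o], z[o], recording_id = recording_id,
                     duration = duration)
}

#' Resonant frequency of the model
#'
#' The unique frequency at which the imaginary part of the constant-phase
#' impedance vanishes (`omega*Iaw = H/omega^alpha`). `Im Z` is strictly
#' increasing in frequency, so the root is found by a bracketed search; used as
#' a sanity diagnostic on fitted parameters.
#'
#' @param params A [constant_phase_params()] object with `iaw > 0` and `h > 0`.
#' @param tol Relative convergence tolerance of the root search.
#' @return Resonant frequency in Hz.
#' @export
resonant_frequency <- function(params, tol = 1e-12) {
  stopifnot(inherits(params, "constant_phase_params"))
  if (params$iaw <= 0 || params$h <= 0) {
    stop("resonance undefined: requires iaw > 0 and h > 0", call. = FALSE)
  }
  alpha <- tissue_alpha(params$g, params$h)
  im <- function(w) w * params$iaw - params$h / w^alpha
  # expand a bracket around a crude scale guess
  w0 <- (params$h / params$iaw)^(1 / 2)
  lo <- w0; hi <- w0
  while (im(lo) >= 0) lo <- lo / 2
  while (im(hi) <= 0) hi <- hi * 2
  w <- stats::uniroot(im, c(lo, hi), tol = tol * w0)$root
  w / (2 * pi)
}

#' Write / read an impedance spectrum as CSV with a JSON sidecar
#'
#' The CSV has columns `frequency_hz,z_real,z_imag`, one row per frequency;
#' the sidecar `<path>.json` carries `recording_id` and `duration`.
#'
#' @param x An [impedance_spectrum()].
#' @param path CSV file path.
#' @return `write_spectrum` returns `path` invisibly; `read_spectrum` returns
#'   the reconstructed [impedance_spectrum()].
#' @export
write_spectrum <- function(x, path) {
  stopifnot(inherits(x, "impedance_spectrum"))
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  meta <- list(recording_id = x$recording_id, duration = x$duration)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_spectrum
#' @export
read_spectrum <- function(path) {
  d <- utils::read.csv(path)
  need <- c("frequency_hz", "z_real", "z_imag")
  if (!all(need %in% names(d))) {
    stop(sprintf("%s: expected columns %s", path,
                 paste(need, collapse = ", ")), call. = FALSE)
  }
  meta <- list(recording_id = NULL, duration = NA_real_)
  side <- paste0(path, ".json")
  if (file.exists(side)) meta <- jsonlite::read_json(side)
  impedance_spectrum(d$frequency_hz,
                     complex(real = d$z_real, imaginary = d$z_imag),
                     recording_id = meta$recording_id,
                     duration = if (is.null(meta$duration)) NA_real_
                                else as.numeric(meta$duration))
}
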