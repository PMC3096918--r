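#' Wave-tube specification
#'
#' Geometry and acoustic constants of the measurement tube used to estimate a
#' terminating (load) impedance from lateral pressures at its two ends. The
#' default propagation model is a lossless tube, `gamma(omega) = j*omega/c`
#' with a real, frequency-independent characteristic impedance; a lossy model
#' can be injected by supplying `gamma` as a function of angular frequency.
#'
#' @param length Tube length, m (> 0).
#' @param characteristic_impedance Characteristic impedance Z0, cmH2O.s/l.
#'   A scalar (applied at all frequencies) or a function of angular frequency
#'   returning a complex value. The default (300) is of the order of the load
#'   impedances measured in rats, which keeps the estimator well conditioned:
#'   the sensitivity of the recovered load to transfer-function noise scales
#'   as `|ZL|^2 / (Z0 |sinh(gamma*L)|)`.
#' @param speed_of_sound Speed of sound in the tube gas, m/s (> 0).
#' @param gamma Optional propagation-constant model: a function of angular
#'   frequency (rad/s) returning complex gamma (1/m). Default: lossless.
#' @return An object of class `wave_tube_spec`.
#' @export
wave_tube_spec <- function(length = 1, characteristic_impedance = 300,
                           speed_of_sound = 343, gamma = NULL) {
  stopifnot(length > 0, speed_of_sound > 0)
  if (is.null(gamma)) {
    c0 <- speed_of_sound
    gamma <- function(omega) complex(real = 0, imaginary = omega / c0)
  }
  stopifnot(is.function(gamma))
  structure(list(length = length,
                 characteristic_impedance = characteristic_impedance,
                 speed_of_sound = speed_of_sound,
                 gamma = gamma),
            class = "wave_tube_spec")
}

# evaluate Z0 and gamma*L on a frequency grid (Hz)
wavetube_constants <- function(spec, frequencies) {
  omega <- 2 * pi * frequencies
  z0 <- spec$characteristic_impedance
  z0 <- if (is.function(z0)) vapply(omega, z0, complex(1)) else
    rep(as.complex(z0), length(omega))
  gl <- vapply(omega, spec$gamma, complex(1)) * spec$length
  list(z0 = z0, gl = gl)
}

#' Default pseudorandom stimulus component set
#'
#' Component frequencies for the pseudorandom forced-oscillation stimulus:
#' prime multiples of the record's frequency resolution `1/duration`, spanning
#' the stimulus band. Prime multiples guarantee that no component is an integer
#' harmonic of another, so nonlinear distortion products of one component do
#' not land on another component's bin.
#'
#' @param duration Record length, s; the frequency resolution is `1/duration`.
#' @param band Two-element numeric, the stimulus band in Hz.
#' @param n_components Number of components to select (spread evenly across
#'   the admissible prime multiples).
#' @return Frequencies in Hz, each an exact multiple of `1/duration`.
#' @export
default_stimulus_frequencies <- function(duration = 6, band = c(0.5, 21),
                                         n_components = 16) {
  lo <- ceiling(band[1] * duration)
  hi <- floor(band[2] * duration)
  k <- lo:hi
  primes <- k[vapply(k, function(x) {
    x >= 2 && all(x %% seq_len(max(1, floor(sqrt(x)))) [-1] != 0)
  }, logical(1))]
  if (length(primes) < n_components) {
    stop("band too narrow for the requested number of components", call. = FALSE)
  }
  idx <- unique(round(seq(1, length(primes), length.out = n_components)))
  primes[idx] / duration
}

#' Synthesize a pseudorandom multifrequency stimulus
#'
#' Sum of sinusoids at the given component frequencies. Each component must be
#' exactly periodic in the record (frequency an integer multiple of
#' `1/duration`), which makes whole-record Fourier coefficients leakage-free
#' without windowing.
#'
#' @param frequencies Component frequencies, Hz.
#' @param duration Record length, s.
#' @param sample_rate Sampling rate, Hz; must exceed twice the highest
#'   component frequency.
#' @param amplitudes Component amplitudes (recycled); default 1.
#' @param phases Component phases in radians; if `NULL`, drawn uniformly on
#'   `[0, 2*pi)` (seeded).
#' @param seed Optional integer seed for the random phases.
#' @return A list of class `fot_stimulus` with elements `t`, `signal`,
#'   `frequencies`, `amplitudes`, `phases`, `sample_rate`, `duration`.
#' @export
synthesize_pseudorandom_stimulus <- function(frequencies, duration = 6,
                                             sample_rate = 256,
                                             amplitudes = 1, phases = NULL,
                                             seed = NULL) {
  frequencies <- as.numeric(frequencies)
  k <- frequencies * duration
  if (any(abs(k - round(k)) > 1e-9)) {
    stop("every component frequency must be an integer multiple of 1/duration",
         call. = FALSE)
  }
  if (sample_rate <= 2 * max(frequencies)) {
    stop("sample_rate must exceed twice the highest stimulus frequency",
         call. = FALSE)
  }
  m <- length(frequencies)
  amplitudes <- rep_len(amplitudes, m)
  if (is.null(phases)) {
    phases <- with_seed(seed, stats::runif(m, 0, 2 * pi))
  }
  stopifnot(length(phases) == m)
  n <- round(duration * sample_rate)
  t <- (seq_len(n) - 1) / sample_rate
  sig <- numeric(n)
  for (i in seq_len(m)) {
    sig <- sig + amplitudes[i] * cos(2 * pi * frequencies[i] * t + phases[i])
  }
  structure(list(t = t, signal = sig, frequencies = frequencies,
                 amplitudes = amplitudes, phases = phases,
                 sample_rate = sample_rate, duration = duration),
            class = "fot_stimulus")
}

#' Crest factor of a sampled signal
#'
#' Peak absolute value over root-mean-square; a measure of how demanding a
#' multifrequency stimulus is for the loudspeaker at a given spectral power.
#'
#' @param x Numeric signal samples.
#' @return The crest factor (dimensionless, >= 1).
#' @export
crest_factor <- function(x) max(abs(x)) / sqrt(mean(x^2))

#' Discrete Fourier coefficients at selected frequencies
#'
#' Two-sided DFT coefficients `sum(x * exp(-2i*pi*f*t)) / n`, so a real cosine
#' of unit amplitude has coefficient magnitude 0.5 at its own frequency. The
#' requested frequencies must be exact bin frequencies of the record.
#'
#' @param x Signal samples.
#' @param sample_rate Sampling rate, Hz.
#' @param frequencies Frequencies at which to extract coefficients, Hz.
#' @return Complex coefficients, one per requested frequency.
#' @export
dft_coefficients <- function(x, sample_rate, frequencies) {
  n <- length(x)
  k <- frequencies * n / sample_rate
  if (any(abs(k - round(k)) > 1e-6)) {
    stop("requested frequencies are not exact DFT bins of this record",
         call. = FALSE)
  }
  X <- stats::fft(x) / n
  X[round(k) + 1L]
}

#' Two-channel pressure recording from the wave-tube
#'
#' One frame of lateral pressure measurements at the loudspeaker end (`p1`)
#' and the tracheal end (`p2`) of the wave-tube.
#'
#' @param sample_rate Sampling rate, Hz.
#' @param p_loudspeaker Pressure samples at the loudspeaker end, cmH2O.
#' @param p_tracheal Pressure samples at the tracheal end, cmH2O.
#' @param stimulus_frequencies Component frequencies of the stimulus, Hz.
#' @return An object of class `pressure_frames`.
#' @export
pressure_frames <- function(sample_rate, p_loudspeaker, p_tracheal,
                            stimulus_frequencies) {
  if (length(p_loudspeaker) != length(p_tracheal)) {
    stop("channels must have the same length", call. = FALSE)
  }
  if (sample_rate <= 2 * max(stimulus_frequencies)) {
    stop("sample_rate must exceed twice the highest stimulus frequency",
         call. = FALSE)
  }
  structure(list(sample_rate = sample_rate,
                 p_loudspeaker = p_loudspeaker,
                 p_tracheal = p_tracheal,
                 stimulus_frequencies = stimulus_frequencies),
            class = "pressure_frames")
}

#' Estimate the pressure transfer function P1/P2
#'
#' Computes, at each stimulus frequency, the ratio of the whole-record discrete
#' Fourier coefficients of the loudspeaker-end and tracheal-end pressures.
#' Given several frames, the estimate is the cross-spectral average
#' `sum(P1 * Conj(P2)) / sum(|P2|^2)` across frames, which down-weights noisy
#' frames coherently.
#'
#' @param frames A [pressure_frames()] object or a list of them (replicate
#'   recordings of the same load).
#' @param noise_floor Minimum tracheal-channel coefficient magnitude; bins
#'   below it are flagged unreliable (returned as attribute `unreliable`).
#' @return Complex transfer-function values, one per stimulus frequency, with
#'   attributes `frequencies` and `unreliable` (logical per bin).
#' @export
estimate_transfer_function <- function(frames, noise_floor = 0) {
  if (inherits(frames, "pressure_frames")) frames <- list(frames)
  stopifnot(length(frames) >= 1L,
            all(vapply(frames, inherits, logical(1), "pressure_frames")))
  freqs <- frames[[1]]$stimulus_frequencies
  num <- complex(length(freqs))
  den <- numeric(length(freqs))
  mag2 <- numeric(length(freqs))
  for (fr in frames) {
    p1 <- dft_coefficients(fr$p_loudspeaker, fr$sample_rate, freqs)
    p2 <- dft_coefficients(fr$p_tracheal, fr$sample_rate, freqs)
    num <- num + p1 * Conj(p2)
    den <- den + Mod(p2)^2
    mag2 <- pmax(mag2, Mod(p2))
  }
  tf <- num / den
  attr(tf, "frequencies") <- freqs
  attr(tf, "unreliable") <- mag2 < noise_floor
  tf
}

#' Load impedance from the wave-tube transfer function
#'
#' The standard two-point relation for a tube of characteristic impedance Z0
#' and propagation constant gamma terminated by a load ZL:
#' `P1/P2 = cosh(gamma*L) + (Z0/ZL)*sinh(gamma*L)`, hence
#' `ZL = Z0*sinh(gamma*L) / (P1/P2 - cosh(gamma*L))`.
#'
#' @param transfer Complex transfer values P1/P2 per stimulus frequency.
#' @param spec A [wave_tube_spec()].
#' @param frequencies Frequencies in Hz; defaults to the `frequencies`
#'   attribute of `transfer`.
#' @param singular_tol Bins where `|P1/P2 - cosh(gamma*L)|` falls below this
#'   tolerance (the closed-end condition) are flagged, not computed.
#' @return An [impedance_spectrum()]; singular bins carry `NA` values and are
#'   listed in the attribute `singular_bins`.
#' @export
load_impedance_from_transfer <- function(transfer, spec,
                                         frequencies = attr(transfer, "frequencies"),
                                         singular_tol = 1e-12) {
  stopifnot(inherits(spec, "wave_tube_spec"), !is.null(frequencies))
  cons <- wavetube_constants(spec, frequencies)
  denom <- transfer - cosh(cons$gl)
  singular <- Mod(denom) < singular_tol
  zl <- cons$z0 * sinh(cons$gl) / denom
  zl[singular] <- NA_complex_
  out <- impedance_spectrum(frequencies, zl)
  attr(out, "singular_bins") <- which(singular)
  out
}

#' Simulate wave-tube pressure recordings for a known load
#'
#' The inverse of the estimator: given a load impedance defined at the
#' stimulus frequencies, generates the two lateral pressure channels whose
#' per-bin coefficient ratio is `cosh(gamma*L) + (Z0/ZL)*sinh(gamma*L)`, with
#' optional additive white Gaussian noise on both channels. Used both for
#' testing the estimator and as the raw-signal layer of synthetic studies.
#'
#' @param load An [impedance_spectrum()] defined at all stimulus frequencies.
#' @param spec A [wave_tube_spec()].
#' @param stimulus A `fot_stimulus` (the tracheal-end pressure waveform); if
#'   `NULL`, a default pseudorandom stimulus at the load's frequencies.
#' @param noise_sd Standard deviation of the additive noise, cmH2O.
#' @param n_frames Number of replicate frames to generate.
#' @param seed Optional integer seed (stimulus phases and noise).
#' @return A list of [pressure_frames()] of length `n_frames`.
#' @export
simulate_pressures_from_load <- function(load, spec, stimulus = NULL,
                                         noise_sd = 0, n_frames = 1,
                                         seed = NULL) {
  stopifnot(inherits(load, "impedance_spectrum"),
            inherits(spec, "wave_tube_spec"))
  with_seed(seed, {
    if (is.null(stimulus)) {
      stimulus <- synthesize_pseudorandom_stimulus(load$frequencies)
    }
    stopifnot(isTRUE(all.equal(sort(stimulus$frequencies), load$frequencies)))
    cons <- wavetube_constants(spec, stimulus$frequencies)
    zl <- load$values[match(stimulus$frequencies, load$frequencies)]
    tf <- cosh(cons$gl) + (cons$z0 / zl) * sinh(cons$gl)
    # p2 is the stimulus; p1 components are scaled/rotated by the transfer
    t <- stimulus$t
    p2_clean <- stimulus$signal
    p1_clean <- numeric(length(t))
    for (i in seq_along(stimulus$frequencies)) {
      a <- stimulus$amplitudes[i] * Mod(tf[i])
      ph <- stimulus$phases[i] + Arg(tf[i])
      p1_clean <- p1_clean + a * cos(2 * pi * stimulus$frequencies[i] * t + ph)
    }
    lapply(seq_len(n_frames), function(k) {
      n <- length(t)
      p1 <- p1_clean + if (noise_sd > 0) stats::rnorm(n, 0, noise_sd) else 0
      p2 <- p2_clean + if (noise_sd > 0) stats::rnorm(n, 0, noise_sd) else 0
      pressure_frames(stimulus$sample_rate, p1, p2, stimulus$frequencies)
    })
  })
}
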