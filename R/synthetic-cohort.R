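#' Synthetic study design
#'
#' Describes a synthetic bronchoprovocation study: per-group sample sizes and
#' distributions of pulmonary arterial pressure (Ppa), end-expiratory lung
#' volume (EELV), baseline constant-phase parameters and true ED50, plus the
#' measurement layer (impedance noise, recordings per condition, dose
#' schedule) and the negative coupling between an animal's Ppa and its
#' log-ED50 that expresses the mechanical-interdependence hypothesis.
#'
#' The six default groups mirror an aorto-caval-shunt (ACS) study of
#' precapillary pulmonary hypertension: sham-operated controls (CC, n = 13),
#' untreated shunt (CS, n = 10), and shunt treated with vasoactive intestinal
#' peptide (VIP, n = 8), iloprost (ILO, n = 10), sildenafil (SIL, n = 7) or
#' tezosentan (TEZ, n = 8). True ED50 is log-normal (positive, right-skewed);
#' Ppa, EELV and mechanics are truncated normal. `ed50_mean` is the
#' arithmetic group mean of true ED50 and `ed50_sdlog` the between-animal
#' log-scale SD. `ppa_missing` is the per-group probability that an animal's
#' Ppa catheterisation is technically unacceptable (recorded as missing,
#' completely at random).
#'
#' @param groups A data frame with one row per group and columns `group`, `n`,
#'   `ppa_sys_mean`, `ppa_sys_sd`, `ppa_dia_mean`, `ppa_dia_sd`,
#'   `ppa_missing`, `eelv_mean`, `eelv_sd` (l), `raw_mean`, `raw_sd`,
#'   `iaw_mean`, `iaw_sd`, `g_mean`, `g_sd`, `h_mean`, `h_sd`, `ed50_mean`,
#'   `ed50_sdlog`. Defaults to [default_study_groups()].
#' @param doses MCh dose schedule, ug/kg/min.
#' @param ppa_ed50_coupling Slope linking an animal's systolic-Ppa deviation
#'   from its group mean (mmHg) to its log-ED50 deviation; negative by
#'   default (higher pressure, lower ED50).
#' @param noise_sd SD of the additive complex Gaussian impedance noise per
#'   real/imaginary component, cmH2O.s/l.
#' @param pressure_noise_sd SD of the additive transducer noise on each
#'   pressure channel in the full-chain (wave-tube) mode, cmH2O.
#' @param baseline_recordings,dose_recordings Integer ranges (vectors to
#'   sample from) for the number of replicate recordings at baseline and at
#'   each dose.
#' @param frequencies Stimulus frequency grid, Hz.
#' @param steepness Dose-response shape exponent `s` of the underlying power
#'   response curve `Raw(d) = b * (1 + 0.5 * (d / ED50)^s)`, which crosses the
#'   50%-increase target exactly at the true ED50; `s = 1` is linear in dose.
#' @param g_change_max,h_change_max Fractional increases of G and H at the top
#'   dose (tissue responses are far more moderate than the airway response).
#' @return An object of class `cohort_design`.
#' @export
cohort_design <- function(groups = default_study_groups(),
                          doses = c(2, 4, 8, 12, 24),
                          ppa_ed50_coupling = -0.02,
                          noise_sd = 1,
                          pressure_noise_sd = 3e-4,
                          baseline_recordings = 4:6,
                          dose_recordings = 3:5,
                          frequencies = default_stimulus_frequencies(),
                          steepness = 1,
                          g_change_max = 0.30,
                          h_change_max = 0.22) {
  need <- c("group", "n", "ppa_sys_mean", "ppa_sys_sd", "ppa_dia_mean",
            "ppa_dia_sd", "ppa_missing", "eelv_mean", "eelv_sd",
            "raw_mean", "raw_sd", "iaw_mean", "iaw_sd", "g_mean", "g_sd",
            "h_mean", "h_sd", "ed50_mean", "ed50_sdlog")
  stopifnot(is.data.frame(groups), all(need %in% names(groups)),
            all(groups$n >= 1),
            all(groups$ed50_mean > 0),
            all(groups$ed50_mean <= 2 * max(doses) * 10))
  sd_cols <- grep("_sd(log)?$", names(groups), value = TRUE)
  stopifnot(all(as.matrix(groups[sd_cols]) >= 0))
  structure(list(groups = groups, doses = doses,
                 ppa_ed50_coupling = ppa_ed50_coupling,
                 noise_sd = noise_sd,
                 pressure_noise_sd = pressure_noise_sd,
                 baseline_recordings = baseline_recordings,
                 dose_recordings = dose_recordings,
                 frequencies = frequencies,
                 steepness = steepness,
                 g_change_max = g_change_max,
                 h_change_max = h_change_max),
            class = "cohort_design")
}

#' Default group-level design table
#'
#' The six study groups with their sample sizes and distributional defaults.
#' Baseline tissue mechanics (G, H) use the group means and between-animal
#' SDs of the emulated study design; baseline Raw, Iaw, EELV and all Ppa
#' levels are plausible adult-rat calibration values chosen for this
#' generator (no published absolute values exist for them in the emulated
#' design), with the untreated-shunt group elevated in systolic Ppa and the
#' iloprost group's hypertension largely reversed. Group-mean true ED50 is
#' 9.9 ug/kg in the untreated-shunt group and 43 ug/kg under iloprost, with
#' the remaining groups at control-like responsiveness.
#'
#' @param subset Optional character vector of group labels to keep.
#' @return The design data frame accepted by [cohort_design()].
#' @export
default_study_groups <- function(subset = NULL) {
  g <- data.frame(
    group = c("CC", "CS", "VIP", "ILO", "SIL", "TEZ"),
    n = c(13L, 10L, 8L, 10L, 7L, 8L),
    ppa_sys_mean = c(24, 38, 36, 27, 36, 36),
    ppa_sys_sd = c(3, 5, 5, 4, 5, 5),
    ppa_dia_mean = c(14, 20, 19, 16, 19, 19),
    ppa_dia_sd = c(2, 3, 3, 3, 3, 3),
    ppa_missing = c(6 / 13, 0, 4 / 8, 5 / 10, 5 / 7, 2 / 8),
    eelv_mean = 5.5e-3, eelv_sd = 0.8e-3,
    raw_mean = 28, raw_sd = 4,
    iaw_mean = 0.10, iaw_sd = 0.02,
    g_mean = c(866, 736, 735, 802, 964, 727),
    g_sd = c(177, 133, 93, 266, 119, 96),
    h_mean = c(2927, 2936, 2589, 2972, 3240, 2370),
    h_sd = c(1078, 528, 730, 1255, 743, 441),
    ed50_mean = c(35, 9.9, 32, 43, 55, 30),
    ed50_sdlog = c(0.5, 0.508, 0.5, 0.709, 0.5, 0.5))
  if (!is.null(subset)) {
    stopifnot(all(subset %in% g$group))
    g <- g[match(subset, g$group), , drop = FALSE]
    rownames(g) <- NULL
  }
  g
}

#' Generate a synthetic cohort
#'
#' Draws per-animal Ppa, EELV and baseline constant-phase parameters from the
#' group distributions (truncated at physiological floors), then draws true
#' log-ED50 as the group log-mean plus the Ppa coupling times the animal's
#' systolic-Ppa deviation plus log-normal noise. The log-mean is set so the
#' arithmetic mean of true ED50 equals the group's `ed50_mean`. Ppa values are
#' masked (missing) completely at random per group; the unmasked truth is kept
#' in a separate truth table, never in the observable records.
#'
#' @param design A [cohort_design()].
#' @param seed Optional integer seed; the draw is fully reproducible given it.
#' @return A list with `cohort` (observable data frame: `animal_id`, `group`,
#'   `ppa_sys`, `ppa_dia`, `eelv`, `raw`, `iaw`, `g`, `h`) and `truth`
#'   (hidden data frame: `animal_id`, `ed50_true`, `ppa_sys_true`,
#'   `ppa_dia_true`).
#' @export
generate_cohort <- function(design, seed = NULL) {
  stopifnot(inherits(design, "cohort_design"))
  with_seed(seed, {
    rows <- list(); truths <- list()
    for (r in seq_len(nrow(design$groups))) {
      gr <- design$groups[r, ]
      n <- gr$n
      id <- sprintf("%s%02d", gr$group, seq_len(n))
      ppa_sys <- rnorm_floor(n, gr$ppa_sys_mean, gr$ppa_sys_sd, 5)
      ppa_dia <- pmin(rnorm_floor(n, gr$ppa_dia_mean, gr$ppa_dia_sd, 2),
                      0.95 * ppa_sys)
      eelv <- rnorm_floor(n, gr$eelv_mean, gr$eelv_sd, 1e-3)
      raw <- rnorm_floor(n, gr$raw_mean, gr$raw_sd, 1)
      iaw <- rnorm_floor(n, gr$iaw_mean, gr$iaw_sd, 1e-3)
      g <- rnorm_floor(n, gr$g_mean, gr$g_sd, 50)
      h <- rnorm_floor(n, gr$h_mean, gr$h_sd, 200)
      meanlog <- log(gr$ed50_mean) - gr$ed50_sdlog^2 / 2
      ed50 <- exp(meanlog +
                    design$ppa_ed50_coupling * (ppa_sys - gr$ppa_sys_mean) +
                    stats::rnorm(n, 0, gr$ed50_sdlog))
      miss <- stats::runif(n) < gr$ppa_missing
      rows[[r]] <- data.frame(
        animal_id = id, group = gr$group,
        ppa_sys = ifelse(miss, NA_real_, ppa_sys),
        ppa_dia = ifelse(miss, NA_real_, ppa_dia),
        eelv = eelv, raw = raw, iaw = iaw, g = g, h = h)
      truths[[r]] <- data.frame(animal_id = id, ed50_true = ed50,
                                ppa_sys_true = ppa_sys,
                                ppa_dia_true = ppa_dia)
    }
    list(cohort = do.call(rbind, rows), truth = do.call(rbind, truths))
  })
}

#' Underlying dose-response truth for one animal
#'
#' Constructs the animal's latent airway response
#' `Raw(d) = baseline * (1 + 0.5 * (d / ed50_true)^steepness)`, which is
#' monotone increasing and crosses the 50%-increase target exactly at the true
#' ED50, and evaluates it (plus far more moderate tissue responses) on the
#' dose schedule. `steepness = 1` makes the response linear in dose, so
#' piecewise-linear ED50 interpolation is exact up to measurement noise; large
#' `steepness` approaches a step at the true ED50.
#'
#' @param baseline_raw Baseline airway resistance, cmH2O.s/l.
#' @param ed50_true True ED50, ug/kg (> 0).
#' @param design A [cohort_design()] (dose schedule, steepness, tissue-change
#'   fractions).
#' @param baseline_g,baseline_h Baseline tissue parameters for the G/H
#'   responses, cmH2O/l.
#' @return A noise-free [dose_response_curve()].
#' @export
generate_dose_response <- function(baseline_raw, ed50_true, design,
                                   baseline_g = NA_real_,
                                   baseline_h = NA_real_) {
  stopifnot(inherits(design, "cohort_design"), ed50_true > 0)
  d <- design$doses
  raw <- baseline_raw * (1 + 0.5 * (d / ed50_true)^design$steepness)
  rel <- d / max(d)
  g <- if (is.finite(baseline_g)) baseline_g * (1 + design$g_change_max * rel)
  h <- if (is.finite(baseline_h)) baseline_h * (1 + design$h_change_max * rel)
  dose_response_curve(d, baseline_raw, raw, g = g, h = h,
                      baseline_g = baseline_g, baseline_h = baseline_h)
}

# one noisy impedance recording of a parameter set
noisy_spectrum <- function(params, frequencies, noise_sd, recording_id) {
  sp <- forward_impedance(params, frequencies, recording_id = recording_id,
                          duration = 6)
  if (noise_sd > 0) {
    n <- length(sp$values)
    sp$values <- sp$values + complex(real = stats::rnorm(n, 0, noise_sd),
                                     imaginary = stats::rnorm(n, 0, noise_sd))
  }
  sp
}

#' Generate the measurement layer for one animal
#'
#' Produces, for baseline and for each dose, the protocol's number of
#' replicate noisy impedance recordings (4-6 at baseline, 3-5 per dose), each
#' a forward constant-phase evaluation of the animal's condition-specific
#' parameters plus complex Gaussian noise; and one synthetic occlusion
#' manoeuvre consistent with the animal's EELV (3-4 inspiratory efforts
#' against a box with a first-order pressure response, which
#' [compute_eelv()] must correct for). In `mode = "wavetube"` each recording
#' is additionally pushed through the wave-tube layer: pressure frames are
#' simulated from the load and the spectrum re-estimated from them.
#'
#' @param animal One row of the observable cohort data frame.
#' @param ed50_true The animal's true ED50 (from the truth table).
#' @param design A [cohort_design()].
#' @param mode `"spectra"` (impedance + noise; default) or `"wavetube"` (full
#'   chain through simulated pressure signals).
#' @param wavetube A [wave_tube_spec()] for the full-chain mode.
#' @param seed Optional integer seed.
#' @return A list with `baseline` (list of [impedance_spectrum()]),
#'   `by_dose` (list per dose of lists of spectra), `manoeuvre`
#'   (an [occlusion_manoeuvre()]) and `truth_curve` (the noise-free
#'   [dose_response_curve()]).
#' @export
generate_measurements <- function(animal, ed50_true, design,
                                  mode = c("spectra", "wavetube"),
                                  wavetube = wave_tube_spec(), seed = NULL) {
  stopifnot(inherits(design, "cohort_design"))
  mode <- match.arg(mode)
  with_seed(seed, {
    curve <- generate_dose_response(animal$raw, ed50_true, design,
                                    baseline_g = animal$g,
                                    baseline_h = animal$h)
    one_condition <- function(params, n_rec, tag) {
      lapply(seq_len(n_rec), function(k) {
        rid <- sprintf("%s_%s_r%d", animal$animal_id, tag, k)
        if (mode == "spectra") {
          noisy_spectrum(params, design$frequencies, design$noise_sd, rid)
        } else {
          load <- forward_impedance(params, design$frequencies)
          fr <- simulate_pressures_from_load(load, wavetube,
                                             noise_sd = design$pressure_noise_sd)
          tf <- estimate_transfer_function(fr)
          sp <- load_impedance_from_transfer(tf, wavetube)
          sp$recording_id <- rid
          sp$duration <- 6
          sp
        }
      })
    }
    nb <- if (length(design$baseline_recordings) > 1)
      sample(design$baseline_recordings, 1) else design$baseline_recordings
    base_params <- constant_phase_params(animal$raw, animal$iaw,
                                         animal$g, animal$h)
    baseline <- one_condition(base_params, nb, "baseline")
    by_dose <- lapply(seq_along(design$doses), function(i) {
      nr <- if (length(design$dose_recordings) > 1)
        sample(design$dose_recordings, 1) else design$dose_recordings
      p <- constant_phase_params(curve$raw[i], animal$iaw,
                                 curve$g[i], curve$h[i])
      one_condition(p, nr, sprintf("d%g", design$doses[i]))
    })
    names(by_dose) <- as.character(design$doses)
    manoeuvre <- generate_occlusion_manoeuvre(animal$eelv)
    list(baseline = baseline, by_dose = by_dose, manoeuvre = manoeuvre,
         truth_curve = curve)
  })
}

#' Synthetic occlusion manoeuvre for a known EELV
#'
#' Sinusoidal inspiratory efforts against the occlusion: the tracheal pressure
#' swings with the given amplitude and the box pressure follows with the
#' volume displacement Boyle's law implies for the target EELV, distorted by
#' the box's first-order response (which the analysis side must undo).
#'
#' @param eelv Target end-expiratory lung volume, l.
#' @param n_efforts Number of efforts (3 or 4 in the protocol).
#' @param swing_amplitude Peak tracheal-pressure amplitude, cmH2O.
#' @param effort_rate Effort frequency, Hz.
#' @param sample_rate Sampling rate, Hz.
#' @param barometric_pressure,water_vapor_pressure As in
#'   [occlusion_manoeuvre()].
#' @param box_calibration Box volume calibration, l/cmH2O.
#' @param box_gain,box_time_constant The box distortion to apply (and record
#'   in the manoeuvre for correction).
#' @param noise_sd SD of additive noise on both traces, as a fraction of each
#'   trace's swing amplitude.
#' @return An [occlusion_manoeuvre()] whose [compute_eelv()] recovers `eelv`.
#' @export
generate_occlusion_manoeuvre <- function(eelv, n_efforts = 3,
                                         swing_amplitude = 10,
                                         effort_rate = 1.5,
                                         sample_rate = 200,
                                         barometric_pressure = 1003,
                                         water_vapor_pressure = 33,
                                         box_calibration = 1e-4,
                                         box_gain = 1,
                                         box_time_constant = 0.02,
                                         noise_sd = 0) {
  dur <- n_efforts / effort_rate
  n <- round(dur * sample_rate)
  t <- (seq_len(n) - 1) / sample_rate
  ptr <- swing_amplitude * sin(2 * pi * effort_rate * t)
  slope <- eelv / (barometric_pressure - water_vapor_pressure) # l per cmH2O
  pbox_true <- ptr * slope / box_calibration
  pbox <- apply_box_distortion(pbox_true, sample_rate, box_gain,
                               box_time_constant)
  if (noise_sd > 0) {
    ptr <- ptr + stats::rnorm(n, 0, noise_sd * swing_amplitude)
    pbox <- pbox + stats::rnorm(n, 0, noise_sd * max(abs(pbox_true)))
  }
  occlusion_manoeuvre(sample_rate, ptr, pbox, n_efforts,
                      barometric_pressure, water_vapor_pressure,
                      box_calibration, box_gain, box_time_constant,
                      effort_id = rep(seq_len(n_efforts),
                                      each = ceiling(n / n_efforts),
                                      length.out = n))
}

#' Simulate a complete synthetic study
#'
#' [generate_cohort()] plus [generate_measurements()] for every animal: the
#' full observable raw material of a study (cohort table, impedance
#' recordings per condition, occlusion manoeuvres) together with the hidden
#' truth table.
#'
#' @inheritParams generate_measurements
#' @param design A [cohort_design()].
#' @param seed Optional integer master seed.
#' @return An object of class `synthetic_study`: list with `design`,
#'   `cohort`, `truth`, `measurements` (named by animal id) and `seed`.
#' @export
simulate_study <- function(design, seed = NULL, mode = c("spectra", "wavetube"),
                           wavetube = wave_tube_spec()) {
  mode <- match.arg(mode)
  with_seed(seed, {
    cg <- generate_cohort(design)
    meas <- lapply(seq_len(nrow(cg$cohort)), function(i) {
      generate_measurements(cg$cohort[i, ], cg$truth$ed50_true[i], design,
                            mode = mode, wavetube = wavetube)
    })
    names(meas) <- cg$cohort$animal_id
    structure(list(design = design, cohort = cg$cohort, truth = cg$truth,
                   measurements = meas, seed = seed),
              class = "synthetic_study")
  })
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf("Synthetic study: %d animals in %d groups (seed %s)\n",
              nrow(x$cohort), length(unique(x$cohort$group)),
              if (is.null(x$seed)) "unset" else x$seed))
  print(table(x$cohort$group))
  invisible(x)
}
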