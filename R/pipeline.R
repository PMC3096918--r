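#' Pipeline configuration
#'
#' Options for the study pipeline: fitting (bounds, multistart, seed,
#' residual-acceptance threshold), ED50 policy, and statistics.
#'
#' @param multistart Starts for each constant-phase fit. The pipeline default
#'   (2) is lower than the single-fit default because the heuristic start is
#'   reliable on protocol-shaped spectra and each study involves thousands of
#'   fits.
#' @param fit_seed Integer seed for the perturbed fit starts.
#' @param residual_threshold Recording-acceptance threshold, cmH2O.s/l
#'   (see [aggregate_recordings()]).
#' @param ed50_policy `"extrapolate"` or `"censor"`, see [compute_ed50()].
#' @param include_censored Include censored ED50s (at the top dose) in group
#'   summaries; default drops them.
#' @param alpha Significance level for the statistical battery.
#' @param eelv_min_swing Minimum effort swing for [compute_eelv()], cmH2O.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(multistart = 2, fit_seed = 1L,
                            residual_threshold = 5,
                            ed50_policy = c("extrapolate", "censor"),
                            include_censored = FALSE,
                            alpha = 0.05, eelv_min_swing = 5) {
  structure(list(multistart = multistart, fit_seed = fit_seed,
                 residual_threshold = residual_threshold,
                 ed50_policy = match.arg(ed50_policy),
                 include_censored = include_censored,
                 alpha = alpha, eelv_min_swing = eelv_min_swing),
            class = "pipeline_config")
}

# fit all recordings of one condition and aggregate
fit_condition <- function(spectra, config) {
  fits <- lapply(spectra, fit_constant_phase,
                 multistart = config$multistart, seed = config$fit_seed)
  aggregate_recordings(fits, residual_threshold = config$residual_threshold)
}

#' Analyse one animal's measurements
#'
#' EELV from the occlusion manoeuvre, aggregated baseline constant-phase fit,
#' aggregated per-dose fits, and ED50 by linear interpolation of the fitted
#' Raw dose-response.
#'
#' @param meas One element of a `synthetic_study`'s `measurements` (or any
#'   list with `baseline`, `by_dose`, `manoeuvre` in the same layout).
#' @param config A [pipeline_config()].
#' @return A one-row data frame: `eelv`, baseline `raw`, `iaw`, `g`, `h`,
#'   per-dose `raw_<dose>`, `ed50`, `ed50_censored`, `ed50_extrapolated`,
#'   and `specific_raw`.
#' @export
analyse_animal <- function(meas, config = pipeline_config()) {
  eelv <- as.numeric(compute_eelv(meas$manoeuvre,
                                  min_swing = config$eelv_min_swing))
  base <- fit_condition(meas$baseline, config)
  doses <- as.numeric(names(meas$by_dose))
  dose_fits <- lapply(meas$by_dose, fit_condition, config = config)
  raw_d <- vapply(dose_fits, function(a) a$params$raw, numeric(1))
  g_d <- vapply(dose_fits, function(a) a$params$g, numeric(1))
  h_d <- vapply(dose_fits, function(a) a$params$h, numeric(1))
  curve <- dose_response_curve(doses, base$params$raw, raw_d,
                               g = g_d, h = h_d,
                               baseline_g = base$params$g,
                               baseline_h = base$params$h)
  ed <- compute_ed50(curve, policy = config$ed50_policy)
  out <- data.frame(eelv = eelv, raw = base$params$raw, iaw = base$params$iaw,
                    g = base$params$g, h = base$params$h,
                    ed50 = ed$ed50, ed50_censored = ed$censored,
                    ed50_extrapolated = ed$extrapolated,
                    specific_raw = specific_raw(base$params$raw, eelv))
  for (i in seq_along(doses)) out[[sprintf("raw_%g", doses[i])]] <- raw_d[i]
  for (i in seq_along(doses)) out[[sprintf("g_%g", doses[i])]] <- g_d[i]
  for (i in seq_along(doses)) out[[sprintf("h_%g", doses[i])]] <- h_d[i]
  out
}

#' Run the full study pipeline on a synthetic (or loaded) study
#'
#' Per animal: EELV, baseline aggregate fit, per-dose aggregate fits and
#' ED50; then the group battery: one-way ANOVAs on baseline EELV, Raw, G, H
#' and specific Raw across groups, mixed-design repeated-measures ANOVA on
#' the fitted Raw across doses, one-way ANOVA plus Student-Newman-Keuls on
#' ED50, and the pooled and per-group Pearson correlation between systolic
#' Ppa and ED50.
#'
#' @param study A `synthetic_study` (from [simulate_study()] or
#'   [read_study()]).
#' @param config A [pipeline_config()].
#' @return An object of class `study_results`: list with `animals` (per-animal
#'   results joined to the cohort table), `group_ed50` (per-group mean, SE, n)
#'   and `stats` (the test results; elements are `NULL` where a test is not
#'   applicable, e.g. a single-group study).
#' @export
run_study_pipeline <- function(study, config = pipeline_config()) {
  stopifnot(inherits(study, "synthetic_study"))
  res <- do.call(rbind, lapply(study$cohort$animal_id, function(id) {
    analyse_animal(study$measurements[[id]], config)
  }))
  animals <- cbind(study$cohort[c("animal_id", "group", "ppa_sys", "ppa_dia")],
                   res)
  use <- if (config$include_censored) rep(TRUE, nrow(animals)) else
    !animals$ed50_censored
  ed <- animals[use, ]
  group_ed50 <- do.call(rbind, lapply(split(ed, ed$group), function(d) {
    data.frame(group = d$group[1], n = nrow(d), ed50_mean = mean(d$ed50),
               ed50_se = stats::sd(d$ed50) / sqrt(nrow(d)))
  }))
  rownames(group_ed50) <- NULL
  multi_group <- length(unique(animals$group)) >= 2
  stats <- list()
  if (multi_group) {
    gl <- function(col) split(animals[[col]], animals$group)
    stats$baseline_anova <- lapply(
      c(eelv = "eelv", raw = "raw", g = "g", h = "h",
        specific_raw = "specific_raw"),
      function(col) oneway_anova(gl(col)))
    doses <- study$design$doses
    long <- do.call(rbind, lapply(doses, function(d) {
      data.frame(animal = animals$animal_id, group = animals$group, dose = d,
                 response = animals[[sprintf("raw_%g", d)]])
    }))
    stats$rm_anova_raw <- rm_anova_two_way(long)
    if (sum(use) >= 4 && length(unique(ed$group)) >= 2 &&
        all(table(ed$group) >= 2)) {
      stats$ed50_anova <- oneway_anova(split(ed$ed50, ed$group))
      stats$ed50_snk <- snk_posthoc(split(ed$ed50, ed$group),
                                    alpha = config$alpha)
    }
  }
  if (sum(is.finite(animals$ppa_sys) & use) >= 3) {
    stats$ppa_ed50 <- pearson_with_groups(animals$ppa_sys[use],
                                          animals$ed50[use],
                                          animals$group[use])
  }
  structure(list(animals = animals, group_ed50 = group_ed50, stats = stats,
                 config = config),
            class = "study_results")
}

#' @export
print.study_results <- function(x, ...) {
  cat(sprintf("Study results: %d animals, %d groups\n", nrow(x$animals),
              length(unique(x$animals$group))))
  print(x$group_ed50)
  if (!is.null(x$stats$ppa_ed50)) {
    cat(sprintf("Pooled Ppa-ED50 Pearson R = %.3f (p = %.3g, n = %d)\n",
                x$stats$ppa_ed50$pooled$r, x$stats$ppa_ed50$pooled$p,
                x$stats$ppa_ed50$pooled$n))
  }
  invisible(x)
}

#' Write / read a study directory
#'
#' Plain-text on-disk layout of a study: `cohort.csv` (one row per animal:
#' `animal_id,group,ppa_sys,ppa_dia`), per-animal spectra under
#' `spectra/<animal_id>/<condition>_<k>.csv` (with JSON sidecars), occlusion
#' manoeuvres under `manoeuvres/<animal_id>.csv`
#' (`t,p_tracheal,p_box` plus a JSON sidecar with the calibration block),
#' a `design.json`, and — for synthetic studies — the hidden truth table
#' under `truth/truth.csv`, kept out of the observable files.
#'
#' @param study A `synthetic_study`.
#' @param dir Directory to create/read.
#' @return `write_study` returns `dir` invisibly; `read_study` returns a
#'   `synthetic_study` (with an empty truth table if `truth/` is absent).
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "synthetic_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(study$cohort, file.path(dir, "cohort.csv"),
                   row.names = FALSE)
  dir.create(file.path(dir, "truth"), showWarnings = FALSE)
  utils::write.csv(study$truth, file.path(dir, "truth", "truth.csv"),
                   row.names = FALSE)
  dsn <- study$design
  dsn$frequencies <- as.numeric(dsn$frequencies)
  jsonlite::write_json(unclass(dsn), file.path(dir, "design.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  for (id in study$cohort$animal_id) {
    m <- study$measurements[[id]]
    sdir <- file.path(dir, "spectra", id)
    dir.create(sdir, recursive = TRUE, showWarnings = FALSE)
    for (k in seq_along(m$baseline)) {
      write_spectrum(m$baseline[[k]],
                     file.path(sdir, sprintf("baseline_%d.csv", k)))
    }
    for (d in names(m$by_dose)) {
      for (k in seq_along(m$by_dose[[d]])) {
        write_spectrum(m$by_dose[[d]][[k]],
                       file.path(sdir, sprintf("dose_%s_%d.csv", d, k)))
      }
    }
    mdir <- file.path(dir, "manoeuvres")
    dir.create(mdir, showWarnings = FALSE)
    mo <- m$manoeuvre
    n <- length(mo$tracheal_pressure)
    utils::write.csv(
      data.frame(t = (seq_len(n) - 1) / mo$sample_rate,
                 p_tracheal = mo$tracheal_pressure,
                 p_box = mo$box_pressure),
      file.path(mdir, paste0(id, ".csv")), row.names = FALSE)
    jsonlite::write_json(
      mo[c("sample_rate", "n_efforts", "barometric_pressure",
           "water_vapor_pressure", "box_calibration", "box_gain",
           "box_time_constant")],
      file.path(mdir, paste0(id, ".csv.json")), auto_unbox = TRUE,
      digits = NA)
  }
  invisible(dir)
}

read_csv_checked <- function(path, need) {
  if (!file.exists(path)) stop(sprintf("missing file: %s", path), call. = FALSE)
  d <- utils::read.csv(path)
  missing_cols <- setdiff(need, names(d))
  if (length(missing_cols)) {
    stop(sprintf("%s: missing column(s) %s", path,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  d
}

#' @rdname write_study
#' @export
read_study <- function(dir) {
  cohort <- read_csv_checked(file.path(dir, "cohort.csv"),
                             c("animal_id", "group", "ppa_sys", "ppa_dia"))
  dj <- jsonlite::read_json(file.path(dir, "design.json"),
                            simplifyVector = TRUE)
  design <- cohort_design(
    groups = as.data.frame(dj$groups), doses = dj$doses,
    ppa_ed50_coupling = dj$ppa_ed50_coupling, noise_sd = dj$noise_sd,
    pressure_noise_sd = dj$pressure_noise_sd,
    baseline_recordings = dj$baseline_recordings,
    dose_recordings = dj$dose_recordings, frequencies = dj$frequencies,
    steepness = dj$steepness, g_change_max = dj$g_change_max,
    h_change_max = dj$h_change_max)
  truth_path <- file.path(dir, "truth", "truth.csv")
  truth <- if (file.exists(truth_path)) utils::read.csv(truth_path) else
    data.frame(animal_id = character(0), ed50_true = numeric(0))
  meas <- lapply(cohort$animal_id, function(id) {
    sdir <- file.path(dir, "spectra", id)
    bfiles <- sort(list.files(sdir, "^baseline_\\d+\\.csv$",
                              full.names = TRUE))
    if (length(bfiles) == 0) {
      stop(sprintf("no baseline spectra for animal %s", id), call. = FALSE)
    }
    baseline <- lapply(bfiles, read_spectrum)
    by_dose <- lapply(design$doses, function(d) {
      dfiles <- sort(list.files(
        sdir, sprintf("^dose_%s_\\d+\\.csv$", d), full.names = TRUE))
      if (length(dfiles) == 0) {
        stop(sprintf("no spectra for animal %s at dose %g", id, d),
             call. = FALSE)
      }
      lapply(dfiles, read_spectrum)
    })
    names(by_dose) <- as.character(design$doses)
    mpath <- file.path(dir, "manoeuvres", paste0(id, ".csv"))
    md <- read_csv_checked(mpath, c("t", "p_tracheal", "p_box"))
    mm <- jsonlite::read_json(paste0(mpath, ".json"), simplifyVector = TRUE)
    manoeuvre <- occlusion_manoeuvre(
      mm$sample_rate, md$p_tracheal, md$p_box, mm$n_efforts,
      mm$barometric_pressure, mm$water_vapor_pressure, mm$box_calibration,
      mm$box_gain, mm$box_time_constant)
    list(baseline = baseline, by_dose = by_dose, manoeuvre = manoeuvre)
  })
  names(meas) <- cohort$animal_id
  structure(list(design = design, cohort = cohort, truth = truth,
                 measurements = meas, seed = NULL),
            class = "synthetic_study")
}

#' Write pipeline results
#'
#' Emits `animals.csv` (per-animal results), `group_ed50.csv`, a JSON
#' statistics report `stats.json` (statistics, degrees of freedom, p-values,
#' post-hoc decisions), and `metadata.json` (package version, seeds, config).
#'
#' @param results A `study_results` from [run_study_pipeline()].
#' @param dir Output directory.
#' @param seed The seed the study was generated with, recorded in metadata.
#' @return `dir`, invisibly.
#' @export
write_results <- function(results, dir, seed = NULL) {
  stopifnot(inherits(results, "study_results"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(results$animals, file.path(dir, "animals.csv"),
                   row.names = FALSE)
  utils::write.csv(results$group_ed50, file.path(dir, "group_ed50.csv"),
                   row.names = FALSE)
  sr <- function(x) if (inherits(x, "stat_result"))
    x[c("test", "statistic", "df", "p_value")] else x
  stats_out <- lapply(results$stats, function(el) {
    if (inherits(el, "stat_result")) return(sr(el))
    if (is.list(el) && !is.data.frame(el)) return(lapply(el, sr))
    el
  })
  jsonlite::write_json(stats_out, file.path(dir, "stats.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows",
                       force = TRUE)
  meta <- list(package = "fotmech",
               version = as.character(utils::packageVersion("fotmech")),
               seed = seed,
               fit_seed = results$config$fit_seed,
               config = unclass(results$config))
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
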