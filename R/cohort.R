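#' Simulate a synthetic maintenance-therapy cohort
#'
#' Emulates the study design the forecaster is validated on: patients on
#' every-8-week infliximab maintenance receive `n_runin` run-in infusions
#' plus the observed cycle's infusion at about 5.9 mg/kg, a mid-cycle serum
#' sample is drawn 26-30 days after that infusion and an end-of-cycle sample
#' 44-56 days after it. Individual parameters are drawn from the prior
#' given simulated covariates (weight log-normal with median 70 kg; albumin
#' normal with mean 42.6 g/L; ATI-positive with probability 0.15);
#' observations carry proportional measurement noise and are flagged as
#' censored below the limit of quantitation.
#'
#' The true parameters and the noise-free end-of-cycle concentration are
#' kept alongside each record for validation, and are never part of the
#' forecaster-facing record.
#'
#' @param prior a [population_prior].
#' @param n_patients number of patients (>= 1).
#' @param dose_mg_per_kg maintenance dose; default 5.9 mg/kg.
#' @param seed optional integer seed.
#' @param n_runin run-in infusions before the observed cycle (default 4,
#'   near steady state).
#' @param cycle_days dosing interval (default 56, q8w).
#' @param weight_median,weight_sdlog log-normal body-weight distribution.
#' @param albumin_mean,albumin_sd normal albumin distribution (g/L),
#'   truncated below at 20.
#' @param ati_prob probability of ATI-positive status.
#' @param mid_window,end_window inclusive integer-day windows (post
#'   infusion) for the mid-cycle and end-of-cycle samples.
#' @param infusion_duration infusion length in days (default 2 h).
#' @param sigma_prop proportional measurement-noise SD; defaults to the
#'   prior's residual error (set 0 for noise-free observations).
#' @return An object of class `"simulated_cohort"`: a list of patients,
#'   each with `record` ([patient_record] carrying the mid-cycle
#'   observation), `true_params`, `true_mid_conc`, `true_end_conc`
#'   (noise-free), `observed_end_conc` (noisy), `mid_time` and `end_time`
#'   (days post infusion).
#' @export
simulate_cohort <- function(prior, n_patients, dose_mg_per_kg = 5.9,
                            seed = NULL, n_runin = 4, cycle_days = 56,
                            weight_median = 70, weight_sdlog = 0.2,
                            albumin_mean = 42.6, albumin_sd = 2.9,
                            ati_prob = 0.15, mid_window = c(26, 30),
                            end_window = c(44, 56),
                            infusion_duration = 1 / 12,
                            sigma_prop = prior$sigma_prop) {
  stopifnot(inherits(prior, "population_prior"))
  if (n_patients < 1) stop("n_patients must be at least 1")
  if (!is.null(seed)) set.seed(seed)
  dose_times <- seq(0, by = cycle_days, length.out = n_runin + 1)
  t_last <- dose_times[n_runin + 1]
  patients <- vector("list", n_patients)
  for (i in seq_len(n_patients)) {
    wt <- stats::rlnorm(1, log(weight_median), weight_sdlog)
    alb <- max(20, stats::rnorm(1, albumin_mean, albumin_sd))
    ati <- stats::runif(1) < ati_prob
    cov <- covariates(wt, alb, ati)
    true_p <- sample_individual(prior, cov)
    dosing <- dosing_history(dose_times, dose_mg_per_kg * wt,
                             infusion_duration)
    mid_t <- sample(seq(mid_window[1], mid_window[2]), 1)
    end_t <- sample(seq(end_window[1], end_window[2]), 1)
    f <- pk_concentration(true_p, dosing, t_last + c(mid_t, end_t))
    noisy <- pmax(0, f * (1 + stats::rnorm(2, 0, sigma_prop)))
    blq <- noisy < prior$loq
    record <- patient_record(sprintf("sim%03d", i), cov, dosing,
                             obs_time = mid_t, obs_conc = noisy[1],
                             blq = blq[1])
    patients[[i]] <- list(record = record, true_params = true_p,
                          true_mid_conc = f[1], true_end_conc = f[2],
                          observed_end_conc = noisy[2],
                          end_blq = blq[2], mid_time = mid_t,
                          end_time = end_t)
  }
  structure(patients, class = "simulated_cohort",
            prior = prior, seed = seed)
}

#' @export
print.simulated_cohort <- function(x, ...) {
  cat(sprintf("Simulated q8w maintenance cohort: %d patients\n", length(x)))
  ec <- vapply(x, `[[`, 0, "true_end_conc")
  cat(sprintf("  true end-of-cycle conc: median %.2f ug/mL (IQR %.2f-%.2f)\n",
              stats::median(ec), stats::quantile(ec, 0.25),
              stats::quantile(ec, 0.75)))
  invisible(x)
}

#' Write a simulated cohort to CSV files
#'
#' Emits `patients.csv` (patient_id, weight_kg, albumin_g_L, ati_positive,
#' obs_time_days, obs_conc_ug_mL, blq — one row per observation) and
#' `dosing.csv` (patient_id, time_days, dose_mg, duration_days) in the
#' forecaster's input dialect, plus `truth.csv` holding the true parameters
#' and concentrations, kept strictly separate from the forecaster inputs.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return Invisibly, the three file paths.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "simulated_cohort"))
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("cannot create output directory: ", dir)
  pat <- do.call(rbind, lapply(cohort, function(p) {
    obs <- p$record$observations
    data.frame(patient_id = p$record$id,
               weight_kg = p$record$covariates$weight,
               albumin_g_L = p$record$covariates$albumin,
               ati_positive = p$record$covariates$ati_positive,
               obs_time_days = obs$time, obs_conc_ug_mL = obs$value,
               blq = obs$blq)
  }))
  dos <- do.call(rbind, lapply(cohort, function(p)
    data.frame(patient_id = p$record$id, time_days = p$record$dosing$time,
               dose_mg = p$record$dosing$dose,
               duration_days = p$record$dosing$duration)))
  tru <- do.call(rbind, lapply(cohort, function(p)
    data.frame(patient_id = p$record$id,
               cl = p$true_params[["cl"]], v1 = p$true_params[["v1"]],
               q = p$true_params[["q"]], v2 = p$true_params[["v2"]],
               mid_time_days = p$mid_time, end_time_days = p$end_time,
               true_mid_conc = p$true_mid_conc,
               true_end_conc = p$true_end_conc,
               observed_end_conc = p$observed_end_conc,
               end_blq = p$end_blq)))
  paths <- file.path(dir, c("patients.csv", "dosing.csv", "truth.csv"))
  utils::write.csv(pat, paths[1], row.names = FALSE)
  utils::write.csv(dos, paths[2], row.names = FALSE)
  utils::write.csv(tru, paths[3], row.names = FALSE)
  invisible(paths)
}

#' Read patient records from the CSV dialect
#'
#' Rebuilds [patient_record] objects from `patients.csv` and `dosing.csv`
#' as written by [write_cohort()] (or assembled by hand). Headers are
#' strict; decimal points and UTF-8 are assumed.
#'
#' @param patients_csv,dosing_csv file paths.
#' @return A named list of [patient_record] objects.
#' @export
read_records <- function(patients_csv, dosing_csv) {
  pat <- utils::read.csv(patients_csv)
  dos <- utils::read.csv(dosing_csv)
  need_p <- c("patient_id", "weight_kg", "albumin_g_L", "ati_positive",
              "obs_time_days", "obs_conc_ug_mL", "blq")
  need_d <- c("patient_id", "time_days", "dose_mg", "duration_days")
  if (!all(need_p %in% names(pat)))
    stop("patients CSV must have columns: ", paste(need_p, collapse = ", "))
  if (!all(need_d %in% names(dos)))
    stop("dosing CSV must have columns: ", paste(need_d, collapse = ", "))
  ids <- unique(pat$patient_id)
  out <- lapply(ids, function(id) {
    pr <- pat[pat$patient_id == id, , drop = FALSE]
    dr <- dos[dos$patient_id == id, , drop = FALSE]
    if (!nrow(dr)) stop("no dosing rows for patient ", id)
    patient_record(id,
                   covariates(pr$weight_kg[1], pr$albumin_g_L[1],
                              pr$ati_positive[1]),
                   dosing_history(dr$time_days, dr$dose_mg,
                                  dr$duration_days),
                   obs_time = pr$obs_time_days,
                   obs_conc = pr$obs_conc_ug_mL,
                   blq = pr$blq)
  })
  names(out) <- as.character(ids)
  out
}
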