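#' A patient record for conditioning the forecast
#'
#' Bundles covariates, the full infusion history, and timed serum
#' concentration observations from the current maintenance cycle.
#' Observation times are expressed in days after the most recent infusion
#' (as trough forecasts are); they are mapped onto the absolute dosing
#' timeline internally.
#'
#' @param id patient identifier (coerced to character).
#' @param cov a [covariates] object.
#' @param dosing a [dosing_history]; must contain at least one infusion.
#' @param obs_time numeric vector of observation times, days after the most
#'   recent infusion (>= 0).
#' @param obs_conc observed concentrations (µg/mL, >= 0). For censored
#'   observations the measured value is ignored and the assay limit of
#'   quantitation is used in the likelihood.
#' @param blq logical vector flagging observations below the limit of
#'   quantitation.
#' @return An object of class `"patient_record"`.
#' @export
patient_record <- function(id, cov, dosing, obs_time = numeric(0),
                           obs_conc = numeric(0), blq = FALSE) {
  stopifnot(inherits(cov, "covariates"), inherits(dosing, "dosing_history"))
  if (nrow(dosing) < 1) stop("a patient record needs at least one infusion")
  obs_time <- as.numeric(obs_time)
  n <- length(obs_time)
  obs_conc <- rep_len(as.numeric(obs_conc), n)
  blq <- rep_len(as.logical(blq), n)
  if (n) {
    if (anyNA(obs_time) || any(obs_time < 0))
      stop("observation times must be non-negative days post infusion")
    if (anyNA(obs_conc) || any(obs_conc < 0))
      stop("observed concentrations must be non-negative")
    if (anyNA(blq)) stop("blq flags must be TRUE/FALSE")
  }
  structure(list(id = as.character(id)[1], covariates = cov, dosing = dosing,
                 observations = data.frame(time = obs_time, value = obs_conc,
                                           blq = blq)),
            class = "patient_record")
}

#' @export
print.patient_record <- function(x, ...) {
  cat(sprintf("Patient %s: %.1f kg, albumin %.1f g/L, ATI %s\n",
              x$id, x$covariates$weight, x$covariates$albumin,
              if (x$covariates$ati_positive) "positive" else "negative"))
  cat(sprintf("  %d infusion(s), last at day %.1f; %d observation(s)\n",
              nrow(x$dosing), last_dose_time(x), nrow(x$observations)))
  if (nrow(x$observations)) print.data.frame(x$observations, row.names = FALSE)
  invisible(x)
}

last_dose_time <- function(record) {
  record$dosing$time[nrow(record$dosing)]
}

# observation times on the absolute dosing timeline
obs_abs_times <- function(record) {
  last_dose_time(record) + record$observations$time
}

#' Censored proportional-error log-likelihood
#'
#' For a quantified observation `y` at time `t` the contribution is the
#' normal log-density with mean `f(t)` and SD `sigma_prop * f(t)`. For an
#' observation censored below the limit of quantitation the contribution is
#' `log Phi((loq - f(t)) / (sigma_prop * f(t)))` (the M3 method). A model
#' prediction of zero with a positive quantified observation yields `-Inf`
#' (returned, not raised).
#'
#' @param params a [pk_params] vector.
#' @param record a [patient_record] with at least one observation.
#' @param prior a [population_prior] supplying `sigma_prop` and `loq`.
#' @return Scalar log-likelihood (sum over observations).
#' @export
log_likelihood <- function(params, record, prior) {
  obs <- record$observations
  if (nrow(obs) < 1) stop("record has no observations; nothing to condition on")
  f <- pk_concentration(params, record$dosing, obs_abs_times(record))
  log_likelihood_conc(f, obs, prior$sigma_prop, prior$loq)
}

# core shared with the sampler: f already evaluated at observation times
log_likelihood_conc <- function(f, obs, sigma, loq) {
  ll <- 0
  for (i in seq_along(f)) {
    fi <- f[i]
    if (obs$blq[i]) {
      # prediction of 0 is certainly below the LOQ
      ll <- ll + if (fi <= 0) 0 else
        stats::pnorm((loq - fi) / (sigma * fi), log.p = TRUE)
    } else {
      if (fi <= 0) return(-Inf)
      ll <- ll + stats::dnorm(obs$value[i], mean = fi, sd = sigma * fi,
                              log = TRUE)
    }
  }
  ll
}

#' Log-density of individual parameters under the population prior
#'
#' The multivariate normal density of `eta = log(params / typical(cov))`
#' under the random-effect covariance `Omega`. Dimensions with `omega = 0`
#' are point masses: the density is evaluated on the remaining dimensions,
#' and is `-Inf` if such a parameter deviates from its typical value.
#'
#' @inheritParams log_likelihood
#' @param cov the patient's [covariates].
#' @return Scalar log-density.
#' @export
log_prior_density <- function(params, prior, cov) {
  validate_pk_params(params)
  typ <- apply_covariates(prior, cov)
  eta <- log(unclass(params) / unclass(typ))
  oc <- omega_chol(prior)
  inactive <- setdiff(1:4, oc$active)
  if (any(abs(eta[inactive]) > 1e-10)) return(-Inf)
  if (!length(oc$active)) return(0)
  z <- forwardsolve(oc$L, eta[oc$active])
  -0.5 * sum(z^2) - sum(log(diag(oc$L))) -
    0.5 * length(oc$active) * log(2 * pi)
}
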