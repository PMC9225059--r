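#' Control parameters for the Metropolis-Hastings sampler
#'
#' @param burnin adaptation iterations discarded before retention (the
#'   proposal scale is tuned here in blocks of `adapt_block`).
#' @param min_span minimum number of post-burn-in iterations the retained
#'   draws must span; the thinning interval is `ceiling(min_span / n_draws)`.
#' @param scale initial log-scale random-walk proposal scale.
#' @param target_accept acceptance rate targeted during adaptation.
#' @param adapt_block iterations per adaptation block.
#' @return A list of class `"mcmc_control"`.
#' @export
mcmc_control <- function(burnin = 500, min_span = 5000, scale = 0.5,
                         target_accept = 0.3, adapt_block = 50) {
  stopifnot(burnin >= 0, min_span >= 1, scale > 0,
            target_accept > 0, target_accept < 1, adapt_block >= 10)
  structure(list(burnin = burnin, min_span = min_span, scale = scale,
                 target_accept = target_accept, adapt_block = adapt_block),
            class = "mcmc_control")
}

#' Condition the population prior on a patient's observations
#'
#' The core fitting function: samples the conditional (posterior)
#' distribution of the individual parameters (Cl, V1, Q, V2) given the
#' patient's dosing history, covariates and timed concentration
#' observations, using a Metropolis-Hastings random walk on the log
#' (random-effect) scale with a jointly Gaussian proposal shaped by the
#' prior covariance. The proposal scale is adapted during burn-in, then
#' frozen; retained draws are thinned so that `n_draws` span at least
#' `min_span` post-burn-in iterations.
#'
#' With zero observations the likelihood is flat and the sampler targets
#' the prior itself (useful for validating the sampler).
#'
#' @param record a [patient_record].
#' @param prior a [population_prior]; defaults to the shipped prior.
#' @param n_draws number of retained posterior draws (default 100).
#' @param seed optional integer seed making the fit fully reproducible.
#' @param control an [mcmc_control] list.
#' @return An object of class `"mipd_fit"` with components `draws` (an
#'   `n_draws x 4` matrix), `acceptance_rate`, `record`, `prior`, `typical`,
#'   `seed` and `control`.
#' @examples
#' prior <- default_prior()
#' rec <- patient_record("p1", covariates(70, 41.5, FALSE),
#'                       dosing_history(c(0, 56, 112, 168, 224), 400),
#'                       obs_time = 28, obs_conc = 9.5)
#' fit <- mipd_fit(rec, prior, n_draws = 50, seed = 1)
#' summary(fit)
#' @export
mipd_fit <- function(record, prior = default_prior(), n_draws = 100,
                     seed = NULL, control = mcmc_control()) {
  stopifnot(inherits(record, "patient_record"),
            inherits(prior, "population_prior"), n_draws >= 1)
  if (!is.null(seed)) set.seed(seed)
  typ <- apply_covariates(prior, record$covariates)
  oc <- omega_chol(prior)
  k <- length(oc$active)
  obs <- record$observations
  have_obs <- nrow(obs) > 0
  t_obs <- if (have_obs) obs_abs_times(record) else numeric(0)

  log_post <- function(eta) {
    lp <- if (k) {
      z <- forwardsolve(oc$L, eta[oc$active])
      -0.5 * sum(z * z)
    } else 0
    if (!have_obs) return(lp)
    p <- unclass(typ) * exp(eta)
    f <- pk_concentration(p, record$dosing, t_obs)
    lp + log_likelihood_conc(f, obs, prior$sigma_prop, prior$loq)
  }

  eta <- rep(0, 4)
  lp_cur <- log_post(eta)
  s <- control$scale
  thin <- max(1L, as.integer(ceiling(control$min_span / n_draws)))
  n_keep_iter <- thin * n_draws
  draws <- matrix(NA_real_, n_draws, 4,
                  dimnames = list(NULL, c("cl", "v1", "q", "v2")))
  acc_post <- 0L
  acc_block <- 0L
  kept <- 0L
  total <- control$burnin + n_keep_iter
  for (it in seq_len(total)) {
    prop <- eta
    if (k) {
      step <- as.numeric(oc$L %*% stats::rnorm(k))
      prop[oc$active] <- eta[oc$active] + s * step
    }
    lp_prop <- log_post(prop)
    if (is.finite(lp_prop) && log(stats::runif(1)) < lp_prop - lp_cur) {
      eta <- prop
      lp_cur <- lp_prop
      if (it <= control$burnin) acc_block <- acc_block + 1L
      else acc_post <- acc_post + 1L
    }
    if (it <= control$burnin && it %% control$adapt_block == 0) {
      rate <- acc_block / control$adapt_block
      s <- max(1e-3, min(10, s * exp(rate - control$target_accept)))
      acc_block <- 0L
    }
    if (it > control$burnin && (it - control$burnin) %% thin == 0) {
      kept <- kept + 1L
      draws[kept, ] <- unclass(typ) * exp(eta)
    }
  }
  acceptance_rate <- acc_post / n_keep_iter
  if (k && (acceptance_rate < 0.05 || acceptance_rate > 0.80))
    warning(sprintf(
      "MH acceptance rate %.2f outside [0.05, 0.80]; inspect mixing", acceptance_rate))
  structure(list(draws = draws, acceptance_rate = acceptance_rate,
                 record = record, prior = prior, typical = typ,
                 seed = seed, control = control, thin = thin),
            class = "mipd_fit")
}

#' @export
print.mipd_fit <- function(x, ...) {
  cat(sprintf(
    "Conditional PK distribution for patient %s: %d draws (MH, acceptance %.2f)\n",
    x$record$id, nrow(x$draws), x$acceptance_rate))
  cat("Posterior medians:\n")
  print(round(apply(x$draws, 2, stats::median), 4))
  invisible(x)
}

#' @describeIn mipd_fit posterior-median individual parameters as
#'   [pk_params].
#' @param object,x a `mipd_fit` object.
#' @param ... unused.
#' @export
coef.mipd_fit <- function(object, ...) {
  m <- apply(object$draws, 2, stats::median)
  pk_params(m[["cl"]], m[["v1"]], m[["q"]], m[["v2"]])
}

#' @describeIn mipd_fit standardized residuals `(y - f) / (sigma * f)` at
#'   the posterior-median parameters; `NA` for censored observations.
#' @export
residuals.mipd_fit <- function(object, ...) {
  obs <- object$record$observations
  if (!nrow(obs)) return(numeric(0))
  f <- pk_concentration(coef(object), object$record$dosing,
                        obs_abs_times(object$record))
  r <- (obs$value - f) / (object$prior$sigma_prop * f)
  r[obs$blq] <- NA_real_
  r
}

#' @describeIn mipd_fit simulate noisy concentration measurements: for each
#'   of `nsim` replicates a posterior draw is taken and proportional
#'   residual error applied at the requested times.
#' @param nsim number of simulated measurement sets.
#' @param seed optional seed.
#' @param times days post most-recent infusion at which to simulate
#'   (defaults to the record's observation times).
#' @export
simulate.mipd_fit <- function(object, nsim = 1, seed = NULL, times = NULL,
                              ...) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(times)) times <- object$record$observations$time
  abs_t <- last_dose_time(object$record) + times
  idx <- sample.int(nrow(object$draws), nsim, replace = TRUE)
  sims <- vapply(idx, function(i) {
    f <- pk_concentration(object$draws[i, ], object$record$dosing, abs_t)
    pmax(0, f * (1 + stats::rnorm(length(f), 0, object$prior$sigma_prop)))
  }, numeric(length(abs_t)))
  m <- matrix(sims, nrow = length(abs_t))
  rownames(m) <- paste0("t", times)
  t(m)
}
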