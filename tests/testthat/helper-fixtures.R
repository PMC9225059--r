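# shared fixtures: cohort-median parameters, q8w dosing, prior variants

median_params <- function() pk_params(cl = 0.300, v1 = 3.36, q = 0.134, v2 = 1.56)

q8w_dosing <- function(n_doses = 4, dose = 350, duration = 1 / 12) {
  dosing_history(seq(0, by = 56, length.out = n_doses), dose, duration)
}

# default prior with selected fields replaced, re-validated
prior_with <- function(...) {
  vals <- unclass(default_prior())
  repl <- list(...)
  vals[names(repl)] <- repl
  population_prior(vals)
}

ref_covariates <- function(ati = FALSE) covariates(70, 41.5, ati)

one_obs_record <- function(obs_conc = 9.5, obs_time = 28, blq = FALSE,
                           cov = ref_covariates(), n_doses = 5, dose = 413) {
  patient_record("t1", cov, q8w_dosing(n_doses, dose),
                 obs_time = obs_time, obs_conc = obs_conc, blq = blq)
}

# draw a random valid parameter set spread around the cohort medians
random_params <- function() {
  pk_params(cl = rlnorm(1, log(0.300), 0.5), v1 = rlnorm(1, log(3.36), 0.3),
            q = rlnorm(1, log(0.134), 0.5), v2 = rlnorm(1, log(1.56), 0.3))
}

# brute-force AUC oracle: concordant-pair fraction with half credit for ties
auc_bruteforce <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# hand-made fit object for methods that only need draws + record + prior
manual_fit <- function(draws, record, prior) {
  structure(list(draws = draws, acceptance_rate = NA_real_, record = record,
                 prior = prior,
                 typical = apply_covariates(prior, record$covariates),
                 seed = NULL, control = mcmc_control(), thin = 1L),
            class = "mipd_fit")
}
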