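#' Dosing history of intravenous infusions
#'
#' Builds an ordered record of zero-order infusion events. Times are days
#' since the first recorded infusion; doses are in mg; durations in days.
#' The default duration corresponds to a standard 2-hour infliximab infusion.
#'
#' @param time numeric vector of infusion start times (days, non-negative,
#'   strictly increasing).
#' @param dose numeric vector of doses (mg, non-negative), recycled to the
#'   length of `time` if scalar.
#' @param duration infusion duration(s) in days (> 0), recycled likewise.
#'   Default `1/12` day (2 h).
#' @return An object of class `"dosing_history"`: a data frame with columns
#'   `time`, `dose`, `duration`.
#' @examples
#' q8w <- dosing_history(time = c(0, 56, 112), dose = 350)
#' @export
dosing_history <- function(time = numeric(0), dose = numeric(0),
                           duration = 1 / 12) {
  time <- as.numeric(time)
  n <- length(time)
  dose <- rep_len(as.numeric(dose), n)
  duration <- rep_len(as.numeric(duration), n)
  if (n > 0) {
    if (anyNA(time) || anyNA(dose) || anyNA(duration))
      stop("dosing history must not contain missing values")
    if (any(time < 0)) stop("infusion start times must be non-negative")
    if (is.unsorted(time, strictly = TRUE))
      stop("infusion start times must be strictly increasing")
    if (any(dose < 0)) stop("doses must be non-negative")
    if (any(duration <= 0)) stop("infusion durations must be positive")
  }
  structure(data.frame(time = time, dose = dose, duration = duration),
            class = c("dosing_history", "data.frame"))
}

#' @export
print.dosing_history <- function(x, ...) {
  cat(sprintf("Dosing history: %d infusion(s)\n", nrow(x)))
  if (nrow(x)) print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Individual pharmacokinetic parameters
#'
#' One realization of the two-compartment disposition parameters: clearance
#' `cl` (L/day), central volume `v1` (L), intercompartmental clearance `q`
#' (L/day) and peripheral volume `v2` (L). All must be strictly positive.
#'
#' @param cl,v1,q,v2 strictly positive scalars.
#' @return Named numeric vector of class `"pk_params"`.
#' @examples
#' pk_params(cl = 0.3, v1 = 3.36, q = 0.134, v2 = 1.56)
#' @export
pk_params <- function(cl, v1, q, v2) {
  p <- c(cl = as.numeric(cl), v1 = as.numeric(v1),
         q = as.numeric(q), v2 = as.numeric(v2))
  validate_pk_params(p)
  structure(p, class = "pk_params")
}

validate_pk_params <- function(p) {
  if (length(p) != 4 || anyNA(p) || any(p <= 0))
    stop("pharmacokinetic parameters (cl, v1, q, v2) must all be strictly positive")
  invisible(p)
}

#' @export
print.pk_params <- function(x, digits = 4, ...) {
  cat("Individual PK parameters (two-compartment):\n")
  print(round(unclass(x), digits))
  invisible(x)
}

# micro-constants k10 = Cl/V1, k12 = Q/V1, k21 = Q/V2
micro_constants <- function(params) {
  validate_pk_params(params)
  c(k10 = params[["cl"]] / params[["v1"]],
    k12 = params[["q"]] / params[["v1"]],
    k21 = params[["q"]] / params[["v2"]])
}

#' Biexponential macro-constants of the two-compartment model
#'
#' Decomposes the two-compartment disposition into its hybrid rate constants
#' `alpha > beta > 0` (roots of `s^2 + (k10+k12+k21) s + k10 k21 = 0`) and
#' coefficients `A`, `B` (1/L) such that a unit intravenous bolus yields a
#' central concentration `A exp(-alpha t) + B exp(-beta t)`; the partial
#' fractions satisfy `A + B = 1/v1`.
#'
#' @param params a [pk_params] object (or equivalent named vector).
#' @return Named numeric vector with `alpha`, `beta` (1/day), `A`, `B` (1/L).
#' @examples
#' macro_constants(pk_params(0.3, 3.36, 0.134, 1.56))
#' @export
macro_constants <- function(params) {
  k <- micro_constants(params)
  s <- k[["k10"]] + k[["k12"]] + k[["k21"]]
  prod <- k[["k10"]] * k[["k21"]]
  disc <- sqrt(s * s - 4 * prod)
  alpha <- (s + disc) / 2
  beta <- 2 * prod / (s + disc)  # stable when disc ~ s
  v1 <- params[["v1"]]
  A <- (alpha - k[["k21"]]) / (v1 * (alpha - beta))
  B <- (k[["k21"]] - beta) / (v1 * (alpha - beta))
  c(alpha = alpha, beta = beta, A = A, B = B)
}

# per-event contribution to central concentration, vectorized over t (days
# relative to the event start). R0 mg/day over tau days; mg/L == ug/mL.
event_concentration <- function(t_rel, R0, tau, mc) {
  out <- numeric(length(t_rel))
  if (R0 <= 0) return(out)
  a <- mc[["alpha"]]; b <- mc[["beta"]]
  Ca <- mc[["A"]] / a; Cb <- mc[["B"]] / b
  during <- t_rel > 0 & t_rel <= tau
  after <- t_rel > tau
  if (any(during)) {
    td <- t_rel[during]
    out[during] <- R0 * (Ca * (1 - exp(-a * td)) + Cb * (1 - exp(-b * td)))
  }
  if (any(after)) {
    ta <- t_rel[after] - tau
    out[after] <- R0 * (Ca * (1 - exp(-a * tau)) * exp(-a * ta) +
                          Cb * (1 - exp(-b * tau)) * exp(-b * ta))
  }
  out
}

#' Central-compartment concentration under a dosing history
#'
#' Closed-form concentration (µg/mL) of the linear two-compartment model with
#' zero-order infusions, by superposition of the per-event solutions. This is
#' the production path used inside the Bayesian sampler; [pk_ode_reference()]
#' provides an independent numerical check.
#'
#' @param params a [pk_params] object.
#' @param dosing a [dosing_history].
#' @param t numeric vector of times (days since the first infusion, >= 0).
#' @return Numeric vector of concentrations (µg/mL); 0 before the first
#'   infusion begins.
#' @examples
#' p <- pk_params(0.3, 3.36, 0.134, 1.56)
#' pk_concentration(p, dosing_history(0, 350, 0.1), t = 28)
#' @export
pk_concentration <- function(params, dosing, t) {
  t <- as.numeric(t)
  if (any(t < 0)) stop("times must be non-negative")
  mc <- macro_constants(params)
  out <- numeric(length(t))
  for (i in seq_len(nrow(dosing))) {
    out <- out + event_concentration(t - dosing$time[i],
                                     dosing$dose[i] / dosing$duration[i],
                                     dosing$duration[i], mc)
  }
  out
}

#' Concentration profile on a time grid
#'
#' Vectorized wrapper around [pk_concentration()] requiring a sorted grid;
#' used for plotting and forecast quantile bands.
#'
#' @inheritParams pk_concentration
#' @param grid sorted numeric vector of times (days).
#' @return Numeric vector, elementwise equal to `pk_concentration`.
#' @export
pk_profile <- function(params, dosing, grid) {
  grid <- as.numeric(grid)
  if (length(grid) == 0) return(numeric(0))
  if (is.unsorted(grid)) stop("time grid must be sorted increasingly")
  pk_concentration(params, dosing, grid)
}

#' Numerical-integration reference for the two-compartment model
#'
#' Independent oracle for [pk_concentration()]: integrates the amount system
#' `dA1/dt = in(t) - (k10 + k12) A1 + k21 A2`, `dA2/dt = k12 A1 - k21 A2`
#' piecewise between infusion start/stop breakpoints with `deSolve::lsoda`
#' at tight tolerances. Used in tests only, never in the forecasting path.
#'
#' @inheritParams pk_profile
#' @param rtol,atol integrator tolerances.
#' @param full if `TRUE`, return a data frame with amounts and the cumulative
#'   eliminated mass (for mass-balance checks) instead of the concentration
#'   vector.
#' @return Numeric vector of concentrations at `grid`, or a data frame when
#'   `full = TRUE`.
#' @export
pk_ode_reference <- function(params, dosing, grid, rtol = 1e-10, atol = 1e-12,
                             full = FALSE) {
  grid <- as.numeric(grid)
  if (length(grid) == 0) return(if (full) data.frame() else numeric(0))
  if (is.unsorted(grid)) stop("time grid must be sorted increasingly")
  if (any(grid < 0)) stop("times must be non-negative")
  k <- micro_constants(params)
  starts <- dosing$time
  ends <- dosing$time + dosing$duration
  rates <- dosing$dose / dosing$duration
  infusion_rate <- function(t) {
    if (!length(starts)) return(0)
    sum(rates[t >= starts & t < ends])
  }
  deriv <- function(t, y, parms) {
    r <- parms$rate
    list(c(r - (k[["k10"]] + k[["k12"]]) * y[1] + k[["k21"]] * y[2],
           k[["k12"]] * y[1] - k[["k21"]] * y[2],
           k[["k10"]] * y[1]))
  }
  brk <- sort(unique(c(0, grid, starts, ends)))
  brk <- brk[brk <= max(grid)]
  y <- c(A1 = 0, A2 = 0, E = 0)
  sol_t <- 0
  sol <- matrix(y, nrow = 1)
  for (i in seq_len(length(brk) - 1)) {
    seg <- c(brk[i], brk[i + 1])
    rate <- infusion_rate(mean(seg))  # constant within segment
    out <- deSolve::lsoda(y, seg, deriv, parms = list(rate = rate),
                          rtol = rtol, atol = atol)
    if (attr(out, "istate")[1] < 0) stop("ODE integration failed")
    y <- out[nrow(out), -1]
    sol_t <- c(sol_t, seg[2])
    sol <- rbind(sol, y)
  }
  idx <- match(grid, sol_t)
  if (anyNA(idx)) stop("internal error: grid point lost during integration")
  res <- data.frame(time = grid, A1 = sol[idx, 1], A2 = sol[idx, 2],
                    eliminated = sol[idx, 3],
                    conc = sol[idx, 1] / params[["v1"]])
  if (full) res else res$conc
}
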