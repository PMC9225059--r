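test_that("dosing history validates its invariants", {
  expect_s3_class(dosing_history(c(0, 56), 350), "dosing_history")
  expect_equal(nrow(dosing_history()), 0)
  expect_error(dosing_history(c(56, 0), 350), "increasing")
  expect_error(dosing_history(c(0, 0), 350), "increasing")
  expect_error(dosing_history(-1, 350), "non-negative")
  expect_error(dosing_history(0, -5), "non-negative")
  expect_error(dosing_history(0, 350, 0), "positive")
  expect_error(pk_params(0, 3.36, 0.134, 1.56), "positive")
})

test_that("macro-constants are the roots of the characteristic polynomial", {
  p <- median_params()
  mc <- macro_constants(p)
  k10 <- 0.300 / 3.36; k12 <- 0.134 / 3.36; k21 <- 0.134 / 1.56
  # independent root-finder oracle on s^2 + (k10+k12+k21) s + k10 k21
  roots <- sort(Re(polyroot(c(k10 * k21, k10 + k12 + k21, 1))))
  expect_equal(mc[["beta"]], -roots[2], tolerance = 1e-12)
  expect_equal(mc[["alpha"]], -roots[1], tolerance = 1e-12)
  expect_gt(mc[["alpha"]], mc[["beta"]])
  expect_gt(mc[["beta"]], 0)
})

test_that("partial fractions satisfy A + B = 1/V1 for random parameter sets", {
  set.seed(101)
  for (i in 1:50) {
    p <- random_params()
    mc <- macro_constants(p)
    expect_equal(mc[["A"]] + mc[["B"]], 1 / p[["v1"]],
                 tolerance = 1e-12)
  }
})

test_that("beta collapses to min(k10, k21) in the one-compartment limit", {
  p <- pk_params(cl = 0.3, v1 = 3.36, q = 1e-12, v2 = 1.56)
  mc <- macro_constants(p)
  expect_equal(mc[["beta"]], min(0.3 / 3.36, 1e-12 / 1.56),
               tolerance = 1e-9)
})

test_that("concentration is zero without dosing and before the first infusion", {
  p <- median_params()
  expect_equal(pk_concentration(p, dosing_history(), c(0, 5, 100)),
               c(0, 0, 0))
  d <- dosing_history(10, 350, 0.1)
  expect_equal(pk_concentration(p, d, c(0, 5, 10)), c(0, 0, 0))
  expect_gt(pk_concentration(p, d, 10.05), 0)
  expect_error(pk_concentration(p, d, -1), "non-negative")
})

test_that("concentration is linear in the dose vector", {
  p <- median_params()
  d1 <- q8w_dosing(4, 350)
  d2 <- q8w_dosing(4, 700)
  tt <- c(0.04, 1, 28, 56, 130, 200)
  expect_equal(pk_concentration(p, d2, tt), 2 * pk_concentration(p, d1, tt),
               tolerance = 1e-12)
})

test_that("closed form matches the ODE oracle at the cohort medians", {
  p <- median_params()
  d <- dosing_history(0, 350, 0.1)
  cf <- pk_concentration(p, d, 28)
  ode <- pk_ode_reference(p, d, c(0, 28))[2]
  expect_equal(cf, ode, tolerance = 1e-6)
})

test_that("profile is continuous at infusion start and stop", {
  p <- median_params()
  d <- q8w_dosing(2)
  eps <- 1e-12
  for (edge in c(0, 1 / 12, 56, 56 + 1 / 12)) {
    lo <- pk_concentration(p, d, max(edge - eps, 0))
    hi <- pk_concentration(p, d, edge + eps)
    expect_lt(abs(hi - lo), 1e-8)
  }
  expect_identical(pk_profile(p, d, numeric(0)), numeric(0))
  expect_error(pk_profile(p, d, c(3, 1)), "sorted")
})

test_that("q8w trough sequence rises monotonically toward steady state", {
  p <- median_params()
  d <- q8w_dosing(6)
  troughs <- pk_concentration(p, d, seq(56, by = 56, length.out = 6) - 1e-6)
  expect_true(all(diff(troughs) > 0))
  expect_true(all(diff(diff(troughs)) < 0))  # approach slows down
  # and agrees with the ODE oracle along the way
  ode <- pk_ode_reference(p, d, seq(56, by = 56, length.out = 6) - 1e-6)
  expect_equal(troughs, ode, tolerance = 1e-6)
})

test_that("ODE reference conserves mass and is zero without drug", {
  p <- median_params()
  expect_equal(pk_ode_reference(p, dosing_history(0, 0, 0.1), c(0, 10, 50)),
               c(0, 0, 0))
  d <- q8w_dosing(3, 350)
  full <- pk_ode_reference(p, d, c(10, 60, 150), full = TRUE)
  infused <- vapply(full$time, function(t)
    sum(pmin(pmax((t - d$time) / d$duration, 0), 1) * d$dose), 0)
  total <- full$A1 + full$A2 + full$eliminated
  expect_equal(total, infused, tolerance = 1e-6)
})

test_that("one-compartment limit reproduces the mono-exponential solution", {
  p <- pk_params(cl = 0.3, v1 = 3.36, q = 1e-10, v2 = 1.56)
  tau <- 1 / 12; R0 <- 350 / tau; k10 <- 0.3 / 3.36
  d <- dosing_history(0, 350, tau)
  tt <- c(1, 7, 28, 56)
  mono <- R0 / (3.36 * k10) * (1 - exp(-k10 * tau)) * exp(-k10 * (tt - tau))
  expect_equal(pk_concentration(p, d, tt), mono, tolerance = 1e-6)
})
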