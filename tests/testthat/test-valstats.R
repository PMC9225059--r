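test_that("dichotomization matches hand enumeration and handles extremes", {
  x <- c(6.1, 7.0, 4.9, 3.2, 5.0, 8.8)
  y <- c(7.2, 4.1, 5.5, 2.0, 6.0, 9.9)
  t <- table_from_threshold(x, y, cutoff = 5)
  # by hand: x>5 & y>5 -> pairs 1,6; x>5 & y<=5 -> 2; x<=5 & y>5 -> 3,5
  expect_equal(unname(c(t[1, 1], t[1, 2], t[2, 1], t[2, 2])), c(2, 1, 2, 1))
  all_pos <- table_from_threshold(rep(9, 4), rep(8, 4), cutoff = 5)
  expect_equal(unname(all_pos[1, 1]), 4)
  expect_equal(sum(all_pos) - all_pos[1, 1], 0)
  low <- table_from_threshold(x, y, cutoff = 0)
  expect_equal(unname(low[1, 1]), 6)
  # ties at the cutoff classify negative (strictly greater is positive)
  expect_equal(unname(table_from_threshold(5, 5, cutoff = 5)[2, 2]), 1)
  expect_error(table_from_threshold(numeric(0), numeric(0)), "non-empty")
})

test_that("kappa reproduces the published concordance value and its limits", {
  k <- cohens_kappa(two_by_two(14, 3, 3, 21))
  expect_equal(round(k$kappa, 2), 0.70)
  expect_equal(round(k$se, 2), 0.11)
  expect_equal(cohens_kappa(two_by_two(9, 0, 0, 12))$kappa, 1)
  expect_equal(cohens_kappa(two_by_two(4, 4, 4, 4))$kappa, 0)
  expect_warning(k0 <- cohens_kappa(two_by_two(7, 0, 0, 0)), "degenerate")
  expect_equal(k0$kappa, 0)
})

test_that("kappa is invariant under transposing the table", {
  set.seed(29)
  for (i in 1:25) {
    cells <- rpois(4, 6)
    if (sum(cells) == 0) cells[1] <- 1
    t1 <- two_by_two(cells[1], cells[2], cells[3], cells[4])
    t2 <- two_by_two(cells[1], cells[3], cells[2], cells[4])
    expect_equal(cohens_kappa(t1)$kappa, cohens_kappa(t2)$kappa)
  }
})

test_that("diagnostic statistics reproduce the published 2x2 summaries", {
  obs <- diagnostic_stats(two_by_two(12, 5, 6, 18))
  expect_equal(round(obs$or, 1), 7.2)
  expect_equal(round(obs$lr_pos, 1), 3.1)
  expect_equal(round(obs$sens, 2), 0.67)
  expect_equal(round(obs$spec, 2), 0.78)
  fc <- diagnostic_stats(two_by_two(12, 2, 6, 21))
  expect_equal(round(fc$or, 1), 21.0)
  expect_equal(round(fc$lr_pos, 1), 7.7)
  # exact value 23/63 = 0.3651; published 0.36 stems from pre-rounded
  # sensitivity/specificity, so allow one unit in the last printed digit
  expect_lt(abs(fc$lr_neg - 0.36), 0.01)
  sym <- diagnostic_stats(two_by_two(3, 3, 3, 3))
  expect_equal(sym$or, 1)
  expect_equal(sym$lr_pos, 1)
  expect_equal(sym$lr_neg, 1)
})

test_that("the odds ratio is invariant to row-wise prevalence scaling", {
  set.seed(31)
  for (i in 1:25) {
    cells <- rpois(4, 5) + 1
    t1 <- two_by_two(cells[1], cells[2], cells[3], cells[4])
    t2 <- two_by_two(3 * cells[1], 3 * cells[2], cells[3], cells[4])
    t3 <- two_by_two(cells[1], cells[2], 4 * cells[3], 4 * cells[4])
    expect_equal(diagnostic_stats(t2)$or, diagnostic_stats(t1)$or)
    expect_equal(diagnostic_stats(t3)$or, diagnostic_stats(t1)$or)
  }
})

test_that("zero cells trigger the continuity correction with a flag", {
  d <- diagnostic_stats(two_by_two(8, 0, 2, 9))
  expect_true(d$corrected)
  expect_equal(d$or, (8.5 * 9.5) / (0.5 * 2.5))
  expect_true(all(is.finite(d$or_ci95)))
  expect_error(diagnostic_stats(two_by_two(0, 0, 0, 0)), "at least one")
})

test_that("Deming regression recovers exact linear relations", {
  x <- c(1, 2, 3.5, 5, 8, 13)
  fit1 <- deming_fit(x, x)
  expect_equal(fit1$slope, 1)
  expect_equal(fit1$intercept, 0, tolerance = 1e-12)
  expect_equal(fit1$r_squared, 1)
  fit2 <- deming_fit(x, 2 * x + 1)
  expect_equal(fit2$slope, 2, tolerance = 1e-10)
  expect_equal(fit2$intercept, 1, tolerance = 1e-9)
  expect_error(deming_fit(x[1:2], x[1:2]), "at least 3")
  expect_error(deming_fit(c(1, 2, 3), c(2, 2, 2)), "uncorrelated")
})

test_that("with lambda = 1 swapping the axes inverts the slope", {
  set.seed(37)
  for (i in 1:10) {
    x <- runif(15, 1, 20)
    y <- 1.4 * x + rnorm(15, 0, 1.5)
    xy <- deming_fit(x, y)$slope
    yx <- deming_fit(y, x)$slope
    expect_equal(xy, 1 / yx, tolerance = 1e-10)
  }
})

test_that("Deming corrects the attenuation that biases least squares", {
  set.seed(41)
  truth <- runif(150, 2, 25)
  x <- truth + rnorm(150, 0, 2)
  y <- truth + rnorm(150, 0, 2)
  ols <- unname(coef(lm(y ~ x))[2])
  dem <- deming_fit(x, y)
  expect_lt(ols, 0.95)  # attenuated
  expect_gt(dem$slope, ols)
  expect_true(dem$slope_ci95[1] <= 1 && 1 <= dem$slope_ci95[2])
})

test_that("AUC equals brute-force pair counting, including ties", {
  scores <- c(0.1, 0.4, 0.35, 0.8, 0.35, 0.9, 0.6, 0.2)
  labels <- c(FALSE, FALSE, TRUE, TRUE, FALSE, TRUE, TRUE, FALSE)
  expect_equal(roc_auc(scores, labels)$auc, auc_bruteforce(scores, labels))
  perfect <- roc_auc(c(1, 2, 3, 7, 8, 9), c(0, 0, 0, 1, 1, 1))
  expect_equal(perfect$auc, 1)
  expect_error(roc_auc(1:5, rep(TRUE, 5)), "both")
})

test_that("AUC of uninformative scores is near one half", {
  set.seed(43)
  scores <- rnorm(2000)
  labels <- rbinom(2000, 1, 0.5)
  a <- roc_auc(scores, labels)
  expect_equal(a$auc, 0.5, tolerance = 0.05)
  expect_true(a$ci95[1] < 0.5 && 0.5 < a$ci95[2])
})

test_that("AUC and DeLong interval agree with an independent implementation", {
  set.seed(47)
  scores <- round(c(rnorm(30, 1), rnorm(40, 0)), 1)  # rounding induces ties
  labels <- rep(c(TRUE, FALSE), c(30, 40))
  ours <- roc_auc(scores, labels)
  ref <- pROC::roc(response = labels, predictor = scores, quiet = TRUE,
                   direction = "<")
  expect_equal(ours$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-12)
  ci <- as.numeric(pROC::ci.auc(ref, method = "delong"))
  expect_equal(ours$ci95, ci[c(1, 3)], tolerance = 1e-6)
})
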