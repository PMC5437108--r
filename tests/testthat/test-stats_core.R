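test_that("crawford_howell_t matches the hand-evaluated formula and rules", {
  ctl <- control_sample(c(10, 12, 14, 16, 18))
  expect_equal(ctl$mean, 14)
  expect_equal(ctl$sd, sqrt(10))

  # zero numerator
  s0 <- crawford_howell_t(14, ctl)
  expect_equal(s0$t_value, 0)
  expect_identical(s0$classification, "spared")

  # hand evaluation: -6 / (3.1623 * sqrt(6/5))
  s <- crawford_howell_t(8, ctl)
  expect_equal(s$t_value, -6 / (sqrt(10) * sqrt(6 / 5)), tolerance = 1e-12)
  expect_equal(s$t_value, -1.732, tolerance = 1e-3)
  expect_equal(s$df, 4)
  expect_equal(s$p, 2 * pt(s$t_value, 4), tolerance = 1e-12)

  # classification boundary: impaired strictly below -1.96
  ctl2 <- control_sample(c(-1, 0, 1, 2, -2, 0.5, -0.5, 1.5))
  mk <- function(t) crawford_howell_t(
    ctl2$mean + t * ctl2$sd * sqrt((ctl2$n + 1) / ctl2$n), ctl2)
  expect_identical(mk(-2.00)$classification, "impaired")
  expect_identical(mk(-1.90)$classification, "spared")
  expect_identical(mk(-1.96)$classification, "indeterminate")

  expect_error(crawford_howell_t(1, control_sample(c(3, 3, 3))), "sd")
  expect_error(control_sample(5), "n >= 2")
})

test_that("crawford_howell_t is invariant under common affine rescaling", {
  set.seed(42)
  for (i in 1:10) {
    ctl <- rnorm(8, 10, 3)
    x <- rnorm(1, 8, 4)
    a <- runif(1, -5, 5); b <- runif(1, 0.1, 10)
    t1 <- crawford_howell_t(x, ctl)$t_value
    t2 <- crawford_howell_t(a + b * x, a + b * ctl)$t_value
    expect_equal(t1, t2, tolerance = 1e-10)
  }
})

test_that("composite_semantic z-transforms per task and centers", {
  comp <- composite_semantic(cbind(A = c(1, 2, 3), B = c(2, 4, 6),
                                   C = c(0, 0, 3)))
  expect_equal(comp$value, c(-0.859, -0.192, 1.052), tolerance = 1e-3)
  expect_equal(sum(comp$value), 0, tolerance = 1e-10)

  # any input sums to zero; a patient at the group mean on all tasks gets 0
  set.seed(7)
  m2 <- matrix(rnorm(12), 4, 3)
  m2[4, ] <- colMeans(m2[1:3, ])    # row 4 sits at the overall column means
  expect_equal(composite_semantic(m2)$value[4], 0, tolerance = 1e-10)
  expect_equal(sum(composite_semantic(matrix(rnorm(30), 10, 3))$value), 0,
               tolerance = 1e-10)

  expect_error(composite_semantic(cbind(c(1, 2), c(3, 3))), "degenerate")
})

test_that("welch and pooled t reproduce hand calculations", {
  expect_equal(welch_t(21.62, 4.60, 21, 27.94, 1.66, 18)$t, -5.87,
               tolerance = 5e-3)
  expect_equal(welch_t(50.95, 9.77, 21, 67.17, 1.54, 18)$t, -7.50,
               tolerance = 5e-3)
  expect_equal(welch_t(5, 2, 10, 5, 2, 10)$t, 0)
  expect_equal(student_t_pooled(10.43, 8.26, 21, 17.06, 6.07, 18)$t, -2.81,
               tolerance = 5e-3)
  # {1,2,3} vs {4,5,6}: sp = 1
  expect_equal(student_t_pooled(2, 1, 3, 5, 1, 3)$t, -3 / sqrt(2 / 3),
               tolerance = 1e-12)
  expect_equal(student_t_pooled(2, 1, 3, 5, 1, 3)$t, -3.674, tolerance = 1e-3)
  expect_error(welch_t(1, 0, 5, 1, 0, 5), "undefined")
  expect_error(student_t_pooled(1, 0, 5, 1, 0, 5), "undefined")
})

test_that("welch equals pooled when n and sd match", {
  set.seed(11)
  for (i in 1:10) {
    m1 <- rnorm(1); m2 <- rnorm(1); s <- runif(1, 0.5, 3)
    n <- sample(3:30, 1)
    w <- welch_t(m1, s, n, m2, s, n)
    p <- student_t_pooled(m1, s, n, m2, s, n)
    expect_equal(w$t, p$t, tolerance = 1e-12)
    expect_equal(w$df, p$df, tolerance = 1e-12)
  }
})

test_that("pearson_r handles the toy cases and perfect linearity", {
  expect_equal(pearson_r(1:5, 1:5)$r, 1)
  expect_equal(pearson_r(1:5, -(1:5))$r, -1)
  r <- pearson_r(c(1, 2, 3), c(1, 3, 2))
  expect_equal(r$r, 0.5, tolerance = 1e-12)
  expect_equal(r$df, 1)
  set.seed(3)
  for (i in 1:5) {
    x <- rnorm(10); b <- runif(1, -4, 4); if (b == 0) b <- 1
    expect_equal(pearson_r(x, 2 + b * x)$r, sign(b), tolerance = 1e-10)
  }
  expect_error(pearson_r(rep(1, 5), rnorm(5)), "constant")
})

test_that("partial_r matches the residualize-then-correlate oracle", {
  # hand case: within-group residuals anti-aligned
  expect_equal(partial_r(c(1, 2, 3, 4), c(2, 1, 4, 3),
                         matrix(c(1, 1, 2, 2)))$r, -1, tolerance = 1e-12)
  # zero covariates = plain Pearson
  set.seed(13)
  x <- rnorm(20); y <- rnorm(20)
  expect_equal(partial_r(x, y)$r, pearson_r(x, y)$r, tolerance = 1e-12)
  # oracle agreement on random problems
  for (i in 1:10) {
    n <- 25
    C <- matrix(rnorm(n * 3), n, 3)
    x <- rnorm(n) + C %*% runif(3)
    y <- rnorm(n) + C %*% runif(3)
    pr <- partial_r(as.numeric(x), as.numeric(y), C)
    expect_equal(pr$r, oracle_partial_r(as.numeric(x), as.numeric(y), C),
                 tolerance = 1e-10)
    expect_equal(pr$df, n - 2L - 3L)
  }
  # degenerate: covariate equal to x
  x <- rnorm(10)
  expect_error(partial_r(x, rnorm(10), matrix(x)), "constant|undefined")
  expect_error(partial_r(rnorm(10), rnorm(10),
                         cbind(1:10, 2 * (1:10))), "collinear")
})

test_that("fisher_z is atanh with saturation errors", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), 0.5493, tolerance = 1e-4)
  r <- runif(5, -0.99, 0.99)
  expect_equal(fisher_z(-r), -fisher_z(r))
  expect_error(fisher_z(1), "saturated")
})

test_that("pearson_chi2 on 2x2 tables", {
  expect_equal(pearson_chi2(matrix(c(10, 5, 20, 10), 2))$chi2, 0)
  # the printed group counts 10/11 vs 7/11: Pearson value is 0.300
  expect_equal(pearson_chi2(matrix(c(10, 7, 11, 11), 2))$chi2, 0.3004,
               tolerance = 1e-3)
  expect_equal(pearson_chi2(matrix(c(10, 0, 0, 10), 2))$chi2, 20)
  expect_error(pearson_chi2(matrix(c(0, 0, 5, 5), 2)), "margin")
})

test_that("classify_sd_diagnosis applies core and other feature rules", {
  ctl_atl <- control_sample(c(10, 11, 12, 9, 10, 11, 10, 11))
  imp <- structure(list(classification = "impaired"), class = "nb_corrected_score")
  spa <- structure(list(classification = "spared"), class = "nb_corrected_score")
  full <- list(oral_picture_naming = imp, oral_sound_naming = imp,
               picture_matching = imp, word_matching = imp,
               word_picture_verification = imp,
               surface_dyslexia = imp, object_knowledge = imp,
               repetition = spa, speech_production = spa)
  atl_low <- ctl_atl$mean - 2 * ctl_atl$sd - 0.01
  expect_true(classify_sd_diagnosis(full, atl_low, ctl_atl)$meets_criteria)

  # all spared -> not SD
  all_spared <- lapply(full, function(x) spa)
  expect_false(classify_sd_diagnosis(all_spared, atl_low, ctl_atl)$meets_criteria)

  # boundary: exactly mean - 2 sd fails the strict atrophy rule
  d <- classify_sd_diagnosis(full, ctl_atl$mean - 2 * ctl_atl$sd, ctl_atl)
  expect_false(d$anterior_temporal_atrophy)
  expect_false(d$meets_criteria)

  # only 2 of 4 other features -> not SD
  two <- full; two$repetition <- imp; two$surface_dyslexia <- spa
  expect_false(classify_sd_diagnosis(two, atl_low, ctl_atl)$meets_criteria)

  expect_error(classify_sd_diagnosis(full[-1], atl_low, ctl_atl), "incomplete")
})
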