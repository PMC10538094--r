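test_that("noise-free responses at the standard levels recover the generating line", {
  b <- simulate_calibration_batch(slope = 0.8466, intercept = 12.36,
                                  levels = printed_levels, noise_cv = 0)
  for (w in c("unweighted", "1/x", "1/x^2")) {
    fit <- fit_calibration(b, w)
    expect_equal(fit$slope, 0.8466, tolerance = 1e-10)
    expect_equal(fit$intercept, 12.36, tolerance = 1e-10)
    expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  }
})

test_that("two points give the interpolating line with r^2 = 1", {
  b <- calibration_batch(c(10, 100), c(20, 200))
  fit <- fit_calibration(b)
  expect_equal(fit$slope, 2)
  expect_equal(fit$intercept, 0, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1)
})

test_that("weighted fit matches a brute-force minimizer of the weighted objective", {
  set.seed(5)
  for (i in 1:10) {
    w <- sample(c("unweighted", "1/x", "1/x^2"), 1)
    b <- simulate_calibration_batch(slope = stats::runif(1, 0.3, 2),
                                    intercept = stats::runif(1, 0, 30),
                                    noise_cv = 0.05, seed = 100 + i)
    fit <- fit_calibration(b, w)
    ref <- oracle_wls(b, w)
    expect_equal(fit$slope, ref[["slope"]], tolerance = 1e-6)
    expect_equal(fit$intercept, ref[["intercept"]], tolerance = 1e-6)
  }
})

test_that("1/x-weighted coefficients scale linearly with the responses", {
  b <- simulate_calibration_batch(noise_cv = 0.05, seed = 8)
  f1 <- fit_calibration(b, "1/x")
  b2 <- b; b2$response <- 3.5 * b$response
  f2 <- fit_calibration(b2, "1/x")
  expect_equal(f2$slope, 3.5 * f1$slope)
  expect_equal(f2$intercept, 3.5 * f1$intercept)
})

test_that("singular or underdetermined designs are rejected", {
  expect_error(calibration_batch(c(50, 50, 50), c(1, 2, 3)), "distinct")
  expect_error(calibration_batch(100, 1), "equal length|distinct")
})

test_that("back-calculation inverts the calibration line and flags sub-blank responses", {
  fit <- fit_calibration(simulate_calibration_batch(noise_cv = 0))
  expect_equal(back_calculate(fit, fit$slope * 100 + fit$intercept),
               100, ignore_attr = TRUE)
  expect_equal(back_calculate(fit, 12.36), 0, ignore_attr = TRUE,
               tolerance = 1e-9)
  neg <- back_calculate(fit, 5)
  expect_lt(as.numeric(neg), 0)
  expect_true(attr(neg, "sub_blank"))
  expect_error(back_calculate(list(slope = 0, intercept = 1), 10), "non-zero")
  # round trip across the calibrated range
  x <- c(7.5, 33, 250, 499)
  expect_equal(back_calculate(fit, fit$slope * x + fit$intercept), x,
               ignore_attr = TRUE)
})

test_that("QC evaluation reproduces hand-computed precision and accuracy", {
  fit <- fit_calibration(simulate_calibration_batch(noise_cv = 0))
  # noiseless replicates: accuracy exactly 100%, RSD 0
  resp <- rep(fit$slope * 50 + fit$intercept, 4)
  ev <- evaluate_qc(fit, resp, 50)
  expect_equal(ev$accuracy_pct, 100)
  expect_equal(ev$rsd_pct, 0)
  # detected {49, 51} at nominal 50
  ev2 <- evaluate_qc(fit, fit$slope * c(49, 51) + fit$intercept, 50)
  expect_equal(ev2$accuracy_pct, 100)
  expect_equal(ev2$rsd_pct, 100 * stats::sd(c(49, 51)) / 50)
  expect_error(evaluate_qc(fit, 42, 50), "2 QC replicates")
})

test_that("a simulated intra/inter-day QC run yields the standard report layout", {
  fit <- fit_calibration(simulate_calibration_batch(noise_cv = 0))
  set.seed(21)
  rows <- list()
  for (nominal in c(50, 250)) {
    for (d in 1:3) {
      resp <- fit$slope * nominal + fit$intercept +
        stats::rnorm(4, 0, 0.01 * fit$slope * nominal)
      rows[[length(rows) + 1L]] <-
        as.data.frame(evaluate_qc(fit, resp, nominal, sprintf("day-%d", d)))
    }
  }
  tab <- do.call(rbind, rows)
  expect_named(tab, c("scope", "nominal_ng_ml", "detected_mean_ng_ml",
                      "rsd_pct", "accuracy_pct", "n"))
  expect_identical(nrow(tab), 6L)
  expect_true(all(tab$rsd_pct < 5))
  expect_true(all(abs(tab$accuracy_pct - 100) < 5))
})

test_that("LOQ acceptance applies closed 80-120% and 20% bounds with reasons", {
  fit <- list(slope = 1, intercept = 0)
  mk <- function(detected, nominal = 7.5)
    evaluate_qc(c(fit, list()), detected, nominal, "LOQ")
  ok <- mk(rep(c(7.4, 7.6), 4)[1:7])
  expect_true(check_loq_acceptance(ok)$pass)
  # boundary cases are accepted (closed bounds)
  at_bounds <- structure(list(nominal = 7.5, detected_mean = 9, rsd_pct = 20,
                              accuracy_pct = 120, n = 7, scope = "LOQ"),
                         class = "qc_evaluation")
  expect_true(check_loq_acceptance(at_bounds)$pass)
  low <- structure(list(nominal = 7.5, detected_mean = 6, rsd_pct = 5,
                        accuracy_pct = 79.9, n = 7, scope = "LOQ"),
                   class = "qc_evaluation")
  res <- check_loq_acceptance(low)
  expect_false(res$pass)
  expect_match(res$reasons, "accuracy")
  expect_warning(check_loq_acceptance(ok <- mk(c(7.4, 7.5, 7.6))), "n = 3")
})

test_that("LOD/LOQ follow S/N proportionality with ratio 10/3", {
  expect_equal(lod_loq_from_sn(7.5, 10)[["loq"]], 7.5)
  res <- lod_loq_from_sn(7.5, 30)
  expect_equal(res[["lod"]], 0.75)
  expect_equal(res[["loq"]], 2.5)
  for (conc in c(1, 7.5, 80)) for (sn in c(3, 10, 42)) {
    r <- lod_loq_from_sn(conc, sn)
    expect_equal(r[["loq"]] / r[["lod"]], 10 / 3)
  }
  expect_error(lod_loq_from_sn(-1, 10), "positive")
  expect_error(lod_loq_from_sn(7.5, 0), "positive")
})

test_that("stability deviation is signed and the 15% bound is closed", {
  at_bound <- assess_stability(c(42.5, 42.5), 50)
  expect_equal(at_bound$deviation_pct, -15)
  expect_true(at_bound$pass)
  expect_true(assess_stability(50, 50)$pass)
  fail <- assess_stability(42.4, 50)
  expect_equal(fail$deviation_pct, -15.2)
  expect_false(fail$pass)
  expect_error(assess_stability(42, -50), "positive")
})

test_that("slope and intercept converge to generator truth as noise vanishes", {
  errs <- vapply(c(0.05, 0.01, 0.001), function(cv) {
    fit <- fit_calibration(simulate_calibration_batch(noise_cv = cv, seed = 31,
                                                      replicates = 4))
    abs(fit$slope - 0.8466) / 0.8466
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[3], 1e-3)
})
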