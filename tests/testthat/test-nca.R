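test_that("Cmax/Tmax is the observed maximum with earliest-time tie-break", {
  p <- pk_profile("S", 100, c(0, 0.5, 1, 2), c(0, 10, 85, 40))
  expect_equal(cmax_tmax(p), c(cmax = 85, tmax = 1))
  tie <- pk_profile("S", 100, c(0, 0.5, 1, 1.5, 2), c(0, 10, 85, 85, 40))
  expect_equal(cmax_tmax(tie)[["tmax"]], 1)
  all_blq <- censor_blq(pk_profile("S", 100, c(1, 2), c(1, 2)), 7.5)
  expect_error(cmax_tmax(all_blq), "no quantifiable")
  # dense noise-free profile: observed Tmax within one grid step of analytic
  p0 <- pk_params(tlag = 0)
  grid <- seq(0, 12, by = 0.05)
  ct <- cmax_tmax(simulate_profile(p0, grid))
  expect_lt(abs(ct[["tmax"]] - tmax_analytic(p0)), 0.05 + 1e-12)
})

test_that("lag time is the last BLQ/zero time before the first quantifiable sample", {
  prof <- pk_profile("S", 100, c(0, 0.5, 1, 2), c(NA, NA, 20, 10),
                     blq = c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(estimate_tlag(prof), 0.5)
  early <- pk_profile("S", 100, c(0, 0.5, 1), c(0, 15, 20),
                      blq = c(TRUE, FALSE, FALSE))
  expect_equal(estimate_tlag(early), 0)
  # generative tlag 0.4 h: grid-limited to 0 on the sparse study schedule...
  p <- pk_params(tlag = 0.4)
  sparse <- censor_blq(simulate_profile(p, study_schedule), 7.5)
  expect_true(estimate_tlag(sparse) %in% c(0, 0.5))
  # ...and recovered on a refined grid
  fine <- censor_blq(simulate_profile(p, c(0, seq(0.05, 24, by = 0.05))), 7.5)
  expect_equal(estimate_tlag(fine), 0.4)
})

test_that("an exactly mono-exponential tail selects the full post-Tmax suffix", {
  times <- c(0, 0.5, 1, 2, 3, 5, 8, 12, 24)
  conc <- c(0, 40, 80, 70 * exp(-0.2 * (2 - 2)), 70 * exp(-0.2 * (3 - 2)),
            70 * exp(-0.2 * 3), 70 * exp(-0.2 * 6), 70 * exp(-0.2 * 10),
            70 * exp(-0.2 * 22))
  prof <- pk_profile("S", 100, times, conc)
  idx <- select_terminal_phase(prof)
  expect_identical(idx, 4:9)  # every point after Tmax = 1 h
  fit <- fit_lambda_z(prof, idx)
  expect_equal(fit$lambda_z, 0.2, tolerance = 1e-12)
})

test_that("terminal window selection matches exhaustive enumeration", {
  profiles <- list(biexp_profile(),
                   censor_blq(simulate_profile(typical_params(), study_schedule), 7.5))
  set.seed(17)
  for (i in 1:15) {
    n <- sample(6:12, 1)
    times <- sort(sample(seq(0.5, 24, by = 0.25), n))
    conc <- 80 * exp(-0.3 * times) * exp(stats::rnorm(n, 0, 0.2))
    conc[1] <- max(conc) * 1.05  # ensure a defined early peak
    profiles[[length(profiles) + 1L]] <- pk_profile("R", 100, times, conc)
  }
  for (prof in profiles) {
    expect_identical(select_terminal_phase(prof), oracle_select_window(prof))
  }
})

test_that("too few post-peak points yield no terminal window", {
  prof <- pk_profile("S", 100, c(0, 1, 2, 3), c(0, 80, 40, 20))
  expect_identical(select_terminal_phase(prof), integer(0))
  res <- run_nca(prof)
  expect_s3_class(res, "nca_result")
  expect_true("lambda_z_unavailable" %in% res$flags)
  expect_true(is.na(res$t_half))
})

test_that("lambda-z regression reproduces exact and hand-computed slopes", {
  prof <- pk_profile("S", 100, c(5, 8, 24), 100 * exp(-0.2 * c(5, 8, 24)))
  fit <- fit_lambda_z(prof, 1:3)
  expect_equal(fit$lambda_z, 0.2, tolerance = 1e-12)
  expect_true(fit$valid)
  # increasing tail: negative lambda-z flagged invalid
  up <- pk_profile("S", 100, c(5, 8, 24), c(10, 20, 40))
  expect_false(fit_lambda_z(up, 1:3)$valid)
  # noisy tail equals the closed-form simple-regression slope
  set.seed(9)
  t <- c(3, 5, 8, 12, 24)
  y <- 90 * exp(-0.25 * t) * exp(stats::rnorm(5, 0, 0.1))
  noisy <- pk_profile("S", 100, t, y)
  slope_hand <- sum((t - mean(t)) * (log(y) - mean(log(y)))) / sum((t - mean(t))^2)
  expect_equal(fit_lambda_z(noisy, 1:5)$lambda_z, -slope_hand, tolerance = 1e-12)
  expect_error(fit_lambda_z(noisy, 1:2), "at least 3")
})

test_that("linear trapezoid handles rectangles, triangles and BLQ conventions", {
  flat <- pk_profile("S", 100, c(0, 1, 2), c(10, 10, 10))
  expect_equal(auc_linear_trapezoid(flat), 20)
  tri <- pk_profile("S", 100, c(0, 1), c(0, 10))
  expect_equal(auc_linear_trapezoid(tri), 5)
  # pre-peak BLQ counts as zero; post-peak BLQ is dropped
  prof <- pk_profile("S", 100, c(0, 0.5, 1, 2, 3), c(NA, 10, 80, NA, 20),
                     blq = c(TRUE, FALSE, FALSE, TRUE, FALSE))
  expect_equal(auc_linear_trapezoid(prof),
               0.5 * 10 / 2 + 0.5 * 90 / 2 + 2 * 100 / 2)
  expect_error(auc_linear_trapezoid(tri, 0.5, 0.6), "fewer than 2")
})

test_that("trapezoid is additive over interior points and close to quadrature", {
  p <- typical_params()
  dense <- simulate_profile(p, seq(0, 48, by = 0.1))
  for (a in c(1, 5, 24)) {
    expect_equal(auc_linear_trapezoid(dense, 0, a) + auc_linear_trapezoid(dense, a, 48),
                 auc_linear_trapezoid(dense, 0, 48))
  }
  quad <- stats::integrate(function(t) conc_one_cpt(p, t), 0, 48,
                           rel.tol = 1e-10)$value
  expect_equal(auc_linear_trapezoid(dense), quad, tolerance = 5e-3)
  # chord above curve: trapezoid never underestimates a convex decay segment
  tail_seg <- pk_profile("S", 100, c(5, 8), 70 * exp(-0.2 * c(5, 8)))
  exact <- 70 / 0.2 * (exp(-0.2 * 5) - exp(-0.2 * 8))
  expect_gte(auc_linear_trapezoid(tail_seg), exact)
})

test_that("tail extrapolation and derived parameters follow the stated formulas", {
  res <- auc_0_inf(auc_0_t = 400, c_last = 8, lambda_z = 0.2)
  expect_equal(res$auc_0_inf, 440)
  expect_equal(res$pct_extrapolated, 100 * 40 / 440)
  expect_false(res$extrapolation_warning)
  expect_true(auc_0_inf(10, 8, 0.2)$extrapolation_warning)
  expect_error(auc_0_inf(400, 8, -0.1), "positive")
  # limit: vanishing Clast
  expect_equal(auc_0_inf(400, 1e-12, 0.2)$auc_0_inf, 400, tolerance = 1e-10)

  expect_equal(derive_parameters(100, 1e5, log(2))[["t_half"]], 1)
  expect_equal(derive_parameters(100, 1e5, log(2))[["cl_over_f"]], 1)
  # hand unit-conversion arithmetic on a published-scale AUC
  d <- derive_parameters(100, 441.86, 0.1764)
  expect_equal(d[["cl_over_f"]], 100 * 1e6 / 441.86 / 1e3)
  expect_equal(d[["vd_over_f"]], d[["cl_over_f"]] / 0.1764)
  expect_error(derive_parameters(0, 1, 1), "positive")
})

test_that("full NCA recovers generative parameters on a dense noise-free profile", {
  p <- typical_params()
  res <- run_nca(simulate_profile(p, seq(0, 48, by = 0.1)))
  expect_s3_class(res, "nca_result")
  expect_lt(abs(res$lambda_z - p$kel) / p$kel, 0.01)
  expect_lt(abs(res$t_half - log(2) / p$kel) / (log(2) / p$kel), 0.01)
  expect_lt(abs(res$auc_0_inf - auc_analytic(p)) / auc_analytic(p), 0.02)
  cl_true <- 1000 * p$dose / auc_analytic(p)
  expect_lt(abs(res$cl_over_f - cl_true) / cl_true, 0.02)
  expect_lt(abs(res$vd_over_f - p$vd_over_f) / p$vd_over_f, 0.02)
})

test_that("NCA identities hold exactly on the sparse study schedule", {
  res <- run_nca(simulate_profile(typical_params(), study_schedule))
  expect_equal(res$t_half * res$lambda_z, log(2), tolerance = 1e-12)
  expect_equal(res$vd_over_f * res$lambda_z, res$cl_over_f, tolerance = 1e-12)
  expect_gte(res$auc_0_inf, res$auc_0_t)
  expect_true(res$pct_extrapolated >= 0 && res$pct_extrapolated < 100)
})

test_that("population means recover generative values under assay noise", {
  cfg <- population_config(iiv_cv = c(ka = 0, kel = 0, vd_over_f = 0),
                           assay_cv = 0.05, lloq = 0.001, n_subjects = 200,
                           seed = 13, tlag_halfwidth = 0,
                           schedule = c(0, 0.5, 1, 1.5, 2, 3, 5, 8, 12, 16, 24))
  results <- lapply(simulate_population(cfg), run_nca)
  summ <- summarize_population(results)
  kel_row <- summ[summ$parameter == "lambda_z", ]
  se <- kel_row$sd / sqrt(kel_row$n)
  expect_lt(abs(kel_row$mean - cfg$typical$kel), 3 * se + 0.02 * cfg$typical$kel)
})

test_that("an all-BLQ subject yields a structured error and correct n accounting", {
  pop <- lapply(1:4, function(i)
    censor_blq(simulate_profile(typical_params(), study_schedule,
                                subject_id = paste0("S", i)), 7.5))
  # one subject with negligible exposure: everything below the LLOQ
  weak <- simulate_profile(pk_params(vd_over_f = 1500 * 1000, dose = 100),
                           study_schedule, subject_id = "S5")
  pop[["S5"]] <- censor_blq(weak, 7.5)
  results <- lapply(pop, run_nca)
  expect_s3_class(results[["S5"]], "nca_error")
  expect_match(results[["S5"]]$message, "insufficient quantifiable data")
  summ <- summarize_population(results)
  expect_identical(attr(summ, "n_failed"), 1L)
  expect_identical(attr(summ, "failed_subjects"), "S5")
  expect_identical(summ$n[summ$parameter == "cmax"], 4L)
})

test_that("population summaries use arithmetic mean and n-1 sample SD", {
  mk <- function(id, cmax) structure(list(subject_id = id, dose = 100,
    cmax = cmax, tmax = 1, tlag = 0, lambda_z = 0.2, lambda_z_n_points = 3L,
    lambda_z_r2_adj = 1, t_half = log(2) / 0.2, auc_0_t = 400,
    auc_0_inf = 440, pct_extrapolated = 9.1, cl_over_f = 227,
    vd_over_f = 1136, flags = character(0)), class = "nca_result")
  same <- summarize_population(list(mk("A", 3), mk("B", 3)))
  expect_equal(same$sd[same$parameter == "cmax"], 0)
  two <- summarize_population(list(mk("A", 1), mk("B", 3)))
  expect_equal(two$mean[two$parameter == "cmax"], 2)
  expect_equal(two$sd[two$parameter == "cmax"], sqrt(2))
  expect_error(summarize_population(list()), "no NCA results")
})
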