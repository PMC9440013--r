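# OLS calibration, bootstrap SEs and nested-model comparison.

noiseless_records <- function(n = 40, seed = 5, truth = get_model("lw", "I")) {
  generate_chemicals(synthetic_config(n = n, seed = seed, truth = truth,
                                      noise_sd = 0))
}

test_that("noiseless data generated from a registry model is recovered exactly", {
  fit <- fit_lfer(noiseless_records(), "lw")
  expect_equal(fit$model$c0, -0.236, tolerance = 1e-10)
  expect_equal(fit$model$c_ow, 1.102, tolerance = 1e-10)
  expect_equal(fit$model$c_aw, 0.069, tolerance = 1e-10)
  expect_equal(fit$stats$r2, 1, tolerance = 1e-12)
  expect_equal(fit$stats$rmse, 0, tolerance = 1e-10)
})

test_that("the four-point toy set reproduces the hand-solved normal equations", {
  rec <- data.frame(record_id = as.character(1:4),
                    log_kow = c(0, 1, 0, 1), log_kaw = c(0, 0, 1, 1),
                    log_klw_exp = c(1, 2, 0, 1))
  fit <- fit_lfer(rec, "lw")
  expect_equal(fit$model$c0, 1, tolerance = 1e-12)
  expect_equal(fit$model$c_ow, 1, tolerance = 1e-12)
  expect_equal(fit$model$c_aw, -1, tolerance = 1e-12)
  expect_equal(fit$stats$rmse, 0, tolerance = 1e-12)
})

test_that("fits agree with an independent normal-equations oracle", {
  rec <- generate_chemicals(synthetic_config(n = 80, seed = 21))
  fit <- fit_lfer(rec, "lw")
  X <- as.matrix(rec[c("log_kow", "log_kaw")])
  cf <- oracle_ols(X, rec$log_klw_exp)
  expect_equal(unname(c(fit$model$c0, fit$model$c_ow, fit$model$c_aw)),
               unname(cf), tolerance = 1e-10)
  se <- oracle_ols_se(X, rec$log_klw_exp)
  expect_equal(unname(fit$model$se), unname(se), tolerance = 1e-10)
  # statistic invariants
  expect_lte(fit$stats$adj_r2, fit$stats$r2)
  expect_gte(fit$stats$rse, fit$stats$rmse)
  expect_equal(mean(fit$residuals), 0, tolerance = 1e-10)
  expect_equal(fit$stats$r2,
               oracle_pearson(fit$fitted, rec$log_klw_exp)^2,
               tolerance = 1e-10)
})

test_that("degenerate designs are refused", {
  rec <- data.frame(record_id = as.character(1:10),
                    log_kow = 1:10, log_kaw = 2 * (1:10) + 3,
                    log_klw_exp = rnorm(10))
  expect_error(fit_lfer(rec, "lw"), "collinear")
  expect_error(fit_lfer(make_records(3), "lw"), "insufficient")
  expect_error(fit_lfer(make_records(10), "pw"), "insufficient")
  nopw <- make_records(10)[setdiff(chem_record_columns, "log_kpw_exp")]
  expect_error(fit_lfer(nopw, "pw"), "log_kpw_exp")
})

test_that("bootstrap SEs are reproducible and track analytic SEs", {
  rec <- generate_chemicals(synthetic_config(n = 300, seed = 8))
  b1 <- bootstrap_se(rec, "lw", B = 400, seed = 17)
  b2 <- bootstrap_se(rec, "lw", B = 400, seed = 17)
  expect_identical(b1$se, b2$se)
  analytic <- oracle_ols_se(as.matrix(rec[c("log_kow", "log_kaw")]),
                            rec$log_klw_exp)
  expect_equal(unname(b1$se), unname(analytic), tolerance = 0.15)
  # noiseless data: SEs collapse
  b0 <- bootstrap_se(noiseless_records(50), "lw", B = 100, seed = 1)
  expect_true(all(b0$se < 1e-8))
  expect_error(bootstrap_se(rec, "lw", B = 50, seed = 1), "B must be >= 100")
})

test_that("dropping the volatility descriptor costs ~0.02-0.03 rmse under the calibrated noise", {
  deltas <- vapply(1:20, function(s) {
    rec <- generate_chemicals(synthetic_config(n = 305, seed = 700 + s))
    full <- fit_lfer(rec, "lw")
    red <- fit_lfer(rec, "lw", predictors = "log_kow")
    cmp <- compare_nested(full, red)
    expect_gte(cmp$delta_rmse, 0)  # extra predictor never hurts in-sample
    cmp$delta_rmse
  }, numeric(1))
  expect_gt(mean(deltas), 0.01)
  expect_lt(mean(deltas), 0.05)
})

test_that("nested comparison: identical models give zero, null c_aw gives uniform p", {
  rec <- generate_chemicals(synthetic_config(n = 100, seed = 3))
  full <- fit_lfer(rec, "lw")
  cmp <- compare_nested(full, full)
  expect_equal(cmp$delta_rmse, 0)
  expect_equal(cmp$f_partial, 0)
  # under a true c_aw = 0, the partial-F p-value is uniform
  null_truth <- lipolfer::get_model("lw", "I")
  null_truth$c_aw <- 0
  pvals <- vapply(1:200, function(s) {
    rec <- generate_chemicals(synthetic_config(n = 60, seed = 4000 + s,
                                               truth = null_truth))
    compare_nested(fit_lfer(rec, "lw"),
                   fit_lfer(rec, "lw", predictors = "log_kow"))$p_value
  }, numeric(1))
  ks <- suppressWarnings(ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
  expect_error(compare_nested(fit_lfer(rec, "lw", predictors = "log_kow"),
                              full), "not nested")
})

test_that("coefficient recovery stays within 4 analytic SEs across replicates", {
  hits <- 0L
  reps <- 60L
  for (s in seq_len(reps)) {
    rec <- generate_chemicals(synthetic_config(n = 120, seed = 9000 + s))
    fit <- fit_lfer(rec, "lw")
    est <- c(fit$model$c0, fit$model$c_ow, fit$model$c_aw)
    truth <- c(-0.236, 1.102, 0.069)
    if (all(abs(est - truth) <= 4 * unname(fit$model$se))) hits <- hits + 1L
  }
  expect_gte(hits / reps, 0.95)
})
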