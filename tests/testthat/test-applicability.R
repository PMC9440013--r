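# Influence diagnostics and applicability-domain assessment.

test_that("diagnostics match a brute-force leave-one-out refit oracle", {
  rec <- generate_chemicals(synthetic_config(n = 15, seed = 77))
  fit <- fit_lfer(rec, "lw")
  rep <- influence_diagnostics(fit)
  orc <- oracle_influence(as.matrix(rec[c("log_kow", "log_kaw")]),
                          rec$log_klw_exp)
  expect_equal(rep$hat, unname(orc$hat), tolerance = 1e-10)
  expect_equal(rep$studentized_residual, orc$rstudent, tolerance = 1e-10)
  expect_equal(rep$cooks_d, orc$cooks, tolerance = 1e-10)
})

test_that("hat values are proper leverages summing to p + 1", {
  rec <- generate_chemicals(synthetic_config(n = 120, seed = 10))
  rep <- influence_diagnostics(fit_lfer(rec, "lw"))
  expect_true(all(rep$hat >= 0 & rep$hat <= 1))
  expect_equal(sum(rep$hat), 3, tolerance = 1e-8)
  expect_true(all(rep$cooks_d >= 0))
  # one-predictor model: sum is 2
  rep1 <- influence_diagnostics(fit_lfer(rec, "lw", predictors = "log_kow"))
  expect_equal(sum(rep1$hat), 2, tolerance = 1e-8)
})

test_that("a balanced symmetric design has equal leverages", {
  rec <- data.frame(record_id = as.character(1:8),
                    log_kow = rep(c(-1, 1), each = 4),
                    log_kaw = rep(c(-1, 1, -1, 1), 2),
                    log_klw_exp = rnorm(8))
  # full factorial +- design replicated twice: every point has h = (p+1)/n
  rec$log_kaw <- c(-1, -1, 1, 1, -1, -1, 1, 1)
  rep <- influence_diagnostics(fit_lfer(rec, "lw"))
  expect_equal(rep$hat, rep(3 / 8, 8), tolerance = 1e-12)
})

test_that("default thresholds flag gross outliers and report is order-invariant", {
  rec <- generate_chemicals(synthetic_config(n = 60, seed = 12))
  rec$log_klw_exp[10] <- rec$log_klw_exp[10] + 4   # gross residual outlier
  rec$log_kow[20] <- 9.9                           # leverage point
  fit <- fit_lfer(rec, "lw")
  rep <- influence_diagnostics(fit)
  expect_true(rep$large_residual[rep$record_id == "syn0010"])
  expect_true(rep$high_leverage[rep$record_id == "syn0020"])
  th <- attr(rep, "thresholds")
  expect_equal(unname(th["hat_crit"]), 3 * 3 / 60)
  expect_equal(unname(th["cooks_crit"]), 4 / 60)
  # permuting rows permutes the report rows but not the values
  perm <- sample(nrow(rec))
  rep2 <- influence_diagnostics(fit_lfer(rec[perm, ], "lw"))
  rep2 <- rep2[match(rep$record_id, rep2$record_id), ]
  expect_equal(rep2$hat, rep$hat, tolerance = 1e-10)
  expect_equal(rep2$cooks_d, rep$cooks_d, tolerance = 1e-10)
  expect_error(influence_diagnostics(fit_lfer(make_records(4)[
    , c("record_id", "log_kow", "log_kaw", "log_klw_exp")], "lw")),
    "insufficient|studentization")
})

test_that("removing a high-Cook's point moves the fit more than a random point", {
  wins <- 0L; trials <- 40L
  for (s in seq_len(trials)) {
    rec <- generate_chemicals(synthetic_config(n = 50, seed = 6000 + s))
    rec$log_klw_exp[1] <- rec$log_klw_exp[1] + 3.5
    fit <- fit_lfer(rec, "lw")
    rep <- influence_diagnostics(fit)
    i_bad <- which.max(rep$cooks_d)
    unflagged <- which(!rep$influential)
    i_ok <- unflagged[((s - 1) %% length(unflagged)) + 1]
    cf <- function(drop_i) {
      f <- fit_lfer(rec[-drop_i, ], "lw")
      c(f$model$c0, f$model$c_ow, f$model$c_aw)
    }
    base <- c(fit$model$c0, fit$model$c_ow, fit$model$c_aw)
    if (sum((cf(i_bad) - base)^2) > sum((cf(i_ok) - base)^2)) wins <- wins + 1L
  }
  expect_gte(wins / trials, 0.9)
})

test_that("prospective leverage defines the applicability domain", {
  rec <- generate_chemicals(synthetic_config(n = 100, seed = 15))
  fit <- fit_lfer(rec, "lw")
  # centroid: minimum leverage 1/n
  centroid <- data.frame(log_kow = mean(rec$log_kow),
                         log_kaw = mean(rec$log_kaw))
  dom <- in_domain(centroid, fit)
  expect_equal(dom$leverage, 1 / 100, tolerance = 1e-10)
  expect_true(dom$in_domain)
  # a training point re-queried reproduces its training hat value
  h <- stats::hatvalues(fit$lm)
  dom3 <- in_domain(rec[7, ], fit)
  expect_equal(dom3$leverage, unname(h[7]), tolerance = 1e-10)
  # a wildly hydrophobic query leaves the domain
  dom2 <- in_domain(data.frame(log_kow = 25, log_kaw = -2), fit)
  expect_false(dom2$in_domain)
  expect_match(dom2$reason, "exceeds")
  expect_error(in_domain(data.frame(log_kow = 2), fit), "log_kaw")
  expect_error(in_domain(centroid, get_model("lw", "I")), "design information")
})

test_that("batch prediction reports domain membership for fitted models", {
  rec <- generate_chemicals(synthetic_config(n = 50, seed = 16))
  fit <- fit_lfer(rec, "lw")
  newrec <- data.frame(record_id = c("a", "b"),
                       log_kow = c(mean(rec$log_kow), 25),
                       log_kaw = c(mean(rec$log_kaw), -2))
  res <- predict_batch(newrec, fit$model)
  expect_equal(res$in_domain, c("TRUE", "FALSE"))
  # published models carry no design: domain unknown
  res2 <- predict_batch(newrec, get_model("lw", "I"))
  expect_equal(res2$in_domain, c("unknown", "unknown"))
})
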