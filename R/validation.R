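# Internal and external validation: LOO, k-fold (optionally repeated),
# bootstrap out-of-bag CV, and random train/validation splitting.

# Fast OLS refit helper on a fixed design.
ols_coef <- function(X, y) qr.coef(qr(X), y)

prepare_xy <- function(records, endpoint, predictors) {
  dat <- suppressMessages(complete_design(records, endpoint, predictors))
  list(dat = dat,
       X = cbind(`(Intercept)` = 1, as.matrix(dat[predictors])),
       y = dat[[endpoint_column(endpoint)]])
}

cv_report <- function(scheme, k = NA_integer_, repeats = 1L, B = NA_integer_,
                      seed = NA_integer_, cv_rmse, cv_r2, per_fold,
                      extra = list()) {
  structure(c(list(scheme = scheme, k = k, repeats = repeats, B = B,
                   seed = seed, cv_rmse = cv_rmse, cv_r2 = cv_r2,
                   per_fold = per_fold), extra),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("Cross-validation [%s]%s: cv_rmse = %.4f, cv_r2 = %.4f\n",
              x$scheme,
              if (!is.na(x$k)) sprintf(" k = %d, repeats = %d", x$k, x$repeats)
              else if (!is.na(x$B)) sprintf(" B = %d", x$B) else "",
              x$cv_rmse, x$cv_r2))
  invisible(x)
}

#' Leave-one-out cross-validation of an LFER
#'
#' Refits the model n times, each omitting one record, and scores the
#' held-out predictions. `cv_rmse = sqrt(PRESS/n)` and
#' `cv_r2 = 1 - PRESS/SST` (predictive R squared). Deterministic.
#'
#' @inheritParams fit_lfer
#' @return A `cv_report` with per-record held-out residuals in
#'   `per_fold`.
#' @export
loo_cv <- function(records, endpoint = c("lw", "pw"),
                   predictors = c("log_kow", "log_kaw")) {
  endpoint <- match.arg(endpoint)
  predictors <- match.arg(predictors, several.ok = TRUE)
  pxy <- prepare_xy(records, endpoint, predictors)
  n <- nrow(pxy$X)
  if (n < 5L) stop("insufficient n for LOO (need >= 5)")
  held <- numeric(n)
  for (i in seq_len(n)) {
    cf <- ols_coef(pxy$X[-i, , drop = FALSE], pxy$y[-i])
    held[i] <- drop(pxy$X[i, ] %*% cf)
  }
  press <- sum((pxy$y - held)^2)
  sst <- sum((pxy$y - mean(pxy$y))^2)
  cv_report("loo", k = n,
            cv_rmse = sqrt(press / n), cv_r2 = 1 - press / sst,
            per_fold = data.frame(fold_id = seq_len(n),
                                  held_out = held,
                                  residual = pxy$y - held))
}

# Round-robin fold assignment after a seeded shuffle.
assign_folds <- function(n, k, seed) {
  with_seed(seed, {
    shuffled <- sample.int(n)
  })
  folds <- integer(n)
  folds[shuffled] <- rep_len(seq_len(k), n)
  folds
}

#' k-fold cross-validation of an LFER
#'
#' Unstratified: record indices are shuffled with the run seed and dealt
#' round-robin into k folds. With `repeats > 1` the partition is redrawn
#' with derived seeds (`seed`, `seed + 1`, ...) and the summary
#' statistics are averaged across runs. `kfold_cv(k = n)` reproduces
#' [loo_cv()] exactly.
#'
#' @inheritParams fit_lfer
#' @param k Number of folds (2 <= k <= n).
#' @param repeats Number of repartitioned runs to average.
#' @param seed Integer RNG seed.
#' @return A `cv_report`; `per_fold` holds (run, fold_id, n, rmse, r2)
#'   rows, and `runs` the per-run summary.
#' @export
kfold_cv <- function(records, endpoint = c("lw", "pw"),
                     predictors = c("log_kow", "log_kaw"),
                     k = 10L, repeats = 1L, seed = 1L) {
  endpoint <- match.arg(endpoint)
  predictors <- match.arg(predictors, several.ok = TRUE)
  pxy <- prepare_xy(records, endpoint, predictors)
  n <- nrow(pxy$X)
  if (k < 2L) stop("k must be >= 2")
  if (k > n) stop("k (", k, ") exceeds n (", n, ")")
  if (repeats < 1L) stop("repeats must be >= 1")
  sst <- sum((pxy$y - mean(pxy$y))^2)
  run_rmse <- numeric(repeats); run_r2 <- numeric(repeats)
  per_fold <- NULL
  for (r in seq_len(repeats)) {
    run_seed <- seed + r - 1L
    folds <- assign_folds(n, k, run_seed)
    held <- numeric(n)
    fold_rows <- vector("list", k)
    for (f in seq_len(k)) {
      test_idx <- which(folds == f)
      cf <- ols_coef(pxy$X[-test_idx, , drop = FALSE], pxy$y[-test_idx])
      held[test_idx] <- drop(pxy$X[test_idx, , drop = FALSE] %*% cf)
      res_f <- pxy$y[test_idx] - held[test_idx]
      r2_f <- if (length(test_idx) >= 2L &&
                  stats::sd(pxy$y[test_idx]) > 0 &&
                  stats::sd(held[test_idx]) > 0)
        stats::cor(held[test_idx], pxy$y[test_idx])^2 else NA_real_
      fold_rows[[f]] <- data.frame(run = r, fold_id = f,
                                   n = length(test_idx),
                                   rmse = sqrt(mean(res_f^2)), r2 = r2_f)
    }
    press <- sum((pxy$y - held)^2)
    run_rmse[r] <- sqrt(press / n)
    run_r2[r] <- 1 - press / sst
    per_fold <- rbind(per_fold, do.call(rbind, fold_rows))
  }
  cv_report(if (repeats > 1L) "repeated_kfold" else "kfold",
            k = k, repeats = repeats, seed = seed,
            cv_rmse = mean(run_rmse), cv_r2 = mean(run_r2),
            per_fold = per_fold,
            extra = list(runs = data.frame(run = seq_len(repeats),
                                           seed = seed + seq_len(repeats) - 1L,
                                           cv_rmse = run_rmse,
                                           cv_r2 = run_r2)))
}

#' Bootstrap (out-of-bag) cross-validation of an LFER
#'
#' For each of `B` case resamples the model is refitted on the resample
#' and scored on the out-of-bag records. Reported `cv_rmse`/`cv_r2` are
#' means over resamples (r2 as squared Pearson correlation on the OOB
#' set). The mean out-of-bag fraction (expected ~ (1-1/n)^n ~ 0.368)
#' is returned as `oob_fraction` and its complement, the unique in-bag
#' fraction (~ 1 - (1-1/n)^n ~ 0.632), as `inbag_fraction`.
#'
#' @inheritParams fit_lfer
#' @param B Number of resamples (>= 100).
#' @param seed Integer RNG seed.
#' @return A `cv_report`.
#' @export
bootstrap_cv <- function(records, endpoint = c("lw", "pw"),
                         predictors = c("log_kow", "log_kaw"),
                         B = 1000L, seed = 1L) {
  endpoint <- match.arg(endpoint)
  predictors <- match.arg(predictors, several.ok = TRUE)
  if (B < 100L) stop("configuration error: B must be >= 100")
  pxy <- prepare_xy(records, endpoint, predictors)
  n <- nrow(pxy$X)
  rmse_b <- rep(NA_real_, B); r2_b <- rep(NA_real_, B)
  oob_frac <- numeric(B)
  with_seed(seed, {
    for (b in seq_len(B)) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        qb <- qr(pxy$X[idx, , drop = FALSE])
        if (qb$rank == ncol(pxy$X)) break
      }
      oob <- setdiff(seq_len(n), unique(idx))
      oob_frac[b] <- length(oob) / n
      if (length(oob) < 2L) next
      cf <- qr.coef(qb, pxy$y[idx])
      pred <- drop(pxy$X[oob, , drop = FALSE] %*% cf)
      res <- pxy$y[oob] - pred
      rmse_b[b] <- sqrt(mean(res^2))
      r2_b[b] <- if (stats::sd(pred) > 0 && stats::sd(pxy$y[oob]) > 0)
        stats::cor(pred, pxy$y[oob])^2 else NA_real_
    }
  })
  cv_report("bootstrap", B = B, seed = seed,
            cv_rmse = mean(rmse_b, na.rm = TRUE),
            cv_r2 = mean(r2_b, na.rm = TRUE),
            per_fold = data.frame(fold_id = seq_len(B), rmse = rmse_b,
                                  r2 = r2_b, oob_fraction = oob_frac),
            extra = list(oob_fraction = mean(oob_frac),
                         inbag_fraction = 1 - mean(oob_frac)))
}

#' Random train/validation split
#'
#' Uniform split without replacement; disjoint and exhaustive,
#' reproducible by seed. The published calibration used 245/60 for the
#' storage-lipid dataset and 107/24 for the phospholipid dataset.
#'
#' @param records Chemical record data frame.
#' @param n_validation Number of records held out (0 < n_validation < n).
#' @param seed Integer RNG seed.
#' @return List with `train` and `validation` data frames.
#' @export
split_train_validation <- function(records, n_validation, seed = 1L) {
  n <- nrow(records)
  if (n_validation <= 0L || n_validation >= n) {
    stop("n_validation must satisfy 0 < n_validation < n (= ", n, ")")
  }
  idx <- with_seed(seed, sample.int(n, n_validation))
  list(train = records[-idx, , drop = FALSE],
       validation = records[idx, , drop = FALSE])
}

#' External validation of a model on an independent test set
#'
#' Applies a fixed coefficient set to test records carrying the observed
#' endpoint and summarises the errors; the residual table is sorted by
#' decreasing absolute residual so outlying chemicals surface first.
#'
#' @param model An `lfer_model`.
#' @param test_records Record data frame with the model's endpoint
#'   observed.
#' @return List: `rmse_test`, `r2_test`, `bias`, `n_test`, `residuals`
#'   (data frame: record_id, observed, predicted, residual).
#' @export
external_validate <- function(model, test_records) {
  ycol <- endpoint_column(model$endpoint)
  test_records <- fill_log_kaw(test_records)
  ok <- !is.na(test_records[[ycol]]) & !is.na(test_records$log_kow) &
    !is.na(test_records$log_kaw)
  dat <- test_records[ok, , drop = FALSE]
  if (nrow(dat) == 0L) stop("empty test set (no predictable records with observed ", ycol, ")")
  pred <- predict(model, dat)
  ev <- evaluate_predictions(pred, dat[[ycol]])
  resid <- data.frame(record_id = if (is.null(dat$record_id))
                        as.character(seq_len(nrow(dat))) else dat$record_id,
                      observed = dat[[ycol]], predicted = pred,
                      residual = dat[[ycol]] - pred,
                      stringsAsFactors = FALSE)
  resid <- resid[order(-abs(resid$residual)), ]
  rownames(resid) <- NULL
  list(rmse_test = ev$rmse, r2_test = ev$r2, bias = ev$bias,
       n_test = ev$n, residuals = resid)
}
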