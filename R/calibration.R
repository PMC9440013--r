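# OLS calibration of one- and two-predictor LFERs.

endpoint_column <- function(endpoint) {
  switch(endpoint, lw = "log_klw_exp", pw = "log_kpw_exp",
         stop("endpoint must be 'lw' or 'pw'"))
}

# Listwise-complete design for an endpoint + predictor set; message()s
# the number of dropped records.
complete_design <- function(records, endpoint, predictors) {
  records <- fill_log_kaw(records)
  ycol <- endpoint_column(endpoint)
  if (!ycol %in% names(records)) {
    stop("records carry no observed ", ycol, " column")
  }
  cols <- c(ycol, predictors)
  ok <- stats::complete.cases(records[cols])
  dropped <- sum(!ok)
  if (dropped > 0) {
    message(dropped, " record(s) excluded listwise (missing endpoint or predictor)")
  }
  records[ok, , drop = FALSE]
}

#' Fit a one- or two-predictor LFER by ordinary least squares
#'
#' Regresses the observed endpoint (`log_klw_exp` for `lw`,
#' `log_kpw_exp` for `pw`) on `log_kow` and/or `log_kaw`. Records with a
#' missing endpoint or predictor are excluded listwise with a message.
#' The reported `rmse` is `sqrt(SSE/n)`; the residual standard error
#' `sqrt(SSE/(n-p-1))` is stored alongside as `rse` so either
#' convention can be checked.
#'
#' @param records Chemical record data frame.
#' @param endpoint `"lw"` or `"pw"`.
#' @param predictors Character subset of `c("log_kow", "log_kaw")`.
#' @return An `lfer_fit`: list with `model` (an `lfer_model`, dataset
#'   tag `"user"`), `stats` (n, r2, adj_r2, rmse, rse, f_stat,
#'   p_predictors), `residuals`, `fitted`, `records` (rows used),
#'   `design_info` (predictor means/sds and unscaled cross-product
#'   inverse) and the underlying `lm` object.
#' @export
#' @examples
#' rec <- generate_chemicals(synthetic_config(n = 60, seed = 1))
#' fit <- fit_lfer(rec, "lw")
#' fit$stats$r2
fit_lfer <- function(records, endpoint = c("lw", "pw"),
                     predictors = c("log_kow", "log_kaw")) {
  endpoint <- match.arg(endpoint)
  predictors <- match.arg(predictors, several.ok = TRUE)
  p <- length(predictors)
  dat <- complete_design(records, endpoint, predictors)
  n <- nrow(dat)
  if (n < p + 2L) stop("insufficient data: need at least ", p + 2L,
                       " complete records, have ", n)
  ycol <- endpoint_column(endpoint)
  X <- as.matrix(dat[predictors])
  if (p > 1L) {
    Xs <- scale(X)
    if (any(attr(Xs, "scaled:scale") == 0) ||
        kappa(crossprod(cbind(1, Xs)), exact = TRUE) > 1e8) {
      stop("predictors are (near-)collinear; singular design")
    }
  }
  fml <- stats::reformulate(predictors, response = ycol)
  lmfit <- stats::lm(fml, data = dat)
  cf <- stats::coef(lmfit)
  res <- stats::residuals(lmfit)
  sse <- sum(res^2)
  sst <- sum((dat[[ycol]] - mean(dat[[ycol]]))^2)
  r2 <- 1 - sse / sst
  adj_r2 <- 1 - (1 - r2) * (n - 1) / (n - p - 1)
  f_stat <- (r2 / p) / ((1 - r2) / (n - p - 1))
  stats_out <- list(n = n, r2 = r2, adj_r2 = adj_r2,
                    rmse = sqrt(sse / n), rse = sqrt(sse / (n - p - 1)),
                    f_stat = f_stat, p_predictors = p)
  Xi <- cbind(`(Intercept)` = 1, X)
  xtx_inv <- solve(crossprod(Xi))
  se <- sqrt(sse / (n - p - 1) * diag(xtx_inv))
  model <- new_lfer_model(
    endpoint, "user",
    c0 = unname(cf[["(Intercept)"]]),
    c_ow = if ("log_kow" %in% predictors) unname(cf[["log_kow"]]) else 0,
    c_aw = if ("log_kaw" %in% predictors) unname(cf[["log_kaw"]]) else 0,
    se = c(c0 = unname(se[["(Intercept)"]]),
           c_ow = if ("log_kow" %in% predictors) unname(se[["log_kow"]]) else NA_real_,
           c_aw = if ("log_kaw" %in% predictors) unname(se[["log_kaw"]]) else NA_real_),
    n = n, stats = stats_out, provenance = "fitted")
  design_info <- list(predictors = predictors,
                      means = colMeans(X), sds = apply(X, 2, stats::sd),
                      xtx_inv = xtx_inv, n = n)
  model$design_info <- design_info
  structure(list(model = model, stats = stats_out,
                 residuals = unname(res), fitted = unname(stats::fitted(lmfit)),
                 records = dat, endpoint = endpoint, predictors = predictors,
                 design_info = design_info, lm = lmfit),
            class = "lfer_fit")
}

#' @export
print.lfer_fit <- function(x, ...) {
  cat(sprintf("LFER fit: %s ~ %s\n", endpoint_column(x$endpoint),
              paste(x$predictors, collapse = " + ")))
  print(x$model)
  cat(sprintf("  n = %d, R2 = %.4f, adj R2 = %.4f, rmse = %.4f, rse = %.4f, F = %.1f\n",
              x$stats$n, x$stats$r2, x$stats$adj_r2, x$stats$rmse,
              x$stats$rse, x$stats$f_stat))
  invisible(x)
}

#' Bootstrap standard errors of LFER coefficients
#'
#' Nonparametric case (pairs) resampling: `B` resamples of the records
#' with replacement at size n, each refitted by OLS; the standard error
#' of each coefficient is the standard deviation of its B estimates.
#' Resamples with a singular design are redrawn and the redraw count
#' reported.
#'
#' @inheritParams fit_lfer
#' @param B Number of bootstrap resamples (>= 100).
#' @param seed Integer RNG seed; required for reproducibility.
#' @return List: `se` (named per coefficient), `B`, `redraws`,
#'   `estimates` (B x (p+1) matrix).
#' @export
bootstrap_se <- function(records, endpoint = c("lw", "pw"),
                         predictors = c("log_kow", "log_kaw"),
                         B = 1000L, seed = 1L) {
  endpoint <- match.arg(endpoint)
  predictors <- match.arg(predictors, several.ok = TRUE)
  if (B < 100L) stop("configuration error: B must be >= 100")
  dat <- suppressMessages(complete_design(records, endpoint, predictors))
  n <- nrow(dat)
  ycol <- endpoint_column(endpoint)
  X <- cbind(`(Intercept)` = 1, as.matrix(dat[predictors]))
  y <- dat[[ycol]]
  est <- matrix(NA_real_, B, ncol(X), dimnames = list(NULL, colnames(X)))
  redraws <- 0L
  with_seed(seed, {
    for (b in seq_len(B)) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        Xb <- X[idx, , drop = FALSE]
        qb <- qr(Xb)
        if (qb$rank == ncol(X)) break
        redraws <- redraws + 1L
      }
      est[b, ] <- qr.coef(qb, y[idx])
    }
  })
  se <- apply(est, 2, stats::sd)
  names(se) <- c("c0", if ("log_kow" %in% predictors) "c_ow",
                 if ("log_kaw" %in% predictors) "c_aw")
  list(se = se, B = B, redraws = redraws, estimates = est)
}

#' Compare nested LFER fits
#'
#' Quantifies the accuracy lost by dropping predictor(s): the change in
#' in-sample rmse and the partial F-test for the dropped terms, both
#' computed on the same records.
#'
#' @param full,reduced `lfer_fit` objects on identical records, with
#'   the reduced predictor set a strict subset of the full one.
#' @return List: `delta_rmse` (rmse_reduced - rmse_full),
#'   `f_partial`, `p_value`, `df` (numerator, denominator).
#' @export
compare_nested <- function(full, reduced) {
  if (!all(reduced$predictors %in% full$predictors)) {
    stop("models are not nested: reduced predictors must be a subset of full")
  }
  if (full$stats$n != reduced$stats$n) {
    stop("fits use different record sets (n differs)")
  }
  sse_f <- sum(full$residuals^2)
  sse_r <- sum(reduced$residuals^2)
  df1 <- full$stats$p_predictors - reduced$stats$p_predictors
  df2 <- full$stats$n - full$stats$p_predictors - 1L
  if (df1 == 0L) {
    return(list(delta_rmse = reduced$stats$rmse - full$stats$rmse,
                f_partial = 0, p_value = 1, df = c(0L, df2)))
  }
  f_partial <- ((sse_r - sse_f) / df1) / (sse_f / df2)
  list(delta_rmse = reduced$stats$rmse - full$stats$rmse,
       f_partial = f_partial,
       p_value = stats::pf(f_partial, df1, df2, lower.tail = FALSE),
       df = c(df1, df2))
}

# Evaluate code with a temporary RNG state; restores the caller's state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}
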