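# Brute-force oracles, independent of the package's computation paths.

# OLS by explicit normal equations.
oracle_ols <- function(X, y) {
  Xi <- cbind(1, X)
  solve(t(Xi) %*% Xi, t(Xi) %*% y)[, 1]
}

# Analytic OLS coefficient standard errors.
oracle_ols_se <- function(X, y) {
  Xi <- cbind(1, X)
  cf <- solve(t(Xi) %*% Xi, t(Xi) %*% y)[, 1]
  res <- y - Xi %*% cf
  s2 <- sum(res^2) / (nrow(Xi) - ncol(Xi))
  sqrt(diag(s2 * solve(t(Xi) %*% Xi)))
}

# Externally studentized residuals and Cook's distance by literal
# leave-one-out refits.
oracle_influence <- function(X, y) {
  n <- length(y)
  Xi <- cbind(1, X)
  p1 <- ncol(Xi)
  H <- Xi %*% solve(t(Xi) %*% Xi) %*% t(Xi)
  cf_full <- solve(t(Xi) %*% Xi, t(Xi) %*% y)[, 1]
  res <- y - drop(Xi %*% cf_full)
  s2_full <- sum(res^2) / (n - p1)
  rstu <- numeric(n); cook <- numeric(n)
  for (i in seq_len(n)) {
    Xm <- Xi[-i, , drop = FALSE]; ym <- y[-i]
    cf_i <- solve(t(Xm) %*% Xm, t(Xm) %*% ym)[, 1]
    res_i <- ym - drop(Xm %*% cf_i)
    s2_i <- sum(res_i^2) / (n - 1 - p1)
    # externally studentized: residual scaled by sigma(-i) and leverage
    rstu[i] <- res[i] / sqrt(s2_i * (1 - H[i, i]))
    # Cook's D: scaled shift in the fitted values upon deletion
    dfit <- drop(Xi %*% (cf_full - cf_i))
    cook[i] <- sum(dfit^2) / (p1 * s2_full)
  }
  list(hat = diag(H), rstudent = rstu, cooks = cook)
}

# Pearson correlation from the definition.
oracle_pearson <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# Synthetic record table built directly (not via the generator), for
# fixture-independent I/O tests.
make_records <- function(n = 10, seed = 99) {
  set.seed(seed)
  kaw <- rnorm(n, -3, 2)
  data.frame(
    record_id = sprintf("chem%02d", seq_len(n)),
    name = paste("chemical", seq_len(n)),
    cas = ifelse(seq_len(n) %% 2 == 0, sprintf("%02d-00-0", seq_len(n)),
                 NA_character_),
    log_kow = rnorm(n, 3, 2),
    log_kaw = kaw,
    hlc_atm_m3_mol = log_kaw_to_hlc(kaw),
    E = NA_real_, S = NA_real_, A = NA_real_, B = NA_real_,
    V = NA_real_, L = NA_real_,
    log_klw_exp = rnorm(n, 3, 2),
    log_kpw_exp = NA_real_,
    source_kow = "experimental", source_kaw = "unknown",
    stringsAsFactors = FALSE)
}
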