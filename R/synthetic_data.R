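# Synthetic chemical datasets with the statistical structure of the
# tp-LFER calibration data, so the calibration/validation/domain
# machinery is testable without any external download.

#' Configuration for the synthetic chemical generator
#'
#' Defaults emulate the structure of the storage-lipid calibration
#' data: a wide hydrophobicity range (log_kow ~ Normal(3.0, 2.2)
#' truncated to \[-2, 10\]), a volatility descriptor loosely coupled to
#' hydrophobicity (log_kaw = 0.45 log_kow - 3.5 + Normal(0, 2.0)), and
#' the endpoint generated from a true coefficient set plus Gaussian
#' noise of sd 0.375. Under these defaults the endpoint-log_kow
#' correlation is ~ 0.98 and a two-predictor refit has rmse ~ 0.375.
#'
#' @param n Number of records.
#' @param seed Integer RNG seed.
#' @param kow_mean,kow_sd Marginal log_kow parameters (log10 units).
#' @param kow_range Truncation bounds for log_kow.
#' @param kaw_slope,kaw_intercept,kaw_resid_sd Conditional log_kaw
#'   model given log_kow.
#' @param truth `lfer_model` used as the generating coefficient set.
#' @param noise_sd Endpoint residual sd (log10 units).
#' @param endpoint `"lw"` or `"pw"`; decides which observed column is
#'   filled.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n = 305L, seed = 1L,
                             kow_mean = 3.0, kow_sd = 2.2,
                             kow_range = c(-2, 10),
                             kaw_slope = 0.45, kaw_intercept = -3.5,
                             kaw_resid_sd = 2.0,
                             truth = get_model("lw", "I"),
                             noise_sd = 0.375,
                             endpoint = c("lw", "pw")) {
  endpoint <- match.arg(endpoint)
  if (n < 1L) stop("n must be >= 1")
  if (kow_sd <= 0 || kaw_resid_sd < 0 || noise_sd < 0) {
    stop("sds must be positive (noise sds may be zero)")
  }
  structure(list(n = as.integer(n), seed = as.integer(seed),
                 kow_mean = kow_mean, kow_sd = kow_sd,
                 kow_range = kow_range,
                 kaw_slope = kaw_slope, kaw_intercept = kaw_intercept,
                 kaw_resid_sd = kaw_resid_sd,
                 truth = truth, noise_sd = noise_sd,
                 endpoint = endpoint),
            class = "synthetic_config")
}

rtruncnorm <- function(n, mean, sd, lower, upper) {
  out <- numeric(0)
  while (length(out) < n) {
    draw <- stats::rnorm(n, mean, sd)
    out <- c(out, draw[draw >= lower & draw <= upper])
  }
  out[seq_len(n)]
}

#' Generate synthetic chemical records
#'
#' Draws predictors and the endpoint per the configuration (see
#' [synthetic_config()]), back-fills the Henry's law constant from
#' log_kaw so records satisfy the HLC/Kaw consistency invariant, and is
#' fully reproducible by seed.
#'
#' @param config A [synthetic_config()].
#' @return Chemical record data frame (canonical columns).
#' @export
#' @examples
#' rec <- generate_chemicals(synthetic_config(n = 20, seed = 42))
#' cor(rec$log_klw_exp, rec$log_kow)
generate_chemicals <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  with_seed(config$seed, {
    log_kow <- rtruncnorm(config$n, config$kow_mean, config$kow_sd,
                          config$kow_range[1], config$kow_range[2])
    log_kaw <- config$kaw_slope * log_kow + config$kaw_intercept +
      stats::rnorm(config$n, 0, config$kaw_resid_sd)
    tr <- config$truth
    y <- tr$c0 + tr$c_ow * log_kow + tr$c_aw * log_kaw +
      stats::rnorm(config$n, 0, config$noise_sd)
  })
  rec <- empty_chem_records()
  rec <- rbind(rec, data.frame(
    record_id = sprintf("syn%04d", seq_len(config$n)),
    name = sprintf("synthetic chemical %d", seq_len(config$n)),
    cas = NA_character_,
    log_kow = log_kow, log_kaw = log_kaw,
    hlc_atm_m3_mol = log_kaw_to_hlc(log_kaw),
    E = NA_real_, S = NA_real_, A = NA_real_, B = NA_real_,
    V = NA_real_, L = NA_real_,
    log_klw_exp = if (config$endpoint == "lw") y else NA_real_,
    log_kpw_exp = if (config$endpoint == "pw") y else NA_real_,
    source_kow = "unknown", source_kaw = "unknown",
    stringsAsFactors = FALSE))
  rec
}

#' Generate a synthetic descriptor matrix of controlled rank
#'
#' Latent-factor construction: `rank` iid standard-normal factors, a
#' seeded loading matrix, plus iid Gaussian column noise. With
#' `noise_sd = 0` a correlation-PCA recovers exactly `rank` nonzero
#' dimensions; small noise spreads variance into the trailing
#' dimensions, mimicking the partially redundant structure of Abraham
#' descriptor tables.
#'
#' @param n Rows (records).
#' @param rank Number of latent factors (1..n_var).
#' @param noise_sd Column noise sd relative to unit-scale factors.
#' @param seed Integer RNG seed.
#' @param n_var Number of variables (default 9: an endpoint, six
#'   Abraham descriptors, log_kow, log_kaw).
#' @return Numeric matrix n x n_var.
#' @export
generate_descriptor_matrix <- function(n, rank, noise_sd = 0, seed = 1L,
                                       n_var = 9L) {
  if (rank < 1L || rank > n_var) stop("rank must be in 1..", n_var)
  with_seed(seed, {
    fac <- matrix(stats::rnorm(n * rank), n, rank)
    w <- matrix(stats::rnorm(n_var * rank), n_var, rank)
    noise <- matrix(stats::rnorm(n * n_var, 0, noise_sd), n, n_var)
  })
  mat <- fac %*% t(w) + noise
  colnames(mat) <- c("endpoint", "E", "S", "A", "B", "V", "L",
                     "log_kow", "log_kaw")[seq_len(n_var)]
  mat
}
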