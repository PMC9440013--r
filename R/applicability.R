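# Applicability-domain assessment via regression influence diagnostics.

#' Influence diagnostics for a fitted LFER
#'
#' Computes, per calibration record, the hat (leverage) value, the
#' externally studentized residual (leave-one-out variance estimate)
#' and Cook's distance, then flags influential observations. Default
#' thresholds are the conventional influence-plot choices:
#' `hat_crit = 3(p+1)/n`, `resid_crit = 2` (absolute studentized
#' residual), `cooks_crit = 4/n`; all three are configurable. A record
#' is influential if it exceeds any threshold.
#'
#' @param fit An `lfer_fit` from [fit_lfer()].
#' @param hat_crit,resid_crit,cooks_crit Threshold overrides.
#' @return An `influence_report`: data frame (record_id, hat,
#'   studentized_residual, cooks_d, high_leverage, large_residual,
#'   high_cooks, influential) with the thresholds, n and p as
#'   attributes.
#' @export
#' @examples
#' rec <- generate_chemicals(synthetic_config(n = 80, seed = 7))
#' rep <- influence_diagnostics(fit_lfer(rec, "lw"))
#' sum(rep$influential)
influence_diagnostics <- function(fit,
                                  hat_crit = NULL,
                                  resid_crit = 2,
                                  cooks_crit = NULL) {
  stopifnot(inherits(fit, "lfer_fit"))
  n <- fit$stats$n
  p <- fit$stats$p_predictors
  if (n <= p + 2L) stop("studentization undefined: n must exceed p + 2")
  if (is.null(hat_crit)) hat_crit <- 3 * (p + 1) / n
  if (is.null(cooks_crit)) cooks_crit <- 4 / n
  hat <- unname(stats::hatvalues(fit$lm))
  rstu <- unname(stats::rstudent(fit$lm))
  cook <- unname(stats::cooks.distance(fit$lm))
  ids <- if (is.null(fit$records$record_id))
    as.character(seq_len(n)) else as.character(fit$records$record_id)
  rep <- data.frame(record_id = ids, hat = hat,
                    studentized_residual = rstu, cooks_d = cook,
                    high_leverage = hat > hat_crit,
                    large_residual = abs(rstu) > resid_crit,
                    high_cooks = cook > cooks_crit,
                    stringsAsFactors = FALSE)
  rep$influential <- rep$high_leverage | rep$large_residual | rep$high_cooks
  structure(rep,
            thresholds = c(hat_crit = hat_crit, resid_crit = resid_crit,
                           cooks_crit = cooks_crit),
            n = n, p = p,
            class = c("influence_report", "data.frame"))
}

#' Prospective leverage of a new chemical against a training design
#'
#' Computes `h_new = x' (X'X)^-1 x` for the new point's predictor
#' vector against the stored calibration design; the point is inside
#' the applicability domain when its leverage does not exceed
#' `hat_crit` (default `3(p+1)/n`). A training point re-queried
#' reproduces its own hat value; the minimum possible leverage, at the
#' training centroid, is `1/n`.
#'
#' @param record One-row data frame with `log_kow` and `log_kaw` (or
#'   `hlc_atm_m3_mol`).
#' @param fit An `lfer_fit` (or an `lfer_model` carrying
#'   `design_info`).
#' @param hat_crit Leverage threshold; default `3(p+1)/n`.
#' @return List: `in_domain` (logical), `leverage`, `hat_crit`,
#'   `reason`.
#' @export
in_domain <- function(record, fit, hat_crit = NULL) {
  di <- if (inherits(fit, "lfer_fit")) fit$design_info
        else if (inherits(fit, "lfer_model")) fit$design_info
        else stop("fit must be an lfer_fit or lfer_model")
  if (is.null(di)) {
    stop("model carries no training design information; ",
         "applicability domain is undefined for published registry models ",
         "unless refitted on data")
  }
  record <- fill_log_kaw(record)
  x <- c(1, vapply(di$predictors, function(pr) {
    v <- record[[pr]][1]
    if (is.null(v) || is.na(v)) stop("missing predictor ", pr)
    v
  }, numeric(1)))
  lev <- drop(t(x) %*% di$xtx_inv %*% x)
  p <- length(di$predictors)
  if (is.null(hat_crit)) hat_crit <- 3 * (p + 1) / di$n
  inside <- lev <= hat_crit
  list(in_domain = inside, leverage = lev, hat_crit = hat_crit,
       reason = if (inside) "leverage within critical hat value"
                else sprintf("leverage %.4g exceeds critical hat value %.4g",
                             lev, hat_crit))
}

#' Influence plot (studentized residual vs hat value)
#'
#' Circle area is proportional to Cook's distance (radius to its square
#' root); dashed lines mark the thresholds and flagged records are
#' labelled.
#'
#' @param x An `influence_report`.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.influence_report <- function(x, ...) {
  th <- attr(x, "thresholds")
  cex <- 0.5 + 3 * sqrt(pmax(x$cooks_d, 0) / max(x$cooks_d, 1e-12))
  graphics::plot(x$hat, x$studentized_residual, cex = cex,
                 xlab = "Hat value (leverage)",
                 ylab = "Externally studentized residual", ...)
  graphics::abline(v = th[["hat_crit"]], lty = 2)
  graphics::abline(h = c(-1, 1) * th[["resid_crit"]], lty = 2)
  flagged <- which(x$influential)
  if (length(flagged)) {
    graphics::text(x$hat[flagged], x$studentized_residual[flagged],
                   labels = x$record_id[flagged], pos = 4, cex = 0.7)
  }
  invisible(x)
}
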