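# Registry of published tp-LFER coefficient sets and the prediction
# operation logK = c0 + c_ow * logKow + c_aw * logKaw.

new_lfer_model <- function(endpoint, dataset_tag, c0, c_ow, c_aw,
                           se = c(c0 = NA_real_, c_ow = NA_real_, c_aw = NA_real_),
                           n = NA_integer_, stats = NULL,
                           provenance = "user", note = NULL) {
  endpoint <- match.arg(endpoint, c("lw", "pw"))
  if (!is.null(se)) {
    if (any(!is.na(se) & se < 0)) stop("standard errors must be >= 0")
  }
  structure(
    list(endpoint = endpoint, dataset_tag = dataset_tag,
         c0 = c0, c_ow = c_ow, c_aw = c_aw,
         se = se, n = n, stats = stats,
         provenance = provenance, note = note,
         design_info = NULL),
    class = "lfer_model")
}

# The eight published coefficient sets. dataset I: ASM-estimated inputs
# (full and training split); II: purely experimental inputs; III:
# experimental with ASM backfill. Coefficients at printed precision.
.registry <- local({
  mk <- function(endpoint, tag, c0, c_ow, c_aw, se0, seow, seaw, n,
                 r2, adj_r2, rmse, f, provenance, note = NULL) {
    m <- new_lfer_model(endpoint, tag, c0, c_ow, c_aw,
                        se = c(c0 = se0, c_ow = seow, c_aw = seaw),
                        n = n,
                        stats = list(n = n, r2 = r2, adj_r2 = adj_r2,
                                     rmse = rmse, f_stat = f,
                                     p_predictors = 2L),
                        provenance = provenance, note = note)
    m
  }
  list(
    "lw.I" = mk("lw", "I", -0.236, 1.102, 0.069, 0.043, 0.016, 0.01,
                305L, 0.971, 0.970, 0.375, 5046, "published model, dataset I"),
    "lw.I-training" = mk("lw", "I-training", -0.210, 1.102, 0.078,
                         0.048, 0.013, 0.012, 245L, 0.970, 0.970, 0.381,
                         3977, "published model, dataset I training split"),
    "pw.I" = mk("pw", "I", -0.247, 1.070, -0.056, 0.095, 0.021, 0.013,
                131L, 0.953, 0.952, 0.414, 1293,
                "published model, dataset I",
                note = "abstract reports rmse 0.413; model text 0.414"),
    "pw.I-training" = mk("pw", "I-training", -0.234, 1.067, -0.049,
                         0.108, 0.024, 0.014, 107L, 0.950, 0.949, 0.423,
                         990, "published model, dataset I training split"),
    "lw.II" = mk("lw", "II", -0.064, 1.049, 0.121, 0.055, 0.014, 0.014,
                 215L, 0.970, 0.969, 0.388, 3299,
                 "published model, dataset II (experimental inputs)"),
    "pw.II" = mk("pw", "II", -0.401, 1.070, -0.111, 0.0109, 0.022, 0.021,
                 93L, 0.963, 0.963, 0.353, 1184,
                 "published model, dataset II (experimental inputs)",
                 note = "intercept SE printed as 0.0109; likely typo for 0.109, stored verbatim"),
    "lw.III" = mk("lw", "III", -0.128, 1.064, 0.110, 0.045, 0.012, 0.011,
                  305L, 0.969, 0.969, 0.385, 4774,
                  "published model, dataset III (experimental + ASM backfill)"),
    "pw.III" = mk("pw", "III", -0.186, 1.059, -0.040, 0.101, 0.022, 0.014,
                  131L, 0.948, 0.947, 0.434, 1168,
                  "published model, dataset III (experimental + ASM backfill)")
  )
})

#' List the published tp-LFER models
#'
#' @return Data frame with one row per registry model: endpoint
#'   (`lw` storage lipid, `pw` phospholipid), dataset tag, coefficients,
#'   bootstrap standard errors, n and fit statistics.
#' @export
#' @examples
#' list_models()
list_models <- function() {
  do.call(rbind, lapply(unname(.registry), function(m) {
    data.frame(endpoint = m$endpoint, dataset_tag = m$dataset_tag,
               c0 = m$c0, c_ow = m$c_ow, c_aw = m$c_aw,
               se_c0 = m$se[["c0"]], se_ow = m$se[["c_ow"]],
               se_aw = m$se[["c_aw"]], n = m$n,
               r2 = m$stats$r2, adj_r2 = m$stats$adj_r2,
               rmse = m$stats$rmse, f_stat = m$stats$f_stat,
               stringsAsFactors = FALSE)
  }))
}

#' Retrieve a published tp-LFER coefficient set
#'
#' Dataset `I` (the largest calibration set, ASM-estimated inputs) is
#' the default and the recommended choice for prediction; `II` was
#' calibrated on purely experimental logKow/logKaw inputs and `III` on
#' experimental values with ASM backfill. The `I-training` variants are
#' the training-split refits used for external validation.
#'
#' @param endpoint `"lw"` (storage lipid-water) or `"pw"`
#'   (phospholipid-water).
#' @param dataset_tag `"I"`, `"I-training"`, `"II"` or `"III"`.
#' @return An `lfer_model` object.
#' @export
#' @examples
#' get_model("lw")            # recommended storage-lipid model
#' get_model("pw", "II")$c_aw
get_model <- function(endpoint = c("lw", "pw"), dataset_tag = "I") {
  endpoint <- match.arg(endpoint)
  key <- paste(endpoint, dataset_tag, sep = ".")
  if (!key %in% names(.registry)) {
    stop("no registry model for (", endpoint, ", ", dataset_tag,
         "); available: ", paste(names(.registry), collapse = ", "))
  }
  .registry[[key]]
}

#' @export
print.lfer_model <- function(x, ...) {
  lab <- if (x$endpoint == "lw") "logKlw" else "logKpw"
  cat(sprintf("tp-LFER model [%s, dataset %s] (%s)\n",
              x$endpoint, x$dataset_tag, x$provenance))
  cat(sprintf("  %s = %.3f + %.3f logKow + %.3f logKaw\n",
              lab, x$c0, x$c_ow, x$c_aw))
  if (!all(is.na(x$se))) {
    cat(sprintf("  SE: (%.4g, %.4g, %.4g); n = %s\n",
                x$se[["c0"]], x$se[["c_ow"]], x$se[["c_aw"]], x$n))
  }
  if (!is.null(x$stats) && !is.null(x$stats$r2)) {
    cat(sprintf("  R2 = %.3f, rmse = %.3f\n", x$stats$r2, x$stats$rmse))
  }
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

#' Predict a lipid-water partition coefficient
#'
#' Evaluates `c0 + c_ow * log_kow + c_aw * log_kaw` for one or more
#' chemicals. `newdata` may be a record table (see
#' [chem_record_columns]); a missing `log_kaw` is derived from
#' `hlc_atm_m3_mol` where available.
#'
#' @param object An `lfer_model`.
#' @param newdata Data frame with `log_kow` and `log_kaw` (or
#'   `hlc_atm_m3_mol`) columns.
#' @param ... Unused.
#' @return Numeric vector of predicted log10 partition coefficients.
#' @export
predict.lfer_model <- function(object, newdata, ...) {
  newdata <- fill_log_kaw(newdata)
  if (!"log_kow" %in% names(newdata) || anyNA(newdata$log_kow)) {
    bad <- if ("log_kow" %in% names(newdata)) which(is.na(newdata$log_kow)) else "all"
    stop("missing predictor log_kow for row(s): ",
         paste(bad, collapse = ", "))
  }
  if (anyNA(newdata$log_kaw)) {
    stop("missing predictor log_kaw (and no HLC to derive it) for row(s): ",
         paste(which(is.na(newdata$log_kaw)), collapse = ", "))
  }
  object$c0 + object$c_ow * newdata$log_kow + object$c_aw * newdata$log_kaw
}

#' Batch prediction with per-record error capture
#'
#' Vectorised prediction over a record table; rows that cannot be
#' predicted (missing predictors) yield `NA` with a reason instead of
#' aborting the batch. Input order is preserved.
#'
#' @param records Chemical record data frame.
#' @param model An `lfer_model`.
#' @return Data frame: `record_id`, `prediction`, `in_domain`
#'   (`"unknown"` unless the model carries training design information;
#'   see [in_domain()]), `error` (`NA` for clean rows).
#' @export
predict_batch <- function(records, model) {
  n <- nrow(records)
  if (is.null(records$record_id)) records$record_id <- as.character(seq_len(n))
  out <- data.frame(record_id = as.character(records$record_id),
                    prediction = rep(NA_real_, n),
                    in_domain = rep("unknown", n),
                    error = rep(NA_character_, n),
                    stringsAsFactors = FALSE)
  if (n == 0L) return(out)
  records <- fill_log_kaw(records)
  if (!"log_kow" %in% names(records)) records$log_kow <- NA_real_
  ok <- !is.na(records$log_kow) & !is.na(records$log_kaw)
  out$prediction[ok] <- model$c0 + model$c_ow * records$log_kow[ok] +
    model$c_aw * records$log_kaw[ok]
  out$error[!ok] <- ifelse(is.na(records$log_kow[!ok]),
                           "missing log_kow",
                           "missing log_kaw/hlc")
  if (!is.null(model$design_info)) {
    for (i in which(ok)) {
      dom <- in_domain(records[i, , drop = FALSE], model)
      out$in_domain[i] <- as.character(dom$in_domain)
    }
  }
  out
}

#' Evaluate predictions against observations
#'
#' External-evaluation convention: `r2` is the squared Pearson
#' correlation between predictions and observations (the in-sample
#' coefficient of determination `1 - SSE/SST` lives in fit statistics
#' instead, where the two coincide).
#'
#' @param pred,obs Equal-length numeric vectors, n >= 2.
#' @return List: `rmse` (sqrt mean squared error), `r2`, `bias`
#'   (mean of pred - obs), `n`.
#' @export
evaluate_predictions <- function(pred, obs) {
  if (length(pred) != length(obs)) stop("pred and obs length mismatch")
  keep <- !is.na(pred) & !is.na(obs)
  pred <- pred[keep]; obs <- obs[keep]
  n <- length(pred)
  if (n < 2L) stop("need at least 2 paired values")
  err <- pred - obs
  r <- if (stats::sd(pred) == 0 || stats::sd(obs) == 0) NA_real_
       else stats::cor(pred, obs)
  list(rmse = sqrt(mean(err^2)), r2 = r^2, bias = mean(err), n = n)
}

#' Export the model registry to YAML or JSON
#'
#' @param path Output file; format chosen from the extension
#'   (`.yaml`/`.yml` or `.json`).
#' @return `path`, invisibly.
#' @export
export_registry <- function(path) {
  entries <- lapply(unname(.registry), function(m) {
    list(endpoint = m$endpoint, dataset_tag = m$dataset_tag,
         c0 = m$c0, c_ow = m$c_ow, c_aw = m$c_aw,
         se_c0 = m$se[["c0"]], se_ow = m$se[["c_ow"]],
         se_aw = m$se[["c_aw"]],
         n = m$n, stats = m$stats, provenance = m$provenance,
         note = m$note)
  })
  payload <- list(registry_version = "1.0", models = entries)
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(payload, path)
  } else {
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = TRUE)
  }
  invisible(path)
}

#' Write one coefficient set to a YAML model file
#'
#' @param model An `lfer_model` (published or fitted).
#' @param path Output `.yaml` path.
#' @return `path`, invisibly.
#' @export
write_model_yaml <- function(model, path) {
  payload <- list(endpoint = model$endpoint, dataset_tag = model$dataset_tag,
                  c0 = model$c0, c_ow = model$c_ow, c_aw = model$c_aw,
                  se_c0 = unname(model$se[["c0"]]),
                  se_ow = unname(model$se[["c_ow"]]),
                  se_aw = unname(model$se[["c_aw"]]),
                  n = model$n, stats = model$stats,
                  provenance = model$provenance)
  yaml::write_yaml(payload, path)
  invisible(path)
}

#' Read a coefficient set from a YAML model file
#'
#' @param path A `.yaml` file written by [write_model_yaml()].
#' @return An `lfer_model`.
#' @export
read_model_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  new_lfer_model(y$endpoint, y$dataset_tag, y$c0, y$c_ow, y$c_aw,
                 se = c(c0 = y$se_c0 %||% NA_real_,
                        c_ow = y$se_ow %||% NA_real_,
                        c_aw = y$se_aw %||% NA_real_),
                 n = y$n %||% NA_integer_, stats = y$stats,
                 provenance = y$provenance %||% "user")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
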