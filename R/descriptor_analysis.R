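# Dimensionality and correlation analyses on descriptor matrices:
# correlation-PCA with variable contributions, and Pearson correlograms
# with strength classification.

#' Principal component analysis of a descriptor matrix
#'
#' Eigen-decomposition of the correlation matrix (`standardize = TRUE`,
#' the default, appropriate when mixing Abraham descriptors with
#' log-partition coefficients on different scales) or the covariance
#' matrix. Rows with any missing cell are dropped listwise. The loading
#' sign convention is deterministic: within each dimension the
#' largest-magnitude loading is made positive.
#'
#' @param mat Numeric matrix or data frame (records x variables).
#' @param standardize Scale variables to unit variance first.
#' @return A `pca_report`: list with `variance_explained` (fractions),
#'   `cumulative`, `loadings` (variables x dimensions, orthonormal
#'   columns), `coordinates` (loadings scaled by component sd),
#'   `cos2` (quality of representation per variable per dimension),
#'   `contribution` (squared loadings; columns sum to 1),
#'   `eigenvalues`, `n`.
#' @export
#' @examples
#' m <- generate_descriptor_matrix(n = 100, rank = 2, noise_sd = 0.3, seed = 1)
#' pca_analysis(m)$cumulative[2]
pca_analysis <- function(mat, standardize = TRUE) {
  mat <- as.matrix(as.data.frame(mat))
  if (!is.numeric(mat)) stop("matrix must be numeric")
  mat <- mat[stats::complete.cases(mat), , drop = FALSE]
  if (ncol(mat) < 2L) stop("need at least 2 variables")
  if (nrow(mat) < 3L) stop("need at least 3 complete rows")
  sds <- apply(mat, 2, stats::sd)
  if (standardize && any(sds == 0)) {
    stop("zero-variance column(s) cannot be standardized: ",
         paste(colnames(mat)[sds == 0], collapse = ", "))
  }
  pc <- stats::prcomp(mat, center = TRUE, scale. = standardize)
  load <- pc$rotation
  # deterministic sign: largest |loading| positive per dimension
  for (j in seq_len(ncol(load))) {
    i_max <- which.max(abs(load[, j]))
    if (load[i_max, j] < 0) {
      load[, j] <- -load[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  eig <- pc$sdev^2
  ve <- eig / sum(eig)
  coord <- sweep(load, 2, pc$sdev, `*`)
  cos2 <- coord^2 / rowSums(coord^2)
  contrib <- load^2
  structure(list(variance_explained = ve, cumulative = cumsum(ve),
                 loadings = load, coordinates = coord, cos2 = cos2,
                 contribution = contrib, eigenvalues = eig,
                 scores = pc$x, n = nrow(mat),
                 standardized = standardize),
            class = "pca_report")
}

#' @export
print.pca_report <- function(x, ...) {
  cat(sprintf("PCA on %d records x %d variables (%s)\n", x$n,
              nrow(x$loadings),
              if (x$standardized) "correlation" else "covariance"))
  cat("  variance explained:",
      paste0(sprintf("%.1f%%", 100 * x$variance_explained), collapse = ", "),
      "\n")
  cat(sprintf("  first two dimensions: %.1f%%\n", 100 * x$cumulative[2]))
  invisible(x)
}

#' Pairwise Pearson correlation with strength labels
#'
#' @param mat Numeric matrix or data frame; rows with missing cells are
#'   dropped listwise (at least 3 complete rows required).
#' @return A `correlation_report`: list with `r_matrix` and `labels`
#'   (strength classes from [classify_correlation()]).
#' @export
#' @examples
#' m <- generate_descriptor_matrix(n = 50, rank = 2, noise_sd = 0.5, seed = 2)
#' correlogram(m)$labels[1, 2]
correlogram <- function(mat) {
  mat <- as.matrix(as.data.frame(mat))
  mat <- mat[stats::complete.cases(mat), , drop = FALSE]
  if (nrow(mat) < 3L) stop("need at least 3 complete rows")
  sds <- apply(mat, 2, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance column(s): ",
         paste(colnames(mat)[sds == 0], collapse = ", "))
  }
  r <- stats::cor(mat)
  labels <- matrix(vapply(as.vector(r), classify_correlation, character(1)),
                   nrow = nrow(r), dimnames = dimnames(r))
  structure(list(r_matrix = r, labels = labels, n = nrow(mat)),
            class = "correlation_report")
}

#' Classify the strength of a Pearson correlation
#'
#' Five contiguous bins on `|r|`: negligible `[0, 0.10)`, weak
#' `[0.10, 0.40)`, moderate `[0.40, 0.70)`, strong `[0.70, 0.90)`,
#' very strong `[0.90, 1]`; boundary values fall in the upper bin.
#' (Published rule-of-thumb tables sometimes print these bins with
#' typographical gaps; the contiguous convention is used here.)
#'
#' @param r Correlation coefficient, `|r| <= 1`.
#' @return One of `"negligible"`, `"weak"`, `"moderate"`, `"strong"`,
#'   `"very strong"`.
#' @export
#' @examples
#' classify_correlation(0.31)   # "weak"
#' classify_correlation(-0.95)  # "very strong"
classify_correlation <- function(r) {
  if (is.na(r)) return(NA_character_)
  if (abs(r) > 1 + 1e-12) stop("|r| must be <= 1, got ", r)
  a <- min(abs(r), 1)
  if (a < 0.10) "negligible"
  else if (a < 0.40) "weak"
  else if (a < 0.70) "moderate"
  else if (a < 0.90) "strong"
  else "very strong"
}
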