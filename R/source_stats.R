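standardize_columns <- function(x) {
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0))
    stop("constant variable(s): ",
         paste(colnames(x)[sds == 0], collapse = ", "))
  scale(x)
}

#' Ward hierarchical clustering of a survey
#'
#' Ward's minimum-variance clustering with Euclidean distance on z-score
#' standardized data (unbiased n-1 standard deviation). In `variables` mode
#' (R-mode) the analytes are clustered on their standardized profiles across
#' samples; `samples` mode (Q-mode) clusters the samples. The merge cost is
#' the increase in total within-cluster sum of squares; reported heights are
#' on the "ward.D2" scale, `sqrt(2 * delta SS)` for a merge of two
#' singletons at Euclidean distance d giving height d.
#'
#' @param survey a `survey_table` or numeric matrix (samples x variables).
#' @param mode cluster `"variables"` (default) or `"samples"`.
#' @return list of class `ward_tree` with the `hclust` object (`hc`), the
#'   leaf `labels`, the `mode` and a `cut(k)` function returning k-group
#'   labels.
#' @examples
#' f <- system.file("extdata", "table1_metals.csv", package = "coastrisk")
#' tree <- ward_cluster(read_survey(f, "metals"))
#' tree$cut(3)
#' @export
ward_cluster <- function(survey, mode = c("variables", "samples")) {
  mode <- match.arg(mode)
  x <- if (is.matrix(survey)) survey else survey_matrix(survey)
  z <- standardize_columns(x)
  entities <- if (mode == "variables") t(z) else z
  if (nrow(entities) < 2) stop("need at least 2 entities to cluster")
  hc <- stats::hclust(stats::dist(entities), method = "ward.D2")
  structure(list(
    hc = hc, labels = hc$labels, mode = mode,
    merge = hc$merge, height = hc$height,
    standardization = "z-score (n-1 sd)",
    cut = function(k) stats::cutree(hc, k = k)
  ), class = "ward_tree")
}

#' @export
print.ward_tree <- function(x, ...) {
  cat("<ward_tree>", length(x$labels), x$mode, "clustered (Ward/Euclidean)\n")
  cat("  merge heights:", paste(signif(x$height, 4), collapse = " "), "\n")
  invisible(x)
}

#' Principal component analysis of a survey
#'
#' Correlation-matrix PCA on standardized data: eigendecomposition of the
#' correlation matrix, so the eigenvalues sum to the number of variables and
#' each explained-variance share is `eigenvalue / p`. Components with
#' eigenvalue > 1 are retained (Kaiser criterion). The Kaiser-Meyer-Olkin
#' sampling adequacy and Bartlett's sphericity test are computed from the
#' same correlation matrix. Loadings are eigenvectors scaled by the square
#' root of their eigenvalue, with the sign convention that each component's
#' largest-magnitude loading is positive.
#'
#' @param survey a `survey_table` or numeric matrix (samples x variables).
#' @param rotate `"none"` (default) or `"varimax"` (applied to the retained
#'   components).
#' @return list of class `pca_result`: `eigenvalues`, `loadings`,
#'   `variance_explained` and `cumulative_variance` (percent), `retained`,
#'   `kmo`, `bartlett_chi2`, `bartlett_df`, `bartlett_p`.
#' @export
pca <- function(survey, rotate = c("none", "varimax")) {
  rotate <- match.arg(rotate)
  x <- if (is.matrix(survey)) survey else survey_matrix(survey)
  if (nrow(x) < 3 || ncol(x) < 2)
    stop("need at least 3 samples and 2 variables")
  standardize_columns(x)  # errors on constant variables
  r <- stats::cor(x)
  eig <- eigen(r, symmetric = TRUE)
  p <- ncol(x)
  values <- eig$values
  vectors <- eig$vectors
  loadings <- sweep(vectors, 2, sqrt(pmax(values, 0)), "*")
  # largest-magnitude loading positive, per component
  for (j in seq_len(p)) {
    mj <- which.max(abs(loadings[, j]))
    if (loadings[mj, j] < 0) loadings[, j] <- -loadings[, j]
  }
  dimnames(loadings) <- list(colnames(x), paste0("PC", seq_len(p)))
  retained <- which(values > 1)
  if (rotate == "varimax" && length(retained) > 1) {
    rot <- stats::varimax(loadings[, retained, drop = FALSE])
    loadings[, retained] <- unclass(rot$loadings)
  }
  bart <- bartlett_sphericity(r, n = nrow(x))
  structure(list(
    eigenvalues = values,
    loadings = loadings,
    variance_explained = 100 * values / p,
    cumulative_variance = cumsum(100 * values / p),
    retained = retained,
    kmo = kmo(r),
    bartlett_chi2 = bart$chi2, bartlett_df = bart$df, bartlett_p = bart$p,
    n = nrow(x), rotate = rotate
  ), class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat("<pca_result>", length(x$eigenvalues), "components;",
      length(x$retained), "retained (eigenvalue > 1)\n")
  cat("  eigenvalues:", paste(signif(x$eigenvalues, 4), collapse = " "), "\n")
  cat(sprintf("  cumulative variance (retained): %.2f%%\n",
              x$cumulative_variance[max(x$retained)]))
  cat(sprintf("  KMO %.3f; Bartlett chi2 %.2f (df %d, p %.3g)\n",
              x$kmo, x$bartlett_chi2, x$bartlett_df, x$bartlett_p))
  invisible(x)
}

#' Kaiser-Meyer-Olkin measure of sampling adequacy
#'
#' Overall KMO from the pairwise correlations r_ij and the anti-image
#' (negative partial) correlations a_ij obtained from the inverse correlation
#' matrix: `KMO = sum r_ij^2 / (sum r_ij^2 + sum a_ij^2)` over the
#' off-diagonal entries; always in `[0, 1]`.
#'
#' @param r positive-definite correlation matrix.
#' @return scalar in `[0, 1]`.
#' @export
kmo <- function(r) {
  stopifnot(is.matrix(r), nrow(r) == ncol(r))
  inv <- tryCatch(solve(r), error = function(e)
    stop("correlation matrix is not invertible"))
  d <- 1 / sqrt(diag(inv))
  partial <- -inv * tcrossprod(d)   # partial correlations, off-diagonal
  off <- upper.tri(r)
  sum(r[off]^2) / (sum(r[off]^2) + sum(partial[off]^2))
}

#' Bartlett's test of sphericity
#'
#' Tests whether a correlation matrix is the identity, using the statistic
#' `-(n - 1 - (2p + 5) / 6) * log(det(R))` with `p (p - 1) / 2` degrees of
#' freedom against a chi-squared reference.
#'
#' @param r correlation matrix.
#' @param n number of observations behind `r`.
#' @return list with `chi2`, `df`, `p`.
#' @export
bartlett_sphericity <- function(r, n) {
  p <- ncol(r)
  chi2 <- -(n - 1 - (2 * p + 5) / 6) * determinant(r, logarithm = TRUE)$modulus
  chi2 <- max(0, as.numeric(chi2))
  df <- p * (p - 1) / 2
  list(chi2 = chi2, df = df, p = stats::pchisq(chi2, df, lower.tail = FALSE))
}
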