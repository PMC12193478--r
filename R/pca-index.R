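## Two-component PCA gait index over the four per-foot, per-trial
## displacement variances, with a deterministic sign convention so that
## loadings and scores are reproducible across linear-algebra backends.

#' Fit the two-component PCA gait index
#'
#' Z-scores each of the four variance features, eigendecomposes the sample
#' correlation matrix, and keeps the first two components. The explained
#' ratios are eigenvalues divided by 4 (the trace of a 4-variable
#' correlation matrix). Sign convention: PC1 is oriented so the sum of its
#' loadings is positive (an index that grows with overall gait variability);
#' PC2 is oriented so the trial-1 loadings are positive (positive scores
#' flag trial-1 variance exceeding trial-2). Eigenvalue ties are broken
#' deterministically by the same orientation rules, then lexicographically
#' by loading vector.
#'
#' @param features data.frame or matrix holding the columns
#'   `var15_test2_1`, `var16_test2_1`, `var15_test2_2`, `var16_test2_2`
#'   (one row per subject, no missing values, >= 3 subjects)
#' @param standardize logical; `TRUE` (default) for correlation-matrix PCA.
#'   `FALSE` switches to covariance PCA (explained ratios then normalize by
#'   the total variance).
#' @return a [PCAIndex-class]
#' @examples
#' X <- simulateFeatureMatrix(30, correlation = blockExchangeableCorrelation())
#' fitPCAIndex(X)
#' @export
fitPCAIndex <- function(features, standardize = TRUE) {
  X <- as.matrix(as.data.frame(features)[, FEATURE_COLS, drop = FALSE])
  storage.mode(X) <- "double"
  if (nrow(X) < 3L)
    stop("PCA requires at least 3 subjects", call. = FALSE)
  if (anyNA(X)) stop("features contain missing values", call. = FALSE)
  ctr <- colMeans(X)
  sds <- apply(X, 2L, stats::sd)
  zero <- sds == 0
  if (any(zero))
    stop("zero-variance column(s): ", paste(FEATURE_COLS[zero], collapse = ", "),
         call. = FALSE)
  scl <- if (standardize) sds else rep(1, 4L)
  Z <- sweep(sweep(X, 2L, ctr), 2L, scl, "/")
  S <- stats::cov(Z)  # correlation matrix when standardized
  eig <- eigen(S, symmetric = TRUE)
  ord <- order(eig$values, decreasing = TRUE)
  vals <- eig$values[ord]
  vecs <- eig$vectors[, ord, drop = FALSE]
  L <- vecs[, 1:2, drop = FALSE]
  ## deterministic orientation
  L[, 1L] <- orientLoading(L[, 1L], sum(L[, 1L]))
  L[, 2L] <- orientLoading(L[, 2L], sum(L[1:2, 2L]))
  dimnames(L) <- list(FEATURE_COLS, c("PC1", "PC2"))
  er <- pmax(vals[1:2], 0) / sum(pmax(vals, 0))
  scores <- Z %*% L
  colnames(scores) <- c("PC1", "PC2")
  new("PCAIndex",
      loadings = L, explained_ratio = er, scores = scores,
      standardized = standardize, center = ctr, scale = scl)
}

## Flip an eigenvector so `key` is positive; on an exactly zero key fall
## back to the first nonzero coordinate (lexicographic tie-break).
orientLoading <- function(v, key) {
  if (abs(key) > 1e-12) return(if (key < 0) -v else v)
  nz <- which(abs(v) > 1e-12)
  if (length(nz) && v[nz[1L]] < 0) -v else v
}

#' @rdname fitPCAIndex
#' @param x a PCAIndex
#' @export
setMethod("pcaLoadings", "PCAIndex", function(x) x@loadings)

#' @rdname fitPCAIndex
#' @export
setMethod("explainedRatio", "PCAIndex", function(x) x@explained_ratio)

#' @rdname fitPCAIndex
#' @export
setMethod("pcaScores", "PCAIndex", function(x) x@scores)

setMethod("show", "PCAIndex", function(object) {
  cat(sprintf("PCAIndex (%s PCA), %d subjects\n",
              if (object@standardized) "correlation-matrix" else "covariance",
              nrow(object@scores)))
  cat(sprintf("  explained ratios: PC1 %.3f, PC2 %.3f (cumulative %.1f%%)\n",
              object@explained_ratio[1L], object@explained_ratio[2L],
              100 * sum(object@explained_ratio)))
  lab <- interpretComponents(object)
  cat(sprintf("  PC1: %s; PC2: %s\n", lab[1L], lab[2L]))
  print(round(object@loadings, 3))
})

#' Interpret the two gait-index components
#'
#' Applies the sign-pattern reading of the components: PC1 is labelled
#' `"muscle-control reserve"` only when all four of its loadings share one
#' sign (synchronous changes of all variance features — overall
#' gait-adjustment capacity); PC2 is labelled `"learning-fatigue response"`
#' only when its trial-1 and trial-2 loadings have opposite signs (the
#' cross-trial contrast separating initial caution from fatigue). Any other
#' pattern is labelled `"unstructured"` rather than forcing an
#' interpretation.
#'
#' @param index a fitted [PCAIndex-class]
#' @return named character vector of length 2 with the component labels
#' @export
interpretComponents <- function(index) {
  stopifnot(is(index, "PCAIndex"))
  L <- index@loadings
  pc1 <- if (all(L[, 1L] > 0) || all(L[, 1L] < 0))
    "muscle-control reserve" else "unstructured"
  s1 <- sign(L[1:2, 2L])
  s2 <- sign(L[3:4, 2L])
  pc2 <- if (all(s1 == s1[1L]) && all(s2 == s2[1L]) &&
             s1[1L] != 0 && s2[1L] == -s1[1L])
    "learning-fatigue response" else "unstructured"
  c(PC1 = pc1, PC2 = pc2)
}
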