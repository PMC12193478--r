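## Mixed-variable-type correlation engine: classify variables, preprocess,
## dispatch the appropriate coefficient per pair, adjust p-values for
## multiple testing, and emit an annotated heatmap-ready matrix.
##
## Dispatch (by declared kind):
##   binary x binary          -> undefined default (blank cell)
##   binary x anything else   -> point-biserial (Pearson on 0/1 coding)
##   ordinal x ordinal        -> Kendall's tau-b (tie-corrected)
##   continuous x continuous  -> Pearson
##   ordinal x continuous     -> Spearman (mixed-type)

#' Classify cohort variables by measurement kind
#'
#' Auto-detects the kind of each column of a cohort/feature table:
#' two-valued columns (e.g. gender) are binary; integer-valued columns with
#' at most `ordinal_max_levels` distinct values (e.g. SPPB test scores) are
#' ordinal; everything else numeric is continuous. Explicit `overrides` win
#' over auto-detection. Constant columns are flagged with a warning and
#' excluded; non-numeric columns with more than two levels are skipped.
#'
#' @param data data.frame of per-subject observations
#' @param overrides named character vector mapping column names to kinds
#'   (`"binary"`, `"ordinal"`, `"continuous"`)
#' @param ordinal_max_levels maximum distinct integer values for the ordinal
#'   auto-rule
#' @param exclude character vector of column names to drop (default:
#'   identifier column `subject_id`)
#' @return named list of [VariableSpec-class] objects
#' @examples
#' sim <- simulateCohort(cohortSimConfig(n_subjects = 12, seed = 2))
#' names(classifyVariables(sim$cohort))
#' @export
classifyVariables <- function(data, overrides = character(),
                              ordinal_max_levels = 6L,
                              exclude = "subject_id") {
  stopifnot(is.data.frame(data), nrow(data) > 0L)
  specs <- list()
  for (nm in setdiff(names(data), exclude)) {
    v <- data[[nm]]
    vals <- v[!is.na(v)]
    uq <- unique(vals)
    if (length(uq) <= 1L) {
      warning("constant column '", nm, "' excluded from correlation analysis",
              call. = FALSE)
      next
    }
    kind <- if (nm %in% names(overrides)) {
      match.arg(overrides[[nm]], c("binary", "ordinal", "continuous"))
    } else if (length(uq) == 2L) {
      "binary"
    } else if (is.numeric(v) && all(vals == round(vals)) &&
               length(uq) <= ordinal_max_levels) {
      "ordinal"
    } else if (is.numeric(v)) {
      "continuous"
    } else {
      warning("non-numeric column '", nm, "' with >2 levels skipped",
              call. = FALSE)
      next
    }
    if (kind == "binary") {
      lev <- as.character(sort(uq))
      num <- as.numeric(factor(as.character(v), levels = lev)) - 1
      specs[[nm]] <- new("VariableSpec", name = nm, kind = kind,
                         values = num, levels = lev)
    } else {
      specs[[nm]] <- new("VariableSpec", name = nm, kind = kind,
                         values = as.numeric(v), levels = character())
    }
  }
  specs
}

setMethod("show", "VariableSpec", function(object) {
  cat(sprintf("VariableSpec '%s': %s, n = %d (%d missing)\n",
              object@name, object@kind, length(object@values),
              sum(is.na(object@values))))
})

#' Preprocess a classified variable before correlation
#'
#' Ordinal variables are converted to midranks (ties averaged) and z-scored;
#' continuous variables are optionally denoised with locally weighted
#' scatterplot smoothing (LOWESS, via [stats::lowess()]) against subject
#' presentation order; binary variables keep their 0/1 coding. Rank-based
#' coefficients (Kendall, Spearman) are unaffected by the monotone ordinal
#' transform; LOWESS does alter Pearson-type coefficients, which is why
#' smoothing is off by default.
#'
#' @param spec a [VariableSpec-class]
#' @param smooth logical; apply LOWESS to continuous variables
#' @param f LOWESS smoother span (fraction of points, default 0.5)
#' @return numeric vector of transformed values
#' @export
preprocessVariable <- function(spec, smooth = FALSE, f = 0.5) {
  stopifnot(is(spec, "VariableSpec"))
  v <- spec@values
  switch(spec@kind,
    binary = v,
    ordinal = {
      r <- rank(v, na.last = "keep")  # midranks
      s <- stats::sd(r, na.rm = TRUE)
      if (is.na(s) || s == 0)
        stop("zero-variance ordinal variable '", spec@name,
             "': all values tied", call. = FALSE)
      (r - mean(r, na.rm = TRUE)) / s
    },
    continuous = {
      if (!smooth) return(v)
      ok <- !is.na(v)
      sm <- stats::lowess(seq_along(v)[ok], v[ok], f = f)
      out <- v
      out[ok] <- sm$y[order(order(seq_along(v)[ok]))]
      out
    })
}

## Dispatch table: declared kinds -> correlation method
.dispatchMethod <- function(kind_a, kind_b) {
  k <- sort(c(kind_a, kind_b))
  if (all(k == "binary")) return("undefined_default")
  if (k[1L] == "binary") return("point_biserial")
  if (all(k == "ordinal")) return("kendall_tau")
  if (all(k == "continuous")) return("pearson")
  "spearman"  # ordinal x continuous
}

#' Correlation between two classified variables
#'
#' Computes the coefficient appropriate to the pair of variable kinds (see
#' the dispatch table in the package overview): point-biserial for a binary
#' with a numeric variable, Kendall's tau-b for two ordinals, Pearson for
#' two continuous variables, Spearman for an ordinal-continuous mix, and an
#' undefined default (missing coefficient, blank cell) for two binaries.
#' Two-sided p-values accompany every defined coefficient; for `n < 10`
#' paired observations the exact small-sample distributions of the rank
#' coefficients are used where ties permit.
#'
#' @param a,b [VariableSpec-class] objects of equal length
#' @param smooth,f smoothing settings passed to [preprocessVariable()]
#' @return list with elements `pair`, `method`, `coefficient`, `p_raw`
#'   (coefficient and p are `NA` for the undefined binary-binary default and
#'   for zero-variance inputs, with a `note` diagnostic)
#' @export
pairwiseCorrelation <- function(a, b, smooth = FALSE, f = 0.5) {
  stopifnot(is(a, "VariableSpec"), is(b, "VariableSpec"),
            length(a@values) == length(b@values))
  method <- .dispatchMethod(a@kind, b@kind)
  res <- list(pair = c(a@name, b@name), method = method,
              coefficient = NA_real_, p_raw = NA_real_, note = "")
  if (method == "undefined_default") {
    res$note <- "binary-binary pair: no defined coefficient"
    return(res)
  }
  x <- preprocessVariable(a, smooth = smooth, f = f)
  y <- preprocessVariable(b, smooth = smooth, f = f)
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 3L)
    stop(sprintf("pair (%s, %s): need >= 3 paired non-missing observations",
                 a@name, b@name), call. = FALSE)
  x <- x[ok]; y <- y[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    res$note <- "zero variance: coefficient undefined"
    return(res)
  }
  exact <- sum(ok) < 10L
  ct <- switch(method,
    point_biserial = ,
    pearson = stats::cor.test(x, y, method = "pearson",
                              alternative = "two.sided"),
    kendall_tau = suppressWarnings(
      stats::cor.test(x, y, method = "kendall", exact = exact,
                      alternative = "two.sided")),
    spearman = suppressWarnings(
      stats::cor.test(x, y, method = "spearman", exact = exact,
                      alternative = "two.sided")))
  ## cor.test's Kendall is tau-b (tie-corrected) when ties are present
  res$coefficient <- unname(ct$estimate)
  res$p_raw <- ct$p.value
  res
}

#' Benjamini-Hochberg adjustment over a family of correlation results
#'
#' Applies the FDR step-up procedure ([stats::p.adjust()], method `"BH"`)
#' across all defined raw p-values of the family — one family per reported
#' matrix, i.e. all off-diagonal pairs. Adjusted values are monotone
#' non-decreasing in the raw p-values, never below them, and capped at 1;
#' undefined entries stay `NA`.
#'
#' @param p_raw numeric vector of raw two-sided p-values (`NA` allowed)
#' @return numeric vector of adjusted p-values, same length and order
#' @export
fdrAdjust <- function(p_raw) {
  out <- rep(NA_real_, length(p_raw))
  ok <- !is.na(p_raw)
  out[ok] <- stats::p.adjust(p_raw[ok], method = "BH")
  out
}

#' Mixed-type correlation matrix with FDR adjustment and stars
#'
#' The full correlation stage: classify (or accept pre-classified)
#' variables, compute every pairwise coefficient with the kind-appropriate
#' method, adjust the family of raw p-values by Benjamini-Hochberg, and
#' annotate significance stars from the adjusted values (`*` < 0.05,
#' `**` < 0.01, `***` < 0.001). The diagonal is fixed at 1 for
#' non-binary-binary self-pairs.
#'
#' @param data data.frame of per-subject observations, or a named list of
#'   [VariableSpec-class] objects
#' @param overrides,ordinal_max_levels,exclude passed to
#'   [classifyVariables()] when `data` is a data.frame
#' @param smooth,f LOWESS settings for continuous variables (off by default)
#' @return a [CorrelationMatrix-class]
#' @examples
#' sim <- simulateCohort(cohortSimConfig(n_subjects = 15, seed = 4))
#' cm <- correlationMatrix(merge(sim$cohort, sim$features))
#' corCoefficients(cm)["var_mean", "duration"]
#' @export
correlationMatrix <- function(data, overrides = character(),
                              ordinal_max_levels = 6L,
                              exclude = "subject_id",
                              smooth = FALSE, f = 0.5) {
  specs <- if (is.data.frame(data))
    classifyVariables(data, overrides, ordinal_max_levels, exclude)
  else data
  stopifnot(length(specs) >= 2L,
            all(vapply(specs, is, logical(1L), "VariableSpec")))
  vars <- vapply(specs, slot, character(1L), "name")
  kinds <- vapply(specs, slot, character(1L), "kind")
  p <- length(vars)
  coef <- matrix(NA_real_, p, p, dimnames = list(vars, vars))
  meth <- matrix("", p, p, dimnames = list(vars, vars))
  praw <- coef
  for (i in seq_len(p)) {
    meth[i, i] <- .dispatchMethod(kinds[i], kinds[i])
    if (kinds[i] != "binary") coef[i, i] <- 1
    for (j in seq_len(p)[-seq_len(i)]) {
      r <- pairwiseCorrelation(specs[[i]], specs[[j]], smooth = smooth, f = f)
      coef[i, j] <- coef[j, i] <- r$coefficient
      meth[i, j] <- meth[j, i] <- r$method
      praw[i, j] <- praw[j, i] <- r$p_raw
    }
  }
  ## one BH family: the upper-triangle off-diagonal pairs
  ut <- upper.tri(praw)
  padj <- praw
  padj[ut] <- fdrAdjust(praw[ut])
  padj[lower.tri(padj)] <- t(padj)[lower.tri(padj)]
  stars <- matrix(significanceStars(padj), p, p, dimnames = dimnames(coef))
  new("CorrelationMatrix", variables = vars, kinds = kinds,
      coef = coef, method = meth, p_raw = praw, p_adjusted = padj,
      stars = stars)
}

#' @rdname correlationMatrix
#' @param x a CorrelationMatrix
#' @export
setMethod("corCoefficients", "CorrelationMatrix", function(x) x@coef)

#' @rdname correlationMatrix
#' @export
setMethod("corMethods", "CorrelationMatrix", function(x) x@method)

#' @rdname correlationMatrix
#' @export
setMethod("rawPvalues", "CorrelationMatrix", function(x) x@p_raw)

#' @rdname correlationMatrix
#' @export
setMethod("adjustedPvalues", "CorrelationMatrix", function(x) x@p_adjusted)

#' @rdname correlationMatrix
#' @export
setMethod("starMatrix", "CorrelationMatrix", function(x) x@stars)

setMethod("show", "CorrelationMatrix", function(object) {
  p <- length(object@variables)
  cat(sprintf("CorrelationMatrix: %d variables (%s)\n", p,
              paste(sprintf("%d %s", table(object@kinds)[unique(object@kinds)],
                            unique(object@kinds)), collapse = ", ")))
  lab <- matrix(paste0(formatCoef(object@coef), object@stars),
                p, p, dimnames = dimnames(object@coef))
  diag(lab) <- ifelse(object@kinds == "binary", "", "1.00")
  print(lab, quote = FALSE)
})

#' Export an annotated correlation matrix to CSV
#'
#' Writes one row per unordered off-diagonal pair: the two variable names,
#' method, coefficient (also rendered to two decimals, half away from zero,
#' matching the heatmap annotation style), raw and adjusted p-values, and
#' stars. Undefined (binary-binary) cells are rendered blank.
#'
#' @param cm a [CorrelationMatrix-class]
#' @param file output CSV path (optional; omit to just get the data.frame)
#' @return the exported data.frame, invisibly when `file` is given
#' @seealso [plotCorrelationHeatmap()]
#' @export
exportCorrelations <- function(cm, file = NULL) {
  stopifnot(is(cm, "CorrelationMatrix"))
  p <- length(cm@variables)
  idx <- which(upper.tri(cm@coef), arr.ind = TRUE)
  df <- data.frame(
    var1 = cm@variables[idx[, 1L]],
    var2 = cm@variables[idx[, 2L]],
    method = cm@method[idx],
    coefficient = cm@coef[idx],
    label = formatCoef(cm@coef[idx]),
    p_raw = cm@p_raw[idx],
    p_adjusted = cm@p_adjusted[idx],
    stars = cm@stars[idx])
  df <- df[order(df$var1, df$var2), ]
  rownames(df) <- NULL
  if (!is.null(file)) {
    utils::write.csv(df, file, row.names = FALSE)
    return(invisible(df))
  }
  df
}

#' Heatmap of an annotated correlation matrix
#'
#' Renders the coefficient matrix with [pheatmap::pheatmap()], each cell
#' annotated `coefficient` + stars in the conventional "-0.96***" style;
#' undefined cells are blank. Row/column order is kept as given (no
#' clustering) so the layout is deterministic.
#'
#' @param cm a [CorrelationMatrix-class]
#' @param file optional output image path (png or pdf by extension)
#' @param ... further arguments to [pheatmap::pheatmap()]
#' @return the pheatmap object, invisibly
#' @export
plotCorrelationHeatmap <- function(cm, file = NULL, ...) {
  stopifnot(is(cm, "CorrelationMatrix"))
  m <- cm@coef
  lab <- matrix(paste0(formatCoef(m), cm@stars), nrow(m), ncol(m))
  m[is.na(m)] <- 0
  args <- list(mat = m, cluster_rows = FALSE, cluster_cols = FALSE,
               display_numbers = lab,
               breaks = seq(-1, 1, length.out = 101),
               labels_row = cm@variables, labels_col = cm@variables,
               silent = !is.null(file), ...)
  if (!is.null(file)) args$filename <- file
  ph <- do.call(pheatmap::pheatmap, args)
  invisible(ph)
}
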