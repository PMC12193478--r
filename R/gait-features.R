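## Core gait-variability statistics: frame-to-frame Euclidean displacements
## of each foot, their unbiased per-trial variance, and the composite
## var_mean index averaging the four per-foot, per-trial variances.

FEATURE_COLS <- c("var15_test2_1", "var16_test2_1",
                  "var15_test2_2", "var16_test2_2")

#' Frame-to-frame Euclidean displacements of a foot track
#'
#' For consecutive surviving frames k and k+1 of one foot,
#' \deqn{d_k = \sqrt{(x_{k+1}-x_k)^2 + (y_{k+1}-y_k)^2}.}
#' Displacements bridging confidence-dropped frames (gaps in the original
#' frame ordinals) are flagged and, by default, retained: the two flanking
#' displacements merge into one displacement across the gap.
#'
#' @param track a [FootTrack-class] with at least 2 coordinates
#' @param include_gap_spanning logical; if `FALSE`, displacements that span
#'   one or more dropped frames are excluded from the series
#' @return a [DisplacementSeries-class]
#' @seealso [displacementVariance()]
#' @export
frameDisplacements <- function(track, include_gap_spanning = TRUE) {
  stopifnot(is(track, "FootTrack"))
  xy <- track@coords
  if (nrow(xy) < 2L)
    stop("insufficient frames: need >= 2 coordinates to form displacements",
         call. = FALSE)
  d <- sqrt(diff(xy[, 1L])^2 + diff(xy[, 2L])^2)
  gap <- diff(track@frame_index) > 1L
  if (!include_gap_spanning) {
    d <- d[!gap]
    gap <- gap[!gap]
  }
  new("DisplacementSeries",
      foot_index = track@foot_index,
      trial_id = track@trial_id,
      values = as.numeric(d),
      gap_spanning = as.logical(gap))
}

#' @rdname frameDisplacements
#' @param x a DisplacementSeries
#' @export
setMethod("displacements", "DisplacementSeries", function(x) x@values)

setMethod("show", "DisplacementSeries", function(object) {
  cat(sprintf("DisplacementSeries: foot %d, trial '%s', %d displacements (%d gap-spanning)\n",
              object@foot_index, object@trial_id,
              length(object@values), sum(object@gap_spanning)))
})

#' Unbiased variance of a displacement series
#'
#' The fluctuation magnitude of one foot within one trial:
#' \deqn{\mathrm{Var}(d) = \frac{1}{N-1}\sum_{k=1}^{N-1} (d_k - \bar d)^2,}
#' the unbiased sample variance about the same trial's mean displacement
#' \eqn{\bar d}, with denominator one less than the count of displacements.
#'
#' @param series a [DisplacementSeries-class] with at least 2 values
#' @return a [TrialVariance-class]
#' @export
displacementVariance <- function(series) {
  stopifnot(is(series, "DisplacementSeries"))
  d <- series@values
  if (length(d) < 2L)
    stop("variance undefined: need >= 2 displacements", call. = FALSE)
  new("TrialVariance",
      foot_index = series@foot_index,
      trial_id = series@trial_id,
      variance = stats::var(d),
      mean_displacement = mean(d),
      n = length(d))
}

setMethod("show", "TrialVariance", function(object) {
  cat(sprintf("TrialVariance: foot %d, trial '%s', var = %.6g px^2 (mean d = %.6g px, n = %d)\n",
              object@foot_index, object@trial_id,
              object@variance, object@mean_displacement, object@n))
})

#' Composite gait-variability index from the four per-foot/per-trial variances
#'
#' Averages the displacement variances of the left (15) and right (16) foot
#' over the two walking trials:
#' \deqn{\mathrm{var\_mean} = \frac{1}{4}\sum_{i \in \{15,16\}}
#'   \left(\mathrm{Var}(d_i)_{2.1} + \mathrm{Var}(d_i)_{2.2}\right),}
#' alongside the per-trial means
#' `var_mean_2_j = (var15_test2_j + var16_test2_j) / 2`. Every term enters;
#' a missing foot/trial variance is an explicit error naming what is absent.
#'
#' @param variances named numeric vector (or list) carrying the four entries
#'   `var15_test2_1`, `var16_test2_1`, `var15_test2_2`, `var16_test2_2`
#'   (pixels squared)
#' @return named numeric vector with the four inputs plus `var_mean_2_1`,
#'   `var_mean_2_2` and `var_mean`
#' @export
compositeVarMean <- function(variances) {
  v <- unlist(variances)
  missing <- setdiff(FEATURE_COLS, names(v))
  if (length(missing) || anyNA(v[FEATURE_COLS]))
    stop("incomplete trials: missing variance(s) ",
         paste(union(missing, FEATURE_COLS[is.na(v[FEATURE_COLS])]),
               collapse = ", "),
         call. = FALSE)
  v <- v[FEATURE_COLS]
  c(v,
    var_mean_2_1 = unname((v["var15_test2_1"] + v["var16_test2_1"]) / 2),
    var_mean_2_2 = unname((v["var15_test2_2"] + v["var16_test2_2"]) / 2),
    var_mean = unname(sum(v) / 4))
}

#' Per-subject gait feature vectors from trial pose sequences
#'
#' Runs the full per-subject feature pipeline: extract confidence-filtered
#' foot tracks from the two walking trials, form displacement series,
#' compute the four per-foot/per-trial variances, and aggregate them into
#' the composite index.
#'
#' @param trials named list, one element per subject; each element is a list
#'   with components `test2_1` and `test2_2`, the two [PoseSequence-class]
#'   trials
#' @param min_confidence confidence threshold for [extractFootTracks()]
#' @param include_gap_spanning passed to [frameDisplacements()]
#' @return data.frame with one row per subject: `subject_id`, the four
#'   variance columns, `var_mean_2_1`, `var_mean_2_2`, `var_mean`
#' @seealso [fitPCAIndex()], [correlationMatrix()]
#' @export
gaitFeatures <- function(trials, min_confidence = 0.3,
                         include_gap_spanning = TRUE) {
  stopifnot(is.list(trials), length(trials) >= 1L)
  rows <- lapply(names(trials), function(sid) {
    tr <- trials[[sid]]
    v <- c(var15_test2_1 = NA_real_, var16_test2_1 = NA_real_,
           var15_test2_2 = NA_real_, var16_test2_2 = NA_real_)
    for (j in 1:2) {
      tname <- paste0("test2_", j)
      seq <- tr[[tname]]
      if (is.null(seq)) next  # left NA; compositeVarMean names it below
      tracks <- tryCatch(extractFootTracks(seq, min_confidence),
                         error = function(e)
                           stop(sprintf("subject '%s', trial '%s': %s",
                                        sid, tname, conditionMessage(e)),
                                call. = FALSE))
      for (side in c("left", "right")) {
        tv <- displacementVariance(
          frameDisplacements(tracks[[side]], include_gap_spanning))
        v[sprintf("var%d_test2_%d", tv@foot_index, j)] <- tv@variance
      }
    }
    vm <- tryCatch(compositeVarMean(v),
                   error = function(e)
                     stop(sprintf("subject '%s': %s", sid, conditionMessage(e)),
                          call. = FALSE))
    data.frame(subject_id = sid, t(vm), check.names = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
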