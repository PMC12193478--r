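#' @import methods
NULL

## Keypoint indices follow the common 17-point skeleton convention in which
## the two foot/ankle landmarks carry 0-based indices 15 (left) and 16 (right).
## Internally keypoints are stored 1-based, so left = row 16, right = row 17.

#' Keypoint index of the left foot (0-based skeleton convention)
#' @export
FOOT_LEFT <- 15L

#' Keypoint index of the right foot (0-based skeleton convention)
#' @export
FOOT_RIGHT <- 16L

N_KEYPOINTS <- 17L

#' PoseSequence: one walking trial of 2-D skeletal keypoints
#'
#' Ordered frames of 17 2-D keypoints with per-keypoint detection
#' confidences, for a single walking trial of one subject. Coordinates are in
#' pixels (image convention: origin top-left, y increases downward); frames
#' are 0-indexed in file order.
#'
#' @slot subject_id character scalar identifying the subject.
#' @slot trial_id character scalar identifying the trial (e.g. "test2_1").
#' @slot keypoints numeric array of dimension `n_frames x 17 x 3`; the last
#'   margin holds `(x, y, confidence)`. Confidences lie in `[0, 1]`.
#'
#' @seealso [readKeypointJSON()], [simulateWalkTrial()], [extractFootTracks()]
#' @export
setClass("PoseSequence",
  representation(
    subject_id = "character",
    trial_id   = "character",
    keypoints  = "array"
  )
)

setValidity("PoseSequence", function(object) {
  kp <- object@keypoints
  d <- dim(kp)
  if (length(d) != 3L || d[2L] != N_KEYPOINTS || d[3L] != 3L)
    return(sprintf("keypoints must be an n x %d x 3 array", N_KEYPOINTS))
  if (length(object@subject_id) != 1L || length(object@trial_id) != 1L)
    return("subject_id and trial_id must be length-1 character")
  conf <- kp[, , 3L]
  if (length(conf) && (anyNA(conf) || any(conf < 0) || any(conf > 1)))
    return("confidences must lie in [0, 1]")
  TRUE
})

#' FootTrack: confidence-filtered coordinate track of one foot
#'
#' The ordered `(x, y)` pixel coordinates of one foot keypoint after
#' confidence filtering, together with the original frame ordinals of the
#' surviving frames and the count of frames removed.
#'
#' @slot foot_index integer, 15 (left) or 16 (right).
#' @slot trial_id character scalar.
#' @slot coords numeric matrix with columns `x`, `y`, one row per kept frame.
#' @slot frame_index integer vector of 0-based frame ordinals of kept frames,
#'   strictly increasing.
#' @slot n_dropped integer count of frames removed by the confidence filter.
#'
#' @seealso [extractFootTracks()], [frameDisplacements()]
#' @export
setClass("FootTrack",
  representation(
    foot_index  = "integer",
    trial_id    = "character",
    coords      = "matrix",
    frame_index = "integer",
    n_dropped   = "integer"
  )
)

setValidity("FootTrack", function(object) {
  if (!object@foot_index %in% c(FOOT_LEFT, FOOT_RIGHT))
    return("foot_index must be 15 (left) or 16 (right)")
  if (ncol(object@coords) != 2L)
    return("coords must have two columns (x, y)")
  if (nrow(object@coords) != length(object@frame_index))
    return("coords and frame_index lengths differ")
  if (length(object@frame_index) > 1L && any(diff(object@frame_index) <= 0L))
    return("frame_index must be strictly increasing")
  if (object@n_dropped < 0L) return("n_dropped must be non-negative")
  TRUE
})

#' DisplacementSeries: per-frame Euclidean foot displacements
#'
#' The `N - 1` frame-to-frame Euclidean displacements `d_k` of one foot in
#' one trial, computed between consecutive surviving frames.
#'
#' @slot foot_index integer, 15 or 16.
#' @slot trial_id character scalar.
#' @slot values numeric vector of displacements (pixels), all `>= 0`.
#' @slot gap_spanning logical vector marking displacements that bridge one or
#'   more confidence-dropped frames.
#'
#' @seealso [frameDisplacements()], [displacementVariance()]
#' @export
setClass("DisplacementSeries",
  representation(
    foot_index   = "integer",
    trial_id     = "character",
    values       = "numeric",
    gap_spanning = "logical"
  )
)

setValidity("DisplacementSeries", function(object) {
  if (!object@foot_index %in% c(FOOT_LEFT, FOOT_RIGHT))
    return("foot_index must be 15 or 16")
  if (length(object@values) != length(object@gap_spanning))
    return("values and gap_spanning lengths differ")
  if (length(object@values) && any(object@values < 0))
    return("displacements must be non-negative")
  TRUE
})

#' TrialVariance: unbiased variance of one displacement series
#'
#' @slot foot_index integer, 15 or 16.
#' @slot trial_id character scalar.
#' @slot variance numeric, unbiased sample variance of the displacements
#'   (pixels squared).
#' @slot mean_displacement numeric, mean displacement (pixels).
#' @slot n integer, number of displacements entering the variance.
#'
#' @seealso [displacementVariance()]
#' @export
setClass("TrialVariance",
  representation(
    foot_index        = "integer",
    trial_id          = "character",
    variance          = "numeric",
    mean_displacement = "numeric",
    n                 = "integer"
  )
)

setValidity("TrialVariance", function(object) {
  if (object@n < 2L) return("variance requires at least 2 displacements")
  if (is.na(object@variance) || object@variance < 0)
    return("variance must be non-negative")
  TRUE
})

#' WalkSimConfig: generative settings for one simulated walking trial
#'
#' Parameters of the synthetic forward-walk model. Per-frame foot steps are
#' `step_mean + trend * k` plus Gaussian noise whose standard deviation is
#' modulated sinusoidally over the gait cycle (the alternating-foot phase);
#' the right foot's step mean and noise SD are multiplied by `lr_asymmetry`.
#'
#' @slot n_frames integer number of frames, `>= 2`.
#' @slot step_mean numeric mean per-frame foot displacement (pixels).
#' @slot step_sd numeric per-frame displacement noise SD (pixels), `>= 0`.
#' @slot trend numeric linear drift in step length (pixels/frame; may be
#'   negative), emulating gradually increasing or decreasing stride length.
#' @slot lr_asymmetry numeric multiplicative factor on right-foot step
#'   statistics, `>= 0`.
#' @slot dropout_rate numeric probability in `[0, 1)` that a frame has one
#'   foot keypoint with confidence below the usual detection threshold.
#' @slot gait_period numeric gait-cycle length in frames.
#' @slot phase_amplitude numeric amplitude in `[0, 1]` of the sinusoidal
#'   modulation of the noise SD over the gait cycle.
#' @slot seed integer RNG seed.
#'
#' @seealso [walkSimConfig()], [simulateWalkTrial()]
#' @export
setClass("WalkSimConfig",
  representation(
    n_frames        = "integer",
    step_mean       = "numeric",
    step_sd         = "numeric",
    trend           = "numeric",
    lr_asymmetry    = "numeric",
    dropout_rate    = "numeric",
    gait_period     = "numeric",
    phase_amplitude = "numeric",
    seed            = "integer"
  )
)

setValidity("WalkSimConfig", function(object) {
  if (object@n_frames < 2L) return("n_frames must be >= 2")
  if (object@step_sd < 0) return("step_sd must be >= 0")
  if (object@dropout_rate < 0 || object@dropout_rate >= 1)
    return("dropout_rate must lie in [0, 1)")
  if (object@lr_asymmetry < 0) return("lr_asymmetry must be >= 0")
  if (object@gait_period <= 0) return("gait_period must be positive")
  if (object@phase_amplitude < 0 || object@phase_amplitude > 1)
    return("phase_amplitude must lie in [0, 1]")
  TRUE
})

#' CohortSimConfig: generative settings for a simulated study cohort
#'
#' Parameters controlling a synthetic cohort: demographics sampling bounds,
#' per-subject walk heterogeneity, and the linear coupling between the
#' composite gait-variability index (var_mean) and walking-test duration.
#' Per-trial duration is `duration_intercept + coupling_beta * var_mean_2_j`
#' plus Gaussian noise; a negative `coupling_beta` reproduces the negative
#' gait-variability/duration association.
#'
#' @slot n_subjects integer, `>= 2`.
#' @slot age_range,height_range,weight_range numeric length-2 sampling bounds
#'   (years, cm, kg).
#' @slot male_fraction numeric in `[0, 1]`.
#' @slot step_mean numeric mean per-frame step (pixels) common to subjects.
#' @slot step_sd_range numeric length-2 bounds of the per-subject step-noise
#'   SD (pixels); this heterogeneity generates the spread of var_mean.
#' @slot trend_range numeric length-2 bounds of the per-subject stride trend
#'   (pixels/frame).
#' @slot n_frames integer frames per trial.
#' @slot duration_intercept numeric baseline per-trial duration (seconds).
#' @slot coupling_beta numeric slope (seconds per pixel^2) linking var_mean
#'   to duration; negative couples higher gait variability to shorter tests.
#' @slot noise_sd numeric duration residual SD (seconds), `>= 0`.
#' @slot score_breaks numeric increasing duration cutpoints (seconds) mapping
#'   a trial duration to the ordinal score scale (below first cutpoint gets
#'   the top score).
#' @slot score_max integer top ordinal score (default 4, SPPB-style).
#' @slot seed integer RNG seed.
#'
#' @seealso [cohortSimConfig()], [simulateCohort()]
#' @export
setClass("CohortSimConfig",
  representation(
    n_subjects         = "integer",
    age_range          = "numeric",
    height_range       = "numeric",
    weight_range       = "numeric",
    male_fraction      = "numeric",
    step_mean          = "numeric",
    step_sd_range      = "numeric",
    trend_range        = "numeric",
    n_frames           = "integer",
    duration_intercept = "numeric",
    coupling_beta      = "numeric",
    noise_sd           = "numeric",
    score_breaks       = "numeric",
    score_max          = "integer",
    seed               = "integer"
  )
)

setValidity("CohortSimConfig", function(object) {
  if (object@n_subjects < 2L) return("n_subjects must be >= 2")
  if (object@noise_sd < 0) return("noise_sd must be >= 0")
  if (object@male_fraction < 0 || object@male_fraction > 1)
    return("male_fraction must lie in [0, 1]")
  if (is.unsorted(object@score_breaks, strictly = TRUE))
    return("score_breaks must be strictly increasing")
  for (s in c("age_range", "height_range", "weight_range",
              "step_sd_range", "trend_range")) {
    r <- slot(object, s)
    if (length(r) != 2L || r[1L] > r[2L])
      return(sprintf("%s must be a length-2 increasing range", s))
  }
  if (object@step_sd_range[1L] < 0) return("step_sd_range must be >= 0")
  TRUE
})

#' PCAIndex: two-component PCA gait index
#'
#' Result of correlation-matrix PCA of the four per-foot, per-trial
#' displacement variances, reduced to two components with a deterministic
#' sign convention. PC1 with same-sign loadings on all four features is read
#' as muscle-control reserve; PC2 contrasting trial-1 against trial-2
#' variances is read as learning-fatigue response.
#'
#' @slot loadings numeric 4 x 2 matrix of unit-norm, mutually orthogonal
#'   loadings; rows ordered var15_test2_1, var16_test2_1, var15_test2_2,
#'   var16_test2_2.
#' @slot explained_ratio numeric length-2 explained-variance ratios
#'   (eigenvalues / 4), non-increasing, each in `[0, 1]`.
#' @slot scores numeric n x 2 matrix of per-subject component scores.
#' @slot standardized logical; `TRUE` for correlation-matrix (z-scored) PCA.
#' @slot center,scale numeric length-4 column centers and scales used.
#'
#' @seealso [fitPCAIndex()], [interpretComponents()]
#' @export
setClass("PCAIndex",
  representation(
    loadings        = "matrix",
    explained_ratio = "numeric",
    scores          = "matrix",
    standardized    = "logical",
    center          = "numeric",
    scale           = "numeric"
  )
)

setValidity("PCAIndex", function(object) {
  L <- object@loadings
  if (!all(dim(L) == c(4L, 2L))) return("loadings must be 4 x 2")
  ctc <- crossprod(L)
  if (max(abs(ctc - diag(2))) > 1e-8)
    return("loading columns must be orthonormal")
  er <- object@explained_ratio
  if (length(er) != 2L || any(er < -1e-12) || any(er > 1 + 1e-12))
    return("explained_ratio must be two fractions in [0, 1]")
  if (er[1L] < er[2L] - 1e-12)
    return("explained_ratio must be non-increasing")
  if (sum(er) > 1 + 1e-9) return("explained ratios must sum to <= 1")
  TRUE
})

#' VariableSpec: a classified analysis variable
#'
#' One cohort variable with its declared or auto-detected measurement kind,
#' which drives the choice of correlation coefficient.
#'
#' @slot name character scalar.
#' @slot kind one of `"binary"`, `"ordinal"`, `"continuous"`.
#' @slot values numeric per-subject observations (binary variables 0/1-coded).
#' @slot levels character; for binary variables the two original labels in
#'   the order coded 0, 1 (empty otherwise).
#'
#' @seealso [classifyVariables()], [pairwiseCorrelation()]
#' @export
setClass("VariableSpec",
  representation(
    name   = "character",
    kind   = "character",
    values = "numeric",
    levels = "character"
  )
)

setValidity("VariableSpec", function(object) {
  if (!object@kind %in% c("binary", "ordinal", "continuous"))
    return("kind must be binary, ordinal or continuous")
  if (object@kind == "binary") {
    v <- object@values[!is.na(object@values)]
    if (length(unique(v)) > 2L)
      return("binary variable has more than 2 distinct values")
  }
  TRUE
})

#' CorrelationMatrix: annotated mixed-type correlation matrix
#'
#' Symmetric matrix of pairwise correlations over classified variables, with
#' the coefficient method used per pair, raw and FDR-adjusted p-values, and
#' significance stars. Binary-binary pairs carry no defined coefficient and
#' are rendered blank.
#'
#' @slot variables character vector of variable names (matrix order).
#' @slot kinds character vector of variable kinds, parallel to `variables`.
#' @slot coef numeric symmetric matrix of coefficients (`NA` where
#'   undefined); unit diagonal for defined kinds.
#' @slot method character matrix: `"pearson"`, `"spearman"`, `"kendall_tau"`,
#'   `"point_biserial"` or `"undefined_default"`.
#' @slot p_raw,p_adjusted numeric matrices of two-sided and BH-adjusted
#'   p-values (`NA` on the diagonal and for undefined pairs).
#' @slot stars character matrix of significance annotations from adjusted
#'   p-values: `***` < 0.001, `**` < 0.01, `*` < 0.05.
#'
#' @seealso [correlationMatrix()], [exportCorrelations()],
#'   [plotCorrelationHeatmap()]
#' @export
setClass("CorrelationMatrix",
  representation(
    variables  = "character",
    kinds      = "character",
    coef       = "matrix",
    method     = "matrix",
    p_raw      = "matrix",
    p_adjusted = "matrix",
    stars      = "matrix"
  )
)

setValidity("CorrelationMatrix", function(object) {
  p <- length(object@variables)
  for (s in c("coef", "method", "p_raw", "p_adjusted", "stars")) {
    m <- slot(object, s)
    if (!all(dim(m) == c(p, p))) return(sprintf("%s must be %d x %d", s, p, p))
  }
  if (length(object@kinds) != p) return("kinds must parallel variables")
  co <- object@coef
  if (any(abs(co[!is.na(co)]) > 1 + 1e-12))
    return("coefficients must lie in [-1, 1]")
  if (max(abs(co - t(co)), na.rm = TRUE) > 1e-12 ||
      any(is.na(co) != is.na(t(co))))
    return("coefficient matrix must be symmetric")
  pr <- object@p_raw; pa <- object@p_adjusted
  ok <- !is.na(pr) & !is.na(pa)
  if (any(pa[ok] < pr[ok] - 1e-12))
    return("adjusted p-values must be >= raw p-values")
  TRUE
})
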