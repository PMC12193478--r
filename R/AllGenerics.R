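#' Number of frames in a pose sequence
#' @param x a [PoseSequence-class] or [FootTrack-class]
#' @return integer frame count
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' Coordinates of a foot track
#' @param x a [FootTrack-class]
#' @return numeric matrix with columns `x`, `y`
#' @export
setGeneric("footCoords", function(x) standardGeneric("footCoords"))

#' Number of frames dropped by confidence filtering
#' @param x a [FootTrack-class]
#' @return integer
#' @export
setGeneric("nDropped", function(x) standardGeneric("nDropped"))

#' Displacement values of a series
#' @param x a [DisplacementSeries-class]
#' @return numeric vector of per-frame displacements (pixels)
#' @export
setGeneric("displacements", function(x) standardGeneric("displacements"))

#' PCA loadings matrix
#' @param x a [PCAIndex-class]
#' @return numeric 4 x 2 loadings matrix
#' @export
setGeneric("pcaLoadings", function(x) standardGeneric("pcaLoadings"))

#' Explained-variance ratios
#' @param x a [PCAIndex-class]
#' @return numeric length-2 vector of fractions
#' @export
setGeneric("explainedRatio", function(x) standardGeneric("explainedRatio"))

#' Per-subject component scores
#' @param x a [PCAIndex-class]
#' @return numeric n x 2 matrix (PC1, PC2)
#' @export
setGeneric("pcaScores", function(x) standardGeneric("pcaScores"))

#' Correlation coefficient matrix
#' @param x a [CorrelationMatrix-class]
#' @return numeric symmetric matrix (NA where undefined)
#' @export
setGeneric("corCoefficients", function(x) standardGeneric("corCoefficients"))

#' Correlation method used per pair
#' @param x a [CorrelationMatrix-class]
#' @return character matrix of method names
#' @export
setGeneric("corMethods", function(x) standardGeneric("corMethods"))

#' Raw two-sided p-values
#' @param x a [CorrelationMatrix-class]
#' @return numeric matrix
#' @export
setGeneric("rawPvalues", function(x) standardGeneric("rawPvalues"))

#' FDR-adjusted p-values
#' @param x a [CorrelationMatrix-class]
#' @return numeric matrix
#' @export
setGeneric("adjustedPvalues", function(x) standardGeneric("adjustedPvalues"))

#' Significance star annotations
#' @param x a [CorrelationMatrix-class]
#' @return character matrix of `""`, `"*"`, `"**"`, `"***"`
#' @export
setGeneric("starMatrix", function(x) standardGeneric("starMatrix"))
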