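## Accessor generics. Slot access from user code goes through these.

#' @rdname accessors
#' @param object an object of a LysoMorph class
#' @export
setGeneric("voxels", function(object) standardGeneric("voxels"))
#' @rdname accessors
#' @export
setGeneric("voxelSize", function(object) standardGeneric("voxelSize"))
#' @rdname accessors
#' @export
setGeneric("objectLabels", function(object) standardGeneric("objectLabels"))
#' @rdname accessors
#' @export
setGeneric("slices", function(object) standardGeneric("slices"))
#' @rdname accessors
#' @export
setGeneric("zExtent", function(object) standardGeneric("zExtent"))
#' @rdname accessors
#' @export
setGeneric("contourPoints", function(object) standardGeneric("contourPoints"))
#' @rdname accessors
#' @export
setGeneric("wasClosed", function(object) standardGeneric("wasClosed"))
#' @rdname accessors
#' @export
setGeneric("splineSamples", function(object) standardGeneric("splineSamples"))
#' @rdname accessors
#' @param deriv derivative order (0, 1 or 2)
#' @export
setGeneric("splineDerivatives",
           function(object, deriv = 1L) standardGeneric("splineDerivatives"))
#' @rdname accessors
#' @export
setGeneric("arcLength", function(object) standardGeneric("arcLength"))
#' @rdname accessors
#' @export
setGeneric("curvatureValues", function(object) standardGeneric("curvatureValues"))
#' @rdname accessors
#' @export
setGeneric("ellipseParams", function(object) standardGeneric("ellipseParams"))
#' @rdname accessors
#' @export
setGeneric("rSquared", function(object) standardGeneric("rSquared"))
#' @rdname accessors
#' @export
setGeneric("rmse", function(object) standardGeneric("rmse"))
#' @rdname accessors
#' @export
setGeneric("fitResiduals", function(object) standardGeneric("fitResiduals"))
#' @rdname accessors
#' @export
setGeneric("atoms", function(object) standardGeneric("atoms"))
#' @rdname accessors
#' @export
setGeneric("boxDims", function(object) standardGeneric("boxDims"))

#' Accessors for LysoMorph classes
#'
#' Read-only accessors for the slots of the data containers; user code
#' should use these rather than reaching into slots.
#'
#' @name accessors
#' @return the corresponding slot value.
NULL

#' @rdname accessors
#' @export
setMethod("voxels", "LabeledVolume", function(object) object@voxels)
#' @rdname accessors
#' @export
setMethod("voxelSize", "LabeledVolume", function(object) object@voxelSize)
#' @rdname accessors
#' @export
setMethod("objectLabels", "LabeledVolume", function(object) object@labels)
#' @rdname accessors
#' @export
setMethod("objectLabels", "SliceStack", function(object) object@objectLabel)
#' @rdname accessors
#' @export
setMethod("slices", "SliceStack", function(object) object@slices)
#' @rdname accessors
#' @export
setMethod("zExtent", "SliceStack", function(object) object@zExtent)
#' @rdname accessors
#' @export
setMethod("contourPoints", "SliceContour", function(object) object@points)
#' @rdname accessors
#' @export
setMethod("wasClosed", "SliceContour", function(object) object@wasClosed)
#' @rdname accessors
#' @export
setMethod("splineSamples", "SplineCurve", function(object) object@samples)
#' @rdname accessors
#' @export
setMethod("splineDerivatives", "SplineCurve", function(object, deriv = 1L) {
  switch(as.character(deriv), "0" = object@samples, "1" = object@deriv1,
         "2" = object@deriv2, stop("deriv must be 0, 1 or 2"))
})
#' @rdname accessors
#' @export
setMethod("arcLength", "SplineCurve", function(object) object@arcLengthPx)
#' @rdname accessors
#' @export
setMethod("curvatureValues", "CurvatureProfile", function(object) object@kappa)
#' @rdname accessors
#' @export
setMethod("ellipseParams", "EllipseFit", function(object) object@params)
#' @rdname accessors
#' @export
setMethod("rSquared", "EllipseFit", function(object) object@rSquared)
#' @rdname accessors
#' @export
setMethod("rmse", "EllipseFit", function(object) object@rmse)
#' @rdname accessors
#' @export
setMethod("fitResiduals", "EllipseFit", function(object) object@residuals)
#' @rdname accessors
#' @export
setMethod("atoms", "PeptideFrame", function(object) object@atoms)
#' @rdname accessors
#' @export
setMethod("boxDims", "PeptideFrame", function(object) object@box)
#' @rdname accessors
#' @export
setMethod("boxDims", "MembraneFrame", function(object) object@box)

#' Convert an EllipseParams or GroupComparison to a one-row data.frame
#'
#' @param x the object
#' @param row.names,optional,... passed through (unused)
#' @return data.frame with one row
#' @export
as.data.frame.EllipseParams <- function(x, row.names = NULL,
                                        optional = FALSE, ...) {
  data.frame(cx = x@cx, cy = x@cy, a = x@a, b = x@b, theta = x@theta)
}

#' @rdname as.data.frame.EllipseParams
#' @export
as.data.frame.GroupComparison <- function(x, row.names = NULL,
                                          optional = FALSE, ...) {
  data.frame(metric = x@metricName, n1 = x@n1, n2 = x@n2,
             normal1 = x@normal1, normal2 = x@normal2,
             test_used = x@testUsed, statistic = x@statistic,
             p_value = x@pValue, p_adjusted = x@pAdjusted,
             cohens_d = x@cohensD)
}
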