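#' @import methods
#' @importFrom stats quantile sd var rnorm runif rcauchy rlnorm median
#'   shapiro.test t.test wilcox.test p.adjust ks.test complete.cases
#' @importFrom utils write.table read.csv head tail
#' @useDynLib LysoMorph, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

## ---------------------------------------------------------------------------
## Volume containers
## ---------------------------------------------------------------------------

#' LabeledVolume: integer-labeled 3D voxel grid
#'
#' A 3D voxel grid in (z, y, x) axis order (tomography convention: slicing is
#' along z) holding non-negative integer object labels, with the physical
#' voxel edge lengths in nanometres. Label 0 is background; every positive
#' label is one segmented object (e.g. one lysosomal membrane).
#'
#' Coordinates throughout the package are 0-based with pixel centres at
#' integer coordinates.
#'
#' @slot voxels integer array, dim (nz, ny, nx).
#' @slot voxelSize numeric(3), physical voxel edge length per axis in nm,
#'   in (z, y, x) order.
#' @slot labels integer vector of positive object identifiers present in
#'   \code{voxels}.
#' @export
setClass("LabeledVolume",
  representation(voxels = "array", voxelSize = "numeric", labels = "integer"),
  validity = function(object) {
    msg <- NULL
    if (length(dim(object@voxels)) != 3L)
      msg <- c(msg, "voxels must be a 3D array (z, y, x)")
    if (any(object@voxels < 0, na.rm = TRUE))
      msg <- c(msg, "voxels must be non-negative integers")
    if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
      msg <- c(msg, "voxelSize must be three positive values (nm)")
    present <- sort(unique(as.integer(object@voxels[object@voxels > 0])))
    if (!all(object@labels %in% present))
      msg <- c(msg, "every identifier in labels must occur in voxels")
    if (is.null(msg)) TRUE else msg
  })

#' SliceStack: per-slice binary masks of one labeled object
#'
#' The slice-by-slice decomposition of a single object along z. Each entry
#' holds the 0-based z index and a logical mask (rows = y, cols = x).
#' \code{zExtent} is the inclusive span from first to last occupied z slice
#' and is the denominator of z-coverage.
#'
#' @slot objectLabel integer(1) object identifier.
#' @slot slices list of \code{list(z = <int>, mask = <logical matrix>)},
#'   z strictly increasing, each mask with >= 1 foreground pixel.
#' @slot zExtent integer(1), last - first occupied z + 1.
#' @export
setClass("SliceStack",
  representation(objectLabel = "integer", slices = "list", zExtent = "integer"),
  validity = function(object) {
    msg <- NULL
    zi <- vapply(object@slices, function(s) s$z, integer(1))
    if (length(zi) && any(diff(zi) <= 0L))
      msg <- c(msg, "z indices must be strictly increasing")
    if (length(zi) && object@zExtent < length(zi))
      msg <- c(msg, "zExtent must be >= number of slices")
    empty <- vapply(object@slices, function(s) !any(s$mask), logical(1))
    if (any(empty))
      msg <- c(msg, "every slice mask must contain >= 1 foreground pixel")
    if (is.null(msg)) TRUE else msg
  })

## ---------------------------------------------------------------------------
## Contour / spline containers
## ---------------------------------------------------------------------------

#' SliceContour: ordered centerline points of one slice
#'
#' Skeleton pixels ordered along the curve by nearest-neighbour traversal.
#' Points are 0-based (x, y) pixel coordinates; consecutive points are
#' 8-connected. A closed loop is cut open at the pixel nearest the image
#' border and flagged via \code{wasClosed} (all boundaries are treated as
#' open arcs).
#'
#' @slot zIndex integer(1), 0-based slice index.
#' @slot points numeric matrix (n x 2) of (x, y) coordinates.
#' @slot wasClosed logical(1), TRUE if the skeleton was a closed loop.
#' @export
setClass("SliceContour",
  representation(zIndex = "integer", points = "matrix", wasClosed = "logical"),
  validity = function(object) {
    msg <- NULL
    if (nrow(object@points) < 1L) msg <- c(msg, "need >= 1 point")
    if (ncol(object@points) != 2L) msg <- c(msg, "points must be n x 2")
    if (anyDuplicated(object@points)) msg <- c(msg, "no point may repeat")
    if (nrow(object@points) > 1L) {
      d <- abs(diff(object@points))
      if (any(d > 1 + 1e-9))
        msg <- c(msg, "consecutive points must be 8-connected")
    }
    if (is.null(msg)) TRUE else msg
  })

#' SplineCurve: smoothed cubic B-spline through an ordered contour
#'
#' Least-squares cubic B-spline x(t), y(t) over t in [0, 1] (chord-length
#' parameter), sampled at 200 uniformly spaced parameter values with
#' analytic first and second derivatives (never finite differences).
#' Arc length is the polyline length of the 200 samples, in pixels.
#'
#' @slot knots numeric, full knot vector (order 4).
#' @slot coef numeric matrix (ncoef x 2) of control coefficients.
#' @slot smoothingValue numeric(1), the residual-sum-of-squares target used
#'   by the automatic smoothing heuristic.
#' @slot samples numeric matrix (nSamples x 2).
#' @slot deriv1,deriv2 numeric matrices (nSamples x 2), analytic spline
#'   derivatives (x', y') and (x'', y'') at each sample.
#' @slot arcLengthPx numeric(1), pixels.
#' @export
setClass("SplineCurve",
  representation(knots = "numeric", coef = "matrix",
                 smoothingValue = "numeric", samples = "matrix",
                 deriv1 = "matrix", deriv2 = "matrix",
                 arcLengthPx = "numeric"),
  validity = function(object) {
    msg <- NULL
    n <- nrow(object@samples)
    if (nrow(object@deriv1) != n || nrow(object@deriv2) != n)
      msg <- c(msg, "derivative sample counts must match samples")
    chord <- sqrt(sum((object@samples[n, ] - object@samples[1, ])^2))
    if (object@arcLengthPx < chord - 1e-6)
      msg <- c(msg, "arc length must be >= endpoint chord")
    if (is.null(msg)) TRUE else msg
  })

#' CurvatureProfile: signed curvature along a spline
#'
#' Signed curvature kappa = (x'y'' - y'x'') / (x'^2 + y'^2)^(3/2) at each of
#' the spline samples, units 1/px; sign follows traversal orientation and is
#' therefore arbitrary for open arcs, so summaries use |kappa|.
#'
#' @slot kappa numeric, one value per sample (NA where the speed vanishes).
#' @slot absMean,absMax numeric(1) summaries of |kappa| over finite samples.
#' @export
setClass("CurvatureProfile",
  representation(kappa = "numeric", absMean = "numeric", absMax = "numeric"),
  validity = function(object) {
    if (length(object@kappa) < 1L) "kappa must be non-empty" else TRUE
  })

## ---------------------------------------------------------------------------
## Ellipse containers
## ---------------------------------------------------------------------------

#' EllipseParams: geometric parameters of a 2D ellipse
#'
#' Centre (cx, cy), semi-major axis a, semi-minor axis b (a >= b > 0) and
#' rotation angle theta of the major axis, canonicalized to [0, pi).
#' All lengths in pixels.
#'
#' @slot cx,cy,a,b,theta numeric(1).
#' @export
setClass("EllipseParams",
  representation(cx = "numeric", cy = "numeric", a = "numeric",
                 b = "numeric", theta = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (!(object@a >= object@b && object@b > 0))
      msg <- c(msg, "need a >= b > 0")
    if (object@theta < 0 || object@theta >= pi)
      msg <- c(msg, "theta must lie in [0, pi)")
    if (is.null(msg)) TRUE else msg
  })

#' EllipseFit: refined ellipse with orthogonal-residual quality metrics
#'
#' Result of the two-stage fit (direct least squares then orthogonal
#' distance regression). Residuals are signed perpendicular distances from
#' each point to the ellipse boundary (negative inside). RMSE is the root
#' mean squared residual; R^2 = 1 - sum(d_i^2) / sum(|p_i - pbar|^2),
#' i.e. residual orthogonal scatter against total point scatter about the
#' centroid.
#'
#' @slot params [EllipseParams-class].
#' @slot rSquared,rmse numeric(1).
#' @slot nPoints integer(1).
#' @slot residuals numeric, signed perpendicular distances (px).
#' @slot converged logical(1), FALSE if the refinement hit max iterations.
#' @export
setClass("EllipseFit",
  representation(params = "EllipseParams", rSquared = "numeric",
                 rmse = "numeric", nPoints = "integer",
                 residuals = "numeric", converged = "logical"),
  validity = function(object) {
    msg <- NULL
    if (object@rSquared > 1 + 1e-12) msg <- c(msg, "rSquared must be <= 1")
    rm2 <- sqrt(mean(object@residuals^2))
    if (abs(rm2 - object@rmse) > 1e-8 * max(1, rm2))
      msg <- c(msg, "rmse must equal root mean squared residual")
    if (is.null(msg)) TRUE else msg
  })

#' BootstrapCI: percentile bootstrap intervals for the semi-axes
#'
#' 95% confidence bounds (2.5th / 97.5th percentiles of the bootstrap
#' distribution) for the semi-major and semi-minor axes, from resampling
#' spline sample points with replacement and repeating the full two-stage
#' fit. Deterministic given the seed.
#'
#' @slot nBoot integer(1), number of bootstrap iterations (default 500).
#' @slot seed integer(1).
#' @slot loA,hiA,loB,hiB numeric(1), bounds in px.
#' @slot nFailed integer(1), iterations whose fit failed (skipped).
#' @slot unreliable logical(1), TRUE if more than 20% of iterations failed.
#' @export
setClass("BootstrapCI",
  representation(nBoot = "integer", seed = "integer",
                 loA = "numeric", hiA = "numeric",
                 loB = "numeric", hiB = "numeric",
                 nFailed = "integer", unreliable = "logical"),
  validity = function(object) {
    msg <- NULL
    if (object@loA > object@hiA) msg <- c(msg, "loA must be <= hiA")
    if (object@loB > object@hiB) msg <- c(msg, "loB must be <= hiB")
    if (is.null(msg)) TRUE else msg
  })

## ---------------------------------------------------------------------------
## Group statistics
## ---------------------------------------------------------------------------

#' GroupComparison: normality-gated two-sample test result
#'
#' Shapiro-Wilk normality is assessed on each group at the given alpha;
#' both normal routes to a Welch t-test, otherwise a two-sided
#' Mann-Whitney U test is used. Cohen's d (pooled SD) is always reported.
#' \code{pAdjusted} is NA until the comparison joins a
#' Benjamini-Hochberg family (see [bhAdjust()]).
#'
#' @slot metricName character(1).
#' @slot n1,n2 integer(1) group sizes.
#' @slot normal1,normal2 logical(1) Shapiro-Wilk verdicts at alpha.
#' @slot alpha numeric(1).
#' @slot testUsed character(1), "t" or "mann_whitney".
#' @slot statistic,pValue,pAdjusted,cohensD numeric(1).
#' @export
setClass("GroupComparison",
  representation(metricName = "character", n1 = "integer", n2 = "integer",
                 normal1 = "logical", normal2 = "logical", alpha = "numeric",
                 testUsed = "character", statistic = "numeric",
                 pValue = "numeric", pAdjusted = "numeric",
                 cohensD = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (!object@testUsed %in% c("t", "mann_whitney"))
      msg <- c(msg, "testUsed must be 't' or 'mann_whitney'")
    if ((object@testUsed == "t") != (object@normal1 && object@normal2))
      msg <- c(msg, "testUsed must be 't' iff both groups are normal")
    if (!is.na(object@pAdjusted) && object@pAdjusted < object@pValue - 1e-12)
      msg <- c(msg, "pAdjusted must be >= pValue")
    if (is.null(msg)) TRUE else msg
  })

## ---------------------------------------------------------------------------
## Trajectory containers
## ---------------------------------------------------------------------------

#' PeptideFrame: one frame of hexapeptide monomers in a periodic box
#'
#' Atom table of peptide monomers (positions in nm) inside an orthorhombic
#' periodic box. Roles: "N" (backbone amide nitrogen), "H" (amide
#' hydrogen), "C" (carbonyl carbon), "O" (carbonyl oxygen), "CA" or other
#' backbone names, and "side" for side-chain atoms. Residue indices are
#' 1-based within each monomer of length \code{monomerLength}.
#'
#' @slot atoms data.frame with columns monomer (int), residue (int),
#'   role (chr), x, y, z (nm), mass (numeric).
#' @slot box numeric(3), orthorhombic box edges (nm).
#' @slot time numeric(1), ns.
#' @slot monomerLength integer(1), residues per monomer (default 6).
#' @export
setClass("PeptideFrame",
  representation(atoms = "data.frame", box = "numeric", time = "numeric",
                 monomerLength = "integer"),
  validity = function(object) {
    msg <- NULL
    need <- c("monomer", "residue", "role", "x", "y", "z", "mass")
    if (!all(need %in% names(object@atoms)))
      msg <- c(msg, paste("atoms needs columns:", paste(need, collapse = ", ")))
    else {
      if (any(object@atoms$residue < 1L) ||
          any(object@atoms$residue > object@monomerLength))
        msg <- c(msg, "residue indices must lie in [1, monomerLength]")
      xyz <- as.matrix(object@atoms[, c("x", "y", "z")])
      if (!all(is.finite(xyz))) msg <- c(msg, "positions must be finite")
      nh <- with(object@atoms[object@atoms$role == "H", , drop = FALSE],
                 table(monomer, residue))
      if (length(nh) && any(nh > 1L))
        msg <- c(msg, "at most one amide H per residue")
    }
    if (length(object@box) != 3L || any(object@box <= 0))
      msg <- c(msg, "box must be three positive edge lengths (nm)")
    if (is.null(msg)) TRUE else msg
  })

#' MembraneFrame: membrane + water + protein geometry of one frame
#'
#' Minimal per-frame geometry for membrane metrics: the z coordinates of
#' all membrane phosphorus atoms (the membrane reference plane is their
#' centre of mass; an oxygen may stand in for cholesterol via role
#' tagging upstream), the z coordinates of water oxygens, and protein atom
#' positions with masses. All coordinates in nm.
#'
#' @slot phosphorusZ numeric, non-empty.
#' @slot waterZ numeric.
#' @slot proteinXyz numeric matrix (n x 3).
#' @slot proteinMass numeric, length n.
#' @slot box numeric(3) nm.
#' @slot time numeric(1) ns.
#' @export
setClass("MembraneFrame",
  representation(phosphorusZ = "numeric", waterZ = "numeric",
                 proteinXyz = "matrix", proteinMass = "numeric",
                 box = "numeric", time = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (length(object@phosphorusZ) < 1L)
      msg <- c(msg, "phosphorusZ must be non-empty for membrane metrics")
    if (nrow(object@proteinXyz) != length(object@proteinMass))
      msg <- c(msg, "proteinMass length must match proteinXyz rows")
    if (is.null(msg)) TRUE else msg
  })

## ---------------------------------------------------------------------------
## show methods
## ---------------------------------------------------------------------------

setMethod("show", "LabeledVolume", function(object) {
  d <- dim(object@voxels)
  cat("LabeledVolume:", d[3], "x", d[2], "x", d[1], "(x, y, z) voxels\n")
  cat("  voxel size (z,y,x):", paste(signif(object@voxelSize, 4),
                                     collapse = ", "), "nm\n")
  cat("  labels:", if (length(object@labels))
    paste(object@labels, collapse = ", ") else "(none)", "\n")
})

setMethod("show", "SliceStack", function(object) {
  cat("SliceStack for label", object@objectLabel, "-",
      length(object@slices), "slices, z-extent", object@zExtent, "\n")
})

setMethod("show", "SliceContour", function(object) {
  cat("SliceContour: z =", object@zIndex, ",", nrow(object@points),
      "ordered points", if (object@wasClosed) "(cut-open loop)" else
        "(open arc)", "\n")
})

setMethod("show", "SplineCurve", function(object) {
  cat("SplineCurve:", nrow(object@samples), "samples, arc length",
      round(object@arcLengthPx, 2), "px, smoothing target",
      signif(object@smoothingValue, 3), "\n")
})

setMethod("show", "EllipseParams", function(object) {
  cat(sprintf(
    "EllipseParams: centre (%.2f, %.2f), a = %.2f, b = %.2f, theta = %.3f\n",
    object@cx, object@cy, object@a, object@b, object@theta))
})

setMethod("show", "EllipseFit", function(object) {
  show(object@params)
  cat(sprintf("  n = %d, R^2 = %.4f, RMSE = %.4g px%s\n", object@nPoints,
              object@rSquared, object@rmse,
              if (object@converged) "" else " (not converged)"))
})

setMethod("show", "BootstrapCI", function(object) {
  cat(sprintf(
    "BootstrapCI (n = %d, seed = %d): a in [%.3f, %.3f], b in [%.3f, %.3f]%s\n",
    object@nBoot, object@seed, object@loA, object@hiA, object@loB,
    object@hiB, if (object@unreliable) " [unreliable]" else ""))
})

setMethod("show", "GroupComparison", function(object) {
  cat(sprintf(
    "GroupComparison '%s': %s test, n = (%d, %d), stat = %.4g, p = %.4g%s, d = %.3f\n",
    object@metricName, object@testUsed, object@n1, object@n2,
    object@statistic, object@pValue,
    if (is.na(object@pAdjusted)) "" else
      sprintf(" (adj %.4g)", object@pAdjusted),
    object@cohensD))
})

setMethod("show", "PeptideFrame", function(object) {
  cat("PeptideFrame: ", nrow(object@atoms), " atoms, ",
      length(unique(object@atoms$monomer)), " monomers of length ",
      object@monomerLength, ", t = ", object@time, " ns\n", sep = "")
})

setMethod("show", "MembraneFrame", function(object) {
  cat("MembraneFrame:", length(object@phosphorusZ), "P atoms,",
      length(object@waterZ), "water O,", nrow(object@proteinXyz),
      "protein atoms, t =", object@time, "ns\n")
})
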