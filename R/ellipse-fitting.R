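## Two-stage ellipse fitting: direct least squares (Fitzgibbon et al., in
## the numerically stable Halir-Flusser formulation) for initialization,
## then orthogonal distance regression by Levenberg-Marquardt on the exact
## perpendicular distances (C++ kernel), plus bootstrap confidence
## intervals, confidence tiering and per-object aggregation.

.conic_to_geometric <- function(A, B, C, D, E, F) {
  den <- B^2 - 4 * A * C
  if (den >= 0) stop("conic is not an ellipse (4AC - B^2 <= 0)")
  cx <- (2 * C * D - B * E) / den
  cy <- (2 * A * E - B * D) / den
  num <- 2 * (A * E^2 + C * D^2 - B * D * E + den * F)
  s <- sqrt((A - C)^2 + B^2)
  a <- -sqrt(num * (A + C + s)) / den
  b <- -sqrt(num * (A + C - s)) / den
  if (is.na(a) || is.na(b) || a <= 0 || b <= 0)
    stop("degenerate conic")
  if (a < b) { tmp <- a; a <- b; b <- tmp; swap <- TRUE } else swap <- FALSE
  ## major-axis angle: atan2(-B, C - A) / 2, i.e. atan2(B, A - C)/2 - pi/2
  theta <- atan2(B, A - C) / 2 - pi / 2
  if (swap) theta <- theta + pi / 2
  theta <- theta %% pi
  new("EllipseParams", cx = cx, cy = cy, a = a, b = b, theta = theta)
}

#' Direct least-squares ellipse fit
#'
#' Constrained conic fit (4AC - B^2 = 1) after Fitzgibbon, Pilu and Fisher,
#' computed with the stable reduced 3x3 eigen-problem of Halir and Flusser,
#' which cannot return a hyperbola or parabola. Points are centred before
#' fitting for numerical stability. The conic is converted to geometric
#' parameters with a >= b and theta canonicalized to [0, pi).
#'
#' @param points n x 2 matrix of (x, y), n >= 5, not collinear.
#' @return an [EllipseParams-class]. Degenerate inputs raise an error of
#'   class `"lysoEllipseFitFailed"`.
#' @export
fitEllipseDirect <- function(points) {
  pts <- as.matrix(points)
  if (nrow(pts) < 5L)
    .fit_fail("need >= 5 points for a conic fit")
  ctr <- colMeans(pts)
  x <- pts[, 1] - ctr[1]; y <- pts[, 2] - ctr[2]
  D1 <- cbind(x^2, x * y, y^2)
  D2 <- cbind(x, y, 1)
  S1 <- crossprod(D1); S2 <- crossprod(D1, D2); S3 <- crossprod(D2)
  Tm <- tryCatch(-solve(S3, t(S2)), error = function(e)
    .fit_fail("collinear or degenerate points"))
  M <- S1 + S2 %*% Tm
  M <- rbind(M[3, ] / 2, -M[2, ], M[1, ] / 2)
  ev <- eigen(M)
  evec <- Re(ev$vectors)
  cond <- 4 * evec[1, ] * evec[3, ] - evec[2, ]^2
  ok <- which(cond > 0)
  if (!length(ok)) .fit_fail("no ellipse solution (degenerate points)")
  a1 <- evec[, ok[1]]
  a2 <- as.numeric(Tm %*% a1)
  ## un-centre the conic
  A <- a1[1]; B <- a1[2]; C <- a1[3]
  D <- a2[1] - 2 * A * ctr[1] - B * ctr[2]
  E <- a2[2] - 2 * C * ctr[2] - B * ctr[1]
  F <- a2[3] + A * ctr[1]^2 + B * ctr[1] * ctr[2] + C * ctr[2]^2 -
    a2[1] * ctr[1] - a2[2] * ctr[2]
  tryCatch(.conic_to_geometric(A, B, C, D, E, F),
           error = function(e) .fit_fail(conditionMessage(e)))
}

.fit_fail <- function(msg) {
  stop(structure(class = c("lysoEllipseFitFailed", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' Exact distance from a point to an ellipse boundary
#'
#' Euclidean distance to the nearest boundary point, found by solving the
#' nearest-point problem in the ellipse frame (root of the standard
#' auxiliary rational function, bisected to double precision). Negative
#' inside the ellipse when `signed = TRUE`.
#'
#' @param p numeric(2) or an n x 2 matrix of points.
#' @param e an [EllipseParams-class]
#' @param signed return signed distances (negative inside)? Default FALSE.
#' @return numeric vector of distances (px).
#' @export
pointEllipseDistance <- function(p, e, signed = FALSE) {
  stopifnot(is(e, "EllipseParams"))
  pts <- if (is.null(dim(p))) matrix(p, ncol = 2) else as.matrix(p)
  d <- as.numeric(.cpp_ellipse_distances(pts,
                                         c(e@cx, e@cy, e@a, e@b, e@theta)))
  if (signed) d else abs(d)
}

#' Refine an ellipse by orthogonal distance regression
#'
#' Levenberg-Marquardt minimization of the sum of squared perpendicular
#' distances from the points to the ellipse boundary, started from the
#' direct least-squares estimate. Only objective-decreasing steps are
#' accepted, so the refined objective never exceeds the initial one.
#' Convergence: relative objective change < 1e-10 or 200 iterations
#' (non-convergence is flagged, the best iterate kept).
#'
#' R^2 is defined against orthogonal scatter: 1 - sum(d_i^2) /
#' sum(|p_i - pbar|^2).
#'
#' @param points n x 2 matrix.
#' @param init an [EllipseParams-class] initial estimate (defaults to
#'   `fitEllipseDirect(points)`).
#' @param maxIter,tol optimizer controls.
#' @return an [EllipseFit-class]
#' @export
refineEllipseODR <- function(points, init = NULL, maxIter = 200L,
                             tol = 1e-10) {
  pts <- as.matrix(points)
  if (is.null(init)) init <- fitEllipseDirect(pts)
  stopifnot(is(init, "EllipseParams"))
  res <- .cpp_ellipse_odr(pts, c(init@cx, init@cy, init@a, init@b,
                                 init@theta),
                          max_iter = as.integer(maxIter), tol = tol)
  par <- res$par
  params <- new("EllipseParams", cx = par[1], cy = par[2], a = par[3],
                b = par[4], theta = par[5])
  d <- as.numeric(res$residuals)
  tot <- sum(rowSums(sweep(pts, 2, colMeans(pts))^2))
  r2 <- if (tot > 0) 1 - sum(d^2) / tot else NA_real_
  new("EllipseFit", params = params, rSquared = r2,
      rmse = sqrt(mean(d^2)), nPoints = nrow(pts), residuals = d,
      converged = isTRUE(res$converged))
}

#' Full two-stage ellipse fit
#'
#' Convenience wrapper: direct least squares then ODR refinement.
#'
#' @inheritParams refineEllipseODR
#' @return an [EllipseFit-class]
#' @export
fitEllipse <- function(points, maxIter = 200L, tol = 1e-10) {
  refineEllipseODR(points, fitEllipseDirect(points), maxIter = maxIter,
                   tol = tol)
}

## run code with a private RNG stream, restoring global state afterwards
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Percentile bootstrap confidence intervals for the semi-axes
#'
#' Resamples the points with replacement `nBoot` times (default 500),
#' repeats the full two-stage fit on each resample, and reports the 2.5th
#' and 97.5th percentiles of the bootstrap distributions of a and b.
#' Resampling uses a fixed random seed, so the bounds are bit-identical
#' across runs with the same seed. Iterations whose fit fails are skipped
#' and counted; if more than 20% fail the interval is flagged unreliable.
#'
#' @param points n x 2 matrix on which the full fit is valid.
#' @param nBoot bootstrap iterations (default 500).
#' @param seed RNG seed (default 42).
#' @return a [BootstrapCI-class]
#' @export
bootstrapEllipseCI <- function(points, nBoot = 500L, seed = 42L) {
  pts <- as.matrix(points)
  n <- nrow(pts)
  idx <- .with_seed(seed,
                    matrix(sample.int(n, n * nBoot, replace = TRUE),
                           nrow = nBoot))
  ab <- matrix(NA_real_, nBoot, 2)
  for (i in seq_len(nBoot)) {
    fit <- tryCatch(fitEllipse(pts[idx[i, ], , drop = FALSE]),
                    error = function(e) NULL)
    if (!is.null(fit))
      ab[i, ] <- c(fit@params@a, fit@params@b)
  }
  ok <- complete.cases(ab)
  nfail <- sum(!ok)
  if (!any(ok)) stop("all bootstrap iterations failed")
  qa <- quantile(ab[ok, 1], c(0.025, 0.975), names = FALSE)
  qb <- quantile(ab[ok, 2], c(0.025, 0.975), names = FALSE)
  new("BootstrapCI", nBoot = as.integer(nBoot), seed = as.integer(seed),
      loA = qa[1], hiA = qa[2], loB = qb[1], hiB = qb[2],
      nFailed = as.integer(nfail), unreliable = nfail > 0.2 * nBoot)
}

#' Classify ellipsoid fit confidence
#'
#' High when R^2 > 0.5 and z-coverage > 70%; Medium when R^2 > 0.3 and
#' z-coverage > 50%; Low otherwise. Thresholds are strict (>) exactly as
#' stated.
#'
#' @param rSquared fit R^2 (<= 1).
#' @param zCoverage fraction in [0, 1] of the object's z-extent with valid
#'   slice data.
#' @return "High", "Medium" or "Low"
#' @export
classifyConfidence <- function(rSquared, zCoverage) {
  stopifnot(rSquared <= 1, zCoverage >= 0, zCoverage <= 1)
  if (rSquared > 0.5 && zCoverage > 0.7) "High"
  else if (rSquared > 0.3 && zCoverage > 0.5) "Medium"
  else "Low"
}

#' Aggregate per-slice ellipse fits into a per-object summary
#'
#' Mean ellipse area over retained slices (pi * a * b, converted to nm^2
#' via the in-plane voxel size), mean perimeter (spline arc length, nm),
#' equivalent diameter 2 * sqrt(mean_area / pi) (the diameter of the circle
#' with the mean cross-sectional area), z-coverage (retained slices over
#' z-extent) and the confidence tier from mean slice R^2 and z-coverage.
#' In-plane pixels are assumed isotropic; the y-voxel size is used and the
#' assumption recorded in the output.
#'
#' @param sliceTable data.frame with one row per retained slice fit,
#'   columns `a`, `b` (px), `arc_length_px`, `r_squared`.
#' @param zExtent integer z-extent of the object (inclusive slice span).
#' @param voxelSizeNm numeric(3) voxel size (z, y, x) in nm, or one value.
#' @param objectLabel identifier carried into the output.
#' @param excludeLow if TRUE and the tier is Low, the summary row is
#'   flagged `excluded = TRUE` (measurements from low-confidence fits can
#'   be excluded from statistical comparisons).
#' @return one-row data.frame (the per-object summary).
#' @export
summarizeObject <- function(sliceTable, zExtent, voxelSizeNm = 1,
                            objectLabel = NA_integer_, excludeLow = FALSE) {
  if (nrow(sliceTable) < 1L)
    stop("no valid slice fits: object dropped")
  if (length(voxelSizeNm) == 1L) voxelSizeNm <- rep(voxelSizeNm, 3)
  px <- voxelSizeNm[2]  # in-plane pixel size (isotropic in-plane assumed)
  nValid <- nrow(sliceTable)
  zCov <- min(nValid / zExtent, 1)
  meanArea <- mean(pi * sliceTable$a * sliceTable$b) * px^2
  meanPerim <- mean(sliceTable$arc_length_px) * px
  meanR2 <- mean(sliceTable$r_squared)
  tier <- classifyConfidence(min(meanR2, 1), zCov)
  data.frame(object_label = objectLabel, n_valid_slices = nValid,
             z_extent = zExtent, z_coverage = zCov, mean_r2 = meanR2,
             mean_rmse_px = if ("rmse_px" %in% names(sliceTable))
               mean(sliceTable$rmse_px) else NA_real_,
             mean_ellipse_area_nm2 = meanArea,
             mean_perimeter_nm = meanPerim,
             equivalent_diameter_nm = 2 * sqrt(meanArea / pi),
             confidence = tier,
             excluded = excludeLow && tier == "Low",
             inplane_isotropic_assumed = TRUE)
}
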