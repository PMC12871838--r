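## Slice mask -> ordered centerline -> smoothed cubic B-spline -> analytic
## curvature and basic shape metrics.

## ---------------------------------------------------------------------------
## Morphological thinning (Zhang-Suen)
## ---------------------------------------------------------------------------

.shift <- function(m, dy, dx) {
  ## neighbour image: value of m at (row+dy, col+dx), zero-padded
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0L, nr, nc)
  rs <- max(1, 1 + dy):min(nr, nr + dy)
  cs <- max(1, 1 + dx):min(nc, nc + dx)
  out[rs - dy, cs - dx] <- m[rs, cs]
  out
}

#' Thin a binary mask to a single-pixel-wide centerline
#'
#' Zhang-Suen iterative morphological thinning. The output is a subset of
#' the input foreground, unit-width (no foreground pixel retains a full
#' 3x3 foreground neighbourhood), and preserves the topology of each
#' connected component; closed thin loops survive as closed loops.
#'
#' @param mask logical or 0/1 matrix (rows = y, cols = x).
#' @return integer 0/1 matrix of the same shape. An empty input yields an
#'   empty output with attribute `empty = TRUE`.
#' @export
skeletonizeSlice <- function(mask) {
  m <- matrix(as.integer(mask != 0), nrow(mask), ncol(mask))
  if (!any(m == 1L)) {
    attr(m, "empty") <- TRUE
    return(m)
  }
  repeat {
    changed <- FALSE
    for (pass in 1:2) {
      ## neighbours P2..P9 clockwise from north; rows = y (north = row - 1)
      p2 <- .shift(m, -1, 0);  p3 <- .shift(m, -1, 1)
      p4 <- .shift(m, 0, 1);   p5 <- .shift(m, 1, 1)
      p6 <- .shift(m, 1, 0);   p7 <- .shift(m, 1, -1)
      p8 <- .shift(m, 0, -1);  p9 <- .shift(m, -1, -1)
      b <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      a <- (p2 == 0 & p3 == 1) + (p3 == 0 & p4 == 1) + (p4 == 0 & p5 == 1) +
           (p5 == 0 & p6 == 1) + (p6 == 0 & p7 == 1) + (p7 == 0 & p8 == 1) +
           (p8 == 0 & p9 == 1) + (p9 == 0 & p2 == 1)
      if (pass == 1) {
        cond <- m == 1L & b >= 2 & b <= 6 & a == 1 &
          (p2 * p4 * p6 == 0) & (p4 * p6 * p8 == 0)
      } else {
        cond <- m == 1L & b >= 2 & b <= 6 & a == 1 &
          (p2 * p4 * p8 == 0) & (p2 * p6 * p8 == 0)
      }
      if (any(cond)) {
        m[cond] <- 0L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m
}

## ---------------------------------------------------------------------------
## Skeleton ordering
## ---------------------------------------------------------------------------

.skeleton_graph <- function(coords) {
  ## coords: n x 2 matrix of (x, y); edges between 8-neighbours, weighted by
  ## Euclidean step length so geodesics measure path length in pixels.
  n <- nrow(coords)
  if (n == 1L)
    return(igraph::make_empty_graph(1, directed = FALSE))
  key <- coords[, 1] * 1e6 + coords[, 2]
  idx <- seq_len(n)
  from <- integer(0); to <- integer(0); w <- numeric(0)
  offs <- cbind(dx = c(1, 1, 0, -1), dy = c(0, 1, 1, 1))  # half-neighbourhood
  for (k in seq_len(nrow(offs))) {
    nk <- (coords[, 1] + offs[k, 1]) * 1e6 + (coords[, 2] + offs[k, 2])
    hit <- match(nk, key)
    sel <- !is.na(hit)
    from <- c(from, idx[sel]); to <- c(to, hit[sel])
    w <- c(w, rep(sqrt(sum(offs[k, ]^2)), sum(sel)))
  }
  g <- igraph::make_graph(rbind(from, to), n = n, directed = FALSE)
  igraph::E(g)$weight <- w
  g
}

.border_distance <- function(coords, imageShape) {
  ## imageShape = c(nrow, ncol); coords are 0-based (x, y)
  h <- imageShape[1]; w <- imageShape[2]
  pmin(coords[, 1], w - 1 - coords[, 1], coords[, 2], h - 1 - coords[, 2])
}

#' Order skeleton pixels along the curve
#'
#' Orders the pixels of a unit-width skeleton by nearest-neighbour traversal
#' starting from a detected end-point, choosing among end-points the one
#' nearest the image border (field-of-view clipped arcs start at the
#' border). If the skeleton has no end-point (closed loop), the loop is cut
#' at the pixel nearest the border and flagged: all boundaries are treated
#' as open arcs. Junction skeletons are reduced to their longest geodesic
#' (end-point to end-point) path, which drops short spurs; skeletons with
#' more than one connected component keep the largest, with a warning.
#'
#' @param skel 0/1 matrix from [skeletonizeSlice()].
#' @param zIndex 0-based slice index stored on the result.
#' @return a [SliceContour-class]
#' @export
orderSkeletonPoints <- function(skel, zIndex = 0L) {
  fg <- which(skel != 0, arr.ind = TRUE)        # (row, col) = (y+1, x+1)
  if (nrow(fg) == 0L) stop("empty skeleton")
  coords <- cbind(x = fg[, 2] - 1, y = fg[, 1] - 1)
  if (nrow(coords) == 1L)
    return(new("SliceContour", zIndex = as.integer(zIndex),
               points = unname(coords), wasClosed = FALSE))
  g <- .skeleton_graph(coords)
  comp <- igraph::components(g)
  if (comp$no > 1L) {
    warning("skeleton has ", comp$no,
            " connected components; keeping the largest")
    keepc <- which(comp$membership == which.max(comp$csize))
    coords <- coords[keepc, , drop = FALSE]
    g <- .skeleton_graph(coords)
  }
  deg <- igraph::degree(g)
  shape <- dim(skel)
  bd <- .border_distance(coords, shape)
  if (any(deg == 1L)) {
    ends <- which(deg == 1L)
    if (length(ends) >= 2L) {
      ## longest geodesic among end-point pairs is the centerline
      dmat <- igraph::distances(g, v = ends, to = ends)
      ij <- which(dmat == max(dmat), arr.ind = TRUE)[1, ]
      v1 <- ends[ij[1]]; v2 <- ends[ij[2]]
    } else {
      ## a single end-point (corner triangles absorb the other): walk to
      ## the geodesically farthest pixel
      v1 <- ends[1]
      dvec <- igraph::distances(g, v = v1)[1, ]
      v2 <- which.max(dvec)
    }
    if (bd[v2] < bd[v1]) { tmp <- v1; v1 <- v2; v2 <- tmp }
    path <- igraph::shortest_paths(g, from = v1, to = v2,
                                   output = "vpath")$vpath[[1]]
    ord <- as.integer(path)
    closed <- FALSE
  } else {
    ## closed loop: cut at the pixel nearest the border, then traverse by
    ## greedy nearest-neighbour steps (robust to redundant staircase
    ## pixels that create local 3-cycles in the adjacency graph)
    s <- which.min(bd)
    adj <- lapply(igraph::adjacent_vertices(g, seq_len(nrow(coords))),
                  as.integer)
    visited <- logical(nrow(coords))
    ord <- integer(nrow(coords))
    cur <- s
    k <- 0L
    repeat {
      k <- k + 1L
      ord[k] <- cur
      visited[cur] <- TRUE
      cand <- adj[[cur]][!visited[adj[[cur]]]]
      if (!length(cand)) break
      d <- (coords[cand, 1] - coords[cur, 1])^2 +
        (coords[cand, 2] - coords[cur, 2])^2
      cur <- cand[which.min(d)]
    }
    ord <- ord[seq_len(k)]
    closed <- TRUE
  }
  new("SliceContour", zIndex = as.integer(zIndex),
      points = unname(coords[ord, , drop = FALSE]), wasClosed = closed)
}

## ---------------------------------------------------------------------------
## Spline fitting
## ---------------------------------------------------------------------------

.auto_smoothing <- function(pts) {
  ## FITPACK-style residual target s = (m - sqrt(2 m)) * sigma^2. The
  ## per-point noise variance sigma^2 is estimated from fourth-order
  ## differences e_i = p_{i-2} - 4 p_{i-1} + 6 p_i - 4 p_{i+1} + p_{i+2},
  ## which annihilate cubics (a smooth arc contributes only O(h^4)) while
  ## iid noise contributes Var(e) = 70 sigma^2 per coordinate. Noise-free
  ## contours therefore get a near-zero target and a tight fit.
  m <- nrow(pts)
  if (m < 5L) return(0)
  e <- pts[1:(m - 4), , drop = FALSE] - 4 * pts[2:(m - 3), , drop = FALSE] +
    6 * pts[3:(m - 2), , drop = FALSE] - 4 * pts[4:(m - 1), , drop = FALSE] +
    pts[5:m, , drop = FALSE]
  ## per-point squared Euclidean noise (both coordinates)
  sigma2 <- mean(rowSums(e^2)) / 70
  max(m - sqrt(2 * m), 0) * sigma2
}

#' Fit a smoothed cubic B-spline to an ordered contour
#'
#' Least-squares cubic B-spline over a chord-length parameter in [0, 1],
#' with the number of uniformly placed interior knots grown until the
#' residual sum of squares drops below an automatically estimated
#' smoothing target based on point density (see Details), then sampled at
#' `nSamples` uniformly spaced parameter values with analytic first and
#' second derivatives. Arc length is the polyline length of the samples.
#'
#' @details The smoothing target is s = (m - sqrt(2m)) * sigma^2 where m is
#' the number of contour points and sigma^2 is a local-roughness estimate
#' of the per-point noise variance (second-difference based); for
#' noise-free points the target is ~0 and the fit tightens until it tracks
#' the curve. The value used is recorded in the `smoothingValue` slot.
#'
#' @param contour a [SliceContour-class] (or an n x 2 point matrix).
#' @param nSamples number of uniform parameter samples (default 200).
#' @param smoothing optional explicit residual-sum-of-squares target
#'   overriding the automatic estimate.
#' @return a [SplineCurve-class]. Contours with fewer than 4 distinct
#'   points are rejected with an error of class `"lysoContourTooShort"`.
#' @export
fitContourSpline <- function(contour, nSamples = 200L, smoothing = NULL) {
  pts <- if (is(contour, "SliceContour")) contourPoints(contour) else
    as.matrix(contour)
  pts <- pts[!duplicated(pts), , drop = FALSE]
  m <- nrow(pts)
  if (m < 4L)
    stop(structure(class = c("lysoContourTooShort", "error", "condition"),
                   list(message = paste0("contour too short for a cubic ",
                                         "spline (", m, " < 4 points)"),
                        call = sys.call(-1))))
  seg <- sqrt(rowSums(diff(pts)^2))
  tt <- c(0, cumsum(seg)) / sum(seg)
  s <- if (is.null(smoothing)) .auto_smoothing(pts) else smoothing
  max_int <- max(0L, min(m - 4L, 120L))
  ## essentially noise-free data: use a dense knot set sized by the point
  ## count alone (two points per coefficient keeps the least-squares
  ## problem well conditioned and the choice symmetric under traversal
  ## reversal); noisy data instead grow knots until the residual target
  nk <- if (s <= 1e-8 * m) min(m %/% 2L, max_int) else 0L
  try_fit <- function(nk) {
    interior <- if (nk > 0) seq(0, 1, length.out = nk + 2L)[-c(1L, nk + 2L)]
      else numeric(0)
    knots <- c(rep(0, 4), interior, rep(1, 4))
    B <- splines::splineDesign(knots, tt, ord = 4L)
    cf <- tryCatch(qr.coef(qr(B), pts), error = function(e) NULL)
    if (is.null(cf) || anyNA(cf)) return(NULL)  # Schoenberg-Whitney violated
    list(knots = knots, coef = cf, rss = sum((B %*% cf - pts)^2))
  }
  ## if the initial knot set is unsupported by the parameter values, back
  ## off until the design is well-posed
  fit <- try_fit(nk)
  while (is.null(fit) && nk > 0L) {
    nk <- nk %/% 2L
    fit <- try_fit(nk)
  }
  if (is.null(fit)) stop("spline fitting failed")
  while (fit$rss > max(s, 1e-10 * m) && nk < max_int) {
    nk <- if (nk == 0L) 1L else min(2L * nk, max_int)
    nxt <- try_fit(nk)
    if (is.null(nxt)) break
    fit <- nxt
  }
  ts <- seq(0, 1, length.out = nSamples)
  S <- splines::splineDesign(fit$knots, ts, ord = 4L) %*% fit$coef
  D1 <- splines::splineDesign(fit$knots, ts, ord = 4L,
                              derivs = rep(1L, nSamples)) %*% fit$coef
  D2 <- splines::splineDesign(fit$knots, ts, ord = 4L,
                              derivs = rep(2L, nSamples)) %*% fit$coef
  arc <- sum(sqrt(rowSums(diff(S)^2)))
  new("SplineCurve", knots = fit$knots, coef = unname(fit$coef),
      smoothingValue = s, samples = unname(S), deriv1 = unname(D1),
      deriv2 = unname(D2), arcLengthPx = arc)
}

## ---------------------------------------------------------------------------
## Curvature and shape metrics
## ---------------------------------------------------------------------------

#' Signed curvature along a spline
#'
#' Evaluates kappa = (x'y'' - y'x'') / (x'^2 + y'^2)^(3/2) at every spline
#' sample from the analytic derivatives. Samples with vanishing speed are
#' reported as NA rather than infinite. The sign follows the traversal
#' orientation (reversing the contour flips it globally), so summary
#' statistics use |kappa|.
#'
#' @param spline a [SplineCurve-class]
#' @return a [CurvatureProfile-class]
#' @export
signedCurvature <- function(spline) {
  stopifnot(is(spline, "SplineCurve"))
  d1 <- splineDerivatives(spline, 1L)
  d2 <- splineDerivatives(spline, 2L)
  speed2 <- rowSums(d1^2)
  kap <- (d1[, 1] * d2[, 2] - d1[, 2] * d2[, 1]) / speed2^1.5
  kap[speed2 <= .Machine$double.eps] <- NA_real_
  ak <- abs(kap[is.finite(kap)])
  new("CurvatureProfile", kappa = kap,
      absMean = if (length(ak)) mean(ak) else NA_real_,
      absMax = if (length(ak)) max(ak) else NA_real_)
}

#' Basic shape metrics of a fitted slice spline
#'
#' Perimeter (the spline arc length), axis-aligned bounding box over the
#' samples with aspect ratio (long/short >= 1; Inf for degenerate boxes),
#' and centroid as the mean of the spline sample points. All in pixels.
#'
#' @param spline a [SplineCurve-class]
#' @return data.frame with columns perimeter_px, bbox_w, bbox_h,
#'   aspect_ratio, centroid_x, centroid_y.
#' @export
sliceShapeMetrics <- function(spline) {
  stopifnot(is(spline, "SplineCurve"))
  S <- splineSamples(spline)
  w <- diff(range(S[, 1])); h <- diff(range(S[, 2]))
  long <- max(w, h); short <- min(w, h)
  data.frame(perimeter_px = arcLength(spline), bbox_w = w, bbox_h = h,
             aspect_ratio = if (short > 0) long / short else Inf,
             centroid_x = mean(S[, 1]), centroid_y = mean(S[, 2]))
}

#' Arc-length retention filter
#'
#' Spline fits with arc lengths below `minArcPx` pixels are excluded from
#' downstream analysis ("below" read strictly: exactly `minArcPx` is
#' retained).
#'
#' @param spline a [SplineCurve-class]
#' @param minArcPx threshold in pixels (default 50).
#' @param strict if TRUE (default) the boundary value is retained
#'   (arc >= threshold); if FALSE the boundary is excluded too.
#' @return logical(1)
#' @export
passesLengthFilter <- function(spline, minArcPx = 50, strict = TRUE) {
  if (strict) arcLength(spline) >= minArcPx else arcLength(spline) > minArcPx
}
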