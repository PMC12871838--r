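test_that("thinning produces unit-width, topology-preserving skeletons", {
  ## 3-px-wide bar thins to a 1-px line along its axis
  m <- matrix(0L, 20, 20); m[9:11, 3:18] <- 1L
  s <- skeletonizeSlice(m)
  expect_true(all(s[m == 0L] == 0L))              # subset of foreground
  expect_identical(unique(which(s == 1L, arr.ind = TRUE)[, 1]), 10L)
  ## no pixel keeps a full 3x3 neighbourhood
  nb <- Reduce(`+`, lapply(list(c(-1, 0), c(-1, 1), c(0, 1), c(1, 1),
                                c(1, 0), c(1, -1), c(0, -1), c(-1, -1)),
                           function(o) LysoMorph:::.shift(s, o[1], o[2])))
  expect_true(all(nb[s == 1L] < 8))

  ## annulus thins to a closed loop: every pixel has >= 2 neighbours
  ann <- genAnnulusMask(c(41, 41), 20, 20, 14.5)
  sa <- skeletonizeSlice(ann)
  nba <- Reduce(`+`, lapply(list(c(-1, 0), c(-1, 1), c(0, 1), c(1, 1),
                                 c(1, 0), c(1, -1), c(0, -1), c(-1, -1)),
                            function(o) LysoMorph:::.shift(sa, o[1], o[2])))
  expect_true(all(nba[sa == 1L] >= 2))

  ## single isolated pixel is its own skeleton
  one <- matrix(0L, 5, 5); one[3, 3] <- 1L
  expect_identical(skeletonizeSlice(one), one)

  ## empty mask flagged
  expect_true(isTRUE(attr(skeletonizeSlice(matrix(0L, 4, 4)), "empty")))
})

test_that("thinning is idempotent", {
  set.seed(11)
  for (i in 1:5) {
    blob <- genAnnulusMask(c(30, 30), runif(1, 12, 18), runif(1, 12, 18),
                           runif(1, 6, 9), hw = runif(1, 1, 2.5))
    s1 <- skeletonizeSlice(blob)
    s2 <- skeletonizeSlice(s1)
    attr(s1, "empty") <- NULL; attr(s2, "empty") <- NULL
    expect_identical(s2, s1)
  }
})

test_that("skeleton ordering follows the curve and honours endpoints", {
  ## L-shaped path: consecutive points 8-adjacent, endpoints degree 1
  m <- matrix(0L, 12, 12)
  m[3, 3:8] <- 1L
  m[4:8, 8] <- 1L
  ct <- orderSkeletonPoints(m)
  P <- contourPoints(ct)
  ## the ordering runs tip to tip (the 90-degree corner pixel may be cut
  ## diagonally), every consecutive pair 8-adjacent
  expect_gte(nrow(P), 10L)
  expect_true(all(abs(diff(P)) <= 1))
  expect_false(wasClosed(ct))
  expect_setequal(paste(P[c(1, nrow(P)), 1], P[c(1, nrow(P)), 2]),
                  c("2 2", "7 7"))
  ## matches the brute-force shortest Hamiltonian path length
  expect_equal(polylineLength(P), heldKarpShortestPath(P))

  ## closed unit ring: all ring pixels appear, flagged as cut-open
  ring <- genUnitRing(c(25, 25), 12, 12, 8)
  ctr <- orderSkeletonPoints(ring)
  expect_true(wasClosed(ctr))
  expect_identical(nrow(contourPoints(ctr)), sum(ring))
  expect_true(all(abs(diff(contourPoints(ctr))) <= 1))

  ## single pixel
  one <- matrix(0L, 5, 5); one[3, 3] <- 1L
  expect_identical(nrow(contourPoints(orderSkeletonPoints(one))), 1L)

  ## two components: largest kept, warning emitted
  two <- matrix(0L, 12, 12)
  two[2, 2:8] <- 1L; two[10, 2:3] <- 1L
  expect_warning(ct2 <- orderSkeletonPoints(two), "components")
  expect_identical(nrow(contourPoints(ct2)), 7L)
})

test_that("ordering matches the Hamiltonian-path oracle on small paths", {
  set.seed(21)
  for (i in 1:8) {
    ## random monotone staircase path of <= 10 px
    n <- sample(5:10, 1)
    steps <- cbind(sample(c(0, 1), n - 1, TRUE), sample(c(0, 1), n - 1, TRUE))
    steps[rowSums(steps) == 0, 1] <- 1
    P <- apply(rbind(c(2, 2), steps), 2, cumsum)
    m <- matrix(0L, 15, 15)
    m[P[, 2:1] + 1] <- 1L
    ct <- orderSkeletonPoints(m)
    expect_equal(polylineLength(contourPoints(ct)),
                 heldKarpShortestPath(contourPoints(ct)), tolerance = 1e-9)
  }
})

test_that("spline arc lengths match analytic values", {
  ## straight 100 px segment
  sp <- fitContourSpline(cbind(0:100, 0))
  expect_equal(arcLength(sp), 100, tolerance = 0.5 / 100)
  expect_identical(nrow(splineSamples(sp)), 200L)

  ## half turn of a circle of radius 20
  t <- seq(0, pi, length.out = 70)
  sph <- fitContourSpline(cbind(20 * cos(t), 20 * sin(t)))
  expect_equal(arcLength(sph), 20 * pi, tolerance = 0.02 * 20 * pi)

  ## 3-point contour rejected with a reason class
  expect_error(fitContourSpline(cbind(c(0, 1, 2), c(0, 0, 0))),
               class = "lysoContourTooShort")
})

test_that("analytic curvature matches circle, line and ellipse vertices", {
  ## straight line: |kappa| ~ 0 everywhere
  spl <- fitContourSpline(cbind(seq(0, 80, 0.5), 0))
  expect_lt(max(abs(curvatureValues(signedCurvature(spl)))), 1e-6)

  ## circle arcs: |kappa| = 1/R within 2% away from the ends
  for (R in c(12, 30)) {
    P <- genEllipsePoints(200, a = R, b = R)
    k <- curvatureValues(signedCurvature(fitContourSpline(P)))
    expect_lt(max(abs(abs(k[10:190]) * R - 1)), 0.02)
  }

  ## ellipse vertex: |kappa| = a/b^2 at the major-axis vertex
  P <- genEllipsePoints(200, a = 30, b = 15, span = c(-pi / 3, pi / 3))
  sp <- fitContourSpline(P)
  k <- curvatureValues(signedCurvature(sp))
  vertex <- which.min(abs(splineSamples(sp)[, 1] - 30) +
                        abs(splineSamples(sp)[, 2]))
  expect_equal(abs(k[vertex]), 30 / 15^2, tolerance = 0.05)
})

test_that("curvature sign flips under reversal; |kappa| is equivariant", {
  P <- genEllipsePoints(150, cx = 3, cy = -2, a = 25, b = 12, theta = 0.4,
                        span = c(0.2, 4.5))
  k1 <- curvatureValues(signedCurvature(fitContourSpline(P)))
  k2 <- curvatureValues(signedCurvature(fitContourSpline(P[150:1, ])))
  expect_equal(k1, -rev(k2), tolerance = 1e-6)

  ## rotating the input by 90 degrees preserves arc length and |kappa|
  P90 <- cbind(-P[, 2], P[, 1])
  s1 <- fitContourSpline(P); s2 <- fitContourSpline(P90)
  expect_equal(arcLength(s2), arcLength(s1), tolerance = 0.01)
  expect_equal(abs(curvatureValues(signedCurvature(s2))),
               abs(curvatureValues(signedCurvature(s1))),
               tolerance = 0.01)
})

test_that("shape metrics and the arc-length filter behave as specified", {
  ## axis-aligned straight segment (0,0) -> (10,0)
  sp <- fitContourSpline(cbind(seq(0, 10, length.out = 21), 0))
  m <- sliceShapeMetrics(sp)
  expect_equal(m$bbox_w, 10, tolerance = 1e-6)
  expect_equal(m$bbox_h, 0, tolerance = 1e-6)
  expect_equal(c(m$centroid_x, m$centroid_y), c(5, 0), tolerance = 1e-6)

  ## full circle radius 10 cut open: bbox ~ 20 x 20, aspect ~ 1
  spc <- fitContourSpline(genEllipsePoints(150, a = 10, b = 10))
  mc <- sliceShapeMetrics(spc)
  expect_equal(c(mc$bbox_w, mc$bbox_h), c(20, 20), tolerance = 0.05)
  expect_equal(mc$aspect_ratio, 1, tolerance = 0.01)

  ## half circle radius 10: centroid offset ~ 2R/pi from the centre
  sph <- fitContourSpline(genEllipsePoints(120, a = 10, b = 10,
                                           span = c(0, pi)))
  mh <- sliceShapeMetrics(sph)
  expect_equal(mh$centroid_y, 2 * 10 / pi, tolerance = 0.05 * 20 / pi)

  ## strict arc-length boundary: 49 out, 50 and 200 in
  short <- fitContourSpline(cbind(seq(0, 49, length.out = 50), 0))
  long <- fitContourSpline(cbind(seq(0, 200, length.out = 100), 0))
  expect_false(passesLengthFilter(short))
  expect_true(passesLengthFilter(long))
  ## boundary semantics probed with an exact stored arc length
  exact <- short
  exact@arcLengthPx <- 50
  expect_true(passesLengthFilter(exact))
  expect_false(passesLengthFilter(exact, strict = FALSE))
})
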