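test_that("direct fit recovers exact ellipses and degenerates cleanly", {
  ## noise-free recovery to near machine precision
  e <- fitEllipseDirect(genEllipsePoints(200, 50, 40, 30, 15, 0.5))
  expect_equal(c(e@cx, e@cy, e@a, e@b, e@theta), c(50, 40, 30, 15, 0.5),
               tolerance = 1e-6)

  ## circle: a = b, theta canonical
  ec <- fitEllipseDirect(genEllipsePoints(100, a = 10, b = 10))
  expect_equal(c(ec@a, ec@b), c(10, 10), tolerance = 1e-6)
  expect_true(ec@theta >= 0 && ec@theta < pi)

  ## collinear points fail with the fit-failure class
  expect_error(fitEllipseDirect(cbind(1:10, 2 * (1:10))),
               class = "lysoEllipseFitFailed")
  expect_error(fitEllipseDirect(cbind(1:4, 1)), class = "lysoEllipseFitFailed")
})

test_that("direct fit agrees with an independent null-space conic solve", {
  ## oracle: exact on-conic points make the design matrix
  ## D = [x^2, xy, y^2, x, y, 1] rank-deficient; its null vector (smallest
  ## right singular vector) is the conic, recovered with no use of the
  ## constrained scatter-matrix machinery under test
  oracle_conic <- function(P) {
    x <- P[, 1]; y <- P[, 2]
    D <- cbind(x^2, x * y, y^2, x, y, 1)
    v <- svd(D, nv = 6)$v[, 6]
    v / sqrt(sum(v^2))
  }
  set.seed(33)
  for (n in c(5, 6, 8, 40)) {
    a <- runif(1, 10, 50); b <- a * runif(1, 0.4, 0.9)
    th <- runif(1, 0, pi)
    P <- genEllipsePoints(n, 4, -5, a, b, th, span = c(0.1, 2 * pi * 0.9))
    e <- fitEllipseDirect(P)
    co <- oracle_conic(P)
    eo <- LysoMorph:::.conic_to_geometric(co[1], co[2], co[3], co[4],
                                          co[5], co[6])
    expect_equal(c(e@a, e@b), c(eo@a, eo@b), tolerance = 1e-5)
    expect_equal(c(e@a, e@b), c(a, b), tolerance = 1e-5)
    ## residual algebraic distance of the 5-point fit is ~ 0
    alg <- cbind(P[, 1]^2, P[, 1] * P[, 2], P[, 2]^2, P, 1) %*% co
    if (n == 5) expect_lt(max(abs(alg)), 1e-6)
  }
})

test_that("ODR refinement attains noise-level RMSE and never worsens", {
  ## exact points: essentially zero residual
  P <- genEllipsePoints(200, 5, -3, 28, 14, 1.1)
  f <- fitEllipse(P)
  expect_lt(rmse(f), 1e-8)
  expect_gt(rSquared(f), 0.9999)
  expect_true(f@converged)

  ## isotropic noise sigma = 0.5: RMSE ~ sigma within 20%
  set.seed(7)
  Pn <- genEllipsePoints(200, 5, -3, 28, 14, 1.1, sd = 0.5)
  fn <- fitEllipse(Pn)
  expect_equal(rmse(fn), 0.5, tolerance = 0.2)

  ## half-arc open contour: parameters within 5%
  set.seed(8)
  Ph <- genEllipsePoints(200, 50, 40, 30, 15, 0.5,
                         span = c(0.4, 0.4 + pi), sd = 0.2)
  fh <- fitEllipse(Ph)
  expect_equal(fh@params@a, 30, tolerance = 0.05)
  expect_equal(fh@params@b, 15, tolerance = 0.05)

  ## two-stage consistency: the refined objective never exceeds the
  ## direct-fit objective
  for (seed in 1:5) {
    set.seed(seed)
    Q <- genEllipsePoints(120, 0, 0, runif(1, 15, 40), runif(1, 8, 15),
                          runif(1, 0, pi), span = c(0, 4.5), sd = 0.5)
    init <- fitEllipseDirect(Q)
    d0 <- sum(pointEllipseDistance(Q, init)^2)
    fit <- refineEllipseODR(Q, init)
    expect_lte(sum(fitResiduals(fit)^2), d0 + 1e-9)
  }
})

test_that("point-to-ellipse distance matches a dense boundary polyline", {
  e <- new("EllipseParams", cx = 1, cy = 2, a = 5, b = 2, theta = 0.3)
  B <- genEllipsePoints(1e5, 1, 2, 5, 2, 0.3)
  set.seed(9)
  for (i in 1:10) {
    p <- runif(2, -8, 10)
    dense <- min(sqrt((B[, 1] - p[1])^2 + (B[, 2] - p[2])^2))
    expect_equal(pointEllipseDistance(p, e), dense, tolerance = 1e-4)
  }
  ## centre of a circle and boundary point
  circ <- new("EllipseParams", cx = 0, cy = 0, a = 7, b = 7, theta = 0)
  expect_equal(pointEllipseDistance(c(0, 0), circ), 7)
  expect_equal(pointEllipseDistance(c(7, 0), circ), 0, tolerance = 1e-10)
  ## signed: inside negative
  expect_lt(pointEllipseDistance(c(1, 0), circ, signed = TRUE), 0)
})

test_that("fits are equivariant under rigid motion", {
  set.seed(10)
  P <- genEllipsePoints(150, 0, 0, 26, 13, 0.2, span = c(0, 5))
  f0 <- fitEllipse(P)
  ang <- 0.77; dxy <- c(12, -8)
  Rm <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2)
  f1 <- fitEllipse(sweep(P %*% t(Rm), 2, dxy, "+"))
  expect_equal(f1@params@a, f0@params@a, tolerance = 1e-6)
  expect_equal(f1@params@b, f0@params@b, tolerance = 1e-6)
  expect_equal(rmse(f1), rmse(f0), tolerance = 1e-6)
  expect_equal(rSquared(f1), rSquared(f0), tolerance = 1e-6)
  c0 <- Rm %*% c(f0@params@cx, f0@params@cy) + dxy
  expect_equal(c(f1@params@cx, f1@params@cy), as.numeric(c0),
               tolerance = 1e-6)
  expect_equal((f1@params@theta - f0@params@theta) %% pi, ang %% pi,
               tolerance = 1e-6)
})

test_that("bootstrap CIs are deterministic, tight for clean data, and bracket the fit", {
  P <- genEllipsePoints(200, 0, 0, 30, 18, 0.9)
  ci1 <- bootstrapEllipseCI(P, nBoot = 100, seed = 42)
  ci2 <- bootstrapEllipseCI(P, nBoot = 100, seed = 42)
  expect_identical(c(ci1@loA, ci1@hiA, ci1@loB, ci1@hiB),
                   c(ci2@loA, ci2@hiA, ci2@loB, ci2@hiB))
  ## noise-free: degenerate bootstrap, width < 1e-4
  expect_lt(ci1@hiA - ci1@loA, 1e-4)
  expect_lt(ci1@hiB - ci1@loB, 1e-4)

  ## noisy: point estimate inside the interval
  set.seed(12)
  Pn <- genEllipsePoints(200, 0, 0, 30, 18, 0.9, sd = 0.5)
  fit <- fitEllipse(Pn)
  ci <- bootstrapEllipseCI(Pn, nBoot = 200, seed = 1)
  expect_true(ci@loA <= fit@params@a && fit@params@a <= ci@hiA)
  expect_true(ci@loB <= fit@params@b && fit@params@b <= ci@hiB)
  expect_false(ci@unreliable)
})

test_that("confidence tiers follow the strict threshold table", {
  expect_identical(classifyConfidence(0.6, 0.8), "High")
  expect_identical(classifyConfidence(0.4, 0.6), "Medium")
  expect_identical(classifyConfidence(0.6, 0.6), "Medium")
  expect_identical(classifyConfidence(0.2, 0.9), "Low")
  ## boundaries are strict
  expect_identical(classifyConfidence(0.5, 0.8), "Medium")
  expect_identical(classifyConfidence(0.6, 0.7), "Medium")
  expect_identical(classifyConfidence(0.3, 0.6), "Low")
})

test_that("object summaries match analytic ellipsoid cross-sections", {
  ## sphere: mean disc area = (2/3) pi R^2, so equivalent diameter < 2R
  R <- 30
  z <- seq(-R + 0.5, R - 0.5, by = 1)
  r <- sqrt(R^2 - z^2)
  tab <- data.frame(a = r, b = r, arc_length_px = 2 * pi * r,
                    r_squared = 0.999)
  s <- summarizeObject(tab, zExtent = length(z), voxelSizeNm = 1,
                       objectLabel = 1L)
  expect_equal(s$mean_ellipse_area_nm2, 2 / 3 * pi * R^2, tolerance = 0.01)
  expect_lt(s$equivalent_diameter_nm, 2 * R)
  expect_identical(s$confidence, "High")
  expect_equal(s$z_coverage, 1)

  ## single valid slice over z-extent 10: coverage 0.1, tier Low
  one <- data.frame(a = 10, b = 8, arc_length_px = 60, r_squared = 0.9)
  s1 <- summarizeObject(one, zExtent = 10L, voxelSizeNm = 1)
  expect_equal(s1$z_coverage, 0.1)
  expect_identical(s1$confidence, "Low")

  ## voxel size scales areas quadratically and perimeters linearly
  s2 <- summarizeObject(one, zExtent = 10L, voxelSizeNm = 2)
  expect_equal(s2$mean_ellipse_area_nm2, 4 * s1$mean_ellipse_area_nm2)
  expect_equal(s2$mean_perimeter_nm, 2 * s1$mean_perimeter_nm)

  expect_error(summarizeObject(one[0, ], 10L), "dropped")
})

test_that("parameter recovery on random noisy arcs meets the 3% median bound", {
  set.seed(50)
  rel <- t(replicate(50, {
    a <- runif(1, 10, 60); b <- a * runif(1, 0.3, 1)
    th <- runif(1, 0, pi)
    frac <- runif(1, 0.5, 1)
    start <- runif(1, 0, 2 * pi)
    P <- genEllipsePoints(200, runif(1, -5, 5), runif(1, -5, 5), a, b, th,
                          span = c(start, start + frac * 2 * pi), sd = 0.5)
    f <- tryCatch(fitEllipse(P), error = function(e) NULL)
    if (is.null(f)) c(NA, NA) else
      c(abs(f@params@a - a) / a, abs(f@params@b - b) / b)
  }))
  expect_lt(median(rel[, 1], na.rm = TRUE), 0.03)
  expect_lt(median(rel[, 2], na.rm = TRUE), 0.03)
})
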