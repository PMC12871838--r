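test_that("DSSP energies match direct evaluation of the formula", {
  ## near-linear N-H...O=C at r_ON = 2.9 Angstrom: strong bond
  N <- c(0, 2.9, 0); H <- c(0, 1.9, 0)
  O <- c(0, 0, 0); C <- c(0, -1.23, 0)
  E <- ksEnergy(N, H, C, O)
  expect_lt(E, -0.5)
  at <- data.frame(
    monomer = c(1, 1, 2, 2, 2), residue = c(1, 1, 2, 2, 2),
    role = c("C", "O", "N", "H", "C"),
    x = c(C[1], O[1], N[1], H[1], 5) / 10,
    y = c(C[2], O[2], N[2], H[2], 5) / 10,
    z = c(C[3], O[3], N[3], H[3], 5) / 10, mass = 12)
  fr <- PeptideFrame(at, box = c(10, 10, 10), monomerLength = 6L)
  hb <- detectBackboneHbonds(fr)
  expect_identical(nrow(hb), 1L)
  expect_equal(hb$energy, E, tolerance = 1e-9)

  ## displaced to r_ON = 6 Angstrom: |E| < 0.5, rejected
  at2 <- at
  at2$y[3:4] <- at2$y[3:4] + (6 - 2.9) / 10
  fr2 <- PeptideFrame(at2, box = c(10, 10, 10), monomerLength = 6L)
  expect_identical(nrow(detectBackboneHbonds(fr2)), 0L)
  E2 <- ksEnergy(N + c(0, 3.1, 0), H + c(0, 3.1, 0), C, O)
  expect_lt(abs(E2), 0.5)

  ## a single extended monomer has no inter-monomer bonds
  iso <- makeIdealBetaSheet("parallel", 2)$frame
  solo <- iso
  solo@atoms <- solo@atoms[solo@atoms$monomer == 1, ]
  hb3 <- detectBackboneHbonds(solo)
  expect_identical(sum(hb3$donor_monomer != hb3$acceptor_monomer), 0L)
})

test_that("H-bond detection honours the minimum-image convention", {
  sheet <- makeIdealBetaSheet("parallel", 2)
  hb0 <- detectBackboneHbonds(sheet$frame)
  ## translate the whole system: invariant
  fr <- sheet$frame
  fr@atoms$x <- fr@atoms$x + 1.3
  fr@atoms$z <- fr@atoms$z - 0.7
  expect_equal(detectBackboneHbonds(fr)$energy, hb0$energy,
               tolerance = 1e-9)
  ## wrap one monomer by a whole box vector: invariant under minimum image
  fr2 <- sheet$frame
  sel <- fr2@atoms$monomer == 2
  fr2@atoms$y[sel] <- fr2@atoms$y[sel] + boxDims(fr2)[2]
  hb2 <- detectBackboneHbonds(fr2)
  expect_equal(hb2$energy, hb0$energy, tolerance = 1e-9)
})

test_that("registry classification matches exhaustive enumeration", {
  expect_identical(classifyRegistry(3, 2), "parallel")
  expect_identical(classifyRegistry(2, 5, L = 6), "antiparallel")
  expect_identical(classifyRegistry(4, 3, L = 6), "excluded_ambiguous")
  expect_identical(classifyRegistry(2, 2, sameMonomer = TRUE), "other")

  for (L in 2:8) {
    for (i in seq_len(L)) for (j in seq_len(L)) {
      got <- classifyRegistry(i, j, FALSE, L)
      isPar <- j == i - 1
      isAnti <- j == L + 1 - i
      want <- if (isPar && isAnti) "excluded_ambiguous"
        else if (isPar) "parallel"
        else if (isAnti) "antiparallel" else "other"
      expect_identical(got, want)
    }
  }
})

test_that("admissible pairing counts match brute-force enumeration", {
  expect_identical(countAdmissiblePairings(6),
                   c(parallel = 4L, antiparallel = 5L))
  for (L in 1:8) {
    grid <- expand.grid(i = seq_len(L), j = seq_len(L))
    cls <- mapply(classifyRegistry, grid$i, grid$j,
                  MoreArgs = list(sameMonomer = FALSE, L = L))
    valid_par <- sum(cls == "parallel" & grid$j == grid$i - 1)
    ## the degenerate same-index pairing (odd L) is excluded alongside
    ## the ambiguous one
    valid_anti <- sum(cls == "antiparallel" & grid$j == L + 1 - grid$i &
                        grid$j != grid$i)
    got <- countAdmissiblePairings(L)
    expect_identical(unname(got["parallel"]), as.integer(valid_par))
    expect_identical(unname(got["antiparallel"]), as.integer(valid_anti))
  }
})

test_that("parallel fraction follows the closed form and its monotonicity", {
  expect_equal(parallelFraction(0, 0), 0)
  expect_equal(parallelFraction(4, 0), 0.8)
  expect_equal(parallelFraction(0, 5), 0)
  expect_equal(parallelFraction(10, 5), 10 / (10 + 0.8 * 5 + 1))
  expect_error(parallelFraction(-1, 0), "non-negative")

  ## strictly increasing in n_p, decreasing in n_ap, bounded in [0, 1)
  np <- 0:40
  expect_true(all(diff(parallelFraction(np, 7)) > 0))
  expect_true(all(diff(parallelFraction(5, np)) < 0))
  f <- parallelFraction(rep(np, each = 41), rep(np, times = 41))
  expect_true(all(f >= 0 & f < 1))
})

test_that("trajectory unwrapping removes box jumps and rigid motion", {
  sheet <- makeIdealBetaSheet("parallel", 3)
  fr <- sheet$frame
  traj <- list(fr, fr, fr)
  for (i in 2:3) traj[[i]]@time <- i - 1
  ## artificial +Lx jump in frames 2..3
  Lx <- boxDims(fr)[1]
  for (i in 2:3) traj[[i]]@atoms$x <- traj[[i]]@atoms$x + Lx
  un <- unwrapAndAlign(traj, align = FALSE)
  steps <- vapply(2:3, function(i)
    max(abs(as.matrix(atoms(un[[i]])[, c("x", "y", "z")]) -
              as.matrix(atoms(un[[i - 1]])[, c("x", "y", "z")]))),
    numeric(1))
  expect_true(all(steps < Lx / 2))

  ## identity trajectory: alignment leaves coordinates unchanged
  al <- unwrapAndAlign(list(fr, fr))
  expect_equal(atoms(al[[2]])$x, atoms(fr)$x, tolerance = 1e-9)

  ## rigidly rotated copies (about the centroid, displacements below half
  ## the box) align back to the reference within 1e-6 nm
  ang <- 0.9
  fr2 <- fr
  mx <- mean(atoms(fr)$x); my <- mean(atoms(fr)$y)
  dx <- atoms(fr)$x - mx; dy <- atoms(fr)$y - my
  fr2@atoms$x <- mx + cos(ang) * dx - sin(ang) * dy + 0.5
  fr2@atoms$y <- my + sin(ang) * dx + cos(ang) * dy - 0.2
  fr2@time <- 1
  al2 <- unwrapAndAlign(list(fr, fr2))
  expect_lt(max(abs(as.matrix(atoms(al2[[2]])[, c("x", "y", "z")]) -
                      as.matrix(atoms(fr)[, c("x", "y", "z")]))), 1e-6)

  bad <- fr; bad@atoms <- bad@atoms[-1, ]
  expect_error(unwrapAndAlign(list(fr, bad)), "mismatch")
})

test_that("backbone RMSD matches closed forms", {
  sheet <- makeIdealBetaSheet("antiparallel", 2)
  fr <- sheet$frame
  expect_equal(backboneRmsd(list(fr), fr)$rmsd_nm, 0)

  ## uniform displacement d (alignment disabled): RMSD = d
  fr2 <- fr; fr2@atoms$x <- fr2@atoms$x + 0.37; fr2@time <- 1
  r <- backboneRmsd(list(fr, fr2), fr)
  expect_equal(r$rmsd_nm, c(0, 0.37), tolerance = 1e-9)

  ## isotropic Gaussian perturbation: RMSD ~ sigma * sqrt(3)
  set.seed(3)
  big <- do.call(rbind, replicate(14, atoms(fr), simplify = FALSE))
  big$monomer <- rep(seq_len(28), each = nrow(atoms(fr)) / 2)
  frB <- PeptideFrame(big, box = boxDims(fr), monomerLength = 6L)
  sigma <- 0.1
  frP <- frB
  n <- nrow(big)
  frP@atoms$x <- frP@atoms$x + rnorm(n, sd = sigma)
  frP@atoms$y <- frP@atoms$y + rnorm(n, sd = sigma)
  frP@atoms$z <- frP@atoms$z + rnorm(n, sd = sigma)
  expect_equal(backboneRmsd(list(frP), frB)$rmsd_nm, sigma * sqrt(3),
               tolerance = 0.1)

  ## exclusion hook removes monomers from the selection
  r2 <- backboneRmsd(list(frP), frB, excludeMonomers = 1:27)
  expect_true(is.finite(r2$rmsd_nm))
  expect_error(backboneRmsd(list(frB), frB, excludeMonomers = 1:28),
               "empty")
})

test_that("insertion depth and pore-water counts equal constructed truth", {
  ## hand-computed CoM: equal-mass atoms at z = 0 and 4, P CoM at 1
  fr <- MembraneFrame(phosphorusZ = c(0.5, 1.5),
                      proteinXyz = rbind(c(0, 0, 0), c(0, 0, 4)),
                      proteinMass = c(1, 1))
  expect_equal(insertionDepth(fr), 1)

  mb <- makeMembraneFrame(100, 5, 7, 13, seed = 21)
  expect_identical(poreWaterCount(mb$frame), 7L)
  expect_equal(insertionDepth(mb$frame), 0, tolerance = 0.35)

  ## protein shifted +2 nm
  fr2 <- mb$frame
  fr2@proteinXyz[, 3] <- fr2@proteinXyz[, 3] + 2
  expect_equal(insertionDepth(fr2), insertionDepth(mb$frame) + 2)

  ## no waters; boundary water exactly at +0.5 nm is counted (closed)
  none <- MembraneFrame(phosphorusZ = c(4, 6), waterZ = numeric(0),
                        proteinXyz = rbind(c(0, 0, 5)))
  expect_identical(poreWaterCount(none), 0L)
  edge <- MembraneFrame(phosphorusZ = c(4, 6), waterZ = c(5.5, 5.5001),
                        proteinXyz = rbind(c(0, 0, 5)))
  expect_identical(poreWaterCount(edge), 1L)

  ## rigid z-translation of the whole frame leaves the count unchanged
  sh <- MembraneFrame(phosphorusZ = mb$frame@phosphorusZ + 1,
                      waterZ = mb$frame@waterZ + 1,
                      proteinXyz = mb$frame@proteinXyz)
  expect_identical(poreWaterCount(sh), 7L)
})

test_that("sheet-order series recovers constructed registry truth", {
  par <- makeIdealBetaSheet("parallel", 2)
  traj <- lapply(0:4, function(t) { f <- par$frame; f@time <- t * 10; f })
  ser <- computeSheetOrderSeries(traj, strideNs = 10)
  expect_identical(nrow(ser), 5L)
  expect_true(all(ser$n_p == 4 & ser$n_ap == 0))
  expect_true(all(ser$f_p == 0.8))

  anti <- makeIdealBetaSheet("antiparallel", 2)
  serA <- computeSheetOrderSeries(list(anti$frame), strideNs = 10)
  expect_identical(c(serA$n_p, serA$n_ap), c(0L, 5L))
  expect_equal(serA$f_p, 0)

  ## mixed interfaces: counts are additive over the pure cases
  mix <- makeIdealBetaSheet("mixed", 3)
  serM <- computeSheetOrderSeries(list(mix$frame), strideNs = 10)
  expect_identical(c(serM$n_p, serM$n_ap), c(4L, 5L))
  expect_equal(serM$f_p, parallelFraction(4, 5))

  ## stride larger than the trajectory: single-frame series
  ser1 <- computeSheetOrderSeries(traj[1:3], strideNs = 1000)
  expect_identical(nrow(ser1), 1L)
})

test_that("PDB and CSV round trips preserve geometry and H-bond truth", {
  sheet <- makeIdealBetaSheet("parallel", 2)
  path <- withr::local_tempfile(fileext = ".pdb")
  writePeptidePDB(sheet$frame, path)
  back <- readPeptidePDB(path, box = boxDims(sheet$frame))
  hb <- detectBackboneHbonds(back)
  expect_identical(nrow(hb), 4L)
  expect_true(all(hb$registry_class == "parallel"))

  ## CSV trajectory round trip
  at <- atoms(sheet$frame)
  csv <- withr::local_tempfile(fileext = ".csv")
  d <- rbind(cbind(time_ns = 0, at), cbind(time_ns = 10, at))
  write.csv(d, csv, row.names = FALSE)
  traj <- readPeptideFramesCsv(csv, box = boxDims(sheet$frame))
  expect_length(traj, 2)
  expect_equal(atoms(traj[[1]])$x, at$x)
  ser <- computeSheetOrderSeries(traj, strideNs = 10)
  expect_identical(ser$n_p, c(4L, 4L))
})
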