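## Ground-truthed synthetic inputs for every pipeline stage: voxelized
## ellipsoidal membrane shells, ideal beta-sheet backbones, membrane
## slabs with placed water oxygens, blob images with known puncta, and
## group samples with analytic effect sizes. Every generator is
## deterministic given its seed and carries a truth record sufficient to
## compute the expected pipeline output without re-deriving geometry.

#' Voxelized ellipsoidal membrane shell with per-slice analytic truth
#'
#' Builds a hollow ellipsoidal shell (a membrane, not a filled body) on a
#' voxel grid: a voxel is foreground when the approximate signed Euclidean
#' distance of its centre to the ellipsoid surface is within half the
#' shell thickness. Cross-sections perpendicular to z are ellipses with
#' semi-axes a(z) = a sqrt(1 - ((z - cz)/c)^2), b(z) likewise, recorded
#' analytically in the truth table before any degradation is applied.
#' Optional degradations (after truth recording): Gaussian boundary
#' jitter, salt-and-pepper voxel flips, and angular clipping that removes
#' a wedge of each slice contour to force open arcs (emulating
#' field-of-view clipping).
#'
#' Orientation is a single in-plane rotation about z, which keeps the
#' slice truth analytic (cross-sections stay ellipses with the same
#' semi-axes, rotated by theta).
#'
#' @param semiAxes numeric(3) ellipsoid semi-axes (a, b, c) in px with
#'   a >= b >= c; c is along z.
#' @param shellThickness shell thickness in px (>= 1).
#' @param voxelSizeNm physical voxel size (nm, isotropic).
#' @param theta in-plane rotation (radians).
#' @param jitterSd boundary jitter SD in px (default 0).
#' @param saltPepper voxel flip rate (default 0).
#' @param clipFraction fraction of each slice contour removed as an
#'   angular wedge, in [0, 1) (default 0).
#' @param seed RNG seed; output is deterministic per seed.
#' @param margin empty border around the shell (px).
#' @return list(volume = [LabeledVolume-class], truth = data.frame with
#'   columns z, a_px, b_px, cx, cy, theta, area_px2, and spec = the
#'   generating parameters).
#' @export
makeEllipsoidShellVolume <- function(semiAxes = c(40, 30, 20),
                                     shellThickness = 2,
                                     voxelSizeNm = 1, theta = 0,
                                     jitterSd = 0, saltPepper = 0,
                                     clipFraction = 0, seed = 1L,
                                     margin = 4L) {
  a <- semiAxes[1]; b <- semiAxes[2]; c3 <- semiAxes[3]
  stopifnot(a >= b, b >= c3, clipFraction >= 0, clipFraction < 1)
  if (shellThickness < 1)
    stop("shell thinner than 1 voxel")
  if (c3 <= shellThickness / 2)
    stop("ellipsoid semi-axes must exceed half the shell thickness")
  nx <- 2L * ceiling(a + shellThickness) + 2L * margin + 1L
  ny <- 2L * ceiling(b + shellThickness) + 2L * margin + 1L
  nz <- 2L * ceiling(c3 + shellThickness) + 2L * margin + 1L
  cx <- (nx - 1) / 2; cy <- (ny - 1) / 2; cz <- (nz - 1) / 2
  xs <- (0:(nx - 1)) - cx
  ys <- (0:(ny - 1)) - cy
  zs <- (0:(nz - 1)) - cz
  ## grids in (z, y, x) order
  X <- array(rep(xs, each = nz * ny), c(nz, ny, nx))
  Y <- array(rep(rep(ys, each = nz), nx), c(nz, ny, nx))
  Z <- array(rep(zs, ny * nx), c(nz, ny, nx))
  ct <- cos(theta); st <- sin(theta)
  U <- ct * X + st * Y
  V <- -st * X + ct * Y
  m <- sqrt((U / a)^2 + (V / b)^2 + (Z / c3)^2)
  gm <- sqrt((U / a^2)^2 + (V / b^2)^2 + (Z / c3^2)^2) / pmax(m, 1e-9)
  dist <- (m - 1) / pmax(gm, 1e-9)     # approx signed distance (px)
  .with_seed(seed, {
    if (jitterSd > 0)
      dist <- dist + array(rnorm(length(dist), sd = jitterSd), dim(dist))
    fg <- abs(dist) <= shellThickness / 2
    if (clipFraction > 0) {
      ang <- (atan2(V, U) + pi) / (2 * pi)          # in [0, 1)
      starts <- runif(nz)                            # wedge start per slice
      s <- array(rep(starts, ny * nx), c(nz, ny, nx))
      inWedge <- ((ang - s) %% 1) < clipFraction
      fg <- fg & !inWedge
    }
    if (saltPepper > 0) {
      flip <- array(runif(length(fg)) < saltPepper, dim(fg))
      fg <- xor(fg, flip)
    }
  })
  vol <- array(0L, c(nz, ny, nx))
  vol[fg] <- 1L
  zIdx <- which(abs(zs) < c3)
  rz <- sqrt(pmax(1 - (zs[zIdx] / c3)^2, 0))
  truth <- data.frame(z = zIdx - 1L, a_px = a * rz, b_px = b * rz,
                      cx = cx, cy = cy, theta = theta,
                      area_px2 = pi * a * rz * b * rz)
  list(volume = LabeledVolume(vol, voxelSizeNm), truth = truth,
       spec = list(semiAxes = semiAxes, shellThickness = shellThickness,
                   voxelSizeNm = voxelSizeNm, theta = theta,
                   jitterSd = jitterSd, saltPepper = saltPepper,
                   clipFraction = clipFraction, seed = seed,
                   center = c(z = cz, y = cy, x = cx)))
}

## ---------------------------------------------------------------------------
## Ideal beta-sheet builder
## ---------------------------------------------------------------------------

## Residue x offset (Angstrom) along the strand axis for residue i of a
## monomer in the given direction (+1 forward, -1 reversed).
.strand_x <- function(i, L, dir, rise = 3.4) {
  if (dir > 0) i * rise else (L + 1 - i) * rise
}

#' Ideal beta-sheet backbone geometry with known H-bond truth
#'
#' Places hexapeptide (or length-L) backbone monomers on an idealized
#' beta-strand lattice (3.4 Angstrom rise per residue, 4.8 Angstrom
#' inter-strand spacing) such that exactly the registry-admissible
#' donor/acceptor pairs of each monomer interface satisfy the DSSP
#' hydrogen-bond criterion and no unintended pair does. Amide N-H groups
#' of intended donors point toward the acceptor strand (r_ON = 2.9
#' Angstrom, near-linear N-H...O); all other N-H and C=O groups are
#' rotated out of plane so they cannot bond. The ambiguous pairing
#' (donor 4 to acceptor 3 for L = 6) is deliberately not built, so
#' detection recovers exactly the enumerated admissible sets.
#'
#' Arrangements: "parallel" (all strands same direction), "antiparallel"
#' (alternating), "mixed" (interfaces alternate parallel, antiparallel,
#' ...). The truth record lists every intended (donor, acceptor) pair with
#' its registry class.
#'
#' @param arrangement "parallel", "antiparallel" or "mixed".
#' @param nMonomers number of strands (>= 2).
#' @param L residues per monomer (default 6).
#' @param registerOffset shift of the parallel register (default 0, the
#'   in-register geometry; non-zero offsets build out-of-register sheets
#'   whose bonds classify as "other").
#' @param box box edges in nm (default 10 x 10 x 10).
#' @return list(frame = [PeptideFrame-class], truth = data.frame of
#'   intended pairs: donor_monomer, donor_residue, acceptor_monomer,
#'   acceptor_residue, registry_class).
#' @export
makeIdealBetaSheet <- function(arrangement = c("parallel", "antiparallel",
                                               "mixed"),
                               nMonomers = 2L, L = 6L, registerOffset = 0L,
                               box = c(10, 10, 10)) {
  arrangement <- match.arg(arrangement)
  stopifnot(nMonomers >= 2L)
  ## strand directions: +1 forward, -1 reversed
  dirs <- rep(1L, nMonomers)
  if (arrangement == "antiparallel")
    dirs <- rep_len(c(1L, -1L), nMonomers)
  if (arrangement == "mixed") {
    ## interfaces alternate parallel, antiparallel, parallel, ...
    for (k in 2:nMonomers) {
      parInterface <- (k %% 2L) == 0L
      dirs[k] <- if (parInterface) dirs[k - 1L] else -dirs[k - 1L]
    }
  }
  spacing <- 4.8
  rise <- 3.4
  ## per-strand x shifts putting each interface's donor/acceptor pairs in
  ## register: a parallel interface needs strand k shifted one rise against
  ## its neighbour (the i -> i-1 registry), an antiparallel one none.
  shifts <- numeric(nMonomers)
  for (k in 2:nMonomers) {
    par <- dirs[k] == dirs[k - 1L]
    shifts[k] <- if (par)
      shifts[k - 1L] - rise * dirs[k] * (1 + registerOffset)
    else shifts[k - 1L] + rise * registerOffset * dirs[k]
  }
  ## intended pairs per interface (donor in monomer k, acceptor in k-1)
  truth <- NULL
  intendedDonor <- matrix(FALSE, nMonomers, L)   # H points toward k-1
  intendedAcceptor <- matrix(FALSE, nMonomers, L) # O points toward k+1
  for (k in 2:nMonomers) {
    par <- dirs[k] == dirs[k - 1L]
    for (i in seq_len(L)) {
      j <- if (par) i - 1L - registerOffset else L + 1L - i - registerOffset
      if (j < 1L || j > L) next
      cls <- classifyRegistry(i, j, FALSE, L)
      if (cls == "excluded_ambiguous") next
      if (registerOffset == 0L && par && cls != "parallel") next
      if (registerOffset == 0L && !par && cls != "antiparallel") next
      ## with the register shifts every admissible pair aligns in x
      xi <- .strand_x(i, L, dirs[k]) + shifts[k]
      xj <- .strand_x(j, L, dirs[k - 1L]) + shifts[k - 1L]
      if (abs(xi - xj) > 1e-6) next
      intendedDonor[k, i] <- TRUE
      intendedAcceptor[k - 1L, j] <- TRUE
      truth <- rbind(truth, data.frame(
        donor_monomer = k, donor_residue = i,
        acceptor_monomer = k - 1L, acceptor_residue = j,
        registry_class = cls))
    }
  }
  ## build atoms (Angstrom, converted to nm at the end)
  rows <- vector("list", nMonomers * L * 5L)
  ri <- 0L
  for (m in seq_len(nMonomers)) {
    y0 <- m * spacing
    for (i in seq_len(L)) {
      x0 <- .strand_x(i, L, dirs[m]) + shifts[m]
      Npos <- c(x0, y0, 0)
      Hdir <- if (intendedDonor[m, i]) c(0, -1, 0) else c(0, 0, 1)
      Hpos <- Npos + 1.0 * Hdir
      CApos <- c(x0 + 1.2, y0, 0.6)
      Cpos <- c(x0 + 1.7, y0 + 0.67, 0)   # carbonyl carbon
      Odir <- if (intendedAcceptor[m, i]) c(0, 1, 0) else c(0, 0, -1)
      Opos <- c(Cpos[1], y0, 0) + 1.9 * Odir + c(0, 0, 0)
      ## place C 1.23 Angstrom from O against the O direction
      Cpos <- Opos - 1.23 * Odir
      ## keep x of O/C aligned with the residue's own x so the intended
      ## donor (same x) sees r_ON = 2.9 exactly
      Opos[1] <- x0; Cpos[1] <- x0
      for (atom in list(list("N", Npos, 14.007), list("H", Hpos, 1.008),
                        list("CA", CApos, 12.011), list("C", Cpos, 12.011),
                        list("O", Opos, 15.999))) {
        ri <- ri + 1L
        rows[[ri]] <- data.frame(monomer = m, residue = i,
                                 role = atom[[1]],
                                 x = atom[[2]][1] / 10,
                                 y = atom[[2]][2] / 10,
                                 z = atom[[2]][3] / 10,
                                 mass = atom[[3]])
      }
    }
  }
  at <- do.call(rbind, rows[seq_len(ri)])
  ## centre the sheet inside the box
  for (k in c("x", "y", "z"))
    at[[k]] <- at[[k]] - mean(range(at[[k]])) + box[match(k, c("x", "y", "z"))] / 2
  frame <- PeptideFrame(at, box = box, time = 0, monomerLength = L)
  if (is.null(truth))
    truth <- data.frame(donor_monomer = integer(0),
                        donor_residue = integer(0),
                        acceptor_monomer = integer(0),
                        acceptor_residue = integer(0),
                        registry_class = character(0))
  list(frame = frame, truth = truth)
}

#' Membrane slab frame with a known pore-water count
#'
#' Phosphorus z coordinates are placed symmetrically about `slabZ` (so
#' their centre of mass is exactly `slabZ`); exactly `nWatersInside`
#' water oxygens fall within `halfWidth` of `slabZ` and the rest strictly
#' outside. A small protein cluster is placed at `proteinZ`.
#'
#' @param nPhosphorus number of phosphorus atoms (>= 2).
#' @param slabZ membrane mid-plane z (nm).
#' @param nWatersInside,nWatersOutside water counts.
#' @param box box edges (nm).
#' @param halfWidth slab half width (nm, default 0.5).
#' @param nProtein number of protein atoms (default 10).
#' @param proteinZ protein centre z (default `slabZ`).
#' @param seed RNG seed.
#' @return list(frame = [MembraneFrame-class], truth = list with the
#'   placed counts and geometry).
#' @export
makeMembraneFrame <- function(nPhosphorus = 100L, slabZ = 5,
                              nWatersInside = 7L, nWatersOutside = 13L,
                              box = c(10, 10, 12), halfWidth = 0.5,
                              nProtein = 10L, proteinZ = slabZ,
                              seed = 1L) {
  stopifnot(nPhosphorus >= 2L, nWatersInside >= 0L, nWatersOutside >= 0L)
  if (box[3] < 2 * (halfWidth + 2.2))
    stop("box too small for inside/outside water placement")
  .with_seed(seed, {
    half <- floor(nPhosphorus / 2)
    off <- runif(half, 1.6, 2.0)           # leaflet offsets
    pz <- c(slabZ + off, slabZ - off)
    if (nPhosphorus %% 2L == 1L) pz <- c(pz, slabZ)
    wIn <- if (nWatersInside > 0)
      slabZ + runif(nWatersInside, -0.95, 0.95) * halfWidth else numeric(0)
    wOut <- if (nWatersOutside > 0)
      slabZ + sample(c(-1, 1), nWatersOutside, replace = TRUE) *
        runif(nWatersOutside, halfWidth + 0.55, halfWidth + 2.05)
      else numeric(0)
    prot <- cbind(runif(nProtein, 0, box[1]), runif(nProtein, 0, box[2]),
                  proteinZ + runif(nProtein, -0.3, 0.3))
  })
  frame <- MembraneFrame(phosphorusZ = pz, waterZ = c(wIn, wOut),
                         proteinXyz = prot, box = box, time = 0)
  list(frame = frame,
       truth = list(nWatersInside = nWatersInside,
                    nWatersOutside = nWatersOutside, slabZ = slabZ,
                    halfWidth = halfWidth))
}

## compact blob of exactly `area` pixels: pixels of a disc ordered by
## distance from the centre, first `area` taken
.blob_pixels <- function(area) {
  r <- ceiling(sqrt(area / pi)) + 2L
  g <- expand.grid(dy = -r:r, dx = -r:r)
  d <- g$dy^2 + g$dx^2
  o <- order(d, g$dy, g$dx)
  g[o[seq_len(area)], , drop = FALSE]
}

#' Blob image with known per-cell puncta counts
#'
#' Places connected blobs of exactly the requested pixel areas inside
#' rectangular cell masks laid out side by side, with enough separation
#' that no two blobs merge under 8-connectivity. The truth count per cell
#' is the number of its blobs with area strictly greater than 15 px.
#'
#' @param blobAreas list with one numeric vector of blob areas per cell.
#' @param cellSize c(height, width) of each rectangular cell mask.
#' @param intensity blob intensity (background 0).
#' @param seed RNG seed for placement.
#' @param maxTries placement retries before failing.
#' @return list(image, masks, truth = data.frame(cell_id, n_puncta)).
#' @export
makePunctaImage <- function(blobAreas, cellSize = c(64L, 64L),
                            intensity = 100, seed = 1L, maxTries = 200L) {
  if (!is.list(blobAreas)) blobAreas <- list(blobAreas)
  K <- length(blobAreas)
  h <- cellSize[1]; w <- cellSize[2]
  img <- matrix(0, h, K * w)
  masks <- matrix(0L, h, K * w)
  occupied <- matrix(FALSE, h, K * w)
  .with_seed(seed, {
    for (cell in seq_len(K)) {
      masks[, ((cell - 1L) * w + 1L):(cell * w)] <- cell
      for (area in blobAreas[[cell]]) {
        px <- .blob_pixels(area)
        placed <- FALSE
        for (try in seq_len(maxTries)) {
          r0 <- sample(seq(8L, h - 8L), 1)
          c0 <- (cell - 1L) * w + sample(seq(8L, w - 8L), 1)
          rr <- r0 + px$dy; cc <- c0 + px$dx
          if (any(rr < 1 | rr > h | cc <= (cell - 1L) * w |
                  cc > cell * w)) next
          ## 1-px guard ring so blobs stay 8-disconnected
          guard <- FALSE
          for (dy in -1:1) for (dx in -1:1) {
            ir <- pmin(pmax(rr + dy, 1), h)
            ic <- pmin(pmax(cc + dx, 1), K * w)
            if (any(occupied[cbind(ir, ic)])) guard <- TRUE
          }
          if (guard) next
          img[cbind(rr, cc)] <- intensity
          occupied[cbind(rr, cc)] <- TRUE
          placed <- TRUE
          break
        }
        if (!placed)
          stop("blob placement failed after ", maxTries, " tries")
      }
    }
  })
  truth <- data.frame(cell_id = seq_len(K),
                      n_puncta = vapply(blobAreas,
                                        function(a) sum(a > 15L),
                                        integer(1)))
  list(image = img, masks = masks, truth = truth)
}

#' Two-group samples with known distribution family and effect size
#'
#' Draws two reproducible samples: y from the base family, x from the
#' same family shifted by `effectSize` standard deviations (so the
#' analytic Cohen's d is `effectSize` for the normal family). Families:
#' "normal", "lognormal", "cauchy" (cauchy has no finite moments; its
#' normality truth flag is FALSE).
#'
#' @param family1,family2 distribution family per group.
#' @param n sample size per group (>= 3).
#' @param effectSize location shift in SD units applied to group x.
#' @param sd scale parameter (default 1).
#' @param seed RNG seed.
#' @return list(x, y, truth = list(d, normal1, normal2)).
#' @export
makeGroupSamples <- function(family1 = "normal", family2 = "normal",
                             n = 50L, effectSize = 0, sd = 1,
                             seed = 1L) {
  stopifnot(n >= 3L)
  draw <- function(fam, shift) {
    switch(fam,
           normal = rnorm(n, mean = shift * sd, sd = sd),
           lognormal = rlnorm(n, meanlog = shift, sdlog = sd),
           cauchy = rcauchy(n, location = shift * sd, scale = sd),
           stop("unknown family: ", fam))
  }
  .with_seed(seed, {
    x <- draw(family1, effectSize)
    y <- draw(family2, 0)
  })
  list(x = x, y = y,
       truth = list(d = if (family1 == "normal" && family2 == "normal")
                      effectSize else NA_real_,
                    normal1 = family1 == "normal",
                    normal2 = family2 == "normal"))
}
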