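## MD trajectory statistics: DSSP-criterion backbone H-bonds, registry
## classification, the weighted parallel-sheet fraction, PBC-safe RMSD,
## membrane insertion depth and pore-water counts.
##
## All positions are nm; H-bond energies are evaluated in Angstrom and
## kcal/mol as in the Kabsch-Sander electrostatic model. Orthorhombic
## boxes only, with the minimum-image convention for distances.

.DSSP_Q <- 27.888          # kcal/mol * Angstrom (= 0.42 * 0.20 * 332)
.DSSP_CUTOFF <- -0.5       # kcal/mol
.DSSP_EMIN <- -9.9         # clamp for near-contact geometries

#' Construct a PeptideFrame
#'
#' @param atoms data.frame with columns monomer, residue, role
#'   ("N","H","C","O","CA","side", ...), x, y, z (nm) and optionally mass.
#' @param box orthorhombic box edges (nm).
#' @param time frame time (ns).
#' @param monomerLength residues per monomer (default 6).
#' @return a [PeptideFrame-class]
#' @export
PeptideFrame <- function(atoms, box, time = 0, monomerLength = 6L) {
  if (is.null(atoms$mass))
    atoms$mass <- c(N = 14.007, H = 1.008, C = 12.011, O = 15.999,
                    CA = 12.011)[atoms$role]
  atoms$mass[is.na(atoms$mass)] <- 12.011
  atoms$monomer <- as.integer(atoms$monomer)
  atoms$residue <- as.integer(atoms$residue)
  new("PeptideFrame", atoms = atoms, box = as.numeric(box),
      time = as.numeric(time), monomerLength = as.integer(monomerLength))
}

#' Construct a MembraneFrame
#'
#' @param phosphorusZ z coordinates (nm) of membrane phosphorus atoms.
#' @param waterZ z coordinates (nm) of water oxygens.
#' @param proteinXyz n x 3 matrix of protein positions (nm).
#' @param proteinMass atomic masses (defaults to 12.011 each).
#' @param box box edges (nm).
#' @param time frame time (ns).
#' @return a [MembraneFrame-class]
#' @export
MembraneFrame <- function(phosphorusZ, waterZ = numeric(0),
                          proteinXyz = matrix(numeric(0), 0, 3),
                          proteinMass = NULL, box = c(10, 10, 10),
                          time = 0) {
  proteinXyz <- as.matrix(proteinXyz)
  if (is.null(proteinMass)) proteinMass <- rep(12.011, nrow(proteinXyz))
  new("MembraneFrame", phosphorusZ = as.numeric(phosphorusZ),
      waterZ = as.numeric(waterZ), proteinXyz = proteinXyz,
      proteinMass = as.numeric(proteinMass), box = as.numeric(box),
      time = as.numeric(time))
}

.min_image <- function(d, L) d - L * round(d / L)

.pair_dists <- function(A, B, box) {
  ## A: na x 3, B: nb x 3 -> na x nb distances under minimum image
  d2 <- 0
  for (k in 1:3) {
    dk <- outer(A[, k], B[, k], "-")
    dk <- .min_image(dk, box[k])
    d2 <- d2 + dk^2
  }
  sqrt(d2)
}

.reconstruct_H <- function(at) {
  ## DSSP fallback: place the amide H 1.01 Angstrom from N along the
  ## O->C direction of the preceding residue's carbonyl (same monomer).
  added <- list()
  for (m in unique(at$monomer)) {
    am <- at[at$monomer == m, ]
    for (i in sort(unique(am$residue[am$role == "N"]))) {
      if (any(am$role == "H" & am$residue == i)) next
      Nrow <- am[am$role == "N" & am$residue == i, ][1, ]
      Cp <- am[am$role == "C" & am$residue == i - 1L, ]
      Op <- am[am$role == "O" & am$residue == i - 1L, ]
      if (!nrow(Cp) || !nrow(Op)) next   # chain start: not a donor
      dir <- c(Cp$x[1] - Op$x[1], Cp$y[1] - Op$y[1], Cp$z[1] - Op$z[1])
      dir <- dir / sqrt(sum(dir^2))
      added[[length(added) + 1L]] <- data.frame(
        monomer = m, residue = i, role = "H",
        x = Nrow$x + 0.101 * dir[1], y = Nrow$y + 0.101 * dir[2],
        z = Nrow$z + 0.101 * dir[3], mass = 1.008)
    }
  }
  if (length(added)) rbind(at, do.call(rbind, added)) else at
}

#' Detect backbone hydrogen bonds with the DSSP criterion
#'
#' For every donor amide (N-H) against every acceptor carbonyl (C=O) the
#' Kabsch-Sander electrostatic energy
#' E = 27.888 (1/rON + 1/rCH - 1/rOH - 1/rCN) kcal/mol (r in Angstrom)
#' is evaluated under the minimum-image convention; a bond is accepted
#' when E < -0.5 kcal/mol. Self-residue pairs and the covalent
#' peptide-bond pair (same monomer, acceptor = donor - 1) are excluded per
#' DSSP convention. Missing amide hydrogens are reconstructed 1.01
#' Angstrom from N along the preceding carbonyl O->C direction (the DSSP
#' fallback) when `reconstructH = TRUE`; otherwise they raise an error
#' naming the offending residues.
#'
#' @param frame a [PeptideFrame-class]
#' @param reconstructH reconstruct missing amide hydrogens? Default TRUE.
#' @return data.frame with columns donor_monomer, donor_residue,
#'   acceptor_monomer, acceptor_residue, energy (kcal/mol) and
#'   registry_class (see [classifyRegistry()]).
#' @export
detectBackboneHbonds <- function(frame, reconstructH = TRUE) {
  stopifnot(is(frame, "PeptideFrame"))
  at <- atoms(frame)
  donors_missing <- NULL
  hres <- paste(at$monomer[at$role == "H"], at$residue[at$role == "H"])
  nres <- at[at$role == "N", c("monomer", "residue")]
  miss <- !paste(nres$monomer, nres$residue) %in% hres
  if (any(miss)) {
    if (!reconstructH) {
      bad <- nres[miss, ]
      ## residue 1 without a preceding carbonyl is simply not a donor
      bad <- bad[bad$residue > 1L, , drop = FALSE]
      if (nrow(bad))
        stop("missing amide H (reconstruction disabled) for: ",
             paste(sprintf("monomer %d residue %d", bad$monomer,
                           bad$residue), collapse = "; "))
    } else {
      at <- .reconstruct_H(at[, c("monomer", "residue", "role",
                                  "x", "y", "z", "mass")])
    }
  }
  don <- merge(at[at$role == "N", c("monomer", "residue", "x", "y", "z")],
               at[at$role == "H", c("monomer", "residue", "x", "y", "z")],
               by = c("monomer", "residue"), suffixes = c("_n", "_h"))
  acc <- merge(at[at$role == "C", c("monomer", "residue", "x", "y", "z")],
               at[at$role == "O", c("monomer", "residue", "x", "y", "z")],
               by = c("monomer", "residue"), suffixes = c("_c", "_o"))
  empty <- data.frame(donor_monomer = integer(0), donor_residue = integer(0),
                      acceptor_monomer = integer(0),
                      acceptor_residue = integer(0), energy = numeric(0),
                      registry_class = character(0))
  if (!nrow(don) || !nrow(acc)) return(empty)
  box <- boxDims(frame) * 10  # nm -> Angstrom
  Nx <- as.matrix(don[, c("x_n", "y_n", "z_n")]) * 10
  Hx <- as.matrix(don[, c("x_h", "y_h", "z_h")]) * 10
  Cx <- as.matrix(acc[, c("x_c", "y_c", "z_c")]) * 10
  Ox <- as.matrix(acc[, c("x_o", "y_o", "z_o")]) * 10
  rON <- .pair_dists(Nx, Ox, box)
  rCH <- .pair_dists(Hx, Cx, box)
  rOH <- .pair_dists(Hx, Ox, box)
  rCN <- .pair_dists(Nx, Cx, box)
  E <- .DSSP_Q * (1 / rON + 1 / rCH - 1 / rOH - 1 / rCN)
  E[rON < 0.5 | rCH < 0.5 | rOH < 0.5 | rCN < 0.5] <- .DSSP_EMIN
  same_res <- outer(don$monomer, acc$monomer, "==") &
    outer(don$residue, acc$residue, "==")
  peptide_pair <- outer(don$monomer, acc$monomer, "==") &
    outer(don$residue, acc$residue, function(i, j) j == i - 1L)
  E[same_res | peptide_pair] <- Inf
  hit <- which(E < .DSSP_CUTOFF, arr.ind = TRUE)
  if (!nrow(hit)) return(empty)
  out <- data.frame(donor_monomer = don$monomer[hit[, 1]],
                    donor_residue = don$residue[hit[, 1]],
                    acceptor_monomer = acc$monomer[hit[, 2]],
                    acceptor_residue = acc$residue[hit[, 2]],
                    energy = E[hit])
  out$registry_class <- mapply(classifyRegistry,
                               out$donor_residue, out$acceptor_residue,
                               out$donor_monomer == out$acceptor_monomer,
                               MoreArgs = list(L = frame@monomerLength))
  out[order(out$donor_monomer, out$donor_residue), , drop = FALSE]
}

#' Classify a backbone H-bond by beta-sheet registry
#'
#' For an in-register parallel beta-sheet the N-H of residue i bonds the
#' C=O of residue i-1 in another monomer; for an in-register antiparallel
#' sheet it bonds residue L+1-i. For L = 6 the (donor 4, acceptor 3)
#' pairing satisfies both rules and is excluded as ambiguous. Bonds within
#' one monomer and pairings matching neither rule are "other".
#'
#' @param donorResidue,acceptorResidue 1-based residue indices.
#' @param sameMonomer logical: donor and acceptor in the same monomer?
#' @param L monomer length in residues (default 6).
#' @return one of "parallel", "antiparallel", "excluded_ambiguous",
#'   "other".
#' @export
classifyRegistry <- function(donorResidue, acceptorResidue,
                             sameMonomer = FALSE, L = 6L) {
  i <- donorResidue; j <- acceptorResidue
  if (sameMonomer) return("other")
  isPar <- (j == i - 1L)
  isAnti <- (j == L + 1L - i)
  if (isPar && isAnti) return("excluded_ambiguous")
  if (isPar) "parallel" else if (isAnti) "antiparallel" else "other"
}

#' Enumerate admissible in-register pairings
#'
#' Counts, for one adjacent monomer pair, the donor residues i in [1, L]
#' whose rule-mapped acceptor lies inside [1, L], excluding the ambiguous
#' pairing that satisfies both rules (for L = 6: donor 4 to acceptor 3)
#' and the degenerate same-index pairing (donor i to acceptor i, which
#' only arises for odd L). For L = 6 this yields 4 parallel and 5
#' antiparallel H bonds, the imbalance behind the 0.8 antiparallel weight
#' in [parallelFraction()].
#'
#' @param L monomer length in residues (default 6).
#' @return named integer vector c(parallel = , antiparallel = ).
#' @export
countAdmissiblePairings <- function(L = 6L) {
  stopifnot(L >= 1L)
  np <- 0L; nap <- 0L
  for (i in seq_len(L)) {
    jp <- i - 1L
    ja <- L + 1L - i
    if (jp >= 1L && jp <= L &&
        classifyRegistry(i, jp, FALSE, L) == "parallel") np <- np + 1L
    if (ja >= 1L && ja <= L && ja != i &&
        classifyRegistry(i, ja, FALSE, L) == "antiparallel") nap <- nap + 1L
  }
  c(parallel = np, antiparallel = nap)
}

#' Weighted parallel beta-sheet fraction
#'
#' f_p,sheet = n_p / (n_p + 0.8 n_ap + 1). The 0.8 weight corrects the
#' 4-vs-5 imbalance of admissible parallel/antiparallel pairings for
#' hexapeptide monomers; the +1 in the denominator avoids division by
#' zero, so (0, 0) maps to 0 and the fraction is bounded in [0, 1).
#'
#' @param nP,nAp non-negative integer counts of parallel and antiparallel
#'   H bonds (vectorized).
#' @return numeric fraction(s) in [0, 1).
#' @export
parallelFraction <- function(nP, nAp) {
  if (any(nP < 0) || any(nAp < 0)) stop("counts must be non-negative")
  nP / (nP + 0.8 * nAp + 1)
}

## ---------------------------------------------------------------------------
## Trajectory geometry
## ---------------------------------------------------------------------------

.kabsch <- function(X, R) {
  ## rotation U minimizing |X U - R| after centering; returns the aligned X
  cx <- colMeans(X); cr <- colMeans(R)
  Xc <- sweep(X, 2, cx); Rc <- sweep(R, 2, cr)
  s <- svd(crossprod(Xc, Rc))
  d <- sign(det(s$u %*% t(s$v)))
  U <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  list(rot = U, shift = cr, center = cx)
}

.frame_xyz <- function(frame) as.matrix(atoms(frame)[, c("x", "y", "z")])

.is_backbone <- function(roles) roles %in% c("N", "H", "C", "O", "CA")

#' Unwrap periodic jumps and align a trajectory on its first frame
#'
#' Per-atom displacements between consecutive frames are wrapped back by
#' whole box vectors (minimum image), so no atom ever jumps by more than
#' half the box and the fibril stays one unit; each frame is then
#' rigid-body aligned to the reference by least-squares superposition of
#' its backbone atoms.
#'
#' @param traj list of [PeptideFrame-class] with identical atom tables.
#' @param ref reference frame (default the first).
#' @param align superpose each frame onto the reference? Default TRUE.
#' @return list of [PeptideFrame-class], unwrapped (and aligned).
#' @export
unwrapAndAlign <- function(traj, ref = traj[[1]], align = TRUE) {
  stopifnot(length(traj) >= 1L)
  nat <- nrow(atoms(traj[[1]]))
  for (f in traj)
    if (nrow(atoms(f)) != nat)
      stop("atom-count mismatch across frames")
  out <- traj
  prev <- .frame_xyz(traj[[1]])
  for (i in seq_along(traj)) {
    X <- .frame_xyz(traj[[i]])
    if (i > 1L) {
      box <- boxDims(traj[[i]])
      for (k in 1:3) {
        d <- X[, k] - prev[, k]
        X[, k] <- prev[, k] + .min_image(d, box[k])
      }
    }
    prev <- X
    out[[i]]@atoms[, c("x", "y", "z")] <- X
  }
  if (align) {
    bb <- .is_backbone(atoms(ref)$role)
    Rbb <- .frame_xyz(ref)[bb, , drop = FALSE]
    for (i in seq_along(out)) {
      X <- .frame_xyz(out[[i]])
      tr <- .kabsch(X[bb, , drop = FALSE], Rbb)
      Xa <- sweep(sweep(X, 2, tr$center) %*% tr$rot, 2, tr$shift, "+")
      out[[i]]@atoms[, c("x", "y", "z")] <- Xa
    }
  }
  out
}

#' Backbone RMSD time series against the t = 0 configuration
#'
#' Root mean square deviation over backbone atoms of each (already
#' unwrapped/aligned) frame from the reference, with an optional exclusion
#' set for atoms whose monomer detached and reattached across the box
#' (such peptides inflate RMSD through poor alignment).
#'
#' @param traj list of [PeptideFrame-class] (see [unwrapAndAlign()]).
#' @param ref reference frame (default the first).
#' @param excludeMonomers monomer ids excluded from the selection.
#' @return data.frame(time_ns, rmsd_nm).
#' @export
backboneRmsd <- function(traj, ref = traj[[1]], excludeMonomers = integer(0)) {
  at <- atoms(ref)
  sel <- .is_backbone(at$role) & !(at$monomer %in% excludeMonomers)
  if (!any(sel)) stop("empty backbone selection")
  R <- .frame_xyz(ref)[sel, , drop = FALSE]
  rmsd <- vapply(traj, function(f) {
    X <- .frame_xyz(f)[sel, , drop = FALSE]
    sqrt(mean(rowSums((X - R)^2)))
  }, numeric(1))
  data.frame(time_ns = vapply(traj, function(f) f@time, numeric(1)),
             rmsd_nm = rmsd)
}

#' Membrane insertion depth
#'
#' Signed z distance (nm) between the mass-weighted centre of mass of the
#' protein and the centre of mass of all membrane phosphorus atoms
#' (positive above the phosphate plane). Trajectories are assumed
#' pre-processed so peptides do not jump across the z boundary.
#'
#' @param frame a [MembraneFrame-class]
#' @return numeric(1), nm.
#' @export
insertionDepth <- function(frame) {
  stopifnot(is(frame, "MembraneFrame"))
  if (nrow(frame@proteinXyz) == 0L) stop("empty protein set")
  zProt <- sum(frame@proteinXyz[, 3] * frame@proteinMass) /
    sum(frame@proteinMass)
  zProt - mean(frame@phosphorusZ)
}

#' Pore-water count
#'
#' Number of water oxygen atoms whose z coordinate lies within
#' `halfWidth` (default 0.5 nm, closed interval) of the z centre of mass
#' of all membrane phosphorus atoms - a proxy for transmembrane pore
#' persistence.
#'
#' @param frame a [MembraneFrame-class]
#' @param halfWidth slab half width (nm, default 0.5).
#' @return integer count.
#' @export
poreWaterCount <- function(frame, halfWidth = 0.5) {
  stopifnot(is(frame, "MembraneFrame"))
  zP <- mean(frame@phosphorusZ)
  sum(abs(frame@waterZ - zP) <= halfWidth)
}

#' Sheet-order time series
#'
#' Detects backbone H-bonds per sampled frame, classifies their registry,
#' and reports parallel/antiparallel counts and the weighted parallel
#' fraction. Frames are sampled every `strideNs` (default 10 ns, the
#' analysis stride used for the sheet-order fraction; other trajectory
#' metrics default to 1 ns); a stride exceeding the trajectory span yields
#' a single-frame series.
#'
#' @param traj list of [PeptideFrame-class]
#' @param strideNs sampling stride in ns (default 10).
#' @return data.frame(time_ns, n_p, n_ap, f_p).
#' @export
computeSheetOrderSeries <- function(traj, strideNs = 10) {
  times <- vapply(traj, function(f) f@time, numeric(1))
  keep <- c(TRUE, diff(floor((times - times[1]) / strideNs + 1e-9)) > 0)
  if (!any(keep[-1])) keep <- seq_along(traj) == 1L
  idx <- which(keep)
  rows <- lapply(idx, function(i) {
    hb <- detectBackboneHbonds(traj[[i]])
    np <- sum(hb$registry_class == "parallel")
    nap <- sum(hb$registry_class == "antiparallel")
    data.frame(time_ns = times[i], n_p = np, n_ap = nap,
               f_p = parallelFraction(np, nap))
  })
  do.call(rbind, rows)
}
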