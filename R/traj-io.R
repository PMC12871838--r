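## Structure / trajectory readers: PDB (and DCD-class trajectories) via
## bio3d, plus a plain per-frame coordinate table (CSV) used for tests and
## the command-line tools. Roles are assigned by an atom-name -> role map;
## monomers come from the chain identifier (or a grouping column).

.DEFAULT_ROLE_MAP <- c(N = "N", H = "H", HN = "H", H1 = "H",
                       C = "C", O = "O", CA = "CA")

.mass_of <- function(elety) {
  m <- c(N = 14.007, H = 1.008, C = 12.011, O = 15.999, CA = 12.011)
  out <- m[sub("[0-9].*$", "", elety)]
  out[is.na(out)] <- 12.011
  unname(out)
}

#' Read a peptide structure from PDB into a PeptideFrame
#'
#' Atom names are mapped to roles ("N", "H", "C", "O", "CA"; everything
#' else becomes "side"); monomers are taken from the chain identifier.
#' PDB coordinates (Angstrom) are converted to nm. The box is taken from
#' `box` (nm) since CRYST1 records are not always present.
#'
#' @param path PDB file path.
#' @param box orthorhombic box edges in nm.
#' @param roleMap named character vector mapping atom names to roles.
#' @param monomerLength residues per monomer (default 6).
#' @return a [PeptideFrame-class]
#' @export
readPeptidePDB <- function(path, box = c(15, 15, 15),
                           roleMap = .DEFAULT_ROLE_MAP,
                           monomerLength = 6L) {
  pdb <- bio3d::read.pdb(path)
  a <- pdb$atom
  role <- roleMap[a$elety]
  role[is.na(role)] <- "side"
  chain <- a$chain
  chain[is.na(chain)] <- "A"
  monomer <- as.integer(factor(chain, levels = unique(chain)))
  ## residue index 1-based within each monomer
  residue <- as.integer(a$resno)
  for (m in unique(monomer)) {
    sel <- monomer == m
    residue[sel] <- residue[sel] - min(residue[sel]) + 1L
  }
  atoms <- data.frame(monomer = monomer, residue = residue,
                      role = unname(role),
                      x = a$x / 10, y = a$y / 10, z = a$z / 10,
                      mass = .mass_of(a$elety))
  PeptideFrame(atoms, box = box, time = 0, monomerLength = monomerLength)
}

#' Write a PeptideFrame to PDB
#'
#' Monomers become chains A, B, ...; coordinates are written in Angstrom.
#'
#' @param frame a [PeptideFrame-class]
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writePeptidePDB <- function(frame, path) {
  at <- atoms(frame)
  n <- nrow(at)
  elety <- ifelse(at$role %in% c("N", "H", "C", "O", "CA"), at$role, "CB")
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(at[, c("x", "y", "z")]) * 10)),
                   resno = at$residue, chain = LETTERS[at$monomer],
                   resid = rep("LEU", n), eleno = seq_len(n),
                   elety = elety, o = rep(1, n), b = rep(0, n))
  invisible(path)
}

#' Read per-frame coordinate tables (CSV) into a trajectory
#'
#' Plain-text trajectory exchange format: one row per atom per frame with
#' columns time_ns, monomer, residue, role, x, y, z (nm) and optionally
#' mass, box_x, box_y, box_z (nm; default `box`).
#'
#' @param path CSV path.
#' @param box fallback box edges (nm) when no box columns are present.
#' @param monomerLength residues per monomer (default 6).
#' @return list of [PeptideFrame-class], ordered by time.
#' @export
readPeptideFramesCsv <- function(path, box = c(15, 15, 15),
                                 monomerLength = 6L) {
  d <- read.csv(path)
  need <- c("time_ns", "monomer", "residue", "role", "x", "y", "z")
  if (!all(need %in% names(d)))
    stop("frame CSV needs columns: ", paste(need, collapse = ", "))
  lapply(sort(unique(d$time_ns)), function(tt) {
    di <- d[d$time_ns == tt, , drop = FALSE]
    b <- if (all(c("box_x", "box_y", "box_z") %in% names(di)))
      c(di$box_x[1], di$box_y[1], di$box_z[1]) else box
    PeptideFrame(di[, setdiff(names(di),
                              c("time_ns", "box_x", "box_y", "box_z"))],
                 box = b, time = tt, monomerLength = monomerLength)
  })
}

#' Read a DCD trajectory onto a PDB topology
#'
#' Thin wrapper over bio3d's DCD reader: each trajectory frame replaces
#' the coordinates of the PDB-derived [PeptideFrame-class].
#'
#' @param pdbPath structure file (PDB).
#' @param dcdPath trajectory file (DCD).
#' @param dtNs time between stored frames (ns).
#' @inheritParams readPeptidePDB
#' @return list of [PeptideFrame-class]
#' @export
readPeptideDCD <- function(pdbPath, dcdPath, dtNs = 1,
                           box = c(15, 15, 15),
                           roleMap = .DEFAULT_ROLE_MAP,
                           monomerLength = 6L) {
  base <- readPeptidePDB(pdbPath, box = box, roleMap = roleMap,
                         monomerLength = monomerLength)
  xyz <- bio3d::read.dcd(dcdPath, verbose = FALSE)
  lapply(seq_len(nrow(xyz)), function(i) {
    f <- base
    f@atoms[, c("x", "y", "z")] <-
      matrix(xyz[i, ], ncol = 3, byrow = TRUE) / 10
    f@time <- (i - 1) * dtNs
    f
  })
}
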