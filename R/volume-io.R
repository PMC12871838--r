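## MRC2014 volume I/O and per-object slice extraction.
##
## Volumes are handled internally in (z, y, x) axis order (slicing is along
## z); the reader converts if the file's mapc/mapr/maps header fields declare
## a different axis-to-dimension assignment. Physical voxel sizes are taken
## from the header cell dimensions (Angstrom, per MRC convention) divided by
## the grid size, and reported in nm.

.MRC_MODES <- c(`0` = "int8", `1` = "int16", `2` = "float32", `6` = "uint16")

#' Construct a LabeledVolume
#'
#' @param voxels 3D integer array in (z, y, x) order; label 0 is background.
#' @param voxelSize numeric voxel edge length(s) in nm: either one value
#'   (isotropic) or three in (z, y, x) order.
#' @return a [LabeledVolume-class]
#' @examples
#' v <- array(0L, c(4, 8, 8)); v[2, 3:5, 3:5] <- 1L
#' LabeledVolume(v, 1)
#' @export
LabeledVolume <- function(voxels, voxelSize = 1) {
  if (length(voxelSize) == 1L) voxelSize <- rep(voxelSize, 3L)
  storage.mode(voxels) <- "integer"
  labs <- sort(unique(as.integer(voxels[voxels > 0L])))
  new("LabeledVolume", voxels = voxels, voxelSize = as.numeric(voxelSize),
      labels = labs)
}

.read_mrc_header <- function(con) {
  ints1 <- readBin(con, "integer", n = 10, size = 4, endian = "little")
  cella <- readBin(con, "numeric", n = 3, size = 4, endian = "little")
  cellb <- readBin(con, "numeric", n = 3, size = 4, endian = "little")
  maps <- readBin(con, "integer", n = 3, size = 4, endian = "little")
  dstats <- readBin(con, "numeric", n = 3, size = 4, endian = "little")
  ispg <- readBin(con, "integer", n = 1, size = 4, endian = "little")
  nsymbt <- readBin(con, "integer", n = 1, size = 4, endian = "little")
  invisible(readBin(con, "raw", n = 1024 - 24 * 4))  # rest of header
  list(nx = ints1[1], ny = ints1[2], nz = ints1[3], mode = ints1[4],
       mx = ints1[8], my = ints1[9], mz = ints1[10],
       cella = cella, mapc = maps[1], mapr = maps[2], maps = maps[3],
       nsymbt = nsymbt)
}

#' Read a labeled segmentation volume from an MRC file
#'
#' Reads an MRC2014 volume (modes 0, 1, 2 and 6; mode-2 floats must be
#' integer-valued within 1e-6 and are cast). Axis order is normalized to
#' (z, y, x) using the mapc/mapr/maps header fields, and voxel sizes are
#' derived from the cell dimensions (Angstrom / grid size, reported in nm).
#'
#' @param path path to an existing MRC file.
#' @return a [LabeledVolume-class]
#' @seealso [writeLabeledVolume()], [extractObjectSlices()]
#' @export
readLabeledVolume <- function(path) {
  if (!file.exists(path)) stop("MRC file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  h <- .read_mrc_header(con)
  if (any(c(h$nx, h$ny, h$nz) < 1L))
    stop("not a 3D volume: header grid is ", h$nx, " x ", h$ny, " x ", h$nz)
  if (!as.character(h$mode) %in% names(.MRC_MODES))
    stop("unsupported MRC mode ", h$mode, " (accepted: 0, 1, 2, 6)")
  if (h$nsymbt > 0) invisible(readBin(con, "raw", n = h$nsymbt))
  n <- h$nx * h$ny * h$nz
  raw <- switch(as.character(h$mode),
    `0` = readBin(con, "integer", n = n, size = 1, signed = TRUE,
                  endian = "little"),
    `1` = readBin(con, "integer", n = n, size = 2, signed = TRUE,
                  endian = "little"),
    `2` = readBin(con, "numeric", n = n, size = 4, endian = "little"),
    `6` = readBin(con, "integer", n = n, size = 2, signed = FALSE,
                  endian = "little"))
  if (length(raw) < n) stop("MRC data block truncated: expected ", n,
                            " voxels, got ", length(raw))
  if (h$mode == 2) {
    if (max(abs(raw - round(raw))) > 1e-6)
      stop("mode-2 MRC volume holds non-integer data; ",
           "labeled volumes must be integer after safe cast")
    raw <- round(raw)
  }
  ## file layout: first (fastest) dim is axis mapc, then mapr, then maps,
  ## where axis 1 = x, 2 = y, 3 = z.
  arr <- array(as.integer(raw), dim = c(h$nx, h$ny, h$nz))
  axis_of_dim <- c(h$mapc, h$mapr, h$maps)
  if (anyDuplicated(axis_of_dim) || !all(sort(axis_of_dim) == 1:3))
    stop("invalid mapc/mapr/maps in MRC header")
  perm <- match(c(3L, 2L, 1L), axis_of_dim)  # target order (z, y, x)
  arr <- aperm(arr, perm)
  vs_xyz <- h$cella / c(h$mx, h$my, h$mz) / 10  # Angstrom -> nm
  if (any(!is.finite(vs_xyz)) || any(vs_xyz <= 0)) vs_xyz <- c(1, 1, 1)
  LabeledVolume(arr, voxelSize = vs_xyz[c(3, 2, 1)])
}

#' Write a LabeledVolume to an MRC2014 file
#'
#' Written as mode 1 (int16) when all labels fit, else mode 2 (float32),
#' with cell dimensions encoding the voxel size (nm written as Angstrom).
#'
#' @param vol a [LabeledVolume-class]
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeLabeledVolume <- function(vol, path) {
  stopifnot(is(vol, "LabeledVolume"))
  v <- voxels(vol)
  d <- dim(v)                       # (nz, ny, nx)
  nx <- d[3]; ny <- d[2]; nz <- d[1]
  mode <- if (max(v) <= 32767L) 1L else 2L
  vs <- voxelSize(vol)[c(3, 2, 1)]  # -> (x, y, z), nm
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.integer(c(nx, ny, nz, mode, 0L, 0L, 0L, nx, ny, nz)), con,
           size = 4, endian = "little")
  writeBin(as.numeric(c(vs * c(nx, ny, nz) * 10, 90, 90, 90)), con,
           size = 4, endian = "little")
  writeBin(as.integer(c(1L, 2L, 3L)), con, size = 4, endian = "little")
  writeBin(as.numeric(c(min(v), max(v), mean(v))), con, size = 4,
           endian = "little")
  writeBin(as.integer(c(1L, 0L)), con, size = 4, endian = "little")  # ispg, nsymbt
  writeBin(raw(100), con)                                   # extra 25-49
  writeBin(as.numeric(c(0, 0, 0)), con, size = 4, endian = "little")  # origin
  writeBin(charToRaw("MAP "), con)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)          # little-endian
  writeBin(as.numeric(stats::sd(v)), con, size = 4, endian = "little")
  writeBin(as.integer(0L), con, size = 4, endian = "little")          # nlabl
  writeBin(raw(800), con)
  arr <- aperm(v, c(3, 2, 1))  # back to x-fastest layout
  if (mode == 1L) {
    writeBin(as.integer(arr), con, size = 2, endian = "little")
  } else {
    writeBin(as.numeric(arr), con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Decompose one labeled object into per-slice binary masks
#'
#' Walks the volume slice-by-slice along z and collects, for every z slice
#' containing at least one voxel of `label`, a logical mask (rows = y,
#' cols = x). The z-extent (inclusive span from first to last occupied
#' slice) is retained as the denominator of z-coverage.
#'
#' @param vol a [LabeledVolume-class]
#' @param label a label present in `objectLabels(vol)`.
#' @return a [SliceStack-class]
#' @export
extractObjectSlices <- function(vol, label) {
  stopifnot(is(vol, "LabeledVolume"))
  label <- as.integer(label)
  if (!label %in% objectLabels(vol))
    stop("unknown label ", label, "; volume has: ",
         paste(objectLabels(vol), collapse = ", "))
  v <- voxels(vol)
  nz <- dim(v)[1]
  keep <- list()
  occupied <- integer(0)
  for (z in seq_len(nz)) {
    mask <- v[z, , ] == label
    if (any(mask)) {
      keep[[length(keep) + 1L]] <- list(z = z - 1L, mask = mask)
      occupied <- c(occupied, z - 1L)
    }
  }
  if (!length(keep)) stop("label ", label, " occupies no slices")
  new("SliceStack", objectLabel = label, slices = keep,
      zExtent = max(occupied) - min(occupied) + 1L)
}

#' Write a results table as TSV
#'
#' Plain tab-separated output with a header row; physical quantities are in
#' nm, filter thresholds in pixels.
#'
#' @param x data.frame
#' @param path output path
#' @return `path`, invisibly
#' @export
writeResultsTsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
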