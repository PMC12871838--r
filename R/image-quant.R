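## Fluorescence image quantification: maximum z-projections, size-filtered
## puncta counts per cell mask, and Manders colocalization coefficients.
##
## Image stacks use the package-wide (z, y, x) axis order; 2D images are
## matrices with rows = y, cols = x.

#' Maximum intensity z-projection
#'
#' Elementwise maximum across the slices of a (z, y, x) intensity stack.
#' A 2D input is returned unchanged.
#'
#' @param stack 3D numeric array (z, y, x) with >= 1 slice, or a matrix.
#' @return 2D matrix (y, x).
#' @export
maxZProjection <- function(stack) {
  if (is.matrix(stack)) return(stack)
  d <- dim(stack)
  if (length(d) != 3L || d[1] < 1L) stop("empty or non-3D stack")
  apply(stack, c(2, 3), max)
}

## 8-connected labeling of a logical matrix via the pixel adjacency graph
.label8 <- function(mask) {
  fg <- which(mask, arr.ind = TRUE)
  lab <- matrix(0L, nrow(mask), ncol(mask))
  if (nrow(fg) == 0L) return(lab)
  coords <- cbind(x = fg[, 2] - 1L, y = fg[, 1] - 1L)
  g <- .skeleton_graph(coords)   # same 8-neighbour adjacency
  comp <- igraph::components(g)
  lab[fg] <- comp$membership
  lab
}

#' Count size-filtered puncta per cell mask
#'
#' Binarizes the projection at a shared intensity threshold (the same
#' value is used for a whole batch), labels 8-connected components, keeps
#' only particles strictly larger than `minSizePx` pixels (excluding
#' random noise), and assigns each retained particle to the cell mask
#' containing its centroid. Particles whose centroid falls outside all
#' masks are reported in an "unassigned" row with cell_id 0.
#'
#' @param img 2D intensity matrix (a maximum projection).
#' @param cellMasks labeled 2D integer mask (cells 1..K, background 0).
#' @param threshold shared intensity threshold; pixels strictly above it
#'   are foreground.
#' @param minSizePx size filter in pixels (default 15, strict: a particle
#'   of exactly `minSizePx` pixels is excluded).
#' @return data.frame with one row per cell (plus an unassigned row when
#'   needed): cell_id, n_puncta, and a list column particle_sizes.
#' @export
countPuncta <- function(img, cellMasks, threshold, minSizePx = 15L) {
  stopifnot(all(dim(img) == dim(cellMasks)))
  lab <- .label8(img > threshold)
  cells <- sort(unique(cellMasks[cellMasks > 0]))
  counts <- stats::setNames(rep(0L, length(cells)), cells)
  sizes <- stats::setNames(rep(list(numeric(0)), length(cells)), cells)
  un_count <- 0L; un_sizes <- numeric(0)
  if (max(lab) > 0) {
    for (k in seq_len(max(lab))) {
      px <- which(lab == k, arr.ind = TRUE)
      area <- nrow(px)
      if (area <= minSizePx) next
      cy <- round(mean(px[, 1])); cx <- round(mean(px[, 2]))
      cell <- cellMasks[min(max(cy, 1), nrow(img)),
                        min(max(cx, 1), ncol(img))]
      if (cell > 0) {
        key <- as.character(cell)
        counts[key] <- counts[key] + 1L
        sizes[[key]] <- c(sizes[[key]], area)
      } else {
        un_count <- un_count + 1L
        un_sizes <- c(un_sizes, area)
      }
    }
  }
  out <- data.frame(cell_id = as.integer(names(counts)),
                    n_puncta = as.integer(counts))
  out$particle_sizes <- I(unname(sizes))
  if (un_count > 0L) {
    un <- data.frame(cell_id = 0L, n_puncta = un_count)
    un$particle_sizes <- I(list(un_sizes))
    out <- rbind(out, un)
  }
  out
}

#' Manders colocalization coefficients
#'
#' M1 is the fraction of channel-a intensity (over pixels with a > thrA)
#' lying where channel b exceeds its threshold; M2 is the symmetric
#' quantity with the roles swapped. With both thresholds 0 this is the
#' classic Manders coefficient; explicit thresholds give the thresholded
#' variant. Both lie in [0, 1]; a zero denominator yields NA.
#'
#' @param a,b 2D intensity matrices of identical shape (maximum
#'   projections).
#' @param thrA,thrB intensity thresholds (default 0).
#' @return named numeric c(M1 = , M2 = ).
#' @export
mandersCoefficients <- function(a, b, thrA = 0, thrB = 0) {
  stopifnot(all(dim(a) == dim(b)))
  selA <- a > thrA; selB <- b > thrB
  denA <- sum(a[selA]); denB <- sum(b[selB])
  M1 <- if (denA > 0) sum(a[selA & selB]) / denA else NA_real_
  M2 <- if (denB > 0) sum(b[selA & selB]) / denB else NA_real_
  c(M1 = M1, M2 = M2)
}

#' Read a TIFF stack as a (z, y, x) intensity array
#'
#' @param path TIFF path (single- or multi-frame).
#' @return 3D array (z, y, x).
#' @export
readTiffStack <- function(path) {
  img <- EBImage::readImage(path)
  d <- dim(img)
  if (length(d) == 2L) d <- c(d, 1L)
  ## EBImage images are (x, y, frames) -> (z, y, x)
  aperm(array(img, d), c(3, 2, 1))
}

#' Write a (z, y, x) intensity array as a TIFF stack
#'
#' Intensities are rescaled to [0, 1] for storage.
#'
#' @param stack 3D array (z, y, x) or matrix (y, x).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeTiffStack <- function(stack, path) {
  if (is.matrix(stack)) stack <- array(stack, c(1L, dim(stack)))
  mx <- max(stack)
  if (mx > 0) stack <- stack / mx
  EBImage::writeImage(EBImage::Image(aperm(stack, c(3, 2, 1))), path,
                      type = "tiff")
  invisible(path)
}
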