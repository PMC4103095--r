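# Pixel-set helpers.
#
# Throughout the package a "pixel set" is a sorted integer vector of
# column-major linear indices into a frame matrix (R convention: index =
# (col - 1) * nrow + row).  Regions, borders, masks-as-sets and ground-truth
# footprints all use this representation.

#' Convert linear pixel indices to (row, col) coordinates
#'
#' @param pixels Integer vector of column-major linear indices.
#' @param dim Frame dimensions `c(nrow, ncol)`.
#' @return Integer matrix with columns `row`, `col`.
#' @keywords internal
px_coords <- function(pixels, dim) {
  nr <- dim[1]
  cbind(row = ((pixels - 1L) %% nr) + 1L,
        col = ((pixels - 1L) %/% nr) + 1L)
}

#' Convert (row, col) coordinates to linear pixel indices
#' @param rows,cols Integer vectors of coordinates.
#' @param dim Frame dimensions `c(nrow, ncol)`.
#' @keywords internal
px_index <- function(rows, cols, dim) {
  as.integer((cols - 1L) * dim[1] + rows)
}

#' Label connected components with 8-connectivity
#'
#' `EBImage::bwlabel()` labels 4-connected components; puncta and cell
#' segmentation use 8-connectivity so that diagonally touching pixels form a
#' single object.  Labels produced by `bwlabel()` are therefore merged across
#' diagonal adjacencies with a union-find pass, then renumbered
#' deterministically by each component's (min row, min col).
#'
#' @param mask Logical or 0/1 numeric matrix.
#' @return Integer matrix of labels, 0 = background; labels are 1..n ordered
#'   by (min row, min col) of the component.
#' @export
label8 <- function(mask) {
  stopifnot(is.matrix(mask))
  m <- matrix(as.numeric(mask != 0), nrow(mask), ncol(mask))
  lab <- EBImage::imageData(EBImage::bwlabel(m))
  lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))
  nlab <- max(lab)
  if (nlab > 1L) {
    parent <- seq_len(nlab)
    find_root <- function(x) {
      while (parent[x] != x) {
        parent[x] <<- parent[parent[x]]
        x <- parent[x]
      }
      x
    }
    nr <- nrow(lab); nc <- ncol(lab)
    if (nr > 1L && nc > 1L) {
      a <- c(lab[-nr, -nc], lab[-1L, -nc])
      b <- c(lab[-1L, -1L], lab[-nr, -1L])
      keep <- a > 0L & b > 0L & a != b
      pairs <- unique(cbind(a[keep], b[keep]))
      for (i in seq_len(nrow(pairs))) {
        ra <- find_root(pairs[i, 1L]); rb <- find_root(pairs[i, 2L])
        if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
      }
      root <- vapply(seq_len(nlab), find_root, integer(1))
      pos <- lab > 0L
      lab[pos] <- root[lab[pos]]
    }
  }
  relabel_ordered(lab)
}

# Renumber labels 1..n by (min row, min col) of each component.
relabel_ordered <- function(lab) {
  idx <- which(lab > 0L)
  if (!length(idx)) return(lab)
  l <- lab[idx]
  nr <- nrow(lab)
  rows <- ((idx - 1L) %% nr) + 1L
  cols <- ((idx - 1L) %/% nr) + 1L
  minr <- tapply(rows, l, min)
  minc <- tapply(cols, l, min)
  ids <- as.integer(names(minr))
  ord <- order(minr, minc)
  map <- integer(max(ids))
  map[ids[ord]] <- seq_along(ids)
  lab[idx] <- map[l]
  lab
}

#' Extract pixel sets from a label matrix
#'
#' @param lab Integer label matrix (0 = background).
#' @return List of sorted integer pixel-index vectors, one per label, in
#'   label order.
#' @export
pixel_sets <- function(lab) {
  idx <- which(lab > 0L)
  if (!length(idx)) return(list())
  unname(split(idx, lab[idx]))
}

#' Ring of pixels within a Euclidean distance of a region
#'
#' Returns the set of pixels whose Euclidean distance to the nearest pixel of
#' `pixels` is in (0, width] — i.e. the dilation of the region by a disk of
#' radius `width`, minus the region itself, clipped to the frame.  Computed
#' with an exact Euclidean distance transform on a cropped window.
#'
#' @param pixels Pixel set (linear indices).
#' @param dim Frame dimensions `c(nrow, ncol)`.
#' @param width Disk radius in pixels (>= 1).
#' @return Sorted integer pixel set of the ring.
#' @export
dilate_ring <- function(pixels, dim, width) {
  stopifnot(width >= 1, length(pixels) > 0)
  nr <- dim[1]; nc <- dim[2]
  co <- px_coords(pixels, dim)
  w <- as.integer(ceiling(width))
  r0 <- max(1L, min(co[, 1L]) - w); r1 <- min(nr, max(co[, 1L]) + w)
  c0 <- max(1L, min(co[, 2L]) - w); c1 <- min(nc, max(co[, 2L]) + w)
  sub <- matrix(1, r1 - r0 + 1L, c1 - c0 + 1L)
  sub[cbind(co[, 1L] - r0 + 1L, co[, 2L] - c0 + 1L)] <- 0
  d <- EBImage::imageData(EBImage::distmap(sub))
  sel <- which(d > 0 & d <= width)
  if (!length(sel)) return(integer(0))
  snr <- nrow(sub)
  srow <- ((sel - 1L) %% snr) + 1L
  scol <- ((sel - 1L) %/% snr) + 1L
  sort(px_index(srow + r0 - 1L, scol + c0 - 1L, dim))
}

# Population mean / sd over all pixels of a matrix (denominator n).
pop_stats <- function(x) {
  mu <- mean(x)
  c(mu = mu, sd = sqrt(mean((x - mu)^2)))
}

# Gaussian blur with the kernel radius capped so it fits the frame; EBImage
# refuses filters larger than the image.
gblur_safe <- function(x, sigma) {
  r <- 2L * as.integer(ceiling(3 * sigma)) + 1L
  mx <- min(dim(x))
  cap <- if (mx %% 2L == 0L) mx - 1L else mx
  r <- min(r, cap)
  if (r < 3L) return(x)
  matrix(EBImage::imageData(EBImage::gblur(x, sigma = sigma, radius = r)),
         nrow(x), ncol(x))
}
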