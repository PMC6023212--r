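## Binary morphology primitives for the spheroid-mask cleanup chain.
## All operators take and return logical matrices; pixels outside the image
## are treated as background.

#' Label connected components
#'
#' @param mask logical matrix.
#' @param connectivity 4 or 8 (default 8, the package-wide foreground
#'   convention; the background is treated 4-connected by duality).
#' @return Integer matrix of component labels (0 = background). Labels are
#'   numbered by the row-major position of each component's first pixel, so
#'   labelling is deterministic.
#' @export
label_components <- function(mask, connectivity = 8L) {
  stopifnot(is.logical(mask), connectivity %in% c(4L, 8L))
  .cc_label(mask, as.integer(connectivity))
}

# area (pixel count) of every label in a label matrix
component_areas <- function(lab) {
  n <- max(lab)
  if (n == 0L) return(integer(0))
  tabulate(lab[lab > 0L], nbins = n)
}

# logical mask of the largest component; ties broken by the lowest label,
# i.e. the component whose first pixel comes first in row-major order
largest_component <- function(mask, connectivity = 8L) {
  lab <- label_components(mask, connectivity)
  a <- component_areas(lab)
  if (length(a) == 0L) return(mask & FALSE)
  lab == which.max(a)
}

# shift a logical matrix by (dr, dc), padding with background
shift_mask <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(FALSE, nr, nc)
  rs <- seq_len(nr) - dr; cs <- seq_len(nc) - dc
  rok <- rs >= 1L & rs <= nr; cok <- cs >= 1L & cs <= nc
  out[rok, cok] <- m[rs[rok], cs[cok]]
  out
}

# structuring-element offsets of a Euclidean disk: {(dr,dc): dr^2+dc^2 <= r^2}
disk_offsets <- function(disk_r) {
  r <- as.integer(ceiling(disk_r))
  g <- expand.grid(dr = -r:r, dc = -r:r)
  g[g$dr^2 + g$dc^2 <= disk_r^2, , drop = FALSE]
}

#' Morphological erosion and dilation with a disk
#'
#' The structuring element is the Euclidean disk
#' `{(dx, dy): dx^2 + dy^2 <= disk_r^2}` (13 pixels at `disk_r = 2`).
#' Pixels outside the image count as background.
#'
#' @param mask logical matrix.
#' @param disk_r disk radius in pixels.
#' @return A logical matrix of the same size.
#' @export
mask_erode <- function(mask, disk_r = 2) {
  stopifnot(is.logical(mask))
  off <- disk_offsets(disk_r)
  out <- matrix(TRUE, nrow(mask), ncol(mask))
  for (i in seq_len(nrow(off)))
    out <- out & shift_mask(mask, -off$dr[i], -off$dc[i])
  out
}

#' @rdname mask_erode
#' @export
mask_dilate <- function(mask, disk_r = 2) {
  stopifnot(is.logical(mask))
  off <- disk_offsets(disk_r)
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  for (i in seq_len(nrow(off)))
    out <- out | shift_mask(mask, off$dr[i], off$dc[i])
  out
}

## Bridge: a background pixel becomes foreground iff its 8-neighbourhood
## contains >= 2 foreground pixels that are not 8-connected to each other
## within that neighbourhood (centre excluded). Decided per pixel from the
## 8-bit neighbour pattern through a precomputed lookup table.

# neighbour offsets, bit order: W NW N NE E SE S SW
.nbr_off <- cbind(dr = c(0, -1, -1, -1, 0, 1, 1, 1),
                  dc = c(-1, -1, 0, 1, 1, 1, 0, -1))

# number of 8-connected groups among the set neighbours of a 3x3 pattern
.nbr_groups <- function(bits) {
  idx <- which(bits)
  if (length(idx) == 0L) return(0L)
  adj <- function(i, j) {
    max(abs(.nbr_off[i, 1] - .nbr_off[j, 1]),
        abs(.nbr_off[i, 2] - .nbr_off[j, 2])) <= 1L
  }
  groups <- 0L
  seen <- rep(FALSE, length(idx))
  for (s in seq_along(idx)) {
    if (seen[s]) next
    groups <- groups + 1L
    queue <- s
    seen[s] <- TRUE
    while (length(queue)) {
      cur <- queue[[1]]; queue <- queue[-1]
      for (t in seq_along(idx)) {
        if (!seen[t] && adj(idx[cur], idx[t])) {
          seen[t] <- TRUE
          queue <- c(queue, t)
        }
      }
    }
  }
  groups
}

bridge_lut <- function() {
  lut <- .spheromon_env$bridge_lut
  if (!is.null(lut)) return(lut)
  lut <- vapply(0:255, function(p) {
    bits <- as.logical(bitwAnd(p, bitwShiftL(1L, 0:7)))
    .nbr_groups(bits) >= 2L
  }, logical(1))
  .spheromon_env$bridge_lut <- lut
  lut
}

#' Bridge unconnected pixels
#'
#' A background pixel is set to foreground iff its 8-neighbourhood contains
#' at least two foreground pixels that are not 8-connected to each other
#' within that neighbourhood (centre excluded). Applied in a single
#' simultaneous pass; foreground pixels are never cleared.
#'
#' @param mask logical matrix.
#' @return A logical matrix of the same size.
#' @export
bridge_pixels <- function(mask) {
  stopifnot(is.logical(mask))
  pat <- matrix(0L, nrow(mask), ncol(mask))
  for (b in 1:8)
    pat <- pat + bitwShiftL(1L, b - 1L) *
      shift_mask(mask, .nbr_off[b, 1], .nbr_off[b, 2])
  mask | (!mask & matrix(bridge_lut()[pat + 1L], nrow(mask)))
}

#' Diagonal fill
#'
#' For every 2x2 block whose foreground is exactly one diagonal pair, both
#' background pixels of the block are set, removing diagonal-only background
#' connectivity. Each sweep is simultaneous; sweeps are repeated until no
#' diagonal-only 2x2 block remains (fills from one sweep can create a new
#' diagonal pair at their border, so a fixed point is required for the
#' operator's stated purpose).
#'
#' @param mask logical matrix.
#' @return A logical matrix of the same size.
#' @export
diagonal_fill <- function(mask) {
  stopifnot(is.logical(mask))
  repeat {
    tl <- mask
    tr <- shift_mask(mask, 0, -1)   # value of pixel to the right
    bl <- shift_mask(mask, -1, 0)   # below
    br <- shift_mask(mask, -1, -1)  # below-right
    d1 <- tl & br & !tr & !bl  # main diagonal pair
    d2 <- tr & bl & !tl & !br  # anti-diagonal pair
    if (!any(d1) && !any(d2)) return(mask)
    # d1 at (r,c): set (r,c+1) and (r+1,c); d2 at (r,c): set (r,c),(r+1,c+1)
    add <- (shift_mask(d1, 0, 1) | shift_mask(d1, 1, 0) |
            d2 | shift_mask(d2, 1, 1))
    newmask <- mask | add
    if (identical(newmask, mask)) return(mask)
    mask <- newmask
  }
}

#' Fill interior holes
#'
#' Holes are 4-connected background components that do not touch the image
#' border. Holes with area `<= max_area` are filled.
#'
#' @param mask logical matrix.
#' @param max_area largest hole area (px^2) to fill; `Inf` fills all holes.
#' @return A logical matrix of the same size.
#' @export
fill_holes <- function(mask, max_area = Inf) {
  stopifnot(is.logical(mask))
  lab <- label_components(!mask, connectivity = 4L)
  if (max(lab) == 0L) return(mask)
  border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  areas <- component_areas(lab)
  fill <- setdiff(which(areas <= max_area), border)
  if (length(fill)) mask[lab %in% fill] <- TRUE
  mask
}
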