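## Per-well spheroid segmentation: circular inner mask, adaptive Otsu on
## in-well intensities, fixed gradient threshold, OR/AND combination and a
## four-step morphological cleanup.

#' Default segmentation parameters
#'
#' @param inner_radius_px inner microwell radius in pixels (75 at the
#'   reference 4x setup: 200 um diameter at 0.75 px/um).
#' @param gradient_threshold fixed threshold on the Roberts gradient
#'   magnitude used by the gradient branch (0.020).
#' @param otsu_bins number of histogram bins for Otsu's method.
#' @param polarity `"dark"` if the foreground (cells) is darker than the
#'   background, `"bright"` otherwise. Bright-field cells are darker than
#'   agarose, hence the default.
#' @param small_keep objects with area `<= small_keep` px^2 are kept next to
#'   the largest object in cleanup step (i).
#' @param hole_fill holes with area `<= hole_fill` px^2 are filled in
#'   cleanup step (iii).
#' @param disk_r radius of the erosion/dilation disk in cleanup step (iii).
#' @return A named list of parameters.
#' @export
segmentation_params <- function(inner_radius_px = 75,
                                gradient_threshold = 0.020,
                                otsu_bins = 256L,
                                polarity = c("dark", "bright"),
                                small_keep = 25,
                                hole_fill = 150,
                                disk_r = 2) {
  list(inner_radius_px = inner_radius_px,
       gradient_threshold = gradient_threshold,
       otsu_bins = as.integer(otsu_bins),
       polarity = match.arg(polarity),
       small_keep = small_keep, hole_fill = hole_fill, disk_r = disk_r)
}

#' Circular well mask
#'
#' A pixel belongs to the mask iff its centre lies inside the closed disk:
#' `(x - cx)^2 + (y - cy)^2 <= inner_radius^2`. The mask is clipped to the
#' image without error when the disk extends past a border.
#'
#' @param center numeric `c(x, y)` centre in pixel coordinates (x = column,
#'   y = row, 1-based).
#' @param inner_radius disk radius in pixels.
#' @param shape integer `c(rows, cols)` of the target grid.
#' @return A logical matrix of dimension `shape`.
#' @export
well_mask <- function(center, inner_radius, shape) {
  stopifnot(inner_radius > 0, length(shape) == 2L)
  yy <- matrix(seq_len(shape[1]), shape[1], shape[2])
  xx <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  (xx - center[1])^2 + (yy - center[2])^2 <= inner_radius^2
}

#' Otsu's threshold
#'
#' Exhaustive search of the threshold maximising the between-class variance
#' over a fixed-bin histogram of the input values. Ties are broken towards
#' the lowest maximising bin, so the result is deterministic.
#'
#' @param values numeric vector of intensities (typically in `[0, 1]`).
#' @param bins number of histogram bins (default 256).
#' @return A list with `threshold` (numeric) and `degenerate` (TRUE when
#'   all input values are identical, in which case that value is returned).
#' @export
otsu_threshold <- function(values, bins = 256L) {
  if (length(values) == 0L) stop("`values` must be non-empty")
  lo <- min(values); hi <- max(values)
  if (lo == hi) return(list(threshold = lo, degenerate = TRUE))
  bins <- as.integer(bins)
  edges <- seq(lo, hi, length.out = bins + 1L)
  idx <- pmin(pmax(findInterval(values, edges, all.inside = TRUE), 1L), bins)
  h <- tabulate(idx, nbins = bins)
  mids <- (edges[-1] + edges[-(bins + 1L)]) / 2
  w1 <- cumsum(h)
  s1 <- cumsum(h * mids)
  tot <- w1[bins]; stot <- s1[bins]
  k <- seq_len(bins - 1L)
  om1 <- w1[k] / tot
  valid <- om1 > 0 & om1 < 1
  mu1 <- s1[k] / w1[k]
  mu2 <- (stot - s1[k]) / (tot - w1[k])
  sb <- ifelse(valid, om1 * (1 - om1) * (mu1 - mu2)^2, -Inf)
  kbest <- which.max(sb)  # lowest maximising bin
  list(threshold = edges[kbest + 1L], degenerate = FALSE)
}

#' Morphological cleanup of a raw spheroid mask
#'
#' Executes, in order: (i) retain the largest object together with all
#' objects of area `<= small_keep`; (ii) bridge unconnected pixels, then
#' diagonally fill; (iii) fill holes `<= hole_fill`, erode with a disk of
#' radius `disk_r`, retain the largest object, dilate with the same disk;
#' (iv) bridge and diagonally fill a second time, then fill all remaining
#' holes. The result has at most one 8-connected component and no interior
#' holes.
#'
#' @param mask logical matrix (raw combined segmentation).
#' @param small_keep,hole_fill,disk_r see [segmentation_params()].
#' @return A logical matrix of the same size.
#' @export
morph_cleanup <- function(mask, small_keep = 25, hole_fill = 150, disk_r = 2) {
  stopifnot(is.logical(mask))
  if (!any(mask)) return(mask)
  # (i) largest object + small objects
  lab <- label_components(mask, 8L)
  areas <- component_areas(lab)
  keep <- unique(c(which.max(areas), which(areas <= small_keep)))
  mask <- matrix(lab %in% keep & lab > 0L, nrow(mask))
  # (ii) bridge + diagonal fill
  mask <- diagonal_fill(bridge_pixels(mask))
  # (iii) fill small holes, open with largest-object selection in between
  mask <- fill_holes(mask, hole_fill)
  er <- mask_erode(mask, disk_r)
  if (!any(er)) return(er)
  mask <- mask_dilate(largest_component(er, 8L), disk_r)
  # (iv) bridge + diagonal fill again, then fill the remaining holes
  mask <- diagonal_fill(bridge_pixels(mask))
  fill_holes(mask, Inf)
}

#' Segment the spheroid inside one detected microwell
#'
#' Implements the per-well segmentation chain: (1) an adaptive Otsu
#' threshold computed from the intensities inside the circular inner-well
#' mask segments the raw image (foreground darker than the threshold for
#' the default `"dark"` polarity); (2) the gradient image is segmented with
#' the fixed `gradient_threshold`; (3) both binaries are combined with OR;
#' (4) the combination is intersected (AND) with the circular well mask;
#' (5) the morphological cleanup chain is applied. Processing happens on a
#' square well-local crop of side `2 * inner_radius + 5`; the crop offset is
#' recorded so full-frame coordinates are exact.
#'
#' @param frame a [new_frame()] object or intensity matrix.
#' @param gradient Roberts gradient magnitude of the same frame
#'   (see [roberts_gradient()]).
#' @param well one-row data frame with `cx`, `cy` (a detection accepted by
#'   [filter_detections()]), or a numeric `c(cx, cy)`.
#' @param params parameter list from [segmentation_params()].
#' @return An object of class `spheromon_mask`: list with logical `pixels`
#'   (the crop), integer `offset` (`c(row0, col0)`, the full-frame position
#'   of crop pixel (1,1) minus one), `center`, `empty_flag`, `degenerate_otsu`.
#' @export
segment_spheroid <- function(frame, gradient, well,
                             params = segmentation_params()) {
  px <- frame_pixels(frame)
  if (!all(dim(gradient) == dim(px)))
    stop("gradient and frame shapes differ")
  if (is.data.frame(well)) well <- c(well$cx[1], well$cy[1])
  rad <- params$inner_radius_px
  half <- as.integer(ceiling(rad)) + 2L  # crop side 2*inner_radius + 5
  r0 <- max(1L, as.integer(round(well[2])) - half)
  r1 <- min(nrow(px), as.integer(round(well[2])) + half)
  c0 <- max(1L, as.integer(round(well[1])) - half)
  c1 <- min(ncol(px), as.integer(round(well[1])) + half)
  crop <- px[r0:r1, c0:c1, drop = FALSE]
  gcrop <- gradient[r0:r1, c0:c1, drop = FALSE]
  ctr <- c(well[1] - c0 + 1, well[2] - r0 + 1)
  wmask <- well_mask(ctr, rad, dim(crop))
  ot <- otsu_threshold(crop[wmask], params$otsu_bins)
  ifg <- if (params$polarity == "dark") crop < ot$threshold
         else crop > ot$threshold
  gfg <- gcrop > params$gradient_threshold
  comb <- (ifg | gfg) & wmask
  cleaned <- morph_cleanup(comb, params$small_keep, params$hole_fill,
                           params$disk_r)
  # containment guard: bridging/filling near the disk boundary may add the
  # odd pixel outside the inner disk; clip and re-select the largest object
  out <- cleaned & wmask
  if (!identical(out, cleaned)) out <- fill_holes(largest_component(out), Inf)
  structure(
    list(pixels = out, offset = c(r0 - 1L, c0 - 1L), center = well,
         empty_flag = !any(out), degenerate_otsu = ot$degenerate),
    class = "spheromon_mask")
}

#' @export
print.spheromon_mask <- function(x, ...) {
  cat(sprintf("<spheromon_mask> %d px at offset (%d,%d)%s\n",
              sum(x$pixels), x$offset[1], x$offset[2],
              if (x$empty_flag) " [empty]" else ""))
  invisible(x)
}

# accept spheromon_mask or plain logical matrix
mask_pixels <- function(mask) {
  if (inherits(mask, "spheromon_mask")) mask$pixels
  else if (is.logical(mask) && is.matrix(mask)) mask
  else stop("expected a spheromon_mask or logical matrix")
}
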