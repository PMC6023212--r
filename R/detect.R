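## Microwell detection: Roberts gradient, fixed threshold, two-stage
## circular Hough transform, then false-positive and boundary filtering.

#' Default detection parameters
#'
#' Radius range, sensitivity and edge threshold follow the reference
#' operating point for 200-um microwells imaged at 4x (outer rim radius
#' 80-86 px); the gradient threshold for edge extraction is 0.015. The
#' strength fraction of the false-positive filter and the inter-well pitch
#' (300 um = 225 px) are configurable.
#'
#' @return A named list of parameters.
#' @export
detection_params <- function() {
  list(r_min = 80L, r_max = 86L, sensitivity = 0.975, edge_threshold = 0.030,
       gradient_threshold = 0.015, pitch_px = 225, strength_fraction = 0.5)
}

#' Roberts gradient magnitude
#'
#' The Roberts cross operator on the 2x2 neighbourhood:
#' `Gx(r,c) = I(r,c) - I(r+1,c+1)`, `Gy(r,c) = I(r+1,c) - I(r,c+1)`;
#' the magnitude `sqrt(Gx^2 + Gy^2)` is returned without normalisation.
#' Samples beyond the last row/column are zero-padded, so the outermost
#' row and column respond to the image border itself (they lie outside any
#' accepted well and are discarded downstream).
#'
#' @param frame a [new_frame()] object or numeric matrix.
#' @return A non-negative numeric matrix of the same shape.
#' @export
roberts_gradient <- function(frame) {
  px <- frame_pixels(frame)
  nr <- nrow(px); nc <- ncol(px)
  pad <- matrix(0, nr + 1L, nc + 1L)
  pad[seq_len(nr), seq_len(nc)] <- px
  gx <- pad[seq_len(nr), seq_len(nc)] - pad[seq_len(nr) + 1L, seq_len(nc) + 1L]
  gy <- pad[seq_len(nr) + 1L, seq_len(nc)] - pad[seq_len(nr), seq_len(nc) + 1L]
  sqrt(gx^2 + gy^2)
}

#' Threshold a gradient image
#'
#' A pixel is edge iff its gradient strictly exceeds `tau` (strict
#' inequality by convention; a value exactly equal to the threshold is
#' background).
#'
#' @param gradient numeric matrix of gradient magnitudes.
#' @param tau non-negative threshold (0.015 for microwell detection).
#' @return A logical matrix.
#' @export
threshold_gradient <- function(gradient, tau = 0.015) {
  stopifnot(tau >= 0)
  gradient > tau
}

# 2D max filter over a (2h+1)^2 window; separable shift/pmax passes
max_filter <- function(m, h) {
  rowpass <- m
  for (dr in seq_len(h)) {
    rowpass <- pmax(rowpass, shift_num(m, dr, 0), shift_num(m, -dr, 0))
  }
  out <- rowpass
  for (dc in seq_len(h)) {
    out <- pmax(out, shift_num(rowpass, 0, dc), shift_num(rowpass, 0, -dc))
  }
  out
}

shift_num <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(-Inf, nr, nc)
  rs <- seq_len(nr) - dr; cs <- seq_len(nc) - dc
  rok <- rs >= 1L & rs <= nr; cok <- cs >= 1L & cs <= nc
  out[rok, cok] <- m[rs[rok], cs[cok]]
  out
}

box_smooth3 <- function(m) {
  out <- matrix(0, nrow(m), ncol(m))
  for (dr in -1:1) for (dc in -1:1) {
    s <- shift_num(m, dr, dc)
    s[!is.finite(s)] <- 0
    out <- out + s
  }
  out / 9
}

#' Two-stage circular Hough transform
#'
#' Stage 1 accumulates centre votes from edge pixels over the whole radius
#' range: every edge pixel casts votes on circles of each integer radius in
#' `[r_min, r_max]` around itself, so true circle centres collect the
#' aligned votes of their rim pixels. The (3x3-smoothed) accumulator is
#' scanned for local maxima; a peak is accepted when its height reaches
#' `(1 - sensitivity)` of the global accumulator maximum, so acceptance
#' scales with `1 - sensitivity`. Centres are refined to sub-pixel accuracy
#' by the vote-weighted centroid of the peak neighbourhood. Stage 2 assigns
#' each accepted centre the radius maximising the radial edge support
#' (histogram of rounded edge-pixel distances over the radius range, with a
#' parabolic refinement).
#'
#' Edge pixels are the cells of `grid` strictly exceeding `edge_threshold`,
#' which accommodates both binary images (any threshold in (0,1)) and raw
#' gradient magnitudes.
#'
#' @param grid numeric or logical matrix (binary edge map or gradient).
#' @param r_min,r_max radius search range in pixels.
#' @param sensitivity acceptance sensitivity in `[0, 1]`; higher accepts
#'   weaker accumulator peaks.
#' @param edge_threshold gating threshold for edge pixels.
#' @return A data frame with columns `cx`, `cy` (sub-pixel centre), `r`
#'   (radius, px) and `strength` (accumulator votes), sorted by descending
#'   strength.
#' @export
detect_circles <- function(grid, r_min = 80L, r_max = 86L,
                           sensitivity = 0.975, edge_threshold = 0.030) {
  if (r_min > r_max) stop("r_min must not exceed r_max")
  if (is.logical(grid)) grid <- grid * 1
  stopifnot(all(is.finite(grid)))
  empty <- data.frame(cx = numeric(0), cy = numeric(0), r = numeric(0),
                      strength = numeric(0))
  edges <- which(grid > edge_threshold, arr.ind = TRUE)
  if (nrow(edges) == 0L) return(empty)
  acc <- .hough_vote(edges[, 1], edges[, 2], nrow(grid), ncol(grid),
                     as.integer(r_min), as.integer(r_max))
  accs <- box_smooth3(acc)
  amax <- max(accs)
  if (amax <= 0) return(empty)
  thr <- (1 - sensitivity) * amax
  peak_sep <- max(3L, as.integer(floor(r_min / 4)))
  loc <- accs >= thr & accs >= max_filter(accs, peak_sep) & accs > 0
  cand <- which(loc, arr.ind = TRUE)
  if (nrow(cand) == 0L) return(empty)
  # deduplicate ties within the separation window, strongest (then
  # row-major) first; cap the number of candidates passed to stage 2
  ord <- order(-accs[cand], cand[, 1], cand[, 2])
  cand <- cand[ord, , drop = FALSE]
  if (nrow(cand) > 2048L) cand <- cand[seq_len(2048L), , drop = FALSE]
  kept <- matrix(numeric(0), ncol = 2)
  for (i in seq_len(nrow(cand))) {
    p <- cand[i, ]
    if (nrow(kept) == 0L ||
        all(pmax(abs(kept[, 1] - p[1]), abs(kept[, 2] - p[2])) > peak_sep))
      kept <- rbind(kept, p)
    if (nrow(kept) >= 256L) break  # bounded stage-2 workload
  }
  res <- lapply(seq_len(nrow(kept)), function(i) {
    pr <- kept[i, 1]; pc <- kept[i, 2]
    # sub-pixel centre: vote-weighted centroid of the 7x7 neighbourhood
    rs <- max(1, pr - 3):min(nrow(accs), pr + 3)
    cs <- max(1, pc - 3):min(ncol(accs), pc + 3)
    w <- accs[rs, cs, drop = FALSE]
    cy <- sum(outer(rs, rep(1, length(cs))) * w) / sum(w)
    cx <- sum(outer(rep(1, length(rs)), cs) * w) / sum(w)
    h <- .radial_hist(edges[, 1], edges[, 2], cy, cx,
                      as.integer(r_min), as.integer(r_max))
    k <- which.max(h)
    r <- r_min + k - 1
    # parabolic refinement on the histogram peak
    if (k > 1 && k < length(h)) {
      denom <- h[k - 1] - 2 * h[k] + h[k + 1]
      if (denom < 0) r <- r + 0.5 * (h[k - 1] - h[k + 1]) / denom
    }
    data.frame(cx = cx, cy = cy, r = r, strength = accs[pr, pc])
  })
  res <- do.call(rbind, res)
  res[order(-res$strength, res$cx, res$cy), , drop = FALSE]
}

#' Filter circle detections
#'
#' Removes false positives and boundary-clipped wells in three steps:
#' (a) detections whose strength falls below `strength_fraction` times the
#' median strength are dropped (applied to convergence, so the operation is
#' idempotent); (b) greedy strongest-first suppression removes any
#' detection whose centre lies closer than `0.8 * pitch` to an already-kept
#' detection; (c) detections whose centre is nearer than their radius to an
#' image edge (wells not completely inside the field of view) are dropped.
#'
#' @param detections data frame from [detect_circles()].
#' @param frame_shape integer `c(rows, cols)`.
#' @param pitch expected centre-to-centre well spacing in pixels.
#' @param strength_fraction relative circle-strength cutoff in `(0, 1]`.
#' @return The filtered data frame (possibly empty), strongest first.
#' @export
filter_detections <- function(detections, frame_shape, pitch = 225,
                              strength_fraction = 0.5) {
  stopifnot(pitch > 0, strength_fraction > 0, strength_fraction <= 1)
  d <- detections
  if (nrow(d) == 0L) return(d)
  # (a) relative circle strength, iterated to a fixed point so that
  # re-filtering an already-filtered list changes nothing
  repeat {
    ok <- d$strength >= strength_fraction * median(d$strength)
    if (all(ok)) break
    d <- d[ok, , drop = FALSE]
    if (nrow(d) == 0L) return(d)
  }
  # (b) spacing suppression, strongest first (ties by cx, cy)
  d <- d[order(-d$strength, d$cx, d$cy), , drop = FALSE]
  keep <- logical(nrow(d))
  for (i in seq_len(nrow(d))) {
    ki <- which(keep)
    keep[i] <- !length(ki) ||
      all(sqrt((d$cx[ki] - d$cx[i])^2 + (d$cy[ki] - d$cy[i])^2) >=
            0.8 * pitch)
  }
  d <- d[keep, , drop = FALSE]
  # (c) complete-containment in the field of view
  inside <- d$cx - d$r >= 0.5 & d$cx + d$r <= frame_shape[2] + 0.5 &
            d$cy - d$r >= 0.5 & d$cy + d$r <= frame_shape[1] + 0.5
  d <- d[inside, , drop = FALSE]
  rownames(d) <- NULL
  d
}

#' Detect microwells in a frame
#'
#' Convenience wrapper chaining [roberts_gradient()],
#' [threshold_gradient()], [detect_circles()] and [filter_detections()].
#' The last image row and column of the gradient — a pure artifact of the
#' zero-padded Roberts kernels, responding to the image border itself — are
#' suppressed before edge extraction so that border responses can never
#' aggregate into a spurious circle.
#'
#' @param frame a [new_frame()] object or intensity matrix.
#' @param params parameter list from [detection_params()].
#' @return A data frame of accepted detections (`cx`, `cy`, `r`,
#'   `strength`).
#' @export
detect_wells <- function(frame, params = detection_params()) {
  px <- frame_pixels(frame)
  g <- roberts_gradient(px)
  g[nrow(g), ] <- 0
  g[, ncol(g)] <- 0
  b <- threshold_gradient(g, params$gradient_threshold)
  d <- detect_circles(b, params$r_min, params$r_max, params$sensitivity,
                      params$edge_threshold)
  filter_detections(d, dim(px), params$pitch_px, params$strength_fraction)
}
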