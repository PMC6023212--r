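## Quantitative validation: per-feature relative error, pixel-level
## sensitivity (TPR) and precision (PPV), per-set summaries and overlays.

#' Relative error of an automatically measured feature
#'
#' `|MS - AS| / |MS| * 100`, where `MS` is the reference (manual or
#' ground-truth) value and `AS` the automatic one. A zero reference yields
#' `NA` (undefined), which set summaries exclude.
#'
#' @param ms reference value(s).
#' @param as_ automatic value(s).
#' @return Relative error in percent (vectorised).
#' @export
relative_error <- function(ms, as_) {
  out <- abs(ms - as_) / abs(ms) * 100
  out[ms == 0] <- NA_real_
  out
}

#' Pixel-level confusion between a reference and a predicted mask
#'
#' `TP` counts pixels in both masks, `FP` pixels only in the prediction,
#' `FN` pixels only in the reference; `TPR = TP / (TP + FN)` (sensitivity)
#' and `PPV = TP / (TP + FP)` (precision). An empty reference leaves `TPR`
#' undefined (`NA`); an empty prediction leaves `PPV` undefined.
#'
#' Masks may be plain logical matrices of identical shape, or
#' `spheromon_mask` crops with offsets, which are aligned in full-frame
#' coordinates before counting.
#'
#' @param truth,pred masks to compare.
#' @return A one-row data frame `TP, FP, FN, TPR, PPV`.
#' @export
pixel_confusion <- function(truth, pred) {
  al <- align_masks(truth, pred)
  tp <- sum(al$a & al$b)
  fp <- sum(al$b & !al$a)
  fn <- sum(al$a & !al$b)
  data.frame(TP = tp, FP = fp, FN = fn,
             TPR = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
             PPV = if (tp + fp > 0) tp / (tp + fp) else NA_real_)
}

# embed two masks (possibly offset crops) on a common grid
align_masks <- function(a, b) {
  offa <- if (inherits(a, "spheromon_mask")) a$offset else c(0L, 0L)
  offb <- if (inherits(b, "spheromon_mask")) b$offset else c(0L, 0L)
  ma <- mask_pixels(a); mb <- mask_pixels(b)
  if (identical(offa, offb) && all(dim(ma) == dim(mb)))
    return(list(a = ma, b = mb))
  if (!inherits(a, "spheromon_mask") && !inherits(b, "spheromon_mask"))
    stop("mask shapes differ")
  r0 <- min(offa[1], offb[1]); c0 <- min(offa[2], offb[2])
  r1 <- max(offa[1] + nrow(ma), offb[1] + nrow(mb))
  c1 <- max(offa[2] + ncol(ma), offb[2] + ncol(mb))
  pa <- pb <- matrix(FALSE, r1 - r0, c1 - c0)
  pa[(offa[1] - r0) + seq_len(nrow(ma)), (offa[2] - c0) + seq_len(ncol(ma))] <- ma
  pb[(offb[1] - r0) + seq_len(nrow(mb)), (offb[2] - c0) + seq_len(ncol(mb))] <- mb
  list(a = pa, b = pb)
}

#' Intersection-over-union of two masks
#'
#' @param truth,pred masks as in [pixel_confusion()].
#' @return IoU in `[0, 1]` (`NA` when both masks are empty).
#' @export
mask_iou <- function(truth, pred) {
  al <- align_masks(truth, pred)
  u <- sum(al$a | al$b)
  if (u == 0) return(NA_real_)
  sum(al$a & al$b) / u
}

#' Per-set summary of validation metrics
#'
#' Summarises per-spheroid validation results as mean and sample standard
#' deviation (n - 1 denominator) per set, plus a pooled column computed
#' over all spheroids (with equal set sizes this coincides with the mean of
#' per-set means). Undefined values (`NA`, e.g. zero-reference relative
#' errors) are excluded and counted.
#'
#' @param results data frame of per-spheroid metrics with a `set` column;
#'   all other numeric columns are summarised.
#' @param pooled_label label of the pooled column (default "Set 1-4" style
#'   is derived from the data).
#' @return A data frame with columns `set, metric, mean, sd, n, n_excluded`.
#' @export
set_summary <- function(results, pooled_label = NULL) {
  stopifnot("set" %in% names(results))
  metrics <- names(results)[vapply(results, is.numeric, TRUE)]
  sets <- unique(results$set)
  if (is.null(pooled_label))
    pooled_label <- paste0(sets[1], "-", length(sets))
  groups <- c(stats::setNames(as.list(sets), sets),
              stats::setNames(list(sets), pooled_label))
  out <- list()
  for (g in names(groups)) {
    sub <- results[results$set %in% groups[[g]], , drop = FALSE]
    for (m in metrics) {
      v <- sub[[m]]
      nex <- sum(is.na(v))
      v <- v[!is.na(v)]
      out[[length(out) + 1L]] <- data.frame(
        set = g, metric = m, mean = mean(v),
        sd = if (length(v) > 1) sd(v) else NA_real_,
        n = length(v), n_excluded = nex)
    }
  }
  do.call(rbind, out)
}

#' Overlay masks on a frame
#'
#' Renders the grayscale frame as RGB and alpha-blends the mask pixels with
#' a solid colour (semi-transparent red by default), the standard
#' qualitative-assessment rendering.
#'
#' @param frame a [new_frame()] object or intensity matrix.
#' @param masks a single mask or list of masks (logical matrices of frame
#'   shape, or `spheromon_mask` crops with offsets).
#' @param alpha blend weight of the overlay colour in `[0, 1]`.
#' @param color overlay colour as an RGB triple in `[0, 1]`.
#' @return A numeric array `rows x cols x 3`.
#' @export
overlay_masks <- function(frame, masks, alpha = 0.4, color = c(1, 0, 0)) {
  px <- frame_pixels(frame)
  if (inherits(masks, "spheromon_mask") ||
      (is.matrix(masks) && is.logical(masks))) masks <- list(masks)
  cover <- matrix(FALSE, nrow(px), ncol(px))
  for (m in masks) {
    mm <- mask_pixels(m)
    off <- if (inherits(m, "spheromon_mask")) m$offset else c(0L, 0L)
    if (!inherits(m, "spheromon_mask") && !all(dim(mm) == dim(px)))
      stop("mask shape does not match frame")
    rs <- off[1] + seq_len(nrow(mm)); cs <- off[2] + seq_len(ncol(mm))
    rok <- rs >= 1 & rs <= nrow(px); cok <- cs >= 1 & cs <= ncol(px)
    cover[rs[rok], cs[cok]] <- cover[rs[rok], cs[cok]] | mm[rok, cok]
  }
  out <- array(0, c(nrow(px), ncol(px), 3))
  for (ch in 1:3) {
    plane <- px
    plane[cover] <- (1 - alpha) * plane[cover] + alpha * color[ch]
    out[, , ch] <- plane
  }
  out
}
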