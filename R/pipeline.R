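## End-to-end orchestration: read frames, detect wells, segment spheroids,
## extract features, track, summarise; reproducible artifacts on disk.

#' Assemble a run configuration
#'
#' Bundles all module parameter blocks with acquisition metadata. The
#' configuration round-trips losslessly through
#' [write_yaml_config()]/[read_yaml_config()].
#'
#' @param frame_interval minutes between frames (default 5).
#' @param pixel_size_um physical pixel size, um/px (default 4/3).
#' @param detection,segmentation,tracking module parameter blocks.
#' @param write_masks write per-well mask PNGs when an output directory is
#'   given.
#' @param seed integer seed for any stochastic phantom use.
#' @param log_level `"quiet"`, `"info"` or `"debug"`.
#' @return A named list of class `spheromon_config`.
#' @export
run_config <- function(frame_interval = 5, pixel_size_um = 4 / 3,
                       detection = detection_params(),
                       segmentation = segmentation_params(),
                       tracking = list(max_shift = 112),
                       write_masks = FALSE, seed = 1L,
                       log_level = c("info", "quiet", "debug")) {
  structure(list(frame_interval = frame_interval,
                 pixel_size_um = pixel_size_um,
                 detection = detection, segmentation = segmentation,
                 tracking = tracking, write_masks = write_masks,
                 seed = as.integer(seed),
                 log_level = match.arg(log_level)),
            class = c("spheromon_config", "list"))
}

log_msg <- function(config, level, ...) {
  lv <- c(quiet = 0, info = 1, debug = 2)
  if (lv[[config$log_level %||% "info"]] >= lv[[level]])
    message(sprintf(...))
}

# list input frames of a directory, ordered by the numeric suffix of the
# file name (zero-padded acquisition numbering)
list_frame_files <- function(dir) {
  files <- list.files(dir, pattern = "\\.tiff?$", full.names = TRUE,
                      ignore.case = TRUE)
  if (!length(files)) stop("no TIFF frames found in ", dir)
  num <- suppressWarnings(as.integer(sub(".*?([0-9]+)\\.[^.]+$", "\\1",
                                         basename(files))))
  num[is.na(num)] <- seq_along(files)[is.na(num)] + 1e6L
  files[order(num, basename(files))]
}

#' Run the full pipeline on a time-lapse dataset
#'
#' For every frame: microwell detection (Roberts gradient, fixed threshold,
#' two-stage circular Hough, false-positive filtering), per-well spheroid
#' segmentation, feature extraction, and frame-to-frame track linking.
#' Wells are re-detected in every frame (robust to insert drift). Corrupt
#' or unreadable frames are logged and skipped, leaving a gap in the
#' tracks; a frame with zero detections is logged and the active tracks
#' carry over to the next frame.
#'
#' @param input directory containing TIFF frames (ordered by the numeric
#'   suffix of their file names), or a list of [new_frame()] objects /
#'   intensity matrices.
#' @param config a [run_config()].
#' @param out_dir optional output directory; when given, per-frame
#'   detections, the long-format track/feature table, population summaries
#'   for every feature, the configuration and a run manifest are written
#'   (plus mask PNGs if `config$write_masks`).
#' @param keep_masks return the per-frame segmentation masks in the result
#'   (memory-heavy for long runs).
#' @return A list with `detections`, `tracks` (long-format per-observation
#'   feature table), `population` (per-feature summaries), `manifest`, and
#'   optionally `masks`.
#' @export
run_timelapse <- function(input, config = run_config(), out_dir = NULL,
                          keep_masks = FALSE) {
  from_dir <- is.character(input)
  files <- if (from_dir) list_frame_files(input) else NULL
  n <- if (from_dir) length(files) else length(input)
  if (n < 1) stop("no input frames")
  tracker <- new_tracker()
  det_rows <- list()
  masks_out <- if (keep_masks) vector("list", n) else NULL
  skipped <- integer(0)
  counts <- data.frame(frame = integer(0), detected = integer(0),
                       segmented = integer(0), empty = integer(0))
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  for (i in seq_len(n)) {
    fidx <- i - 1L
    t_min <- fidx * config$frame_interval
    frame <- tryCatch({
      if (from_dir) new_frame(read_tiff_gray16(files[i]), fidx, t_min)
      else {
        f <- input[[i]]
        if (inherits(f, "spheromon_frame")) f else new_frame(f, fidx, t_min)
      }
    }, error = function(e) {
      warning(sprintf("frame %d unreadable (%s); skipped", fidx,
                      conditionMessage(e)), call. = FALSE)
      NULL
    })
    if (is.null(frame)) { skipped <- c(skipped, fidx); next }
    det <- detect_wells(frame, config$detection)
    if (nrow(det) == 0L) {
      log_msg(config, "info", "frame %d: no wells detected", fidx)
      counts <- rbind(counts, data.frame(frame = fidx, detected = 0L,
                                         segmented = 0L, empty = 0L))
      next  # active tracks carry over
    }
    grad <- roberts_gradient(frame)
    feats <- list()
    fmasks <- list()
    for (j in seq_len(nrow(det))) {
      sm <- segment_spheroid(frame, grad, det[j, , drop = FALSE],
                             config$segmentation)
      fr <- extract_features(sm, config$pixel_size_um)
      fr$cx <- det$cx[j]; fr$cy <- det$cy[j]  # well centre drives tracking
      fr$well_r <- det$r[j]; fr$strength <- det$strength[j]
      feats[[j]] <- fr
      fmasks[[j]] <- sm
      if (!is.null(out_dir) && isTRUE(config$write_masks))
        write_png_gray8(sm$pixels, file.path(
          out_dir, sprintf("well%03d_f%04d.png", j, fidx)))
    }
    featdf <- do.call(rbind, feats)
    tracker <- link_frames(tracker, featdf, fidx, t_min,
                           config$tracking$max_shift %||% 112)
    if (keep_masks) masks_out[[i]] <- fmasks
    det$frame <- fidx
    det_rows[[length(det_rows) + 1L]] <- det
    counts <- rbind(counts, data.frame(
      frame = fidx, detected = nrow(det), segmented = nrow(det),
      empty = sum(featdf$empty_flag)))
    log_msg(config, "debug", "frame %d: %d wells, %d empty", fidx,
            nrow(det), sum(featdf$empty_flag))
  }
  detections <- if (length(det_rows)) do.call(rbind, det_rows) else
    data.frame()
  tracks <- track_table(tracker)
  feat_cols <- intersect(
    c("area_px", "area_um2", "perimeter_px", "minor_px", "major_px",
      "roundness", "circularity", "eq_diam_px", "eccentricity", "solidity"),
    names(tracks))
  population <- lapply(stats::setNames(feat_cols, feat_cols),
                       function(f) population_average(tracks, f))
  cfg_raw <- serialize(unclass(config), NULL, version = 2L)
  manifest <- list(
    package = "spheromon",
    version = as.character(utils::packageVersion("spheromon")),
    n_frames_in = n, n_frames_processed = n - length(skipped),
    skipped_frames = skipped, config_crc32 = .crc32(cfg_raw, 0),
    frame_files = if (from_dir) basename(files) else NULL,
    stage_counts = counts)
  if (!is.null(out_dir)) {
    write.csv(detections, file.path(out_dir, "detections.csv"),
              row.names = FALSE)
    write.csv(tracks, file.path(out_dir, "tracks.csv"), row.names = FALSE)
    pop <- do.call(rbind, lapply(names(population), function(f)
      cbind(data.frame(feature = f), population[[f]])))
    write.csv(pop, file.path(out_dir, "population.csv"), row.names = FALSE)
    write_yaml_config(unclass(config), file.path(out_dir, "config.yaml"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out <- list(detections = detections, tracks = tracks,
              population = population, manifest = manifest)
  if (keep_masks) out$masks <- masks_out
  out
}

#' Validate the pipeline against phantom ground truth
#'
#' Runs the full detection + segmentation pipeline on a phantom benchmark
#' (see [validation_benchmark()]) and compares the predicted masks with the
#' generator truth: pixel-level sensitivity/precision and per-feature
#' relative errors (truth as the reference of the relative error), plus
#' per-set and pooled summaries.
#'
#' @param bench benchmark structure from [validation_benchmark()].
#' @param detection,segmentation parameter blocks.
#' @param match_radius maximum centre distance (px) for pairing a
#'   detection with a truth well.
#' @return A list with `per_spheroid` (one row per validated well),
#'   `detection` (per-frame recall/precision of well detection), and
#'   `summary` (a [set_summary()] table).
#' @export
run_validation <- function(bench, detection = detection_params(),
                           segmentation = segmentation_params(),
                           match_radius = 15) {
  per <- list(); dets <- list()
  for (set in bench) {
    for (f in seq_along(set$frames)) {
      frame <- set$frames[[f]]
      truth <- set$truth[[f]]
      det <- detect_wells(frame, detection)
      tw <- truth$wells[truth$wells$fully_visible, , drop = FALSE]
      matched <- rep(NA_integer_, nrow(tw))
      used <- logical(nrow(det))
      for (i in seq_len(nrow(tw))) {
        if (!nrow(det)) break
        d <- sqrt((det$cx - tw$cx[i])^2 + (det$cy - tw$cy[i])^2)
        d[used] <- Inf
        j <- which.min(d)
        if (d[j] <= match_radius) { matched[i] <- j; used[j] <- TRUE }
      }
      dets[[length(dets) + 1L]] <- data.frame(
        set = set$label, frame = f, n_truth = nrow(tw), n_det = nrow(det),
        n_matched = sum(!is.na(matched)),
        recall = sum(!is.na(matched)) / nrow(tw),
        precision = if (nrow(det)) sum(used) / nrow(det) else NA_real_)
      grad <- roberts_gradient(frame)
      for (i in seq_len(nrow(tw))) {
        tm <- truth$masks[[as.character(tw$well_id[i])]]
        if (is.null(tm) || tm$empty_flag) next
        if (is.na(matched[i])) {
          per[[length(per) + 1L]] <- data.frame(
            set = set$label, frame = f, well_id = tw$well_id[i],
            detected = FALSE, TPR = 0, PPV = NA_real_, iou = 0,
            minor_axis = NA_real_, major_axis = NA_real_,
            roundness = NA_real_, area = NA_real_, perimeter = NA_real_,
            circularity = NA_real_)
          next
        }
        pm <- segment_spheroid(frame, grad,
                               det[matched[i], , drop = FALSE], segmentation)
        pc <- pixel_confusion(tm, pm)
        ft <- extract_features(tm)
        fp <- extract_features(pm)
        per[[length(per) + 1L]] <- data.frame(
          set = set$label, frame = f, well_id = tw$well_id[i],
          detected = TRUE, TPR = pc$TPR, PPV = pc$PPV,
          iou = mask_iou(tm, pm),
          minor_axis = relative_error(ft$minor_px, fp$minor_px),
          major_axis = relative_error(ft$major_px, fp$major_px),
          roundness = relative_error(ft$roundness, fp$roundness),
          area = relative_error(ft$area_px, fp$area_px),
          perimeter = relative_error(ft$perimeter_px, fp$perimeter_px),
          circularity = relative_error(ft$circularity, fp$circularity))
      }
    }
  }
  per <- do.call(rbind, per)
  summary_cols <- per[, c("set", "TPR", "PPV", "iou", "minor_axis",
                          "major_axis", "roundness", "area", "perimeter",
                          "circularity")]
  list(per_spheroid = per, detection = do.call(rbind, dets),
       summary = set_summary(summary_cols, pooled_label = "Set 1-4"))
}

#' Export a monitoring video of a processed run
#'
#' Builds semi-transparent red overlays of the segmentation masks on their
#' frames, stamps each well with the rounded spheroid area, and encodes the
#' sequence as an uncompressed AVI at `fps` frames per second (default 5).
#'
#' @param frames list of frames (matrices or [new_frame()] objects).
#' @param masks per-frame lists of masks, as from
#'   `run_timelapse(..., keep_masks = TRUE)$masks`.
#' @param path output `.avi` path.
#' @param fps frames per second.
#' @param annotate stamp per-well area labels.
#' @return The path, invisibly.
#' @export
export_video <- function(frames, masks, path, fps = 5, annotate = TRUE) {
  if (!length(frames) || length(frames) != length(masks))
    stop("frames and masks must be non-empty lists of equal length")
  imgs <- lapply(seq_along(frames), function(i) {
    ov <- overlay_masks(frames[[i]], masks[[i]])
    if (annotate) {
      for (m in masks[[i]]) {
        if (m$empty_flag) next
        fr <- extract_features(m)
        ov <- draw_label(ov, sprintf("%d", round(fr$area_px)),
                         x = round(fr$cx) - 10L, y = round(fr$cy) - 3L,
                         scale = 2L, value = c(1, 1, 0))
      }
    }
    ov
  })
  write_avi(imgs, path, fps)
}
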