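## Frame-to-frame linking of detected wells/spheroids into tracks and
## population-level aggregation of the per-track feature series.

#' Create an empty tracker state
#'
#' @return An object of class `spheromon_tracker` holding the track table
#'   and the registry of active tracks.
#' @export
new_tracker <- function() {
  structure(list(
    next_id = 1L,
    active = data.frame(track_id = integer(0), cx = numeric(0),
                        cy = numeric(0)),
    lost = integer(0),
    rows = list()), class = "spheromon_tracker")
}

#' @export
print.spheromon_tracker <- function(x, ...) {
  cat(sprintf("<spheromon_tracker> %d active, %d lost, %d observations\n",
              nrow(x$active), length(x$lost), length(x$rows)))
  invisible(x)
}

#' Link one frame of detections into the track state
#'
#' Greedy mutual-nearest-neighbour assignment between the active tracks'
#' last centres and the new detections, restricted to pairs closer than
#' `max_shift` (default: inner well radius plus half the inter-well gap,
#' 75 + 37 = 112 px, below which assignment is unambiguous at a 225-px well
#' pitch). Unmatched detections start new tracks; unmatched active tracks
#' become `lost` and their ids are never reused, so a well re-entering the
#' field of view starts a new track. Ties (including exactly duplicated
#' centres) are resolved deterministically by `(cx, cy)` order.
#'
#' @param tracker a [new_tracker()] state.
#' @param detections data frame with columns `cx`, `cy` (one row per
#'   detected well), optionally extended by feature columns to store.
#' @param frame_index 0-based frame index.
#' @param time_min acquisition time of this frame, minutes.
#' @param max_shift linking threshold, px.
#' @return The updated tracker; the per-observation table is available via
#'   [track_table()].
#' @export
link_frames <- function(tracker, detections, frame_index, time_min,
                        max_shift = 112) {
  stopifnot(inherits(tracker, "spheromon_tracker"))
  det <- as.data.frame(detections)
  if (nrow(det))
    det <- det[order(det$cx, det$cy), , drop = FALSE]
  nA <- nrow(tracker$active); nD <- nrow(det)
  assign_track <- integer(nD)  # 0 = unmatched
  if (nA > 0 && nD > 0) {
    dist <- outer(tracker$active$cx, det$cx, "-")^2 +
            outer(tracker$active$cy, det$cy, "-")^2
    dist <- sqrt(dist)
    dist[dist > max_shift] <- Inf
    # mutual nearest neighbours, greedy by increasing distance
    repeat {
      if (all(!is.finite(dist))) break
      k <- which.min(dist)  # ties: first in column-major = (cx, cy) order
      i <- (k - 1) %% nA + 1; j <- (k - 1) %/% nA + 1
      assign_track[j] <- tracker$active$track_id[i]
      dist[i, ] <- Inf
      dist[, j] <- Inf
    }
  }
  newA <- data.frame(track_id = integer(0), cx = numeric(0), cy = numeric(0))
  for (j in seq_len(nD)) {
    if (assign_track[j] == 0L) {
      assign_track[j] <- tracker$next_id
      tracker$next_id <- tracker$next_id + 1L
    }
    newA <- rbind(newA, data.frame(track_id = assign_track[j],
                                   cx = det$cx[j], cy = det$cy[j]))
    row <- cbind(data.frame(track_id = assign_track[j],
                            frame = as.integer(frame_index),
                            time_min = time_min), det[j, , drop = FALSE])
    rownames(row) <- NULL
    tracker$rows[[length(tracker$rows) + 1L]] <- row
  }
  lost_now <- setdiff(tracker$active$track_id, newA$track_id)
  tracker$lost <- c(tracker$lost, lost_now)
  tracker$active <- newA
  tracker
}

#' Long-format track table
#'
#' One row per (track, frame) observation, with a `status` column marking
#' tracks that were lost before the last processed frame.
#'
#' @param tracker a tracker state after [link_frames()] calls.
#' @return A data frame.
#' @export
track_table <- function(tracker) {
  stopifnot(inherits(tracker, "spheromon_tracker"))
  if (!length(tracker$rows))
    return(data.frame(track_id = integer(0), frame = integer(0),
                      time_min = numeric(0)))
  tab <- do.call(rbind, tracker$rows)
  tab$status <- ifelse(tab$track_id %in% tracker$lost, "lost", "active")
  rownames(tab) <- NULL
  tab[order(tab$track_id, tab$frame), , drop = FALSE]
}

#' Population-level average of a tracked feature
#'
#' Per frame, the mean and sample standard deviation (n - 1 denominator)
#' over all tracks with a non-missing value of the feature at that frame;
#' missing values are excluded, not zero-filled, and the contributing count
#' `n` is reported.
#'
#' @param tracks long-format table from [track_table()] (or any data frame
#'   with `frame`, `time_min` and the feature column).
#' @param feature_name column to average (e.g. `"area_px"`).
#' @param condition_label optional label attached to the output.
#' @return A data frame `frame, time_min, mean, sd, n` (+ `condition`).
#' @export
population_average <- function(tracks, feature_name, condition_label = NULL) {
  if (!feature_name %in% names(tracks))
    stop(sprintf("unknown feature '%s'", feature_name))
  frames <- sort(unique(tracks$frame))
  out <- lapply(frames, function(f) {
    v <- tracks[[feature_name]][tracks$frame == f]
    t <- tracks$time_min[tracks$frame == f][1]
    v <- v[!is.na(v)]
    data.frame(frame = f, time_min = t,
               mean = if (length(v)) mean(v) else NA_real_,
               sd = if (length(v) > 1) sd(v) else NA_real_,
               n = length(v))
  })
  out <- do.call(rbind, out)
  if (!is.null(condition_label)) out$condition <- condition_label
  out
}
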