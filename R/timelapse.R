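#' Link cells across frames and detect division events
#'
#' Tracks cells between consecutive frames by maximal overlap of their
#' bounding extents (non-motile cells at 20-min intervals barely move, so a
#' motion model is unnecessary). A cell in frame t claimed by exactly one
#' cell in frame t+1 is a continuation; a cell claimed by two is a division,
#' yielding one event with the parent's cluster signal (frame t) and both
#' daughters' signals (frame t+1). Daughters with ambiguous parentage (tied
#' maximal overlap with two parents) are flagged and excluded from fission
#' statistics.
#'
#' @param frames Data frame of per-frame cell records with columns `frame`,
#'   `cell_id`, `x0`, `x1`, `y0`, `y1`, `cluster_signal` (as produced by
#'   [simulate_timelapse()], or from segmented data).
#' @return List of class `lineage_map`: `events` (data frame: `parent_id`,
#'   `daughter1`, `daughter2`, `frame`, `parent_cluster_signal`,
#'   `daughter_signal1`, `daughter_signal2`), `links` (frame-to-frame
#'   assignments), `flagged` (ambiguous daughter ids).
#' @export
link_generations <- function(frames) {
  if (is.list(frames) && !is.data.frame(frames) && !is.null(frames$frames))
    frames <- frames$frames
  need <- c("frame", "cell_id", "x0", "x1", "y0", "y1", "cluster_signal")
  if (!all(need %in% names(frames)))
    stop_input("frames must have columns ", paste(need, collapse = ", "))

  fids <- sort(unique(frames$frame))
  links <- list(); events <- list(); flagged <- character(0)
  for (k in seq_along(fids)[-1]) {
    prev <- frames[frames$frame == fids[k - 1], ]
    cur <- frames[frames$frame == fids[k], ]
    # overlap area between every current and previous record
    ov <- outer(seq_len(nrow(cur)), seq_len(nrow(prev)), function(i, j) {
      pmax(0, pmin(cur$x1[i], prev$x1[j]) - pmax(cur$x0[i], prev$x0[j])) *
        pmax(0, pmin(cur$y1[i], prev$y1[j]) - pmax(cur$y0[i], prev$y0[j]))
    })
    parent_idx <- integer(nrow(cur))
    for (i in seq_len(nrow(cur))) {
      best <- max(ov[i, ])
      if (best <= 0) { parent_idx[i] <- NA_integer_; next }  # new appearance
      cand <- which(ov[i, ] == best)
      if (length(cand) > 1) {
        flagged <- c(flagged, cur$cell_id[i])
        parent_idx[i] <- NA_integer_
      } else parent_idx[i] <- cand
    }
    links[[length(links) + 1]] <- data.frame(
      frame = fids[k], cell_id = cur$cell_id,
      parent_cell_id = ifelse(is.na(parent_idx), NA_character_,
                              prev$cell_id[parent_idx]))
    for (j in unique(parent_idx[!is.na(parent_idx)])) {
      kids <- which(parent_idx == j)
      if (length(kids) == 2 && prev$cell_id[j] != cur$cell_id[kids[1]] &&
          prev$cell_id[j] != cur$cell_id[kids[2]]) {
        events[[length(events) + 1]] <- data.frame(
          parent_id = prev$cell_id[j],
          daughter1 = cur$cell_id[kids[1]], daughter2 = cur$cell_id[kids[2]],
          frame = fids[k],
          parent_cluster_signal = prev$cluster_signal[j],
          daughter_signal1 = cur$cluster_signal[kids[1]],
          daughter_signal2 = cur$cluster_signal[kids[2]])
      } else if (length(kids) > 2) {
        flagged <- c(flagged, cur$cell_id[kids])
      }
    }
  }
  structure(list(events = if (length(events)) do.call(rbind, events)
                          else data.frame(),
                 links = do.call(rbind, links),
                 flagged = unique(flagged)),
            class = "lineage_map")
}

#' @export
print.lineage_map <- function(x, ...) {
  cat(sprintf("<lineage_map: %d division events, %d links, %d flagged>\n",
              nrow(x$events), nrow(x$links), length(x$flagged)))
  invisible(x)
}

#' Classify a division as with or without cluster fission
#'
#' With exactly one daughter's cluster signal at or above the detection
#' floor the undivided cluster segregated into that daughter
#' (`no_fission`). With both daughters above the floor the cluster underwent
#' fission, sub-labelled `fission_symmetric` when the smaller share of the
#' summed signal is at least `symmetric_cutoff`, else `fission_asymmetric`.
#' Events with both daughters below the floor (cluster lost) are returned as
#' `NA` with a warning and should be excluded from fission statistics.
#' The classification is invariant to daughter order.
#'
#' @param signal1,signal2 Daughter cluster signals (vectorized).
#' @param detection_floor Minimum signal counting as a visible cluster.
#' @param symmetric_cutoff Smaller-share cutoff separating symmetric from
#'   asymmetric fission.
#' @return Factor with levels `fission_symmetric`, `fission_asymmetric`,
#'   `no_fission` (NA for excluded events).
#' @export
classify_fission <- function(signal1, signal2, detection_floor = 10,
                             symmetric_cutoff = 0.3) {
  if (detection_floor < 0) stop_input("detection_floor must be >= 0")
  if (any(signal1 < 0 | signal2 < 0, na.rm = TRUE))
    stop_input("daughter signals must be >= 0")
  vis1 <- signal1 >= detection_floor
  vis2 <- signal2 >= detection_floor
  lost <- !vis1 & !vis2
  if (any(lost)) warning(sum(lost), " event(s) with no visible daughter cluster excluded")
  share <- pmin(signal1, signal2) / (signal1 + signal2)
  lab <- ifelse(lost, NA_character_,
         ifelse(xor(vis1, vis2), "no_fission",
         ifelse(share >= symmetric_cutoff, "fission_symmetric",
                "fission_asymmetric")))
  factor(lab, levels = c("fission_symmetric", "fission_asymmetric",
                         "no_fission"))
}

#' Summarize fission classes over tracked division events
#'
#' @param events The `events` table of a [link_generations()] result (or the
#'   result itself).
#' @param ... Passed to [classify_fission()].
#' @return List: `n_events`, `n_excluded`, `counts` per class,
#'   `fission_fraction` (symmetric + asymmetric over non-excluded events).
#' @export
fission_summary <- function(events, ...) {
  if (inherits(events, "lineage_map")) events <- events$events
  if (nrow(events) == 0) stop_input("no division events")
  cls <- classify_fission(events$daughter_signal1, events$daughter_signal2,
                          ...)
  ok <- !is.na(cls)
  counts <- table(cls[ok])
  list(n_events = nrow(events), n_excluded = sum(!ok), counts = counts,
       fission_fraction = sum(counts[c("fission_symmetric",
                                       "fission_asymmetric")]) / sum(ok))
}

#' Time from division to cluster regeneration in an empty daughter
#'
#' @param track Data frame of one daughter's per-frame records, starting at
#'   the division frame, with columns `frame` and `cluster_signal`.
#' @param frame_interval Minutes between frames.
#' @param detection_floor Minimum signal counting as a visible cluster.
#' @return List: `delay_min` (NA when censored), `censored`.
#' @export
regeneration_delay <- function(track, frame_interval, detection_floor = 10) {
  if (nrow(track) == 0) stop_input("empty track")
  track <- track[order(track$frame), ]
  hit <- which(track$cluster_signal >= detection_floor)
  if (length(hit) == 0) return(list(delay_min = NA_real_, censored = TRUE))
  list(delay_min = (track$frame[hit[1]] - track$frame[1]) * frame_interval,
       censored = FALSE)
}
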