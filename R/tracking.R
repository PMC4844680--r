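#' Track segmented cells across frames
#'
#' Greedy nearest-centroid matching frame to frame: each object in frame
#' k+1 is matched to the closest unmatched track end within
#' `max_displacement`; unmatched objects start new tracks, and tracks
#' without a match are left without an object for that frame (and are
#' therefore incomplete). Tracks never cross: a swap beyond
#' `max_displacement` terminates both tracks rather than exchanging them.
#'
#' @param frames list of per-frame segmentations (from [segment_movie()]),
#'   each with a `stats` data.frame carrying `label`, `centroid_x`,
#'   `centroid_y`.
#' @param max_displacement maximum centroid displacement (px) per frame.
#' @return data.frame with `track_id`, `frame`, `label`, and a `complete`
#'   logical per track (present in every frame), merged in.
#' @export
track_cells <- function(frames, max_displacement = 10) {
  stopifnot(length(frames) >= 2)
  cent <- function(k) {
    s <- frames[[k]]$stats
    if (!nrow(s)) return(data.frame(label = integer(), x = numeric(),
                                    y = numeric()))
    s <- s[!duplicated(s$label), ]
    data.frame(label = s$label, x = s$centroid_x, y = s$centroid_y)
  }
  nt <- length(frames)
  c0 <- cent(1)
  tracks <- data.frame(track_id = seq_len(nrow(c0)), frame = 1L,
                       label = c0$label)
  ends <- data.frame(track_id = tracks$track_id, x = c0$x, y = c0$y,
                     last_frame = 1L)
  next_id <- nrow(c0) + 1L
  for (k in seq_len(nt - 1L) + 1L) {
    ck <- cent(k)
    live <- ends[ends$last_frame == k - 1L, ]
    used_obj <- logical(nrow(ck))
    used_trk <- logical(nrow(live))
    if (nrow(ck) && nrow(live)) {
      d <- outer(live$x, ck$x, "-")^2 + outer(live$y, ck$y, "-")^2
      d <- sqrt(d)
      ord <- order(d)
      for (idx in ord) {
        if (d[idx] > max_displacement) break
        i <- (idx - 1L) %% nrow(live) + 1L
        j <- (idx - 1L) %/% nrow(live) + 1L
        if (used_trk[i] || used_obj[j]) next
        used_trk[i] <- TRUE; used_obj[j] <- TRUE
        tid <- live$track_id[i]
        tracks <- rbind(tracks, data.frame(track_id = tid, frame = k,
                                           label = ck$label[j]))
        ends[ends$track_id == tid, c("x", "y", "last_frame")] <-
          list(ck$x[j], ck$y[j], k)
      }
    }
    for (j in which(!used_obj)) {
      tracks <- rbind(tracks, data.frame(track_id = next_id, frame = k,
                                         label = ck$label[j]))
      ends <- rbind(ends, data.frame(track_id = next_id, x = ck$x[j],
                                     y = ck$y[j], last_frame = k))
      next_id <- next_id + 1L
    }
  }
  nper <- table(tracks$track_id)
  tracks$complete <- tracks$track_id %in%
    as.integer(names(nper)[nper == nt])
  tracks
}

#' Assemble tidy per-cell traces from tracked segmentations
#'
#' Joins tracking to per-frame measurements, producing the trace-table
#' contract consumed by the quantification stage: one row per
#' track x frame x channel.
#'
#' @param frames per-frame segmentations (from [segment_movie()]).
#' @param tracks output of [track_cells()].
#' @param frame_times minutes, one per frame.
#' @param complete_only keep only tracks present in every frame.
#' @return data.frame with columns `track_id`, `time_min`, `channel`,
#'   `nuc_mean`, `cyt_mean`, `nuc_area_px`, `cell_area_px`.
#' @export
build_traces <- function(frames, tracks, frame_times,
                         complete_only = TRUE) {
  if (complete_only) tracks <- tracks[tracks$complete, ]
  rows <- list()
  for (k in seq_along(frames)) {
    tk <- tracks[tracks$frame == k, ]
    if (!nrow(tk)) next
    s <- frames[[k]]$stats
    m <- merge(tk[, c("track_id", "label")], s, by = "label")
    if (!nrow(m)) next
    rows[[k]] <- data.frame(track_id = m$track_id,
                            time_min = frame_times[k],
                            channel = m$channel,
                            nuc_mean = m$nuc_mean, cyt_mean = m$cyt_mean,
                            nuc_area_px = m$nuc_area_px,
                            cell_area_px = m$cell_area_px)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) return(data.frame())
  out <- out[order(out$track_id, out$channel, out$time_min), ]
  rownames(out) <- NULL
  out
}

#' Match tracks to ground-truth cells by first-frame centroid
#'
#' Associates each complete track with the simulated cell whose geometry
#' centroid is nearest in the first frame (used to compare pipeline output
#' with ground truth on synthetic movies).
#'
#' @param frames per-frame segmentations.
#' @param tracks output of [track_cells()].
#' @param geometries the [layout_cells()] list used for rendering.
#' @return data.frame `track_id`, `cell` (geometry index), `dist_px`.
#' @export
match_tracks_to_cells <- function(frames, tracks, geometries) {
  t1 <- tracks[tracks$frame == 1, ]
  s1 <- frames[[1]]$stats
  s1 <- s1[!duplicated(s1$label), ]
  gx <- vapply(geometries, function(g) g$centroid[1], 0)
  gy <- vapply(geometries, function(g) g$centroid[2], 0)
  out <- merge(t1[, c("track_id", "label")], s1[, c("label", "centroid_x",
                                                    "centroid_y")],
               by = "label")
  d <- outer(out$centroid_x, gx, "-")^2 + outer(out$centroid_y, gy, "-")^2
  out$cell <- apply(d, 1, which.min)
  out$dist_px <- sqrt(apply(d, 1, min))
  out[, c("track_id", "cell", "dist_px")]
}

#' Quality-control filter on tracked traces
#'
#' A trace passes if the cell was tracked over the whole movie and the
#' coefficient of variation (SD/mean) of its nuclear area, cell area and
#' nuclear-marker intensity over the movie are each at or below their
#' limits. Mirrors the retention rule of time-lapse pipelines where
#' typically more than 65% of tracked cells survive.
#'
#' @param traces trace table from [build_traces()].
#' @param cv_limits named numeric limits for `nuclear_area`, `cell_area`,
#'   `nuclear_marker_intensity`.
#' @param nuclear_channel channel whose `nuc_mean` is the marker intensity.
#' @return list with `traces` (passing rows, plus `qc_pass` column on the
#'   full table in `$all`) and `report` (per-criterion rejection counts).
#' @export
qc_filter <- function(traces, cv_limits = c(nuclear_area = 0.15,
                                            cell_area = 0.15,
                                            nuclear_marker_intensity = 0.15),
                      nuclear_channel = "nuclear_marker") {
  cv <- function(x) {
    x <- x[is.finite(x)]
    if (length(x) < 2 || mean(x) == 0) return(Inf)
    sd(x) / mean(x)
  }
  ids <- unique(traces$track_id)
  res <- data.frame(track_id = ids, cv_nuc_area = NA_real_,
                    cv_cell_area = NA_real_, cv_marker = NA_real_)
  for (r in seq_along(ids)) {
    tr <- traces[traces$track_id == ids[r], ]
    one <- tr[tr$channel == tr$channel[1], ]
    res$cv_nuc_area[r] <- cv(one$nuc_area_px)
    res$cv_cell_area[r] <- cv(one$cell_area_px)
    mk <- tr[tr$channel == nuclear_channel, ]
    res$cv_marker[r] <- if (nrow(mk)) cv(mk$nuc_mean) else Inf
  }
  fail_na <- res$cv_nuc_area > cv_limits[["nuclear_area"]]
  fail_ca <- res$cv_cell_area > cv_limits[["cell_area"]]
  fail_mk <- res$cv_marker > cv_limits[["nuclear_marker_intensity"]]
  pass <- !(fail_na | fail_ca | fail_mk)
  report <- list(n_tracks = length(ids), n_pass = sum(pass),
                 pass_fraction = mean(pass),
                 rejected_nuclear_area = sum(fail_na),
                 rejected_cell_area = sum(fail_ca),
                 rejected_marker_intensity = sum(fail_mk),
                 cv_limits = cv_limits)
  traces$qc_pass <- traces$track_id %in% ids[pass]
  list(traces = traces[traces$qc_pass, ], all = traces, report = report)
}
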