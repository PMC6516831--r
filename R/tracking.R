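#' Link segmented nuclei across time-lapse frames
#'
#' Greedy mutual-nearest-centroid linking in physical (micrometre)
#' coordinates. Links are resolved in ascending distance order (ties by
#' ascending label, then track id) and never exceed `max_displacement`,
#' so the result is deterministic. A track that finds no match may
#' survive up to `max_gap` frames before terminating.
#'
#' Divisions: after matching, a track whose previous position has two
#' nuclei of the new frame within `max_displacement` — its own match plus
#' an otherwise-unmatched newcomer, or two unmatched newcomers if the
#' track went unmatched — is ended as a division parent, and the two
#' nuclei start daughter tracks carrying `parent_track_id`.
#'
#' @param masks_per_frame List of `nucleus_mask` objects, one per frame,
#'   in frame order.
#' @param max_displacement Maximum per-frame movement in micrometres;
#'   also the division detection radius.
#' @param max_gap Maximum number of consecutive unmatched frames a track
#'   survives (default 1).
#' @return data.frame of class `track_table`: one row per track per frame
#'   with `track_id`, `parent_track_id`, `frame`, `cell_label`, `z`, `y`,
#'   `x` (voxel coordinates).
#' @export
link_nuclei <- function(masks_per_frame, max_displacement, max_gap = 1L) {
  if (length(masks_per_frame) == 0L) stop("no frames supplied")
  if (length(masks_per_frame) < 2L) stop("need >= 2 frames to track")
  if (max_displacement <= 0) stop("`max_displacement` must be > 0")
  for (m in masks_per_frame) stopifnot(inherits(m, "nucleus_mask"))
  vs <- masks_per_frame[[1]]$voxel_size

  cent_um <- function(mask) {
    tb <- mask$table
    cbind(tb$centroid_z * vs[1], tb$centroid_y * vs[2], tb$centroid_x * vs[3])
  }
  row_for <- function(id, parent, f, tb, j) {
    data.frame(track_id = id, parent_track_id = parent, frame = f,
               cell_label = tb$label[j], z = tb$centroid_z[j],
               y = tb$centroid_y[j], x = tb$centroid_x[j])
  }

  rows <- list()
  active <- list()   # each: list(id, parent, pos (um), gap)
  next_id <- 0L
  tb0 <- masks_per_frame[[1]]$table
  c0 <- cent_um(masks_per_frame[[1]])
  for (i in seq_len(nrow(tb0))) {
    next_id <- next_id + 1L
    active[[length(active) + 1L]] <- list(
      id = next_id, parent = NA_integer_, pos = c0[i, ], gap = 0L)
    rows[[length(rows) + 1L]] <- row_for(next_id, NA_integer_, 0L, tb0, i)
  }

  n_frames <- length(masks_per_frame)
  for (f in seq_len(n_frames - 1L)) {
    tb <- masks_per_frame[[f + 1L]]$table
    cf <- cent_um(masks_per_frame[[f + 1L]])
    n_new <- nrow(tb)
    n_act <- length(active)
    match_of <- rep(NA_integer_, n_act)   # new-nucleus index per track
    new_taken <- rep(FALSE, max(n_new, 0L))
    dmat <- NULL
    if (n_act > 0L && n_new > 0L) {
      dmat <- matrix(Inf, n_act, n_new)
      for (i in seq_len(n_act))
        dmat[i, ] <- sqrt(colSums((t(cf) - active[[i]]$pos)^2))
      dmat[dmat > max_displacement] <- Inf
      d <- dmat
      repeat {
        if (!any(is.finite(d))) break
        best <- which(d == min(d), arr.ind = TRUE)
        best <- best[order(tb$label[best[, 2]],
                           vapply(best[, 1], function(i) active[[i]]$id, 0L)), ,
                     drop = FALSE]
        i <- best[1, 1]; j <- best[1, 2]
        match_of[i] <- j
        new_taken[j] <- TRUE
        d[i, ] <- Inf; d[, j] <- Inf
      }
    }
    # division pass: a track with two candidate nuclei in radius, at most
    # one of them claimed by itself and the rest unclaimed, divides
    divided <- rep(FALSE, n_act)
    daughter_rows <- list()
    new_tracks <- list()
    if (n_act > 0L && n_new > 0L) {
      for (i in seq_len(n_act)) {
        free <- which(!new_taken & is.finite(dmat[i, ]))
        own <- match_of[i]
        cand <- c(own[!is.na(own)], free)
        if (length(cand) < 2L) next
        ord <- cand[order(dmat[i, cand], tb$label[cand])]
        daughters <- ord[1:2]
        parent_id <- active[[i]]$id
        for (j in daughters) {
          next_id <- next_id + 1L
          new_taken[j] <- TRUE
          new_tracks[[length(new_tracks) + 1L]] <- list(
            id = next_id, parent = parent_id, pos = cf[j, ], gap = 0L)
          daughter_rows[[length(daughter_rows) + 1L]] <-
            row_for(next_id, parent_id, f, tb, j)
        }
        divided[i] <- TRUE
        match_of[i] <- NA_integer_      # parent ends at frame f-1
      }
    }
    # write continuation rows for matched, undivided tracks
    for (i in seq_len(n_act)) {
      j <- match_of[i]
      if (is.na(j)) next
      tr <- active[[i]]
      tr$pos <- cf[j, ]; tr$gap <- 0L
      active[[i]] <- tr
      rows[[length(rows) + 1L]] <- row_for(tr$id, tr$parent, f, tb, j)
    }
    rows <- c(rows, daughter_rows)
    # leftover nuclei start fresh tracks
    for (j in which(!new_taken)) {
      next_id <- next_id + 1L
      new_tracks[[length(new_tracks) + 1L]] <- list(
        id = next_id, parent = NA_integer_, pos = cf[j, ], gap = 0L)
      rows[[length(rows) + 1L]] <- row_for(next_id, NA_integer_, f, tb, j)
    }
    # age unmatched tracks; retire divided parents and stale tracks
    keep <- list()
    for (i in seq_len(n_act)) {
      tr <- active[[i]]
      if (divided[i]) next
      if (is.na(match_of[i])) tr$gap <- tr$gap + 1L
      if (tr$gap <= max_gap) keep[[length(keep) + 1L]] <- tr
    }
    active <- c(keep, new_tracks)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(track_id = integer(), parent_track_id = integer(),
               frame = integer(), cell_label = integer(),
               z = numeric(), y = numeric(), x = numeric())
  out <- out[order(out$track_id, out$frame), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("track_table", "data.frame")
  out
}

#' Normalised intensity trace of one track
#'
#' For each frame of a track, the nuclear mean green and red intensities
#' are measured over the tracked label's voxels; the normalised green
#' trace divides each frame's green mean by the track-level mean of the
#' red means, so a common gain applied to both channels cancels while
#' genuine reporter dynamics remain.
#'
#' @param track_table A `track_table` from [link_nuclei()].
#' @param track_id Which track to trace.
#' @param grids List of [voxel_grid()]s, one per frame (`frame_index`
#'   0-based matching the track table's `frame`).
#' @param masks List of `nucleus_mask`s aligned with `grids`.
#' @return data.frame: `frame`, `cell_label`, `mean_green`, `mean_red`,
#'   `normalized_green`, `division` (TRUE on the frame where this track
#'   ends by dividing, i.e. its daughters start at the next frame).
#' @export
track_intensity_trace <- function(track_table, track_id, grids, masks) {
  stopifnot(inherits(track_table, "track_table"))
  tr <- track_table[track_table$track_id == track_id, , drop = FALSE]
  if (nrow(tr) == 0L) stop(sprintf("track %d not found", track_id))
  if (length(grids) != length(masks))
    stop("grids and masks must align frame by frame")
  max_frame <- max(tr$frame)
  if (max_frame + 1L > length(grids))
    stop(sprintf("frame %d missing its grid", max_frame))
  g <- numeric(nrow(tr)); r <- numeric(nrow(tr))
  for (i in seq_len(nrow(tr))) {
    f <- tr$frame[i]
    g[i] <- nuclear_mean_intensity(grids[[f + 1L]], masks[[f + 1L]],
                                   tr$cell_label[i], "green")
    r[i] <- nuclear_mean_intensity(grids[[f + 1L]], masks[[f + 1L]],
                                   tr$cell_label[i], "red")
  }
  red_track_mean <- mean(r)
  if (red_track_mean <= 0) stop("track-level red mean is not positive")
  kids <- track_table$parent_track_id == track_id &
    !is.na(track_table$parent_track_id)
  division <- rep(FALSE, nrow(tr))
  if (any(kids)) division[which.max(tr$frame)] <- TRUE
  data.frame(frame = tr$frame, cell_label = tr$cell_label,
             mean_green = g, mean_red = r,
             normalized_green = g / red_track_mean,
             division = division)
}
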