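# Cross-frame tracking of z-discs and sarcomeres.
#
# Frame-to-frame linking assigns detections to open tracks by minimizing
# total squared displacement over the candidate graph of moves shorter
# than `tp_depth` pixels per elapsed frame (optimal assignment, not
# greedy).  A track that goes unmatched for more than `memory` consecutive
# frames is closed; unmatched detections open new tracks.

#' Tracking parameters
#'
#' @param tp_depth farthest distance in pixels a tracked entity can travel
#'   between consecutive frames (default 4; use 3 for low-resolution
#'   movies).  During a gap of `g` frames the allowed radius scales to
#'   `g * tp_depth`.
#' @param memory number of consecutive frames a lost particle may be
#'   reacquired over (default 5).
#' @export
tracking_params <- function(tp_depth = 4, memory = 5) {
  stopifnot(tp_depth > 0, memory >= 0)
  structure(list(tp_depth = tp_depth, memory = as.integer(memory)),
            class = "tracking_params")
}

# Optimal one-to-one assignment between open tracks and detections.
# cost: squared displacement; forbidden pairs get a cost so large that the
# solver prefers leaving both sides unmatched, which also makes minimum
# total cost maximize the number of admissible links.
.assign_links <- function(track_pos, det_pos, max_d) {
  nt <- nrow(track_pos)
  nd <- nrow(det_pos)
  if (nt == 0 || nd == 0) return(cbind(track = integer(0), det = integer(0)))
  d2 <- pdist2(track_pos, det_pos)
  allowed <- d2 <= outer(max_d^2, rep(1, nd))
  if (!any(allowed)) return(cbind(track = integer(0), det = integer(0)))
  big <- max(d2[allowed], 1) * 1e6
  cost <- d2
  cost[!allowed] <- big
  if (nt <= nd) {
    sol <- clue::solve_LSAP(cost)
    tr <- seq_len(nt)
    de <- as.integer(sol)
  } else {
    sol <- clue::solve_LSAP(t(cost))
    de <- seq_len(nd)
    tr <- as.integer(sol)
  }
  keep <- allowed[cbind(tr, de)]
  cbind(track = tr[keep], det = de[keep])
}

#' Link per-frame detections into tracks
#'
#' @param detections data.frame with columns `frame`, `local_id`, `x`,
#'   `y` (one row per detection; frames may be empty).
#' @param params a [tracking_params()].
#' @param n_frames total number of movie frames (defaults to the maximum
#'   frame index present).
#' @return data.frame with columns `track_id`, `frame`, `local_id`, `x`,
#'   `y`; `track_id` is assigned in order of track creation.
#' @export
link_frames <- function(detections, params = tracking_params(),
                        n_frames = max(detections$frame)) {
  stopifnot(all(c("frame", "local_id", "x", "y") %in% names(detections)))
  act_id <- integer(0)     # track ids of open tracks
  act_x <- numeric(0)
  act_y <- numeric(0)
  act_last <- integer(0)   # frame each open track was last seen
  next_id <- 1L
  rows <- vector("list", n_frames)
  for (t in seq_len(n_frames)) {
    det <- detections[detections$frame == t, , drop = FALSE]
    open <- act_last >= t - 1L - params$memory
    act_id <- act_id[open]; act_x <- act_x[open]; act_y <- act_y[open]
    act_last <- act_last[open]
    nd <- nrow(det)
    matched_det <- integer(0)
    if (nd > 0 && length(act_id) > 0) {
      gaps <- t - act_last
      links <- .assign_links(cbind(act_x, act_y), cbind(det$x, det$y),
                             max_d = gaps * params$tp_depth)
      if (nrow(links) > 0) {
        act_x[links[, "track"]] <- det$x[links[, "det"]]
        act_y[links[, "track"]] <- det$y[links[, "det"]]
        act_last[links[, "track"]] <- t
        matched_det <- links[, "det"]
        rows[[t]] <- data.frame(track_id = act_id[links[, "track"]],
                                frame = t,
                                local_id = det$local_id[links[, "det"]],
                                x = det$x[links[, "det"]],
                                y = det$y[links[, "det"]])
      }
    }
    if (nd > 0) {
      new <- setdiff(seq_len(nd), matched_det)
      if (length(new) > 0) {
        ids <- next_id + seq_along(new) - 1L
        next_id <- next_id + length(new)
        act_id <- c(act_id, ids)
        act_x <- c(act_x, det$x[new])
        act_y <- c(act_y, det$y[new])
        act_last <- c(act_last, rep(t, length(new)))
        rows[[t]] <- rbind(rows[[t]],
                           data.frame(track_id = ids, frame = t,
                                      local_id = det$local_id[new],
                                      x = det$x[new], y = det$y[new]))
      }
    }
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) {
    out <- data.frame(track_id = integer(0), frame = integer(0),
                      local_id = integer(0), x = numeric(0), y = numeric(0))
  }
  out[order(out$track_id, out$frame), , drop = FALSE]
}

#' Keep tracks present in more than a minimum fraction of frames
#'
#' Tracks present in more than `min_presence` of the movie frames receive
#' a deterministic `global_id` (ordered by first frame, then x, then y at
#' first observation); the rest are dropped.
#'
#' @param tracks data.frame from [link_frames()].
#' @param n_frames total number of movie frames.
#' @param min_presence presence fraction threshold (default 0.10, strict).
#' @return the filtered data.frame with a `global_id` column and a
#'   `presence` attribute (named vector of presence fractions).
#' @export
filter_tracks <- function(tracks, n_frames, min_presence = 0.10) {
  if (nrow(tracks) == 0) {
    out <- cbind(tracks, global_id = integer(0))
    attr(out, "presence") <- numeric(0)
    return(out)
  }
  cnt <- table(tracks$track_id)
  presence <- as.numeric(cnt) / n_frames
  names(presence) <- names(cnt)
  keep_ids <- names(presence)[presence > min_presence]
  kept <- tracks[tracks$track_id %in% as.integer(keep_ids), , drop = FALSE]
  if (nrow(kept) == 0) {
    out <- cbind(kept, global_id = integer(0))
    attr(out, "presence") <- numeric(0)
    return(out)
  }
  first <- do.call(rbind, lapply(split(kept, kept$track_id), function(d) {
    d[which.min(d$frame), c("track_id", "frame", "x", "y")]
  }))
  ord <- order(first$frame, first$x, first$y)
  gid <- seq_along(ord)
  names(gid) <- as.character(first$track_id[ord])
  kept$global_id <- as.integer(gid[as.character(kept$track_id)])
  kept <- kept[order(kept$global_id, kept$frame), , drop = FALSE]
  pres <- presence[as.character(first$track_id[ord])]
  names(pres) <- as.character(gid[as.character(first$track_id[ord])])
  attr(kept, "presence") <- pres
  kept
}

#' Track z-discs and sarcomeres independently across a movie
#'
#' @param seg a `segmentation` from [segment_movie()].
#' @param params a [tracking_params()].
#' @param min_presence presence threshold for [filter_tracks()].
#' @return list of class `tracking` with `zdiscs` and `sarcomeres`
#'   filtered track tables and `n_frames`.
#' @export
track_movie <- function(seg, params = tracking_params(),
                        min_presence = 0.10) {
  stopifnot(inherits(seg, "segmentation"))
  zt <- link_frames(seg$zdiscs, params, n_frames = seg$n_frames)
  st <- link_frames(seg$sarcomeres, params, n_frames = seg$n_frames)
  structure(list(
    zdiscs = filter_tracks(zt, seg$n_frames, min_presence),
    sarcomeres = filter_tracks(st, seg$n_frames, min_presence),
    n_frames = seg$n_frames, params = params
  ), class = "tracking")
}
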