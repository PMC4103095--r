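# Overlap-based linking of segmented regions across frames.

#' Link regions across frames by pixel overlap
#'
#' Greedy frame-to-frame linking: each region in frame t+1 claims the frame-t
#' region with which it shares the most pixels (ties go to the lower track
#' id); a frame-t region receiving several claimants keeps the one with the
#' largest overlap (ties go to the earlier claimant) and the rest start new
#' tracks; regions sharing no pixel with the previous frame start new
#' tracks.  There is no gap closing: a track ends the first frame its region
#' receives no claimant.  Every input region belongs to exactly one track.
#'
#' Track ids are assigned deterministically: tracks are numbered by
#' (start frame, region order within that frame), and regions within a frame
#' are expected in the (min row, min col) order produced by segmentation.
#'
#' @param per_frame_regions List over frames; each element a list of
#'   pairwise-disjoint pixel sets.
#' @param dim Frame dimensions `c(nrow, ncol)`.
#' @return List of tracks; each track is a list with `track_id`,
#'   `start_frame`, `end_frame` and `regions`, a list of pixel sets named by
#'   frame index.
#' @export
link_by_overlap <- function(per_frame_regions, dim) {
  nt <- length(per_frame_regions)
  tracks <- list()
  # active: map region-index-in-previous-frame -> track id
  prev_track <- integer(0)
  prev_lab <- NULL
  for (t in seq_len(nt)) {
    regs <- per_frame_regions[[t]]
    n <- length(regs)
    if (n) {
      all_px <- unlist(regs, use.names = FALSE)
      if (anyDuplicated(all_px))
        stop(sprintf("regions overlap within frame %d", t), call. = FALSE)
    }
    cur_track <- integer(n)
    if (n && length(prev_track)) {
      # best previous region for each current region
      claims <- lapply(seq_len(n), function(i) {
        ov <- prev_lab[regs[[i]]]
        ov <- ov[ov > 0L]
        if (!length(ov)) return(c(prev = 0L, count = 0L))
        cnt <- tabulate(ov, nbins = length(prev_track))
        best <- cnt == max(cnt)
        # ties -> lower track id
        cand <- which(best)
        c(prev = cand[which.min(prev_track[cand])], count = max(cnt))
      })
      claimed_prev <- vapply(claims, `[[`, integer(1), "prev")
      counts <- vapply(claims, `[[`, integer(1), "count")
      for (p in unique(claimed_prev[claimed_prev > 0L])) {
        claimants <- which(claimed_prev == p)
        winner <- claimants[which.max(counts[claimants])]  # ties -> earlier
        cur_track[winner] <- prev_track[p]
      }
    }
    # new tracks for unlinked regions, in region order
    for (i in seq_len(n)) {
      if (cur_track[i] == 0L) {
        id <- length(tracks) + 1L
        tracks[[id]] <- list(track_id = id, start_frame = t, end_frame = t,
                             regions = stats::setNames(list(regs[[i]]),
                                                       as.character(t)))
        cur_track[i] <- id
      } else {
        id <- cur_track[i]
        tracks[[id]]$end_frame <- t
        tracks[[id]]$regions[[as.character(t)]] <- regs[[i]]
      }
    }
    # label matrix of current frame, by region index
    if (n) {
      prev_lab <- matrix(0L, dim[1], dim[2])
      for (i in seq_len(n)) prev_lab[regs[[i]]] <- i
      prev_track <- cur_track
    } else {
      prev_lab <- NULL
      prev_track <- integer(0)
    }
  }
  lapply(tracks, function(tr) {
    tr$lifetime_frames <- tr$end_frame - tr$start_frame + 1L
    tr
  })
}

#' Lifetime of a track in minutes
#' @param track A track from [link_by_overlap()].
#' @param frame_interval_min Minutes per frame.
#' @export
track_lifetime_min <- function(track, frame_interval_min) {
  track$lifetime_frames * frame_interval_min
}

#' Filter tracks by minimum lifetime
#'
#' Keeps tracks whose lifetime (frames present x frame interval) is at least
#' `min_lifetime_min`, inclusive — so 12 frames at 5 min pass a 60-min
#' threshold and 20 frames at 30 min pass a 600-min threshold.
#'
#' @param tracks List of tracks.
#' @param min_lifetime_min Minimum lifetime in minutes (>= 0).
#' @param frame_interval_min Minutes per frame.
#' @return Filtered list of tracks (original `track_id`s preserved).
#' @export
filter_by_lifetime <- function(tracks, min_lifetime_min, frame_interval_min) {
  stopifnot(min_lifetime_min >= 0)
  keep <- vapply(tracks, function(tr)
    track_lifetime_min(tr, frame_interval_min) >= min_lifetime_min, logical(1))
  tracks[keep]
}

#' Summarize tracks as a tibble
#'
#' @param tracks List of tracks.
#' @param frame_interval_min Minutes per frame.
#' @return Tibble: `track_id`, `start_frame`, `end_frame`, `lifetime_frames`,
#'   `lifetime_min`.
#' @export
tracks_summary <- function(tracks, frame_interval_min) {
  tibble::tibble(
    track_id = vapply(tracks, `[[`, integer(1), "track_id"),
    start_frame = vapply(tracks, `[[`, integer(1), "start_frame"),
    end_frame = vapply(tracks, `[[`, integer(1), "end_frame"),
    lifetime_frames = vapply(tracks, `[[`, integer(1), "lifetime_frames"),
    lifetime_min = vapply(tracks, `[[`, integer(1), "lifetime_frames") *
      frame_interval_min
  )
}
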