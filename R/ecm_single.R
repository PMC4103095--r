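# Per-track ECM degradation signal: local fluorescence difference, pre-birth
# baseline, and corrected difference.

#' Border ring around a puncta, excluding other puncta
#'
#' The ring of pixels within Euclidean distance `width` of the region
#' (dilation by a disk of radius `width` minus the region itself), clipped to
#' the frame, with pixels belonging to any other identified puncta in the
#' same frame removed.
#'
#' @param pixels Region pixel set.
#' @param other_regions List of the frame's other puncta pixel sets.
#' @param dim Frame dimensions.
#' @param width Ring radius in pixels (default 5).
#' @return Sorted pixel set; may be empty after exclusions (the caller marks
#'   that frame's measurement missing).
#' @export
puncta_border <- function(pixels, other_regions = list(), dim, width = 5) {
  ring <- dilate_ring(pixels, dim, width)
  if (length(other_regions))
    ring <- setdiff(ring, unlist(other_regions, use.names = FALSE))
  sort(ring)
}

#' Local fluorescence difference
#'
#' Mean ECM intensity over the border ring minus mean over the pixels under
#' the puncta.  Positive when the matrix beneath the puncta is darker than
#' its surroundings (degradation); near zero for non-degrading puncta;
#' negative when the puncta accumulates signal.
#'
#' @param ecm_frame ECM intensity matrix.
#' @param under,border Pixel sets.
#' @return Numeric, or `NA` when either set is empty.
#' @export
local_difference <- function(ecm_frame, under, border) {
  if (!length(under) || !length(border)) return(NA_real_)
  mean(ecm_frame[border]) - mean(ecm_frame[under])
}

#' Pre-birth local differences for a track
#'
#' Evaluates each frame's (under, border) pixel sets on the fixed ECM image
#' immediately preceding the track's first frame — capturing pre-existing
#' matrix irregularities at the puncta's successive positions.  For tracks
#' present from the first frame, the first ECM image is used.
#'
#' @param ecm_stack Corrected ECM [timelapse_stack()].
#' @param track A track from [link_by_overlap()].
#' @param sets List (one per track frame, in frame order) of lists with
#'   `under` and `border` pixel sets.
#' @return Numeric vector of `P_t`, one per track frame.
#' @export
pre_birth_difference <- function(ecm_stack, track, sets) {
  r <- if (track$start_frame > 1L) track$start_frame - 1L else 1L
  ref <- ecm_stack$frames[[r]]
  vapply(sets, function(s) local_difference(ref, s$under, s$border), numeric(1))
}

#' Assemble the degradation series of a track
#'
#' For every frame of the track: the under-puncta pixel set, the 5-pixel
#' border ring with other-puncta exclusions, the local difference `L_t`, the
#' pre-birth difference `P_t` (same pixel sets on the pre-birth ECM image)
#' and the corrected difference `C_t = L_t - P_t`.  Frames whose border is
#' empty after exclusions yield missing values; a series with more than half
#' of its frames missing is flagged unusable for classification.
#'
#' @param ecm_stack Corrected ECM [timelapse_stack()].
#' @param track A track.
#' @param all_regions_by_frame Per-frame lists of all puncta pixel sets (for
#'   border exclusions).
#' @param width Border ring radius in pixels (default 5).
#' @return An object of class `degradation_series`: list with `track_id`,
#'   `data` (tibble: `frame`, `n_under`, `n_border`, `L`, `P`, `C`),
#'   `mean_L`, `mean_C` (over non-missing frames) and `usable`.
#' @export
degradation_series <- function(ecm_stack, track, all_regions_by_frame,
                               width = 5) {
  d <- frame_dim(ecm_stack)
  frames <- track$start_frame:track$end_frame
  sets <- lapply(frames, function(t) {
    under <- track$regions[[as.character(t)]]
    others <- all_regions_by_frame[[t]]
    others <- others[!vapply(others, identical, logical(1), under)]
    list(under = under,
         border = puncta_border(under, others, d, width))
  })
  L <- vapply(seq_along(frames), function(i)
    local_difference(ecm_stack$frames[[frames[i]]],
                     sets[[i]]$under, sets[[i]]$border), numeric(1))
  P <- pre_birth_difference(ecm_stack, track, sets)
  C <- L - P
  ok <- !is.na(C)
  structure(list(
    track_id = track$track_id,
    data = tibble::tibble(
      frame = frames,
      n_under = vapply(sets, function(s) length(s$under), integer(1)),
      n_border = vapply(sets, function(s) length(s$border), integer(1)),
      L = L, P = P, C = C),
    mean_L = if (any(ok)) mean(L[ok]) else NA_real_,
    mean_C = if (any(ok)) mean(C[ok]) else NA_real_,
    usable = mean(!ok) <= 0.5
  ), class = "degradation_series")
}

#' @export
print.degradation_series <- function(x, ...) {
  cat(sprintf(
    "<degradation_series> track %d: %d frames (%d usable), mean L %.3g, mean C %.3g%s\n",
    x$track_id, nrow(x$data), sum(!is.na(x$data$C)), x$mean_L, x$mean_C,
    if (x$usable) "" else " [unusable]"))
  invisible(x)
}
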