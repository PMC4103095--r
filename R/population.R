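# Whole-cell "degrader" analysis for population-scale (20x-style) image sets.

#' Segment cells in a marker frame
#'
#' Connected components (8-connectivity) of the cell mask produced by
#' [segment_cell_mask()].  Touching cells form a single component; clusters
#' are excluded downstream by the maximum-size filter rather than split.
#'
#' @param marker_frame Numeric matrix.
#' @param sigma,k_cell,min_size_px Passed to [segment_cell_mask()].
#' @return List of pixel sets in (min row, min col) order.
#' @export
segment_cells <- function(marker_frame, sigma = 2, k_cell = 1,
                          min_size_px = 50) {
  mask <- segment_cell_mask(marker_frame, sigma, k_cell, min_size_px)
  if (!any(mask)) return(list())
  pixel_sets(label8(mask))
}

#' Filter cell regions by area
#'
#' Keeps regions with `a_min <= area <= a_max` (inclusive).  The defaults
#' exclude small debris (< 1,500 px) and multi-cell clusters (> 20,000 px).
#'
#' @param regions List of pixel sets.
#' @param a_min,a_max Inclusive pixel-area bounds.
#' @return Filtered list.
#' @export
size_filter_cells <- function(regions, a_min = 1500, a_max = 20000) {
  stopifnot(a_min > 0, a_min < a_max)
  n <- vapply(regions, length, integer(1))
  regions[n >= a_min & n <= a_max]
}

#' Border ring around a cell, excluding other cells
#'
#' Ring of pixels within Euclidean distance `width` (default 40) of the cell,
#' minus the cell itself and minus any pixels belonging to the excluded
#' regions (other cells, in either the current or the prior frame).
#'
#' @param pixels Cell pixel set.
#' @param exclude List of pixel sets to remove from the ring.
#' @param dim Frame dimensions.
#' @param width Ring radius in pixels (default 40).
#' @return Sorted pixel set (possibly empty).
#' @export
cell_border <- function(pixels, exclude = list(), dim, width = 40) {
  ring <- dilate_ring(pixels, dim, width)
  if (length(exclude))
    ring <- setdiff(ring, unlist(exclude, use.names = FALSE))
  sort(ring)
}

#' Frame-to-frame percentage ECM degradation under a cell
#'
#' With `U_p`, `U_c` the mean ECM under the cell on the previous and current
#' frames and `B_p`, `B_c` the means over the border ring:
#' `D_t = 100 * ((U_p - U_c) - (B_p - B_c)) / B_c`.  Positive when the cell's
#' footprint darkened more than the surrounding matrix did, so uniform
#' bleaching or illumination changes cancel.
#'
#' @param ecm_prev,ecm_curr ECM frames (same dimensions).
#' @param under,border Pixel sets.
#' @return Percentage, or `NA` when a set is empty or `B_c <= 0`.
#' @export
frame_degradation_pct <- function(ecm_prev, ecm_curr, under, border) {
  if (!length(under) || !length(border)) return(NA_real_)
  U_p <- mean(ecm_prev[under]);  U_c <- mean(ecm_curr[under])
  B_p <- mean(ecm_prev[border]); B_c <- mean(ecm_curr[border])
  if (!is.finite(B_c) || B_c <= 0) return(NA_real_)
  100 * ((U_p - U_c) - (B_p - B_c)) / B_c
}

#' Area of influence of a cell track
#'
#' Pixels the cell covered for at least `min_coverage_h` hours cumulatively
#' (coverage = frames containing the pixel x frame interval; the threshold
#' is inclusive).
#'
#' @param track A cell track from [link_by_overlap()].
#' @param dim Frame dimensions.
#' @param frame_interval_min Minutes per frame.
#' @param min_coverage_h Minimum cumulative coverage in hours (default 2.5).
#' @return Sorted pixel set (possibly empty for fast-moving cells).
#' @export
area_of_influence <- function(track, dim, frame_interval_min,
                              min_coverage_h = 2.5) {
  cov <- integer(prod(dim))
  for (px in track$regions) cov[px] <- cov[px] + 1L
  need <- min_coverage_h * 60 / frame_interval_min
  sort(which(cov >= need - 1e-9))
}

#' Overall percentage ECM degradation over the area of influence
#'
#' Same background-corrected percentage as [frame_degradation_pct()], with
#' (prev, curr) = (first, last) ECM frames and the cell's area of influence
#' as the under set.
#'
#' @param ecm_first,ecm_last First and last ECM frames.
#' @param influence Area-of-influence pixel set.
#' @param border Border pixel set around the influence area.
#' @return Percentage, or `NA`.
#' @export
overall_degradation_pct <- function(ecm_first, ecm_last, influence, border) {
  frame_degradation_pct(ecm_first, ecm_last, influence, border)
}

#' Calibrate degrader cutoffs on a negative control
#'
#' The cutoffs are order statistics of the negative-control sample: `c_tot`
#' is the smallest value such that at most `fp_budget` control cells have
#' `D_tot` strictly above it (so with budget 0, the control maximum), and
#' `c_frame` likewise on each control cell's maximum per-frame percentage.
#'
#' @param negative_control Tibble with columns `D_tot` and `max_D_t` (one
#'   row per control cell; `NA`s dropped).
#' @param fp_budget Number of control cells allowed above the cutoff.
#' @return List of class `degrader_cutoffs` with `c_frame` and `c_tot`.
#' @export
calibrate_degrader_cutoffs <- function(negative_control, fp_budget = 0) {
  dt <- negative_control$D_tot[!is.na(negative_control$D_tot)]
  df <- negative_control$max_D_t[!is.na(negative_control$max_D_t)]
  if (!length(dt) || !length(df))
    stop("empty negative-control set: supply explicit cutoffs", call. = FALSE)
  kth_largest <- function(x, b) sort(x, decreasing = TRUE)[min(b + 1L, length(x))]
  structure(list(c_tot = kth_largest(dt, fp_budget),
                 c_frame = kth_largest(df, fp_budget)),
            class = "degrader_cutoffs")
}

#' Classify a cell as degrader or non-degrader
#'
#' A cell is a degrader when its overall percentage exceeds `c_tot` or any
#' per-frame percentage exceeds `c_frame` (both strict).
#'
#' @param D_tot Overall degradation percentage.
#' @param D_t Numeric vector of per-frame percentages.
#' @param cutoffs A `degrader_cutoffs` object.
#' @return List with `is_degrader` and `degrader_at_frame` (logical vector,
#'   `D_t > c_frame` per frame).
#' @export
classify_degrader <- function(D_tot, D_t, cutoffs) {
  per_frame <- !is.na(D_t) & D_t > cutoffs$c_frame
  list(is_degrader = isTRUE(!is.na(D_tot) && D_tot > cutoffs$c_tot) ||
         any(per_frame),
       degrader_at_frame = per_frame)
}

#' Degraded ECM area attributed to a cell
#'
#' Compares the first and last ECM frames per pixel within the cell's area
#' of influence: a pixel is degraded when its intensity decreased by at
#' least `drop_fraction` (inclusive; per-pixel ratio, robust to spatial ECM
#' heterogeneity).  Pixels with non-positive initial intensity are skipped.
#'
#' @param ecm_first,ecm_last First and last ECM frames.
#' @param influence Area-of-influence pixel set.
#' @param drop_fraction Fractional decrease marking degradation (default 0.20).
#' @param pixel_size_um Pixel edge in micrometres.
#' @return List with `pixels` (degraded pixel set) and `area_um2`.
#' @export
degraded_area <- function(ecm_first, ecm_last, influence,
                          drop_fraction = 0.20, pixel_size_um = 1) {
  f <- ecm_first[influence]
  l <- ecm_last[influence]
  sel <- f > 0 & l <= (1 - drop_fraction) * f
  list(pixels = influence[sel],
       area_um2 = sum(sel) * pixel_size_um^2)
}

#' Degradation rate
#'
#' Total degraded area divided by the cell lifetime, in µm² per hour.
#'
#' @param area_um2 Degraded area (µm²).
#' @param lifetime_min Cell lifetime in minutes (> 0).
#' @return Rate in µm²/h.
#' @export
degradation_rate <- function(area_um2, lifetime_min) {
  if (lifetime_min <= 0) stop("lifetime must be positive", call. = FALSE)
  area_um2 / (lifetime_min / 60)
}

#' Whole-cell degradation analysis of a population field
#'
#' Runs the population chain on preprocessed stacks: per-frame cell
#' segmentation and size filtering, overlap tracking with the >= 10 h
#' lifetime filter, per-frame and overall background-corrected degradation
#' percentages (40-px border, prior-frame cell occupancy excluded), area of
#' influence (>= 2.5 h), degraded area (>= 20% drop) and degradation rate.
#' Degrader classification is applied when cutoffs are supplied.
#'
#' @param marker,ecm Preprocessed [timelapse_stack()] pair.
#' @param params [seg_params()] (cell-mask settings are used).
#' @param border_width Border ring radius in pixels (default 40).
#' @param min_lifetime_min Track lifetime filter in minutes (default 600).
#' @param min_coverage_h Area-of-influence threshold in hours (default 2.5).
#' @param drop_fraction Degraded-pixel drop fraction (default 0.20).
#' @param a_min,a_max Cell size bounds in pixels.
#' @param cutoffs Optional `degrader_cutoffs`; when `NULL` the `is_degrader`
#'   column is `NA`.
#' @return List with `per_cell` (tibble: `track_id`, `lifetime_h`, `D_tot`,
#'   `max_D_t`, `is_degrader`, `degraded_area_um2`, `rate_um2_per_h`),
#'   `per_frame` (tibble: `track_id`, `frame`, `area_px`, `D_t`,
#'   `degrader_at_frame`), `tracks`, `influence` and `degraded` (named lists
#'   of pixel sets by track id).
#' @export
analyze_population <- function(marker, ecm, params = seg_params(),
                               border_width = 40, min_lifetime_min = 600,
                               min_coverage_h = 2.5, drop_fraction = 0.20,
                               a_min = 1500, a_max = 20000, cutoffs = NULL) {
  d <- frame_dim(marker)
  nt <- n_frames(marker)
  regions_by_frame <- lapply(seq_len(nt), function(t)
    size_filter_cells(segment_cells(marker$frames[[t]], params$cell_sigma,
                                    params$k_cell, params$cell_min_px),
                      a_min, a_max))
  tracks <- link_by_overlap(regions_by_frame, d)
  tracks <- filter_by_lifetime(tracks, min_lifetime_min,
                               marker$frame_interval_min)
  per_frame <- list(); per_cell <- list()
  influence_sets <- list(); degraded_sets <- list()
  for (tr in tracks) {
    frames <- tr$start_frame:tr$end_frame
    D_t <- rep(NA_real_, length(frames))
    areas <- integer(length(frames))
    for (i in seq_along(frames)) {
      t <- frames[i]
      under <- tr$regions[[as.character(t)]]
      areas[i] <- length(under)
      if (t == 1L) next  # no prior image for the first frame of the movie
      # exclude every cell's pixels in frame t and t-1 (other than this cell)
      excl <- c(regions_by_frame[[t]], regions_by_frame[[t - 1L]])
      excl <- excl[!vapply(excl, identical, logical(1), under)]
      border <- cell_border(under, excl, d, border_width)
      D_t[i] <- frame_degradation_pct(ecm$frames[[t - 1L]], ecm$frames[[t]],
                                      under, border)
    }
    infl <- area_of_influence(tr, d, marker$frame_interval_min, min_coverage_h)
    D_tot <- NA_real_
    deg <- list(pixels = integer(0), area_um2 = 0)
    if (length(infl)) {
      # exclude every cell footprint present in the first or last frame
      # (including this cell's own pixels outside its influence area)
      excl_all <- c(regions_by_frame[[1L]], regions_by_frame[[nt]])
      border_tot <- cell_border(infl, excl_all, d, border_width)
      D_tot <- overall_degradation_pct(ecm$frames[[1L]], ecm$frames[[nt]],
                                       infl, border_tot)
      deg <- degraded_area(ecm$frames[[1L]], ecm$frames[[nt]], infl,
                           drop_fraction, marker$pixel_size_um)
    }
    lifetime_min <- tr$lifetime_frames * marker$frame_interval_min
    cls <- if (is.null(cutoffs)) list(is_degrader = NA,
                                      degrader_at_frame = rep(NA, length(frames)))
           else classify_degrader(D_tot, D_t, cutoffs)
    per_frame[[length(per_frame) + 1L]] <- tibble::tibble(
      track_id = tr$track_id, frame = frames, area_px = areas, D_t = D_t,
      degrader_at_frame = cls$degrader_at_frame)
    per_cell[[length(per_cell) + 1L]] <- tibble::tibble(
      track_id = tr$track_id,
      lifetime_h = lifetime_min / 60,
      D_tot = D_tot,
      max_D_t = if (all(is.na(D_t))) NA_real_ else max(D_t, na.rm = TRUE),
      is_degrader = cls$is_degrader,
      degraded_area_um2 = deg$area_um2,
      rate_um2_per_h = degradation_rate(deg$area_um2, lifetime_min))
    influence_sets[[as.character(tr$track_id)]] <- infl
    degraded_sets[[as.character(tr$track_id)]] <- deg$pixels
  }
  empty_cell <- tibble::tibble(track_id = integer(), lifetime_h = numeric(),
                               D_tot = numeric(), max_D_t = numeric(),
                               is_degrader = logical(),
                               degraded_area_um2 = numeric(),
                               rate_um2_per_h = numeric())
  empty_frame <- tibble::tibble(track_id = integer(), frame = integer(),
                                area_px = integer(), D_t = numeric(),
                                degrader_at_frame = logical())
  list(per_cell = if (length(per_cell)) dplyr::bind_rows(per_cell) else empty_cell,
       per_frame = if (length(per_frame)) dplyr::bind_rows(per_frame) else empty_frame,
       tracks = tracks, influence = influence_sets, degraded = degraded_sets)
}
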