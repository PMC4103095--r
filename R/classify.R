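# Classification of tracked puncta as matrix-degrading invadopodia, and
# extraction of dynamic invadopodia properties.

#' One-sample t-test against zero
#'
#' Classical two-sided one-sample t-test of the mean against 0 with
#' `df = n - 1`.  With fewer than two non-missing values, or zero variance,
#' both statistic and p-value are undefined (`NA`) and the caller treats the
#' track as non-invadopodia.
#'
#' @param values Numeric vector (missing values dropped).
#' @return Named numeric vector `c(t, p)`.
#' @export
t_test_one_sample <- function(values) {
  v <- values[!is.na(values)]
  if (length(v) < 2L || stats::var(v) == 0)
    return(c(t = NA_real_, p = NA_real_))
  ht <- stats::t.test(v, mu = 0)
  c(t = unname(ht$statistic), p = ht$p.value)
}

#' Classify degradation series as invadopodia
#'
#' For each usable series, one-sample t-tests ask whether the mean local
#' difference and the mean corrected local difference differ from zero.  A
#' Bonferroni correction is applied for the number of tests run in the batch
#' (2 tests per usable series); a track is called an invadopodium when both
#' adjusted p-values fall below `alpha` *and* both means are positive (the
#' direction expected of degradation).
#'
#' @param series_list List of [degradation_series()] objects.
#' @param alpha Significance level after correction (default 0.05).
#' @return Tibble, one row per series: `track_id`, `n_obs`, `mean_L`,
#'   `mean_C`, `p_L`, `p_C`, `p_adj_L`, `p_adj_C`, `is_invadopodia`,
#'   `usable`, and `manual_exclude` — a column initialized to `FALSE` where
#'   a reviewer can mark calls judged false positive on inspection.
#' @export
classify_tracks <- function(series_list, alpha = 0.05) {
  if (!length(series_list))
    return(tibble::tibble(track_id = integer(), n_obs = integer(),
                          mean_L = numeric(), mean_C = numeric(),
                          p_L = numeric(), p_C = numeric(),
                          p_adj_L = numeric(), p_adj_C = numeric(),
                          is_invadopodia = logical(), usable = logical(),
                          manual_exclude = logical()))
  usable <- vapply(series_list, `[[`, logical(1), "usable")
  m <- 2L * sum(usable)
  rows <- lapply(series_list, function(s) {
    L <- s$data$L; C <- s$data$C
    tl <- t_test_one_sample(L)
    tc <- t_test_one_sample(C)
    p_adj_L <- pmin(1, tl["p"] * m)
    p_adj_C <- pmin(1, tc["p"] * m)
    call <- isTRUE(s$usable &&
                   !is.na(p_adj_L) && !is.na(p_adj_C) &&
                   p_adj_L < alpha && p_adj_C < alpha &&
                   s$mean_L > 0 && s$mean_C > 0)
    tibble::tibble(track_id = s$track_id, n_obs = sum(!is.na(C)),
                   mean_L = s$mean_L, mean_C = s$mean_C,
                   p_L = unname(tl["p"]), p_C = unname(tc["p"]),
                   p_adj_L = unname(p_adj_L), p_adj_C = unname(p_adj_C),
                   is_invadopodia = call, usable = s$usable,
                   manual_exclude = FALSE)
  })
  dplyr::bind_rows(rows)
}

#' Smooth a degradation series
#'
#' Missing values are linearly interpolated, then a centered moving average
#' of window 5 frames is applied, with the window shrunk symmetrically near
#' the series ends so the output has the same length as the input.  Series
#' with fewer than 3 non-missing values are returned unchanged (after
#' interpolation).
#'
#' @param values Numeric vector (the per-frame corrected differences).
#' @param window Odd window length (default 5).
#' @return Numeric vector, same length as `values`.
#' @export
smooth_series <- function(values, window = 5) {
  stopifnot(window %% 2 == 1)
  n <- length(values)
  ok <- !is.na(values)
  if (sum(ok) == 0) return(values)
  v <- values
  if (any(!ok)) {
    v <- stats::approx(which(ok), values[ok], xout = seq_len(n),
                       rule = 2)$y
  }
  if (sum(ok) < 3L) return(v)
  half <- (window - 1L) %/% 2L
  vapply(seq_len(n), function(i) {
    h <- min(half, i - 1L, n - i)
    mean(v[(i - h):(i + h)])
  }, numeric(1))
}

#' Time to maximum matrix degradation
#'
#' Smooths the corrected-difference series, finds its maximum `M`, and
#' returns the time from the track's first frame to the earliest frame whose
#' smoothed value reaches 90% of `M`.  Undefined (`NA`) when the smoothed
#' maximum is not positive (the quantity is only meaningful for degrading
#' tracks); invariant to positive rescaling of the series.
#'
#' @param C_series Per-frame corrected differences.
#' @param frame_interval_min Minutes per frame.
#' @param window Smoothing window (see [smooth_series()]).
#' @return Minutes from track start, or `NA`.
#' @export
time_to_max_degradation <- function(C_series, frame_interval_min, window = 5) {
  s <- smooth_series(C_series, window)
  M <- max(s, na.rm = TRUE)
  if (!is.finite(M) || M <= 0) return(NA_real_)
  idx <- which(s >= 0.9 * M)[1]
  (idx - 1) * frame_interval_min
}

#' Dynamic properties of classified invadopodia
#'
#' For each track called an invadopodium: mean area over frames (µm²), mean
#' distance from the nearest cell edge (µm), lifetime (min) and time to 90%
#' of maximum smoothed degradation (min).
#'
#' @param tracks List of tracks (lifetime-filtered).
#' @param calls Tibble from [classify_tracks()].
#' @param series_list The matching list of [degradation_series()] objects.
#' @param cell_masks Per-frame logical cell masks.
#' @param pixel_size_um Pixel edge in micrometres.
#' @param frame_interval_min Minutes per frame.
#' @param window Smoothing window for time-to-max.
#' @return Tibble: `track_id`, `mean_area_um2`, `mean_edge_distance_um`,
#'   `lifetime_min`, `time_to_max_min`.
#' @export
invadopodia_properties <- function(tracks, calls, series_list, cell_masks,
                                   pixel_size_um, frame_interval_min,
                                   window = 5) {
  ids <- calls$track_id[calls$is_invadopodia]
  by_id <- stats::setNames(tracks, vapply(tracks, `[[`, numeric(1), "track_id"))
  ser_id <- stats::setNames(series_list,
                            vapply(series_list, `[[`, numeric(1), "track_id"))
  rows <- lapply(ids, function(id) {
    tr <- by_id[[as.character(id)]]
    frames <- tr$start_frame:tr$end_frame
    areas <- vapply(frames, function(t)
      length(tr$regions[[as.character(t)]]), integer(1))
    eds <- vapply(frames, function(t)
      edge_distance(tr$regions[[as.character(t)]], cell_masks[[t]],
                    pixel_size_um), numeric(1))
    ttm <- time_to_max_degradation(ser_id[[as.character(id)]]$data$C,
                                   frame_interval_min, window)
    tibble::tibble(track_id = id,
                   mean_area_um2 = mean(areas) * pixel_size_um^2,
                   mean_edge_distance_um = mean(eds),
                   lifetime_min = tr$lifetime_frames * frame_interval_min,
                   time_to_max_min = ttm)
  })
  if (!length(rows))
    return(tibble::tibble(track_id = integer(), mean_area_um2 = numeric(),
                          mean_edge_distance_um = numeric(),
                          lifetime_min = numeric(),
                          time_to_max_min = numeric()))
  dplyr::bind_rows(rows)
}
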