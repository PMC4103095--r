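# Seed-based region-growing segmentation of actin puncta, and whole-cell
# mask segmentation from the marker channel.

#' Segmentation parameters
#'
#' Bundles the tunable parameters of puncta and cell-mask segmentation.
#' Defaults follow the pipeline's calibrated operating point: seeds are
#' pixels more than 3 standard deviations above the mean of the high-pass
#' filtered frame, in connected groups of at least 6 pixels; seeds are
#' expanded at 1.75 standard deviations; accepted puncta must satisfy area
#' and major/minor axis-ratio bounds.
#'
#' @param sigma_hp High-pass Gaussian scale in pixels.
#' @param k_seed Seed threshold in standard deviations (> `k_expand`).
#' @param min_seed_px Minimum seed size in pixels (>= 1).
#' @param k_expand Expansion threshold in standard deviations (>= 0).
#' @param area_bounds `c(min, max)` puncta area in pixels, inclusive.
#' @param ratio_bounds `c(min, max)` major/minor axis ratio, inclusive.
#' @param cell_sigma Gaussian scale for cell-mask smoothing (px).
#' @param k_cell Cell-mask threshold in standard deviations.
#' @param cell_min_px Minimum retained cell-component size (px).
#' @return A list of class `seg_params`.
#' @export
seg_params <- function(sigma_hp = 10, k_seed = 3, min_seed_px = 6,
                       k_expand = 1.75, area_bounds = c(6, 200),
                       ratio_bounds = c(1, 4),
                       cell_sigma = 2, k_cell = 1, cell_min_px = 50) {
  stopifnot(sigma_hp > 0, k_expand >= 0, k_seed > k_expand, min_seed_px >= 1,
            length(area_bounds) == 2, area_bounds[1] < area_bounds[2],
            length(ratio_bounds) == 2, ratio_bounds[1] >= 1,
            ratio_bounds[1] < ratio_bounds[2],
            cell_sigma > 0, cell_min_px >= 1)
  structure(list(sigma_hp = sigma_hp, k_seed = k_seed,
                 min_seed_px = as.integer(min_seed_px), k_expand = k_expand,
                 area_bounds = area_bounds, ratio_bounds = ratio_bounds,
                 cell_sigma = cell_sigma, k_cell = k_cell,
                 cell_min_px = as.integer(cell_min_px)),
            class = "seg_params")
}

#' High-pass filter a frame
#'
#' Subtracts a Gaussian blur of the frame from the frame itself, removing
#' the diffuse cell-body background and leaving compact bright structures.
#' The output has (approximately) zero mean; a constant frame maps to zero.
#'
#' @param frame Numeric matrix.
#' @param sigma_hp Gaussian scale in pixels.
#' @return Matrix of the same dimensions.
#' @export
high_pass <- function(frame, sigma_hp = 10) {
  stopifnot(sigma_hp > 0)
  frame - gblur_safe(frame, sigma_hp)
}

#' Mean and population standard deviation of a filtered frame
#'
#' @param filtered Numeric matrix (the high-pass filtered frame).
#' @return Named numeric vector `c(mu, sd)`; `sd` uses the population
#'   (divide-by-n) formula.
#' @export
filtered_stats <- function(filtered) {
  stopifnot(length(filtered) > 0)
  pop_stats(filtered)
}

#' Detect puncta seeds
#'
#' Seeds are 8-connected components of pixels exceeding `mu + k_seed * sd`,
#' keeping only components of at least `min_seed_px` pixels.  Components are
#' returned in deterministic (min row, min col) order.  With `sd = 0`
#' (constant filtered frame) no pixel exceeds the threshold and the result
#' is empty.
#'
#' @param filtered High-pass filtered frame.
#' @param mu,sd Frame statistics from [filtered_stats()].
#' @param k_seed Threshold in standard deviations.
#' @param min_seed_px Minimum component size.
#' @return List of pixel sets (sorted linear indices), possibly empty.
#' @export
detect_seeds <- function(filtered, mu, sd, k_seed = 3, min_seed_px = 6) {
  stopifnot(sd >= 0)
  mask <- filtered > mu + k_seed * sd
  if (!any(mask)) return(list())
  lab <- label8(mask)
  sets <- pixel_sets(lab)
  sets[vapply(sets, length, integer(1)) >= min_seed_px]
}

# Minimum Euclidean distance from each of a set of pixels to a seed set.
min_dist_to_set <- function(coords, seed_coords) {
  d2 <- outer(coords[, 1], seed_coords[, 1], "-")^2 +
        outer(coords[, 2], seed_coords[, 2], "-")^2
  sqrt(apply(d2, 1, min))
}

#' Expand seeds at a lower threshold
#'
#' Each seed grows to the 8-connected component of pixels exceeding
#' `mu + k_expand * sd` that contains it.  When several seeds fall in one
#' expansion component, the component's pixels are split by nearest-seed
#' assignment (Euclidean distance to the seed's pixel set; ties go to the
#' lower seed index).  Output regions are pairwise disjoint and each
#' contains its seed.
#'
#' @param filtered High-pass filtered frame.
#' @param seeds List of pairwise-disjoint pixel sets from [detect_seeds()].
#' @param mu,sd Frame statistics.
#' @param k_expand Expansion threshold in standard deviations.
#' @return List of pixel sets, one per seed, in seed order.
#' @export
expand_seeds <- function(filtered, seeds, mu, sd, k_expand = 1.75) {
  if (!length(seeds)) return(list())
  dim <- dim(filtered)
  mask <- filtered > mu + k_expand * sd
  lab <- label8(mask)
  seed_comp <- vapply(seeds, function(s) lab[s[1]], integer(1))
  # a seed is by construction above the (higher) seed threshold
  stopifnot(all(seed_comp > 0L))
  out <- vector("list", length(seeds))
  for (comp in unique(seed_comp)) {
    members <- which(seed_comp == comp)
    comp_px <- which(lab == comp)
    if (length(members) == 1L) {
      out[[members]] <- sort(comp_px)
    } else {
      co <- px_coords(comp_px, dim)
      dmat <- vapply(members, function(i)
        min_dist_to_set(co, px_coords(seeds[[i]], dim)),
        numeric(length(comp_px)))
      assign <- apply(dmat, 1, which.min)  # ties -> first = lower seed index
      for (j in seq_along(members))
        out[[members[j]]] <- sort(comp_px[assign == j])
    }
  }
  out
}

#' Major/minor axis ratio of a pixel set
#'
#' Ratio of the best-fit-ellipse axis lengths, computed from the unweighted
#' second moments (eigenvalues of the coordinate covariance) of the pixel
#' set.  Degenerate sets with zero minor moment (single-pixel-wide lines,
#' single pixels) return `Inf` and thus fail any finite upper ratio bound.
#'
#' @param pixels Pixel set (linear indices).
#' @param dim Frame dimensions.
#' @return Numeric >= 1, possibly `Inf`.
#' @export
axis_ratio <- function(pixels, dim) {
  co <- px_coords(pixels, dim)
  n <- nrow(co)
  r <- co[, 1] - mean(co[, 1]); c <- co[, 2] - mean(co[, 2])
  cov <- matrix(c(sum(r * r), sum(r * c), sum(r * c), sum(c * c)) / n, 2, 2)
  ev <- eigen(cov, symmetric = TRUE, only.values = TRUE)$values
  if (ev[2] < 1e-12) return(Inf)
  sqrt(ev[1] / ev[2])
}

#' Region features
#'
#' @param pixels Pixel set.
#' @param dim Frame dimensions.
#' @param frame_index 1-based frame number.
#' @param pixel_size_um Pixel edge in micrometres.
#' @param marker_frame Optional marker frame for the mean intensity.
#' @return One-row tibble: `frame`, `area_px`, `area_um2`, `centroid_row`,
#'   `centroid_col`, `axis_ratio`, `mean_marker`.
#' @export
region_features <- function(pixels, dim, frame_index, pixel_size_um,
                            marker_frame = NULL) {
  co <- px_coords(pixels, dim)
  tibble::tibble(
    frame = frame_index,
    area_px = length(pixels),
    area_um2 = length(pixels) * pixel_size_um^2,
    centroid_row = mean(co[, 1]),
    centroid_col = mean(co[, 2]),
    axis_ratio = axis_ratio(pixels, dim),
    mean_marker = if (is.null(marker_frame)) NA_real_ else
      mean(marker_frame[pixels])
  )
}

#' Filter regions by area and axis ratio
#'
#' Keeps regions with `area_bounds[1] <= area_px <= area_bounds[2]` and
#' `ratio_bounds[1] <= axis_ratio <= ratio_bounds[2]` (both inclusive),
#' preserving order.
#'
#' @param regions List of pixel sets.
#' @param dim Frame dimensions.
#' @param area_bounds,ratio_bounds Inclusive `c(min, max)` bounds.
#' @return Filtered list of pixel sets.
#' @export
shape_filter <- function(regions, dim, area_bounds = c(6, 200),
                         ratio_bounds = c(1, 4)) {
  keep <- vapply(regions, function(px) {
    a <- length(px)
    if (a < area_bounds[1] || a > area_bounds[2]) return(FALSE)
    r <- axis_ratio(px, dim)
    r >= ratio_bounds[1] && r <= ratio_bounds[2]
  }, logical(1))
  regions[keep]
}

#' Calibrate area and axis-ratio bounds from annotated puncta
#'
#' Recomputes the shape-filter bounds as the minimum and maximum area and
#' axis ratio observed over a user-supplied set of labeled puncta regions —
#' the procedure used to derive the filters from manually annotated puncta.
#' Degenerate regions (infinite axis ratio) are excluded from the ratio
#' bounds.
#'
#' @param regions List of pixel sets of annotated puncta.
#' @param dim Frame dimensions.
#' @return List with `area_bounds` and `ratio_bounds`, each `c(min, max)`.
#' @export
calibrate_shape_bounds <- function(regions, dim) {
  stopifnot(length(regions) > 0)
  areas <- vapply(regions, length, integer(1))
  ratios <- vapply(regions, axis_ratio, numeric(1), dim = dim)
  ratios <- ratios[is.finite(ratios)]
  if (!length(ratios))
    stop("all annotated regions have degenerate axis ratios", call. = FALSE)
  list(area_bounds = range(areas), ratio_bounds = range(ratios))
}

#' Segment the cell-body mask of a marker frame
#'
#' Gaussian-smooths the frame, thresholds at `mean + k_cell * sd` of the
#' smoothed frame, fills interior holes and removes components smaller than
#' `min_size_px`.  A constant (blank) frame yields an empty mask.
#'
#' @param marker_frame Numeric matrix.
#' @param sigma Smoothing scale in pixels.
#' @param k_cell Threshold in standard deviations of the smoothed frame.
#' @param min_size_px Minimum retained component size.
#' @return Logical matrix, `TRUE` inside cell bodies.
#' @export
segment_cell_mask <- function(marker_frame, sigma = 2, k_cell = 1,
                              min_size_px = 50) {
  g <- gblur_safe(marker_frame, sigma)
  st <- pop_stats(g)
  mask <- g > st["mu"] + k_cell * st["sd"]
  if (!any(mask)) return(matrix(FALSE, nrow(g), ncol(g)))
  filled <- EBImage::imageData(EBImage::fillHull(matrix(as.numeric(mask),
                                                        nrow(g), ncol(g))))
  lab <- label8(filled > 0)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= min_size_px)
  matrix(lab %in% keep & lab > 0L, nrow(g), ncol(g))
}

#' Distance from a region centroid to the nearest cell edge
#'
#' Finds the mask component containing the region's centroid and returns the
#' Euclidean distance from the (sub-pixel) centroid to the nearest boundary
#' pixel of that component, scaled to micrometres.  Boundary pixels are
#' component pixels 4-adjacent to background or lying on the image border.
#'
#' @param pixels Region pixel set.
#' @param mask Logical cell mask.
#' @param pixel_size_um Pixel edge in micrometres.
#' @return Distance in micrometres.
#' @export
edge_distance <- function(pixels, mask, pixel_size_um) {
  dim <- dim(mask)
  co <- px_coords(pixels, dim)
  cen <- c(mean(co[, 1]), mean(co[, 2]))
  ri <- as.integer(round(cen[1])); ci <- as.integer(round(cen[2]))
  ri <- max(1L, min(dim[1], ri)); ci <- max(1L, min(dim[2], ci))
  if (!mask[ri, ci])
    stop("region centroid lies outside the cell mask", call. = FALSE)
  lab <- label8(mask)
  comp <- lab == lab[ri, ci]
  nr <- dim[1]; nc <- dim[2]
  pad <- matrix(FALSE, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- comp
  interior <- pad[2:(nr + 1L), 1:nc] & pad[2:(nr + 1L), 3:(nc + 2L)] &
              pad[1:nr, 2:(nc + 1L)] & pad[3:(nr + 2L), 2:(nc + 1L)]
  boundary <- which(comp & !interior)
  bc <- px_coords(boundary, dim)
  min(sqrt((bc[, 1] - cen[1])^2 + (bc[, 2] - cen[2])^2)) * pixel_size_um
}

#' Segment puncta in every frame of a marker stack
#'
#' Runs the full per-frame chain: high-pass filter, frame statistics, seed
#' detection, seed expansion, area/axis-ratio filtering, and restriction to
#' puncta whose centroid lies inside the frame's cell mask.
#'
#' @param marker A [timelapse_stack()] (marker channel).
#' @param params A [seg_params()] object.
#' @param cell_masks Optional precomputed per-frame logical masks; segmented
#'   from the marker frames when `NULL`.
#' @return List with `regions` (list over frames of pixel-set lists),
#'   `cell_masks`, and `features`, a tibble of per-region properties with a
#'   `region` index column per frame.
#' @export
segment_puncta <- function(marker, params = seg_params(), cell_masks = NULL) {
  d <- frame_dim(marker)
  if (is.null(cell_masks))
    cell_masks <- lapply(marker$frames, segment_cell_mask,
                         sigma = params$cell_sigma, k_cell = params$k_cell,
                         min_size_px = params$cell_min_px)
  regions <- vector("list", n_frames(marker))
  feats <- list()
  for (t in seq_len(n_frames(marker))) {
    f <- marker$frames[[t]]
    hp <- high_pass(f, params$sigma_hp)
    st <- filtered_stats(hp)
    seeds <- detect_seeds(hp, st["mu"], st["sd"], params$k_seed,
                          params$min_seed_px)
    regs <- expand_seeds(hp, seeds, st["mu"], st["sd"], params$k_expand)
    regs <- shape_filter(regs, d, params$area_bounds, params$ratio_bounds)
    # invadopodia are intracellular: drop regions whose centroid is outside
    mask <- cell_masks[[t]]
    inside <- vapply(regs, function(px) {
      co <- px_coords(px, d)
      ri <- max(1L, min(d[1], as.integer(round(mean(co[, 1])))))
      ci <- max(1L, min(d[2], as.integer(round(mean(co[, 2])))))
      mask[ri, ci]
    }, logical(1))
    regs <- regs[inside]
    regions[[t]] <- regs
    if (length(regs))
      feats[[length(feats) + 1L]] <- dplyr::bind_rows(
        lapply(seq_along(regs), function(i) {
          ft <- region_features(regs[[i]], d, t, marker$pixel_size_um, f)
          ft$region <- i
          ft
        }))
  }
  features <- if (length(feats)) dplyr::bind_rows(feats) else
    tibble::tibble(frame = integer(), area_px = integer(), area_um2 = numeric(),
                   centroid_row = numeric(), centroid_col = numeric(),
                   axis_ratio = numeric(), mean_marker = numeric(),
                   region = integer())
  list(regions = regions, cell_masks = cell_masks, features = features)
}
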