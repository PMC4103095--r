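# Synthetic two-channel time-lapse scenes with ground truth, emulating the
# two acquisition regimes the pipeline targets: single-invadopodia fields
# (60x, one frame every 5 min for 12 h) and population fields (20x, one
# frame every 30 min for 25 h).

#' Synthetic scene parameters
#'
#' Defaults follow the two acquisition regimes.  Single mode: a 256 x 256 px
#' field holding one cell with 40 actin puncta (half degrading), 144 frames
#' at 5 min (12 h), 0.1075 µm/px.  Population mode: a 520 x 696 px field
#' with 12 cells (one third degrading) plus small short-lived debris,
#' 50 frames at 30 min (25 h), 0.267 µm/px.  Degrading objects remove ECM
#' intensity under their footprint at a constant rate per frame; the
#' rendered stacks then receive a multiplicative flat-field gradient,
#' exponential photobleaching and additive Gaussian noise.
#'
#' @param mode `"single"` or `"population"`.
#' @param image_shape `c(nrow, ncol)` in pixels.
#' @param n_frames Number of frames.
#' @param frame_interval_min Minutes per frame.
#' @param pixel_size_um Micrometres per pixel.
#' @param n_cells Number of cells.
#' @param cell_radius `c(min, max)` cell radius in px.
#' @param cell_step_px Per-frame random-walk step of cell centers (px).
#' @param cell_amp Marker intensity of cell bodies above background.
#' @param n_puncta Number of puncta (single mode).
#' @param puncta_radius `c(min, max)` puncta footprint radius in px.
#' @param puncta_amp Peak marker intensity of puncta above the cell body.
#' @param min_puncta_sep Minimum distance between puncta centers (px).
#' @param degrading_fraction Fraction of objects that degrade ECM.
#' @param degradation_rate ECM intensity removed per frame under a degrading
#'   object's footprint.
#' @param marker_bg Marker background level.
#' @param ecm_base Mean ECM intensity before corrections.
#' @param texture_amp Relative amplitude of the static smooth ECM texture.
#' @param bleach_halflife_frames Photobleaching half-life in frames
#'   (`Inf` disables bleaching).
#' @param flatfield_amp Relative amplitude of the illumination gradient
#'   (0 disables).
#' @param noise_sd Standard deviation of the additive Gaussian noise.
#' @param n_debris Number of small short-lived debris objects (population).
#' @param rng_seed Integer seed; fixed seed gives bit-identical scenes.
#' @return List of class `scene_params`.
#' @export
scene_params <- function(mode = c("single", "population"),
                         image_shape = NULL, n_frames = NULL,
                         frame_interval_min = NULL, pixel_size_um = NULL,
                         n_cells = NULL, cell_radius = NULL,
                         cell_step_px = NULL, cell_amp = 120,
                         n_puncta = 40, puncta_radius = c(2, 3),
                         puncta_amp = 150, min_puncta_sep = 18,
                         degrading_fraction = NULL, degradation_rate = NULL,
                         marker_bg = 100, ecm_base = 2000, texture_amp = 0.04,
                         bleach_halflife_frames = 240, flatfield_amp = 0.1,
                         noise_sd = NULL, n_debris = 2, rng_seed = 1L) {
  mode <- match.arg(mode)
  dflt <- function(x, s, p) if (!is.null(x)) x else if (mode == "single") s else p
  p <- list(
    mode = mode,
    image_shape = dflt(image_shape, c(256L, 256L), c(520L, 696L)),
    n_frames = dflt(n_frames, 144L, 50L),
    frame_interval_min = dflt(frame_interval_min, 5, 30),
    pixel_size_um = dflt(pixel_size_um, 0.1075, 0.267),
    n_cells = dflt(n_cells, 1L, 12L),
    cell_radius = dflt(cell_radius, c(75, 85), c(28, 40)),
    cell_step_px = dflt(cell_step_px, 0, 1),
    cell_amp = cell_amp, n_puncta = n_puncta,
    puncta_radius = puncta_radius, puncta_amp = puncta_amp,
    min_puncta_sep = min_puncta_sep,
    degrading_fraction = dflt(degrading_fraction, 0.5, 1 / 3),
    degradation_rate = dflt(degradation_rate, 4, 20),
    marker_bg = marker_bg, ecm_base = ecm_base, texture_amp = texture_amp,
    bleach_halflife_frames = bleach_halflife_frames,
    flatfield_amp = flatfield_amp,
    noise_sd = dflt(noise_sd, 15, 10),
    n_debris = n_debris, rng_seed = as.integer(rng_seed))
  stopifnot(p$n_frames >= 1, p$frame_interval_min > 0, p$pixel_size_um > 0,
            p$degrading_fraction >= 0, p$degrading_fraction <= 1,
            p$degradation_rate >= 0, p$noise_sd >= 0)
  structure(p, class = "scene_params")
}

# Pixel set of a disk, clipped to the frame.
disk_pixels <- function(center, radius, dim) {
  r0 <- max(1L, floor(center[1] - radius)); r1 <- min(dim[1], ceiling(center[1] + radius))
  c0 <- max(1L, floor(center[2] - radius)); c1 <- min(dim[2], ceiling(center[2] + radius))
  if (r0 > r1 || c0 > c1) return(integer(0))
  rows <- r0:r1; cols <- c0:c1
  g <- expand.grid(row = rows, col = cols)
  sel <- (g$row - center[1])^2 + (g$col - center[2])^2 <= radius^2
  sort(px_index(g$row[sel], g$col[sel], dim))
}

# Add a soft-edged disk (logistic edge profile) to `frame`.
add_soft_disk <- function(frame, center, radius, amp, edge = 2) {
  dim <- dim(frame)
  ext <- ceiling(radius + 4 * edge)
  r0 <- max(1L, floor(center[1] - ext)); r1 <- min(dim[1], ceiling(center[1] + ext))
  c0 <- max(1L, floor(center[2] - ext)); c1 <- min(dim[2], ceiling(center[2] + ext))
  if (r0 > r1 || c0 > c1) return(frame)
  rows <- r0:r1; cols <- c0:c1
  dist <- sqrt(outer((rows - center[1])^2, (cols - center[2])^2, "+"))
  frame[rows, cols] <- frame[rows, cols] + amp / (1 + exp((dist - radius) / edge))
  frame
}

# Add a Gaussian bump of given peak amplitude at `center` to `frame`.
add_gaussian_spot <- function(frame, center, sigma, amp) {
  dim <- dim(frame)
  ext <- ceiling(4 * sigma)
  r0 <- max(1L, floor(center[1] - ext)); r1 <- min(dim[1], ceiling(center[1] + ext))
  c0 <- max(1L, floor(center[2] - ext)); c1 <- min(dim[2], ceiling(center[2] + ext))
  if (r0 > r1 || c0 > c1) return(frame)
  rows <- r0:r1; cols <- c0:c1
  gr <- exp(-((rows - center[1])^2) / (2 * sigma^2))
  gc <- exp(-((cols - center[2])^2) / (2 * sigma^2))
  frame[rows, cols] <- frame[rows, cols] + amp * outer(gr, gc)
  frame
}

# Smooth random field with unit sd, zero mean (static ECM texture).
smooth_field <- function(dim, scale = 20) {
  f <- gblur_safe(matrix(stats::rnorm(prod(dim)), dim[1], dim[2]), scale)
  st <- pop_stats(f)
  if (st["sd"] == 0) return(matrix(0, dim[1], dim[2]))
  (f - st["mu"]) / st["sd"]
}

# Sample object centers with minimum pairwise separation.  Free placement
# uses dart throwing with restarts (dart throwing jams near capacity);
# placement inside a disk (`within = list(center=, radius=)`) uses a
# jittered hexagonal grid, which has deterministic capacity and keeps the
# pairwise spacing close to `min_sep` even for dense puncta fields.
sample_centers <- function(n, dim, margin, min_sep, within = NULL) {
  if (!is.null(within)) {
    s <- min_sep * 0.9            # grid pitch; jitter recovers the variety
    jit <- min_sep * 0.12
    rows <- seq(-within$radius, within$radius, by = s * sqrt(3) / 2)
    sites <- do.call(rbind, lapply(seq_along(rows), function(i) {
      off <- if (i %% 2 == 0) s / 2 else 0
      cols <- seq(-within$radius + off, within$radius, by = s)
      cbind(rows[i], cols)
    }))
    sites <- sites[sites[, 1]^2 + sites[, 2]^2 <= within$radius^2, , drop = FALSE]
    if (nrow(sites) < n)
      stop("could not place objects with the requested separation", call. = FALSE)
    pick <- sites[sample.int(nrow(sites), n), , drop = FALSE]
    pick <- pick + matrix(stats::runif(2 * n, -jit, jit), n, 2)
    return(cbind(within$center[1] + pick[, 1], within$center[2] + pick[, 2]))
  }
  for (attempt in seq_len(50L)) {
    centers <- matrix(numeric(0), 0, 2)
    tries <- 0L
    while (nrow(centers) < n && tries < 3000L) {
      tries <- tries + 1L
      cand <- c(stats::runif(1, margin, dim[1] - margin),
                stats::runif(1, margin, dim[2] - margin))
      if (nrow(centers) == 0 ||
          min((centers[, 1] - cand[1])^2 + (centers[, 2] - cand[2])^2) >= min_sep^2)
        centers <- rbind(centers, cand)
    }
    if (nrow(centers) == n) return(centers)
  }
  stop("could not place objects with the requested separation", call. = FALSE)
}

#' Generate a synthetic two-channel scene with ground truth
#'
#' Renders a marker stack (cells as smooth bright blobs, puncta as Gaussian
#' spots) and an ECM stack (static textured matrix from which degrading
#' objects remove intensity under their footprint at a constant per-frame
#' rate), then applies the flat-field gradient, exponential photobleaching
#' and additive Gaussian noise.  Deterministic for a fixed `rng_seed`.
#'
#' @param params A [scene_params()] object.
#' @return List with `marker` and `ecm` ([timelapse_stack()]s) and `truth`:
#'   a list with `objects` (tibble: `id`, `type`, `degrading`, `birth`,
#'   `death`, `radius`, plus list-columns `masks` — per-frame pixel sets —
#'   and `depth` — cumulative ECM depth per frame), `flat_field`, `bleach`
#'   (per-frame factors), `ecm_clean_first`, `ecm_clean_last` (noise-free
#'   uncorrupted first/last ECM frames), `influence_true` and
#'   `degraded_true` (per cell, population mode).
#' @export
generate_scene <- function(params = scene_params()) {
  p <- params
  set.seed(p$rng_seed)
  d <- as.integer(p$image_shape)
  nt <- p$n_frames
  texture <- smooth_field(d, 20) * p$texture_amp
  E0 <- p$ecm_base * (1 + texture)
  flat <- if (p$flatfield_amp > 0) {
    g <- outer((seq_len(d[1]) / d[1]) - 0.5, (seq_len(d[2]) / d[2]) - 0.5, "+")
    ff <- 1 + p$flatfield_amp * g
    ff / mean(ff)
  } else matrix(1, d[1], d[2])
  bleach <- if (is.finite(p$bleach_halflife_frames))
    2^(-(seq_len(nt) - 1) / p$bleach_halflife_frames) else rep(1, nt)

  objects <- make_objects(p, d)
  depth <- matrix(0, d[1], d[2])    # cumulative ECM loss
  marker_frames <- vector("list", nt)
  ecm_frames <- vector("list", nt)
  ecm_clean_first <- NULL; ecm_clean_last <- NULL
  coverage <- vector("list", nrow(objects))
  for (i in seq_len(nrow(objects))) coverage[[i]] <- integer(prod(d))

  for (t in seq_len(nt)) {
    mk <- matrix(p$marker_bg, d[1], d[2])
    for (i in seq_len(nrow(objects))) {
      ob <- objects[i, ]
      if (t < ob$birth || t > ob$death) next
      cen <- ob$centers[[1]][[t]]
      px <- ob$masks[[1]][[as.character(t)]]
      if (ob$type == "cell" || ob$type == "debris") {
        mk <- add_soft_disk(mk, cen, ob$radius, ob$amp)
      } else {
        mk <- add_gaussian_spot(mk, cen, ob$radius / 1.5, ob$amp)
      }
      if (ob$degrading && length(px)) depth[px] <- depth[px] + p$degradation_rate
      coverage[[i]][px] <- coverage[[i]][px] + 1L
    }
    ec_clean <- pmax(E0 - depth, 0)
    if (t == 1L) ecm_clean_first <- ec_clean
    if (t == nt) ecm_clean_last <- ec_clean
    mkf <- mk * flat * bleach[t]
    ecf <- ec_clean * flat * bleach[t]
    if (p$noise_sd > 0) {
      mkf <- mkf + matrix(stats::rnorm(prod(d), 0, p$noise_sd), d[1], d[2])
      ecf <- ecf + matrix(stats::rnorm(prod(d), 0, p$noise_sd), d[1], d[2])
    }
    marker_frames[[t]] <- pmax(mkf, 0)
    ecm_frames[[t]] <- pmax(ecf, 0)
  }

  # true per-cell influence and degraded sets (population bookkeeping)
  need <- 2.5 * 60 / p$frame_interval_min
  influence_true <- list(); degraded_true <- list()
  for (i in seq_len(nrow(objects))) {
    if (objects$type[i] != "cell") next
    infl <- which(coverage[[i]] >= need)
    influence_true[[as.character(objects$id[i])]] <- infl
    degraded_true[[as.character(objects$id[i])]] <-
      infl[ecm_clean_last[infl] <= 0.8 * ecm_clean_first[infl]]
  }

  truth <- list(objects = objects, flat_field = flat, bleach = bleach,
                ecm_clean_first = ecm_clean_first,
                ecm_clean_last = ecm_clean_last,
                influence_true = influence_true,
                degraded_true = degraded_true,
                params = p)
  list(marker = timelapse_stack(marker_frames, p$frame_interval_min,
                                p$pixel_size_um, "marker"),
       ecm = timelapse_stack(ecm_frames, p$frame_interval_min,
                             p$pixel_size_um, "ecm"),
       truth = truth)
}

# Build the object table (cells, puncta, debris) with per-frame masks.
make_objects <- function(p, d) {
  nt <- p$n_frames
  rows <- list()
  nid <- 0L
  add_obj <- function(type, degrading, birth, death, radius, amp, center0) {
    nid <<- nid + 1L
    centers <- vector("list", nt)
    masks <- list()
    cen <- center0
    for (t in seq_len(nt)) {
      if (t >= birth && t <= death) {
        if (t > birth && p$cell_step_px > 0 && type == "cell")
          cen <- cen + stats::rnorm(2, 0, p$cell_step_px)
        centers[[t]] <- cen
        masks[[as.character(t)]] <- disk_pixels(cen, radius, d)
      }
    }
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      id = nid, type = type, degrading = degrading,
      birth = birth, death = death, radius = radius, amp = amp,
      centers = list(centers), masks = list(masks))
    nid
  }

  if (p$mode == "single") {
    margin <- max(p$cell_radius) + 10
    ccen <- c(d[1] / 2 + stats::runif(1, -5, 5), d[2] / 2 + stats::runif(1, -5, 5))
    crad <- stats::runif(1, p$cell_radius[1], p$cell_radius[2])
    add_obj("cell", FALSE, 1L, nt, crad, p$cell_amp, ccen)
    if (p$n_puncta > 0) {
      pcen <- sample_centers(p$n_puncta, d, 0, p$min_puncta_sep,
                             within = list(center = ccen, radius = crad - 12))
      n_deg <- round(p$degrading_fraction * p$n_puncta)
      degrading <- rep(FALSE, p$n_puncta)
      if (n_deg > 0) degrading[sample.int(p$n_puncta, n_deg)] <- TRUE
      for (i in seq_len(p$n_puncta)) {
        # lifetimes: all candidates live >= 14 frames so they pass the 1 h
        # filter; births spread over the first half of the movie
        life <- 14L + stats::rgeom(1, 1 / 40)
        birth <- sample.int(max(1L, nt - life), 1)
        death <- min(nt, birth + life - 1L)
        rad <- stats::runif(1, p$puncta_radius[1], p$puncta_radius[2])
        add_obj("punctum", degrading[i], birth, death, rad, p$puncta_amp,
                pcen[i, ])
      }
    }
  } else {
    radii <- stats::runif(p$n_cells, p$cell_radius[1], p$cell_radius[2])
    margin <- max(radii) + 45
    cen <- sample_centers(p$n_cells, d, margin, 2 * max(radii) + 30)
    n_deg <- round(p$degrading_fraction * p$n_cells)
    degrading <- rep(FALSE, p$n_cells)
    if (n_deg > 0) degrading[sample.int(p$n_cells, n_deg)] <- TRUE
    for (i in seq_len(p$n_cells))
      add_obj("cell", degrading[i], 1L, nt, radii[i], p$cell_amp, cen[i, ])
    if (p$n_debris > 0) {
      dcen <- sample_centers(p$n_debris, d, 20, 30)
      for (i in seq_len(p$n_debris)) {
        birth <- sample.int(max(1L, nt - 5L), 1)
        death <- min(nt, birth + sample.int(5L, 1) - 1L)
        add_obj("debris", FALSE, birth, death, 8, p$cell_amp, dcen[i, ])
      }
    }
  }
  dplyr::bind_rows(rows)
}

#' Score pipeline calls against the scene's ground truth
#'
#' Matches every eligible ground-truth object to the detected track sharing
#' the most pixels with it (summed over frames), then scores the
#' degrading/non-degrading calls.  Sensitivity is the fraction of true
#' degrading objects that are matched and called positive; specificity the
#' fraction of true non-degrading objects that are not; recall the fraction
#' of eligible objects matched by any track; false positives are positive
#' calls whose track matches no true degrading object.
#'
#' @param tracks Detected tracks ([link_by_overlap()]).
#' @param calls Tibble with `track_id` and a logical call column
#'   (`is_invadopodia` or `is_degrader`).
#' @param truth Ground truth from [generate_scene()].
#' @param dim Frame dimensions.
#' @param types Truth object types to score (default `"punctum"` for single
#'   mode; use `"cell"` for population mode).
#' @param min_truth_frames Only truth objects alive at least this many
#'   frames are scored.
#' @return List with `matches` (per-object tibble), `sensitivity`,
#'   `specificity`, `recall` and `false_positives`.
#' @export
score_against_truth <- function(tracks, calls, truth, dim,
                                types = "punctum", min_truth_frames = 1L) {
  call_col <- intersect(c("is_invadopodia", "is_degrader"), names(calls))[1]
  ob <- truth$objects
  keep <- ob$type %in% types & (ob$death - ob$birth + 1L) >= min_truth_frames
  ob <- ob[keep, ]
  track_ids <- vapply(tracks, `[[`, integer(1), "track_id")
  overlap_with <- function(masks, tr) {
    tot <- 0L
    for (t in names(tr$regions)) {
      m <- masks[[t]]
      if (!is.null(m)) tot <- tot + length(intersect(m, tr$regions[[t]]))
    }
    tot
  }
  rows <- lapply(seq_len(nrow(ob)), function(i) {
    ov <- vapply(tracks, function(tr) overlap_with(ob$masks[[i]], tr),
                 integer(1))
    best <- if (length(ov) && max(ov) > 0) which.max(ov) else NA_integer_
    matched_id <- if (is.na(best)) NA_integer_ else track_ids[best]
    called <- if (is.na(matched_id)) FALSE else
      isTRUE(any(calls[[call_col]][calls$track_id == matched_id]))
    tibble::tibble(object_id = ob$id[i], degrading = ob$degrading[i],
                   matched_track = matched_id,
                   overlap_px = if (is.na(best)) 0L else ov[best],
                   called = called)
  })
  matches <- dplyr::bind_rows(rows)
  pos <- matches$degrading
  sens <- if (any(pos)) mean(matches$called[pos]) else NA_real_
  spec <- if (any(!pos)) mean(!matches$called[!pos]) else NA_real_
  # a called track is a false positive when its own best-overlap truth
  # object is non-degrading (or it overlaps no truth object at all)
  called_tracks <- calls$track_id[!is.na(calls[[call_col]]) & calls[[call_col]]]
  fp <- 0L
  for (id in called_tracks) {
    tr <- tracks[[which(track_ids == id)]]
    ov <- vapply(seq_len(nrow(ob)), function(i)
      overlap_with(ob$masks[[i]], tr), integer(1))
    best <- if (length(ov) && max(ov) > 0) which.max(ov) else NA_integer_
    if (is.na(best) || !ob$degrading[best]) fp <- fp + 1L
  }
  list(matches = matches, sensitivity = sens, specificity = spec,
       recall = mean(!is.na(matches$matched_track)), false_positives = fp)
}
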