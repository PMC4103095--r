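# Preprocessing of two-channel time-lapse stacks.
#
# Order contract: flat-field -> registration -> photobleach -> normalization.
# Photobleaching and normalization are estimated exclusively from pixels
# outside the cell bodies, so that true ECM degradation (which happens under
# cells) is never mistaken for bleaching.

#' Estimate a retrospective flat-field image
#'
#' When no acquired illumination reference is available the flat field is
#' estimated as the pixel-wise temporal median frame, blurred at a large
#' smoothing scale and normalized to unit mean.
#'
#' @param stack A [timelapse_stack()].
#' @param sigma Gaussian smoothing scale in pixels.
#' @return A positive matrix with unit mean.
#' @export
estimate_flat_field <- function(stack, sigma = 50) {
  d <- frame_dim(stack)
  arr <- vapply(stack$frames, identity, matrix(0, d[1], d[2]))
  med <- apply(arr, c(1, 2), stats::median)
  ff <- gblur_safe(med, sigma)
  ff <- ff / mean(ff)
  if (any(ff <= 0))
    stop("estimated flat field has non-positive pixels; supply one explicitly",
         call. = FALSE)
  ff
}

#' Flat-field correct a stack
#'
#' Divides every frame pixel-wise by the flat field scaled to unit mean.  A
#' uniform flat field therefore leaves the stack unchanged.  With
#' `flat_field = NULL` a retrospective estimate ([estimate_flat_field()]) is
#' used.
#'
#' @param stack A [timelapse_stack()].
#' @param flat_field Matrix matching the frame dimensions, strictly positive,
#'   or `NULL` to estimate retrospectively.
#' @param sigma Smoothing scale for the retrospective estimate.
#' @return List with `stack` (corrected) and `flat_field` (unit-mean matrix
#'   actually used).
#' @export
flat_field_correct <- function(stack, flat_field = NULL, sigma = 50) {
  if (is.null(flat_field)) {
    flat_field <- estimate_flat_field(stack, sigma = sigma)
  } else {
    if (!is.matrix(flat_field) || !identical(dim(flat_field), frame_dim(stack)))
      stop("`flat_field` must match the frame dimensions", call. = FALSE)
    if (any(flat_field <= 0))
      stop("`flat_field` must be strictly positive", call. = FALSE)
    flat_field <- flat_field / mean(flat_field)
  }
  frames <- lapply(stack$frames, function(f) f / flat_field)
  list(stack = with_frames(stack, frames), flat_field = flat_field)
}

outside_means <- function(stack, cell_masks) {
  vapply(seq_along(stack$frames), function(t) {
    out <- !cell_masks[[t]]
    if (!any(out))
      stop(sprintf("frame %d has no pixels outside the cell mask", t),
           call. = FALSE)
    mean(stack$frames[[t]][out])
  }, numeric(1))
}

check_masks <- function(stack, cell_masks) {
  if (length(cell_masks) != n_frames(stack))
    stop("need one cell mask per frame", call. = FALSE)
  d <- frame_dim(stack)
  ok <- vapply(cell_masks, function(m) is.matrix(m) && identical(dim(m), d),
               logical(1))
  if (!all(ok)) stop("cell masks must match the frame dimensions", call. = FALSE)
  lapply(cell_masks, function(m) m != 0)
}

#' Photobleach-correct an ECM stack from outside-cell pixels
#'
#' Each frame t is multiplied by `s_t = mean(frame 1 outside cells) /
#' mean(frame t outside cells)`, so `s_1 = 1` and the outside-cell mean is
#' constant over time after correction.  Only pixels outside the cell bodies
#' enter the estimate, so degradation under cells cannot masquerade as
#' bleaching.
#'
#' @param ecm A [timelapse_stack()] (ECM channel).
#' @param cell_masks List of per-frame logical matrices, `TRUE` inside cells.
#' @return List with `stack` (corrected), `bleach_scale` (numeric vector
#'   `s_t`) and `outside_mean` (post-correction per-frame outside means).
#' @export
photobleach_correct <- function(ecm, cell_masks) {
  cell_masks <- check_masks(ecm, cell_masks)
  om <- outside_means(ecm, cell_masks)
  s <- om[1] / om
  frames <- lapply(seq_along(ecm$frames), function(t) ecm$frames[[t]] * s[t])
  out <- with_frames(ecm, frames)
  list(stack = out, bleach_scale = s,
       outside_mean = outside_means(out, cell_masks))
}

#' Normalize an ECM stack so the outside-cell mean equals a target
#'
#' A single global factor `g = target / (outside-cell mean of frame 1)` is
#' applied to every frame, setting the background ECM fluorescence to a fixed
#' level (1000 by default) so local-difference values are comparable between
#' ECM preparations.  Assumes photobleach correction has already equalized
#' the per-frame outside means.
#'
#' @param ecm A [timelapse_stack()].
#' @param cell_masks Per-frame logical matrices, `TRUE` inside cells.
#' @param target Target outside-cell mean (default 1000).
#' @return List with `stack` and `norm_scale` (the factor `g`).
#' @export
normalize_ecm <- function(ecm, cell_masks, target = 1000) {
  cell_masks <- check_masks(ecm, cell_masks)
  m0 <- mean(ecm$frames[[1]][!cell_masks[[1]]])
  if (!is.finite(m0) || m0 <= 0)
    stop("outside-cell mean of frame 1 must be positive", call. = FALSE)
  g <- target / m0
  list(stack = with_frames(ecm, lapply(ecm$frames, function(f) f * g)),
       norm_scale = g)
}

# Integer-shift a frame by (dy, dx), filling vacated pixels.
shift_frame <- function(frame, dy, dx, fill) {
  if (dy == 0 && dx == 0) return(frame)
  nr <- nrow(frame); nc <- ncol(frame)
  out <- matrix(fill, nr, nc)
  sr <- max(1, 1 + dy):min(nr, nr + dy)   # destination rows
  sc <- max(1, 1 + dx):min(nc, nc + dx)
  out[sr, sc] <- frame[sr - dy, sc - dx]
  out
}

# Integer shift maximizing cross-correlation of `frame` against `ref`,
# searched within +/- max_shift (circular FFT correlation, mean-subtracted).
# Returns the (dy, dx) such that frame ~ ref shifted by (dy, dx).
estimate_shift <- function(ref, frame, max_shift) {
  a <- ref - mean(ref)
  b <- frame - mean(frame)
  cc <- Re(stats::fft(Conj(stats::fft(a)) * stats::fft(b), inverse = TRUE))
  nr <- nrow(cc); nc <- ncol(cc)
  ms <- as.integer(max_shift)
  dys <- c(0:min(ms, nr - 1), if (ms > 0) -(1:min(ms, nr - 1)))
  dxs <- c(0:min(ms, nc - 1), if (ms > 0) -(1:min(ms, nc - 1)))
  dys <- unique(dys); dxs <- unique(dxs)
  best <- c(0L, 0L)
  bestv <- cc[1L, 1L]  # zero shift; later candidates must beat it clearly
  for (dy in dys) for (dx in dxs) {
    v <- cc[(dy %% nr) + 1L, (dx %% nc) + 1L]
    if (v > bestv + 1e-9 * abs(bestv)) {
      bestv <- v
      best <- c(dy, dx)
    }
  }
  best
}

#' Register two co-acquired stacks by integer translation
#'
#' Per-frame integer offsets are estimated on the reference channel by
#' maximizing cross-correlation against its first frame (bounded search,
#' `max_shift` pixels), then the same offset is applied to both channels.
#' Vacated pixels are filled with the frame's outside-cell mean when masks
#' are supplied, otherwise with the frame mean.
#'
#' @param reference Stack used to estimate the drift (typically the ECM
#'   channel, whose texture is the most stable landmark).
#' @param follower Co-registered stack receiving the same offsets.
#' @param max_shift Maximum absolute shift searched, in pixels.
#' @param cell_masks Optional per-frame logical masks (`TRUE` inside cells)
#'   used for the fill value.
#' @return List with `reference`, `follower` (registered stacks) and
#'   `offsets`, an n x 2 matrix of applied translations `(dy, dx)`.
#' @export
register_translation <- function(reference, follower, max_shift = 20,
                                 cell_masks = NULL) {
  if (!identical(frame_dim(reference), frame_dim(follower)) ||
      n_frames(reference) != n_frames(follower))
    stop("reference and follower stacks must have identical shape", call. = FALSE)
  nt <- n_frames(reference)
  offsets <- matrix(0L, nt, 2, dimnames = list(NULL, c("dy", "dx")))
  ref0 <- reference$frames[[1]]
  rframes <- reference$frames
  fframes <- follower$frames
  for (t in seq_len(nt)[-1]) {
    s <- estimate_shift(ref0, rframes[[t]], max_shift)
    off <- -s
    offsets[t, ] <- off
    if (any(off != 0)) {
      fill_r <- if (is.null(cell_masks)) mean(rframes[[t]]) else
        mean(rframes[[t]][!(cell_masks[[t]] != 0)])
      fill_f <- if (is.null(cell_masks)) mean(fframes[[t]]) else
        mean(fframes[[t]][!(cell_masks[[t]] != 0)])
      rframes[[t]] <- shift_frame(rframes[[t]], off[1], off[2], fill_r)
      fframes[[t]] <- shift_frame(fframes[[t]], off[1], off[2], fill_f)
    }
  }
  list(reference = with_frames(reference, rframes),
       follower = with_frames(follower, fframes),
       offsets = offsets)
}

#' Preprocess a marker/ECM stack pair
#'
#' Applies the full correction chain in the fixed order flat-field ->
#' registration -> photobleach -> normalization.  In single-invadopodia mode
#' the marker channel is left unprocessed and the ECM channel receives all
#' four steps; in population mode the marker channel is flat-field corrected,
#' registration is skipped and the ECM is not normalized (population metrics
#' are percentages, invariant to the global scale).
#'
#' Cell masks needed by the bleach/normalization steps are segmented from the
#' marker channel ([segment_cell_mask()]); when registration is enabled,
#' provisional masks provide the fill value and masks are re-segmented on the
#' registered marker stack.
#'
#' @param marker,ecm [timelapse_stack()] objects of identical shape.
#' @param mode `"single"` or `"population"`.
#' @param flat_field Optional acquired illumination reference; `NULL` uses
#'   the retrospective estimate.
#' @param register Estimate and apply per-frame translation? Defaults by mode.
#' @param normalize Normalize the ECM outside-cell mean? Defaults by mode.
#' @param target Normalization target (default 1000).
#' @param max_shift Registration search bound in pixels.
#' @param flat_sigma Smoothing scale of the retrospective flat-field estimate.
#' @param cell_params [seg_params()] controlling cell-mask segmentation.
#' @return List with `marker`, `ecm` (corrected stacks), `cell_masks`
#'   (per-frame logical matrices) and `report`, a tibble with one row per
#'   frame: `frame`, `bleach_scale`, `dy`, `dx`, `outside_mean`, plus the
#'   global `norm_scale` as an attribute.
#' @export
preprocess_pair <- function(marker, ecm, mode = c("single", "population"),
                            flat_field = NULL,
                            register = NULL, normalize = NULL, target = 1000,
                            max_shift = 20, flat_sigma = 50,
                            cell_params = seg_params()) {
  mode <- match.arg(mode)
  if (is.null(register)) register <- mode == "single"
  if (is.null(normalize)) normalize <- mode == "single"
  if (!identical(frame_dim(marker), frame_dim(ecm)) ||
      n_frames(marker) != n_frames(ecm))
    stop("marker and ECM stacks must have identical shape", call. = FALSE)

  # flat-field
  ecm_ff <- flat_field_correct(ecm, flat_field, sigma = flat_sigma)
  ecm <- ecm_ff$stack
  if (mode == "population")
    marker <- flat_field_correct(marker, flat_field, sigma = flat_sigma)$stack

  masks <- lapply(marker$frames, segment_cell_mask,
                  sigma = cell_params$cell_sigma, k_cell = cell_params$k_cell,
                  min_size_px = cell_params$cell_min_px)

  # registration (offsets estimated on the ECM channel)
  offsets <- matrix(0L, n_frames(ecm), 2, dimnames = list(NULL, c("dy", "dx")))
  if (register) {
    reg <- register_translation(ecm, marker, max_shift = max_shift,
                                cell_masks = masks)
    ecm <- reg$reference
    marker <- reg$follower
    offsets <- reg$offsets
    masks <- lapply(marker$frames, segment_cell_mask,
                    sigma = cell_params$cell_sigma, k_cell = cell_params$k_cell,
                    min_size_px = cell_params$cell_min_px)
  }

  # photobleach
  pb <- photobleach_correct(ecm, masks)
  ecm <- pb$stack

  # normalization
  norm_scale <- 1
  if (normalize) {
    nm <- normalize_ecm(ecm, masks, target = target)
    ecm <- nm$stack
    norm_scale <- nm$norm_scale
  }

  report <- tibble::tibble(
    frame = seq_len(n_frames(ecm)),
    bleach_scale = pb$bleach_scale,
    dy = offsets[, 1], dx = offsets[, 2],
    outside_mean = pb$outside_mean * norm_scale
  )
  attr(report, "norm_scale") <- norm_scale
  list(marker = marker, ecm = ecm, cell_masks = masks, report = report)
}
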