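#' Time-lapse stack of single-channel fluorescence frames
#'
#' Container for one channel of a time-lapse acquisition: an ordered list of
#' 2-D intensity matrices plus acquisition metadata.  Intensities are stored
#' as doubles in arbitrary fluorescence units; all frames must share the same
#' dimensions.
#'
#' @param frames List of numeric matrices, all the same dimensions, ordered
#'   by acquisition time.
#' @param frame_interval_min Minutes between consecutive frames (> 0).
#' @param pixel_size_um Physical edge length of one pixel in micrometres (> 0).
#' @param channel_label `"marker"` (intracellular actin marker, e.g.
#'   LifeAct-GFP) or `"ecm"` (labeled extracellular matrix).
#' @return An object of class `timelapse_stack`.
#' @export
timelapse_stack <- function(frames, frame_interval_min, pixel_size_um,
                            channel_label = c("marker", "ecm")) {
  channel_label <- match.arg(channel_label)
  if (!is.list(frames) || length(frames) == 0)
    stop("`frames` must be a non-empty list of matrices", call. = FALSE)
  if (!all(vapply(frames, is.matrix, logical(1))))
    stop("every frame must be a matrix", call. = FALSE)
  d <- dim(frames[[1]])
  for (i in seq_along(frames)) {
    if (!identical(dim(frames[[i]]), d))
      stop(sprintf("frame %d has dimensions %s; expected %s", i,
                   paste(dim(frames[[i]]), collapse = "x"),
                   paste(d, collapse = "x")), call. = FALSE)
    if (!all(is.finite(frames[[i]])))
      stop(sprintf("frame %d contains non-finite values", i), call. = FALSE)
  }
  if (!is.numeric(frame_interval_min) || frame_interval_min <= 0)
    stop("`frame_interval_min` must be > 0", call. = FALSE)
  if (!is.numeric(pixel_size_um) || pixel_size_um <= 0)
    stop("`pixel_size_um` must be > 0", call. = FALSE)
  frames <- lapply(frames, function(f) {
    storage.mode(f) <- "double"
    f
  })
  structure(
    list(frames = frames,
         frame_interval_min = as.numeric(frame_interval_min),
         pixel_size_um = as.numeric(pixel_size_um),
         channel_label = channel_label),
    class = "timelapse_stack"
  )
}

#' @export
print.timelapse_stack <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf(
    "<timelapse_stack> %s channel: %d frames of %dx%d px, %.3g min/frame, %.4g um/px\n",
    x$channel_label, length(x$frames), d[1], d[2],
    x$frame_interval_min, x$pixel_size_um))
  invisible(x)
}

#' Number of frames in a stack
#' @param stack A `timelapse_stack`.
#' @export
n_frames <- function(stack) length(stack$frames)

#' Frame dimensions of a stack
#' @param stack A `timelapse_stack`.
#' @return `c(nrow, ncol)`.
#' @export
frame_dim <- function(stack) dim(stack$frames[[1]])

# Replace the frames of a stack, keeping metadata.
with_frames <- function(stack, frames) {
  stack$frames <- frames
  stack
}

#' Load a time-lapse stack from TIFF files
#'
#' Reads either one multi-page TIFF or an ordered list of TIFF files (pages
#' of multi-page members are appended in order).  Integer pixel data are read
#' at native scale (e.g. 0..65535 for 16-bit) and cast to double.
#'
#' @param path_spec A single file path (multi-page TIFF) or a character
#'   vector of paths in acquisition order.
#' @inheritParams timelapse_stack
#' @return A [timelapse_stack()].
#' @export
load_timelapse <- function(path_spec, frame_interval_min, pixel_size_um,
                           channel_label = c("marker", "ecm")) {
  paths <- as.character(path_spec)
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop("cannot read TIFF: file not found: ", missing[1], call. = FALSE)
  frames <- list()
  for (p in paths) {
    pages <- tiff::readTIFF(p, all = TRUE, as.is = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    for (pg in pages) {
      if (length(dim(pg)) == 3L && dim(pg)[3] == 1L) pg <- pg[, , 1L]
      if (length(dim(pg)) != 2L)
        stop("multi-channel TIFF pages are not supported: ", p, call. = FALSE)
      frames[[length(frames) + 1L]] <- matrix(as.numeric(pg), nrow(pg), ncol(pg))
    }
  }
  d <- dim(frames[[1]])
  for (i in seq_along(frames))
    if (!identical(dim(frames[[i]]), d))
      stop(sprintf("frame %d has dimensions %s; expected %s (shape mismatch)",
                   i, paste(dim(frames[[i]]), collapse = "x"),
                   paste(d, collapse = "x")), call. = FALSE)
  timelapse_stack(frames, frame_interval_min, pixel_size_um, channel_label)
}

#' Write a time-lapse stack as a multi-page 16-bit TIFF
#'
#' Values are clamped to \[0, 65535\] and rounded to the nearest integer, the
#' native range of the CCD cameras the pipeline targets.
#'
#' @param stack A `timelapse_stack`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_timelapse <- function(stack, path) {
  pages <- lapply(stack$frames, function(f) round(pmin(pmax(f, 0), 65535)) / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}
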