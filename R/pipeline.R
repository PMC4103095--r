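# End-to-end orchestration of the two analysis modes, driven by a config
# list (or YAML file).  Every run writes its fully resolved configuration
# beside the outputs so results are reproducible.

#' Default configuration for an analysis run
#'
#' Mode-specific defaults: single-invadopodia mode uses the 5-px degradation
#' border, the 60-min (12 frames at 5 min) lifetime filter and ECM
#' normalization to 1000; population mode uses the 40-px border, the 600-min
#' lifetime filter, the 1,500-20,000 px cell-size window, the 2.5-h area of
#' influence, the 20% degraded-pixel drop, and skips registration and
#' normalization.
#'
#' @param mode `"single"` or `"population"`.
#' @param ... Named overrides of any default.
#' @return A named list of class `invado_config`.
#' @export
default_config <- function(mode = c("single", "population"), ...) {
  mode <- match.arg(mode)
  cfg <- list(
    mode = mode,
    marker_path = NULL, ecm_path = NULL, flat_field_path = NULL,
    frame_interval_min = if (mode == "single") 5 else 30,
    pixel_size_um = if (mode == "single") 0.1075 else 0.267,
    sigma_hp = 10, k_seed = 3, min_seed_px = 6, k_expand = 1.75,
    area_bounds = c(6, 200), ratio_bounds = c(1, 4),
    cell_sigma = 2, k_cell = 1, cell_min_px = 50,
    border_width = if (mode == "single") 5 else 40,
    min_lifetime_min = if (mode == "single") 60 else 600,
    register = mode == "single", normalize = mode == "single",
    norm_target = 1000, max_shift = 20, flat_sigma = 50,
    alpha = 0.05,
    a_min = 1500, a_max = 20000,
    min_coverage_h = 2.5, drop_fraction = 0.20, fp_budget = 0,
    cutoffs = NULL, outdir = NULL, rng_seed = NULL)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  cfg[names(over)] <- over
  structure(cfg, class = "invado_config")
}

#' Read a configuration from a YAML file
#' @param path YAML file with a `mode` key and any [default_config()] keys.
#' @return An `invado_config` list.
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$mode)) stop("config must name a `mode`", call. = FALSE)
  mode <- y$mode; y$mode <- NULL
  do.call(default_config, c(list(mode = mode), y))
}

cfg_seg_params <- function(cfg) {
  seg_params(sigma_hp = cfg$sigma_hp, k_seed = cfg$k_seed,
             min_seed_px = cfg$min_seed_px, k_expand = cfg$k_expand,
             area_bounds = cfg$area_bounds, ratio_bounds = cfg$ratio_bounds,
             cell_sigma = cfg$cell_sigma, k_cell = cfg$k_cell,
             cell_min_px = cfg$cell_min_px)
}

resolve_inputs <- function(cfg, marker, ecm) {
  if (is.null(marker)) {
    if (is.null(cfg$marker_path) || is.null(cfg$ecm_path))
      stop("config must provide marker/ecm paths or in-memory stacks",
           call. = FALSE)
    marker <- load_timelapse(cfg$marker_path, cfg$frame_interval_min,
                             cfg$pixel_size_um, "marker")
    ecm <- load_timelapse(cfg$ecm_path, cfg$frame_interval_min,
                          cfg$pixel_size_um, "ecm")
  }
  flat <- NULL
  if (!is.null(cfg$flat_field_path)) {
    pg <- tiff::readTIFF(cfg$flat_field_path, as.is = TRUE)
    flat <- matrix(as.numeric(pg), nrow(pg), ncol(pg))
  }
  list(marker = marker, ecm = ecm, flat = flat)
}

write_outputs <- function(outdir, cfg, tables) {
  if (is.null(outdir)) return(invisible(NULL))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(tables))
    utils::write.csv(tables[[nm]], file.path(outdir, paste0(nm, ".csv")),
                     row.names = FALSE)
  cfg_plain <- unclass(cfg)
  cfg_plain <- cfg_plain[!vapply(cfg_plain, is.null, logical(1))]
  yaml::write_yaml(cfg_plain, file.path(outdir, "resolved_config.yaml"))
  invisible(NULL)
}

#' Run the single-invadopodia analysis end to end
#'
#' Preprocess (flat-field, registration, photobleach, normalization of the
#' ECM channel), segment puncta per frame, link by overlap, keep tracks
#' alive at least `min_lifetime_min`, measure the degradation series,
#' classify invadopodia and extract their dynamic properties.
#'
#' @param config An `invado_config` (or path to a YAML config).
#' @param marker,ecm Optional in-memory [timelapse_stack()] pair; when
#'   omitted, the config's `marker_path`/`ecm_path` are loaded.
#' @return List with `calls`, `properties`, `tracks_summary`, `degradation`
#'   (long per-track-frame tibble), `preprocess_report`, plus the
#'   intermediate `tracks`, `series`, `cell_masks` and preprocessed stacks.
#'   When `config$outdir` is set, the tibbles and the resolved config are
#'   written there as CSV/YAML.
#' @export
run_single_mode <- function(config = default_config("single"),
                            marker = NULL, ecm = NULL) {
  if (is.character(config)) config <- read_config(config)
  stopifnot(config$mode == "single")
  if (!is.null(config$rng_seed)) set.seed(config$rng_seed)
  inp <- resolve_inputs(config, marker, ecm)
  params <- cfg_seg_params(config)

  pre <- preprocess_pair(inp$marker, inp$ecm, mode = "single",
                         flat_field = inp$flat, register = config$register,
                         normalize = config$normalize,
                         target = config$norm_target,
                         max_shift = config$max_shift,
                         flat_sigma = config$flat_sigma, cell_params = params)

  seg <- segment_puncta(pre$marker, params, cell_masks = pre$cell_masks)
  tracks <- link_by_overlap(seg$regions, frame_dim(pre$marker))
  kept <- filter_by_lifetime(tracks, config$min_lifetime_min,
                             pre$marker$frame_interval_min)
  series <- lapply(kept, degradation_series, ecm_stack = pre$ecm,
                   all_regions_by_frame = seg$regions,
                   width = config$border_width)
  calls <- classify_tracks(series, alpha = config$alpha)
  props <- invadopodia_properties(kept, calls, series, pre$cell_masks,
                                  pre$marker$pixel_size_um,
                                  pre$marker$frame_interval_min)
  degradation <- if (length(series))
    dplyr::bind_rows(lapply(series, function(s)
      dplyr::mutate(s$data, track_id = s$track_id, .before = 1))) else
    tibble::tibble(track_id = integer(), frame = integer(),
                   n_under = integer(), n_border = integer(),
                   L = numeric(), P = numeric(), C = numeric())

  out <- list(calls = calls, properties = props,
              tracks_summary = tracks_summary(kept,
                                              pre$marker$frame_interval_min),
              degradation = degradation,
              preprocess_report = pre$report,
              tracks = kept, all_tracks = tracks, series = series,
              regions = seg$regions, cell_masks = pre$cell_masks,
              marker = pre$marker, ecm = pre$ecm, config = config)
  write_outputs(config$outdir, config,
                list(calls = calls, properties = props,
                     tracks = out$tracks_summary, degradation = degradation,
                     preprocess_report = pre$report))
  out
}

#' Run the whole-cell population analysis end to end
#'
#' Preprocess (flat-field on both channels, photobleach on the ECM, no
#' registration), segment and size-filter cells, track them, keep tracks
#' alive at least 10 h, measure per-frame and overall degradation
#' percentages, area of influence, degraded area and rate, and classify
#' degraders when cutoffs are available.  Cutoffs may be supplied in the
#' config or calibrated on a negative-control run via
#' [calibrate_degrader_cutoffs()].
#'
#' @inheritParams run_single_mode
#' @return List with `per_cell`, `per_frame`, `preprocess_report`, `tracks`,
#'   `influence`, `degraded`, the preprocessed stacks and the config.
#' @export
run_population_mode <- function(config = default_config("population"),
                                marker = NULL, ecm = NULL) {
  if (is.character(config)) config <- read_config(config)
  stopifnot(config$mode == "population")
  if (!is.null(config$rng_seed)) set.seed(config$rng_seed)
  inp <- resolve_inputs(config, marker, ecm)
  params <- cfg_seg_params(config)

  pre <- preprocess_pair(inp$marker, inp$ecm, mode = "population",
                         flat_field = inp$flat, register = config$register,
                         normalize = config$normalize,
                         target = config$norm_target,
                         flat_sigma = config$flat_sigma, cell_params = params)

  res <- analyze_population(pre$marker, pre$ecm, params,
                            border_width = config$border_width,
                            min_lifetime_min = config$min_lifetime_min,
                            min_coverage_h = config$min_coverage_h,
                            drop_fraction = config$drop_fraction,
                            a_min = config$a_min, a_max = config$a_max,
                            cutoffs = config$cutoffs)
  out <- c(res, list(preprocess_report = pre$report, marker = pre$marker,
                     ecm = pre$ecm, config = config))
  write_outputs(config$outdir, config,
                list(per_cell = res$per_cell, per_frame = res$per_frame,
                     preprocess_report = pre$report))
  if (!is.null(config$outdir) && !is.null(config$cutoffs))
    jsonlite::write_json(unclass(config$cutoffs),
                         file.path(config$outdir, "cutoffs.json"),
                         auto_unbox = TRUE, digits = NA)
  out
}
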