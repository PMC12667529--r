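#' Pipeline configuration
#'
#' Collects every tunable threshold and parameter of the analysis chain in a
#' single validated list. Defaults are the acquisition and analysis settings
#' of the SiMPull/dSTORM workflow: 107 nm camera pixels, mean projection over
#' the trailing 40 frames, a 4-pixel colocalization radius, a strict < 30 nm
#' localization-precision filter after discarding the first 300 frames,
#' DBSCAN at eps 0.5 px / 5 localizations, subpopulation thresholds of
#' 100 nm (long), 0.9 (fibrillar), 0.01 loc/nm^2 (dense) and 0.9 A.U.
#' (bright), a 101-point cumulative-distribution grid, 1000-assembly matched
#' subsamples for KS comparisons, and volcano cut-offs of |log2| > 1 and
#' -log10 p > 1.3.
#'
#' @param ... named overrides of any default listed above.
#' @return An object of class `aggrefinger_config` (a named list).
#' @examples
#' cfg <- pipeline_config(coloc_radius_px = 5)
#' cfg$pixel_size_nm
#' @seealso [write_config()], [read_config()], [config_hash()]
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    pixel_size_nm       = 107,
    image_width_px      = 512L,
    image_height_px     = 512L,
    projection_last_n   = 40L,
    detect_smooth_sigma = 1,
    detect_k            = 5,
    detect_min_sep_px   = 3,
    intensity_window_px = 2L,
    border_policy       = "exclude",
    coloc_radius_px     = 4,
    chance_transpose    = "mirror_x",
    max_precision_nm    = 30,
    discard_first_frames = 300L,
    eps_px              = 0.5,
    min_samples         = 5L,
    render_px_nm        = 10.7,
    morph_radii         = c(dilate = 1L, close = 2L, erode = 1L),
    long_nm             = 100,
    fibrillar_ecc       = 0.9,
    dense_loc_per_nm2   = 0.01,
    bright_au           = 0.9,
    threshold_boundary  = "inclusive",
    cdf_grid_n          = 101L,
    subsample_n         = 1000L,
    n_boot              = 100L,
    volcano_log2        = 1,
    volcano_neglog10p   = 1.3,
    contaminant_prefixes = c("CON__", "KRT"),
    seed                = 42L
  )
  dots <- list(...)
  if (length(dots)) {
    unknown <- setdiff(names(dots), names(cfg))
    if (length(unknown)) {
      stop("unknown configuration field(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    cfg[names(dots)] <- dots
  }
  validate_config(cfg)
  structure(cfg, class = "aggrefinger_config")
}

validate_config <- function(cfg) {
  pos <- c("pixel_size_nm", "image_width_px", "image_height_px",
           "projection_last_n", "detect_smooth_sigma", "detect_k",
           "detect_min_sep_px", "coloc_radius_px", "max_precision_nm",
           "eps_px", "min_samples", "render_px_nm", "long_nm",
           "fibrillar_ecc", "dense_loc_per_nm2", "bright_au", "cdf_grid_n",
           "subsample_n", "n_boot", "volcano_log2", "volcano_neglog10p")
  for (f in pos) stopifnot_positive(cfg[[f]], f)
  if (cfg$fibrillar_ecc >= 1) stop("`fibrillar_ecc` must be < 1", call. = FALSE)
  if (cfg$discard_first_frames < 0) stop("`discard_first_frames` must be >= 0", call. = FALSE)
  if (any(cfg$morph_radii < 0)) stop("`morph_radii` must be >= 0", call. = FALSE)
  invisible(cfg)
}

#' @export
print.aggrefinger_config <- function(x, ...) {
  cat("aggrefinger pipeline configuration (hash ", config_hash(x), ")\n", sep = "")
  flat <- vapply(x, function(v) paste(format(v), collapse = ","), character(1))
  cat(paste0("  ", format(names(flat)), " : ", flat, collapse = "\n"), "\n")
  invisible(x)
}

#' Serialize / restore a pipeline configuration
#'
#' YAML round trips are lossless: `read_config(write_config(cfg, path))`
#' returns a configuration identical to `cfg`.
#'
#' @param cfg an `aggrefinger_config` object.
#' @param path file path for the YAML document.
#' @return `write_config()` returns `path` invisibly; `read_config()` returns
#'   an `aggrefinger_config`.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "aggrefinger_config"))
  yaml::write_yaml(unclass(cfg), path, precision = 15L)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  int_fields <- c("image_width_px", "image_height_px", "projection_last_n",
                  "intensity_window_px", "discard_first_frames", "min_samples",
                  "cdf_grid_n", "subsample_n", "n_boot", "seed")
  for (f in int_fields) raw[[f]] <- as.integer(raw[[f]])
  raw$morph_radii <- setNames(as.integer(raw$morph_radii),
                              c("dilate", "close", "erode"))
  do.call(pipeline_config, raw)
}

#' Deterministic fingerprint of a configuration
#'
#' @param cfg an `aggrefinger_config` object.
#' @return An 8-character hexadecimal hash, recorded in every pipeline
#'   output manifest so results can be traced to the exact settings used.
#' @export
config_hash <- function(cfg) {
  stopifnot(inherits(cfg, "aggrefinger_config"))
  flat <- vapply(seq_along(cfg), function(i) {
    paste0(names(cfg)[i], "=", paste(format(cfg[[i]], digits = 15), collapse = ","))
  }, character(1))
  fnv1a_hash(flat)
}
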