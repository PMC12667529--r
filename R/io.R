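#' Read and write localization tables
#'
#' Localization tables are CSV files with the columns `frame`, `x`, `y`,
#' `photons`, `sx`, `sy`, `bg`, `lpx`, `lpy` (coordinates and per-axis
#' precisions in camera pixels), the common SMLM localization-table layout.
#' Round trips through [write_localizations()] and
#' [read_localization_table()] are identity up to numeric printing
#' precision.
#'
#' @param locs localization table.
#' @param path CSV file path.
#' @param pixel_size_nm camera pixel size attached to the table.
#' @return `read_localization_table()` returns the validated table with the
#'   `pixel_size_nm` attribute set; an empty file yields an empty table
#'   with the full schema and a warning.
#' @export
write_localizations <- function(locs, path) {
  cols <- localization_schema()
  stopifnot(all(cols %in% names(locs)))
  write.csv(locs[, cols], path, row.names = FALSE)
  invisible(path)
}

localization_schema <- function() {
  c("frame", "x", "y", "photons", "sx", "sy", "bg", "lpx", "lpy")
}

#' @rdname write_localizations
#' @export
read_localization_table <- function(path, pixel_size_nm = 107) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  tab <- read.csv(path)
  cols <- localization_schema()
  missing <- setdiff(cols, names(tab))
  if (length(missing)) {
    stop("localization table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (nrow(tab) == 0L) {
    warning("empty localization table: ", path)
  } else if (any(!is.finite(tab$x) | !is.finite(tab$y))) {
    stop("non-finite coordinates in ", path, call. = FALSE)
  }
  tab <- tab[, cols]
  attr(tab, "pixel_size_nm") <- pixel_size_nm
  tab
}

#' Read and write TIRF image stacks
#'
#' Stacks are stored as multi-frame TIFF files of integer photon counts
#' (16-bit). [read_stack()] returns a `height x width x frames` array with
#' the pixel size attached from the argument; [write_stack()] rounds to
#' integers and clips at the 16-bit range.
#'
#' @param stack `height x width x frames` numeric array.
#' @param path TIFF file path.
#' @param pixel_size_nm camera pixel size attached on read.
#' @return `read_stack()` returns the stack array.
#' @export
write_stack <- function(stack, path) {
  if (is.matrix(stack)) stack <- array(stack, dim = c(dim(stack), 1L))
  frames <- lapply(seq_len(dim(stack)[3]), function(f) {
    m <- pmin(pmax(round(stack[, , f]), 0), 65535)
    m / 65535
  })
  tiff::writeTIFF(frames, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_stack
#' @export
read_stack <- function(path, pixel_size_nm = 107) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  frames <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE),
                     error = function(e) {
                       stop("cannot parse TIFF file ", path, ": ",
                            conditionMessage(e), call. = FALSE)
                     })
  if (!is.list(frames)) frames <- list(frames)
  stack <- array(0, dim = c(nrow(frames[[1]]), ncol(frames[[1]]),
                            length(frames)))
  for (f in seq_along(frames)) stack[, , f] <- frames[[f]]
  attr(stack, "pixel_size_nm") <- pixel_size_nm
  stack
}

#' Run the full fingerprinting pipeline on a synthetic cohort
#'
#' End-to-end orchestration: simulates a donor cohort, measures every
#' replicate's localization table ([analyze_localizations()]), classifies
#' aggregates, computes colabelling proportions ([coloc_analysis()]),
#' assembles donor profiles, runs the cohort statistics (Welch's t on
#' donor-level counts, subsampled KS on pooled length distributions),
#' fits the linear-discriminant signature, and produces a corrected-ratio
#' volcano table from simulated two-fraction proteomics. All stage outputs
#' are written as CSV files together with a JSON manifest recording the
#' seed, configuration hash and package version; a rerun with the same
#' seed and configuration reproduces the outputs.
#'
#' @param config an [pipeline_config()] object.
#' @param spec a [cohort_spec()].
#' @param out_dir output directory (created if needed); `NULL` skips
#'   writing.
#' @param proteomics_effects optional `effects` data.frame passed to
#'   [simulate_proteomics()].
#' @param verbose print stage-level progress.
#' @return A list with `profiles`, `records`, `subpopulations`, `stats`,
#'   `lda`, `contributions`, `volcano`, `manifest`.
#' @export
run_profile <- function(config = pipeline_config(), spec = cohort_spec(),
                        out_dir = NULL, proteomics_effects = NULL,
                        verbose = FALSE) {
  say <- function(...) if (verbose) message("[run_profile] ", ...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage `%s` failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  set.seed(config$seed)
  say("simulating cohort")
  sim <- stage("simulate", simulate_cohort(spec, seed = config$seed))

  say("measuring ", length(sim$datasets), " replicate datasets")
  thresholds <- subpop_thresholds(config$long_nm, config$fibrillar_ecc,
                                  config$dense_loc_per_nm2, config$bright_au,
                                  boundary = if (config$threshold_boundary ==
                                                 "inclusive") "inclusive" else "exclusive")
  records <- counts <- intensities <- coloc <- list()
  stage("measure", for (ds in sim$datasets) {
    res <- analyze_localizations(ds$locs, config)
    if (nrow(res$records)) {
      rec <- res$records
      rec$donor <- ds$donor; rec$cohort <- ds$cohort
      rec$region <- ds$region; rec$replicate <- ds$replicate
      records[[length(records) + 1L]] <- rec
    }
    counts[[length(counts) + 1L]] <- data.frame(
      donor = ds$donor, cohort = ds$cohort, region = ds$region,
      replicate = ds$replicate, count = nrow(ds$spots))
    intensities[[length(intensities) + 1L]] <- data.frame(
      donor = ds$donor, region = ds$region, replicate = ds$replicate,
      intensity = ds$spots$intensity)
    cres <- coloc_analysis(ds$spots[, c("x_px", "y_px")], ds$colabel,
                           image_width_px = config$image_width_px,
                           radius = config$coloc_radius_px)
    coloc[[length(coloc) + 1L]] <- data.frame(
      donor = ds$donor, region = ds$region, replicate = ds$replicate,
      proportion = cres$proportion, chance = cres$chance_proportion)
  })
  records <- classify_aggregates(do.call(rbind, records), thresholds)
  counts <- do.call(rbind, counts)
  intensities <- do.call(rbind, intensities)
  coloc <- do.call(rbind, coloc)

  say("building donor profiles")
  profiles <- stage("profiles", build_donor_profiles(
    records, counts, intensities, coloc, thresholds))
  subpop <- lapply(split(records, paste(records$cohort, records$region)),
                   tabulate_subpopulations)

  say("cohort statistics")
  stats_rows <- stage("stats", cohort_statistics(records, counts, config))

  say("fitting discriminant signature")
  fm <- stage("lda", build_feature_matrix(profiles))
  fit <- stage("lda", fit_lda(fm$x, fm$labels))
  contributions <- rank_contributions(fit)

  say("proteomics")
  prot <- stage("proteomics", {
    ps <- simulate_proteomics(effects = proteomics_effects,
                              seed = config$seed)
    tot <- reference_normalize(filter_quantified(
      ps$total, config$contaminant_prefixes), "per_run")
    agg <- reference_normalize(filter_quantified(
      ps$aggregate, config$contaminant_prefixes), "per_channel")
    ctrl <- grep("^control_", attr(ps$total, "design")$column, value = TRUE)
    case <- grep("^case_", attr(ps$total, "design")$column, value = TRUE)
    volcano_classify(compute_corrected_ratios(tot, agg, ctrl, case),
                     config$volcano_log2, config$volcano_neglog10p)
  })

  manifest <- list(
    package = "aggrefinger",
    version = as.character(utils::packageVersion("aggrefinger")),
    seed = config$seed,
    config_hash = config_hash(config),
    n_datasets = length(sim$datasets),
    n_aggregates = nrow(records),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(records, file.path(out_dir, "aggregate_records.csv"),
              row.names = FALSE)
    write.csv(profiles, file.path(out_dir, "donor_profiles.csv"),
              row.names = FALSE)
    write.csv(stats_rows, file.path(out_dir, "cohort_stats.csv"),
              row.names = FALSE)
    proj <- data.frame(label = fit$labels, fit$projection)
    write.csv(proj, file.path(out_dir, "lda_projection.csv"),
              row.names = FALSE)
    write.csv(contributions$LD1, file.path(out_dir, "lda_contributions.csv"),
              row.names = FALSE)
    write.csv(prot, file.path(out_dir, "volcano.csv"), row.names = FALSE)
    sankey <- do.call(rbind, lapply(names(subpop), function(k) {
      cbind(group = k, subpop[[k]]$cells)
    }))
    write.csv(sankey, file.path(out_dir, "sankey_counts.csv"),
              row.names = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(list(profiles = profiles, records = records,
                 subpopulations = subpop, stats = stats_rows, lda = fit,
                 contributions = contributions, volcano = prot,
                 coloc = coloc, counts = counts, manifest = manifest))
}

# Donor-level Welch comparisons (counts) and pooled KS comparisons
# (lengths) between MND_TDP and CRL per region; Holm correction within the
# per-cohort KS family.
cohort_statistics <- function(records, counts, config) {
  rows <- list()
  for (region in unique(counts$region)) {
    creg <- counts[counts$region == region, ]
    donor_counts <- aggregate(count ~ donor + cohort, creg, mean)
    a <- donor_counts$count[donor_counts$cohort == "CRL"]
    b <- donor_counts$count[donor_counts$cohort == "MND_TDP"]
    if (length(a) >= 2 && length(b) >= 2) {
      wt <- welch_t(a, b)
      rows[[length(rows) + 1L]] <- data.frame(
        comparison = "count CRL vs MND_TDP", region = region,
        statistic = wt$t, p_raw = wt$p_value, p_corrected = wt$p_value,
        family = "welch", n = length(a) + length(b))
    }
    rreg <- records[records$region == region, ]
    la <- rreg$skeleton_length_nm[rreg$cohort == "CRL"]
    lb <- rreg$skeleton_length_nm[rreg$cohort == "MND_TDP"]
    if (length(la) >= 5 && length(lb) >= 5) {
      ks <- bootstrap_ks(la, lb, subsample_n = config$subsample_n,
                         n_boot = config$n_boot)
      rows[[length(rows) + 1L]] <- data.frame(
        comparison = "length CRL vs MND_TDP", region = region,
        statistic = ks$statistic, p_raw = ks$p_value,
        p_corrected = NA_real_, family = "ks", n = ks$subsample_n)
    }
  }
  out <- do.call(rbind, rows)
  ksel <- out$family == "ks"
  out$p_corrected[ksel] <- correct_family(out$p_raw[ksel], "holm")
  out
}
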