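#' Subpopulation thresholds
#'
#' The cumulative category thresholds used to segregate individual
#' assemblies: long (skeleton length >= 100 nm), fibrillar (eccentricity
#' >= 0.9), dense (localization density >= 0.01 loc/nm^2, with sparse as its
#' complement) and bright (scaled intensity >= 0.9 A.U.). Thresholds are
#' applied inclusively by default.
#'
#' @param long_nm,fibrillar_ecc,dense_loc_per_nm2,bright_au threshold values.
#' @param boundary `"inclusive"` (`>=`) or `"exclusive"` (`>`).
#' @return A named list of class `subpop_thresholds`.
#' @export
subpop_thresholds <- function(long_nm = 100, fibrillar_ecc = 0.9,
                              dense_loc_per_nm2 = 0.01, bright_au = 0.9,
                              boundary = c("inclusive", "exclusive")) {
  boundary <- match.arg(boundary)
  stopifnot(long_nm > 0, fibrillar_ecc > 0, fibrillar_ecc < 1,
            dense_loc_per_nm2 > 0, bright_au > 0)
  structure(list(long_nm = long_nm, fibrillar_ecc = fibrillar_ecc,
                 dense_loc_per_nm2 = dense_loc_per_nm2, bright_au = bright_au,
                 boundary = boundary), class = "subpop_thresholds")
}

#' Classify aggregates into morphological subpopulations
#'
#' Adds the category flags `long`, `fibrillar`, `dense`, `sparse` (the
#' complement of dense) and — where a `scaled_intensity` column is present —
#' `bright` to a table of aggregate records.
#'
#' @param records data.frame of aggregate records (columns
#'   `skeleton_length_nm`, `eccentricity`, `density_loc_per_nm2`, optionally
#'   `scaled_intensity`).
#' @param thresholds a [subpop_thresholds()] object.
#' @return `records` with logical category columns appended.
#' @examples
#' rec <- data.frame(skeleton_length_nm = 120, eccentricity = 0.95,
#'                   density_loc_per_nm2 = 0.005)
#' classify_aggregates(rec)[, c("long", "fibrillar", "sparse")]
#' @export
classify_aggregates <- function(records, thresholds = subpop_thresholds()) {
  ge <- if (thresholds$boundary == "inclusive") `>=` else `>`
  records$long <- ge(records$skeleton_length_nm, thresholds$long_nm)
  records$fibrillar <- ge(records$eccentricity, thresholds$fibrillar_ecc)
  records$dense <- ge(records$density_loc_per_nm2, thresholds$dense_loc_per_nm2)
  records$sparse <- !records$dense
  if (!is.null(records$scaled_intensity)) {
    records$bright <- ge(records$scaled_intensity, thresholds$bright_au)
  }
  records
}

#' Tabulate subpopulation membership
#'
#' Counts aggregates in each of the eight (long x fibrillar x dense) cells —
#' the quantities visualised by a Sankey diagram of cumulative category
#' membership — together with marginal proportions. Cell counts always sum
#' to the number of records.
#'
#' @param records classified records (see [classify_aggregates()]).
#' @return A list with `cells` (8-row data.frame: `long`, `fibrillar`,
#'   `dense`, `count`, `proportion`) and `marginals` (named proportions of
#'   long, fibrillar, dense, sparse).
#' @export
tabulate_subpopulations <- function(records) {
  lv <- c(FALSE, TRUE)
  grid <- expand.grid(long = lv, fibrillar = lv, dense = lv)
  n <- nrow(records)
  if (n == 0L) {
    grid$count <- 0L
    grid$proportion <- NaN
    return(list(cells = grid,
                marginals = c(long = NaN, fibrillar = NaN, dense = NaN,
                              sparse = NaN)))
  }
  key <- paste(records$long, records$fibrillar, records$dense)
  gkey <- paste(grid$long, grid$fibrillar, grid$dense)
  grid$count <- as.integer(table(factor(key, levels = gkey)))
  grid$proportion <- grid$count / n
  list(cells = grid,
       marginals = c(long = mean(records$long),
                     fibrillar = mean(records$fibrillar),
                     dense = mean(records$dense),
                     sparse = mean(records$sparse)))
}

#' Assemble per-donor feature profiles
#'
#' Builds one profile row per donor x region from replicate-level
#' measurements: continuous features are averaged per technical replicate
#' and then across replicates; proportion features are computed over all of
#' the donor's aggregates; the count feature is expressed as a proportion of
#' the maximum donor count within the same region (so exactly one donor per
#' region attains 1). Spot intensities are min-max scaled to \[0, 1\] by
#' the batch (per-region) maximum before the bright proportion and the mean
#' scaled intensity are computed.
#'
#' The 15 signature features per profile: `count` (normalised),
#' `mean_area_nm2`, `mean_eccentricity`, `mean_perimeter_nm`,
#' `mean_minor_axis_nm`, `mean_major_axis_nm`, `mean_n_localizations`,
#' `mean_length_nm`, `mean_density`, `mean_scaled_intensity`, `prop_bright`,
#' `prop_pser`, `prop_fibrillar`, `prop_long`, `prop_sparse`.
#'
#' @param records classified aggregate records with `donor`, `cohort`,
#'   `region`, `replicate` columns.
#' @param counts data.frame of per-replicate spot counts (`donor`, `cohort`,
#'   `region`, `replicate`, `count`).
#' @param intensities data.frame of per-spot intensities (`donor`, `region`,
#'   `replicate`, `intensity`).
#' @param coloc data.frame of per-replicate colabelling proportions
#'   (`donor`, `region`, `replicate`, `proportion`).
#' @param thresholds a [subpop_thresholds()] object (used for `bright`).
#' @return A data.frame of donor profiles, one row per donor x region.
#' @export
build_donor_profiles <- function(records, counts, intensities, coloc,
                                 thresholds = subpop_thresholds()) {
  stopifnot(nrow(counts) >= 1L)
  ge <- if (thresholds$boundary == "inclusive") `>=` else `>`
  out <- list()
  for (region in unique(counts$region)) {
    creg <- counts[counts$region == region, ]
    ireg <- intensities[intensities$region == region, ]
    batch_max <- max(ireg$intensity)
    ireg$scaled <- ireg$intensity / batch_max
    donor_count <- aggregate(count ~ donor + cohort, creg, mean)
    max_count <- max(donor_count$count)
    for (i in seq_len(nrow(donor_count))) {
      d <- donor_count$donor[i]
      rrec <- records[records$donor == d & records$region == region, ]
      rint <- ireg[ireg$donor == d, ]
      rcol <- coloc[coloc$donor == d & coloc$region == region, ]
      if (nrow(rrec) == 0L) {
        warning(sprintf("donor %s region %s has no aggregates; proportions undefined",
                        d, region))
      }
      rep_mean <- function(col) {
        if (nrow(rrec) == 0L) return(NA_real_)
        mean(tapply(rrec[[col]], rrec$replicate, mean))
      }
      prop <- function(flag) if (nrow(rrec) == 0L) NA_real_ else mean(flag)
      out[[length(out) + 1L]] <- data.frame(
        donor = d, cohort = donor_count$cohort[i], region = region,
        n_replicates = length(unique(creg$replicate[creg$donor == d])),
        count = donor_count$count[i] / max_count,
        raw_count = donor_count$count[i],
        mean_area_nm2 = rep_mean("area_nm2"),
        mean_eccentricity = rep_mean("eccentricity"),
        mean_perimeter_nm = rep_mean("perimeter_nm"),
        mean_minor_axis_nm = rep_mean("minor_axis_nm"),
        mean_major_axis_nm = rep_mean("major_axis_nm"),
        mean_n_localizations = rep_mean("n_localizations"),
        mean_length_nm = rep_mean("skeleton_length_nm"),
        mean_density = rep_mean("density_loc_per_nm2"),
        mean_scaled_intensity = mean(tapply(rint$scaled, rint$replicate, mean)),
        prop_bright = mean(ge(rint$scaled, thresholds$bright_au)),
        prop_pser = mean(tapply(rcol$proportion, rcol$replicate, mean)),
        prop_fibrillar = prop(rrec$fibrillar),
        prop_long = prop(rrec$long),
        prop_sparse = prop(rrec$sparse),
        prop_dense = prop(rrec$dense))
    }
  }
  profiles <- do.call(rbind, out)
  rownames(profiles) <- NULL
  profiles
}

#' Radar-profile measures of a donor profile table
#'
#' Extracts the six summary measures of the per-cohort radar visualisation:
#' count (proportion of the maximum donor count), pSER colabelling, and the
#' proportions of long, fibrillar, dense and bright assemblies.
#'
#' @param profiles output of [build_donor_profiles()].
#' @return A data.frame with `donor`, `cohort`, `region` and the six radar
#'   measures.
#' @export
radar_measures <- function(profiles) {
  profiles[, c("donor", "cohort", "region", "count", "prop_pser",
               "prop_long", "prop_fibrillar", "prop_dense", "prop_bright")]
}
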