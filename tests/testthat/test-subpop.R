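record <- function(len, ecc, dens, scaled = NULL) {
  df <- data.frame(skeleton_length_nm = len, eccentricity = ecc,
                   density_loc_per_nm2 = dens)
  if (!is.null(scaled)) df$scaled_intensity <- scaled
  df
}

test_that("category flags follow the inclusive thresholds", {
  r <- classify_aggregates(record(120, 0.95, 0.005))
  expect_true(r$long && r$fibrillar && r$sparse && !r$dense)

  # boundary: exactly 100 nm is long under the inclusive policy
  expect_true(classify_aggregates(record(100, 0.5, 0.5))$long)
  expect_false(classify_aggregates(record(100, 0.5, 0.5),
                                   subpop_thresholds(boundary = "exclusive"))$long)

  z <- classify_aggregates(record(0, 0, 0))
  expect_false(z$long || z$fibrillar || z$dense)
  expect_true(z$sparse)

  b <- classify_aggregates(record(10, 0.1, 0.1, scaled = c(0.95)))
  expect_true(b$bright)
})

test_that("subpopulation tables conserve counts and match marginals", {
  set.seed(3)
  n <- 400
  recs <- classify_aggregates(record(rlnorm(n, log(80), 0.6),
                                     runif(n, 0.5, 1),
                                     rlnorm(n, log(0.01), 0.7)))
  tab <- tabulate_subpopulations(recs)
  expect_equal(sum(tab$cells$count), n)
  expect_equal(tab$marginals[["long"]],
               sum(tab$cells$count[tab$cells$long]) / n)
  expect_equal(tab$marginals[["sparse"]], 1 - tab$marginals[["dense"]])

  # known mixture: 30% long within the binomial interval
  set.seed(4)
  long30 <- classify_aggregates(record(
    ifelse(runif(n) < 0.3, 150, 50), 0.5, 0.5))
  m <- tabulate_subpopulations(long30)$marginals[["long"]]
  expect_lt(abs(m - 0.3), 3 * sqrt(0.3 * 0.7 / n))

  same <- classify_aggregates(record(rep(150, 5), rep(0.95, 5), rep(0.5, 5)))
  expect_equal(sum(tabulate_subpopulations(same)$cells$count > 0), 1)
})

fixture_profiles <- function(counts_by_donor = c(10, 20, 40)) {
  donors <- seq_along(counts_by_donor)
  counts <- expand.grid(donor = donors, replicate = 1:3)
  counts$cohort <- "CRL"; counts$region <- "cerebellum"
  counts$count <- counts_by_donor[counts$donor]
  set.seed(9)
  records <- do.call(rbind, lapply(donors, function(d) {
    r <- record(rlnorm(30, log(120), 0.3), runif(30, 0.85, 0.99),
                rlnorm(30, log(0.02), 0.3))
    r$area_nm2 <- 5000; r$perimeter_nm <- 300; r$minor_axis_nm <- 40
    r$major_axis_nm <- 150; r$n_localizations <- 100
    r$donor <- d; r$cohort <- "CRL"; r$region <- "cerebellum"
    r$replicate <- rep(1:3, each = 10)
    r
  }))
  records <- classify_aggregates(records)
  intensities <- data.frame(donor = rep(donors, each = 30),
                            region = "cerebellum",
                            replicate = rep(rep(1:3, each = 10), 3),
                            intensity = runif(90, 100, 1000))
  coloc <- expand.grid(donor = donors, region = "cerebellum", replicate = 1:3)
  coloc$proportion <- 0.2
  list(records = records, counts = counts, intensities = intensities,
       coloc = coloc)
}

test_that("donor profiles normalise counts by the maximum donor", {
  fx <- fixture_profiles(c(10, 20, 40))
  prof <- build_donor_profiles(fx$records, fx$counts, fx$intensities, fx$coloc)
  expect_equal(prof$count[order(prof$donor)], c(0.25, 0.5, 1.0))
  expect_equal(sum(prof$count == 1), 1)
  expect_equal(prof$n_replicates, rep(3L, 3))
  expect_equal(prof$prop_pser, rep(0.2, 3))
})

test_that("profiles are invariant to replicate order and recover known fractions", {
  fx <- fixture_profiles()
  p1 <- build_donor_profiles(fx$records, fx$counts, fx$intensities, fx$coloc)
  shuf <- fx$records[sample(nrow(fx$records)), ]
  p2 <- build_donor_profiles(shuf, fx$counts, fx$intensities, fx$coloc)
  expect_equal(p1$mean_length_nm, p2$mean_length_nm, tolerance = 1e-12)

  # all-long records give proportion one
  fx$records$long <- TRUE
  p3 <- build_donor_profiles(fx$records, fx$counts, fx$intensities, fx$coloc)
  expect_true(all(p3$prop_long == 1))

  # known mixture fractions recovered within the binomial interval
  set.seed(13)
  n <- 600
  recs <- record(rlnorm(n, log(80), 0.4), ifelse(runif(n) < 0.2, 0.95, 0.5),
                 ifelse(runif(n) < 0.5, 0.02, 0.002))
  recs$area_nm2 <- 1; recs$perimeter_nm <- 1; recs$minor_axis_nm <- 1
  recs$major_axis_nm <- 1; recs$n_localizations <- 1
  recs$donor <- 1; recs$cohort <- "CRL"; recs$region <- "cerebellum"
  recs$replicate <- rep(1:3, each = n / 3)
  recs <- classify_aggregates(recs)
  counts <- data.frame(donor = 1, cohort = "CRL", region = "cerebellum",
                       replicate = 1:3, count = 10)
  ints <- data.frame(donor = 1, region = "cerebellum", replicate = 1,
                     intensity = c(1, 2))
  col <- data.frame(donor = 1, region = "cerebellum", replicate = 1,
                    proportion = 0.1)
  p <- build_donor_profiles(recs, counts, ints, col)
  expect_lt(abs(p$prop_fibrillar - 0.2), 3 * sqrt(0.2 * 0.8 / n))
  expect_lt(abs(p$prop_dense - 0.5), 3 * sqrt(0.25 / n))
  expect_equal(radar_measures(p)$prop_dense, p$prop_dense)
})
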