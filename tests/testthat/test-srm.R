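make_locs <- function(x, y, frame = 500L, precision_nm = 12,
                      pixel_size_nm = 1) {
  n <- length(x)
  locs <- data.frame(frame = rep_len(frame, n), x = x, y = y,
                     photons = 1000, sx = 1.3, sy = 1.3, bg = 50,
                     lpx = rep_len(precision_nm, n) / pixel_size_nm,
                     lpy = rep_len(precision_nm, n) / pixel_size_nm)
  attr(locs, "pixel_size_nm") <- pixel_size_nm
  locs
}

test_that("precision filter is strict, frame-aware and idempotent", {
  locs <- make_locs(1:4, 1:4, frame = c(100, 400, 500, 600),
                    precision_nm = c(10, 29.9, 30, 35))
  f <- filter_localizations(locs)
  expect_equal(f$precision_nm, 29.9) # frame 100 dropped, strict < 30
  locs2 <- make_locs(1:4, 1:4, frame = 400, precision_nm = c(10, 29.9, 30, 35))
  f2 <- filter_localizations(locs2)
  expect_setequal(f2$precision_nm, c(10, 29.9))
  expect_equal(as.data.frame(filter_localizations(f2)),
               as.data.frame(f2), ignore_attr = TRUE)

  expect_warning(filter_localizations(make_locs(1, 1, frame = 10)),
                 "no localizations")
  all_kept <- filter_localizations(locs2, max_precision_nm = Inf)
  expect_equal(nrow(all_kept), 4)
  expect_error(filter_localizations(locs2[0, ]), "empty")
})

test_that("DBSCAN meets its minimum-density contract", {
  # five points within eps of a core point form one cluster
  xy <- cbind(c(0, 0.1, -0.1, 0, 0), c(0, 0, 0, 0.1, -0.1))
  expect_equal(cluster_localizations(xy, 0.5, 5), rep(1L, 5))
  # four co-located points stay noise
  xy4 <- xy[1:4, ]
  expect_equal(cluster_localizations(xy4, 0.5, 5), rep(-1L, 4))
})

test_that("DBSCAN labels equal the brute-force density-reachability oracle", {
  set.seed(42)
  for (r in 1:50) {
    n <- sample(10:200, 1)
    xy <- cbind(runif(n, 0, 10), runif(n, 0, 10))
    if (r %% 2 == 0) {
      k <- sample(1:3, 1)
      for (j in seq_len(k)) {
        xy <- rbind(xy, cbind(rnorm(15, runif(1, 2, 8), 0.1),
                              rnorm(15, runif(1, 2, 8), 0.1)))
      }
    }
    expect_identical(cluster_localizations(xy, 0.5, 5),
                     oracle_dbscan(xy, 0.5, 5))
  }
})

test_that("regionization yields single, faithful masks", {
  # separate clusters 500 nm apart give disjoint regions in nm space
  c1 <- cbind(rnorm(30, 10, 0.05), rnorm(30, 10, 0.05))
  c2 <- cbind(rnorm(30, 10 + 500 / 107, 0.05), rnorm(30, 10, 0.05))
  r1 <- regionize_cluster(c1)
  r2 <- regionize_cluster(c2)
  hi1 <- r1$origin_nm["x"] + ncol(r1$mask) * r1$render_px_nm
  lo2 <- r2$origin_nm["x"]
  expect_lt(hi1, lo2)

  # collinear localizations spanning 200 nm become one connected region
  t <- seq(0, 200, length.out = 40) / 107
  rr <- regionize_cluster(cbind(10 + t, 10 + 0 * t))
  lab <- aggrefinger:::label_components8(rr$mask)
  expect_equal(max(lab), 1L)

  # zero radii: occupied bins exactly
  pts <- cbind(c(10, 10.05, 10.2), c(10, 10, 10.1))
  r0 <- regionize_cluster(pts, radii = c(0, 0, 0))
  nm_x <- pts[, 1] * 107; nm_y <- pts[, 2] * 107
  n_bins <- nrow(unique(cbind(floor((nm_x - min(nm_x)) / 10.7),
                              floor((nm_y - min(nm_y)) / 10.7))))
  expect_equal(sum(r0$mask), n_bins)

  # degenerate identical localizations still give a non-empty mask
  rdeg <- regionize_cluster(cbind(rep(5, 10), rep(5, 10)))
  expect_gte(sum(rdeg$mask), 1)
})

test_that("measurements follow their geometric definitions", {
  # filled disc of radius 20 bins
  xy <- expand.grid(x = -25:25, y = -25:25)
  xy <- xy[xy$x^2 + xy$y^2 <= 20^2, ]
  region <- structure(list(mask = NULL, render_px_nm = 10.7, n_loc = nrow(xy)),
                      class = "aggregate_region")
  mask <- matrix(0L, 51, 51)
  mask[cbind(xy$y + 26, xy$x + 26)] <- 1L
  region$mask <- mask
  m <- measure_aggregate(region)
  expect_lt(m$eccentricity, 0.05)
  expect_equal(m$area_nm2, pi * 20^2 * 10.7^2, tolerance = 0.05)
  expect_lte(m$minor_axis_nm, m$major_axis_nm)

  # density arithmetic is exact: density * area == n
  expect_equal(m$density_loc_per_nm2 * m$area_nm2, m$n_localizations)

  # skeleton length can never exceed the crack perimeter
  expect_lte(m$skeleton_length_nm, m$perimeter_nm)
})

test_that("simulated 150 nm rods are recovered within tolerance", {
  res <- t(vapply(1:10, function(s) {
    m <- measure_simulated_rod(150, seed = s, n_loc = 200)
    c(len = m$skeleton_length_nm, ecc = m$eccentricity)
  }, numeric(2)))
  expect_lt(abs(mean(res[, "len"]) / 150 - 1), 0.2)
  expect_gt(mean(res[, "ecc"]), 0.9)
})

test_that("measurements are invariant to translation and rotation", {
  base <- vapply(1:10, function(s)
    measure_simulated_rod(250, seed = s, theta = 0)$skeleton_length_nm,
    numeric(1))
  rot <- vapply(1:10, function(s)
    measure_simulated_rod(250, seed = s, theta = pi / 3)$skeleton_length_nm,
    numeric(1))
  expect_equal(mean(rot), mean(base), tolerance = 0.05)

  set.seed(15)
  xy <- cbind(rnorm(80, 10, 0.3), rnorm(80, 10, 0.15))
  m1 <- measure_aggregate(regionize_cluster(xy))
  m2 <- measure_aggregate(regionize_cluster(xy + 7.25))
  expect_equal(m1$area_nm2, m2$area_nm2, tolerance = 0.02)
  expect_equal(m1$skeleton_length_nm, m2$skeleton_length_nm, tolerance = 0.05)
})

test_that("drift is estimated from block correlations and corrected", {
  set.seed(21)
  n_agg <- 40
  agg <- aggregate_truth(kind = "globule",
                         radius_nm = rlnorm(n_agg, log(40), 0.3),
                         x_nm = runif(n_agg, 500, 13000),
                         y_nm = runif(n_agg, 500, 13000),
                         n_loc = 150, sigma_nm = 12)
  still <- simulate_localization_table(agg, frames = 5000, fov_px = 128,
                                       seed = 31)
  d0 <- estimate_and_correct_drift(still$locs, n_blocks = 10, render_px = 1)
  expect_lt(sqrt(mean(c(d0$blocks$dx_px, d0$blocks$dy_px)^2)), 0.1)

  drifted <- simulate_localization_table(agg, frames = 5000, fov_px = 128,
                                         drift_px_per_frame = c(0.002, 0),
                                         seed = 32)
  d1 <- estimate_and_correct_drift(drifted$locs, n_blocks = 10, render_px = 1)
  terminal <- d1$trace$dx_px[nrow(d1$trace)] - d1$trace$dx_px[1]
  expect_equal(terminal, 0.002 * 4999, tolerance = 0.1)
  # corrected coordinates regain the undrifted spread
  expect_lt(max(abs(d1$locs$x - drifted$locs$x + d1$trace$dx_px[drifted$locs$frame + 1])), 1e-9)

  expect_error(estimate_and_correct_drift(still$locs, n_blocks = 1),
               "at least 2")
})

test_that("analyze_localizations chains the stages end to end", {
  agg <- aggregate_truth(kind = c("rod", "globule"),
                         length_nm = c(200, 100), radius_nm = c(30, 40),
                         x_nm = c(1000, 4000), y_nm = c(1000, 4000),
                         theta = c(0.3, 0), n_loc = c(200, 150),
                         sigma_nm = 12)
  sim <- simulate_localization_table(agg, background_rate = 0.5,
                                     frames = 5000, fov_px = 64, seed = 41)
  res <- analyze_localizations(sim$locs, pipeline_config())
  expect_equal(nrow(res$records), 2)
  expect_true(all(res$records$density_loc_per_nm2 > 0))
  expect_true(all(res$records$minor_axis_nm <= res$records$major_axis_nm))
  expect_true(all(res$records$eccentricity >= 0 & res$records$eccentricity < 1))
  expect_true(all(res$records$skeleton_length_nm <= res$records$perimeter_nm))
})
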