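test_that("noise-free stack renders the baseline everywhere and is deterministic", {
  sim <- simulate_tirf_stack(spots = data.frame(x_px = numeric(0),
                                                y_px = numeric(0),
                                                amplitude = numeric(0)),
                             width = 16, height = 16, frames = 3,
                             baseline = 7, read_noise_sd = 0,
                             shot_noise = FALSE, seed = 1)
  expect_true(all(sim$stack == 7))
  expect_equal(dim(sim$stack), c(16, 16, 3))

  a <- simulate_tirf_stack(n_spots = 5, width = 32, height = 32, seed = 9)
  b <- simulate_tirf_stack(n_spots = 5, width = 32, height = 32, seed = 9)
  expect_identical(a$stack, b$stack)
  expect_identical(a$truth, b$truth)
  expect_error(simulate_tirf_stack(width = 0, height = 16),
               "dimensions")
})

test_that("rendered spots are recovered by detection within 1 px", {
  for (seed in 1:5) {
    sim <- simulate_tirf_stack(n_spots = 10, width = 64, height = 64,
                               seed = seed)
    det <- detect_puncta(mean_projection(sim$stack))
    expect_equal(nrow(det), 10)
    for (i in 1:10) {
      d <- sqrt((det$x_px - sim$truth$x_px[i])^2 +
                  (det$y_px - sim$truth$y_px[i])^2)
      expect_lt(min(d), 1)
    }
  }
})

test_that("noise-free rod localizations lie exactly on the segment", {
  agg <- aggregate_truth(kind = "rod", length_nm = 300, x_nm = 1000,
                         y_nm = 2000, theta = pi / 6, n_loc = 100,
                         sigma_nm = 1e-9)
  sim <- simulate_localization_table(agg, rod_width_fwhm_nm = 0, seed = 3)
  x_nm <- sim$locs$x * 107 - 1000
  y_nm <- sim$locs$y * 107 - 2000
  # transverse deviation from the rod axis is zero, axial within length/2
  trans <- -sin(pi / 6) * x_nm + cos(pi / 6) * y_nm
  axial <- cos(pi / 6) * x_nm + sin(pi / 6) * y_nm
  expect_lt(max(abs(trans)), 1e-6)
  expect_true(all(abs(axial) <= 150 + 1e-6))
})

test_that("precision columns store exactly the jitter sigma", {
  agg <- aggregate_truth(kind = "globule", radius_nm = 50, n_loc = 40,
                         sigma_nm = 12)
  sim <- simulate_localization_table(agg, seed = 2)
  expect_true(all(sim$locs$lpx == 12 / 107))
  expect_true(all(sim$locs$lpy == 12 / 107))
  # and the filter therefore sees precisely 12 nm
  filt <- filter_localizations(sim$locs, discard_first_frames = 0)
  expect_true(all(filt$precision_nm == 12))
})

test_that("background-only fields are labelled noise by clustering", {
  sim <- simulate_localization_table(
    aggregate_truth(kind = "globule", n_loc = 1)[0, ],
    background_rate = 2, frames = 1000, fov_px = 64, seed = 5)
  lab <- cluster_localizations(sim$locs, eps_px = 0.5, min_samples = 5)
  expect_gt(mean(lab == -1L), 0.95)
})

test_that("cohort simulation keeps the declared bookkeeping", {
  spec <- cohort_spec(donors = c(CRL = 2L, MND_SOD = 1L, MND_TDP = 2L),
                      n_replicates = 3L, aggregates_per_replicate = 5L,
                      frames = 1000L, fov_px = 64L)
  sim <- simulate_cohort(spec, seed = 4)
  expect_length(sim$datasets, 5 * 2 * 3)
  expect_equal(nrow(sim$donor_params), 5 * 2)
  reps <- vapply(sim$datasets, `[[`, integer(1), "replicate")
  expect_equal(sort(unique(reps)), 1:3)
  # disease-direction ground truth: TDP donors have longer mean lengths
  dp <- sim$donor_params
  expect_gt(mean(dp$mean_length_nm[dp$cohort == "MND_TDP"]),
            mean(dp$mean_length_nm[dp$cohort == "CRL"]))
})

test_that("proteomics generator honours effects, errors and the correction identity", {
  expect_error(simulate_proteomics(n_control = 1), "at least 2")
  expect_error(simulate_proteomics(
    effects = data.frame(protein = 1, e_agg = -2, e_tot = 1)), "positive")
  ps <- simulate_proteomics(n_proteins = 150,
                            effects = data.frame(protein = 1:5, e_agg = 3,
                                                 e_tot = 3),
                            cv = 0.05, seed = 8)
  expect_true(any(ps$total$contaminant))
  filt <- filter_quantified(ps$total)
  expect_false(any(filt$contaminant))
  expect_false(any(startsWith(filt$accession, "CON__")))
  # e_agg == e_tot: the corrected ratio has no enrichment to find
  rr <- compute_corrected_ratios(
    filter_quantified(ps$total), filter_quantified(ps$aggregate),
    paste0("control_", 1:5), paste0("case_", 1:5))
  sp <- rr$accession %in% sprintf("P%05d", 1:5)
  expect_lt(max(abs(rr$mean_log2_corrected[sp])), 0.3)
})
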