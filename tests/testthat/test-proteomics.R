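quant_table <- function(abund, channels = names(abund),
                        n_peptides = 3L, n_unique = 1L, runs = 1L) {
  tab <- data.frame(accession = sprintf("P%03d", seq_len(nrow(abund))),
                    n_peptides = n_peptides, n_unique = n_unique,
                    contaminant = FALSE, reference = rowMeans(abund))
  tab <- cbind(tab, abund)
  attr(tab, "design") <- data.frame(
    column = channels,
    group = ifelse(startsWith(channels, "control"), "control", "case"),
    run = rep_len(runs, length(channels)))
  tab
}

test_that("quantification filter enforces the two-peptide one-unique rule", {
  tab <- data.frame(accession = c("P1", "P2", "P3", "P4"),
                    n_peptides = c(2, 3, 1, 5),
                    n_unique = c(1, 0, 1, 2),
                    contaminant = c(FALSE, FALSE, FALSE, TRUE))
  kept <- filter_quantified(tab)
  expect_equal(kept$accession, "P1")
  con <- data.frame(accession = "CON__KRT01", n_peptides = 5, n_unique = 3,
                    contaminant = FALSE)
  expect_equal(nrow(filter_quantified(con)), 0)
  expect_error(filter_quantified(data.frame(accession = "P1")), "n_peptides")
})

test_that("reference normalization scales runs and channels as declared", {
  ab <- data.frame(control_1 = c(10, 20), case_1 = c(30, 40))
  tab <- quant_table(ab)
  # a single run with its own reference: nothing changes
  norm <- reference_normalize(tab, "per_run")
  expect_equal(norm$control_1, tab$control_1)

  # two runs where run B's reference sum is twice run A's
  tab2 <- data.frame(accession = c("P1", "P2"), n_peptides = 3, n_unique = 1,
                     contaminant = FALSE,
                     reference_1 = c(10, 10), reference_2 = c(20, 20),
                     control_1 = c(100, 100), case_1 = c(100, 100))
  attr(tab2, "design") <- data.frame(column = c("control_1", "case_1"),
                                     group = c("control", "case"),
                                     run = c(1L, 2L))
  norm2 <- reference_normalize(tab2, "per_run")
  expect_equal(norm2$case_1 / norm2$control_1, c(0.5, 0.5))

  # per-channel mode equalises channel sums
  tab3 <- quant_table(data.frame(control_1 = c(10, 10), case_1 = c(40, 40)))
  norm3 <- reference_normalize(tab3, "per_channel")
  expect_equal(sum(norm3$control_1), sum(norm3$case_1))

  zero <- quant_table(data.frame(control_1 = c(0, 0), case_1 = c(1, 1)))
  expect_error(reference_normalize(zero, "per_channel"), "zero channel")
})

test_that("corrected ratios cancel proteome-wide changes", {
  ctrl <- c("control_1", "control_2")
  case <- c("case_1", "case_2", "case_3")
  # protein 1: aggregate and total both double -> corrected 1
  # protein 2: aggregate x4, total unchanged -> corrected 4
  tot <- quant_table(data.frame(control_1 = c(10, 10), control_2 = c(10, 10),
                                case_1 = c(20, 10), case_2 = c(20, 10),
                                case_3 = c(20, 10)),
                     channels = c(ctrl, case))
  agg <- quant_table(data.frame(control_1 = c(5, 5), control_2 = c(5, 5),
                                case_1 = c(10, 20), case_2 = c(10, 20),
                                case_3 = c(10, 20)),
                     channels = c(ctrl, case))
  rr <- compute_corrected_ratios(tot, agg, ctrl, case)
  expect_equal(rr$mean_log2_corrected, c(0, 2), tolerance = 1e-12)
  expect_equal(rr$n_cases, c(3L, 3L))

  # correction identity: scaling one case's both fractions cancels
  tot2 <- tot; agg2 <- agg
  tot2$case_1 <- tot2$case_1 * 7
  agg2$case_1 <- agg2$case_1 * 7
  rr2 <- compute_corrected_ratios(tot2, agg2, ctrl, case)
  expect_equal(rr2$mean_log2_corrected, rr$mean_log2_corrected,
               tolerance = 1e-12)

  # zero control mean drops the protein with a reason
  agg3 <- agg; agg3$control_1 <- c(0, 0); agg3$control_2 <- c(0, 0)
  agg3$case_1[1] <- 0; agg3$case_2[1] <- 0; agg3$case_3[1] <- 0
  rr3 <- compute_corrected_ratios(tot, agg3, ctrl, case)
  dropped <- attr(rr3, "dropped")
  expect_true("P001" %in% dropped$accession)
})

test_that("volcano calls use the printed thresholds", {
  rec <- data.frame(mean_log2_corrected = c(-0.022, 0.49, 1.5, -1.5, 1.5),
                    neg_log10_p = c(0.0357, 1.69, 2.0, 2.0, 1.0))
  calls <- volcano_classify(rec)$call
  expect_equal(calls, c("ns", "ns", "enriched", "depleted", "ns"))
})

test_that("spike-ins are recovered through the full proteomics chain", {
  eff <- data.frame(protein = 1:12,
                    e_agg = c(rep(4, 6), rep(0.25, 6)), e_tot = 1)
  set.seed(77)
  hits <- replicate(5, {
    seed <- sample.int(1e6, 1)
    ps <- simulate_proteomics(n_proteins = 200, effects = eff, cv = 0.1,
                              seed = seed)
    tot <- reference_normalize(filter_quantified(ps$total), "per_run")
    agg <- reference_normalize(filter_quantified(ps$aggregate), "per_channel")
    rr <- volcano_classify(compute_corrected_ratios(
      tot, agg, paste0("control_", 1:5), paste0("case_", 1:5)))
    en <- rr$accession %in% sprintf("P%05d", 1:6)
    de <- rr$accession %in% sprintf("P%05d", 7:12)
    c(mean(rr$call[en] == "enriched"), mean(rr$call[de] == "depleted"),
      mean(rr$call[!(en | de)] != "ns"))
  })
  expect_gte(mean(hits[1, ]), 0.95)
  expect_gte(mean(hits[2, ]), 0.95)
  expect_lte(mean(hits[3, ]), 0.05)
})
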