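#' Filter to confidently quantified proteins
#'
#' Removes common contaminants (flag column and/or accession prefixes such
#' as `CON__`) and keeps proteins identified by at least two peptides, at
#' least one of which is unique — the quantification rule applied before
#' any ratio is computed.
#'
#' @param table protein quantification table with columns `accession`,
#'   `n_peptides`, `n_unique` and optionally `contaminant`.
#' @param contaminant_prefixes accession prefixes flagged as contaminants.
#' @return The filtered table.
#' @examples
#' tab <- data.frame(accession = c("P1", "P2"), n_peptides = c(2, 3),
#'                   n_unique = c(1, 0), contaminant = FALSE)
#' filter_quantified(tab)$accession # "P1"
#' @export
filter_quantified <- function(table, contaminant_prefixes = c("CON__", "KRT")) {
  need <- c("accession", "n_peptides", "n_unique")
  missing <- setdiff(need, names(table))
  if (length(missing)) {
    stop("table is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  con <- if (is.null(table$contaminant)) rep(FALSE, nrow(table)) else table$contaminant
  for (pre in contaminant_prefixes) {
    con <- con | startsWith(table$accession, pre)
  }
  keep <- !con & table$n_peptides >= 2L & table$n_unique >= 1L
  out <- table[keep, , drop = FALSE]
  attributes(out)[c("design", "fraction")] <- attributes(table)[c("design", "fraction")]
  out
}

#' Reference-channel normalization of reporter abundances
#'
#' Corrects channel abundances using the summed abundance of the pooled
#' reference sample: each channel is divided by its reference sum relative
#' to the grand mean of reference sums. In `per_run` mode (total-proteome
#' tables) all channels of a run share the run's reference-channel sum; in
#' `per_channel` mode (affinity-captured aggregate tables, where loading
#' differs per capture) each channel is scaled by its own summed abundance
#' relative to the grand mean of channel sums.
#'
#' @param table quantification table carrying a `design` attribute
#'   (data.frame with `column`, `group`, `run`) and a `reference` column.
#' @param mode `"per_run"` or `"per_channel"`.
#' @return The table with normalized channel abundances.
#' @export
reference_normalize <- function(table, mode = c("per_run", "per_channel")) {
  mode <- match.arg(mode)
  design <- attr(table, "design")
  if (is.null(design)) stop("table has no `design` attribute", call. = FALSE)
  chans <- design$column
  if (mode == "per_run") {
    runs <- unique(design$run)
    # one pooled-reference column per run: `reference` for a single run,
    # `reference_<run>` otherwise
    refcol <- function(r) {
      if (length(runs) == 1L && !is.null(table$reference)) "reference"
      else paste0("reference_", r)
    }
    for (r in runs) {
      if (is.null(table[[refcol(r)]])) {
        stop("missing reference column `", refcol(r), "`", call. = FALSE)
      }
    }
    ref_sums <- vapply(runs, function(r) sum(table[[refcol(r)]]), numeric(1))
    if (any(ref_sums <= 0)) stop("zero reference sum", call. = FALSE)
    grand <- mean(ref_sums)
    for (i in seq_along(runs)) {
      cols <- chans[design$run == runs[i]]
      table[cols] <- table[cols] / (ref_sums[i] / grand)
    }
  } else {
    sums <- vapply(chans, function(ch) sum(table[[ch]]), numeric(1))
    if (any(sums <= 0)) stop("zero channel sum", call. = FALSE)
    grand <- mean(sums)
    for (ch in chans) table[[ch]] <- table[[ch]] / (sums[[ch]] / grand)
  }
  table
}

#' Total-proteome-corrected aggregate-fraction ratios
#'
#' The correction at the heart of the aggregate proteomics: for each
#' protein quantified (non-zero) in at least one donor in both the total
#' and the aggregate fraction, per-case abundance ratios are formed against
#' the mean control abundance in each fraction, and the aggregate ratio is
#' divided by the total ratio of the same protein. This cancels
#' proteome-wide disease effects and isolates aggregate-specific
#' enrichment. Corrected ratios are summarised by their mean log2 and a
#' one-sample t-test of the log2 ratios against 0 (equivalently, of the
#' ratios against the no-difference value 1).
#'
#' @param total_table,aggregate_table filtered, normalized quantification
#'   tables with identical channel naming.
#' @param control_cols,case_cols channel column names for controls/cases.
#' @return A data.frame of `RatioRecord`s: `accession`, `n_cases`,
#'   `mean_log2_corrected`, `p_value`, `neg_log10_p`, plus a `dropped`
#'   attribute naming proteins excluded and why.
#' @export
compute_corrected_ratios <- function(total_table, aggregate_table,
                                     control_cols, case_cols) {
  shared <- intersect(total_table$accession, aggregate_table$accession)
  tot <- total_table[match(shared, total_table$accession), , drop = FALSE]
  agg <- aggregate_table[match(shared, aggregate_table$accession), , drop = FALSE]
  tot_mat <- as.matrix(tot[, c(control_cols, case_cols), drop = FALSE])
  agg_mat <- as.matrix(agg[, c(control_cols, case_cols), drop = FALSE])
  nctrl <- length(control_cols)
  records <- list()
  dropped <- list()
  for (i in seq_along(shared)) {
    t_row <- tot_mat[i, ]
    a_row <- agg_mat[i, ]
    if (!any(t_row > 0) || !any(a_row > 0)) {
      dropped[[length(dropped) + 1L]] <- data.frame(
        accession = shared[i], reason = "not quantified in both fractions")
      next
    }
    t_ctrl <- mean(t_row[seq_len(nctrl)])
    a_ctrl <- mean(a_row[seq_len(nctrl)])
    if (t_ctrl <= 0 || a_ctrl <= 0) {
      dropped[[length(dropped) + 1L]] <- data.frame(
        accession = shared[i], reason = "zero control mean")
      next
    }
    t_case <- t_row[-seq_len(nctrl)]
    a_case <- a_row[-seq_len(nctrl)]
    ok <- t_case > 0 & a_case > 0
    if (sum(ok) < 2L) {
      dropped[[length(dropped) + 1L]] <- data.frame(
        accession = shared[i], reason = "fewer than 2 cases quantified")
      next
    }
    corrected <- (a_case[ok] / a_ctrl) / (t_case[ok] / t_ctrl)
    lg <- log2(corrected)
    tt <- if (var(lg) == 0) {
      list(p.value = if (all(lg == 0)) 1 else NA_real_)
    } else t.test(lg, mu = 0)
    records[[length(records) + 1L]] <- data.frame(
      accession = shared[i], n_cases = sum(ok),
      mean_log2_corrected = mean(lg),
      p_value = tt$p.value,
      neg_log10_p = -log10(tt$p.value))
  }
  out <- if (length(records)) do.call(rbind, records) else
    data.frame(accession = character(0), n_cases = integer(0),
               mean_log2_corrected = numeric(0), p_value = numeric(0),
               neg_log10_p = numeric(0))
  attr(out, "dropped") <- if (length(dropped)) do.call(rbind, dropped) else
    data.frame(accession = character(0), reason = character(0))
  out
}

#' Volcano classification of corrected ratios
#'
#' Partitions ratio records with the standard thresholds: enriched when
#' log2 corrected ratio > `log2_threshold` (default 1) and -log10 p >
#' `neglog10p_threshold` (default 1.3, i.e. p < 0.05); depleted when log2 <
#' -threshold with the same significance cut; otherwise not significant.
#'
#' @param records output of [compute_corrected_ratios()].
#' @param log2_threshold absolute log2 fold cut.
#' @param neglog10p_threshold significance cut on -log10 p.
#' @return `records` with a `call` column (`"enriched"`, `"depleted"`,
#'   `"ns"`).
#' @examples
#' rec <- data.frame(mean_log2_corrected = c(1.5, -0.02), neg_log10_p = c(2, 0.04))
#' volcano_classify(rec)$call
#' @export
volcano_classify <- function(records, log2_threshold = 1,
                             neglog10p_threshold = 1.3) {
  lg <- records$mean_log2_corrected
  sig <- records$neg_log10_p > neglog10p_threshold
  call <- rep("ns", nrow(records))
  call[sig & lg > log2_threshold] <- "enriched"
  call[sig & lg < -log2_threshold] <- "depleted"
  records$call <- call
  records
}
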