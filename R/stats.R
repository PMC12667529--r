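#' Interpolate an empirical cumulative distribution on a fixed grid
#'
#' Evaluates a sample's empirical CDF at 101 equidistant cumulative
#' proportions (0, 0.01, ..., 0.99, 1) by nearest-neighbour inversion: the
#' grid value at proportion p is the sample value whose empirical
#' cumulative proportion is closest to p (lower rank on ties). Fixing the
#' grid lets distributions from samples of different sizes be averaged
#' point-wise across donors.
#'
#' @param values numeric vector (at least one finite value).
#' @param grid_n number of grid points (default 101).
#' @return A list of class `interpolated_cdf` with `proportion` (the grid),
#'   `value` (non-decreasing interpolated values) and `n` (source sample
#'   size).
#' @examples
#' interpolate_cdf(c(5))$value[1:3]
#' @export
interpolate_cdf <- function(values, grid_n = 101L) {
  values <- values[is.finite(values)]
  if (length(values) == 0L) stop("need at least one finite value", call. = FALSE)
  s <- sort(values)
  n <- length(s)
  p_i <- seq_len(n) / n
  grid <- seq(0, 1, length.out = grid_n)
  # nearest empirical proportion; ties go to the lower rank
  idx <- vapply(grid, function(g) which.min(abs(p_i - g)), integer(1))
  structure(list(proportion = grid, value = s[idx], n = n),
            class = "interpolated_cdf")
}

#' Subsampled (bootstrapped) Kolmogorov-Smirnov comparison
#'
#' Compares two assembly populations while removing the confounding effect
#' of unequal population sizes: `n_boot` matched-n subsample pairs are drawn
#' without replacement (subsample size `subsample_n`, lowered to the smaller
#' population size when necessary), each pair is compared with a two-sample
#' KS test (asymptotic p-value), and the median statistic and median
#' p-value are reported. When both populations are no larger than the
#' subsample size the subsamples are the full populations and a single test
#' is performed.
#'
#' Note the median-p summary is exactly calibrated when the populations are
#' at the matched size and becomes conservative for much larger populations
#' (overlapping subsamples correlate the repeats).
#'
#' @param pop_a,pop_b numeric vectors (non-empty).
#' @param subsample_n matched subsample size (default 1000).
#' @param n_boot number of subsample pairs.
#' @param seed integer seed for the subsampling.
#' @return A list of class `bootstrap_ks` with `statistic` (median KS D),
#'   `p_value` (median p), `statistics`, `p_values`, `subsample_n`,
#'   `n_boot`, `n_a`, `n_b`.
#' @export
bootstrap_ks <- function(pop_a, pop_b, subsample_n = 1000L, n_boot = 100L,
                         seed = NULL) {
  if (length(pop_a) == 0L || length(pop_b) == 0L) {
    stop("both populations must be non-empty", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  n_sub <- min(subsample_n, length(pop_a), length(pop_b))
  if (n_sub < subsample_n) {
    message(sprintf("subsample size lowered to %d (smallest population)", n_sub))
  }
  if (n_sub == length(pop_a) && n_sub == length(pop_b)) {
    # without-replacement subsamples of the full size are the populations
    ks <- suppressWarnings(ks.test(pop_a, pop_b))
    stats <- rep(unname(ks$statistic), 1L)
    ps <- rep(ks$p.value, 1L)
  } else {
    stats <- ps <- numeric(n_boot)
    for (b in seq_len(n_boot)) {
      sa <- pop_a[sample.int(length(pop_a), n_sub)]
      sb <- pop_b[sample.int(length(pop_b), n_sub)]
      ks <- suppressWarnings(ks.test(sa, sb))
      stats[b] <- unname(ks$statistic)
      ps[b] <- ks$p.value
    }
  }
  structure(list(statistic = median(stats), p_value = median(ps),
                 statistics = stats, p_values = ps, subsample_n = n_sub,
                 n_boot = length(ps), n_a = length(pop_a),
                 n_b = length(pop_b)),
            class = "bootstrap_ks")
}

#' @export
print.bootstrap_ks <- function(x, ...) {
  cat(sprintf("bootstrap KS: D = %.4f, p = %.4g (median of %d matched-%d subsamples)\n",
              x$statistic, x$p_value, x$n_boot, x$subsample_n))
  invisible(x)
}

#' Multiplicity correction across a declared comparison family
#'
#' Applies Holm-Bonferroni (for per-cohort families) or plain Bonferroni
#' (for per-population families) to a vector of raw p-values. Family
#' membership is always an explicit argument of the caller — it is never
#' inferred. Corrected p-values are never below the raw values and are
#' capped at 1.
#'
#' @param p numeric vector of raw p-values.
#' @param method `"holm"` or `"bonferroni"`.
#' @return Corrected p-values.
#' @export
correct_family <- function(p, method = c("holm", "bonferroni")) {
  method <- match.arg(method)
  p.adjust(p, method = method)
}

#' Welch's two-sample t-test
#'
#' Unequal-variance t-test with Welch-Satterthwaite degrees of freedom and a
#' two-sided p-value, used for donor-level cohort comparisons. Two groups
#' with zero variance and equal means give t = 0, p = 1.
#'
#' @param group_a,group_b numeric vectors with at least 2 values each.
#' @return A list with `t`, `df`, `p_value`, means and group sizes.
#' @export
welch_t <- function(group_a, group_b) {
  if (length(group_a) < 2L || length(group_b) < 2L) {
    stop("each group needs at least 2 values", call. = FALSE)
  }
  if (var(group_a) == 0 && var(group_b) == 0) {
    if (mean(group_a) == mean(group_b)) {
      return(list(t = 0, df = NA_real_, p_value = 1,
                  mean_a = mean(group_a), mean_b = mean(group_b),
                  n_a = length(group_a), n_b = length(group_b)))
    }
    stop("both groups are constant with different means; t is undefined",
         call. = FALSE)
  }
  tt <- t.test(group_a, group_b, var.equal = FALSE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, mean_a = mean(group_a), mean_b = mean(group_b),
       n_a = length(group_a), n_b = length(group_b))
}

#' One-sample t-test of relative proportions against 1
#'
#' Tests whether case/control ratios differ from the no-difference value of
#' 1, with Bonferroni correction for the number of targets tested
#' (`m_tests`). Constant input equal to the hypothetical mean gives t = 0,
#' p = 1.
#'
#' @param ratios numeric vector of relative values (>= 2 values).
#' @param hypothetical_mean null value (default 1).
#' @param m_tests Bonferroni family size.
#' @return A list with `t`, `df`, `p_value` (raw) and `p_corrected`
#'   (`min(1, p * m_tests)`).
#' @export
one_sample_relative_t <- function(ratios, hypothetical_mean = 1,
                                  m_tests = 1L) {
  if (length(ratios) < 2L) stop("need at least 2 ratios", call. = FALSE)
  if (var(ratios) == 0) {
    if (ratios[1] == hypothetical_mean) {
      return(list(t = 0, df = length(ratios) - 1, p_value = 1,
                  p_corrected = 1))
    }
    stop("ratios are constant and unequal to the hypothetical mean",
         call. = FALSE)
  }
  tt <- t.test(ratios, mu = hypothetical_mean)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, p_corrected = min(1, tt$p.value * m_tests))
}
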