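# Independent oracles used by the test suite. These deliberately share no
# code with the package implementation.

# Brute-force DBSCAN by explicit density reachability over the full
# distance matrix: core points have >= min_samples neighbours (self
# included); clusters grow by repeated expansion over core neighbours;
# non-core points join the cluster of their lowest-index core neighbour.
oracle_dbscan <- function(xy, eps, min_samples) {
  n <- nrow(xy)
  d <- as.matrix(dist(xy))
  nb <- lapply(seq_len(n), function(i) which(d[i, ] <= eps))
  core <- lengths(nb) >= min_samples
  labels <- rep(-1L, n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (!core[i] || labels[i] != -1L) next
    cl <- cl + 1L
    labels[i] <- cl
    memb <- i
    repeat {
      grow <- unique(unlist(nb[memb[core[memb]]]))
      grow <- grow[core[grow] & labels[grow] == -1L]
      if (!length(grow)) break
      labels[grow] <- cl
      memb <- c(memb, grow)
    }
  }
  for (i in which(!core)) {
    cn <- nb[[i]][core[nb[[i]]]]
    if (length(cn)) labels[i] <- labels[min(cn)]
  }
  labels
}

# Direct ECDF-inversion quantile at cumulative proportion p: the sorted
# sample value whose empirical proportion i/n is closest to p (lower rank
# on ties).
oracle_nearest_quantile <- function(values, p) {
  s <- sort(values)
  props <- seq_along(s) / length(s)
  s[which.min(abs(props - p))]
}

# Closed-form Welch t statistic.
oracle_welch_t <- function(a, b) {
  (mean(a) - mean(b)) / sqrt(var(a) / length(a) + var(b) / length(b))
}

# Closed-form one-sample t statistic.
oracle_one_sample_t <- function(x, mu) {
  (mean(x) - mu) / (sd(x) / sqrt(length(x)))
}

# Simulate a rod localization cloud and measure it through the package
# pipeline (filter -> cluster -> regionize -> measure); returns the record
# of the largest cluster.
measure_simulated_rod <- function(length_nm, seed, n_loc = NULL,
                                  sigma_nm = 12, theta = NULL) {
  if (is.null(n_loc)) n_loc <- max(50L, round(4 / 3 * length_nm))
  set.seed(seed * 1000L)
  if (is.null(theta)) theta <- runif(1, 0, pi)
  agg <- aggregate_truth(kind = "rod", length_nm = length_nm,
                         x_nm = 2000, y_nm = 2000, theta = theta,
                         n_loc = n_loc, sigma_nm = sigma_nm)
  sim <- simulate_localization_table(agg, frames = 5000, seed = seed)
  filt <- filter_localizations(sim$locs)
  lab <- cluster_localizations(filt, 0.5, 5)
  main <- which.max(tabulate(lab[lab > 0]))
  sel <- lab == main
  reg <- regionize_cluster(cbind(filt$x[sel], filt$y[sel]))
  measure_aggregate(reg)
}
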