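#' Simulate a diffraction-limited TIRF stack
#'
#' Renders sub-resolution fluorescent puncta as 2-D Gaussian point-spread
#' functions on a constant baseline, with optional Poisson shot noise and
#' Gaussian read noise per frame — the camera-like image model of a SiMPull
#' acquisition (by default 50 frames per field of view). Ground truth is
#' returned alongside the stack so detection can be benchmarked.
#'
#' @param spots optional data.frame with columns `x_px`, `y_px`,
#'   `amplitude` (photons) and optionally `channel`; generated randomly when
#'   `NULL`.
#' @param n_spots number of spots to place when `spots` is `NULL`.
#' @param width,height image size in pixels.
#' @param frames number of frames (>= 1).
#' @param psf_sigma_px Gaussian PSF standard deviation in pixels.
#' @param amplitude peak amplitude (photons) used for generated spots.
#' @param baseline constant camera baseline added to every pixel.
#' @param read_noise_sd standard deviation of additive Gaussian read noise.
#' @param shot_noise apply Poisson shot noise to the expected signal.
#' @param min_separation_px minimum centre-to-centre distance between
#'   generated spots.
#' @param channel channel label stored on the stack.
#' @param seed integer seed; identical seed and arguments give bit-identical
#'   stacks.
#' @return A list with `stack` (a `height x width x frames` array with
#'   attributes `pixel_size_nm` and `channel`) and `truth` (a data.frame of
#'   ground-truth spots).
#' @examples
#' sim <- simulate_tirf_stack(n_spots = 5, width = 48, height = 48, seed = 1)
#' dim(sim$stack)
#' @export
simulate_tirf_stack <- function(spots = NULL, n_spots = 10L, width = 64L,
                                height = 64L, frames = 50L,
                                psf_sigma_px = 1.3, amplitude = 100,
                                baseline = 100, read_noise_sd = 2,
                                shot_noise = TRUE, min_separation_px = 8,
                                channel = "ch1", seed = 1L) {
  if (width < 1 || height < 1) stop("image dimensions must be positive", call. = FALSE)
  if (frames < 1) stop("`frames` must be >= 1", call. = FALSE)
  stopifnot_positive(psf_sigma_px, "psf_sigma_px")
  set.seed(seed)
  if (is.null(spots)) {
    spots <- place_random_spots(n_spots, width, height, min_separation_px,
                                margin = 4)
    spots$amplitude <- rep(amplitude, nrow(spots))
  }
  if (nrow(spots) > 0) {
    stopifnot(all(spots$x_px >= 0 & spots$x_px < width),
              all(spots$y_px >= 0 & spots$y_px < height),
              all(spots$amplitude > 0))
  }
  if (is.null(spots$channel)) spots$channel <- rep(channel, nrow(spots))

  signal <- matrix(0, height, width)
  if (nrow(spots) > 0) {
    xg <- matrix(rep(0:(width - 1), each = height), height, width)
    yg <- matrix(rep(0:(height - 1), width), height, width)
    for (i in seq_len(nrow(spots))) {
      signal <- signal + spots$amplitude[i] *
        exp(-((xg - spots$x_px[i])^2 + (yg - spots$y_px[i])^2) /
              (2 * psf_sigma_px^2))
    }
  }
  expected <- signal + baseline
  stack <- array(0, dim = c(height, width, frames))
  for (f in seq_len(frames)) {
    frame <- if (shot_noise) {
      matrix(rpois(length(expected), expected), height, width)
    } else {
      expected
    }
    if (read_noise_sd > 0) {
      frame <- frame + matrix(rnorm(length(frame), 0, read_noise_sd), height, width)
    }
    stack[, , f] <- frame
  }
  attr(stack, "pixel_size_nm") <- 107
  attr(stack, "channel") <- channel
  list(stack = stack, truth = spots)
}

place_random_spots <- function(n, width, height, min_sep, margin) {
  xs <- numeric(0); ys <- numeric(0)
  tries <- 0L
  while (length(xs) < n) {
    x <- runif(1, margin, width - 1 - margin)
    y <- runif(1, margin, height - 1 - margin)
    if (!length(xs) || min(sqrt((xs - x)^2 + (ys - y)^2)) >= min_sep) {
      xs <- c(xs, x); ys <- c(ys, y)
    }
    tries <- tries + 1L
    if (tries > 10000L) stop("cannot place spots at the requested separation",
                             call. = FALSE)
  }
  data.frame(x_px = xs, y_px = ys)
}

#' Describe ground-truth aggregates for localization simulation
#'
#' @param kind `"rod"` or `"globule"`.
#' @param length_nm rod length (ignored for globules).
#' @param radius_nm globule radius (ignored for rods).
#' @param x_nm,y_nm centre position in nm.
#' @param theta rod orientation in radians.
#' @param n_loc true number of localizations drawn from the shape.
#' @param sigma_nm per-axis localization precision used for jitter.
#' @return A data.frame, one row per aggregate, with an `id` column.
#' @export
aggregate_truth <- function(kind = "rod", length_nm = 150, radius_nm = 40,
                            x_nm = 0, y_nm = 0, theta = 0, n_loc = 200L,
                            sigma_nm = 12) {
  df <- data.frame(kind = kind, length_nm = length_nm, radius_nm = radius_nm,
                   x_nm = x_nm, y_nm = y_nm, theta = theta,
                   n_loc = as.integer(n_loc), sigma_nm = sigma_nm)
  stopifnot(all(df$kind %in% c("rod", "globule")),
            all(df$length_nm > 0 | df$kind != "rod"),
            all(df$n_loc >= 1L))
  df$id <- seq_len(nrow(df))
  df
}

#' Simulate an SMLM localization table
#'
#' Draws localizations from parametric aggregate shapes — rods are line
#' segments convolved with a Gaussian of 20 nm full width at half maximum
#' (near-1-D fibrils), globules are uniform discs — jitters them by the
#' per-axis localization precision, assigns frames uniformly over the
#' acquisition, adds uniform background localizations, and optionally
#' applies cumulative linear drift. The precision columns (`lpx`, `lpy`)
#' store exactly the sigma used for jitter, in camera pixels.
#'
#' @param aggregates data.frame as produced by [aggregate_truth()].
#' @param background_rate uniform background localizations per square
#'   micrometre of field (expected total over the acquisition).
#' @param drift_px_per_frame length-2 numeric, linear drift in px/frame
#'   applied cumulatively (position + drift * frame).
#' @param frames number of acquisition frames.
#' @param fov_px field-of-view side length in camera pixels (used for
#'   background placement and bounds).
#' @param pixel_size_nm camera pixel size.
#' @param rod_width_fwhm_nm transverse full width at half maximum of the rod
#'   profile.
#' @param seed integer seed.
#' @return A list with `locs` (the localization table: `frame`, `x`, `y`,
#'   `photons`, `sx`, `sy`, `bg`, `lpx`, `lpy`, in pixels, with attribute
#'   `pixel_size_nm`) and `truth` (the aggregate table, per-localization
#'   `source` ids with 0 = background, and the injected `drift` trace).
#' @examples
#' agg <- aggregate_truth(kind = "rod", length_nm = 150, n_loc = 100)
#' sim <- simulate_localization_table(agg, seed = 1)
#' head(sim$locs)
#' @export
simulate_localization_table <- function(aggregates,
                                        background_rate = 0,
                                        drift_px_per_frame = c(0, 0),
                                        frames = 5000L,
                                        fov_px = 64L,
                                        pixel_size_nm = 107,
                                        rod_width_fwhm_nm = 20,
                                        seed = 1L) {
  if (frames < 1) stop("`frames` must be >= 1", call. = FALSE)
  if (background_rate < 0) stop("`background_rate` must be >= 0", call. = FALSE)
  set.seed(seed)
  xs <- ys <- sig <- numeric(0)
  src <- integer(0)
  width_sigma <- rod_width_fwhm_nm / (2 * sqrt(2 * log(2)))
  for (i in seq_len(nrow(aggregates))) {
    a <- aggregates[i, ]
    n <- a$n_loc
    if (a$kind == "rod") {
      t <- runif(n, -a$length_nm / 2, a$length_nm / 2)
      # isotropic width kernel: transverse profile v, tip rounding u
      u <- rnorm(n, 0, width_sigma)
      v <- rnorm(n, 0, width_sigma)
      ax <- t + u
      x0 <- a$x_nm + cos(a$theta) * ax - sin(a$theta) * v
      y0 <- a$y_nm + sin(a$theta) * ax + cos(a$theta) * v
    } else {
      r <- a$radius_nm * sqrt(runif(n))
      ang <- runif(n, 0, 2 * pi)
      x0 <- a$x_nm + r * cos(ang)
      y0 <- a$y_nm + r * sin(ang)
    }
    x0 <- x0 + rnorm(n, 0, a$sigma_nm)
    y0 <- y0 + rnorm(n, 0, a$sigma_nm)
    xs <- c(xs, x0 / pixel_size_nm)
    ys <- c(ys, y0 / pixel_size_nm)
    sig <- c(sig, rep(a$sigma_nm, n))
    src <- c(src, rep(a$id, n))
  }
  fov_um2 <- (fov_px * pixel_size_nm / 1000)^2
  n_bg <- rpois(1, background_rate * fov_um2)
  if (n_bg > 0) {
    xs <- c(xs, runif(n_bg, 0, fov_px))
    ys <- c(ys, runif(n_bg, 0, fov_px))
    sig <- c(sig, runif(n_bg, 8, 25))
    src <- c(src, rep(0L, n_bg))
  }
  n_tot <- length(xs)
  frame <- sample.int(frames, n_tot, replace = TRUE) - 1L
  xs <- xs + drift_px_per_frame[1] * frame
  ys <- ys + drift_px_per_frame[2] * frame
  locs <- data.frame(
    frame = frame,
    x = xs, y = ys,
    photons = rlnorm(n_tot, log(1000), 0.4),
    sx = rnorm(n_tot, 1.3, 0.1),
    sy = rnorm(n_tot, 1.3, 0.1),
    bg = rlnorm(n_tot, log(50), 0.3),
    lpx = sig / pixel_size_nm,
    lpy = sig / pixel_size_nm
  )
  attr(locs, "pixel_size_nm") <- pixel_size_nm
  drift <- data.frame(frame = c(0L, frames - 1L),
                      dx_px = c(0, drift_px_per_frame[1] * (frames - 1)),
                      dy_px = c(0, drift_px_per_frame[2] * (frames - 1)))
  list(locs = locs, truth = list(aggregates = aggregates, source = src,
                                 drift = drift))
}

#' Cohort specification for synthetic donor datasets
#'
#' Encodes the study design emulated by [simulate_cohort()]: three cohorts
#' (neurologically normal controls `CRL`, `MND_SOD`, `MND_TDP`), two brain
#' regions per donor (cerebellum and frontal cortex), and three technical
#' replicates per donor and region. Disease-direction defaults: `MND_TDP`
#' aggregates are longer, more frequently rod-shaped (more eccentric) and
#' carry fewer localizations per unit length (sparser); puncta counts are
#' higher in disease cerebellum but lower in disease frontal cortex; pSER
#' colabelling is raised in disease frontal cortex.
#'
#' @param donors named integer vector of donors per cohort.
#' @param n_replicates technical replicates per donor and region.
#' @param aggregates_per_replicate expected super-resolved aggregates per
#'   replicate field.
#' @param donor_cv between-donor log-normal coefficient of variation applied
#'   to every mean parameter.
#' @param background_rate background localizations per square micrometre.
#' @param frames dSTORM frames per acquisition.
#' @param fov_px localization field of view (camera pixels).
#' @param sigma_nm localization precision.
#' @param overrides named list of `cohort:region` parameter overrides, e.g.
#'   `list("MND_TDP.cerebellum" = list(length_meanlog = log(130)))`.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(donors = c(CRL = 3L, MND_SOD = 2L, MND_TDP = 5L),
                        n_replicates = 3L,
                        aggregates_per_replicate = 40L,
                        donor_cv = 0.08,
                        background_rate = 1,
                        frames = 5000L,
                        fov_px = 128L,
                        sigma_nm = 12,
                        overrides = list()) {
  stopifnot(all(donors >= 1L), n_replicates >= 1L)
  base <- list(
    CRL = list(spot_count = c(cerebellum = 120, frontal_cortex = 150),
               intensity_meanlog = log(450), intensity_sdlog = 0.5,
               length_meanlog = log(80), length_sdlog = 0.40,
               rod_fraction = 0.35, globule_radius_meanlog = log(40),
               loc_rate_per_nm = 1.5, colabel_p = c(cerebellum = 0.10,
                                                    frontal_cortex = 0.10)),
    MND_SOD = list(spot_count = c(cerebellum = 140, frontal_cortex = 135),
                   intensity_meanlog = log(480), intensity_sdlog = 0.5,
                   length_meanlog = log(90), length_sdlog = 0.42,
                   rod_fraction = 0.40, globule_radius_meanlog = log(40),
                   loc_rate_per_nm = 1.3, colabel_p = c(cerebellum = 0.13,
                                                        frontal_cortex = 0.15)),
    MND_TDP = list(spot_count = c(cerebellum = 180, frontal_cortex = 110),
                   intensity_meanlog = log(550), intensity_sdlog = 0.55,
                   length_meanlog = log(120), length_sdlog = 0.45,
                   rod_fraction = 0.55, globule_radius_meanlog = log(40),
                   loc_rate_per_nm = 0.9, colabel_p = c(cerebellum = 0.15,
                                                        frontal_cortex = 0.30))
  )
  for (key in names(overrides)) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    cohort <- parts[1]
    if (!cohort %in% names(base)) stop("unknown cohort in overrides: ", cohort,
                                       call. = FALSE)
    ov <- overrides[[key]]
    for (p in names(ov)) {
      if (length(parts) == 2L && length(base[[cohort]][[p]]) == 2L) {
        base[[cohort]][[p]][[parts[2]]] <- ov[[p]]
      } else {
        base[[cohort]][[p]] <- ov[[p]]
      }
    }
  }
  probs <- c(vapply(base, function(b) b$rod_fraction, numeric(1)),
             unlist(lapply(base, function(b) b$colabel_p)))
  stopifnot(all(probs >= 0 & probs <= 1))
  structure(list(donors = donors, n_replicates = as.integer(n_replicates),
                 aggregates_per_replicate = aggregates_per_replicate,
                 donor_cv = donor_cv, background_rate = background_rate,
                 frames = as.integer(frames), fov_px = fov_px,
                 sigma_nm = sigma_nm, params = base,
                 regions = c("cerebellum", "frontal_cortex")),
            class = "cohort_spec")
}

#' Simulate per-donor SiMPull datasets for a cohort design
#'
#' For every donor, region and technical replicate, draws a diffraction-
#' limited spot table (centroids and intensities), a matched colabel-channel
#' centroid table realised from the donor's colabelling probability, and a
#' super-resolution localization table rendered from ground-truth aggregate
#' shapes via [simulate_localization_table()]. Donor-level parameters (the
#' ground truth for all recovery tests) are exported.
#'
#' @param spec a [cohort_spec()].
#' @param seed integer seed.
#' @return A list with `datasets` (one entry per donor x region x replicate:
#'   `donor`, `cohort`, `region`, `replicate`, `spots`, `colabel`, `locs`,
#'   `truth_aggregates`) and `donor_params` (data.frame of realised
#'   per-donor, per-region means).
#' @export
simulate_cohort <- function(spec = cohort_spec(), seed = 1L) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(seed)
  datasets <- list()
  donor_rows <- list()
  donor_id <- 0L
  for (cohort in names(spec$donors)) {
    p <- spec$params[[cohort]]
    for (d in seq_len(spec$donors[[cohort]])) {
      donor_id <- donor_id + 1L
      # one multiplicative donor effect per parameter family
      eff <- rlnorm(5, 0, spec$donor_cv)
      for (region in spec$regions) {
        mu_count <- p$spot_count[[region]] * eff[1]
        mu_len <- exp(p$length_meanlog) * eff[2]
        rod_f <- min(1, p$rod_fraction * eff[3])
        loc_rate <- p$loc_rate_per_nm * eff[4]
        col_p <- min(1, p$colabel_p[[region]] * eff[5])
        donor_rows[[length(donor_rows) + 1L]] <- data.frame(
          donor = donor_id, cohort = cohort, region = region,
          mean_count = mu_count, mean_length_nm = mu_len,
          rod_fraction = rod_f, loc_rate_per_nm = loc_rate,
          colabel_p = col_p)
        for (rep_i in seq_len(spec$n_replicates)) {
          n_spots <- rpois(1, mu_count)
          spots <- data.frame(
            x_px = runif(n_spots, 0, 512), y_px = runif(n_spots, 0, 512),
            intensity = rlnorm(n_spots, p$intensity_meanlog, p$intensity_sdlog))
          lab <- runif(n_spots) < col_p
          colabel <- data.frame(
            x_px = pmin(pmax(spots$x_px[lab] + runif(sum(lab), -1, 1), 0), 511.99),
            y_px = pmin(pmax(spots$y_px[lab] + runif(sum(lab), -1, 1), 0), 511.99))
          # unrelated spots in the colabel channel (not matching channel A)
          n_extra <- rpois(1, max(2, n_spots * 0.1))
          colabel <- rbind(colabel, data.frame(
            x_px = runif(n_extra, 0, 512), y_px = runif(n_extra, 0, 512)))
          n_agg <- max(1L, rpois(1, spec$aggregates_per_replicate))
          kind <- ifelse(runif(n_agg) < rod_f, "rod", "globule")
          len <- rlnorm(n_agg, log(mu_len), p$length_sdlog)
          rad <- rlnorm(n_agg, p$globule_radius_meanlog, 0.3)
          extent <- ifelse(kind == "rod", len, 2 * rad)
          nloc <- pmax(10L, rpois(n_agg, loc_rate * extent))
          centers <- place_random_spots(n_agg, spec$fov_px, spec$fov_px,
                                        min_sep = 8, margin = 4)
          agg <- aggregate_truth(kind = kind, length_nm = len,
                                 radius_nm = rad,
                                 x_nm = centers$x_px * 107,
                                 y_nm = centers$y_px * 107,
                                 theta = runif(n_agg, 0, pi),
                                 n_loc = nloc, sigma_nm = spec$sigma_nm)
          sim <- simulate_localization_table(
            agg, background_rate = spec$background_rate,
            frames = spec$frames, fov_px = spec$fov_px,
            seed = sample.int(.Machine$integer.max, 1))
          datasets[[length(datasets) + 1L]] <- list(
            donor = donor_id, cohort = cohort, region = region,
            replicate = rep_i, spots = spots, colabel = colabel,
            locs = sim$locs, truth_aggregates = agg)
        }
      }
    }
  }
  list(datasets = datasets, donor_params = do.call(rbind, donor_rows))
}

#' Simulate two-fraction TMT-style protein quantification tables
#'
#' Generates log-normal protein abundances for a total-proteome and an
#' aggregate-fraction table over control and case channels, with a pooled
#' reference channel (the mean of all true channel abundances), log-normal
#' measurement noise at a given coefficient of variation, peptide and unique
#' peptide counts, and contaminant-flagged rows. Spiked effects multiply
#' case-channel abundances by `e_tot` (total fraction) and `e_agg`
#' (aggregate fraction); the exported truth lists them.
#'
#' @param n_proteins number of non-contaminant proteins.
#' @param n_control,n_case channels per group (each >= 2).
#' @param effects optional data.frame with columns `protein` (index in
#'   `1:n_proteins`), `e_agg`, `e_tot` (positive fold changes).
#' @param cv measurement coefficient of variation.
#' @param n_contaminants contaminant-flagged rows appended (keratins etc.).
#' @param seed integer seed.
#' @return A list with `total` and `aggregate` quantification tables (each a
#'   data.frame with accession, peptide counts, contaminant flag, reference
#'   column and one abundance column per channel, plus a `design`
#'   attribute), and `truth`.
#' @export
simulate_proteomics <- function(n_proteins = 800L, n_control = 5L,
                                n_case = 5L, effects = NULL, cv = 0.1,
                                n_contaminants = 15L, seed = 1L) {
  if (n_control < 2L || n_case < 2L) {
    stop("at least 2 control and 2 case channels are required", call. = FALSE)
  }
  if (!is.null(effects) && any(effects$e_agg <= 0 | effects$e_tot <= 0)) {
    stop("fold changes must be positive", call. = FALSE)
  }
  set.seed(seed)
  acc <- sprintf("P%05d", seq_len(n_proteins))
  base <- rlnorm(n_proteins, log(1e6), 1)
  sdlog <- sqrt(log(1 + cv^2))
  e_agg <- e_tot <- rep(1, n_proteins)
  if (!is.null(effects)) {
    e_agg[effects$protein] <- effects$e_agg
    e_tot[effects$protein] <- effects$e_tot
  }
  channels <- c(paste0("control_", seq_len(n_control)),
                paste0("case_", seq_len(n_case)))
  make_table <- function(fold, fraction) {
    true <- sapply(channels, function(ch) {
      if (startsWith(ch, "case")) base * fold else base
    })
    ref_true <- rowMeans(true)
    noisy <- true * matrix(rlnorm(length(true), -sdlog^2 / 2, sdlog),
                           nrow(true), ncol(true))
    tab <- data.frame(accession = acc,
                      n_peptides = 2L + rpois(n_proteins, 4),
                      n_unique = 1L + rpois(n_proteins, 2),
                      contaminant = FALSE,
                      reference = ref_true * rlnorm(n_proteins, -sdlog^2 / 2, sdlog))
    tab <- cbind(tab, as.data.frame(noisy))
    if (n_contaminants > 0) {
      con <- tab[sample.int(n_proteins, n_contaminants), ]
      con$accession <- sprintf("CON__KRT%02d", seq_len(n_contaminants))
      con$contaminant <- TRUE
      tab <- rbind(tab, con)
    }
    rownames(tab) <- NULL
    attr(tab, "design") <- data.frame(
      column = channels,
      group = c(rep("control", n_control), rep("case", n_case)),
      run = 1L)
    attr(tab, "fraction") <- fraction
    tab
  }
  list(total = make_table(e_tot, "total"),
       aggregate = make_table(e_agg, "aggregate"),
       truth = data.frame(accession = acc, e_agg = e_agg, e_tot = e_tot,
                          log2_corrected = log2(e_agg / e_tot)))
}
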