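#' Mean intensity projection of a TIRF stack
#'
#' Projects a multi-frame acquisition to a single image by pixel-wise mean
#' over the trailing `last_n` frames (the early frames of a SiMPull movie
#' carry the highest background). Stacks shorter than `last_n` are averaged
#' over all their frames.
#'
#' @param stack a `height x width x frames` array (or a single matrix).
#' @param last_n number of trailing frames to average (default 40).
#' @return A `height x width` matrix carrying the stack's attributes.
#' @export
mean_projection <- function(stack, last_n = 40L) {
  if (is.matrix(stack)) stack <- array(stack, dim = c(dim(stack), 1L))
  nf <- dim(stack)[3]
  if (is.na(nf) || nf < 1) stop("stack must contain at least one frame", call. = FALSE)
  use <- max(1L, nf - min(last_n, nf) + 1L):nf
  proj <- apply(stack[, , use, drop = FALSE], c(1, 2), mean)
  attr(proj, "pixel_size_nm") <- attr(stack, "pixel_size_nm")
  attr(proj, "channel") <- attr(stack, "channel")
  proj
}

#' Detect diffraction-limited puncta
#'
#' Background-relative spot detection: the image is Gaussian-smoothed, a
#' robust threshold of median + `k` * MAD is applied, local maxima above the
#' threshold become candidates, candidates closer than `min_separation_px`
#' are merged (brightest wins), and each surviving spot receives a sub-pixel
#' centroid from the intensity-weighted mean of a window around the maximum.
#' Detection counts are invariant to an additive constant background and
#' monotone non-increasing in `k`.
#'
#' @param image 2-D numeric matrix (e.g. from [mean_projection()]).
#' @param smooth_sigma Gaussian smoothing sigma in pixels.
#' @param k threshold in robust standard deviation (MAD) units above the
#'   median.
#' @param min_separation_px candidates closer than this are merged.
#' @param centroid_window_px half-width of the centroid window.
#' @param channel channel label attached to the output.
#' @param fov field-of-view identifier attached to the output.
#' @return A `SpotTable` data.frame: `x_px`, `y_px` (0-based sub-pixel
#'   centroids), `peak` (smoothed peak height above background), `fov`,
#'   `channel`.
#' @export
detect_puncta <- function(image, smooth_sigma = 1, k = 5,
                          min_separation_px = 3, centroid_window_px = 2L,
                          channel = attr(image, "channel"), fov = 1L) {
  if (!all(is.finite(image))) stop("image contains non-finite pixels", call. = FALSE)
  sm <- if (smooth_sigma > 0) {
    as.matrix(EBImage::gblur(image, sigma = smooth_sigma))
  } else image
  bgr <- median(sm)
  thr <- bgr + k * mad(sm)
  nr <- nrow(sm); nc <- ncol(sm)
  pad <- matrix(-Inf, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- sm
  sh <- function(dr, dc) pad[(2L + dr):(nr + 1L + dr), (2L + dc):(nc + 1L + dc)]
  is_max <- sm > thr &
    sm >= sh(-1, 0) & sm >= sh(1, 0) & sm >= sh(0, -1) & sm > sh(0, 1) &
    sm >= sh(-1, -1) & sm > sh(-1, 1) & sm > sh(1, -1) & sm > sh(1, 1)
  idx <- which(is_max, arr.ind = TRUE)
  empty <- data.frame(x_px = numeric(0), y_px = numeric(0),
                      peak = numeric(0), fov = integer(0),
                      channel = character(0))
  if (nrow(idx) == 0L) return(empty)
  vals <- sm[idx]
  ord <- order(-vals, idx[, 1], idx[, 2])
  idx <- idx[ord, , drop = FALSE]
  vals <- vals[ord]
  keep <- rep(TRUE, nrow(idx))
  for (i in seq_len(nrow(idx))) {
    if (!keep[i]) next
    if (i < nrow(idx)) {
      j <- (i + 1L):nrow(idx)
      d <- sqrt((idx[j, 1] - idx[i, 1])^2 + (idx[j, 2] - idx[i, 2])^2)
      keep[j][d < min_separation_px] <- FALSE
    }
  }
  idx <- idx[keep, , drop = FALSE]
  vals <- vals[keep]
  w <- centroid_window_px
  cx <- cy <- numeric(nrow(idx))
  for (i in seq_len(nrow(idx))) {
    r0 <- max(1L, idx[i, 1] - w); r1 <- min(nr, idx[i, 1] + w)
    c0 <- max(1L, idx[i, 2] - w); c1 <- min(nc, idx[i, 2] + w)
    win <- pmax(sm[r0:r1, c0:c1, drop = FALSE] - bgr, 0)
    rows <- matrix(r0:r1, r1 - r0 + 1L, c1 - c0 + 1L)
    cols <- matrix(c0:c1, r1 - r0 + 1L, c1 - c0 + 1L, byrow = TRUE)
    tot <- sum(win)
    if (tot <= 0) { cy[i] <- idx[i, 1]; cx[i] <- idx[i, 2] }
    else { cy[i] <- sum(rows * win) / tot; cx[i] <- sum(cols * win) / tot }
  }
  # matrix rows are y, columns are x; convert 1-based indices to 0-based px
  out <- data.frame(x_px = cx - 1, y_px = cy - 1, peak = vals - bgr,
                    fov = fov,
                    channel = if (is.null(channel)) NA_character_ else channel)
  out[order(out$y_px, out$x_px), , drop = FALSE]
}

#' Measure spot intensities
#'
#' Adds mean and background-subtracted integrated intensity, measured in a
#' square window around each centroid, to a `SpotTable`. The background is
#' the image median. Spots whose window crosses the image border are
#' excluded from measurement (flagged, intensities `NA`) under the default
#' border policy.
#'
#' @param image 2-D numeric matrix.
#' @param spots `SpotTable` from [detect_puncta()] (columns `x_px`, `y_px`).
#' @param window_px half-width of the measurement window.
#' @param border `"exclude"` (flag and skip border spots) or `"clip"`
#'   (measure over the in-bounds part of the window).
#' @return The `SpotTable` with `mean_intensity`, `integrated_intensity` and
#'   `measured` columns.
#' @export
measure_spot_intensity <- function(image, spots, window_px = 2L,
                                   border = c("exclude", "clip")) {
  border <- match.arg(border)
  nr <- nrow(image); nc <- ncol(image)
  if (2L * window_px + 1L > min(nr, nc)) {
    stop("measurement window is larger than the image", call. = FALSE)
  }
  bgr <- median(image)
  n <- nrow(spots)
  mean_i <- int_i <- rep(NA_real_, n)
  measured <- rep(FALSE, n)
  for (i in seq_len(n)) {
    r <- round(spots$y_px[i]) + 1L
    c <- round(spots$x_px[i]) + 1L
    r0 <- r - window_px; r1 <- r + window_px
    c0 <- c - window_px; c1 <- c + window_px
    inside <- r0 >= 1L && r1 <= nr && c0 >= 1L && c1 <= nc
    if (!inside && border == "exclude") next
    r0 <- max(1L, r0); r1 <- min(nr, r1); c0 <- max(1L, c0); c1 <- min(nc, c1)
    win <- image[r0:r1, c0:c1]
    mean_i[i] <- mean(win)
    int_i[i] <- sum(win - bgr)
    measured[i] <- TRUE
  }
  spots$mean_intensity <- mean_i
  spots$integrated_intensity <- int_i
  spots$measured <- measured
  spots
}

#' Scale a puncta count by sample load
#'
#' Normalises a field-of-view count to material loaded: the raw count is
#' divided by the product of the original sample weight and the total
#' protein concentration, yielding counts per (mg tissue x mg/ml protein)
#' that are comparable across technical replicates and samples.
#'
#' @param raw_count non-negative spot count.
#' @param sample_weight_mg original sample weight before processing (mg).
#' @param protein_conc_mg_per_ml total protein concentration of the assayed
#'   extract (mg/ml).
#' @return The scaled count.
#' @examples
#' scale_count(100, 2, 1) # 50
#' @export
scale_count <- function(raw_count, sample_weight_mg, protein_conc_mg_per_ml) {
  stopifnot_positive(sample_weight_mg, "sample_weight_mg")
  stopifnot_positive(protein_conc_mg_per_ml, "protein_conc_mg_per_ml")
  if (any(raw_count < 0)) stop("`raw_count` must be >= 0", call. = FALSE)
  raw_count / (sample_weight_mg * protein_conc_mg_per_ml)
}
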