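#' Match spots between two channels
#'
#' One-to-one matching of centroids by Euclidean distance: every candidate
#' pair within `radius` is considered, pairs are accepted greedily in order
#' of ascending distance (so each spot ends up matched to its closest
#' available partner), and no spot takes part in more than one pair. Ties at
#' identical distance are broken by the lower channel-A index, then the
#' lower channel-B index.
#'
#' @param centroids_a,centroids_b data.frames (or 2-column matrices) with
#'   columns `x_px`, `y_px`, in the same coordinate frame.
#' @param radius matching radius in pixels (default 4).
#' @return A data.frame with `index_a`, `index_b`, `distance`, one row per
#'   matched pair.
#' @export
match_spots <- function(centroids_a, centroids_b, radius = 4) {
  if (radius < 0) stop("`radius` must be >= 0", call. = FALSE)
  a <- as_centroids(centroids_a)
  b <- as_centroids(centroids_b)
  empty <- data.frame(index_a = integer(0), index_b = integer(0),
                      distance = numeric(0))
  if (nrow(a) == 0L || nrow(b) == 0L) return(empty)
  d <- outer(a$x_px, b$x_px, "-")^2 + outer(a$y_px, b$y_px, "-")^2
  cand <- which(d <= radius^2, arr.ind = TRUE)
  if (nrow(cand) == 0L) return(empty)
  dist_c <- sqrt(d[cand])
  ord <- order(dist_c, cand[, 1], cand[, 2])
  cand <- cand[ord, , drop = FALSE]
  dist_c <- dist_c[ord]
  used_a <- logical(nrow(a)); used_b <- logical(nrow(b))
  ia <- ib <- integer(0); dd <- numeric(0)
  for (i in seq_len(nrow(cand))) {
    ra <- cand[i, 1]; rb <- cand[i, 2]
    if (used_a[ra] || used_b[rb]) next
    used_a[ra] <- TRUE; used_b[rb] <- TRUE
    ia <- c(ia, ra); ib <- c(ib, rb); dd <- c(dd, dist_c[i])
  }
  data.frame(index_a = ia, index_b = ib, distance = dd)
}

as_centroids <- function(x) {
  if (is.matrix(x)) x <- data.frame(x_px = x[, 1], y_px = x[, 2])
  stopifnot(all(c("x_px", "y_px") %in% names(x)))
  x
}

#' Chance colocalization proportion
#'
#' Estimates the proportion of spurious matches expected by chance:
#' channel-B x-coordinates are mirrored about the image's vertical axis
#' (x -> width - 1 - x), which preserves spot density and y-structure while
#' destroying any true correspondence, and the matching of [match_spots()]
#' is repeated. For independent, spatially uniform channels the chance
#' proportion approaches 1 - exp(-rho * pi * r^2) where rho is the
#' channel-B density per px^2.
#'
#' @inheritParams match_spots
#' @param image_width_px image width in pixels (x range is `[0, width)`).
#' @return Proportion of channel-A spots matched after mirroring.
#' @export
chance_coloc_proportion <- function(centroids_a, centroids_b,
                                    image_width_px, radius = 4) {
  stopifnot_positive(image_width_px, "image_width_px")
  a <- as_centroids(centroids_a)
  b <- as_centroids(centroids_b)
  if (nrow(b) == 0L || nrow(a) == 0L) return(0)
  if (any(b$x_px < 0 | b$x_px >= image_width_px) ||
      any(a$x_px < 0 | a$x_px >= image_width_px)) {
    stop("centroid x-coordinates must lie in [0, image width)", call. = FALSE)
  }
  b$x_px <- (image_width_px - 1) - b$x_px
  nrow(match_spots(a, b, radius)) / nrow(a)
}

#' Two-channel colocalization analysis
#'
#' Runs [match_spots()] and [chance_coloc_proportion()] and reports the
#' colabelled proportion: the number of co-labelled spots divided by the
#' total number of spots detected in the reference channel (channel A).
#'
#' @inheritParams chance_coloc_proportion
#' @return A `ColocResult` list: `pairs`, `n_a`, `n_b`, `n_matched`,
#'   `proportion`, `chance_proportion`, `radius`.
#' @examples
#' a <- data.frame(x_px = c(10, 30), y_px = c(10, 30))
#' b <- data.frame(x_px = c(12, 50), y_px = c(12, 50))
#' coloc_analysis(a, b, image_width_px = 64)$proportion
#' @export
coloc_analysis <- function(centroids_a, centroids_b, image_width_px,
                           radius = 4) {
  a <- as_centroids(centroids_a)
  b <- as_centroids(centroids_b)
  pairs <- match_spots(a, b, radius)
  prop <- if (nrow(a) == 0L) NA_real_ else nrow(pairs) / nrow(a)
  chance <- if (nrow(a) == 0L) NA_real_ else {
    chance_coloc_proportion(a, b, image_width_px, radius)
  }
  structure(list(pairs = pairs, n_a = nrow(a), n_b = nrow(b),
                 n_matched = nrow(pairs), proportion = prop,
                 chance_proportion = chance, radius = radius),
            class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf(
    "coloc_result: %d/%d channel-A spots matched (proportion %.3f, chance %.3f)\n",
    x$n_matched, x$n_a, x$proportion, x$chance_proportion))
  invisible(x)
}
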