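#' Filter localizations by acquisition frame and precision
#'
#' Quality control ahead of clustering: discards the first
#' `discard_first_frames` frames of the acquisition (early frames carry
#' unconverted fluorophores) and keeps only localizations with pooled
#' precision strictly below `max_precision_nm` (default < 30 nm). The pooled
#' precision is the mean of the per-axis values (`lpx`, `lpy`, in camera
#' pixels) converted to nm. The filter is idempotent.
#'
#' @param locs localization table (columns `frame`, `x`, `y`, `lpx`, `lpy`).
#' @param max_precision_nm strict upper precision bound in nm.
#' @param discard_first_frames keep only `frame >= discard_first_frames`.
#' @param pixel_size_nm camera pixel size; taken from the table's
#'   `pixel_size_nm` attribute when present.
#' @return The filtered table (attributes preserved), with a `precision_nm`
#'   column added. Warns when the result is empty.
#' @export
filter_localizations <- function(locs, max_precision_nm = 30,
                                 discard_first_frames = 300L,
                                 pixel_size_nm = NULL) {
  if (nrow(locs) == 0L) stop("localization table is empty", call. = FALSE)
  pixel_size_nm <- pixel_size_nm %||% attr(locs, "pixel_size_nm") %||% 107
  precision_nm <- (locs$lpx + locs$lpy) / 2 * pixel_size_nm
  keep <- locs$frame >= discard_first_frames & precision_nm < max_precision_nm
  out <- locs[keep, , drop = FALSE]
  out$precision_nm <- precision_nm[keep]
  attr(out, "pixel_size_nm") <- pixel_size_nm
  if (nrow(out) == 0L) {
    warning("no localizations survive the precision/frame filter")
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Estimate and correct microscope drift
#'
#' Block-wise image-correlation drift estimation: the acquisition is split
#' into `n_blocks` equal frame ranges, each block is rendered as a 2-D
#' histogram on a common grid, and every block image is cross-correlated
#' (via FFT) against the first block. The correlation peak is refined to
#' sub-bin accuracy by parabolic interpolation, block shifts are
#' interpolated piecewise-linearly over frames, and the resulting drift
#' trace is subtracted from the coordinates. Blocks without localizations
#' are interpolated from their neighbours. This is a single-reference
#' simplification of redundant (all-pairs) cross-correlation.
#'
#' @param locs localization table (`frame`, `x`, `y`, in camera pixels).
#' @param n_blocks number of temporal blocks (>= 2).
#' @param render_px bin size of the correlation histograms, in camera
#'   pixels (coarser bins are more robust for large drifts).
#' @param frames_total total frames in the acquisition (defaults to
#'   `max(frame) + 1`).
#' @return A list with `locs` (drift-corrected table), `blocks` (per-block
#'   centre frame and estimated shift in px) and `trace` (per-frame drift).
#' @export
estimate_and_correct_drift <- function(locs, n_blocks = 10L, render_px = 1,
                                       frames_total = NULL) {
  if (n_blocks < 2L) stop("drift estimation requires at least 2 temporal blocks",
                          call. = FALSE)
  frames_total <- frames_total %||% (max(locs$frame) + 1L)
  block_len <- frames_total / n_blocks
  block <- pmin(n_blocks - 1L, floor(locs$frame / block_len))
  x0 <- min(locs$x); y0 <- min(locs$y)
  nbx <- floor((max(locs$x) - x0) / render_px) + 1L
  nby <- floor((max(locs$y) - y0) / render_px) + 1L
  # pad so that circular correlation does not wrap real structure
  nbx <- nbx + 2L * ceiling(nbx / 4); nby <- nby + 2L * ceiling(nby / 4)
  hist_block <- function(i) {
    sel <- block == i
    if (!any(sel)) return(NULL)
    bx <- floor((locs$x[sel] - x0) / render_px) + 1L
    by <- floor((locs$y[sel] - y0) / render_px) + 1L
    matrix(tabulate((bx - 1L) * nby + by, nbins = nbx * nby), nby, nbx)
  }
  ref <- NULL
  shifts <- matrix(NA_real_, n_blocks, 2)
  centers <- (seq_len(n_blocks) - 0.5) * block_len
  imgs <- lapply(0:(n_blocks - 1L), hist_block)
  have <- !vapply(imgs, is.null, logical(1))
  if (sum(have) < 2L) stop("need at least 2 blocks with localizations", call. = FALSE)
  ref_idx <- which(have)[1]
  ref <- imgs[[ref_idx]]
  fref <- fft(ref)
  for (i in which(have)) {
    if (i == ref_idx) { shifts[i, ] <- c(0, 0); next }
    cc <- Re(fft(fref * Conj(fft(imgs[[i]])), inverse = TRUE))
    pk <- which(cc == max(cc), arr.ind = TRUE)[1, , drop = TRUE]
    sub <- function(dim_n, p, get) {
      cm <- get(((p - 2) %% dim_n) + 1L)
      c0 <- get(p)
      cp <- get((p %% dim_n) + 1L)
      den <- cm - 2 * c0 + cp
      if (den == 0) 0 else 0.5 * (cm - cp) / den
    }
    dy <- pk[1] - 1L + sub(nby, pk[1], function(r) cc[r, pk[2]])
    dx <- pk[2] - 1L + sub(nbx, pk[2], function(c) cc[pk[1], c])
    if (dy > nby / 2) dy <- dy - nby
    if (dx > nbx / 2) dx <- dx - nbx
    # cc peaks at the displacement of the reference relative to block i,
    # so block i has drifted by -peak
    shifts[i, ] <- -c(dx, dy) * render_px
  }
  # anchor the trace at the first block and fill missing blocks
  shifts[, 1] <- fill_interp(centers, shifts[, 1])
  shifts[, 2] <- fill_interp(centers, shifts[, 2])
  frames_seq <- 0:(frames_total - 1L)
  trace_x <- interp_extrap(centers, shifts[, 1], frames_seq)
  trace_y <- interp_extrap(centers, shifts[, 2], frames_seq)
  out <- locs
  out$x <- locs$x - trace_x[locs$frame + 1L]
  out$y <- locs$y - trace_y[locs$frame + 1L]
  attr(out, "pixel_size_nm") <- attr(locs, "pixel_size_nm")
  list(locs = out,
       blocks = data.frame(block = seq_len(n_blocks), center_frame = centers,
                           dx_px = shifts[, 1], dy_px = shifts[, 2]),
       trace = data.frame(frame = 0:(frames_total - 1L), dx_px = trace_x,
                          dy_px = trace_y))
}

fill_interp <- function(x, y) {
  ok <- is.finite(y)
  if (all(ok)) return(y)
  stats::approx(x[ok], y[ok], xout = x, rule = 2)$y
}

# piecewise-linear interpolation with linear extrapolation beyond the first
# and last knots (using the slope of the adjacent segment)
interp_extrap <- function(x, y, xout) {
  out <- stats::approx(x, y, xout = xout, rule = 2)$y
  n <- length(x)
  lo <- xout < x[1]
  if (any(lo)) {
    s <- (y[2] - y[1]) / (x[2] - x[1])
    out[lo] <- y[1] + s * (xout[lo] - x[1])
  }
  hi <- xout > x[n]
  if (any(hi)) {
    s <- (y[n] - y[n - 1]) / (x[n] - x[n - 1])
    out[hi] <- y[n] + s * (xout[hi] - x[n])
  }
  out
}

#' Density-based clustering of localizations (DBSCAN)
#'
#' Separates aggregate localizations from random background using DBSCAN
#' with a maximum neighbourhood radius `eps_px` (default 0.5 camera pixels)
#' and minimum neighbourhood size `min_samples` (default 5, the point itself
#' included). Core points are density-connected into clusters; non-core
#' points within `eps_px` of a core point join the cluster of their
#' lowest-index core neighbour (a deterministic tie rule); remaining points
#' are noise.
#'
#' @param locs localization table or a 2-column matrix/data.frame of
#'   coordinates in camera pixels (columns `x`, `y`).
#' @param eps_px neighbourhood radius in pixels.
#' @param min_samples minimum neighbourhood size for a core point.
#' @return Integer vector of cluster labels: `-1` for noise, clusters
#'   numbered `1..k` in order of their lowest-index core point.
#' @export
cluster_localizations <- function(locs, eps_px = 0.5, min_samples = 5L) {
  xy <- if (is.matrix(locs)) locs else cbind(locs$x, locs$y)
  n <- nrow(xy)
  if (n == 0L) return(integer(0))
  cellx <- floor(xy[, 1] / eps_px)
  celly <- floor(xy[, 2] / eps_px)
  key <- paste(cellx, celly)
  cells <- split(seq_len(n), key)
  # neighbour lists via the 3x3 block of grid cells around each point
  neigh <- vector("list", n)
  eps2 <- eps_px^2
  lookup <- new.env(hash = TRUE, parent = emptyenv(), size = length(cells))
  for (k in names(cells)) assign(k, cells[[k]], envir = lookup)
  for (i in seq_len(n)) {
    cand <- integer(0)
    for (dx in -1:1) for (dy in -1:1) {
      k <- paste(cellx[i] + dx, celly[i] + dy)
      v <- lookup[[k]]
      if (!is.null(v)) cand <- c(cand, v)
    }
    d2 <- (xy[cand, 1] - xy[i, 1])^2 + (xy[cand, 2] - xy[i, 2])^2
    neigh[[i]] <- cand[d2 <= eps2]
  }
  core <- lengths(neigh) >= min_samples
  labels <- rep(-1L, n)
  cluster <- 0L
  for (i in seq_len(n)) {
    if (!core[i] || labels[i] != -1L) next
    cluster <- cluster + 1L
    labels[i] <- cluster
    frontier <- i
    while (length(frontier)) {
      nb <- unique(unlist(neigh[frontier]))
      nb <- nb[core[nb] & labels[nb] == -1L]
      labels[nb] <- cluster
      frontier <- nb
    }
  }
  # border points: cluster of the lowest-index core point within eps
  for (i in seq_len(n)) {
    if (core[i]) next
    cn <- neigh[[i]][core[neigh[[i]]]]
    if (length(cn)) labels[i] <- labels[min(cn)]
  }
  labels
}

#' Render a localization cluster as a single connected region
#'
#' Bins the cluster's localizations onto a super-resolution grid
#' (`render_px_nm`, default 10.7 nm — one tenth of the camera pixel) and
#' applies morphological dilation, closing and erosion with disc-shaped
#' elements to bridge the gaps left by localization jitter, yielding a
#' single connected region of interest. The largest 8-connected component
#' is retained.
#'
#' @param xy_px 2-column matrix or data.frame of cluster localizations in
#'   camera pixels.
#' @param render_px_nm super-resolution bin size in nm.
#' @param pixel_size_nm camera pixel size in nm.
#' @param radii integer radii (render bins) of the dilation, closing and
#'   erosion elements; a radius of 0 skips the operation.
#' @return A list of class `aggregate_region`: `mask` (binary matrix, rows =
#'   y bins), `origin_nm` (nm coordinates of the centre of bin `[1,1]`),
#'   `render_px_nm`, `n_loc`.
#' @export
regionize_cluster <- function(xy_px, render_px_nm = 10.7,
                              pixel_size_nm = 107,
                              radii = c(dilate = 1L, close = 2L, erode = 1L)) {
  xy <- if (is.matrix(xy_px)) xy_px else cbind(xy_px$x, xy_px$y)
  if (nrow(xy) < 1L) stop("cluster has no localizations", call. = FALSE)
  x_nm <- xy[, 1] * pixel_size_nm
  y_nm <- xy[, 2] * pixel_size_nm
  pad <- sum(radii) + 2L
  bx <- floor((x_nm - min(x_nm)) / render_px_nm) + 1L + pad
  by <- floor((y_nm - min(y_nm)) / render_px_nm) + 1L + pad
  mask <- matrix(0L, max(by) + pad, max(bx) + pad)
  mask[cbind(by, bx)] <- 1L
  brush <- function(r) EBImage::makeBrush(2L * r + 1L, "disc")
  if (radii[1] > 0) mask <- EBImage::dilate(mask, brush(radii[1]))
  if (radii[2] > 0) mask <- EBImage::closing(mask, brush(radii[2]))
  if (radii[3] > 0) mask <- EBImage::erode(mask, brush(radii[3]))
  mask <- matrix(as.integer(mask != 0), nrow(mask), ncol(mask))
  lab <- label_components8(mask)
  if (max(lab) == 0L) {
    # degenerate fall-back: keep the occupied bins themselves
    mask[cbind(by, bx)] <- 1L
  } else {
    sizes <- tabulate(lab[lab > 0L])
    mask <- matrix(as.integer(lab == which.max(sizes)), nrow(mask), ncol(mask))
  }
  structure(list(
    mask = mask,
    origin_nm = c(x = min(x_nm) + (0.5 - pad) * render_px_nm,
                  y = min(y_nm) + (0.5 - pad) * render_px_nm),
    render_px_nm = render_px_nm,
    n_loc = nrow(xy)), class = "aggregate_region")
}

#' Measure one super-resolved aggregate
#'
#' Computes the morphometric record of a regionized aggregate:
#' \itemize{
#'   \item area: occupied bins x (render pixel)^2;
#'   \item perimeter: boundary crack length (exposed bin edges x render
#'     pixel);
#'   \item eccentricity and major/minor axes from the region's second
#'     central moments (ellipse-of-same-second-moments convention, with the
#'     1/12 bin-extent term so single-bin-wide regions stay below
#'     eccentricity 1);
#'   \item skeleton length: Zhang-Suen topological thinning, length summed
#'     as Euclidean steps along all skeleton branches ("summed branch
#'     distance");
#'   \item localization density: localizations per nm^2 of area, so that
#'     density x area equals the localization count exactly.
#' }
#'
#' @param region an `aggregate_region` from [regionize_cluster()].
#' @param n_loc number of localizations in the aggregate (defaults to the
#'   count stored on the region).
#' @param id aggregate identifier.
#' @return A one-row data.frame (`AggregateRecord`): `id`, `area_nm2`,
#'   `perimeter_nm`, `eccentricity`, `major_axis_nm`, `minor_axis_nm`,
#'   `skeleton_length_nm`, `n_localizations`, `density_loc_per_nm2`.
#' @export
measure_aggregate <- function(region, n_loc = region$n_loc, id = 1L) {
  mask <- region$mask
  if (sum(mask) < 1L) stop("mask is empty", call. = FALSE)
  px <- region$render_px_nm
  area <- sum(mask) * px^2
  perim <- crack_perimeter(mask) * px
  idx <- which(mask == 1L, arr.ind = TRUE)
  yc <- idx[, 1] - mean(idx[, 1])
  xc <- idx[, 2] - mean(idx[, 2])
  mxx <- mean(xc^2) + 1 / 12
  myy <- mean(yc^2) + 1 / 12
  mxy <- mean(xc * yc)
  common <- sqrt((mxx - myy)^2 + 4 * mxy^2)
  l1 <- (mxx + myy + common) / 2
  l2 <- (mxx + myy - common) / 2
  ecc <- sqrt(max(0, 1 - l2 / l1))
  sk <- zs_thin(mask)
  data.frame(
    id = id,
    area_nm2 = area,
    perimeter_nm = perim,
    eccentricity = ecc,
    major_axis_nm = 4 * sqrt(l1) * px,
    minor_axis_nm = 4 * sqrt(l2) * px,
    skeleton_length_nm = skeleton_length(sk) * px,
    n_localizations = n_loc,
    density_loc_per_nm2 = n_loc / area)
}

# Exposed bin edges (4-neighbourhood), including edges on the matrix border.
crack_perimeter <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  P <- matrix(0L, nr + 2L, nc + 2L)
  P[2:(nr + 1L), 2:(nc + 1L)] <- mask
  cur <- P[2:(nr + 1L), 2:(nc + 1L)]
  exposed <- (cur & !P[1:nr, 2:(nc + 1L)]) + (cur & !P[3:(nr + 2L), 2:(nc + 1L)]) +
    (cur & !P[2:(nr + 1L), 1:nc]) + (cur & !P[2:(nr + 1L), 3:(nc + 2L)])
  sum(exposed)
}

# Summed branch distance of a thinned skeleton: total weight of the minimum
# spanning forest of the 8-adjacency graph (drops the redundant diagonal of
# orthogonal/diagonal triangles, as a branch-wise path trace would).
# Terminal spurs — leaf-to-junction branches shorter than `prune_bins`
# (default 5 bins ~ 55 nm, the typical mask half-width, below which a side
# branch cannot be distinguished from outline noise) — are thinning
# artifacts of a jittered outline and are removed before summing; branches
# that end at another leaf (the backbone of a fibril) are never pruned.
skeleton_length <- function(sk, prune_bins = 5) {
  idx <- which(sk == 1L, arr.ind = TRUE)
  n <- nrow(idx)
  if (n < 2L) return(0)
  d <- as.matrix(dist(idx))
  e <- which(d > 0 & d < 1.5, arr.ind = TRUE)
  e <- e[e[, 1] < e[, 2], , drop = FALSE]
  if (nrow(e) == 0L) return(0)
  g <- igraph::graph_from_data_frame(
    data.frame(from = e[, 1], to = e[, 2], weight = d[e]),
    directed = FALSE, vertices = data.frame(name = seq_len(n)))
  g <- igraph::mst(g)
  repeat {
    deg <- igraph::degree(g)
    pruned <- FALSE
    for (leaf in igraph::V(g)[deg == 1]) {
      branch <- integer(0)
      len <- 0
      cur <- leaf; prev <- 0L
      repeat {
        nb <- setdiff(as.integer(igraph::neighbors(g, cur)), prev)
        if (length(nb) == 0L) { cur <- 0L; break } # reached another leaf
        len <- len + igraph::E(g)[cur %--% nb[1]]$weight
        branch <- c(branch, as.integer(cur))
        prev <- as.integer(cur); cur <- nb[1]
        if (igraph::degree(g, cur) != 2L) break
      }
      at_junction <- length(cur) == 1L && cur != 0L && igraph::degree(g, cur) >= 3L
      if (at_junction && len < prune_bins) {
        g <- igraph::delete_vertices(g, branch)
        pruned <- TRUE
        break
      }
    }
    if (!pruned) break
  }
  sum(igraph::E(g)$weight)
}

#' Full per-field super-resolution analysis
#'
#' Chains the precision filter, optional drift correction, DBSCAN
#' clustering, per-cluster regionization and measurement into a table of
#' aggregate records for one localization table.
#'
#' @param locs localization table.
#' @param config an [pipeline_config()] object supplying all thresholds.
#' @param drift_correct run [estimate_and_correct_drift()] before
#'   clustering.
#' @param n_blocks temporal blocks for drift correction.
#' @return A list with `records` (one row per aggregate) and `labels` (the
#'   cluster label of every filtered localization).
#' @export
analyze_localizations <- function(locs, config = pipeline_config(),
                                  drift_correct = FALSE, n_blocks = 10L) {
  filt <- filter_localizations(locs,
                               max_precision_nm = config$max_precision_nm,
                               discard_first_frames = config$discard_first_frames,
                               pixel_size_nm = config$pixel_size_nm)
  if (drift_correct) {
    filt <- estimate_and_correct_drift(filt, n_blocks = n_blocks)$locs
  }
  labels <- cluster_localizations(filt, eps_px = config$eps_px,
                                  min_samples = config$min_samples)
  records <- list()
  for (cl in sort(unique(labels[labels > 0L]))) {
    sel <- labels == cl
    region <- regionize_cluster(cbind(filt$x[sel], filt$y[sel]),
                                render_px_nm = config$render_px_nm,
                                pixel_size_nm = config$pixel_size_nm,
                                radii = config$morph_radii)
    records[[length(records) + 1L]] <- measure_aggregate(region, id = cl)
  }
  records <- if (length(records)) do.call(rbind, records) else
    measure_aggregate(structure(list(mask = matrix(1L, 1, 1),
                                     render_px_nm = config$render_px_nm,
                                     n_loc = 1L), class = "aggregate_region"))[0, ]
  list(records = records, labels = labels)
}
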