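#' Build the standardized feature matrix for the disease signature
#'
#' Turns donor profiles into the observation matrix of the linear
#' discriminant analysis: one row per donor x region, the 15 signature
#' features as columns, each standardized to zero mean and unit variance
#' (the features mix nm, counts and proportions), and combined
#' region-cohort class labels (e.g. `cerebellum-CRL`).
#'
#' @param profiles output of [build_donor_profiles()] (or any data.frame
#'   with the feature columns plus `cohort` and `region`).
#' @param features character vector of feature columns.
#' @return A list with `x` (standardized matrix), `labels` (region-cohort
#'   factor), `features` (columns retained; zero-variance features are
#'   dropped with a warning).
#' @export
build_feature_matrix <- function(profiles,
                                 features = signature_features()) {
  missing <- setdiff(features, names(profiles))
  if (length(missing)) {
    stop("profiles are missing feature(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  x <- as.matrix(profiles[, features, drop = FALSE])
  if (any(!is.finite(x))) {
    bad <- features[colSums(!is.finite(x)) > 0]
    stop("non-finite values in feature(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  sds <- apply(x, 2, sd)
  if (any(sds == 0)) {
    warning("dropping zero-variance feature(s): ",
            paste(features[sds == 0], collapse = ", "))
    x <- x[, sds > 0, drop = FALSE]
    features <- features[sds > 0]
  }
  x <- scale(x)
  labels <- factor(paste(profiles$region, profiles$cohort, sep = "-"))
  list(x = x, labels = labels, features = features)
}

#' The 15 signature features
#'
#' Column names of the donor-profile features entering the disease
#' signature: mean assembly count, area, eccentricity, perimeter, minor and
#' major axis lengths, localization count, smoothed (skeleton) length,
#' localization density and scaled fluorescence intensity, plus the
#' proportions of assemblies classified bright, pSER-colocalized, fibrillar,
#' long and sparse.
#'
#' @return Character vector of length 15.
#' @export
signature_features <- function() {
  c("count", "mean_area_nm2", "mean_eccentricity", "mean_perimeter_nm",
    "mean_minor_axis_nm", "mean_major_axis_nm", "mean_n_localizations",
    "mean_length_nm", "mean_density", "mean_scaled_intensity",
    "prop_bright", "prop_pser", "prop_fibrillar", "prop_long", "prop_sparse")
}

#' Fit the linear discriminant signature
#'
#' Solves the within/between-class scatter eigenproblem of linear
#' discriminant analysis: discriminant directions are eigenvectors of
#' Sw^-1 Sb, where Sw is the pooled within-class scatter (ridge-regularized
#' by `ridge` x trace(Sw)/p when near-singular, as happens at small donor
#' numbers) and Sb the between-class scatter. Returns the projection onto
#' at most (number of classes - 1) discriminants, the explained-variance
#' ratio of each discriminant (its eigenvalue over the retained total,
#' non-increasing), and the per-feature coefficient matrix whose columns
#' act as pseudo-eigenvectors measuring each parameter's contribution to
#' the separation.
#'
#' @param x numeric observation matrix (rows = observations).
#' @param labels class labels (>= 2 classes, each non-empty; fewer classes
#'   than observations).
#' @param ridge relative ridge added to Sw when its condition is poor.
#' @return An object of class `aggregate_lda`: `projection`,
#'   `explained_variance`, `coefficients` (features x discriminants),
#'   `labels`, `class_means`, `center`, `features`.
#' @export
fit_lda <- function(x, labels, ridge = 1e-6) {
  x <- as.matrix(x)
  labels <- factor(labels)
  k <- nlevels(labels)
  if (k < 2L) stop("need at least 2 classes", call. = FALSE)
  if (nrow(x) <= k) stop("need more observations than classes", call. = FALSE)
  p <- ncol(x)
  mu <- colMeans(x)
  Sw <- matrix(0, p, p)
  Sb <- matrix(0, p, p)
  for (cl in levels(labels)) {
    xc <- x[labels == cl, , drop = FALSE]
    mc <- colMeans(xc)
    if (nrow(xc) > 1L) {
      cen <- sweep(xc, 2, mc)
      Sw <- Sw + crossprod(cen)
    }
    Sb <- Sb + nrow(xc) * tcrossprod(mc - mu)
  }
  if (rcond(Sw) < 1e-10) {
    Sw <- Sw + diag(ridge * sum(diag(Sw)) / p, p)
  }
  e <- eigen(solve(Sw, Sb))
  vals <- Re(e$values)
  vecs <- Re(e$vectors)
  n_d <- min(k - 1L, p)
  ord <- order(vals, decreasing = TRUE)[seq_len(n_d)]
  vals <- pmax(vals[ord], 0)
  W <- vecs[, ord, drop = FALSE]
  # unit-norm coefficients with a deterministic sign (largest |coef| > 0)
  for (j in seq_len(ncol(W))) {
    W[, j] <- W[, j] / sqrt(sum(W[, j]^2))
    lead <- which.max(abs(W[, j]))
    if (W[lead, j] < 0) W[, j] <- -W[, j]
  }
  rownames(W) <- colnames(x)
  colnames(W) <- paste0("LD", seq_len(n_d))
  proj <- sweep(x, 2, mu) %*% W
  colnames(proj) <- colnames(W)
  cm <- apply(proj, 2, function(col) tapply(col, labels, mean))
  structure(list(projection = proj,
                 explained_variance = vals / sum(vals),
                 coefficients = W,
                 labels = labels,
                 class_means = cm,
                 center = mu,
                 features = colnames(x)),
            class = "aggregate_lda")
}

#' @export
print.aggregate_lda <- function(x, ...) {
  ev <- round(100 * x$explained_variance, 1)
  cat("Linear discriminant signature:", nlevels(x$labels), "classes,",
      length(x$features), "features\n")
  cat("  explained variance:", paste0(colnames(x$coefficients), " = ",
                                      ev, "%", collapse = ", "), "\n")
  invisible(x)
}

#' Rank feature contributions per discriminant
#'
#' Orders the features by the absolute value of their discriminant
#' coefficients (pseudo-eigenvectors), the measure of each parameter's
#' relative contribution to class separation. Ties are broken by feature
#' name for a stable order.
#'
#' @param fit an `aggregate_lda` object.
#' @return A named list (one element per discriminant) of data.frames with
#'   `feature`, `coefficient`, `rank`.
#' @export
rank_contributions <- function(fit) {
  stopifnot(inherits(fit, "aggregate_lda"))
  out <- lapply(seq_len(ncol(fit$coefficients)), function(j) {
    co <- fit$coefficients[, j]
    ord <- order(-abs(co), names(co))
    data.frame(feature = names(co)[ord], coefficient = unname(co[ord]),
               rank = seq_along(co))
  })
  names(out) <- colnames(fit$coefficients)
  out
}

#' Leave-one-out nearest-centroid accuracy of the 2-D signature
#'
#' For each observation, refits the discriminant signature without it,
#' projects the held-out observation onto the first two discriminants, and
#' predicts the class with the nearest centroid. Used to quantify how well
#' the 2-D projection separates classes.
#'
#' @inheritParams fit_lda
#' @param collapse optional function applied to the predicted and true label
#'   strings before comparison (e.g. stripping the region prefix of a
#'   region-cohort label to score cohort identity only).
#' @return Fraction of observations whose predicted label matches (after
#'   `collapse`, when given).
#' @export
loo_nearest_centroid <- function(x, labels, ridge = 1e-6, collapse = identity) {
  x <- as.matrix(x)
  labels <- factor(labels)
  correct <- logical(nrow(x))
  for (i in seq_len(nrow(x))) {
    train_lab <- droplevels(labels[-i])
    fit <- fit_lda(x[-i, , drop = FALSE], train_lab, ridge)
    d2 <- min(2L, ncol(fit$coefficients))
    proj <- as.numeric((x[i, ] - fit$center) %*%
                         fit$coefficients[, 1:d2, drop = FALSE])
    cents <- as.matrix(apply(fit$projection[, 1:d2, drop = FALSE], 2,
                             function(col) tapply(col, train_lab, mean)))
    dist2 <- rowSums((cents - matrix(proj, nrow(cents), d2, byrow = TRUE))^2)
    pred <- rownames(cents)[which.min(dist2)]
    correct[i] <- collapse(pred) == collapse(as.character(labels[i]))
  }
  mean(correct)
}
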