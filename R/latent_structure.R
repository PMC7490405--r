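# Latent structure of the adherence measures: column scaling regimes and
# principal component analysis with a cumulative-variance component rule.

#' Scale a measure matrix under one of three regimes
#'
#' `center_only` subtracts each column mean; `unit_variance` additionally
#' divides by the column spread; `min_max` maps each column linearly onto
#' `[0, 1]`. Fitted parameters are returned so the transform is reproducible
#' and invertible.
#'
#' @param m Numeric matrix (>= 2 rows, no missing entries).
#' @param method One of `"center_only"`, `"unit_variance"`, `"min_max"`.
#' @param denominator For `unit_variance`: `"sd"` (default) divides by the
#'   population standard deviation, `"variance"` divides by the variance.
#' @return List with `scaled` (matrix) and `scaling` (an object of class
#'   `scaling_method` holding the method and fitted per-column parameters).
#' @export
scale_measures <- function(m, method = c("center_only", "unit_variance",
                                         "min_max"),
                           denominator = c("sd", "variance")) {
  method <- match.arg(method)
  denominator <- match.arg(denominator)
  m <- as.matrix(m)
  if (nrow(m) < 2) stop("need at least two rows to fit scaling", call. = FALSE)
  if (anyNA(m)) stop("measure matrix contains missing values", call. = FALSE)
  mu <- colMeans(m)
  centered <- sweep(m, 2, mu)
  if (method == "center_only") {
    scaled <- centered
    params <- list(mean = mu)
  } else if (method == "unit_variance") {
    # population (divide-by-n) variance; see package vignette
    v <- colMeans(centered^2)
    spread <- if (denominator == "sd") sqrt(v) else v
    zero <- spread <= 0
    if (any(zero)) {
      stop("zero-spread column(s) under unit_variance scaling: ",
           paste(colnames(m)[zero], collapse = ", "), call. = FALSE)
    }
    scaled <- sweep(centered, 2, spread, "/")
    params <- list(mean = mu, spread = spread, denominator = denominator)
  } else {
    lo <- apply(m, 2, min)
    hi <- apply(m, 2, max)
    const <- hi - lo <= 0
    if (any(const)) {
      stop("constant column(s) under min_max scaling: ",
           paste(colnames(m)[const], collapse = ", "), call. = FALSE)
    }
    scaled <- sweep(sweep(m, 2, lo), 2, hi - lo, "/")
    params <- list(min = lo, max = hi)
  }
  scaling <- structure(c(list(method = method), params),
                       class = "scaling_method")
  list(scaled = scaled, scaling = scaling)
}

#' Principal component analysis of a scaled measure matrix
#'
#' Components are ordered by decreasing explained variance and each
#' component's sign is flipped, if needed, so that the first measure
#' (percentage of doses taken) loads non-negatively — PCA signs are
#' arbitrary and this fixes a reproducible orientation in which good
#' adherence points the same way on every component.
#'
#' @param scaled Centered (optionally scaled) numeric matrix, patients in
#'   rows.
#' @param scaling Optional `scaling_method` used to produce `scaled`;
#'   recorded in the result.
#' @return Object of class `pca_result` with `rotation` (orthonormal
#'   variables x components basis), `cor_loadings` (variable-component
#'   correlations, the +/-1-bounded loadings conventionally reported),
#'   `variance_explained` (fractions summing to 1), `sdev`, `scores`
#'   (patients x components) and `n_components_95`.
#' @export
fit_pca <- function(scaled, scaling = NULL) {
  scaled <- as.matrix(scaled)
  if (nrow(scaled) < 2) stop("need at least two rows for PCA", call. = FALSE)
  # principal components of the covariance of the scaled matrix: centering
  # here is idempotent for the center_only / unit_variance regimes and
  # supplies the centering min_max leaves to the PCA step
  p <- stats::prcomp(scaled, center = TRUE, scale. = FALSE)
  rotation <- p$rotation
  scores <- p$x
  # orient components so measure A (row 1) loads non-negatively; if its
  # loading is zero, use the first non-zero loading in the column
  for (j in seq_len(ncol(rotation))) {
    pivot <- rotation[, j][abs(rotation[, j]) > 1e-12]
    if (length(pivot) && pivot[1] < 0) {
      rotation[, j] <- -rotation[, j]
      scores[, j] <- -scores[, j]
    }
  }
  ve <- p$sdev^2 / sum(p$sdev^2)
  # variable-component correlations (Table-style loadings); undefined for
  # degenerate zero-variance columns or components
  suppressWarnings(cl <- stats::cor(scaled, scores))
  cl[!is.finite(cl)] <- 0
  res <- structure(
    list(rotation = rotation, cor_loadings = cl,
         variance_explained = ve, sdev = p$sdev, scores = scores,
         center = p$center, scaling = scaling,
         n_components_95 = NA_integer_),
    class = "pca_result"
  )
  res$n_components_95 <- select_components(res, threshold = 0.95)
  res
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("<pca_result> %d components; variance explained: %s\n",
              length(x$variance_explained),
              paste(sprintf("%.1f%%", 100 * x$variance_explained),
                    collapse = ", ")))
  cat(sprintf("  components for >=95%% variance: %d\n", x$n_components_95))
  invisible(x)
}

#' Number of components needed to reach a cumulative variance threshold
#'
#' @param result A `pca_result` (or anything with a `variance_explained`
#'   field).
#' @param threshold Cumulative variance fraction in (0, 1]; default 0.95.
#' @return The smallest m such that the first m components explain at least
#'   `threshold` of the variance.
#' @export
select_components <- function(result, threshold = 0.95) {
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      threshold <= 0 || threshold > 1) {
    stop("`threshold` must be in (0, 1]", call. = FALSE)
  }
  ve <- result$variance_explained
  stopifnot(is.numeric(ve), length(ve) >= 1)
  cum <- cumsum(ve)
  m <- which(cum >= threshold - 1e-12)[1]
  if (is.na(m)) m <- length(ve)  # guard against rounding shortfall
  as.integer(m)
}

#' Component scores retained for clustering
#'
#' @param result A `pca_result`.
#' @param n_components Number of leading components; defaults to the
#'   >=95%-variance count.
#' @return Matrix of scores (patients x retained components).
#' @export
retained_scores <- function(result, n_components = result$n_components_95) {
  result$scores[, seq_len(n_components), drop = FALSE]
}

#' Loadings and variance-explained table
#'
#' @param result A `pca_result`.
#' @param loadings `"correlation"` (default, +/-1-bounded entries) or
#'   `"rotation"` (orthonormal basis).
#' @return Data frame: one row per measure plus a final
#'   `variance explained (%)` row, one column per component.
#' @export
pca_table <- function(result, loadings = c("correlation", "rotation")) {
  loadings <- match.arg(loadings)
  L <- if (loadings == "correlation") result$cor_loadings else
    result$rotation
  tab <- as.data.frame(round(L, 2))
  names(tab) <- paste0("PC", seq_len(ncol(L)))
  tab <- rbind(tab, round(100 * result$variance_explained, 1))
  rownames(tab) <- c(rownames(L), "variance explained (%)")
  tab
}
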