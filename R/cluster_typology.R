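# Cluster typology over principal-component scores: seeded k-means with
# multiple random initialisations, elbow selection of k from the
# within-group sum-of-squares curve, bootstrap Jaccard stability with
# dissolution rates, and stability-based selection of the scaling regime.

# k-means core: consumes the current RNG stream. Best of n_init random
# initialisations by total within-group sum of squares.
kmeans_core <- function(x, k, n_init = 25L, iter_max = 100L) {
  x <- as.matrix(x)
  n_distinct <- nrow(unique(x))
  if (k > n_distinct) {
    stop(sprintf("k = %d exceeds the %d distinct points", k, n_distinct),
         call. = FALSE)
  }
  if (k == n_distinct) {
    # every distinct point is its own centroid; stats::kmeans rejects k = n
    centers <- unique(x)
    key <- apply(x, 1, paste, collapse = "\r")
    labels <- match(key, unique(key))
    names(labels) <- rownames(x)
    return(structure(
      list(k = as.integer(k), labels = labels, centroids = centers,
           wss_total = 0, n_init = as.integer(n_init)),
      class = "cluster_solution"))
  } else {
    fit <- NULL
    for (attempt in seq_len(10L)) {
      fit <- tryCatch(
        stats::kmeans(x, centers = k, nstart = n_init, iter.max = iter_max),
        error = function(e) NULL)  # duplicate sampled centers; redraw
      if (!is.null(fit)) break
    }
    if (is.null(fit)) stop("k-means failed to initialise", call. = FALSE)
  }
  labels <- fit$cluster
  names(labels) <- rownames(x)
  structure(
    list(k = as.integer(k), labels = labels, centroids = fit$centers,
         wss_total = fit$tot.withinss, n_init = as.integer(n_init)),
    class = "cluster_solution"
  )
}

#' Seeded k-means with multiple random initialisations
#'
#' Runs `n_init` random initialisations and keeps the solution with the
#' lowest total within-group sum of squares; deterministic given `seed`.
#'
#' @param scores Numeric matrix, patients in rows (rownames used as patient
#'   identifiers).
#' @param k Number of clusters (1 <= k <= number of distinct points).
#' @param n_init Number of random initialisations (default 25).
#' @param seed Integer seed.
#' @return A `cluster_solution`: `k`, `labels` (named by patient),
#'   `centroids`, `wss_total`, `n_init`.
#' @export
kmeans_fit <- function(scores, k, n_init = 25L, seed = 1L) {
  assert_count(k, "k", min = 1L)
  with_seed(seed, kmeans_core(scores, k, n_init))
}

#' @export
print.cluster_solution <- function(x, ...) {
  cat(sprintf("<cluster_solution> k = %d, n = %d, WSS = %.4g (sizes: %s)\n",
              x$k, length(x$labels), x$wss_total,
              paste(tabulate(x$labels, x$k), collapse = ", ")))
  invisible(x)
}

#' Within-group sum-of-squares curve over a range of k
#'
#' The scree curve used to choose the number of clusters. Each k is fitted
#' with `n_init` random initialisations; if a solution breaks monotone
#' non-increase of the curve it is refitted with four times as many
#' initialisations.
#'
#' @inheritParams kmeans_fit
#' @param k_range Integer vector of cluster counts (default `1:15`,
#'   truncated to n - 1).
#' @return Object of class `wss_curve`: data frame `k`, `wss`.
#' @export
wss_curve <- function(scores, k_range = 1:15, n_init = 25L, seed = 1L) {
  scores <- as.matrix(scores)
  k_range <- sort(unique(as.integer(k_range)))
  if (min(k_range) < 1 || max(k_range) > nrow(scores) - 1) {
    stop("k_range must lie within [1, n - 1]", call. = FALSE)
  }
  n_distinct <- nrow(unique(scores))
  k_range <- k_range[k_range <= n_distinct]
  wss <- with_seed(seed, {
    out <- numeric(length(k_range))
    for (i in seq_along(k_range)) {
      sol <- kmeans_core(scores, k_range[i], n_init)
      if (i > 1 && sol$wss_total > out[i - 1] + 1e-8) {
        sol2 <- kmeans_core(scores, k_range[i], 4L * n_init)
        if (sol2$wss_total < sol$wss_total) sol <- sol2
      }
      out[i] <- sol$wss_total
    }
    out
  })
  structure(data.frame(k = k_range, wss = wss),
            class = c("wss_curve", "data.frame"))
}

#' Elbow selection of the number of clusters
#'
#' Automates the visual scree-plot reading: after min-max normalizing both
#' axes, returns the k whose curve point lies farthest (perpendicular
#' distance) from the chord joining the first and last points. Ties are
#' broken toward smaller k; a flat curve returns 1 with a warning; an
#' `override` reproduces analyst judgement.
#'
#' @param curve A `wss_curve`.
#' @param override Optional integer: return this k regardless of the curve.
#' @return Selected number of clusters.
#' @export
select_k_elbow <- function(curve, override = NULL) {
  if (!is.null(override)) return(assert_count(override, "override", 1L))
  k <- curve$k
  w <- curve$wss
  if (length(k) < 3) stop("need at least 3 points on the curve", call. = FALSE)
  if (diff(range(w)) <= 1e-12) {
    warning("flat WSS curve; returning k = 1", call. = FALSE)
    return(1L)
  }
  x <- (k - k[1]) / (k[length(k)] - k[1])
  y <- (w - min(w)) / (max(w) - min(w))
  x1 <- x[1]; y1 <- y[1]
  xn <- x[length(x)]; yn <- y[length(y)]
  dist <- abs((yn - y1) * x - (xn - x1) * y + xn * y1 - yn * x1) /
    sqrt((yn - y1)^2 + (xn - x1)^2)
  interior <- seq(2L, length(k) - 1L)
  if (max(dist[interior]) <= 1e-12) {
    warning("degenerate (linear) WSS curve; returning smallest interior k",
            call. = FALSE)
    return(k[interior[1]])
  }
  k[interior[which.max(dist[interior])]]
}

#' Jaccard similarity between two sets of patient identifiers
#'
#' @param set_a,set_b Vectors of identifiers (duplicates ignored).
#' @return `|intersection| / |union|`; 0 when both sets are empty.
#' @export
jaccard <- function(set_a, set_b) {
  a <- unique(set_a)
  b <- unique(set_b)
  u <- length(union(a, b))
  if (u == 0) return(0)
  length(intersect(a, b)) / u
}

#' Bootstrap stability of a k-means solution
#'
#' For each bootstrap replicate, patients are resampled with replacement and
#' re-clustered; each full-sample cluster — restricted to the patients
#' present in the resample — is matched to the resample cluster with the
#' highest Jaccard similarity. A cluster is dissolved in a replicate when
#' that best-match Jaccard falls below `dissolution_threshold`.
#'
#' @inheritParams kmeans_fit
#' @param n_bootstrap Number of bootstrap replicates (default 1000).
#' @param dissolution_threshold Jaccard value below which a cluster counts
#'   as dissolved (default 0.5).
#' @param solution Optional precomputed full-sample `cluster_solution`;
#'   fitted internally when `NULL`.
#' @return Object of class `stability_report`: `k`, `n_bootstrap`,
#'   per-cluster `mean_jaccard` and `dissolution_rate`, the full-sample
#'   `solution`, and the replicate-level `jaccard` matrix.
#' @export
bootstrap_stability <- function(scores, k, n_bootstrap = 1000L,
                                n_init = 25L, seed = 1L,
                                dissolution_threshold = 0.5,
                                solution = NULL) {
  assert_count(n_bootstrap, "n_bootstrap", min = 1L)
  scores <- as.matrix(scores)
  n <- nrow(scores)
  ids <- rownames(scores)
  if (is.null(ids)) ids <- as.character(seq_len(n))

  with_seed(seed, {
    if (is.null(solution)) solution <- kmeans_core(scores, k, n_init)
    orig_sets <- split(ids, solution$labels)
    jac <- matrix(NA_real_, n_bootstrap, solution$k)
    for (b in seq_len(n_bootstrap)) {
      idx <- sample.int(n, n, replace = TRUE)
      boot <- kmeans_core(scores[idx, , drop = FALSE], k, n_init)
      boot_sets <- split(ids[idx], boot$labels)
      present <- unique(ids[idx])
      for (i in seq_along(orig_sets)) {
        restricted <- intersect(orig_sets[[i]], present)
        jac[b, i] <- max(vapply(boot_sets, jaccard, numeric(1),
                                set_b = restricted))
      }
    }
    structure(
      list(k = solution$k, n_bootstrap = as.integer(n_bootstrap),
           mean_jaccard = colMeans(jac),
           dissolution_rate = colMeans(jac < dissolution_threshold),
           dissolution_threshold = dissolution_threshold,
           solution = solution, jaccard = jac),
      class = "stability_report"
    )
  })
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf("<stability_report> k = %d, %d bootstrap replicates\n",
              x$k, x$n_bootstrap))
  for (i in seq_len(x$k)) {
    cat(sprintf("  cluster %d: mean Jaccard %.3f, dissolution rate %.3f\n",
                i, x$mean_jaccard[i], x$dissolution_rate[i]))
  }
  invisible(x)
}

#' Select the scaling regime that yields the most stable clusters
#'
#' Runs the full chain — scaling, PCA, component retention by the
#' cumulative-variance rule, elbow selection of k, bootstrap stability —
#' once per candidate scaling method, and returns the method whose clusters
#' have the highest mean (over clusters) of the per-cluster mean Jaccard
#' similarity. Ties are broken by lower mean dissolution rate, then by the
#' order methods are supplied.
#'
#' @param m Patients x measures matrix (see [cohort_measure_matrix()]).
#' @param methods Scaling methods to compare.
#' @param variance_threshold Cumulative variance fraction for component
#'   retention (default 0.95).
#' @param k_range Candidate cluster counts (default `1:15`).
#' @param n_init Random initialisations per k-means fit (default 25).
#' @param n_bootstrap Bootstrap replicates per method (default 1000).
#' @param seed Integer seed governing k-means and bootstrap streams.
#' @param k_override Optional fixed k bypassing elbow selection.
#' @param dissolution_threshold Jaccard dissolution cut-off (default 0.5).
#' @param denominator Spread definition for `unit_variance` scaling.
#' @return List with `best` (winning method name) and `per_method`, a named
#'   list holding, for each method, the `scaling`, `pca`, retained `scores`,
#'   `wss_curve`, selected `k`, full-sample `solution` and
#'   `stability` report.
#' @export
select_scaling <- function(m, methods = c("center_only", "unit_variance",
                                          "min_max"),
                           variance_threshold = 0.95,
                           k_range = 1:15, n_init = 25L,
                           n_bootstrap = 1000L, seed = 1L,
                           k_override = NULL,
                           dissolution_threshold = 0.5,
                           denominator = "sd") {
  stopifnot(length(methods) >= 1)
  seeds <- with_seed(seed,
                     sample.int(.Machine$integer.max - 1L,
                                2L * length(methods)))
  per_method <- list()
  for (i in seq_along(methods)) {
    method <- methods[i]
    sc <- scale_measures(m, method, denominator = denominator)
    pca <- fit_pca(sc$scaled, sc$scaling)
    n_comp <- select_components(pca, variance_threshold)
    scores <- retained_scores(pca, n_comp)
    curve <- wss_curve(scores, k_range, n_init, seed = seeds[2 * i - 1])
    k <- select_k_elbow(curve, override = k_override)
    stab <- bootstrap_stability(scores, k, n_bootstrap, n_init,
                                seed = seeds[2 * i],
                                dissolution_threshold = dissolution_threshold)
    per_method[[method]] <- list(
      scaling = sc$scaling, pca = pca, n_components = n_comp,
      scores = scores, wss_curve = curve, k = k,
      solution = stab$solution, stability = stab)
  }
  mean_jac <- vapply(per_method, function(x) mean(x$stability$mean_jaccard),
                     numeric(1))
  mean_diss <- vapply(per_method,
                      function(x) mean(x$stability$dissolution_rate),
                      numeric(1))
  best <- order(-mean_jac, mean_diss, seq_along(per_method))[1]
  list(best = methods[best], per_method = per_method,
       mean_jaccard = mean_jac, mean_dissolution = mean_diss)
}

#' Renumber clusters by ascending adherence
#'
#' Relabels clusters 1..k by ascending within-cluster median of the
#' percentage of doses taken (measure A), so cluster 1 is always the
#' poorest-adherence group. Ties are broken by cluster size, descending.
#'
#' @param solution A `cluster_solution`.
#' @param profiles Adherence profiles covering every clustered patient.
#' @return The solution with relabelled `labels` and reordered `centroids`.
#' @export
order_clusters <- function(solution, profiles) {
  stopifnot(inherits(solution, "cluster_solution"))
  ids <- names(solution$labels)
  if (is.null(ids) || !all(ids %in% profiles$patient_id)) {
    stop("profiles must cover every clustered patient", call. = FALSE)
  }
  a <- profiles$A[match(ids, profiles$patient_id)]
  med_a <- vapply(split(a, solution$labels), stats::median, numeric(1))
  size <- tabulate(solution$labels, solution$k)
  perm <- order(med_a, -size[as.integer(names(med_a))])
  # perm[j] = old cluster that becomes new cluster j
  relabel <- integer(solution$k)
  relabel[as.integer(names(med_a))[perm]] <- seq_len(solution$k)
  solution$labels <- stats::setNames(relabel[solution$labels], ids)
  solution$centroids <- solution$centroids[as.integer(names(med_a))[perm], ,
                                           drop = FALSE]
  rownames(solution$centroids) <- seq_len(solution$k)
  solution
}
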