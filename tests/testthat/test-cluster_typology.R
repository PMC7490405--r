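test_that("k-means fits satisfy their boundary contracts", {
  set.seed(6)
  x <- matrix(rnorm(60), 30, 2)
  rownames(x) <- paste0("P", 1:30)

  s1 <- kmeans_fit(x, 1, seed = 1)
  tss <- sum(sweep(x, 2, colMeans(x))^2)
  expect_equal(s1$wss_total, tss, tolerance = 1e-8)

  # two tight far-separated groups are recovered exactly
  y <- rbind(matrix(rnorm(30, 0, 0.1), 15, 2),
             matrix(rnorm(30, 50, 0.1), 15, 2))
  rownames(y) <- paste0("Q", 1:30)
  s2 <- kmeans_fit(y, 2, seed = 2)
  expect_equal(length(unique(s2$labels[1:15])), 1)
  expect_equal(length(unique(s2$labels[16:30])), 1)
  expect_false(s2$labels[1] == s2$labels[16])

  # k = n distinct points -> zero within-group scatter
  sn <- kmeans_fit(x, nrow(x), seed = 3)
  expect_equal(sn$wss_total, 0, tolerance = 1e-10)
  expect_error(kmeans_fit(x, nrow(x) + 1, seed = 3), "distinct")

  # wss equals the summed squared distances to assigned centroids
  s3 <- kmeans_fit(x, 4, seed = 4)
  d <- sum((x - s3$centroids[s3$labels, ])^2)
  expect_equal(s3$wss_total, d, tolerance = 1e-8)

  # determinism
  expect_identical(kmeans_fit(x, 3, seed = 9), kmeans_fit(x, 3, seed = 9))
})

test_that("the WSS curve is deterministic and non-increasing", {
  pc <- make_processed_cohort(n_patients = 80, seed = 8)
  sc <- scale_measures(pc$measures, "unit_variance")
  scores <- retained_scores(fit_pca(sc$scaled))
  c1 <- wss_curve(scores, 1:15, n_init = 25, seed = 77)
  c2 <- wss_curve(scores, 1:15, n_init = 25, seed = 77)
  expect_identical(c1, c2)
  expect_true(all(diff(c1$wss) <= 1e-8))
  expect_error(wss_curve(scores, 1:200), "1, n - 1")
})

test_that("elbow selection finds the documented knees", {
  mk <- function(k, w) structure(data.frame(k = k, wss = w),
                                 class = c("wss_curve", "data.frame"))
  # frozen worked example: normalized chord distances peak at k = 3
  expect_equal(select_k_elbow(mk(1:5, c(100, 50, 2, 1.5, 1))), 3)
  # flat curve
  expect_warning(kf <- select_k_elbow(mk(1:5, rep(4, 5))), "flat")
  expect_equal(kf, 1)
  # strictly linear curve: degenerate geometry, smallest interior k
  expect_warning(kl <- select_k_elbow(mk(1:5, c(50, 40, 30, 20, 10))),
                 "linear")
  expect_equal(kl, 2)
  # manual override wins regardless of the curve
  expect_equal(select_k_elbow(mk(1:5, c(100, 50, 2, 1.5, 1)),
                              override = 5), 5)
  expect_error(select_k_elbow(mk(1:2, c(2, 1))), "at least 3")
})

test_that("jaccard similarity behaves as a set overlap measure", {
  expect_equal(jaccard(c(1, 2, 3), c(2, 3, 4)), 0.5)
  expect_equal(jaccard(letters[1:3], letters[1:3]), 1)
  expect_equal(jaccard(1:3, 4:6), 0)
  expect_equal(jaccard(integer(), integer()), 0)
  expect_equal(jaccard(c(1, 1, 2), c(2, 2, 1)), 1)  # duplicates ignored
  set.seed(10)
  for (i in 1:50) {
    a <- sample(1:20, sample(0:10, 1))
    b <- sample(1:20, sample(0:10, 1))
    expect_equal(jaccard(a, b), jaccard(b, a))
    expect_true(jaccard(a, b) >= 0 && jaccard(a, b) <= 1)
    if (length(a) && jaccard(a, b) == 1) expect_setequal(a, b)
  }
})

test_that("bootstrap stability separates real from spurious clusters", {
  set.seed(99)
  x <- rbind(matrix(rnorm(100, 0, 0.5), 50, 2),
             matrix(rnorm(100, 10, 0.5), 50, 2),
             matrix(rnorm(100, 20, 0.5), 50, 2))
  rownames(x) <- paste0("P", 1:150)
  st <- bootstrap_stability(x, 3, n_bootstrap = 60, n_init = 10, seed = 11)
  expect_true(all(st$mean_jaccard >= 0.95))
  expect_true(all(st$dissolution_rate <= 0.01))

  u <- matrix(runif(500), 100, 5)
  rownames(u) <- paste0("U", 1:100)
  su <- bootstrap_stability(u, 3, n_bootstrap = 60, n_init = 10, seed = 12)
  expect_gt(max(su$dissolution_rate), 0.2)

  expect_error(bootstrap_stability(x, 3, n_bootstrap = 0), "n_bootstrap")
})

test_that("scaling selection returns the stability argmax with full reports", {
  pc <- make_processed_cohort(n_patients = 80, seed = 14)
  sel <- select_scaling(pc$measures,
                        methods = c("center_only", "unit_variance"),
                        n_bootstrap = 40, seed = 5)
  expect_true(sel$best %in% c("center_only", "unit_variance"))
  expect_equal(sel$best, names(which.max(sel$mean_jaccard)))
  for (pm in sel$per_method) {
    expect_s3_class(pm$stability, "stability_report")
    expect_true(all(pm$stability$mean_jaccard >= 0 &
                      pm$stability$mean_jaccard <= 1))
  }
  # single method supplied -> returned as best
  one <- select_scaling(pc$measures, methods = "min_max",
                        n_bootstrap = 5, seed = 5)
  expect_equal(one$best, "min_max")
})

test_that("clusters are renumbered by ascending median adherence", {
  pc <- make_processed_cohort(n_patients = 90, seed = 19)
  sc <- scale_measures(pc$measures, "unit_variance")
  scores <- retained_scores(fit_pca(sc$scaled))
  sol <- order_clusters(kmeans_fit(scores, 3, seed = 31), pc$profiles)
  med <- vapply(split(pc$profiles$A[match(names(sol$labels),
                                          pc$profiles$patient_id)],
                      sol$labels), stats::median, numeric(1))
  expect_equal(names(med), c("1", "2", "3"))
  expect_true(all(diff(med) > 0))

  # k = 1 is an identity relabelling
  s1 <- kmeans_fit(scores, 1, seed = 31)
  expect_equal(unname(order_clusters(s1, pc$profiles)$labels),
               unname(s1$labels))
})
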