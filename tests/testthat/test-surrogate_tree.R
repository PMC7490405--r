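test_that("partition sizes follow nearest-integer allocation with remainder to training", {
  ids <- sprintf("P%03d", 1:211)
  sp <- split_data(ids, seed = 1)
  expect_equal(length(sp$test), 32)        # round(0.15 * 211)
  expect_equal(length(sp$validation), 32)
  expect_equal(length(sp$train), 147)      # 211 - 32 - 32
  expect_setequal(c(sp$train, sp$validation, sp$test), ids)
  expect_equal(anyDuplicated(c(sp$train, sp$validation, sp$test)), 0)

  all_train <- split_data(ids, fractions = c(train = 1, test = 0), seed = 1)
  expect_equal(length(all_train$train), 211)

  two_way <- split_data(ids, fractions = c(train = 0.7, test = 0.3),
                        seed = 1)
  expect_equal(length(two_way$test), round(0.3 * 211))

  expect_error(split_data(ids, fractions = c(0.7, 0.2)), "sum to 1")
  expect_identical(split_data(ids, seed = 4), split_data(ids, seed = 4))
})

test_that("trees recover separable thresholds and degrade gracefully", {
  # one threshold separates the labels perfectly
  x <- c(seq(1, 10, length.out = 30), seq(20, 30, length.out = 30))
  y <- rep(c("lo", "hi"), each = 30)
  tr <- fit_cart(x, y, cart_params(), seed = 2)
  cm <- evaluate(tr, x, y)
  expect_equal(accuracy(cm), 1)

  # constant measure: no admissible split, majority class everywhere
  const <- fit_cart(rep(3.3, 40), rep(c("a", "b"), c(25, 15)),
                    cart_params(), seed = 2)
  expect_equal(as.character(unique(predict(const, c(1, 3.3, 9)))), "a")

  # under min_split patients: root-only tree with a warning
  expect_warning(small <- fit_cart(1:10, rep(c("a", "b"), 5),
                                   cart_params(), seed = 2),
                 "root-only")
  expect_equal(as.character(unique(predict(small, 1:10))), "a")
})

test_that("a depth-2 tree recovers two well-separated thresholds", {
  # labels defined by thresholds at 35 and 75 with wide gaps
  set.seed(33)
  x <- c(runif(20, 5, 30), runif(20, 40, 70), runif(20, 80, 100))
  y <- rep(c("1", "2", "3"), each = 20)
  tr <- fit_cart(x, y, cart_params(min_split = 10, min_leaf = 3), seed = 3)
  expect_equal(accuracy(evaluate(tr, x, y)), 1)
  # recovered thresholds lie inside the construction gaps
  thr <- sort(c(tree_thresholds <- local({
    node <- adhertype:::tree_to_list(tr)
    th <- c()
    walk <- function(nd) {
      if (nd$type == "split") {
        th <<- c(th, nd$threshold)
        walk(nd$left); walk(nd$right)
      }
    }
    walk(node)
    th
  })))
  expect_equal(length(thr), 2)
  expect_true(thr[1] > 30 && thr[1] < 40)
  expect_true(thr[2] > 70 && thr[2] < 80)
})

test_that("depth-1 trees match the exhaustive Gini threshold oracle", {
  set.seed(44)
  params <- cart_params(min_split = 4, min_leaf = 2, max_depth = 1,
                        cv_folds = 5)
  n_compared <- 0
  for (i in 1:40) {
    n <- sample(30:200, 1)
    k <- sample(2:3, 1)
    centers <- sort(runif(k, 0, 100))
    y <- sample(seq_len(k), n, replace = TRUE)
    x <- rnorm(n, centers[y], 12)
    tr <- fit_cart(x, factor(y), params, seed = i)
    if (is.null(tr$fit) || nrow(tr$fit$frame) == 1) next  # pruned to root
    got <- adhertype:::tree_to_list(tr)
    want <- oracle_best_split(x, y, min_leaf = 2)
    expect_equal(split_impurity(x, y, got$threshold), want$impurity,
                 tolerance = 1e-9)
    n_compared <- n_compared + 1
  }
  expect_gte(n_compared, 30)  # the comparison must actually exercise splits
})

test_that("the best measure is selected by validation accuracy with A-E tie order", {
  pc <- make_processed_cohort(n_patients = 90, seed = 55)
  sc <- scale_measures(pc$measures, "unit_variance")
  sol <- order_clusters(
    kmeans_fit(retained_scores(fit_pca(sc$scaled)), 3, seed = 6),
    pc$profiles)
  sp <- split_data(pc$profiles$patient_id, seed = 7)
  sel <- select_best_measure(pc$profiles, sol$labels, sp, cart_params(),
                             seed = 8)
  expect_equal(sel$best_measure,
               names(sel$validation_accuracy)[
                 which.max(sel$validation_accuracy)])
  expect_length(sel$trees, 5)
  # ties break toward the earlier measure: duplicate measure columns give
  # identical accuracies, so the first must win
  prof2 <- pc$profiles
  prof2$B <- prof2$A
  sel2 <- select_best_measure(prof2, sol$labels, sp, cart_params(),
                              seed = 8, measures = c("A", "B"))
  expect_equal(sel2$validation_accuracy[["A"]],
               sel2$validation_accuracy[["B"]])
  expect_equal(sel2$best_measure, "A")
})

test_that("confusion matrices and accuracy follow their definitions", {
  x <- c(1, 2, 3, 10, 11)
  y <- c("a", "a", "a", "b", "b")
  tr <- fit_cart(x, y, cart_params(min_split = 2, min_leaf = 1), seed = 9)
  cm <- evaluate(tr, x, y)
  expect_equal(sum(cm), 5)
  expect_equal(sum(diag(cm)), 5)
  expect_equal(accuracy(cm), 1)

  # single-class truth occupies one column
  cm1 <- evaluate(tr, c(1, 2), c("a", "a"))
  expect_equal(sum(cm1[, "a"]), 2)
  expect_equal(sum(cm1) - sum(cm1[, "a"]), 0)

  expect_error(evaluate(tr, numeric(), character()), "empty")
  expect_equal(accuracy(matrix(c(3, 0, 0, 4), 2)), 1)
  expect_equal(accuracy(matrix(c(0, 2, 5, 0), 2)), 0)
  expect_error(accuracy(matrix(0, 2, 2)), "empty")
})

test_that("tree export is consistent between text and JSON forms", {
  x <- c(seq(1, 10, length.out = 30), seq(20, 30, length.out = 30))
  y <- rep(c("lo", "hi"), each = 30)
  tr <- fit_cart(x, y, cart_params(), seed = 2, measure = "A")
  txt <- tree_to_text(tr)
  expect_true(any(grepl("^if A < ", txt)))
  js <- jsonlite::fromJSON(tree_to_json(tr), simplifyVector = FALSE)
  expect_equal(js$type, "split")
  expect_equal(js$measure, "A")
  expect_true(js$left$type == "leaf" || js$right$type == "leaf")
})
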