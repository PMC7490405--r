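# Single-measure CART surrogate for cluster membership.
#
# One shallow classification tree is grown per adherence measure against the
# cluster labels; the measure whose tree best predicts held-out labels
# becomes the interpretable surrogate for the full multi-measure typology.
# Trees are grown with rpart (Gini impurity, midpoint thresholds) under the
# protocol constraints, and pruned at the complexity parameter minimizing
# seeded, label-stratified 10-fold cross-validated misclassification.

#' CART protocol constraints
#'
#' @param min_split Minimum patients at a node for a split to be considered
#'   (default 20).
#' @param min_leaf Minimum patients at any terminal node (default 6).
#' @param max_depth Maximum number of split levels below the root
#'   (default 2, i.e. at most 4 leaves).
#' @param cv_folds Folds for complexity-parameter cross-validation
#'   (default 10).
#' @return Object of class `cart_params`.
#' @export
cart_params <- function(min_split = 20L, min_leaf = 6L, max_depth = 2L,
                        cv_folds = 10L) {
  assert_count(min_split, "min_split", 2L)
  assert_count(min_leaf, "min_leaf", 1L)
  assert_count(max_depth, "max_depth", 1L)
  assert_count(cv_folds, "cv_folds", 2L)
  structure(list(min_split = as.integer(min_split),
                 min_leaf = as.integer(min_leaf),
                 max_depth = as.integer(max_depth),
                 cv_folds = as.integer(cv_folds)),
            class = "cart_params")
}

#' Random partition of patients into train / validation / test sets
#'
#' Assignment is uniform at random and unstratified. Partition sizes are the
#' nearest-integer allocations of the fractions, with the rounding remainder
#' absorbed by the first (training) partition; with the default fractions
#' and n = 211 this yields 147 / 32 / 32.
#'
#' @param ids Patient identifiers.
#' @param fractions Named fractions summing to 1 (default
#'   `c(train = 0.70, validation = 0.15, test = 0.15)`; use
#'   `c(train = 0.70, test = 0.30)` for a two-way split).
#' @param seed Integer seed.
#' @return Object of class `data_split`: named list of id vectors plus the
#'   `fractions` and `seed` used.
#' @export
split_data <- function(ids, fractions = c(train = 0.70, validation = 0.15,
                                          test = 0.15),
                       seed = 1L) {
  if (abs(sum(fractions) - 1) > 1e-9 || any(fractions < 0)) {
    stop("`fractions` must be non-negative and sum to 1", call. = FALSE)
  }
  if (is.null(names(fractions))) {
    names(fractions) <- paste0("part", seq_along(fractions))
  }
  n <- length(ids)
  sizes <- round(fractions * n)
  sizes[1] <- n - sum(sizes[-1])
  if (sizes[1] < 0) stop("fraction rounding left a negative partition",
                         call. = FALSE)
  perm <- with_seed(seed, sample(ids))
  bounds <- cumsum(sizes)
  parts <- list()
  start <- 1L
  for (i in seq_along(sizes)) {
    parts[[names(fractions)[i]]] <-
      if (sizes[i] > 0) perm[start:bounds[i]] else character(0)
    start <- bounds[i] + 1L
  }
  structure(c(parts, list(fractions = fractions, seed = as.integer(seed))),
            class = "data_split")
}

# Stratified fold assignment: within each class, shuffled patients are dealt
# cyclically across folds so no fold loses an entire class unnecessarily.
stratified_folds <- function(labels, k) {
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Fit a constrained, CV-pruned classification tree on one measure
#'
#' Grows a Gini-impurity CART on a single continuous predictor under the
#' [cart_params()] constraints, then prunes by cost complexity at the value
#' minimizing cross-validated misclassification over the nested-subtree
#' complexity sequence. Cross-validation folds are seeded and
#' label-stratified. With fewer than `min_split` patients no split is
#' admissible and a root-only majority-class tree is returned with a
#' warning.
#'
#' @param x Numeric vector: one adherence measure per patient.
#' @param labels Cluster labels (coerced to factor).
#' @param params A [cart_params()] object.
#' @param seed Integer seed for CV fold assignment.
#' @param measure Name of the measure (used in reporting).
#' @return Object of class `tree_model`.
#' @export
fit_cart <- function(x, labels, params = cart_params(), seed = 1L,
                     measure = "x") {
  stopifnot(is.numeric(x), length(x) == length(labels))
  y <- factor(labels)
  if (length(x) < params$min_split) {
    warning(sprintf(
      "only %d patients (< min_split = %d); returning root-only tree",
      length(x), params$min_split), call. = FALSE)
    maj <- majority_level(y)
    return(new_tree_model(NULL, cp = Inf, params = params,
                          measure = measure, levels = levels(y),
                          root_class = maj))
  }
  df <- data.frame(.y = y, .x = x)
  control <- rpart::rpart.control(minsplit = params$min_split,
                                  minbucket = params$min_leaf,
                                  maxdepth = params$max_depth,
                                  cp = 0, xval = 0,
                                  maxcompete = 0, maxsurrogate = 0,
                                  usesurrogate = 0)
  fit <- rpart::rpart(.y ~ .x, data = df, method = "class",
                      control = control)
  cps <- fit$cptable[, "CP"]
  if (length(cps) == 1L) {
    return(new_tree_model(fit, cp = cps[1], params = params,
                          measure = measure, levels = levels(y),
                          root_class = majority_level(y)))
  }
  # candidate cp realizing each nested subtree: geometric mean of adjacent
  # complexity values (the largest candidate realizes the root)
  cand <- c(cps[1], sqrt(cps[-length(cps)] * cps[-1]))
  cv_err <- with_seed(seed, {
    fold <- stratified_folds(y, params$cv_folds)
    err <- numeric(length(cand))
    for (f in seq_len(params$cv_folds)) {
      hold <- fold == f
      if (!any(hold) || all(hold)) next
      fit_f <- rpart::rpart(.y ~ .x, data = df[!hold, , drop = FALSE],
                            method = "class", control = control)
      for (j in seq_along(cand)) {
        pr <- rpart::prune(fit_f, cp = cand[j])
        pred <- predict(pr, newdata = df[hold, , drop = FALSE],
                        type = "class")
        err[j] <- err[j] + sum(pred != y[hold])
      }
    }
    err
  })
  best <- which.min(cv_err)  # ties -> first, i.e. the simpler tree
  pruned <- rpart::prune(fit, cp = cand[best])
  new_tree_model(pruned, cp = cand[best], params = params,
                 measure = measure, levels = levels(y),
                 root_class = majority_level(y))
}

majority_level <- function(y) {
  tab <- table(y)
  names(tab)[which.max(tab)]  # ties -> first level
}

new_tree_model <- function(fit, cp, params, measure, levels, root_class) {
  structure(list(fit = fit, cp = cp, params = params, measure = measure,
                 levels = levels, root_class = root_class),
            class = "tree_model")
}

#' Predict cluster membership from a fitted surrogate tree
#'
#' @param object A `tree_model`.
#' @param newdata Numeric vector of measure values.
#' @param ... Unused.
#' @return Factor of predicted cluster labels.
#' @export
predict.tree_model <- function(object, newdata, ...) {
  if (is.null(object$fit)) {
    return(factor(rep(object$root_class, length(newdata)),
                  levels = object$levels))
  }
  predict(object$fit, newdata = data.frame(.x = as.numeric(newdata)),
          type = "class")
}

#' @export
print.tree_model <- function(x, ...) {
  cat(sprintf("<tree_model> measure %s, pruning cp = %.4g\n",
              x$measure, x$cp))
  cat(tree_to_text(x), sep = "\n")
  invisible(x)
}

# Walk an rpart frame into a nested node list (split variable, threshold,
# children, leaf class).
tree_to_list <- function(model) {
  if (is.null(model$fit) || nrow(model$fit$frame) == 1L) {
    cls <- if (is.null(model$fit)) model$root_class else
      model$levels[model$fit$frame$yval[1]]
    return(list(type = "leaf", class = cls))
  }
  frame <- model$fit$frame
  splits <- model$fit$splits
  node_ids <- as.integer(rownames(frame))
  build <- function(id) {
    row <- match(id, node_ids)
    if (frame$var[row] == "<leaf>") {
      return(list(type = "leaf", class = model$levels[frame$yval[row]]))
    }
    # primary split threshold for this node: splits rows appear in node order
    n_before <- sum(frame$var[seq_len(row - 1)] != "<leaf>")
    s <- splits[n_before + 1L, ]
    left_first <- s[["ncat"]] < 0  # ncat = -1: left branch is x < threshold
    list(type = "split", measure = model$measure,
         threshold = unname(s[["index"]]),
         left = build(if (left_first) 2L * id else 2L * id + 1L),
         right = build(if (left_first) 2L * id + 1L else 2L * id),
         left_op = "<", right_op = ">=")
  }
  build(1L)
}

#' Export a surrogate tree as indented text
#'
#' @param model A `tree_model`.
#' @return Character vector of lines.
#' @export
tree_to_text <- function(model) {
  node <- tree_to_list(model)
  walk <- function(nd, indent) {
    pad <- strrep("  ", indent)
    if (nd$type == "leaf") {
      return(sprintf("%spredict cluster %s", pad, nd$class))
    }
    c(sprintf("%sif %s < %.4g:", pad, nd$measure, nd$threshold),
      walk(nd$left, indent + 1L),
      sprintf("%selse (%s >= %.4g):", pad, nd$measure, nd$threshold),
      walk(nd$right, indent + 1L))
  }
  walk(node, 0L)
}

#' Export a surrogate tree as JSON
#'
#' @param model A `tree_model`.
#' @param path Optional file to write to.
#' @return JSON string (invisibly when `path` is given).
#' @export
tree_to_json <- function(model, path = NULL) {
  js <- jsonlite::toJSON(tree_to_list(model), auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Train one tree per measure and pick the best on the validation partition
#'
#' Fits a surrogate tree for each of the five adherence measures on the
#' training partition and selects the measure whose tree attains the highest
#' accuracy on the validation partition; ties go to the earlier measure in
#' the order A, B, C, D, E.
#'
#' @param profiles Adherence profiles (one row per patient).
#' @param labels Named vector of cluster labels (names = patient ids).
#' @param split A [split_data()] partition with `train` and `validation`
#'   sets.
#' @param params A [cart_params()] object.
#' @param seed Integer seed for CV fold assignment.
#' @param measures Measures to compare (default A-E).
#' @return List with `best_measure`, `validation_accuracy` (named vector),
#'   `trees` (named list of `tree_model`s).
#' @export
select_best_measure <- function(profiles, labels, split,
                                params = cart_params(), seed = 1L,
                                measures = MEASURE_NAMES) {
  stopifnot(inherits(split, "data_split"),
            all(c("train", "validation") %in% names(split)))
  lab <- labels[profiles$patient_id]
  names(lab) <- profiles$patient_id
  train_idx <- profiles$patient_id %in% split$train
  val_idx <- profiles$patient_id %in% split$validation
  trees <- list()
  acc <- stats::setNames(numeric(length(measures)), measures)
  for (m in measures) {
    tree <- fit_cart(profiles[[m]][train_idx], lab[train_idx], params,
                     seed = seed, measure = m)
    cm <- evaluate(tree, profiles[[m]][val_idx], lab[val_idx])
    trees[[m]] <- tree
    acc[m] <- accuracy(cm)
  }
  best <- measures[which.max(acc)]  # ties -> earlier measure
  list(best_measure = best, validation_accuracy = acc, trees = trees)
}

#' Confusion matrix of tree estimates against cluster labels
#'
#' @param tree A `tree_model`.
#' @param x Measure values for the evaluation partition.
#' @param labels True cluster labels for the same patients.
#' @return Object of class `confusion_matrix`: a k x k table with rows =
#'   tree-estimated group, columns = cluster label.
#' @export
evaluate <- function(tree, x, labels) {
  if (!length(x)) stop("empty evaluation partition", call. = FALSE)
  lv <- union(tree$levels, unique(as.character(labels)))
  pred <- factor(as.character(predict(tree, x)), levels = lv)
  truth <- factor(as.character(labels), levels = lv)
  cm <- table(estimated = pred, cluster = truth)
  class(cm) <- c("confusion_matrix", class(cm))
  cm
}

#' Classification accuracy from a confusion matrix
#'
#' Accuracy = number of correctly classified patients / number of patients,
#' i.e. the trace over the total.
#'
#' @param cm A square confusion matrix (rows = estimated, columns = truth).
#' @return Fraction in `[0, 1]`.
#' @export
accuracy <- function(cm) {
  cm <- as.matrix(cm)
  if (nrow(cm) != ncol(cm)) stop("confusion matrix must be square",
                                 call. = FALSE)
  total <- sum(cm)
  if (total <= 0) stop("empty confusion matrix", call. = FALSE)
  sum(diag(cm)) / total
}
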