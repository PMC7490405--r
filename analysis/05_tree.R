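#!/usr/bin/env Rscript
# Step 5 — single-measure decision-tree surrogate for cluster membership.
#
# Splits patients 70/15/15, fits one constrained CV-pruned CART per measure
# on the training set, picks the measure with the best validation accuracy,
# and reports the held-out test confusion matrix and accuracy.

suppressPackageStartupMessages(library(adhertype))

seed <- 20201L
profiles <- utils::read.csv("results/profiles.csv")
clusters <- utils::read.csv("results/clusters.csv")
labels <- stats::setNames(clusters$cluster, clusters$patient_id)

seeds <- stage_seeds(seed)
split <- split_data(profiles$patient_id, seed = seeds[["split"]])
sel <- select_best_measure(profiles, labels, split, cart_params(),
                           seed = seeds[["cv"]])

utils::write.csv(
  data.frame(measure = names(sel$validation_accuracy),
             validation_accuracy = unname(sel$validation_accuracy)),
  "results/measure_accuracy.csv", row.names = FALSE)

best_tree <- sel$trees[[sel$best_measure]]
tree_to_json(best_tree, "results/surrogate_tree.json")

test_idx <- match(split$test, profiles$patient_id)
cm <- evaluate(best_tree, profiles[[sel$best_measure]][test_idx],
               labels[split$test])
cmd <- as.data.frame.matrix(cm)
utils::write.csv(cbind(estimated = rownames(cmd), cmd),
                 "results/confusion_matrix.csv", row.names = FALSE)

cat(sprintf("partitions: train %d / validation %d / test %d\n",
            length(split$train), length(split$validation),
            length(split$test)))
cat("validation accuracy per measure:",
    paste(sprintf("%s=%.2f", names(sel$validation_accuracy),
                  sel$validation_accuracy), collapse = " "), "\n")
cat(sprintf("best surrogate measure: %s\n", sel$best_measure))
cat("pruned tree:\n")
cat(paste0("  ", tree_to_text(best_tree)), sep = "\n")
cat(sprintf("test confusion matrix (n = %d):\n", sum(cm)))
print(cm)
cat(sprintf("test accuracy: %.1f%% (%d/%d)\n", 100 * accuracy(cm),
            sum(diag(cm)), sum(cm)))
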