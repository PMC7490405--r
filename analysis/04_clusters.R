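#!/usr/bin/env Rscript
# Step 4 — cluster typology with bootstrap stability.
#
# For each scaling regime: PCA scores (95% variance rule), the WSS curve
# over k = 1..15 (25 k-means initialisations each), elbow selection of k,
# and 1,000-replicate bootstrap Jaccard stability. The regime with the most
# stable clusters wins; clusters are then renumbered 1..k by ascending
# median % of doses taken.

suppressPackageStartupMessages(library(adhertype))

seed <- 20201L
profiles <- utils::read.csv("results/profiles.csv")
m <- cohort_measure_matrix(profiles)

sel <- select_scaling(m, n_bootstrap = 1000L,
                      seed = stage_seeds(seed)[["kmeans"]])

stab <- do.call(rbind, lapply(names(sel$per_method), function(mth) {
  s <- sel$per_method[[mth]]$stability
  data.frame(scaling = mth, k = s$k, cluster = seq_len(s$k),
             mean_jaccard = s$mean_jaccard,
             dissolution_rate = s$dissolution_rate)
}))
utils::write.csv(stab, "results/stability.csv", row.names = FALSE)

best <- sel$per_method[[sel$best]]
utils::write.csv(as.data.frame(best$wss_curve), "results/wss_curve.csv",
                 row.names = FALSE)
solution <- order_clusters(best$solution, profiles)
utils::write.csv(data.frame(patient_id = names(solution$labels),
                            cluster = unname(solution$labels)),
                 "results/clusters.csv", row.names = FALSE)

# scree plot of the winning regime's WSS curve
png("results/scree_wss.png", width = 700, height = 500)
plot(best$wss_curve$k, best$wss_curve$wss, type = "b", pch = 19,
     xlab = "number of clusters k", ylab = "within-group sum of squares",
     main = sprintf("Scree plot (%s scaling), elbow at k = %d",
                    sel$best, best$k))
abline(v = best$k, lty = 2)
invisible(dev.off())

cat("per-regime elbow k:",
    paste(sprintf("%s=%d", names(sel$per_method),
                  vapply(sel$per_method, `[[`, integer(1), "k")),
          collapse = " "), "\n")
cat(sprintf("most stable scaling: %s (mean Jaccard %.3f, mean dissolution %.3f)\n",
            sel$best, sel$mean_jaccard[[sel$best]],
            sel$mean_dissolution[[sel$best]]))
for (cl in seq_len(solution$k)) {
  ids <- names(solution$labels)[solution$labels == cl]
  cat(sprintf("cluster %d: n = %3d, median %% doses taken = %.1f\n",
              cl, length(ids),
              median(profiles$A[profiles$patient_id %in% ids])))
}
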