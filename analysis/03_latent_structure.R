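#!/usr/bin/env Rscript
# Step 3 — latent structure of the adherence measures.
#
# Runs PCA on the patients x 5 measure matrix under each scaling regime
# (zero-centering only, unit variance, min-max) and reports, per regime, the
# variance-explained profile, the correlation loadings and the number of
# components needed to reach 95% cumulative variance.

suppressPackageStartupMessages(library(adhertype))

profiles <- utils::read.csv("results/profiles.csv")
m <- cohort_measure_matrix(profiles)

for (method in c("center_only", "unit_variance", "min_max")) {
  sc <- scale_measures(m, method)
  pca <- fit_pca(sc$scaled, sc$scaling)
  tab <- pca_table(pca)
  utils::write.csv(cbind(measure = rownames(tab), tab),
                   sprintf("results/pca_%s.csv", method), row.names = FALSE)
  cat(sprintf("\n== %s ==\n", method))
  cat(sprintf("variance explained: %s\n",
              paste(sprintf("%.1f%%", 100 * pca$variance_explained),
                    collapse = " ")))
  cat(sprintf("components for >= 95%%: %d\n", pca$n_components_95))
  cat(sprintf("PC1 correlation loadings: %s\n",
              paste(sprintf("%s=%+.2f", rownames(pca$cor_loadings),
                            pca$cor_loadings[, 1]), collapse = " ")))
}
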