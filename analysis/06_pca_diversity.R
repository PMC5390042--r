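#!/usr/bin/env Rscript
# Stage 6: phytochemical overview — Pareto-scaled PCA and per-group
# chemical diversity.
#
# PCA uses centering and Pareto scaling on the raw intensities; a
# two-standard-deviation ellipse summarizes each activity group's score
# cloud.  Chemical diversity counts distinct detected features per
# activity class.

suppressPackageStartupMessages(library(phytokappa))

peaks <- read_peak_table("results/synthetic/peaks.csv")
labels <- read.csv("results/labels.csv")
class(labels) <- c("activity_labels", "data.frame")
am <- activity_vector(labels, "AM")

p <- pca_pareto(peaks, n_components = 2)
cat(sprintf("PC1 + PC2 explain %.1f%% of the Pareto-scaled variance\n",
            sum(p$explained_variance[1:2])))

group <- ifelse(am[peaks$species_ids], "active", "inactive")
ell <- group_ellipse(p$scores, group)
write.csv(cbind(species_id = rownames(p$scores), group,
                as.data.frame(p$scores)),
          "results/pca_scores.csv", row.names = FALSE, quote = FALSE)
write.csv(ell, "results/pca_ellipses.csv", row.names = FALSE, quote = FALSE)

bp <- filter_ubiquitous(binarize(peaks))
div <- chemical_diversity(bp, setNames(group, peaks$species_ids))
print(div)
write.csv(div, "results/chemical_diversity.csv", row.names = FALSE,
          quote = FALSE)
cat("PCA scores, ellipses and diversity tables written under results/\n")
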