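#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study fixtures.
#
# Emulates the study design end to end with known ground truth: a Yule
# phylogeny of 87 species, a phylogenetically clumped antimicrobial trait
# (17/87 active species), random cytotoxicity traits for the two cell lines
# (HaCaT: a single species; IEC-6: ~30%), a 2000-feature LC-MS peak table
# with one planted causal feature, one AND-synergy pair and one
# OR-redundancy pair at 5% flip noise, and triplicate bioassay readings.

suppressPackageStartupMessages({library(phytokappa); library(ape)})

seed <- 20241L
out <- "results/synthetic"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

scfg <- synthetic_config(seed = seed)
tree <- generate_tree(scfg$n_species, seed = seed)
activity <- simulate_binary_trait(tree, "brownian_threshold",
                                  prevalence = scfg$active_fraction,
                                  seed = seed)
cyto <- list(
  HaCaT = simulate_binary_trait(tree, "random", scfg$hacat_prevalence,
                                seed = seed + 1L),
  IEC6 = simulate_binary_trait(tree, "random", scfg$iec6_prevalence,
                               seed = seed + 2L))
peaks <- generate_peak_table(scfg, activity)
assays <- generate_bioassays(scfg, activity, cyto)

write.tree(tree, file.path(out, "tree.nwk"))
write_peak_table(peaks$table, file.path(out, "peaks.csv"))
write.csv(assays$inhibition, file.path(out, "inhibition.csv"),
          row.names = FALSE, quote = FALSE)
write.csv(assays$viability, file.path(out, "viability.csv"),
          row.names = FALSE, quote = FALSE)
jsonlite::write_json(
  list(causal_feature_ids = peaks$truth$causal_feature_ids,
       synergy_pairs = peaks$truth$synergy_pairs,
       redundancy_pairs = peaks$truth$redundancy_pairs,
       true_activity = as.list(peaks$truth$true_activity),
       true_cytotoxicity = lapply(cyto, as.list),
       seed = seed),
  file.path(out, "truth.json"), auto_unbox = TRUE, digits = NA)

cat(sprintf("Simulated %d species x %d features (seed %d)\n",
            scfg$n_species, scfg$n_features, seed))
cat(sprintf("  active species: %d | HaCaT-cytotoxic: %d | IEC-6-cytotoxic: %d\n",
            sum(activity), sum(cyto$HaCaT), sum(cyto$IEC6)))
cat(sprintf("  planted: causal %s | AND pair %s | OR pair %s\n",
            peaks$truth$causal_feature_ids,
            paste(peaks$truth$synergy_pairs[[1]], collapse = "+"),
            paste(peaks$truth$redundancy_pairs[[1]], collapse = "+")))
cat("Artifacts in", out, "\n")
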