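# End-to-end orchestration: simulate (or load) -> classify -> binarize ->
# kappa screen -> combined score -> Boolean pair screens -> D statistics ->
# summary report.  All stage randomness derives from the single config seed
# via named substreams, so reruns are bit-identical and stages are
# independently reproducible.

#' Default pipeline configuration
#'
#' Gathers the study constants (0.6 cm radius, 1e4 intensity, alpha 0.05,
#' strong 0.68) with a synthetic simulate block.
#'
#' @param seed integer master seed.
#' @param simulate a [synthetic_config()]; its seed is overridden by `seed`.
#' @param n_perm permutations per null for the D statistics.
#' @param operators Boolean operators to screen (`"AND"`, `"OR"`).
#' @param am_trait_mode trait model for the simulated antimicrobial
#'   activity: `"brownian_threshold"` (phylogenetically clumped, as observed
#'   for antimicrobial activity) or `"random"`.
#' @return a `pipeline_config` list with fields `simulate`, `thresholds`
#'   (`radius_cm`, `intensity`, `alpha`, `strong`), `operators`, `n_perm`,
#'   `seed`, `am_trait_mode`.
#' @export
pipeline_config <- function(seed = 1L,
                            simulate = synthetic_config(seed = seed),
                            n_perm = 1000L,
                            operators = c("AND", "OR"),
                            am_trait_mode = "brownian_threshold") {
  simulate$seed <- as.integer(seed)
  structure(list(simulate = simulate,
                 thresholds = list(radius_cm = 0.6, intensity = 1e4,
                                   alpha = 0.05, strong = 0.68),
                 operators = match.arg(operators, c("AND", "OR"),
                                       several.ok = TRUE),
                 n_perm = as.integer(n_perm),
                 seed = as.integer(seed),
                 am_trait_mode = am_trait_mode),
            class = "pipeline_config")
}

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

write_csv_file <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Simulates the study fixtures (tree, traits, peak table, bioassays),
#' classifies bioactivity, binarizes and filters the peak matrix, screens
#' every feature against the three classifications, computes the combined
#' antimicrobial-but-non-cytotoxic score, runs the requested Boolean pair
#' screens, tests phylogenetic signal of each classification, and writes
#' all artifacts plus a summary and a provenance manifest into `out_dir`.
#' Outputs are pure functions of the config: rerunning with the same config
#' yields bit-identical files.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if absent).
#' @return invisibly, a list with all in-memory stage results.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  scfg <- config$simulate
  thr <- config$thresholds
  stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  # --- simulate ---------------------------------------------------------
  sim <- stage("simulate", {
    tree <- generate_tree(scfg$n_species, seed = scfg$seed)
    activity <- simulate_binary_trait(tree, config$am_trait_mode,
                                      prevalence = scfg$active_fraction,
                                      seed = scfg$seed)
    cyto <- list(
      HaCaT = simulate_binary_trait(tree, "random",
                                    prevalence = scfg$hacat_prevalence,
                                    seed = derive_seed(scfg$seed, "hacat")),
      IEC6 = simulate_binary_trait(tree, "random",
                                   prevalence = scfg$iec6_prevalence,
                                   seed = derive_seed(scfg$seed, "iec6")))
    peaks <- generate_peak_table(scfg, activity)
    assays <- generate_bioassays(scfg, activity, cyto)
    ape::write.tree(tree, file.path(out_dir, "tree.nwk"))
    write_peak_table(peaks$table, file.path(out_dir, "peaks.csv"))
    write_csv_file(assays$inhibition, file.path(out_dir, "inhibition.csv"))
    write_csv_file(assays$viability, file.path(out_dir, "viability.csv"))
    write_json_file(list(
      causal_feature_ids = peaks$truth$causal_feature_ids,
      synergy_pairs = peaks$truth$synergy_pairs,
      redundancy_pairs = peaks$truth$redundancy_pairs,
      true_activity = as.list(peaks$truth$true_activity),
      true_cytotoxicity = lapply(cyto, as.list)),
      file.path(out_dir, "truth.json"))
    list(tree = tree, activity = activity, cyto = cyto, peaks = peaks,
         assays = assays)
  })

  # --- classify ---------------------------------------------------------
  labels <- stage("classify", {
    am <- classify_antimicrobial(sim$assays$inhibition,
                                 radius_threshold_cm = thr$radius_cm)
    tox <- classify_cytotoxicity(sim$assays$viability, alpha = thr$alpha)
    lab <- bind_labels(am, tox)
    write_csv_file(as.data.frame(lab), file.path(out_dir, "labels.csv"))
    lab
  })

  # --- binarize + screen ------------------------------------------------
  bp <- stage("binarize", {
    filter_ubiquitous(binarize(sim$peaks$table, threshold = thr$intensity))
  })
  screens <- stage("kappa_screen", {
    out <- lapply(c(AM = "AM", HaCaT = "HaCaT", `IEC-6` = "IEC-6"),
                  function(a) kappa_screen(bp, labels, a,
                                           alpha = thr$alpha))
    for (a in names(out)) {
      write_csv_file(out[[a]], file.path(out_dir,
                                         paste0("kappa_", a, ".csv")))
    }
    out
  })
  combined <- stage("combined_score", {
    cs <- combined_score(screens$AM, screens$HaCaT, screens$`IEC-6`,
                         strong = thr$strong)
    meta <- sim$peaks$table$features
    cs_out <- cbind(feature = feature_label(
      meta$mz[match(cs$feature_id, meta$feature_id)],
      meta$rt[match(cs$feature_id, meta$feature_id)]), cs)
    write_csv_file(cs_out, file.path(out_dir, "combined.csv"))
    cs
  })

  # --- pair screens -----------------------------------------------------
  pairs <- stage("pairwise_screen", {
    out <- list()
    strong_am <- screens$AM$feature_id[!is.na(screens$AM$kappa) &
                                         screens$AM$kappa >= thr$strong]
    for (op in config$operators) {
      ps <- pairwise_screen(bp, labels, "AM", operator = op,
                            strong = thr$strong)
      outp <- ps$records[ps$records$outperforming, , drop = FALSE]
      inv <- involvement_stats(outp, strong_am)
      ps$summary$involvement_strong_individuals <- inv$fraction
      write_csv_file(ps$records,
                     file.path(out_dir, paste0("pairs_", op, ".csv")))
      write_json_file(ps$summary,
                      file.path(out_dir,
                                paste0("pair_summary_", op, ".json")))
      out[[op]] <- ps
    }
    out
  })

  # --- phylogenetic signal ---------------------------------------------
  dstats <- stage("dstat", {
    rows <- lapply(c("AM", "HaCaT", "IEC-6"), function(a) {
      trait <- as.numeric(activity_vector(labels, a))
      names(trait) <- names(activity_vector(labels, a))
      if (sum(trait) == 0 || sum(trait) == length(trait)) {
        return(data.frame(assay = a, d_obs = NA_real_, D = NA_real_,
                          p_random = NA_real_, p_brownian = NA_real_,
                          n_permutations = config$n_perm,
                          note = "monomorphic trait; D undefined"))
      }
      r <- fritz_purvis_d(sim$tree, trait, n_perm = config$n_perm,
                          seed = derive_seed(config$seed, paste0("d-", a)))
      data.frame(assay = a, d_obs = r$d_obs, D = r$D,
                 p_random = r$p_random, p_brownian = r$p_brownian,
                 n_permutations = r$n_permutations, note = "")
    })
    df <- do.call(rbind, rows)
    write_csv_file(df, file.path(out_dir, "dstat.csv"))
    df
  })

  # --- summary + manifest ----------------------------------------------
  stage("report", {
    tiers <- lapply(screens, function(s) {
      k <- s$kappa[!is.na(s$kappa)]
      as.list(table(factor(strength_class(k),
                           levels = c("strong", "moderate", "low"))))
    })
    summary <- list(
      n_species = scfg$n_species,
      n_features_screened = length(bp$feature_ids),
      n_features_removed_ubiquitous = length(attr(bp, "removed")),
      strength_tiers = tiers,
      n_selected_candidates = sum(combined$selected),
      selected_features = combined$feature_id[combined$selected],
      pair_screens = lapply(pairs, `[[`, "summary"),
      dstat = stats::setNames(as.list(dstats$D), dstats$assay))
    write_json_file(summary, file.path(out_dir, "summary.json"))
    write_json_file(list(
      package = "phytokappa",
      version = as.character(utils::packageVersion("phytokappa")),
      seed = config$seed,
      thresholds = thr,
      operators = config$operators,
      n_perm = config$n_perm,
      am_trait_mode = config$am_trait_mode,
      simulate = unclass(scfg)),
      file.path(out_dir, "manifest.json"))
    summary
  }) -> summary

  invisible(list(sim = sim, labels = labels, binary = bp,
                 screens = screens, combined = combined, pairs = pairs,
                 dstats = dstats, summary = summary))
}
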