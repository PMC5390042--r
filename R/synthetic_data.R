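# Synthetic study fixtures with known ground truth: Yule trees, binary
# bioactivity traits (Brownian-threshold or random), LC-MS peak tables with
# planted causal features / AND-synergy pairs / OR-redundancy pairs, and
# triplicate bioassay readings.  Every generator is a pure function of
# (config, seed).

#' Configuration for the synthetic study generator
#'
#' Defaults mirror the study design this package exercises: 87 species of
#' which 17 are antimicrobially active, triplicate assays, a 0.6 cm
#' activity radius and a 1e4 intensity threshold; the feature count (2000)
#' is a desk-scale stand-in for a full TOF-MS feature matrix.
#'
#' @param n_species number of species.
#' @param n_features number of LC-MS features.
#' @param background_prevalence Bernoulli presence probability of background
#'   features, in (0, 1).
#' @param n_causal_single number of planted single causal features.
#' @param n_synergy_pairs number of planted AND-synergy pairs.
#' @param n_redundancy_pairs number of planted OR-redundancy pairs.
#' @param flip_noise per-species label-flip probability for planted
#'   profiles, in \[0, 0.5).
#' @param active_fraction fraction of antimicrobially active species.
#' @param intensity_log_mean_present,intensity_log_mean_absent log10
#'   intensity means for present/absent draws (present clamps above the
#'   1e4 detection threshold, absent below).
#' @param intensity_log_sd log10 intensity standard deviation.
#' @param replicates replicate readings per assay (>= 2).
#' @param effect_radius_cm mean inhibition radius of active species (>= 0.6).
#' @param inactive_radius_cm mean radius of inactive species (< 0.6).
#' @param radius_sd replicate standard deviation of radii.
#' @param control_absorbance,cytotoxic_absorbance,absorbance_sd MTT
#'   absorbance means (solvent control / cytotoxic species) and replicate
#'   standard deviation.
#' @param hacat_prevalence,iec6_prevalence cytotoxic-species fractions per
#'   cell line.
#' @param seed integer seed; fully determines all generated data.
#' @return a validated `synthetic_config` list.
#' @export
synthetic_config <- function(n_species = 87L,
                             n_features = 2000L,
                             background_prevalence = 0.15,
                             n_causal_single = 1L,
                             n_synergy_pairs = 1L,
                             n_redundancy_pairs = 1L,
                             flip_noise = 0.05,
                             active_fraction = 17 / 87,
                             intensity_log_mean_present = 5,
                             intensity_log_mean_absent = 3,
                             intensity_log_sd = 0.3,
                             replicates = 3L,
                             effect_radius_cm = 0.9,
                             inactive_radius_cm = 0.2,
                             radius_sd = 0.05,
                             control_absorbance = 1.0,
                             cytotoxic_absorbance = 0.4,
                             absorbance_sd = 0.05,
                             hacat_prevalence = 1 / 87,
                             iec6_prevalence = 0.3,
                             seed = 1L) {
  cfg <- list(n_species = as.integer(n_species),
              n_features = as.integer(n_features),
              background_prevalence = background_prevalence,
              n_causal_single = as.integer(n_causal_single),
              n_synergy_pairs = as.integer(n_synergy_pairs),
              n_redundancy_pairs = as.integer(n_redundancy_pairs),
              flip_noise = flip_noise,
              active_fraction = active_fraction,
              intensity_log_mean_present = intensity_log_mean_present,
              intensity_log_mean_absent = intensity_log_mean_absent,
              intensity_log_sd = intensity_log_sd,
              replicates = as.integer(replicates),
              effect_radius_cm = effect_radius_cm,
              inactive_radius_cm = inactive_radius_cm,
              radius_sd = radius_sd,
              control_absorbance = control_absorbance,
              cytotoxic_absorbance = cytotoxic_absorbance,
              absorbance_sd = absorbance_sd,
              hacat_prevalence = hacat_prevalence,
              iec6_prevalence = iec6_prevalence,
              seed = as.integer(seed))
  with(cfg, {
    if (n_species < 3L) stop_invalid("n_species must be >= 3")
    if (background_prevalence <= 0 || background_prevalence >= 1) {
      stop_invalid("background_prevalence must lie in (0, 1)")
    }
    if (flip_noise < 0 || flip_noise >= 0.5) {
      stop_invalid("flip_noise must lie in [0, 0.5)")
    }
    if (active_fraction <= 0 || active_fraction >= 1) {
      stop_invalid("active_fraction must lie in (0, 1)")
    }
    planted <- n_causal_single + 2L * (n_synergy_pairs + n_redundancy_pairs)
    if (planted > n_features) {
      stop_invalid("planted features (", planted, ") exceed n_features")
    }
    if (replicates < 2L) stop_invalid("replicates must be >= 2")
    if (effect_radius_cm < 0.6) {
      stop_invalid("effect_radius_cm must be >= 0.6 (active mean)")
    }
    if (inactive_radius_cm >= 0.6) {
      stop_invalid("inactive_radius_cm must be < 0.6")
    }
  })
  structure(cfg, class = "synthetic_config")
}

species_labels <- function(n) {
  sprintf("sp_%0*d", max(3L, nchar(n)), seq_len(n))
}

#' Simulate a Yule (pure-birth) species tree
#'
#' Rooted, strictly bifurcating, positive branch lengths, unit birth rate;
#' tip labels `sp_001...` match the species ids of all other generated
#' tables.
#'
#' @param n_species number of tips, >= 3.
#' @param seed integer seed.
#' @return an `ape` `phylo`.
#' @export
generate_tree <- function(n_species, seed = 1L) {
  if (n_species < 3L) stop_invalid("n_species must be >= 3")
  tree <- with_seed(derive_seed(seed, "tree"), {
    ape::rphylo(n_species, birth = 1, death = 0)
  })
  tree$tip.label <- species_labels(n_species)
  tree
}

#' Simulate a binary trait on a tree
#'
#' `brownian_threshold`: Brownian liabilities on the branches (variance
#' proportional to branch length), thresholded so the tips with the
#' `ceiling(prevalence * n)` largest liabilities are 1 — a phylogenetically
#' clumped trait (Fritz-Purvis D near 0).  `random`: a uniform random tip
#' subset of the same size (D near 1).
#'
#' @param tree bifurcating `phylo`.
#' @param mode `"brownian_threshold"` or `"random"`.
#' @param prevalence target fraction of 1s, in (0, 1); must yield neither 0
#'   nor n ones.
#' @param seed integer seed.
#' @return named binary vector over the tips.
#' @export
simulate_binary_trait <- function(tree,
                                  mode = c("brownian_threshold", "random"),
                                  prevalence, seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(inherits(tree, "phylo"))
  n <- length(tree$tip.label)
  k <- ceiling(prevalence * n)
  if (k <= 0 || k >= n) {
    stop_invalid("prevalence ", prevalence, " yields ", k,
                 " ones on ", n, " tips; need 0 < ones < n")
  }
  trait <- if (mode == "random") {
    with_seed(derive_seed(seed, "trait-random"), {
      v <- numeric(n); v[sample.int(n, k)] <- 1; v
    })
  } else {
    with_seed(derive_seed(seed, "trait-brownian"), {
      drop(threshold_liabilities(bm_tip_liabilities(tree, 1L), k))
    })
  }
  stats::setNames(trait, tree$tip.label)
}

# Flip each entry of a binary vector independently with probability p.
flip_bits <- function(v, p) {
  if (p <= 0) return(v)
  fl <- stats::runif(length(v)) < p
  ifelse(fl, 1 - v, v)
}

# Smallest padding-set size s making a profile (target OR s extra species)
# individually weak (kappa vs `activity` below `weak`).  avail = number of
# species available for padding (two disjoint sets must fit).
weak_padding_size <- function(target, activity, avail, weak = 0.45) {
  n <- length(activity)
  n1 <- sum(activity); n0 <- n - n1
  a0 <- sum(target * activity)          # padding never overlaps the target
  b0 <- sum(target * (1 - activity))
  s <- max(1L, floor(0.35 * avail))
  while (s <= floor(avail / 2)) {
    # worst (most-agreeing) padding composition: as many padded species as
    # possible are active-but-target-absent, maximizing a
    m <- min(s, n1 - a0)
    a <- a0 + m
    b <- b0 + (s - m)
    k <- cohen_kappa(a, b, n1 - a, n0 - b)
    if (!is.na(k) && k < weak) return(s)
    s <- s + 1L
  }
  stop_invalid("cannot plant an individually weak component: too few ",
               "species available for padding")
}

#' Generate a synthetic LC-MS peak table with planted structure
#'
#' Causal features reproduce the activity vector up to independent
#' per-species flips (probability `flip_noise`).  Each synergy pair plants
#' two components present in (flipped active set) union a private padding
#' set, the two padding sets disjoint, so the AND of the components equals
#' the flipped active set while each component alone agrees only weakly
#' with activity (kappa < 0.45 by construction).  Each redundancy pair
#' splits the flipped active set between the components, so their OR
#' restores it.  Background features are independent Bernoulli draws.
#' Intensities are log10-normal around the present/absent means, clamped to
#' the correct side of the 1e4 detection threshold so binarization exactly
#' recovers the planted presence pattern.  No feature is ever present in
#' all species.
#'
#' @param config a [synthetic_config()].
#' @param activity binary vector of length `n_species` (named by species or
#'   unnamed); must contain at least one active species.
#' @return list with `table` (a [peak_table()]) and `truth` (list:
#'   `causal_feature_ids`, `synergy_pairs`, `redundancy_pairs`,
#'   `true_activity`).
#' @export
generate_peak_table <- function(config, activity) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- config$n_species
  if (length(activity) != n) stop_invalid("activity length != n_species")
  activity <- as.numeric(activity)
  if (!is_binary_vector(activity)) stop_invalid("activity must be binary")
  if (sum(activity) == 0) stop_invalid("active set is empty; cannot plant")
  sp <- species_labels(n)
  nf <- config$n_features
  fid <- sprintf("F%05d", seq_len(nf))

  with_seed(derive_seed(config$seed, "peaks"), {
    pres <- matrix(0, n, nf)
    truth <- list(causal_feature_ids = character(0),
                  synergy_pairs = list(), redundancy_pairs = list(),
                  true_activity = stats::setNames(activity, sp))
    col <- 1L
    for (i in seq_len(config$n_causal_single)) {
      pres[, col] <- flip_bits(activity, config$flip_noise)
      truth$causal_feature_ids <- c(truth$causal_feature_ids, fid[col])
      col <- col + 1L
    }
    for (i in seq_len(config$n_synergy_pairs)) {
      z <- flip_bits(activity, config$flip_noise)
      if (sum(z) == 0) z <- activity  # degenerate flip; fall back
      zeros <- which(z == 0)
      s <- weak_padding_size(z, activity, length(zeros))
      pad <- sample(zeros, 2L * s)
      a_prof <- z; a_prof[pad[seq_len(s)]] <- 1
      b_prof <- z; b_prof[pad[(s + 1L):(2L * s)]] <- 1
      pres[, col] <- a_prof
      pres[, col + 1L] <- b_prof
      truth$synergy_pairs <- c(truth$synergy_pairs,
                               list(c(fid[col], fid[col + 1L])))
      col <- col + 2L
    }
    for (i in seq_len(config$n_redundancy_pairs)) {
      z <- flip_bits(activity, config$flip_noise)
      ones <- which(z == 1)
      if (length(ones) < 2L) { z <- activity; ones <- which(z == 1) }
      half <- sample(ones, floor(length(ones) / 2))
      a_prof <- z; a_prof[half] <- 0            # keeps ones \ half
      b_prof <- z; b_prof[setdiff(ones, half)] <- 0  # keeps half
      pres[, col] <- a_prof
      pres[, col + 1L] <- b_prof
      truth$redundancy_pairs <- c(truth$redundancy_pairs,
                                  list(c(fid[col], fid[col + 1L])))
      col <- col + 2L
    }
    if (col <= nf) {
      nb <- nf - col + 1L
      pres[, col:nf] <- matrix(
        as.numeric(stats::runif(n * nb) < config$background_prevalence),
        n, nb)
    }
    # ubiquitous-filter precondition: no feature present in all species
    full <- which(colSums(pres) == n)
    for (j in full) pres[sample.int(n, 1L), j] <- 0

    lg <- matrix(stats::rnorm(n * nf,
                              mean = ifelse(pres == 1,
                                            config$intensity_log_mean_present,
                                            config$intensity_log_mean_absent),
                              sd = config$intensity_log_sd), n, nf)
    thr <- log10(1e4)
    lg[pres == 1] <- pmax(lg[pres == 1], thr + 0.01)
    lg[pres == 0] <- pmin(lg[pres == 0], thr - 0.01)
    inten <- 10^lg

    # unique (mz, rt) metadata
    repeat {
      mz <- round(stats::runif(nf, 100, 1000), 2)
      rt <- round(stats::runif(nf, 1, 70), 1)
      if (!anyDuplicated(paste(mz, rt))) break
    }
    tbl <- peak_table(features = data.frame(feature_id = fid, mz = mz,
                                            rt = rt),
                      species_ids = sp, intensity = inten)
    list(table = tbl, truth = truth)
  })
}

#' Generate synthetic bioassay readings
#'
#' Inhibition radii: active species draw replicates around
#' `effect_radius_cm`, inactive around `inactive_radius_cm` (both truncated
#' at 0).  MTT absorbances: one solvent-control row per cell line; treated
#' rows draw around the control mean for non-cytotoxic species (viability
#' near 100%) and around `cytotoxic_absorbance` for cytotoxic ones.
#'
#' @param config a [synthetic_config()].
#' @param activity binary antimicrobial vector of length `n_species`.
#' @param cytotoxicity list with binary vectors `HaCaT` and `IEC6` of the
#'   same length.
#' @return list with `inhibition` (data.frame `species_id`, `rep1..repK`)
#'   and `viability` (data.frame `species_id`, `cell_line`, `role`,
#'   `rep1..repK`).
#' @export
generate_bioassays <- function(config, activity, cytotoxicity) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- config$n_species
  k <- config$replicates
  if (k < 2L) stop_invalid("replicates must be >= 2")
  if (length(activity) != n) stop_invalid("activity length != n_species")
  stopifnot(is.list(cytotoxicity),
            all(c("HaCaT", "IEC6") %in% names(cytotoxicity)))
  if (length(cytotoxicity$HaCaT) != n || length(cytotoxicity$IEC6) != n) {
    stop_invalid("cytotoxicity vectors must have length n_species")
  }
  sp <- species_labels(n)
  with_seed(derive_seed(config$seed, "bioassay"), {
    mu_r <- ifelse(as.numeric(activity) == 1,
                   config$effect_radius_cm, config$inactive_radius_cm)
    radii <- matrix(pmax(0, stats::rnorm(n * k, mean = rep(mu_r, k),
                                         sd = config$radius_sd)), n, k)
    inhibition <- data.frame(species_id = sp, radii,
                             stringsAsFactors = FALSE)
    names(inhibition) <- c("species_id", paste0("rep", seq_len(k)))

    make_cell_line <- function(cl_name, tox) {
      ctrl <- pmax(1e-6, stats::rnorm(k, config$control_absorbance,
                                      config$absorbance_sd))
      mu_a <- ifelse(as.numeric(tox) == 1, config$cytotoxic_absorbance,
                     config$control_absorbance)
      trt <- matrix(pmax(1e-6, stats::rnorm(n * k, mean = rep(mu_a, k),
                                            sd = config$absorbance_sd)),
                    n, k)
      df <- rbind(
        data.frame(species_id = "solvent_control", cell_line = cl_name,
                   role = "control", t(ctrl), stringsAsFactors = FALSE,
                   check.names = FALSE),
        data.frame(species_id = sp, cell_line = cl_name, role = "treated",
                   trt, stringsAsFactors = FALSE, check.names = FALSE))
      names(df) <- c("species_id", "cell_line", "role",
                     paste0("rep", seq_len(k)))
      df
    }
    viability <- rbind(make_cell_line("HaCaT", cytotoxicity$HaCaT),
                      make_cell_line("IEC-6", cytotoxicity$IEC6))
    list(inhibition = inhibition, viability = viability)
  })
}
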