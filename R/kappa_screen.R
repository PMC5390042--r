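# Per-feature Cohen's-kappa screening of binarized LC-MS profiles against a
# binary bioactivity classification; combined antimicrobial-but-non-cytotoxic
# score with competition ranking; compound-level t-test screen; BH correction.

#' Cohen's kappa for a 2x2 contingency table
#'
#' Chance-corrected agreement between two binary raters:
#' `kappa = (p_o - p_e) / (1 - p_e)` with observed agreement
#' `p_o = (a + d) / n` and chance agreement
#' `p_e = ((a+b)(a+c) + (c+d)(b+d)) / n^2`.  Here one rater is a feature's
#' presence profile and the other a bioactivity classification, so `a` =
#' present & active, `b` = present & inactive, `c` = absent & active, `d` =
#' absent & inactive.  Vectorized over the four counts.
#'
#' @param a,b,c,d non-negative counts with `a + b + c + d >= 1`.
#' @return kappa in `[-1, 1]`; `NA` where chance agreement is 1 (a constant
#'   rater), in which case kappa is undefined and the feature is excluded
#'   from ranking.
#' @export
cohen_kappa <- function(a, b, c, d) {
  if (anyNA(c(a, b, c, d))) stop_invalid("counts must not be NA")
  if (any(a < 0) || any(b < 0) || any(c < 0) || any(d < 0)) {
    stop_invalid("counts must be non-negative")
  }
  n <- a + b + c + d
  if (any(n < 1)) stop_invalid("table total must be >= 1")
  po <- (a + d) / n
  pe <- ((a + b) * (a + c) + (c + d) * (b + d)) / n^2
  k <- (po - pe) / (1 - pe)
  k[abs(1 - pe) < 1e-12] <- NA_real_
  k
}

#' Cohen's kappa between two binary vectors
#'
#' @param x,y binary vectors of equal length (x = rater 1, y = rater 2).
#' @return kappa (see [cohen_kappa()]).
#' @export
kappa_profiles <- function(x, y) {
  if (length(x) != length(y)) stop_invalid("profiles differ in length")
  if (!is_binary_vector(as.numeric(x)) || !is_binary_vector(as.numeric(y))) {
    stop_invalid("profiles must be binary (0/1)")
  }
  x <- as.numeric(x); y <- as.numeric(y)
  cohen_kappa(sum(x * y), sum(x * (1 - y)), sum((1 - x) * y),
              sum((1 - x) * (1 - y)))
}

# Align a binary_peaks matrix to a named activity vector; error listing any
# species-set difference.
align_presence <- function(b, act) {
  only_b <- setdiff(b$species_ids, names(act))
  only_l <- setdiff(names(act), b$species_ids)
  if (length(only_b) || length(only_l)) {
    stop_invalid("species mismatch between peak matrix and labels; ",
                 "only in peaks: [", paste(only_b, collapse = ", "),
                 "]; only in labels: [", paste(only_l, collapse = ", "), "]")
  }
  b$presence[match(names(act), b$species_ids), , drop = FALSE]
}

# Two-sided Fisher's exact p for vectors of 2x2 counts.  fisher.test can
# exceed 1 by a few ulp when summing tail probabilities; clamp.
fisher_p <- function(a, b, c, d) {
  pmin(1, vapply(seq_along(a), function(i) {
    stats::fisher.test(matrix(c(a[i], c[i], b[i], d[i]), 2L))$p.value
  }, numeric(1)))
}

#' Screen every feature against one bioactivity classification
#'
#' Computes Cohen's kappa between each feature's presence profile and the
#' binary labels of one assay, a per-feature significance p (two-sided
#' Fisher's exact test on the 2x2 table), Benjamini-Hochberg flags at
#' `alpha`, and competition ranks on descending kappa (tied values share the
#' minimum rank of their block).  Features with undefined kappa (a constant
#' profile, chance agreement 1) get `NA` kappa and no rank.
#'
#' @param b a `binary_peaks` object.
#' @param labels an `activity_labels` data.frame covering the same species.
#' @param assay which assay's labels to screen against.
#' @param alpha FDR level for the BH flags.
#' @param compute_p logical; skip the (comparatively slow) exact tests when
#'   only kappas and ranks are needed, e.g. in large simulations.
#' @return data.frame, one row per feature, sorted by rank then feature id:
#'   `feature_id`, `assay`, `kappa`, `p_value`, `bh_significant`, `rank`.
#' @export
kappa_screen <- function(b, labels, assay, alpha = 0.05, compute_p = TRUE) {
  stopifnot(inherits(b, "binary_peaks"))
  act <- activity_vector(labels, assay)
  X <- align_presence(b, act)
  n1 <- sum(act); n0 <- sum(!act)
  sA <- colSums(X[act, , drop = FALSE])
  sI <- colSums(X[!act, , drop = FALSE])
  kap <- cohen_kappa(sA, sI, n1 - sA, n0 - sI)
  if (compute_p) {
    p <- fisher_p(sA, sI, n1 - sA, n0 - sI)
    bh <- benjamini_hochberg(p, alpha = alpha)
    sig <- bh$reject
  } else {
    p <- rep(NA_real_, length(kap))
    sig <- rep(NA, length(kap))
  }
  out <- data.frame(feature_id = b$feature_ids, assay = assay, kappa = kap,
                    p_value = p, bh_significant = sig,
                    rank = competition_rank(kap), stringsAsFactors = FALSE)
  out[order(out$rank, out$feature_id, na.last = TRUE), , drop = FALSE]
}

#' Qualitative strength tier of a kappa coefficient
#'
#' `strong` at kappa >= 0.68, `moderate` in \[0.35, 0.68), `low` below; the
#' boundaries are the phenomenological tiers used throughout this analysis.
#'
#' @param kappa numeric vector of defined kappas.
#' @return character vector in `{strong, moderate, low}`.
#' @export
strength_class <- function(kappa) {
  if (anyNA(kappa)) stop_invalid("kappa must be defined (non-NA)")
  ifelse(kappa >= 0.68, "strong", ifelse(kappa >= 0.35, "moderate", "low"))
}

#' Combined antimicrobial-but-non-cytotoxic score
#'
#' Per feature, `kappa_combined = kappa_am - (kappa_hacat + kappa_iec6)`:
#' agreement with antimicrobial activity is rewarded, agreement with either
#' cytotoxicity classification penalized.  A feature is `selected` (a
#' most-predictive candidate for an antimicrobial but non-cytotoxic
#' compound) when both `kappa_combined >= strong` and `kappa_am >= strong`.
#'
#' @param am,hacat,iec6 screen outputs from [kappa_screen()] for the three
#'   assays, covering the same features.  Features missing from any assay
#'   (or with undefined kappa in any) are excluded with a warning.
#' @param strong selection threshold, default 0.68.
#' @return data.frame sorted by `rank_c` (ties by feature id):
#'   `feature_id`, `kappa_am`, `kappa_hacat`, `kappa_iec6`,
#'   `kappa_combined`, `rank_c`, `rank_am`, `rank_hacat`, `rank_iec6`,
#'   `selected`.
#' @export
combined_score <- function(am, hacat, iec6, strong = 0.68) {
  common <- Reduce(intersect, list(am$feature_id, hacat$feature_id,
                                   iec6$feature_id))
  all_ids <- unique(c(am$feature_id, hacat$feature_id, iec6$feature_id))
  dropped <- setdiff(all_ids, common)
  i_am <- match(common, am$feature_id)
  i_h <- match(common, hacat$feature_id)
  i_i <- match(common, iec6$feature_id)
  defined <- !is.na(am$kappa[i_am]) & !is.na(hacat$kappa[i_h]) &
    !is.na(iec6$kappa[i_i])
  dropped <- c(dropped, common[!defined])
  if (length(dropped)) {
    warning(length(dropped), " feature(s) excluded from the combined score ",
            "(missing from an assay or undefined kappa)", call. = FALSE)
  }
  keep <- common[defined]
  i_am <- i_am[defined]; i_h <- i_h[defined]; i_i <- i_i[defined]
  kc <- am$kappa[i_am] - (hacat$kappa[i_h] + iec6$kappa[i_i])
  out <- data.frame(
    feature_id = keep,
    kappa_am = am$kappa[i_am], kappa_hacat = hacat$kappa[i_h],
    kappa_iec6 = iec6$kappa[i_i], kappa_combined = kc,
    rank_c = competition_rank(kc),
    rank_am = am$rank[i_am], rank_hacat = hacat$rank[i_h],
    rank_iec6 = iec6$rank[i_i],
    selected = kc >= strong & am$kappa[i_am] >= strong,
    stringsAsFactors = FALSE)
  out[order(out$rank_c, out$feature_id), , drop = FALSE]
}

#' Compound-level intensity t-test against the antimicrobial classification
#'
#' For each annotated compound, the LC-MS intensities (summed over the
#' compound's features when it is represented by more than one peak) of
#' active vs inactive species are compared by a two-tailed unpaired
#' pooled-variance t-test.
#'
#' @param table a [peak_table()].
#' @param annotation data.frame mapping `feature_id` to `compound`.
#' @param labels `activity_labels` providing the `"AM"` classification.
#' @param alpha significance level for the `significant` flag (raw p).
#' @return data.frame: `compound`, `n_features`, `t`, `p_value`,
#'   `significant`.  Compounds where the statistic is undefined (zero
#'   variance in both classes) carry `NA` with `significant = FALSE`.
#' @export
compound_ttest <- function(table, annotation, labels, alpha = 0.05) {
  stopifnot(inherits(table, "peak_table"),
            all(c("feature_id", "compound") %in% names(annotation)))
  act <- activity_vector(labels, "AM")
  if (sum(act) < 2L || sum(!act) < 2L) {
    stop_invalid("need >= 2 species per activity class")
  }
  X <- table$intensity[match(names(act), table$species_ids), , drop = FALSE]
  unknown <- setdiff(annotation$feature_id, table$features$feature_id)
  if (length(unknown)) {
    stop_invalid("annotation names unknown features: ",
                 paste(unknown, collapse = ", "))
  }
  out <- lapply(unique(as.character(annotation$compound)), function(cmp) {
    fids <- annotation$feature_id[annotation$compound == cmp]
    v <- rowSums(X[, fids, drop = FALSE])
    x1 <- v[act]; x0 <- v[!act]
    if (stats::var(x1) == 0 && stats::var(x0) == 0) {
      return(data.frame(compound = cmp, n_features = length(fids),
                        t = NA_real_, p_value = NA_real_,
                        significant = FALSE))
    }
    tt <- stats::t.test(x1, x0, var.equal = TRUE)
    data.frame(compound = cmp, n_features = length(fids),
               t = unname(tt$statistic), p_value = tt$p.value,
               significant = tt$p.value < alpha)
  })
  do.call(rbind, out)
}

#' Benjamini-Hochberg step-up procedure
#'
#' Standard step-up FDR control: with ordered p-values `p_(1) <= ... <=
#' p_(m)`, reject the hypotheses with the `k` smallest p-values where `k` is
#' the largest `i` such that `p_(i) <= i * alpha / m`.  Adjusted p-values
#' are the monotone BH-adjusted values of [stats::p.adjust()]; rejection is
#' equivalent to `p_adj <= alpha`.
#'
#' @param p p-values in `[0, 1]`.
#' @param alpha FDR level.
#' @return list with logical `reject` and numeric `p_adj`, both in the
#'   input order.
#' @export
benjamini_hochberg <- function(p, alpha = 0.05) {
  if (anyNA(p) || any(p < 0) || any(p > 1)) {
    stop_invalid("p-values must lie in [0, 1]")
  }
  p_adj <- stats::p.adjust(p, method = "BH")
  list(reject = p_adj <= alpha, p_adj = p_adj)
}
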