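# Exhaustive pairwise Boolean AND/OR combination screen over binary feature
# profiles.  AND combinations probe synergy/additivity (both compounds
# needed), OR combinations functional redundancy (either suffices).
#
# Kernel: contingency counts for all pairs in a feature block come from two
# cross-products of the presence matrix restricted to active and to inactive
# species — for AND, present-present counts are the cross-products directly;
# for OR they follow by inclusion-exclusion from the column sums.  Counts
# are exact integers, per-pair cost is O(n) inside BLAS, and blocks bound
# memory so the screen streams over the C(F,2) pairs without ever holding
# them all.

#' Combine two binary profiles with a Boolean operator
#'
#' @param x,y binary vectors of equal length.
#' @param operator `"AND"` (elementwise conjunction) or `"OR"`
#'   (disjunction).
#' @return binary vector.
#' @export
combine_profiles <- function(x, y, operator = c("AND", "OR")) {
  operator <- match.arg(operator)
  if (length(x) != length(y)) stop_invalid("profiles differ in length")
  if (!is_binary_vector(as.numeric(x)) || !is_binary_vector(as.numeric(y))) {
    stop_invalid("profiles must be binary (0/1)")
  }
  if (operator == "AND") as.numeric(x) * as.numeric(y)
  else 1 - (1 - as.numeric(x)) * (1 - as.numeric(y))
}

# kappa from count matrices (vectorized over matrix cells); NA where
# chance agreement is 1 (constant combined profile or constant labels).
kappa_from_counts <- function(a, b, c, d) {
  n <- a + b + c + d
  po <- (a + d) / n
  pe <- ((a + b) * (a + c) + (c + d) * (b + d)) / n^2
  k <- (po - pe) / (1 - pe)
  k[abs(1 - pe) < 1e-12] <- NA_real_
  k
}

#' Screen all feature pairs under a Boolean combination
#'
#' Evaluates Cohen's kappa between the combined profile of every unordered
#' feature pair and one assay's binary labels.  Summary tallies (pairs
#' evaluated, strong pairs, outperforming pairs, best pair kappa) cover all
#' `C(F,2)` pairs; individual pair records are materialized only when their
#' kappa reaches `report_threshold` or beats the best individual feature
#' kappa, keeping memory bounded.  A pair is `outperforming` when its kappa
#' is strictly greater than the best defined individual-feature kappa on
#' the same inputs.  Pairs with a constant combined profile (undefined
#' kappa) count as evaluated but are excluded from the strong/outperforming
#' tallies.
#'
#' @param b a `binary_peaks` object with >= 2 features.
#' @param labels `activity_labels` covering the same species.
#' @param assay assay to screen against.
#' @param operator `"AND"` or `"OR"`.
#' @param strong threshold for the strong-pair tally, default 0.68.
#' @param report_threshold materialize records with kappa at or above this
#'   value (default `strong`).
#' @param block_size feature-block width of the kernel.
#' @return list with `records` (data.frame `feature_i`, `feature_j`
#'   with `i < j` in column order, `kappa`, `outperforming`, sorted by
#'   descending kappa) and `summary` (list: `operator`,
#'   `n_pairs_evaluated`, `n_strong`, `n_outperforming`, `n_undefined`,
#'   `best_pair_kappa`, `best_individual_kappa`, `strong_threshold`,
#'   `report_threshold`).
#' @export
pairwise_screen <- function(b, labels, assay, operator = c("AND", "OR"),
                            strong = 0.68, report_threshold = strong,
                            block_size = 1024L) {
  operator <- match.arg(operator)
  stopifnot(inherits(b, "binary_peaks"))
  nf <- length(b$feature_ids)
  if (nf < 2L) stop_invalid("pair screen needs >= 2 features")
  act <- activity_vector(labels, assay)
  X <- align_presence(b, act)
  storage.mode(X) <- "double"
  n1 <- sum(act); n0 <- sum(!act); n <- n1 + n0
  XA <- X[act, , drop = FALSE]
  XI <- X[!act, , drop = FALSE]
  sA <- colSums(XA); sI <- colSums(XI)

  # individual kappas define the outperformance cutoff
  ind <- kappa_from_counts(sA, sI, n1 - sA, n0 - sI)
  best_ind <- if (all(is.na(ind))) -Inf else max(ind, na.rm = TRUE)

  blocks <- split(seq_len(nf), ceiling(seq_len(nf) / block_size))
  n_strong <- 0; n_outperf <- 0; n_undef <- 0
  best_pair <- -Inf
  recs <- list()
  for (bi in seq_along(blocks)) {
    I <- blocks[[bi]]
    for (bj in bi:length(blocks)) {
      J <- blocks[[bj]]
      PA <- crossprod(XA[, I, drop = FALSE], XA[, J, drop = FALSE])
      PI <- crossprod(XI[, I, drop = FALSE], XI[, J, drop = FALSE])
      if (operator == "AND") {
        a <- PA; bb <- PI
      } else {
        a <- outer(sA[I], sA[J], "+") - PA
        bb <- outer(sI[I], sI[J], "+") - PI
      }
      K <- kappa_from_counts(a, bb, n1 - a, n0 - bb)
      valid <- if (bi == bj) upper.tri(K) else
        matrix(TRUE, length(I), length(J))
      n_undef <- n_undef + sum(valid & is.na(K))
      kv <- K[valid]
      kv_def <- kv[!is.na(kv)]
      if (length(kv_def)) {
        n_strong <- n_strong + sum(kv_def >= strong)
        n_outperf <- n_outperf + sum(kv_def > best_ind)
        best_pair <- max(best_pair, kv_def)
      }
      hit <- valid & !is.na(K) & (K >= report_threshold | K > best_ind)
      if (any(hit)) {
        w <- which(hit, arr.ind = TRUE)
        recs[[length(recs) + 1L]] <- data.frame(
          feature_i = b$feature_ids[I[w[, 1L]]],
          feature_j = b$feature_ids[J[w[, 2L]]],
          kappa = K[hit],
          outperforming = K[hit] > best_ind,
          stringsAsFactors = FALSE)
      }
    }
  }
  records <- if (length(recs)) do.call(rbind, recs) else
    data.frame(feature_i = character(0), feature_j = character(0),
               kappa = numeric(0), outperforming = logical(0))
  records <- records[order(-records$kappa, records$feature_i,
                           records$feature_j), , drop = FALSE]
  rownames(records) <- NULL
  list(records = records,
       summary = list(operator = operator,
                      n_pairs_evaluated = nf * (nf - 1) / 2,
                      n_strong = n_strong,
                      n_outperforming = n_outperf,
                      n_undefined = n_undef,
                      best_pair_kappa = if (is.finite(best_pair))
                        best_pair else NA_real_,
                      best_individual_kappa = if (is.finite(best_ind))
                        best_ind else NA_real_,
                      strong_threshold = strong,
                      report_threshold = report_threshold))
}

#' Involvement of a feature set in outperforming pair combinations
#'
#' @param records pair records (e.g. the outperforming subset of
#'   [pairwise_screen()] records).
#' @param focus_set character vector of feature ids of interest (typically
#'   the most-predictive individual features).
#' @return list with `fraction` (share of records with at least one
#'   endpoint in `focus_set`; `NA` when there are no records) and
#'   `per_feature` (named containment fraction for each focus feature).
#' @export
involvement_stats <- function(records, focus_set) {
  focus_set <- as.character(focus_set)
  if (nrow(records) == 0L) {
    return(list(fraction = NA_real_,
                per_feature = stats::setNames(rep(NA_real_,
                                                  length(focus_set)),
                                              focus_set)))
  }
  hit <- records$feature_i %in% focus_set | records$feature_j %in% focus_set
  per <- vapply(focus_set, function(f) {
    mean(records$feature_i == f | records$feature_j == f)
  }, numeric(1))
  list(fraction = mean(hit), per_feature = per)
}

#' Pair-kappa matrix over the most-involved features, for heatmap plotting
#'
#' Selects the `k` features most often contained in outperforming pair
#' records (ties broken by individual kappa, then feature id) and lays out
#' their pairwise kappas as a symmetric matrix with `NA` sentinels on the
#' diagonal (self-pairs are never evaluated) and for pairs absent from
#' `records`.
#'
#' @param records pair records from [pairwise_screen()].
#' @param k number of features, >= 2.
#' @param individual_kappa named vector of individual feature kappas (tie
#'   break and marginal annotation).
#' @return list with `features` (selected ids, in order), `matrix`
#'   (k x k symmetric kappa matrix) and `individual` (their individual
#'   kappas).
#' @export
top_pairs_heatmap_table <- function(records, k, individual_kappa) {
  if (k < 2L) stop_invalid("k must be >= 2")
  outp <- records[records$outperforming, , drop = FALSE]
  counts <- table(c(outp$feature_i, outp$feature_j))
  ids <- union(names(individual_kappa), names(counts))
  cnt <- stats::setNames(rep(0L, length(ids)), ids)
  cnt[names(counts)] <- as.integer(counts)
  ik <- stats::setNames(rep(-Inf, length(ids)), ids)
  ik[names(individual_kappa)] <- ifelse(is.na(individual_kappa), -Inf,
                                        individual_kappa)
  ord <- order(-cnt, -ik[names(cnt)], names(cnt))
  sel <- names(cnt)[ord][seq_len(min(k, length(ids)))]
  m <- matrix(NA_real_, length(sel), length(sel), dimnames = list(sel, sel))
  keep <- records$feature_i %in% sel & records$feature_j %in% sel
  rr <- records[keep, , drop = FALSE]
  if (nrow(rr)) {
    m[cbind(rr$feature_i, rr$feature_j)] <- rr$kappa
    m[cbind(rr$feature_j, rr$feature_i)] <- rr$kappa
  }
  list(features = sel, matrix = m,
       individual = stats::setNames(
         individual_kappa[match(sel, names(individual_kappa))], sel))
}
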