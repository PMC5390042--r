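# Independent oracles and small fixture builders shared across tests.

# Independent closed form for 2x2 kappa (distinct algebraic route from the
# (p_o - p_e)/(1 - p_e) implementation): 2(ad - bc) / ((a+b)(b+d)+(a+c)(c+d)).
kappa_oracle <- function(a, b, c, d) {
  den <- (a + b) * (b + d) + (a + c) * (c + d)
  if (den == 0) return(NA_real_)
  2 * (a * d - b * c) / den
}

# Naive per-pair Boolean screen: explicit profile combination and direct
# count tabulation, one pair at a time.
naive_pair_screen <- function(presence, feature_ids, act, operator) {
  nf <- ncol(presence)
  out <- vector("list", nf * (nf - 1) / 2)
  r <- 0L
  for (i in seq_len(nf - 1L)) {
    for (j in (i + 1L):nf) {
      z <- if (operator == "AND") presence[, i] & presence[, j]
           else presence[, i] | presence[, j]
      a <- sum(z & act); b <- sum(z & !act)
      c <- sum(!z & act); d <- sum(!z & !act)
      r <- r + 1L
      out[[r]] <- data.frame(feature_i = feature_ids[i],
                             feature_j = feature_ids[j],
                             kappa = kappa_oracle(a, b, c, d))
    }
  }
  do.call(rbind, out)
}

# Brute-force BH step-up straight from the definition.
bh_oracle <- function(p, alpha) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  k <- suppressWarnings(max(which(ps <= seq_len(m) * alpha / m)))
  reject <- rep(FALSE, m)
  if (is.finite(k) && k >= 1) reject[o[seq_len(k)]] <- TRUE
  reject
}

# Labels object built directly from a binary activity vector (bypasses the
# bioassay classifiers when a test targets the screens alone).
labels_from_vector <- function(act, assay = "AM") {
  df <- data.frame(species_id = names(act), assay = assay,
                   label = ifelse(act == 1, "active", "inactive"),
                   statistic = NA_real_, p_value = NA_real_,
                   p_adj = NA_real_, stringsAsFactors = FALSE)
  structure(df, class = c("activity_labels", "data.frame"),
            thresholds = list())
}

# Random binary_peaks object over given species.
random_binary_peaks <- function(n_species, n_features, prevalence = 0.3,
                                seed = 1) {
  set.seed(seed)
  sp <- sprintf("sp_%03d", seq_len(n_species))
  pres <- matrix(as.numeric(runif(n_species * n_features) < prevalence),
                 n_species, n_features,
                 dimnames = list(sp, sprintf("F%05d", seq_len(n_features))))
  structure(list(presence = pres, species_ids = sp,
                 feature_ids = colnames(pres), threshold_used = 1e4),
            class = "binary_peaks")
}

# Tiny peak table with explicit intensities.
toy_peak_table <- function() {
  peak_table(
    features = data.frame(feature_id = c("A", "B", "C"),
                          mz = c(499.17, 523.19, 333.19),
                          rt = c(68.4, 67.7, 64.8)),
    species_ids = c("sp1", "sp2"),
    intensity = matrix(c(2e4, 0, 1e4, 9999.9, 5e3, 1e6), nrow = 2))
}
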