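test_that("combine_profiles satisfies the Boolean identities", {
  set.seed(61)
  x <- as.numeric(runif(20) < 0.4)
  y <- as.numeric(runif(20) < 0.4)
  ones <- rep(1, 20); zeros <- rep(0, 20)
  expect_equal(combine_profiles(x, ones, "AND"), x)
  expect_equal(combine_profiles(x, zeros, "OR"), x)
  expect_equal(combine_profiles(x, x, "AND"), x)
  expect_equal(combine_profiles(x, x, "OR"), x)
  expect_equal(combine_profiles(x, y, "AND"), combine_profiles(y, x, "AND"))
  expect_equal(combine_profiles(x, y, "OR"), combine_profiles(y, x, "OR"))
  expect_error(combine_profiles(x, y[1:10], "AND"), "length")
  expect_error(combine_profiles(x, y, "XOR"))
})

test_that("pairwise_screen evaluates exactly C(F,2) pairs", {
  b <- random_binary_peaks(20, 25, seed = 62)
  act <- setNames(as.numeric(runif(20) < 0.4), b$species_ids)
  if (sum(act) == 0) act[1] <- 1
  ps <- pairwise_screen(b, labels_from_vector(act), "AM", "AND")
  expect_equal(ps$summary$n_pairs_evaluated, 25 * 24 / 2)
})

test_that("block kernel equals the naive per-pair screen exactly", {
  # moderate size here; the full 100x200 equivalence runs in the
  # acceptance suite
  b <- random_binary_peaks(30, 40, prevalence = 0.35, seed = 63)
  act <- setNames(as.numeric(runif(30) < 0.4), b$species_ids)
  if (sum(act) == 0) act[1] <- 1
  lab <- labels_from_vector(act)
  for (op in c("AND", "OR")) {
    # small block size exercises the block boundaries
    ps <- pairwise_screen(b, lab, "AM", op, report_threshold = -Inf,
                          block_size = 7L)
    naive <- naive_pair_screen(b$presence, b$feature_ids, act == 1, op)
    key <- function(d) paste(d$feature_i, d$feature_j)
    m <- match(key(naive), key(ps$records))
    defined <- !is.na(naive$kappa)
    expect_true(all(!is.na(m[defined])))
    expect_equal(ps$records$kappa[m[defined]], naive$kappa[defined],
                 tolerance = 1e-12)
    expect_equal(ps$summary$best_pair_kappa, max(naive$kappa, na.rm = TRUE),
                 tolerance = 1e-12)
    expect_equal(ps$summary$n_strong, sum(naive$kappa >= 0.68, na.rm = TRUE))
    expect_equal(ps$summary$n_undefined, sum(is.na(naive$kappa)))
  }
})

test_that("pair kappa is invariant under swapping the pair order", {
  set.seed(64)
  x <- as.numeric(runif(40) < 0.4)
  y <- as.numeric(runif(40) < 0.4)
  act <- as.numeric(runif(40) < 0.4)
  for (op in c("AND", "OR")) {
    k1 <- kappa_profiles(combine_profiles(x, y, op), act)
    k2 <- kappa_profiles(combine_profiles(y, x, op), act)
    expect_equal(k1, k2)
  }
})

test_that("a noiseless planted AND pair is the unique top pair and outperforms", {
  cfg <- synthetic_config(n_species = 40, n_features = 120, flip_noise = 0,
                          n_causal_single = 0, n_redundancy_pairs = 0,
                          active_fraction = 0.3, seed = 65)
  act <- c(rep(1, 12), rep(0, 28))
  g <- generate_peak_table(cfg, act)
  bp <- filter_ubiquitous(binarize(g$table))
  lab <- labels_from_vector(setNames(act, g$table$species_ids))
  ps <- pairwise_screen(bp, lab, "AM", "AND")
  expect_equal(ps$records$kappa[1], 1)
  expect_setequal(unlist(ps$records[1, c("feature_i", "feature_j")]),
                  g$truth$synergy_pairs[[1]])
  expect_true(ps$records$outperforming[1])
  # components individually weak by construction
  sc <- kappa_screen(bp, lab, "AM", compute_p = FALSE)
  comp_k <- sc$kappa[match(g$truth$synergy_pairs[[1]], sc$feature_id)]
  expect_true(all(comp_k < 0.5))
})

test_that("outperforming records are materialized even below the report threshold", {
  b <- random_binary_peaks(30, 15, prevalence = 0.25, seed = 66)
  act <- setNames(as.numeric(runif(30) < 0.3), b$species_ids)
  if (sum(act) == 0) act[1] <- 1
  ps <- pairwise_screen(b, labels_from_vector(act), "AM", "AND",
                        report_threshold = 0.99)
  if (ps$summary$n_outperforming > 0) {
    expect_equal(sum(ps$records$outperforming), ps$summary$n_outperforming)
  }
})

test_that("involvement fractions hit the trivial bounds", {
  rec <- data.frame(feature_i = c("A", "B", "C"),
                    feature_j = c("B", "C", "D"),
                    kappa = c(0.9, 0.8, 0.7),
                    outperforming = TRUE)
  expect_equal(involvement_stats(rec, c("A", "B", "C", "D"))$fraction, 1)
  expect_equal(involvement_stats(rec, character(0))$fraction, 0)
  inv <- involvement_stats(rec, c("B", "Z"))
  expect_equal(inv$fraction, 2 / 3)
  expect_equal(unname(inv$per_feature["B"]), 2 / 3)
  expect_equal(unname(inv$per_feature["Z"]), 0)
  # no records: undefined, reported as such
  expect_true(is.na(involvement_stats(rec[0, ], c("A"))$fraction))
})

test_that("heatmap table is symmetric with sentinel diagonal and count-based selection", {
  rec <- data.frame(feature_i = c("A", "A", "B", "C"),
                    feature_j = c("B", "C", "C", "D"),
                    kappa = c(0.9, 0.85, 0.8, 0.75),
                    outperforming = c(TRUE, TRUE, TRUE, FALSE))
  ik <- c(A = 0.7, B = 0.5, C = 0.6, D = 0.4)
  ht <- top_pairs_heatmap_table(rec, k = 3, individual_kappa = ik)
  # membership counts among outperforming pairs: A=2, C=2, B=2, D=0;
  # ties broken by individual kappa: A (0.7), C (0.6), B (0.5)
  expect_equal(ht$features, c("A", "C", "B"))
  expect_true(all(is.na(diag(ht$matrix))))
  expect_equal(ht$matrix, t(ht$matrix))
  expect_equal(ht$matrix["A", "B"], 0.9)
  expect_error(top_pairs_heatmap_table(rec, k = 1, ik), ">= 2")
})
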