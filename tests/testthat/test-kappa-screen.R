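test_that("cohen_kappa reproduces hand-computed tables and rejects bad input", {
  expect_equal(cohen_kappa(5, 0, 0, 5), 1)
  expect_equal(cohen_kappa(0, 5, 5, 0), -1)
  # p_o = 0.8, p_e = 0.5 -> kappa = 0.6
  expect_equal(cohen_kappa(4, 1, 1, 4), 0.6, tolerance = 1e-12)
  expect_error(cohen_kappa(-1, 0, 0, 5), "non-negative")
  expect_error(cohen_kappa(0, 0, 0, 0), ">= 1")
  # one constant rater: chance agreement below 1, kappa defined and 0
  expect_equal(cohen_kappa(3, 4, 0, 0), 0)
  # full marginal homogeneity (all mass in one agreeing cell): p_e = 1,
  # kappa undefined
  expect_true(is.na(cohen_kappa(7, 0, 0, 0)))
})

test_that("cohen_kappa invariances hold on random tables", {
  set.seed(11)
  for (i in 1:50) {
    tb <- as.numeric(rmultinom(1, sample(5:200, 1), runif(4, 0.05, 1)))
    k1 <- cohen_kappa(tb[1], tb[2], tb[3], tb[4])
    # swapping (a<->d, b<->c) leaves kappa unchanged
    k2 <- cohen_kappa(tb[4], tb[3], tb[2], tb[1])
    expect_equal(k1, k2, tolerance = 1e-12)
  }
  # kappa(x, x) = 1 and independence from species ordering
  set.seed(12)
  x <- as.numeric(runif(87) < 0.3)
  y <- as.numeric(runif(87) < 0.2)
  expect_equal(kappa_profiles(x, x), 1)
  perm <- sample(87)
  expect_equal(kappa_profiles(x, y), kappa_profiles(x[perm], y[perm]))
})

test_that("mean kappa of independent random raters is near zero", {
  set.seed(13)
  n <- 87
  draws <- 10000
  X <- matrix(as.numeric(runif(n * draws) < 0.3), n, draws)
  y <- as.numeric(runif(n) < 0.25)
  a <- colSums(X * y); b <- colSums(X * (1 - y))
  k <- cohen_kappa(a, b, sum(y) - a, sum(1 - y) - b)
  expect_lt(abs(mean(k, na.rm = TRUE)), 0.02)
})

test_that("kappa_screen ranks a label-identical feature first and uses competition ranks", {
  set.seed(21)
  b <- random_binary_peaks(40, 30, seed = 21)
  act <- setNames(as.numeric(runif(40) < 0.4), b$species_ids)
  if (sum(act) == 0) act[1] <- 1
  # make three features identical to the labels (tied at kappa 1)
  b$presence[, 1:3] <- act
  res <- kappa_screen(b, labels_from_vector(act), "AM", compute_p = FALSE)
  top <- res[res$rank == 1, ]
  expect_setequal(top$feature_id, b$feature_ids[1:3])
  expect_equal(top$kappa, rep(1, 3))
  # competition ranking: next distinct value takes rank 4
  expect_equal(min(res$rank[res$rank > 1], na.rm = TRUE), 4)
})

test_that("kappa_screen reports species mismatches", {
  b <- random_binary_peaks(10, 5, seed = 3)
  act <- setNames(rep(c(1, 0), 5), sprintf("other_%02d", 1:10))
  expect_error(kappa_screen(b, labels_from_vector(act), "AM"),
               "species mismatch")
})

test_that("screen p-values agree with Fisher's exact test and BH flags with p.adjust", {
  set.seed(22)
  b <- random_binary_peaks(30, 20, seed = 22)
  act <- setNames(as.numeric(runif(30) < 0.4), b$species_ids)
  b$presence[, 1] <- act  # one real association
  res <- kappa_screen(b, labels_from_vector(act), "AM")
  i <- match("F00001", res$feature_id)
  tb <- table(factor(b$presence[, 1], 0:1), factor(act, 0:1))
  expect_equal(res$p_value[i], fisher.test(tb)$p.value, tolerance = 1e-12)
  expect_true(res$bh_significant[i])
})

test_that("strength tiers split at 0.68 and 0.35", {
  expect_equal(strength_class(c(0.68, 0.9, 0.35, 0.67, 0.34, -1)),
               c("strong", "strong", "moderate", "moderate", "low", "low"))
  expect_error(strength_class(c(0.5, NA)), "defined")
})

test_that("combined score is the stated linear combination with conjunctive selection", {
  mk <- function(k) data.frame(feature_id = c("A", "B", "C"), assay = "x",
                               kappa = k, p_value = NA, bh_significant = NA,
                               rank = rank(-k, ties.method = "min"))
  am <- mk(c(0.8, 0.9, 0.7)); ha <- mk(c(0.05, 0, 0)); ie <- mk(c(0.05, 0.3, 0))
  cs <- combined_score(am, ha, ie)
  expect_equal(cs$kappa_combined[match("A", cs$feature_id)], 0.7)
  # kappa_am 0.9 but combined 0.6: conjunction fails
  expect_equal(cs$kappa_combined[match("B", cs$feature_id)], 0.6)
  expect_false(cs$selected[match("B", cs$feature_id)])
  expect_true(cs$selected[match("A", cs$feature_id)])
  # reduces to kappa_am when both cytotoxicity kappas are zero
  expect_equal(cs$kappa_combined[match("C", cs$feature_id)],
               cs$kappa_am[match("C", cs$feature_id)])
  # missing feature excluded with a warning
  expect_warning(cs2 <- combined_score(am[1:2, ], ha, ie), "excluded")
  expect_setequal(cs2$feature_id, c("A", "B"))
})

test_that("compound t-test is symmetric under label swap and near-null on equal groups", {
  set.seed(31)
  n <- 40
  sp <- sprintf("sp_%03d", 1:n)
  inten <- matrix(10^rnorm(n * 4, 4.5, 0.3), n, 4)
  pt <- peak_table(data.frame(feature_id = paste0("F", 1:4),
                              mz = 100 + 1:4, rt = 1:4), sp, inten)
  ann <- data.frame(feature_id = paste0("F", 1:4),
                    compound = c("cmpA", "cmpA", "cmpB", "cmpC"))
  act <- setNames(as.numeric(seq_len(n) <= 15), sp)
  lab <- labels_from_vector(act)
  r1 <- compound_ttest(pt, ann, lab)
  lab_sw <- labels_from_vector(setNames(1 - act, sp))
  r2 <- compound_ttest(pt, ann, lab_sw)
  expect_equal(abs(r1$t), abs(r2$t), tolerance = 1e-12)
  expect_equal(nrow(r1), 3)  # one row per compound, not per feature
  # null: no mean shift, typical p is large; assert no tiny p across compounds
  expect_gt(min(r1$p_value), 1e-4)
})

test_that("compound t-test detects a planted mean shift", {
  set.seed(32)
  hits <- vapply(1:30, function(s) {
    set.seed(s)
    n <- 87
    act <- as.numeric(seq_len(n) <= 17)
    v <- rnorm(n, 1e4, 2e3) + act * 6e3  # +3 SD shift in active class
    pt <- peak_table(data.frame(feature_id = "F1", mz = 300, rt = 10),
                     sprintf("sp_%03d", 1:n), matrix(pmax(v, 1), ncol = 1))
    lab <- labels_from_vector(setNames(act, sprintf("sp_%03d", 1:n)))
    compound_ttest(pt, data.frame(feature_id = "F1", compound = "X"),
                   lab)$significant
  }, logical(1))
  expect_true(all(hits))
})

test_that("benjamini_hochberg matches the step-up definition on fixed cases", {
  expect_true(all(benjamini_hochberg(rep(0, 5))$reject))
  expect_true(benjamini_hochberg(0.04, alpha = 0.05)$reject)
  expect_false(benjamini_hochberg(0.06, alpha = 0.05)$reject)
  # frozen from the brute-force step-up oracle: 0.04 > 3 * 0.05 / 4, so only
  # the two smallest are rejected
  p <- c(0.01, 0.02, 0.04, 0.8)
  expect_equal(benjamini_hochberg(p, 0.05)$reject, c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(benjamini_hochberg(p, 0.05)$reject, bh_oracle(p, 0.05))
  expect_error(benjamini_hochberg(c(0.5, 1.2)), "\\[0, 1\\]")
  # adjusted p is monotone in p
  set.seed(41)
  pr <- runif(50)
  adj <- benjamini_hochberg(pr)$p_adj
  expect_true(all(diff(adj[order(pr)]) >= -1e-15))
})
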