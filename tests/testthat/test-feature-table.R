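test_that("peak table round-trips through CSV exactly", {
  pt <- toy_peak_table()
  path <- tempfile(fileext = ".csv")
  write_peak_table(pt, path)
  back <- read_peak_table(path)
  expect_equal(back, pt)
  unlink(path)
})

test_that("peak table construction and CSV parsing report malformed input", {
  expect_error(peak_table(data.frame(feature_id = c("A", "A"),
                                     mz = c(1, 2), rt = c(1, 2)),
                          "sp1", matrix(0, 1, 2)),
               "duplicate feature_id: A")
  expect_error(peak_table(data.frame(feature_id = c("A", "B"),
                                     mz = c(1, 1), rt = c(2, 2)),
                          "sp1", matrix(0, 1, 2)),
               "duplicate \\(mz, rt\\)")
  # missing cell -> 0 with a warning naming the line
  path <- tempfile(fileext = ".csv")
  writeLines(c("feature_id,mz,rt,sp1,sp2",
               "A,100.1,5.0,20000,",
               "B,200.2,6.0,5000,30000"), path)
  expect_warning(pt <- read_peak_table(path), "line\\(s\\) 2")
  expect_equal(unname(pt$intensity["sp2", "A"]), 0)
  # non-numeric intensity is an error naming column and line
  writeLines(c("feature_id,mz,rt,sp1",
               "A,100.1,5.0,oops"), path)
  expect_error(read_peak_table(path), "non-numeric intensity")
  unlink(path)
})

test_that("binarize applies the >= threshold and is monotone in it", {
  pt <- toy_peak_table()
  b <- binarize(pt, 1e4)
  expect_equal(unname(b$presence["sp1", ]), c(1, 1, 0))  # 1e4 is present
  expect_equal(unname(b$presence["sp2", "B"]), 0)        # 9999.9 is absent
  # higher threshold shrinks the presence set
  b2 <- binarize(pt, 5e4)
  expect_true(all(b2$presence <= b$presence))
  expect_error(binarize(pt, -1), "positive")
})

test_that("ubiquitous filter removes only all-present features and is idempotent", {
  b <- random_binary_peaks(8, 6, seed = 5)
  b$presence[, 2] <- 1            # present in all 8
  b$presence[, 3] <- c(0, rep(1, 7))  # present in 7/8: retained
  f <- filter_ubiquitous(b)
  expect_equal(attr(f, "removed"), "F00002")
  expect_true("F00003" %in% f$feature_ids)
  f2 <- filter_ubiquitous(f)
  expect_equal(f2$feature_ids, f$feature_ids)
  # empty matrix passes through
  b$presence <- b$presence[, 0, drop = FALSE]
  b$feature_ids <- character(0)
  expect_equal(length(filter_ubiquitous(b)$feature_ids), 0)
})

test_that("Pareto scaling divides centered columns by sqrt(sd)", {
  set.seed(6)
  m <- cbind(a = rnorm(50, sd = 2), b = rnorm(50, sd = 0.5))
  m[, 1] <- m[, 1] / sd(m[, 1]) * 4  # force sd exactly 4
  s <- pareto_scale(m)
  expect_equal(s[, 1], (m[, 1] - mean(m[, 1])) / 2, tolerance = 1e-12)
  expect_warning(pareto_scale(cbind(m, c = rep(1, 50))), "zero-variance")
})

test_that("PCA scores respect duplicates, permutation and variance conservation", {
  set.seed(7)
  n <- 12
  pt <- peak_table(data.frame(feature_id = sprintf("F%02d", 1:20),
                              mz = 100 + 1:20, rt = 1:20),
                   sprintf("sp_%03d", 1:n),
                   matrix(10^rnorm(n * 20, 4, 0.5), n, 20))
  pt$intensity[2, ] <- pt$intensity[1, ]  # duplicate species rows
  p <- pca_pareto(pt, n_components = 3)
  expect_equal(p$scores[1, ], p$scores[2, ], tolerance = 1e-8)
  expect_equal(sum(p$explained_variance), 100, tolerance = 1e-8)
  # row permutation changes only the row order (up to component sign)
  perm <- sample(n)
  pt2 <- pt
  pt2$intensity <- pt$intensity[perm, ]
  pt2$species_ids <- pt$species_ids[perm]
  dimnames(pt2$intensity) <- list(pt2$species_ids, pt$features$feature_id)
  p2 <- pca_pareto(pt2, n_components = 3)
  for (k in 1:3) {
    expect_equal(abs(p2$scores[match(pt$species_ids, pt2$species_ids), k]),
                 abs(p$scores[, k]), tolerance = 1e-6)
  }
})

test_that("group ellipses need 3 members and describe the 2-SD contour", {
  set.seed(8)
  scores <- cbind(rnorm(20), rnorm(20))
  group <- rep(c("g1", "g2"), c(18, 2))
  expect_warning(e <- group_ellipse(scores, group), "< 3 members")
  expect_equal(e$group, "g1")
  expect_equal(e$center1, mean(scores[1:18, 1]))
  ev <- eigen(cov(scores[1:18, ]))$values
  expect_equal(e$semi_major, 2 * sqrt(ev[1]), tolerance = 1e-10)
})

test_that("chemical diversity counts are deterministic and order-invariant", {
  b <- random_binary_peaks(6, 10, seed = 9)
  grouping <- setNames(rep(c("X", "Y"), each = 3), b$species_ids)
  d <- chemical_diversity(b, grouping)
  expect_equal(d$mean_per_species[d$group == "X"],
               mean(rowSums(b$presence[1:3, ])))
  overall <- sum(colSums(b$presence) > 0)
  expect_true(all(d$total_distinct <= overall))
  # permuting species leaves counts unchanged
  perm <- c(3, 1, 2, 6, 5, 4)
  b2 <- b
  b2$presence <- b$presence[perm, ]
  b2$species_ids <- b$species_ids[perm]
  rownames(b2$presence) <- b2$species_ids
  expect_equal(chemical_diversity(b2, grouping), d)
  expect_error(chemical_diversity(b, grouping[1:4]), "does not cover")
  expect_error(chemical_diversity(b, c(grouping, zz = "X")), "unknown species")
})
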