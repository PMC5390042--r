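# Fritz-Purvis D statistic for phylogenetic signal of a binary trait on a
# rooted bifurcating tree, with permutation p-values against two nulls:
# random tip shuffles (D approx 1) and a Brownian-threshold model (D approx
# 0).  The observed quantity d is the sum over internal nodes of the
# absolute difference between the two daughter values, where tip values are
# the trait and each internal value is the mean of its daughters
# (post-order daughter-mean recursion); D scales d between the two null
# means.

# Topological order of nodes with every node after its descendants
# (iterative preorder, reversed).  Returns list(order, children) where
# children is a 2-column matrix indexed by internal node.
tree_traversal <- function(tree) {
  n <- length(tree$tip.label)
  m <- tree$Nnode
  edge <- tree$edge
  ch <- vector("list", n + m)
  for (e in seq_len(nrow(edge))) {
    ch[[edge[e, 1L]]] <- c(ch[[edge[e, 1L]]], edge[e, 2L])
  }
  if (any(lengths(ch[(n + 1L):(n + m)]) != 2L)) {
    stop_invalid("tree must be strictly bifurcating; ",
                 "run resolve_polytomies() first")
  }
  root <- n + 1L
  stack <- root
  ord <- integer(0)
  while (length(stack)) {
    nd <- stack[length(stack)]
    stack <- stack[-length(stack)]
    ord <- c(nd, ord)
    if (nd > n) stack <- c(stack, ch[[nd]])
  }
  list(order = ord, children = ch, n_tips = n, root = root)
}

# Sum of sister-clade differences for each trait column.
# traits: n_tips x m matrix, rows in tree$tip.label order.
sister_diff_sum <- function(tree, traits, trav = tree_traversal(tree)) {
  traits <- as.matrix(traits)
  n <- trav$n_tips
  stopifnot(nrow(traits) == n)
  V <- matrix(NA_real_, n + tree$Nnode, ncol(traits))
  V[seq_len(n), ] <- traits
  d <- numeric(ncol(traits))
  for (nd in trav$order) {
    if (nd <= n) next
    cs <- trav$children[[nd]]
    d <- d + abs(V[cs[1L], ] - V[cs[2L], ])
    V[nd, ] <- (V[cs[1L], ] + V[cs[2L], ]) / 2
  }
  d
}

# Brownian-motion tip liabilities: root value 0, edge increments
# Normal(0, branch length); rate 1 (scale cancels through thresholding).
# Returns n_tips x m matrix in tip order.  Caller controls the seed.
bm_tip_liabilities <- function(tree, m) {
  n <- length(tree$tip.label)
  tr <- ape::reorder.phylo(tree, "cladewise")  # parents before children
  V <- matrix(0, n + tree$Nnode, m)
  bl <- tr$edge.length
  if (is.null(bl)) stop_invalid("tree must have branch lengths")
  if (any(bl <= 0)) stop_invalid("branch lengths must be positive")
  for (e in seq_len(nrow(tr$edge))) {
    V[tr$edge[e, 2L], ] <- V[tr$edge[e, 1L], ] +
      stats::rnorm(m, sd = sqrt(bl[e]))
  }
  V[seq_len(n), , drop = FALSE]
}

# Threshold liabilities column-wise so each column has exactly k ones
# (the k largest liabilities; ties broken by first occurrence).
threshold_liabilities <- function(L, k) {
  n <- nrow(L)
  apply(L, 2L, function(col) {
    as.numeric(rank(col, ties.method = "first") > n - k)
  })
}

#' Resolve polytomies into arbitrary bifurcations
#'
#' Multifurcations are split into random bifurcations (deterministically,
#' given `seed`); the zero-length internal branches this creates are
#' replaced by a small epsilon (1e-3 times the smallest positive branch
#' length) so Brownian simulation variance stays positive.  Bifurcating
#' input is returned unchanged.
#'
#' @param tree an `ape` `phylo` object.
#' @param seed integer seed controlling the resolution.
#' @return a bifurcating `phylo`; when branches were adjusted, the epsilon
#'   used is recorded in attribute `"epsilon"`.
#' @export
resolve_polytomies <- function(tree, seed = 1L) {
  stopifnot(inherits(tree, "phylo"))
  if (ape::is.binary(tree)) return(tree)
  res <- with_seed(derive_seed(seed, "resolve"),
                   ape::multi2di(tree, random = TRUE))
  if (!is.null(res$edge.length) && any(res$edge.length <= 0)) {
    pos <- res$edge.length[res$edge.length > 0]
    eps <- if (length(pos)) min(pos) * 1e-3 else 1e-8
    res$edge.length[res$edge.length <= 0] <- eps
    attr(res, "epsilon") <- eps
  }
  res
}

#' Fritz-Purvis D statistic with permutation p-values
#'
#' `D = (d_obs - mean(d_b)) / (mean(d_r) - mean(d_b))` where `d_obs` is the
#' observed sum of sister-clade differences, `d_r` its distribution under
#' `n_perm` random shuffles of the tip states, and `d_b` under `n_perm`
#' Brownian-threshold simulations on the same tree conditioned on the
#' observed prevalence.  `D` is near 1 for a phylogenetically random trait
#' and near 0 for Brownian-clumped one.  `p_random` (fraction of shuffled
#' `d_r <= d_obs`) is small when the trait is more clustered than random —
#' the test of whether D departs from one; `p_brownian` (fraction of
#' `d_b >= d_obs`) is small when it is more overdispersed than Brownian.
#'
#' @param tree rooted, bifurcating `phylo` with positive branch lengths
#'   (use [resolve_polytomies()] first if needed).
#' @param trait binary vector over the tips, both states present; if named,
#'   names must match the tip labels.
#' @param n_perm permutations per null, default 1000.
#' @param seed integer seed; the two nulls use independent substreams.
#' @return object of class `dstat_result`: `d_obs`, `D`, `p_random`,
#'   `p_brownian`, `mean_d_random`, `mean_d_brownian`, `n_permutations`,
#'   `seed`, `prevalence`.  `D` is `NA` (flagged) when the two null means
#'   coincide.
#' @export
fritz_purvis_d <- function(tree, trait, n_perm = 1000L, seed = 1L) {
  stopifnot(inherits(tree, "phylo"))
  n <- length(tree$tip.label)
  if (!is.null(names(trait))) {
    if (!setequal(names(trait), tree$tip.label)) {
      stop_invalid("trait names do not match tip labels")
    }
    trait <- trait[tree$tip.label]
  }
  trait <- as.numeric(trait)
  if (length(trait) != n) stop_invalid("trait must cover all tips")
  if (!is_binary_vector(trait)) stop_invalid("trait must be binary (0/1)")
  k <- sum(trait)
  if (k == 0 || k == n) stop_invalid("trait is monomorphic; D undefined")
  trav <- tree_traversal(tree)

  d_obs <- sister_diff_sum(tree, matrix(trait, ncol = 1L), trav)
  S <- with_seed(derive_seed(seed, "dstat-shuffle"), {
    matrix(replicate(n_perm, sample(trait)), nrow = n)
  })
  d_r <- sister_diff_sum(tree, S, trav)
  B <- with_seed(derive_seed(seed, "dstat-brownian"), {
    threshold_liabilities(bm_tip_liabilities(tree, n_perm), k)
  })
  d_b <- sister_diff_sum(tree, B, trav)

  mr <- mean(d_r); mb <- mean(d_b)
  D <- if (abs(mr - mb) < 1e-12) NA_real_ else (d_obs - mb) / (mr - mb)
  structure(list(d_obs = d_obs, D = D,
                 p_random = mean(d_r <= d_obs),
                 p_brownian = mean(d_b >= d_obs),
                 mean_d_random = mr, mean_d_brownian = mb,
                 n_permutations = as.integer(n_perm),
                 seed = as.integer(seed),
                 prevalence = k / n),
            class = "dstat_result")
}

#' @export
print.dstat_result <- function(x, ...) {
  cat(sprintf(paste0("Fritz-Purvis D = %s (d_obs = %.4f)\n",
                     "  p (vs random shuffles,   D = 1): %.4g\n",
                     "  p (vs Brownian threshold, D = 0): %.4g\n",
                     "  %d permutations per null, prevalence %.3f\n"),
              ifelse(is.na(x$D), "NA", sprintf("%.3f", x$D)), x$d_obs,
              x$p_random, x$p_brownian, x$n_permutations, x$prevalence))
  invisible(x)
}
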