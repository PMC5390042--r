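# LC-MS feature (peak) table: container, CSV dialect, binarization,
# ubiquitous-peak filter, Pareto-scaled PCA and chemical-diversity counts.

#' Construct a peak table
#'
#' A peak table holds one row of feature metadata per LC-MS feature (an
#' opaque `feature_id` plus the m/z and retention-time pair that uniquely
#' defines the peak) and a species-by-feature intensity matrix.  Missing
#' intensities are coded 0 (absent): downstream analysis is presence/absence,
#' so nothing is imputed.
#'
#' @param features data.frame with columns `feature_id`, `mz`, `rt`.
#' @param species_ids character vector of species labels, no duplicates.
#' @param intensity numeric matrix, species (rows) by features (columns),
#'   non-negative.
#' @return an object of class `peak_table`.
#' @export
peak_table <- function(features, species_ids, intensity) {
  stopifnot(is.data.frame(features),
            all(c("feature_id", "mz", "rt") %in% names(features)))
  features$feature_id <- as.character(features$feature_id)
  species_ids <- as.character(species_ids)
  intensity <- as.matrix(intensity)
  if (anyDuplicated(features$feature_id)) {
    dup <- unique(features$feature_id[duplicated(features$feature_id)])
    stop_invalid("duplicate feature_id: ", paste(dup, collapse = ", "))
  }
  key <- paste(features$mz, features$rt)
  if (anyDuplicated(key)) {
    dup <- unique(key[duplicated(key)])
    stop_invalid("duplicate (mz, rt) pair: ", paste(dup, collapse = "; "))
  }
  if (any(features$mz <= 0) || any(features$rt < 0)) {
    stop_invalid("mz must be > 0 and rt >= 0")
  }
  if (anyDuplicated(species_ids)) stop_invalid("duplicate species_ids")
  if (nrow(intensity) != length(species_ids) ||
      ncol(intensity) != nrow(features)) {
    stop_invalid("intensity matrix dimensions do not match species/features")
  }
  if (anyNA(intensity)) stop_invalid("intensity must not contain NA")
  if (any(intensity < 0)) stop_invalid("intensity must be non-negative")
  dimnames(intensity) <- list(species_ids, features$feature_id)
  structure(list(features = features, species_ids = species_ids,
                 intensity = intensity),
            class = "peak_table")
}

#' @export
print.peak_table <- function(x, ...) {
  cat(sprintf("<peak_table> %d species x %d features\n",
              length(x$species_ids), nrow(x$features)))
  invisible(x)
}

#' Read a peak table from CSV
#'
#' Expected dialect: columns `feature_id`, `mz`, `rt`, then one intensity
#' column per species.  Empty cells are read as intensity 0 (absent) with a
#' warning naming the affected lines; non-numeric intensities and duplicate
#' identifiers are errors reporting the offending rows.
#'
#' @param path CSV file path.
#' @return a [peak_table()].
#' @export
read_peak_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("feature_id", "mz", "rt")
  if (!all(need %in% names(df))) {
    stop_invalid("peak table CSV must have columns feature_id, mz, rt")
  }
  sp_cols <- setdiff(names(df), need)
  if (length(sp_cols) == 0L) stop_invalid("peak table CSV has no species columns")
  inten <- df[sp_cols]
  bad_lines <- integer(0)
  for (j in seq_along(inten)) {
    col <- inten[[j]]
    if (is.character(col)) {
      col[!nzchar(trimws(col))] <- NA
      num <- suppressWarnings(as.numeric(col))
      if (any(is.na(num) & !is.na(col))) {
        rows <- which(is.na(num) & !is.na(col))
        stop_invalid("non-numeric intensity in column '", sp_cols[j],
                     "', CSV line(s) ", paste(rows + 1L, collapse = ", "))
      }
      col <- num
    }
    if (anyNA(col)) {
      bad_lines <- c(bad_lines, which(is.na(col)) + 1L)
      col[is.na(col)] <- 0
    }
    inten[[j]] <- col
  }
  if (length(bad_lines)) {
    warning("missing intensity cells parsed as 0 (absent) on CSV line(s) ",
            paste(sort(unique(bad_lines)), collapse = ", "), call. = FALSE)
  }
  # columns of a data.frame -> species x feature matrix
  m <- t(as.matrix(inten))
  peak_table(features = df[need], species_ids = sp_cols, intensity = m)
}

#' Write a peak table to CSV
#'
#' Inverse of [read_peak_table()]: `read_peak_table(write_peak_table(t, p))`
#' reproduces `t` exactly.
#'
#' @param table a [peak_table()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_peak_table <- function(table, path) {
  stopifnot(inherits(table, "peak_table"))
  out <- cbind(table$features,
               as.data.frame(t(table$intensity), check.names = FALSE))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Binarize a peak table into a presence/absence matrix
#'
#' A peak counts as present in a species when its intensity is at or above
#' `threshold` (default 1e4, the detection threshold used for TOF-MS peak
#' calls in this analysis).
#'
#' @param table a [peak_table()].
#' @param threshold positive intensity cutoff.
#' @return an object of class `binary_peaks` with fields `presence`
#'   (species-by-feature 0/1 matrix), `species_ids`, `feature_ids`,
#'   `threshold_used`.
#' @export
binarize <- function(table, threshold = 1e4) {
  stopifnot(inherits(table, "peak_table"))
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0) {
    stop_invalid("`threshold` must be a single positive number")
  }
  pres <- (table$intensity >= threshold) * 1L
  structure(list(presence = pres,
                 species_ids = table$species_ids,
                 feature_ids = table$features$feature_id,
                 threshold_used = threshold),
            class = "binary_peaks")
}

#' @export
print.binary_peaks <- function(x, ...) {
  cat(sprintf("<binary_peaks> %d species x %d features (threshold %g)\n",
              length(x$species_ids), length(x$feature_ids), x$threshold_used))
  invisible(x)
}

#' Discard features present in every species
#'
#' Ubiquitous peaks (solvent impurities, primary metabolites shared by all
#' extracts) carry no discriminating information for any binary
#' classification and are removed before screening.  Idempotent.
#'
#' @param b a `binary_peaks` object.
#' @return filtered `binary_peaks`; removed ids in attribute `"removed"`.
#' @export
filter_ubiquitous <- function(b) {
  stopifnot(inherits(b, "binary_peaks"))
  if (length(b$feature_ids) == 0L) {
    attr(b, "removed") <- character(0)
    return(b)
  }
  ubiquitous <- colSums(b$presence) == nrow(b$presence)
  removed <- b$feature_ids[ubiquitous]
  b$presence <- b$presence[, !ubiquitous, drop = FALSE]
  b$feature_ids <- b$feature_ids[!ubiquitous]
  attr(b, "removed") <- removed
  b
}

# Pareto scaling: mean-center, then divide by sqrt(sd) (n - 1 denominator).
# Exposed for testability of the scaling itself.
#' Pareto-scale a numeric matrix
#'
#' Each column is mean-centered and divided by the square root of its
#' standard deviation — the metabolomics-standard compromise between
#' unit-variance and no scaling.  Zero-variance columns are dropped with a
#' warning (they carry no information and would divide by zero).
#'
#' @param m numeric matrix (observations x variables).
#' @return scaled matrix, possibly with fewer columns; dropped column
#'   indices in attribute `"dropped"`.
#' @export
pareto_scale <- function(m) {
  m <- as.matrix(m)
  sds <- apply(m, 2L, stats::sd)
  zero <- sds == 0 | is.na(sds)
  if (any(zero)) {
    warning(sum(zero), " zero-variance column(s) dropped before scaling",
            call. = FALSE)
  }
  kept <- which(!zero)
  out <- scale(m[, kept, drop = FALSE], center = TRUE, scale = sqrt(sds[kept]))
  attr(out, "scaled:center") <- NULL
  attr(out, "scaled:scale") <- NULL
  attr(out, "dropped") <- which(zero)
  out
}

#' PCA of a peak table with centering and Pareto scaling
#'
#' @param table a [peak_table()].
#' @param n_components number of components to retain.
#' @param use_binary logical; if `TRUE`, run the PCA on the binarized
#'   presence/absence values instead of raw intensities (default raw).
#' @param threshold binarization threshold when `use_binary = TRUE`.
#' @return list with `scores` (species x components), `loadings`,
#'   `explained_variance` (percent of retained variance per component) and
#'   `sdev`.
#' @export
pca_pareto <- function(table, n_components = 2L, use_binary = FALSE,
                       threshold = 1e4) {
  stopifnot(inherits(table, "peak_table"))
  x <- if (use_binary) binarize(table, threshold)$presence else table$intensity
  if (nrow(x) < 2L) stop_invalid("PCA needs at least 2 species")
  xs <- pareto_scale(x)
  n_components <- min(n_components, nrow(xs) - 1L, ncol(xs))
  p <- stats::prcomp(xs, center = FALSE, scale. = FALSE)
  ev <- p$sdev^2
  list(scores = p$x[, seq_len(n_components), drop = FALSE],
       loadings = p$rotation[, seq_len(n_components), drop = FALSE],
       explained_variance = 100 * ev / sum(ev),
       sdev = p$sdev)
}

#' Two-standard-deviation ellipse per group of PCA scores
#'
#' For each group with at least 3 members, computes the mean and the 2-SD
#' contour of the group's 2x2 score covariance in the first two components:
#' semi-axis lengths are twice the square roots of the covariance
#' eigenvalues, and `angle` is the orientation (radians) of the major axis.
#'
#' @param scores score matrix with >= 2 columns (species x components).
#' @param group factor/character vector, one entry per score row.
#' @return data.frame with one row per group: `group`, `n`, `center1`,
#'   `center2`, `semi_major`, `semi_minor`, `angle`.  Groups with fewer than
#'   3 members are skipped with a warning.
#' @export
group_ellipse <- function(scores, group) {
  scores <- as.matrix(scores)
  stopifnot(ncol(scores) >= 2L, nrow(scores) == length(group))
  group <- as.character(group)
  out <- lapply(unique(group), function(g) {
    s <- scores[group == g, 1:2, drop = FALSE]
    if (nrow(s) < 3L) {
      warning("group '", g, "' has < 3 members; no ellipse", call. = FALSE)
      return(NULL)
    }
    cv <- stats::cov(s)
    eg <- eigen(cv, symmetric = TRUE)
    data.frame(group = g, n = nrow(s),
               center1 = mean(s[, 1]), center2 = mean(s[, 2]),
               semi_major = 2 * sqrt(max(eg$values[1], 0)),
               semi_minor = 2 * sqrt(max(eg$values[2], 0)),
               angle = atan2(eg$vectors[2, 1], eg$vectors[1, 1]))
  })
  do.call(rbind, out[!vapply(out, is.null, logical(1))])
}

#' Per-group chemical diversity of a binary peak matrix
#'
#' Diversity is measured as the number of distinct features detected: per
#' species (mean and median within the group) and in total across the group
#' (features present in at least one member).
#'
#' @param b a `binary_peaks` object.
#' @param grouping named character vector mapping every species id to a
#'   group label.
#' @return data.frame with one row per group: `group`, `n_species`,
#'   `mean_per_species`, `median_per_species`, `total_distinct`.
#' @export
chemical_diversity <- function(b, grouping) {
  stopifnot(inherits(b, "binary_peaks"))
  unknown <- setdiff(names(grouping), b$species_ids)
  if (length(unknown)) {
    stop_invalid("grouping names unknown species: ",
                 paste(unknown, collapse = ", "))
  }
  missing <- setdiff(b$species_ids, names(grouping))
  if (length(missing)) {
    stop_invalid("grouping does not cover species: ",
                 paste(missing, collapse = ", "))
  }
  per_species <- rowSums(b$presence)
  groups <- sort(unique(as.character(grouping)))
  out <- lapply(groups, function(g) {
    sp <- names(grouping)[grouping == g]
    idx <- match(sp, b$species_ids)
    data.frame(group = g, n_species = length(sp),
               mean_per_species = mean(per_species[idx]),
               median_per_species = stats::median(per_species[idx]),
               total_distinct = sum(colSums(
                 b$presence[idx, , drop = FALSE]) > 0))
  })
  do.call(rbind, out)
}

# Table-style feature label: m/z to 2 decimals, rt (minutes) to 1 decimal.
#' @export
#' @rdname peak_table
#' @param mz,rt numeric vectors of mass-to-charge ratios and retention times.
feature_label <- function(mz, rt) {
  sprintf("%.2f %.1f", mz, rt)
}
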