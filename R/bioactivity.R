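# Bioassay readings -> binary bioactivity classifications ("raters").
#
# Antimicrobial: agar-diffusion inhibition-zone radii (cm), mean of
# replicates, active at >= 0.6 cm.  Cytotoxicity: MTT absorbances of treated
# cells vs a solvent control, per-species two-group one-way ANOVA with
# Benjamini-Hochberg correction across the species of a cell line, and a
# direction requirement (mean viability < 100%) so hyper-proliferative
# extracts are not called cytotoxic.

#' Percent cell viability from MTT absorbances
#'
#' Viability is the ratio of mean treated-cell absorbance to mean
#' solvent-control absorbance, on a percent scale.  Values above 100%
#' indicate induced hyper-proliferation rather than cytotoxicity.
#'
#' @param a_treated numeric vector of treated-well absorbances.
#' @param a_control numeric vector of solvent-control absorbances.
#' @return viability percentage (single number).
#' @seealso [is_hyperproliferative()]
#' @export
viability_percent <- function(a_treated, a_control) {
  if (length(a_treated) < 1L || length(a_control) < 1L) {
    stop_invalid("need at least one absorbance reading per group")
  }
  mc <- mean(a_control)
  if (!is.finite(mc) || mc <= 0) {
    stop_invalid("mean control absorbance must be positive")
  }
  100 * mean(a_treated) / mc
}

#' Flag viability values indicating hyper-proliferation
#'
#' @param viability viability percentage(s) from [viability_percent()].
#' @return logical: `TRUE` where viability exceeds 100%.
#' @export
is_hyperproliferative <- function(viability) viability > 100

# Internal constructor for the labels container shared by all assays.
new_activity_labels <- function(df, thresholds) {
  rownames(df) <- NULL
  structure(df, class = c("activity_labels", "data.frame"),
            thresholds = thresholds)
}

#' Extract one assay's classification as a named logical vector
#'
#' @param labels an `activity_labels` data.frame.
#' @param assay one of `"AM"`, `"HaCaT"`, `"IEC-6"`.
#' @return named logical vector (TRUE = active/cytotoxic), names = species.
#' @export
activity_vector <- function(labels, assay) {
  stopifnot(inherits(labels, "activity_labels") || is.data.frame(labels))
  sub <- labels[labels$assay == assay, , drop = FALSE]
  if (nrow(sub) == 0L) stop_invalid("no labels for assay '", assay, "'")
  stats::setNames(sub$label == "active", sub$species_id)
}

# Replicate columns of a wide bioassay table (rep1..repK).
rep_matrix <- function(df) {
  rep_cols <- grep("^rep[0-9]+$", names(df), value = TRUE)
  if (length(rep_cols) == 0L) stop_invalid("no replicate columns (rep1..repK)")
  as.matrix(df[rep_cols])
}

#' Classify species as antimicrobial active or inactive
#'
#' A species is active when its mean replicate inhibition-zone radius is at
#' or above `radius_threshold_cm` (ties at the threshold are active).
#'
#' @param inhibition data.frame with `species_id` and replicate columns
#'   `rep1..repK` holding inhibition-zone radii in cm.
#' @param radius_threshold_cm activity threshold, default 0.6 cm.
#' @param species optional character vector of species that must be present;
#'   missing ones raise an error listing them.
#' @return an `activity_labels` data.frame (`assay = "AM"`, `statistic` =
#'   mean radius).
#' @export
classify_antimicrobial <- function(inhibition, radius_threshold_cm = 0.6,
                                   species = NULL) {
  stopifnot(is.data.frame(inhibition), "species_id" %in% names(inhibition))
  if (!is.null(species)) {
    missing <- setdiff(species, inhibition$species_id)
    if (length(missing)) {
      stop_invalid("missing inhibition measurements for species: ",
                   paste(missing, collapse = ", "))
    }
  }
  radii <- rep_matrix(inhibition)
  if (any(radii < 0, na.rm = TRUE)) stop_invalid("radii must be >= 0")
  m <- rowMeans(radii)
  df <- data.frame(species_id = as.character(inhibition$species_id),
                   assay = "AM",
                   label = ifelse(m >= radius_threshold_cm,
                                  "active", "inactive"),
                   statistic = m, p_value = NA_real_, p_adj = NA_real_,
                   stringsAsFactors = FALSE)
  new_activity_labels(df, list(radius_cm = radius_threshold_cm))
}

# Two-group one-way ANOVA p-value (treated vs control absorbances).
# Equivalent to the two-sided pooled-variance t-test (F = t^2).
anova_two_group_p <- function(treated, control) {
  y <- c(treated, control)
  g <- factor(rep(c("treated", "control"), c(length(treated), length(control))))
  if (stats::var(treated) == 0 && stats::var(control) == 0) return(NA_real_)
  stats::anova(stats::lm(y ~ g))[["Pr(>F)"]][1]
}

#' Classify species as cytotoxic per cell line
#'
#' For each species of a cell line, treated absorbances are compared with
#' the solvent control by a two-group one-way ANOVA; p-values are corrected
#' across all species of that cell line by Benjamini-Hochberg at FDR
#' `alpha`.  A species is cytotoxic when the corrected test is significant
#' AND its mean viability is below 100% (significant increases are
#' hyper-proliferation, not cytotoxicity).  Species where both groups have
#' zero variance have an undefined p and are treated as not significant
#' (flagged by `p_value = NA`).
#'
#' @param viability data.frame with columns `species_id`, `cell_line`,
#'   `role` (`"treated"` or `"control"`), and replicate columns `rep1..repK`
#'   of absorbances.  Each cell line needs at least one control row (pooled
#'   if several).
#' @param alpha FDR level, default 0.05.
#' @return an `activity_labels` data.frame, one row per species and cell
#'   line (`assay` = cell line, `label` `"active"` = cytotoxic, `statistic`
#'   = viability percent).
#' @export
classify_cytotoxicity <- function(viability, alpha = 0.05) {
  stopifnot(is.data.frame(viability),
            all(c("species_id", "cell_line", "role") %in% names(viability)))
  reps <- rep_matrix(viability)
  if (ncol(reps) < 2L) stop_invalid("need >= 2 replicates per group")
  if (any(reps <= 0, na.rm = TRUE)) stop_invalid("absorbances must be > 0")
  out <- list()
  for (cl in unique(as.character(viability$cell_line))) {
    idx <- viability$cell_line == cl
    ctrl_rows <- idx & viability$role == "control"
    if (!any(ctrl_rows)) stop_invalid("no control rows for cell line ", cl)
    control <- as.numeric(reps[ctrl_rows, , drop = FALSE])
    trt_rows <- which(idx & viability$role == "treated")
    sp <- as.character(viability$species_id[trt_rows])
    via <- vapply(trt_rows, function(i) viability_percent(reps[i, ], control),
                  numeric(1))
    p <- vapply(trt_rows, function(i) anova_two_group_p(reps[i, ], control),
                numeric(1))
    bh <- benjamini_hochberg(ifelse(is.na(p), 1, p), alpha = alpha)
    signif <- bh$reject & !is.na(p)
    out[[cl]] <- data.frame(
      species_id = sp, assay = cl,
      label = ifelse(signif & via < 100, "active", "inactive"),
      statistic = via, p_value = p,
      p_adj = ifelse(is.na(p), NA_real_, bh$p_adj),
      stringsAsFactors = FALSE)
  }
  new_activity_labels(do.call(rbind, out), list(alpha = alpha))
}

#' Bind label tables from several assays
#'
#' @param ... `activity_labels` data.frames.
#' @return a single `activity_labels` data.frame; threshold attributes are
#'   merged.
#' @export
bind_labels <- function(...) {
  parts <- list(...)
  thresholds <- do.call(c, lapply(parts, attr, "thresholds"))
  new_activity_labels(do.call(rbind, lapply(parts, as.data.frame)),
                      thresholds)
}
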