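# qPCR relative copy number, recovery-course normalisation and statistics,
# and heavy-isotope pool inference.

#' Relative mtDNA copies per diploid genome from a Ct pair
#'
#' `2^(ct_b2m - ct_mt) * 2`, assuming 100% amplification efficiency for both
#' targets and two copies of the single-copy nuclear reference gene (B2M)
#' per diploid genome.  Vectorised; missing Ct values yield `NA` (flagged,
#' to be excluded downstream).
#'
#' @param ct_mt,ct_b2m threshold cycles of the mtDNA and B2M targets.
#' @return mtDNA copies per diploid genome (relative units).
#' @export
copy_number_from_ct <- function(ct_mt, ct_b2m) {
  out <- 2^(ct_b2m - ct_mt) * 2
  out[is.na(ct_mt) | is.na(ct_b2m)] <- NA_real_
  out
}

#' Normalise a depletion-recovery course to its pre-depletion reference
#'
#' Converts every Ct pair to relative copies, averages the pre-depletion
#' baseline replicates (`phase == "baseline"`) per cell line, and divides
#' all measurements by that reference so the pre-depletion level is 1 by
#' construction.  Replicates are carried through.
#'
#' @param measurements `data.frame` as produced by
#'   [generate_recovery_course()] (or read from a qPCR CSV): columns
#'   `cell_line`, `treated`, `phase`, `day`, `replicate`, `ct_mt`,
#'   `ct_b2m`.
#' @return `data.frame` of class `recovery_course`: the recovery-phase rows
#'   with `rel_copies` (fraction of pre-depletion baseline); the reference
#'   level per line is attached as attribute `"reference"`.
#' @export
normalize_course <- function(measurements) {
  m <- measurements
  m$copies <- copy_number_from_ct(m$ct_mt, m$ct_b2m)
  m <- m[!is.na(m$copies), , drop = FALSE]
  ref <- m[m$phase == "baseline", , drop = FALSE]
  if (nrow(ref) == 0L) stop("no pre-depletion reference (phase == 'baseline')")
  ref_mean <- tapply(ref$copies, ref$cell_line, mean)
  rec <- m[m$phase != "baseline", , drop = FALSE]
  rec$rel_copies <- rec$copies / as.numeric(ref_mean[as.character(rec$cell_line)])
  rec$copies <- NULL
  class(rec) <- c("recovery_course", class(rec))
  attr(rec, "reference") <- ref_mean
  rec
}

#' Two-way ANOVA for a treatment effect across a recovery course
#'
#' Blocks time and tests treatment on the normalised copy numbers:
#' `rel_copies ~ treatment + factor(day)`, no interaction term (replication
#' per cell is minimal in this design).  Also reports per-day unpaired
#' Welch t-tests between arms where both arms have at least two replicates.
#'
#' @param course_treated,course_untreated normalised courses from
#'   [normalize_course()].
#' @return List with `p_treatment`, `p_time`, the `anova` table and a
#'   per-day `data.frame` `per_day` of t-test p-values (`NA` where
#'   replication is insufficient or variance is zero).
#' @export
treatment_effect_anova <- function(course_treated, course_untreated) {
  d <- rbind(
    data.frame(rel = course_treated$rel_copies, day = course_treated$day,
               treatment = TRUE),
    data.frame(rel = course_untreated$rel_copies, day = course_untreated$day,
               treatment = FALSE))
  if (length(unique(d$day)) < 2L)
    stop("at least 2 timepoints are required")
  reps <- table(d$day, d$treatment)
  if (any(reps < 1L)) stop("both arms must cover every timepoint")
  fit <- stats::aov(rel ~ treatment + factor(day), data = d)
  tab <- summary(fit)[[1]]
  p_treatment <- tab["treatment", "Pr(>F)"]
  # identical arms give SS_treatment ~ 0 up to rounding; report p = 1
  if (is.na(p_treatment) || tab["treatment", "Sum Sq"] < .Machine$double.eps^0.5 *
      sum(tab[, "Sum Sq"]))
    p_treatment <- if (is.na(p_treatment)) 1 else p_treatment
  per_day <- do.call(rbind, lapply(sort(unique(d$day)), function(dy) {
    a <- d$rel[d$day == dy & d$treatment]
    b <- d$rel[d$day == dy & !d$treatment]
    p <- if (length(a) >= 2 && length(b) >= 2 &&
             (stats::sd(a) > 0 || stats::sd(b) > 0))
      tryCatch(stats::t.test(a, b)$p.value, error = function(e) NA_real_)
    else NA_real_
    data.frame(day = dy, mean_treated = mean(a), mean_untreated = mean(b),
               p_value = p)
  }))
  list(p_treatment = p_treatment,
       p_time = tab["factor(day)", "Pr(>F)"],
       anova = tab, per_day = per_day)
}

#' Specific activity from isotopologue peak areas
#'
#' The heavy-label molar fraction `heavy / (heavy + light)` per nucleoside,
#' assuming equal instrument response of the isotopologues (only the ratio
#' is used downstream).
#'
#' @param table `data.frame` with columns `nucleoside`, `heavy_area`,
#'   `light_area` (one row per nucleoside, e.g. from
#'   [generate_isotope_table()]).
#' @return The table with a `specific_activity` column in `[0, 1]`; rows
#'   with zero total area get `NA` and are flagged in attribute
#'   `"undefined"`.
#' @export
specific_activity <- function(table) {
  tot <- table$heavy_area + table$light_area
  sa <- ifelse(tot > 0, table$heavy_area / tot, NA_real_)
  out <- table
  out$specific_activity <- sa
  attr(out, "undefined") <- table$nucleoside[is.na(sa)]
  out
}

#' Infer relative nucleoside pool sizes and the limiting nucleoside
#'
#' Normalises each patient nucleoside's specific activity to the median of
#' the control replicates, takes the reciprocal as a relative pool-size
#' index (a large endogenous pool dilutes the label, giving low activity
#' and a large index), and calls the limiting nucleoside as the one with
#' the highest patient specific activity (smallest available pool).
#' Nucleosides whose activities lie within `tie_tol` (relative) of the top
#' one are reported jointly (e.g. `"dT/dG"`: no single limiting
#' nucleoside).  The synthesis-rate proxy is the reciprocal of the
#' normalised activity of the limiting nucleoside.
#'
#' @param patient a one-table `data.frame` with `nucleoside` and
#'   `specific_activity` columns (see [specific_activity()]).
#' @param controls a `data.frame` of control replicates with the same
#'   columns (several rows per nucleoside).
#' @param tie_tol relative difference below which two candidate limiting
#'   nucleosides are declared a tie.
#' @return List with `normalized` (named activities / control median),
#'   `pool_index` (named reciprocals), `limiting_nucleoside` (single
#'   symbol or `"x/y"` tie), and `synthesis_rate_proxy`.
#' @export
infer_pools <- function(patient, controls, tie_tol = 0.05) {
  stopifnot(all(c("nucleoside", "specific_activity") %in% names(patient)),
            all(c("nucleoside", "specific_activity") %in% names(controls)))
  nuc <- patient$nucleoside
  ctrl_med <- tapply(controls$specific_activity, controls$nucleoside,
                     stats::median, na.rm = TRUE)[nuc]
  if (any(is.na(ctrl_med)) || any(ctrl_med <= 0))
    stop("control median specific activity must be positive for every nucleoside")
  act <- stats::setNames(patient$specific_activity, nuc)
  normalized <- act / as.numeric(ctrl_med)
  pool_index <- 1 / normalized
  top <- max(act)
  tied <- names(act)[act >= top * (1 - tie_tol)]
  # order tied symbols by activity (highest first), breaking exact ties by
  # reverse symbol order for a stable joint label ("dT/dG")
  tied <- tied[order(act[tied], tied, decreasing = TRUE, method = "radix")]
  limiting <- paste(tied, collapse = "/")
  list(normalized = normalized, pool_index = pool_index,
       limiting_nucleoside = limiting,
       synthesis_rate_proxy = unname(1 / normalized[tied[1]]))
}
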