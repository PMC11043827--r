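# Screen statistics: condition-level summaries of the per-cell records,
# percentage change against the DMSO baseline of the same context, a
# Shapiro-Wilk-gated two-sample test, and linear mixed models for group
# effects across runs and cell lines.

#' Summarise one screen condition
#'
#' Computes cell count, Rho-0 proportion, raw-scale and log10 summaries of
#' summed nucleoid area, and mean mitochondrial integrated density for the
#' cells of one condition.  mtDNA content summaries on the log scale exclude
#' Rho-0 cells (whose summed area is 0 and has no logarithm); Rho-0 cells
#' still count towards `cell_count` and `rho0_proportion`.  Raw-scale means
#' include every cell.
#'
#' @param records per-cell records of a single condition (any rows with the
#'   columns `puncta_summed_area`, `mmp_integrated_density`, `is_rho0`).
#' @param condition optional label attached to the output.
#' @return A one-row `data.frame` of class `condition_summary`.  When all
#'   cells are Rho-0 the log-scale mtDNA summaries are `NA` and
#'   `mtdna_defined` is `FALSE`.
#' @export
summarize_condition <- function(records, condition = NULL) {
  if (is.null(records) || nrow(records) == 0L) {
    out <- data.frame(condition = condition %||% NA_character_,
                      cell_count = 0L, rho0_proportion = NA_real_,
                      mean_summed_area = NA_real_,
                      mean_log10_area = NA_real_, median_log10_area = NA_real_,
                      mean_mmp = NA_real_, mtdna_defined = FALSE,
                      empty = TRUE)
    class(out) <- c("condition_summary", class(out))
    return(out)
  }
  pos <- records$puncta_summed_area[!records$is_rho0 &
                                      records$puncta_summed_area > 0]
  mtdna_defined <- length(pos) > 0L
  out <- data.frame(
    condition = condition %||% NA_character_,
    cell_count = nrow(records),
    rho0_proportion = mean(records$is_rho0),
    mean_summed_area = mean(records$puncta_summed_area),
    mean_log10_area = if (mtdna_defined) mean(log10(pos)) else NA_real_,
    median_log10_area = if (mtdna_defined) stats::median(log10(pos)) else NA_real_,
    mean_mmp = mean(records$mmp_integrated_density),
    mtdna_defined = mtdna_defined,
    empty = FALSE)
  class(out) <- c("condition_summary", class(out))
  out
}

#' Percentage change of a condition against its DMSO baseline
#'
#' `100 * (treated - baseline) / baseline` for the three screen readouts:
#' mtDNA content (raw-scale mean summed nucleoid area), cell number
#' (cells per condition) and membrane potential (mean mitochondrial
#' integrated density).  Both summaries must come from the same run /
#' cell-line / serum context for the ratio to be meaningful.
#'
#' @param treated,baseline one-row summaries from [summarize_condition()].
#' @return Named numeric vector `c(mtdna, cells, mmp)` of percentages; a
#'   readout whose baseline mean is zero is returned as `NA` (flagged by
#'   attribute `"undefined"`).
#' @export
percent_change_vs_baseline <- function(treated, baseline) {
  pct <- function(t, b) if (!is.na(b) && b != 0) 100 * (t - b) / b else NA_real_
  out <- c(mtdna = pct(treated$mean_summed_area, baseline$mean_summed_area),
           cells = pct(treated$cell_count, baseline$cell_count),
           mmp = pct(treated$mean_mmp, baseline$mean_mmp))
  attr(out, "undefined") <- names(out)[is.na(out)]
  out
}

#' Normality-gated two-sample comparison against baseline
#'
#' Applies a Shapiro-Wilk test to each sample at `alpha`; when either sample
#' departs from normality (or is degenerate) the two-sided Mann-Whitney U
#' test is used, otherwise a two-sided Welch t-test.  The Mann-Whitney test
#' uses exact enumeration for small samples (both n <= 20, no ties) and the
#' normal approximation with tie and continuity correction otherwise.
#'
#' @param treated,baseline numeric vectors (each `n >= 3`).
#' @param alpha Shapiro-Wilk gate level.
#' @return List with `test_used` (`"t"` or `"MW"`), `p_value`, and the two
#'   Shapiro-Wilk p-values (`NA` for degenerate samples).
#' @export
compare_to_baseline <- function(treated, baseline, alpha = 0.05) {
  if (length(treated) < 3L || length(baseline) < 3L)
    stop("both samples must have at least 3 observations")
  sw <- function(x) {
    if (stats::sd(x) == 0 || length(x) > 5000L) return(NA_real_)
    stats::shapiro.test(x)$p.value
  }
  p_sw_t <- sw(treated); p_sw_b <- sw(baseline)
  normal <- !is.na(p_sw_t) && !is.na(p_sw_b) &&
    p_sw_t > alpha && p_sw_b > alpha
  if (normal) {
    res <- stats::t.test(treated, baseline, alternative = "two.sided")
    list(test_used = "t", p_value = res$p.value,
         shapiro_treated = p_sw_t, shapiro_baseline = p_sw_b)
  } else {
    exact <- length(treated) <= 20L && length(baseline) <= 20L &&
      !any(duplicated(c(treated, baseline)))
    res <- suppressWarnings(
      stats::wilcox.test(treated, baseline, alternative = "two.sided",
                         exact = exact, correct = TRUE))
    p <- res$p.value
    # complete-tie degeneracy: no evidence of a difference
    if (is.nan(p)) p <- 1
    list(test_used = "MW", p_value = p,
         shapiro_treated = p_sw_t, shapiro_baseline = p_sw_b)
  }
}

#' Mixed-model estimate of a treatment group effect
#'
#' Fits `log10(puncta_summed_area) ~ treatment + (1 | run)` (plus a random
#' cell-line intercept when the records span more than one line) to the
#' non-Rho-0 cells, so run-to-run (and line-to-line) shifts are absorbed as
#' random intercepts while the treatment effect is estimated within runs.
#' Falls back to a fixed-effects fit with run indicator variables when the
#' mixed fit is singular.
#'
#' @param records per-cell records spanning at least 2 runs, containing
#'   `puncta_summed_area`, `run_id`, `cell_line` and a logical/factor
#'   `treatment` column (or supply `treatment` separately).
#' @param treatment optional vector overriding `records$treatment`.
#' @return List of class `mixed_model_result`: `estimate` (log10 units),
#'   `se`, `p_value`, `random_sd` (named vector of random-intercept sds),
#'   `singular` flag and the fitted model.
#' @export
fit_group_effect <- function(records, treatment = NULL) {
  tr <- treatment %||% records$treatment
  stopifnot(!is.null(tr), length(tr) == nrow(records))
  keep <- !records$is_rho0 & records$puncta_summed_area > 0
  d <- data.frame(y = log10(records$puncta_summed_area[keep]),
                  treatment = as.logical(tr)[keep],
                  run = factor(records$run_id[keep]),
                  line = factor(records$cell_line[keep]))
  if (nlevels(droplevels(d$run)) < 2L)
    stop("at least 2 runs are required for a mixed-model fit")
  multi_line <- nlevels(droplevels(d$line)) > 1L
  form <- if (multi_line) y ~ treatment + (1 | run) + (1 | line)
          else y ~ treatment + (1 | run)
  fit <- suppressMessages(lmerTest::lmer(form, data = d))
  singular <- lme4::isSingular(fit)
  if (singular) {
    # degenerate random effects: fall back to run fixed effects
    warning("singular mixed-model fit; falling back to run fixed effects")
    lmfit <- stats::lm(y ~ treatment + run, data = d)
    co <- summary(lmfit)$coefficients["treatmentTRUE", ]
    out <- list(estimate = unname(co["Estimate"]),
                se = unname(co["Std. Error"]),
                p_value = unname(co["Pr(>|t|)"]),
                random_sd = c(run = NA_real_),
                singular = TRUE, fit = lmfit)
  } else {
    co <- stats::coef(summary(fit))["treatmentTRUE", ]
    vc <- as.data.frame(lme4::VarCorr(fit))
    rsd <- stats::setNames(vc$sdcor[vc$grp != "Residual"],
                           vc$grp[vc$grp != "Residual"])
    out <- list(estimate = unname(co["Estimate"]),
                se = unname(co["Std. Error"]),
                p_value = unname(co["Pr(>|t|)"]),
                random_sd = rsd, singular = FALSE, fit = fit)
  }
  class(out) <- "mixed_model_result"
  out
}

#' @export
print.mixed_model_result <- function(x, ...) {
  cat(sprintf("treatment effect on log10 summed area: %.4f (se %.4f), p = %.3g%s\n",
              x$estimate, x$se, x$p_value,
              if (x$singular) " [singular fit: run fixed effects]" else ""))
  if (!all(is.na(x$random_sd)))
    cat("random-intercept sd:",
        paste(sprintf("%s %.3f", names(x$random_sd), x$random_sd),
              collapse = ", "), "\n")
  invisible(x)
}

#' Galactose viability
#'
#' Growth under energetic stress as a surrogate of respiratory function:
#' the number of cells remaining after culture in galactose medium expressed
#' as a percentage of the cells counted in high-glucose medium.
#'
#' @param count_galactose,count_glucose cell counts.
#' @return Percentage (0 when no cells survive galactose).
#' @export
galactose_viability <- function(count_galactose, count_glucose) {
  stopifnot(count_galactose >= 0)
  if (any(count_glucose <= 0)) stop("glucose-medium count must be positive")
  100 * count_galactose / count_glucose
}

#' Full per-condition screen table with baseline-normalised statistics
#'
#' Groups records by condition within a run / line / serum / concentration
#' context, summarises each condition, computes percent change against the
#' DMSO baseline of the same context, and runs the normality-gated test of
#' log10 summed area against baseline.  A Benjamini-Hochberg adjusted
#' p-value column is appended for reference; the per-condition p-values
#' themselves are the headline values.
#'
#' @param cells per-cell records with `supplement`, `concentration`,
#'   `serum`, `run_id`, `cell_line` columns (e.g.
#'   `generate_screen_dataset()$cells`).
#' @param baseline_label condition label of the vehicle baseline.
#' @return `data.frame`, one row per condition x context.
#' @export
screen_condition_table <- function(cells, baseline_label = "DMSO") {
  stopifnot(nrow(cells) > 0)
  ctx_key <- interaction(cells$run_id, cells$cell_line, cells$serum,
                         cells$concentration, drop = TRUE)
  rows <- list()
  for (ctx in levels(ctx_key)) {
    sub <- cells[ctx_key == ctx, , drop = FALSE]
    base <- sub[sub$supplement == baseline_label, , drop = FALSE]
    base_sum <- summarize_condition(base, baseline_label)
    base_log <- log10(base$puncta_summed_area[!base$is_rho0 &
                                                base$puncta_summed_area > 0])
    for (lab in unique(sub$supplement)) {
      tre <- sub[sub$supplement == lab, , drop = FALSE]
      s <- summarize_condition(tre, lab)
      if (lab != baseline_label && nrow(base) > 0) {
        pc <- percent_change_vs_baseline(s, base_sum)
        tre_log <- log10(tre$puncta_summed_area[!tre$is_rho0 &
                                                  tre$puncta_summed_area > 0])
        tst <- if (length(tre_log) >= 3 && length(base_log) >= 3)
          compare_to_baseline(tre_log, base_log) else
            list(test_used = NA_character_, p_value = NA_real_)
      } else {
        pc <- c(mtdna = NA_real_, cells = NA_real_, mmp = NA_real_)
        tst <- list(test_used = NA_character_, p_value = NA_real_)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        context = ctx, run_id = tre$run_id[1], cell_line = tre$cell_line[1],
        serum = tre$serum[1], concentration = tre$concentration[1],
        supplement = lab, cell_count = s$cell_count,
        rho0_proportion = s$rho0_proportion,
        mean_summed_area = s$mean_summed_area,
        mean_log10_area = s$mean_log10_area,
        mean_mmp = s$mean_mmp,
        pct_change_mtdna = unname(pc["mtdna"]),
        pct_change_cells = unname(pc["cells"]),
        pct_change_mmp = unname(pc["mmp"]),
        test_used = tst$test_used, p_value = tst$p_value)
    }
  }
  out <- do.call(rbind, rows)
  out$p_adj_bh <- stats::p.adjust(out$p_value, method = "BH")
  out
}
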