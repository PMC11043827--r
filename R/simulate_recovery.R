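# Depletion-recovery simulation: ddC-depleted cultures recover along a
# saturating exponential; the qPCR readout is generated by inverting the
# relative copy-number formula at perfect amplification efficiency and
# adding Gaussian Ct noise.

# True relative copy number (fraction of pre-depletion baseline) at day t.
recovery_curve <- function(t, depletion_fraction, rate) {
  depletion_fraction + (1 - depletion_fraction) * (1 - exp(-rate * t))
}

#' Simulate a qPCR depletion-recovery time course
#'
#' Generates Ct measurements for the mtDNA and B2M targets along a recovery
#' course `C(t) = C0 (d + (1 - d)(1 - e^{-rt}))`, where `d` is the residual
#' fraction after depletion and `r` the recovery rate of the chosen arm.
#' Pre-depletion reference replicates (`phase = "baseline"`, the untreated
#' sample all later values are normalised to) are included.  Ct values are
#' exact inversions of the relative copy-number formula (2 B2M copies per
#' diploid genome, 100% efficiency) plus Gaussian noise of sd
#' `ct_noise_sd` on every Ct.
#'
#' @param spec a [recovery_spec()].
#' @param treated logical: use the treated or untreated recovery rate.
#' @param seed integer seed.
#' @param cell_line label carried through.
#' @param include_baseline logical: emit the pre-depletion reference
#'   replicates (set `FALSE` when the course will be normalised to a shared
#'   reference from another arm).
#' @return `data.frame` with columns `sample_id`, `cell_line`, `treated`,
#'   `phase` (`"baseline"` or `"recovery"`), `day`, `replicate`, `ct_mt`,
#'   `ct_b2m` and the generating truth `true_rel_copies`.
#' @export
generate_recovery_course <- function(spec, treated = FALSE, seed = 1L,
                                     cell_line = "LINE1",
                                     include_baseline = TRUE) {
  stopifnot(inherits(spec, "recovery_spec"))
  if (any(spec$timepoints < 0)) stop("negative times are not allowed")
  rate <- if (treated) spec$recovery_rate_treated else spec$recovery_rate_untreated
  with_seed(seed, {
    ct_b2m_true <- 22
    rows <- list()
    emit <- function(phase, day, rel) {
      copies <- spec$baseline_copies * rel
      # invert copies = 2^(ct_b2m - ct_mt) * 2
      ct_mt_true <- ct_b2m_true - log2(copies / 2)
      for (rep_i in seq_len(spec$replicates)) {
        rows[[length(rows) + 1L]] <<- data.frame(
          sample_id = sprintf("%s_%s_%s_r%d", cell_line,
                              if (treated) "T" else "U",
                              if (phase == "baseline") "base" else paste0("d", day),
                              rep_i),
          cell_line = cell_line, treated = treated, phase = phase,
          day = day, replicate = rep_i,
          ct_mt = ct_mt_true + stats::rnorm(1, 0, spec$ct_noise_sd),
          ct_b2m = ct_b2m_true + stats::rnorm(1, 0, spec$ct_noise_sd),
          true_rel_copies = rel)
      }
    }
    if (include_baseline) emit("baseline", NA_real_, 1)
    for (d in spec$timepoints)
      emit("recovery", d, recovery_curve(d, spec$depletion_fraction, rate))
    do.call(rbind, rows)
  })
}

#' Simulate a full two-arm depletion-recovery experiment
#'
#' Generates the treated and untreated recovery arms together with a single
#' shared pre-depletion reference (both arms derive from the same depleted
#' culture, so they are normalised to the same untreated baseline sample).
#'
#' @inheritParams generate_recovery_course
#' @return `data.frame` stacking the shared baseline rows
#'   (`phase == "baseline"`) and both arms' recovery rows.
#' @export
generate_recovery_experiment <- function(spec, seed = 1L,
                                         cell_line = "LINE1") {
  untreated <- generate_recovery_course(spec, treated = FALSE, seed = seed,
                                        cell_line = cell_line,
                                        include_baseline = TRUE)
  treated <- generate_recovery_course(spec, treated = TRUE,
                                      seed = child_seed(seed, 1L),
                                      cell_line = cell_line,
                                      include_baseline = FALSE)
  rbind(untreated, treated)
}
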