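#' Specification of one synthetic imaging field
#'
#' Bundles the parameters of the synthetic data-generating process for a
#' single two-channel field: fibroblast-like cells with a Gaussian-blob
#' nucleus, diffraction-limited mtDNA nucleoid puncta scattered through the
#' cytoplasm, and a filamentous membrane-potential reticulum.  Defaults
#' emulate a 96-well high-content acquisition of a quiescent primary
#' fibroblast culture: mononucleated cells, a mean of ~50 nucleoids per cell,
#' a small S/G2 subpopulation whose nuclear DNA signal sits at twice the G1
#' mode, and a configurable fraction of Rho-0 cells carrying no mtDNA at all.
#'
#' Intensity scale is arbitrary fluorescence units (AU).  The signal-to-noise
#' ratio of a nucleoid spot is `spot_intensity / noise_sd` (peak over the
#' read-noise standard deviation); the defaults give SNR 10.
#'
#' @param field_size integer vector of length 2, field size in pixels
#'   (rows, cols).
#' @param pixel_size pixel size in micrometres per pixel.
#' @param n_cells number of cells placed in the field.
#' @param rho0_fraction fraction of cells that are Rho-0 (void of mtDNA);
#'   the generator places exactly `round(rho0_fraction * n_cells)` such cells
#'   so the configured fraction is the exact per-field ground truth.
#' @param nucleoid_count_mean mean nucleoid count per mtDNA-positive cell
#'   (zero-truncated Poisson, with a lognormal cell-to-cell factor of
#'   coefficient of variation `cell_cv`).
#' @param puncta_sigma Gaussian width (sd) of a nucleoid spot, micrometres.
#' @param spot_intensity peak amplitude of a nucleoid spot, AU.
#' @param nucleus_intensity_mean peak amplitude of a G1 nucleus, AU. S/G2
#'   nuclei double this value (intensity, not area), so nuclear integrated
#'   density is the ploidy readout.
#' @param nucleus_area_mean mean nucleus area, square micrometres.
#' @param mito_mass_mean mean polarized mitochondrial mass per cell, AU
#'   (total channel-2 intensity above background contributed by the cell).
#' @param background constant background level added to both channels, AU.
#' @param noise_sd standard deviation of additive Gaussian read noise, AU.
#' @param s_phase_fraction probability that a cell is in S/G2.
#' @param cell_cv lognormal coefficient of variation of the per-cell nucleoid
#'   count mean and mitochondrial mass (cell-to-cell biological spread).
#' @param seed integer seed; together with the spec it fully determines the
#'   rendered field.
#' @return An object of class `field_spec` (a validated list).
#' @export
field_spec <- function(field_size = c(768L, 768L),
                       pixel_size = 0.35,
                       n_cells = 20L,
                       rho0_fraction = 0,
                       nucleoid_count_mean = 50,
                       puncta_sigma = 0.3,
                       spot_intensity = 200,
                       nucleus_intensity_mean = 400,
                       nucleus_area_mean = 100,
                       mito_mass_mean = 5e4,
                       background = 100,
                       noise_sd = 20,
                       s_phase_fraction = 0.1,
                       cell_cv = 0.3,
                       seed = 1L) {
  spec <- list(field_size = as.integer(field_size), pixel_size = pixel_size,
               n_cells = as.integer(n_cells), rho0_fraction = rho0_fraction,
               nucleoid_count_mean = nucleoid_count_mean,
               puncta_sigma = puncta_sigma, spot_intensity = spot_intensity,
               nucleus_intensity_mean = nucleus_intensity_mean,
               nucleus_area_mean = nucleus_area_mean,
               mito_mass_mean = mito_mass_mean, background = background,
               noise_sd = noise_sd, s_phase_fraction = s_phase_fraction,
               cell_cv = cell_cv, seed = seed)
  validate_field_spec(spec)
  class(spec) <- "field_spec"
  spec
}

validate_field_spec <- function(spec) {
  stopifnot(
    length(spec$field_size) == 2L, all(spec$field_size >= 16L),
    spec$pixel_size > 0, spec$n_cells >= 0L,
    spec$rho0_fraction >= 0, spec$rho0_fraction <= 1,
    spec$s_phase_fraction >= 0, spec$s_phase_fraction <= 1,
    spec$nucleoid_count_mean > 0, spec$puncta_sigma > 0,
    spec$noise_sd >= 0, spec$background >= 0,
    is.numeric(spec$seed), length(spec$seed) == 1L
  )
  invisible(spec)
}

#' @export
print.field_spec <- function(x, ...) {
  cat(sprintf(
    "field_spec: %d x %d px @ %.3g um/px, %d cells (rho0 %.0f%%, S/G2 %.0f%%), %g nucleoids/cell, SNR %.3g\n",
    x$field_size[1], x$field_size[2], x$pixel_size, x$n_cells,
    100 * x$rho0_fraction, 100 * x$s_phase_fraction, x$nucleoid_count_mean,
    if (x$noise_sd > 0) x$spot_intensity / x$noise_sd else Inf))
  invisible(x)
}

#' Specification of one supplementation-screen condition
#'
#' A screen condition is a subset of the four deoxynucleosides (dA, dT, dG,
#' dC, written `A`/`T`/`G`/`C`), a concentration, a serum state, and the
#' multiplicative effects the treatment exerts on the data-generating
#' process: on mean nucleoid content per cell (`effect_mtdna`), on the number
#' of cells surviving to imaging (`effect_cells`) and on polarized
#' mitochondrial mass (`effect_mmp`).  The DMSO vehicle baseline has all
#' three factors fixed at 1.
#'
#' @param supplements character vector drawn from `c("A","T","G","C")`, or
#'   `character(0)` for the DMSO baseline.
#' @param concentration supplement concentration, micromolar (screen design
#'   uses 50 or 200).
#' @param serum serum percentage of dialysed FCS (10 = cycling, 0.1 =
#'   quiescent).
#' @param effect_mtdna,effect_cells,effect_mmp multiplicative treatment
#'   effects (all 1 for the baseline).
#' @return An object of class `screen_condition`.
#' @export
screen_condition <- function(supplements, concentration = 50, serum = 0.1,
                             effect_mtdna = 1, effect_cells = 1,
                             effect_mmp = 1) {
  supplements <- sort(unique(as.character(supplements)))
  if (!all(supplements %in% c("A", "T", "G", "C")))
    stop("supplements must be a subset of {A, T, G, C}")
  if (length(supplements) == 0L &&
      !(effect_mtdna == 1 && effect_cells == 1 && effect_mmp == 1))
    stop("the DMSO baseline must have all effect factors equal to 1")
  structure(list(
    supplements = supplements,
    label = if (length(supplements)) condition_label(supplements) else "DMSO",
    concentration = concentration, serum = serum,
    effect_mtdna = effect_mtdna, effect_cells = effect_cells,
    effect_mmp = effect_mmp), class = "screen_condition")
}

# Canonical label: nucleosides in alphabetical order (so enumeration order
# and labels agree; the full mix is "ACGT").
condition_label <- function(supplements) {
  paste(sort(supplements), collapse = "")
}

#' @export
print.screen_condition <- function(x, ...) {
  cat(sprintf("screen_condition: %s @ %g uM, %g%% dFCS (effects mtDNA %.3g, cells %.3g, MMP %.3g)\n",
              x$label, x$concentration, x$serum,
              x$effect_mtdna, x$effect_cells, x$effect_mmp))
  invisible(x)
}

#' Specification of a depletion-recovery time course
#'
#' Parameters of the ddC depletion / nucleoside-supplemented recovery
#' experiment: cells are depleted to `depletion_fraction` of their baseline
#' mtDNA copy number, then recover along the saturating exponential
#' `C(t) = C0 * (d + (1 - d) * (1 - exp(-r t)))` with rate `r` per day
#' (treated or untreated).  qPCR readout adds Gaussian noise to the Ct values
#' of the mtDNA and B2M targets.
#'
#' @param baseline_copies pre-depletion mtDNA copies per diploid genome.
#' @param depletion_fraction fraction of baseline remaining at day 0
#'   (in (0, 1]).
#' @param recovery_rate_untreated,recovery_rate_treated recovery rates,
#'   per day.
#' @param timepoints sampling days of the recovery phase.
#' @param ct_noise_sd Gaussian noise sd on each Ct value, cycles.
#' @param replicates biological replicates per arm and timepoint.
#' @return An object of class `recovery_spec`.
#' @export
recovery_spec <- function(baseline_copies = 500,
                          depletion_fraction = 0.5,
                          recovery_rate_untreated = 0.14,
                          recovery_rate_treated = 0.28,
                          timepoints = c(0, 7, 14, 21),
                          ct_noise_sd = 0.05,
                          replicates = 2L) {
  stopifnot(baseline_copies > 0,
            depletion_fraction > 0, depletion_fraction <= 1,
            recovery_rate_untreated >= 0, recovery_rate_treated >= 0,
            all(timepoints >= 0), ct_noise_sd >= 0, replicates >= 1L)
  structure(list(baseline_copies = baseline_copies,
                 depletion_fraction = depletion_fraction,
                 recovery_rate_untreated = recovery_rate_untreated,
                 recovery_rate_treated = recovery_rate_treated,
                 timepoints = timepoints, ct_noise_sd = ct_noise_sd,
                 replicates = as.integer(replicates)),
            class = "recovery_spec")
}

#' Rate for which the recovery curve reaches baseline by a given day
#'
#' The saturating exponential `C(t) = C0 (d + (1-d)(1 - e^{-rt}))` approaches
#' the baseline `C0` only asymptotically, so "reaches baseline by day `day`"
#' is operationalised as coming within a tolerance: the returned rate
#' satisfies `C(day) = (1 - tol) * C0`.  The default 1% tolerance is well
#' inside qPCR measurement noise.
#'
#' @param depletion_fraction fraction of baseline remaining at day 0.
#' @param day day at which the course should reach `(1 - tol)` of baseline.
#' @param tol relative shortfall from baseline that counts as "reached".
#' @return Recovery rate, per day.
#' @export
recovery_rate_to_baseline <- function(depletion_fraction, day, tol = 0.01) {
  stopifnot(depletion_fraction > 0, depletion_fraction < 1, day > 0,
            tol > 0, tol < 1 - depletion_fraction)
  -log(tol / (1 - depletion_fraction)) / day
}

#' Specification of a heavy-isotope labelling experiment
#'
#' Models dilution of a 10%-heavy-labelled exogenous deoxynucleoside supply
#' through finite endogenous pools.  For nucleoside N the heavy fraction in
#' newly synthesised DNA is
#' `heavy_fraction_supplement * flux_N / (flux_N + pool_N)`, and the observed
#' specific activity of total DNA is that fraction times the fraction of DNA
#' synthesised during labelling.
#'
#' @param endogenous_pools named numeric vector (names `dA`, `dC`, `dG`,
#'   `dT`): endogenous pool sizes, arbitrary units.  The defaults order the
#'   pools dA > dC > dG > dT (purine pools largest, thymidine limiting) with
#'   a geometric 2x spacing, which keeps adjacent specific activities about
#'   1.7x apart — resolvable at the 10% measurement cv of the assay.
#' @param supplement_flux named numeric vector, exogenous supply entering the
#'   precursor pool per nucleoside (same units as the pools).
#' @param heavy_fraction_supplement heavy isotopologue fraction of the
#'   supplement (the labelling design uses 0.10).
#' @param new_dna_fraction fraction of total DNA synthesised during the
#'   labelling window.
#' @param measurement_cv lognormal coefficient of variation of the measured
#'   peak areas.
#' @return An object of class `pool_spec`.
#' @export
pool_spec <- function(endogenous_pools = c(dA = 8, dC = 4, dG = 2, dT = 1),
                      supplement_flux = c(dA = 0.5, dC = 0.5, dG = 0.5,
                                          dT = 0.5),
                      heavy_fraction_supplement = 0.10,
                      new_dna_fraction = 0.5,
                      measurement_cv = 0.1) {
  nuc <- c("dA", "dC", "dG", "dT")
  stopifnot(all(nuc %in% names(endogenous_pools)),
            all(nuc %in% names(supplement_flux)))
  endogenous_pools <- endogenous_pools[nuc]
  supplement_flux <- supplement_flux[nuc]
  if (any(endogenous_pools < 0) || any(supplement_flux < 0))
    stop("pools and fluxes must be non-negative")
  if (any(endogenous_pools + supplement_flux <= 0))
    stop("zero total supply (pool + flux) for at least one nucleoside")
  stopifnot(heavy_fraction_supplement >= 0, heavy_fraction_supplement <= 1,
            new_dna_fraction >= 0, new_dna_fraction <= 1,
            measurement_cv >= 0, measurement_cv <= 1)
  structure(list(endogenous_pools = endogenous_pools,
                 supplement_flux = supplement_flux,
                 heavy_fraction_supplement = heavy_fraction_supplement,
                 new_dna_fraction = new_dna_fraction,
                 measurement_cv = measurement_cv),
            class = "pool_spec")
}
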