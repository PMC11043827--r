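# Heavy-isotope labelling simulation: a supplement containing a fixed heavy
# isotopologue fraction is diluted by the endogenous nucleoside pool before
# incorporation, so the heavy fraction observed in DNA reports the relative
# pool sizes.

#' Simulate a mass-spectrometry isotopologue peak-area table
#'
#' For each nucleoside N, the heavy fraction among newly synthesised DNA is
#' `heavy_fraction_supplement * flux_N / (flux_N + pool_N)` (label dilution
#' by the endogenous pool), and the observed specific activity of total DNA
#' is that fraction multiplied by `new_dna_fraction`.  Heavy and light peak
#' areas are drawn log-normally around their expected values with
#' coefficient of variation `measurement_cv`; at cv = 0 the table reproduces
#' the dilution formula exactly.
#'
#' @param spec a [pool_spec()].
#' @param seed integer seed.
#' @param total_area expected total (heavy + light) peak area per
#'   nucleoside, arbitrary units.
#' @return `data.frame` with columns `nucleoside`, `heavy_area`,
#'   `light_area` and the generating truth `true_specific_activity`.
#' @export
generate_isotope_table <- function(spec, seed = 1L, total_area = 1e6) {
  stopifnot(inherits(spec, "pool_spec"))
  flux <- spec$supplement_flux; pool <- spec$endogenous_pools
  if (any(flux + pool <= 0))
    stop("zero total supply (pool + flux) for at least one nucleoside")
  heavy_new <- spec$heavy_fraction_supplement * flux / (flux + pool)
  sa <- heavy_new * spec$new_dna_fraction
  with_seed(seed, {
    cv <- spec$measurement_cv
    jitter <- function(mu) {
      if (cv == 0) return(mu)
      sdlog <- sqrt(log(1 + cv^2))
      mu * exp(stats::rnorm(length(mu), -0.5 * sdlog^2, sdlog))
    }
    heavy <- jitter(total_area * sa)
    light <- jitter(total_area * (1 - sa))
    data.frame(nucleoside = names(flux), heavy_area = as.numeric(heavy),
               light_area = as.numeric(light),
               true_specific_activity = as.numeric(sa),
               row.names = NULL)
  })
}
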