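# Screen-level simulation: conditions x runs x fields, with run-level
# random intercepts on nucleoid content (differences within a run are more
# reproducible than between runs, which is what the mixed models downstream
# are for).  Treatment effects act multiplicatively on the base field spec.

# Draw per-cell ground-truth records from a field spec without rasterising
# an image; the distributions match render_field's draws.  Used for
# statistical simulations where segmentation is not under study.
simulate_cell_records <- function(spec, n_cells = spec$n_cells) {
  n <- n_cells
  if (n == 0L) {
    return(data.frame(cell_id = integer(0), nucleoid_count = integer(0),
                      puncta_summed_area = numeric(0),
                      puncta_integrated_density = numeric(0),
                      nuclear_integrated_density = numeric(0),
                      mmp_integrated_density = numeric(0),
                      reticulum_length = numeric(0), is_rho0 = logical(0),
                      ploidy_class = character(0)))
  }
  rho0 <- rep(FALSE, n)
  n_rho0 <- round(spec$rho0_fraction * n)
  if (n_rho0 > 0) rho0[sample.int(n, n_rho0)] <- TRUE
  ploidy <- ifelse(stats::runif(n) < spec$s_phase_fraction, "S_G2", "G1")
  cell_factor <- exp(stats::rnorm(n, -0.5 * spec$cell_cv^2, spec$cell_cv))
  counts <- integer(n)
  counts[!rho0] <- rpois_positive(sum(!rho0),
                                  spec$nucleoid_count_mean * cell_factor[!rho0])
  a0 <- spot_truth_area(spec$puncta_sigma)
  nuc_content <- ifelse(ploidy == "S_G2", 2, 1) *
    exp(stats::rnorm(n, -0.5 * 0.1^2, 0.1))
  mito_mass <- spec$mito_mass_mean *
    exp(stats::rnorm(n, -0.5 * spec$cell_cv^2, spec$cell_cv))
  data.frame(
    cell_id = seq_len(n),
    nucleoid_count = counts,
    puncta_summed_area = counts * a0,
    puncta_integrated_density = counts * a0 * spec$spot_intensity,
    nuclear_integrated_density = spec$nucleus_area_mean *
      spec$nucleus_intensity_mean * nuc_content,
    mmp_integrated_density = mito_mass * spec$pixel_size^2,
    reticulum_length = 250 * mito_mass / spec$mito_mass_mean,
    is_rho0 = rho0,
    ploidy_class = ploidy)
}

# Apply a condition's multiplicative effects and a run intercept to a base
# field spec.  The run intercept acts on nucleoid content, matching the
# run-to-run variability the mixed models absorb.
modulate_spec <- function(base, condition, run_intercept = 1) {
  spec <- base
  spec$nucleoid_count_mean <- base$nucleoid_count_mean *
    condition$effect_mtdna * run_intercept
  spec$mito_mass_mean <- base$mito_mass_mean * condition$effect_mmp
  spec
}

#' Simulate a supplementation screen with known ground truth
#'
#' Lays out one well per condition per run, draws a log-normal run intercept
#' applied multiplicatively to nucleoid content, draws the number of cells
#' per field as Poisson with mean `n_cells * effect_cells`, and generates
#' per-cell records for `fields_per_well` fields per well (nine in the
#' acquisition design this emulates).  With `render_images = TRUE` every
#' field is rasterised with [render_field()] and the returned records are
#' the generator's ground truth for those images; with the default
#' `FALSE`, records are drawn directly from the same distributions, which
#' is what the screen-statistics simulations need.
#'
#' @param conditions list of [screen_condition()] objects (e.g. from
#'   [enumerate_supplement_conditions()]).
#' @param base a [field_spec()]: the untreated data-generating process.
#' @param fields_per_well number of imaged fields per well.
#' @param runs number of experimental runs (plates).
#' @param run_sd standard deviation of the log-normal run intercept on
#'   nucleoid content (0 disables run effects).
#' @param cell_line label recorded in the output.
#' @param seed integer seed; fully determines the dataset.
#' @param render_images logical, rasterise every field.
#' @return A list of class `screen_dataset`:
#'   \describe{
#'     \item{cells}{per-cell records with well / run / condition metadata}
#'     \item{platemap}{one row per well: condition assignment}
#'     \item{fields}{list of [render_field()] results (if rendered)}
#'     \item{conditions}{the input condition list}
#'   }
#' @export
generate_screen_dataset <- function(conditions, base = field_spec(),
                                    fields_per_well = 9L, runs = 2L,
                                    run_sd = 0.15, cell_line = "LINE1",
                                    seed = 1L, render_images = FALSE) {
  stopifnot(fields_per_well >= 1L, runs >= 1L, run_sd >= 0)
  if (inherits(conditions, "screen_condition")) conditions <- list(conditions)
  with_seed(seed, {
    run_intercepts <- exp(stats::rnorm(runs, -0.5 * run_sd^2, run_sd))
    cells <- list(); platemap <- list(); fields <- list()
    widx <- 0L
    for (r in seq_len(runs)) {
      run_id <- sprintf("run%d", r)
      for (ci in seq_along(conditions)) {
        cond <- conditions[[ci]]
        widx <- widx + 1L
        well_id <- sprintf("%s-W%02d", run_id, widx)
        spec <- modulate_spec(base, cond, run_intercepts[r])
        platemap[[widx]] <- data.frame(
          well_id = well_id, run_id = run_id, cell_line = cell_line,
          serum = cond$serum, supplement = cond$label,
          concentration = cond$concentration, day = 7)
        for (fi in seq_len(fields_per_well)) {
          n_field <- stats::rpois(1, base$n_cells * cond$effect_cells)
          if (render_images) {
            spec_f <- spec
            spec_f$n_cells <- n_field
            spec_f$seed <- child_seed(seed, widx * 1000L + fi)
            rf <- render_field(spec_f, well_id = well_id, field_index = fi,
                               run_id = run_id, cell_line = cell_line)
            fields[[length(fields) + 1L]] <- rf
            rec <- rf$cells
            rec <- rec[, setdiff(names(rec), c("center_row", "center_col",
                                               "nucleus_area")), drop = FALSE]
            rec$puncta_integrated_density <- NA_real_
            rec$nuclear_integrated_density <- NA_real_
            rec$mmp_integrated_density <- rec$mito_polarized_mass
            rec$reticulum_length <- NA_real_
            rec$mito_polarized_mass <- NULL
          } else {
            rec <- simulate_cell_records(spec, n_cells = n_field)
          }
          if (nrow(rec)) {
            rec$well_id <- well_id; rec$field_index <- fi
            rec$run_id <- run_id; rec$cell_line <- cell_line
            rec$serum <- cond$serum; rec$supplement <- cond$label
            rec$concentration <- cond$concentration
            cells[[length(cells) + 1L]] <- rec
          }
        }
      }
    }
    structure(list(
      cells = if (length(cells)) do.call(rbind, cells) else NULL,
      platemap = do.call(rbind, platemap),
      fields = if (render_images) fields else NULL,
      conditions = conditions),
      class = "screen_dataset")
  })
}
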