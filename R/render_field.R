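# Synthetic field rendering: cells as disc territories around seeded centres,
# nuclei as 2-D Gaussian blobs, nucleoids as diffraction-limited Gaussian
# spots placed in the cytoplasm, and a filamentous reticulum drawn as smooth
# random curves whose total intensity equals the cell's polarized
# mitochondrial mass.  Identical spec + seed gives bit-identical output.

# Half-maximum footprint of a Gaussian spot; the per-spot ground-truth area.
spot_truth_area <- function(puncta_sigma) pi * (1.1774 * puncta_sigma)^2

# Width (sd, um) used to rasterise reticulum filaments.
MITO_SIGMA_UM <- 0.36

#' Render one synthetic two-channel field with ground truth
#'
#' Draws `spec$n_cells` cells with non-overlapping territories, stamps a
#' Gaussian nucleus per cell into the DNA channel (S/G2 nuclei at twice the
#' G1 peak intensity), scatters each cell's nucleoid puncta uniformly in an
#' annulus between the nucleus margin and the territory edge, renders 2-6
#' smooth reticulum filaments per cell into the membrane-potential channel
#' normalised so their summed intensity equals the cell's
#' `mito_polarized_mass`, and finally adds constant background plus Gaussian
#' read noise to both channels.
#'
#' Rho-0 cells (exactly `round(rho0_fraction * n_cells)` per field) carry
#' zero nucleoid puncta; all other cells carry at least one.
#'
#' @param spec a [field_spec()].
#' @param well_id,field_index,run_id,cell_line metadata stamped on the
#'   returned [field_image()].
#' @return A list of class `rendered_field` with elements
#'   \describe{
#'     \item{field}{the [field_image()]}
#'     \item{cells}{per-cell ground truth (`data.frame`): 0-based centre
#'       coordinates, nucleus area (um^2), ploidy class, nucleoid count,
#'       true summed puncta area (um^2), polarized mitochondrial mass,
#'       Rho-0 flag}
#'     \item{nucleoids}{0-based (row, col) positions of every punctum with
#'       its parent `cell_id`}
#'   }
#' @export
render_field <- function(spec, well_id = "", field_index = 1L,
                         run_id = "", cell_line = "") {
  validate_field_spec(spec)
  with_seed(spec$seed, render_field_impl(spec, well_id, field_index,
                                         run_id, cell_line))
}

render_field_impl <- function(spec, well_id, field_index, run_id, cell_line) {
  nr <- spec$field_size[1]; nc <- spec$field_size[2]
  px <- spec$pixel_size
  dna <- matrix(0, nr, nc)
  mmp <- matrix(0, nr, nc)
  n <- spec$n_cells

  empty_cells <- data.frame(
    cell_id = integer(0), center_row = numeric(0), center_col = numeric(0),
    nucleus_area = numeric(0), ploidy_class = character(0),
    nucleoid_count = integer(0), puncta_summed_area = numeric(0),
    mito_polarized_mass = numeric(0), is_rho0 = logical(0))
  empty_nucleoids <- data.frame(cell_id = integer(0), row = numeric(0),
                                col = numeric(0))

  if (n == 0L) {
    dna <- dna + spec$background
    mmp <- mmp + spec$background
    if (spec$noise_sd > 0) {
      dna <- dna + matrix(stats::rnorm(nr * nc, 0, spec$noise_sd), nr, nc)
      mmp <- mmp + matrix(stats::rnorm(nr * nc, 0, spec$noise_sd), nr, nc)
    }
    return(structure(list(
      field = field_image(dna, mmp, px, well_id, field_index, run_id, cell_line),
      cells = empty_cells, nucleoids = empty_nucleoids),
      class = "rendered_field"))
  }

  ## --- cell centres: rejection sampling with minimum separation ---
  d_min <- 0.72 * sqrt(nr * nc / n)          # pixels between neighbouring cells
  margin <- max(6, 0.30 * d_min)
  if (nr - 2 * margin < 1 || nc - 2 * margin < 1)
    stop("field too small for the requested number of cells")
  centers <- matrix(NA_real_, n, 2)
  placed <- 0L; tries <- 0L
  while (placed < n) {
    tries <- tries + 1L
    if (tries > 200L * n)
      stop("field too small for the requested number of cells")
    cand <- c(stats::runif(1, margin, nr - margin),
              stats::runif(1, margin, nc - margin))
    if (placed == 0L ||
        min((centers[seq_len(placed), 1] - cand[1])^2 +
            (centers[seq_len(placed), 2] - cand[2])^2) >= d_min^2) {
      placed <- placed + 1L
      centers[placed, ] <- cand
    }
  }
  r_terr <- 0.5 * d_min                      # disc territory radius, pixels

  ## --- per-cell ground truth draws ---
  n_rho0 <- round(spec$rho0_fraction * n)
  rho0 <- rep(FALSE, n)
  if (n_rho0 > 0) rho0[sample.int(n, n_rho0)] <- TRUE
  ploidy <- ifelse(stats::runif(n) < spec$s_phase_fraction, "S_G2", "G1")
  nuc_area <- spec$nucleus_area_mean *
    exp(stats::rnorm(n, -0.5 * 0.15^2, 0.15))              # um^2
  # DNA content (integrated density target) is the controlled quantity:
  # 2x for S/G2, ~10% cv; peak intensity compensates the drawn area so that
  # integrated density, not brightness, carries the ploidy signal
  nuc_content <- ifelse(ploidy == "S_G2", 2, 1) *
    exp(stats::rnorm(n, -0.5 * 0.1^2, 0.1))
  nuc_peak <- spec$nucleus_intensity_mean * nuc_content *
    (spec$nucleus_area_mean / nuc_area)
  cell_factor <- exp(stats::rnorm(n, -0.5 * spec$cell_cv^2, spec$cell_cv))
  counts <- integer(n)
  counts[!rho0] <- rpois_positive(sum(!rho0),
                                  spec$nucleoid_count_mean * cell_factor[!rho0])
  mito_mass <- spec$mito_mass_mean *
    exp(stats::rnorm(n, -0.5 * spec$cell_cv^2, spec$cell_cv))

  sig_px <- spec$puncta_sigma / px
  a0 <- spot_truth_area(spec$puncta_sigma)

  ## --- nuclei ---
  aspect <- exp(stats::rnorm(n, 0, 0.1))
  # footprint modelled as the 2-sigma ellipse: area = pi * (2 s_r) * (2 s_c)
  s_geo <- sqrt(nuc_area / (px^2 * 4 * pi))
  s_r <- s_geo * aspect; s_c <- s_geo / aspect
  for (i in seq_len(n))
    dna <- stamp_gaussian(dna, centers[i, 1], centers[i, 2],
                          s_r[i], s_c[i], nuc_peak[i])

  ## --- nucleoid puncta (splat then one blur) ---
  total <- sum(counts)
  nucleoids <- empty_nucleoids
  if (total > 0) {
    cell_id <- rep(seq_len(n), counts)
    r_in <- pmin(2.2 * pmax(s_r, s_c) + 2, 0.75 * r_terr)
    rad <- sqrt(stats::runif(total, (r_in[cell_id])^2, r_terr^2))
    theta <- stats::runif(total, 0, 2 * pi)
    prow <- centers[cell_id, 1] + rad * sin(theta)
    pcol <- centers[cell_id, 2] + rad * cos(theta)
    prow <- pmin(pmax(prow, 2), nr - 1)
    pcol <- pmin(pmax(pcol, 2), nc - 1)
    amp <- spec$spot_intensity * exp(stats::rnorm(total, -0.5 * 0.2^2, 0.2))
    impulses <- splat_points(matrix(0, nr, nc), prow, pcol,
                             amp * 2 * pi * sig_px^2)
    dna <- dna + as.matrix(EBImage::gblur(impulses, sigma = sig_px))
    nucleoids <- data.frame(cell_id = cell_id, row = prow - 1, col = pcol - 1)
  }

  ## --- reticulum: 2-6 smooth random curves per cell ---
  # Each curve is a unit-step random walk with an Ornstein-Uhlenbeck-like
  # smooth heading; excursions beyond the territory are folded back radially.
  # Every cell's points carry equal mass summing to its mito_polarized_mass,
  # so total channel-2 signal above background is conserved exactly.
  msig_px <- max(MITO_SIGMA_UM / px, 0.8)
  all_r <- vector("list", n); all_c <- vector("list", n); all_m <- vector("list", n)
  fold_rad <- 0.92 * r_terr
  for (i in seq_len(n)) {
    n_curves <- sample(2:6, 1)
    n_steps <- max(10L, as.integer(round(1.6 * r_terr)))
    pts_r <- numeric(0); pts_c <- numeric(0)
    for (k in seq_len(n_curves)) {
      th <- stats::runif(1, 0, 2 * pi)
      start_rad <- stats::runif(1, 0.3, 0.6) * r_terr
      dir <- stats::runif(1, 0, 2 * pi) +
        cumsum(stats::rnorm(n_steps, 0, 0.3))
      rr <- centers[i, 1] + start_rad * sin(th) + cumsum(sin(dir))
      cc <- centers[i, 2] + start_rad * cos(th) + cumsum(cos(dir))
      # fold radius into [0, fold_rad] (triangle-wave reflection)
      drad <- sqrt((rr - centers[i, 1])^2 + (cc - centers[i, 2])^2)
      out <- drad > fold_rad
      if (any(out)) {
        folded <- abs(((drad[out]) %% (2 * fold_rad)) - fold_rad)
        folded <- fold_rad - folded
        scale <- ifelse(drad[out] > 0, folded / drad[out], 0)
        rr[out] <- centers[i, 1] + (rr[out] - centers[i, 1]) * scale
        cc[out] <- centers[i, 2] + (cc[out] - centers[i, 2]) * scale
      }
      pts_r <- c(pts_r, rr); pts_c <- c(pts_c, cc)
    }
    # clamp to the field interior (keeps total filament mass exact)
    all_r[[i]] <- pmin(pmax(pts_r, 6), nr - 5)
    all_c[[i]] <- pmin(pmax(pts_c, 6), nc - 5)
    all_m[[i]] <- rep(mito_mass[i] / length(pts_r), length(pts_r))
  }
  curve_img <- splat_points(matrix(0, nr, nc), unlist(all_r), unlist(all_c),
                            unlist(all_m))
  mmp <- mmp + as.matrix(EBImage::gblur(curve_img, sigma = msig_px))

  ## --- background and read noise ---
  dna <- dna + spec$background
  mmp <- mmp + spec$background
  if (spec$noise_sd > 0) {
    dna <- dna + matrix(stats::rnorm(nr * nc, 0, spec$noise_sd), nr, nc)
    mmp <- mmp + matrix(stats::rnorm(nr * nc, 0, spec$noise_sd), nr, nc)
  }

  cells <- data.frame(
    cell_id = seq_len(n),
    center_row = centers[, 1] - 1, center_col = centers[, 2] - 1,
    nucleus_area = nuc_area, ploidy_class = ploidy,
    nucleoid_count = counts, puncta_summed_area = counts * a0,
    mito_polarized_mass = mito_mass, is_rho0 = rho0)

  structure(list(
    field = field_image(dna, mmp, px, well_id, field_index, run_id, cell_line),
    cells = cells, nucleoids = nucleoids),
    class = "rendered_field")
}
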