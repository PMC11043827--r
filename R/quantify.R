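# Per-cell metric extraction: integrated densities are defined throughout as
# object area (um^2) times mean object intensity above background, summed
# over the object class, with the background level taken as the median
# intensity outside all objects of the channel.

#' Quantify one field: segmentation plus per-cell records
#'
#' Runs the full per-field pipeline: nucleus segmentation, territory
#' assignment, nucleoid detection, reticulum segmentation, and per-cell
#' metric computation, then calls Rho-0 state per cell.  Ploidy calling is a
#' per-culture operation and is applied afterwards with [classify_ploidy()]
#' on the pooled records.
#'
#' @param field a [field_image()].
#' @param params a [quant_params()].
#' @return A list of class `field_quant` with the label matrices
#'   (`nucleus_labels`, `cell_labels`, `nucleoid_labels`, `mito_mask`),
#'   per-channel `background` levels, and `records`, one row per analysed
#'   (non-border) cell.
#' @export
quantify_field <- function(field, params = quant_params()) {
  stopifnot(inherits(field, "field_image"))
  nucleus_labels <- segment_nuclei(field, params)
  cell_labels <- assign_cell_territories(nucleus_labels, field)
  nucleoid_labels <- detect_nucleoids(field, nucleus_labels, params)
  mito <- if (params$compute_reticulum)
    segment_mito_network(field, cell_labels, params)
  else list(mask = field$mmp > stats::median(field$mmp) +
              max(params$mito_k * stats::mad(field$mmp),
                  params$mito_floor * (max(field$mmp) - stats::median(field$mmp))),
            skeleton = NULL,
            length = stats::setNames(rep(NA_real_, max(cell_labels)),
                                     seq_len(max(cell_labels))))
  seg <- list(nucleus_labels = nucleus_labels, cell_labels = cell_labels,
              nucleoid_labels = nucleoid_labels, mito_mask = mito$mask,
              reticulum_length = mito$length)
  records <- compute_cell_records(seg, field, params)
  records <- classify_rho0(records, params)
  structure(c(seg, list(background = attr(records, "background"),
                        records = records)),
            class = "field_quant")
}

#' Compute per-cell records from a segmentation
#'
#' @param seg list with `nucleus_labels`, `cell_labels`, `nucleoid_labels`,
#'   `mito_mask` and optionally `reticulum_length` (named vector, um).
#' @param field the [field_image()] the segmentation came from.
#' @param params a [quant_params()].
#' @return `data.frame` with one row per cell: nucleoid count, summed puncta
#'   area (um^2), puncta / nuclear / mitochondrial integrated densities
#'   (AU um^2), reticulum length (um), nucleus centroid (0-based row/col)
#'   and the field's metadata.  The per-channel background levels are
#'   attached as attribute `"background"`.
#' @export
compute_cell_records <- function(seg, field, params = quant_params()) {
  px2 <- field$pixel_size^2
  nuc <- seg$nucleus_labels; terr <- seg$cell_labels
  pun <- seg$nucleoid_labels; mito <- seg$mito_mask
  n <- max(nuc)

  dna_bg <- stats::median(field$dna[nuc == 0L & pun == 0L])
  mmp_bg <- stats::median(field$mmp[!mito])

  rec <- data.frame(
    cell_id = seq_len(n),
    nucleoid_count = 0L, puncta_summed_area = 0,
    puncta_integrated_density = 0,
    nuclear_integrated_density = 0,
    mmp_integrated_density = 0,
    reticulum_length = 0,
    nucleus_row = NA_real_, nucleus_col = NA_real_)
  attr(rec, "background") <- c(dna = dna_bg, mmp = mmp_bg)
  if (n == 0L) return(cbind(rec, field_metadata(field)[0, , drop = FALSE]))

  ## nucleus centroid and integrated density
  idx <- which(nuc > 0L)
  lab <- nuc[idx]
  rows <- (idx - 1) %% nrow(nuc) + 1
  cols <- (idx - 1) %/% nrow(nuc) + 1
  ctr_r <- tapply(rows, lab, mean)
  ctr_c <- tapply(cols, lab, mean)
  rec$nucleus_row <- as.numeric(ctr_r[as.character(seq_len(n))]) - 1
  rec$nucleus_col <- as.numeric(ctr_c[as.character(seq_len(n))]) - 1
  nid <- tapply(field$dna[idx] - dna_bg, lab, sum) * px2
  rec$nuclear_integrated_density <- as.numeric(nid[as.character(seq_len(n))])

  ## nucleoid puncta: assign each punctum to the territory of its centroid
  if (max(pun) > 0L) {
    pidx <- which(pun > 0L)
    plab <- pun[pidx]
    prow <- (pidx - 1) %% nrow(pun) + 1
    pcol <- (pidx - 1) %/% nrow(pun) + 1
    crow <- round(tapply(prow, plab, mean))
    ccol <- round(tapply(pcol, plab, mean))
    cell_of <- terr[cbind(crow, ccol)]
    areas <- tabulate(plab, nbins = max(pun)) * px2
    dens <- tapply(field$dna[pidx] - dna_bg, plab, sum) * px2
    keep <- cell_of > 0L
    if (any(keep)) {
      cnt <- tapply(rep(1L, sum(keep)), cell_of[keep], sum)
      ar <- tapply(areas[keep], cell_of[keep], sum)
      dn <- tapply(as.numeric(dens)[keep], cell_of[keep], sum)
      ids <- as.integer(names(cnt))
      rec$nucleoid_count[ids] <- as.integer(cnt)
      rec$puncta_summed_area[ids] <- as.numeric(ar)
      rec$puncta_integrated_density[ids] <- as.numeric(dn)
    }
  }

  ## mitochondrial integrated density within each territory
  if (any(mito)) {
    midx <- which(mito & terr > 0L)
    if (length(midx)) {
      md <- tapply(field$mmp[midx] - mmp_bg, terr[midx], sum) * px2
      ids <- as.integer(names(md))
      rec$mmp_integrated_density[ids] <- as.numeric(md)
    }
  }

  if (!is.null(seg$reticulum_length) && length(seg$reticulum_length)) {
    ids <- as.integer(names(seg$reticulum_length))
    ok <- ids >= 1 & ids <= n
    rec$reticulum_length[ids[ok]] <- as.numeric(seg$reticulum_length)[ok]
  }

  out <- cbind(rec, field_metadata(field))
  attr(out, "background") <- attr(rec, "background")
  out
}

field_metadata <- function(field) {
  data.frame(well_id = field$well_id, field_index = field$field_index,
             run_id = field$run_id, cell_line = field$cell_line)
}

#' Call Rho-0 cells
#'
#' A cell is Rho-0 (void of detectable mtDNA) when both its nucleoid count
#' and its summed puncta area fall at or below the configured bounds
#' (defaults: count <= 2 and area <= 0.5 um^2, tolerating rare false spots).
#'
#' @param records per-cell records from [compute_cell_records()].
#' @param params a [quant_params()].
#' @return `records` with a logical `is_rho0` column.
#' @export
classify_rho0 <- function(records, params = quant_params()) {
  records$is_rho0 <- records$nucleoid_count <= params$rho0_max_count &
    records$puncta_summed_area <= params$rho0_max_area
  records
}

#' Proportion of Rho-0 cells in a set of records
#' @param records records carrying an `is_rho0` column.
#' @return Proportion in `[0, 1]`.
#' @export
rho0_proportion <- function(records) {
  if (!nrow(records)) return(NA_real_)
  mean(records$is_rho0)
}

#' Call ploidy class from nuclear DNA content
#'
#' Groups the cells of one culture by nuclear integrated density: the G1
#' mode is located as the highest kernel-density peak, and cells above
#' `ploidy_threshold` times that mode (default 1.5x, halfway to the 2x S/G2
#' mode) are called S/G2.
#'
#' @param records per-cell records of a single culture.
#' @param params a [quant_params()].
#' @return `records` with a `ploidy_class` column (`"G1"` or `"S_G2"`).
#' @export
classify_ploidy <- function(records, params = quant_params()) {
  x <- records$nuclear_integrated_density
  if (length(x) < 10L) {
    warning("fewer than 10 cells: ploidy calling degenerate, all cells G1")
    records$ploidy_class <- rep("G1", nrow(records))
    return(records)
  }
  if (stats::sd(x) == 0) {
    records$ploidy_class <- rep("G1", nrow(records))
    return(records)
  }
  d <- stats::density(x, n = 512)
  g1_mode <- d$x[which.max(d$y)]
  records$ploidy_class <- ifelse(x > params$ploidy_threshold * g1_mode,
                                 "S_G2", "G1")
  records
}

#' Fraction of S/G2 cells
#' @param records records carrying a `ploidy_class` column.
#' @return Proportion in `[0, 1]`.
#' @export
s_phase_fraction <- function(records) {
  if (!nrow(records)) return(NA_real_)
  mean(records$ploidy_class == "S_G2")
}

#' Match measured cell records to generator ground truth
#'
#' Pairs each analysed cell with the nearest ground-truth cell by nucleus
#' centre (pixels).  Used to benchmark the pipeline on synthetic fields.
#'
#' @param records records from one field ([quantify_field()]).
#' @param truth_cells `cells` ground-truth table of the matching
#'   [render_field()] call.
#' @param max_dist maximum centre distance (pixels) for a valid match.
#' @return `records` with appended `truth_*` columns for matched cells;
#'   unmatched cells are dropped.
#' @export
match_records_to_truth <- function(records, truth_cells, max_dist = 20) {
  if (!nrow(records) || !nrow(truth_cells)) return(records[0, , drop = FALSE])
  d2 <- outer(records$nucleus_row, truth_cells$center_row, "-")^2 +
    outer(records$nucleus_col, truth_cells$center_col, "-")^2
  j <- apply(d2, 1, which.min)
  dist <- sqrt(d2[cbind(seq_len(nrow(records)), j)])
  keep <- dist <= max_dist
  out <- records[keep, , drop = FALSE]
  tc <- truth_cells[j[keep], , drop = FALSE]
  out$truth_cell_id <- tc$cell_id
  out$truth_nucleoid_count <- tc$nucleoid_count
  out$truth_puncta_summed_area <- tc$puncta_summed_area
  out$truth_is_rho0 <- tc$is_rho0
  out$truth_ploidy_class <- tc$ploidy_class
  out$truth_mito_polarized_mass <- tc$mito_polarized_mass
  out
}
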