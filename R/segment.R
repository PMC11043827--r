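# Size-based segmentation of the two channels: nuclei and nucleoid puncta are
# separated in the DNA channel purely by object size, mirroring analysis
# pipelines that segment PicoGreen signal "on size"; the membrane-potential
# channel is thresholded relative to background and skeletonized for
# reticulum length.  All thresholds are relative (Otsu on a min-max
# normalised image; median + k*MAD with a relative floor), which makes every
# mask invariant to global multiplicative intensity scaling.

#' Parameters of the per-cell quantification pipeline
#'
#' @param nucleus_min_area minimum nucleus area, um^2; smaller DNA-channel
#'   objects are left for nucleoid detection (the size-based gate).
#' @param nucleus_blur_sigma Gaussian smoothing sd for nucleus segmentation,
#'   pixels.
#' @param puncta_sigma expected nucleoid spot width (Gaussian sd), um; tunes
#'   the difference-of-Gaussians band-pass.
#' @param puncta_k MAD multiplier of the puncta detection threshold.
#' @param puncta_floor relative floor of the puncta threshold as a fraction
#'   of the band-pass maximum (guards the threshold in near-noiseless
#'   images where the MAD collapses to zero).
#' @param nucleoid_max_area maximum area of a nucleoid punctum, um^2;
#'   larger candidates are rejected.
#' @param nucleoid_min_area minimum area of a nucleoid punctum, um^2
#'   (0 disables the gate; the Rho-0 calling rule already tolerates rare
#'   single-pixel noise detections).
#' @param mito_k MAD multiplier of the reticulum threshold.
#' @param mito_floor relative floor of the reticulum threshold.
#' @param rho0_max_count,rho0_max_area a cell is called Rho-0 when its
#'   nucleoid count and summed puncta area both fall at or below these
#'   bounds (counts tolerate rare false spots).
#' @param ploidy_threshold S/G2 calling threshold as a multiple of the G1
#'   mode of nuclear integrated density.
#' @param compute_reticulum logical; skeletonize the membrane-potential
#'   channel and report reticulum length.
#' @return A list of class `quant_params`.
#' @export
quant_params <- function(nucleus_min_area = 30,
                         nucleus_blur_sigma = 1,
                         puncta_sigma = 0.3,
                         puncta_k = 5,
                         puncta_floor = 0.1,
                         nucleoid_max_area = 2,
                         nucleoid_min_area = 0,
                         mito_k = 3,
                         mito_floor = 0.05,
                         rho0_max_count = 2,
                         rho0_max_area = 0.5,
                         ploidy_threshold = 1.5,
                         compute_reticulum = TRUE) {
  structure(list(nucleus_min_area = nucleus_min_area,
                 nucleus_blur_sigma = nucleus_blur_sigma,
                 puncta_sigma = puncta_sigma, puncta_k = puncta_k,
                 puncta_floor = puncta_floor,
                 nucleoid_max_area = nucleoid_max_area,
                 nucleoid_min_area = nucleoid_min_area,
                 mito_k = mito_k, mito_floor = mito_floor,
                 rho0_max_count = rho0_max_count,
                 rho0_max_area = rho0_max_area,
                 ploidy_threshold = ploidy_threshold,
                 compute_reticulum = compute_reticulum),
            class = "quant_params")
}

# Drop labels listed in `drop` and renumber the survivors 1..k.
relabel <- function(labels, drop = integer(0)) {
  ids <- setdiff(sort(unique(as.vector(labels))), c(0L, drop))
  out <- matrix(0L, nrow(labels), ncol(labels))
  if (length(ids)) {
    m <- integer(max(ids)); m[ids] <- seq_along(ids)
    pos <- labels > 0 & !(labels %in% drop)
    out[pos] <- m[labels[pos]]
  }
  out
}

border_labels <- function(labels) {
  nr <- nrow(labels); nc <- ncol(labels)
  setdiff(unique(c(labels[1, ], labels[nr, ], labels[, 1], labels[, nc])), 0L)
}

#' Segment nuclei in the DNA channel
#'
#' Smooths the DNA channel, thresholds it with Otsu's method on the min-max
#' normalised image (hence invariant to global intensity scaling), and keeps
#' connected components whose area reaches `nucleus_min_area`; smaller
#' objects are nucleoid candidates, not nuclei.  Components touching the
#' field border are removed, implementing the border-cell exclusion policy.
#'
#' @param field a [field_image()].
#' @param params a [quant_params()].
#' @return Integer label matrix (0 = background), labels 1..n.
#' @export
segment_nuclei <- function(field, params = quant_params()) {
  img <- field$dna
  rng <- range(img)
  if (!is.finite(diff(rng)) || diff(rng) <= 0)
    return(matrix(0L, nrow(img), ncol(img)))
  norm <- (img - rng[1]) / (rng[2] - rng[1])
  sm <- as.matrix(EBImage::gblur(norm, sigma = params$nucleus_blur_sigma))
  sm <- pmin(pmax(sm, 0), 1)
  th <- EBImage::otsu(EBImage::Image(sm), range = c(0, 1))
  mask <- sm > th
  # a field with no cells is noise only: Otsu then splits the noise mid-way
  # and floods the mask; real nuclei cover a small fraction of the field
  if (mean(mask) > 0.25) return(matrix(0L, nrow(img), ncol(img)))
  labels <- as.matrix(EBImage::bwlabel(mask))
  storage.mode(labels) <- "integer"
  if (max(labels) == 0L) return(labels)
  min_px <- params$nucleus_min_area / field$pixel_size^2
  sizes <- tabulate(labels[labels > 0], nbins = max(labels))
  small <- which(sizes < min_px)
  relabel(labels, drop = union(small, border_labels(labels)))
}

#' Partition a field into one territory per nucleus
#'
#' Grows every nucleus outwards simultaneously (Voronoi-style seeded region
#' growing), assigning each pixel of the field to its nearest nucleus.  The
#' returned labels correspond one-to-one to the nucleus labels.
#'
#' @param nucleus_labels label matrix from [segment_nuclei()].
#' @param field the [field_image()] (for its dimensions).
#' @return Integer label matrix of cell territories covering the field.
#' @export
assign_cell_territories <- function(nucleus_labels, field) {
  if (max(nucleus_labels) == 0L)
    return(matrix(0L, nrow(nucleus_labels), ncol(nucleus_labels)))
  blank <- EBImage::Image(matrix(0, nrow(nucleus_labels), ncol(nucleus_labels)))
  terr <- EBImage::propagate(blank, EBImage::Image(nucleus_labels),
                             lambda = 1e10)
  out <- round(as.matrix(terr))
  storage.mode(out) <- "integer"
  out
}

#' Detect mtDNA nucleoid puncta
#'
#' Band-pass filters the DNA channel with a difference of Gaussians tuned to
#' the expected spot width, thresholds at `median + puncta_k * MAD` of the
#' filtered image (with a relative floor for near-noiseless data), splits
#' touching spots at intensity saddles by watershed, and rejects candidates
#' that overlap a nucleus footprint or exceed `nucleoid_max_area`.  Two
#' spots closer than about one spot sd merge into one object (the documented
#' resolution limit); spots beyond about four sd are always resolved.
#'
#' @param field a [field_image()].
#' @param nucleus_labels label matrix from [segment_nuclei()].
#' @param params a [quant_params()].
#' @return Integer label matrix of puncta.
#' @export
detect_nucleoids <- function(field, nucleus_labels, params = quant_params()) {
  img <- field$dna
  sig <- params$puncta_sigma / field$pixel_size
  dog <- as.matrix(EBImage::gblur(img, sigma = sig)) -
    as.matrix(EBImage::gblur(img, sigma = 2 * sig))
  med <- stats::median(dog)
  s <- stats::mad(dog)
  peak <- max(dog) - med
  if (peak <= 0) return(matrix(0L, nrow(img), ncol(img)))
  th <- med + max(params$puncta_k * s, params$puncta_floor * peak)
  mask <- dog > th
  if (!any(mask)) return(matrix(0L, nrow(img), ncol(img)))
  relief <- (dog - th) * mask
  tol <- max(params$puncta_k * s, params$puncta_floor * peak) * 0.4
  labels <- as.matrix(EBImage::watershed(EBImage::Image(relief),
                                         tolerance = tol, ext = 1))
  storage.mode(labels) <- "integer"
  if (max(labels) == 0L) return(labels)
  max_px <- params$nucleoid_max_area / field$pixel_size^2
  min_px <- params$nucleoid_min_area / field$pixel_size^2
  sizes <- tabulate(labels[labels > 0], nbins = max(labels))
  bad_size <- which(sizes > max_px | sizes < min_px)
  in_nucleus <- unique(labels[labels > 0 & nucleus_labels > 0])
  relabel(labels, drop = union(bad_size, in_nucleus))
}

#' Segment and skeletonize the mitochondrial reticulum
#'
#' Thresholds the membrane-potential channel at `median + mito_k * MAD`
#' above background, thins the mask to a one-pixel skeleton (Zhang-Suen),
#' and measures skeleton path length per cell territory (orthogonal steps
#' count 1 pixel, diagonal steps `sqrt(2)`, redundant diagonals skipped).
#'
#' @param field a [field_image()].
#' @param cell_labels territory label matrix.
#' @param params a [quant_params()].
#' @return List with `mask` (logical matrix), `skeleton` (logical matrix) and
#'   `length` (named numeric vector, um per cell label).
#' @export
segment_mito_network <- function(field, cell_labels, params = quant_params()) {
  img <- field$mmp
  med <- stats::median(img)
  s <- stats::mad(img)
  peak <- max(img) - med
  n_cells <- max(cell_labels)
  lengths <- stats::setNames(numeric(n_cells), seq_len(n_cells))
  if (peak <= 0)
    return(list(mask = matrix(FALSE, nrow(img), ncol(img)),
                skeleton = matrix(FALSE, nrow(img), ncol(img)),
                length = lengths))
  th <- med + max(params$mito_k * s, params$mito_floor * peak)
  mask <- img > th
  skel <- thin_mask(mask)
  len <- skeleton_lengths(skel, cell_labels, field$pixel_size)
  if (n_cells > 0) {
    common <- intersect(names(len), names(lengths))
    lengths[common] <- len[common]
  }
  list(mask = mask, skeleton = skel, length = lengths)
}

# Zhang-Suen morphological thinning of a binary mask to a 1-px skeleton
# (compiled kernel; see src/thinning.cpp).
thin_mask <- function(mask) {
  out <- .thin_zhang_suen(mask)
  dim(out) <- dim(mask)
  out
}

# Path length of a skeleton per territory label.  Each adjacency is counted
# once; diagonals that merely shortcut an existing orthogonal connection are
# skipped so corners are not double-counted.
skeleton_lengths <- function(skel, cell_labels, pixel_size) {
  nr <- nrow(skel); nc <- ncol(skel)
  lens <- numeric(0)
  add <- function(lens, labs, w) {
    if (length(labs) == 0) return(lens)
    t <- tapply(rep(w, length(labs)), labs, sum)
    for (nm in names(t)) lens[nm] <- (if (nm %in% names(lens)) lens[nm] else 0) + t[[nm]]
    lens
  }
  # horizontal edges
  h <- skel[, -nc, drop = FALSE] & skel[, -1, drop = FALSE]
  lab_h <- cell_labels[, -nc, drop = FALSE][h]
  lens <- add(lens, lab_h[lab_h > 0], 1)
  # vertical edges
  v <- skel[-nr, , drop = FALSE] & skel[-1, , drop = FALSE]
  lab_v <- cell_labels[-nr, , drop = FALSE][v]
  lens <- add(lens, lab_v[lab_v > 0], 1)
  # diagonal \ : count only when neither completing orthogonal pixel is set
  a <- skel[-nr, -nc, drop = FALSE]; d <- skel[-1, -1, drop = FALSE]
  r <- skel[-nr, -1, drop = FALSE];  l <- skel[-1, -nc, drop = FALSE]
  dg <- a & d & !r & !l
  lab_d <- cell_labels[-nr, -nc, drop = FALSE][dg]
  lens <- add(lens, lab_d[lab_d > 0], sqrt(2))
  # diagonal / :
  ad <- r & l & !a & !d
  lab_a <- cell_labels[-nr, -1, drop = FALSE][ad]
  lens <- add(lens, lab_a[lab_a > 0], sqrt(2))
  lens * pixel_size
}
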