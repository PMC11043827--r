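#' Two-channel field image container
#'
#' Holds one imaged field: the DNA-dye channel (PicoGreen-like; nuclei plus
#' mtDNA nucleoid puncta) and the membrane-potential channel (TMRM/CMXRos-
#' like; the polarized mitochondrial reticulum), both as numeric matrices in
#' arbitrary fluorescence units, together with the pixel size and acquisition
#' metadata.
#'
#' @param dna,mmp numeric matrices of identical dimensions.
#' @param pixel_size pixel size, micrometres per pixel.
#' @param well_id,field_index,run_id,cell_line acquisition identifiers.
#' @return An object of class `field_image`.
#' @export
field_image <- function(dna, mmp, pixel_size,
                        well_id = "", field_index = 1L,
                        run_id = "", cell_line = "") {
  stopifnot(is.matrix(dna), is.matrix(mmp), all(dim(dna) == dim(mmp)),
            pixel_size > 0)
  structure(list(dna = dna, mmp = mmp, pixel_size = pixel_size,
                 well_id = well_id, field_index = as.integer(field_index),
                 run_id = run_id, cell_line = cell_line),
            class = "field_image")
}

#' @export
print.field_image <- function(x, ...) {
  cat(sprintf("field_image: %d x %d px @ %.3g um/px  well=%s field=%d run=%s line=%s\n",
              nrow(x$dna), ncol(x$dna), x$pixel_size,
              x$well_id, x$field_index, x$run_id, x$cell_line))
  invisible(x)
}

#' Write / read a field image as a two-page 16-bit TIFF
#'
#' Page 1 is the DNA channel, page 2 the membrane-potential channel.
#' Intensities are stored as 16-bit counts (values clamped to 0..65535).
#' Pixel size and acquisition identifiers travel in a plain-text sidecar
#' (`<path>.meta`, `key=value` lines) next to the image.
#'
#' @param field a [field_image()].
#' @param path file path.
#' @return `write_field_tiff` returns `path` invisibly; `read_field_tiff`
#'   returns a [field_image()].
#' @export
write_field_tiff <- function(field, path) {
  stopifnot(inherits(field, "field_image"))
  clamp <- function(m) pmin(pmax(round(m), 0), 65535) / 65535
  tiff::writeTIFF(list(clamp(field$dna), clamp(field$mmp)), path,
                  bits.per.sample = 16L, compression = "none")
  writeLines(c(sprintf("pixel_size=%.10g", field$pixel_size),
               sprintf("well_id=%s", field$well_id),
               sprintf("field_index=%d", field$field_index),
               sprintf("run_id=%s", field$run_id),
               sprintf("cell_line=%s", field$cell_line)),
             paste0(path, ".meta"))
  invisible(path)
}

#' @rdname write_field_tiff
#' @param pixel_size fallback pixel size if the image has no metadata
#'   sidecar.
#' @export
read_field_tiff <- function(path, pixel_size = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) < 2L) stop("expected a two-page TIFF (DNA, MMP)")
  fields <- list(pixel_size = pixel_size, well_id = "", field_index = 1L,
                 run_id = "", cell_line = "")
  meta_path <- paste0(path, ".meta")
  if (file.exists(meta_path)) {
    for (kv in readLines(meta_path)) {
      parts <- strsplit(kv, "=", fixed = TRUE)[[1]]
      if (length(parts) == 2L && parts[1] %in% names(fields))
        fields[[parts[1]]] <- parts[2]
    }
  }
  if (is.null(fields$pixel_size))
    stop("pixel size not found in sidecar metadata; supply pixel_size=")
  field_image(pages[[1]] * 65535, pages[[2]] * 65535,
              pixel_size = as.numeric(fields$pixel_size),
              well_id = fields$well_id,
              field_index = as.integer(fields$field_index),
              run_id = fields$run_id, cell_line = fields$cell_line)
}
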