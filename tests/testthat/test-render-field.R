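test_that("rendering is bit-identical for identical spec and seed", {
  spec <- small_spec(seed = 7L)
  a <- render_field(spec)
  b <- render_field(spec)
  expect_identical(a$field$dna, b$field$dna)
  expect_identical(a$field$mmp, b$field$mmp)
  expect_identical(a$cells, b$cells)
  expect_identical(a$nucleoids, b$nucleoids)
  # a different seed changes the pixels
  c <- render_field(small_spec(seed = 8L))
  expect_false(identical(a$field$dna, c$field$dna))
})

test_that("an empty field is background plus noise with empty truth", {
  rf <- render_field(small_spec(n_cells = 0L, noise_sd = 3, seed = 2L))
  expect_equal(nrow(rf$cells), 0L)
  expect_equal(nrow(rf$nucleoids), 0L)
  expect_equal(mean(rf$field$dna), 100, tolerance = 0.01)
  expect_equal(sd(as.vector(rf$field$dna)), 3, tolerance = 0.1)
})

test_that("Rho-0 cells carry exactly zero nucleoids, others at least one", {
  rf <- render_field(small_spec(n_cells = 10L, rho0_fraction = 0.4,
                                seed = 5L))
  expect_equal(sum(rf$cells$is_rho0), 4L)  # exact composition
  expect_true(all(rf$cells$nucleoid_count[rf$cells$is_rho0] == 0L))
  expect_true(all(rf$cells$nucleoid_count[!rf$cells$is_rho0] >= 1L))
  # truth invariant: is_rho0 <=> count == 0
  expect_identical(rf$cells$is_rho0, rf$cells$nucleoid_count == 0L)
  # the per-cell nucleoid position table matches the drawn counts
  tab <- table(factor(rf$nucleoids$cell_id, levels = rf$cells$cell_id))
  expect_equal(as.integer(tab), rf$cells$nucleoid_count)
})

test_that("channel-2 intensity above background conserves mitochondrial mass", {
  rf <- render_field(small_spec(n_cells = 6L, noise_sd = 0, seed = 3L))
  total <- sum(rf$field$mmp - 100)
  expect_equal(total, sum(rf$cells$mito_polarized_mass), tolerance = 1e-6)
})

test_that("nucleoids are placed outside the nucleus footprint", {
  rf <- render_field(small_spec(n_cells = 6L, seed = 9L))
  spec <- small_spec(n_cells = 6L, seed = 9L)
  for (i in rf$cells$cell_id) {
    pts <- rf$nucleoids[rf$nucleoids$cell_id == i, ]
    if (!nrow(pts)) next
    d <- sqrt((pts$row - rf$cells$center_row[i])^2 +
                (pts$col - rf$cells$center_col[i])^2)
    # nucleus footprint radius ~ 2 * geometric sd of the Gaussian blob
    s_geo <- sqrt(rf$cells$nucleus_area[i] / (spec$pixel_size^2 * 4 * pi))
    expect_true(all(d > 1.8 * s_geo))
  }
})

test_that("overfull fields are refused", {
  expect_error(render_field(small_spec(field_size = c(64L, 64L),
                                       n_cells = 60L)),
               "too small")
})

test_that("field images round-trip through two-page TIFF", {
  rf <- render_field(small_spec(n_cells = 3L, seed = 12L))
  path <- tempfile(fileext = ".tif")
  write_field_tiff(rf$field, path)
  back <- read_field_tiff(path)
  expect_equal(back$pixel_size, rf$field$pixel_size)
  expect_equal(dim(back$dna), dim(rf$field$dna))
  # 16-bit quantisation: intensities equal to within one count
  expect_lt(max(abs(back$dna - pmin(pmax(round(rf$field$dna), 0), 65535))), 0.51)
})
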