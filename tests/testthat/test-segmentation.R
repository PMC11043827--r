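test_that("blank fields segment to zero nuclei and zero puncta", {
  f0 <- blank_field()
  expect_equal(max(segment_nuclei(f0)), 0L)
  expect_equal(max(detect_nucleoids(f0, matrix(0L, 128, 128))), 0L)
  # background + noise only
  rf <- render_field(small_spec(n_cells = 0L, seed = 2L))
  expect_equal(max(segment_nuclei(rf$field)), 0L)
})

test_that("every interior nucleus is found at screening signal-to-noise", {
  rf <- render_field(small_spec(field_size = c(512L, 512L), n_cells = 8L,
                                seed = 41L))
  nuc <- segment_nuclei(rf$field)
  expect_equal(max(nuc), 8L)
})

test_that("segmentation is invariant to global intensity scaling", {
  rf <- render_field(small_spec(field_size = c(384L, 384L), n_cells = 6L,
                                nucleoid_count_mean = 25, seed = 17L))
  f2 <- rf$field
  f2$dna <- f2$dna * 2
  f2$mmp <- f2$mmp * 2
  nuc1 <- segment_nuclei(rf$field); nuc2 <- segment_nuclei(f2)
  expect_identical(nuc1, nuc2)
  expect_identical(detect_nucleoids(rf$field, nuc1),
                   detect_nucleoids(f2, nuc2))
  terr <- assign_cell_territories(nuc1, rf$field)
  expect_identical(terr, assign_cell_territories(nuc2, f2))
})

test_that("territories partition the field around their nuclei", {
  # single nucleus: the whole field is its territory
  dna <- matrix(100, 128, 128)
  nr <- 128
  for (r in 1:nr) for (c in 1:nr)
    dna[r, c] <- dna[r, c] + 400 * exp(-((r - 64)^2 + (c - 64)^2) / (2 * 36))
  f <- field_image(dna, matrix(100, nr, nr), pixel_size = 0.5)
  nuc <- segment_nuclei(f)
  expect_equal(max(nuc), 1L)
  terr <- assign_cell_territories(nuc, f)
  expect_true(all(terr == 1L))

  # two nuclei symmetric about the field centre split along the bisector
  dna2 <- matrix(100, 128, 128)
  for (r in 1:nr) for (c in 1:nr)
    dna2[r, c] <- dna2[r, c] +
      400 * exp(-((r - 40)^2 + (c - 64)^2) / (2 * 36)) +
      400 * exp(-((r - 88)^2 + (c - 64)^2) / (2 * 36))
  f2 <- field_image(dna2, matrix(100, nr, nr), pixel_size = 0.5)
  nuc2 <- segment_nuclei(f2)
  expect_equal(max(nuc2), 2L)
  terr2 <- assign_cell_territories(nuc2, f2)
  top <- nuc2[40, 64]; bottom <- nuc2[88, 64]
  expect_true(all(terr2[1:56, ] == top))
  expect_true(all(terr2[73:128, ] == bottom))
  split_frac <- mean(terr2 == top)
  expect_equal(split_frac, 0.5, tolerance = 0.03)
})

test_that("nucleoids land in their parent cell's territory", {
  rf <- render_field(field_spec(n_cells = 20L, seed = 61L))
  nuc <- segment_nuclei(rf$field)
  terr <- assign_cell_territories(nuc, rf$field)
  # map each truth cell to the territory of the label nearest its centre
  cell_terr <- terr[cbind(round(rf$cells$center_row) + 1,
                          round(rf$cells$center_col) + 1)]
  keep <- cell_terr > 0  # border-excluded cells have no territory claim
  pt_terr <- terr[cbind(round(rf$nucleoids$row) + 1,
                        round(rf$nucleoids$col) + 1)]
  expected <- cell_terr[rf$nucleoids$cell_id]
  ok <- keep[rf$nucleoids$cell_id]
  expect_gt(mean(pt_terr[ok] == expected[ok]), 0.99)
})

test_that("two-spot probes resolve beyond 4 sigma and merge below 1 sigma", {
  # spots of sigma = 1 px at 0.35 um/px, i.e. the pipeline's default
  # puncta_sigma of 0.35 um
  mk_spots <- function(sep_px) {
    img <- matrix(100, 128, 128)
    for (r in 1:128) for (c in 1:128)
      img[r, c] <- img[r, c] +
        200 * exp(-((r - 64)^2 + (c - 60)^2) / 2) +
        200 * exp(-((r - 64)^2 + (c - 60 - sep_px)^2) / 2)
    field_image(img, matrix(100, 128, 128), pixel_size = 0.35)
  }
  p <- quant_params(puncta_sigma = 0.35)
  zero_nuc <- matrix(0L, 128, 128)
  far <- detect_nucleoids(mk_spots(5), zero_nuc, p)   # > 4 sigma apart
  expect_equal(max(far), 2L)
  near <- detect_nucleoids(mk_spots(0.8), zero_nuc, p) # < 1 sigma apart
  expect_equal(max(near), 1L)
})

test_that("skeleton length recovers straight filaments and scales with their number", {
  line_field <- function(rows) {
    mmp <- matrix(100, 128, 160)
    for (r in rows) mmp[r, 21:120] <- 300   # 100-px straight filaments
    field_image(matrix(100, 128, 160), mmp, pixel_size = 0.5)
  }
  cells <- matrix(1L, 128, 160)
  one <- segment_mito_network(line_field(64), cells)
  # 100 px at 0.5 um/px: path length 49.5 um, tolerance 2 px-equivalents
  expect_lt(abs(one$length[["1"]] - 50), 1)
  two <- segment_mito_network(line_field(c(40, 88)), cells)
  four <- segment_mito_network(line_field(c(20, 56, 92, 116)), cells)
  expect_equal(four$length[["1"]] / two$length[["1"]], 2, tolerance = 0.05)
  # blank channel: zero length everywhere
  blank <- segment_mito_network(blank_field(), matrix(1L, 128, 128))
  expect_equal(unname(blank$length), 0)
})
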