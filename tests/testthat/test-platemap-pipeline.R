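test_that("a valid 96-well plate map loads and enumerates its contexts", {
  pm <- make_platemap(96)
  path <- tempfile(fileext = ".csv")
  write.csv(pm, path, row.names = FALSE)
  loaded <- read_platemap(path)
  expect_s3_class(loaded, "platemap")
  expect_equal(nrow(loaded), 96L)
  expect_equal(nrow(validate_platemap(pm)), 0L)
})

test_that("the full screen design enumerates 64 condition contexts", {
  # (15 subsets + DMSO) x 2 concentrations x 2 serum states
  conds <- enumerate_supplement_conditions(c("A", "T", "G", "C"),
                                           concentrations = c(50, 200))
  rows <- list()
  i <- 0L
  for (serum in c(10, 0.1)) for (cond in conds) {
    i <- i + 1L
    rows[[i]] <- data.frame(well_id = sprintf("W%03d", i),
                            cell_line = "LINE1", run_id = "run1",
                            serum = serum, supplement = cond$label,
                            concentration = cond$concentration, day = 7)
  }
  pm <- do.call(rbind, rows)
  expect_equal(nrow(platemap_contexts(pm)), 64L)
})

test_that("plate-map violations are reported with row numbers and block loading", {
  pm <- make_platemap(8)
  pm$supplement[3] <- "U"
  pm$well_id[5] <- pm$well_id[4]
  pm$serum[6] <- 5
  rep <- validate_platemap(pm)
  expect_setequal(rep$row, c(3L, 5L, 6L))
  expect_match(rep$message[rep$row == 3], "'U'")
  path <- tempfile(fileext = ".csv")
  write.csv(pm, path, row.names = FALSE)
  expect_error(read_platemap(path), "row 3")
})

test_that("unknown configuration keys are rejected before any computation", {
  expect_error(pipeline_config(overrides = list(bogus = 1)),
               "unknown configuration key 'bogus'")
  expect_error(pipeline_config(overrides = list(screen = list(n_celsl = 3))),
               "screen.n_celsl")
  cfg <- pipeline_config(overrides = list(screen = list(runs = 3L)))
  expect_equal(cfg$screen$runs, 3L)
  # the hash tracks the configuration content
  expect_false(identical(attr(cfg, "hash"), attr(pipeline_config(), "hash")))
})

test_that("yaml configs round-trip through pipeline_config", {
  path <- tempfile(fileext = ".yaml")
  writeLines(c("seed: 9", "screen:", "  runs: 4", "  run_sd: 0.2"), path)
  cfg <- pipeline_config(path)
  expect_equal(cfg$seed, 9)
  expect_equal(cfg$screen$runs, 4)
  expect_equal(cfg$screen$run_sd, 0.2)
})

test_that("the demo pipeline is byte-identical under a fixed config and seed", {
  cfg <- pipeline_config(overrides = list(
    screen = list(fields_per_well = 2L, n_cells = 10L)))
  d1 <- file.path(tempdir(), "ppl1"); d2 <- file.path(tempdir(), "ppl2")
  man <- run_pipeline(cfg, d1)
  run_pipeline(cfg, d2)
  files <- list.files(d1)
  expect_setequal(c(man$outputs, "manifest.json"), files)
  for (f in files)
    expect_identical(readBin(file.path(d1, f), "raw", n = 10^7),
                     readBin(file.path(d2, f), "raw", n = 10^7),
                     label = f)
  # a different seed changes the cell table
  cfg2 <- pipeline_config(overrides = list(
    seed = 2L, screen = list(fields_per_well = 2L, n_cells = 10L)))
  d3 <- file.path(tempdir(), "ppl3")
  run_pipeline(cfg2, d3)
  expect_false(identical(readBin(file.path(d1, "cells.csv"), "raw", 10^7),
                         readBin(file.path(d3, "cells.csv"), "raw", 10^7)))
  unlink(c(d1, d2, d3), recursive = TRUE)
})

test_that("pipeline tables refuse to mix configurations", {
  cfg <- pipeline_config(overrides = list(
    screen = list(fields_per_well = 1L, n_cells = 8L)))
  d <- file.path(tempdir(), "pplh")
  run_pipeline(cfg, d)
  tab <- read_pipeline_table(file.path(d, "cells.csv"),
                             expect_hash = attr(cfg, "hash"))
  expect_identical(attr(tab, "config_hash"), attr(cfg, "hash"))
  expect_error(read_pipeline_table(file.path(d, "cells.csv"),
                                   expect_hash = "deadbeef"),
               "config hash mismatch")
  plain <- tempfile(fileext = ".csv")
  write.csv(data.frame(x = 1), plain, row.names = FALSE)
  expect_error(read_pipeline_table(plain), "missing config-hash")
  unlink(d, recursive = TRUE)
})
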