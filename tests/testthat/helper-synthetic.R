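# Shared fixtures: small, fast field specifications used across tests.

small_spec <- function(...) {
  args <- list(field_size = c(256L, 256L), n_cells = 5L,
               nucleoid_count_mean = 20, seed = 101L)
  over <- list(...)
  args[names(over)] <- over
  do.call(field_spec, args)
}

# A uniform-background two-channel field with nothing in it.
blank_field <- function(nr = 128, nc = 128, background = 100,
                        pixel_size = 0.5) {
  field_image(matrix(background, nr, nc), matrix(background, nr, nc),
              pixel_size = pixel_size)
}

# All permutations of 1..4 (24 rows), for exhaustive pool-ordering checks.
all_perms4 <- function() {
  out <- list()
  for (a in 1:4) for (b in setdiff(1:4, a)) for (cc in setdiff(1:4, c(a, b)))
    out[[length(out) + 1L]] <- c(a, b, cc, setdiff(1:4, c(a, b, cc)))
  out
}

# Plate-map builder used by the IO tests.
make_platemap <- function(n = 96) {
  conds <- enumerate_supplement_conditions(c("A", "T", "G", "C"),
                                           concentrations = c(50, 200))
  rows <- lapply(seq_len(n), function(i) {
    cond <- conds[[(i - 1) %% length(conds) + 1]]
    data.frame(well_id = sprintf("W%03d", i), cell_line = "LINE1",
               run_id = "run1", serum = if (i %% 2) 10 else 0.1,
               supplement = cond$label, concentration = cond$concentration,
               day = 7)
  })
  do.call(rbind, rows)
}
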