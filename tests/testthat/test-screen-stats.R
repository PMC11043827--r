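mk_records <- function(area, rho0 = rep(FALSE, length(area)),
                       mmp = rep(1, length(area))) {
  data.frame(puncta_summed_area = area, is_rho0 = rho0,
             mmp_integrated_density = mmp)
}

test_that("condition summaries use log10 area excluding Rho-0 cells", {
  s <- summarize_condition(mk_records(c(1, 10, 100)))
  expect_equal(s$mean_log10_area, 1)
  expect_equal(s$cell_count, 3L)

  # all Rho-0: mtDNA summary undefined, proportion 1
  s0 <- summarize_condition(mk_records(c(0, 0), rho0 = c(TRUE, TRUE)))
  expect_false(s0$mtdna_defined)
  expect_true(is.na(s0$mean_log10_area))
  expect_equal(s0$rho0_proportion, 1)

  # Rho-0 cells count towards the total but not the log summary
  s1 <- summarize_condition(mk_records(c(0, 10, 1000), c(TRUE, FALSE, FALSE)))
  expect_equal(s1$cell_count, 3L)
  expect_equal(s1$mean_log10_area, 2)
})

test_that("percent change against baseline is the textbook ratio", {
  a <- summarize_condition(mk_records(rep(2, 100), mmp = rep(5, 100)))
  b <- summarize_condition(mk_records(rep(2, 100), mmp = rep(5, 100)))
  expect_equal(as.numeric(percent_change_vs_baseline(a, b)), c(0, 0, 0))

  treated <- summarize_condition(mk_records(rep(2, 60)))
  baseline <- summarize_condition(mk_records(rep(2, 100)))
  expect_equal(unname(percent_change_vs_baseline(treated, baseline)["cells"]),
               -40)

  zero_base <- summarize_condition(mk_records(c(0, 0), c(TRUE, TRUE)))
  pc <- percent_change_vs_baseline(treated, zero_base)
  expect_true(is.na(pc["mtdna"]))
  expect_true("mtdna" %in% attr(pc, "undefined"))
})

test_that("generator cell-number effects are recovered as percent change", {
  conds <- list(screen_condition(character(0)),
                screen_condition("T", effect_cells = 0.5))
  ds <- generate_screen_dataset(conds, base = small_spec(n_cells = 100L),
                                fields_per_well = 6L, runs = 1L,
                                run_sd = 0, seed = 13L)
  tab <- screen_condition_table(ds$cells)
  pc <- tab$pct_change_cells[tab$supplement == "T"]
  expect_equal(pc, -50, tolerance = 0.12)
})

test_that("the Shapiro-Wilk gate picks the right test", {
  x <- c(1.3, 2.1, 0.7, 1.8, 1.1, 1.6, 0.9, 2.3)
  same <- compare_to_baseline(x, x)
  expect_equal(same$p_value, 1)

  set.seed(31)
  skew <- compare_to_baseline(exp(rnorm(30, 0, 1.3)), rnorm(30, 1, 0.3))
  expect_identical(skew$test_used, "MW")

  set.seed(33)
  gauss <- compare_to_baseline(rnorm(30), rnorm(30))
  expect_identical(gauss$test_used, "t")

  expect_error(compare_to_baseline(c(1, 2), c(1, 2, 3)), "at least 3")
  # degenerate (zero-variance) samples fall to the rank test, no error
  const <- compare_to_baseline(rep(1, 5), rep(1, 5))
  expect_identical(const$test_used, "MW")
  expect_equal(const$p_value, 1)
})

test_that("mixed-model effect collapses to the mean difference without run variance", {
  conds <- list(screen_condition(character(0)),
                screen_condition("T", effect_mtdna = 2))
  ds <- generate_screen_dataset(conds, base = small_spec(n_cells = 120L),
                                fields_per_well = 3L, runs = 2L,
                                run_sd = 0, seed = 17L)
  ds$cells$treatment <- ds$cells$supplement == "T"
  fit <- suppressWarnings(fit_group_effect(ds$cells))
  raw_diff <- mean(log10(ds$cells$puncta_summed_area[ds$cells$treatment])) -
    mean(log10(ds$cells$puncta_summed_area[!ds$cells$treatment]))
  expect_equal(fit$estimate, raw_diff, tolerance = 0.02)
  expect_equal(fit$estimate, log10(2), tolerance = 0.05)
  expect_lt(fit$p_value, 0.001)
})

test_that("mixed-model fits demand at least two runs", {
  ds <- generate_screen_dataset(list(screen_condition(character(0))),
                                base = small_spec(n_cells = 30L),
                                fields_per_well = 2L, runs = 1L, seed = 19L)
  ds$cells$treatment <- FALSE
  expect_error(fit_group_effect(ds$cells), "2 runs")
})

test_that("galactose viability is the percentage surviving energetic stress", {
  expect_equal(galactose_viability(50, 100), 50)
  expect_equal(galactose_viability(0, 100), 0)
  expect_equal(galactose_viability(120, 120), 100)
  expect_error(galactose_viability(10, 0), "positive")
})
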