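test_that("the copy-number closed form behaves as 2^dCt times ploidy", {
  expect_equal(copy_number_from_ct(20, 20), 2)
  expect_equal(copy_number_from_ct(15, 25), 2048)
  # one-cycle shift in ct_mt exactly halves the estimate
  ct <- seq(14, 30, by = 0.5)
  expect_equal(copy_number_from_ct(ct + 1, 25), copy_number_from_ct(ct, 25) / 2)
  # strictly decreasing in ct_mt, strictly increasing in ct_b2m
  expect_true(all(diff(copy_number_from_ct(ct, 25)) < 0))
  expect_true(all(diff(copy_number_from_ct(20, ct)) > 0))
  expect_true(is.na(copy_number_from_ct(NA, 25)))
})

test_that("normalisation sets the pre-depletion reference to one", {
  spec <- recovery_spec(depletion_fraction = 1, recovery_rate_untreated = 0,
                        ct_noise_sd = 0)
  course <- normalize_course(generate_recovery_course(spec, seed = 1L))
  expect_equal(course$rel_copies, rep(1, nrow(course)))
  no_ref <- generate_recovery_course(spec, seed = 1L,
                                     include_baseline = FALSE)
  expect_error(normalize_course(no_ref), "reference")
})

test_that("identical treated and untreated courses give a null ANOVA", {
  spec <- recovery_spec(ct_noise_sd = 0.05)
  course <- normalize_course(generate_recovery_course(spec, seed = 5L))
  res <- treatment_effect_anova(course, course)
  expect_equal(res$p_treatment, 1)
  expect_equal(nrow(res$per_day), length(spec$timepoints))
})

test_that("per-day tests are skipped without replication", {
  spec <- recovery_spec(ct_noise_sd = 0.05, replicates = 1L)
  m <- generate_recovery_experiment(spec, seed = 6L)
  co <- normalize_course(m)
  res <- treatment_effect_anova(co[co$treated, ], co[!co$treated, ])
  expect_true(all(is.na(res$per_day$p_value)))
})

test_that("specific activity is the heavy molar fraction and scale-invariant", {
  tab <- data.frame(nucleoside = c("dA", "dC", "dG", "dT"),
                    heavy_area = c(0, 5, 3, 2),
                    light_area = c(10, 5, 7, 0))
  sa <- specific_activity(tab)$specific_activity
  expect_equal(sa, c(0, 0.5, 0.3, 1))
  tab7 <- tab; tab7$heavy_area <- tab$heavy_area * 7
  tab7$light_area <- tab$light_area * 7
  expect_equal(specific_activity(tab7)$specific_activity, sa)
  # zero total area flagged
  z <- tab; z$heavy_area[1] <- 0; z$light_area[1] <- 0
  out <- specific_activity(z)
  expect_true(is.na(out$specific_activity[1]))
  expect_identical(attr(out, "undefined"), "dA")
})

test_that("pool inference is the identity on patient == control", {
  spec <- pool_spec(measurement_cv = 0)
  tab <- specific_activity(generate_isotope_table(spec, seed = 1L))
  inf <- infer_pools(tab, tab)
  expect_equal(unname(inf$normalized), rep(1, 4))
  expect_equal(unname(inf$pool_index), rep(1, 4))
  # dT has the smallest default pool, hence the highest activity
  expect_identical(inf$limiting_nucleoside, "dT")
})

test_that("equal smallest pools are reported as a joint limiting call", {
  spec <- pool_spec(endogenous_pools = c(dA = 4, dC = 3, dG = 1, dT = 1),
                    measurement_cv = 0)
  tab <- specific_activity(generate_isotope_table(spec, seed = 1L))
  ctrl <- specific_activity(generate_isotope_table(
    pool_spec(endogenous_pools = c(dA = 2, dC = 2, dG = 2, dT = 2),
              measurement_cv = 0), seed = 2L))
  inf <- infer_pools(tab, ctrl)
  expect_identical(inf$limiting_nucleoside, "dT/dG")
})

test_that("the inferred pool ordering reverses the true pool ordering", {
  sizes <- c(1, 2, 3, 4)
  nucs <- c("dA", "dC", "dG", "dT")
  ctrl_spec <- pool_spec(endogenous_pools = c(dA = 2, dC = 2, dG = 2, dT = 2),
                         measurement_cv = 0)
  ctrl <- specific_activity(generate_isotope_table(ctrl_spec, seed = 3L))
  for (perm in all_perms4()) {
    pools <- stats::setNames(sizes[perm], nucs)
    spec <- pool_spec(endogenous_pools = pools, measurement_cv = 0)
    tab <- specific_activity(generate_isotope_table(spec, seed = 4L))
    inf <- infer_pools(tab, ctrl)
    expect_identical(inf$limiting_nucleoside, names(pools)[pools == 1])
    # full ordering: pool_index ranks equal the true pool ranks
    expect_identical(order(inf$pool_index), order(pools))
  }
})
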