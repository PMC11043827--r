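# nucleoscreen

Simulation and analysis toolkit for high-content imaging screens of
mitochondrial DNA (mtDNA) content in fibroblasts — the assay used to
evaluate deoxynucleoside supplementation in mtDNA depletion syndrome (MDS)
models — together with the companion qPCR depletion–recovery and
heavy-isotope nucleoside-pool analyses.

## Who this is for

Groups running (or reviewing) per-cell mtDNA quantification with vital DNA
dyes: cells are co-stained with a PicoGreen-like DNA dye and a TMRM/
CMXRos-like membrane-potential dye; a single DNA channel then yields both
nuclear DNA and mtDNA nucleoid readouts, separated purely by object size.
Because no raw images are publicly deposited for this assay, every analysis
stage ships with a synthetic generator that produces the same data
structures with known ground truth, so the whole pipeline is testable
end to end.

## The quantities at the core

* Per cell: nucleoid **count** and **summed puncta area** (mtDNA content),
  and **integrated densities** — object area (µm²) × mean
  background-subtracted intensity, summed per object class — for the
  nuclear, nucleoid and membrane-potential signals; **reticulum length**
  from a skeletonized membrane-potential mask; a **Rho-0** flag (count ≤ 2
  and area ≤ 0.5 µm²) and a **ploidy class** (above 1.5× the G1 mode of
  nuclear integrated density ⇒ S/G2).
* Screens: percent change vs the DMSO baseline of the same run/line/serum
  context; Shapiro–Wilk-gated Mann–Whitney/t tests; linear mixed models
  `log10(area) ~ treatment + (1 | run) [+ (1 | line)]`.
* Recovery: relative copies `2^(Ct_B2M − Ct_mt) × 2`, courses normalised to
  a shared pre-depletion reference, two-way ANOVA blocking time.
* Pools: specific activity `heavy/(heavy+light)`; label dilution
  `h·φ/(φ+P)`; the reciprocal of control-normalised activity indexes the
  pool size, and the highest activity marks the **limiting nucleoside**
  (ties within 5% reported jointly, e.g. `"dT/dG"`).

## Worked example

```r
library(nucleoscreen)

## render one synthetic field and quantify it
spec <- field_spec(n_cells = 20, nucleoid_count_mean = 40,
                   rho0_fraction = 0.1, seed = 42)
rf <- render_field(spec)
q  <- quantify_field(rf$field)
m  <- match_records_to_truth(q$records, rf$cells)
head(m[, c("cell_id", "nucleoid_count", "truth_nucleoid_count",
           "puncta_summed_area", "is_rho0")], 3)
#>   cell_id nucleoid_count truth_nucleoid_count puncta_summed_area is_rho0
#> 1       1             26                   30            17.7625   FALSE
#> 2       2             30                   30            16.9050   FALSE
#> 3       3             40                   42            24.6225   FALSE
mean(m$is_rho0)        # 0.1  -- the generated Rho-0 fraction, recovered
```

Each row is one analysed (non-border) cell: the detected nucleoid count
sits close to the generator's truth (counts a few percent low at this
density is the documented spot-merging limit), summed puncta area is in
µm², and the Rho-0 flag recovers the planted 10% fraction exactly.

```r
## a small two-condition screen: ATGC supplement doubling mtDNA content
## but costing ~40% of cells, vs DMSO, 2 runs
conds <- list(screen_condition(character(0)),
              screen_condition(c("A","T","G","C"),
                               effect_mtdna = 2, effect_cells = 0.6))
ds  <- generate_screen_dataset(conds, base = field_spec(n_cells = 25, seed = 1),
                               fields_per_well = 4, runs = 2, seed = 7)
tab <- screen_condition_table(ds$cells)
tab[, c("run_id", "supplement", "pct_change_mtdna", "pct_change_cells",
        "test_used")]
#>   run_id supplement pct_change_mtdna pct_change_cells test_used
#> 1   run1       DMSO               NA               NA      <NA>
#> 2   run1       ACGT               93            -33.7         t
#> 3   run2       DMSO               NA               NA      <NA>
#> 4   run2       ACGT              116            -37.3         t

ds$cells$treatment <- ds$cells$supplement == "ACGT"
fit_group_effect(ds$cells)
#> treatment effect on log10 summed area: 0.3144 (se 0.0168), p = 7.33e-54
#> random-intercept sd: run 0.179
```

The per-run percent changes scatter around the planted +100% / −40%
(ratiometric displays are noisy by nature), while the mixed model pools the
runs and recovers the planted effect on the log scale,
log10(2) ≈ 0.301, within its standard error.

The one-command demo (`run_pipeline(pipeline_config(), "out/")`) chains
simulate → screen stats → recovery → pools and writes hash-stamped CSVs
plus a manifest; identical config and seed reproduce every byte.

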