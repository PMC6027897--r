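# larvascreen

NGLY1 deficiency is an ultra-rare congenital disorder of deglycosylation.
Its *Drosophila* model — loss of the fly homolog *Pngl* — shows global
developmental delay, pupal semi-lethality and small larvae, a phenotype
quantitative enough to screen against: culture three mutant larvae per
well of a 96-well plate with one library compound each, photograph whole
plates, measure total larval area per well, and look for compounds that
restore mutant size.

`larvascreen` is a tested R re-implementation of that screen's complete
analysis pipeline, for screeners and computational biologists who want to
run, audit or extend a whole-organism plate-image screen:

* **synthetic data** — plate images and well-area tables with full ground
  truth (lognormal larval sizes, genotype and DMSO-dose effects, planted
  true hits, and the screen's two artifact processes: uneaten-food high
  background and low/absent DMSO);
* **imaging** — the screen's larval-detection algorithm: locate the
  96-well grid, estimate what each well would look like empty (gradient
  edge exclusion + quadratic surface interpolation), segment larvae from
  the difference image, and compute a background-residual artifact
  metric;
* **screen statistics** — plate QC via the Z′ factor
  `1 − 3(σ_pos + σ_neg)/|μ_pos − μ_neg|`, per-well Z-scores
  `(x − μ_NEG)/σ_NEG` against the eight same-plate negative controls,
  replicate merging, and full vs extreme-|Z| replicate correlations;
* **triage** — the pre-hit rule (Z > 2, strictly, in ≥ 2 of 3
  replicates), per-replicate-pair artifact bookkeeping, unique-substance
  accounting and hit-rate reporting;
* **developmental assays** — survivor-normalised eclosion/pupariation
  timecourses, eclosion fold changes and size ratios with Student's
  t-tests, and 4-parameter-logistic dose–response fits with IC50 ratios
  (the statistic behind the mutant's ~10× bortezomib hypersensitivity).

The package ships the screen's published worked examples as data: the 19
pre-hit library wells with their replicate Z-scores
(`prehit_zscore_table()`) and the per-pair triage counts
(`triage_count_table()`).

## Worked example

Simulate a 4-plate triplicate screen with two planted hits (`C0007`,
strong rescue 0.9; `C0200`, rescue 0.6), QC the plates, call pre-hits and
triage them:

```r
library(larvascreen)

cfg <- screen_config(n_plates = 4, true_hit_ids = c("C0007", "C0200"),
                     hit_rescues = c(0.9, 0.6), rng_seed = 1)
areas <- simulate_screen_areas(cfg)

plate_stats(areas)[1:3, ]
#>   rep plate mu_pos sd_pos mu_neg sd_neg zprime
#> 1   1     1    729   59.0    374   27.7  0.268
#> 2   1     2    758   60.6    374   13.1  0.425
#> 3   1     3    722   53.4    361   22.7  0.366
```

Heterozygote control wells (`mu_pos`, ~729 px² for three larvae) are
about twice the size of the vehicle-sensitised mutant negatives
(`mu_neg`); Z′ > 0 means the control separation exceeds three standard
deviations of each group, i.e. the plate is screenable (10 of 12 plates
here).

```r
ph <- call_prehits(screen_ztable(areas))
subset(as.data.frame(ph), is_prehit,
       c(compound_id, z_rep1, z_rep2, z_rep3, n_reps_above))[c(1, 14), ]
#>     compound_id z_rep1 z_rep2 z_rep3 n_reps_above
#> 49        C0007   8.48  9.658 11.446            3
#> 236       C0200   9.64  4.231  9.862            3

apply_artifact_filters(ph)
#>   pair n_prehit n_high_bg n_low_dmso n_clean
#>    1&2       11         7          1       3
#>    1&3       17         7          2       8
#>    2&3       10         7          1       2
#>  total       38        21          4      13
```

Both planted hits are recalled with Z ≫ 2 in all three replicates; most
other pre-hits are artifact-driven false positives that the
high-background and low-DMSO flags remove — the same two-thirds-scale
attrition the real screen saw. On the published side, the same functions
reproduce the screen's accounting exactly: `call_prehits` on
`prehit_zscore_table()` finds the two triple-qualifiers (crustecdysone
and piceid), `triage_from_counts(triage_count_table())` yields the
162 → 45 clean-compound whittling, `unique_substances` collapses the 19
wells to 18 compounds, and `hit_rate(1, 2532)` prints `0.04` (%).

The imaging half runs the same way (see `analysis/02_detect_larvae.R`):
render a plate with `simulate_plate_image()`, then
`locate_well_grid()` → `measure_plate()` gives per-well areas whose
medians track rendered ground truth to well under 10%.

## The analysis workflow

The `analysis/` scripts are thin narrative drivers over the package and
write their tables under `results/`:

1. `01_simulate_screen.R` — triplicate 32-plate screen (area level) plus
   one rendered example plate;
2. `02_detect_larvae.R` — full imaging pipeline on a two-genotype plate,
   detection-vs-truth accuracy and the recovered 75% size ratio;
3. `03_plate_qc.R` — Z′ per plate, replicate Z table, full vs extreme
   pairwise R²;
4. `04_triage.R` — pre-hit calling, artifact filtering,
   recall/precision against planted truth, and the published worked
   examples;
5. `05_validation_assays.R` — eclosion timecourses, fold change, size
   comparison and the bortezomib IC50 shift.

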