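# colonyfit

Colony-level fitness analysis of boom-and-bust *Caenorhabditis elegans*
populations on finite food patches.

A colony founded by a few L4 hermaphrodites on a fixed bacterial patch grows
through overlapping generations until the food runs out ("bust"). Its
lasting output is dauer larvae — arrested, stress-resistant dispersal forms
that arise from L1/L2 larvae caught by starvation at the right age. More
founders exhaust the patch *faster* but can leave a population whose
structure at bust yields *fewer* dauers: a colony-level trade-off between
speed and efficiency of resource use. `colonyfit` provides:

* **`simulate_colony()` / `founder_sweep()`** — a deterministic,
  stage-structured, hourly matrix projection of colony growth with food
  accounting against a fixed patch and post-hoc bust detection
  (`detect_bust()`);
* **`structure_at()`, `dominant_l1_generation()`, `predauer_pool()`,
  `futile_consumption_share()`** — population-structure statistics at bust;
* **`summarize_assay()`, `compare_groups()`, `yield_timecourse()`,
  `recovery_check()`, `lawn_qc()`, `tradeoff_table()`** — the plate-assay
  analysis pipeline (aliquot-count scaling, contamination filtering, ANOVA
  with Tukey–Kramer comparisons via `stats::aov`/`stats::TukeyHSD`);
* **`assay_params()`, `generate_assay()`, `assay_round_trip()`** — a seeded
  synthetic generator emulating the assay's plate-level data, used to
  validate the pipeline end to end;
* **`read_assay_csvs()` / `write_assay_csvs()` / `colony_cli()`** — CSV
  schemas with row-level violation reporting, TSV/JSON reports with run
  manifests, and a command-line interface.

Functions are data-frame-first: tabular results are tibbles, models carry
`tidy()`/`glance()` methods, and key objects have `autoplot()` methods.

## Worked example

```r
library(colonyfit)

cfg <- colony_config()        # 25 °C defaults; patch = 1e7 food units
sw  <- founder_sweep(cfg = cfg)
sw[, c("founder_number", "bust_hr", "dominant_l1_generation", "predauer_pool")]
#>   founder_number bust_hr dominant_l1_generation predauer_pool
#> 1              1     176                      4       152746.
#> 2              3     158                      4       119775.
#> 3             10     140                      4       125238.
#> 4             50     116                      3       167319.
#> 5            200      94                      3       142406.
```

Bust comes strictly earlier with more founders (176 → 94 hr), while the
pre-dauer pool (L1+L2 at bust, the model's dauer-yield proxy) peaks at 50
founders and bottoms out at 3 — speed and efficiency optimize at different
founder numbers. A single trajectory:

```r
traj <- simulate_colony(200, cfg)
detect_bust(traj)$bust_hr        # 94
sum(traj$eggs_laid[, 1])         # 34000 F1 eggs (200 founders x 170 brood)
autoplot(traj)                   # stacked stage composition by generation
```

Assay side, on synthetic data:

```r
ds     <- generate_assay(assay_params(), seed = 1)
plates <- scale_dauer_counts(drop_contaminated(ds$plates))
tradeoff_table(summarize_assay(plates), reference_timepoint_hr = 72)
tidy(compare_groups(plates, "dauer_yield", timepoint_hr = 72))  # Tukey pairs
peak_hr(yield_timecourse(plates, 3))                            # 144
```

CLI (same functionality, file in, file out, with a JSON manifest per run):

```sh
Rscript inst/cli/colonyfit.R synth --seed 42 --out-dir data/
Rscript inst/cli/colonyfit.R analyze --plates data/plates.csv \
  --lawn data/lawn_qc.csv --lengths data/lengths.csv --out-dir reports/
Rscript inst/cli/colonyfit.R simulate --founders 200 --out-dir run/
```

## Tests

```sh
Rscript -e 'testthat::test_dir("tests/testthat", package = "colonyfit",
                               load_package = "installed")'
```

The suite validates the projection against an independent individual-based
enumeration oracle (exact equality on randomized configurations), the
ANOVA/Tukey output against brute-force sums-of-squares and studentized-range
computation (1e-8), and the generator→pipeline round trip. One acceptance
sub-assertion is knowingly failing: the published dominant-generation
*labels* at bust (F2/F1) are unreachable under the published quantities, and
the model instead produces the same founder-number split one generation
later (F3/F2). See the "Generation indexing at bust" section of the methods
vignette (`vignettes/colonyfit-methods.Rmd`) for the argument; the assertion
was left at the quoted values rather than tuned to pass.

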