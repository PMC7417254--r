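# lionden

Detect lion parturition (denning) events from GPS collar telemetry, backdate
conception over the three-month gestation, and test the association of
reproduction with rainfall seasonality and prey birth pulses by AICc model
selection.

## The science

A lioness gives birth away from her pride and keeps her cubs at a den for
about three weeks. On a GPS collar the birth month shows up as a joint
anomaly in three movement indicators:

* **residency** — a maximal run of consecutive fixes within a 200 m radius
  lasting ~20 days (background runs, mostly carcasses, average ~5 days);
* **core-range contraction** — the monthly 50% LoCoh (local convex hull)
  core collapses from ~3.4 km² to ~0.2 km²;
* **displacement reduction** — mean daily net displacement drops by roughly
  half from its ~7–9 km ranging level.

`lionden` computes these indicators per female-month, scores each month with
a weighted z-score against the female's own months (weights proportional to
the Akaike weights of the published denning-indicator model selection, so
core contraction dominates), and declares a birth when the score clears a
threshold. Detected birth months are backdated three months to conception
and classified against the wet season (October–March) and prey birth pulses
(late October, January–March); candidate binomial GLMs for the 0/1
conception/birth series are compared by small-sample AICc and Akaike
weights.

The original SANParks collar data are not publicly downloadable, so the
package ships a seeded synthetic-telemetry generator (a diel central-place
movement model: rest sites, out-and-back forays, multi-day camps, and a den
window for pregnant females) whose defaults realize the study system's
published summaries — 7.2/9.1 km daily displacement, 0.2/3.4 km² cores,
19.7/4.9 day residency, ~51% birth-month displacement reduction, 73%/71%
wet-season conception — each within 15%. The full pipeline is validated
end to end against the generator's truth log. See the vignette
(`vignette("denning-detection")`) for the model, calibration and
limitations.

## Worked example

Simulate a small two-region study, fit the detector, and compare the calls
with the generator's truth:

```r
library(lionden)

study <- simulate_study(sim_config(n_females_south = 3, n_females_north = 2,
                                   n_pregnant = 3, n_months = 12, seed = 1))
study
#> Synthetic telemetry study: 5 females, 12 months from 2010-01
#>   pregnant: 3  fixes: 9502

fit <- parturition(study)
fit
#> Parturition detection fit: 5 females, 60 female-months
#>   birth calls (score > 2 ): 2

summary(fit)
#> Top-ranked birth-month candidate per female:
#>  female_id birth_month conception_month score called conception_season
#>        S01     2010-07          2010-04  2.02   TRUE               dry
#>        S02     2010-04          2010-01  2.03   TRUE               wet
#>        S03     2010-05          2010-02  1.73  FALSE               wet
#>        N01     2010-04          2010-01  1.59  FALSE               wet
#>        N02     2010-11          2010-08  1.04  FALSE               dry
#>
#> Birth calls: 2  wet-season conception fraction among calls: 0.50

study$truth[study$truth$pregnant, c("female_id", "region", "birth_month")]
#>  female_id region birth_month
#>        S01  south     2010-07
#>        S02  south     2010-04
#>        N01  north     2010-04
```

All three pregnant females' top-ranked candidates are exactly their true
birth months, and the two nonpregnant females stay well below threshold.
N01 misses the call cut in this deliberately tiny example — with only
twelve baseline months the z-scores are noisy; at the default 36-month
span every pregnant female in this seed is called.

Model-selection arithmetic on the published denning-indicator table:

```r
ref <- reference_aic_tables("denning")
akaike_table(ref$AICc, names = ref$model)
#> Model selection table (7 candidates)
#>          name  k AIC  AICc delta    weight
#>      50% Core NA  NA 14.22  0.00 7.445e-01
#>  Core + Total NA  NA 17.44  3.22 1.488e-01
#>     90% Total NA  NA 18.12  3.90 1.059e-01
#>       Biomass NA  NA 30.22 16.00 2.498e-04
#>        SL Wet NA  NA 30.22 16.00 2.498e-04
#>        SL Dry NA  NA 31.12 16.90 1.593e-04
#>           BTb NA  NA 33.59 19.37 4.632e-05
```

A one-call driver runs everything (simulate or read CSVs, detect, backdate,
associate) and writes a report bundle of CSV/GeoJSON artifacts:

```r
cfg <- pipeline_config(sim = list(), seed = 42, out_dir = "lionden-out")
res <- run_pipeline(cfg)
```

## Reproduction

Everything is seeded and deterministic:

* `simulate_study(sim_config(seed = s))` is bit-identical across runs, and
  per-female streams are derived by hashing the female id, so a female's
  trajectory does not depend on who else is simulated.
* The test suite (`testthat::test_dir("tests/testthat")`) contains the full
  acceptance battery: published-table arithmetic, brute-force geometry and
  cluster oracles, generator calibration checks (fixed seed pools 1..30),
  birth-month recovery across seeds 1..20 (≥ 80% within ±1 month), and the
  wet-season conception fraction on a 500-female cohort.
* `Rscript scripts/acceptance.R --seed 42 --out report.json` recomputes the
  headline model-selection quantities from the packaged reference tables
  and writes them as JSON.

The reference AIC/AICc tables ship as plain CSVs in `inst/extdata/` and are
inputs, not outputs: the package reproduces the deltas and weights derived
from them.
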