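# intakeval

Validation toolkit for leftover-based food-intake estimation in clinical
nutrition. Hospitals need to know how much of each served dish a patient
ate; the reference method is weighing every dish before and after the
meal, but routine practice relies on leftover *estimation* — a nurse
looking at the tray, a dietitian looking at a photograph, or an
image-analysis (AI) model — all reporting on an 11-point scale where the
converted value `v ∈ {0, …, 10}` encodes intake in tenths of the served
portion. `intakeval` is for researchers running such method-comparison
studies: it implements the scale, the nutrient arithmetic, and the full
agreement analysis between any estimation channel and the weighing
reference.

The core pieces:

* **Converted scale** — weighed intake fraction
  `f = (w_pre − w_post)/w_pre` binned to `v`: 0 for f ≤ 5%, 10 for
  f > 95%, else the decile bin (lower-open/upper-closed); plus the
  leftover complement `v = 10 − leftover_class`.
* **Nutrient intake** — full-portion menu content × `v/10`, summed over
  a meal's evaluable dishes (packaged beverages/seasonings excluded).
* **Agreement statistics** (orientation estimated − actual throughout):
  RMSE; mean-reference `R² = 1 − Σ(x−y)²/Σ(y−ȳ)²` (not squared Pearson,
  may be negative); signed ME and MAE; Spearman ρ of midranks with
  t-approximation p; paired t test; tie-corrected Friedman test across
  channels; Bland–Altman limits of agreement `mean(d) ± 1.96·sd(d)`;
  and 11×11 ordinal confusion matrices with embedded MAE.
* **Synthetic cohorts** — seeded generator emulating a liquid-food
  validation study: gruel + soup + one of five side-2 items per meal
  (counts 31/18/12/13/26 per 100 meals), true intake drawn from the
  empirical distribution with mean intake rate 84.7%, and per-dish,
  per-channel additive-Gaussian rater error discretized and clamped to
  the scale.

## Worked example

```r
library(intakeval)

cfg <- cohort_config(n_meals = 100, seed = 42)   # study-sized cohort
ratings <- generate_dataset(cfg)                 # weighing + 3 channels
report <- run_evaluation(reference_menu(), ratings)
report
#> <intake_report> 100 meals, 300 dish instances (0 excluded), methods: ai, image_visual, direct_visual
#> mean intake rate: 82.8%

subset(report$per_nutrient, nutrient == "energy",
       c(method, measured_mean, estimated_mean, rmse, r2, rho, t_p))
#>          method measured_mean estimated_mean rmse    r2   rho      t_p
#> 1            ai          69.8           67.5 4.07 0.970 0.970 5.12e-10
#> 2  image_visual          69.8           69.3 3.99 0.971 0.948 2.72e-01
#> 3 direct_visual          69.8           69.6 2.22 0.991 0.985 3.26e-01
```

Reading the energy table: weighed meal energy averaged 69.8 kcal in this
cohort; the AI channel underestimates (67.5 kcal, paired-t p ≈ 5e-10 —
its configured negative gruel/soup bias is detectable), while the two
visual channels are statistically indistinguishable from the reference.
All channels correlate strongly with weighing (ρ ≥ 0.95); direct-visual
has about half the meal-level RMSE of the photo-based channels, the
expected accuracy ordering. Per-dish signed errors with a Friedman test
across channels are in `report$per_dish_me`, dish-level RMSE/R² in
`report$per_dish`, and the ordinal confusion matrices in
`report$confusions`. `render_report(report, dir)` writes a
full-precision `report.json` plus 2-decimal markdown tables (protein and
fat in mg).

A command-line front end covers the same flow:

```sh
intakeval demo --seed 7 --out out/            # simulate + evaluate
intakeval simulate --config cohort.json --out data/
intakeval evaluate --menu data/menu.csv --ratings data/ratings.csv --out out/
```

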