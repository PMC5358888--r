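# rbcforecast

Quantitative forecasting of metabolite concentration time courses in stored
red blood cells (RBCs) from a small panel of extracellular biomarkers.

Stored RBCs decay along a well-characterized three-phase "storage lesion";
a few extracellular metabolites (glucose, hypoxanthine, lactate, malate,
xanthine, plus adenine, nicotinamide and 5-oxoproline as candidates) track
that decay. This package implements, as tested reusable components, a
workflow that predicts the concentration profile of every *other* measured
metabolite from such a biomarker panel alone, and decides per metabolite
whether the prediction beats noise:

* **Output-Error / FIR identification** — per-replicate least-squares fits
  of `y(t) = Σᵢ Bᵢ(q)/Fᵢ(q) uᵢ(t−nk) + e(t)`; the working structure is the
  simplest member (`nb = 1, nf = 0, nk = 0`: a static linear mix of the
  biomarkers), selected by cross-validated comparison against more complex
  orders (`fit_oe()`, `simulate_oe()`, `select_model_order()`).
* **Ensemble prediction** — one model per training blood bag, combined by
  the per-time-point median into a consensus profile for each test bag
  (`train_ensemble()`, `predict_consensus()`).
* **SMAPE scoring** — `SMAPE = (1/n) Σₜ |yₜ − ŷₜ| / (yₜ + ŷₜ)`, bounded in
  [0, 1], plus global summaries and a Welch-t / Benjamini–Hochberg
  train-vs-test divergence screen (`smape()`, `summarize_predictions()`,
  `compare_train_test()`).
* **Random-walk significance benchmark** — 10,000 seeded naive random walks
  per metabolite (step sd estimated from observed per-step changes, starts
  drawn from measured starting concentrations); a metabolite is significant
  when fewer than 5% of walks score a lower SMAPE than the ensemble
  (`benchmark_dataset()`).
* **Exhaustive biomarker selection** — all C(8,5) = 56 candidate panels
  scored by leave-one-replicate-out cross-validation within the training
  half (`select_biomarkers()`).
* **Synthetic study generator** — replicate-resolved datasets with
  three-phase biomarker templates, lognormal bag effects, proportional
  measurement noise, planted linear mixing coefficients for recovery tests,
  pure-noise targets, and an optional day-31 dispersion artifact
  (`synth_spec()`, `generate_dataset()`), so the whole workflow runs with
  no external data.

## Worked example

```r
library(rbcforecast)

cfg <- run_config(seed = 1, n_walks = 10000)  # default synthetic study:
                                              # 96 metabolites, 5 biomarkers,
                                              # 20 bags, 14 sampling days
summary <- run_pipeline(cfg, "run1")
report_run("run1")
```

```
run summary (run1)
  metabolites: 96 (5 biomarkers: bm01, bm02, bm03, bm04, bm05)
  ensembles: 91 x 10 members over 14 time points
  significant vs random walk: 85/91 (93%) at 10000 walks
  global SMAPE: median 0.0208 +/- 0.0125 (sd)
  train/test divergence: 0.0% of cells flagged
```

Reading this: the 20 replicates were split 10/10 into training and testing
halves; each of the 91 non-biomarker metabolites got a 10-member ensemble
(one model per training bag). On the testing bags, the median consensus
prediction — computed from each bag's five biomarker profiles alone —
deviates from the measured profiles by a median of about 2% (SMAPE 0.0208),
and for 85 of the 91 metabolites fewer than 5% of 10,000 naive random walks
predict better, so their dynamics are declared informative rather than
noise. The six non-significant metabolites are exactly the generator's
planted pure-noise targets, which is the desired false-positive behavior.
The divergence screen found no (metabolite, time) cell where the training
and testing halves differ significantly by more than 20% in mean.

Stage outputs (`predictions.csv`, `smape_summary.csv`, `divergence.csv`,
`benchmark.csv`, `selection.csv` when panel selection is enabled,
`summary.json`) are plain CSV/JSON written into the run directory.
`vignettes/biomarker-forecasting.Rmd` documents the model, the conventions
and the generator in detail.

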