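# ftiruq

Uncertainty-aware classification of ATR-FTIR biofluid spectra in R.

## The problem

ATR-FTIR spectroscopy of dried saliva is a candidate noninvasive
screening test for Sjögren's disease: a few absorbance spectra are
collected from different locations of each donor's dried sample, and a
classifier separates disease from control. Two properties of such cohorts
break naive analyses. First, spectra are nested within donors, so any
cross-validation that splits a donor's spectra between training and test
leaks identity. Second, a dried stain is heterogeneous: some locations of
a diseased donor's sample carry little or none of the disease-associated
biomolecules, so a fraction of disease-labelled spectra are effectively
control spectra — label noise that only affects the positive class.

`ftiruq` implements, as tested reusable components, the full analysis
this situation calls for:

* **EMSC preprocessing** — each spectrum `x` is decomposed by least
  squares as `x = b·r + Σₖ pₖ Pₖ + e` against a reference `r` (the
  training-fold mean) with a degree-6 Legendre polynomial baseline, and
  corrected to `(x − Σ pₖPₖ)/b`, removing baseline drift and
  multiplicative scatter in one step.
* **PCA-LDA baseline** — components retained by cumulative explained
  variance, then a Fisher discriminant `w ∝ Sw⁻¹(μ_dis − μ_con)` with the
  threshold at the midpoint of the projected class means.
* **Windowed neural classifier** — overlapping spectral windows feed
  per-window dense ReLU blocks, concatenated into a dropout head with a
  sigmoid output; trained 200 epochs by Adam, fully seed-reproducible.
* **Monte Carlo dropout (MCD)** — T stochastic forward passes give a
  predictive mean `ŷ = (1/T) Σ f⁽ᵗ⁾(x)` and uncertainty
  `Var(y) = (1/T) Σ f⁽ᵗ⁾(x)² − ŷ²` per spectrum.
* **Two-phase refinement** — train on everything; score the training
  spectra by MCD variance; keep all controls and, per diseased donor, the
  lowest-variance spectra (default 40 %, floor `max(1, ⌈0.2·n⌉)`);
  retrain from fresh random weights on the refined set. Test folds are
  never filtered.
* **Donor-stratified 7-fold CV** with donor-level majority voting, and
  spectrum-/donor-level accuracy and sensitivity reporting.
* **Zone-level Shapley attribution** — exact-coalition Shapley values
  over wavenumber zones of the fingerprint region, with background
  imputation from control spectra.
* **Synthetic cohort generator** — donor-level random effects, Gaussian
  saliva bands, polynomial baseline drift, multiplicative scatter, white
  noise, and a tunable fraction ρ of ambiguous diseased-donor spectra
  drawn from the control law, with ground truth recorded. The pipeline is
  validated end to end against this generator's truth.

## Worked example

```r
library(ftiruq)

# A synthetic cohort mirroring the clinical shape: 23 control + 24
# disease donors, 5 spectra each, 40% of disease spectra ambiguous.
cohort <- generate_cohort(cohort_config(seed = 1))
cohort$set
#> <spectrum_set> 235 spectra from 47 donors
#>   grid: 1526 points, 650-3700 cm^-1
#>   donors: control=23, disease=24

# Cross-validated uncertainty-refined network (EMSC reference and all
# models fitted per training fold; test folds never filtered).
exp <- run_experiment(cohort$set, method = "nn_uncertainty", K = 7, seed = 1)
exp
#> <ftir_experiment> method = nn_uncertainty, 7-fold donor-stratified CV (seed 1)
#> <metrics_report>
#>   spectrum level: accuracy 77.9%, sensitivity 60.8%, mean sensitivity 78.2%
#>   donor level:    accuracy 78.7%, sensitivity 62.5%, mean sensitivity 79.1%
#>   7 folds, 235 spectra, 47 donors
#> phase-1 (pre-refinement) metrics:
#> <metrics_report>
#>   spectrum level: accuracy 70.6%, sensitivity 66.7%, mean sensitivity 70.7%
#>   donor level:    accuracy 74.5%, sensitivity 70.8%, mean sensitivity 74.5%
#>   7 folds, 235 spectra, 47 donors
```

Refinement lifts donor-level accuracy from 74.5 % (single-phase network)
to 78.7 % here, because the spectra it drops are enriched for the truly
ambiguous ones the generator planted:

```r
exp$fold_details[[1]]$mask
#> <selection_mask> 137 spectra kept, 63 dropped
mean(sapply(exp$fold_details, function(fd)
  mean(fd$mask$dropped$spectrum_id %in% cohort$truth$ambiguous_ids)))
#> [1] 0.4799347   # vs. the 0.4 ambiguous base rate among disease spectra
```

Zone-level attribution of the trained model against control backgrounds
(`default_zones()`, `zone_attributions()`, `summarize_global()`) ranks
the wavenumber zones driving disease calls; `plot()` on the summary draws
the per-spectrum beeswarm.

A command-line wrapper over the same functions ships in `inst/cli/ftiruq`
(subcommands `simulate`, `preprocess`, `baseline`, `train`,
`uncertainty`, `refine-train`, `evaluate`, `explain`), and
`ftiruq_cli()` exposes it in-process.

## Package layout

| Area | Functions |
| --- | --- |
| Data model & I/O | `spectrum_set()`, `read_spectra()`, `write_spectra()`, `crop_region()` |
| Synthetic cohorts | `cohort_config()`, `generate_cohort()`, `class_shift_profile()`, `saliva_bands()` |
| Preprocessing | `emsc_model()`, `emsc_fit()`, `emsc_correct()`, `legendre_basis()` |
| Chemometrics | `fit_pca()`, `fit_lda()`, `pca_lda()`, `predict_lda()` |
| Network | `net_config()`, `window_slices()`, `build_net()`, `train_net()`, `windowed_net()` |
| Uncertainty | `mc_predict()`, `rank_by_uncertainty()` |
| Refinement | `selection_policy()`, `select_training_spectra()`, `two_phase_train()` |
| Evaluation | `make_folds()`, `majority_vote()`, `score_report()`, `run_experiment()` |
| Attribution | `default_zones()`, `zone_features()`, `shapley_attribution()`, `zone_attributions()`, `summarize_global()` |

The methods vignette (`vignettes/uncertainty-aware-ftir.Rmd`) documents
the generative model, every tunable parameter with its default and
rationale, the numerical choices, and the limits of what the synthetic
validation shows.
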