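---
title: "Uncertainty-aware classification of ATR-FTIR saliva spectra: methods"
author: "ftiruq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Uncertainty-aware classification of ATR-FTIR saliva spectra: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Screening for Sjögren's disease from saliva is attractive because saliva
collection is noninvasive and the disease directly alters salivary
composition. ATR-FTIR spectroscopy of dried saliva stains produces, per
donor, a handful of absorbance spectra over the mid-IR range whose
fingerprint region (~650–1800 cm⁻¹) carries protein, lipid, carbohydrate
and nucleic-acid bands. Two features make naive classification of such
cohorts misleading:

1. **Donor hierarchy.** Several spectra come from each donor and are
   strongly correlated; any split that mixes a donor's spectra between
   training and validation leaks donor identity and inflates performance.
2. **Ambiguous positive spectra.** A diseased donor's stain is
   heterogeneous: some probed locations may simply not contain the
   disease-associated biomolecules, so a fraction of disease-labelled
   spectra are indistinguishable from controls. They act as label noise
   for spectrum-level training, while every control spectrum is a valid
   negative.

`ftiruq` implements a pipeline built around these two facts: EMSC
preprocessing, a PCA-LDA chemometric baseline, a windowed dense network
with Monte Carlo dropout (MCD) uncertainty, a two-phase
uncertainty-refined training workflow, donor-stratified cross-validation
with donor-level majority voting, and zone-level Shapley attribution.
Because no public cohort accompanies the problem, the package ships a
synthetic cohort generator that emulates exactly the structure above, so
every stage is testable end to end with known ground truth.

## The generative model behind `generate_cohort()`

Each spectrum of donor $d$ is

$$ x(\nu) \;=\; b \,\Big[\textstyle\sum_j a_{dj}\, g_j(\nu) \;+\;
   \mathbb{1}[\text{informative disease}]\; s(\nu)\Big] \;+\;
   \sum_{k=0}^{6} c_k P_k(\nu) \;+\; \varepsilon(\nu) $$

* $g_j$ are Gaussian bands at the characteristic saliva positions
  (Amide I 1636, Amide II 1549, CH₃ 1447, COO⁻ 1398, PO₂⁻ 1342, the
  Amide III/C–O composite near 1072, and a broad O–H/N–H envelope near
  3290 cm⁻¹).
* $a_{dj} = A_j e^{\eta_{dj}}$, $\eta_{dj}\sim N(0, 0.15^2)$ are
  donor-level lognormal amplitude effects — the within-donor correlation
  that makes donor-stratified CV measurably different from spectrum-level
  CV.
* $s(\nu)$ is the additive class shift: by default $+0.030$ absorbance
  across 956–1210 cm⁻¹ and $-0.015$ across 1579–1800 cm⁻¹, with 20 cm⁻¹
  half-cosine tapers at the zone edges. These are the directions reported
  for the disease class (carbohydrate/nucleic-acid region up, Amide I
  neighbourhood down).
* $b = e^{\zeta}$, $\zeta \sim N(0, 0.08^2)$ is multiplicative scatter,
  $c_k \sim N(0, 0.02^2)$ are random degree-6 Legendre baseline
  coefficients and $\varepsilon \sim N(0, 0.005^2)$ is white noise — the
  three distortions EMSC is designed to remove. The baseline degree
  deliberately equals the EMSC degree so preprocessing is exactly matched
  to the corruption model; both are configurable to study mismatch.
* With probability $\rho = 0.4$ (per spectrum, independently), a diseased
  donor's spectrum is **ambiguous**: $s(\nu)$ is omitted and the spectrum
  is drawn from the control law. The generator records which ids were
  ambiguous, giving the ground truth that uncertainty-based selection is
  evaluated against.

Default cohort shape: 23 control + 24 disease donors, 5 spectra each
(235 spectra), all female, on a 650–3700 cm⁻¹ grid at 2 cm⁻¹ intervals
(1526 points; the underlying instrument resolution is 4 cm⁻¹, but the
digitized interval is not fixed by it, so the step is configurable).

**Calibration.** The magnitudes of the class shift and of the donor-level
variability are not published quantities; they were chosen once so that
naive donor-level classification of the default cohort lands in the
65–80 % accuracy band — the regime reported for comparable clinical
cohorts, and the regime in which sample-selection refinement has room to
act. With `disease_shift` deltas (+0.030/−0.015) and `donor_sd = 0.15`,
single-phase networks reach ~70–75 % donor accuracy.

**What the generator does not emulate:** Mie/ATR penetration-depth
physics, water-vapor and CO₂ lines, Lorentzian/Voigt line shapes,
instrument drift between sessions, and male/female compositional
differences (metadata carries `sex`, but the default cohort is
all-female). Passing tests therefore demonstrate correctness of the
*pipeline* under the assumed statistical structure, not clinical
performance.

## EMSC preprocessing

Each raw spectrum is decomposed by least squares as
$x = b\,r + \sum_{k\le 6} p_k P_k + e$, where $r$ is the reference
spectrum and $P_k$ are Legendre polynomials on the wavenumber axis mapped
to $[-1,1]$; the corrected spectrum is $(x - \sum_k p_k P_k)/b$. Choices
that matter:

* **Reference = training-fold mean, recomputed per CV fold.** The
  reference is part of the fitted preprocessing; sharing it with test
  spectra would leak. (With the default generator the cohort mean and
  fold means differ negligibly, but the discipline is structural.)
* **Legendre rather than raw powers.** At degree 6 over a ~3000 cm⁻¹
  span, raw powers of the wavenumber produce a catastrophically
  ill-conditioned design; the orthogonal basis keeps the condition number
  small (tested against the raw-power design).
* **Degenerate fits.** A spectrum whose multiplicative coefficient
  satisfies $|b| < 10^{-6}$ cannot be meaningfully rescaled; it is left
  baseline-subtracted but unscaled, flagged in the fit table, and
  reported with a warning, rather than dividing by ~0.
* **Cropping to 650–3700 cm⁻¹ happens after correction** (closed
  interval), matching the stated order of operations; the polynomial is
  fitted on the full recorded range.
* A caveat worth knowing: a degree-6 baseline can partially absorb a
  broad box-shaped class difference and push mirror-image artifacts into
  adjacent zones. Zone-level attributions on EMSC-corrected spectra
  therefore couple neighbouring zones — an effect of preprocessing, not
  of biochemistry — which is why attribution results should always be
  read jointly with the preprocessing in mind (see the attribution
  section).

## PCA-LDA baseline

PCA is fitted on centered training spectra (no scaling — after EMSC all
spectra share an absorbance scale). The retained dimension is the
smallest $k$ whose cumulative explained-variance ratio reaches
`variance_target` (default 0.99, capped at the data rank). LDA in score
space uses the two-class closed form: direction
$\propto S_w^{-1}(\mu_{dis}-\mu_{con})$ with equal priors (the cohort is
nearly balanced and the use case is screening), threshold at the midpoint
of the projected class means. A near-singular pooled scatter is
ridge-regularized with $\varepsilon = 10^{-6}\,\mathrm{tr}(S_w)/d$. A
score exactly at the threshold is called control — the deterministic,
conservative tie-break for a positive screen. The pseudo-probability
`plogis(score − threshold)` is only a monotone convenience for the
majority-voting interface; it is not calibrated.

## The windowed network

The classifier cuts the spectrum into overlapping windows (default 50
grid points, stride 25, i.e. 50 % overlap, plus a tail window anchored at
the end so no grid point is dropped), passes each window through its own
small dense ReLU block (8 units), concatenates, and feeds a 16-unit ReLU
head with dropout ($p = 0.3$) and a single sigmoid output. This windowed
dense design mimics a sparse 1-D convolution while keeping the parameter
count at a few tens of thousands for a 1526-point grid — appropriate for
a ~200-spectrum training fold. Exact window size, stride and unit counts
are not published for the reference architecture; the defaults here are
the package's own and are fully configurable.

Training: binary cross-entropy, mini-batch Adam (fixed learning rate
1e-3, batch 32), exactly 200 epochs, no early stopping, from He-initialized
random weights. All randomness — initialization, batch order, dropout
masks — derives from the configured seed through R's RNG, so runs are
bit-reproducible single-threaded.

**Dropout semantics.** Masks are plain Bernoulli (no inverted rescaling
at train time); deterministic inference scales the dropout-site
activations by the keep probability (classical weight scaling). This
matches the MCD convention in which a stochastic pass is exactly a masked
forward pass: a one-unit linear net with input dropout $p=0.5$, input 1
and weight 2 produces passes in {0, 2} with mean 1 — the enumerable
oracle used in the tests.

## Monte Carlo dropout and two-phase refinement

`mc_predict()` keeps dropout active and runs $T$ stochastic passes
(default $T = 100$; the variance of the variance estimate scales as
$1/T$, and 100 keeps a full-cohort scoring pass under a second). Per
spectrum it reports $\hat y = \frac1T\sum_t f^{(t)}(x)$ and the
*population* variance $\frac1T\sum_t f^{(t)}(x)^2 - \hat y^2$ — exactly
this biased form, not the $T-1$ estimator, because that is the quantity
the selection rule is defined on. Tiny negative variances from
floating-point cancellation are clipped to zero and counted. The
uncertainty score is the raw variance; entropy or $|\hat y - 0.5|$ are
deliberately not offered as defaults.

The two-phase workflow, per CV fold:

1. Train a network on **all** training spectra.
2. Score every *training* spectrum by MCD variance (validation spectra
   never participate).
3. Keep all control spectra. For each diseased donor, rank spectra
   ascending by variance and keep the most confident: by default the
   lowest 40 % (one or two of five spectra), never fewer than
   `max(1, ceiling(0.2 n))` — the 20 % per-patient floor. An absolute
   variance threshold rule is provided as an alternative; the fraction
   rule is the default because it is reproducible across cohorts without
   a variance scale.
4. Train a **fresh** network (new seed, offset by 1000; never a warm
   start — continuing from phase-1 weights tends to keep the optimizer in
   the minimum shaped by the noisy samples) on the refined set, for the
   full epoch budget.

At prediction time all test-fold spectra are used — selection applies to
training only — and donor-level calls are made by majority vote over the
donor's spectrum-level calls (probability cut 0.5; an exact tie votes
disease, the sensitivity-favoring rule for a screen; with the usual odd
number of spectra per donor ties cannot occur).

## Evaluation protocol

`make_folds()` assigns whole donors to K = 7 folds: donors are shuffled
within class by the seed and dealt round-robin, with each class's deal
continuing where the previous class stopped, so per-class counts *and*
total fold sizes each stay within one donor of balance. Metrics are
pooled over folds (micro-averaged from pooled confusion counts; per-fold
breakdowns are also reported). "Sensitivity" is reported both as the
disease-class true-positive rate and as the unweighted mean of the two
class recalls (balanced accuracy), since both conventions are common and
summary tables rarely say which they use. A fold that lacks one class
reports `NA` for that per-fold sensitivity; pooled metrics are unaffected.

## Zone-level Shapley attribution

Attributions are computed on zone-aggregated features: the analysis range
650–1800 cm⁻¹ is tiled into contiguous zones (coarse: 8 zones with edges
650 | 825 | 956 | 1210 | 1312 | 1372 | 1477 | 1579 | 1800, the unnamed
1372–1477 interval kept as its own zone so the scheme tiles; fine: the
956–1210 zone split into 956–1030, 1030–1170 and 1170–1210). The
network is exposed to zone values through a surrogate: each zone mean is
broadcast across its zone's grid points, out-of-zone points come from a
fixed template (the training mean), and the network predicts
deterministically.

Shapley values use background imputation: absent zones are drawn from a
background set (training-fold control zone features — attributions then
answer "what pushes this spectrum toward disease *relative to
controls*"). For ≤ 12 zones all $2^m$ coalitions are enumerated exactly,
which removes estimator noise and makes the local-accuracy identity
$\sum_i \phi_i = f(x) - \mathbb{E}_{bg} f$ hold to machine precision;
beyond 12 zones sampled feature permutations are used.

Validation of the localization property uses cohorts generated *without*
scatter and baseline drift and attributes the raw spectra: as noted
above, EMSC couples adjacent zones when the class effect is broad, so a
localization check through EMSC would test the preprocessing rather than
the attribution. On distortion-free cohorts with a single injected zone
shift, the injected zone ranks first by mean |φ| with the correct sign in
10/10 seeds.

## Numerical choices and degenerate inputs

* Grids are stored ascending; descending instrument exports are
  canonicalized on read. Cropping uses closed intervals and is
  idempotent.
* EMSC solves one QR decomposition per model and reuses it for every
  spectrum; fits match a normal-equations oracle to 1e-8.
* Uncertainty ranking uses a stable sort with spectrum-id tie-break, so
  selection is deterministic under tied variances.
* `fit_pca()` refuses an all-identical training set; `fit_lda()` requires
  both classes; training requires both classes and a sigmoid output;
  `mc_predict()` requires $T \ge 2$ and a trained network.
* Non-finite training losses abort with the epoch index rather than
  propagating NaNs.

## Problem sizes used in validation

The shipped checks run at the sizes the science needs and no more: the
EMSC oracle uses 500 random spectra on the full 1526-point grid; the MCD
oracle uses $T = 10^4$ enumerable passes; selection invariants use 1000
randomized report sets; leakage audits retrain full-size networks on
three representative folds of the default cohort; the
refinement-benefit study uses 10 independent default cohorts under
7-fold CV (140 network trainings); attribution localization uses 10
reduced cohorts on a fingerprint-only grid. The full suite runs in
roughly ten minutes on one CPU.

## Known limitations

* The synthetic cohort is a statistical emulation; nothing here estimates
  clinical performance on real saliva spectra.
* The refinement guarantee is directional and in expectation: on any
  single cohort seed, phase 2 can tie or slightly trail phase 1.
* The zone surrogate evaluates the network on spectra whose within-zone
  shape is flattened; attributions describe the model's response to zone
  *levels*, not to sub-zone band shapes.
* With `keep_rule = "below_threshold"` the variance scale depends on the
  dropout rate, `T` and the architecture; thresholds do not transfer
  across configurations.
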