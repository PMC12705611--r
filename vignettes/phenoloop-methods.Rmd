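---
title: "Closed-loop dose-response phenotyping: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Closed-loop dose-response phenotyping: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenoloop)
```

phenoloop analyses dose-stress experiments on small model plants grown in
fabricated-ecosystem chambers on an automated imaging platform. A round of
experimentation exposes replicated plants to a set of stressor doses (copper
sulfate in the motivating system, 0–500 µM), images roots and shoots every
other day, and harvests fresh weights at the end. The package covers the full
analysis loop: a generative simulator of such experiments, the image-derived
phenotype metrics, Gaussian-process (GP) dose-response models, variance-based
Bayesian-optimisation design of the next round, a cross-validated model
evaluation protocol, and time-series analytics of the daily phenotypes.

## The generative model behind the simulator

Each plant carries a latent size $S(t)$ per organ (root, shoot) following
logistic growth whose *rate* is inhibited by dose:

$$\frac{dS}{dt} = r\,S\left(1 - \frac{S}{K}\right) I(d, t), \qquad
I_\infty(d) = \frac{1}{1 + (d/\mathrm{EC50})^h}.$$

$I(d,t)$ equals 1 before the amendment day $t_0$ (default day 10) and ramps
linearly to $I_\infty(d)$ over a phenotype-specific onset lag. Acting on the
rate rather than on accumulated size produces the observed "window of
impact" phenomenology: trajectories diverge gradually after amendment instead
of stepping. Writing the logistic in logit form shows $S$ depends only on
$\int I\,dt$, which is piecewise polynomial, so the simulator evaluates the
trajectory in closed form; the test suite checks it against Runge–Kutta
integration of the ODE.

Choices worth knowing:

* **Sensitivity ordering.** Default EC50s are 50 µM (root size), 105 µM
  (shoot size) and 300 µM (shoot health), with Hill exponents 1.5, 3.5 and 5
  and onset lags 1, 3 and 5 days. These were set once so that the simulated
  phenomenology reproduces the qualitative behaviour of copper-stressed
  *Brachypodium distachyon*: root inhibition detectable at 25 µM within a few
  days of amendment, shoot-size effects requiring ≥ 100 µM and appearing
  late, health loss requiring ≥ 200 µM and appearing last.
* **Per-plant variability** is a lognormal multiplier (sd 0.2 on the log
  scale) applied to the whole trajectory — biological size variation between
  genetically identical plants in controlled chambers.
* **Observation noise** is multiplicative lognormal on pixel counts
  (cv 0.15): segmentation counts are scale-free, so relative noise is the
  natural model. Harvest fresh weights get a larger relative noise
  (cv 0.40) — blot-drying and weighing milligram-scale tissue is
  considerably noisier than imaging. With these two values the Pearson
  correlation between final root pixel counts and root fresh weights across
  a two-round experiment settles around 0.87, matching what imaging/harvest
  agreement looks like in practice; the test suite asserts the [0.75, 0.95]
  calibration band.
* **Health fraction** is modelled directly as a saturating post-lag decline,
  $h(d,t) = h_0\,(1 - L(d)\,(1 - e^{-(t-t_0-\ell)/\tau}))$, rather than
  derived from simulated spectral cubes; `make_cube()` exists separately for
  when actual spectra are needed. This keeps the simulator fast.
* **Imaging schedule** defaults to every second day from day 4 to 24 plus
  day 25; real deployments image "approximately every other day", and the
  exact days are configurable rather than inferred.

What the simulator deliberately does *not* emulate: plant architecture
(tillers, leaf counts), realistic root images, spatially structured
segmentation errors, batch/chamber effects, heteroscedastic weighing error,
or microbial treatments. Tests passing on the simulator therefore show the
pipeline is correct and well-calibrated under its stated noise model, not
that real data will meet, e.g., a particular NRMSE.

## Spectral phenotype metrics

The NDVI variant used for shoot health is minimum-corrected:

$$\mathrm{NDVI} = \frac{m_{750} - m_{550}}{m_{750} + m_{550} + 2\,m_{\min}},$$

with $m_{750}$, $m_{550}$ mean reflectances over 740–750 nm and 540–560 nm,
and $m_{\min}$ the per-pixel minimum over the retained 430–800 nm range. The
extra $2 m_{\min}$ damps the index on dark pixels; for nonnegative
reflectance the value stays in $[-1, 1]$. Per image, pixel values are sorted
and aggregated into 50 equal-count bins whose means are averaged. Equal-count
(rather than equal-width) binning was chosen because it preserves the plain
pixel mean exactly whenever the bin count divides the pixel count, making the
summary insensitive to the binning step; this is an interpretation the data
format does not pin down.

Shoot health is a two-atom nonnegative spectral dictionary: plant mean
spectra are factorised by alternating nonnegative least squares into a
"green" and a "non-green" atom (labelled by their NDVI), and each pixel is
called healthy when its nonnegative projection weight on the green atom
exceeds the non-green weight. With only two atoms, each nonnegative
least-squares subproblem has a closed form (solve the 2×2 normal equations;
if a coefficient goes negative, the optimum lies on an axis), so the fit is
deterministic given its initialisation — the input spectra with the highest
and lowest NDVI. Per-view health fractions are combined weighted by view
pixel counts, and the three shoot views are reduced to one size proxy by the
Euclidean norm of their pixel counts.

## GP dose-response models

Phenotype endpoints (fresh weight or scaled final pixel size) are regressed
on dose with a GP using a stationary ARD kernel (squared exponential by
default; Matérn 3/2 available) and a single constant noise variance. The
prior mean is the training-target mean. Hyperparameters maximise the log
marginal likelihood inside data-driven boxes: per-dimension lengthscales in
$[0.01, 5] \times$ the observed input span, signal variance in
$[10^{-3}, 10^{2}] \times \mathrm{var}(y)$, noise variance in
$[10^{-6}, 2] \times \mathrm{var}(y)$. The span reading of the lengthscale
rule (rather than multiples of the raw min/max values) keeps the bounds
meaningful when the input range starts at 0.

The optimiser is a seeded stochastic search over log-hyperparameters —
greedy acceptance, step size annealed from half the box to 2% of it, a 20%
chance of a uniform restart draw — followed by box-constrained L-BFGS-B
refinement. The fitted optimum is never worse than its starting point, and a
test asserts it also beats 100 random in-bounds draws. The search budget
defaults to 2 000 iterations, which on the 40–90-point dose-response
problems here reaches the same optimum as much longer runs; production fits
can raise it to 10 000–25 000. Numerically, the kernel matrix gets a jitter
of $10^{-10}$ signal variance on the diagonal, and a failed Cholesky simply
scores the candidate as unusable.

`dose_at_fraction()` reads effective doses off a fitted posterior: the
first downward crossing of a fraction (default 50%) of the 0 µM prediction,
interpolated between grid points. Two caveats apply when comparing such a
half-response dose with the generator's EC50. First, the EC50 parametrises
the growth-*rate* inhibition, while the endpoint is accumulated size under
logistic saturation; with the default dynamics the dose halving final size
sits roughly 10–15% above the rate EC50. Second, GP smoothing flattens the
steep low-dose shoulder and biases the crossing slightly upward. Together
these put the recovered half-response dose within about 25% of the
generating EC50 under default conditions — adequate for dose-ranging, but
not a calibrated EC50 estimator.

Predictions report both the epistemic standard deviation (posterior sd of
the latent function) and the predictive sd with noise,
$\sqrt{\sigma_{\text{epi}}^2 + \sigma_n^2}$, on a 0–500 µM grid in 1 µM
steps. Scoring uses NRMSE — RMSE divided by the range of the evaluated
target set — and the closed-form Gaussian CRPS.

## Proposing the next round

The next round's doses maximise posterior epistemic variance: greedily pick
the best grid point, excise a 20 µM neighbourhood, repeat (5 picks by
default). The posterior is *not* re-conditioned between picks ("fantasy"
updates); plain greedy selection is the simplest reading of a variance
acquisition rule, and the minimum-separation constraint already prevents the
degenerate behaviour re-conditioning would fix. Exact variance ties break
toward the lower dose, which makes the data-free prior model propose the
lowest admissible grid points — a useful determinism contract. Floating-point
variance values are rounded to 10 significant digits before comparison so
that genuine ties are treated as ties. The executed round-2 design is always
the proposals plus 0 and 500 µM anchor arms.

## Model evaluation protocol

Model quality is assessed by 5 repeats of 6-fold cross-validation (30
splits), stratified on dose via 3 equal-frequency (quantile) bins; within
each repeat every bin is shuffled and dealt round-robin into folds, so
per-fold bin counts differ by at most one. Equal-frequency binning on a
fixed dose set makes re-binning per repeat a no-op, so one binning is used
throughout. Each test fold is scored with its own target range as the NRMSE
normaliser; folds with zero target range are flagged and excluded from
summaries, never silently dropped. Split-level NRMSEs are summarised by
their mean and a 1 000-resample percentile bootstrap 95% interval.

Two calibration guards accompany every evaluation. The *full-data NRMSE*
is the in-sample score of a fit on everything, and the *null ratio* divides
it by the same quantity computed after scrambling the targets (one seeded
scramble by default; averaging over several is available). Ratios well below
1 indicate genuine dose signal; under target-dose independence the ratio is
calibrated around 1, which the test suite checks over 50 seeds. Model
variants are compared on their 30 split scores with a t-test (two variants)
or one-way ANOVA plus Tukey HSD (three or more), plus percent improvement
$(\bar e_A - \bar e_B)/\bar e_A \cdot 100$ computed from unrounded means —
rounding the means first can shift the quoted percentage by a few tenths.

Run end to end (`run_loop()`), the two-round closed loop on the default
generator improves the cross-validated fresh-weight NRMSE of the combined
model over the round-1 model by a median of roughly 25–35% across master
seeds — the same order as reported for the motivating platform — mostly
because the second round concentrates observations where round-1 posterior
variance was largest and because doubling the data stabilises the fitted
noise level. The acceptance checks run this over 20 seeds.

## Daily time series and clustering

Per-plant daily series for root pixels, Euclidean shoot size, weighted
health fraction and NDVI are built by Savitzky–Golay smoothing (window 7;
polyorder 3 for pixel features, 5 for health and NDVI) applied along the
observation sequence — the sequence, not the day axis, which matters when
imaging is irregular and is exposed as a knob — followed by a cubic spline
evaluated on integer days 4–25, clamped to the observed day range (no
extrapolation). The spline end conditions fit exact cubics through the
terminal points, so polynomials up to degree 3 pass through the whole
pipeline unchanged; note that a window of 7 observations spans about two
weeks at every-other-day imaging, so sharp onsets bleed a little backward in
time — a real property of this smoothing choice, visible in the simulated
screens as occasional early first-significant days.

Two per-day screens follow the exposure window (days 11–25): Pearson
correlation of each feature with dose, with percentile bootstrap intervals
over plants (10 000 resamples by default), and a one-way ANOVA + Tukey HSD
against the 0 µM control per day, keeping only control contrasts. Because
Tukey controls error only within a day, an additional Benjamini–Hochberg
correction is applied across the retained (day × dose) family within each
feature; the screening method itself does not name a second-stage
correction, and BH is the standard choice for such a family.

For unsupervised structure, the three phenotype series over days 11–25 are
each MinMax-scaled globally across all plants and days, concatenated into a
plants × 45 matrix, embedded in 2-D with UMAP (`n_neighbors = 5`,
`min_dist = 0.05`, seeded and single-threaded, hence deterministic — a
contract this package imposes) and clustered with HDBSCAN
(`min_cluster_size = 8`, `min_samples = 3`). No R implementation of HDBSCAN
was suitable here, so the package carries a compact one: core distances,
mutual-reachability minimum spanning tree, single-linkage condensation at
the minimum cluster size, and excess-of-mass cluster extraction with the
root excluded. Its scope is deliberately the small 2-D embeddings this
pipeline produces (it builds the full distance matrix, so hundreds of
points, not millions). Low-density plants keep the noise label −1 and are
excluded from per-cluster statistics but always reported. On the default
two-round simulation the pipeline recovers four dose-ordered clusters
covering most plants, and ANOVA/Tukey across clusters separates their dose
means and final-day phenotypes.

## Problem sizes and numerical conventions

The shipped defaults are desk-scale study conditions: 7 dose arms × 6
replicates per round, 12 imaging days, 30 CV splits per evaluation, 2 000
optimiser iterations per fit, 1 000 bootstrap resamples (10 000 for the
daily correlations). The acceptance checks use these same conditions; the
one reduction is that repeated-seed calibration checks shrink the CV scheme,
since the quantity under test does not depend on the splits. Degenerate
inputs are first-class: constant targets drive the signal variance to its
lower bound and predictions to the prior mean; constant input columns are a
named error (the lengthscale rule would degenerate); all-identical spectra
make the dictionary warn and go single-atom; fewer pixels than bins makes
the binner warn and collapse to singletons; an all-noise clustering is a
warning, not an error.

## Known limitations

The GP is a point estimate over hyperparameters (no marginalisation), noise
is homoscedastic by design while the generator's is multiplicative, the
acquisition is single-objective with a fixed separation rather than a batch
diversity criterion, and the clustering stack is quadratic in plants. The
simulator's fidelity limits are listed above; where a real experiment
violates them (batch effects, dropout imbalance), the evaluation and
comparison machinery still applies, but the calibration bands quoted here do
not transfer automatically.
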