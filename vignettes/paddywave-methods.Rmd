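---
title: "Estimating rice yield from multi-stage canopy spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating rice yield from multi-stage canopy spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 7,
                      fig.height = 4)
library(paddywave)
library(dplyr)
```

## The problem

Grain yield integrates everything that happens to a rice crop across the
season. Canopy reflectance spectra (350–2500 nm) taken at the key
phenological stages — elongation, heading, flowering, milky — carry
indirect but rich information about the canopy state at each stage, so a
natural question is how much of the final yield (g·m⁻²) can be predicted
from them, and whether *combining* stages and *transforming* the spectra
improves the prediction.

`paddywave` implements that full analysis as a pipeline of small, typed
steps: spectral transforms, scalar feature extraction, correlation-based
screening of yield-sensitive bands, multi-stage feature fusion, and
regression by stepwise linear models or random forests, each evaluated by
R², RMSE and MAPE. Because multi-year field spectra are rarely
redistributable, the package ships a calibrated synthetic trial generator
with a *known* latent link between stage-wise canopy state and yield, so
every claim the package makes is testable end to end.

## Spectral representations

Four representations of each spectrum are used, all computed on a common
1 nm grid (350–2500 nm, 2151 bands; instrument grids are first linearly
resampled, never extrapolated):

* **OR** — the measured curve after Savitzky–Golay smoothing (window 11
  samples, cubic polynomial; the usual spectroscopy defaults, exposed in
  the configuration). The filter is a running least-squares polynomial
  fit, so it reproduces polynomials up to its order exactly.
* **FD** — the first derivative of OR (central differences, one-sided at
  the ends, per nm). Derivatives amplify the shape information used by
  edge parameters but also amplify band-wise noise.
* **CR** — continuum removal: the spectrum divided by its upper convex
  hull (computed by a monotone-chain construction). Absorption features
  become wells in (0, 1]; hull vertices sit at exactly 1, and applying
  the operator twice changes nothing.
* **CWT** — the continuous wavelet transform
  $W(a,b) = \int f(\lambda)\, a^{-1/2} \psi\!\big(\tfrac{\lambda-b}{a}\big)\, d\lambda$
  at the ten dyadic scales $a = 2^1, \dots, 2^{10}$, giving a scale × band
  coefficient plane per spectrum.

Three CWT choices deserve a note because the method itself does not fix
them:

* *Mother wavelet.* The Mexican hat (negative second derivative of a
  Gaussian) is the de-facto standard for vegetation-spectra CWT: its
  symmetric, band-pass shape turns absorption wells into localised
  coefficient extrema. It is the default and the only built-in.
* *Boundaries.* The integral is discretised as a sum over the grid with
  symmetric (mirror, edge-repeated) extension of the signal. At scale
  $2^{10}$ the kernel spans more than the whole measured range, so the
  boundary rule matters; mirroring avoids the spurious edge ringing that
  zero-padding would create. The kernel is truncated at $|x| \le 8$,
  where the Mexican hat tail is below 10⁻¹² of its peak, and the
  convolution is computed exactly (FFT), so the transform agrees with
  adaptive quadrature of the defining integral to ~10⁻¹⁰ relative on
  smooth test spectra — the test suite pins this.
* *Input.* CWT is applied to OR (smoothed) spectra, consistent with
  smoothing being the first preprocessing step for all transforms.

## Features

From each plot-stage the package extracts:

* **Vegetation indices** from single red (670 nm) and NIR (800 nm)
  bands: NDVI, DVI, EVI, and RVI. RVI is computed as **R/NIR** — the
  convention this analysis descends from — with `rvi_inverted = TRUE`
  for the more common NIR/R. The band positions are configurable; no
  band averaging is applied.
* **Tri-edge parameters** from FD in three windows: red 680–760 nm,
  blue 490–530 nm, yellow 560–640 nm (window bounds are a field
  convention, configurable). Per window: the FD maximum $D$, its
  wavelength $\lambda$ (smallest on ties), and the trapezoidal FD
  integral $SD$. Note $SD$ telescopes to the reflectance difference
  across the window for smooth spectra — a useful internal check. For
  the blue and yellow edges the derivative is typically negative; $D$ is
  still defined as the maximum.
* **Eight edge combinations**: the differences, ratios and normalised
  differences of $SD_r$, $SD_b$, $SD_y$.
* **Screened FD bands and CWT cells** (below), as raw feature values.

## Screening and fusion

Per stage and representation, Pearson correlation of each band (or each
scale × band cell) with yield is computed over the inner join of plots.
The significance bound is the usual two-tailed threshold
$r^* = t^*/\sqrt{t^{*2} + n - 2}$ (≈ 0.254 at $n = 60$, $\alpha = 0.05$).
Selection is greedy: take labels in decreasing $|r|$ above the bound,
suppressing neighbours within 10 nm at the same scale, at most `top_k = 5`
per stage. The suppression radius exists because adjacent bands are nearly
collinear; the cap keeps model inputs comparable across stages. The
source analysis reports sensitive bands but not a selection rule, so this
rule is the package's own, fixed for reproducibility and overridable.

Stage fusion is column-wise concatenation of per-stage feature tables
over the 15 non-empty subsets of the four stages (4 singles, 6 pairs,
4 triples, 1 quadruple), with stage-tagged column names.

## Models and metrics

**MSR** — multivariate stepwise regression, implemented from its
procedure: repeatedly add the candidate with the smallest partial-F entry
p-value if below `p_enter = 0.05`, then drop any retained variable whose
removal p-value exceeds `p_remove = 0.10`, until a fixed point; the final
model is OLS on the retained set. Rank-deficient candidates (e.g. exact
duplicates) are skipped, and entry stops once the fit is numerically
perfect (RSS below 10⁻¹² of the total), where partial F tests are
meaningless. The thresholds are the common default pair; the source
analysis does not state its own.

**RF** — a 500-tree random regression forest with `mtry = ⌈p/3⌉` (the
regression convention), seeded for exact reproducibility.

**Metrics** — $R^2 = 1 - \mathrm{SSE}/\mathrm{SST}$,
$\mathrm{RMSE} = \sqrt{\mathrm{SSE}/n}$ (g·m⁻²), and MAPE in percent with
the **predicted** value in the denominator. Two deliberate choices: the
printed formula this implementation descends from shows the $R^2$ ratio
without the "1 −", which would invert its own "higher is better"
interpretation, so the standard form is used; and its MAPE denominator is
the predicted value, which is kept as the default with
`mape_denom = "observed"` as the conventional alternative.

The model grid (`stage_combination_grid()`) crosses
{FD-VI, CWT-FD-VI} × 15 stage combinations × {MSR, RF}, fitting on the
training year and evaluating on the training year and both validation
years. Band and cell screening happens on the training year only; the
same selections then index features in every year, so validation data
never influence model selection. Edge parameters are available as an
optional extra feature group (`groups_extra = "EDGE"`), off by default,
because it is not established that they entered the final fused models.

## The synthetic trial generator

`simulate_trial()` emulates one year of a 60-plot nitrogen × variety
experiment: five N rates (0–400 kg·ha⁻¹) crossed with three varieties,
four replicate plots each. Per plot × stage, three positive latent
proxies — chlorophyll, LAI, water — are monotone functions of the N dose,
scaled by a variety vigour multiplier, a plot-level fertility effect
shared across stages (log-normal, sd 0.10) and stage-specific log-normal
noise (sd 0.18). Phenology multipliers peak the latents at heading and
flowering.

Reflectance is rendered from the latents: Gaussian chlorophyll wells at
450 and 670 nm whose depth saturates in chlorophyll; a logistic red edge
whose inflection is planted at $690 + 50\,c/(c+1)$ nm (so tri-edge
recovery has a known truth); an NIR plateau mixed with a flat soil line
by fractional cover $1 - e^{-0.5\,\mathrm{LAI}}$; water wells at 1450 and
1940 nm; and additive sensor noise (sd 0.006 reflectance units, tripled
inside the 1350–1450 and 1800–1950 nm atmospheric water-vapour windows).
The 670 nm well is kept spectrally narrow (σ = 12 nm) so that the well
and the red edge contribute separably — the well drives visible-band
yield signal while the planted inflection stays recoverable to ±1 nm.

Yield is assembled from the latents through a saturating "sink capacity"
$z = cL/(cL+3)$ per stage and the stage weights (105, 185, 175, 95
g·m⁻² for elongation, heading, flowering, milky) plus a 406 g·m⁻² base
and Gaussian noise (sd 30 g·m⁻²). The weights put heading and flowering
first, matching the agronomic expectation that the reproductive
transition dominates yield formation; their absolute values and the base
were moment-matched once so that the training year reproduces the
published trial's yield distribution (mean ≈ 686 g·m⁻², CV ≈ 0.16; see
`reference_yield_summary()`), and were then frozen.

`make_three_year_benchmark()` produces training and first-validation
years from the same configuration (different seeds) and a deliberately
perturbed second validation year: two varieties with weaker vigour, a
narrower mid-range fertiliser mix standing in for an N × P × K factorial,
and the *same* latent-to-yield mapping — so a model trained on year 1
faces a genuinely shifted covariate distribution (yield mean ≈ 600
g·m⁻², CV ≈ 0.12) rather than a different physiology.

What the generator does *not* emulate: radiative-transfer physics
(PROSAIL-style), row structure and soil BRDF, weather trajectories,
disease, or variety-specific spectral signatures beyond a scalar vigour
effect. Consequently, passing tests demonstrate that the pipeline's
machinery is correct and that its comparative conclusions hold under a
controlled spectra-yield dependency — not that the same accuracies would
be attained on any particular field data set.

## What the pipeline shows on synthetic benchmarks

Run end to end (`run_pipeline()`, or `scripts/acceptance.R` at the
repository root), the package reproduces the qualitative structure the
method is known for, computed fresh each run over 20 benchmark seeds with
the random-forest model:

* adding screened CWT cells to the FD + vegetation-index feature set
  does not reduce — and typically raises — median held-out R²;
* fusing all four growth stages beats the best single stage;
* the most yield-sensitive wavelet cells concentrate at mid scales
  (2⁴–2⁹) rather than the finest or coarsest ones.

The problem sizes (60 plots × 4 stages × 2151 bands, 10 scales, 20
seeds) were chosen as the smallest that make these medians stable; they
are the package's own defaults, not external constraints.

## A short worked example

```{r example, eval = FALSE}
trial <- simulate_trial(seed = 1)
or <- sg_smooth(trial$spectra)
fd <- first_derivative(or)

# where is the yield signal?
corr <- band_yield_correlation(fd, trial$yields)
select_sensitive(corr, top_k = 3)

# a quick single-stage model
bands <- select_sensitive(corr, top_k = 5)[c("stage", "wavelength_nm")]
feats <- build_feature_table(trial$spectra, groups = c("VI", "FD"),
                             fd_bands = bands)
df <- dplyr::inner_join(feats, trial$yields, by = "plot_id")
model <- fit_msr(df)
evaluate(predict(model, df), df$yield_g_per_m2)
```

## Numerical corners and limitations

* Degenerate inputs are rejected loudly: non-monotone grids name their
  first inversion, non-numeric CSV cells name their row, resampling
  outside the source range is an error (no extrapolation, ever).
* Zero-variance bands and zero denominators (RVI, NDVI, MAPE, edge
  ratios) produce `NA` with a message, never silent zeros.
* Ties: the FD maximum takes the smallest wavelength; greedy selection
  breaks |r| ties by lower wavelength then lower scale; stepwise entry
  ties resolve by column order.
* The stepwise p-value loop tests one variable at a time; it inherits
  the usual caveats of stepwise inference (post-selection p-values are
  optimistic) and is used here as a selection device, not an inferential
  one.
* Random-forest predictions are bounded by the training response range,
  so extrapolating to higher-yielding conditions than the training year
  systematically under-predicts — visible in the perturbed validation
  year.
* MAPE with the predicted-value denominator is asymmetric and undefined
  at zero predictions; the observed-denominator switch exists for
  conventional reporting.
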