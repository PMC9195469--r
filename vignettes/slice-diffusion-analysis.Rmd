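---
title: "Quantifying nanoparticle diffusion and tissue viability in brain-slice models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying nanoparticle diffusion and tissue viability in brain-slice models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slicetrack)
library(dplyr)
```

## The measurement problem

Multiple particle tracking (MPT) probes the geometry of the brain
extracellular space (ECS) by following individual fluorescent
nanoparticles — here 40 nm PEG-coated polystyrene probes — as they
diffuse between cells in living tissue such as organotypic
whole-hemisphere brain slices. Videos are acquired at 33.3 frames per
second for up to 651 frames; a tracker (e.g. TrackMate) turns each video
into a set of x/y positions per frame per particle. Everything downstream
of the tracker is this package's job:

1. per-trajectory time-averaged mean squared displacement (MSD),
2. effective diffusion coefficients via the Einstein–Smoluchowski
   relation,
3. anomalous-diffusion exponents from log–log fits,
4. classification of each trajectory into a diffusion mode, and
5. population summaries (median, IQR, mode fractions) that can be
   compared across ages, brain regions, timepoints and treatments.

Companion modules quantify the slice-viability experiments that accompany
such studies (metabolic-activity normalization, cumulative LDH release,
marker-positive nuclei percentages, intensity ratios) and implement the
normality-gated statistical decision tree used to compare groups.

## The diffusion model

For a trajectory with positions $(x_i, y_i)$ at frames $i = 0 \dots N-1$
on a uniform grid with frame interval $\Delta t$, the time-averaged MSD
at lag $n$ frames ($\tau = n\,\Delta t$) is

$$\langle r^2(\tau)\rangle \;=\; \frac{1}{N-n} \sum_{i=0}^{N-n-1}
\left[(x_{i+n}-x_i)^2 + (y_{i+n}-y_i)^2\right].$$

Imaging is two-dimensional (the focal plane), so the
Einstein–Smoluchowski relation for 2-D diffusion gives the effective
diffusion coefficient

$$D_\mathrm{eff} = \frac{\langle r^2(\tau)\rangle}{4\tau},$$

and hindered or driven motion is captured by the anomalous diffusion
law $\langle r^2(\tau)\rangle = 4 D \tau^{\alpha}$, fitted as a straight
line in log–log coordinates. Each trajectory is assigned a mode from its
fitted $\alpha$: immobile ($\alpha < 0.1$), subdiffusive
($0.1 \le \alpha < 0.9$), normally diffusive
($0.9 \le \alpha \le 1.1$), superdiffusive ($1.1 < \alpha$). The
boundaries are deliberately inclusive exactly as written: 0.1 is
subdiffusive, 0.9 and 1.1 are normal.

The ensemble MSD is a **precision-weighted geometric mean** across
trajectories at each lag. Geometric averaging respects the roughly
log-normal spread of per-trajectory MSDs in tissue; the default weights
are the number of displacement pairs $N - n$ contributing at that lag,
which is the natural precision proxy (an inverse-variance option,
$w = (N-n)/\mathrm{msd}^2$, is available; by the delta method the
variance of $\log \mathrm{msd}$ scales as $1/(N-n)$, so pair weighting is
also a log-space precision weighting). Lags where a trajectory has zero
MSD cannot enter a log mean and are excluded; a lag where *all*
trajectories are at zero reports 0.

### Tunable parameters and their defaults

| parameter | default | units | why |
|---|---|---|---|
| `frame_interval` | 1/33.3 ≈ 0.03003 | s | acquisition frame rate |
| `max_lag` | `floor(N/3)` | frames | long lags average few pairs and are dominated by noise; N/3 is the common SPT convention |
| `deff_lags` | 1:10 | frames | ≈ 0.03–0.30 s; short-lag window where the MSD is most precise |
| `alpha_lags` | 1:min(30, max_lag) | frames | enough dynamic range in $\tau$ for a stable slope |
| `min_length` | 10 | frames | a power-law fit on fewer than ~9 lags is meaningless |
| `max_gap` / `gap_policy` | 1 / `"split"` | frames | splitting at tracker gaps avoids fabricating displacements; interpolation would bias the MSD downward at short lags |

The lag at which an effective diffusion coefficient is quoted, and the
window over which $\alpha$ is fitted, are genuinely open choices in the
field; both are arguments everywhere they matter and are echoed in the
`settings` block of `analyze_diffusion()` output so a result can always
be reproduced.

### Numerical choices and degenerate inputs

* The $\alpha$ fit is ordinary least squares of $\log \mathrm{msd}$ on
  $\log \tau$, unweighted. Zero-MSD lags are dropped; if fewer than
  3 positive lags remain the particle is, to machine precision, pinned —
  it is assigned $\alpha = 0$ with a `degenerate` flag and classified
  immobile rather than raising an error.
* $R^2$ is computed directly from the residuals (a perfect closed-form
  fit returns exactly 1).
* MSD, $D_\mathrm{eff}$ and $\alpha$ are invariant under global
  translation and rotation of a trajectory; the tests enforce this to
  floating tolerance.
* Trajectories must be on a consecutive frame grid when they reach
  `compute_msd()`; the quality filter (`filter_trajectories()`) is the
  place where gaps are resolved, and it is idempotent.

## What the synthetic generators emulate

No raw tracking videos are publicly deposited for this kind of
experiment, so the package ships generators that emulate the acquisition
with known ground truth. They are first-class, tested code — every
recovery claim in the test suite is made against their labels.

* **Brownian** (`simulate_brownian`): per-axis Gaussian increments of
  variance $2 D \Delta t$; ensemble MSD $4 D \tau + 4\sigma^2$ with
  localization noise $\sigma$.
* **Fractional Brownian motion** (`simulate_fbm`): exact Cholesky
  factorization of the fractional-Gaussian-noise covariance, per axis,
  so the true exponent is exactly $\alpha = 2H$. One factorization is
  shared by all trajectories of a set.
* **Immobile** (`simulate_immobile`): constant true position plus
  noise; MSD plateaus at $4\sigma^2$.
* **Directed** (`simulate_directed`): drift $v$ along a random unit
  direction superposed on Brownian motion; $\mathrm{MSD} \to v^2\tau^2$.
* **Mixtures** (`simulate_mixture`): trajectory counts follow the
  requested fractions exactly (largest-remainder apportionment), so
  recovered mode fractions can be compared to exact targets.

Localization noise is i.i.d. Gaussian per frame and axis
(σ = 0.02 µm by default, a typical high-magnification localization
precision; the pixel size default is 0.1 µm/px). Neither value is a
measured property of any particular microscope — both are configuration.

The **nuclei-image generator** renders symmetric 2-D Gaussian blobs
(peak 1.0) at rejection-sampled centres with a minimum separation, adds
Gaussian background noise and clips to [0, 1] (detector saturation).
Marker-positive nuclei reuse nuclear centres — perfect colocalization,
matching overlap-based counting of marker+/nuclear+ cells. The
**assay-table generator** draws triplicate wells around scheduled means
and always carries a TX-100 full-lysis acute control group.

What these fixtures deliberately do **not** contain: obstacle fields or
viscoelastic memory in the trajectories (regimes are parameterized
directly), optics (no point-spread function, no uneven illumination,
no touching nuclei), plate effects (no edge wells, no drift). Passing
recovery tests therefore demonstrates that the estimators are correct
and well-calibrated on clean realizations of their motion models — not
that any particular tissue result is reproduced.

## Viability and imaging quantification

* **Metabolic activity** (alamarBlue-style): readings are averaged over
  replicates and expressed as a percentage of the mean reading at the
  acute timepoint of the same group (acute = 100%); for treated-group
  reporting the basis is instead the normal-control mean at the same
  timepoint and the % difference from NC is carried alongside.
  Normalization commutes with replicate averaging and is invariant to a
  common gain — both are enforced by tests.
* **Cumulative LDH release**: media are exchanged at every collection,
  so each reading is the release during that interval; per slice the
  running sum of interval readings is divided by the pooled mean
  absorbance of the acute TX-100 lysis control. The series is
  nondecreasing by construction and deliberately uncapped — total
  release beyond a single lysis control is biologically meaningful, so
  values above 100% are reported as-is.
* **Nuclei counting**: Otsu's threshold (256-bin histogram over the
  observed range, between-class variance maximization) segments the
  nuclear channel; 8-connected components of at least `min_area = 20`
  pixels are nuclei. A nucleus is marker-positive when its mean marker
  intensity exceeds the cutoff; `cutoff = "otsu"` resolves the cutoff on
  the marker channel and echoes the numeric value so it can be held
  fixed across a series of images. An image with zero segmentable nuclei
  yields an undefined (NA) percentage, never 0%. No watershed splitting
  is attempted — the generator enforces separation, and suspiciously
  large components are the user's cue to lower density or add one.
* **Intensity ratio**: whole-frame mean marker divided by whole-frame
  mean nuclear intensity (HIF1α-style readouts); gain applied to both
  channels cancels.

## The statistical decision tree

Group comparisons follow a normality-gated tree: each group is tested
with the D'Agostino–Pearson omnibus K2 (skewness and kurtosis z-scores
combined, $\chi^2_2$ reference); any rejection at 0.05 routes to
Kruskal–Wallis (tie-corrected H) with Dunn's rank comparisons under a
Bonferroni family adjustment. Otherwise spread is compared with the
Brown–Forsythe median-centred variance test: rejection routes to the
heteroscedastic branch — Brown–Forsythe and Welch ANOVA (Welch p
reported as the omnibus p) with Dunnett T3 comparisons (pairwise Welch t
with Šidák adjustment); acceptance routes to ordinary one-way ANOVA with
Tukey's studentized-range comparisons. Groups below n = 8 cannot be
normality-tested and fall back to the rank branch with a logged note.
All statistics are implemented from the published formulas, using base
R's distribution functions, and the test suite cross-checks them against
`oneway.test`, `kruskal.test`, `TukeyHSD`, `car::leveneTest` and frozen
reference values of the K2 test.

Two behaviours are worth knowing. First, branch selection is a pure
function of the data: the plan records every intermediate p-value, and
re-running returns the identical plan. Second, because the gates are
hypothesis tests with ~5% size, truly Gaussian homoscedastic data are
routed to the ANOVA branch only about
$0.95^3 \times 0.95 \approx 80\%$ of the time for three groups of
n = 30 — this is a property of any correctly-sized implementation of
the tree, not a defect of this one. The family-wise false-positive rate
of the full pipeline on all-null Gaussian data stays at ≈ 5%.

## Problem sizes used in the tests

Recovery tests use the acquisition geometry (651 frames at 33.3 fps)
with 100–200 trajectories per regime; decision-tree routing uses 100
replicates of three groups of 30 and error control uses 500 all-null
replicates; image recovery uses a 3 × 5 grid of 448×448-px fixtures with
50–200 nuclei. These sizes put Monte-Carlo noise comfortably below every
asserted bound while keeping the full suite under a minute of
simulation per module.

## Known limitations

* Static and dynamic localization error are not deconvolved from the
  MSD; noise inflates $D_\mathrm{eff}$ by $\sigma^2/\tau$ at short lags.
* No drift correction: stage drift masquerades as directed motion.
* `percent_positive()` does not split touching nuclei; dense tissue
  images need upstream segmentation better than a global threshold.
* The Dunn adjustment is the Bonferroni-style variant; Prism-flavoured
  variants differ slightly in how they count the family.
* Cumulative LDH assumes complete media exchange at each collection; a
  partial exchange would need carry-over correction upstream.
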