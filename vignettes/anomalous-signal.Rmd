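---
title: "Scaling, merging and estimating the anomalous signal in SAD data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scaling, merging and estimating the anomalous signal in SAD data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(anomsig)
```

## The model

A SAD experiment measures, for each acentric reflection, the Bijvoet pair
of amplitudes $F^+$ and $F^-$. Their difference
$\Delta_{\mathrm{ano}} = F^+ - F^-$ carries the phasing information; its
useful part is quantified by the *useful anomalous correlation*
$\mathrm{CC_{ano}}$, the Pearson correlation between the observed
differences and the ideal differences computed from the refined structure
with anomalous scattering restricted to the $n_{\mathrm{sites}}$
substructure atoms. Substructure solvability, in turn, is governed by the
*anomalous signal* $S_{\mathrm{ano}}$: the mean model-phased anomalous
difference Fourier peak height at the substructure sites, in map-rms
units.

The two are linked by

$$S_{\mathrm{ano}} \;=\; \mathrm{CC_{ano}}
  \sqrt{\frac{N_{\mathrm{refl}}}{n_{\mathrm{sites}}}} \; \frac{1}{f_B},
  \qquad
  f_B = \frac{\sqrt{\langle f_{h,B}^2\rangle}}{\langle f_{h,B}\rangle},$$

where $f_{h,B} = f'' e^{-B s^2}$ (with $s = \sin\theta/\lambda$) is the
substructure's effective anomalous scattering factor at each reflection's
resolution and the averages run over the reflections in the data set. The
relation follows from the statistics of a Fourier synthesis whose
coefficients are $\Delta_{\mathrm{ano}}
e^{i(\varphi_{\mathrm{model}} - \pi/2)}$: the part of each coefficient
coherent with the $f''$ substructure contributes $\propto N \langle
f\rangle$ at a site, while the map variance collects
$\propto N\, n_{\mathrm{sites}} \langle f^2 \rangle$, and imperfect
measurement scales the coherent part by $\mathrm{CC_{ano}}$. The package
verifies this relation end-to-end: predicted and directly measured
$S_{\mathrm{ano}}$ agree within a factor of two across the entire
validation corpus (`test-acceptance.R`, `scripts/acceptance.R`). $f_B \ge 1$
is dimensionless, so the overall size of $f''$ cancels — signal strength
enters only through $\mathrm{CC_{ano}}$.

$N_{\mathrm{refl}}$ is the unique-reflection count; for planning it is
estimated from the asymmetric-unit volume as
$N \approx (2\pi/3)\,V_{\mathrm{au}}/d_{\mathrm{min}}^3$ (a reciprocal
sphere count halved for Friedel pairs). This count includes centric
reflections, which carry no anomalous difference; plan reports state the
caveat rather than correcting for it, keeping the planning estimate
conservative in the direction a cautious experimenter would want.

## Scaling and merging multiple crystals

`scale_and_merge()` runs seven steps:

1. **Unit-cell grouping** — data sets whose cells agree within 1% in
   lengths and 1° in angles (alternatively, within a fraction of
   $d_{\mathrm{min}}$ in lengths) form groups; the group with the most
   measured reflections proceeds.
2. **Anisotropy homogenization** — each data set's anisotropic fall-off
   tensor is fitted by least squares on $\ln I$ and adjusted to the
   ensemble average, so inter-data-set scaling differences are minimized
   while the ensemble's overall fall-off is preserved.
3. **Splitting** — observations are processed in file order; a repeated
   full-sphere index opens the next sub-data set, so each sub-data set
   holds at most one observation per index. Sub-data sets below 30% of
   their largest sibling are discarded; acentric observations without
   their Bijvoet mate in the same sub-data set are excluded.
4. **Local scaling** — all observations of each unique reflection are
   averaged into a scaling target; the Bijvoet-plus and Bijvoet-minus
   partial sets are each scaled to it with per-reflection local scale
   factors (the ratio of summed target to summed own amplitudes over at
   least 30 reciprocal-space neighbours, taken in symmetric $\pm$ offset
   pairs), then recombined without further scaling.
5. **Overall scaling** — one least-squares scalar per sub-data set against
   a provisional inverse-variance merge.
6. **Inter-data-set variance** — per sub-data set and resolution bin,
   $D_i^2 = \max\!\big(0,\; \langle(\Delta_i-\Delta_m)^2\rangle -
   \langle\sigma_i^2\rangle - \langle\sigma_m^2\rangle\big)$, the
   deviation from the merged differences beyond what measurement error
   explains. $\langle\sigma_m^2\rangle$ is the inverse of the summed
   inverse variances of the contributors; the small self-inclusion bias
   this carries is ignored, as it shrinks with the number of data sets.
7. **Weighted merge** — anomalous differences merge with weights
   $w_i \propto 1/(\sigma_i^2 + D_i^2)$; mean amplitudes merge with plain
   inverse-variance weights; $F^\pm = \bar F \pm \Delta/2$.

### Design choices in the merge

*Two variance passes.* The deviations in step 6 are measured against a
reference merge. When several strongly deviant crystals are present, a
reference built with uncertainty-only weights is itself contaminated,
which inflates $D_i^2$ for the good crystals and dulls the weighting.
`merge_scaled()` therefore re-estimates the variances once against the
variance-weighted merge and merges again (`n_variance_passes = 2`). In
simulations with eight crystals of which half deviate badly, the single
pass lets the merged $\mathrm{CC_{ano}}$ sag by $\approx 0.04$ at full
ensemble size; the refinement pass removes the sag entirely while being a
no-op when all crystals are consistent.

*Variance mode.* $D_i^2$ can be computed from anomalous differences
(default, `variance_mode = "anom"`), from Bijvoet-averaged amplitudes
(`"mean"`), or disabled (`"off"`). Anomalous-difference-based weighting is
the right default because inter-crystal differences (for example, small
wavelength drifts near an absorption edge) can leave mean amplitudes
nearly identical while disrupting the differences badly; the `"mean"` mode
exists to quantify exactly that gap.

*Negative variances are clamped to zero* — a variance estimate below zero
is sampling noise, not information. *Resolution bins* default to 10
equal-count shells; bins with fewer than 20 contributing pairs borrow the
nearest populated bin's value.

*Local-scaling neighbourhoods* use exact k-nearest-neighbour search in the
Cartesian reciprocal metric, implemented over integer index offsets sorted
by length with $\pm$ pairs adjacent, so symmetric pairs are preferred
whenever both members exist. The default of 30 neighbours doubles as the
minimum; the search radius widens automatically, and queries that still
fail fall back to unit scale with a warning. One property worth knowing:
because the scaling target is the Bijvoet *average*, local scaling
perturbs even perfect data by
$O\!\big(\mathrm{rms}(\Delta)/(2\sqrt{k}\,\bar F)\big)$ per mate. For
signal-free data the procedure is an exact identity; with signal it sets a
ceiling slightly below 1 on the achievable merged correlation
($\approx 0.98$ at the validation problem sizes). This is intrinsic to
scaling against an average that contains the anomalous imbalance, not an
implementation artifact, and it is dwarfed by the systematic errors local
scaling removes.

*One pass of local scaling* is applied to the anisotropy-corrected
amplitudes; the steps are listed once and iterating them showed no benefit
in simulation.

## Data-quality metrics

**Half-data-set correlation.** Crystals are divided into two balanced
groups (keeping each crystal's reflections together, so systematic
inter-crystal differences do not masquerade as random error); each half is
scaled and merged independently, and $\mathrm{CC_{1/2}}$ is the Pearson
correlation of their anomalous differences. A single unmerged file is
split per-reflection into first/second halves in file order, or randomly
(seeded) when observations are not grouped. The expected squared
correlation of the merged differences with the truth is

$$E^2 = \frac{2\,\mathrm{CC_{1/2}}}{2 - w + w\,\mathrm{CC_{1/2}}},$$

where $w$ is the fraction of unique acentric reflections measured in both
halves. At $w = 1$ this is the familiar half-set extrapolation
$2\mathrm{CC_{1/2}}/(1+\mathrm{CC_{1/2}})$; as $w \to 0$ it degrades
toward $\mathrm{CC_{1/2}}$ itself, since singly measured reflections gain
nothing from merging. The squared form stays defined for negative
$\mathrm{CC_{1/2}}$ (the value then carries the negative sign); the pole
at $\mathrm{CC_{1/2}} = -1$, $w = 1$ is flagged as undefined.

**Patterson skew.** The anomalous difference Patterson (coefficients
$\Delta^2$ minus their resolution-shell means, which removes the origin
peak and zeroes the map mean) has positive peaks at substructure
interatomic vectors. The skew $s = \langle P^3\rangle/\sigma^3$ of the map
after truncation at $\pm4\sigma$ summarizes that excess; optionally the
map is further truncated at $\pm3\sigma$ wherever a native Patterson is
extreme, to suppress translational-NCS peaks (off by default). Maps are
synthesized by FFT on a grid of spacing $d_{\mathrm{min}}/3$.

**Normalized error.** Reported uncertainties are rescaled by the factor
$\beta$ that makes the extrapolated highest-shell mean-square uncertainty
of the differences equal their extrapolated mean-square value — at the
resolution edge the anomalous signal is assumed negligible, so differences
there are pure noise. Extrapolation is a linear fit of the shell means
against $1/d^2$ over the outer half of shells (the functional form is a
package choice; shell means are nearly linear in $1/d^2$ over that range).
The normalized error is then
$e = \sqrt{\langle(\beta\sigma)^2\rangle / \langle\Delta^2\rangle}$ over
the whole data set; by construction $e \approx 1$ in the highest shell,
and for a no-minor-scatterer data set the expected useful correlation is
$\mathrm{CC_{ano}} = \sqrt{1 - e^2}$ (observed variance = signal variance
+ noise variance). All metric correlations are restricted to acentric
reflections.

## Bayesian estimation

`train_bayes_estimator()` builds, per predictor, a Gaussian conditional
model (mean and variance of the predictor within each target bin,
smoothed with a triangular kernel over three bins, standard deviation
floored at one predictor-bin width) plus the marginal target distribution
of the training set. `bayes_posterior()` multiplies the prior by the
independent-predictor likelihoods on a 50-bin $\mathrm{CC_{ano}}$ grid
over $[0,1]$ (40 log-spaced bins over $[5,200]$ Å$^2$ for the
substructure-B estimator). Both a flat and a training-distribution prior
are available; **the default is the training prior**, which encodes how
often each signal level actually occurs and is the better calibrated
choice when the training corpus resembles the data at hand — pass
`prior_mode = "flat"` to remove that influence.

Packaged training tables are synthetic, seeded and versioned: the
estimator corpus is generated by `graded_corpus()`, the
Wilson-B-to-substructure-B table encodes a substructure displacement
factor about 40% above the Wilson B with log-normal scatter, and the
solved/not-solved and map-correlation tables place the 50% success point
near an anomalous signal of 10, saturating above 20 — consistent with the
working target of $S_{\mathrm{ano}} \gtrsim 15$ for a confident
experiment. These stand in for archival corpora of solved structures;
their filenames and documentation say so, and every function accepts a
user-supplied table instead.

`probability_of_solution()` and `expected_map_cc()` are deliberately
simple binned estimators (per-bin solved fraction / mean map correlation,
triangular smoothing for sparse bins, nearest-bin fallback), mirroring how
such outcome tables are used in practice.

## The synthetic-data generator

`generate_truth()` draws a protein structure-factor field with Wilson
statistics (complex Gaussian for acentrics; phase-restricted real Gaussian
for centrics, with the restricted phase $\pi\,h\!\cdot\!t$ derived from
the symmetry operation mapping $-h$ to $h$), places the substructure at
random positions, sums over all symmetry copies with the full complex
factor $f_0(s) + f' + i f''$, and reports exact $F^+$, $F^-$, ideal
differences, and model phases. Optional low-occupancy minor scatterers add
anomalous differences that the ideal set excludes, reproducing the
situation where even perfectly measured data correlate imperfectly with
the main substructure.

`simulate_unmerged()` layers per-data-set systematic errors on the truth:
an overall scale, a trace-free anisotropy perturbation, a smooth
multiplicative field in reciprocal space (low-order cosine waves whose
bandwidth controls whether local scaling can track them — both regimes are
tested), Gaussian measurement noise whose standard deviation grows with
resolution as $e^{B_{\mathrm{noise}} s^2}$ (default
$B_{\mathrm{noise}} = 22$ Å$^2$, matching the Wilson fall-off, so the
resolution edge is noise-dominated as the $\beta$ rescaling assumes),
mis-reported uncertainties (reported $\sigma$ = true $\sigma / c$), and
intrinsic inter-data-set perturbations with an antisymmetric
($\Delta$-affecting) component and a symmetric (mean-amplitude) component
half its size — the regime, analogous to small wavelength drifts, in which
$\Delta$-based variance modelling outperforms amplitude-based modelling.
Observations are emitted grouped by unique reflection in measurement
order, Bijvoet-plus before Bijvoet-minus, which is what the order-based
splitting rule assumes.

**Default study conditions.** The default crystal is triclinic P1
(33 × 36 × 39 Å, angles 85/95/100°), $d_{\mathrm{min}} = 2.4$ Å (about
6 900 unique reflections), five Se-like sites ($f'' = 4\,e^-$,
$B = 18$ Å$^2$) on a 900-atom carbon-like background at Wilson
$B = 22$ Å$^2$. P1 keeps the number of substructure copies small relative
to the reflection count, which preserves the Patterson peak contrast the
skew metric needs at desk scale — in a high-symmetry cell of this size the
hundreds of symmetry-related interatomic vectors wash the skew toward
zero, a genuine smallness effect rather than a property of the metric.
Rotational Sohncke symmetry (P2$_1$2$_1$2$_1$ and others) is fully
supported and exercised by the symmetry, splitting and centric-reflection
tests. `graded_corpus()` spans true $\mathrm{CC_{ano}}$ from roughly 0.3
to 0.97 by grading the noise level log-uniformly from 0.25 to 6 times the
rms ideal difference and cycling 5–8 sites across members; each member
carries two simulated crystals and a full pipeline run takes a few
seconds.

**What passing tests do and do not show.** The generator produces Gaussian
noise with honest (or deliberately mis-scaled) uncertainties, smooth
systematic errors, and complete, randomly thinned data. Real data add
non-Gaussian outliers, radiation damage trends within a data set, ice
rings and absorption effects with sharp angular structure, and unmodelled
correlations between mates measured on the same image. Passing the
validation suite shows the algorithms are implemented correctly and behave
as designed in the statistical regime the generator emulates; it does not
certify performance under pathologies the noise model omits.

## Numerical choices and degenerate inputs

* Intensities convert to amplitudes by $F = \sqrt{\max(I, 0)}$;
  $\sigma_F = \sigma_I / (2\max(F, \sqrt{\sigma_I}/2))$ guards the
  weak-reflection blow-up.
* ASU mapping uses the lexicographically greatest image over the
  rotational orbit and its Friedel mates; the convention is stated in
  written file headers. Centric reflections are assigned to the plus set.
* Inverse-variance weights floor variances at $10^{-12}$ so noise-free
  test data do not divide by zero; equal-$\sigma$, zero-$D^2$ merging
  reduces exactly to the arithmetic mean.
* Zero-variance maps have skew 0 by convention; empty merges, missing
  Bijvoet overlap, and sub-3-reflection correlations are errors or
  flagged `NA`s, never silent numbers.
* Site values in the anomalous difference Fourier are trilinearly
  interpolated from the FFT grid (spacing $d_{\mathrm{min}}/3$); the
  direct summation oracle in the tests bounds the interpolation loss.
* The Wilson plot divides shell intensities by the squared carbon form
  factor before fitting, otherwise the form-factor fall-off of a protein
  masquerades as roughly 10 Å$^2$ of extra B.
* All pipeline functions are deterministic given their inputs; every
  stochastic step (half-set splits, simulation) takes an explicit seed.

## Problem sizes used in validation

The validation suite runs entirely on generated data: a 30-member graded
corpus (two crystals each, ~6 900 unique reflections), twenty 8-crystal
ensembles at $d_{\mathrm{min}} = 2.8$ Å for the variance-weighting
comparison, and 2 500-reflection constructions for the variance-recovery
checks. These sizes were chosen so that each check isolates the property
it tests while a full suite run stays in the minutes range on a single
core; all of the qualitative behaviour they probe is scale-free.

## Known limitations

* Local scaling against the Bijvoet-averaged target sets a merged-
  correlation ceiling slightly below 1 (see above).
* The $\beta$ rescaling assumes the resolution edge is signal-free; for
  data truncated well inside the signal range, $\beta$ (and hence $e$)
  overestimates the error. The Bayesian estimator absorbs this because
  its training corpus carries the same convention.
* Cromer–Liberman $f''$ lacks white-line enhancement at absorption edge
  peaks; measured values from a fluorescence scan should override the
  bundled table when available.
* Space-group support covers the 65 Sohncke groups in standard settings;
  non-standard settings must be reindexed first.
* MAD-style multi-wavelength treatment, frame-level scaling models and
  radiation-damage corrections are out of scope.
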