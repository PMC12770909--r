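---
title: "Phase-lag-dependent electric-field metrics for dual-site tACS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phase-lag-dependent electric-field metrics for dual-site tACS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dstacs)
library(dplyr)
```

## The problem

Dual-site transcranial alternating current stimulation (ds-tACS) drives two
cortical sites — here the left and right primary motor cortices (M1) — with
sinusoidal currents whose relative timing is set by a phase lag φ. The phase
lag is the experimental variable of interest (it is what entrains or
de-couples oscillations between the two regions), but it also changes the
*electric field itself*: wherever the two sites' fields overlap, shifting the
phase of one current redistributes, reorients and rescales the total field on
the cortex. An experiment that interprets behavioural differences across
phase lags as purely "connectivity" effects therefore needs to know how much
of the field changed along the way.

`dstacs` quantifies exactly that. Given a cortical surface and the three
single-channel basis fields of a two-site high-definition (HD) montage, it
reconstructs the time-resolved field at any phase lag, computes a set of
phase-lag-sensitive field metrics, tests whether those metrics are modulated
by the lag, quantifies how much they vary between individuals, and evaluates
whether choosing a montage per individual improves the field properties that
matter for dual-site stimulation.

## Field model

One period of stimulation at frequency $f$ is reconstructed from three
static basis fields by linear superposition:

$$
E(p, t) = I_o\left[\,(E_{R1}(p) - E_{C1}(p))\,\sin(2\pi f t)
  + E_{R2}(p)\,\sin(2\pi f t + \varphi)\,\right]
$$

$E_{R1}$, $E_{C1}$ and $E_{R2}$ are the fields of three single-channel
(tDCS-like) solves against one common return electrode: return vs. the
surround electrodes of site 1, return vs. the central electrode of site 1,
and return vs. the surround electrodes of site 2. Because each solve is
stored per unit channel current, any central:surround current split of the
montage is already contained in the basis fields, and the whole field is
linear in the amplitude $I_o$. The phase lag is applied to the second site's
term only.

Defaults follow the standard stimulation protocol: $I_o = 2$ mA (a 4 mA
peak-to-peak current), $f = 20$ Hz, eight phase lags $\{0, \pi/4, \dots,
7\pi/4\}$, and 24 time steps per cycle.

**Time-grid anchoring.** The 24 equally spaced steps are placed at
$t_k = (k + \tfrac12)/(24 f)$. An anchored grid ($t_k = k/(24f)$) would make
the whole zero-lag field exactly zero at two steps, leaving normalized
comparison metrics undefined there; the half-step offset avoids exact
zero-crossings for all eight default lags. Because $\pi/4$ is an integer
multiple of the grid spacing $2\pi/24$, the multiset of $|\sin|$ values is
identical across the default lags, which is what makes peak metrics exactly
lag-invariant for non-overlapping sites. A degenerate-step guard (below)
covers accidental cancellations for non-default grids.

## Thresholding

Before any metric is computed, each condition (montage × phase lag) is
cleaned with two thresholds, applied to the cycle envelope of the field
magnitude and, separately, of the absolute cortex-normal component:

* values above the 99.9th percentile are **excluded** — they leave the metric
  node set entirely (numerical outliers of a forward solve);
* values below 2% of that percentile are **set to zero** — the node stays in
  the set, its area still counts, but its unreliable direction no longer
  contributes.

Percentiles use linear interpolation between order statistics
(`stats::quantile` type 7); percentile dialects differ enough across
software that this is worth stating. Masks are computed once per condition
on the envelope rather than per time step, so the node support of a metric
cannot flicker across the cycle. Magnitude-based and normal-component-based
metrics each use their own mask family. Comparison metrics between two
conditions are evaluated on the nodes kept by both.

## Metrics

All comparison metrics are computed on the *cortex-normal component* of the
field — the projection onto the outward surface normal, which is the
direction that polarizes pyramidal neurones — on the target sheet (both M1s
pooled) and on the surrounding grey-matter sheet.

* **Peak magnitude** and **peak normal component** (V/m): maxima over kept
  region nodes and all time steps.
* **RDM** (relative difference measure): per time step, the element-wise
  absolute normal components of the zero-lag and lagged conditions are each
  Euclidean-normalized and the norm of their difference is taken; steps are
  then averaged. 0 means the spatial distribution is unchanged. Note that
  with the element-wise absolute value the attainable maximum is $\sqrt 2$
  (fully disjoint supports), not 2 as it would be for signed vectors; the
  implementation follows the absolute-value form. An alternative
  `envelope` mode applies the same formula once to the per-node cycle
  envelopes, comparing where the field *can* reach over a cycle rather than
  its instant-by-instant pattern; for perfectly separated sites the
  envelope is lag-invariant and this mode reports exactly 0 at every lag,
  whereas the literal per-step form reports nonzero values at lags other
  than $0$ and $\pi$ even for separated sites (the instantaneous balance
  between the two sites shifts within the cycle). Both are available;
  `timewise` is the default.
* **DotP**: the per-step cosine similarity between the signed
  normal-component vectors of the zero-lag and lagged conditions, averaged
  over steps; 1 = same direction everywhere, −1 = globally opposed.
* **ΔDotP**: $|{\rm DotP}_{\rm ideal} - {\rm DotP}_{\rm observed}|$, the
  deviation from what perfectly separated sites would give. The ideal value
  is computed by brute force: two disjoint single-node sites carrying the
  montage's lag-fixed and lag-shifted powers are run through the same
  superposition and DotP code. The power ratio is taken from the
  *post-threshold normal-component* powers of the two sites on the same
  node set the observed DotP uses ($P_1 = \sum \hat n\!\cdot\!(E_{R1} -
  E_{C1})^2$, $P_2 = \sum \hat n\!\cdot\!E_{R2}^2$), i.e. per individual
  and montage rather than a fixed montage-level constant. This choice makes
  a genuinely non-overlapping montage score exactly ΔDotP = 0, which is the
  property the metric is meant to measure.
* **Effective area of stimulation** (mm², per M1): the target-region area
  whose absolute normal component reaches at least 50% of the per-step peak
  over the whole analysed sheet (surrounding plus both M1s), averaged over
  the cycle. A focality measure.

**Degenerate-step guard.** Steps where either condition's normal-component
vector norm falls below $10^{-8}$ times that condition's maximum step norm
are dropped from RDM/DotP averages; 0/0 normalizations are thereby excluded
without affecting any well-conditioned step.

**Node-based evaluation.** All metrics are evaluated at mesh nodes, with
each node weighted by one third of its incident triangle area (so node
areas sum exactly to the surface area); normals are angle-weighted averages
of incident triangle normals, oriented outward. Evaluating at triangle
centres instead would be an equivalent discretization; it is not taken.

## Statistical testing

Whether a metric is modulated across the eight lags is tested per (metric,
montage, region set) with a weighted Hermans–Rasson (WHR) statistic:

$$
T = \sum_i \sum_j w_i w_j \left[\,|\pi - |\theta_i - \theta_j|| - \pi/2
  + 2.895\,(|\sin(\theta_i - \theta_j)| - 2/\pi)\,\right]
$$

with the phase lags as angles and the metric values, min–max scaled to
$[0,1]$ per cell, as weights. The published weighted variant's exact
weighting scheme is not fully specified, so the second-form Hermans–Rasson
kernel with value-weights is used; since significance comes from a
permutation null — phase-lag labels permuted *within each individual*,
preserving every individual's value multiset — type-I control holds for any
fixed kernel, and the kernel only affects power. $p = (1 + \#\{T_{\rm perm}
\ge T_{\rm obs}\})/(1 + n_{\rm perm})$ guarantees valid p-values at finite
$n_{\rm perm}$ (10000 by default). Across montages, p-values are
Bonferroni–Holm corrected within each metric and region set. Because the
lags take eight distinct values, the double sum collapses to
$T = s^\top K_8\, s$ with per-lag weight sums $s$ — algebraically identical
and fast enough to calibrate the test by simulation (the identity is
itself under test).

Peak metrics enter the test as max-over-time values and the comparison
metrics as time averages, which is how the metric table already stores
them.

Inter-individual variability is reported as the coefficient of variation
(sample SD / mean × 100%), computed across individuals per (metric,
montage, phase lag) and then averaged across lags. Lags where every
individual scores exactly zero (the trivial zero-lag rows of RDM and
ΔDotP) have no defined CV and are skipped.

## Montage individualization

`select_best_montage()` picks, per individual, the candidate montage
optimizing the phase-lag-averaged objective (minimizing RDM or ΔDotP;
maximizing peaks or areas). The zero-lag rows of the comparison metrics are
excluded from the average — they are identically 0 and would only dilute
the objective; peaks and areas include all lags. A worst-case-over-lags
aggregation is available via `aggregate = "worst"`. Ties break by montage
id order, making selection deterministic. `individualized_summary()`
compares the selection against the single best fixed montage; the
individualized mean can never be worse than the fixed-best mean (it is a
pointwise minimum), and the interesting quantity is how much it improves
and what happens to the between-individual CV.

## The synthetic cohort generator

Real inputs for this analysis are MRI-derived head meshes and FEM solves,
neither of which belongs in a metrics package. The generator replaces them
with a construction that preserves exactly the structural features the
analysis is sensitive to:

* a spherical cortical sheet (icosphere, radius 80 mm, 642 nodes at the
  default 3 subdivisions) with two M1-like caps of angular radius 0.15 rad
  (≈ 4.5 cm², about the size of the M1 hand region) and a surrounding band;
* per-site fields built from normal-dominant Gaussian lobes: an
  inward-normal central lobe, opposite-polarity outward surround lobes
  (3×1, 4×1 or ring geometry) flux-balanced against it, and tangential
  components along the lobe gradients (relative strength 0.3);
* every lobe is a focal Gaussian (σ = 0.12 rad) plus a 3×-wider diffuse
  component whose weight is the `overlap` parameter (default 0.3): real HD
  fields are never confined to the array, and it is this diffuse part that
  survives the 2% floor and makes the two sites interact;
* `separated` mode truncates each site's support to a cap smaller than
  half the inter-site distance, producing the ideal two-site limit that a
  spherical benchmark model approximates: envelope-RDM and ΔDotP vanish
  and peaks are exactly lag-invariant — properties the test suite asserts;
* cohorts draw per-individual site-centre jitter in the tangent plane
  (σ = 0.04 rad ≈ 3 mm), lognormal per-site amplitudes (sdlog 0.2, ≈ 20%
  field-strength spread, on the order of reported inter-individual
  variation), and a random surround-array azimuth; zero jitter yields a
  bit-identical cohort. Site-1 drives are normalized to peak at
  0.1 V/m per mA, placing peaks near 0.2 V/m at the default 2 mA.

The construction is phenomenological, not electrostatically exact: fields
are not curl-free interpolants of a potential, the sphere has no
conductivity layers, and the smooth geometry cannot reproduce the
sulcus-scale sign flips of a folded cortex. Consequently overlapping-mode
ΔDotP values here are much smaller than on real head models, and passing
tests demonstrate correctness of the *metrics and inference machinery*
under controlled conditions, not predictions for any particular head.
Region labels are always consumed as given; nothing in the package computes
an atlas.

## Worked example

```{r example}
spec <- synthetic_montage_spec()
sheet <- make_sphere_sheet(spec = spec)
basis <- make_basis_fields(sheet, spec, seed = 1, montage_id = "4x1a")
metrics <- compute_metrics(sheet, basis)
metrics %>%
  filter(metric %in% c("rdm", "dotp", "delta_dotp"),
         region_set == "M1s") %>%
  tidyr::pivot_wider(names_from = metric, values_from = value,
                     id_cols = phase_lag)
```

A cohort analysis chains the same pieces:

```{r cohort, eval = FALSE}
cohort <- make_cohort(spec, n_individuals = 18, seed = 1)
metrics <- cohort_metrics(cohort)
tests <- test_phase_modulation(metrics, n_perm = 10000, seed = 1)
tidy(tests)
metric_cv(metrics)
individualized_summary(metrics, "delta_dotp")
autoplot(metrics, "rdm")
```

`run_pipeline(pipeline_config(out_dir = "out", ...))` performs the same
sequence end-to-end and writes tidy TSV tables plus a JSON provenance
manifest; the configuration keys mirror the function arguments, and file
inputs (Gmsh MSH v2 ASCII or PLY meshes, wide-TSV field containers, TSV
label maps — see `FORMATS.md`) are interchangeable with generated data.
The pipeline stages are deliberately exposed as plain functions — generate,
superpose, compute metrics, test, individualize — rather than behind a
shell wrapper, since every consumer of this analysis works in R.

## Problem sizes and numerical conventions

The shipped tests run cohorts of 3–6 individuals with 2–3 candidate
montages on 642-node spheres, 2000 simulated null tables at 999
permutations for the type-I calibration of the permutation test, and 20
random basis sets for the time-reversal symmetry property; these sizes give
stable assertions (binomial SE of the rejection rate ≈ 0.005) while keeping
the suite fast. Symmetry and oracle identities are asserted at 10⁻⁹–10⁻¹²;
statistical calibration at ±0.01 on the rejection rate. Meshes coarser than
3 subdivisions are not used for metric pipelines: with 162 nodes the M1
caps contain only one or two nodes, which the outlier exclusion can empty.

## Known limitations

* The generator's fields are phenomenological (see above); absolute metric
  values on real SimNIBS-derived inputs will differ, the machinery will
  not.
* The WHR kernel is one defensible reading of the weighted Hermans–Rasson
  statistic; permutation inference makes this a power choice only.
* `ideal_dotp` assumes the two sites' *relative* power is what matters;
  per-step cosines depend only on $P_2/P_1$, which is exact for disjoint
  supports and an idealization otherwise.
* Thresholding follows the percentile/floor recipe exactly; on very small
  node sets (tens of nodes) a 99.9th percentile is dominated by the
  maximum and the floor can zero a large fraction of nodes — another
  reason metric evaluation expects realistic mesh resolutions.
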