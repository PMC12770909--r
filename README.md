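# dstacs

Electric-field metrics for dual-site transcranial alternating current
stimulation (ds-tACS).

Dual-site tACS applies sinusoidal currents at two scalp sites with a
controllable phase lag φ between them, aiming to modulate functional
connectivity between two cortical regions (here the left and right primary
motor cortices). Wherever the two sites' electric fields overlap, changing
φ does not only change relative timing — it changes the field itself:
its spatial distribution, its direction relative to the cortical surface,
and the area it stimulates effectively. `dstacs` quantifies those
phase-lag-dependent field changes, tests them statistically, measures how
much they vary between individuals, and evaluates per-individual montage
selection.

## Model and metrics

The time-resolved field over one cycle is reconstructed from three
single-channel basis fields by linear superposition,

    E(p, t) = Io [ (E_R1(p) − E_C1(p)) sin(2πft) + E_R2(p) sin(2πft + φ) ]

evaluated at 24 half-step-offset time steps and eight phase lags
{0, π/4, …, 7π/4} (defaults: Io = 2 mA, f = 20 Hz). After a two-sided
cleanup (values above the 99.9th percentile excluded, values below 2% of
it zeroed), five metric families are computed on the cortex-normal
component of the field, for the pooled M1 targets and the surrounding
grey-matter sheet:

* **peak magnitude** and **peak normal component** (V/m);
* **RDM** — relative difference measure between the normalized absolute
  normal-component distributions at lag 0 and lag φ (0 = unchanged);
* **DotP** and **ΔDotP** — the averaged cosine similarity between the
  signed normal-component vectors of the two conditions, and its absolute
  deviation from the value perfectly separated sites would give;
* **effective area of stimulation** (mm², per M1) — target area at ≥ 50%
  of the sheet-wide per-step peak.

Phase-lag modulation is tested with a weighted Hermans–Rasson permutation
test (labels permuted within individual, Bonferroni–Holm across montages),
inter-individual variability with coefficients of variation, and montage
individualization by per-individual objective minimization. A synthetic
generator (spherical sheet, two-site Gaussian-lobe HD fields with a
controllable overlap, seeded cohorts with anatomical jitter) exercises the
whole pipeline without MRI or FEM inputs; its `separated` mode reproduces
the ideal two-site limit exactly.

## Worked example

```r
library(dstacs)
library(dplyr)

spec   <- synthetic_montage_spec()            # two-site 4x1 HD montage
sheet  <- make_sphere_sheet(spec = spec)      # labelled spherical cortex
basis  <- make_basis_fields(sheet, spec, seed = 1, montage_id = "4x1a")
metrics <- compute_metrics(sheet, basis)

metrics %>%
  filter(metric %in% c("rdm", "dotp", "delta_dotp"), region_set == "M1s") %>%
  tidyr::pivot_wider(names_from = metric, values_from = value,
                     id_cols = phase_lag)
#> # A tibble: 8 × 4
#>   phase_lag    rdm  dotp delta_dotp
#>       <dbl>  <dbl> <dbl>      <dbl>
#> 1     0     0      1       1.11e-16
#> 2     0.785 0.318  0.729   1.04e- 3
#> 3     1.57  0.386  0.509   8.02e- 4
#> 4     2.36  0.321  0.317   2.37e- 4
#> 5     3.14  0.0259 0.150   1.86e- 5
#> 6     3.93  0.321  0.317   2.37e- 4
#> 7     4.71  0.386  0.509   8.02e- 4
#> 8     5.50  0.318  0.729   1.04e- 3
```

Reading this: the spatial distribution of the field on the M1s shifts
moderately at intermediate lags (RDM ≈ 0.32–0.39) and is nearly restored
in antiphase (RDM ≈ 0.026 at φ = π); the field direction decorrelates
smoothly with the lag (DotP from 1 down to 0.15); and ΔDotP stays within
~10⁻³ of the ideal separated-site value — on this smooth spherical
geometry the two 4×1 sites barely interact. All comparison metrics are
symmetric about the half cycle, as they must be. Peak magnitudes for this
montage are ≈ 0.20 V/m on the targets at 2 mA.

Cohort-level analysis chains the same verbs:

```r
cohort  <- make_cohort(spec, n_individuals = 18, seed = 1)
metrics <- cohort_metrics(cohort)
tidy(test_phase_modulation(metrics, n_perm = 10000, seed = 1))
metric_cv(metrics)
individualized_summary(metrics, "delta_dotp")
autoplot(metrics, "rdm")
```

`run_pipeline(pipeline_config(out_dir = "out", n_individuals = 18))` runs
generate → metrics → tests → individualization end-to-end and writes tidy
TSVs plus a provenance manifest. File-based inputs (Gmsh MSH v2 / PLY
meshes, wide-TSV basis-field containers, TSV label maps; see
`inst/FORMATS.md`) are interchangeable with generated data.

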