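# tofmlaa

Joint reconstruction of emission activity and attenuation maps from 2D
time-of-flight (TOF) PET sinograms, with the attenuation scale anchored by
an external reference object of known attenuation.

## Why

TOF-PET emission data almost determine the attenuation map: joint
MLAA-type reconstructions (maximum likelihood estimation of attenuation
and activity) recover the attenuation sinogram only up to an additive
constant in its logarithm. Left alone, the reconstruction drifts along
this degenerate family and both images come out biased by tens of
percent. Placing a small object of known attenuation — a 4-cm water
cylinder in the patient table, filled with activity comparable to the
patient mean A₀ — outside the patient and pinning the reconstructed
attenuation inside it to its known value removes the degeneracy with a
single scalar shift per update. This package implements that modified
MLAA in 2D simulation, for researchers studying attenuation correction
without CT/MRI priors (PET/MRI, stand-alone scanners).

## What is inside

* **Projector** — Siddon ray tracing over a 128×128, 5-mm grid; sparse
  system matrix with Gaussian TOF weighting (`c_ij^TOF = l_ij · w_TOF`),
  27 TOF bins at CRT 300 ps (13 at 540 ps, 81 at 100 ps); exact adjoint
  back projection.
* **Reconstruction** — TOF-MLEM activity updates
  `λ_j ← λ_j · [Σ c_ij^TOF y/b] / [Σ c_ij^TOF a_i]`, gradient-ascent
  attenuation updates `μ_j ← μ_j + (α_p/D)(1 − Σ l y / Σ l a b)` with
  α_p = 2, D = 903 mm every 3 MLEM iterations, and the reference-object
  bias correction `μ ← μ + (μ̄_ref − μ̄_ROI)` after every attenuation
  update; watershed-based initialization from a non-attenuation-corrected
  reconstruction.
* **Phantoms** — synthetic thorax slice (soft tissue, adipose ring, lungs,
  spine, patient table, configurable reference cylinders) and the 20-cm
  water calibration cylinder.
* **Noise** — acceptance-rejection Monte Carlo with a fixed total count
  (literal loop + equivalent fast multinomial mode), plus the count-level
  calibration targeting 5% ROI SD.
* **Evaluation** — per-tissue mean percentage difference Δᵗ and SDᵗ,
  difference maps, convergence curves; tidy tibbles, `tidy()`/`glance()`
  and `autoplot()` methods throughout.

## A worked example

```r
library(tofmlaa)

# the reference configuration: one 4-cm water cylinder at A0 activity,
# CRT 300 ps, 1e7 coincidences, 1000 MLEM iterations
spec <- experiment_preset("reference", master_seed = 1)
res  <- run_experiment(spec, verbose = TRUE)
res$metrics
#> # A tibble: 4 × 7
#>   experiment                          replicate tissue  delta    sd     n n_excluded
#>   <chr>                                   <int> <chr>   <dbl> <dbl> <int>      <int>
#> 1 reference_A1_water_n1_crt300_N1e+07         1 lung     4.95 16.9    832          0
#> 2 reference_A1_water_n1_crt300_N1e+07         1 soft     3.47  7.94  1288          0
#> 3 reference_A1_water_n1_crt300_N1e+07         1 adipose  2.74 13.7    544          0
#> 4 reference_A1_water_n1_crt300_N1e+07         1 bone     2.29 10.8     60          0
```

`delta` is the mean percentage difference between reconstructed and true
emission values over each tissue (here all within a few percent of the
truth — the reference object has removed the degeneracy); `sd` is the SD
of the per-pixel percentages. Running the same conditions through
`experiment_preset("standard-mlaa")` (no reference object) leaves every
tissue ~25-30% off on this phantom — the flat, tissue-independent offset
that is the signature of the additive-constant family (on the original
patient slice the deviation exceeded 50%; where the degenerate solution
lands depends on the anatomy and the initialization).

A thin CLI wraps the presets:

```sh
Rscript inst/cli/tofmlaa simulate --preset reference --seed 1 --out runs/
Rscript inst/cli/tofmlaa sweep --presets reference,standard-mlaa --out runs/
```

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes, from scratch at full scale (~10 min): the percent ROI SD of a
standard-MLEM reconstruction of the 20-cm water cylinder at 10⁷ counts
(average over 3 seeds); the minimum per-tissue |Δᵗ| of standard MLAA
without a reference object on the thorax phantom; and the maximum
per-tissue |Δᵗ| of the reference-corrected mode with one water cylinder
at A₀ — writing the three numbers to the given JSON path.

See `vignettes/joint-reconstruction.Rmd` for the model, the synthetic
phantom's scope, and every declared numerical choice.
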