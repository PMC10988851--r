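# renaldki

Diffusion kurtosis imaging (DKI) analysis of layered renal tissue, with a
calibrated synthetic-data generator and the cohort statistics used in
longitudinal renal-fibrosis studies.

Renal interstitial fibrosis makes tissue microstructure more complex and
less freely diffusive; DKI quantifies this through the non-Gaussian
component of water diffusion. `renaldki` implements the full analysis chain
for a multi-b-value renal acquisition — three shells (b = 0, 400, 800
s/mm²) with 25 encoding directions — in a rat model of hyperuricemic kidney
injury, for researchers who want a tested, reproducible reimplementation of
that pipeline on simulated data.

## The model

The diffusion-weighted signal along unit direction **n** at weighting *b*
follows the kurtosis expansion of the log signal:

    ln[S(n,b)/S0] = −b Σᵢⱼ nᵢnⱼ Dᵢⱼ + (1/6) b² D̄² Σᵢⱼₖₗ nᵢnⱼnₖnₗ Wᵢⱼₖₗ

where `D` is the rank-2 diffusion tensor (6 unique components), `W` the
fully symmetric rank-4 kurtosis tensor (15 unique components, dimensionless
under the D̄² scaling), and D̄ = trace(D)/3. Voxelwise estimation is the
standard two-step linearization: the 22 parameters (ln S0, D, V = D̄²W) are
solved by weighted least squares on the log signal (one reweighting pass
with squared predicted signals), then W = V/D̄². From the fitted tensors the
package derives the three reported scalars:

- **MD** (mean diffusivity) = trace(D)/3, reported ×10⁻³ mm²/s;
- **FA** (fractional anisotropy) = √(3/2)·√Σ(λᵢ−D̄)² / √Σλᵢ²;
- **MK** (mean kurtosis) = the directional apparent kurtosis
  K(n) = (D̄²/D(n)²)·W(n) averaged over a 250-direction spherical
  quadrature.

Around that core sit: NIfTI-1 and FSL bval/bvec I/O, electrostatic-repulsion
gradient-scheme generation, a three-layer kidney phantom (cortex CO, outer
stripe OS, inner stripe IS) with Rician noise, tensor calibration to target
(MD, FA, MK) triples, a longitudinal 4-group × 6-timepoint cohort generator
matched to the study's printed regional means ± SDs, and the statistical
layer: two-rater ICC(2,1), per-timepoint one-way ANOVA with LSD post-hoc
pairs, and Pearson correlation against synthetic histological fibrosis
scores (Masson mean optical density).

## Worked example

Calibrate tensors to the baseline control outer-stripe regional values
(MD 2.735 ×10⁻³ mm²/s, FA 0.444, MK 0.760), simulate the noiseless
51-volume acquisition, fit, and recompute the metrics:

```r
library(renaldki)

scheme <- build_scheme(25, c(0, 400, 800), seed = 7)
scheme
#> gradient_scheme: 51 volumes; shells b = 0/400/800 s/mm^2; 1 b0 volume(s)

cal <- calibrate_tensors(tissue_params(2.735, 0.444, 0.760, region = "OS"))
sig <- forward_signal(cal$D, cal$W, s0 = 1000, scheme)
fit <- fit_voxel(sig, scheme, estimator = "WLS")

c(MK = mean_kurtosis(fit$D, fit$W),
  FA = fractional_anisotropy(fit$D),
  MD = mean_diffusivity(fit$D) * 1e3)
#>    MK    FA    MD
#> 0.760 0.444 2.735
```

The fit inverts the forward model to its calibration targets — the
round-trip identity the acceptance checks rely on. The same chain runs
end-to-end on a noisy phantom and cohort:

```r
res <- pipeline_full_run(default_config(seed = 5), "run1")
res$roi[res$roi$metric == "MK", c("region", "value")]
#>   region     value
#> 1     CO 0.8389916
#> 2     OS 0.7346302
#> 3     IS 0.5913852
```

At the default SNR of 25 the regional MK means sit below their noiseless
targets (0.857/0.760/0.640) — the Rician noise-floor bias discussed in the
methods vignette. A shell front end with `simulate | fit | roi | stats |
full-run` subcommands is installed at `inst/cli/renaldki.R`.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes, from scratch against the installed package: the noiseless
round-trip MK/FA (outer stripe) and MD (inner stripe) of the baseline
control calibration targets; the 5th percentile of ICC(2,1) over 500
replicates of the two-rater remeasurement study (19 disease-group subjects,
rater noise at 20% of the between-subject SD); the 99th percentile of the
day-9 inner-stripe MK ANOVA P over 500 replicates (n = 6 per group); and
the mean sample Pearson r over 200 replicates of the 27-pair fibrosis
correlation study. Results land in the JSON file given by `--out`.
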