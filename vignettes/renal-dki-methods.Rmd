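---
title: "Methods: renal diffusion kurtosis analysis on calibrated synthetic data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: renal diffusion kurtosis analysis on calibrated synthetic data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(renaldki)
```

## The signal model and its sign convention

The package models the diffusion-weighted magnitude signal along unit
direction $n$ at weighting $b$ (s/mm²) as

$$\ln\frac{S(n,b)}{S_0} = -b\sum_{ij} n_i n_j D_{ij}
  + \frac{1}{6} b^2 \bar D^2 \sum_{ijkl} n_i n_j n_k n_l W_{ijkl},$$

with $\bar D = \mathrm{trace}(D)/3$. The diffusion term carries a negative
sign: signal must decay with $b$ in the Gaussian limit, and the kurtosis
term is the first correction of the cumulant expansion. Some renderings of
this equation drop the minus sign typographically; the physically meaningful
(decaying) form is implemented, and the Gaussian limit
$S = S_0 e^{-b d}$ is pinned by tests. $W$ is dimensionless under the
$\bar D^2$ scaling, which is why the directional apparent kurtosis carries
the factor $\bar D^2 / D(n)^2$:

$$K_{\mathrm{app}}(n) = \frac{\bar D^2}{D(n)^2}\, W(n).$$

Tensor components are stored once, in a fixed order — $(xx, yy, zz, xy, xz,
yz)$ for $D$ and the 15 lexicographic index quadruples for $W$ with
multiplicities $(1,4,4,6,12,6,4,12,12,4,1,4,6,4,1)$ — and every module
shares those conventions.

## Estimation

Fitting is the standard two-step linearization. The design matrix has 22
columns: an intercept estimating $\ln S_0$, six columns $-b\,n_i n_j$ (with
multiplicity 2 off-diagonal), and fifteen columns $(b^2/6)\,n_i n_j n_k n_l$
(with multinomial multiplicities) that estimate the auxiliary products
$V_{ijkl} = \bar D^2 W_{ijkl}$, keeping the system linear. After the solve,
$W = V / \bar D^2$ with $\bar D$ from the fitted diffusion tensor.

* **OLS vs WLS.** The default estimator is weighted least squares with one
  reweighting pass, weights equal to the squared predicted signals of an
  unweighted first pass — the usual variance-stabilizing choice for
  log-transformed magnitude data. Further passes move estimates by well
  under 0.1% at realistic SNR and are omitted. On noiseless data OLS, WLS
  and a full nonlinear signal-space fit coincide to $10^{-6}$ (tested).
* **Degenerate inputs.** Nonpositive signals are clipped to $10^{-6}$ of the
  voxel's $b_0$ signal before the log transform and the voxel is flagged
  `clipped-signal`. A rank-deficient solve or $\bar D \le 10^{-12}$ flags
  `rank-deficient` and zeroes $W$ rather than dividing by a vanishing
  $\bar D^2$. Negative fitted eigenvalues flag `negative-eigenvalue`.
  Estimation itself is unconstrained — flags record violations, nothing is
  silently clamped — and flagged voxels become NA sentinels in the metric
  maps, which ROI statistics exclude (with counts) rather than average as
  zeros.
* **Determinability.** A kurtosis fit needs at least one $b=0$ volume, two
  distinct nonzero shells, and 15 independent directions; the scheme
  builder and the fitting layer both enforce this, and the 51-volume design
  matrix is verified to have full rank 22.

## Mean kurtosis and the quadrature choice

MK is defined here as the equal-weight average of $K_{\mathrm{app}}$ over a
250-direction electrostatic-repulsion point set (seed fixed package-wide).
Vendor workstations differ in whether they average over a dense sphere or
over the acquired directions; both are provided
(`default_quadrature()` / `acquisition_quadrature()`), the dense sphere is
the default, and tensor calibration uses the same default so round trips
close exactly. On the calibrated renal tensors the two conventions differ by
under 2% (tested), and the 250-point average matches a $10^5$-direction
brute-force sphere cover within $10^{-3}$. A caveat discovered while
testing: an equal-weight 250-point set is rotation-invariant only to its own
discretization error (about $10^{-3}$ relative), so MK rotation invariance
is asserted at that scale, while MD and FA are exact invariants at
$10^{-6}$.

## What the generators emulate

* **Acquisition.** One $b=0$ volume plus 25 repulsion-spread directions
  repeated on the 400 and 800 s/mm² shells (51 volumes), matching the
  study protocol. How many $b_0$ volumes the scanner interleaved is not
  documented; one is the minimal anchor and is a convention, not a fact.
* **Tissue.** Each kidney layer (cortex, outer stripe, inner stripe) is an
  axially symmetric prolate diffusion tensor, principal axis $+z$, with
  eigenvalues solved in closed form from the target (MD, FA):
  $\Delta = \lambda_1-\lambda_{23} = \mathrm{FA}\cdot\mathrm{MD}
  \sqrt{3/(1-\tfrac23\mathrm{FA}^2)}$. Orientation is immaterial because
  all reported metrics are rotation invariants. The kurtosis tensor is
  isotropic, $W = w_0 W_{\mathrm{iso}}$ with $W_{\mathrm{iso}}(n)\equiv 1$;
  only MK is reported, so kurtosis anisotropy is out of scope. MK is
  exactly linear in $W$, so $w_0$ comes from one linear solve
  ($w_0 = \mathrm{MK}_{\mathrm{target}} / \mathrm{MK}|_{w_0=1}$) rather
  than the bisection a root-finder would use — same contract, exact result.
  The closed form is valid for FA < 0.95; the renal values stay below 0.8.
* **Phantom geometry.** Three nested slabs along $x$ (CO outermost, OS, IS
  core) with a background rim; the second array axis plays the coronal
  slice axis, and ROI means default to the three central coronal slices, as
  in the manual ROI protocol. Slabs are not anatomy — they give each layer
  enough voxels (≥ 30 enforced, 1200 at the default 20×20×10 grid) for
  stable means, nothing more.
* **Noise.** Rician: $\sqrt{(S+g_1\sigma)^2+(g_2\sigma)^2}$ with standard
  normal $g_1,g_2$, the magnitude-MRI model. $\sigma = s_0/\mathrm{SNR}$
  with a default SNR of 25 — a typical small-animal 3T body-coil regime;
  the study reports no SNR, so this is a stated choice, not a fact.
* **Cohort.** Per-cell Normal draws with the study's printed regional
  means ± SDs (4 groups × 6 timepoints × 3 regions × 3 metrics, n = 6 per
  cell by default) — the minimal model consistent with mean ± SD reporting.
  Two printed SDs contain an obvious extra decimal point
  ("0.0.13"); both are read as 0.013. Rater remeasurement adds independent
  Normal noise at a configurable fraction (default 20%) of the
  between-subject SD. Fibrosis scores are bivariate-normal conditionals on
  regional MK with marginal Normal(0.13, 0.01) truncated at zero, matching
  the reported Masson mean-optical-density range; each region's scores are
  conditioned on that region's own MK so the within-region correlation is
  the configured one (default 0.687).

## What a green test does and does not establish

Noiseless round trips close to $10^{-4}$; that validates the forward model,
the design matrix, the estimator, and the calibration as mutual inverses.
It does not validate against real scanner data — no raw images are
deposited, so the in-vivo statistics can only be reproduced *distributionally*
through the calibrated generator. The generator draws independent Normal
cells: it reproduces printed means, SDs, and the qualitative findings
(ICC above 0.8, day-9 group separation, fibrosis correlations), but has no
within-subject longitudinal correlation, no partial-volume mixing, no
perfusion compartment (the study's $b \ge 400$ floor deliberately
suppresses perfusion), and no anatomical geometry.

A quantitative caveat the test suite documents rather than hides: at the
default SNR 25, the $b=800$ shell of high-diffusivity renal tissue decays
to ~10% of $s_0$, i.e. per-volume SNR ≈ 2.5, and magnitude noise then
biases the log-linear estimator materially — cortical FA reads ~18% high
and inner-stripe MK ~12% low on phantom averages. This is the physics of
the stated acquisition, not an implementation defect: the bias property
test asserts a 20% envelope at SNR 25 and < 2% at SNR 100, and the WLS mean
of each diffusion-tensor component stays within 2% of truth at SNR 50
(500-replicate test). Noise-floor corrections (e.g. subtracting $2\sigma^2$
in quadrature) are deliberately not applied — the reference workstation
used "no constraints or smoothing", and silent correction would change what
the maps mean.

## Statistical layer choices

* **ICC.** The study says only "intraclass correlation coefficient";
  `icc_absolute_agreement()` implements ICC(2,1) — two-way random effects,
  absolute agreement, single measures — the standard form for two raters
  measuring the same subjects, with the F-based 95% CI. The test oracle is
  an independent variance-components decomposition (REML via lme4).
* **ANOVA + LSD.** Classical one-way decomposition per timepoint × region ×
  metric, then Fisher's LSD: unadjusted pairwise $t$ with the pooled MSE
  and $N-k$ df. No multiplicity correction across timepoints or regions —
  mirroring the per-timepoint reporting convention. With $k=2$ groups LSD
  reduces exactly to the pooled two-sample $t$ test (tested), and the null
  rejection rate is calibrated at 5% ± 1% over 5000 replicates.
* **Correlation pooling.** Fibrosis correlations pool subjects across the
  disease groups and the histology timepoints (days 1, 5, 9), giving n = 27
  at the study's cell sizes (3 rats × 3 groups × 3 timepoints); the subject
  set entering the original analysis is not stated, so the pooling rule is
  a documented, configurable assumption.

## Reproducibility

Every stochastic stage takes an explicit integer seed; pipeline stages
derive theirs from the global seed by a stage-name hash (decorrelated,
32-bit safe). Full runs write a manifest of artifact MD5 checksums, and
rerunning a config reproduces it byte-for-byte. File formats are NIfTI-1
(via a minimal built-in reader/writer, there being no NIfTI package in the
target environment — verified against nibabel round trips during
development), FSL bval/bvec text, CSV metric tables (15-significant-digit
round trip), and YAML configs.

## Known limitations

Single-compartment kurtosis model only (no IVIM/perfusion term, no axial or
radial kurtosis, no kurtosis FA); no eddy-current, motion, or
Gibbs-ringing handling; slab phantom geometry; independent-cell cohort
model; DICOM and vendor formats out of scope.
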