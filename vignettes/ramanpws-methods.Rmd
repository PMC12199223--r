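---
title: "Methods: hybrid RS-PWS analysis of field cancerization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hybrid RS-PWS analysis of field cancerization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ramanpws)
```

This vignette documents the statistical models behind `ramanpws`, the
choices made where several reasonable implementations exist, and what
the synthetic-cohort tests do and do not establish about real data.

## The measurement model

One observation is a field of view (FOV): a 10 × 10 grid of Raman
spectra (100 spectra, 50 µm spacing) plus a PWS reflectance stack of
151 frames recorded at 550–700 nm in 1 nm steps, with an
instrument-response (IRF) stack of the empty slide recorded alongside.
Cohorts compare control FOVs against FOVs from macroscopically normal
tissue adjacent to premalignant lesions.

## Raman preprocessing

Each spectrum passes, in order, through:

1. **Savitzky–Golay smoothing**, first order. The window length is not
   fixed by the method; the default of 7 samples preserves bands of
   ~10 cm⁻¹ width on a 2 cm⁻¹ axis while suppressing shot noise. The
   filter's boundary handling evaluates the boundary polynomial fits,
   so affine spectra pass through unchanged (a test asserts this
   exactly).
2. **iModPoly baseline removal.** The iterative modified
   multi-polynomial algorithm: fit a polynomial of order *p* (5 for the
   fingerprint region, whose autofluorescence is broad and curved; 3
   for the high-wavenumber region), compute `DEV = sd(y − fit)`, clip
   the spectrum at `fit + DEV` so peaks are excluded from the next fit
   — clipping already in the first iteration, which is what
   distinguishes iModPoly from its predecessor when peaks are present —
   and stop when the relative change of `DEV` falls below `tol`.
   Defaults `tol = 0.05`, `max_iter = 100` are typical for this
   algorithm family; non-convergence sets a flag rather than failing,
   since a usable baseline exists at every iteration. The polynomial is
   evaluated on a [0, 1]-rescaled axis for conditioning. A degenerate
   (constant) input returns itself as baseline with zero corrected
   signal.
3. **Region cropping** to 800–1800 cm⁻¹ (FP) or 2800–3050 cm⁻¹ (HWVN).
   HWVN analysis is a configuration flag, off by default, because thin
   or dehydrated samples may not support it.
4. **Vector normalization** to unit Euclidean norm.
5. **DBSCAN screening** across the grid of normalized spectra. The
   radius is not stated by the method; the default is scale-adaptive:
   the 95th percentile of each spectrum's distance to its 5th-nearest
   neighbour. This is deterministic, needs no tuning per FOV, and
   flags cosmic-ray-like spikes and baseline jumps whose normalized
   shape leaves the dense cluster. With fewer spectra than `min_pts`
   the screen is skipped.

The per-FOV observation used downstream is the arithmetic mean of the
kept spectra, re-normalized to unit norm. Whether the original analysis
classified per-FOV aggregates or all 100 spectra per FOV is not
documented; the per-FOV mean is the default here because it matches the
FOV-level group sizes that the statistics report, and a per-spectrum
mode would inflate the effective sample size.

## PWS texture

The PWS image is formed as the per-pixel standard deviation over
wavelength of the IRF-normalized reflectance `m(λ) = I(λ)/I_IRF(λ)`
after detrending. The exact detrending inside the original image
formation is not public; both mean removal (default) and a linear fit
over λ are provided, and the choice only matters when the reflectance
has a strong per-pixel spectral slope. The sigma map is invariant to
any common per-wavelength factor in `I` and `I_IRF`, which is what
makes the IRF normalization meaningful.

Texture is quantified by gray-level co-occurrence matrices on the
16-level uniform quantization of the sigma map. Sixteen levels keeps
co-occurrence counts stable on frames of ~10²-pixel scale; more levels
sharpen the histogram but starve the matrix. The inverse difference
moment `IDM = Σ P(i,j)/(1+(i−j)²)` is computed at pixel distances 1–20
along the four standard directions and averaged, since no anisotropy
claim is made. The full IDM-vs-offset curve (20 values) is the PWS
feature vector for classification; a scalar summary would discard the
offset dependence that distinguishes smooth from rough disorder maps.

## Band statistics

Band intensity is the mean normalized intensity over a ±4 cm⁻¹ window
(the window half-width is a configuration parameter; ±4 cm⁻¹ covers a
band's core without bleeding into the 1441/1449 cm⁻¹ neighbours).
Group differences use the unpaired Mann–Whitney U test with midranks;
the p-value is the exact permutation value when the combined sample
size is ≤ 20 without ties — group sizes like 10 vs 26 fall in the
normal-approximation regime with tie correction and continuity
correction. Per-band p-values are reported without multiplicity
correction, matching per-band reporting conventions; a
Benjamini–Hochberg option exists but is off by default.

## Multimodal PLS-DA

Classification regresses the 0/1 class code on the features with SIMPLS
partial least squares. Feature sets: the IDM curve (PWS), the per-FOV
mean spectrum channels (RS), and their column-wise concatenation after
z-scoring (sample-sd convention, as in common statistical toolboxes).
z-scoring is applied globally before cross-validation to match the
published recipe; a leakage-safe per-fold scaling mode is provided and
is the statistically preferred option for honest error estimates.

Component count is chosen by stratified 4-fold cross-validation with
the one-standard-error rule: the fewest components whose mean CV error
is within one SE (computed across the fold errors of the minimizing
count) of the minimum. Stratification is necessary because 10-vs-26
imbalance makes unstratified folds degenerate. Fold assignment is
seeded and recorded, so every CV table is bit-reproducible.

Performance is summarized by `R² = 1 − SS_res/SS_tot` of the fitted
response against the class code and the residual norm `‖r‖`, which
satisfy `‖r‖² = SS_tot(1 − R²)` identically. Because it is ambiguous
whether published values of this kind are in-sample or cross-validated,
`compare_modalities()` reports both, labelled `r_squared` (in-sample at
the selected component count) and `cv_r_squared` (out-of-fold).

## The synthetic cohort generator

The generator is the package's test bed and emulates:

- Raman spectra as Gaussian peaks (Lorentzian optional; line shapes are
  not documented for the original data) at the marker-band positions,
  on a polynomial autofluorescence background of order ≤ 5 that
  dominates the peaks severalfold, with additive Gaussian noise
  (`noise_sd = 0.01` against peak amplitudes of 0.4–1.2, i.e. a
  post-integration SNR of order 10², typical of confocal tissue Raman
  at seconds-per-spectrum integration).
- Disease effects as multiplicative factors on peak amplitudes
  (defaults: amino-acid bands up ~25%, lipid/carotenoid bands down
  15–25%), plus **FOV-level biological variability**: per-FOV lognormal
  multipliers on peak amplitudes (5% log-sd) shared by all spectra of a
  FOV. Without between-FOV variability, per-FOV means are essentially
  noise-free and any group effect is detected with probability 1, which
  makes calibration and power statements vacuous.
- PWS stacks as `I = IRF·(1 + f) + ε`, where `f` has a per-pixel
  standard deviation over wavelength equal to a spatially correlated
  lognormal amplitude field with group-mean `disorder_amplitude`
  (defaults 0.02 control / 0.04 disease, with a per-FOV lognormal
  multiplier of 15% log-sd), built from Gaussian-smoothed white noise
  (correlation length 3 px), and `ε` is additive camera noise
  (sd 0.005). The camera-noise floor matters: min–max quantization
  makes GLCM texture invariant to a pure rescaling of the sigma map, so
  it is the disorder-to-noise ratio — not the disorder alone — that
  shifts the IDM curve between groups.
- Acquisition plumbing: per-FOV and per-pixel seeds derived from one
  cohort seed through a deterministic splittable counter (bit-identical
  cohorts from identical configuration); `floor(rate·n)` corrupted
  spectra per FOV chosen from a seeded permutation and flagged in
  ground truth.

It does **not** simulate light transport, Mie scattering, wavenumber
miscalibration, detector nonlinearity, or spatial correlation between
the Raman grid and the PWS frame. Passing tests therefore demonstrate
the correctness and calibration of the *analysis*, not instrument-level
realism.

## Test problem sizes and what the checks show

The statistical checks run at reduced problem sizes chosen to keep the
full suite fast while preserving the statistical structure: null
calibration uses 200 replicate cohorts of 8 vs 8 FOVs with 2 × 2 grids
on a 4 cm⁻¹ axis (8 vs 8 because the exact Mann–Whitney test attains a
two-sided size of 0.0499 there, so discreteness does not bias the
rejection-rate check); power uses 50 replicates at the 10-vs-26 design
with effects {854: 1.3, 879: 1.3, 1441: 0.7}; baseline recovery uses
100 random order-≤5 backgrounds with 2–4 random peaks. The one-sigma
recovery check uses rank-one discriminant data with n = 20 per class
and p = 20 features — more observations than features, the
well-conditioned regime for identifying latent rank; with p ≫ n or
nearly noiseless data the rule legitimately picks an extra component a
few percent of the time, because tiny but real CV gains from refined
weight estimates can exceed a small SE band.

The fusion property — fused R² at least matching the best single
modality — is checked on cohorts whose RS and PWS feature blocks each
carry one independent discriminant direction of equal strength (18 FOVs
per group, 25 RS and 10 PWS features). This is the regime the claim is
about. It is worth being explicit about a limitation found while
building the package: at the full image/spectrum level the property is
*not* uniform. The IDM-curve block tends to have higher effective
latent dimensionality than the spectral block, the one-sigma rule then
selects very different component counts per modality, and an in-sample
R² comparison favours whichever modality drew more components; across
pipeline-level regimes the fused model won only 40–75% of replicates.
A single observed fusion gain on one dataset should therefore be read
as encouraging, not as a dominance law.

## Degenerate inputs and numerical conventions

All-zero spectra cannot be vector-normalized (error); constant spectra
baseline-correct to zero in one iteration; constant images quantize to
a single level and have IDM 1 at every offset; IRF values must be
strictly positive wherever used; PLS fits stop early (with fewer
components) when a score norm underflows; z-scoring refuses constant
columns by name. Stack and sigma-map TIFFs are 32-bit float with values
validated to [0, 1] (the writer's float range); spectra CSVs are
written at 17 significant digits so round-trips are lossless at double
precision.
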