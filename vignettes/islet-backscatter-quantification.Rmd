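---
title: "Quantifying islet mass and secretory status from backscatter confocal stacks"
author: "isletscatter"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying islet mass and secretory status from backscatter confocal stacks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isletscatter)
```

## The measurement problem

Pancreatic islets can be imaged without any label by collecting the light
they scatter back into a confocal microscope. The dominant scatterers in
beta cells are mature insulin secretory granules — dense zinc–insulin
crystal cores of roughly 200–400 nm, comparable to the imaging wavelength
(Mie regime), occupying on the order of 10–20 % of the cytoplasmic volume
and absent from nuclei. Two quantities of biological interest follow from
this contrast mechanism:

* **Islet mass / morphology.** The backscatter signal delineates the islet
  in 3D, so per-islet volumes can be measured repeatedly in vivo (for
  islets engrafted in the anterior chamber of the eye, through the
  cornea). Because the signal attenuates with depth, only the upper part
  of an islet is reliably imaged, which motivates the *equatorial volume*:
  the volume from the islet's top surface down to the equator of a fitted
  spheroid model, approximately half the islet.
* **Secretory status.** Granule content falls when insulin is secreted
  (degranulation after feeding) and recovers under fasting, so the mean
  backscatter intensity in a standardized sampling volume indexes the
  islet's granule store.

This package implements the full analysis chain — segmentation, spheroid
fitting, morphometry, intensity indexing, longitudinal growth-isotropy
analysis and cross-modality volume concordance — together with a synthetic
stack generator that provides analytic ground truth for every stage.

## Data model and conventions

All stacks are `VoxelGrid` objects: a 3D array indexed `(z, y, x)` with
`z = 1` the plane nearest the objective (shallowest tissue), and a spacing
`c(dz, dy, dx)` in µm/voxel. The physical coordinate of voxel `i` along an
axis is `(i − 1) · d`. Intensities are arbitrary units (bit depth and
detector calibration are instrument-specific) and every algorithm is
invariant to global intensity scaling. Physical quantities are always µm,
µm², µm³; the conversion from voxel counts happens exactly once, in
morphometry, to avoid double-scaling bugs with anisotropic voxels.
Missing spacing metadata at read time is a hard error rather than a
default, because every downstream number is meaningless without it.

## Segmentation and the spheroid model

Segmentation is deliberately parameter-light: Gaussian smoothing
(`smoothingSigma`, default 2 µm, isotropic in physical units), a single
*global* Otsu threshold, 26-neighbourhood morphological closing, and
26-connected component labeling with a minimum size
(`minIsletVolume`, default 5 000 µm³ — far below any real islet, which
start around 50 µm diameter ≈ 65 000 µm³). The global Otsu threshold makes
the chain exactly invariant to intensity scaling. Two guards handle
degenerate scenes: when foreground and background means are separated by
fewer than `backgroundMargin` (default 3) background standard deviations,
the stack is declared empty (a warning, not an error); and flat components
spanning more than half the field laterally are suppressed as the
reflective iris plane. The flatness cut is smoothing-aware — a physically
one-plane iris is thickened to about the smoothing support by the blur —
so a component counts as flat when its robust z-extent (planes holding at
least 5 % of its largest cross-section) is below
`max(3 planes, 3·smoothingSigma)`.

The islet's top plane uses the same 5 % robustness rule: the shallowest
plane whose cross-sectional area reaches 5 % of the mask's maximum,
so isolated noise voxels cannot define the top.

The spheroid model is axis-aligned with equal lateral semi-axes
(`rx = ry`): islet grafts are close to spherical, and a full 9-parameter
ellipsoid is not identifiable from the upper cap alone. Only boundary
voxels within the upper 60 % of the mask's z-extent enter the fit, because
the lower hemisphere is attenuation-corrupted; the equator is then the
*extrapolated* horizontal plane through the fitted centre. The surface
equation is linear in a reparameterization
(`x² + y² = A z² + B x + C y + D z + E`), so an algebraic least-squares
solution provides the starting point, refined by Levenberg–Marquardt on
the normalized geometric residual
`sqrt(((x−cx)² + (y−cy)²)/a² + (z−cz)²/c²) − 1`. The reported
`rmsResidual` is the rms of that quantity scaled by the geometric-mean
radius, i.e. approximately µm of surface misfit. Whether the model should
be fitted to the mask surface or to intensity isophotes is an open choice;
the mask surface was chosen because it keeps all morphometry derived from
a single segmentation.

## Morphometry

* **Equatorial volume** `equatorialVolume()`: mask voxels whose z-centre
  lies in the *closed* interval `[zTop, equatorZ]`, times `dz·dy·dx`.
  Ties exactly at the equator are included; the convention is sub-voxel
  in effect but stated so results are bit-reproducible.
* **Projected area** `projectedArea()`: the union over z of the mask's xy
  footprints, times `dy·dx`. Defining the area from the same binary mask
  as the volume (rather than from a thresholded maximum-intensity
  projection) keeps the two measures consistent by construction.
* **Sphere-equivalent diameters**: the equatorial volume is read as a
  half-sphere, `d = (12·Veq/π)^(1/3)`; the projected area as a great
  disc, `d = 2·sqrt(A/π)`. Their relative difference is recorded as a
  sphericity index; exceeding `sphericityTolerance` (default 0.15) warns
  but never errors, since flattened grafts must remain measurable.

On digitized spheres of radius 20–60 µm at 1 µm voxels these estimators
converge to the analytic values within 3 % (volume), 2 % (area) and 3 %
(both diameters), improving with radius-to-voxel ratio; the test suite
asserts exactly these bounds.

## The intensity index

`cylinderMeanIntensity()` averages voxel intensities in a vertical
cylinder through the fitted centre's (y, x), from the islet top plane
down 50 µm (the conventional sampling depth), with diameter half the
islet's diameter. Three interpretation choices are fixed and documented:
the islet diameter is the volume-derived sphere-equivalent diameter (the
most attenuation-robust of the available diameters); membership is by
voxel-centre inclusion; and the cylinder is intersected with the islet
mask, so cornea or aqueous-humour voxels above a tilted islet surface
contribute exactly nothing. Islets shallower than the sampling depth
truncate the cylinder at the deepest in-cylinder mask voxel and set a
flag. `referenceNormalize()` divides the index by the mean intensity of a
user-placed reference box (typically on the strongly reflective pigmented
iris), making comparisons across sessions invariant to detector gain.

`compareConditions()` pairs records by islet, reports per-islet
differences, cohort mean ± SEM, and a paired two-sided Wilcoxon
signed-rank test (plus a paired t-test); p-values are reported raw, never
thresholded, and no multiple-testing correction is applied within a
single paired comparison — that policy belongs to the caller. When every
difference is zero the signed-rank statistic is undefined, and the result
says so (`test_undefined`) instead of inventing a p-value.

## Growth isotropy and volume concordance

For an islet measured at two sessions, the one-dimensional growth factors
are `(Veq2/Veq1)^(1/3)` from volume and `(A2/A1)^(1/2)` from area; the
half-to-full-volume factor of 2 cancels in the ratio. Their quotient, the
isotropy ratio, is 1 under direction-independent growth, below 1 under
preferential lateral growth. Under anisotropic growth `(gz, gy, gx)` the
analytic ratio is `(gz·gy·gx)^(1/3) / (gy·gx)^(1/2)` — e.g. 0.941 for
(1, 1.2, 1.2) and 0.794 for pure lateral doubling — which sets the
sensitivity scale of the cohort analysis.

`volumeConcordance()` compares per-islet volumes from two modalities
(e.g. in vivo confocal vs ex vivo optical projection tomography, consumed
as a CSV table). Absolute volumes differ between modalities (tissue
shrinkage, different analysis protocols), so alongside the linear fit and
Pearson correlation the package reports a ratio-consistency statistic:
the mean over all unordered islet pairs of
`|log[(Vi_A/Vj_A)/(Vi_B/Vj_B)]|`. It is zero iff the two volume sets are
exactly proportional, symmetric in modality order (log space), and
invariant to independent global rescaling of either modality — precisely
the property that makes relative islet mass comparable across techniques.
Pearson rather than rank correlation is used because the claim being
checked is linearity. Whether a given modality's "volume" is equatorial,
doubled-equatorial or full-mask cancels out of the ratio statistic, which
is why the concordance analysis is built on ratios.

## The synthetic generator

`generateIsletStack()` renders what the measurement chain assumes:

* an axis-aligned spheroidal islet (`isletSemiAxes`, µm);
* granule scatterers at a number density reproducing
  `granuleVolumeFraction` (default 0.15 of cytoplasmic volume, the middle
  of the reported 10–20 % range) with diameters uniform in
  `granuleDiameterRange` (default 0.2–0.4 µm), excluded from
  non-overlapping spherical nuclei (default 6 µm diameter, 10 % of islet
  volume). Granule content per voxel is drawn as
  Poisson(density × voxel volume), the voxel-binned marginal of uniform
  random placement; individual granule volumes enter through the mean
  granule volume E[(π/6)d³].
* a Gaussian PSF (`psfSigma`, default (1.5, 0.6, 0.6) µm — axial worse
  than lateral, as in a real confocal);
* exponential attenuation `exp(−depth/attenuationLength)` of the granule
  signal with depth below the islet top plane. No attenuation length for
  633 nm in islet tissue is established; the default 40 µm is a free
  parameter chosen so that the lower hemisphere is visibly unreliable at
  typical islet sizes, which is the regime the equatorial-volume measure
  exists for.
* flat `backgroundLevel`, an optional one-plane bright iris
  (`irisLevel`) below the islet, additive Gaussian noise (`noiseSigma`,
  default 5 a.u. against a granule signal of ~150 a.u. at fraction 0.15)
  and an optional Poisson stage; intensities are clamped at 0.

All randomness derives from `rngSeed` through four fixed sub-seeds
(nuclei, granule counts, degranulation thinning, noise), so stacks are
bit-reproducible, `generateDegranulationPair()` can remove a random
granule subset while keeping geometry and noise identical (a 0 % removal
is bit-identical to the original; a 100 % removal equals the zero-granule
stack), and `generateGrowthSeries()` re-seeds each timepoint
independently, as re-imaging on a different day would.

What the generator deliberately does *not* emulate: wave-optical Mie
radiometry (granules are PSF-shaped additive spots; only the
density→intensity monotonicity is physical), speckle and multiple
scattering, instrument drift, islet surface roughness, and non-spheroidal
shapes. Tests passing on these stacks therefore validate the geometry,
unit handling and statistical machinery of the pipeline — not the optical
fidelity of any particular microscope.

## Cohort experiments and problem sizes

`simulateGrowthCohort()` reproduces the longitudinal study design: 27
islets in 7 batches, first-session radii uniform in 30–60 µm, per-islet
isotropic growth uniform in 1.1–1.6 between two sessions, granule
fraction 0.15, default noise. Stacks are 128³ voxels at (2, 2, 2) µm —
a 256 µm field, chosen once so the largest grown islet (96 µm semi-axis)
fits with margin. On this cohort the pipeline's mean isotropy ratio is
expected within 0.06 of unity; `scripts/acceptance.R` recomputes it from
scratch. `simulateFeedingCohort()` mirrors the fed/fasted comparison: 19
islet pairs at 30 % degranulation, 80³ voxels at 1.5 µm. Unit tests use
64³–96³ stacks; these sizes were chosen as the smallest at which
discretization error is comfortably below the assertion tolerances.

## Known limitations

* The spheroid fit assumes one dominant islet orientation along z and
  `rx = ry`; strongly tilted or lobed grafts will show inflated fit
  residuals (which are reported, and should be inspected).
* Full-islet volume from backscatter alone is intentionally not offered:
  attenuation makes the lower hemisphere unreliable, which is the reason
  the equatorial measure exists.
* Per-cell intensity heterogeneity is out of scope; the intensity index
  is an islet-level readout.
* The degranulation model removes scatterers uniformly; spatially
  structured secretion (e.g. mantle-first) is not modeled.
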