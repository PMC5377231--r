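# isletscatter

Label-free quantification of pancreatic islets from backscatter
(reflectance) confocal microscopy stacks.

Mature insulin secretory granules — dense zinc–insulin crystal cores of
~200–400 nm occupying ~10–20 % of beta-cell cytoplasm — scatter incident
laser light strongly (Mie regime), so islets can be imaged in 3D with no
stain, repeatedly and in vivo. This package turns such stacks into
numbers, for researchers monitoring islet mass and secretory function
(e.g. islets engrafted in the anterior chamber of the eye):

* **Segmentation + spheroid model.** Gaussian smoothing, global Otsu
  threshold, 3D connected components; an axis-aligned spheroid
  (rx = ry) is least-squares fitted to the upper-cap boundary — depth
  attenuation corrupts the lower hemisphere — and its centre plane
  defines the islet equator.
* **Morphometry.** Equatorial volume V<sub>eq</sub> (mask voxels from
  the islet top down to the equator, ≈ half the islet), projected area
  A (union of xy footprints), and sphere-equivalent diameters
  d<sub>vol</sub> = (12·V<sub>eq</sub>/π)<sup>1/3</sup> and
  d<sub>area</sub> = 2·√(A/π); their agreement indexes sphericity.
* **Secretory-status index.** Mean intensity in a vertical cylinder of
  50 µm length from the islet top, diameter half the islet diameter,
  restricted to the islet mask; optional normalization to an iris
  reference region. Paired fed/fasted comparisons with Wilcoxon
  signed-rank statistics.
* **Longitudinal growth isotropy.** Per-islet 1D growth factors
  (V<sub>eq,2</sub>/V<sub>eq,1</sub>)<sup>1/3</sup> and
  (A₂/A₁)<sup>1/2</sup>; their ratio is 1 under direction-independent
  growth.
* **Cross-modality concordance.** Linear fit, Pearson r, and a
  rescaling-invariant ratio-consistency statistic (mean absolute
  pairwise log-ratio discrepancy) between volume tables from two
  modalities.
* **Synthetic ground truth.** A generator rendering spheroidal islets
  with granule scatterers (nucleus-excluded), PSF blur, exponential
  depth attenuation, iris plane and detector noise — bit-reproducible,
  with analytic truth for every measure — so the entire pipeline is
  testable without a microscope.

## Worked example

```r
library(isletscatter)

# simulate a 40 um-radius islet with 15% granule volume fraction
cfg <- syntheticConfig(rngSeed = 7, dim = c(96L, 96L, 96L),
                       spacing = c(1, 1, 1),
                       isletSemiAxes = c(40, 40, 40))
out <- generateIsletStack(cfg)
out$truth
#> GroundTruth: total volume 2.681e+05 um^3, equatorial 1.34e+05 um^3,
#>   projected area 5027 um^2, granule fraction 0.150

res <- analyzeStack(out$grid)
res$records[, c("equatorial_volume_um3", "projected_area_um2",
                "diameter_from_volume_um", "diameter_from_area_um")]
#>   equatorial_volume_um3 projected_area_um2 diameter_from_volume_um diameter_from_area_um
#> 1                127030               4966                 78.5801              79.51671
```

The measured equatorial volume (1.27 × 10⁵ µm³) sits within 5 % of the
analytic half-sphere volume (1.34 × 10⁵ µm³; segmentation trims the
blurred rim slightly), the projected area within 2 % of π·40², and the
two sphere-equivalent diameters agree within ~1 % — the islet is
spherical — and both are within 2 % of the true 80 µm diameter.

A command-line front end with `simulate`, `segment`, `measure`,
`intensity`, `growth` and `concordance` subcommands is installed at
`inst/scripts/isletscatter-cli.R`:

```sh
Rscript inst/scripts/isletscatter-cli.R simulate --seed 7 --out islet.ome.tif
Rscript inst/scripts/isletscatter-cli.R measure --in islet.ome.tif --out morphometry.csv
```

## Vignette

`vignettes/islet-backscatter-quantification.Rmd` documents the model
assumptions, parameter choices, numerical conventions and limitations.
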