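# endoquant

Ratiometric quantification of membrane-protein density on endocytic
vesicles, relative to the plasma membrane, from multi-channel confocal
images — with a ground-truth synthetic image generator for validating the
whole pipeline, BRET (bioluminescence resonance energy transfer) ratio
analytics, and the accompanying statistical tests.

## Who this is for

Cell biologists and imaging analysts who ask: *what fraction of its
plasma-membrane density does a membrane protein retain on endocytic
vesicles?* Raw fluorescence cannot answer this — a sub-resolution vesicle
packs an unknown amount of membrane surface into the imaging volume. The
package implements the lipophilic-dye-normalized estimator that divides
that geometry out: co-stain with a membrane surface-area standard (an
FM4-64/CellMask analog, which enters newly internalized vesicles at
PM-equal density), measure both channels identically, and form

```
D = (peak_prot/PM_prot − bg_prot/PM_prot) / (peak_dye/PM_dye − bg_dye/PM_dye)
```

per vesicle, where `peak` is the maximum of a 3 µm line profile across the
vesicle, `PM` is the same peak operator applied to a nearby
plasma-membrane crossing, and `bg` is nearby cytosol. Numerator and
denominator share geometry and optics, so vesicle size, PSF width and
per-channel gain cancel: `D` estimates the protein's vesicle membrane
density as a fraction of its PM density. Datasets are summarized as
mean ± t-based 95% CI.

Because the estimator is validated by parameter recovery, the package
ships a full forward model: circular cells with nucleus, cytosol and
vesicles whose membranes carry known per-channel densities, rendered
through a Gaussian PSF with Poisson/read noise, plus experiment presets
that emulate three study conditions (constitutive endocytosis, ρ = 0.20,
n = 45; receptor-positive vesicles, ρ = 0.28, n = 91, with a ~3× enriched
receptor channel; a lipid-anchored control probe, ρ = 0.64, n = 78).

## Worked example

```r
library(endoquant)
ex <- run_experiment("constitutive", seed = 5)
ex
#> <eq_experiment> preset 'constitutive' (seed 5, config 3a228724)
#> Density ratio: 16 +/- 6.25 (mean +/- 95% CI; n=45)
#>   (percent of plasma-membrane density)
head(ex$measurements[, c("vesicle_id", "density_ratio", "truth_rho_protein")], 3)
#>   vesicle_id density_ratio truth_rho_protein
#> 1    c001_v1       0.00228             0.000
#> 2    c002_v1       0.00306             0.000
#> 3    c003_v1       0.28229             0.276
```

This simulates 45 cells (one measured vesicle each) at a true mean density
of 20% with realistic vesicle-to-vesicle heterogeneity — note the vesicles
with no detectable protein, which are measurements of 0, not failures —
then runs the full measurement pipeline. This particular dataset happens to
draw low (16 ± 6.3%): a single 45-vesicle dataset has a CI half-width of
roughly ±7–8 percentage points, and the interval covers the true 20%.
Pooling replicate datasets (as `scripts/acceptance.R` does) recovers the
truth to well under a point. `confint(ex)` and `coef(ex)` expose the
interval and point estimate.

Individual stages are available directly: `build_cell_geometry()`,
`place_vesicles()`, `render_image()`, `write_dataset()`/`read_dataset()`
(multi-page TIFF + ground-truth JSON), `extract_line_profile()`,
`pm_reference()`, `vesicle_density_ratio()`, `enrichment_ratio()`,
`summarize_density()`, `measure_sb()`. BRET: `raw_bret()`, `net_bret()`,
`agonist_delta()`, `simulate_kinetic_trace()`,
`simulate_bystander_study()`, `paired_t_fdr()` (two-stage
Benjamini–Krieger–Yekutieli at 1% FDR), `unpaired_t()`. A thin CLI wraps
the same functions: `inst/cli/endoquant run --preset constitutive --seed 1
--out results/`.

See `vignettes/density-quantification.Rmd` for the model, conventions and
their rationale.

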