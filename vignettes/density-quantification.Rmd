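---
title: "Quantifying membrane protein density on endocytic vesicles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying membrane protein density on endocytic vesicles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(endoquant)
```

## The measurement problem

A fluorescently tagged membrane-associated protein (here, the Gβ₁ subunit of
heterotrimeric G proteins, or a lipid-anchored control probe) is visible both
on the plasma membrane (PM) and on endocytic vesicles in confocal sections.
Comparing raw intensities between these structures does not compare protein
*density*: a sub-resolution vesicle contributes however much membrane its
surface packs into the imaging volume, while a PM crossing contributes a
single membrane sheet. The amount of membrane sampled must be divided out.

The solution is ratiometric: co-stain with a lipophilic dye (an
FM4-64/CellMask analog) that partitions into membranes and therefore reports
membrane *surface area* at a density that is the same on the PM and on newly
internalized vesicles. For each vesicle, both channels are measured the same
way and each is normalized to its own PM signal; the quotient of the two
normalized, background-subtracted peak signals,

$$
D \;=\;
\frac{\;\mathrm{peak}_{\mathrm{prot}}/\mathrm{PM}_{\mathrm{prot}}
      \;-\; \mathrm{bg}_{\mathrm{prot}}/\mathrm{PM}_{\mathrm{prot}}\;}
     {\;\mathrm{peak}_{\mathrm{dye}}/\mathrm{PM}_{\mathrm{dye}}
      \;-\; \mathrm{bg}_{\mathrm{dye}}/\mathrm{PM}_{\mathrm{dye}}\;},
$$

estimates the protein's surface density on the vesicle membrane as a
fraction of its PM density. Because numerator and denominator share the
same geometry and the same optics, vesicle size, point-spread function
(PSF) width, and per-channel detector gain all cancel. The package
implements this estimator, a synthetic-image generator that provides ground
truth for validating it, the BRET analytics used in the companion
plate-reader experiments, and the statistical layer (t summaries, unpaired
t, paired t with two-stage Benjamini–Krieger–Yekutieli FDR control).

## Forward model of the synthetic generator

A simulated cell is a circular PM contour (default radius 7.5 µm) enclosing
a circular nucleus (3.5 µm) in a 20 µm field. Membranes are one-dimensional
curves carrying line densities (photons per µm of membrane): the PM at a
per-channel level, and each vesicle — a circle of radius 0.25–0.6 µm, the
equatorial section of a sphere — at a per-channel fraction ρ of the PM
density of the same channel. The reference dye has ρ = 1 by definition
(surface area at PM-equal density). Cytosol is an area source (photons per
µm²) filling the cell interior outside the nucleus; it is *not* excluded
under vesicle footprints, because in a confocal section the cytosol above
and below a sub-micron vesicle still contributes. Vesicle lumens default to
dark (the dye is membrane-partitioned) but accept a `lumen_level` for
lysosome-like content.

Rendering rasterizes these sources at 0.1 µm/px (bilinear splatting of
finely spaced arc samples), convolves with an isotropic Gaussian PSF
(default σ = 0.15 µm, plausible for a 63×/1.40 NA objective at ~500–700 nm),
and applies the detector model: Poisson shot noise on the expected photon
count, additive Gaussian read noise (σ = 2 counts), rounding, and clipping
to 16 bits. Pixel size, PSF width, and detector gain are not stated for the
source experiments; the defaults here are declared assumptions, chosen once
for realism, with PM peaks around 2500 counts (protein channel) and 4000
counts (reference dye) and dim cytosol (~80 and ~25 counts respectively) —
endogenous-expression imaging is photon-limited but usable.

Two exact properties follow from the construction and are enforced by the
test suite:

* **Geometry cancellation.** With zero background, the noiseless protein
  and dye planes of a shared structure are proportional pixel-for-pixel, so
  the measured $D$ equals ρ to machine precision for *any* PSF width and
  vesicle radius. This is what makes the estimator geometry-free.
* **Conservation under blur.** The PSF kernel is normalized, so total
  photon rate per channel is invariant to σ.

## Measurement conventions

The measurement layer mirrors an ImageJ-style manual workflow, with each
ambiguity resolved once and fixed:

* **Line profiles** are 3 µm long, centred on the vesicle, sampled at the
  pixel pitch by bilinear interpolation and averaged across a 0.3 µm line
  width. The default orientation is tangential (maximizing distance of the
  line ends from the PM); on real data the angle is caller-supplied.
* **Peak** means the maximum within the central third of the profile, so
  line ends cannot capture the PM or neighbouring structures. No
  pre-smoothing is applied before peak picking — smoothing biases the peaks
  of small vesicles, and robustness comes from averaging across vesicles.
* **PM reference**: the peak of a 3 µm profile drawn across the nearest PM
  segment, i.e. the same operator applied to the PM, so both structures are
  treated symmetrically. (A mean-over-segment alternative would change only
  a per-channel scale factor, which cancels in $D$.)
* **Background**: the mean of a 0.3 µm-radius disc of nearby cytosol,
  placed deterministically at the candidate position with the largest
  clearance from PM, nucleus and all vesicles. Signal and background are
  both normalized by the PM reference and then subtracted — algebraically
  identical to subtract-then-normalize, fixed for reproducibility.
* **Negative protein numerators are clipped to 0**, not discarded: a
  vesicle with no detectable protein is a legitimate measurement of zero,
  and discarding such vesicles would bias the mean upward.
* An unmeasurable *reference* numerator (no membrane signal) is an error:
  without dye signal there is no vesicle to measure.
* **Summary**: mean with a Student-t two-sided 95% CI
  ($t_{0.975,\,n-1}\,s/\sqrt{n}$), the standard small-sample choice for
  "mean ± 95% CI".
* Signal/background ratios use a 1.5 × 0.4 µm rectangle across the PM, a
  disc of radius (vesicle radius + 0.25 µm) around each vesicle, and 0.3 µm
  cytosol background discs. The rectangle hugs the blurred membrane (FWHM
  ≈ 0.35 µm at the default PSF); the vesicle disc "surrounds the structure"
  as in the source workflow.

## Emulated study conditions

The experiment presets fix ground truth, sample size and channels:

| preset | ρ (mean) | per-vesicle sd | n cells | extra channel |
|---|---|---|---|---|
| `constitutive` | 0.20 | 0.2663 | 45 | — |
| `receptor` | 0.28 | 0.3841 | 91 | receptor, ρ ≈ 3.0 (sd 1.2) |
| `hras_ct` | 0.64 | 0.7540 | 78 | — |

One vesicle is measured per cell (each cell contains five, so blur tails
from neighbours — which share ρ and therefore cancel — are present).
Vesicle-to-vesicle heterogeneity is drawn from a normal clipped at zero,
moment-matched to the target mean and sd; the atom at zero reproduces the
observation that a sizeable fraction of vesicles carries no detectable
protein (~44% under the constitutive condition). The per-vesicle sd values
are calibrated so that a dataset's 95% CI half-width reproduces the
reported intervals (±8, ±8 and ±17 percentage points):
$s = h\sqrt{n}/t_{0.975,n-1}$. The receptor channel's enrichment spread
(sd 1.2, CV 0.4) is a realism choice; only its mean (~3×) is a stated
condition.

What the generator does *not* emulate: 3-D optics and axial sectioning,
spectral bleed-through, chromatic offsets, membrane ruffles and non-circular
cell outlines, vesicle motion, and photobleaching. Passing recovery tests
therefore show that the estimator and its implementation are correct under
the stated forward model — not that real images are free of those
confounds.

## BRET analytics and simulation

Raw BRET is the acceptor-window (520–545 nm) count divided by the
donor-window (475–495 nm) count; net BRET subtracts the raw ratio of
donor-only cells. Spectral windows are treated as pre-integrated counts, as
plate readers report them. Kinetic traces relax exponentially to a new
steady state after each injection (time constants configurable). Bystander
panels are simulated at the well level — net signal = amplitude ×
colocalization fraction + noise — with the amplitude an explicitly free
scale: bystander signals are not comparable across compartments, so only
within-compartment contrasts are simulated and tested. The paired study
simulator reproduces the paired design: each independent experiment carries
control, all agonist conditions and one shared donor-only set, so the
donor-only correction noise cancels from paired contrasts (this is the
reason paired t-tests are the right analysis, and a study-level simulation
with per-condition donor-only wells would *fail* to control the FDR).

The source panels are graphical; no numeric BRET value is treated as a
quantitative target. Default compartment fractions (PM 1.0, RE 0.30,
EE 0.25, LE 0.20, ER 0.03, MT 0.02) encode the qualitative ordering only.

## Statistical layer

The unpaired t is the classical pooled-variance test (the source states
only "unpaired t-test"; Welch is available via `var_equal = FALSE`). The
two-stage Benjamini–Krieger–Yekutieli procedure is implemented directly —
first-stage Benjamini–Hochberg at $q' = q/(1+q)$ to estimate the number of
true nulls, second stage at $q'm/m_0$ — rather than through a generic
wrapper, so that its oracle test against an independent implementation is
meaningful. Tests confirm the two-sided type-I error of the pooled t
(0.04–0.06 at α = 0.05 over 10⁴ null replicates) and FDR control of the
full simulate → net → paired-t pipeline under the global null (≤ 1% plus
Monte-Carlo margin at q = 1%).

## Numerical choices and degenerate inputs

* Rasterized membranes are deposited by bilinear splatting; together with
  bilinear profile reads this smooths measurements by an effective
  $\sigma_{\mathrm{eff}} = \sqrt{\sigma^2 + p^2/3}$ (pixel pitch $p$).
  The smoothing is identical in all channels, so it cancels in $D$; oracle
  tests against the closed-form blurred circle use $\sigma_{\mathrm{eff}}$
  with 5% slack for residual grid alignment.
* FFT convolution leaves O(10⁻¹²) negative ripple; the field is clamped at
  zero before Poisson sampling.
* Ground-truth JSON is serialized with 17 significant digits so that
  re-rendering from stored truth and seed reproduces rasters bit-exactly.
* All randomness is seeded: scenes and noise take explicit seeds, and
  experiment runs derive per-cell seeds as `master × 1000 + cell`, recorded
  in the outputs together with a config hash.
* Degenerate inputs error early with the offending field named: nucleus not
  smaller than the cell, vesicles that cannot be placed within the retry
  budget (reporting the achieved count), lines leaving the image, all-zero
  PM references, zero donor counts, mismatched paired replicates, n < 2
  summaries.

## Problem sizes used by the shipped checks

The test suite recovers each preset over 50 independent replicate datasets
and checks that the dataset CI covers the true density at its nominal rate
(with a binomial Monte-Carlo allowance: observed coverage ≥ 0.88 at 50
replicates for a nominal 0.95 property). `scripts/acceptance.R` reports
each condition's mean density pooled over 40 replicate datasets — chosen so
the Monte-Carlo standard error of the reported percentage is ~0.6 points —
and the FDR null simulation uses 600 studies. These sizes are the package's
own reporting choices and can be scaled up by editing one constant each.

## Known limitations

* The 2-D single-section forward model is exact for the estimator's
  geometry-cancellation argument but cannot probe axial-sectioning effects
  on real data.
* The PM reference convention (profile peak) differs from a mean-over-ROI
  reading of the source description ("mean intensity of a nearby section");
  the two differ by a per-channel scale that cancels in $D$, but absolute
  per-channel normalized profiles would differ.
* Peak-of-noisy-profile estimators carry a small positive max-bias at low
  photon counts; at the default brightness this is ≲ 1 percentage point and
  is included in what the recovery tests validate.
* The bystander simulator's compartment fractions and amplitude are free
  parameters; no absolute BRET value should be read quantitatively.
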