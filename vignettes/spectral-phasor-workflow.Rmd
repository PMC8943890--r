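---
title: "Phasor-based segmentation and lipid droplet quantification for hyperspectral SRS microscopy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phasor-based segmentation and lipid droplet quantification for hyperspectral SRS microscopy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srsphasor)
```

## The measurement and the model

Hyperspectral stimulated Raman scattering (SRS) microscopy acquires one
image per Raman shift while the pump laser is retuned in fixed steps,
yielding a 3D block in which every pixel carries a vibrational spectrum.
In the CH-stretch window (2800--3050 cm^-1^, nominally 40 channels at
~6.4 cm^-1^ spacing) the informative bands are the CH~2~ symmetric stretch
at 2851 cm^-1^ (lipids), the CH~2~ asymmetric stretch at 2880 cm^-1^, the
CH~3~ symmetric stretch at 2930 cm^-1^ (protein), a band near 2965 cm^-1^
associated with cholesteryl esters (CE), and the unsaturated =CH stretch
near 3015 cm^-1^ associated with triacylglycerols (TAG).

The spectral phasor transform reduces each pixel spectrum $I_k$
($k = 0, \dots, N-1$ the channel index, $T = \sum_k I_k$) to two
normalised first-harmonic Fourier coefficients,

$$G = \frac{1}{T}\sum_k I_k \cos\!\frac{2\pi n k}{N}, \qquad
  S = \frac{1}{T}\sum_k I_k \sin\!\frac{2\pi n k}{N},$$

with harmonic $n = 1$ by default. Because the coordinates are normalised
by $T$, the phasor depends only on spectral *shape*: pixels with similar
spectra cluster at the same (G, S) location regardless of brightness, and
the transform of a sum of spectra is the intensity-weighted mean of the
component phasors (the mixing rule). Non-negative spectra always land in
the unit disk. Raw intensities are used directly -- no smoothing,
baseline removal or normalisation -- which is what makes the transform a
faithful, parameter-free front end for segmentation.

Three conventions matter for portability of ROI coordinates and are fixed
in this package:

* the Fourier kernel runs over the *channel index*, not the wavenumber
  value, which is why `wavenumber_axis()` enforces near-uniform spacing
  (spacing deviations under 10% of the mean step);
* $S$ uses $+\sin$, so a spectrum concentrated in the first channel maps
  to $(1, 0)$;
* pixels with non-positive spectral sum (possible in noisy background,
  where the detector noise model allows negative excursions) are marked
  *invalid* and excluded from histograms and segmentation, rather than
  clamped; clamping would smear noise-dominated background across the
  phasor plane and contaminate the compartment clusters.

Segmentation then happens entirely in the phasor plane: labelled regions
(axis-aligned boxes or polygons, `roi_rect()` / `roi_polygon()`) select
clusters, every valid pixel is assigned the first ROI (in list order)
containing its (G, S) -- boundaries closed, first-listed ROI winning
overlaps -- and the labels are mapped back to image space. The manual
ROI-drawing step of interactive phasor tools is replaced by
`default_phasor_rois()`, which centres a box of half-width 0.05 (phasor
units) on each compartment's noiseless template phasor position, making
the segmentation fully scripted and reproducible.

## The quantification endpoints

Four phenotype metrics are computed from a segmented stack
(`quantify_stack()`):

* **Percent droplet area** (`percent_area()`): droplet-class pixels inside
  the cell mask as a percentage of cell-mask area. The cell mask is the
  Otsu threshold of the average intensity projection. Only the droplet
  class counts -- the droplet-periphery class is a mixed-spectrum boundary
  shell and is deliberately excluded; the cell footprint includes nuclei.
* **TAG/CE peak ratio** (`peak_ratio()`): the 3015/2965 cm^-1^ height
  ratio of the *un-normalised* droplet-class mean spectrum, with each
  height linearly interpolated between the two flanking channels (the
  ~6.4 cm^-1^ sampling does not land on either wavenumber exactly). A
  value near 0.75 indicates TAG-dominant droplet composition. The ratio is
  computed from the class mean spectrum rather than per droplet: the mean
  over hundreds of pixels suppresses channel noise, and a per-droplet
  variant can be built from `render_segmented_image()` masks if needed.
* **Percent droplet-positive cells** (`percent_cells_with_droplets()`):
  cells whose footprint contains at least `min_droplet_px = 4`
  droplet-class pixels, a guard against isolated misclassified pixels.
* **Per-cell mean intensity** (`per_cell_mean_intensity()`): projection
  intensity averaged over each cell instance, the per-cell CH~2~ signal
  readout of a maximum-intensity Z-projection.

Dose series are summarised by `dose_response_table()`: per-condition mean
and sample SD, plus a two-tailed pooled-variance Student's t-test of each
dose's percent-area replicates against the control. The pooled (not
Welch) form matches the equal replicate design (n = 3 per condition);
stars are `*` for $P \le 0.05$ and `**` for $P \le 0.01$. No
multiple-testing correction is applied across doses -- each dose is
reported with its own star, which is the convention this report format
follows; readers comparing many doses should keep that caveat in mind.

## The synthetic phantom and what it does (not) emulate

No public numerically-accessioned raw data accompany the imaging study
this workflow targets, so validation is built on seeded phantoms
(`generate_phantom()`) with exact ground truth. A phantom is a field of
elliptical cells (default eight cells of 24--30 px by 17--22 px semi-axes
in a 256 x 256 field), each with a disc nucleus (42% of the minor
semi-axis) containing one or two nucleoli, cytoplasmic lipid droplets
(discs of 2--3 px radius, Poisson-distributed count per cell with mean
`droplet_density`), a 1 px droplet-periphery annulus, a 2 px
cell-periphery annulus, and background elsewhere. Label codes are fixed:
0 background, 1 cytoplasm, 2 nucleus, 3 nucleolus, 4 cell periphery,
5 droplet periphery, 6 droplet.

Every compartment has a spectral template (baseline plus Gaussian bands;
`default_templates()`). The shapes follow the qualitative CH-stretch
signatures of cellular compartments -- protein compartments dominated by
2930 cm^-1^ with a 2880 shoulder and weak 2851 signal, droplets dominated
by 2851/2880 with CE and =CH bands -- without claiming quantitative
fidelity to any particular cell line. Two choices are calibrated, both at
template-construction time and never per-dataset:

* the droplet =CH amplitude is solved in closed form
  (`calibrate_tag_band()`) so the evaluated 3015/2965 height ratio is
  exactly 0.75, the literature value for TAG-dominant droplets; recovery
  of this number through segmentation and interpolation is then a genuine
  end-to-end test, and linear interpolation on the 6.4 cm^-1^ grid biases
  it by under 0.5%;
* amplitudes and baselines are set so that the seven template phasor
  positions are mutually separated by at least ~0.11 (infinity norm) in
  phasor units while every compartment keeps enough total intensity that
  its phasor scatter at the acceptance operating points stays well inside
  the 0.05 ROI half-width, and so that cell compartments remain brighter
  than background in the average projection (the Otsu cell mask needs
  that contrast). This coupling is intrinsic to phasor analysis --
  normalisation makes cluster spread scale with noise over *total*
  intensity -- and is why the solvent/non-resonant background baseline is
  set relatively high (0.59 against a droplet peak of ~1.15): dim
  background pixels would otherwise scatter across the whole phasor
  plane. The same effect is present in real SRS data, where background
  pixels carry appreciable non-resonant signal and form a tight cluster
  near the origin.

The periphery classes are rendered as fixed mixtures: droplet periphery
as 50/50 droplet + cytoplasm, cell periphery as 70/30 cytoplasm +
background. By the mixing rule their phasors sit on the segment between
the parent clusters; the 70/30 cell-edge weighting keeps that cluster
clear of both the cytoplasm and the droplet boxes. Periphery pixels are
genuinely ambiguous mixtures, so compartment-recovery statements in the
tests are made over the five pure classes.

Noise is additive zero-mean Gaussian with standard deviation
`max(droplet template)/snr`; at the powers used for live-cell SRS the
laser/shot noise floor is well approximated as additive and
signal-independent, and a single `snr` knob makes operating points
explicit. The default is `snr = 20`, a mid-range value for this kind of
acquisition; validation additionally uses `Inf` (noiseless) and 10.
What the phantom does *not* emulate: optical point-spread blur, spatial
noise correlation, intensity inhomogeneity across the field,
out-of-focus light and true 3D sectioning (Z-stack phantoms place each
droplet in a single focal plane over a constant cell body), cell-to-cell
spectral variability, and touching/overlapping cells. Passing the test
suite therefore demonstrates correctness of the *algorithms* under a
known forward model, not instrument-level robustness on real
acquisitions.

## The simulated dose-response study

`generate_dose_series()` emulates a statin dose-response experiment:
atorvastatin-like doses (0, 0.5, 1, 5, 10, 25 uM) with droplet-density
multipliers (1, 1, 1, 3, 5, 6) -- no accumulation at sub-threshold doses,
then a steep rise -- three replicate fields per dose, and per-phantom
seeds derived deterministically from (master seed, dose index,
replicate). The dose-response validation runs this at 288 x 288 px with
ten cells per field so that Poisson counting noise on ~100 droplets per
field leaves the expected ordering of the top doses detectable from three
replicates; the statistical endpoint is a monotone non-decreasing mean
percent area across the top three doses plus a significant
($P \le 0.05$) pooled-t comparison of the top dose against control.

## Numerical choices and degenerate inputs

* Stacks are written as 64-bit float multi-page TIFF with a YAML axis
  sidecar, so write/read round trips are bit-exact even for negative
  noise excursions; standard 8/16/32-bit TIFFs are read via `libtiff`.
* Otsu thresholding (256-bin between-class variance maximisation) is the
  automatic threshold; a constant image has no Otsu threshold and raises
  an error rather than guessing.
* In ratio images, pixels with non-positive denominator map to 0
  (background semantics) instead of NaN/Inf, keeping area arithmetic
  downstream well defined; ratio values are stored unclipped and the
  0--0.8 display range is metadata only.
* Min-max normalisation of a constant ROI spectrum returns all zeros by
  convention.
* A t-test on two groups with zero pooled variance returns $t = 0,
  p = 1$ when the means agree (and $\pm\infty, p = 0$ otherwise) instead
  of failing.
* Cell instances come from ground truth when available; otherwise from
  8-connected components of the cell mask (diagonally touching pixels
  connect). Droplet placement uses rejection sampling (droplets must lie
  wholly in cytoplasm of their cell) with a bounded retry count; an
  over-packed request fails loudly rather than silently under-filling.
* Phasor histogram bins are half-open on $[-1, 1)^2$ with the last bin
  closed; out-of-square coordinates (only possible with negative spectra)
  are clamped into edge bins so counts are conserved.

## Problem sizes used in validation

Unit tests run on 96 x 96 two-cell phantoms and small random arrays. The
end-to-end checks use the full default geometry: single 256 x 256 x 40
phantoms for segmentation recovery (noiseless and snr = 10), droplet-load
recovery across ~0--10% area fractions, TAG-ratio recovery, and ten
independent 6-dose x 3-replicate series at 288 x 288 for dose-response
detection. These sizes keep a complete run to a few minutes while leaving
Poisson and detector noise realistically visible in the statistics.

## Known limitations

* ROI boxes are placed at *template* phasor positions; on real data the
  cluster centres must be located from the phasor histogram (the package
  supports arbitrary rectangles/polygons for exactly that, but does not
  auto-locate clusters).
* The TAG/CE ratio is reported from the droplet-class mean spectrum; with
  very few droplet pixels the interpolated heights become noisy and the
  pipeline reports `NA` when a field contains no droplet pixels at all.
* First-harmonic phasors project a 40-channel spectrum to two numbers;
  compartments with genuinely similar CH-band shapes may overlap, and no
  second-harmonic disambiguation is implemented.
* The statistical layer implements exactly the per-dose pooled-t
  convention of the report format it mirrors; it is not a general
  dose-response modelling tool (no trend tests, no multiplicity
  control).
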