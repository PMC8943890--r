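# srsphasor

Label-free drug phenotyping from hyperspectral stimulated Raman scattering
(SRS) microscopy, built around the spectral phasor transform.

## The problem

Statins perturb lipid metabolism in cancer cells, and the resulting lipid
droplet accumulation can be imaged label-free by SRS microscopy in the
CH-stretch region (2800–3050 cm⁻¹): lipids report at 2851/2880 cm⁻¹
(CH₂ stretches), protein at 2930 cm⁻¹ (CH₃), cholesteryl esters near
2965 cm⁻¹ and unsaturated triacylglycerol =CH near 3015 cm⁻¹. A
hyperspectral stack gives every pixel a vibrational spectrum; the analysis
problem is to segment cellular compartments from those spectra — without
dyes, manual outlining, or per-dataset tuning — and to quantify
dose-dependent lipid droplet load across treatment conditions. This
package is for microscopists and image analysts who need that chain as
tested, scriptable R functions rather than interactive plug-in clicks.

## The method

Each pixel spectrum `I_k` (`k = 0…N−1`, `T = Σ I_k`) is reduced to its
normalised first-harmonic Fourier coefficients

```
G = Σ_k I_k cos(2πnk/N) / T,   S = Σ_k I_k sin(2πnk/N) / T   (n = 1)
```

so spectrally similar pixels cluster at the same (G, S) regardless of
brightness, non-negative spectra stay inside the unit disk, and mixtures
obey the intensity-weighted mixing rule. Labelled phasor-plane regions
(boxes/polygons) assign each valid pixel a compartment — nucleus,
nucleoli, cytoplasm, cell periphery, lipid droplets, droplet periphery,
background — and the labels map back to image space. Downstream
quantification reproduces the standard phenotype readouts: percent
droplet area of total cell area (cell mask = Otsu threshold of the
average intensity projection), the 3015/2965 cm⁻¹ TAG/CE peak ratio of
the droplet-class mean spectrum (linear interpolation between flanking
channels; ≈0.75 for TAG-dominant droplets), percent droplet-positive
cells, per-cell projection intensities, and per-dose pooled-variance
Student's t-tests against control (`*` P ≤ 0.05, `**` P ≤ 0.01).

Because the raw microscopy of such studies is generally not deposited in
reusable numeric form, the package ships a seeded phantom generator:
multi-cell fields with known compartment labels, spectra built from
Gaussian CH-band templates (droplet =CH band calibrated in closed form to
the 0.75 TAG ratio), dose-dependent droplet counts and Gaussian detector
noise. Every quantitative claim in the test suite is checked against this
ground truth or against an independent naive implementation.

## Worked example

```r
library(srsphasor)

axis <- wavenumber_axis(seq(2800, 3050, length.out = 40))
spec <- phantom_spec(droplet_density = 4, snr = 20, seed = 42)
ph   <- generate_phantom(spec, axis)
ph$stack
#> <hyper_stack> 256 x 256 pixels, 40 channels (2800.0-3050.0 cm^-1)
ph$ground_truth$true_droplet_area_fraction
#> 0.0379

field <- phasor_transform(ph$stack)          # per-pixel (G, S)
field
#> <phasor_field> 256 x 256 pixels, harmonic 1, 65536 valid
seg <- segment_by_rois(field, default_phasor_rois(axis))
seg
#> <segmentation_map> 256 x 256, 7 ROIs (droplet, nucleolus, nucleus,
#>   cytoplasm, droplet_periphery, cell_periphery, background)

quantify_stack(ph$stack, seg, ph$ground_truth,
               condition = "control", replicate = 1L)
#>   condition replicate percent_area peak_ratio n_cells
#> 1   control         1        3.808     0.7531       8
#>   percent_cells_with_droplets mean_cell_intensity
#> 1                         100              0.6969
```

The segmentation recovers a droplet area of 3.81% against a ground truth
of 3.79% at snr = 20, and the droplet-class spectrum returns a TAG/CE
peak ratio of 0.753 against the calibrated 0.75 — i.e. the phasor chain
reproduces the generator's droplet load and composition. Replicate-level
statistics use the pooled two-sample t-test:

```r
students_t_test(c(9.8, 10.4, 10.1), c(3.1, 3.4, 2.9))
#> t = 30.8154, df = 4, p = 6.608e-06 (**)
```

The full simulate → phasor → segment → quantify chain, including a
six-dose atorvastatin-like series with three replicates, per-image
records, a dose-response summary table and figures, runs from one
configuration:

```r
run_pipeline(default_config(seed = 1), "runs/demo")
```

A thin CLI wrapper with `simulate`/`project`/`ratio`/`phasor`/`segment`/
`quantify`/`run` subcommands is installed at
`inst/scripts/srsphasor-cli.R`.

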