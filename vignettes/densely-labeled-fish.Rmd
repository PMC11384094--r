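---
title: "Densely labeled FISH probes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Densely labeled FISH probes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(denseFISH)
```

## Scope

denseFISH covers the computational side of FISH with enzymatically
synthesized, densely labeled oligonucleotide probes: sequence design,
a stochastic labeling model, a ground-truth synthetic microscopy generator,
the quantitative image-analysis pipeline, and the statistical summaries used
to report such experiments. Everything is exposed as ordinary R functions;
the package deliberately ships no shell entry point, since its users work
from R scripts and the functions, tests and this vignette are the interface.

## Probe chemistry, as modeled

A probe is synthesized by annealing a short primer to a 5'-phosphorylated
template (the reverse complement of the desired probe sequence) and
extending with a polymerase in the presence of dye-labeled dCTP; the
template is then removed enzymatically. Two consequences drive the whole
design module:

* Only bases synthesized *beyond the primer* can carry a dye, so the
  labelable sites of a probe are the cytosines of its sequence strictly
  after the primer region (`count_labelable_sites()`). For the classic
  40-nt screening probe with a 20-nt primer that count is 8.
* Dyes land only on cytosines, so sequences that should carry dyes at a
  fixed spacing must contain C exactly every *k* bases and nowhere else
  (`check_c_spacing()`, default period 10). Barcodes are built by merging
  orthogonal parent sequences, trimming, and filtering with this predicate.

Extended ("xNOVA-style") probes append 10-mer units of the form
`NNNNNNNNNC` to a 40-nt binding sequence (`assemble_xnova()`). With
`unit_seq = "auto"` the nine N positions are drawn from A/G/T only, a design
choice: since labeling happens via dCTP, excluding interior C guarantees
exactly one labelable position per unit at an exact 10-base spacing. One to
three units give 50-70 nt probes with 40-nt primers; plain probes use 20-nt
primers on 40-nt templates.

Probe sets for a genomic target are tiled greedily left to right
(`select_probes_for_region()`), taking each filter-passing window that does
not overlap an already-chosen probe. Filters default to GC between 35 and
65 percent, homopolymer runs of at most 5, and an optional background
k-mer exclusion (k = 16) — standard oligo-FISH practice; all are
configurable because no canonical values exist. Leftmost-first tiling was
chosen over optimization because it is deterministic, order-preserving and
trivially auditable. Coordinates are stored 0-based half-open internally;
printed coordinates are treated as 1-based inclusive and converted on
ingest, and spans in kb are rounded half-up to one decimal, matching how
such spans are conventionally printed.

## The labeling model

The number of dyes on a probe is modeled as Binomial(n_sites, p), where p
is the labeled fraction of the dCTP pool (`dye_count_distribution()`).
Site-independence is a modeling choice — polymerase context bias is not
modeled — and is consistent with the observation that intermediate ratios
produce a ladder of distinct dye-count species. The expectation is
n_sites × p; at the 1:4 labeled:unlabeled screening ratio (p = 0.2) an
8-site probe carries 1.6 dyes on average.

Fluorophores too close together partially quench. The package models this
with a user-supplied monotone curve of relative emission efficiency versus
dye-dye separation in bases (`quench_curve()`): clamped to [0, 1], linearly
interpolated, constant beyond the supplied range, defaulting to identity
(no quenching). Each dye emits at the efficiency of its distance to its
*nearest* labeled neighbor; the probe brightness is the sum over dyes
(`predicted_relative_brightness()`). Nearest-neighbor-only quenching is the
simplest rule matching a pairwise dye-spacing experiment; no physical
FRET or H-dimer mechanism is implied. `brightness_vs_density_curve()` takes
the Monte-Carlo expectation of this quantity over Bernoulli labeling
patterns, which with the identity curve reduces to n_sites × ratio.

Degree of labeling from absorbance follows the standard correction

    DOL = (A_dye / eps_dye) / ((A260 - CF260 * A_dye) / eps_oligo)

with dye correction factors CF260 of 0.22 (ATTO488), 0.22 (ATTO594) and
0.04 (ATTO647N) in the shipped registry. The registry's extinction
coefficients are vendor-typical values, and the default oligo extinction is
a plain per-base monomer sum — both clearly marked, both replaceable.

## The synthetic microscopy generator

`synthetic_scene()` + `render_scene()` produce multi-channel `(z, y, x)`
stacks with complete ground truth. The model, in rendering order:

1. Nuclei are ellipsoids of constant counterstain intensity; FISH channels
   get a constant background inside nuclei and an optional constant base
   level (camera offset) everywhere. Extra ellipsoidal regions (satellite
   blobs) can be added per channel.
2. This structural content is blurred with a Gaussian PSF (default
   `c(xy = 60, z = 200)` nm), because a microscope convolves everything it
   images — without this, segmented-object edges would be unphysically
   sharp.
3. Spots are anisotropic 3D Gaussians *integrated over each voxel* (erf
   differences per axis), so the noiseless voxel sum of a spot equals the
   analytic mass `A (2pi)^{3/2} sigma_xy^2 sigma_z / (dxy^2 dz)` and the
   peak voxel is within discretization error of `A + background`. A
   Gaussian PSF is used rather than vectorial optics because the analysis
   pipeline itself fits Gaussians.
4. Poisson shot noise, then additive Gaussian read noise, both drawn under
   the scene seed. Rendering is bit-identical for identical scene + seed.

The default grid is 30 nm lateral pixels and 80 nm z-steps, matching 3D
STED acquisition settings. Spot amplitudes default to peak SNR around 8
(amplitude 60 over a 50-photon nuclear background), a deliberately moderate
difficulty; real amplitudes are unknown, so this is a package choice, not a
measured property.

`make_pair_scene()` emulates a two-color paired-locus experiment: cells on
a tile grid, one A/B pair per nucleus, the true separation drawn from a
configurable distribution, and a configurable fraction of truly
colocalizing pairs; non-colocalizing partners are re-placed uniformly
within the nucleus conditional on exceeding the 500 nm radius (plus a
100 nm guard band), or dropped via per-channel dropout.
`make_density_series_scene()` emulates the labeling-density experiment:
satellite blobs carrying a ratio-independent reference ("binding") channel
and a brightness channel scaled by the labeling model's mean predicted
brightness. Blobs are spread at distinct angles so they cannot overlap,
which keeps the reference intensity identical across blobs by construction.

What the generator does *not* emulate: optical aberrations, bleaching,
chromatic shift, intensity texture inside nuclei, autofluorescence, or
segmentation-confusing cell clumps. Passing pipeline tests on these scenes
therefore demonstrates correctness of the algorithms under the stated image
model, not performance on real microscopy data.

## The quantification pipeline

`run_pair_pipeline()` chains the stages; each is exported separately.

* **Segmentation** (`segment_nuclei()`): global Otsu threshold on the
  counterstain z-maximum projection, hole filling, connected components,
  minimum-area filter (default 0.5 um^2), optional exclusion of
  border-touching nuclei (on by default in the pipeline: only entirely
  imaged cells are summarized). A constant image yields zero nuclei with a
  warning rather than an error.
* **Detection** (`detect_spots_log()`): anisotropic Gaussian smoothing
  matched to the expected spot size, scale-normalized negative Laplacian
  (per-axis `sigma^2` × second difference), local 26-neighborhood maxima
  above threshold, restricted to nuclei. The default threshold is
  median + 6 × MAD of the in-mask response — robust to the spots
  themselves — with an absolute-threshold mode for manual tuning. Plateau
  ties keep only the lexicographically first voxel so detection is
  deterministic. Sigmas below one voxel are refused.
* **Fitting** (`fit_spot_gaussian()`): Levenberg-Marquardt least squares of
  a voxel-integrated Gaussian plus constant background in a 7 × 7 × 5
  window (max 200 iterations, relative cost tolerance 1e-8). The
  voxel-integrated model matches the physics of pixel binning and avoids
  the few-percent amplitude bias a point-sampled model shows at
  sigma ≈ 2 voxels. Failures (non-convergence, center outside the window,
  non-positive amplitude, flat or over-clipped windows) mark
  `status = "failed"` and never raise. Single-slice stacks degrade to a 2D
  fit.
* **Metrics** (`spot_metrics()`): signal-over-background is amplitude over
  the nucleus background mean; SNR is amplitude over the background SD.
  The background statistics exclude boxes of `2 sigma + 2` voxels around
  detected spots. These formulas are package definitions — the field uses
  several — and both numerator and denominators are exported so users can
  recompute alternatives.
* **Pairing** (`pair_and_colocalize()`): greedy mutual-nearest-neighbor
  matching on 3D physical distance (anisotropic calibration), at most one
  partner per spot, ties broken by lower id; pairs under 500 nm are
  colocalized. Greedy was chosen for determinism and O(n^2) simplicity;
  `pair_spots_optimal()` provides exhaustive minimum-total-distance
  matching for up to 8 spots per channel as a validation mode, and the two
  agree on the small configurations tested.
* **Density series** (`quantify_density_series()`): per-cell medians of
  reference and brightness channels over satellite regions (second Otsu
  within the cell mask), background-subtracted using a user-chosen ROI
  outside the cells; condition means normalized to the 100 percent
  condition for the binding channel and the 25 percent condition for the
  brightness channel.

## Statistical conventions

`wilcoxon_rank_sum()` is exact by full enumeration of rank assignments for
combined n ≤ 12 (average ranks make the exact path valid under ties, which
the asymptotic-free textbook enumeration would not be) and switches to the
tie- and continuity-corrected normal approximation above that. The cutoff
of 12 keeps the enumeration below C(12, 6) = 924 assignments — effectively
free — while covering the small per-cell group comparisons where exactness
matters. Bonferroni correction multiplies by the number of comparisons
actually performed, which `pairwise_rank_sum()` records. Boxplot summaries
use 25th/75th percentile boxes and 5th/95th percentile whiskers with linear
interpolation between order statistics (quantile type 7); values outside
the whiskers are listed as outliers. `normalize_by_reference()` divides by
the median of the first depicted condition and is idempotent.

## Numerical choices and degenerate inputs

* Span rounding: half-up at one decimal (base `round()` is half-even).
* Sequence ingest is case-insensitive; U maps to T with a warning;
  non-ACGT characters error with the offending position.
* `primer_len` equal to the probe length is a valid degenerate input
  (nothing to label); greater is an error.
* Quench curves must be nondecreasing; efficiencies are clamped to [0, 1].
* Empty spot lists, empty pools, zero-nucleus images and spotless cells
  all flow through as empty-but-valid results; cells without signal are
  retained as zero rows in summaries.
* Exact rank-sum p-values use tail doubling, capped at 1; degenerate
  all-equal samples return p = 1 with a warning.

## Problem sizes

The shipped tests run the full pipeline on a 200-cell two-color scene
(about 900 × 1000 × 12 voxels), 10-60-cell scenes for unit checks, and a
5-condition density series with 4 cells per condition; enumeration oracles
go up to 2^10 labeling patterns and C(12, 6) rank assignments. These sizes
were chosen so the whole suite completes in minutes on a single core while
keeping every statistical check adequately powered; the same sizes are used
by `scripts/acceptance.R`.

## Known limitations

* The binomial incorporation model ignores polymerase sequence bias and
  reaction kinetics.
* The quench curve is phenomenological; it encodes measured monotone
  recovery with separation, not photophysics.
* Detection assumes isolated, diffraction-limited spots; overlapping loci
  closer than roughly one PSF width merge into single candidates.
* The pipeline's background model is a constant per nucleus; textured
  nuclear background would bias SNR estimates.
* The synthetic scenes are the package's own image model; agreement there
  is a necessary, not sufficient, condition for accuracy on real stacks.
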