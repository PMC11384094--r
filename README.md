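# denseFISH

Design, simulation and quantification of densely labeled FISH probes.

## The problem

Fluorescence in situ hybridization (FISH) detects genomic loci by
hybridizing labeled DNA probes to fixed cells. Oligonucleotide probes that
carry *many* fluorophores — incorporated enzymatically as dye-labeled dCTP
during primer extension on a 5'-phosphorylated template — give far brighter
spots than end-labeled or readout-based probes, at a fraction of the cost.
But working with them raises computational questions at every step:

* **Design.** Which tiling oligos pass sequence filters for a target
  region? How do you build barcode or extension sequences whose cytosines
  sit at an exact spacing, so each 10-mer unit carries exactly one dye?
  Which template/primer pairs synthesize a given probe, and how do primer
  subsets select probe subsets from one common pool?
* **Labeling.** How many dyes does a probe carry at a given
  labeled:unlabeled nucleotide ratio? How does fluorophore crowding quench
  brightness, and how is degree of labeling estimated from absorbance?
* **Quantification.** Given multi-channel z-stacks: segment nuclei, detect
  diffraction-limited spots, localize them with subpixel precision,
  measure intensities and SNR, pair two-color spots, and measure 3D
  distances with anisotropic voxel calibration.

denseFISH implements all of this for R users — probe designers and
microscopists alike — plus a seeded synthetic microscopy generator that
renders ground-truth-annotated image stacks, so every stage of the analysis
is testable end to end without real data.

## Models at the core

* **Labelable sites.** Only bases beyond the primer incorporate labeled
  dCTP, so a probe's labelable sites are the cytosines of its sequence
  after the primer region. The classic 40-nt screening probe with a 20-nt
  primer has 8.
* **Dye counts.** Incorporation is modeled site-independently: the dye
  count per probe is Binomial(n_sites, p), with mean n_sites x p, where p
  is the labeled fraction of the dCTP pool.
* **Quenching.** Each dye emits at an efficiency q(d) given by a monotone
  curve of its base-distance d to the nearest other dye; probe brightness
  is the sum of efficiencies. Identity curve = no quenching = brightness
  equals dye count.
* **Degree of labeling.** DOL = (A_dye / eps_dye) / ((A260 − CF260 ·
  A_dye) / eps_oligo), with CF260 = 0.22 / 0.22 / 0.04 for ATTO488 /
  ATTO594 / ATTO647N.
* **Spot analysis.** Scale-normalized Laplacian-of-Gaussian detection
  inside Otsu-segmented nuclei; Levenberg-Marquardt fits of a
  voxel-integrated 3D Gaussian plus constant background (the fitted peak
  height is the spot intensity); greedy mutual-nearest-neighbor two-color
  pairing with spots closer than 500 nm counted as colocalized; distances
  computed with 30 nm lateral / 80 nm axial calibration by default.
* **Statistics.** Median normalization to the first condition, two-sided
  Wilcoxon rank-sum tests (exact by enumeration for combined n ≤ 12,
  tie-corrected normal approximation above), Bonferroni correction, and
  boxplots with 5th/95th-percentile whiskers.

## Worked example

```r
library(denseFISH)

# The 40-nt polymerase-screen probe: template, primer, labelable sites
probe <- polymerase_screen_probe()
build_template_primer(probe, primer_len = 20)
#> <template_primer_pair> 40 nt template (5'-phos), 20 nt primer
#>  template: AGGATGGGCCCAGGTAAGCATGGACCATTCCTTCAGGATG
#>  primer:   CATCCTGAAGGAATGGTCCA
count_labelable_sites(probe, 20)
#> [1] 8

# Dye-count distribution at a 25% labeling ratio
d <- dye_count_distribution(8, 0.25)
d$mean            # 2
round(d$pmf[3], 4)  # P(2 dyes) = 0.3115

# Synthetic two-color experiment: 30 cells, half truly colocalizing at 300 nm
cfg <- pair_scene_config(n_cells = 30, coloc_fraction = 0.5)
stack <- render_scene(make_pair_scene(cfg, seed = 1))
res <- run_pair_pipeline(stack)
nrow(res$cells); nrow(res$spots); sum(res$pairs$colocalized)
#> [1] 30
#> [1] 60
#> [1] 20
median(res$pairs$distance_nm[res$pairs$colocalized])
#> [1] 285.3

# Statistics
wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))
#> Wilcoxon rank-sum: W = 6, p = 0.1 (exact, n = 3 vs 3)
```

All 60 planted spots are recovered; 20 of the 30 cells measure as
colocalized (the truth draw at seed 1 contains 20 truly colocalizing
pairs), and the median measured separation of 285 nm reflects the true
300 nm up to localization noise. The 3-vs-3 rank-sum p of 0.1 is the
smallest attainable exact two-sided p at those sample sizes.

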