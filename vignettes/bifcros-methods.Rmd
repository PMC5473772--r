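---
title: "Models and methods behind bifcros"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind bifcros}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bifcros)
```

# The measurement problem

A fluorescence repressor operator system (FROS) marks a genomic locus with
an array of operator sites bound by a repressor fused to a fluorescent
protein: bound molecules pile up into a diffraction-limited focus, while
every unbound fusion molecule diffuses through the cytoplasm and
contributes background. A bimolecular-complementation variant (BiFCROS)
splits the fluorophore between two different repressors (the lambda cI
repressor, binding OL1 operators, and Gal4, binding UAS sites) and
interleaves both site types on one hybrid array. Only reporter halves
brought together on the array reconstitute a fluorophore, so the
background collapses and, in principle, whole-cell fluorescence becomes a
single-cell readout of how many copies of the array — and hence of the
tagged locus — a cell carries.

`bifcros` implements that measurement chain as testable code: the array
designer and assembly simulator, an equilibrium occupancy model linking
reporter supply to focus brightness, a synthetic microscopy generator with
ground truth, cell detection and per-cell pixel extraction, the
signal/background statistics with their retention filters, and the
population-level analyses (area binning, control subtraction, regression,
copy-number fold change).

# Array design and simulated assembly

The array is grown from one synthetic building block:

```
[OL1 3' half] - spacer - [UAS] - spacer - [OL1 5' half]
```

flanked in the source plasmids by BpiI and BsaI recognition sites. Because
type-IIS enzymes cut outside their recognition sequence, digestion exposes
a 4-nt overhang spanning the OL1 split, and ligating two inserts
reconstitutes one complete OL1 at the junction. Each digest/ligate cycle
doubles the insert, so an $n$-unit array needs $1 + \log_2 n$ steps
(counting the initial block construction): 7 steps for the 64-unit design.
A raw $n$-unit ligation product contains $n-1$ internal OL1 sites plus an
orphan half-site at each end; `finalize_array()` appends the completing 3'
half-site on the right flank so the emitted construct carries exactly $n$
full OL1 and $n$ UAS motifs — making the design's advertised "64 of each"
literally countable by substring scan, which is how the package validates
it (`count_motifs()` against a naive scanner in the tests).

Design choices worth knowing:

* **Motif sequences.** The construct's true OL1/UAS/spacer sequences are
  not public. Defaults are the canonical 17-bp lambda OL1 operator and a
  17-bp CGG-N11-CCG Gal4 UAS consensus, both checked to be free of
  BpiI/BsaI sites on either strand and both user-overridable through
  `operator_motif()`. No downstream statistic depends on the letters, only
  on the counts and geometry.
* **Split point.** Unknown for the real construct; the default splits OL1
  at the midpoint (5' part = first 9 bases), configurable via
  `split_after`.
* **Spacers.** Random, except a fixed leading dinucleotide (`"CA"` by
  default), mirroring designs in which two determined base pairs anchor
  each spacer. Spacers are resampled until no enzyme site appears anywhere
  in the block or across a simulated junction; an error is raised if that
  is impossible.
* **Coordinates** are 1-based inclusive in all user-facing output.

# The occupancy model

No binding constants or protein copy numbers are published for this
system, so the model is deliberately the simplest one that carries the
saturation argument. Each adjacent OL1/UAS pair is one reconstitution
site; a cell holds $P$ functional reporter pairs and
$S = n_\text{arrays} \times \text{sites\_per\_array}$ identical,
independent sites. With dimensionless association constant $K$, the bound
count $B$ solves

$$B = K (P - B)(S - B),$$

taken in the cancellation-free closed form
$B = 2KPS / \left(K(P+S) + 1 + \sqrt{(K(P+S)+1)^2 - 4K^2PS}\right)$,
cross-checked in the tests against numeric root bracketing at $10^{-9}$
relative tolerance. Unbound pairs self-assemble at rate
`free_complementation_rate`, giving the small diffuse term of the split
system. Complementation is not treated as irreversible: the diffuse term
is exactly the place where an "assembly platform" reading (complemented
proteins leaving the array but staying fluorescent) would add signal, and
it is exposed as a parameter rather than hard-coded away.

Defaults, chosen once as the package's study conditions and not fitted to
anything: `pool_size = 600` pairs/cell (a moderately induced repressor
fusion), `affinity = 1` (tight binding at that pool: a single 64-site
array is ~99.8% occupied), `sites_per_array = 64` (the designed array),
`free_complementation_rate = 0.002` (a split engineered against
self-assembly, e.g. by an I152L-type mutation in the N fragment). Two
regimes fall out of the same model rather than being dialled in
separately:

* **Non-limiting pool** (default): 1 → 2 array copies doubles the bound
  count, so whole-cell fluorescence reads copy number linearly.
* **Limiting pool** (`pool_size = 100` against 20 × 64 sites in the
  multicopy scenario): $B$ is concave and sub-linear in
  $n_\text{arrays}$; the simulated 20-copy strain gains well under 3-fold
  over single copy. This is the regime that makes whole-cell FROS readouts
  unreliable for extreme copy-number comparisons.

# The synthetic microscopy generator

`sample_population()` draws rod-shaped cells — capsules of normal length
(mean 28 px, SD 5 px, truncated at 18 px) and width (9 ± 0.5 px) — onto
non-overlapping grid slots with random jitter and orientation; areas are
in pixels throughout because no physical pixel size is attached to the
model. Per-cell expression noise is lognormal (`sdlog = 0.3`, unit mean);
when an `occupancy_params` object is supplied the titration is re-solved
per cell with the scaled pool, so a saturated array stays at 64 bound
fluorophores no matter how strongly a cell expresses — the honest
behaviour, and the reason focus brightness is nearly constant in the
saturated regime while the limiting regime inherits the expression
spread.

Photon budgets by construct:

| construct | diffuse term | foci |
|---|---|---|
| `FULL_LENGTH` | $(P - B)\,b/\text{area}$ — every unbound molecule fluoresces | one per array copy, $B/n_\text{arrays} \cdot b$ photons |
| `SPLIT` | free-complemented pairs only | same |
| `EMPTY` | none | none |

with $b$ = `brightness_per_fluorophore` (50 photons/exposure) on top of an
autofluorescence floor (3 photons/px). The camera model is Poisson shot
noise, gain 16 counts/photon, offset 100 counts, Gaussian read noise
(SD 10 counts), and 16-bit quantization; exposure-time differences between
regimes are absorbed into the gain rather than modelled explicitly. Foci
are spread by an isotropic Gaussian PSF (σ = 1.3 px) whose discretized
kernel is renormalized per focus, so the noise-free renderer conserves
photons exactly; the invariant is asserted at $10^{-6}$ on the
`expected_counts` plane (pre-quantization — integer rounding would
otherwise dominate a whole-frame comparison) and at 1% per cell on the
quantized pixels, which also absorbs the ~0.25% of focus light that the
PSF pushes outside the cell outline.

Under these defaults the full-length construct's whole-cell mean exceeds
the split construct's by roughly an order of magnitude (~11× at the
default pool; the tests require ≥ 5×). That ratio is a model consequence
of the unbound-pool diffuse term, not a separate dial.

What the generator does **not** emulate: phase-contrast channels,
3-D/PSF anisotropy, photobleaching, fluorophore maturation delays, cell
overlap or chaining, sister-locus cohesion (foci per cell always equals
the array copy number), and cell-cycle-coupled locus replication. Passing
regime tests therefore demonstrates that the *statistics pipeline*
recovers the designed contrasts from realistic image noise — not that
real cells behave this simply.

# Quantification and population analysis

Per cell, pixels are ranked; **signal** is the mean of the brightest
`ceiling(0.10 n)` pixels and **background** the mean of the dimmest
`ceiling(0.50 n)` (ceiling with a 1-pixel floor keeps the statistic
defined for tiny cells; ties at the fraction boundary are resolved by a
stable sort taking exactly the computed count). Cells are retained only if
intensity stays **strictly below 65,000** counts — applied to the
brightest pixel by default, as a near-saturation guard on a 16-bit
camera; a whole-cell-mean variant is available via
`intensity_filter_on = "cell_mean"` since either reading of the cutoff is
defensible — and the signal/background ratio is **strictly above 5**.

Population procedures:

* `bin_by_area()` groups cells into 10-px area windows and drops groups
  with fewer than 10 cells. Disjoint tiling is the default because bin
  counts are then unambiguous; a 1-px-step sliding mode is provided.
* `subtract_control()` removes the grand mean of a no-array control
  strain from each cell's mean intensity, clamping at zero with a flagged
  count (the clamp is audited in tests against an independent count of
  below-control cells).
* `regress_signal_vs_background()` fits ordinary least squares of
  background on signal after the axis caps (65,000 on x, 15,000 on y). A
  flat slope means bright cells do not drag their own background up — the
  signature of a low-background system.
* `estimate_fold_change()` optionally restricts each strain to its
  brightest half (`subset_fraction = 0.5`), then control-subtracts, then
  takes the ratio of means. Subsetting before subtraction is a
  documented ordering choice; with a common control it shifts both arms
  identically. The default is `subset_fraction = 1`.

Cell detection (`segment_cells()`) is a global Otsu threshold — computed
on a log-intensity scale, because fluorescence frames pair a narrow
offset-dominated background peak with cell intensities spread over a
decade, and linear-scale Otsu truncates dim expressers — followed by
8-connected components and an area filter. All downstream analyses of
simulated data bypass it via the ground-truth label mask, so statistical
conclusions never depend on detection quality; detection has its own
fidelity tests (≥ 95% recall/precision on default frames).

# Problem sizes, determinism, numerics

Every stochastic stage draws from a named substream of one top-level seed
(`substream_seed()`), so reruns are byte-identical and changing one
stage's parameters never perturbs another's draws. The test suite and the
bundled analyses use populations of 120–1000 cells per arm rendered on
512×512 frames (≤ 80 cells per frame), sizes at which the regime
contrasts are far larger than their standard errors: the twofold
copy-number recovery at n = 1000 has a ~1–2% standard error against an
acceptance band of ±10%. Degenerate inputs are defined, not fatal: zero
pool/affinity/sites give zero occupancy; a constant frame segments to an
empty mask; an empty pixel vector, an empty control population, and
fewer than 3 post-cap regression points raise explicit errors.

# Known limitations

The occupancy defaults are order-of-magnitude choices, not measurements;
absolute intensities in counts are therefore only internally meaningful.
The one-focus-per-array-copy rule ignores locus cohesion, so focus
*counting* (which the package deliberately does not offer) cannot be
validated here. The fold-change estimator assumes the two strains share
an area distribution; a systematic size difference between strains would
bias whole-cell means and should be handled by the area-binned view
instead.
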