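# bifcros

Simulation and quantification tools for low-background fluorescence
repressor operator systems (FROS) in bacteria.

A FROS labels a genomic locus with an operator array bound by a
fluorescent repressor fusion; the bound molecules form a visible focus,
but every unbound fusion molecule adds diffuse background. In the
bimolecular-complementation variant (BiFCROS) the fluorophore is split
between two repressors — lambda cI (binding OL1 operators) and Gal4
(binding UAS sites) — that meet only on a hybrid array of alternating
OL1/UAS sites, so fluorescence is confined to the tagged locus and
whole-cell intensity can, within limits, read out locus copy number.
`bifcros` provides the full measurement chain for studying that idea in
silico:

- **Array design** — simulate the hierarchical type-IIS (BpiI/BsaI)
  doubling assembly of the hybrid array from a single split-OL1/UAS
  building block, validate motif counts, write FASTA/GenBank.
- **Occupancy model** — closed-form equilibrium titration of a finite
  reporter-pair pool `P` against `S` array sites,
  `B = K(P−B)(S−B)`, linking copy number, reporter supply and focus
  brightness, including the sub-linear multicopy (limiting-pool) regime.
- **Synthetic microscopy** — seeded 16-bit frames of rod-shaped cells
  with diffuse cytoplasmic signal, PSF-blurred foci, autofluorescence,
  shot/read noise, plus ground-truth label masks and per-cell truth
  tables.
- **Segmentation & quantification** — Otsu/connected-components cell
  detection (or ground-truth bypass), per-cell signal (mean of the
  brightest 10% of pixels) and background (mean of the dimmest 50%),
  strict `< 65,000` intensity and `> 5`-fold ratio retention filters,
  pooled pixel histograms.
- **Population analysis** — 10-px area binning (≥ 10 cells/bin),
  control-strain background subtraction, OLS regression of background on
  signal with 65,000/15,000 axis caps, and copy-number fold-change
  estimation with an optional brightest-50% subset.

## Worked example

```r
library(bifcros)

# design the 64-unit hybrid array by simulated hierarchical assembly
block <- make_building_block(seed = 1)
array <- assemble_to_target(block, 64)
array
#> <hybrid_array> 64 units, 3464 bp; 64 OL1 + 64 UAS motifs; 7 assembly steps

# equilibrium occupancy under the default study conditions
compute_occupancy(occupancy_params())
#> <occupancy_result> total bound 63.881 (63.881/array of 64 sites); free complemented 1.072

# simulate one- and two-copy split-reporter strains plus a no-array
# control, quantify against ground truth, and estimate the fold change
ctrl <- simulate_regime("SPLIT", 0L, 300, seed = 103)
one  <- simulate_regime("SPLIT", 1L, 300, seed = 101)
two  <- simulate_regime("SPLIT", 2L, 300, seed = 102)
estimate_fold_change(one$quants, two$quants, control = ctrl$quants)
#> <fold_change> 2.028 = 456.74 / 225.23 (brightest 100%, n = 300 vs 300)

# the split system's background barely rises with signal...
regress_signal_vs_background(one$quants)
#> <regression_result> background = 0.0108 * signal + 112.61 (n = 300)
# ...while the full-length fusion drags its background along
full <- simulate_regime("FULL_LENGTH", 1L, 300, seed = 101)
regress_signal_vs_background(full$quants)
#> <regression_result> background = 0.7744 * signal + -1164.96 (n = 300)
```

The 64-unit array assembles in 7 steps (1 initial block + 6 doublings)
and carries exactly 64 of each operator. With the default (non-limiting)
reporter pool a single array is ~99.8% occupied, two chromosomal copies
double the whole-cell signal (fold ≈ 2.0), and the background-on-signal
slope is ~70× flatter for the split system than for the conventional
full-length fusion — the low-background property the design exists for.
Swapping in a limiting pool (`occupancy_params(pool_size = 100)`) makes a
20-copy strain gain well under 3-fold, the saturation regime that limits
whole-cell readouts of extreme copy numbers.

`run_pipeline(run_config(seed = 1), "out/")` runs five simulated arms
(full-length ± array, split ± array, split two-copy) end to end and
writes TIFF images/masks, per-cell CSVs, histogram and bin CSVs,
regression and fold-change JSON, and a provenance log. A thin CLI over
the same functions lives at `inst/scripts/bifcros-cli.R`
(`design-array`, `titrate`, `simulate`, `segment`, `quantify`,
`analyze`, `run-all`).

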