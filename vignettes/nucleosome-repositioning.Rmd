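---
title: "Detecting drug-induced nucleosome repositioning from promoter tiling arrays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting drug-induced nucleosome repositioning from promoter tiling arrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nucshift)
```

## The measurement and the model

nucshift analyses two-channel tiling microarrays that interrogate 2-kb
windows centered on transcription start sites (TSS). The Cy3 channel
carries mononucleosomally-protected DNA — the ~147-bp fragments that
survive MNase digestion because they were wrapped around a histone
octamer — and the Cy5 channel carries bare genomic DNA from the same
cells. For a probe $p$ the occupancy signal is

$$ y_p = \log_2 \frac{\text{Cy3}_p}{\text{Cy5}_p}, $$

which is positive where DNA was nucleosome-protected and negative over
naked linker or nucleosome-depleted regions (NDRs). Each locus yields an
*occupancy profile*: the vector of $y$ values over the probe-midpoint
positions of its window, on a TSS-relative axis (upstream negative; the
axis is flipped for minus-strand genes so this holds regardless of
orientation).

Repositioning is called per locus by profile correlation. For a treated
condition with replicates $t_i$ and a drug-naive control with replicates
$c_j$, the Pearson correlation $r_{ij}$ is computed over the shared
position grid for every pair, and the locus is *changed* iff

$$ \max_{i,j} r_{ij} < r^\ast, \qquad r^\ast = 0.7 . $$

A large translational shift, eviction, or gain of nucleosomes
decorrelates the treated profile from the basal one; replicate noise
alone does not. The per-gene summary printed in reports is
$\bar r \pm \mathrm{sd}(r_{ij})$ over the comparison pairs.

### Why these conventions

* **Pearson, not rank, correlation.** The signal is a continuous
  log-ratio on a common grid and the threshold is quoted as an $r$
  value; product-moment correlation is the natural reading. The
  correlation is invariant to the affine scale of the profiles, so it is
  also insensitive to normalization constants.
* **Conjunction over all replicate pairs.** With two replicates per
  side there are four comparisons, and *all four* must fall below the
  threshold. This is the strictest reading of requiring changes to be
  "common among all comparisons"; a `comparison = "matched"` switch
  (replicate $i$ vs control replicate $i$ only) is provided for
  sensitivity analysis.
* **Strict inequality** at $r^\ast$, so a correlation of exactly 0.7 is
  *unchanged*.
* **Indeterminate loci.** A constant (zero-variance) profile has no
  defined correlation; such loci are reported with `changed = NA` and
  excluded from both changed and unchanged counts rather than silently
  absorbed into either.
* **Probe anchor.** Probes are summarized at their midpoint; bins are
  exact midpoints (1-bp resolution), which avoids any arbitrary bin
  width. Co-located probes within one array (forward/reverse strand,
  duplicate spots) are arithmetic-mean averaged; biological replicates
  are never merged before change calling (only for display and model
  scoring).
* **Normalization.** Per-array median scaling of each channel to a
  common reference is the default: it is ratio-preserving and makes no
  distributional assumption. Quantile normalization (via limma) and
  `"none"` are selectable. Which algorithm the original arrays used is
  not recorded, so the default is the most conservative choice.
* **Percentages.** All printed percentages use round-half-away-from-zero
  to integers (`percent_of()`). This convention reproduces every
  count/percent pairing we checked (611/858 → 71, 547/858 → 64,
  223/858 → 26, 116/223 → 52) with one exception: a printed "534 genes
  (63%)" pairing is internally inconsistent with the same rule
  (534/858 → 62) and is documented here rather than special-cased.

## The synthetic-data generator

Because the deposited arrays are not needed for building or testing, the
generator produces two-channel intensities with *known* nucleosome-map
truth. It emulates the study design: 858 loci, 2000-bp TSS-centered
windows, 60-mer probes tiled at a 13-bp per-strand step on both strands
(reverse strand offset 6 bp, pooled median spacing 6.5 bp), two
biological replicates, a control plus three treatment time points.

* **Basal maps.** Footprints of 147 bp are laid down with exponential
  linkers (mean 50 bp), giving a stationary placement with a ~197-bp
  repeat; 60% of loci get an NDR forced over `[-150, +50)` relative to
  the TSS, as accessible promoters typically show.
* **Events.** A quarter of loci receive a repositioning event at the
  first time point: a whole-window shift of 80–140 bp (half a nucleosomal
  repeat, the strongest decorrelator), an eviction over `[-500, +500)`,
  or a trio of nucleosome gains near the promoter. By default 20% of
  event loci revert at a random later time point, restoring the basal
  map — the ground truth for restoration arithmetic. A locus is "truly
  changed" at a time point iff at least one *realized* event is active
  then (a gain with no room is recorded as unrealized).
* **Intensities.** Cy5 is flat at `baseline`; Cy3 follows
  $\mathrm{baseline}\cdot 2^{b + g\,\bar\pi}$ where $\bar\pi$ is the mean
  MNase-protection over the probe and $b = -1.5$, $g = 3$ place naked
  DNA well below and protected DNA well above the zero line, crossing at
  half protection. Both channels carry independent multiplicative
  log-normal noise (`sigma_channel`) plus a shared per-array log-normal
  batch effect; the expected log2 ratio is affine and monotone in
  protection.
* **Noise calibration.** The per-channel sd (0.15 on the natural-log
  scale) was fixed once so that the synthetic correlation ranges bracket
  the values printed for real genes: unchanged loci land at
  $r \approx 0.85$–$0.95$ (the printed stable examples sit at
  0.75–0.85), changed loci at $r \approx -0.4$ to $0.5$, and
  replicate-consistency scatters at $r \approx 0.94$ ("very high"
  consistency). It was not revisited after the validation suite was run.

What the generator deliberately does **not** emulate: sequence-dependent
MNase bias, dye-swap asymmetries, spatial (print-tip) artifacts, probe
cross-hybridization, or repeat masking of the real design (the real
arrays carry ~180 probes/locus after masking; the unmasked synthetic
design carries 299). Passing the recovery tests therefore demonstrates
that the *statistical machinery* behaves as specified under a realistic
noise model — not that the thresholds are optimal for any particular
real dataset.

## Time-course and drug set arithmetic

Changed sets per time point are partitioned exactly: Venn regions by
subset membership (`venn_partition()`), cumulative unions
(`cumulative_changed()`), restoration as the set difference between the
cumulative union and the still-changed set at a late time point
(`restored_loci()`), and drug-specific fractions computed on each drug's
cumulative union (`drug_overlap()`). Partitions are reported under the
actual time-point labels supplied; nothing is inferred about labels.

## The sequence-directed occupancy model

Intrinsic nucleosome favorability is scored from sequence alone with a
simple, transparent statistic: for every 147-bp window, the in-phase
fraction of WW (AA/AT/TA/TT) dinucleotides at a 10-bp period — the
rotational positioning signal — plus half-weighted G+C content,
z-normalized per locus. The score is exactly strand-symmetric and `N`
bases contribute to neither term. This is a documented stand-in with the
right qualitative structure, not a re-fit of any published model; any
externally computed per-base occupancy track can be substituted through
`load_model_track()` (TSV or wiggle), and everything downstream is
agnostic to the track's origin.

Per locus and condition, the control and treated (replicate-averaged)
profiles are correlated with the model track, and the *difference score*
is $r_{\text{treated,model}} - r_{\text{control,model}}$. A
repositioning event is classified **DNA-directed** when the profile
moved *toward* the model (difference score > 0) *and* resembles it
strongly ($r_{\text{treated,model}} \ge 0.7$). The printed examples this
rule must separate span 0.56–0.82 on the treated-model correlation and
do not pin down a unique cutoff, so the threshold is an exposed
parameter; 0.7 mirrors the change-call convention. The classifier is
validated on simulations where treated states relax either toward their
own intrinsic track (directed truth) or toward the track of an unrelated
decoy sequence (orthogonal truth).

## Regulatory annotation

Occupancy state of an interval is the sign of the mean profile signal
over it — "occupied" above the zero line, "depleted" below — requiring
at least three grid positions. A control-relative mode (sign of the
treated-minus-control delta) covers occupancy changes that do not cross
the baseline. NDRs are maximal below-zero runs spanning at least 140 bp
(~one nucleosome; narrower dips are not interpretable as depleted
regions). A promoter's configuration verdict after treatment is
**permissive** when the TSS or at least half of the permissive TF sites
become depleted while no repressive site does; **restrictive** for the
mirror case; **mixed** otherwise. The sign-of-mean rule is our
formalization of what is, in the source figures, a visual call; TFBS
regulatory classes are user-supplied annotations, never inferred.

## Enrichment

Changed sets are tested for gene-set over-representation with a
one-sided Fisher exact test (hypergeometric upper tail,
`stats::phyper`) and Bonferroni correction across the terms tested. The
background universe defaults to the loci on the array, not the genome:
a hit set drawn from an 858-gene design must be tested against that
design. Results are sorted by fold enrichment, `(k/n)/(K/N)`.

## Numerical choices and degenerate inputs

* Correlations require ≥ 10 shared grid positions; profile grids are
  intersected, never interpolated, before correlating.
* Zero-variance profiles and constant model tracks raise typed errors
  (`nucshift_zero_variance`, `nucshift_model_error`); change calls
  convert the former into `NA` verdicts.
* Probe placements that would run past a window end are dropped, never
  truncated; `overlap >= probe_len` is rejected as an invalid design.
* Event collisions resolve conservatively: a shifted footprint that
  would overlap a stationary one (or leave the window) is dropped; a
  gain with no room is unrealized.
* All coordinates are 0-based half-open internally; BED export is
  native, wiggle export is 1-based per that format's convention.
* Every stochastic function is reproducible from a single integer seed;
  pipeline runs write a manifest with the configuration, seed, and
  output checksums, and two runs with the same seed are byte-identical.

## Problem sizes used in validation

The test suite exercises the full 858-locus design for truth recovery
(sensitivity ≥ 0.9 and false-positive rate ≤ 0.05 at $r^\ast = 0.7$
under default noise with events at 25% of loci, checked at a fixed
seed), 300 loci for restoration logic, 60 loci for the DNA-directed
classifier (recovery ≥ 0.8 for directed truth, ≤ 0.2 for orthogonal
truth), exhaustive enumeration up to universe size 20 for the Fisher
tail, and 1000 random profile pairs against a sum-formula Pearson oracle
at $10^{-12}$. The `analysis/` scripts run the same stages at full scale
and write their tables under `results/`.

## Known limitations

* The intrinsic score is a qualitative stand-in; absolute
  directed-fraction estimates on real data should use a published
  occupancy track via `load_model_track()`.
* The $r < 0.7$ threshold is taken as given (its original justification
  is external to this package) and is exposed as a parameter, not
  re-derived.
* Enrichment against array-scale universes has limited power for small
  terms; fold estimates for terms with $K < 5$ are unstable.
* The generator's truth labels treat any realized active event as
  "changed"; a sub-threshold biological change that leaves correlation
  above 0.7 is counted as a miss even though no detector at this
  threshold could find it.
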