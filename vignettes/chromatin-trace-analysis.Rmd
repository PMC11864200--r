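---
title: "Methods: cell type-resolved 3D genome analysis of chromatin traces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cell type-resolved 3D genome analysis of chromatin traces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromtrace)
```

# Scope

`chromtrace` re-implements, as a tested pipeline, the analysis stack used to
study cell type-specific 3D genome organization from multiplexed DNA-FISH
(DNA-MERFISH) chromatin traces. Its input is a long-format trace table — one
row per decoded locus per homolog per cell, with 3D coordinates in
micrometers — together with a locus panel (BED-like), and optionally
matched expression and chromatin-accessibility tables. Image processing
(spot fitting, decoding, segmentation) is out of scope: the pipeline starts
where decoded coordinates end.

The package covers eight areas: file I/O and configuration; a synthetic
trace generator with planted ground truth; constant-weight error-correcting
barcode (codebook) design; locus panel design including probe-window
filters and super-enhancer calling; per-cell nuclear geometry; spatial-vs-
genomic distance scaling; A/B compartment, insulation and megadomain
statistics; and locus-level chromatin-environment scores with WT-vs-KO
comparisons.

# The synthetic-data generator

Real brain-scale datasets (~10^5 cells) are not reproducible at desk scale,
so every estimator here is validated against a generator that plants the
statistical structure the analysis assumes. The generator is first-class,
tested code; its defaults describe one fixed set of study conditions.

## Backbone: spectral synthesis with a broken power-law spectrum

Each chromosome homolog is a Gaussian chain. Coordinates are sums of
random-phase Fourier modes in the genomic coordinate, with power spectrum

$$ S(k) \propto \begin{cases} k^{-(2H_\text{short}+1)} & k \ge k_c \\
 k_c^{-(2H_\text{short}+1)} (k/k_c)^{-(2H_\text{long}+1)} & k < k_c
 \end{cases} $$

with $k_c = 1/g_c$ and $g_c$ the crossover genomic distance (default
10 Mb). The structure function of such a process scales as
$g^{H_\text{short}}$ below $g_c$ and $g^{H_\text{long}}$ above it, so the
median spatial distance between loci follows a two-regime power law with a
*downward* bend when $H_\text{short} > H_\text{long}$ — the neuron-like
signature. This is equivalent to summing a band-limited fine chain
(exponent $H_\text{short}$) and a coarse chain (exponent $H_\text{long}$)
whose amplitudes meet at the crossover. We note for the record that a naive
sum of two *unrestricted* fractional-Brownian chains cannot produce this
bend: the log-log slope of a sum of two power laws always increases with
distance, so the fine component must be band-limited; this drove the
spectral formulation.

The mode grid extends to twice the locus-spacing Nyquist frequency over a
period four times the chromosome span (capped at 4000 modes). The chain is
scaled deterministically so its expected radius of gyration is
`rg_frac * R` (default 0.35 of the nuclear radius), placed at a territory
center drawn uniformly from the half-radius ball, and kept inside the
nucleus by a smooth monotone radial squash with asymptote 0.95 R (a hard
clip would kink the chain).

## Planted compartments, megadomains, and the KO mode

* **Compartments.** Loci alternate between A and B in blocks of
  `block_size`. Segregation is planted by a radial warp of strength
  $\gamma$: A loci are translated inward and B loci outward along the
  territory's radial direction by $0.45\,\gamma R$ each, followed by a
  window-3 moving-average smoothing that restores chain continuity at the
  block boundaries. Label-wise translations preserve the within-compartment
  backbone, so A-A and B-B contacts keep their genomic-distance expectation
  while A-B contacts are depleted — a plaid pattern — and the mean
  normalized radial position of A minus B decreases with $\gamma$ (zero at
  $\gamma = 0$ within Monte-Carlo error). An earlier power-map variant
  ($r \to r^{1\pm\gamma}$) was rejected during development because scaling
  radii about the nuclear center dilates B-B distances exactly like A-B
  ones, leaving compartment B detectable only as "not A" and capping label
  recovery well below the planted-structure contract.
* **Megadomains.** Loci beyond the megadomain boundary (default: half the
  chromosome) are offset by `mega_amp` micrometers along a random direction
  per homolog, separating the two domains without touching the A/B plaid.
* **KO de-segregation.** A knockout cell is a convex mixture
  $(1-m)\,p_\text{warped} + m\,p_\text{unwarped}$ toward the label-blind
  configuration, so `mixing = 0.5` halves the planted radial bias — A loci
  lose interior enrichment, B loci gain it, which propagates to the local
  A/B density ratio with the expected sign pattern.
* **Detection.** Each locus is retained independently with probability
  `p_det` (default 0.75 — real per-locus decoding efficiency is
  experiment-specific, so this is a free, fixed choice) and blurred with isotropic
  Gaussian localization noise (default sd 50 nm).

Per-cell RNG streams are derived from `(seed, cell counter)` through an
integer hash, so populations are reproducible and independent of
generation order.

## Matched expression

Gene counts are negative binomial with mean
`activity_scale(cell type) * exp(alpha * A + eps_gene)`; `nb_size = Inf`
gives the Poisson limit. Nuclear radii default to
`3 * activity_scale^(1/3)` um so total transcription and nuclear volume are
coupled across cell types (radii roughly 2.5-5.5 um over the default
eight-type activity range, a realistic span for brain nuclei). KO cells add
a per-gene log-shift whose sign follows the locus's planted radial position
(interior down, peripheral up), scaled by `ko_expr_shift` and a per-cell-
type factor — the coupling that makes DE-score profiles cross zero from
nuclear interior to periphery.

What the generator does **not** emulate: loop extrusion or any polymer
physics beyond the two-regime contract, chromatin fiber stiffness,
inter-homolog pairing, nuclear envelope irregularity, segmentation errors,
or spatially correlated detection artifacts. Passing tests demonstrate
estimator correctness on data with planted structure, not biological
discovery on real tissue.

# Codebook design

MERFISH barcodes are constant-weight binary codes: `n_bits` rounds of
imaging, exactly `w` "on" bits per target, minimum pairwise Hamming
distance 4 (for equal-weight words, HD(a,b) = 2(w - shared on-bits), which
makes the constraint a bound on shared on-bits and single-error correction
valid). `build_code()` enumerates all `choose(n_bits, w)` words and runs a
randomized greedy accept/reject pass over each of `restarts` shuffles,
keeping the largest code; the pairwise minimum distance is re-verified
exhaustively before return. Such codes are often drawn from external
covering-design repositories; the greedy construction is self-contained,
verifiable, and comfortably exceeds the panel sizes used in practice
(22-bit/HW4: ~299 words vs 242 genes; 99-bit/HW3: ~1500 vs 988 loci;
95-bit/HW3: ~1390 vs 965 loci).

`assign_barcodes()` follows the stated design goals: per-bit usage balanced
within each chromosome and globally (greedy min-max load, candidate order
seeded), then within-chromosome barcode swaps to a fixed point that
lexicographically maximize the minimum genomic distance between loci
sharing an on-bit and, at ties, minimize the coefficient of variation of
those distances. The seeded candidate order doubles as the tie-break so
that distinct seeds can yield distinct, equally balanced assignments while
a fixed seed is fully deterministic.

# Panel design

Genome-wide loci are 20-kb windows placed at fixed spacing (default
2.5 Mb), excluding chromosome Y. Probe target windows are 42-nt; windows
are filtered on GC (40-60%) and nearest-neighbor melting temperature
(57-67 C) and selected greedily left-to-right without overlap; a locus is
rejected below 50 windows. The Tm model uses unified nearest-neighbor
thermodynamics with a monovalent-salt entropy correction and a linear
formamide depression; the default buffer (0.3 M Na+, 30% formamide, 5 nM
oligo) was chosen once so that typical 40-60% GC 42-mers fall inside the
57-67 C band — at a bare 1 M Na+ reference, 42-mers melt in the high 70s
and the band would reject nearly everything, so a 57-67 C window
implicitly assumes a hybridization buffer.

Super-enhancer calling per cell type: drop peaks within 2.5 kb of a TSS,
stitch peaks within 12.5 kb (edge-to-edge), rank stitched regions by
summed signal and keep those above the slope-1 tangent point of the
min-max-scaled rank curve (the classic ROSE rule — implemented as the rank
minimizing scaled signal minus scaled rank). Across cell types,
super-enhancers within 100 kb are merged iteratively to a fixed point;
merged regions are kept when the mean member-length/merged-length ratio is
at least 0.8 and the merged length exceeds 15 kb. Member lengths are
post-ROSE region lengths: only called super-enhancers enter the merge
(merging pre-ROSE stitched regions is the plausible alternative).

# Nuclear geometry

The nucleus of a cell is proxied by the 3D convex hull of all its decoded
loci (at least 1250 loci for volume estimates, 600 for radial analyses).
The hull is computed by an incremental algorithm in compiled code and was
cross-checked against an independent qhull implementation (identical
volumes to 10 decimal places on a 5000-point sample). A finite sample of a
ball underestimates the ball: 5.7% missing volume at 5000 uniform points,
4.4% at 10000 — relative comparisons between cells of similar locus counts
are unaffected.

Normalized radial positions divide the distance of a locus from the hull's
*volume* centroid (robust to locus-density asymmetry, unlike the mean of
points) by the distance at which that ray exits the hull; for a convex
polytope the exit parameter is the minimum over faces with positive
normal-dot-direction, which needs no triangle test and is deterministic at
edges. Values marginally above 1 are clipped; more than 1% substantive
clips trigger a warning. Territory size is the radius of gyration of a
homolog's loci; territory intermixing is the mean fraction of a locus's k
nearest neighbors (default 10) on a different chromosome — a stand-in
definition, since no published formula for the intermixing metric is
available to us.

# Scaling analysis

`pairwise_distance_table()` computes, per cis locus pair (same chromosome,
same homolog — homologs are never mixed), the median spatial distance over
all copies with both loci decoded, dropping pairs seen fewer than 20
times. `fit_scaling()` fits log-median-distance against log-genomic-
distance by least squares separately below and at-or-above the 10-Mb
boundary (boundary pairs go long; each pair weighs equally, matching a
scatter of locus pairs rather than of distance bins), plus an order-2
polynomial over the full range for plotting. Exponents are invariant to
global spatial rescaling and genomic-unit changes. Proximity fractions use
the 0.75-um cutoff. Activity-binned fits split pairs by mean locus
activity into quantile bins, so constant activity degenerates to a single
bin and `n_bins = 1` reproduces the plain fit exactly. Both pooled and
per-chromosome fits are available (`--per-chrom` in the CLI); the pooled
mode is the default summary.

# Compartments, insulation, megadomains

The per-chromosome observed/expected proximity matrix divides the fraction
of copies within 0.75 um by the mean over all pairs in the same log-spaced
genomic-distance bin (20 bins per decade; the bin count is a free choice
and the property tests do not depend on it).
Compartments are called by PCA on the column-centered cross-correlation
matrix — Pearson correlation between matrix rows, excluding for each pair
the diagonal and its two adjacent entries to avoid self-correlation
inflation. Among the first three PCs, the one best correlated (in absolute
value) with CpG density is selected, sign-oriented so the correlation is
positive, and loci with positive values are labeled A. Restricting to
three candidates reflects that a megadomain-dominated chromosome puts the
A/B axis on a lower PC; the synthetic megadomain configuration exercises
exactly this case.

The segregation score divides each pair's distance by the median of its
genomic-distance bin, then takes median(A-B) / median(A-A and B-B pooled);
permuted labels give 1.00 +/- 0.02 on synthetic data. Insulation at
position i is the mean O/E over the w x w square spanning the boundary
(w = 5 loci, about 12.5 Mb at 2.5-Mb spacing), normalized as log2 of its
ratio to the chromosome mean; its IQR summarizes domain prominence and its
global minimum is the de novo megadomain boundary. Megadomain strength is
the median distance of boundary-crossing pairs over non-crossing pairs, on
raw distances by default (a genomic-distance-normalized variant is
provided but non-default, because the defining ratio is stated on raw
distances).

# Local chromatin environment and perturbation comparisons

The local A/B density ratio of a locus in a cell is the Gaussian-kernel
density (sd 1 um; the sensitivity of conclusions to 0.5-2 um is exercised
in tests) of trans-chromosomal compartment-A loci over compartment-B loci,
with a 1e-3 pseudocount; both homologs are scored independently, and cells
need at least 10 trans loci. Per-locus summaries take the median over
cells (the median-of-ratios reading; ratio-of-medians is the plausible
alternative). Group normalization divides by the grand mean over loci so
each group's mean is 1, removing global between-group offsets.

Genes map to the nearest locus with a TSS within 100 kb of the locus
interval (ties to the lower coordinate); locus activity is the summed
counts of mapped genes with top/bottom-quartile classes. DE scores are
Welch t statistics (KO minus WT) on per-cell counts scaled to the median
total. The WT-vs-KO comparison reports per-locus changes of group-
normalized median ratios and radial positions, deciles on WT radial
position, per-compartment one-sample t tests against zero with Bonferroni
correction, and the Spearman correlation between delta-ratio deciles and
mean DE scores. Comparisons default to at least 50 cells per genotype.

# Numerical choices and degenerate inputs

Coordinates are 0-based half-open genomically (BED) and micrometer-scaled
spatially; genomic distance between loci is midpoint-to-midpoint; strand
is ignored throughout. Missing data are absent rows or NaN, never
sentinels. Readers reject invariant violations (duplicate keys, non-finite
coordinates, unknown loci) rather than coercing. Degenerate hulls
(coplanar cells) yield NA volumes with a reason flag. Constant proximity
matrices abort compartment calling with a "no structure" error. Zero
variance in both DE groups yields NA. All stochastic operations take seeds
from the configuration; per-cell streams are counter-derived.

Problem sizes used in the validation suite — e.g. 200 cells x 100 loci for
exponent recovery, 500 cells x 40 loci for compartment recovery, 150
cells per genotype x 4 chromosomes for the KO contracts — were chosen as
the smallest populations at which the planted effects are comfortably
resolved, and are fixed.

# Known limitations

* The hull-based nucleus underestimates true nuclear volume at low locus
  counts; comparisons should hold locus-count thresholds fixed.
* The intermixing metric is a kNN stand-in, not a published definition.
* The generator's KO mode alters only radial segregation and expression;
  it does not model compartment identity switching, so conserved-
  compartment filtering on synthetic data conserves nearly all loci.
* Compartment calling assumes CpG density is informative for orientation
  (the generator defaults to correlation 0.8); with uninformative CpG the
  A/B orientation is arbitrary even though the partition is recovered.
* The two-regime fit reports attenuated short-range exponents when the
  short regime spans less than a decade of genomic distance (only three
  distinct separations below 10 Mb at 2.5-Mb spacing); the single-regime
  recovery contract (+/- 0.05) is met with the full range.
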