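# chromtrace

Cell type-resolved 3D genome analysis of multiplexed DNA-FISH chromatin
traces.

Genome-scale chromatin tracing (DNA-MERFISH) decodes the 3D positions of
hundreds of genomic loci in each of thousands of single cells, homolog by
homolog. `chromtrace` is an R package for everything that happens after
decoding: it is written for computational biologists who have (or want to
simulate) a table of per-cell, per-locus 3D coordinates and need the
standard battery of 3D-genome statistics, per cell type and between
genotypes.

The package implements:

* **Codebook design** — constant-weight error-correcting barcodes
  (`n` bits, Hamming weight `w`, minimum pairwise distance 4; for
  equal-weight words HD(a,b) = 2(w − |a∩b|)), built by randomized greedy
  search over the full enumeration with restarts, verified exhaustively;
  balanced, genomic-distance-aware barcode-to-locus assignment; and
  single-error-correcting decoding.
* **Panel design** — evenly spaced 20-kb loci (Y excluded), 42-nt probe
  windows filtered on GC and nearest-neighbor T_m, and super-enhancer
  calling from ATAC peaks (TSS exclusion, 12.5-kb stitching, ROSE tangent
  cutoff, cross-cell-type merging).
* **Nuclear geometry** — convex-hull nuclear volume (own incremental 3D
  hull, qhull-verified), normalized radial positions `r = |p−c| / |q−c|`
  along the centroid ray, territory radius of gyration and intermixing.
* **Scaling** — median spatial distance versus genomic distance for cis
  pairs, two-regime power-law fits around a 10-Mb boundary
  (`d ∝ g^S`), proximity fractions within 0.75 µm, activity-binned fits.
* **Compartments** — observed/expected proximity matrices,
  cross-correlation PCA with CpG-oriented A/B labels, segregation score,
  insulation profiles and IQR, megadomain strength, compartment-change
  accounting.
* **Local environment** — per-cell trans-chromosomal local A/B density
  ratio (Gaussian kernel), gene-to-locus mapping, locus activity, Welch-t
  DE scores, radial-decile profiles, and WT-vs-KO perturbation
  comparisons with Bonferroni-corrected per-compartment tests.
* **Synthetic data** — a generator that plants compartments, megadomains,
  two-regime scaling, radial biases, detection dropout and a KO
  de-segregation mode, so every estimator is tested against ground truth.

## Worked example

Simulate a neuron-like cell type (two-regime scaling bending at 10 Mb,
compartment-A loci biased toward the nuclear interior with strength
γ = 0.4), then recover the planted structure:

```r
library(chromtrace)

p <- sim_params(
  chromosomes = data.frame(name = c("chr1", "chr2"), n_loci = 40L,
                           spacing = 2.5e6),
  cell_types  = data.frame(name = "neuron_like", activity_scale = 2),
  block_size = 20L, gamma = 0.4, H_short = 0.45, H_long = 0.2, seed = 7L)
tp     <- make_truth_panel(p)
traces <- simulate_cells(tp$panel, tp$truth, p, n_cells = 300)

fit <- fit_scaling(pairwise_distance_table(traces, tp$panel, min_cells = 20))
print(fit)
#> scaling fit: S_short = 0.737 (n=228, R2=0.890), S_long = 0.376 (n=1332,
#> R2=0.814), boundary 1e+07 bp

prox <- normalized_proximity_matrix(traces, tp$panel, "chr1")
cc   <- call_compartments(prox, tp$panel$cpg_density[tp$panel$chrom == "chr1"])
mean(cc$profile$label == tp$truth$compartment[tp$truth$chrom == "chr1"])
#> [1] 1

labels <- setNames(tp$truth$compartment, tp$truth$locus_id)
segregation_score(traces, tp$panel, labels, "chr1")
#> [1] 1.133

median(cell_geometry(traces, min_loci = 100)$nuclear_volume)
#> [1] 28.3
```

Reading the output: the fitted exponents drop from 0.74 below 10 Mb to
0.38 above it — the downward bend characteristic of neurons (in this demo
the short-range exponent also absorbs the compartment warp, so it sits
above the backbone value of 0.45). Compartment calling recovers all 40
planted A/B labels on chr1 from the proximity matrix alone, the
segregation score of 1.13 means A–B pairs are 13% farther apart than
same-compartment pairs after controlling for genomic distance, and the
median convex-hull volume of ~28 µm³ is the nuclear-size proxy used for
volume-versus-activity comparisons.

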