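# Shared builders for the synthetic test bed. Small configurations keep the
# default suite fast; the acceptance tests use larger populations.

synth_params <- function(n_chrom = 2, n_loci = 30L, block_size = 15L,
                         gamma = 0.4, mixing = 0, mega_amp = 0,
                         H_short = 0.45, H_long = 0.2, p_det = 0.85,
                         seed = 1L, ...) {
  sim_params(
    chromosomes = data.frame(name = paste0("chr", seq_len(n_chrom)),
                             n_loci = n_loci, spacing = 2.5e6,
                             stringsAsFactors = FALSE),
    cell_types = data.frame(name = "ct1", activity_scale = 1,
                            stringsAsFactors = FALSE),
    block_size = block_size, gamma = gamma, mixing = mixing,
    mega_amp = mega_amp, H_short = H_short, H_long = H_long,
    p_det = p_det, seed = seed, ...)
}

synth_traces <- function(params, n_cells = 100, genotype = "WT") {
  tp <- make_truth_panel(params)
  list(panel = tp$panel, truth = tp$truth,
       labels = setNames(tp$truth$compartment, tp$truth$locus_id),
       traces = simulate_cells(tp$panel, tp$truth, params,
                               n_cells = n_cells, genotype = genotype))
}

# a minimal hand-built trace table (one cell, arbitrary positions)
toy_trace <- function(coords, chrom = "chr1", cell_id = "c1",
                      locus_id = sprintf("L%03d", seq_len(nrow(coords))),
                      homolog = 1L, cell_type = "t", genotype = "WT") {
  data.frame(cell_id = cell_id, cell_type = cell_type, genotype = genotype,
             chrom = chrom, locus_id = locus_id, homolog = homolog,
             x = coords[, 1], y = coords[, 2], z = coords[, 3],
             stringsAsFactors = FALSE)
}

toy_panel <- function(n = 3, chrom = "chr1", spacing = 2.5e6,
                      locus_id = sprintf("L%03d", seq_len(n))) {
  data.frame(locus_id = locus_id, chrom = chrom,
             start = (seq_len(n) - 1) * spacing,
             end = (seq_len(n) - 1) * spacing + 20000,
             stringsAsFactors = FALSE)
}
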