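test_that("median distance matrix is symmetric, zero-diagonal, hand-checked", {
  panel <- toy_panel(3)
  tr <- rbind(toy_trace(cbind(c(0, 1, 3), 0, 0)),
              toy_trace(cbind(c(0, 2, 7), 0, 0), cell_id = "c2"))
  dm <- median_distance_matrix(tr, panel, "chr1", min_cells = 1)
  D <- dm$distances
  expect_true(isSymmetric(D))
  expect_equal(unname(diag(D)), rep(0, 3))
  expect_equal(D["L001", "L002"], median(c(1, 2)))
  expect_equal(D["L002", "L003"], median(c(2, 5)))
  expect_equal(D["L001", "L003"], median(c(3, 7)))
  expect_error(median_distance_matrix(tr, panel, "chrX"), "absent")
  # a never-decoded locus leaves an NA row/column
  panel4 <- toy_panel(4)
  dm4 <- median_distance_matrix(tr, panel4, "chr1", min_cells = 1)
  expect_true(all(is.na(dm4$distances["L004", -4])))
})

test_that("observed/expected proximity is 1 when the cutoff swallows all", {
  p <- synth_params(n_chrom = 1, n_loci = 20L, block_size = 10L, p_det = 1)
  s <- synth_traces(p, n_cells = 25)
  prox <- normalized_proximity_matrix(s$traces, s$panel, "chr1",
                                      cutoff = Inf, min_cells = 1)
  off <- prox$normalized[!diag(TRUE, 20)]
  expect_true(all(abs(off - 1) < 1e-12, na.rm = TRUE))
  expect_true(all(prox$observed[!diag(TRUE, 20)] == 1, na.rm = TRUE))
})

test_that("uniform random coordinates give O/E within [0.5, 2]", {
  set.seed(30)
  n_cells <- 500
  panel <- toy_panel(20)
  rows <- do.call(rbind, lapply(seq_len(n_cells), function(i)
    toy_trace(matrix(runif(60, 0, 2), ncol = 3),
              cell_id = sprintf("c%03d", i),
              locus_id = sprintf("L%03d", 1:20))))
  prox <- normalized_proximity_matrix(rows, panel, "chr1", cutoff = 0.75,
                                      min_cells = 10)
  off <- prox$normalized[!diag(TRUE, 20)]
  expect_true(all(is.finite(off)))
  expect_true(all(off >= 0.5 & off <= 2))
})

test_that("planted blocks enrich within-block proximity", {
  p <- synth_params(n_chrom = 1, n_loci = 30L, block_size = 15L,
                    gamma = 0.4, seed = 2L)
  s <- synth_traces(p, n_cells = 150)
  prox <- normalized_proximity_matrix(s$traces, s$panel, "chr1",
                                      min_cells = 20)
  lab <- s$truth$compartment
  same <- outer(lab, lab, `==`) & !diag(TRUE, 30)
  cross <- outer(lab, lab, `!=`)
  expect_gt(mean(prox$normalized[same], na.rm = TRUE),
            mean(prox$normalized[cross], na.rm = TRUE))
})

test_that("compartment calling recovers planted labels and orients by CpG", {
  p <- synth_params(n_chrom = 1, n_loci = 40L, block_size = 20L,
                    gamma = 0.4, seed = 7L)
  s <- synth_traces(p, n_cells = 300)
  prox <- normalized_proximity_matrix(s$traces, s$panel, "chr1",
                                      min_cells = 20)
  cpg <- s$panel$cpg_density
  cc <- call_compartments(prox, cpg)
  expect_gte(mean(cc$profile$label == s$truth$compartment), 0.95)
  expect_gt(cor(cc$profile$pc_value, cpg), 0)
  # constant matrix: no structure
  flat <- prox
  flat$normalized[] <- 1
  expect_error(call_compartments(flat, cpg), "no structure")
})

test_that("megadomain-dominant structure pushes compartments off PC1", {
  p <- synth_params(n_chrom = 1, n_loci = 40L, block_size = 4L,
                    gamma = 0.15, mega_amp = 1.2, seed = 11L)
  s <- synth_traces(p, n_cells = 250)
  prox <- normalized_proximity_matrix(s$traces, s$panel, "chr1",
                                      min_cells = 20)
  cc <- call_compartments(prox, s$panel$cpg_density)
  expect_gt(cc$pc_index, 1)
})

test_that("segregation score exceeds 1 when planted and is 1 under permutation", {
  p <- synth_params(n_chrom = 1, n_loci = 40L, block_size = 4L,
                    gamma = 0.4, seed = 13L)
  s <- synth_traces(p, n_cells = 150)
  sc <- segregation_score(s$traces, s$panel, s$labels, "chr1")
  expect_gt(sc, 1.05)
  set.seed(4)
  null <- replicate(40, {
    pl <- setNames(sample(s$labels), names(s$labels))
    segregation_score(s$traces, s$panel, pl, "chr1")
  })
  expect_lt(abs(mean(null) - 1), 0.02)
  all_a <- setNames(rep("A", length(s$labels)), names(s$labels))
  expect_error(segregation_score(s$traces, s$panel, all_a, "chr1"),
               "both compartment labels")
})

test_that("insulation profile flags block junctions and flat matrices", {
  # uniform matrix: flat profile, IQR 0
  U <- matrix(1, 30, 30)
  ins_u <- insulation_profile(U, window = 5)
  expect_equal(ins_u$iqr, 0)
  expect_true(all(abs(ins_u$profile$normalized) < 1e-12))
  # constructed two-block matrix: global minimum at the junction
  M <- matrix(0.2, 30, 30)
  M[1:15, 1:15] <- 1
  M[16:30, 16:30] <- 1
  ins <- insulation_profile(M, window = 5)
  expect_equal(ins$boundary, 16)
  expect_error(insulation_profile(M, window = 15), "n/2")
})

test_that("megadomain strength is 1 on uniform input and > 1 when planted", {
  U <- matrix(1, 20, 20)
  diag(U) <- 0
  expect_equal(megadomain_strength(U, 10), 1)
  expect_error(megadomain_strength(U, 20), "strictly inside")
  expect_error(megadomain_strength(U, 0), "strictly inside")
  p <- synth_params(n_chrom = 1, n_loci = 30L, block_size = 5L,
                    gamma = 0.1, mega_amp = 1, seed = 15L)
  s <- synth_traces(p, n_cells = 120)
  dm <- median_distance_matrix(s$traces, s$panel, "chr1", min_cells = 20)
  b <- floor(30 * 0.5)
  expect_gt(megadomain_strength(dm, b), 1)
  # insulation IQR higher with megadomain than without
  p0 <- synth_params(n_chrom = 1, n_loci = 30L, block_size = 5L,
                     gamma = 0.1, mega_amp = 0, seed = 15L)
  s0 <- synth_traces(p0, n_cells = 120)
  pr1 <- normalized_proximity_matrix(s$traces, s$panel, "chr1", min_cells = 20)
  pr0 <- normalized_proximity_matrix(s0$traces, s0$panel, "chr1",
                                     min_cells = 20)
  expect_gt(insulation_profile(pr1, 5)$iqr, insulation_profile(pr0, 5)$iqr)
  # de novo boundary detection lands near the planted boundary
  expect_lt(abs(detect_megadomain_boundary(pr1, 5) - b), 4)
})

test_that("compartment change fractions sum to one and match hand counts", {
  ref <- c("A", "A", "A", "B", "B", "B", "A", "B", "A", "B")
  oth <- c("A", "B", "A", "B", "A", "B", "A", "B", "B", "B")
  ch <- compartment_change(ref, oth)
  expect_equal(sum(ch), 1)
  expect_equal(unname(ch["A_B"]), 0.2)  # positions 2 and 9
  expect_equal(unname(ch["B_A"]), 0.1)  # position 5
  expect_equal(unname(ch["A_A"]), 0.3)
  expect_equal(unname(ch["B_B"]), 0.4)
  expect_equal(unname(compartment_change(ref, ref)[c("A_B", "B_A")]),
               c(0, 0))
  flip <- ifelse(ref == "A", "B", "A")
  expect_equal(unname(compartment_change(ref, flip)[c("A_A", "B_B")]),
               c(0, 0))
  expect_error(compartment_change(ref, oth[-1]), "length")
})
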