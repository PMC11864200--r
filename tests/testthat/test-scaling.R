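test_that("pair table medians match hand computation", {
  panel <- toy_panel(3)
  # one cell, collinear loci at 0, 3, 4 um -> pair distances 3, 1, 4
  tr <- toy_trace(cbind(c(0, 3, 4), 0, 0))
  tab <- pairwise_distance_table(tr, panel, min_cells = 1)
  expect_equal(tab$median_spatial_dist[tab$locus_i == "L001" &
                                         tab$locus_j == "L002"], 3)
  expect_equal(tab$median_spatial_dist[tab$locus_i == "L002" &
                                         tab$locus_j == "L003"], 1)
  expect_equal(tab$median_spatial_dist[tab$locus_i == "L001" &
                                         tab$locus_j == "L003"], 4)
  expect_equal(unique(tab$genomic_dist[tab$locus_i == "L001" &
                                         tab$locus_j == "L002"]), 2.5e6)
  # two cells with distances 1 and 3 for one pair: median 2
  tr2 <- rbind(toy_trace(cbind(c(0, 1), 0, 0), locus_id = c("L001", "L002")),
               toy_trace(cbind(c(0, 3), 0, 0), locus_id = c("L001", "L002"),
                         cell_id = "c2"))
  tab2 <- pairwise_distance_table(tr2, panel, min_cells = 1)
  expect_equal(tab2$median_spatial_dist, 2)
  expect_equal(tab2$n_obs, 2L)
  # min_cells excludes under-observed pairs
  expect_equal(nrow(pairwise_distance_table(tr2, panel, min_cells = 3)), 0)
})

test_that("homologs are never mixed when computing cis distances", {
  panel <- toy_panel(2)
  tr <- rbind(toy_trace(cbind(c(0, 1), 0, 0), locus_id = c("L001", "L002"),
                        homolog = 1L),
              toy_trace(cbind(c(10, 30), 0, 0), locus_id = c("L001", "L002"),
                        homolog = 2L))
  tab <- pairwise_distance_table(tr, panel, min_cells = 1)
  expect_equal(tab$n_obs, 2L)          # one obs per homolog
  expect_equal(tab$median_spatial_dist, median(c(1, 20)))
})

test_that("an exact power law is fitted exactly and units do not matter", {
  g <- 10^seq(5.5, 8.5, length.out = 40)
  tab <- data.frame(chrom = "chr1", locus_i = sprintf("a%02d", 1:40),
                    locus_j = sprintf("b%02d", 1:40), genomic_dist = g,
                    median_spatial_dist = g^0.5, n_obs = 50L)
  fit <- fit_scaling(tab, boundary = 1e7)
  expect_equal(fit$S_short, 0.5, tolerance = 1e-9)
  expect_equal(fit$S_long, 0.5, tolerance = 1e-9)
  # genomic unit change (bp -> Mb) shifts intercepts only
  tab_mb <- tab
  tab_mb$genomic_dist <- tab_mb$genomic_dist / 1e6
  fit_mb <- fit_scaling(tab_mb, boundary = 10)
  expect_equal(fit_mb$S_short, fit$S_short, tolerance = 1e-9)
  # global spatial rescaling leaves exponents unchanged
  tab_sc <- tab
  tab_sc$median_spatial_dist <- tab_sc$median_spatial_dist * 3.7
  fit_sc <- fit_scaling(tab_sc, boundary = 1e7)
  expect_equal(fit_sc$S_short, fit$S_short, tolerance = 1e-9)
  expect_equal(fit_sc$S_long, fit$S_long, tolerance = 1e-9)
  # a regime with < 3 distinct distances yields NA
  fit_na <- fit_scaling(tab[tab$genomic_dist > 1e7, ], boundary = 1e7)
  expect_true(is.na(fit_na$S_short))
  expect_false(is.na(fit_na$S_long))
})

test_that("single-regime simulation recovers its exponent", {
  p <- synth_params(n_chrom = 1, n_loci = 60L, block_size = 30L,
                    gamma = 0, H_short = 0.33, H_long = 0.33, p_det = 1,
                    seed = 3L)
  s <- synth_traces(p, n_cells = 80)
  tab <- pairwise_distance_table(s$traces, s$panel, min_cells = 20)
  fit <- fit_scaling(tab, boundary = 1e7)
  expect_lt(abs(fit$S_short - 0.33), 0.05)
  expect_lt(abs(fit$S_long - 0.33), 0.05)
})

test_that("two-regime simulation bends downward at the crossover", {
  p <- synth_params(n_chrom = 1, n_loci = 80L, block_size = 40L,
                    gamma = 0, H_short = 0.45, H_long = 0.2,
                    p_det = 1, seed = 4L)
  s <- synth_traces(p, n_cells = 80)
  tab <- pairwise_distance_table(s$traces, s$panel, min_cells = 20)
  fit <- fit_scaling(tab, boundary = 1e7)
  expect_gt(fit$S_short, fit$S_long)
})

test_that("proximity fractions partition proximal pairs", {
  panel <- toy_panel(4)
  tr <- toy_trace(cbind(c(0, 0.1, 0.2, 0.3), 0, 0),
                  locus_id = sprintf("L%03d", 1:4))
  pf <- proximity_fractions(tr, panel, cutoff = 10,
                            genomic_bins = c(0, 5e6, Inf))
  expect_equal(sum(pf$fraction), 1)
  # all 6 pairs proximal; genomic bins: <5 Mb holds the 3 adjacent pairs
  expect_equal(pf$n_proximal[1], 3L)
  expect_equal(pf$n_proximal[2], 3L)
  expect_error(proximity_fractions(tr, panel, cutoff = 0.01), "no proximal")
})

test_that("short-range-compact generator shifts proximal pairs to short bins", {
  mk <- function(H) {
    p <- synth_params(n_chrom = 1, n_loci = 40L, block_size = 20L, gamma = 0,
                      H_short = H, H_long = H, p_det = 1, seed = 8L)
    s <- synth_traces(p, n_cells = 40)
    proximity_fractions(s$traces, s$panel, cutoff = 0.75,
                        genomic_bins = c(0, 1e7, Inf))
  }
  compact_short <- mk(0.2)   # shallow decay: distant loci still proximal
  steep <- mk(0.55)          # steep decay: proximity concentrated short-range
  expect_gt(steep$fraction[1], compact_short$fraction[1])
})

test_that("activity binning is consistent with the plain fit", {
  g <- 10^seq(5.5, 8.5, length.out = 60)
  tab <- data.frame(chrom = "chr1", locus_i = sprintf("a%02d", 1:60),
                    locus_j = sprintf("b%02d", 1:60), genomic_dist = g,
                    median_spatial_dist = g^0.4, n_obs = 50L)
  act <- setNames(runif(120), c(sprintf("a%02d", 1:60), sprintf("b%02d", 1:60)))
  one <- scaling_by_activity(tab, act, n_bins = 1)
  expect_equal(one$S_short, fit_scaling(tab)$S_short, tolerance = 1e-12)
  # constant activity: everything lands in bin 1
  const <- scaling_by_activity(tab, setNames(rep(2, 120), names(act)),
                               n_bins = 10)
  expect_equal(const$n_pairs[1], 60)
  expect_true(all(const$n_pairs[-1] == 0))
})

test_that("activity-coupled generator links activity to the short exponent", {
  # two chromosomes with different fine-scale exponents; activity higher on
  # the high-H chromosome
  p <- sim_params(chromosomes = data.frame(name = c("chr1", "chr2"),
                                           n_loci = 40L, spacing = 2.5e6,
                                           H_short = c(0.5, 0.25)),
                  cell_types = data.frame(name = "ct1", activity_scale = 1),
                  block_size = 20L, gamma = 0, H_short = 0.4, H_long = 0.4,
                  p_det = 1, seed = 21L)
  tp <- make_truth_panel(p)
  tr <- simulate_cells(tp$panel, tp$truth, p, n_cells = 40)
  tab <- pairwise_distance_table(tr, tp$panel, min_cells = 20)
  act <- setNames(ifelse(tp$panel$chrom == "chr1", 10, 1) +
                    runif(nrow(tp$panel)), tp$panel$locus_id)
  sba <- scaling_by_activity(tab, act, n_bins = 4)
  ok <- !is.na(sba$S_short)
  expect_gt(cor(sba$mean_activity[ok], sba$S_short[ok],
                method = "spearman"), 0)
})
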