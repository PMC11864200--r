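test_that("local A/B ratio is 1 for mirror-symmetric clouds and caps all-A", {
  # query locus at origin on chr1; trans loci mirror-symmetric A/B pairs
  set.seed(2)
  n <- 30
  pts <- matrix(rnorm(n * 3), ncol = 3)
  trans <- rbind(pts, -pts)
  tr <- rbind(
    toy_trace(matrix(0, 1, 3), chrom = "chr1", locus_id = "q"),
    toy_trace(trans, chrom = "chr2",
              locus_id = sprintf("t%03d", seq_len(2 * n))))
  labels <- c(q = "A", setNames(rep(c("A", "B"), each = n),
                                sprintf("t%03d", seq_len(2 * n))))
  env <- local_ab_density_ratio(tr, labels, kernel_scale = 1)
  expect_equal(env$local_ab_ratio[env$locus_id == "q"], 1, tolerance = 1e-9)
  # all trans loci labeled A: ratio = (D + eps)/eps, large and finite
  labels_a <- labels
  labels_a[] <- "A"
  env_a <- local_ab_density_ratio(tr, labels_a, kernel_scale = 1)
  r <- env_a$local_ab_ratio[env_a$locus_id == "q"]
  expect_true(is.finite(r) && r > 100)
  # fewer than min_trans trans loci: NA
  small <- tr[1:8, ]
  env_s <- local_ab_density_ratio(small, labels, min_trans = 10)
  expect_true(all(is.na(env_s$local_ab_ratio)))
  expect_error(local_ab_density_ratio(tr, labels[-1]), "labels missing")
})

test_that("ratio is rigid-motion invariant and A/B swap takes the reciprocal", {
  set.seed(9)
  tr <- rbind(
    toy_trace(matrix(rnorm(30), 10), chrom = "chr1",
              locus_id = sprintf("a%02d", 1:10)),
    toy_trace(matrix(rnorm(60), 20), chrom = "chr2",
              locus_id = sprintf("b%02d", 1:20)))
  labels <- setNames(rep(c("A", "B"), 15), c(sprintf("a%02d", 1:10),
                                             sprintf("b%02d", 1:20)))
  env <- local_ab_density_ratio(tr, labels, eps = 0)
  th <- 0.8
  Rz <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3)
  p2 <- sweep(as.matrix(tr[, c("x", "y", "z")]) %*% Rz, 2, c(4, -1, 2), `+`)
  tr2 <- tr
  tr2[, c("x", "y", "z")] <- p2
  env2 <- local_ab_density_ratio(tr2, labels, eps = 0)
  expect_equal(env2$local_ab_ratio, env$local_ab_ratio, tolerance = 1e-9)
  swapped <- setNames(ifelse(labels == "A", "B", "A"), names(labels))
  env_sw <- local_ab_density_ratio(tr, swapped, eps = 0)
  expect_equal(env_sw$local_ab_ratio, 1 / env$local_ab_ratio,
               tolerance = 1e-9)
})

test_that("interior-A planting raises the ratio of interior loci", {
  p <- synth_params(n_chrom = 4, n_loci = 15L, block_size = 5L,
                    gamma = 0.4, seed = 3L)
  s <- synth_traces(p, n_cells = 80)
  env <- local_env_table(s$traces, s$labels, min_loci = 60, min_trans = 10)
  loc <- locus_env_summary(env)
  dec <- equal_count_bins(loc$median_radial, 10)
  expect_gt(median(loc$median_ratio[dec == 1]),
            median(loc$median_ratio[dec == 10]))
})

test_that("group normalization removes global scale only", {
  s1 <- data.frame(locus_id = sprintf("L%02d", 1:10),
                   median_ratio = seq(0.5, 5, length.out = 10),
                   median_radial = runif(10), n_obs = 50L)
  s2 <- s1
  s2$median_ratio <- s1$median_ratio * 2  # global x2
  norm <- normalize_ratio_across_groups(list(g1 = s1, g2 = s2))
  expect_equal(norm$g1$norm_ratio, norm$g2$norm_ratio, tolerance = 1e-12)
  expect_equal(mean(norm$g1$norm_ratio), 1)
  expect_equal(mean(norm$g2$norm_ratio), 1)
  # per-locus differences survive normalization
  s3 <- s1
  s3$median_ratio[1] <- s3$median_ratio[1] * 3
  norm2 <- normalize_ratio_across_groups(list(g1 = s1, g2 = s3))
  expect_gt(norm2$g2$norm_ratio[1] / norm2$g1$norm_ratio[1], 1)
  expect_error(normalize_ratio_across_groups(list(g1 = s1)), "2 groups")
  expect_error(normalize_ratio_across_groups(list(g1 = s1, g2 = s1[0, ])),
               "empty group")
})

test_that("gene-to-locus mapping respects the window and tie-break rules", {
  panel <- toy_panel(2, spacing = 2e5)  # loci [0,20k) and [2e5,2.2e5)
  genes <- data.frame(
    gene_id = c("mid", "far", "tie", "off_chrom"),
    chrom = c("chr1", "chr1", "chr1", "chr9"),
    tss = c(10000,    # at locus 1 midpoint
            320001,   # 100,001 bp beyond locus 2: just outside the window
            110000,   # 90 kb from both edges, equidistant midpoints
            10000))
  map <- map_genes_to_loci(genes, panel, window = 1e5)
  expect_equal(map$locus_id[map$gene_id == "mid"], "L001")
  expect_true(is.na(map$locus_id[map$gene_id == "far"]))
  expect_equal(map$locus_id[map$gene_id == "tie"], "L001")  # lower coordinate
  expect_true(is.na(map$locus_id[map$gene_id == "off_chrom"]))
  # exactly at the window edge still maps
  edge <- data.frame(gene_id = "edge", chrom = "chr1", tss = -1e5)
  expect_equal(map_genes_to_loci(edge, panel, 1e5)$locus_id, "L001")
  just_out <- data.frame(gene_id = "j", chrom = "chr1", tss = -100001)
  expect_true(is.na(map_genes_to_loci(just_out, panel, 1e5)$locus_id))
})

test_that("locus activity sums mapped genes and classes split quartiles", {
  panel <- toy_panel(8)
  genes <- data.frame(gene_id = sprintf("g%d", 1:7), chrom = "chr1",
                      tss = c(1e4, 1.1e4, 2.51e6, 5.01e6, 7.51e6, 1.001e7,
                              1.251e7))
  map <- map_genes_to_loci(genes, panel, window = 1e5)
  counts <- setNames(c(7, 3, 5, 2, 9, 4, 6), genes$gene_id)
  act <- locus_activity(counts, map, panel)
  expect_equal(act$activity[act$locus_id == "L001"], 10)  # 7 + 3
  expect_equal(act$activity[act$locus_id == "L002"], 5)
  expect_true(is.na(act$activity[act$locus_id == "L008"]))
  expect_true(is.na(act$class[act$locus_id == "L008"]))
  n_ok <- sum(!is.na(act$activity))
  expect_equal(sum(act$class == "high", na.rm = TRUE),
               ceiling(n_ok * 0.25), tolerance = 1)
  one <- locus_activity(setNames(7, "g1"),
                        data.frame(gene_id = "g1", locus_id = "L001"), panel)
  expect_equal(one$activity[1], 7)
})

test_that("DE score matches the closed-form Welch t statistic", {
  set.seed(21)
  n_g <- 40
  wt <- matrix(rpois(n_g * 6, 20), n_g, dimnames = list(sprintf("g%02d", 1:n_g)))
  ko <- matrix(rpois(n_g * 8, 25), n_g, dimnames = list(sprintf("g%02d", 1:n_g)))
  # equalize totals so the normalization step is the identity
  wt <- sweep(wt, 2, colSums(wt), `/`) * 1000
  ko <- sweep(ko, 2, colSums(ko), `/`) * 1000
  t_pkg <- de_score(wt, ko)
  t_ref <- vapply(seq_len(n_g), function(g)
    unname(t.test(ko[g, ], wt[g, ])$statistic), numeric(1))
  expect_equal(unname(t_pkg), t_ref, tolerance = 1e-10)
  # identical groups: t = 0
  expect_true(all(de_score(wt, wt) == 0, na.rm = TRUE))
  expect_error(de_score(wt[, 1, drop = FALSE], ko), "2 cells")
  # zero variance in both groups: NA
  cz <- matrix(5, 3, 3, dimnames = list(c("a", "b", "c")))
  expect_true(all(is.na(de_score(cz, cz))))
})

test_that("radial bins are equal-count and profiles behave", {
  x <- runif(103)
  bins <- equal_count_bins(x, 10)
  expect_lte(diff(range(table(bins))), 1)
  prof_const <- radial_bin_analysis(rep(2, 100), runif(100), 10)
  expect_true(all(prof_const$mean == 2))
  expect_true(all(prof_const$ci_lo == 2 & prof_const$ci_hi == 2))
  r <- runif(200)
  prof_inc <- radial_bin_analysis(r, r, 10)
  expect_true(all(diff(prof_inc$mean) > 0))
  expect_error(radial_bin_analysis(1:5, runif(5), 10), "fewer")
})

test_that("KO with unchanged mixing yields null deltas; m = 0.5 the sign pattern", {
  p <- synth_params(n_chrom = 4, n_loci = 15L, block_size = 5L,
                    gamma = 0.4, mixing = 0, seed = 27L)
  tp <- make_truth_panel(p)
  labels <- setNames(tp$truth$compartment, tp$truth$locus_id)
  wt <- simulate_cells(tp$panel, tp$truth, p, n_cells = 60, genotype = "WT")
  ko0 <- simulate_cells(tp$panel, tp$truth, p, n_cells = 60, genotype = "KO")
  env_wt <- local_env_table(wt, labels, min_loci = 60, min_trans = 10)
  env_ko0 <- local_env_table(ko0, labels, min_loci = 60, min_trans = 10)
  pc0 <- perturbation_comparison(env_wt, env_ko0, labels, n_bins = 10)
  # m = 0: KO cells are statistically identical; no significant tests
  expect_true(all(pc0$tests$p_bonferroni > 0.05, na.rm = TRUE))
  expect_lt(max(abs(pc0$tests$mean_delta)), 0.05)
  # m = 0.5: de-segregation lowers A ratios, raises B ratios
  p5 <- synth_params(n_chrom = 4, n_loci = 15L, block_size = 5L,
                     gamma = 0.4, mixing = 0.5, seed = 27L)
  ko5 <- simulate_cells(tp$panel, tp$truth, p5, n_cells = 60, genotype = "KO")
  env_ko5 <- local_env_table(ko5, labels, min_loci = 60, min_trans = 10)
  pc5 <- perturbation_comparison(env_wt, env_ko5, labels, n_bins = 10)
  expect_lt(pc5$tests$mean_delta[pc5$tests$label == "A"], 0)
  expect_gt(pc5$tests$mean_delta[pc5$tests$label == "B"], 0)
  # interior-to-periphery increase of the delta profile
  prof <- pc5$decile_profile
  expect_lt(prof$mean_delta_ratio[1], prof$mean_delta_ratio[10])
})

test_that("conserved-compartment filtering reports change fractions", {
  lw <- setNames(rep(c("A", "B"), each = 10), sprintf("L%02d", 1:20))
  lk <- lw
  lk[c(3, 14)] <- c("B", "A")
  cons <- conserved_compartment_filter(lw, lk)
  expect_equal(length(cons$loci), 18)
  expect_equal(unname(cons$fractions["conserved"]), 0.9)
  expect_equal(unname(cons$fractions["A_B"]), 0.05)
  expect_equal(unname(cons$fractions["B_A"]), 0.05)
  ident <- conserved_compartment_filter(lw, lw)
  expect_equal(unname(ident$fractions["conserved"]), 1)
})
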