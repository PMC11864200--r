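# Synthetic chromatin-trace generator with planted ground truth.
#
# Each chromosome homolog is a Gaussian chain drawn by spectral synthesis:
# positions are sums of random-phase Fourier modes whose power spectrum is a
# broken power law, so the spatial-vs-genomic distance structure function
# scales as g^H_short below the crossover g_c and g^H_long above it (the
# fine, high-frequency band carries H_short; the coarse band H_long;
# amplitudes are continuous at the crossover). The chain is scaled to a
# target territory radius of gyration, placed in a spherical nucleus,
# optionally given a megadomain offset, radially warped so compartment-A
# loci move inward (strength gamma), optionally de-segregated by convex
# mixing toward the unwarped label-blind configuration (KO, weight m), then
# thinned by detection dropout and blurred by localization noise.

#' Simulation parameters
#'
#' Validated container for all generator tunables. Defaults describe a
#' neuron-like condition: two-regime scaling with a 10-Mb crossover,
#' compartment-A radial enrichment gamma = 0.4, 2.5-Mb locus spacing,
#' detection efficiency 0.75 and 50-nm localization noise.
#'
#' @param cell_types data.frame(name, activity_scale, nucleus_radius); when
#'   `nucleus_radius` is omitted it is set to `3 * activity_scale^(1/3)` um,
#'   an increasing function of transcriptional activity
#' @param chromosomes data.frame(name, n_loci, spacing) (+ optional
#'   per-chromosome H_short override column `H_short`)
#' @param block_size compartment block size in loci (alternating A/B blocks)
#' @param megadomain_frac fraction of each chromosome in megadomain 1
#' @param mega_amp megadomain separation offset in um (0 disables)
#' @param H_short,H_long scaling exponents in (0,1) below/above the crossover
#' @param crossover crossover genomic distance g_c in bp
#' @param gamma radial segregation strength (>= 0); compartment-A loci are
#'   warped inward via r -> r^(1+gamma), B outward via r -> r^(1-gamma)
#' @param mixing KO de-segregation weight m between 0 and 1
#' @param p_det per-locus detection probability in (0,1]
#' @param localization_sigma isotropic localization noise sd in um
#' @param cpg_rho target correlation between CpG density and the A indicator
#' @param rg_frac territory radius of gyration as a fraction of the nuclear
#'   radius
#' @param genes_per_locus genes simulated per locus neighborhood
#' @param alpha log-scale expression effect of the A compartment
#' @param nb_size negative-binomial size (dispersion) parameter; `Inf` gives
#'   Poisson counts
#' @param ko_expr_shift magnitude of the KO expression shift coupled to the
#'   locus truth radial position (interior down, peripheral up)
#' @param seed master seed; per-cell streams are derived by a counter scheme
#' @return validated list of class `ct_sim_params`
#' @export
sim_params <- function(cell_types = NULL,
                       chromosomes = NULL,
                       block_size = 4L,
                       megadomain_frac = 0.5,
                       mega_amp = 0,
                       H_short = 0.45, H_long = 0.2, crossover = 1e7,
                       gamma = 0.4, mixing = 0,
                       p_det = 0.75, localization_sigma = 0.05,
                       cpg_rho = 0.8, rg_frac = 0.35,
                       genes_per_locus = 3L, alpha = 1.0, nb_size = 2,
                       ko_expr_shift = 1.0, seed = 1L) {
  if (is.null(cell_types)) {
    act <- round(exp(seq(log(0.6), log(6), length.out = 8)), 3)
    cell_types <- data.frame(name = sprintf("ct%02d", seq_along(act)),
                             activity_scale = act,
                             stringsAsFactors = FALSE)
  }
  if (is.null(cell_types$nucleus_radius))
    cell_types$nucleus_radius <- 3 * cell_types$activity_scale^(1 / 3)
  if (is.null(cell_types$ko_factor)) cell_types$ko_factor <- 1
  if (is.null(chromosomes))
    chromosomes <- data.frame(name = c("chr1", "chr2"), n_loci = 40L,
                              spacing = 2.5e6, stringsAsFactors = FALSE)
  stopifnot(all(chromosomes$n_loci >= 2), all(chromosomes$spacing > 0),
            all(cell_types$nucleus_radius > 0),
            all(cell_types$activity_scale > 0))
  if (H_short <= 0 || H_short >= 1 || H_long <= 0 || H_long >= 1)
    stop("scaling exponents must lie in (0,1)")
  if (!is.null(chromosomes$H_short) &&
      any(chromosomes$H_short <= 0 | chromosomes$H_short >= 1, na.rm = TRUE))
    stop("per-chromosome H_short must lie in (0,1)")
  if (gamma < 0) stop("gamma must be >= 0")
  if (gamma >= 1) stop("gamma must be < 1 (B-outward warp exponent 1-gamma)")
  if (mixing < 0 || mixing > 1) stop("mixing must lie in [0,1]")
  if (p_det <= 0 || p_det > 1) stop("p_det must lie in (0,1]")
  if (localization_sigma < 0) stop("localization_sigma must be >= 0")
  if (cpg_rho < -1 || cpg_rho > 1) stop("cpg_rho must lie in [-1,1]")
  if (crossover <= 0) stop("crossover must be > 0")
  if (block_size < 1) stop("block_size must be >= 1")
  if (any(block_size > chromosomes$n_loci))
    stop("compartment block size exceeds chromosome length in loci")
  structure(list(cell_types = cell_types, chromosomes = chromosomes,
                 block_size = as.integer(block_size),
                 megadomain_frac = megadomain_frac, mega_amp = mega_amp,
                 H_short = H_short, H_long = H_long, crossover = crossover,
                 gamma = gamma, mixing = mixing, p_det = p_det,
                 localization_sigma = localization_sigma,
                 cpg_rho = cpg_rho, rg_frac = rg_frac,
                 genes_per_locus = as.integer(genes_per_locus),
                 alpha = alpha, nb_size = nb_size,
                 ko_expr_shift = ko_expr_shift, seed = as.integer(seed)),
            class = "ct_sim_params")
}

#' Build the locus panel and planted truth labels
#'
#' Loci are fixed 20-kb segments with starts at multiples of the spacing.
#' Compartment labels alternate in blocks of `block_size` loci; megadomain 1
#' covers the first `megadomain_frac` of each chromosome. CpG density is
#' drawn so that its correlation with the A indicator is `cpg_rho` in
#' expectation (`cpg_rho = 1` separates A from B exactly in rank order).
#'
#' @param params `ct_sim_params`
#' @return list(panel = locus panel data.frame, truth = data.frame(locus_id,
#'   chrom, index, compartment, megadomain, radial_truth))
#' @export
make_truth_panel <- function(params) {
  stopifnot(inherits(params, "ct_sim_params"))
  set.seed(derive_seed(params$seed, 90001))
  panels <- list()
  truths <- list()
  for (i in seq_len(nrow(params$chromosomes))) {
    ch <- params$chromosomes$name[i]
    n <- params$chromosomes$n_loci[i]
    sp <- params$chromosomes$spacing[i]
    k <- seq_len(n) - 1
    panels[[ch]] <- data.frame(
      locus_id = sprintf("%s_L%03d", ch, k + 1),
      chrom = ch, start = k * sp, end = k * sp + 20000,
      panel_group = "genome_wide", stringsAsFactors = FALSE)
    comp <- rep(rep(c("A", "B"), each = params$block_size), length.out = n)
    mega <- ifelse(k < floor(n * params$megadomain_frac), 1L, 2L)
    truths[[ch]] <- data.frame(
      locus_id = panels[[ch]]$locus_id, chrom = ch, index = k + 1L,
      compartment = comp, megadomain = mega, stringsAsFactors = FALSE)
  }
  panel <- do.call(rbind, panels)
  truth <- do.call(rbind, truths)
  a_ind <- as.numeric(truth$compartment == "A")
  a_std <- if (sd(a_ind) > 0) (a_ind - mean(a_ind)) / sd(a_ind) else a_ind * 0
  rho <- params$cpg_rho
  z <- rho * a_std + sqrt(max(0, 1 - rho^2)) * rnorm(nrow(truth))
  panel$cpg_density <- pmax(0, 5 + 1.5 * z)  # CpG per kb, non-negative
  # planted expected normalized radius: baseline ~0.45 shifted inward for A
  # and outward for B in proportion to the segregation strength
  truth$radial_truth <- 0.45 + ifelse(truth$compartment == "A", -1, 1) *
    0.3 * params$gamma
  panel <- panel[order(panel$chrom, panel$start), , drop = FALSE]
  truth <- truth[match(panel$locus_id, truth$locus_id), , drop = FALSE]
  rownames(panel) <- rownames(truth) <- NULL
  validate_locus_panel(panel)
  list(panel = panel, truth = truth)
}

# Precompute the spectral basis for one chromosome: an n x 2J matrix whose
# product with iid standard normal coefficients yields one chain coordinate
# with the broken power-law structure function, plus the deterministic scale
# factor mapping the chain to a target radius of gyration.
chain_basis <- function(mids, H_short, H_long, crossover, target_rg) {
  span <- max(mids) - min(mids)
  sp_min <- min(diff(sort(mids)))
  L <- 4 * span
  J <- min(4000L, max(32L, ceiling(2 * L / sp_min)))
  k <- (seq_len(J)) / L
  k_c <- 1 / crossover
  S <- ifelse(k >= k_c, k^(-(2 * H_short + 1)),
              k_c^(-(2 * H_short + 1)) * (k / k_c)^(-(2 * H_long + 1)))
  amp <- sqrt(S)
  ph <- outer(mids - min(mids), 2 * pi * k)
  B <- cbind(sweep(cos(ph), 2, amp, `*`), sweep(sin(ph), 2, amp, `*`))
  C <- tcrossprod(B)  # per-coordinate covariance of the chain
  rg2 <- 3 * (mean(diag(C)) - mean(C))  # expected 3D Rg^2 before scaling
  list(B = B, scale = sqrt(target_rg^2 / rg2))
}

# smooth a chain (n x 3) with a centered moving average, window 3
smooth_chain <- function(p) {
  n <- nrow(p)
  if (n < 3) return(p)
  up <- p[c(1, 1:(n - 1)), , drop = FALSE]
  dn <- p[c(2:n, n), , drop = FALSE]
  (up + p + dn) / 3
}

# draw one homolog chain already placed in the nucleus, before warping.
# Returns positions (n x 3) in um relative to the nuclear center.
draw_chain <- function(basis, R, mega, mega_amp, rg_frac) {
  n <- nrow(basis$B)
  coef <- matrix(rnorm(ncol(basis$B) * 3), ncol = 3)
  X <- basis$B %*% coef * basis$scale
  if (mega_amp > 0) {
    u <- rnorm(3)
    u <- u / sqrt(sum(u^2))
    X[mega == 2L, ] <- X[mega == 2L, , drop = FALSE] +
      rep(mega_amp, sum(mega == 2L)) %o% u
  }
  # territory center uniform in a ball of radius R/2
  repeat {
    cen <- runif(3, -1, 1)
    if (sum(cen^2) <= 1) break
  }
  p <- sweep(X, 2, cen * R / 2, `+`)
  # smooth radial squash keeps every locus strictly inside the nucleus
  r <- sqrt(rowSums(p^2)) / R
  f <- (1 + (r / 0.95)^8)^(-1 / 8)
  p * f
}

# Radial segregation warp: compartment-A loci are shifted inward and B loci
# outward along the homolog territory's radial direction by gamma * 0.45 * R
# each, then the chain is re-squashed into the nucleus and smoothed
# (window 3) to restore continuity. Label-wise translations preserve the
# within-compartment backbone structure, so A-A and B-B contacts keep their
# genomic-distance expectation while A-B pairs are stretched - the planted
# plaid - and the mean normalized radial position of A minus B decreases
# with gamma (0 at gamma = 0).
warp_chain <- function(p, R, labels, gamma) {
  if (gamma == 0) return(p)
  cen <- colMeans(p)
  nc <- sqrt(sum(cen^2))
  u <- if (nc > 1e-9) cen / nc else c(0, 0, 1)
  shift <- gamma * 0.45 * R
  a_sel <- labels == "A"
  p[a_sel, ] <- sweep(p[a_sel, , drop = FALSE], 2, shift * u, `-`)
  p[!a_sel, ] <- sweep(p[!a_sel, , drop = FALSE], 2, shift * u, `+`)
  r <- sqrt(rowSums(p^2)) / R
  f <- (1 + (r / 0.95)^8)^(-1 / 8)
  smooth_chain(p * f)
}

#' Simulate chromatin-trace rows for one cell
#'
#' @param bases list of chain bases per chromosome (internal; built by
#'   [simulate_cells()])
#' @param panel,truth from [make_truth_panel()]
#' @param params `ct_sim_params`
#' @param cell_id cell identifier string
#' @param cell_type row of `params$cell_types`
#' @param genotype "WT" or "KO" (KO applies the mixing de-segregation)
#' @return data.frame of trace rows for the cell
#' @export
simulate_cell <- function(bases, panel, truth, params, cell_id, cell_type,
                          genotype = "WT") {
  R <- cell_type$nucleus_radius
  m <- if (identical(genotype, "KO")) params$mixing else 0
  rows <- list()
  for (ch in names(bases)) {
    tr <- truth[truth$chrom == ch, , drop = FALSE]
    n <- nrow(tr)
    for (hom in 1:2) {
      p0 <- draw_chain(bases[[ch]], R, tr$megadomain, params$mega_amp,
                       params$rg_frac)
      pw <- warp_chain(p0, R, tr$compartment, params$gamma)
      p <- (1 - m) * pw + m * p0
      keep <- runif(n) < params$p_det
      if (!any(keep)) next
      p <- p[keep, , drop = FALSE] +
        matrix(rnorm(3 * sum(keep), sd = params$localization_sigma), ncol = 3)
      rows[[paste(ch, hom)]] <- data.frame(
        cell_id = cell_id, cell_type = cell_type$name, genotype = genotype,
        chrom = ch, locus_id = tr$locus_id[keep], homolog = hom,
        x = p[, 1], y = p[, 2], z = p[, 3], stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(NULL)
  do.call(rbind, rows)
}

#' Simulate a population of cells for one cell type and genotype
#'
#' Each cell draws from an independent RNG stream derived from
#' `(params$seed, cell counter)`, so the result is reproducible and
#' insensitive to generation order.
#'
#' @param panel,truth from [make_truth_panel()]
#' @param params `ct_sim_params`
#' @param n_cells number of cells
#' @param cell_type cell type name (must appear in `params$cell_types`)
#' @param genotype "WT" or "KO"
#' @param cell_offset counter offset so different populations get disjoint
#'   streams
#' @return chromatin trace data.frame
#' @export
simulate_cells <- function(panel, truth, params, n_cells,
                           cell_type = params$cell_types$name[1],
                           genotype = "WT", cell_offset = 0L) {
  stopifnot(inherits(params, "ct_sim_params"), n_cells >= 1)
  ct <- params$cell_types[params$cell_types$name == cell_type, , drop = FALSE]
  if (nrow(ct) != 1) stop("unknown cell type: ", cell_type)
  bases <- list()
  for (i in seq_len(nrow(params$chromosomes))) {
    ch <- params$chromosomes$name[i]
    mids <- locus_midpoints(panel[panel$chrom == ch, , drop = FALSE])
    Hs <- params$H_short
    if (!is.null(params$chromosomes$H_short) &&
        !is.na(params$chromosomes$H_short[i]))
      Hs <- params$chromosomes$H_short[i]
    bases[[ch]] <- chain_basis(mids, Hs, params$H_long, params$crossover,
                               params$rg_frac * ct$nucleus_radius)
  }
  out <- vector("list", n_cells)
  geno_tag <- if (identical(genotype, "KO")) 5e5 else 0
  for (i in seq_len(n_cells)) {
    set.seed(derive_seed(params$seed, i + cell_offset + geno_tag))
    out[[i]] <- simulate_cell(bases, panel, truth, params,
                              cell_id = sprintf("%s_%s_c%05d", cell_type,
                                                genotype, i + cell_offset),
                              cell_type = ct, genotype = genotype)
  }
  traces <- do.call(rbind, out)
  rownames(traces) <- NULL
  traces
}

#' Simulate matched expression (and accessibility) tables
#'
#' Genes are placed near locus midpoints (`genes_per_locus` per locus).
#' Mean counts are `activity_scale(cell type) * exp(alpha * A + eps_gene)`;
#' counts are negative binomial with size `nb_size` (Poisson when
#' `nb_size = Inf`). With `n_cells > 0`, per-cell columns are drawn for every
#' requested genotype; KO cells receive a per-gene log-shift of magnitude
#' `ko_expr_shift * ko_factor(cell type)` whose sign follows the locus truth
#' radial position (interior down, peripheral up). The per-cell-type columns
#' are scaled to a nominal 100 cells.
#'
#' @param panel,truth from [make_truth_panel()]
#' @param params `ct_sim_params` (requires `alpha`; see [sim_params()])
#' @param n_cells per-cell-type, per-genotype cell count (0 = type-level only)
#' @param genotypes character vector among "WT", "KO"
#' @return list(genes, counts_by_type, cells, counts, accessibility)
#' @export
simulate_expression <- function(panel, truth, params, n_cells = 0,
                                genotypes = "WT") {
  stopifnot(inherits(params, "ct_sim_params"))
  if (is.null(params$alpha) || is.na(params$alpha))
    stop("expression effect alpha is unset")
  set.seed(derive_seed(params$seed, 70001))
  g_per <- params$genes_per_locus
  mids <- locus_midpoints(panel)
  genes <- do.call(rbind, lapply(seq_len(nrow(panel)), function(i) {
    off <- round(seq(-5e4, 5e4, length.out = g_per))
    data.frame(gene_id = sprintf("%s_g%d", panel$locus_id[i], seq_len(g_per)),
               chrom = panel$chrom[i], tss = mids[i] + off,
               gene_length = round(exp(rnorm(g_per, log(3e4), 1))),
               locus_id = panel$locus_id[i], stringsAsFactors = FALSE)
  }))
  a_ind <- as.numeric(truth$compartment == "A")[match(genes$locus_id,
                                                      truth$locus_id)]
  eps <- rnorm(nrow(genes), 0, 0.3)
  base_mu <- exp(params$alpha * a_ind + eps)
  r_truth <- truth$radial_truth[match(genes$locus_id, truth$locus_id)]
  shift <- (r_truth - mean(range(truth$radial_truth))) * 4  # interior < 0
  cts <- params$cell_types
  draw <- function(mu) {
    if (is.infinite(params$nb_size)) rpois(length(mu), mu)
    else rnbinom(length(mu), mu = mu, size = params$nb_size)
  }
  counts_by_type <- sapply(seq_len(nrow(cts)), function(j)
    draw(100 * cts$activity_scale[j] * base_mu))
  colnames(counts_by_type) <- cts$name
  cells <- NULL
  counts <- NULL
  if (n_cells > 0) {
    cells <- expand.grid(idx = seq_len(n_cells), genotype = genotypes,
                         cell_type = cts$name, stringsAsFactors = FALSE)
    cells$cell_id <- sprintf("%s_%s_e%04d", cells$cell_type, cells$genotype,
                             cells$idx)
    counts <- matrix(0L, nrow(genes), nrow(cells),
                     dimnames = list(genes$gene_id, cells$cell_id))
    for (k in seq_len(nrow(cells))) {
      j <- match(cells$cell_type[k], cts$name)
      lmu <- log(cts$activity_scale[j] * base_mu) + rnorm(1, 0, 0.2)
      if (identical(cells$genotype[k], "KO"))
        lmu <- lmu + params$ko_expr_shift * cts$ko_factor[j] * shift
      counts[, k] <- draw(exp(lmu))
    }
    cells <- cells[, c("cell_id", "cell_type", "genotype")]
  }
  accessibility <- do.call(rbind, lapply(seq_len(nrow(cts)), function(j) {
    data.frame(cell_type = cts$name[j], locus_id = truth$locus_id,
               signal = cts$activity_scale[j] *
                 exp(0.8 * (truth$compartment == "A") +
                       rnorm(nrow(truth), 0, 0.2)),
               stringsAsFactors = FALSE)
  }))
  list(genes = genes, counts_by_type = counts_by_type, cells = cells,
       counts = counts, accessibility = accessibility)
}
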