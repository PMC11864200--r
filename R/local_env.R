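# Locus-level chromatin environment and its coupling to expression: the
# trans-chromosomal local A/B density ratio, gene-to-locus mapping and
# locus activity, DE scores (Welch t), radial-binned profiles, and the
# WT-vs-KO perturbation comparison.

#' Local A/B density ratio for one cell
#'
#' For each decoded locus p (each homolog scored independently), the
#' Gaussian-kernel-weighted density of trans-chromosomal compartment-A loci
#' divided by that of compartment-B loci:
#' `density_X = sum over trans loci q with label X of exp(-|p-q|^2/(2 s^2))`,
#' `ratio = (density_A + eps) / (density_B + eps)` with eps = 1e-3. NA when
#' fewer than `min_trans` trans-chromosomal loci are decoded in the cell.
#'
#' @param cell_trace trace rows of one cell
#' @param labels named character vector locus_id -> "A"/"B"
#' @param kernel_scale Gaussian kernel sd s in um (default 1)
#' @param eps pseudocount (default 1e-3)
#' @param min_trans minimum trans loci required (default 10)
#' @return data.frame(cell_id, locus_id, homolog, local_ab_ratio)
#' @export
local_ab_density_ratio <- function(cell_trace, labels, kernel_scale = 1,
                                   eps = 1e-3, min_trans = 10) {
  lab <- labels[cell_trace$locus_id]
  if (anyNA(lab)) stop("labels missing for ",
                       paste(head(unique(cell_trace$locus_id[is.na(lab)]), 5),
                             collapse = ", "))
  p <- as.matrix(cell_trace[, c("x", "y", "z")])
  n <- nrow(p)
  d2 <- as.matrix(stats::dist(p))^2
  K <- exp(-d2 / (2 * kernel_scale^2))
  trans <- outer(cell_trace$chrom, cell_trace$chrom, `!=`)
  KA <- K * trans * (rep(1, n) %o% as.numeric(lab == "A"))
  KB <- K * trans * (rep(1, n) %o% as.numeric(lab == "B"))
  n_trans <- rowSums(trans)
  ratio <- ifelse(n_trans >= min_trans,
                  (rowSums(KA) + eps) / (rowSums(KB) + eps), NA_real_)
  data.frame(cell_id = cell_trace$cell_id, locus_id = cell_trace$locus_id,
             homolog = cell_trace$homolog, local_ab_ratio = ratio,
             stringsAsFactors = FALSE)
}

#' Local environment table for a trace population
#'
#' Per (cell, locus, homolog): local A/B density ratio and normalized
#' radial position, for cells with at least `min_loci` decoded loci.
#'
#' @param traces chromatin trace table
#' @param labels named character vector locus_id -> "A"/"B"
#' @param kernel_scale Gaussian kernel sd in um
#' @param min_loci minimum decoded loci per cell (default 600; lower it for
#'   small synthetic panels)
#' @param min_trans minimum trans-chromosomal loci per cell
#' @return data.frame(cell_id, cell_type, genotype, locus_id, homolog,
#'   local_ab_ratio, radial)
#' @export
local_env_table <- function(traces, labels, kernel_scale = 1,
                            min_loci = 600, min_trans = 10) {
  per_cell <- lapply(split(traces, traces$cell_id), function(ct) {
    if (nrow(ct) < min_loci) return(NULL)
    env <- local_ab_density_ratio(ct, labels, kernel_scale,
                                  min_trans = min_trans)
    rad <- radial_positions(ct, min_loci = min_loci)
    if (is.null(rad)) return(NULL)
    env$radial <- rad$radial[match(paste(env$locus_id, env$homolog),
                                   paste(rad$locus_id, rad$homolog))]
    env$cell_type <- ct$cell_type[1]
    env$genotype <- ct$genotype[1]
    env
  })
  out <- data.table::rbindlist(per_cell[!vapply(per_cell, is.null,
                                                logical(1))])
  as.data.frame(out[, .(cell_id, cell_type, genotype, locus_id, homolog,
                        local_ab_ratio, radial)])
}

#' Per-locus medians of a local environment table
#'
#' Median-over-cells of the per-cell ratio and radial position.
#'
#' @param env table from [local_env_table()]
#' @return data.frame(locus_id, median_ratio, median_radial, n_obs)
#' @export
locus_env_summary <- function(env) {
  dt <- data.table::as.data.table(env)
  out <- dt[!is.na(local_ab_ratio),
            .(median_ratio = median(local_ab_ratio),
              median_radial = median(radial, na.rm = TRUE), n_obs = .N),
            by = locus_id]
  as.data.frame(out[order(locus_id)])
}

#' Normalize local A/B ratios across groups
#'
#' Removes the overall between-group difference: within each group
#' (e.g. cell type or genotype), every locus's median ratio is divided by
#' the group's grand mean over loci, so every group's grand mean is 1
#' afterward and only relative, per-locus differences remain.
#'
#' @param summaries named list of per-locus summaries from
#'   [locus_env_summary()], one per group
#' @return the list with an added `norm_ratio` column per group
#' @export
normalize_ratio_across_groups <- function(summaries) {
  if (length(summaries) < 2) stop("need at least 2 groups")
  lapply(summaries, function(s) {
    if (!nrow(s)) stop("empty group")
    s$norm_ratio <- s$median_ratio / mean(s$median_ratio)
    s
  })
}

#' Map genes to panel loci
#'
#' A gene maps to a locus when its TSS is within `window` bp of the locus
#' interval; among several qualifying loci the nearest by midpoint distance
#' wins, ties going to the lower-coordinate locus.
#'
#' @param genes data.frame(gene_id, chrom, tss)
#' @param panel locus panel
#' @param window maximum TSS-to-interval distance in bp (default 100 kb)
#' @return data.frame(gene_id, locus_id) — `locus_id` NA for unmapped genes
#' @export
map_genes_to_loci <- function(genes, panel, window = 1e5) {
  mids <- locus_midpoints(panel)
  locus <- vapply(seq_len(nrow(genes)), function(g) {
    on <- which(panel$chrom == genes$chrom[g])
    if (!length(on)) return(NA_character_)
    t <- genes$tss[g]
    edge_dist <- pmax(0, pmax(panel$start[on] - t, t - panel$end[on]))
    ok <- on[edge_dist <= window]
    if (!length(ok)) return(NA_character_)
    md <- abs(mids[ok] - t)
    best <- ok[md == min(md)]
    if (length(best) > 1) best <- best[which.min(panel$start[best])]
    panel$locus_id[best]
  }, character(1))
  data.frame(gene_id = genes$gene_id, locus_id = locus,
             stringsAsFactors = FALSE)
}

#' Transcriptional activity per locus
#'
#' Activity is the summed counts of the genes mapped to the locus (NaN when
#' no gene maps); high/low classes are the top and bottom quartiles of the
#' non-NaN activities.
#'
#' @param counts numeric vector or matrix of gene counts (rows = genes,
#'   columns = cell types), rownames = gene ids
#' @param map gene-to-locus map from [map_genes_to_loci()]
#' @param panel locus panel
#' @return data.frame(locus_id, one activity column per counts column, class)
#'   with class in {"high","mid","low",NA}
#' @export
locus_activity <- function(counts, map, panel) {
  if (is.vector(counts)) counts <- matrix(counts, ncol = 1,
                                          dimnames = list(names(counts), "activity"))
  act <- matrix(NA_real_, nrow(panel), ncol(counts),
                dimnames = list(panel$locus_id, colnames(counts)))
  mapped <- map[!is.na(map$locus_id), , drop = FALSE]
  for (l in unique(mapped$locus_id)) {
    g <- mapped$gene_id[mapped$locus_id == l]
    act[l, ] <- colSums(counts[g, , drop = FALSE])
  }
  total <- rowSums(act)
  cls <- rep(NA_character_, nrow(panel))
  ok <- !is.na(total)
  if (any(ok)) {
    q <- quantile(total[ok], c(0.25, 0.75))
    cls[ok] <- ifelse(total[ok] >= q[2], "high",
                      ifelse(total[ok] <= q[1], "low", "mid"))
  }
  out <- data.frame(locus_id = panel$locus_id, act, class = cls,
                    stringsAsFactors = FALSE, check.names = FALSE)
  rownames(out) <- NULL
  out
}

#' Differential-expression score (Welch t statistic)
#'
#' Per-cell counts are first scaled so every cell has the median total
#' count, then a Welch two-sample t statistic (KO minus WT) is computed per
#' gene. Genes with zero variance in both groups get NA.
#'
#' @param counts_wt,counts_ko matrices (genes x cells), same rownames
#' @return named numeric vector of t statistics per gene
#' @export
de_score <- function(counts_wt, counts_ko) {
  if (ncol(counts_wt) < 2 || ncol(counts_ko) < 2)
    stop("need at least 2 cells per group")
  stopifnot(identical(rownames(counts_wt), rownames(counts_ko)))
  all_counts <- cbind(counts_wt, counts_ko)
  tot <- colSums(all_counts)
  target <- median(tot)
  scl <- ifelse(tot > 0, target / tot, 1)
  norm <- sweep(all_counts, 2, scl, `*`)
  wt <- norm[, seq_len(ncol(counts_wt)), drop = FALSE]
  ko <- norm[, ncol(counts_wt) + seq_len(ncol(counts_ko)), drop = FALSE]
  m_w <- rowMeans(wt); m_k <- rowMeans(ko)
  v_w <- apply(wt, 1, stats::var); v_k <- apply(ko, 1, stats::var)
  se <- sqrt(v_k / ncol(ko) + v_w / ncol(wt))
  t_stat <- ifelse(se > 0, (m_k - m_w) / se, NA_real_)
  setNames(t_stat, rownames(counts_wt))
}

#' Radial-binned means with 95 percent confidence intervals
#'
#' Values are grouped into `n_bins` equal-count bins of radial position;
#' per bin: mean and a normal-approximation 95 percent CI.
#'
#' @param values numeric vector
#' @param radial_positions numeric vector, same length
#' @param n_bins number of equal-count bins (default 10)
#' @return data.frame(bin, mean_radial, mean, ci_lo, ci_hi, n)
#' @export
radial_bin_analysis <- function(values, radial_positions, n_bins = 10) {
  ok <- !is.na(values) & !is.na(radial_positions)
  values <- values[ok]
  radial_positions <- radial_positions[ok]
  if (length(values) < n_bins)
    stop("fewer points (", length(values), ") than bins (", n_bins, ")")
  bins <- equal_count_bins(radial_positions, n_bins)
  out <- lapply(seq_len(n_bins), function(b) {
    v <- values[bins == b]
    se <- sd(v) / sqrt(length(v))
    data.frame(bin = b, mean_radial = mean(radial_positions[bins == b]),
               mean = mean(v), ci_lo = mean(v) - 1.96 * se,
               ci_hi = mean(v) + 1.96 * se, n = length(v))
  })
  do.call(rbind, out)
}

#' WT-vs-KO perturbation comparison
#'
#' Per locus: the change (KO minus WT) of group-normalized median local A/B
#' density ratios and of median radial positions; loci are assigned to
#' `n_bins` equal-count radial bins from their WT radial positions. Per
#' compartment, a one-sample t test of the per-locus deltas against 0 is
#' Bonferroni-corrected over the set of tests. When per-locus DE scores are
#' supplied, the per-decile mean DE score and the Spearman correlation of
#' delta-ratio deciles vs DE score are reported.
#'
#' @param env_wt,env_ko local environment tables from [local_env_table()]
#' @param labels named character vector locus_id -> "A"/"B"
#' @param n_bins radial bins (default 10)
#' @param de_scores optional named numeric vector locus_id -> DE score
#' @param min_loci_per_test minimum loci per compartment test (default 5)
#' @return list of class `ct_perturbation`: per_locus data.frame(locus_id,
#'   label, delta_ratio, delta_radial, radial_bin, de_score), tests
#'   data.frame(label, mean_delta, t, p, p_bonferroni), decile_profile,
#'   de_spearman
#' @export
perturbation_comparison <- function(env_wt, env_ko, labels, n_bins = 10,
                                    de_scores = NULL,
                                    min_loci_per_test = 5) {
  s <- normalize_ratio_across_groups(list(WT = locus_env_summary(env_wt),
                                          KO = locus_env_summary(env_ko)))
  common <- intersect(s$WT$locus_id, s$KO$locus_id)
  if (!length(common)) stop("no loci shared between genotypes")
  wt <- s$WT[match(common, s$WT$locus_id), ]
  ko <- s$KO[match(common, s$KO$locus_id), ]
  per_locus <- data.frame(
    locus_id = common,
    label = unname(labels[common]),
    delta_ratio = ko$norm_ratio - wt$norm_ratio,
    delta_radial = ko$median_radial - wt$median_radial,
    radial_wt = wt$median_radial,
    stringsAsFactors = FALSE)
  per_locus$radial_bin <- equal_count_bins(per_locus$radial_wt, n_bins)
  per_locus$de_score <- if (is.null(de_scores)) NA_real_
                        else unname(de_scores[per_locus$locus_id])
  tests <- lapply(c("A", "B"), function(lb) {
    d <- per_locus$delta_ratio[per_locus$label == lb]
    if (length(d) < min_loci_per_test)
      return(data.frame(label = lb, n = length(d), mean_delta = mean(d),
                        t = NA_real_, p = NA_real_))
    tt <- t.test(d, mu = 0)
    data.frame(label = lb, n = length(d), mean_delta = mean(d),
               t = unname(tt$statistic), p = tt$p.value)
  })
  tests <- do.call(rbind, tests)
  tests$p_bonferroni <- pmin(1, tests$p * sum(!is.na(tests$p)))
  decile <- data.table::as.data.table(per_locus)[
    , .(mean_delta_ratio = mean(delta_ratio),
        mean_de = mean(de_score, na.rm = TRUE), n = .N), by = radial_bin][
          order(radial_bin)]
  de_spearman <- NA_real_
  if (!is.null(de_scores)) {
    ok <- !is.na(decile$mean_de)
    if (sum(ok) >= 3)
      de_spearman <- cor(decile$mean_delta_ratio[ok], decile$mean_de[ok],
                         method = "spearman")
  }
  structure(list(per_locus = per_locus, tests = tests,
                 decile_profile = as.data.frame(decile),
                 de_spearman = de_spearman),
            class = "ct_perturbation")
}

#' Restrict to loci with conserved compartment identity
#'
#' @param labels_wt,labels_ko named character vectors locus_id -> "A"/"B"
#'   from independent compartment calls
#' @return list(loci = conserved locus ids, fractions = named fractions
#'   conserved, A_B, B_A)
#' @export
conserved_compartment_filter <- function(labels_wt, labels_ko) {
  common <- intersect(names(labels_wt), names(labels_ko))
  lw <- labels_wt[common]
  lk <- labels_ko[common]
  conserved <- common[lw == lk]
  list(loci = conserved,
       fractions = c(conserved = mean(lw == lk),
                     A_B = mean(lw == "A" & lk == "B"),
                     B_A = mean(lw == "B" & lk == "A")))
}
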