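# Matrix-level chromosome structure: median spatial distance and
# observed/expected proximity matrices, A/B compartment calling by PCA of
# the cross-correlation matrix (PC chosen by correlation with CpG density),
# segregation score, insulation profile, megadomain strength, and
# compartment-change accounting.

# pair observations for one chromosome / cell type, with locus indices
chrom_pairs <- function(traces, panel, chrom, cell_type = NULL) {
  loci <- panel$locus_id[panel$chrom == chrom]
  if (!length(loci)) stop("chromosome ", chrom, " absent from panel")
  pairs <- cis_pair_distances(traces, panel, cell_type = cell_type,
                              chrom = chrom)
  list(loci = loci, pairs = pairs)
}

#' Median pairwise spatial distance matrix
#'
#' Entry (i, j) is the median spatial distance between loci i and j over all
#' homolog copies (cells x homologs) in which both were decoded; entries
#' with fewer than `min_cells` observations are NA. Symmetric with zero
#' diagonal.
#'
#' @param traces chromatin trace table
#' @param panel locus panel
#' @param chrom chromosome name
#' @param cell_type optional cell type filter
#' @param min_cells minimum observations per entry (default 20)
#' @return list of class `ct_dist_matrix`: distances (n x n), counts, loci,
#'   chrom, cell_type
#' @export
median_distance_matrix <- function(traces, panel, chrom, cell_type = NULL,
                                   min_cells = 20) {
  cp <- chrom_pairs(traces, panel, chrom, cell_type)
  n <- length(cp$loci)
  D <- matrix(NA_real_, n, n, dimnames = list(cp$loci, cp$loci))
  N <- matrix(0L, n, n, dimnames = list(cp$loci, cp$loci))
  if (nrow(cp$pairs)) {
    agg <- cp$pairs[, .(med = median(sdist), n = .N), by = .(locus_i, locus_j)]
    i <- match(agg$locus_i, cp$loci)
    j <- match(agg$locus_j, cp$loci)
    D[cbind(i, j)] <- D[cbind(j, i)] <- ifelse(agg$n >= min_cells, agg$med, NA)
    N[cbind(i, j)] <- N[cbind(j, i)] <- agg$n
  }
  diag(D) <- 0
  structure(list(distances = D, counts = N, loci = cp$loci, chrom = chrom,
                 cell_type = cell_type), class = "ct_dist_matrix")
}

#' Normalized (observed/expected) proximity matrix
#'
#' Observed(i, j) is the fraction of homolog copies with both loci decoded
#' that lie within `cutoff` um. The expected value for a pair is the mean
#' observed proximity over all pairs in the same log-spaced
#' genomic-distance bin (`bins_per_decade` bins per decade), and the matrix
#' holds observed/expected; values near 1 mean no enrichment.
#'
#' @param traces chromatin trace table
#' @param panel locus panel
#' @param chrom chromosome name
#' @param cutoff proximity cutoff in um (default 0.75; `Inf` gives all 1)
#' @param cell_type optional cell type filter
#' @param min_cells minimum observations per entry (default 20)
#' @param bins_per_decade genomic-distance bins per decade (default 20)
#' @return list of class `ct_prox_matrix`: normalized (n x n), observed,
#'   expected (per entry), gdist, loci, chrom
#' @export
normalized_proximity_matrix <- function(traces, panel, chrom, cutoff = 0.75,
                                        cell_type = NULL, min_cells = 20,
                                        bins_per_decade = 20) {
  cp <- chrom_pairs(traces, panel, chrom, cell_type)
  n <- length(cp$loci)
  mids <- setNames(locus_midpoints(panel), panel$locus_id)
  O <- matrix(NA_real_, n, n, dimnames = list(cp$loci, cp$loci))
  G <- abs(outer(mids[cp$loci], mids[cp$loci], `-`))
  if (nrow(cp$pairs)) {
    agg <- cp$pairs[, .(obs = mean(sdist < cutoff), n = .N),
                    by = .(locus_i, locus_j)]
    i <- match(agg$locus_i, cp$loci)
    j <- match(agg$locus_j, cp$loci)
    O[cbind(i, j)] <- O[cbind(j, i)] <- ifelse(agg$n >= min_cells, agg$obs, NA)
  }
  ut <- upper.tri(O)
  bin <- matrix(NA_integer_, n, n)
  bin[ut] <- genomic_distance_bin(G[ut], bins_per_decade)
  bin[lower.tri(bin)] <- t(bin)[lower.tri(bin)]
  exp_by_bin <- tapply(O[ut], bin[ut], mean, na.rm = TRUE)
  E <- matrix(NA_real_, n, n, dimnames = dimnames(O))
  E[!is.na(bin)] <- exp_by_bin[as.character(bin[!is.na(bin)])]
  zero_bins <- names(exp_by_bin)[!is.na(exp_by_bin) & exp_by_bin == 0]
  if (length(zero_bins))
    warning("expected proximity 0 in ", length(zero_bins),
            " genomic-distance bin(s); entries set to NaN")
  M <- O / E
  diag(M) <- NA_real_
  structure(list(normalized = M, observed = O, expected = E, gdist = G,
                 loci = cp$loci, chrom = chrom, cell_type = cell_type,
                 cutoff = cutoff), class = "ct_prox_matrix")
}

# impute NAs of a square matrix by the mean of its genomic-distance bin,
# falling back to the overall off-diagonal mean
impute_by_gdist <- function(M, gdist, bins_per_decade = 20) {
  ut <- upper.tri(M)
  bin <- matrix(NA_integer_, nrow(M), ncol(M))
  bin[ut] <- genomic_distance_bin(gdist[ut], bins_per_decade)
  bin[lower.tri(bin)] <- t(bin)[lower.tri(bin)]
  mbin <- tapply(M[ut], bin[ut], mean, na.rm = TRUE)
  idx <- which(is.na(M) & !is.na(bin), arr.ind = TRUE)
  if (nrow(idx)) {
    fill <- mbin[as.character(bin[idx])]
    fill[is.na(fill)] <- mean(M[ut], na.rm = TRUE)
    M[idx] <- fill
  }
  M
}

#' Call A/B compartments from a normalized proximity matrix
#'
#' The cross-correlation matrix holds the Pearson correlation between every
#' pair of matrix rows, computed over columns at least 2 loci away from
#' both row indices (the diagonal and its two adjacent entries are
#' excluded). PCA is run on the column-centered cross-correlation matrix;
#' among the first three PCs the one with the highest absolute correlation
#' with CpG density is selected and sign-oriented so that the correlation
#' is positive. Loci with positive oriented PC value are labeled A.
#'
#' @param prox `ct_prox_matrix` (at most 20 percent NA after masking)
#' @param cpg_density numeric vector of CpG density per locus (panel order)
#' @param n_pcs candidate PCs (default 3)
#' @param max_na maximum tolerated NA fraction before imputation (0.2)
#' @return list of class `ct_compartments`: data.frame profile (locus_id,
#'   pc1..pc3, pc_value, label), pc_index, cpg_cor, orientation
#' @export
call_compartments <- function(prox, cpg_density, n_pcs = 3, max_na = 0.2) {
  M <- prox$normalized
  n <- nrow(M)
  offdiag <- !diag(TRUE, n)
  if (mean(is.na(M[offdiag])) > max_na)
    stop("more than ", 100 * max_na, "% missing entries")
  M <- impute_by_gdist(M, prox$gdist)
  diag(M) <- NA_real_
  if (sd(M[offdiag], na.rm = TRUE) == 0) stop("no structure: constant matrix")
  # cross-correlation with near-diagonal exclusion
  C <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) for (j in i:n) {
    keep <- abs(seq_len(n) - i) > 1 & abs(seq_len(n) - j) > 1
    xi <- M[i, keep]
    xj <- M[j, keep]
    ok <- !is.na(xi) & !is.na(xj)
    C[i, j] <- C[j, i] <- if (sum(ok) >= 3 && sd(xi[ok]) > 0 && sd(xj[ok]) > 0)
      cor(xi[ok], xj[ok]) else NA_real_
  }
  if (anyNA(C)) C[is.na(C)] <- 0
  pca <- prcomp(C, center = TRUE, scale. = FALSE)
  k <- min(n_pcs, ncol(pca$x))
  scores <- pca$x[, seq_len(k), drop = FALSE]
  cors <- apply(scores, 2, function(s)
    if (sd(s) > 0 && sd(cpg_density) > 0) cor(s, cpg_density) else 0)
  pc_index <- which.max(abs(cors))
  orientation <- ifelse(cors[pc_index] >= 0, 1, -1)
  pc_value <- scores[, pc_index] * orientation
  profile <- data.frame(locus_id = prox$loci,
                        pc1 = scores[, 1],
                        pc2 = if (k >= 2) scores[, 2] else NA_real_,
                        pc3 = if (k >= 3) scores[, 3] else NA_real_,
                        pc_value = pc_value,
                        label = ifelse(pc_value > 0, "A", "B"),
                        stringsAsFactors = FALSE)
  structure(list(profile = profile, pc_index = pc_index,
                 cpg_cor = abs(cors[pc_index]), orientation = orientation,
                 chrom = prox$chrom), class = "ct_compartments")
}

#' A/B segregation score
#'
#' Each cis pair's spatial distance is divided by the median distance of
#' all pairs in its log-spaced genomic-distance bin (controlling for the
#' genomic-distance effect); the score is the median normalized distance of
#' A-B pairs divided by that of the pooled A-A and B-B pairs. Values above
#' 1 indicate spatial segregation of the compartments.
#'
#' @param traces chromatin trace table
#' @param panel locus panel
#' @param labels named character vector locus_id -> "A"/"B"
#' @param chrom chromosome name
#' @param cell_type optional cell type filter
#' @param bins_per_decade genomic-distance bins per decade
#' @return segregation score (numeric)
#' @export
segregation_score <- function(traces, panel, labels, chrom, cell_type = NULL,
                              bins_per_decade = 20) {
  cp <- chrom_pairs(traces, panel, chrom, cell_type)
  li <- labels[cp$pairs$locus_i]
  lj <- labels[cp$pairs$locus_j]
  if (length(unique(labels[cp$loci])) < 2)
    stop("both compartment labels must be present on ", chrom)
  pr <- cp$pairs
  pr[, gbin := genomic_distance_bin(gdist, bins_per_decade)]
  pr[, norm_dist := sdist / median(sdist), by = gbin]
  cross <- li != lj
  within <- li == lj
  median(pr$norm_dist[cross]) / median(pr$norm_dist[within])
}

#' Insulation profile and its IQR
#'
#' `IS(i)` is the mean of the normalized proximity matrix over the w x w
#' square spanning rows (i-w)..(i-1) and columns i..(i+w-1) — the
#' cross-boundary window at position i. The normalized score is
#' `log2(IS / mean(IS))`; its interquartile range summarizes domain
#' prominence, and local minima are boundary candidates.
#'
#' @param prox `ct_prox_matrix` (or plain matrix)
#' @param window window size w in loci (default 5; must satisfy w < n/2)
#' @return list of class `ct_insulation`: data.frame profile (position,
#'   insulation, normalized), iqr, boundary (position of global minimum)
#' @export
insulation_profile <- function(prox, window = 5) {
  M <- if (inherits(prox, "ct_prox_matrix")) prox$normalized else prox
  n <- nrow(M)
  w <- as.integer(window)
  if (w >= n / 2) stop("window ", w, " >= n/2 (n = ", n, ")")
  pos <- (w + 1):(n - w + 1)
  is_raw <- vapply(pos, function(i)
    mean(M[(i - w):(i - 1), i:(i + w - 1)], na.rm = TRUE), numeric(1))
  norm <- log2(is_raw / mean(is_raw, na.rm = TRUE))
  iqr <- unname(diff(quantile(norm, c(0.25, 0.75), na.rm = TRUE)))
  structure(list(
    profile = data.frame(position = pos, insulation = is_raw,
                         normalized = norm),
    iqr = iqr, boundary = pos[which.min(norm)], window = w),
    class = "ct_insulation")
}

#' Megadomain strength
#'
#' Ratio of the median spatial distance of locus pairs crossing the
#' megadomain boundary to the median distance of pairs not crossing it
#' (raw distances, no genomic-distance normalization; set
#' `normalized = TRUE` for a distance-bin-normalized variant).
#'
#' @param dist_matrix `ct_dist_matrix` (or plain symmetric matrix)
#' @param boundary boundary index b: loci 1..b are megadomain 1 (must be
#'   strictly inside 1..n)
#' @param normalized use genomic-distance-bin-normalized distances
#'   (non-default variant)
#' @param gdist genomic-distance matrix, required when `normalized = TRUE`
#'   and a plain matrix is given
#' @param bins_per_decade bins per decade for the normalized variant
#' @return strength (numeric, > 1 means megadomain separation)
#' @export
megadomain_strength <- function(dist_matrix, boundary, normalized = FALSE,
                                gdist = NULL, bins_per_decade = 20) {
  D <- if (inherits(dist_matrix, "ct_dist_matrix")) dist_matrix$distances
       else dist_matrix
  n <- nrow(D)
  b <- as.integer(boundary)
  if (b < 1 || b >= n) stop("boundary must lie strictly inside 1..n")
  if (normalized) {
    if (is.null(gdist)) stop("gdist required for the normalized variant")
    ut <- upper.tri(D)
    bin <- genomic_distance_bin(gdist[ut], bins_per_decade)
    med <- tapply(D[ut], bin, median, na.rm = TRUE)
    Dn <- D
    Dn[ut] <- D[ut] / med[as.character(bin)]
    Dn[lower.tri(Dn)] <- t(Dn)[lower.tri(Dn)]
    D <- Dn
  }
  side <- c(rep(1L, b), rep(2L, n - b))
  cross <- outer(side, side, `!=`) & upper.tri(D)
  within <- outer(side, side, `==`) & upper.tri(D)
  median(D[cross], na.rm = TRUE) / median(D[within], na.rm = TRUE)
}

#' Detect a megadomain boundary de novo
#'
#' The global minimum of the normalized insulation profile.
#'
#' @param prox `ct_prox_matrix`
#' @param window insulation window
#' @return boundary locus index
#' @export
detect_megadomain_boundary <- function(prox, window = 5) {
  insulation_profile(prox, window)$boundary - 1L
}

#' Compartment conservation and change fractions
#'
#' @param labels_ref,labels_other character vectors of "A"/"B" labels on the
#'   same locus set (same order)
#' @return named numeric: fractions A_A, B_B, A_B, B_A (sum to 1)
#' @export
compartment_change <- function(labels_ref, labels_other) {
  if (length(labels_ref) != length(labels_other))
    stop("label vectors differ in length")
  n <- length(labels_ref)
  key <- paste(labels_ref, labels_other, sep = "_")
  out <- c(A_A = sum(key == "A_A"), B_B = sum(key == "B_B"),
           A_B = sum(key == "A_B"), B_A = sum(key == "B_A")) / n
  out
}
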