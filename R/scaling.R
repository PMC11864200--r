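# Spatial-vs-genomic distance statistics for cis-chromosomal locus pairs:
# median pairwise distance tables, two-regime log-log power-law fits
# (boundary 10 Mb by default), proximity fractions within a spatial cutoff,
# and activity-binned scaling fits.

#' Cis pairwise distances per cell and homolog
#'
#' All same-chromosome, same-homolog locus pairs of every cell, with
#' genomic distance between locus midpoints. Internal workhorse shared by
#' the pair table and the matrix-level statistics.
#'
#' @param traces chromatin trace table
#' @param panel locus panel (for midpoints)
#' @param cell_type optional cell type filter
#' @param chrom optional chromosome filter
#' @return data.table(cell_id, chrom, homolog, locus_i, locus_j, gdist, sdist)
#' @export
cis_pair_distances <- function(traces, panel, cell_type = NULL, chrom = NULL) {
  dt <- data.table::as.data.table(traces)
  ct_filter <- cell_type
  ch_filter <- chrom
  if (!is.null(ct_filter)) dt <- dt[dt[["cell_type"]] %in% ct_filter]
  if (!is.null(ch_filter)) dt <- dt[dt[["chrom"]] %in% ch_filter]
  if (!nrow(dt)) return(data.table::data.table(
    cell_id = character(0), chrom = character(0), homolog = integer(0),
    locus_i = character(0), locus_j = character(0), gdist = numeric(0),
    sdist = numeric(0)))
  mids <- setNames(locus_midpoints(panel), panel$locus_id)
  dt[, midpoint := mids[locus_id]]
  pairs <- dt[dt, on = .(cell_id, chrom, homolog), allow.cartesian = TRUE][
    locus_id < i.locus_id]
  pairs[, `:=`(
    gdist = abs(i.midpoint - midpoint),
    sdist = sqrt((x - i.x)^2 + (y - i.y)^2 + (z - i.z)^2))]
  out <- pairs[, .(cell_id, chrom, homolog, locus_i = locus_id,
                   locus_j = i.locus_id, gdist, sdist)]
  out
}

#' Median spatial distance per cis locus pair
#'
#' For each same-chromosome locus pair, the median spatial distance over all
#' cells and homolog copies in which both loci were decoded; homologs are
#' never mixed. Pairs observed in fewer than `min_cells` copies are dropped.
#'
#' @param traces chromatin trace table
#' @param panel locus panel
#' @param cell_type optional cell type filter
#' @param min_cells minimum observations per pair (default 20)
#' @return data.frame(chrom, locus_i, locus_j, genomic_dist,
#'   median_spatial_dist, n_obs)
#' @export
pairwise_distance_table <- function(traces, panel, cell_type = NULL,
                                    min_cells = 20) {
  pairs <- cis_pair_distances(traces, panel, cell_type = cell_type)
  if (!nrow(pairs)) return(data.frame(
    chrom = character(0), locus_i = character(0), locus_j = character(0),
    genomic_dist = numeric(0), median_spatial_dist = numeric(0),
    n_obs = integer(0)))
  tab <- pairs[, .(genomic_dist = gdist[1],
                   median_spatial_dist = median(sdist), n_obs = .N),
               by = .(chrom, locus_i, locus_j)]
  tab <- tab[n_obs >= min_cells]
  as.data.frame(tab[order(chrom, locus_i, locus_j)])
}

#' Two-regime power-law fit of spatial vs genomic distance
#'
#' Least-squares line fits of log(median spatial distance) against
#' log(genomic distance), separately for pairs below and at-or-above the
#' regime boundary (default 10 Mb; boundary pairs go to the long regime).
#' Each locus pair carries equal weight. A regime needs at least 3 distinct
#' genomic distances, else its exponent is NA. A second-order polynomial fit
#' over the full log-log range is stored for plotting.
#'
#' @param table pair table from [pairwise_distance_table()]
#' @param boundary regime boundary in bp (default 1e7)
#' @return list of class `ct_scaling_fit`: S_short, S_long, intercepts,
#'   r_squared per regime, n_pairs per regime, poly_coef (order 2)
#' @export
fit_scaling <- function(table, boundary = 1e7) {
  if (!nrow(table)) stop("empty pair table")
  lg <- log10(table$genomic_dist)
  ls <- log10(table$median_spatial_dist)
  fit1 <- function(sel) {
    if (length(unique(lg[sel])) < 3)
      return(list(S = NA_real_, b = NA_real_, r2 = NA_real_, n = sum(sel)))
    m <- lm(ls[sel] ~ lg[sel])
    # suppressWarnings: exact power-law input is a legitimate perfect fit
    list(S = unname(coef(m)[2]), b = unname(coef(m)[1]),
         r2 = suppressWarnings(summary(m)$r.squared), n = sum(sel))
  }
  short <- fit1(table$genomic_dist < boundary)
  long <- fit1(table$genomic_dist >= boundary)
  poly_coef <- if (length(unique(lg)) >= 3)
    unname(coef(lm(ls ~ lg + I(lg^2)))) else rep(NA_real_, 3)
  structure(list(S_short = short$S, S_long = long$S,
                 intercept_short = short$b, intercept_long = long$b,
                 r2_short = short$r2, r2_long = long$r2,
                 n_short = short$n, n_long = long$n,
                 boundary = boundary, poly_coef = poly_coef),
            class = "ct_scaling_fit")
}

#' @export
print.ct_scaling_fit <- function(x, ...) {
  cat(sprintf(
    "scaling fit: S_short = %.3f (n=%d, R2=%.3f), S_long = %.3f (n=%d, R2=%.3f), boundary %.3g bp\n",
    x$S_short, x$n_short, x$r2_short, x$S_long, x$n_long, x$r2_long,
    x$boundary))
  invisible(x)
}

#' Fraction of spatially proximal pairs per genomic-distance bin
#'
#' Among all cis pairs within `cutoff` (um), the fraction falling in each
#' genomic-distance bin; fractions sum to 1 over the reported bins.
#'
#' @param traces chromatin trace table
#' @param panel locus panel
#' @param cutoff spatial proximity cutoff in um (default 0.75)
#' @param genomic_bins numeric breaks in bp (left-closed, right-open; the
#'   last break closes the final bin)
#' @param cell_type optional cell type filter
#' @return data.frame(bin, lower, upper, n_proximal, fraction)
#' @export
proximity_fractions <- function(traces, panel, cutoff = 0.75,
                                genomic_bins = c(0, 5e6, 1e7, 2.5e7, 5e7, Inf),
                                cell_type = NULL) {
  stopifnot(cutoff > 0)
  pairs <- cis_pair_distances(traces, panel, cell_type = cell_type)
  prox <- pairs[sdist < cutoff]
  if (!nrow(prox))
    stop("no proximal pairs within cutoff ", cutoff, " um")
  bin <- cut(prox$gdist, breaks = genomic_bins, right = FALSE,
             include.lowest = TRUE)
  counts <- table(bin)
  data.frame(bin = names(counts),
             lower = genomic_bins[-length(genomic_bins)],
             upper = genomic_bins[-1],
             n_proximal = as.integer(counts),
             fraction = as.numeric(counts) / sum(counts),
             stringsAsFactors = FALSE)
}

#' Scaling fits for locus pairs binned by transcriptional activity
#'
#' Pair activity is the mean of the two loci's activities; pairs with
#' activity defined for both loci are split into `n_bins` equal-count bins
#' and a two-regime fit is computed per bin (`n_bins = 1` reproduces
#' [fit_scaling()] exactly).
#'
#' @param table pair table from [pairwise_distance_table()]
#' @param locus_activity named numeric vector (locus_id -> activity)
#' @param n_bins number of equal-count activity bins (default 10)
#' @param boundary regime boundary in bp
#' @return data.frame(bin, mean_activity, S_short, S_long, n_pairs)
#' @export
scaling_by_activity <- function(table, locus_activity, n_bins = 10,
                                boundary = 1e7) {
  act <- (locus_activity[table$locus_i] + locus_activity[table$locus_j]) / 2
  keep <- !is.na(act)
  table <- table[keep, , drop = FALSE]
  act <- act[keep]
  if (!nrow(table)) stop("no pairs with defined activity")
  # quantile breaks: ties collapse into one bin (constant activity -> bin 1)
  breaks <- unique(quantile(act, probs = seq(0, 1, length.out = n_bins + 1)))
  bins <- if (length(breaks) == 1) rep(1L, length(act)) else
    as.integer(cut(act, breaks = breaks, include.lowest = TRUE))
  out <- lapply(seq_len(n_bins), function(b) {
    sel <- bins == b
    fit <- tryCatch(fit_scaling(table[sel, , drop = FALSE], boundary),
                    error = function(e) NULL)
    data.frame(bin = b, mean_activity = mean(act[sel]),
               S_short = if (is.null(fit)) NA_real_ else fit$S_short,
               S_long = if (is.null(fit)) NA_real_ else fit$S_long,
               n_pairs = sum(sel))
  })
  do.call(rbind, out)
}
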