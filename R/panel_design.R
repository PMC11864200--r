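# Locus panel design: evenly spaced genome-wide loci, 42-nt encoding-probe
# target windows filtered on GC and nearest-neighbor melting temperature,
# and cell type-specific super-enhancer calling from ATAC peaks
# (TSS exclusion, 12.5-kb stitching, ROSE tangent cutoff, cross-cell-type
# merging with overlap-ratio and size filters).

#' Select evenly spaced genome-wide loci
#'
#' Per chromosome (Y excluded), fixed-width loci are placed with their start
#' at multiples of `spacing` and clipped to the chromosome, giving
#' `floor((size - locus_length)/spacing) + 1` loci. Chromosomes shorter than
#' one locus are skipped with a warning.
#'
#' @param chrom_sizes named numeric vector of chromosome sizes (bp)
#' @param spacing locus spacing in bp (default 2.5 Mb)
#' @param locus_length locus width in bp (default 20 kb)
#' @return locus panel data.frame (panel_group = "genome_wide")
#' @export
select_genomewide_loci <- function(chrom_sizes, spacing = 2.5e6,
                                   locus_length = 20000) {
  stopifnot(spacing > 0, !is.null(names(chrom_sizes)))
  out <- list()
  for (chrom in names(chrom_sizes)) {
    if (grepl("^(chr)?Y$", chrom)) next
    size <- chrom_sizes[[chrom]]
    if (size < locus_length) {
      warning("chromosome ", chrom, " shorter than locus width; skipped")
      next
    }
    k <- 0:floor((size - locus_length) / spacing)
    out[[chrom]] <- data.frame(
      locus_id = sprintf("%s_L%03d", chrom, k + 1),
      chrom = chrom,
      start = k * spacing,
      end = k * spacing + locus_length,
      panel_group = "genome_wide",
      stringsAsFactors = FALSE
    )
  }
  if (!length(out)) stop("no chromosomes admit a locus")
  panel <- do.call(rbind, out)
  panel <- panel[order(panel$chrom, panel$start), , drop = FALSE]
  rownames(panel) <- NULL
  validate_locus_panel(panel)
  panel
}

# SantaLucia unified nearest-neighbor parameters (dH kcal/mol, dS cal/mol/K)
NN_DH <- c(AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2, CA = -8.5, TG = -8.5,
           GT = -8.4, AC = -8.4, CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
           CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0)
NN_DS <- c(AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3, CA = -22.7,
           TG = -22.7, GT = -22.4, AC = -22.4, CT = -21.0, AG = -21.0,
           GA = -22.2, TC = -22.2, CG = -27.2, GC = -24.4, GG = -19.9,
           CC = -19.9)

#' Nearest-neighbor melting temperature of a DNA oligo
#'
#' Unified nearest-neighbor thermodynamics with initiation terms, a
#' monovalent-salt entropy correction and a linear formamide correction.
#' Defaults (0.3 M Na+, 30 percent formamide, 5 nM oligo) describe a typical
#' FISH hybridization buffer and put ordinary 40-60 percent GC 42-mers in the
#' high-50s to mid-60s C.
#'
#' @param seq DNA string over ACGT (vectorized)
#' @param na_molar monovalent cation concentration (mol/L)
#' @param formamide_pct formamide percentage (0.65 C depression per percent)
#' @param oligo_conc total oligo concentration (mol/L)
#' @return melting temperature in degrees C
#' @export
oligo_tm <- function(seq, na_molar = 0.3, formamide_pct = 30,
                     oligo_conc = 5e-9) {
  vapply(seq, function(s) {
    b <- strsplit(toupper(s), "")[[1]]
    if (length(b) < 2 || !all(b %in% c("A", "C", "G", "T"))) return(NA_real_)
    nn <- paste0(b[-length(b)], b[-1])
    dh <- sum(NN_DH[nn])
    ds <- sum(NN_DS[nn])
    for (term in c(b[1], b[length(b)])) {
      if (term %in% c("G", "C")) { dh <- dh + 0.1; ds <- ds - 2.8 }
      else { dh <- dh + 2.3; ds <- ds + 4.1 }
    }
    ds <- ds + 0.368 * (length(b) - 1) * log(na_molar)
    tm_k <- dh * 1000 / (ds + 1.9872 * log(oligo_conc / 4))
    tm_k - 273.15 - 0.65 * formamide_pct
  }, numeric(1), USE.NAMES = FALSE)
}

#' Design 42-nt probe target windows for one locus
#'
#' Scores every 42-nt window of the sequence (windows containing N are
#' rejected), keeps those with GC in `gc_range` and nearest-neighbor Tm in
#' `tm_range`, then selects a non-overlapping subset greedily left to right
#' so that no genomic overlap exists between any pair of target sequences.
#' The locus is rejected when fewer than `min_probes` windows are selected.
#'
#' @param sequence DNA string over ACGTN (the 20-kb locus segment)
#' @param min_probes minimum number of selected windows to keep the locus
#' @param gc_range GC-fraction bounds (default 0.40-0.60)
#' @param tm_range melting-temperature bounds in C (default 57-67)
#' @param window_size probe target length (42 nt)
#' @param ... passed to [oligo_tm()] (buffer conditions)
#' @return list(windows = data.frame(start, end, gc_frac, tm) of selected
#'   windows (0-based half-open within the sequence), n_passing = windows
#'   passing filters before overlap selection, rejected = logical)
#' @export
design_probe_windows <- function(sequence, min_probes = 50,
                                 gc_range = c(0.40, 0.60),
                                 tm_range = c(57, 67), window_size = 42, ...) {
  if (!nzchar(sequence)) stop("empty sequence")
  b <- strsplit(toupper(sequence), "")[[1]]
  L <- length(b)
  empty <- data.frame(start = integer(0), end = integer(0),
                      gc_frac = numeric(0), tm = numeric(0))
  if (L < window_size)
    return(list(windows = empty, n_passing = 0L, rejected = TRUE))
  # cumulative dinucleotide dH/dS and base classes -> O(1) window scores
  nn <- paste0(b[-L], b[-1])
  known <- nn %in% names(NN_DH)
  dh_s <- ifelse(known, NN_DH[nn], NA_real_)
  ds_s <- ifelse(known, NN_DS[nn], NA_real_)
  cgc <- cumsum(b %in% c("G", "C"))
  cn <- cumsum(!(b %in% c("A", "C", "G", "T")))
  cdh <- cumsum(ifelse(is.na(dh_s), 0, dh_s))
  cds <- cumsum(ifelse(is.na(ds_s), 0, ds_s))
  cbad <- cumsum(is.na(dh_s))
  starts <- seq_len(L - window_size + 1)  # 1-based window starts
  ends <- starts + window_size - 1
  has_n <- (cn[ends] - c(0, cn)[starts]) > 0
  bad_nn <- (cbad[ends - 1] - c(0, cbad)[starts]) > 0
  gc <- (cgc[ends] - c(0, cgc)[starts]) / window_size
  dh <- cdh[ends - 1] - c(0, cdh)[starts]
  ds <- cds[ends - 1] - c(0, cds)[starts]
  dots <- list(...)
  na_molar <- dots$na_molar %||% 0.3
  formamide_pct <- dots$formamide_pct %||% 30
  oligo_conc <- dots$oligo_conc %||% 5e-9
  term_adj <- function(base) ifelse(base %in% c("G", "C"), 1, 0)
  dh <- dh + ifelse(term_adj(b[starts]) == 1, 0.1, 2.3) +
    ifelse(term_adj(b[ends]) == 1, 0.1, 2.3)
  ds <- ds + ifelse(term_adj(b[starts]) == 1, -2.8, 4.1) +
    ifelse(term_adj(b[ends]) == 1, -2.8, 4.1)
  ds <- ds + 0.368 * (window_size - 1) * log(na_molar)
  tm <- dh * 1000 / (ds + 1.9872 * log(oligo_conc / 4)) - 273.15 -
    0.65 * formamide_pct
  pass <- !has_n & !bad_nn &
    gc >= gc_range[1] & gc <= gc_range[2] &
    tm >= tm_range[1] & tm <= tm_range[2]
  # greedy left-to-right non-overlapping selection
  sel <- integer(0)
  next_free <- 1L
  for (i in which(pass)) {
    if (starts[i] >= next_free) {
      sel <- c(sel, i)
      next_free <- starts[i] + window_size
    }
  }
  windows <- data.frame(start = starts[sel] - 1L, end = ends[sel],
                        gc_frac = gc[sel], tm = tm[sel])
  list(windows = windows, n_passing = sum(pass),
       rejected = length(sel) < min_probes)
}

# stitch sorted intervals on one chromosome when the edge gap <= max_gap;
# signal is summed over members
stitch_intervals <- function(df, max_gap) {
  if (nrow(df) == 0) return(df)
  df <- df[order(df$start), , drop = FALSE]
  grp <- cumsum(c(1, ifelse(df$start[-1] - df$end[-nrow(df)] > max_gap, 1, 0)))
  out <- do.call(rbind, lapply(split(df, grp), function(g) {
    data.frame(chrom = g$chrom[1], start = min(g$start), end = max(g$end),
               signal = sum(g$signal), n_members = nrow(g),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' ROSE tangent cutoff on a ranked signal curve
#'
#' Regions are ranked ascending by signal; rank and signal are min-max
#' scaled to the unit square, and the cutoff is the tangent point of a
#' slope-1 line from below (the rank minimizing scaled signal minus scaled
#' rank). Regions strictly above the tangent rank are super-enhancers.
#'
#' @param signal numeric vector of region signals
#' @return logical vector, TRUE for regions above the cutoff
#' @export
rose_cutoff <- function(signal) {
  n <- length(signal)
  if (n == 0) return(logical(0))
  if (n < 3) return(rep(TRUE, n))
  ord <- order(signal)
  x <- (seq_len(n) - 1) / (n - 1)
  y <- (signal[ord] - min(signal)) / (max(signal) - min(signal))
  if (max(signal) == min(signal)) return(rep(TRUE, n))
  tangent <- which.min(y - x)
  keep_rank <- seq_len(n) > tangent
  keep <- logical(n)
  keep[ord] <- keep_rank
  keep
}

#' Call cell type-specific super-enhancer loci from ATAC peaks
#'
#' Per cell type: peaks with any point within `tss_exclusion` of a TSS are
#' dropped; remaining peaks within `stitch_gap` of each other (edge to edge)
#' are stitched; stitched regions are ranked by total signal and kept above
#' the ROSE tangent cutoff. Across cell types, super-enhancers within
#' `merge_window` of each other are merged iteratively to a fixed point, and
#' merged regions are kept when the mean member-length/merged-length ratio
#' is at least `min_overlap_ratio` and the merged length exceeds `min_size`.
#'
#' @param peaks data.frame(chrom, start, end, signal, cell_type)
#' @param tss data.frame(chrom, pos) of TSS coordinates
#' @param stitch_gap stitching gap in bp (default 12.5 kb)
#' @param tss_exclusion TSS exclusion distance in bp (default 2.5 kb)
#' @param merge_window cross-cell-type merge distance in bp (default 100 kb)
#' @param min_overlap_ratio minimum mean member/merged length ratio (0.8)
#' @param min_size minimum merged length in bp (15 kb, exclusive)
#' @return data.frame(chrom, start, end, score, n_members, cell_types) of
#'   merged super-enhancer loci (empty when no peaks survive)
#' @export
call_super_enhancers <- function(peaks, tss, stitch_gap = 12500,
                                 tss_exclusion = 2500, merge_window = 1e5,
                                 min_overlap_ratio = 0.8, min_size = 15000) {
  empty <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), score = numeric(0),
                      n_members = integer(0), cell_types = character(0),
                      stringsAsFactors = FALSE)
  if (nrow(peaks) == 0) return(empty)
  per_type <- list()
  for (ct in unique(peaks$cell_type)) {
    pk <- peaks[peaks$cell_type == ct, , drop = FALSE]
    # TSS exclusion: any point of the peak within tss_exclusion of a TSS
    near_tss <- vapply(seq_len(nrow(pk)), function(i) {
      t_on <- tss$pos[tss$chrom == pk$chrom[i]]
      length(t_on) > 0 &&
        any(t_on >= pk$start[i] - tss_exclusion &
            t_on <= pk$end[i] + tss_exclusion)
    }, logical(1))
    pk <- pk[!near_tss, , drop = FALSE]
    if (nrow(pk) == 0) next
    stitched <- do.call(rbind, lapply(split(pk, pk$chrom), stitch_intervals,
                                      max_gap = stitch_gap))
    keep <- rose_cutoff(stitched$signal)
    se <- stitched[keep, , drop = FALSE]
    if (nrow(se)) {
      se$cell_type <- ct
      per_type[[ct]] <- se
    }
  }
  if (!length(per_type)) return(empty)
  pooled <- do.call(rbind, per_type)
  rownames(pooled) <- NULL
  pooled$members <- as.list(pooled$end - pooled$start)
  pooled$cts <- as.list(pooled$cell_type)
  # iterative merge across cell types until fixed point (single-linkage
  # chaining converges in <= n iterations; one grouped pass per iteration)
  merged <- do.call(rbind, lapply(split(pooled, pooled$chrom), function(df) {
    df <- df[order(df$start), , drop = FALSE]
    repeat {
      grp <- cumsum(c(1, ifelse(df$start[-1] - cummax(df$end)[-nrow(df)] >
                                  merge_window, 1, 0)))
      if (length(unique(grp)) == nrow(df)) break
      df <- do.call(rbind, lapply(split(df, grp), function(g) {
        data.frame(chrom = g$chrom[1], start = min(g$start), end = max(g$end),
                   signal = sum(g$signal), n_members = sum(g$n_members),
                   members = I(list(unlist(g$members))),
                   cts = I(list(unlist(g$cts))),
                   stringsAsFactors = FALSE)
      }))
      df <- df[order(df$start), , drop = FALSE]
    }
    df
  }))
  rownames(merged) <- NULL
  merged_len <- merged$end - merged$start
  ratio <- vapply(seq_len(nrow(merged)), function(i)
    mean(unlist(merged$members[[i]]) / merged_len[i]), numeric(1))
  keep <- ratio >= min_overlap_ratio & merged_len > min_size
  out <- data.frame(chrom = merged$chrom, start = merged$start,
                    end = merged$end, score = merged$signal,
                    n_members = merged$n_members,
                    cell_types = vapply(merged$cts, function(x)
                      paste(sort(unique(unlist(x))), collapse = ","),
                      character(1)),
                    stringsAsFactors = FALSE)[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
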