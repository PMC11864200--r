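# Per-cell nuclear and chromosome-territory geometry. The nucleus is
# proxied by the 3D convex hull of all decoded loci of the cell: its volume
# estimates nuclear volume, its volume centroid is the nuclear center, and
# normalized radial positions are measured along the ray from the centroid
# to each locus, divided by the distance at which that ray exits the hull.

trace_coords <- function(cell_trace) {
  as.matrix(cell_trace[, c("x", "y", "z")])
}

#' Convex hull of one cell's loci
#'
#' @param cell_trace trace rows of a single cell
#' @return list(degenerate, volume, centroid, faces, points) — `degenerate`
#'   is TRUE for < 4 points or (near-)coplanar input
#' @export
cell_hull <- function(cell_trace) {
  pts <- trace_coords(cell_trace)
  h <- .convex_hull_3d(pts)
  h$points <- pts
  h
}

#' Nuclear volume of one cell
#'
#' Convex-hull volume (um^3) of all decoded locus coordinates. Returns `NA`
#' when fewer than `min_loci` loci are decoded (default 1250; use 600 for
#' sparse datasets) or when the hull is degenerate.
#'
#' @param cell_trace trace rows of a single cell
#' @param min_loci minimum decoded loci required
#' @return volume in um^3, or NA (with attribute `reason`)
#' @export
nuclear_volume <- function(cell_trace, min_loci = 1250) {
  if (nrow(cell_trace) < min_loci)
    return(structure(NA_real_, reason = "too_few_loci"))
  h <- cell_hull(cell_trace)
  if (h$degenerate) return(structure(NA_real_, reason = "degenerate_hull"))
  h$volume
}

#' Normalized radial positions of one cell's loci
#'
#' For each locus p, `r = |p - c| / |q - c|` where c is the hull volume
#' centroid and q is the point where the ray c -> p exits the hull surface;
#' r = 0 at the centroid and 1 on the surface. Values marginally above 1
#' (localization noise) are clipped to 1; more than `clip_warn` clipped
#' fraction triggers a warning.
#'
#' @param cell_trace trace rows of a single cell
#' @param min_loci minimum decoded loci (default 600)
#' @param clip_warn warn when more than this fraction of loci clip (0.01)
#' @return data.frame(cell_id, locus_id, homolog, radial, clipped), or NULL
#'   when the hull is degenerate or the cell has too few loci
#' @export
radial_positions <- function(cell_trace, min_loci = 600, clip_warn = 0.01) {
  if (nrow(cell_trace) < min_loci) return(NULL)
  h <- cell_hull(cell_trace)
  if (h$degenerate) return(NULL)
  r <- .hull_radial(h$points, h$faces, h$centroid, h$points)
  # hull vertices land at r = 1 + numerical eps; only count substantive clips
  clipped <- !is.na(r) & r > 1 + 1e-6
  if (mean(clipped) > clip_warn)
    warning(sprintf("%.1f%% of loci outside the hull (clipped to 1)",
                    100 * mean(clipped)))
  r <- pmin(r, 1)
  data.frame(cell_id = cell_trace$cell_id, locus_id = cell_trace$locus_id,
             homolog = cell_trace$homolog, radial = r, clipped = clipped,
             stringsAsFactors = FALSE)
}

#' Radial positions for every eligible cell in a trace table
#'
#' @param traces chromatin trace table
#' @param min_loci minimum decoded loci per cell (default 600)
#' @return data.frame(cell_id, cell_type, genotype, locus_id, homolog,
#'   radial, clipped)
#' @export
radial_profile <- function(traces, min_loci = 600) {
  dt <- data.table::as.data.table(traces)
  meta <- unique(dt[, .(cell_id, cell_type, genotype)])
  out <- lapply(split(traces, traces$cell_id), radial_positions,
                min_loci = min_loci)
  out <- data.table::rbindlist(out[!vapply(out, is.null, logical(1))])
  if (!nrow(out)) return(NULL)
  res <- merge(out, meta, by = "cell_id")
  as.data.frame(res[, .(cell_id, cell_type, genotype, locus_id, homolog,
                        radial, clipped)])
}

#' Radius of gyration of one chromosome territory
#'
#' Root mean squared distance of the homolog's decoded loci from their
#' centroid (um). `NA` with fewer than 2 loci.
#'
#' @param cell_trace trace rows of a single cell
#' @param chrom chromosome name
#' @param homolog homolog index
#' @return Rg in um, or NA
#' @export
territory_radius_of_gyration <- function(cell_trace, chrom, homolog) {
  sel <- cell_trace$chrom == chrom & cell_trace$homolog == homolog
  p <- trace_coords(cell_trace[sel, , drop = FALSE])
  if (nrow(p) < 2) return(NA_real_)
  cen <- colMeans(p)
  sqrt(mean(rowSums(sweep(p, 2, cen)^2)))
}

#' Chromosome-territory intermixing score
#'
#' For each homolog: the mean, over its loci, of the fraction of the k
#' nearest neighboring loci in the same cell (all chromosomes) that belong
#' to a different chromosome. 0 = fully demixed territories; for randomly
#' permuted labels the score approaches the trans-locus fraction. This kNN
#' definition is this package's own stand-in for an intermixing metric; no
#' standard published formula is implemented.
#'
#' @param cell_trace trace rows of a single cell
#' @param k number of nearest neighbors (default 10)
#' @return data.frame(chrom, homolog, intermixing), or NULL when fewer than
#'   k+1 loci or a single chromosome is decoded
#' @export
territory_intermixing <- function(cell_trace, k = 10) {
  if (length(unique(cell_trace$chrom)) < 2) return(NULL)
  n <- nrow(cell_trace)
  if (n < k + 1) return(NULL)
  p <- trace_coords(cell_trace)
  d <- as.matrix(stats::dist(p))
  diag(d) <- Inf
  other <- vapply(seq_len(n), function(i) {
    nn <- order(d[i, ])[seq_len(k)]
    mean(cell_trace$chrom[nn] != cell_trace$chrom[i])
  }, numeric(1))
  dt <- data.table::data.table(chrom = cell_trace$chrom,
                               homolog = cell_trace$homolog, frac = other)
  out <- dt[, .(intermixing = mean(frac)), by = .(chrom, homolog)]
  as.data.frame(out)
}

#' Per-cell geometry summary over a trace table
#'
#' @param traces chromatin trace table
#' @param min_loci minimum loci for nuclear volume (default 1250)
#' @return data.frame(cell_id, cell_type, genotype, n_loci, nuclear_volume)
#' @export
cell_geometry <- function(traces, min_loci = 1250) {
  out <- lapply(split(traces, traces$cell_id), function(ct) {
    data.frame(cell_id = ct$cell_id[1], cell_type = ct$cell_type[1],
               genotype = ct$genotype[1], n_loci = nrow(ct),
               nuclear_volume = as.numeric(nuclear_volume(ct, min_loci)),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
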