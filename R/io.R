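# Readers/writers for the on-disk formats: locus panels (BED-like TSV),
# chromatin trace tables (CSV), expression tables (TSV), YAML run configs.
# All readers validate invariants and reject rather than coerce.

PANEL_GROUPS <- c("genome_wide", "super_enhancer", "tss")

#' Default run configuration
#'
#' All pipeline tunables in one list. Defaults: spatial proximity cutoff
#' 0.75 um, scaling-regime boundary 10 Mb, minimum 1250 decoded loci per
#' cell for nuclear-volume estimation (600 for radial/density analyses),
#' Gaussian kernel scale 1 um for local A/B density, 10 equal-count radial
#' bins, 20 observed cells per locus pair, 20 log-spaced genomic-distance
#' bins per decade.
#'
#' @param ... named overrides of any default
#' @return named list of class `ct_config`
#' @export
ct_config <- function(...) {
  cfg <- list(
    proximity_cutoff = 0.75,     # um
    scaling_boundary = 1e7,      # bp
    min_loci_volume = 1250L,     # loci per cell for nuclear volume
    min_loci_radial = 600L,      # loci per cell for radial / density scores
    kernel_scale = 1.0,          # um, local A/B density kernel sd
    n_radial_bins = 10L,
    min_cells_per_pair = 20L,
    bins_per_decade = 20L,
    insulation_window = 5L,      # loci
    min_trans_loci = 10L,
    gene_locus_window = 1e5,     # bp
    seed = 1L
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop("unknown config fields: ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  structure(cfg, class = "ct_config")
}

#' Read a run configuration from YAML
#'
#' Unknown keys are rejected; missing keys take the [ct_config()] defaults.
#'
#' @param path YAML file
#' @return `ct_config` list
#' @export
read_config <- function(path) {
  stopifnot(file.exists(path))
  do.call(ct_config, yaml::read_yaml(path))
}

#' Write a run configuration to YAML
#' @param cfg `ct_config` list
#' @param path output file
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Validate a locus panel
#'
#' Checks the panel invariants: required columns, unique locus ids, sorted
#' by (chrom, start), non-negative CpG density, valid panel groups, and
#' (optionally) the fixed 20-kb locus width.
#'
#' @param panel data.frame with columns locus_id, chrom, start, end and
#'   optionally panel_group, cpg_density, barcode_id
#' @param strict_length require `end - start == locus_length` for all loci
#' @param locus_length expected width in bp (default 20000)
#' @return the panel, invisibly, after validation
#' @export
validate_locus_panel <- function(panel, strict_length = FALSE, locus_length = 20000L) {
  req <- c("locus_id", "chrom", "start", "end")
  miss <- setdiff(req, names(panel))
  if (length(miss)) stop("panel missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(panel$locus_id))
    stop("duplicate locus_id: ",
         paste(unique(panel$locus_id[duplicated(panel$locus_id)]), collapse = ", "))
  if (any(panel$end <= panel$start)) stop("loci with end <= start")
  if (!is.null(panel$cpg_density) && any(panel$cpg_density < 0, na.rm = TRUE))
    stop("negative cpg_density")
  if (!is.null(panel$panel_group)) {
    bad <- setdiff(unique(panel$panel_group), PANEL_GROUPS)
    if (length(bad)) stop("unknown panel_group: ", paste(bad, collapse = ", "))
  }
  ord <- order(panel$chrom, panel$start)
  if (!identical(ord, seq_len(nrow(panel))))
    stop("panel not sorted by (chrom, start)")
  if (strict_length && any(panel$end - panel$start != locus_length))
    stop("loci violating fixed width ", locus_length, " bp: ",
         paste(panel$locus_id[panel$end - panel$start != locus_length][1:5],
               collapse = ", "))
  invisible(panel)
}

#' Read a locus panel from a BED-like TSV
#'
#' Columns: chrom, start, end, locus_id and optionally panel_group,
#' cpg_density, barcode_id. Coordinates are 0-based half-open (BED
#' convention). Lines starting with `#` or a `track` line are skipped.
#'
#' @inheritParams validate_locus_panel
#' @param path BED/TSV file
#' @return data.frame sorted by (chrom, start), validated
#' @export
read_locus_panel <- function(path, strict_length = FALSE, locus_length = 20000L) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(lines)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nfield <- lengths(fields)
  if (length(fields) == 0) stop("empty panel file: ", path)
  if (any(nfield < 4)) {
    bad <- which(keep)[which(nfield < 4)[1]]
    stop("malformed panel line ", bad, " in ", path, ": fewer than 4 fields")
  }
  get <- function(i, default = NA) vapply(fields, function(f)
    if (length(f) >= i) f[[i]] else as.character(default), character(1))
  start <- suppressWarnings(as.numeric(get(2)))
  end <- suppressWarnings(as.numeric(get(3)))
  if (anyNA(start) || anyNA(end)) {
    bad <- which(keep)[which(is.na(start) | is.na(end))[1]]
    stop("malformed panel line ", bad, " in ", path, ": non-numeric coordinates")
  }
  panel <- data.frame(
    locus_id = get(4),
    chrom = get(1),
    start = start,
    end = end,
    stringsAsFactors = FALSE
  )
  if (max(nfield) >= 5) panel$panel_group <- get(5, "genome_wide")
  if (max(nfield) >= 6) panel$cpg_density <- suppressWarnings(as.numeric(get(6, NA)))
  if (max(nfield) >= 7) panel$barcode_id <- get(7, NA)
  panel <- panel[order(panel$chrom, panel$start), , drop = FALSE]
  rownames(panel) <- NULL
  validate_locus_panel(panel, strict_length = strict_length, locus_length = locus_length)
  panel
}

#' Write a locus panel as BED-like TSV
#' @param panel locus panel data.frame
#' @param path output file
#' @export
write_locus_panel <- function(panel, path) {
  validate_locus_panel(panel)
  cols <- c("chrom", "start", "end", "locus_id")
  for (extra in c("panel_group", "cpg_density", "barcode_id"))
    if (!is.null(panel[[extra]])) cols <- c(cols, extra)
  out <- panel[, cols, drop = FALSE]
  # fixed decimal formatting so that read/write round-trips byte-identically
  out$start <- format(out$start, scientific = FALSE, trim = TRUE)
  out$end <- format(out$end, scientific = FALSE, trim = TRUE)
  if (!is.null(out$cpg_density))
    out$cpg_density <- formatC(out$cpg_density, format = "g", digits = 15)
  lines <- do.call(paste, c(unname(as.list(out)), sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Validate a chromatin trace table
#'
#' Invariants: required columns, unique (cell_id, locus_id, homolog), finite
#' coordinates, genotype in WT/KO/NA, and (when a panel is given) every
#' locus_id present in the panel.
#'
#' @param traces data.frame of trace rows
#' @param panel optional companion locus panel
#' @return the traces, invisibly
#' @export
validate_traces <- function(traces, panel = NULL) {
  req <- c("cell_id", "cell_type", "genotype", "chrom", "locus_id",
           "homolog", "x", "y", "z")
  miss <- setdiff(req, names(traces))
  if (length(miss)) stop("trace table missing columns: ", paste(miss, collapse = ", "))
  key <- paste(traces$cell_id, traces$locus_id, traces$homolog, sep = "\r")
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1]
    stop("duplicate (cell_id, locus_id, homolog) key: ",
         gsub("\r", ", ", d, fixed = TRUE),
         " (", sum(duplicated(key)), " duplicated rows)")
  }
  if (!all(is.finite(traces$x) & is.finite(traces$y) & is.finite(traces$z)))
    stop("non-finite coordinates in trace table")
  bad_g <- setdiff(unique(as.character(traces$genotype)), c("WT", "KO", "NA"))
  if (length(bad_g)) stop("unknown genotype: ", paste(bad_g, collapse = ", "))
  if (any(traces$homolog < 0)) stop("negative homolog index")
  if (!is.null(panel)) {
    unknown <- setdiff(unique(traces$locus_id), panel$locus_id)
    if (length(unknown))
      stop("trace locus_id absent from panel: ",
           paste(head(unknown, 10), collapse = ", "))
  }
  invisible(traces)
}

#' Read a chromatin trace table (CSV)
#'
#' Required columns: cell_id, cell_type, genotype, chrom, locus_id, homolog,
#' x, y, z (um); optional: score. Validated against [validate_traces()].
#'
#' @param path CSV file
#' @param panel optional companion locus panel used to check locus ids
#' @return data.frame of trace rows
#' @export
read_traces <- function(path, panel = NULL) {
  stopifnot(file.exists(path))
  traces <- read.csv(path, stringsAsFactors = FALSE)
  validate_traces(traces, panel)
  traces
}

#' Write a chromatin trace table (CSV)
#' @param traces trace data.frame
#' @param path output file
#' @export
write_traces <- function(traces, path) {
  validate_traces(traces)
  write.csv(traces, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an expression table (TSV)
#'
#' Columns: gene_id, chrom, tss, gene_length, then one count column per cell
#' type or per cell. Counts must be non-negative; gene ids unique.
#'
#' @param path TSV file
#' @return data.frame
#' @export
read_expression <- function(path) {
  stopifnot(file.exists(path))
  expr <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  req <- c("gene_id", "chrom", "tss", "gene_length")
  miss <- setdiff(req, names(expr))
  if (length(miss)) stop("expression table missing columns: ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(expr$gene_id)) stop("duplicate gene_id")
  counts <- expr[, setdiff(names(expr), req), drop = FALSE]
  if (any(as.matrix(counts) < 0, na.rm = TRUE)) stop("negative counts")
  expr
}

#' Write an expression table (TSV)
#' @param expr expression data.frame
#' @param path output file
#' @export
write_expression <- function(expr, path) {
  write.table(expr, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an ATAC peak table (BED with signal and cell type)
#'
#' Columns: chrom, start, end, signal, cell_type (tab-separated, no header).
#'
#' @param path BED file
#' @return data.frame sorted by (cell_type, chrom, start)
#' @export
read_peaks <- function(path) {
  stopifnot(file.exists(path))
  pk <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(pk) < 5) stop("peak BED needs 5 columns: chrom start end signal cell_type")
  names(pk)[1:5] <- c("chrom", "start", "end", "signal", "cell_type")
  if (any(pk$start >= pk$end)) stop("peak with start >= end")
  if (any(pk$signal < 0)) stop("negative peak signal")
  pk <- pk[order(pk$cell_type, pk$chrom, pk$start), , drop = FALSE]
  rownames(pk) <- NULL
  pk
}
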