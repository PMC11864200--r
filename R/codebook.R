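# Constant-weight error-correcting barcodes for RNA- and DNA-MERFISH.
# A codebook holds n_bits, the Hamming weight w, the minimum pairwise
# Hamming distance, and the codewords as a matrix of on-bit positions
# (rows = words, sorted positions, bit 1 = MSB of the printed bit-string).
# For equal-weight words HD = 2*(w - shared on-bits), so the minimum-distance
# constraint is a bound on shared on-bits.

#' Enumerate all constant-weight binary words
#'
#' All `choose(n_bits, w)` binary words of length `n_bits` with exactly `w`
#' on-bits, as a matrix of sorted on-bit positions (1 = MSB). Rows are in
#' ascending lexicographic order of the printed bit-string.
#'
#' @param n_bits word length
#' @param w Hamming weight (number of on-bits)
#' @return integer matrix, `choose(n_bits, w)` rows x `w` columns
#' @export
enumerate_weight_words <- function(n_bits, w) {
  stopifnot(length(n_bits) == 1, length(w) == 1)
  if (w <= 0 || w > n_bits) stop("need 0 < w <= n_bits")
  m <- t(combn(n_bits, w))
  # combn is lexicographic in position sets; with bit 1 = MSB that is
  # descending bit-string order, so reverse for ascending
  m[rev(seq_len(nrow(m))), , drop = FALSE]
}

#' Bit-string representation of codewords
#' @param pos integer matrix of on-bit positions (rows = words)
#' @param n_bits word length
#' @return character vector of 0/1 strings, MSB = bit 1
#' @export
words_to_bitstrings <- function(pos, n_bits) {
  apply(pos, 1, function(p) {
    b <- rep("0", n_bits)
    b[p] <- "1"
    paste(b, collapse = "")
  })
}

#' Parse bit-strings into an on-bit position matrix
#' @param bits character vector of equal-length 0/1 strings
#' @return integer matrix of on-bit positions
#' @export
bitstrings_to_words <- function(bits) {
  stopifnot(length(unique(nchar(bits))) == 1)
  pos <- lapply(strsplit(bits, ""), function(b) which(b == "1"))
  w <- unique(lengths(pos))
  if (length(w) != 1) stop("bit-strings of unequal Hamming weight")
  matrix(unlist(pos), ncol = w, byrow = TRUE)
}

#' Build a constant-weight code by randomized greedy search
#'
#' Enumerates all weight-`w` words, and for each of `restarts` seeds shuffles
#' the candidate list and greedily accepts a word iff its Hamming distance to
#' every accepted word is at least `min_hd`. The largest code over all
#' restarts is kept and its pairwise minimum distance re-verified
#' exhaustively before return. Errors if the best size is below
#' `target_size`.
#'
#' @param n_bits word length
#' @param w Hamming weight
#' @param min_hd minimum pairwise Hamming distance (even, <= 2w)
#' @param target_size required code size (default 1 = any non-empty code)
#' @param restarts number of shuffled greedy passes
#' @param seed RNG seed
#' @return object of class `ct_codebook`: list(n_bits, weight, min_hd,
#'   words, size, assignment = NULL)
#' @export
build_code <- function(n_bits, w, min_hd = 4, target_size = 1,
                       restarts = 20, seed = 1) {
  if (min_hd %% 2 != 0) stop("min_hd must be even for constant-weight codes")
  if (min_hd > 2 * w) stop("min_hd > 2w is unsatisfiable for weight-", w, " words")
  if (n_bits > 128) stop("n_bits > 128 not supported")
  cand <- enumerate_weight_words(n_bits, w)
  max_shared <- w - min_hd / 2
  best <- integer(0)
  for (r in seq_len(restarts)) {
    set.seed(derive_seed(seed, r))
    ord <- sample.int(nrow(cand))
    acc <- .cw_greedy(cand, ord, as.integer(max_shared))
    if (length(acc) > length(best)) best <- acc
  }
  if (length(best) < target_size)
    stop("capacity not reached: best code size ", length(best),
         " < target ", target_size, " after ", restarts, " restarts")
  words <- cand[best, , drop = FALSE]
  hd_obs <- .cw_min_hd(words, n_bits)
  if (nrow(words) > 1 && hd_obs < min_hd)
    stop("internal error: built code violates min_hd (", hd_obs, ")")
  structure(list(n_bits = as.integer(n_bits), weight = as.integer(w),
                 min_hd = as.integer(min_hd), words = words,
                 size = nrow(words), assignment = NULL),
            class = "ct_codebook")
}

#' @export
print.ct_codebook <- function(x, ...) {
  cat(sprintf("ct_codebook: %d words, %d bits, weight %d, min HD %d%s\n",
              x$size, x$n_bits, x$weight, x$min_hd,
              if (is.null(x$assignment)) "" else
                sprintf(", %d loci assigned", nrow(x$assignment))))
  invisible(x)
}

#' Verify the pairwise minimum Hamming distance of a codebook exhaustively
#' @param codebook `ct_codebook`
#' @return minimum pairwise Hamming distance observed
#' @export
verify_code <- function(codebook) {
  .cw_min_hd(codebook$words, codebook$n_bits)
}

# Objective used by the within-chromosome swap search: minimum genomic
# distance between consecutive loci sharing an on-bit, and the coefficient
# of variation of all such consecutive same-bit distances.
samebit_objective <- function(word_rows, words, mids) {
  n_bits <- max(words)
  dists <- numeric(0)
  for (b in seq_len(n_bits)) {
    on <- which(apply(words[word_rows, , drop = FALSE], 1, function(p) b %in% p))
    if (length(on) >= 2) {
      m <- sort(mids[on])
      dists <- c(dists, diff(m))
    }
  }
  if (!length(dists)) return(c(min = Inf, cv = 0))
  c(min = min(dists), cv = stats::sd(dists) / mean(dists))
}

#' Assign barcodes to panel loci
#'
#' Two-phase assignment following the design goals for genomic-locus panels:
#' (1) greedy balance — loci are processed chromosome by chromosome and each
#' receives the unused codeword minimizing (per-chromosome max per-bit load,
#' global max per-bit load, summed global load), so per-bit usage counts
#' differ by at most 1 wherever combinatorially feasible; (2) within each
#' chromosome, barcode swaps between loci are applied to a fixed point when
#' they lexicographically improve (minimum genomic distance between loci
#' sharing an on-bit, -CV of those same-bit distances). Genomic distance is
#' midpoint-to-midpoint.
#'
#' @param panel locus panel (sorted by chrom, start)
#' @param codebook `ct_codebook` with at least as many words as loci
#' @param seed RNG seed (shuffles candidate-word scan order; ties in the
#'   balance score follow this order)
#' @param max_pass maximum swap-search passes per chromosome
#' @return the codebook with `assignment`: data.frame(locus_id, word_row,
#'   barcode)
#' @export
assign_barcodes <- function(panel, codebook, seed = 1, max_pass = 25) {
  validate_locus_panel(panel)
  n <- nrow(panel)
  if (codebook$size < n)
    stop("codebook has ", codebook$size, " words < ", n, " loci")
  set.seed(derive_seed(seed, 0))
  cand <- sample.int(codebook$size)
  chrom_id <- as.integer(factor(panel$chrom, levels = unique(panel$chrom)))
  rows <- .cw_balance_assign(codebook$words, codebook$n_bits,
                             as.integer(cand), chrom_id)
  mids <- locus_midpoints(panel)
  # phase 2: swap search within each chromosome
  for (ch in unique(chrom_id)) {
    idx <- which(chrom_id == ch)
    if (length(idx) < 3) next
    obj <- samebit_objective(rows[idx], codebook$words, mids[idx])
    for (pass in seq_len(max_pass)) {
      improved <- FALSE
      for (a in seq_along(idx)) for (b in seq_along(idx)) {
        if (b <= a) next
        r2 <- rows[idx]
        r2[c(a, b)] <- r2[c(b, a)]
        o2 <- samebit_objective(r2, codebook$words, mids[idx])
        if (o2["min"] > obj["min"] ||
            (o2["min"] == obj["min"] && o2["cv"] < obj["cv"] - 1e-12)) {
          rows[idx] <- r2
          obj <- o2
          improved <- TRUE
        }
      }
      if (!improved) break
    }
  }
  codebook$assignment <- data.frame(
    locus_id = panel$locus_id,
    word_row = rows,
    barcode = words_to_bitstrings(codebook$words[rows, , drop = FALSE],
                                  codebook$n_bits),
    stringsAsFactors = FALSE
  )
  codebook
}

#' Per-bit usage counts of an assignment
#' @param codebook assigned `ct_codebook`
#' @return integer vector of length n_bits
#' @export
bit_usage <- function(codebook) {
  if (is.null(codebook$assignment)) stop("codebook has no assignment")
  pos <- codebook$words[codebook$assignment$word_row, , drop = FALSE]
  tabulate(as.vector(pos), nbins = codebook$n_bits)
}

#' Decode a readout bit vector against a codebook
#'
#' Exact codeword match returns its locus (or word index when unassigned);
#' otherwise a unique codeword at Hamming distance 1 is accepted
#' (single-error correction, valid because min HD = 4); otherwise `NA`.
#'
#' @param bits 0/1 vector of length n_bits, a bit-string, or a matrix of
#'   0/1 rows for vectorized decoding
#' @param codebook `ct_codebook`
#' @return locus_id (if assigned) or codeword row index; NA when not decodable
#' @export
decode_readout <- function(bits, codebook) {
  if (is.character(bits)) bits <- t(vapply(strsplit(bits, ""), as.integer,
                                           integer(codebook$n_bits)))
  if (is.vector(bits)) bits <- matrix(as.integer(bits), nrow = 1)
  if (ncol(bits) != codebook$n_bits)
    stop("readout length ", ncol(bits), " != n_bits ", codebook$n_bits)
  rows <- .cw_decode(bits, codebook$words)
  out <- ifelse(rows == 0L, NA_integer_, rows)
  if (!is.null(codebook$assignment)) {
    map <- rep(NA_character_, codebook$size)
    map[codebook$assignment$word_row] <- codebook$assignment$locus_id
    res <- ifelse(is.na(out), NA_character_, map[out])
    return(if (length(res) == 1) res[[1]] else res)
  }
  if (length(out) == 1) out[[1]] else out
}

#' Write a codebook to CSV
#'
#' Columns: locus_id (empty when unassigned), barcode (bit-string, MSB =
#' bit 1), on_bits (semicolon-separated 1-based indices). Bit-exact round
#' trip via [read_codebook()].
#'
#' @param codebook `ct_codebook`
#' @param path output CSV
#' @export
write_codebook <- function(codebook, path) {
  bits <- words_to_bitstrings(codebook$words, codebook$n_bits)
  on_bits <- apply(codebook$words, 1, paste, collapse = ";")
  locus <- rep(NA_character_, codebook$size)
  if (!is.null(codebook$assignment))
    locus[codebook$assignment$word_row] <- codebook$assignment$locus_id
  df <- data.frame(locus_id = locus, barcode = bits, on_bits = on_bits,
                   stringsAsFactors = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read a codebook from CSV written by [write_codebook()]
#' @param path CSV file
#' @param min_hd declared minimum Hamming distance (re-verified)
#' @return `ct_codebook`
#' @export
read_codebook <- function(path, min_hd = 4) {
  df <- read.csv(path, stringsAsFactors = FALSE, na.strings = "",
                 colClasses = "character")
  words <- bitstrings_to_words(df$barcode)
  n_bits <- nchar(df$barcode[1])
  hd_obs <- .cw_min_hd(words, n_bits)
  if (nrow(words) > 1 && hd_obs < min_hd)
    stop("codebook file violates min_hd ", min_hd, " (observed ", hd_obs, ")")
  cb <- structure(list(n_bits = as.integer(n_bits), weight = ncol(words),
                       min_hd = as.integer(min_hd), words = words,
                       size = nrow(words), assignment = NULL),
                  class = "ct_codebook")
  if (any(!is.na(df$locus_id))) {
    keep <- which(!is.na(df$locus_id))
    cb$assignment <- data.frame(locus_id = df$locus_id[keep], word_row = keep,
                                barcode = df$barcode[keep],
                                stringsAsFactors = FALSE)
  }
  cb
}
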