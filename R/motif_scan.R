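#' G-quadruplex and G-run block scanning
#'
#' The consensus G4 motif is four or more runs of at least three guanines
#' separated by loops of 1-7 nucleotides (G>=3 N1-7 G>=3 N1-7 G>=3 N1-7
#' G>=3).  Scanning tokenises a sequence into maximal G-runs (runs absorb
#' consecutive Gs greedily) and chains consecutive runs whose gaps are 1-7
#' nt; a chain of k runs is a G-run block of order k, and a chain with
#' k >= 4 is a consensus G4.  Hits are therefore leftmost, maximal and
#' non-overlapping within one strand.  Minus-strand hits are found by
#' scanning the same sequence for C-runs, so coordinates stay on the plus
#' strand in a single pass.  'N' never counts as G but is allowed inside
#' loops.
#'
#' @name motif_scan
NULL

scan_strand <- function(seq, chrom, strand, kind) {
  base <- if (strand == "+") "G" else "C"
  bl <- run_blocks_cpp(seq, base = base)
  if (kind == "g4") bl <- bl[bl$k >= 4L, , drop = FALSE]
  if (nrow(bl) == 0) return(empty_hits())
  data.frame(chrom = chrom, start = bl$start, end = bl$end, strand = strand,
             kind = if (kind == "g4") "g4" else "g_run_block",
             n_g_runs = pmin(bl$k, 6L),
             matched_sequence = substring(seq, bl$start + 1L, bl$end),
             stringsAsFactors = FALSE)
}

empty_hits <- function() {
  data.frame(chrom = character(), start = integer(), end = integer(),
             strand = character(), kind = character(), n_g_runs = integer(),
             matched_sequence = character(), stringsAsFactors = FALSE)
}

scan_seq <- function(seq, chrom, strand_mode, kind) {
  if (!strand_mode %in% c("both", "plus", "minus"))
    stop_ctx("invalid strand_mode '", strand_mode, "'")
  seq <- toupper(seq)
  if (nchar(seq) == 0) return(empty_hits())
  out <- empty_hits()
  if (strand_mode %in% c("both", "plus"))
    out <- rbind(out, scan_strand(seq, chrom, "+", kind))
  if (strand_mode %in% c("both", "minus"))
    out <- rbind(out, scan_strand(seq, chrom, "-", kind))
  out <- out[order(out$start, out$strand), ]
  rownames(out) <- NULL
  out
}

#' Scan a sequence for consensus G4 motifs
#'
#' @param seq nucleotide string (upper-cased internally).
#' @param chrom chromosome name recorded on the hits.
#' @param strand_mode `"both"`, `"plus"` or `"minus"`.
#' @return data.frame of motif hits: chrom, start, end (0-based half-open),
#'   strand, kind, n_g_runs (capped at 6), matched_sequence (plus-strand
#'   orientation).
#' @examples
#' scan_g4("GGGAGTGGGCAGGGGTGGGGG", "oligo")
#' @export
scan_g4 <- function(seq, chrom = "seq", strand_mode = "both") {
  scan_seq(seq, chrom, strand_mode, "g4")
}

#' Scan a sequence for consecutive G-run blocks
#'
#' Maximal blocks of k consecutive runs of >= 3 G separated by 1-7 nt
#' loops; reported order `n_g_runs` is capped at 6.
#'
#' @inheritParams scan_g4
#' @return data.frame of block hits (see [scan_g4()]).
#' @export
scan_g_runs <- function(seq, chrom = "seq", strand_mode = "both") {
  scan_seq(seq, chrom, strand_mode, "g_runs")
}

#' Scan a whole genome
#'
#' Per-chromosome scans on both strands, concatenated in deterministic
#' (chrom, start, strand) order.
#'
#' @param genome a `genome_seq` object.
#' @param kind `"g4"` or `"g_runs"`.
#' @return data.frame of motif hits.
#' @export
scan_genome <- function(genome, kind = c("g4", "g_runs")) {
  kind <- match.arg(kind)
  f <- if (kind == "g4") scan_g4 else scan_g_runs
  out <- do.call(rbind, lapply(names(genome), function(ch) {
    f(unclass(genome)[[ch]], chrom = ch, strand_mode = "both")
  }))
  out <- out[order(out$chrom, out$start, out$strand), ]
  rownames(out) <- NULL
  out
}

#' Write motif hits as BED6
#'
#' Name column is "G4" or "GRUNxK"; score column is `n_g_runs`.
#'
#' @param hits motif hit data.frame.
#' @param path output file.
#' @export
write_hits_bed <- function(hits, path) {
  label <- ifelse(hits$kind == "g4", "G4", paste0("GRUNx", hits$n_g_runs))
  write_intervals(data.frame(chrom = hits$chrom, start = hits$start,
                             end = hits$end, strand = hits$strand,
                             label = label, score = hits$n_g_runs),
                  path, format = "bed6")
}

#' Count consensus G4 hits in sequences
#'
#' Fast counting path used by the permutation null; agrees with
#' [scan_g4()] / [scan_g_runs()] hit counts by construction.
#'
#' @param seqs character vector of sequences.
#' @param kind `"g4"` (blocks of >= 4 runs) or `"g_runs"` (all blocks).
#' @param strand_mode `"both"` or `"plus"`.
#' @return integer total count over all sequences.
#' @export
count_hits <- function(seqs, kind = c("g4", "g_runs"),
                       strand_mode = c("both", "plus")) {
  kind <- match.arg(kind)
  strand_mode <- match.arg(strand_mode)
  min_runs <- if (kind == "g4") 4L else 1L
  sum(vapply(toupper(seqs), count_g4_cpp, integer(1),
             both_strands = strand_mode == "both", min_runs = min_runs,
             USE.NAMES = FALSE))
}
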