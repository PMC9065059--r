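#' Dinucleotide-preserving sequence shuffle
#'
#' Exact Altschul-Erickson shuffle: a uniform random Eulerian path through
#' the dinucleotide transition multigraph.  The output has exactly the
#' same dinucleotide count multiset as the input, the same first (and
#' hence last) character, and the same length.  Sequences shorter than 2
#' characters are returned unchanged.
#'
#' @param seqs character vector of sequences.
#' @param seed optional RNG seed for reproducibility.
#' @return character vector of shuffled sequences.
#' @export
dinuc_shuffle <- function(seqs, seed = NULL) {
  with_seed(seed, vapply(seqs, dinuc_shuffle_cpp, character(1),
                         USE.NAMES = FALSE))
}

#' Dinucleotide counts of a sequence
#' @param seq a nucleotide string.
#' @return named integer vector of 2-mer counts.
#' @export
dinuc_counts <- function(seq) {
  v <- strsplit(seq, "", fixed = TRUE)[[1]]
  if (length(v) < 2) return(integer(0))
  tab <- table(paste0(v[-length(v)], v[-1]))
  setNames(as.integer(tab), names(tab))
}

#' Permutation-corrected motif enrichment in splice-site windows
#'
#' Each permutation independently applies the dinucleotide-preserving
#' shuffle to every window and recounts motifs, so no motif can span a
#' window boundary.  The corrected fold is the observed count over the
#' median permuted count; the one-sided empirical p uses the add-one
#' estimator (1 + #\{perm >= obs\}) / (N + 1), with the raw exceedance
#' fraction also reported.
#'
#' @param windows character vector of window sequences.
#' @param kind `"g4"` or `"g_runs"`.
#' @param n_perm number of permutations N (default 1000).
#' @param seed master RNG seed.
#' @param strand_mode `"both"` (default) or `"plus"`.
#' @return object of class `perm_result`: observed, perm_counts, fold,
#'   p (add-one), p_raw, n_perm, seed.
#' @export
corrected_enrichment <- function(windows, kind = c("g4", "g_runs"),
                                 n_perm = 1000, seed = NULL,
                                 strand_mode = c("both", "plus")) {
  kind <- match.arg(kind)
  strand_mode <- match.arg(strand_mode)
  if (length(windows) == 0) stop_ctx("no windows")
  windows <- toupper(windows)
  observed <- count_hits(windows, kind, strand_mode)
  min_runs <- if (kind == "g4") 4L else 1L
  perm <- with_seed(seed,
    permute_counts_cpp(windows, n_perm,
                       both_strands = strand_mode == "both",
                       min_runs = min_runs))
  med <- median(perm)
  fold <- if (med > 0) observed / med else NA_real_
  exceed <- sum(perm >= observed)
  structure(list(observed = observed, perm_counts = perm, fold = fold,
                 p = (1 + exceed) / (n_perm + 1), p_raw = exceed / n_perm,
                 n_perm = n_perm, seed = seed),
            class = "perm_result")
}

#' @export
print.perm_result <- function(x, ...) {
  cat("permutation test: observed =", x$observed,
      "median permuted =", median(x$perm_counts),
      sprintf("fold = %.3f", x$fold),
      sprintf("p = %.4g (raw %.4g), N = %d", x$p, x$p_raw, x$n_perm), "\n")
  invisible(x)
}

#' Extract splice-site window sequences from a genome
#'
#' Plus-strand sequences of the (junction - flank, junction + flank)
#' windows, clipped at chromosome ends.  Strand orientation does not
#' matter to the permutation null (the motif count is strand-symmetric).
#'
#' @param sites splice-site data.frame.
#' @param genome a `genome_seq`.
#' @param flank half-width in nt (default 100).
#' @param side `"both"`, `"intronic"` or `"exonic"`.
#' @return character vector of window sequences.
#' @export
site_window_seqs <- function(sites, genome, flank = 100,
                             side = c("both", "intronic", "exonic")) {
  side <- match.arg(side)
  g <- unclass(genome)
  len <- chrom_lengths(genome)
  if (side == "both") {
    ws <- pmax(sites$junction - flank, 0L)
    we <- pmin(sites$junction + flank, unname(len[sites$chrom]))
  } else {
    w <- site_windows(sites, flank, chrom_len = len)
    if (side == "intronic") {
      ws <- w$intronic_start; we <- w$intronic_end
    } else {
      ws <- w$exonic_start; we <- w$exonic_end
    }
  }
  substring(g[sites$chrom], ws + 1L, we)
}
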