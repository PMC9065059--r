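#' Positional frequency matrices for splice-site scoring
#'
#' Matrices are stored as TSV with a header row `A C G T`, one row per
#' position, and a metadata line `#junction_offset=K` where K is the
#' number of matrix columns on the transcription-upstream side of the
#' junction (so matrix position K+1 is the first base after the junction:
#' the first intronic base for a donor matrix, the first exonic base for
#' an acceptor matrix).  Default widths follow the SpliceRack / MaxEnt
#' convention: donor 9-mer (3 exonic + 6 intronic, K = 3), acceptor 23-mer
#' (20 intronic + 3 exonic, K = 20).
#'
#' @name splice_strength
NULL

#' Read a positional frequency matrix
#'
#' @param path matrix TSV (see [splice_strength]).
#' @return list with `freq` (positions x 4 matrix, columns A,C,G,T) and
#'   `junction_offset`, class `pfm`.
#' @export
read_pfm <- function(path) {
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  off <- sub("^#junction_offset=", "", grep("^#junction_offset=", meta,
                                            value = TRUE))
  if (length(off) != 1) stop_ctx("missing #junction_offset metadata",
                                 ctx = path)
  tab <- read.table(text = lines[!grepl("^#", lines)], header = TRUE,
                    sep = "\t")
  as_pfm(as.matrix(tab[, BASES]), as.integer(off))
}

#' Construct a PFM object
#' @param freq positions x 4 numeric matrix (columns A, C, G, T).
#' @param junction_offset columns upstream of the junction.
#' @return a `pfm` object.
#' @export
as_pfm <- function(freq, junction_offset) {
  colnames(freq) <- BASES
  if (any(freq < 0)) stop_ctx("negative PFM frequency")
  if (any(abs(rowSums(freq) - 1) > 1e-6))
    stop_ctx("PFM column sums must be 1 (row ",
             which(abs(rowSums(freq) - 1) > 1e-6)[1], ")")
  structure(list(freq = freq, junction_offset = as.integer(junction_offset)),
            class = "pfm")
}

#' Write a PFM to TSV
#' @param pfm a `pfm` object.
#' @param path output file.
#' @export
write_pfm <- function(pfm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#junction_offset=", pfm$junction_offset), con)
  write.table(as.data.frame(pfm$freq), con, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Log-odds score of a window against a PFM
#'
#' score = sum_i log2((f(b_i, i) + eps) / 0.25) against a uniform
#' background; higher is stronger.  Windows containing N score NA.
#'
#' @param window nucleotide string, length equal to the matrix width,
#'   extracted on the gene strand and aligned by the junction offset.
#' @param pfm a `pfm` object.
#' @param pseudocount added to each frequency (default 1e-3).
#' @return numeric score in bits (NA for windows with N).
#' @export
score_window <- function(window, pfm, pseudocount = 1e-3) {
  w <- nrow(pfm$freq)
  vapply(toupper(window), function(s) {
    if (nchar(s) != w) stop_ctx("window length ", nchar(s),
                                " != matrix width ", w)
    b <- strsplit(s, "", fixed = TRUE)[[1]]
    if (any(!b %in% BASES)) return(NA_real_)
    f <- pfm$freq[cbind(seq_len(w), match(b, BASES))]
    sum(log2((f + pseudocount) / 0.25))
  }, numeric(1), USE.NAMES = FALSE)
}

# gene-strand window of pfm width aligned to the junction:
# transcription offsets [-K, width-K) relative to the junction
site_pfm_window <- function(sites, genome, pfm) {
  w <- nrow(pfm$freq)
  k <- pfm$junction_offset
  j <- sites$junction
  plus <- sites$strand == "+"
  gs <- ifelse(plus, j - k, j - w + k)
  ge <- gs + w
  g <- unclass(genome)
  raw <- substring(g[sites$chrom], gs + 1L, ge)
  bad <- nchar(raw) != w
  raw[bad] <- NA
  out <- raw
  out[!plus & !is.na(out)] <- revcomp(out[!plus & !is.na(out)])
  out
}

#' Score splice sites from donor and acceptor matrices
#'
#' Extracts the gene-strand window around each junction, scores it with the
#' matching matrix, and drops (with a warning) sites whose window contains
#' N or runs off the chromosome.
#'
#' @param sites splice-site data.frame.
#' @param genome a `genome_seq`.
#' @param donor_pfm,acceptor_pfm `pfm` objects.
#' @param pseudocount log-odds pseudocount.
#' @return sites with a `score` column; undefined-score sites removed.
#' @export
score_splice_sites <- function(sites, genome, donor_pfm, acceptor_pfm,
                               pseudocount = 1e-3) {
  score <- rep(NA_real_, nrow(sites))
  for (kind in c("donor", "acceptor")) {
    pfm <- if (kind == "donor") donor_pfm else acceptor_pfm
    sel <- sites$kind == kind
    if (!any(sel)) next
    win <- site_pfm_window(sites[sel, ], genome, pfm)
    ok <- !is.na(win)
    score[sel][ok] <- score_window(win[ok], pfm, pseudocount)
  }
  drop <- is.na(score)
  if (any(drop))
    warning(sum(drop), " site(s) dropped: window undefined (N or out of range)")
  out <- sites[!drop, ]
  out$score <- score[!drop]
  out
}

#' Quantile bins for splice-strength scores
#'
#' Near-equal occupancy bins; bin 1 is the weakest.  Ties are assigned to
#' the lower bin, so binning is invariant to adding a constant to all
#' scores.
#'
#' @param scores numeric vector.
#' @param n_bins number of bins (4 for quartiles, 10 for deciles).
#' @return integer vector of bins in 1..n_bins.
#' @export
assign_quantiles <- function(scores, n_bins = 4) {
  n <- length(scores)
  if (n < n_bins) stop_ctx("fewer scores (", n, ") than bins (", n_bins, ")")
  sizes <- diff(round(seq(0, n, length.out = n_bins + 1)))
  pos_bin <- rep(seq_len(n_bins), sizes)
  r <- rank(scores, ties.method = "min")
  bins <- pos_bin[r]
  if (length(unique(scores)) == 1)
    warning("all scores equal; every site in bin 1")
  as.integer(bins)
}

#' Synthetic GT-AG frequency matrices
#'
#' Documented synthetic consensus matrices used as package fixtures for
#' testing and for the synthetic pipeline: a 9-mer donor (consensus
#' mAGGTaAGT, GT near-invariant) and a 23-mer acceptor (pyrimidine tract,
#' near-invariant AG, consensus exonic G).  These are illustrative
#' matrices, not empirical splice-site frequencies.
#'
#' @param kind `"donor"` or `"acceptor"`.
#' @return a `pfm` object.
#' @export
synthetic_pfm <- function(kind = c("donor", "acceptor")) {
  kind <- match.arg(kind)
  row4 <- function(a, c, g, t) c(A = a, C = c, G = g, T = t)
  if (kind == "donor") {
    freq <- rbind(
      row4(.33, .36, .18, .13),  # exonic -3
      row4(.60, .13, .14, .13),  # exonic -2 (A)
      row4(.09, .05, .78, .08),  # exonic -1 (G)
      row4(.001, .001, .997, .001),  # intron +1 G
      row4(.001, .001, .001, .997),  # intron +2 T
      row4(.60, .05, .28, .07),  # +3 A/G
      row4(.70, .08, .10, .12),  # +4 A
      row4(.08, .06, .80, .06),  # +5 G
      row4(.17, .16, .19, .48))  # +6 T
    return(as_pfm(freq, 3L))
  }
  tract <- row4(.10, .32, .10, .48)          # pyrimidine tract
  freq <- rbind(
    do.call(rbind, rep(list(tract), 16)),    # intron -20..-5
    row4(.25, .30, .21, .24),                # -4
    row4(.06, .65, .01, .28),                # -3 C
    row4(.997, .001, .001, .001),            # -2 A
    row4(.001, .001, .997, .001),            # -1 G
    row4(.28, .14, .49, .09),                # exonic +1 G
    row4(.25, .25, .25, .25),                # exonic +2
    row4(.25, .25, .25, .25))                # exonic +3
  as_pfm(freq, 20L)
}
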