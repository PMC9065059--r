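#' Splice-site anchors from gene models
#'
#' Internal exons (all exons of a transcript except the first and last in
#' transcription order) contribute one acceptor (3'ss) and one donor (5'ss)
#' each.  The junction coordinate is the 0-based position of the boundary
#' between the last intronic and first exonic base (acceptor) or the last
#' exonic and first intronic base (donor), in transcription order.  When a
#' genome is attached, a site is canonical iff its intron begins GT and
#' ends AG on the gene strand; non-canonical sites are dropped by default.
#'
#' @param models a `gene_models` data.frame (see [read_gene_models()]).
#' @param genome optional `genome_seq` for the GT-AG check.
#' @param keep_noncanonical keep non-canonical sites (flagged) instead of
#'   dropping them.
#' @param collapse_duplicates collapse sites shared by several transcripts
#'   to one record keyed by (chrom, junction, kind, strand).
#' @param include_terminal also emit the single internal junction of the
#'   first (donor) and last (acceptor) exon of each transcript; used by the
#'   exon-position-group analysis, off for the default internal-exon set.
#' @return data.frame of splice sites with columns site_id, kind
#'   ("acceptor" / "donor"), chrom, junction, strand, gene_id,
#'   transcript_id, exon_start, exon_end, exon_length, intron_start,
#'   intron_end, intron_length, canonical, is_microexon, exon_group.
#' @export
extract_internal_splice_sites <- function(models, genome = NULL,
                                          keep_noncanonical = FALSE,
                                          collapse_duplicates = TRUE,
                                          include_terminal = FALSE) {
  sp <- split(seq_len(nrow(models)), models$transcript_id)
  res <- lapply(sp, function(idx) {
    m <- models[idx, ]
    m <- m[order(m$start), ]
    n <- nrow(m)
    if (n < 2) return(NULL)
    if (any(m$start[-1] < m$end[-n])) stop_ctx("overlapping exons in ",
                                               m$transcript_id[1])
    if (n < 3 && !include_terminal) return(NULL)
    internal <- if (n >= 3) 2:(n - 1) else integer(0)
    strand <- m$strand[1]
    build <- function(i, kind) {
      if (strand == "+") {
        junction <- if (kind == "acceptor") m$start[i] else m$end[i]
        if (kind == "acceptor") {
          is <- m$end[i - 1]; ie <- m$start[i]
        } else {
          is <- m$end[i]; ie <- m$start[i + 1]
        }
      } else {
        junction <- if (kind == "acceptor") m$end[i] else m$start[i]
        if (kind == "acceptor") {
          is <- m$end[i]; ie <- m$start[i + 1]
        } else {
          is <- m$end[i - 1]; ie <- m$start[i]
        }
      }
      data.frame(kind = kind, chrom = m$chrom[1], junction = junction,
                 strand = strand, gene_id = m$gene_id[1],
                 transcript_id = m$transcript_id[1],
                 exon_start = m$start[i], exon_end = m$end[i],
                 exon_length = m$end[i] - m$start[i],
                 intron_start = is, intron_end = ie,
                 intron_length = ie - is, stringsAsFactors = FALSE)
    }
    acc_i <- internal
    don_i <- internal
    if (include_terminal) {
      # transcription-first exon has a donor, transcription-last an acceptor
      don_i <- sort(unique(c(don_i, if (strand == "+") 1L else n)))
      acc_i <- sort(unique(c(acc_i, if (strand == "+") n else 1L)))
    }
    do.call(rbind, c(lapply(acc_i, build, kind = "acceptor"),
                     lapply(don_i, build, kind = "donor")))
  })
  sites <- do.call(rbind, res)
  if (is.null(sites) || nrow(sites) == 0) {
    sites <- data.frame(kind = character(), chrom = character(),
                        junction = integer(), strand = character(),
                        gene_id = character(), transcript_id = character(),
                        exon_start = integer(), exon_end = integer(),
                        exon_length = integer(), intron_start = integer(),
                        intron_end = integer(), intron_length = integer(),
                        stringsAsFactors = FALSE)
  }
  sites$canonical <- if (is.null(genome)) rep(NA, nrow(sites)) else
    intron_is_canonical(genome, sites$chrom, sites$intron_start,
                        sites$intron_end, sites$strand)
  if (!is.null(genome) && !keep_noncanonical)
    sites <- sites[sites$canonical, ]
  sites$is_microexon <- sites$exon_length < 30L
  sites$exon_group <- rep("none", nrow(sites))
  if (collapse_duplicates) {
    key <- paste(sites$chrom, sites$junction, sites$kind, sites$strand)
    sites <- sites[!duplicated(key), ]
  }
  sites <- sites[order(sites$chrom, sites$junction, sites$kind), ]
  sites$site_id <- if (nrow(sites) == 0) character(0) else
    paste0(sites$chrom, ":", sites$junction, ":",
           substr(sites$kind, 1, 1), sites$strand)
  rownames(sites) <- NULL
  sites[, c("site_id", setdiff(names(sites), "site_id"))]
}

#' GT-AG check for introns on the gene strand
#'
#' @param genome a `genome_seq`.
#' @param chrom,start,end intron coordinates (0-based half-open).
#' @param strand gene strand.
#' @return logical vector.
#' @export
intron_is_canonical <- function(genome, chrom, start, end, strand) {
  g <- unclass(genome)
  first2 <- substring(g[chrom], start + 1L, start + 2L)
  last2 <- substring(g[chrom], end - 1L, end)
  ifelse(strand == "+", first2 == "GT" & last2 == "AG",
         last2 == "AC" & first2 == "CT")
}

#' Template / non-template strand context of a motif at a site
#'
#' A motif is on the non-template (coding, mRNA-like) strand iff its strand
#' equals the gene's transcription strand; such G4 motifs appear in the
#' transcript as RNA G4s.
#'
#' @param hit_strand,gene_strand strand vectors ("+" / "-").
#' @param hit_chrom,site_chrom optional chromosome vectors; a mismatch is
#'   an error.
#' @return character vector, "non_template" or "template".
#' @export
classify_strand_context <- function(hit_strand, gene_strand,
                                    hit_chrom = NULL, site_chrom = NULL) {
  if (!is.null(hit_chrom) && !is.null(site_chrom) &&
      any(hit_chrom != site_chrom))
    stop_ctx("hit and site on different chromosomes")
  ifelse(hit_strand == gene_strand, "non_template", "template")
}

#' Position-in-gene groups for exons
#'
#' For the longest transcript (largest summed exon length, ties by
#' transcript id) of each gene with nine or more exons, exons are labelled
#' first1..first4, middle, last4..last1 in transcription order.  Sites of
#' other transcripts/genes keep group "none".
#'
#' @param sites splice-site data.frame.
#' @param models the `gene_models` the sites came from.
#' @return sites with the `exon_group` column filled in.
#' @export
assign_exon_position_groups <- function(sites, models) {
  exlen <- tapply(models$end - models$start, models$transcript_id, sum)
  tx2gene <- tapply(models$gene_id, models$transcript_id, function(g) g[1])
  ord <- order(-exlen, names(exlen))
  longest <- names(exlen)[ord][!duplicated(tx2gene[names(exlen)[ord]])]
  sites$exon_group <- "none"
  for (tx in longest) {
    m <- models[models$transcript_id == tx, ]
    m <- m[order(m$start), ]
    n <- nrow(m)
    if (n < 9) next
    idx <- seq_len(n)
    tx_order <- if (m$strand[1] == "+") idx else rev(idx)
    group <- character(n)
    group[tx_order <= 4] <- paste0("first", tx_order[tx_order <= 4])
    group[tx_order > n - 4] <- paste0("last", n - tx_order[tx_order > n - 4] + 1)
    group[group == ""] <- "middle"
    hit <- sites$transcript_id == tx
    key <- paste(m$start, m$end)
    match_i <- match(paste(sites$exon_start[hit], sites$exon_end[hit]), key)
    sites$exon_group[hit][!is.na(match_i)] <- group[match_i[!is.na(match_i)]]
  }
  sites
}

#' Intronic and exonic windows around splice sites
#'
#' Windows are not trimmed at neighbouring features; they are clipped only
#' at chromosome ends when lengths are supplied.  Offsets are signed in
#' transcription direction (negative = upstream of the junction).
#'
#' @param sites splice-site data.frame.
#' @param flank window width in nt (>= 1).
#' @param chrom_len optional named vector of chromosome lengths for
#'   clipping.
#' @return data.frame per site with intronic_start/end and exonic_start/end
#'   genomic intervals plus the full window win_start/win_end.
#' @export
site_windows <- function(sites, flank, chrom_len = NULL) {
  stopifnot(flank >= 1)
  j <- sites$junction
  plus <- sites$strand == "+"
  upstream_is_intron <- (sites$kind == "acceptor")
  # genomic interval upstream (transcription) of the junction
  up_s <- ifelse(plus, j - flank, j)
  up_e <- ifelse(plus, j, j + flank)
  dn_s <- ifelse(plus, j, j - flank)
  dn_e <- ifelse(plus, j + flank, j)
  out <- data.frame(
    site_id = sites$site_id, chrom = sites$chrom, strand = sites$strand,
    kind = sites$kind, junction = j,
    intronic_start = ifelse(upstream_is_intron, up_s, dn_s),
    intronic_end = ifelse(upstream_is_intron, up_e, dn_e),
    exonic_start = ifelse(upstream_is_intron, dn_s, up_s),
    exonic_end = ifelse(upstream_is_intron, dn_e, up_e),
    win_start = j - flank, win_end = j + flank,
    stringsAsFactors = FALSE)
  clip <- function(v, ch, upper) {
    if (is.null(chrom_len)) return(pmax(v, 0L))
    pmin(pmax(v, 0L), unname(chrom_len[ch]))
  }
  for (col in c("intronic_start", "intronic_end", "exonic_start",
                "exonic_end", "win_start", "win_end"))
    out[[col]] <- clip(out[[col]], out$chrom)
  out
}

#' Write splice sites as extended BED
#'
#' BED6 plus kind, intron length, exon length, canonical and group columns.
#'
#' @param sites splice-site data.frame.
#' @param path output file.
#' @export
write_sites_bed <- function(sites, path) {
  out <- data.frame(sites$chrom, sites$junction, sites$junction + 1L,
                    sites$site_id, 0, sites$strand, sites$kind,
                    sites$intron_length, sites$exon_length,
                    sites$canonical, sites$exon_group)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
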