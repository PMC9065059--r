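#' Construct a genome object from named sequences
#'
#' A genome is a named character vector of chromosome sequences over the
#' A/C/G/T/N alphabet, upper-cased on construction.  Names must be unique
#' and sequences non-empty.
#'
#' @param x named character vector of nucleotide sequences.
#' @param ctx optional context string used in error messages.
#' @return an object of class `genome_seq`.
#' @export
as_genome <- function(x, ctx = NULL) {
  if (!is.character(x)) stop_ctx("genome sequences must be character", ctx = ctx)
  nm <- names(x)
  if (is.null(nm) || any(!nzchar(nm)))
    stop_ctx("every chromosome needs a non-empty name", ctx = ctx)
  if (anyDuplicated(nm))
    stop_ctx("duplicated chromosome name: ", nm[duplicated(nm)][1], ctx = ctx)
  if (any(!nzchar(x))) {
    stop_ctx("empty sequence for chromosome '", nm[!nzchar(x)][1], "'", ctx = ctx)
  }
  x <- toupper(x)
  bad <- grepl("[^ACGTN]", x)
  if (any(bad)) {
    i <- which(bad)[1]
    ch <- regmatches(x[i], regexpr("[^ACGTN]", x[i]))
    stop_ctx("disallowed character '", ch, "' in chromosome '", nm[i], "'",
             ctx = ctx)
  }
  structure(x, class = "genome_seq")
}

#' Chromosome lengths of a genome
#' @param genome a `genome_seq` object.
#' @return named integer vector.
#' @export
chrom_lengths <- function(genome) {
  setNames(nchar(unclass(genome)), names(genome))
}

#' @export
print.genome_seq <- function(x, ...) {
  cat("genome_seq with", length(x), "chromosome(s):\n")
  len <- chrom_lengths(x)
  for (i in seq_along(len)) cat(" ", names(len)[i], len[i], "bp\n")
  invisible(x)
}

#' Read a multi-record FASTA file
#'
#' Record names are taken from the header up to the first whitespace.
#' Sequences are upper-cased; characters outside A/C/G/T/N are an error.
#'
#' @param path FASTA file.
#' @return a `genome_seq` object.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop_ctx("no such file: ", path)
  ss <- tryCatch(Biostrings::readBStringSet(path),
                 error = function(e) stop_ctx("malformed FASTA: ",
                                              conditionMessage(e), ctx = path))
  if (length(ss) == 0) stop_ctx("no FASTA records", ctx = path)
  x <- as.character(ss)
  names(x) <- sub("\\s.*$", "", names(ss))
  as_genome(x, ctx = path)
}

#' Write a genome to FASTA
#' @param genome a `genome_seq` object.
#' @param path output file.
#' @export
write_fasta <- function(genome, path) {
  ss <- Biostrings::BStringSet(unclass(genome))
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}

new_intervals <- function(chrom, start, end, strand = ".", label = "",
                          score = NA_real_) {
  data.frame(chrom = as.character(chrom), start = as.integer(start),
             end = as.integer(end), strand = as.character(strand),
             label = as.character(label), score = as.numeric(score),
             stringsAsFactors = FALSE)
}

int_or_fail <- function(x, what, path) {
  suppressWarnings(v <- as.integer(x))
  bad <- which(is.na(v) & !is.na(x))
  if (length(bad))
    stop_ctx("non-integer ", what, " at line ", bad[1], ": '", x[bad[1]], "'",
             ctx = path)
  v
}

#' Read genomic intervals from BED-like files
#'
#' All coordinates are 0-based half-open, as in BED.  Strand is `"."` when
#' the format does not carry one.  Input order is preserved.
#'
#' @param path file to read.
#' @param format one of `"bed3"`, `"bed6"`, `"bedgraph"`, `"tsv_spec"`.
#' @param col_map for `tsv_spec`: named integer vector mapping any of
#'   `chrom`, `start`, `end`, `strand`, `label`, `score` to column indices
#'   (`chrom`, `start`, `end` required).
#' @param header whether a `tsv_spec` file has a header row.
#' @return a data.frame with columns chrom, start, end, strand, label, score.
#' @export
read_intervals <- function(path, format = c("bed3", "bed6", "bedgraph",
                                            "tsv_spec"),
                           col_map = NULL, header = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_ctx("no such file: ", path)
  tab <- read.table(path, sep = "\t", header = header && format == "tsv_spec",
                    colClasses = "character", quote = "", comment.char = "",
                    stringsAsFactors = FALSE)
  need <- switch(format, bed3 = 3L, bed6 = 6L, bedgraph = 4L, tsv_spec = NA)
  if (!is.na(need) && ncol(tab) < need)
    stop_ctx(format, " needs >= ", need, " columns, found ", ncol(tab),
             ctx = path)
  if (format == "tsv_spec") {
    if (is.null(col_map) || !all(c("chrom", "start", "end") %in% names(col_map)))
      stop_ctx("tsv_spec requires col_map with chrom, start, end", ctx = path)
    pick <- function(f, default) {
      if (f %in% names(col_map)) tab[[col_map[[f]]]] else default
    }
    out <- new_intervals(pick("chrom", NA), 0L, 0L,
                         pick("strand", "."), pick("label", ""),
                         suppressWarnings(as.numeric(pick("score", NA))))
    out$start <- int_or_fail(pick("start", NA), "start", path)
    out$end <- int_or_fail(pick("end", NA), "end", path)
  } else {
    out <- new_intervals(tab[[1]],
                         int_or_fail(tab[[2]], "start", path),
                         int_or_fail(tab[[3]], "end", path))
    if (format == "bed6") {
      if (!all(tab[[6]] %in% c("+", "-", ".")))
        stop_ctx("invalid strand at line ",
                 which(!tab[[6]] %in% c("+", "-", "."))[1], ctx = path)
      out$label <- tab[[4]]
      out$score <- suppressWarnings(as.numeric(tab[[5]]))
      out$strand <- tab[[6]]
    } else if (format == "bedgraph") {
      sc <- suppressWarnings(as.numeric(tab[[4]]))
      if (anyNA(sc))
        stop_ctx("non-numeric bedGraph value at line ", which(is.na(sc))[1],
                 ctx = path)
      out$score <- sc
    }
  }
  bad <- which(out$start >= out$end)
  if (length(bad))
    stop_ctx("start >= end at line ", bad[1], " (", out$start[bad[1]], " >= ",
             out$end[bad[1]], ")", ctx = path)
  if (any(out$start < 0)) stop_ctx("negative coordinate", ctx = path)
  out
}

#' Write intervals as BED
#'
#' @param x interval data.frame (chrom, start, end, strand, label, score).
#' @param path output file.
#' @param format `"bed6"`, `"bed3"` or `"bedgraph"`.
#' @export
write_intervals <- function(x, path, format = c("bed6", "bed3", "bedgraph")) {
  format <- match.arg(format)
  out <- switch(format,
    bed3 = x[, c("chrom", "start", "end")],
    bed6 = data.frame(x$chrom, x$start, x$end,
                      ifelse(nzchar(x$label %||% ""), x$label, "."),
                      ifelse(is.na(x$score), 0, x$score), x$strand),
    bedgraph = data.frame(x$chrom, x$start, x$end, x$score))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Validate intervals against a genome
#'
#' Checks chromosome names and that 0 <= start < end <= chromosome length.
#' Name mismatches between annotation and genome are an error, never
#' silently reconciled; see [normalize_chrom_names()].
#'
#' @param x interval data.frame.
#' @param genome a `genome_seq`.
#' @return x, invisibly.
#' @export
validate_intervals <- function(x, genome) {
  len <- chrom_lengths(genome)
  unknown <- setdiff(unique(x$chrom), names(len))
  if (length(unknown))
    stop_ctx("chromosome '", unknown[1], "' absent from genome ",
             "(names are not silently reconciled; see normalize_chrom_names)")
  over <- which(x$end > len[x$chrom])
  if (length(over))
    stop_ctx("interval beyond chromosome end at row ", over[1])
  invisible(x)
}

#' Strip or add a "chr" prefix on chromosome names
#'
#' Explicit opt-in normaliser for FASTA/annotation naming mismatches
#' ("chr1" vs "1").
#'
#' @param x character vector of chromosome names.
#' @param style `"strip"` removes a leading "chr", `"add"` prepends it.
#' @return character vector.
#' @export
normalize_chrom_names <- function(x, style = c("strip", "add")) {
  style <- match.arg(style)
  if (style == "strip") sub("^chr", "", x) else
    ifelse(grepl("^chr", x), x, paste0("chr", x))
}

#' Read gene models from BED12 or GTF
#'
#' Returns one row per exon with exons sorted by genomic coordinate within
#' each transcript.  GTF (1-based closed) is converted to the internal
#' 0-based half-open convention at this boundary.
#'
#' @param path annotation file.
#' @param format `"bed12"` or `"gtf"`.
#' @return a data.frame with columns gene_id, transcript_id, chrom, strand,
#'   start, end (class `gene_models`).
#' @export
read_gene_models <- function(path, format = c("bed12", "gtf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_ctx("no such file: ", path)
  if (format == "bed12") {
    tab <- read.table(path, sep = "\t", header = FALSE,
                      colClasses = "character", quote = "",
                      comment.char = "", stringsAsFactors = FALSE)
    if (ncol(tab) < 12) stop_ctx("BED12 needs 12 columns", ctx = path)
    n <- nrow(tab)
    rows <- vector("list", n)
    for (i in seq_len(n)) {
      strand <- tab[i, 6]
      if (!strand %in% c("+", "-"))
        stop_ctx("unknown strand '", strand, "' at line ", i, ctx = path)
      cs <- as.integer(tab[i, 2])
      bc <- as.integer(tab[i, 10])
      sizes <- as.integer(strsplit(sub(",$", "", tab[i, 11]), ",")[[1]])
      starts <- as.integer(strsplit(sub(",$", "", tab[i, 12]), ",")[[1]])
      if (length(sizes) != bc || length(starts) != bc)
        stop_ctx("blockCount ", bc, " does not match ", length(sizes),
                 " sizes / ", length(starts), " starts at line ", i, ctx = path)
      es <- cs + starts
      ee <- es + sizes
      o <- order(es)
      es <- es[o]; ee <- ee[o]
      if (bc > 1 && any(es[-1] < ee[-bc]))
        stop_ctx("overlapping blocks within transcript at line ", i, ctx = path)
      rows[[i]] <- data.frame(gene_id = tab[i, 4], transcript_id = tab[i, 4],
                              chrom = tab[i, 1], strand = strand,
                              start = es, end = ee, stringsAsFactors = FALSE)
    }
    models <- do.call(rbind, rows)
  } else {
    gr <- rtracklayer::import(path, format = "gtf")
    gr <- gr[gr$type == "exon"]
    if (length(gr) == 0) stop_ctx("no exon features in GTF", ctx = path)
    if (is.null(gr$transcript_id)) stop_ctx("GTF exons lack transcript_id",
                                            ctx = path)
    models <- data.frame(
      gene_id = as.character(gr$gene_id %||% gr$transcript_id),
      transcript_id = as.character(gr$transcript_id),
      chrom = as.character(GenomicRanges::seqnames(gr)),
      strand = as.character(GenomicRanges::strand(gr)),
      start = GenomicRanges::start(gr) - 1L,   # to 0-based half-open
      end = GenomicRanges::end(gr),
      stringsAsFactors = FALSE)
    if (any(!models$strand %in% c("+", "-")))
      stop_ctx("unknown strand in GTF exon", ctx = path)
    models <- models[order(models$transcript_id, models$start), ]
    rownames(models) <- NULL
  }
  class(models) <- c("gene_models", "data.frame")
  models
}

#' Build gene models from an exon table
#'
#' @param exons data.frame with gene_id, transcript_id, chrom, strand,
#'   start, end (0-based half-open exon intervals).
#' @return a `gene_models` data.frame sorted by transcript and coordinate.
#' @export
as_gene_models <- function(exons) {
  need <- c("gene_id", "transcript_id", "chrom", "strand", "start", "end")
  if (!all(need %in% names(exons))) stop_ctx("missing gene model columns")
  exons <- exons[order(exons$transcript_id, exons$start), need]
  rownames(exons) <- NULL
  class(exons) <- c("gene_models", "data.frame")
  exons
}

#' Write gene models as BED12 (one line per transcript)
#' @param models a `gene_models` data.frame.
#' @param path output file.
#' @export
write_gene_models_bed12 <- function(models, path) {
  sp <- split(models, models$transcript_id)
  lines <- vapply(sp, function(m) {
    m <- m[order(m$start), ]
    cs <- min(m$start); ce <- max(m$end)
    paste(m$chrom[1], cs, ce, m$transcript_id[1], 0, m$strand[1], cs, ce,
          "0,0,0", nrow(m),
          paste0(paste(m$end - m$start, collapse = ","), ","),
          paste0(paste(m$start - cs, collapse = ","), ","),
          sep = "\t")
  }, character(1))
  writeLines(unname(lines), path)
  invisible(path)
}

#' Read point variants from TSV
#'
#' Expected columns (with header): chrom, pos (0-based), class.
#'
#' @param path TSV file.
#' @return data.frame with chrom, pos, class.
#' @export
read_variants <- function(path) {
  tab <- read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
  if (!all(c("chrom", "pos") %in% names(tab)))
    stop_ctx("variant TSV needs chrom and pos columns", ctx = path)
  tab$pos <- int_or_fail(as.character(tab$pos), "pos", path)
  if (is.null(tab$class)) tab$class <- "variant"
  tab
}
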