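# shared helpers: random sequences, brute-force scanner oracle, tiny genomes

rand_seq <- function(n, probs = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  paste(sample(names(probs), n, replace = TRUE, prob = probs), collapse = "")
}

# G-rich composition so consensus motifs actually occur in random draws
grich <- c(A = 0.18, C = 0.26, G = 0.38, T = 0.18)

# maximal runs (>= 3) of `base`, 0-based half-open
oracle_runs <- function(seq, base) {
  m <- gregexpr(paste0(base, "{3,}"), seq)[[1]]
  if (m[1] == -1) return(data.frame(start = integer(), end = integer()))
  data.frame(start = as.integer(m) - 1L,
             end = as.integer(m) - 1L + attr(m, "match.length"))
}

# exhaustive candidate enumeration + leftmost-longest non-overlap selection
oracle_scan <- function(seq, base, min_runs) {
  r <- oracle_runs(seq, base)
  n <- nrow(r)
  empty <- data.frame(start = integer(), end = integer(), k = integer())
  if (n == 0) return(empty)
  cand <- list()
  for (i in seq_len(n)) {
    j <- i
    while (j < n) {
      gap <- r$start[j + 1] - r$end[j]
      if (gap >= 1 && gap <= 7) j <- j + 1 else break
    }
    for (j2 in i:j)
      if (j2 - i + 1L >= min_runs)
        cand[[length(cand) + 1]] <- c(r$start[i], r$end[j2], j2 - i + 1L)
  }
  if (length(cand) == 0) return(empty)
  cd <- do.call(rbind, cand)
  cd <- cd[order(cd[, 1], -cd[, 2]), , drop = FALSE]
  out <- list()
  cursor <- -1L
  for (row in seq_len(nrow(cd))) {
    if (cd[row, 1] < cursor) next
    out[[length(out) + 1]] <- cd[row, ]
    cursor <- cd[row, 2]
  }
  m <- do.call(rbind, out)
  data.frame(start = as.integer(m[, 1]), end = as.integer(m[, 2]),
             k = as.integer(m[, 3]))
}

expect_matches_oracle <- function(seq, kind = "g4") {
  min_runs <- if (kind == "g4") 4L else 1L
  f <- if (kind == "g4") scan_g4 else scan_g_runs
  got <- f(seq, "s", "both")
  for (st in c("+", "-")) {
    base <- if (st == "+") "G" else "C"
    ora <- oracle_scan(seq, base, min_runs)
    g <- got[got$strand == st, ]
    expect_equal(g$start, ora$start, info = paste(kind, st, seq))
    expect_equal(g$end, ora$end, info = paste(kind, st, seq))
    expect_equal(g$n_g_runs, pmin(ora$k, 6L), info = paste(kind, st, seq))
  }
  invisible(got)
}

# three-exon plus/minus toy genome with canonical introns
toy_models <- function(strand = "+") {
  as_gene_models(data.frame(
    gene_id = "g1", transcript_id = "g1.t1", chrom = "c1", strand = strand,
    start = c(0L, 20L, 40L), end = c(10L, 30L, 50L)))
}

toy_genome <- function(strand = "+") {
  s <- strsplit(paste(rep("A", 60), collapse = ""), "")[[1]]
  if (strand == "+") {
    s[11:12] <- c("G", "T"); s[19:20] <- c("A", "G")   # intron 1 (1-based)
    s[31:32] <- c("G", "T"); s[39:40] <- c("A", "G")   # intron 2
  } else {
    s[11:12] <- c("C", "T"); s[19:20] <- c("A", "C")
    s[31:32] <- c("C", "T"); s[39:40] <- c("A", "C")
  }
  as_genome(c(c1 = paste(s, collapse = "")))
}

# fabricated splice-site table for profile/eclip tests
fake_sites <- function(n, chrom = "chr1", spacing = 1000L, strand = NULL,
                       kind = "acceptor", start_at = 2000L) {
  strand <- strand %||% rep(c("+", "-"), length.out = n)
  data.frame(site_id = paste0("s", seq_len(n)), kind = kind, chrom = chrom,
             junction = start_at + spacing * (seq_len(n) - 1L),
             strand = rep(strand, length.out = n),
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
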