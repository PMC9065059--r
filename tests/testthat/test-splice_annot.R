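test_that("internal exons yield oriented acceptor/donor junctions", {
  s <- extract_internal_splice_sites(toy_models("+"), toy_genome("+"))
  expect_equal(nrow(s), 2)
  acc <- s[s$kind == "acceptor", ]
  don <- s[s$kind == "donor", ]
  expect_equal(acc$junction, 20L)
  expect_equal(don$junction, 30L)
  expect_true(all(s$canonical))
  expect_equal(acc$intron_length, 10L)
  expect_equal(acc$exon_length, 10L)

  s2 <- extract_internal_splice_sites(toy_models("-"), toy_genome("-"))
  expect_equal(s2$junction[s2$kind == "acceptor"], 30L)
  expect_equal(s2$junction[s2$kind == "donor"], 20L)
  expect_true(all(s2$canonical))
})

test_that("non-canonical introns are dropped by default, kept on request", {
  g <- toy_genome("+")
  raw <- unclass(g)[["c1"]]
  substr(raw, 11, 12) <- "GC"            # first intron now GC..AG
  g2 <- as_genome(c(c1 = raw))
  s <- extract_internal_splice_sites(toy_models("+"), g2)
  expect_equal(nrow(s), 1)               # acceptor of exon 2 lost
  expect_equal(s$kind, "donor")
  s2 <- extract_internal_splice_sites(toy_models("+"), g2,
                                      keep_noncanonical = TRUE)
  expect_equal(nrow(s2), 2)
  expect_false(s2$canonical[s2$kind == "acceptor"])
})

test_that("transcripts with fewer than three exons yield no internal sites", {
  m <- as_gene_models(data.frame(gene_id = "g", transcript_id = "t",
                                 chrom = "c1", strand = "+",
                                 start = c(0L, 20L), end = c(10L, 30L)))
  expect_equal(nrow(extract_internal_splice_sites(m)), 0)
  term <- extract_internal_splice_sites(m, include_terminal = TRUE)
  expect_equal(sort(term$junction), c(10L, 20L))
})

test_that("acceptor and donor of an exon differ by exactly its length", {
  b <- synth_bundle(11, synth_config(11, genes = list(n = 25)))
  s <- b$sites
  key <- paste(s$transcript_id, s$exon_start)
  acc <- s[s$kind == "acceptor", ]
  don <- s[s$kind == "donor", ]
  m <- match(paste(acc$transcript_id, acc$exon_start),
             paste(don$transcript_id, don$exon_start))
  ok <- !is.na(m)
  expect_gt(sum(ok), 0)
  expect_equal(abs(don$junction[m[ok]] - acc$junction[ok]),
               acc$exon_length[ok])
})

test_that("strand context is non-template iff motif and gene strands match", {
  expect_equal(classify_strand_context("+", "+"), "non_template")
  expect_equal(classify_strand_context("-", "+"), "template")
  expect_equal(classify_strand_context("-", "-"), "non_template")
  expect_error(classify_strand_context("+", "+", "c1", "c2"), "chromosome")
  # flipping both strands never changes the classification
  for (h in c("+", "-")) for (g in c("+", "-")) {
    flip <- function(x) ifelse(x == "+", "-", "+")
    expect_equal(classify_strand_context(h, g),
                 classify_strand_context(flip(h), flip(g)))
  }
})

test_that("exon position groups label only long transcripts, in tx order", {
  mk <- function(n, strand = "+") as_gene_models(data.frame(
    gene_id = "g", transcript_id = "t", chrom = "c1", strand = strand,
    start = seq(0L, by = 200L, length.out = n),
    end = seq(0L, by = 200L, length.out = n) + 100L))
  lab <- function(models) {
    s <- extract_internal_splice_sites(models, include_terminal = TRUE,
                                       collapse_duplicates = FALSE)
    assign_exon_position_groups(s, models)
  }
  grp <- function(s, start) unique(s$exon_group[s$exon_start == start])
  g9 <- lab(mk(9))
  # exon index = exon_start / 200 + 1; exon 5 is the sole middle
  expect_equal(grp(g9, 800L), "middle")
  expect_equal(grp(g9, 200L), "first2")
  expect_equal(grp(g9, 1600L), "last1")
  expect_equal(grp(g9, 0L), "first1")    # terminal exon via its donor

  g8 <- lab(mk(8))
  expect_true(all(g8$exon_group == "none"))

  g12 <- lab(mk(12))
  mid <- unique(g12$exon_start[g12$exon_group == "middle"])
  expect_equal(sort(mid), c(800L, 1000L, 1200L, 1400L))  # exons 5-8

  g9m <- lab(mk(9, "-"))                 # transcription order reversed
  expect_equal(grp(g9m, 1600L), "first1")
  expect_equal(grp(g9m, 800L), "middle")
  expect_equal(grp(g9m, 0L), "last1")
})

test_that("site windows are oriented and clipped at chromosome ends", {
  s <- data.frame(site_id = "a", kind = "acceptor", chrom = "c1",
                  junction = 1000L, strand = "+", stringsAsFactors = FALSE)
  w <- site_windows(s, 100)
  expect_equal(c(w$intronic_start, w$intronic_end), c(900L, 1000L))
  expect_equal(c(w$exonic_start, w$exonic_end), c(1000L, 1100L))

  d <- data.frame(site_id = "d", kind = "donor", chrom = "c1",
                  junction = 1000L, strand = "-", stringsAsFactors = FALSE)
  wd <- site_windows(d, 100)
  expect_equal(c(wd$exonic_start, wd$exonic_end), c(1000L, 1100L))
  expect_equal(c(wd$intronic_start, wd$intronic_end), c(900L, 1000L))

  near <- data.frame(site_id = "n", kind = "acceptor", chrom = "c1",
                     junction = 30L, strand = "+", stringsAsFactors = FALSE)
  wn <- site_windows(near, 100, chrom_len = c(c1 = 500L))
  expect_equal(wn$win_start, 0L)
  expect_equal(wn$intronic_start, 0L)
})

test_that("derived site descriptors are invariant under strand flip", {
  b <- synth_bundle(13, synth_config(13, genes = list(n = 20)))
  models <- b$models
  g <- unclass(b$genome)
  # mirror the whole genome and annotation
  len <- chrom_lengths(b$genome)
  flipped_g <- as_genome(vapply(g, revcomp, character(1)))
  fm <- models
  fm$start2 <- len[fm$chrom] - fm$end
  fm$end <- len[fm$chrom] - fm$start
  fm$start <- fm$start2
  fm$start2 <- NULL
  fm$strand <- ifelse(fm$strand == "+", "-", "+")
  fs <- extract_internal_splice_sites(as_gene_models(fm), flipped_g)
  os <- extract_internal_splice_sites(models, b$genome)
  expect_equal(nrow(fs), nrow(os))
  expect_equal(sort(fs$intron_length), sort(os$intron_length))
  expect_equal(sort(fs$exon_length), sort(os$exon_length))
  expect_equal(table(fs$kind), table(os$kind))
  expect_true(all(fs$canonical))
})
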