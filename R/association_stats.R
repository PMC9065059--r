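#' Classify splicing nodes as differentially included
#'
#' A node is differential when |dPSI| >= delta and probability >= pi (both
#' thresholds inclusive; defaults dPSI 0.1, probability 0.9).  Direction
#' follows the sign of dPSI ("included" for positive, "excluded" for
#' negative).
#'
#' @param psi data.frame with columns gene, node, chrom, start, end,
#'   strand, type, psi_a, psi_b, delta_psi, probability (as read from a
#'   Whippet-style `.diff` table).
#' @param delta dPSI threshold.
#' @param prob probability threshold.
#' @return the table with differential, direction, and the thresholds
#'   recorded as attributes.
#' @export
classify_nodes <- function(psi, delta = 0.1, prob = 0.9) {
  bad <- which(abs(psi$delta_psi) > 1)
  if (length(bad))
    stop_ctx("delta_psi outside [-1, 1] at row ", bad[1], " (",
             psi$delta_psi[bad[1]], ")")
  if (any(psi$probability < 0 | psi$probability > 1))
    stop_ctx("probability outside [0, 1]")
  psi$differential <- abs(psi$delta_psi) >= delta & psi$probability >= prob
  psi$direction <- ifelse(!psi$differential, "none",
                          ifelse(psi$delta_psi > 0, "included", "excluded"))
  attr(psi, "delta") <- delta
  attr(psi, "prob") <- prob
  psi
}

# minimum distance from any of the given positions to the nearest value in
# the sorted vector `mids` on the same chromosome
min_dist_to_mids <- function(chrom, pos, mids_by_chrom) {
  vapply(seq_along(pos), function(i) {
    m <- mids_by_chrom[[chrom[i]]]
    if (is.null(m) || length(m) == 0) return(Inf)
    min(abs(m - pos[i]))
  }, numeric(1))
}

#' Label splicing nodes by G4 association
#'
#' A node is G4-associated when the nearer of its two boundaries lies
#' within `motif_dist` bp of a G4 motif midpoint or within `peak_dist` bp
#' of a G4-seq peak midpoint (defaults 100 and 45 bp).
#'
#' @param nodes classified node table (see [classify_nodes()]).
#' @param motif_hits motif hit data.frame (or NULL).
#' @param peak_hits peak interval data.frame (or NULL).
#' @param motif_dist,peak_dist association distances in bp.
#' @param strand_context restrict motifs to `"non_template"` or
#'   `"template"` relative to the node strand; NULL for both.
#' @return nodes with a logical `g4_associated` column.
#' @export
label_g4_association <- function(nodes, motif_hits = NULL, peak_hits = NULL,
                                 motif_dist = 100, peak_dist = 45,
                                 strand_context = NULL) {
  assoc <- rep(FALSE, nrow(nodes))
  dist_ok <- function(hits, limit) {
    mids <- (hits$start + hits$end) %/% 2L
    byc <- split(mids, hits$chrom)
    byc <- lapply(byc, sort)
    d1 <- min_dist_to_mids(nodes$chrom, nodes$start, byc)
    d2 <- min_dist_to_mids(nodes$chrom, nodes$end, byc)
    pmin(d1, d2) <= limit
  }
  if (!is.null(motif_hits) && nrow(motif_hits)) {
    if (!is.null(strand_context)) {
      # context is relative to each node's strand: non_template motifs
      # share the node strand, template motifs oppose it
      assoc_m <- rep(FALSE, nrow(nodes))
      for (s in unique(nodes$strand)) {
        keep_strand <- if (strand_context == "non_template") s else
          setdiff(c("+", "-"), s)
        mh <- motif_hits[motif_hits$strand %in% keep_strand, , drop = FALSE]
        sel <- nodes$strand == s
        if (nrow(mh) && any(sel))
          assoc_m[sel] <- dist_ok(mh, motif_dist)[sel]
      }
      assoc <- assoc | assoc_m
    } else {
      assoc <- assoc | dist_ok(motif_hits, motif_dist)
    }
  }
  if (!is.null(peak_hits) && nrow(peak_hits))
    assoc <- assoc | dist_ok(peak_hits, peak_dist)
  nodes$g4_associated <- assoc
  nodes
}

#' Odds ratio with Yates chi-squared for one 2x2 table
#'
#' Cells: a = G4+ differential, b = G4+ non-differential, c = G4-
#' differential, d = G4- non-differential.  When any cell is zero the
#' Haldane correction (add 0.5 to every cell) is applied to the odds
#' ratio and flagged.
#'
#' @param a,b,c,d non-negative counts.
#' @return list: counts, odds_ratio, haldane, log_or, log_or_se, chisq, p,
#'   testable.
#' @export
assoc_2x2 <- function(a, b, c, d) {
  m <- matrix(c(a, b, c, d), 2, 2, byrow = TRUE)
  testable <- all(rowSums(m) > 0) && all(colSums(m) > 0)
  haldane <- any(m == 0)
  mm <- if (haldane) m + 0.5 else m
  or <- (mm[1, 1] * mm[2, 2]) / (mm[1, 2] * mm[2, 1])
  se <- sqrt(sum(1 / mm))
  if (testable) {
    ct <- suppressWarnings(chisq.test(m, correct = TRUE))
    chisq <- unname(ct$statistic)
    p <- ct$p.value
  } else {
    chisq <- NA_real_
    p <- NA_real_
  }
  list(a = a, b = b, c = c, d = d, odds_ratio = or, haldane = haldane,
       log_or = log(or), log_or_se = se, chisq = chisq, p = p,
       testable = testable)
}

#' G4 x differential-inclusion association tests per node stratum
#'
#' One Yates-corrected chi-squared test per (node type x direction)
#' stratum: differential nodes of that type and direction versus all
#' non-differential nodes of that type, split by G4 association.
#' Bonferroni adjustment uses the number of testable strata as the family
#' size m.
#'
#' @param nodes labelled node table (see [label_g4_association()]).
#' @param directions directions to test (default included and excluded;
#'   `"any"` pools both directions into one differential stratum).
#' @return data.frame with one row per stratum: type, direction, the 2x2
#'   counts, odds_ratio, haldane, chisq, p, p_adj, m, testable.
#' @export
association_test <- function(nodes, directions = c("included", "excluded")) {
  strata <- expand.grid(type = unique(nodes$type), direction = directions,
                        stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(strata)), function(i) {
    ty <- strata$type[i]
    dir <- strata$direction[i]
    nn <- nodes[nodes$type == ty, ]
    in_dir <- if (dir == "any") nn$differential else nn$direction == dir
    a <- sum(nn$g4_associated & in_dir)
    b <- sum(nn$g4_associated & !nn$differential)
    c_ <- sum(!nn$g4_associated & in_dir)
    d <- sum(!nn$g4_associated & !nn$differential)
    r <- assoc_2x2(a, b, c_, d)
    data.frame(type = ty, direction = dir, a = a, b = b, c = c_, d = d,
               odds_ratio = r$odds_ratio, haldane = r$haldane,
               log_or = r$log_or, log_or_se = r$log_or_se,
               chisq = r$chisq, p = r$p, testable = r$testable,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  m <- sum(out$testable)
  out$m <- m
  out$p_adj <- pmin(1, out$p * m)
  out
}

#' GC fraction of intervals
#' @param genome a `genome_seq`.
#' @param chrom,start,end interval coordinates (0-based half-open).
#' @return numeric vector of G+C fractions.
#' @export
gc_fraction <- function(genome, chrom, start, end) {
  g <- unclass(genome)
  s <- substring(g[chrom], start + 1L, end)
  vapply(s, function(x) {
    n <- nchar(x)
    if (n == 0) return(NA_real_)
    (n - nchar(gsub("[GC]", "", x))) / n
  }, numeric(1), USE.NAMES = FALSE)
}

#' GC-matched long-intron controls for short introns
#'
#' Greedy nearest-GC matching without replacement: short introns are
#' processed in seeded random order and each is paired with the unused
#' long intron of closest GC content; pairs differing by more than `tol`
#' are discarded.
#'
#' @param gc_short,gc_long GC fractions of the short (< 500 nt) and long
#'   (> 500 nt) intron groups.
#' @param tol maximum |GC difference| per pair (default 0.01).
#' @param seed RNG seed for the processing order.
#' @param min_pairs minimum accepted pairs (default 10); fewer is an error.
#' @return data.frame: short_idx, long_idx, gc_short, gc_long.
#' @export
gc_matched_controls <- function(gc_short, gc_long, tol = 0.01, seed = NULL,
                                min_pairs = 10) {
  ord <- with_seed(seed, sample.int(length(gc_short)))
  avail <- rep(TRUE, length(gc_long))
  pairs <- vector("list", length(ord))
  np <- 0L
  for (si in ord) {
    cand <- which(avail)
    if (length(cand) == 0) break
    d <- abs(gc_long[cand] - gc_short[si])
    best <- cand[which.min(d)]
    if (min(d) <= tol) {
      avail[best] <- FALSE
      np <- np + 1L
      pairs[[np]] <- c(si, best)
    }
  }
  if (np < min_pairs)
    stop_ctx("only ", np, " GC-matched pairs (need >= ", min_pairs, ")")
  m <- do.call(rbind, pairs[seq_len(np)])
  data.frame(short_idx = m[, 1], long_idx = m[, 2],
             gc_short = gc_short[m[, 1]], gc_long = gc_long[m[, 2]])
}

#' Intron/exon length comparisons by G4 presence
#'
#' Median lengths per group with Mann-Whitney U (two-sided) and
#' Kolmogorov-Smirnov tests comparing the G4+ and G4- length
#' distributions; optionally sub-split by strand context.
#'
#' @param length numeric vector of intron (or exon) lengths.
#' @param g4 logical vector: G4 within the association window.
#' @param context optional strand-context vector ("non_template" /
#'   "template") for sub-splits.
#' @return list with `summary` (group, n, median) and `tests`
#'   (mwu_p, ks_p), NULL tests when a group is empty.
#' @export
length_comparisons <- function(length, g4, context = NULL) {
  groups <- ifelse(g4, "g4", "no_g4")
  if (!is.null(context)) groups[g4] <- paste0("g4_", context[g4])
  med <- tapply(length, groups, median)
  summary <- data.frame(group = names(med), n = as.integer(table(groups)),
                        median = as.numeric(med))
  tests <- NULL
  if (any(g4) && any(!g4)) {
    mwu <- suppressWarnings(wilcox.test(length[g4], length[!g4]))
    ks <- suppressWarnings(ks.test(length[g4], length[!g4]))
    tests <- list(mwu_p = mwu$p.value, ks_p = ks$p.value)
  }
  list(summary = summary, tests = tests)
}

#' sQTL enrichment at G4s, adjusted by SNP enrichment
#'
#' Within uniform bins spanning [-L, +L) around the splice sites (in
#' transcription orientation), the per-bin density is the number of
#' variants falling inside G4 intervals divided by the G4 base pairs in
#' the bin; enrichment is density over the mean density across defined
#' bins, computed separately for sQTLs and SNPs, and the adjusted value is
#' their ratio.  Bins with no G4 base pairs (or zero SNP enrichment) are
#' reported as NA.
#'
#' @param g4_hits motif or peak interval data.frame.
#' @param sqtls,snps variant data.frames with chrom, pos (0-based).
#' @param sites splice-site data.frame.
#' @param L half-range in bp (default 500).
#' @param w bin width in bp (default 25).
#' @return data.frame: bin_start, bin_end, g4_bp, n_sqtl, n_snp, e_sqtl,
#'   e_snp, adjusted.
#' @export
sqtl_adjusted_enrichment <- function(g4_hits, sqtls, snps, sites,
                                     L = 500, w = 25) {
  stopifnot((2 * L) %% w == 0)
  nb <- (2L * L) %/% w
  bin_start <- seq(-L, L - w, by = w)
  g4_bp <- numeric(nb)
  n_sqtl <- numeric(nb)
  n_snp <- numeric(nb)
  for (ch in unique(sites$chrom)) {
    s <- sites[sites$chrom == ch, ]
    hh <- g4_hits[g4_hits$chrom == ch, , drop = FALSE]
    maxpos <- max(s$junction) + L + 1L
    hh <- hh[hh$start < maxpos & hh$end > 0, , drop = FALSE]
    ing4 <- integer(maxpos)
    if (nrow(hh)) {
      ir <- IRanges::IRanges(pmax(hh$start + 1L, 1L), pmin(hh$end, maxpos))
      ing4 <- as.integer(as.integer(IRanges::coverage(ir,
                                                      width = maxpos)) > 0)
    }
    cnt_at <- function(v) {
      pos <- v$pos[v$chrom == ch]
      pos <- pos[pos >= 0 & pos < maxpos]
      tabulate(pos + 1L, nbins = maxpos)
    }
    sq <- cnt_at(sqtls) * ing4
    sn <- cnt_at(snps) * ing4
    idx <- outer(s$junction - L, 0:(2L * L - 1L), "+") + 1L
    ok <- idx >= 1L & idx <= maxpos
    take <- function(vec) {
      m <- matrix(0, nrow(s), 2L * L)
      m[ok] <- vec[idx[ok]]
      minus <- s$strand == "-"
      if (any(minus)) m[minus, ] <- m[minus, rev(seq_len(2L * L)),
                                      drop = FALSE]
      colSums(m)
    }
    per_off_g4 <- take(ing4)
    per_off_sq <- take(sq)
    per_off_sn <- take(sn)
    bin_of <- rep(seq_len(nb), each = w)
    g4_bp <- g4_bp + tapply(per_off_g4, bin_of, sum)
    n_sqtl <- n_sqtl + tapply(per_off_sq, bin_of, sum)
    n_snp <- n_snp + tapply(per_off_sn, bin_of, sum)
  }
  d_sqtl <- ifelse(g4_bp > 0, n_sqtl / g4_bp, NA_real_)
  d_snp <- ifelse(g4_bp > 0, n_snp / g4_bp, NA_real_)
  e_sqtl <- d_sqtl / mean(d_sqtl, na.rm = TRUE)
  e_snp <- d_snp / mean(d_snp, na.rm = TRUE)
  adjusted <- ifelse(!is.na(e_snp) & e_snp > 0, e_sqtl / e_snp, NA_real_)
  data.frame(bin_start = bin_start, bin_end = bin_start + w,
             g4_bp = as.numeric(g4_bp), n_sqtl = as.numeric(n_sqtl),
             n_snp = as.numeric(n_snp), e_sqtl = e_sqtl, e_snp = e_snp,
             adjusted = adjusted)
}

#' Read a Whippet-style PSI difference table
#'
#' TSV with header: gene, node, chrom, start, end, strand, type, psi_a,
#' psi_b, delta_psi, probability.
#'
#' @param path TSV file.
#' @return data.frame.
#' @export
read_psi_table <- function(path) {
  tab <- read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
  need <- c("gene", "node", "chrom", "start", "end", "strand", "type",
            "delta_psi", "probability")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop_ctx("PSI table missing column(s): ",
                             paste(miss, collapse = ", "), ctx = path)
  tab
}
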