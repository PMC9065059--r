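#' Synthetic study configuration
#'
#' Seeded defaults for the desk-scale synthetic bundle: a ~5 Mb
#' four-chromosome genome from a first-order Markov model, 300 multi-exon
#' genes (~1500 internal junctions), G4 motifs planted near splice sites
#' at a 2:1 non-template:template ratio, variant tracks with an sQTL
#' uplift inside G4s, PSI tables with a planted odds ratio, and per-group
#' eCLIP binding probabilities.  Override any entry with a named list.
#'
#' @param seed master seed; every generator derives child seeds from it.
#' @param ... named sub-list overrides, e.g. `genes = list(n = 50)`.
#' @return a config list.
#' @export
synth_config <- function(seed = 1, ...) {
  cfg <- list(
    seed = as.integer(seed),
    genome = list(n_chroms = 4L, chrom_len = 1250000L, gc = 0.42,
                  cpg_factor = 0.4),
    genes = list(n = 300L, exon_count = 5:9,
                 exon_meanlog = log(140), exon_sdlog = 0.5,
                 intron_meanlog = log(1000), intron_sdlog = 1.0,
                 exon_min = 10L, exon_max = 2000L,
                 intron_min = 70L, intron_max = 20000L,
                 gap_min = 500L, gap_max = 3000L),
    plant = list(rate = 0.35, offset_mean = 50, offset_sd = 15,
                 nontemplate_prob = 2 / 3, n_runs = 4L, run_len = 3:5,
                 loop_len = 1:7, loop_alphabet = c("A", "C", "T")),
    peaks = list(overlap_prob = 0.8, jitter = 20L),
    variants = list(snp_rate = 0.002, sqtl_rate = 0.002,
                    sqtl_uplift = 2.0, window = 500L, uplift_within = 100L),
    psi = list(base_rate = 0.15, odds_ratio = 2.0, excl_prob = 0.85,
               dpsi_max = 0.6, delta = 0.1, prob = 0.9),
    eclip = list(region = c(-100, 100), w = 10L, p_no_g4 = 0.3,
                 p_g4 = 0.6, effect_bins = c(-50, 0)))
  over <- list(...)
  for (nm in names(over)) {
    if (is.list(over[[nm]]) && nm %in% names(cfg)) {
      cfg[[nm]][names(over[[nm]])] <- over[[nm]]
    } else cfg[[nm]] <- over[[nm]]
  }
  cfg
}

#' Markov transition matrix with tunable GC and CpG depletion
#'
#' @param gc stationary G+C fraction.
#' @param cpg_factor multiplier on the C->G transition (CpG depletion
#'   when < 1).
#' @return 4x4 row-stochastic matrix (A, C, G, T).
#' @export
markov_transition <- function(gc = 0.42, cpg_factor = 1) {
  pi0 <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  tr <- matrix(rep(pi0, each = 4), 4, 4, dimnames = list(BASES, BASES))
  tr["C", "G"] <- tr["C", "G"] * cpg_factor
  tr <- tr / rowSums(tr)
  tr
}

#' Generate a synthetic genome
#'
#' First-order Markov sequence per chromosome; deterministic given the
#' master seed.
#'
#' @param config a [synth_config()] list.
#' @return a `genome_seq`.
#' @export
generate_genome <- function(config) {
  gcfg <- config$genome
  tr <- gcfg$transition %||% markov_transition(gcfg$gc, gcfg$cpg_factor)
  if (any(rowSums(tr) <= 0) || any(tr < 0))
    stop_ctx("degenerate transition matrix")
  init <- gcfg$init %||% rep(0.25, 4)
  lens <- rep_len(gcfg$chrom_len, gcfg$n_chroms)
  seqs <- with_seed(child_seed(config$seed, 1L), {
    vapply(seq_len(gcfg$n_chroms), function(i)
      markov_seq_cpp(lens[i], tr, init), character(1))
  })
  names(seqs) <- paste0("chr", seq_len(gcfg$n_chroms))
  as_genome(seqs)
}

# sample() treats a length-1 numeric as 1:x; guard scalar choices
sample1 <- function(x) if (length(x) == 1L) x else sample(x, 1L)

# replace substrings at 0-based starts (non-overlapping) in one sequence
apply_edits <- function(seq, starts, repls) {
  if (length(starts) == 0) return(seq)
  o <- order(starts)
  starts <- starts[o]
  repls <- repls[o]
  ends <- starts + nchar(repls)
  if (any(starts[-1] < ends[-length(ends)]))
    stop_ctx("overlapping sequence edits")
  pieces <- character(2 * length(starts) + 1)
  prev <- 0L
  for (i in seq_along(starts)) {
    pieces[2 * i - 1] <- substring(seq, prev + 1L, starts[i])
    pieces[2 * i] <- repls[i]
    prev <- ends[i]
  }
  pieces[2 * length(starts) + 1] <- substring(seq, prev + 1L, nchar(seq))
  paste(pieces, collapse = "")
}

#' Generate non-overlapping gene models on a synthetic genome
#'
#' Genes are laid along the chromosomes with random inter-gene gaps,
#' random strands, exon/intron lengths from log-normal distributions, and
#' every intron's terminal dinucleotides overwritten to GT..AG on the gene
#' strand.
#'
#' @param genome a `genome_seq`.
#' @param config a [synth_config()] list.
#' @return list: models (`gene_models`), genome (with GT/AG written),
#'   sites (canonical internal splice sites as ground truth).
#' @export
generate_annotation <- function(genome, config) {
  gcfg <- config$genes
  len <- chrom_lengths(genome)
  models <- with_seed(child_seed(config$seed, 2L), {
    rows <- list()
    chrom_i <- 1L
    pos <- sample(gcfg$gap_min:gcfg$gap_max, 1)
    for (g in seq_len(gcfg$n)) {
      n_ex <- sample1(gcfg$exon_count)
      ex <- pmin(pmax(round(rlnorm(n_ex, gcfg$exon_meanlog,
                                   gcfg$exon_sdlog)), gcfg$exon_min),
                 gcfg$exon_max)
      it <- pmin(pmax(round(rlnorm(n_ex - 1, gcfg$intron_meanlog,
                                   gcfg$intron_sdlog)), gcfg$intron_min),
                 gcfg$intron_max)
      span <- sum(ex) + sum(it)
      gap <- sample(gcfg$gap_min:gcfg$gap_max, 1)
      while (chrom_i <= length(len) && pos + span + gap > len[chrom_i]) {
        chrom_i <- chrom_i + 1L
        pos <- sample(gcfg$gap_min:gcfg$gap_max, 1)
      }
      if (chrom_i > length(len))
        stop_ctx("cannot place ", gcfg$n, " genes on this genome")
      starts <- pos + c(0L, cumsum(ex[-n_ex] + it))
      strand <- sample(c("+", "-"), 1)
      gid <- sprintf("gene%03d", g)
      rows[[g]] <- data.frame(gene_id = gid, transcript_id = paste0(gid, ".t1"),
                              chrom = names(len)[chrom_i], strand = strand,
                              start = as.integer(starts),
                              end = as.integer(starts + ex),
                              stringsAsFactors = FALSE)
      pos <- pos + span + gap
    }
    as_gene_models(do.call(rbind, rows))
  })
  # force canonical GT..AG dinucleotides on every intron
  g <- unclass(genome)
  sp <- split(models, models$transcript_id)
  edits <- list()
  for (tx in sp) {
    tx <- tx[order(tx$start), ]
    n <- nrow(tx)
    if (n < 2) next
    is <- tx$end[-n]
    ie <- tx$start[-1]
    first2 <- if (tx$strand[1] == "+") "GT" else "CT"
    last2 <- if (tx$strand[1] == "+") "AG" else "AC"
    edits[[length(edits) + 1L]] <- data.frame(
      chrom = tx$chrom[1], start = c(is, ie - 2L),
      repl = c(rep(first2, n - 1), rep(last2, n - 1)),
      stringsAsFactors = FALSE)
  }
  edits <- do.call(rbind, edits)
  for (ch in unique(edits$chrom)) {
    e <- edits[edits$chrom == ch, ]
    g[[ch]] <- apply_edits(g[[ch]], e$start, e$repl)
  }
  genome <- as_genome(g)
  sites <- extract_internal_splice_sites(models, genome)
  list(models = models, genome = genome, sites = sites)
}

# one consensus G4 motif string (G-run form)
random_g4_motif <- function(pcfg) {
  runs <- vapply(seq_len(pcfg$n_runs), function(i)
    strrep("G", sample1(pcfg$run_len)), character(1))
  loops <- vapply(seq_len(pcfg$n_runs - 1), function(i)
    paste(sample(pcfg$loop_alphabet, sample1(pcfg$loop_len),
                 replace = TRUE), collapse = ""), character(1))
  paste0(paste0(runs[-pcfg$n_runs], loops, collapse = ""),
         runs[pcfg$n_runs])
}

#' Plant consensus G4 motifs near splice sites
#'
#' For each selected site a consensus motif (4 runs of 3-5 G, loops 1-7
#' nt) overwrites the background sequence on the intronic side, with its
#' junction-proximal edge at a drawn offset; the strand is the gene
#' strand (non-template) or its opposite (template) with the configured
#' probability.  An 8 nt A/T buffer is written on each side of the motif
#' so a planted block can never fuse with background G- or C-runs (gaps
#' of up to 7 nt would otherwise chain runs together), keeping the truth
#' coordinates exact.  Planted motifs never overlap the junction
#' dinucleotides or each other; colliding draws are retried up to 50
#' times.
#'
#' @param genome a `genome_seq`.
#' @param sites splice-site data.frame.
#' @param config a [synth_config()] list.
#' @return list: genome (with motifs written), truth (data.frame chrom,
#'   start, end, strand, site_id, offset, context).
#' @export
plant_g4s <- function(genome, sites, config) {
  pcfg <- config$plant
  stopifnot(pcfg$rate >= 0, pcfg$rate <= 1)
  g <- unclass(genome)
  truth <- list()
  occupied <- lapply(setNames(nm = names(g)), function(x) integer(0))
  edits <- list()
  # optional coupling of the planting rate to intron length (short-intron
  # enrichment scenarios): list(threshold =, short =, long =)
  rate <- rep(pcfg$rate, nrow(sites))
  if (!is.null(pcfg$rate_by_length)) {
    rb <- pcfg$rate_by_length
    rate <- ifelse(sites$intron_length < rb$threshold, rb$short, rb$long)
  }
  with_seed(child_seed(config$seed, 3L), {
    pick <- runif(nrow(sites)) < rate
    buf <- 8L
    for (i in which(pick)) {
      s <- sites[i, ]
      motif <- random_g4_motif(pcfg)
      L <- nchar(motif)
      for (attempt in 1:50) {
        d <- max(buf + 3L, round(rnorm(1, pcfg$offset_mean, pcfg$offset_sd)))
        if (s$intron_start == s$junction) {       # intron to the right
          ms <- s$junction + d
          if (ms + L + buf > s$intron_end - 2L) next
        } else {                                  # intron to the left
          ms <- s$junction - d - L
          if (ms - buf < s$intron_start + 2L) next
        }
        span <- (ms - buf):(ms + L + buf - 1L)
        if (any(span %in% occupied[[s$chrom]])) next
        nontemp <- runif(1) < pcfg$nontemplate_prob
        strand <- if (nontemp) s$strand else setdiff(c("+", "-"), s$strand)
        core <- if (strand == "+") motif else revcomp(motif)
        pad <- function(n) paste(sample(c("A", "T"), n, TRUE), collapse = "")
        written <- paste0(pad(buf), core, pad(buf))
        occupied[[s$chrom]] <- c(occupied[[s$chrom]], span)
        edits[[length(edits) + 1L]] <- data.frame(
          chrom = s$chrom, start = ms - buf, repl = written,
          stringsAsFactors = FALSE)
        truth[[length(truth) + 1L]] <- data.frame(
          chrom = s$chrom, start = ms, end = ms + L, strand = strand,
          site_id = s$site_id, offset = d,
          context = if (nontemp) "non_template" else "template",
          stringsAsFactors = FALSE)
        break
      }
    }
  })
  edits <- if (length(edits)) do.call(rbind, edits) else NULL
  if (!is.null(edits)) {
    for (ch in unique(edits$chrom)) {
      e <- edits[edits$chrom == ch, ]
      g[[ch]] <- apply_edits(g[[ch]], e$start, e$repl)
    }
  }
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               strand = character(), site_id = character(),
               offset = integer(), context = character(),
               stringsAsFactors = FALSE)
  list(genome = as_genome(g), truth = truth)
}

#' Cassette-exon nodes from internal splice sites
#'
#' One CE node per internal exon (the acceptor record carries the exon
#' interval).
#'
#' @param sites splice-site data.frame.
#' @return node data.frame: gene, node, chrom, start, end, strand, type.
#' @export
nodes_from_sites <- function(sites) {
  acc <- sites[sites$kind == "acceptor", ]
  data.frame(gene = acc$gene_id, node = paste0(acc$gene_id, ":",
                                               acc$exon_start),
             chrom = acc$chrom, start = acc$exon_start, end = acc$exon_end,
             strand = acc$strand, type = "CE", stringsAsFactors = FALSE)
}

#' Generate a PSI table with a planted G4 odds ratio
#'
#' Each node's differential-inclusion status is Bernoulli with baseline
#' odds multiplied by the planted odds ratio when the node is G4-flagged.
#' Differential nodes draw |dPSI| in [delta, dpsi_max] and probability in
#' [prob, 1]; non-differential nodes draw |dPSI| < delta and uniform
#' probability.  Differential nodes are exclusions with the configured
#' probability (depolarisation-style skewing).
#'
#' @param nodes node data.frame (see [nodes_from_sites()]).
#' @param g4 logical vector: node is G4-flagged (ground truth).
#' @param config a [synth_config()] list.
#' @return list: psi (table for [classify_nodes()]), truth (planted OR and
#'   rates).
#' @export
generate_psi_table <- function(nodes, g4, config) {
  pcfg <- config$psi
  stopifnot(pcfg$odds_ratio > 0, length(g4) == nrow(nodes))
  psi <- with_seed(child_seed(config$seed, 4L), {
    p <- plogis(qlogis(pcfg$base_rate) + log(pcfg$odds_ratio) * g4)
    diff <- runif(nrow(nodes)) < p
    mag <- ifelse(diff, runif(nrow(nodes), pcfg$delta, pcfg$dpsi_max),
                  runif(nrow(nodes), 0, pcfg$delta * 0.999))
    sign <- ifelse(diff,
                   ifelse(runif(nrow(nodes)) < pcfg$excl_prob, -1, 1),
                   sample(c(-1, 1), nrow(nodes), replace = TRUE))
    prob <- ifelse(diff, runif(nrow(nodes), pcfg$prob, 1),
                   runif(nrow(nodes), 0, pcfg$prob * 0.999))
    psi_a <- runif(nrow(nodes), 0.2, 0.8)
    data.frame(nodes, psi_a = psi_a,
               psi_b = pmin(pmax(psi_a + sign * mag, 0), 1),
               delta_psi = sign * mag, probability = prob,
               stringsAsFactors = FALSE)
  })
  list(psi = psi, truth = list(odds_ratio = pcfg$odds_ratio,
                               base_rate = pcfg$base_rate))
}

#' Generate sQTL and SNP tracks with a planted uplift inside G4s
#'
#' Per-position Bernoulli draws over the union of splice-site windows:
#' SNPs at a uniform background rate; sQTLs at the background rate times
#' the uplift at positions inside a G4 interval within `uplift_within` bp
#' of a junction.
#'
#' @param sites splice-site data.frame.
#' @param g4_hits G4 interval data.frame.
#' @param config a [synth_config()] list.
#' @return list: sqtls, snps (chrom, pos, class), truth.
#' @export
generate_variants <- function(sites, g4_hits, config) {
  vcfg <- config$variants
  out_sq <- list()
  out_sn <- list()
  with_seed(child_seed(config$seed, 5L), {
    for (ch in unique(sites$chrom)) {
      s <- sites[sites$chrom == ch, ]
      win <- IRanges::reduce(IRanges::IRanges(
        pmax(s$junction - vcfg$window, 0L) + 1L,
        s$junction + vcfg$window))
      pos <- unlist(lapply(seq_along(win), function(i)
        seq(IRanges::start(win)[i], IRanges::end(win)[i]))) - 1L
      near <- IRanges::reduce(IRanges::IRanges(
        pmax(s$junction - vcfg$uplift_within, 0L) + 1L,
        s$junction + vcfg$uplift_within))
      hh <- g4_hits[g4_hits$chrom == ch, , drop = FALSE]
      in_g4 <- rep(FALSE, length(pos))
      if (nrow(hh)) {
        ir <- IRanges::IRanges(hh$start + 1L, hh$end)
        q <- IRanges::IRanges(pos + 1L, pos + 1L)
        in_g4 <- IRanges::overlapsAny(q, ir)
        in_near <- IRanges::overlapsAny(q, near)
        in_g4 <- in_g4 & in_near
      }
      p_sq <- vcfg$sqtl_rate * ifelse(in_g4, vcfg$sqtl_uplift, 1)
      keep_sq <- runif(length(pos)) < p_sq
      keep_sn <- runif(length(pos)) < vcfg$snp_rate
      if (any(keep_sq))
        out_sq[[ch]] <- data.frame(chrom = ch, pos = pos[keep_sq],
                                    class = "sqtl",
                                    stringsAsFactors = FALSE)
      if (any(keep_sn))
        out_sn[[ch]] <- data.frame(chrom = ch, pos = pos[keep_sn],
                                    class = "snp", stringsAsFactors = FALSE)
    }
  })
  list(sqtls = do.call(rbind, out_sq), snps = do.call(rbind, out_sn),
       truth = list(uplift = vcfg$sqtl_uplift,
                    uplift_within = vcfg$uplift_within))
}

#' Generate structure-supporting peaks over motif hits
#'
#' Each motif gains an overlapping peak with the configured probability;
#' peak boundaries are jittered outward by up to `jitter` bp.
#'
#' @param hits motif hit data.frame.
#' @param config a [synth_config()] list.
#' @return peak interval data.frame.
#' @export
generate_peaks <- function(hits, config) {
  kcfg <- config$peaks
  with_seed(child_seed(config$seed, 6L), {
    keep <- runif(nrow(hits)) < kcfg$overlap_prob
    h <- hits[keep, , drop = FALSE]
    if (nrow(h) == 0)
      return(data.frame(chrom = character(), start = integer(),
                        end = integer(), strand = character(),
                        label = character(), score = numeric(),
                        stringsAsFactors = FALSE))
    data.frame(chrom = h$chrom,
               start = pmax(h$start - sample(0:kcfg$jitter, nrow(h), TRUE),
                            0L),
               end = h$end + sample(0:kcfg$jitter, nrow(h), TRUE),
               strand = ".", label = "peak", score = 1,
               stringsAsFactors = FALSE)
  })
}

#' Generate eCLIP peaks for one factor with group-dependent occupancy
#'
#' Per site and per bin, a Bernoulli draw decides whether the factor
#' binds; bound bins emit a peak covering the bin.  G4-flanked sites use
#' `p_g4` inside the effect bins and `p_no_g4` elsewhere; non-flanked
#' sites use `p_no_g4` everywhere.
#'
#' @param sites_g4,sites_no_g4 splice-site groups.
#' @param config a [synth_config()] list.
#' @param seed_offset child-seed counter (vary per factor/replicate).
#' @return list: peaks (interval data.frame), truth.
#' @export
generate_eclip <- function(sites_g4, sites_no_g4, config, seed_offset = 7L) {
  ecfg <- config$eclip
  region <- ecfg$region
  w <- ecfg$w
  nb <- (region[2] - region[1]) %/% w
  bin_start <- seq(region[1], region[2] - w, by = w)
  p_g4 <- rep(ecfg$p_no_g4, nb)
  eff <- bin_start >= ecfg$effect_bins[1] & bin_start < ecfg$effect_bins[2]
  p_g4[eff] <- ecfg$p_g4
  gen <- function(sites, pvec) {
    if (nrow(sites) == 0) return(NULL)
    rows <- list()
    for (b in seq_len(nb)) {
      bound <- runif(nrow(sites)) < pvec[b]
      if (!any(bound)) next
      s <- sites[bound, ]
      lo <- bin_start[b]
      hi <- lo + w
      gs <- ifelse(s$strand == "+", s$junction + lo, s$junction - hi)
      rows[[b]] <- data.frame(chrom = s$chrom, start = gs, end = gs + w,
                              strand = ".", label = "eclip", score = 1,
                              stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
  }
  peaks <- with_seed(child_seed(config$seed, seed_offset), {
    rbind(gen(sites_g4, p_g4), gen(sites_no_g4, rep(ecfg$p_no_g4, nb)))
  })
  list(peaks = peaks, truth = list(p_g4 = p_g4,
                                   p_no_g4 = rep(ecfg$p_no_g4, nb),
                                   effect_bins = which(eff)))
}

#' Build the full synthetic bundle
#'
#' Genome, annotation, planted G4s, genome-wide motif scan and per-site
#' planting flags — everything needed to exercise the pipeline end to
#' end, deterministic in the master seed.
#'
#' @param seed master seed.
#' @param config optional [synth_config()]; built from `seed` otherwise.
#' @return list: config, genome, models, sites, planted, hits.
#' @export
synth_bundle <- function(seed = 1, config = NULL) {
  config <- config %||% synth_config(seed)
  genome <- generate_genome(config)
  ann <- generate_annotation(genome, config)
  pl <- plant_g4s(ann$genome, ann$sites, config)
  hits <- scan_genome(pl$genome, "g4")
  sites <- ann$sites
  sites$planted <- sites$site_id %in% pl$truth$site_id
  list(config = config, genome = pl$genome, models = ann$models,
       sites = sites, planted = pl$truth, hits = hits)
}
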