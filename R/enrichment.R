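#' Positional metaprofiles around splice-site anchors
#'
#' For every signed offset in transcription orientation around a set of
#' oriented anchors, the profile counts the anchors at which a feature
#' registers at that offset.  In `coverage` mode a position registers when
#' any feature base pair overlaps it; `start` and `midpoint` modes register
#' only the feature's anchor position.  Enrichment is the per-offset count
#' over the median count across a fixed 1 kb normalization window,
#' regardless of the displayed half-width, with Wilson 95\% confidence
#' bands scaled by the same constant.
#'
#' @param sites data.frame with chrom, junction, strand (and site_id).
#' @param features interval data.frame (chrom, start, end).
#' @param W displayed half-width in nt.
#' @param mode `"coverage"`, `"start"` or `"midpoint"`.
#' @param norm_window width of the normalization window (default 1000 nt).
#' @return a `meta_profile` data.frame: offset, count, n, enrichment,
#'   ci_lo, ci_hi; the normalization constant and mode are attributes.
#' @export
positional_profile <- function(sites, features, W = 100,
                               mode = c("coverage", "start", "midpoint"),
                               norm_window = 1000) {
  mode <- match.arg(mode)
  H <- max(W, norm_window %/% 2)
  counts <- offset_presence_counts(sites, features, H, mode)$counts
  offsets <- seq(-H, H - 1L)
  norm_idx <- offsets >= -(norm_window %/% 2) & offsets < norm_window %/% 2
  norm <- median(counts[norm_idx])
  if (is.na(norm) || norm == 0) {
    warning("zero median count; enrichment undefined")
    norm <- NA_real_
  }
  n <- nrow(sites)
  ci <- wilson_ci(counts, n)
  keep <- offsets >= -W & offsets < W
  out <- data.frame(offset = offsets[keep], count = counts[keep], n = n,
                    enrichment = counts[keep] / norm,
                    ci_lo = ci$lower[keep] * n / norm,
                    ci_hi = ci$upper[keep] * n / norm)
  attr(out, "norm_constant") <- norm
  attr(out, "mode") <- mode
  attr(out, "norm_window") <- norm_window
  class(out) <- c("meta_profile", "data.frame")
  out
}

# per-offset site counts (presence of feature signal) over offsets -H..H-1
offset_presence_counts <- function(sites, features, H, mode = "coverage") {
  if (mode != "coverage") {
    anchor <- if (mode == "start") features$start else
      (features$start + features$end) %/% 2L
    features <- data.frame(chrom = features$chrom, start = anchor,
                           end = anchor + 1L)
  }
  pres <- offset_presence_matrix(sites, features, H)
  list(offsets = seq(-H, H - 1L), counts = as.integer(colSums(pres)))
}

#' Stratified metaprofiles
#'
#' One independent profile per level of a stratum column carried on the
#' sites (strength quantile, strand context, exon group, event type, ...).
#' Empty strata are omitted with a message.
#'
#' @param sites splice-site data.frame carrying `stratum_col`.
#' @param features interval data.frame.
#' @param stratum_col name of the column to stratify on.
#' @param ... passed to [positional_profile()].
#' @return named list of `meta_profile` objects with per-stratum n.
#' @export
strata_profiles <- function(sites, features, stratum_col, ...) {
  stopifnot(stratum_col %in% names(sites))
  lv <- unique(sites[[stratum_col]])
  out <- list()
  for (l in lv) {
    s <- sites[sites[[stratum_col]] == l, ]
    if (nrow(s) == 0) {
      message("stratum ", l, " empty; omitted")
      next
    }
    out[[as.character(l)]] <- positional_profile(s, features, ...)
  }
  out
}

#' Signed distance from splice sites to the nearest feature midpoint
#'
#' Distances are signed in transcription orientation (positive =
#' downstream of the junction).  Ties between two equidistant midpoints
#' are broken toward the intronic side of the site.  Sites on chromosomes
#' with no feature get NA.
#'
#' @param sites splice-site data.frame (chrom, junction, strand, kind).
#' @param features interval data.frame.
#' @return numeric vector of signed distances, one per site.
#' @export
nearest_distance <- function(sites, features) {
  res <- rep(NA_real_, nrow(sites))
  mids <- (features$start + features$end) %/% 2L
  for (ch in unique(sites$chrom)) {
    si <- which(sites$chrom == ch)
    m <- sort(mids[features$chrom == ch])
    if (length(m) == 0) next
    for (i in si) {
      j <- sites$junction[i]
      strand <- sites$strand[i]
      d <- if (strand == "+") m - j else j - 1L - m
      a <- abs(d)
      best <- which(a == min(a))
      if (length(best) > 1) {
        # tie: intronic side is upstream (-) for acceptors, downstream (+)
        # for donors
        want_pos <- sites$kind[i] == "donor"
        pref <- best[(d[best] > 0) == want_pos]
        best <- if (length(pref)) pref[1] else best[1]
      }
      res[i] <- d[best[1]]
    }
  }
  res
}

#' Three-way interval overlap summary
#'
#' For each of three interval sets, counts its elements by which of the
#' other sets they intersect (>= 1 bp after symmetric slop).  Reported per
#' set because interval overlap is not an equivalence relation.
#'
#' @param a,b,c interval data.frames.
#' @param slop symmetric extension (bp) applied to the classified element.
#' @param names names for the three sets.
#' @return data.frame with set, region ("only", "+<other>", "+both") and
#'   count.
#' @export
overlap_venn <- function(a, b, c, slop = 0, names = c("A", "B", "C")) {
  gr <- function(x) GenomicRanges::GRanges(
    x$chrom, IRanges::IRanges(x$start + 1L, x$end))
  sets <- list(gr(a), gr(b), gr(c))
  out <- list()
  for (i in 1:3) {
    el <- sets[[i]]
    if (slop > 0) el <- GenomicRanges::GRanges(
      GenomicRanges::seqnames(el),
      IRanges::IRanges(pmax(GenomicRanges::start(el) - slop, 1L),
                       GenomicRanges::end(el) + slop))
    others <- setdiff(1:3, i)
    hit1 <- GenomicRanges::countOverlaps(el, sets[[others[1]]]) > 0
    hit2 <- GenomicRanges::countOverlaps(el, sets[[others[2]]]) > 0
    region <- ifelse(hit1 & hit2, "both",
                     ifelse(hit1, names[others[1]],
                            ifelse(hit2, names[others[2]], "only")))
    tab <- table(factor(region, levels = c("only", names[others[1]],
                                           names[others[2]], "both")))
    out[[i]] <- data.frame(set = names[i], region = names(tab),
                           count = as.integer(tab))
  }
  do.call(rbind, out)
}

#' Feature density around splice sites with bootstrap SD
#'
#' Density is the total number of feature occurrences inside the windows
#' (junction +/- flank) over the total window base pairs.  The SD comes
#' from resampling sites with replacement.
#'
#' @param sites splice-site data.frame.
#' @param features interval data.frame.
#' @param flank half-width of the window (nt).
#' @param n_boot bootstrap resamples (default 1000).
#' @param seed optional RNG seed.
#' @param chrom_len optional chromosome lengths for clipping.
#' @return list: density, sd, n_boot, n_sites, per_site counts.
#' @export
density_with_bootstrap <- function(sites, features, flank = 100,
                                   n_boot = 1000, seed = NULL,
                                   chrom_len = NULL) {
  stopifnot(nrow(sites) >= 2)
  ws <- pmax(sites$junction - flank, 0L)
  we <- sites$junction + flank
  if (!is.null(chrom_len)) we <- pmin(we, unname(chrom_len[sites$chrom]))
  win <- GenomicRanges::GRanges(sites$chrom, IRanges::IRanges(ws + 1L, we))
  fgr <- GenomicRanges::GRanges(features$chrom,
                                IRanges::IRanges(features$start + 1L,
                                                 features$end))
  cnt <- GenomicRanges::countOverlaps(win, fgr)
  bp <- we - ws
  boot <- with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      idx <- sample.int(length(cnt), replace = TRUE)
      sum(cnt[idx]) / sum(bp[idx])
    }, numeric(1))
  })
  list(density = sum(cnt) / sum(bp), sd = stats::sd(boot), n_boot = n_boot,
       n_sites = nrow(sites), per_site = cnt)
}

#' Export a metaprofile as TSV
#' @param profile a `meta_profile` (or named list of them).
#' @param path output file.
#' @export
write_profile <- function(profile, path) {
  if (!is.data.frame(profile)) {
    profile <- do.call(rbind, lapply(names(profile), function(nm) {
      p <- profile[[nm]]
      p$stratum <- nm
      p
    }))
  }
  write.table(profile, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
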