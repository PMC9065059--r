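#' Binned eCLIP differential-binding profile for one factor
#'
#' Splice-site regions are cut into fixed-width bins (10 bp by default,
#' transcription orientation).  For each bin the binding fraction is the
#' share of sites in a group whose bin window overlaps at least one peak
#' base pair; the differential value is fraction(G4-flanked group) minus
#' fraction(non-flanked group).  Each bin gets a 2x2 chi-squared test
#' (bound/unbound x group) with Bonferroni correction over the profile's
#' bins; non-significant differentials are set to zero by
#' [mask_profile()].
#'
#' @param sites_g4,sites_no_g4 disjoint splice-site groups.
#' @param peaks peak interval data.frame for one factor/replicate.
#' @param region c(lo, hi) offsets around the junction (default -100..100).
#' @param w bin width in bp (default 10).
#' @param alpha significance level after Bonferroni (default 0.05).
#' @return a `factor_profile` data.frame: bin_start, bin_end, frac_g4,
#'   frac_no_g4, differential, p, p_adj, significant, masked; attribute
#'   `low_power` when either group has < 20 sites.
#' @export
binned_binding_enrichment <- function(sites_g4, sites_no_g4, peaks,
                                      region = c(-100, 100), w = 10,
                                      alpha = 0.05) {
  stopifnot((region[2] - region[1]) %% w == 0)
  nb <- (region[2] - region[1]) %/% w
  bin_start <- seq(region[1], region[2] - w, by = w)
  bound_frac <- function(sites) {
    n <- nrow(sites)
    if (n == 0) return(list(frac = rep(NA_real_, nb), bound = rep(0L, nb),
                            n = 0L))
    H <- max(abs(region))
    pres <- offset_presence_matrix(sites, peaks, H)
    off <- seq(-H, H - 1L)
    bound <- integer(nb)
    for (b in seq_len(nb)) {
      cols <- off >= bin_start[b] & off < bin_start[b] + w
      bound[b] <- sum(rowSums(pres[, cols, drop = FALSE]) > 0)
    }
    list(frac = bound / n, bound = bound, n = n)
  }
  g <- bound_frac(sites_g4)
  ng <- bound_frac(sites_no_g4)
  p <- vapply(seq_len(nb), function(b) {
    m <- matrix(c(g$bound[b], g$n - g$bound[b],
                  ng$bound[b], ng$n - ng$bound[b]), 2, 2, byrow = TRUE)
    if (any(rowSums(m) == 0) || any(colSums(m) == 0)) return(NA_real_)
    suppressWarnings(chisq.test(m, correct = TRUE)$p.value)
  }, numeric(1))
  p_adj <- pmin(1, p * nb)
  out <- data.frame(bin_start = bin_start, bin_end = bin_start + w,
                    frac_g4 = g$frac, frac_no_g4 = ng$frac,
                    differential = g$frac - ng$frac, p = p, p_adj = p_adj,
                    significant = !is.na(p_adj) & p_adj < alpha)
  out$masked <- ifelse(out$significant, out$differential, 0)
  attr(out, "low_power") <- g$n < 20 || ng$n < 20
  attr(out, "n_g4") <- g$n
  attr(out, "n_no_g4") <- ng$n
  class(out) <- c("factor_profile", "data.frame")
  out
}

# per-site x per-offset presence matrix (shared with the metaprofile path)
offset_presence_matrix <- function(sites, features, H) {
  pres <- matrix(0L, nrow(sites), 2L * H)
  for (ch in unique(sites$chrom)) {
    rows <- which(sites$chrom == ch)
    s <- sites[rows, ]
    f <- features[features$chrom == ch, , drop = FALSE]
    maxpos <- max(s$junction) + H + 1L
    f <- f[f$start < maxpos & f$end > 0, , drop = FALSE]
    cov <- integer(maxpos)
    if (nrow(f)) {
      ir <- IRanges::IRanges(pmax(f$start + 1L, 1L), pmin(f$end, maxpos))
      cov <- as.integer(IRanges::coverage(ir, width = maxpos))
    }
    idx <- outer(s$junction - H, 0:(2L * H - 1L), "+") + 1L
    ok <- idx >= 1L & idx <= maxpos
    m <- matrix(0L, nrow(s), 2L * H)
    m[ok] <- as.integer(cov[idx[ok]] > 0L)
    minus <- s$strand == "-"
    if (any(minus)) m[minus, ] <- m[minus, rev(seq_len(2L * H)),
                                    drop = FALSE]
    pres[rows, ] <- m
  }
  pres
}

#' Zero out non-significant differential bins
#'
#' Idempotent: masking a masked profile changes nothing.
#'
#' @param profile a `factor_profile`.
#' @return the profile with `masked` = differential where significant,
#'   else 0.
#' @export
mask_profile <- function(profile) {
  profile$masked <- ifelse(profile$significant, profile$differential, 0)
  profile
}

#' Ward clustering of masked differential-binding profiles
#'
#' Profiles (concatenated non-template and template masked tracks) are
#' clustered with Ward's method (`hclust`, "ward.D2") on Euclidean
#' distance and cut at k clusters.  Rows are ordered by profile id before
#' clustering so the assignment does not depend on input order; missing
#' values are imputed as 0.
#'
#' @param profiles named list of numeric vectors, or a numeric matrix with
#'   rownames (one row per profile).
#' @param k number of clusters (default 10).
#' @return data.frame (profile_id, cluster); the `hclust` object is
#'   attached as attribute `tree`.
#' @export
mask_and_cluster <- function(profiles, k = 10) {
  if (is.list(profiles)) profiles <- do.call(rbind, profiles)
  if (is.null(rownames(profiles)))
    rownames(profiles) <- paste0("profile", seq_len(nrow(profiles)))
  if (nrow(profiles) < k)
    stop_ctx("fewer profiles (", nrow(profiles), ") than clusters (", k, ")")
  profiles <- profiles[order(rownames(profiles)), , drop = FALSE]
  profiles[is.na(profiles)] <- 0
  tree <- hclust(dist(profiles, method = "euclidean"), method = "ward.D2")
  cl <- cutree(tree, k = k)
  out <- data.frame(profile_id = rownames(profiles),
                    cluster = as.integer(cl), stringsAsFactors = FALSE)
  attr(out, "tree") <- tree
  out
}

#' High-confidence factors concordant between eCLIP and LoF splicing
#'
#' A factor qualifies when (i) it has a significant eCLIP differential
#' profile and a significant loss-of-function splicing association
#' (Bonferroni-adjusted p < alpha) in the same cell line, and (ii) at
#' least `min_replicates` of its eCLIP replicates fall in the same
#' cluster.
#'
#' @param eclip data.frame: factor, cell_line, replicate, profile_id,
#'   significant (any significant bin).
#' @param lof data.frame: factor, cell_line, log_or, p_adj.
#' @param clusters data.frame from [mask_and_cluster()].
#' @param min_replicates minimum co-clustered replicates (default 2).
#' @param alpha LoF significance level (default 0.05).
#' @return data.frame of high-confidence factors: factor, cell_line,
#'   n_coclustered, lof_log_or, lof_direction.
#' @export
lof_concordance <- function(eclip, lof, clusters, min_replicates = 2,
                            alpha = 0.05) {
  eclip$cluster <- clusters$cluster[match(eclip$profile_id,
                                          clusters$profile_id)]
  out <- list()
  for (f in unique(eclip$factor)) {
    ef <- eclip[eclip$factor == f, ]
    # replicate consistency: largest set of replicates sharing a cluster
    n_co <- max(table(ef$cluster[!is.na(ef$cluster)]), 0)
    if (n_co < min_replicates) next
    for (cl_line in unique(ef$cell_line)) {
      sig_e <- any(ef$significant[ef$cell_line == cl_line])
      lf <- lof[lof$factor == f & lof$cell_line == cl_line, ]
      sig_l <- nrow(lf) > 0 && any(lf$p_adj < alpha)
      if (sig_e && sig_l) {
        best <- lf[which.min(lf$p_adj), ]
        out[[length(out) + 1L]] <- data.frame(
          factor = f, cell_line = cl_line, n_coclustered = n_co,
          lof_log_or = best$log_or,
          lof_direction = ifelse(best$log_or >= 0, "positive", "negative"),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0)
    return(data.frame(factor = character(), cell_line = character(),
                      n_coclustered = integer(), lof_log_or = numeric(),
                      lof_direction = character(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}
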