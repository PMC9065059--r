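test_that("a feature planted at fixed offsets produces a clean spike", {
  sites <- fake_sites(200)
  feats <- data.frame(chrom = "chr1",
                      start = ifelse(sites$strand == "+",
                                     sites$junction + 40L,
                                     sites$junction - 60L),
                      end = ifelse(sites$strand == "+",
                                   sites$junction + 60L,
                                   sites$junction - 40L))
  pr <- suppressWarnings(positional_profile(sites, feats, W = 100))
  spike <- pr$offset >= 40 & pr$offset < 60
  expect_true(all(pr$count[spike] == 200))
  expect_true(all(pr$count[!spike] == 0))
  # with no off-spike signal the median normalizer is zero by construction
  expect_true(all(is.na(pr$enrichment)))

  # adding uniform background makes the spike quantifiable
  set.seed(2)
  pos <- sample.int(max(sites$junction) + 1000L, 20000)
  bg <- data.frame(chrom = "chr1", start = pos, end = pos + 1L)
  pr2 <- positional_profile(sites, rbind(feats, bg), W = 100)
  expect_gt(min(pr2$enrichment[spike]), 5 * max(pr2$enrichment[!spike]))
  ok <- pr2$count > 0
  expect_true(all(pr2$ci_lo[ok] <= pr2$enrichment[ok] &
                    pr2$enrichment[ok] <= pr2$ci_hi[ok]))
})

test_that("uniformly placed features give enrichment about 1 everywhere", {
  set.seed(31)
  sites <- fake_sites(4000, spacing = 1200L)
  n_feat <- 60000
  pos <- sample.int(max(sites$junction) + 1000L, n_feat)
  feats <- data.frame(chrom = "chr1", start = pos, end = pos + 1L)
  pr <- positional_profile(sites, feats, W = 100)
  expect_true(all(abs(pr$enrichment - 1) < 0.35))
  expect_lt(abs(mean(pr$enrichment) - 1), 0.05)
})

test_that("median normalization is idempotent and tied to the 1 kb window", {
  sites <- fake_sites(50)
  set.seed(7)
  pos <- sample.int(max(sites$junction) + 500L, 5000)
  feats <- data.frame(chrom = "chr1", start = pos, end = pos + 2L)
  pr <- positional_profile(sites, feats, W = 100, norm_window = 1000)
  # re-normalizing the enrichment track by its own median (over the same
  # window it was normalized on) changes nothing: the median there is 1
  full <- positional_profile(sites, feats, W = 500, norm_window = 1000)
  expect_equal(median(full$enrichment), 1)
  expect_equal(pr$enrichment, full$enrichment[full$offset >= -100 &
                                                full$offset < 100])
})

test_that("strata profiles split by label and match the single profile", {
  sites <- fake_sites(80)
  sites$grp <- "all"
  feats <- data.frame(chrom = "chr1", start = sites$junction + 10L,
                      end = sites$junction + 20L)
  one <- suppressWarnings(strata_profiles(sites, feats, "grp", W = 50))
  expect_named(one, "all")
  expect_equal(one$all$count,
               suppressWarnings(positional_profile(sites, feats,
                                                   W = 50))$count)
})

test_that("nearest distances match a quadratic all-pairs oracle", {
  site <- data.frame(site_id = "s", kind = "acceptor", chrom = "c1",
                     junction = 100L, strand = "+",
                     stringsAsFactors = FALSE)
  feat <- data.frame(chrom = "c1", start = 140L, end = 160L)
  expect_equal(nearest_distance(site, feat), 50)

  set.seed(17)
  for (rep in 1:30) {
    ns <- 20
    nf <- 15
    sites <- data.frame(site_id = paste0("s", 1:ns),
                        kind = sample(c("acceptor", "donor"), ns, TRUE),
                        chrom = "c1",
                        junction = sample.int(5000, ns),
                        strand = sample(c("+", "-"), ns, TRUE),
                        stringsAsFactors = FALSE)
    fs <- sample.int(5000, nf)
    feats <- data.frame(chrom = "c1", start = fs, end = fs + sample.int(30, nf))
    got <- nearest_distance(sites, feats)
    mids <- (feats$start + feats$end) %/% 2L
    for (i in 1:ns) {
      d <- if (sites$strand[i] == "+") mids - sites$junction[i] else
        sites$junction[i] - 1L - mids
      expect_equal(abs(got[i]), min(abs(d)))
    }
  }
  # missing chromosome yields NA
  expect_true(is.na(nearest_distance(
    data.frame(site_id = "x", kind = "donor", chrom = "cX", junction = 5L,
               strand = "+", stringsAsFactors = FALSE), feat)))
})

test_that("nearest-distance ties break toward the intronic side", {
  feats <- data.frame(chrom = "c1", start = c(79L, 119L), end = c(82L, 122L))
  # midpoints 80 and 120, both 20 bp from junction 100
  acc <- data.frame(site_id = "a", kind = "acceptor", chrom = "c1",
                    junction = 100L, strand = "+", stringsAsFactors = FALSE)
  don <- data.frame(site_id = "d", kind = "donor", chrom = "c1",
                    junction = 100L, strand = "+", stringsAsFactors = FALSE)
  expect_equal(nearest_distance(acc, feats), -20)   # intron upstream
  expect_equal(nearest_distance(don, feats), 20)    # intron downstream
})

test_that("three-way overlap counts match expectations", {
  mk <- function(starts) data.frame(chrom = "c1", start = starts,
                                    end = starts + 10L)
  v <- overlap_venn(mk(c(0, 100)), mk(c(300, 400)), mk(c(600, 700)))
  expect_true(all(v$count[v$region == "only"] == 2))
  expect_true(all(v$count[v$region != "only"] == 0))

  same <- mk(c(0, 50, 90))
  v2 <- overlap_venn(same, same, same)
  expect_true(all(v2$count[v2$region == "both"] == 3))

  set.seed(23)
  for (rep in 1:20) {
    a <- mk(sample.int(500, 8)); b <- mk(sample.int(500, 8))
    c_ <- mk(sample.int(500, 8))
    v3 <- overlap_venn(a, b, c_)
    ov <- function(x, y) vapply(seq_len(nrow(x)), function(i)
      any(x$start[i] < y$end & y$start < x$end[i]), logical(1))
    inB <- ov(a, b); inC <- ov(a, c_)
    expect_equal(v3$count[v3$set == "A" & v3$region == "only"],
                 sum(!inB & !inC))
    expect_equal(v3$count[v3$set == "A" & v3$region == "both"],
                 sum(inB & inC))
  }
})

test_that("window density and its bootstrap behave as expected", {
  sites <- fake_sites(40)
  feats <- data.frame(chrom = "chr1", start = sites$junction - 5L,
                      end = sites$junction + 5L)
  d <- density_with_bootstrap(sites, feats, flank = 100, n_boot = 200,
                              seed = 1)
  expect_equal(d$density, 1 / 200)
  expect_equal(density_with_bootstrap(sites, feats, flank = 100,
                                      n_boot = 200, seed = 1)$sd, d$sd)

  dup <- rbind(sites, transform(sites, site_id = paste0(site_id, "b")))
  d2 <- density_with_bootstrap(dup, feats, flank = 100, n_boot = 200,
                               seed = 2)
  expect_equal(d2$density, d$density)
  expect_lt(d2$sd, d$sd + 1e-12)

  # SD shrinks with the number of sites at fixed density
  sds <- vapply(c(25, 100, 400), function(n) {
    s <- fake_sites(n)
    f <- data.frame(chrom = "chr1", start = s$junction - 5L,
                    end = s$junction + 5L)
    set.seed(3)
    keep <- runif(n) < 0.5
    density_with_bootstrap(s, f[keep, ], flank = 100, n_boot = 300,
                           seed = 4)$sd
  }, numeric(1))
  expect_true(sds[1] > sds[2] && sds[2] > sds[3])
})
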