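mk_psi <- function(delta_psi, probability, type = "CE") {
  n <- length(delta_psi)
  data.frame(gene = paste0("g", seq_len(n)), node = paste0("n", seq_len(n)),
             chrom = "c1", start = 1000L * seq_len(n),
             end = 1000L * seq_len(n) + 100L, strand = "+", type = type,
             psi_a = 0.5, psi_b = 0.5 + delta_psi, delta_psi = delta_psi,
             probability = probability, stringsAsFactors = FALSE)
}

test_that("node classification applies inclusive thresholds and direction", {
  psi <- mk_psi(c(-0.177, 0.05, 0.10, -0.09), c(0.95, 0.99, 0.90, 0.95))
  cl <- classify_nodes(psi)
  expect_equal(cl$differential, c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(cl$direction, c("excluded", "none", "included", "none"))
  expect_error(classify_nodes(mk_psi(1.5, 0.95)), "outside")
})

test_that("G4 association uses the nearer boundary and midpoint distances", {
  psi <- classify_nodes(mk_psi(c(-0.2, -0.2), c(0.95, 0.95)))
  psi$start <- c(1000L, 5000L)
  psi$end <- c(1100L, 5100L)
  hits <- data.frame(chrom = "c1", start = c(1080L, 5201L),
                     end = c(1100L, 5203L), strand = "+")
  # midpoints 1090 (within 100 of boundary 1000) and 5202 (102 from 5100)
  lab <- label_g4_association(psi, hits)
  expect_equal(lab$g4_associated, c(TRUE, FALSE))

  peaks <- data.frame(chrom = "c1", start = 5140L, end = 5150L)
  lab2 <- label_g4_association(psi, hits, peaks)   # 45 bp from 5100
  expect_equal(lab2$g4_associated, c(TRUE, TRUE))
})

test_that("association labels match a brute-force all-pairs check", {
  set.seed(61)
  for (rep in 1:20) {
    n <- 40
    psi <- classify_nodes(mk_psi(runif(n, -0.5, 0.5), runif(n)))
    psi$chrom <- sample(c("c1", "c2"), n, TRUE)
    psi$start <- sample.int(50000, n)
    psi$end <- psi$start + sample.int(300, n)
    hs <- sample.int(50000, 25)
    hits <- data.frame(chrom = sample(c("c1", "c2"), 25, TRUE),
                       start = hs, end = hs + sample.int(40, 25),
                       strand = "+")
    got <- label_g4_association(psi, hits)$g4_associated
    mids <- (hits$start + hits$end) %/% 2L
    want <- vapply(seq_len(n), function(i) {
      m <- mids[hits$chrom == psi$chrom[i]]
      if (!length(m)) return(FALSE)
      min(abs(m - psi$start[i]), abs(m - psi$end[i])) <= 100
    }, logical(1))
    expect_equal(got, want)
  }
  # shuffling input chromosome order never changes the labels
  psi <- classify_nodes(mk_psi(runif(30, -0.5, 0.5), runif(30)))
  psi$start <- sample.int(30000, 30)
  psi$end <- psi$start + 50L
  hs <- sample.int(30000, 20)
  hits <- data.frame(chrom = "c1", start = hs, end = hs + 20L, strand = "+")
  a <- label_g4_association(psi, hits)$g4_associated
  b <- label_g4_association(psi, hits[sample.int(20), ])$g4_associated
  expect_equal(a, b)
})

test_that("odds ratio arithmetic, Haldane correction and Yates chi-squared", {
  r <- assoc_2x2(10, 5, 2, 8)
  expect_equal(r$odds_ratio, 8)
  expect_false(r$haldane)
  # independent check of the Yates statistic
  m <- matrix(c(10, 5, 2, 8), 2, 2, byrow = TRUE)
  expect_equal(r$chisq, unname(suppressWarnings(
    chisq.test(m, correct = TRUE))$statistic))
  e <- outer(rowSums(m), colSums(m)) / sum(m)
  yates <- sum((abs(m - e) - 0.5)^2 / e)
  expect_equal(r$chisq, yates, tolerance = 1e-12)

  r0 <- assoc_2x2(0, 5, 2, 8)
  expect_true(r0$haldane)
  expect_equal(r0$odds_ratio, (0.5 * 8.5) / (5.5 * 2.5))
})

test_that("per-stratum tests report Bonferroni over testable strata", {
  set.seed(71)
  psi <- classify_nodes(mk_psi(runif(400, -0.5, 0.5), runif(400),
                               type = sample(c("CE", "RI"), 400, TRUE)))
  psi$g4_associated <- runif(400) < 0.4
  at <- association_test(psi)
  expect_equal(nrow(at), 4)              # 2 types x 2 directions
  expect_equal(unique(at$m), sum(at$testable))
  expect_equal(at$p_adj, pmin(1, at$p * at$m))
  # pooled stratum
  any_dir <- association_test(psi, directions = "any")
  expect_equal(any_dir$a + any_dir$c,
               tapply(psi$differential, psi$type, sum)[any_dir$type],
               ignore_attr = TRUE)
})

test_that("untestable strata are flagged, not silently dropped", {
  psi <- classify_nodes(mk_psi(rep(0.01, 20), rep(0.5, 20)))
  psi$g4_associated <- FALSE
  at <- association_test(psi)
  expect_true(all(!at$testable))
  expect_true(all(is.na(at$p)))
})

test_that("GC matching pairs closest values and enforces the tolerance", {
  gc <- seq(0.3, 0.6, length.out = 40)
  m <- gc_matched_controls(gc, gc, tol = 0.01, seed = 1)
  expect_equal(nrow(m), 40)
  expect_true(all(abs(m$gc_short - m$gc_long) == 0))

  expect_error(gc_matched_controls(runif(30, 0.2, 0.3),
                                   runif(30, 0.6, 0.7), tol = 0.01,
                                   seed = 1), "GC-matched pairs")

  # matched groups have indistinguishable GC distributions
  set.seed(81)
  short <- rnorm(300, 0.45, 0.05)
  long <- rnorm(600, 0.5, 0.07)
  mm <- gc_matched_controls(short, long, tol = 0.01, seed = 2)
  expect_gt(suppressWarnings(ks.test(mm$gc_short, mm$gc_long))$p.value, 0.05)
})

test_that("length comparisons recover medians and test group differences", {
  lc <- length_comparisons(c(rep(500, 50), rep(1500, 50)),
                           rep(c(TRUE, FALSE), each = 50))
  expect_equal(lc$summary$median[lc$summary$group == "g4"], 500)
  expect_equal(lc$summary$median[lc$summary$group == "no_g4"], 1500)

  set.seed(91)
  same <- rlnorm(200, log(1000), 1)
  lc2 <- length_comparisons(c(same, same), rep(c(TRUE, FALSE), each = 200))
  expect_gt(lc2$tests$mwu_p, 0.9)
})

test_that("adjusted sQTL enrichment is flat under uniform variants and
           scale-invariant", {
  sites <- fake_sites(200, spacing = 2500L, start_at = 3000L)
  set.seed(101)
  # G4 intervals scattered across the +/-500 windows
  gs <- unlist(lapply(sites$junction, function(j) j + sample(-480:460, 8)))
  hits <- data.frame(chrom = "chr1", start = gs, end = gs + 20L,
                     strand = "+")
  pool <- unique(unlist(lapply(sites$junction, function(j)
    (j - 500L):(j + 499L))))
  sq <- data.frame(chrom = "chr1", pos = sample(pool, 8000), class = "sqtl")
  sn <- data.frame(chrom = "chr1", pos = sample(pool, 8000), class = "snp")
  tr <- sqtl_adjusted_enrichment(hits, sq, sn, sites)
  expect_equal(nrow(tr), 40)
  ok <- !is.na(tr$adjusted)
  expect_gt(sum(ok), 30)
  expect_lt(abs(mean(tr$adjusted[ok]) - 1), 0.25)

  dbl <- sqtl_adjusted_enrichment(hits, rbind(sq, sq), rbind(sn, sn), sites)
  expect_equal(dbl$adjusted, tr$adjusted)
  expect_equal(dbl$e_sqtl, tr$e_sqtl)
})
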