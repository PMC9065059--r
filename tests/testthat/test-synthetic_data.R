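test_that("genome generation hits dinucleotide targets and is deterministic", {
  cfg <- synth_config(3, genome = list(n_chroms = 1L, chrom_len = 1000000L,
                                       gc = 0.5, cpg_factor = 1))
  g <- generate_genome(cfg)
  s <- unclass(g)[[1]]
  dn <- dinuc_counts(s)
  freq <- dn / sum(dn)
  expect_true(all(abs(freq - 1 / 16) < 0.02))

  cfg2 <- synth_config(3, genome = list(n_chroms = 1L, chrom_len = 500000L,
                                        gc = 0.6, cpg_factor = 1))
  g2 <- unclass(generate_genome(cfg2))[[1]]
  gc_obs <- mean(strsplit(g2, "")[[1]] %in% c("G", "C"))
  expect_lt(abs(gc_obs - 0.6), 0.02)

  expect_identical(unclass(generate_genome(cfg)),
                   unclass(generate_genome(cfg)))
  bad <- synth_config(1, genome = list(transition = matrix(-1, 4, 4)))
  expect_error(generate_genome(bad), "degenerate")
})

test_that("annotation is placeable, GT-AG forced, junction count as designed", {
  cfg <- synth_config(5, genes = list(n = 40, exon_count = 5L))
  g <- generate_genome(cfg)
  ann <- generate_annotation(g, cfg)
  # 5 exons -> 3 internal exons -> 6 sites per gene before dedup
  expect_equal(nrow(ann$sites), 40 * 6)
  expect_true(all(ann$sites$canonical))
  ok <- intron_is_canonical(ann$genome, ann$sites$chrom,
                            ann$sites$intron_start, ann$sites$intron_end,
                            ann$sites$strand)
  expect_true(all(ok))
  too_many <- synth_config(5, genes = list(n = 100000L))
  expect_error(generate_annotation(g, too_many), "cannot place")
})

test_that("full-rate planting at a fixed offset is fully recovered by scanning", {
  cfg <- synth_config(9, genes = list(n = 30),
                      plant = list(rate = 1, offset_mean = 50, offset_sd = 0,
                                   nontemplate_prob = 1))
  g <- generate_genome(cfg)
  ann <- generate_annotation(g, cfg)
  pl <- plant_g4s(ann$genome, ann$sites, cfg)
  hits <- scan_genome(pl$genome, "g4")
  key_t <- paste(pl$truth$chrom, pl$truth$start, pl$truth$end,
                 pl$truth$strand)
  key_h <- paste(hits$chrom, hits$start, hits$end, hits$strand)
  expect_true(all(key_t %in% key_h))
  expect_gt(nrow(pl$truth) / nrow(ann$sites), 0.9)  # nearly all placeable
  expect_true(all(pl$truth$offset == 50))
  # non-template only: motif strand always equals the gene strand
  ctx <- classify_strand_context(
    pl$truth$strand,
    ann$sites$strand[match(pl$truth$site_id, ann$sites$site_id)])
  expect_true(all(ctx == "non_template"))
})

test_that("rate zero plants nothing and leaves only background hits", {
  cfg <- synth_config(15, genes = list(n = 20), plant = list(rate = 0))
  g <- generate_genome(cfg)
  ann <- generate_annotation(g, cfg)
  pl <- plant_g4s(ann$genome, ann$sites, cfg)
  expect_equal(nrow(pl$truth), 0)
  expect_identical(unclass(pl$genome), unclass(ann$genome))
})

test_that("the planted strand-context ratio is realised near its target", {
  b <- synth_bundle(19, synth_config(19, genes = list(n = 150)))
  n <- nrow(b$planted)
  p_hat <- mean(b$planted$context == "non_template")
  ci <- wilson_ci(sum(b$planted$context == "non_template"), n)
  expect_true(ci$lower <= 2 / 3 && 2 / 3 <= ci$upper)
})

test_that("PSI generation respects thresholds and the null odds ratio", {
  nodes <- data.frame(gene = paste0("g", 1:2000),
                      node = paste0("n", 1:2000), chrom = "c1",
                      start = 1000L * (1:2000), end = 1000L * (1:2000) + 100L,
                      strand = "+", type = "CE", stringsAsFactors = FALSE)
  set.seed(23)
  g4 <- runif(2000) < 0.3
  cfg <- synth_config(23, psi = list(odds_ratio = 1.0))
  out <- generate_psi_table(nodes, g4, cfg)
  cl <- classify_nodes(out$psi)
  # classification reproduces the generator's own differential draws
  expect_true(all(cl$differential == (abs(out$psi$delta_psi) >= 0.1 &
                                        out$psi$probability >= 0.9)))
  cl$g4_associated <- g4
  at <- association_test(cl, directions = "any")
  expect_lt(abs(at$log_or), 2 * at$log_or_se)   # null OR recovered

  all_flat <- generate_psi_table(nodes, g4,
                                 synth_config(29, psi = list(base_rate = 1e-9)))
  cl2 <- classify_nodes(all_flat$psi)
  cl2$g4_associated <- g4
  expect_false(any(association_test(cl2, directions = "any")$testable))
})

test_that("variant generation plants the uplift only inside near-junction G4s", {
  sites <- fake_sites(300, spacing = 3000L, start_at = 5000L)
  # one G4 interval per site at +50, another far outside the uplift zone
  hits <- data.frame(chrom = "chr1",
                     start = c(sites$junction + 50L, sites$junction + 400L),
                     end = c(sites$junction + 80L, sites$junction + 430L),
                     strand = "+")
  cfg <- synth_config(31, variants = list(snp_rate = 0.05, sqtl_rate = 0.05,
                                          sqtl_uplift = 3.0))
  v <- generate_variants(sites, hits, cfg)
  near <- unlist(lapply(sites$junction, function(j) (j + 50L):(j + 79L)))
  far <- unlist(lapply(sites$junction, function(j) (j + 400L):(j + 429L)))
  rate_near <- sum(v$sqtls$pos %in% near) / length(near)
  rate_far <- sum(v$sqtls$pos %in% far) / length(far)
  expect_gt(rate_near / rate_far, 2)
  snp_near <- sum(v$snps$pos %in% near) / length(near)
  snp_far <- sum(v$snps$pos %in% far) / length(far)
  expect_lt(abs(snp_near / snp_far - 1), 0.3)
})

test_that("peak generation tracks the overlap probability", {
  b <- synth_bundle(37, synth_config(37, genes = list(n = 60)))
  pk <- generate_peaks(b$hits, b$config)
  frac <- nrow(pk) / nrow(b$hits)
  ci <- wilson_ci(nrow(pk), nrow(b$hits))
  expect_true(ci$lower <= 0.8 && 0.8 <= ci$upper)
  v <- overlap_venn(b$hits, pk, pk)
  both <- v$count[v$set == "A" & v$region == "both"]
  expect_equal(both / nrow(b$hits), frac, tolerance = 0.1)
})

test_that("the bundle is fully deterministic in the master seed", {
  b1 <- synth_bundle(41, synth_config(41, genes = list(n = 15)))
  b2 <- synth_bundle(41, synth_config(41, genes = list(n = 15)))
  expect_identical(unclass(b1$genome), unclass(b2$genome))
  expect_identical(b1$hits, b2$hits)
  expect_identical(b1$planted, b2$planted)
  expect_identical(b1$sites, b2$sites)
})
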