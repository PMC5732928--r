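test_that("Jost's D is ~0 for identical samples and ~1 for fixed demes", {
  # identical samples: the sample-size corrections leave a small negative
  # bias of order 1/n, vanishing with sample size
  a <- matrix(rep(c(rep(1L, 20), rep(2L, 10)), 2), ncol = 1)
  g <- genotype_matrix(a, a)
  md <- sample_metadata(g$ids, rep(c("A", "B"), each = 30))
  expect_lt(abs(jost_dest(g, md)$overall), 0.02)
  # two large demes fixed for different alleles
  b1 <- matrix(c(rep(1L, 30), rep(2L, 30)), ncol = 1)
  g2 <- genotype_matrix(b1, b1)
  md2 <- sample_metadata(g2$ids, rep(c("A", "B"), each = 30))
  expect_gt(jost_dest(g2, md2)$overall, 0.99)
})

test_that("Jost's D matches an independently coded formula oracle", {
  # 2 demes, 1 locus, freqs (0.7,0.3) vs (0.3,0.7), n = 10 each
  a <- matrix(c(rep(1L, 7), rep(2L, 3), rep(1L, 3), rep(2L, 7)), ncol = 1)
  g <- genotype_matrix(a, a)
  md <- sample_metadata(g$ids, rep(c("A", "B"), each = 10))
  D <- jost_dest(g, md)$overall
  # oracle written straight from the estimator definition
  nh <- 10
  hs <- (2 * nh / (2 * nh - 1)) *
    (1 - mean(c(0.7^2 + 0.3^2, 0.3^2 + 0.7^2)))
  ht <- 1 - (0.5^2 + 0.5^2) + hs / (2 * nh * 2)
  oracle <- (ht - hs) / (1 - hs) * 2 / (2 - 1)
  expect_equal(D, oracle, tolerance = 1e-12)
})

test_that("D is invariant to population label order", {
  sp <- sim_structured_pops(3, 8, 0.5, 4, n_loci = 5, seed = 16)
  d1 <- jost_dest(sp$genotypes, sp$metadata,
                  populations = c("deme1", "deme2", "deme3"))$overall
  d2 <- jost_dest(sp$genotypes, sp$metadata,
                  populations = c("deme3", "deme1", "deme2"))$overall
  expect_equal(d1, d2, tolerance = 1e-12)
})

test_that("Hs = 1 loci are skipped with a warning", {
  # every individual a distinct heterozygote: Hs estimate can hit 1
  a1 <- matrix(c(1L, 3L, 5L, 7L), ncol = 1)
  a2 <- matrix(c(2L, 4L, 6L, 8L), ncol = 1)
  g <- genotype_matrix(a1, a2)
  md <- sample_metadata(g$ids, c("A", "A", "B", "B"))
  expect_warning(res <- jost_dest(g, md), "skipped")
  expect_true(is.na(res$per_locus[1]))
})

test_that("bootstrap significance finds structure and respects the floor", {
  sp <- sim_structured_pops(2, 12, 0.8, 4, n_loci = 8, seed = 17)
  res <- dest_significance(sp$genotypes, sp$metadata, n_bootstrap = 99,
                           seed = 1)
  expect_equal(res$p, 1 / 100)   # strongly diverged demes sit at the floor
  expect_error(dest_significance(sp$genotypes, sp$metadata,
                                 n_bootstrap = 50), ">= 99")
})

test_that("D significance is calibrated on panmictic data", {
  set.seed(24)
  ps <- replicate(40, {
    sp <- sim_structured_pops(2, 10, 0, 4, n_loci = 5)
    dest_significance(sp$genotypes, sp$metadata, n_bootstrap = 99)$p
  })
  expect_lt(mean(ps < 0.05), 0.05 + 2 * sqrt(0.05 * 0.95 / 40) + 0.03)
})

test_that("phi_ST is 1 for fixed haplotype differences and symmetric", {
  aln <- haplotype_alignment(c(a = "AAAA", b = "AAAA", c = "TTTA",
                               d = "TTTA"))
  md <- sample_metadata(c("a", "b", "c", "d"), c("P", "P", "Q", "Q"))
  res <- amova_phist(aln, md, n_perm = 99, seed = 1)
  expect_equal(res$phi_st, 1)
  expect_equal(res$sigma_within, 0)
})

test_that("AMOVA components match a brute-force SSD oracle", {
  aln <- haplotype_alignment(c(s1 = "AATTGG", s2 = "AATTGC", s3 = "AATACC",
                               s4 = "CCTACC", s5 = "CCTAGC", s6 = "CATAGC"))
  md <- sample_metadata(paste0("s", 1:6), rep(c("P", "Q"), each = 3))
  res <- amova_phist(aln, md, n_perm = 0)
  # oracle: direct sums of squared deviations from the distance matrix
  seqs <- aln$seq
  d <- matrix(0, 6, 6)
  for (i in 1:5) for (j in (i + 1):6)
    d[i, j] <- d[j, i] <- sum(seqs[i, ] != seqs[j, ])
  ssd_tot <- sum(d[upper.tri(d)]) / 6
  ssd_w <- sum(d[1:3, 1:3][upper.tri(d[1:3, 1:3])]) / 3 +
    sum(d[4:6, 4:6][upper.tri(d[4:6, 4:6])]) / 3
  ms_a <- (ssd_tot - ssd_w) / 1
  ms_w <- ssd_w / 4
  n0 <- (6 - (9 + 9) / 6) / 1
  sig_a <- (ms_a - ms_w) / n0
  expect_equal(res$sigma_among, sig_a, tolerance = 1e-12)
  expect_equal(res$sigma_within, ms_w, tolerance = 1e-12)
  expect_equal(res$phi_st, sig_a / (sig_a + ms_w), tolerance = 1e-12)
})

test_that("phi_ST can be negative on panmictic data and NA when invariant", {
  set.seed(25)
  found_negative <- FALSE
  for (r in 1:20) {
    aln <- sim_mtdna(12, 60, 4)
    md <- sample_metadata(aln$ids, sample(rep(c("P", "Q"), each = 6)))
    res <- amova_phist(aln, md, n_perm = 0)
    if (!is.na(res$phi_st) && res$phi_st < 0) found_negative <- TRUE
  }
  expect_true(found_negative)
  same <- haplotype_alignment(c(a = "AAAA", b = "AAAA", c = "AAAA",
                                d = "AAAA"))
  md2 <- sample_metadata(c("a", "b", "c", "d"), c("P", "P", "Q", "Q"))
  expect_true(is.na(amova_phist(same, md2, n_perm = 0)$phi_st))
})

test_that("a single-sequence population contributes no within-group df", {
  aln <- haplotype_alignment(c(a = "AATT", b = "AATA", c = "TTAA",
                               d = "TTAT", e = "TTGT"))
  md <- sample_metadata(letters[1:5], c("P", "P", "Q", "Q", "R"))
  res <- amova_phist(aln, md, n_perm = 0)
  expect_equal(unname(res$df["within"]), 2L)  # 5 seqs - 3 groups
  expect_false(is.na(res$phi_st))
})

test_that("median D and phi_ST increase with divergence time", {
  set.seed(26)
  times <- c(0.05, 0.3, 1.0)
  medD <- vapply(times, function(tt) {
    stats::median(replicate(12, {
      sp <- sim_structured_pops(2, 10, tt, 4, n_loci = 5, pool_size = 60)
      jost_dest(sp$genotypes, sp$metadata)$overall
    }))
  }, numeric(1))
  expect_true(all(diff(medD) > 0))
})

test_that("pairwise matrices are symmetric with Holm-adjusted decisions", {
  sp <- sim_structured_pops(3, 8, 0.8, 4, n_loci = 6, seed = 27)
  pw <- pairwise_differentiation(sp$genotypes, sp$metadata, "dest",
                                 n_rep = 99, seed = 2)
  expect_true(isSymmetric(unname(pw$statistic)))
  expect_true(isSymmetric(unname(pw$p)))
  expect_true(all(is.na(diag(pw$statistic))))
  expect_true(all(pw$p[upper.tri(pw$p)] > 0 & pw$p[upper.tri(pw$p)] <= 1))
})
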