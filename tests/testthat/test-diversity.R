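test_that("locus summary matches hand-computed values", {
  g <- genotype_matrix(rbind(100L, 100L, 120L), rbind(100L, 120L, 120L))
  s <- locus_summary(g, 1)
  expect_equal(s$He, 1.2 * 0.5)        # (2n/(2n-1)) (1 - sum p^2), p = .5/.5
  expect_equal(s$Ho, 1 / 3)
  expect_equal(s$Fis, 1 - (1 / 3) / 0.6)
  expect_equal(s$A, 2L)
})

test_that("monomorphic locus gives He = 0 and undefined Fis", {
  g <- genotype_matrix(matrix(7L, 3, 1), matrix(7L, 3, 1))
  s <- locus_summary(g, 1)
  expect_equal(s$A, 1L)
  expect_equal(s$He, 0)
  expect_equal(s$Ho, 0)
  expect_true(is.na(s$Fis))
})

test_that("rarefied allelic richness matches the combinatorial formula", {
  # copy counts (3, 1), N = 4 genes, g = 2: Ar = 1 + (1 - C(3,2)/C(4,2))
  g <- genotype_matrix(rbind(1L, 1L), rbind(1L, 2L))
  expect_equal(locus_summary(g, 1, rarefaction_g = 2)$Ar,
               (1 - 0) + (1 - choose(3, 2) / choose(4, 2)))
  expect_equal(locus_summary(g, 1, rarefaction_g = 2)$Ar, 1.5)
  expect_error(locus_summary(g, 1, rarefaction_g = 5), "exceeds")
})

test_that("Ar at g = N equals A exactly", {
  set.seed(19)
  for (rep in 1:10) {
    g <- random_genotypes(n = 12, L = 3)
    for (j in 1:3) {
      s <- locus_summary(g, j)
      expect_equal(s$Ar, s$A)
    }
  }
})

test_that("He on HWE-simulated data tracks the true gene diversity", {
  set.seed(20)
  p <- c(0.4, 0.3, 0.2, 0.1)
  true_he <- 1 - sum(p^2)
  hes <- replicate(200, {
    a <- sample(4, 50, TRUE, p); b <- sample(4, 50, TRUE, p)
    g <- genotype_matrix(matrix(pmin(a, b)), matrix(pmax(a, b)))
    locus_summary(g, 1)$He
  })
  expect_lt(abs(mean(hes) - true_he) / true_he, 0.01)
})

test_that("HWE exact MCMC reproduces the two-allele enumeration oracle", {
  # counts AA=3, Aa=0, aa=3; Levene enumeration over het counts {0,2,4,6}
  hs <- c(0, 2, 4, 6)
  lp <- vapply(hs, function(h) {
    n11 <- (6 - h) / 2
    lgamma(7) + 2 * lgamma(7) + h * log(2) - lgamma(13) -
      lgamma(n11 + 1) - lgamma(h + 1) - lgamma(n11 + 1)
  }, numeric(1))
  ps <- exp(lp) / sum(exp(lp))
  p_exact <- sum(ps[lp <= lp[1] + 1e-9])
  g <- genotype_matrix(matrix(c(1L, 1L, 1L, 2L, 2L, 2L)),
                       matrix(c(1L, 1L, 1L, 2L, 2L, 2L)))
  res <- hwe_exact_mcmc(g, 1, dememorization = 500, batches = 40,
                        iters_per_batch = 2000, seed = 5)
  expect_false(res$untestable)
  expect_lt(abs(res$p - p_exact), 3 * res$se + 0.003)
})

test_that("perfect HWE proportions give a large p", {
  set.seed(21)
  a <- sample(1:2, 150, TRUE, c(.6, .4)); b <- sample(1:2, 150, TRUE, c(.6, .4))
  g <- genotype_matrix(matrix(pmin(a, b)), matrix(pmax(a, b)))
  res <- hwe_exact_mcmc(g, 1, 1000, 25, 2000, seed = 6)
  expect_gt(res$p, 0.2)
})

test_that("monomorphic or tiny samples are untestable with p = 1", {
  g <- genotype_matrix(matrix(1L, 5, 1), matrix(1L, 5, 1))
  res <- hwe_exact_mcmc(g, 1)
  expect_true(res$untestable)
  expect_equal(res$p, 1)
})

test_that("LD permutation test flags perfect and absent association", {
  g <- sim_population_equilibrium(30, 1, 3, mutation_model("IAM"), seed = 7)
  gdup <- genotype_matrix(cbind(g$a1[, 1], g$a1[, 1]),
                          cbind(g$a2[, 1], g$a2[, 1]))
  res <- ld_permutation_test(gdup, 1, 2, n_perm = 199, seed = 1)
  expect_equal(res$p, 1 / 200)          # duplicated locus sits at the floor
  expect_error(ld_permutation_test(gdup, 1, 2, n_perm = 0), "n_perm")
  gmono <- genotype_matrix(cbind(g$a1[, 1], 1L), cbind(g$a2[, 1], 1L))
  res2 <- ld_permutation_test(gmono, 1, 2, n_perm = 99)
  expect_true(res2$untestable)
  expect_equal(res2$p, 1)
})

test_that("LD test is calibrated on independent loci", {
  set.seed(22)
  ps <- replicate(60, {
    g <- sim_population_equilibrium(25, 2, 3, mutation_model("IAM"))
    ld_permutation_test(g, 1, 2, n_perm = 99)$p
  })
  rate <- mean(ps < 0.05)
  expect_lt(rate, 0.05 + 2 * sqrt(0.05 * 0.95 / 60) + 0.02)
})

test_that("private alleles match a brute-force set oracle", {
  # two pops fixed for different alleles at one locus
  g <- genotype_matrix(matrix(c(1L, 1L, 2L, 2L)), matrix(c(1L, 1L, 2L, 2L)))
  md <- sample_metadata(g$ids, c("A", "A", "B", "B"))
  expect_equal(unname(private_alleles(g, md)), c(1L, 1L))
  # identical pops: none
  g2 <- genotype_matrix(matrix(c(1L, 1L, 1L, 1L)), matrix(c(2L, 2L, 2L, 2L)))
  expect_equal(unname(private_alleles(g2, md)), c(0L, 0L))
  # random 3-deme fixture vs set-difference oracle
  sp <- sim_structured_pops(3, 8, 0.5, 4, n_loci = 6, seed = 14)
  obs <- private_alleles(sp$genotypes, sp$metadata)
  oracle <- stats::setNames(integer(3), paste0("deme", 1:3))
  for (j in 1:6) {
    per <- lapply(paste0("deme", 1:3), function(s) {
      sub <- subset_individuals(sp$genotypes, sp$metadata$site == s)
      as.integer(names(allele_counts(sub, j)))
    })
    for (d in 1:3) {
      oracle[d] <- oracle[d] +
        length(setdiff(per[[d]], unlist(per[-d])))
    }
  }
  expect_equal(obs, oracle)
})

test_that("diversity table rarefies to the smallest gene count", {
  sp <- sim_structured_pops(2, 6, 0.2, 4, n_loci = 4, seed = 15)
  tab <- diversity_table(sp$genotypes, sp$metadata)
  expect_true(all(tab$Ar <= tab$A + 1e-12))
  ov <- attr(tab, "overall")
  expect_equal(nrow(ov), 2L)
  # multi-locus Fis is the ratio of sums
  for (s in ov$site) {
    sub <- tab[tab$site == s, ]
    expect_equal(ov$Fis[ov$site == s],
                 sum(sub$He - sub$Ho) / sum(sub$He))
  }
})
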