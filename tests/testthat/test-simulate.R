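test_that("generators are deterministic under a fixed seed", {
  g1 <- sim_population_equilibrium(10, 3, 2, mutation_model("SMM"), seed = 5)
  g2 <- sim_population_equilibrium(10, 3, 2, mutation_model("SMM"), seed = 5)
  expect_identical(g1, g2)
  a1 <- sim_mtdna(8, 50, 3, seed = 5)
  a2 <- sim_mtdna(8, 50, 3, seed = 5)
  expect_identical(a1$seq, a2$seq)
  b1 <- sim_bottleneck(8, 3, 2, mutation_model("IAM"), 0.1, 3, seed = 5)
  b2 <- sim_bottleneck(8, 3, 2, mutation_model("IAM"), 0.1, 3, seed = 5)
  expect_identical(b1, b2)
})

test_that("pedigree categories carry the standard k-coefficients", {
  expect_equal(pedigree_category("U")$k, c(1, 0, 0))
  expect_equal(pedigree_category("HS")$k, c(0.5, 0.5, 0))
  expect_equal(pedigree_category("FS")$k, c(0.25, 0.5, 0.25))
  expect_equal(pedigree_category("PO")$k, c(0, 1, 0))
  expect_equal(pedigree_category("HS")$r, 0.25)
  expect_equal(pedigree_category("PO")$r, 0.5)
})

test_that("parent-offspring pairs share an allele at every locus", {
  sim <- sim_pedigree_pairs(equifreqs(10, 6), "PO", 200, seed = 2)
  shares <- (sim$x$a1 == sim$y$a1) | (sim$x$a1 == sim$y$a2) |
    (sim$x$a2 == sim$y$a1) | (sim$x$a2 == sim$y$a2)
  expect_true(all(shares))
  expect_true(all(sim$ibd == 1L))
})

test_that("realized IBD sharing matches the category k-coefficients", {
  sim <- sim_pedigree_pairs(equifreqs(20, 10), "FS", 5000, seed = 3)
  k2_hat <- mean(sim$ibd == 2L)
  k1_hat <- mean(sim$ibd == 1L)
  se <- sqrt(0.25 * 0.75 / (5000 * 20))
  expect_lt(abs(k2_hat - 0.25), 4 * se)
  expect_lt(abs(k1_hat - 0.5), 4 * sqrt(0.5 * 0.5 / (5000 * 20)))
  simU <- sim_pedigree_pairs(equifreqs(5, 4), "U", 500, seed = 4)
  expect_true(all(simU$ibd == 0L))
})

test_that("pedigree means match theoretical relatedness within 3 MC SE", {
  fr <- equifreqs(20, 10)
  for (cat in c("U", "HS", "FS", "PO")) {
    sim <- sim_pedigree_pairs(fr, cat, 2000, seed = 17)
    r <- relatedness_moment(sim$x, sim$y, fr, "QG")
    se <- stats::sd(r) / sqrt(length(r))
    expect_lt(abs(mean(r) - pedigree_category(cat)$r), 3 * se)
  }
})

test_that("degenerate frequency tables are flagged", {
  mono <- list(c("1" = 1))
  expect_warning(sim_pedigree_pairs(mono, "U", 5, seed = 1), "monomorphic")
})

test_that("equilibrium IAM allele counts match Ewens' expectation", {
  set.seed(23)
  mean_a <- mean(replicate(500, {
    g <- sim_population_equilibrium(25, 1, 5, mutation_model("IAM"))
    length(allele_counts(g, 1))
  }))
  expected <- ewens_expected_alleles(5, 50)
  expect_lt(abs(mean_a - expected) / expected, 0.02)
})

test_that("tiny theta gives monomorphic loci; model state spaces differ", {
  g <- sim_population_equilibrium(10, 5, 1e-9, mutation_model("IAM"),
                                  seed = 6)
  expect_true(all(vapply(1:5, function(j) length(allele_counts(g, j)), 1L)
                  == 1L))
  gs <- sim_population_equilibrium(40, 1, 4, mutation_model("SMM"), seed = 7)
  al <- as.integer(names(allele_counts(gs, 1)))
  expect_true(max(al) - min(al) < 60)  # SMM alleles sit on a tight ladder
  expect_true(all(diff(sort(al)) <= 8))
  gi <- sim_population_equilibrium(40, 1, 4, mutation_model("IAM"), seed = 8)
  expect_true(length(allele_counts(gi, 1)) >= 2)  # IAM: fresh labels
})

test_that("a crash loses alleles faster than heterozygosity", {
  set.seed(9)
  ratio_a <- ratio_he <- numeric(60)
  for (r in 1:60) {
    ge <- sim_population_equilibrium(20, 4, 4, mutation_model("IAM"))
    gb <- sim_bottleneck(20, 4, 4, mutation_model("IAM"),
                         crash_factor = 0.05, generations_since = 5,
                         pool_size = 200)
    stat <- function(g) {
      s <- vapply(seq_along(g$loci), function(j) {
        cnt <- allele_counts(g, j)
        p <- cnt / sum(cnt)
        c(length(cnt), 1 - sum(p^2))
      }, numeric(2))
      rowMeans(s)
    }
    se <- stat(ge); sb <- stat(gb)
    ratio_a[r] <- sb[1] / se[1]
    ratio_he[r] <- (sb[2] + 1e-9) / (se[2] + 1e-9)
  }
  # allele count drops proportionally more than gene diversity: this is the
  # mechanism the heterozygosity-excess test exploits
  expect_lt(mean(ratio_a), mean(ratio_he))
})

test_that("bottleneck guards its parameters", {
  expect_error(sim_bottleneck(5, 2, 1, mutation_model("IAM"), 0.001, 2,
                              pool_size = 100), "reduced size")
  expect_error(sim_bottleneck(5, 2, 1, mutation_model("IAM"), 0, 2),
               "crash_factor")
})

test_that("mtDNA simulator hits Watterson's expected S and the ts bias", {
  an <- sum(1 / (1:69))
  theta <- 38 / an
  set.seed(10)
  S <- replicate(40, segregating_sites(sim_mtdna(70, 791, theta)))
  expect_lt(abs(mean(S) - 38) / 38, 0.12)  # finite sites eat a few hits
  ts <- tv <- 0
  for (r in 1:30) {
    a <- sim_mtdna(40, 400, 8, ts_bias = 34 / 7)
    ts <- ts + sum(a$site_classes$transitions)
    tv <- tv + sum(a$site_classes$transversions)
  }
  expect_gt(ts / tv, 3)   # strongly transition-biased, near 34:7
  expect_lt(ts / tv, 7)
  expect_equal(sim_mtdna(6, 30, 0, seed = 1)$h, 1L)  # no mutation
})

test_that("structured demes carry matching metadata and drift apart", {
  sp <- sim_structured_pops(3, 10, divergence = 0.8, theta = 5,
                            n_loci = 10, seed = 12)
  expect_equal(sp$metadata$site,
               rep(paste0("deme", 1:3), each = 10))
  expect_equal(sp$genotypes$ids, sp$metadata$id)
  D_div <- jost_dest(sp$genotypes, sp$metadata)$overall
  sp0 <- sim_structured_pops(3, 10, divergence = 0, theta = 5,
                             n_loci = 10, seed = 13)
  D_0 <- jost_dest(sp0$genotypes, sp0$metadata)$overall
  expect_gt(D_div, 0.2)
  expect_lt(abs(D_0), 0.1)
})

test_that("mutation model validates its parameters", {
  expect_error(mutation_model("TPM", p_single = 1.2), "p_single")
  expect_equal(mutation_model("TPM")$p_single, 0.70)
})
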