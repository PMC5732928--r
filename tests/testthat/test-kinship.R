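test_that("identity-mode genotype-pair probabilities normalise to one", {
  for (p in list(c("1" = 0.5, "2" = 0.5),
                 c("1" = 0.5, "2" = 0.3, "3" = 0.2),
                 c("1" = 0.7, "2" = 0.1, "3" = 0.1, "4" = 0.1))) {
    al <- as.integer(names(p))
    gt <- unique(t(apply(expand.grid(al, al), 1, sort)))
    pairs <- expand.grid(seq_len(nrow(gt)), seq_len(nrow(gt)))
    P <- riverkin:::.jacquard_probs(gt[pairs[, 1], 1], gt[pairs[, 1], 2],
                                    gt[pairs[, 2], 1], gt[pairs[, 2], 2], p)
    expect_equal(unname(colSums(P)), rep(1, 9), tolerance = 1e-12)
  }
})

test_that("identical heterozygotes give Queller-Goodnight r of 1", {
  x <- genotype_matrix(matrix(1L), matrix(2L))
  y <- genotype_matrix(matrix(1L), matrix(2L))
  expect_equal(relatedness_moment(x, y, list(c("1" = 0.5, "2" = 0.5)),
                                  "QG"), 1)
  # same conclusion away from the degenerate frequency point
  fr <- list(c("1" = 0.4, "2" = 0.4, "3" = 0.2))
  expect_equal(relatedness_moment(x, y, fr, "QG"), 1)
})

test_that("every moment estimator is unbiased for each pedigree category", {
  fr <- equifreqs(20, 10)
  for (cat in c("U", "HS", "FS")) {
    sim <- sim_pedigree_pairs(fr, cat, 2000, seed = 60 + match(cat, c("U", "HS", "FS")))
    target <- pedigree_category(cat)$r
    for (est in c("QG", "LynchLi", "LynchRd", "Ritland", "Wang")) {
      r <- relatedness_moment(sim$x, sim$y, fr, est)
      se <- stats::sd(r, na.rm = TRUE) / sqrt(sum(!is.na(r)))
      expect_lt(abs(mean(r, na.rm = TRUE) - target), 3 * se + 0.005)
    }
  }
})

test_that("estimators are exchangeable in pair order", {
  fr <- equifreqs(8, 6)
  sim <- sim_pedigree_pairs(fr, "HS", 50, seed = 64)
  for (est in c("QG", "LynchLi", "LynchRd", "Ritland", "Wang")) {
    r_xy <- relatedness_moment(sim$x, sim$y, fr, est)
    r_yx <- relatedness_moment(sim$y, sim$x, fr, est)
    expect_equal(r_xy, r_yx, tolerance = 1e-12)
  }
  d_xy <- relatedness_dyadml(subset_individuals(sim$x, 1:10),
                             subset_individuals(sim$y, 1:10), fr)$r
  d_yx <- relatedness_dyadml(subset_individuals(sim$y, 1:10),
                             subset_individuals(sim$x, 1:10), fr)$r
  expect_equal(d_xy, d_yx, tolerance = 1e-6)
})

test_that("moment estimators leave [0,1]; DyadML never does", {
  fr <- equifreqs(10, 8)
  sim <- sim_pedigree_pairs(fr, "U", 400, seed = 65)
  qg <- relatedness_moment(sim$x, sim$y, fr, "QG")
  expect_true(any(qg < 0))                 # unbounded moment estimator
  d <- relatedness_dyadml(subset_individuals(sim$x, 1:40),
                          subset_individuals(sim$y, 1:40), fr)$r
  expect_true(all(d >= -1e-9 & d <= 1 + 1e-9))
})

test_that("DyadML recovers parent-offspring structure", {
  fr <- equifreqs(20, 10)
  sim <- sim_pedigree_pairs(fr, "PO", 150, seed = 66)
  d <- relatedness_dyadml(sim$x, sim$y, fr)
  expect_lt(abs(mean(d$r) - 0.5), 0.03)
  expect_gt(mean(d$k1), 0.9)              # fitted k1 ~ 1
})

test_that("single-locus pair with no shared alleles forces r = 0", {
  x <- genotype_matrix(matrix(1L), matrix(2L))
  y <- genotype_matrix(matrix(3L), matrix(4L))
  fr <- list(stats::setNames(rep(0.25, 4), 1:4))
  d <- relatedness_dyadml(x, y, fr)
  expect_equal(d$r, 0, tolerance = 1e-9)
  expect_equal(d$k1 + d$k2, 0, tolerance = 1e-9)
})

test_that("EM maximum agrees with a brute-force simplex grid search", {
  fr <- equifreqs(10, 8)
  sim <- sim_pedigree_pairs(fr, "FS", 50, seed = 67)
  # grid over the (k1, k2) simplex at 0.01 resolution
  grid <- expand.grid(k1 = seq(0, 1, 0.01), k2 = seq(0, 1, 0.01))
  grid <- grid[grid$k1 + grid$k2 <= 1, ]
  K <- rbind(pmax(0, 1 - grid$k1 - grid$k2), grid$k1, grid$k2)
  d <- relatedness_dyadml(sim$x, sim$y, fr)
  for (i in seq_len(nrow(sim$x$a1))) {
    A <- sapply(seq_along(fr), function(j) {
      riverkin:::.jacquard_probs(sim$x$a1[i, j], sim$x$a2[i, j],
                                 sim$y$a1[i, j], sim$y$a2[i, j],
                                 fr[[j]])[, c(9, 8, 7)]
    })   # 3 x L
    ll <- colSums(log(t(A) %*% K))
    best <- which.max(ll)
    r_grid <- grid$k1[best] / 2 + grid$k2[best]
    expect_lt(abs(d$r[i] - r_grid), 1.5e-2)
  }
})

test_that("Jacquard-mode DyadML matches the non-inbred fit on outbred data", {
  fr <- equifreqs(15, 8)
  sim <- sim_pedigree_pairs(fr, "FS", 25, seed = 68)
  d3 <- relatedness_dyadml(sim$x, sim$y, fr)
  d9 <- relatedness_dyadml(sim$x, sim$y, fr, allow_inbreeding = TRUE)
  expect_lt(mean(abs(d3$r - d9$r)), 0.05)
  expect_true(all(d9$r >= -1e-9 & d9$r <= 1 + 1e-9))
})

test_that("relationship classification is Mendelian-aware and conservative", {
  fr <- equifreqs(20, 10)
  sim <- sim_pedigree_pairs(fr, "FS", 400, seed = 69)
  cl <- classify_relationship(sim$x, sim$y, fr)
  expect_gte(mean(cl$category %in% c("FS", "PO")), 0.8)
  # a pair sharing no alleles at some locus excludes PO outright
  x <- genotype_matrix(cbind(1L, 1L), cbind(2L, 1L))
  y <- genotype_matrix(cbind(3L, 1L), cbind(4L, 2L))
  fr4 <- rep(list(stats::setNames(rep(0.25, 4), 1:4)), 2)
  cl2 <- classify_relationship(x, y, fr4)
  expect_true(is.infinite(cl2$PO))
  expect_false(cl2$category[1] == "PO")
})

test_that("single-locus category likelihoods match the hand table", {
  # genotypes (ab, ab), uniform frequencies over 4 alleles (p = 1/4 each):
  # P|k2 = 2pq = 1/8; P|k1 = pq(p+q) = 1/32; P|k0 = 4 p^2 q^2 = 1/64
  x <- genotype_matrix(matrix(1L), matrix(2L))
  y <- genotype_matrix(matrix(1L), matrix(2L))
  fr <- list(stats::setNames(rep(0.25, 4), 1:4))
  cl <- classify_relationship(x, y, fr)
  lik <- c(U = 1 / 64, HS = 0.5 / 64 + 0.5 / 32,
           FS = 0.25 / 64 + 0.5 / 32 + 0.25 / 8, PO = 1 / 32)
  expect_equal(unname(unlist(cl[1, c("U", "HS", "FS", "PO")])),
               unname(log(lik)), tolerance = 1e-12)
  expect_equal(as.character(cl$category[1]), "FS")
})

test_that("estimator evaluation orders categories and ranks variances", {
  fr <- equifreqs(15, 8)
  ev <- evaluate_estimators(fr, n_pairs = 300,
                            estimators = c("QG", "Ritland", "DyadML"),
                            seed = 70)
  s <- ev$summary
  for (est in unique(s$estimator)) {
    m <- s$mean[s$estimator == est]
    expect_true(all(diff(m) > 0))  # U < HS < FS
  }
  vU <- s$var[s$category == "U"]
  names(vU) <- s$estimator[s$category == "U"]
  expect_lte(vU[["DyadML"]], vU[["Ritland"]])
  ev2 <- evaluate_estimators(fr, n_pairs = 300,
                             estimators = c("QG", "Ritland", "DyadML"),
                             seed = 70)
  expect_identical(ev$summary, ev2$summary)  # seeded determinism
})

test_that("all-pairs table is complete and frequency-consistent", {
  g <- sim_population_equilibrium(8, 6, 3, mutation_model("IAM"), seed = 71)
  rel <- pairwise_relatedness(g, estimators = c("QG", "LynchLi"))
  expect_equal(nrow(rel), choose(8, 2))
  expect_true(all(c("QG", "LynchLi") %in% names(rel)))
  expect_false(anyNA(rel$QG))
})

test_that("individual inbreeding ML estimates rank selfed individuals", {
  set.seed(83)
  p <- stats::setNames(rep(0.2, 5), 1:5)
  fr <- rep(list(p), 30)
  # outbred: HWE draws; inbred: f = 0.5 via mode mixture
  draw_ind <- function(f) {
    a <- integer(30); b <- integer(30)
    for (j in 1:30) {
      if (stats::runif(1) < f) a[j] <- b[j] <- sample(5, 1, prob = p)
      else { a[j] <- sample(5, 1, prob = p); b[j] <- sample(5, 1, prob = p) }
    }
    list(a = a, b = b)
  }
  inds <- c(replicate(6, draw_ind(0), simplify = FALSE),
            replicate(6, draw_ind(0.5), simplify = FALSE))
  a1 <- do.call(rbind, lapply(inds, `[[`, "a"))
  a2 <- do.call(rbind, lapply(inds, `[[`, "b"))
  g <- genotype_matrix(a1, a2)
  est <- individual_inbreeding(g, fr)
  expect_true(all(est$f >= 0 & est$f <= 1))
  expect_gt(mean(est$f[7:12]), mean(est$f[1:6]) + 0.2)
  # fully heterozygous individual across informative loci -> f = 0
  gh <- genotype_matrix(matrix(1L, 1, 10), matrix(2L, 1, 10))
  expect_equal(individual_inbreeding(gh, rep(list(p), 10))$f, 0)
})
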