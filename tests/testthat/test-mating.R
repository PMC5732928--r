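test_that("pairing enumeration reproduces the F*M + U*(N-1) arithmetic", {
  md <- sample_metadata(paste0("i", 1:70), rep("X", 70),
                        c(rep("F", 44), rep("M", 21), rep("U", 5)))
  pairs <- enumerate_pairings(md)
  expect_equal(nrow(pairs), 44 * 21 + 5 * 69)
  expect_equal(nrow(pairs), 1269L)
  expect_equal(sum(pairs$type == "FxM"), 924L)
  # the unknown-unknown duplicates are flagged and removable
  expect_equal(sum(pairs$duplicate), choose(5, 2))
  uniq <- enumerate_pairings(md, unique_pairs = TRUE)
  expect_equal(nrow(uniq), 1269L - choose(5, 2))
})

test_that("edge cases: one pair, all-unknown broodstock", {
  md <- sample_metadata(c("f", "m"), c("X", "X"), c("F", "M"))
  expect_equal(nrow(enumerate_pairings(md)), 1L)
  md3 <- sample_metadata(c("a", "b", "c"), rep("X", 3), rep("U", 3))
  e <- enumerate_pairings(md3)
  expect_equal(nrow(e), 6L)               # each of 3 unique pairs twice
  expect_equal(sum(e$duplicate), 3L)
  expect_error(enumerate_pairings(md3[1, , drop = FALSE]), ">= 2")
})

test_that("enumeration count identity holds over random sex assignments", {
  set.seed(80)
  for (rep in 1:25) {
    n <- sample(3:30, 1)
    sex <- sample(c("F", "M", "U"), n, replace = TRUE)
    md <- sample_metadata(paste0("i", 1:n), rep("X", n), sex)
    f <- sum(sex == "F"); m <- sum(sex == "M"); u <- sum(sex == "U")
    expect_equal(nrow(enumerate_pairings(md)), f * m + u * (n - 1))
  }
})

test_that("threshold classification and severity-max consensus", {
  expect_equal(as.character(mating_category(c(0.1, 0.25, 0.4, 0.5, 0.51))),
               c("advisable", "marginal", "marginal", "marginal",
                 "inadvisable"))
  md <- sample_metadata(c("f", "m"), c("X", "X"), c("F", "M"))
  pairs <- enumerate_pairings(md)
  rel <- data.frame(id1 = "f", id2 = "m", A = 0.1, B = 0.3)
  plan <- classify_pairings(pairs, rel, "A", "B")
  expect_equal(as.character(plan$pairs$consensus), "marginal")
  rel2 <- data.frame(id1 = "f", id2 = "m", A = 0.1, B = 0.1)
  expect_equal(as.character(classify_pairings(pairs, rel2, "A",
                                              "B")$pairs$consensus),
               "advisable")
  # consensus is never less severe than either method
  set.seed(81)
  sev <- c(advisable = 1, marginal = 2, inadvisable = 3)
  for (rep in 1:20) {
    ra <- runif(1); rb <- runif(1)
    rel3 <- data.frame(id1 = "f", id2 = "m", A = ra, B = rb)
    cons <- classify_pairings(pairs, rel3, "A", "B")$pairs$consensus
    expect_gte(sev[as.character(cons)],
               max(sev[as.character(mating_category(c(ra, rb)))]))
  }
})

test_that("report percentages reproduce the count arithmetic", {
  md <- sample_metadata(paste0("i", 1:70), rep("X", 70),
                        c(rep("F", 44), rep("M", 21), rep("U", 5)))
  pairs <- enumerate_pairings(md)
  # assign relatedness per unique pair: the 10 doubly listed U-U pairs get
  # advisable values, so listed-pair counts come out 1108/140/21
  uniq <- pairs[!pairs$duplicate, ]
  dup_key <- paste(pmin(pairs$id1, pairs$id2), pmax(pairs$id1, pairs$id2))
  is_dup_pair <- paste(pmin(uniq$id1, uniq$id2),
                       pmax(uniq$id1, uniq$id2)) %in%
    dup_key[pairs$duplicate]
  r <- numeric(nrow(uniq))
  r[is_dup_pair] <- 0.1                       # 10 pairs -> 20 listings
  rest <- which(!is_dup_pair)                 # 1249 unique single listings
  r[rest] <- c(rep(0.1, 1088), rep(0.3, 140), rep(0.6, 21))
  rel <- data.frame(id1 = uniq$id1, id2 = uniq$id2, A = r, B = r)
  rep_out <- mating_report(classify_pairings(pairs, rel, "A", "B"))
  expect_equal(rep_out$summary$count, c(1108L, 140L, 21L))
  expect_equal(rep_out$summary$percent, c(87.3, 11.0, 1.7))
  expect_equal(rep_out$total, 1269L)
  # percentages recompute exactly from the matrix
  m <- rep_out$matrix
  counts <- table(factor(m[upper.tri(m)],
                         levels = c("advisable", "marginal", "inadvisable")))
  recomputed <- round(100 * as.integer(counts) / sum(counts), 1)
  expect_equal(sum(rep_out$summary$percent), 100, tolerance = 0.11)
})

test_that("single advisable pair reports 100/0/0", {
  md <- sample_metadata(c("f", "m"), c("X", "X"), c("F", "M"))
  pairs <- enumerate_pairings(md)
  rel <- data.frame(id1 = "f", id2 = "m", A = 0.05, B = 0.05)
  rep_out <- mating_report(classify_pairings(pairs, rel, "A", "B"))
  expect_equal(rep_out$summary$percent, c(100, 0, 0))
})

test_that("missing relatedness yields unevaluated pairs with a warning", {
  md <- sample_metadata(c("f", "m", "u"), rep("X", 3), c("F", "M", "U"))
  pairs <- enumerate_pairings(md)
  rel <- data.frame(id1 = "f", id2 = "m", A = 0.1, B = 0.1)
  expect_warning(plan <- classify_pairings(pairs, rel, "A", "B"),
                 "unevaluated")
  rep_out <- mating_report(plan)
  expect_equal(rep_out$total, 1L)
})

test_that("true sib pairs rarely land in the advisable category", {
  fr <- equifreqs(20, 10)
  sim <- sim_pedigree_pairs(fr, "FS", 60, seed = 82)
  d <- relatedness_dyadml(sim$x, sim$y, fr)$r
  expect_gte(mean(d >= 0.25), 0.95)
})
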