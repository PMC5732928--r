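#' Jost's D differentiation estimator
#'
#' Per locus, `D = [(Ht - Hs) / (1 - Hs)] * [k / (k - 1)]` with `k` the
#' number of populations and `Hs`, `Ht` the Nei-Chesser sample-size-
#' corrected within-population and total heterozygosities:
#' `Hs = (nh / (nh - 1)) * (1 - mean_j sum_i p_ij^2)` with `nh` the harmonic
#' mean sample size, and `Ht = 1 - sum_i pbar_i^2 + Hs / (2 nh k)`. The
#' overall multi-locus D is the arithmetic mean over usable loci.
#'
#' @param g a [genotype_matrix()].
#' @param metadata metadata data.frame with a `site` column.
#' @param populations character vector of populations to compare (default:
#'   all sites present).
#' @return A list: `per_locus` (named numeric, `NA` where a locus was
#'   skipped), `overall` (mean over non-`NA` loci), `k`.
#' @export
jost_dest <- function(g, metadata, populations = NULL) {
  sites <- .sites_for(g, metadata)
  if (is.null(populations)) populations <- unique(sites)
  if (length(populations) < 2L) stop("need >= 2 populations")
  keep <- sites %in% populations
  g <- subset_individuals(g, keep)
  sites <- sites[keep]
  k <- length(populations)
  D <- stats::setNames(rep(NA_real_, length(g$loci)), g$loci)
  for (j in seq_along(g$loci)) {
    comp <- .dest_components(g$a1[, j], g$a2[, j], sites, populations)
    if (is.null(comp)) next
    if (1 - comp$Hs < 1e-12) {
      warning("Hs = 1 at locus ", g$loci[j], "; locus skipped")
      next
    }
    D[j] <- (comp$Ht - comp$Hs) / (1 - comp$Hs) * k / (k - 1)
  }
  list(per_locus = D, overall = mean(D, na.rm = TRUE), k = k)
}

# Nei-Chesser corrected Hs/Ht for one locus; NULL when some population has
# no genotyped individual.
.dest_components <- function(a1, a2, sites, populations) {
  k <- length(populations)
  nj <- numeric(k)
  al <- sort(unique(c(a1, a2)))
  al <- al[!is.na(al)]
  if (length(al) == 0L) return(NULL)
  P <- matrix(0, k, length(al))
  for (d in seq_len(k)) {
    sel <- sites == populations[d] & !is.na(a1)
    nj[d] <- sum(sel)
    if (nj[d] == 0L) return(NULL)
    cnt <- table(factor(c(a1[sel], a2[sel]), levels = al))
    P[d, ] <- as.numeric(cnt) / sum(cnt)
  }
  nh <- k / sum(1 / nj)                      # harmonic mean sample size
  hs_raw <- 1 - mean(rowSums(P^2))
  Hs <- (2 * nh / (2 * nh - 1)) * hs_raw
  pbar <- colMeans(P)
  Ht <- 1 - sum(pbar^2) + Hs / (2 * nh * k)
  list(Hs = Hs, Ht = Ht)
}

#' Bootstrap significance for Jost's D
#'
#' The null distribution is built by resampling: alleles of the compared
#' populations are pooled, genotypes are re-drawn per individual under the
#' pooled allele frequencies (sample sizes preserved), and the overall D is
#' recomputed. The p-value uses the add-one rule.
#'
#' @inheritParams jost_dest
#' @param n_bootstrap number of bootstrap replicates (>= 99).
#' @param seed integer RNG seed, or `NULL`.
#' @return A list: `D` (observed overall), `p`, `null` (the bootstrap
#'   values).
#' @export
dest_significance <- function(g, metadata, populations = NULL,
                              n_bootstrap = 1000L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (n_bootstrap < 99L) stop("n_bootstrap must be >= 99")
  sites <- .sites_for(g, metadata)
  if (is.null(populations)) populations <- unique(sites)
  keep <- sites %in% populations
  g <- subset_individuals(g, keep)
  metadata <- metadata[metadata$id %in% g$ids, ]
  obs <- jost_dest(g, metadata, populations)$overall
  # pooled frequencies per locus
  pooled <- allele_freqs(g)
  n_ind <- length(g$ids)
  nullD <- numeric(n_bootstrap)
  for (b in seq_len(n_bootstrap)) {
    a1 <- a2 <- matrix(NA_integer_, n_ind, length(g$loci))
    for (j in seq_along(g$loci)) {
      typed <- !is.na(g$a1[, j])
      al <- as.integer(names(pooled[[j]]))
      p <- unname(pooled[[j]])
      nt <- sum(typed)
      a1[typed, j] <- al[sample.int(length(al), nt, replace = TRUE, prob = p)]
      a2[typed, j] <- al[sample.int(length(al), nt, replace = TRUE, prob = p)]
    }
    gb <- genotype_matrix(a1, a2, ids = g$ids, loci = g$loci)
    nullD[b] <- jost_dest(gb, metadata, populations)$overall
  }
  p <- (1 + sum(nullD >= obs - 1e-12)) / (1 + n_bootstrap)
  list(D = obs, p = p, null = nullD)
}

#' AMOVA phi_ST on a haplotype alignment
#'
#' Two-level analysis of molecular variance on pairwise nucleotide
#' difference counts (complete-deletion sites). Sums of squared deviations
#' are partitioned among and within populations; variance components give
#' `phi_ST = sigma2_a / (sigma2_a + sigma2_b)`. Significance is assessed by
#' permuting individuals among populations. Negative `phi_ST` estimates are
#' reported as computed.
#'
#' @param aln a [haplotype_alignment()].
#' @param metadata metadata data.frame with a `site` column.
#' @param populations populations to compare (default all).
#' @param n_perm number of permutations (0 skips the test).
#' @param seed integer RNG seed, or `NULL`.
#' @return A list: `phi_st`, `p`, `sigma_among`, `sigma_within`, `df`.
#' @export
amova_phist <- function(aln, metadata, populations = NULL, n_perm = 10000L,
                        seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- match(aln$ids, metadata$id)
  if (anyNA(m)) stop("metadata missing individuals")
  sites <- metadata$site[m]
  if (is.null(populations)) populations <- unique(sites)
  keep <- sites %in% populations
  ids <- aln$ids[keep]
  seqs <- aln$seq[keep, aln$usable_sites, drop = FALSE]
  grp <- sites[keep]
  n <- length(ids)
  if (length(unique(grp)) < 2L) stop("need >= 2 populations")
  if (n < 2L) stop("need >= 2 sequences")
  d <- .pairwise_diff_matrix(seqs)
  if (all(d == 0)) {
    return(list(phi_st = NA_real_, p = NA_real_, sigma_among = 0,
                sigma_within = 0, df = c(among = NA, within = NA)))
  }
  obs <- .amova_components(d, grp)
  p <- NA_real_
  if (n_perm > 0L) {
    exceed <- 0L
    for (b in seq_len(n_perm)) {
      stat <- .amova_components(d, sample(grp))$phi_st
      if (!is.na(stat) && stat >= obs$phi_st - 1e-12) exceed <- exceed + 1L
    }
    p <- (1 + exceed) / (1 + n_perm)
  }
  list(phi_st = obs$phi_st, p = p, sigma_among = obs$sigma_a,
       sigma_within = obs$sigma_b, df = obs$df)
}

#' Pairwise differentiation matrices over populations
#'
#' Builds the classic symmetric pairwise tables: Jost's D (nuclear) or
#' AMOVA phi_ST (mitochondrial) for every pair of populations, with
#' p-values and Holm-Bonferroni decisions.
#'
#' @param g a [genotype_matrix()] (for `statistic = "dest"`) or a
#'   [haplotype_alignment()] (for `statistic = "phist"`).
#' @param metadata metadata data.frame.
#' @param statistic `"dest"` or `"phist"`.
#' @param n_rep bootstrap replicates (dest) or permutations (phist).
#' @param alpha family-wise error rate for the Holm-Bonferroni decisions.
#' @param seed integer RNG seed, or `NULL`.
#' @return A list: `statistic` (matrix), `p` (matrix), `reject` (matrix of
#'   adjusted decisions), `populations`.
#' @export
pairwise_differentiation <- function(g, metadata,
                                     statistic = c("dest", "phist"),
                                     n_rep = 1000L, alpha = 0.05,
                                     seed = NULL) {
  statistic <- match.arg(statistic)
  if (!is.null(seed)) set.seed(seed)
  ids <- if (statistic == "dest") g$ids else g$ids
  sites <- metadata$site[match(ids, metadata$id)]
  pops <- unique(sites)
  k <- length(pops)
  val <- p <- matrix(NA_real_, k, k, dimnames = list(pops, pops))
  pairs <- utils::combn(k, 2)
  pvec <- numeric(ncol(pairs))
  for (c in seq_len(ncol(pairs))) {
    pr <- pops[pairs[, c]]
    if (statistic == "dest") {
      res <- dest_significance(g, metadata, populations = pr,
                               n_bootstrap = n_rep)
      v <- res$D
    } else {
      res <- amova_phist(g, metadata, populations = pr, n_perm = n_rep)
      v <- res$phi_st
    }
    val[pr[1], pr[2]] <- val[pr[2], pr[1]] <- v
    p[pr[1], pr[2]] <- p[pr[2], pr[1]] <- res$p
    pvec[c] <- res$p
  }
  rej <- holm_bonferroni(pvec, alpha)
  reject <- matrix(NA, k, k, dimnames = list(pops, pops))
  for (c in seq_len(ncol(pairs))) {
    pr <- pops[pairs[, c]]
    reject[pr[1], pr[2]] <- reject[pr[2], pr[1]] <- rej[c]
  }
  list(statistic = val, p = p, reject = reject, populations = pops)
}

# pairwise nucleotide difference counts between rows of a character matrix
.pairwise_diff_matrix <- function(seqs) {
  n <- nrow(seqs)
  d <- matrix(0, n, n)
  if (n < 2L || ncol(seqs) == 0L) return(d)
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      d[i, j] <- d[j, i] <- sum(seqs[i, ] != seqs[j, ])
    }
  }
  d
}

# Two-level AMOVA variance components from a squared-distance matrix.
# Populations with a single sequence contribute no within-group df.
.amova_components <- function(d, grp) {
  n <- nrow(d)
  groups <- unique(grp)
  G <- length(groups)
  ssd_total <- sum(d[upper.tri(d)]) / n
  ssd_within <- 0
  ng <- numeric(G)
  for (gi in seq_len(G)) {
    idx <- which(grp == groups[gi])
    ng[gi] <- length(idx)
    if (ng[gi] > 1L) {
      dg <- d[idx, idx, drop = FALSE]
      ssd_within <- ssd_within + sum(dg[upper.tri(dg)]) / ng[gi]
    }
  }
  ssd_among <- ssd_total - ssd_within
  df_a <- G - 1L
  df_w <- n - G
  if (df_w <= 0L) return(list(phi_st = NA_real_, sigma_a = NA_real_,
                              sigma_b = NA_real_,
                              df = c(among = df_a, within = df_w)))
  ms_a <- ssd_among / df_a
  ms_w <- ssd_within / df_w
  n0 <- (n - sum(ng^2) / n) / df_a
  sigma_b <- ms_w
  sigma_a <- (ms_a - ms_w) / n0
  tot <- sigma_a + sigma_b
  phi <- if (abs(tot) < 1e-15) NA_real_ else sigma_a / tot
  list(phi_st = phi, sigma_a = sigma_a, sigma_b = sigma_b,
       df = c(among = df_a, within = df_w))
}
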