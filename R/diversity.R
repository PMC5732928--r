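#' Per-locus diversity summary for one population
#'
#' Computes the standard microsatellite summary statistics on the
#' non-missing calls at one locus: allele count `A`, rarefied allelic
#' richness `Ar`, observed heterozygosity `Ho`, Nei's unbiased expected
#' heterozygosity `He = (2n/(2n-1)) (1 - sum p_i^2)`, and the fixation
#' index `Fis = 1 - Ho/He` (`NA` when `He = 0`).
#'
#' Allelic richness is rarefied to `rarefaction_g` genes:
#' `Ar = sum_i [1 - choose(N - N_i, g) / choose(N, g)]` with `N` the total
#' gene count and `N_i` the copies of allele i.
#'
#' @param g a [genotype_matrix()] restricted to one population.
#' @param locus locus name or index.
#' @param rarefaction_g rarefaction gene count (defaults to `N`, in which
#'   case `Ar = A` exactly).
#' @return A one-row data.frame: `locus`, `n`, `A`, `Ar`, `Ho`, `He`, `Fis`.
#' @export
locus_summary <- function(g, locus, rarefaction_g = NULL) {
  if (is.character(locus)) {
    j <- match(locus, g$loci)
    if (is.na(j)) stop("unknown locus: ", locus)
  } else j <- locus
  a1 <- g$a1[, j]; a2 <- g$a2[, j]
  keep <- !is.na(a1)
  n <- sum(keep)
  if (n == 0L) stop("no non-missing calls at locus ", g$loci[j])
  a1 <- a1[keep]; a2 <- a2[keep]
  cnt <- allele_counts(subset_individuals(g, keep), j)
  N <- sum(cnt)
  if (is.null(rarefaction_g)) rarefaction_g <- N
  if (rarefaction_g > N)
    stop("rarefaction_g exceeds the number of genes at locus ", g$loci[j])
  p <- cnt / N
  A <- length(cnt)
  Ar <- sum(1 - exp(lchoose(N - cnt, rarefaction_g) - lchoose(N, rarefaction_g)))
  Ho <- mean(a1 != a2)
  He <- (2 * n / (2 * n - 1)) * (1 - sum(p^2))
  Fis <- if (He > 0) 1 - Ho / He else NA_real_
  data.frame(locus = g$loci[j], n = n, A = A, Ar = Ar, Ho = Ho, He = He,
             Fis = Fis, stringsAsFactors = FALSE)
}

#' Diversity table for every locus and population
#'
#' Applies [locus_summary()] per population and locus, with a shared
#' rarefaction gene count. The multi-locus `Fis` per population is the
#' ratio of sums `sum(He - Ho) / sum(He)` (stable when some loci have
#' near-zero `He`), reported in the `overall` attribute.
#'
#' @param g a [genotype_matrix()].
#' @param metadata metadata data.frame with a `site` column.
#' @param rarefaction_g rarefaction gene count, or `"auto"` (the smallest
#'   per-population, per-locus gene count across the data).
#' @return A data.frame with a `site` column prepended to the
#'   [locus_summary()] columns; attribute `overall` holds per-population
#'   means and multi-locus `Fis`.
#' @export
diversity_table <- function(g, metadata, rarefaction_g = "auto") {
  sites <- .sites_for(g, metadata)
  pops <- unique(sites)
  if (identical(rarefaction_g, "auto")) {
    gene_counts <- unlist(lapply(pops, function(s) {
      sub <- subset_individuals(g, sites == s)
      vapply(seq_along(g$loci),
             function(j) 2L * sum(!is.na(sub$a1[, j])), 1L)
    }))
    rarefaction_g <- max(2L, min(gene_counts[gene_counts > 0L]))
  }
  rows <- list()
  overall <- list()
  for (s in pops) {
    sub <- subset_individuals(g, sites == s)
    tab <- do.call(rbind, lapply(seq_along(g$loci), function(j) {
      N <- 2L * sum(!is.na(sub$a1[, j]))
      locus_summary(sub, j, rarefaction_g = min(rarefaction_g, N))
    }))
    rows[[s]] <- cbind(site = s, tab, stringsAsFactors = FALSE)
    overall[[s]] <- data.frame(
      site = s,
      mean_A = mean(tab$A), mean_Ar = mean(tab$Ar),
      mean_Ho = mean(tab$Ho), mean_He = mean(tab$He),
      Fis = if (sum(tab$He) > 0) sum(tab$He - tab$Ho) / sum(tab$He)
            else NA_real_,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "overall") <- do.call(rbind, overall)
  out
}

# Log conditional probability of a genotype table given its allele counts
# (Levene's distribution): P = n! prod(m_i!) 2^het / ((2n)! prod(n_ij!))
.log_table_prob <- function(tab) {
  n <- sum(tab)
  m <- rowSums(tab) + colSums(tab)  # allele copy counts (diag counts twice)
  het <- sum(tab[upper.tri(tab)]) + sum(tab[lower.tri(tab)])
  lgamma(n + 1) + sum(lgamma(m + 1)) + het * log(2) -
    lgamma(2 * n + 1) - sum(lgamma(tab + 1))
}

# genotype count table (k x k, upper-triangle convention not enforced:
# heterozygote ij counts split arbitrarily; we store in full symmetric-use
# form with counts in [i<=j])
.genotype_table <- function(a1, a2) {
  al <- sort(unique(c(a1, a2)))
  k <- length(al)
  tab <- matrix(0L, k, k)
  i <- match(pmin(a1, a2), al)
  j <- match(pmax(a1, a2), al)
  for (t in seq_along(i)) tab[i[t], j[t]] <- tab[i[t], j[t]] + 1L
  tab
}

#' Exact Hardy-Weinberg test by Markov chain Monte Carlo
#'
#' Guo-Thompson chain over genotype tables with fixed allele counts. The
#' test statistic is the conditional probability of the table under
#' Levene's distribution (two-sided "probability test"): the p-value is the
#' chain proportion of visited tables with probability less than or equal
#' to the observed table's. The chain proposes allele swaps between two
#' random genotypes and accepts by the Metropolis rule; batch means give a
#' Monte Carlo standard error.
#'
#' @param g a [genotype_matrix()] for one population.
#' @param locus locus name or index.
#' @param dememorization burn-in steps.
#' @param batches number of batches.
#' @param iters_per_batch chain steps per batch.
#' @param seed integer RNG seed, or `NULL`.
#' @return A list: `p`, `se`, `untestable` (logical; monomorphic or < 3
#'   individuals give `p = 1` by convention).
#' @export
hwe_exact_mcmc <- function(g, locus, dememorization = 1000L, batches = 100L,
                           iters_per_batch = 10000L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.character(locus)) locus <- match(locus, g$loci)
  a1 <- g$a1[, locus]; a2 <- g$a2[, locus]
  keep <- !is.na(a1)
  a1 <- a1[keep]; a2 <- a2[keep]
  n <- length(a1)
  if (n < 3L || length(unique(c(a1, a2))) < 2L)
    return(list(p = 1, se = 0, untestable = TRUE))
  # genotype list representation: two allele-index vectors, a1 <= a2
  al <- sort(unique(c(a1, a2)))
  cur1 <- match(pmin(a1, a2), al); cur2 <- match(pmax(a1, a2), al)
  tab <- .genotype_table(cur1, cur2)  # counts at [i <= j]
  lp_obs <- .log_table_prob(tab)
  lp_cur <- lp_obs
  log2 <- log(2)
  # Metropolis step: swap one allele between two random genotypes.
  # The genotype-class count table is maintained incrementally, so each
  # step is O(1); allele counts are invariant under the swap.
  step <- function() {
    pick <- sample.int(n, 2L)
    i <- pick[1]; j <- pick[2]
    oi1 <- cur1[i]; oi2 <- cur2[i]; oj1 <- cur1[j]; oj2 <- cur2[j]
    # swap one randomly chosen allele of i with one of j
    x <- if (stats::runif(1) < 0.5) oi1 else oi2
    y <- if (stats::runif(1) < 0.5) oj1 else oj2
    if (x == y) return(invisible(NULL))   # identity move (self-loop)
    keep_i <- if (x == oi1) oi2 else oi1
    keep_j <- if (y == oj1) oj2 else oj1
    ni1 <- min(keep_i, y); ni2 <- max(keep_i, y)
    nj1 <- min(keep_j, x); nj2 <- max(keep_j, x)
    # On the labeled-individual state space the Levene-conditional target
    # is proportional to 2^(#heterozygotes); the proposal multiplicity
    # (homozygotes offer two identical allele choices) enters as a
    # Hastings correction. The full table-probability change d (including
    # the genotype-count factorials) is tracked only for the statistic.
    c_fwd <- ((oi1 == x) + (oi2 == x)) * ((oj1 == y) + (oj2 == y))
    c_rev <- ((ni1 == y) + (ni2 == y)) * ((nj1 == x) + (nj2 == x))
    dhet <- log2 * ((ni1 != ni2) + (nj1 != nj2) -
                    (oi1 != oi2) - (oj1 != oj2))
    laccept <- dhet + log(c_rev) - log(c_fwd)
    d <- dhet
    d <- d + log(tab[oi1, oi2]); tab[oi1, oi2] <<- tab[oi1, oi2] - 1L
    d <- d + log(tab[oj1, oj2]); tab[oj1, oj2] <<- tab[oj1, oj2] - 1L
    d <- d - log(tab[ni1, ni2] + 1L); tab[ni1, ni2] <<- tab[ni1, ni2] + 1L
    d <- d - log(tab[nj1, nj2] + 1L); tab[nj1, nj2] <<- tab[nj1, nj2] + 1L
    if (log(stats::runif(1)) < laccept) {
      cur1[i] <<- ni1; cur2[i] <<- ni2
      cur1[j] <<- nj1; cur2[j] <<- nj2
      lp_cur <<- lp_cur + d
    } else { # roll the table back
      tab[oi1, oi2] <<- tab[oi1, oi2] + 1L
      tab[oj1, oj2] <<- tab[oj1, oj2] + 1L
      tab[ni1, ni2] <<- tab[ni1, ni2] - 1L
      tab[nj1, nj2] <<- tab[nj1, nj2] - 1L
    }
    invisible(NULL)
  }
  for (t in seq_len(dememorization)) step()
  batch_means <- numeric(batches)
  for (b in seq_len(batches)) {
    lp_cur <- .log_table_prob(tab)  # refresh against accumulated drift
    hits <- 0L
    for (t in seq_len(iters_per_batch)) {
      step()
      if (lp_cur <= lp_obs + 1e-9) hits <- hits + 1L
    }
    batch_means[b] <- hits / iters_per_batch
  }
  list(p = mean(batch_means),
       se = stats::sd(batch_means) / sqrt(batches),
       untestable = FALSE)
}

#' Two-locus linkage-disequilibrium permutation test
#'
#' G-statistic on the two-locus genotype contingency table; the null is
#' built by permuting the single-locus genotypes of one locus among
#' individuals. The p-value uses the add-one rule
#' `(1 + #(perm >= obs)) / (1 + n_perm)`, counting ties as exceedances.
#'
#' @param g a [genotype_matrix()] for one population.
#' @param locusA,locusB locus names or indices.
#' @param n_perm number of permutations (>= 1).
#' @param seed integer RNG seed, or `NULL`.
#' @return A list: `p`, `G`, `untestable` (TRUE when either locus is
#'   monomorphic, in which case `p = 1`).
#' @export
ld_permutation_test <- function(g, locusA, locusB, n_perm = 1000L,
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (n_perm < 1L) stop("n_perm must be >= 1")
  if (is.character(locusA)) locusA <- match(locusA, g$loci)
  if (is.character(locusB)) locusB <- match(locusB, g$loci)
  keep <- !is.na(g$a1[, locusA]) & !is.na(g$a1[, locusB])
  ga <- paste(g$a1[keep, locusA], g$a2[keep, locusA])
  gb <- paste(g$a1[keep, locusB], g$a2[keep, locusB])
  if (length(unique(ga)) < 2L || length(unique(gb)) < 2L)
    return(list(p = 1, G = NA_real_, untestable = TRUE))
  gstat <- function(x, y) {
    tab <- table(x, y)
    e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    nz <- tab > 0
    2 * sum(tab[nz] * log(tab[nz] / e[nz]))
  }
  obs <- gstat(ga, gb)
  exceed <- 0L
  for (b in seq_len(n_perm)) {
    if (gstat(ga, sample(gb)) >= obs - 1e-12) exceed <- exceed + 1L
  }
  list(p = (1 + exceed) / (1 + n_perm), G = obs, untestable = FALSE)
}

#' Private allele counts per population
#'
#' An allele is private to a population when it is observed there and in no
#' other population; counts are summed over loci.
#'
#' @param g a [genotype_matrix()].
#' @param metadata metadata data.frame with a `site` column.
#' @return Named integer vector of private-allele counts per population.
#' @export
private_alleles <- function(g, metadata) {
  sites <- .sites_for(g, metadata)
  pops <- unique(sites)
  if (length(pops) < 2L) stop("need >= 2 populations")
  out <- stats::setNames(integer(length(pops)), pops)
  for (j in seq_along(g$loci)) {
    present <- lapply(pops, function(s) {
      al <- c(g$a1[sites == s, j], g$a2[sites == s, j])
      unique(al[!is.na(al)])
    })
    names(present) <- pops
    for (s in pops) {
      others <- unique(unlist(present[setdiff(pops, s)]))
      out[s] <- out[s] + length(setdiff(present[[s]], others))
    }
  }
  out
}
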