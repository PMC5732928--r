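#' Mitochondrial summary statistics
#'
#' Computes the classic control-region table: sample size `n`, segregating
#' sites `S`, haplotype count `h`, haplotype diversity
#' `Hd = (n/(n-1)) (1 - sum f_i^2)` with its standard (Nei) variance,
#' nucleotide diversity per site `pi` (mean pairwise differences over
#' usable sites) with its standard variance, base composition, and
#' transition/transversion mutation counts. All counts use complete
#' deletion of gap/N-containing sites.
#'
#' @param aln a [haplotype_alignment()].
#' @return A list of class `mtdna_summary`: `n`, `S`, `h`, `Hd`, `Hd_sd`,
#'   `pi`, `pi_sd`, `mean_pairwise_diff`, `base_composition`,
#'   `transitions`, `transversions`, `L_usable`. All statistics are `NA`
#'   for a single sequence.
#' @export
mtdna_summary <- function(aln) {
  n <- length(aln$ids)
  L <- sum(aln$usable_sites)
  comp <- table(factor(aln$seq[, aln$usable_sites],
                       levels = c("A", "C", "G", "T")))
  comp <- as.numeric(comp) / sum(comp)
  names(comp) <- c("A", "C", "G", "T")
  ts <- sum(aln$site_classes$transitions)
  tv <- sum(aln$site_classes$transversions)
  if (n < 2L) {
    return(structure(list(n = n, S = 0L, h = 1L, Hd = NA_real_,
                          Hd_sd = NA_real_, pi = NA_real_, pi_sd = NA_real_,
                          mean_pairwise_diff = NA_real_,
                          base_composition = comp, transitions = ts,
                          transversions = tv, L_usable = L),
                     class = "mtdna_summary"))
  }
  S <- segregating_sites(aln)
  h <- aln$h
  f <- as.numeric(table(aln$haplotype)) / n
  Hd <- n / (n - 1) * (1 - sum(f^2))
  # Nei (1987) variance of haplotype diversity
  s2 <- sum(f^2)
  Hd_var <- 2 / (n * (n - 1)) *
    (2 * (n - 2) * (sum(f^3) - s2^2) + s2 - s2^2)
  d <- .pairwise_diff_matrix(aln$seq[, aln$usable_sites, drop = FALSE])
  k <- mean(d[upper.tri(d)])
  pi <- k / L
  # standard total variance of pi (no recombination)
  pi_var <- (n + 1) / (3 * (n - 1) * L) * pi +
    2 * (n^2 + n + 3) / (9 * n * (n - 1)) * pi^2
  structure(list(n = n, S = S, h = h, Hd = Hd, Hd_sd = sqrt(max(Hd_var, 0)),
                 pi = pi, pi_sd = sqrt(max(pi_var, 0)),
                 mean_pairwise_diff = k, base_composition = comp,
                 transitions = ts, transversions = tv, L_usable = L),
            class = "mtdna_summary")
}

#' @export
print.mtdna_summary <- function(x, ...) {
  cat(sprintf("mtdna_summary: n=%d S=%d h=%d Hd=%.3f (%.3f) pi=%.4f (%.4f)\n",
              x$n, x$S, x$h, x$Hd, x$Hd_sd, x$pi, x$pi_sd))
  invisible(x)
}

# log unsigned Stirling numbers of the first kind, rows 1..n
# returns vector logS[k] for the requested n
.log_stirling_first <- function(n) {
  cur <- 0  # n = 1: s(1,1) = 1
  if (n == 1L) return(cur)
  for (m in seq_len(n - 1L)) {
    # build row m+1 from row m: s(m+1, k) = s(m, k-1) + m * s(m, k)
    nxt <- numeric(m + 1L)
    prev <- c(cur, -Inf)              # s(m, k) for k = 1..m+1
    shifted <- c(-Inf, cur)           # s(m, k-1)
    a <- shifted
    b <- prev + log(m)
    mx <- pmax(a, b)
    nxt <- ifelse(is.infinite(mx), -Inf, mx + log(exp(a - mx) + exp(b - mx)))
    cur <- nxt
  }
  cur
}

#' Probability of observing at least k alleles under Ewens' sampling
#'
#' `Pr(K >= k | theta, n)` with `Pr(K = k) = |s(n,k)| theta^k / theta^(n)`
#' (rising factorial), computed in log space via Stirling numbers of the
#' first kind.
#'
#' @param k allele (haplotype) count threshold.
#' @param n sample size.
#' @param theta scaled mutation rate.
#' @return The tail probability.
#' @export
ewens_k_tail <- function(k, n, theta) {
  logS <- .log_stirling_first(n)
  log_rising <- sum(log(theta + seq(0L, n - 1L)))
  logp <- logS + seq_len(n) * log(theta) - log_rising
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  sum(p[seq(k, n)])
}

#' Fu's Fs neutrality statistic
#'
#' Uses the observed mean pairwise difference as the theta estimate and
#' computes `S' = Pr(K >= h_obs | theta, n)` under Ewens' sampling
#' distribution; `Fs = ln(S' / (1 - S'))`. An excess of haplotypes for the
#' observed pairwise diversity (as after expansion) drives Fs strongly
#' negative.
#'
#' @param aln a [haplotype_alignment()].
#' @return The Fs statistic (`NA` if there is a single haplotype or the
#'   tail probability is numerically 0 or 1).
#' @export
fu_fs <- function(aln) {
  n <- length(aln$ids)
  if (n < 2L || aln$h < 2L) return(NA_real_)
  d <- .pairwise_diff_matrix(aln$seq[, aln$usable_sites, drop = FALSE])
  theta_pi <- mean(d[upper.tri(d)])
  .fs_from_parts(aln$h, n, theta_pi)
}

.fs_from_parts <- function(k_obs, n, theta_pi) {
  if (k_obs < 2L || theta_pi <= 0) return(NA_real_)
  sp <- ewens_k_tail(k_obs, n, theta_pi)
  if (sp <= 0 || sp >= 1) return(NA_real_)
  log(sp / (1 - sp))
}

#' Ramos-Onsins & Rozas R2 statistic
#'
#' `R2 = sqrt( (1/n) sum_i (U_i - k/2)^2 ) / S` where `U_i` is the number
#' of singleton mutations carried by sequence i (minor-state count 1,
#' outgroup-free), `k` the mean pairwise difference and `S` the number of
#' segregating sites. Small values indicate the excess of singletons
#' relative to pairwise diversity expected after population growth.
#'
#' @param aln a [haplotype_alignment()].
#' @return The R2 statistic (`NA` when `S = 0`).
#' @export
r2_statistic <- function(aln) {
  n <- length(aln$ids)
  if (n < 2L) return(NA_real_)
  seqs <- aln$seq[, aln$usable_sites, drop = FALSE]
  S <- segregating_sites(aln)
  if (S == 0L) return(NA_real_)
  U <- numeric(n)
  for (j in seq_len(ncol(seqs))) {
    tab <- table(seqs[, j])
    if (length(tab) < 2L) next
    singles <- names(tab)[tab == 1L]
    for (b in singles) U[which(seqs[, j] == b)] <- U[which(seqs[, j] == b)] + 1
  }
  d <- .pairwise_diff_matrix(seqs)
  k <- mean(d[upper.tri(d)])
  sqrt(mean((U - k / 2)^2)) / S
}

.r2_from_incidence <- function(inc) {
  n <- nrow(inc); S <- ncol(inc)
  if (S == 0L) return(NA_real_)
  cs <- colSums(inc)
  U <- numeric(n)
  for (j in seq_len(S)) {
    if (cs[j] == 1L) {
      U[inc[, j] == 1L] <- U[inc[, j] == 1L] + 1
    } else if (cs[j] == n - 1L) {
      U[inc[, j] == 0L] <- U[inc[, j] == 0L] + 1
    }
  }
  k <- sum(cs * (n - cs)) / choose(n, 2)
  sqrt(mean((U - k / 2)^2)) / S
}

.fs_from_incidence <- function(inc) {
  n <- nrow(inc)
  cs <- colSums(inc)
  k_obs <- nrow(unique(inc))
  theta_pi <- sum(cs * (n - cs)) / choose(n, 2)
  .fs_from_parts(k_obs, n, theta_pi)
}

#' Coalescent p-values for Fu's Fs and R2
#'
#' Simulates constant-size coalescent samples conditioned on the observed
#' sample size and number of segregating sites (fixed-S: mutations placed
#' on the genealogy proportionally to branch length), recomputes both
#' statistics, and returns lower-tail probabilities
#' `Pr(sim <= obs)` for each (small Fs and small R2 both signal growth).
#'
#' @param fs_obs,r2_obs observed statistics (either may be `NA`).
#' @param n sample size.
#' @param S number of segregating sites.
#' @param n_sims coalescent replicates (>= 1000).
#' @param seed integer RNG seed, or `NULL`.
#' @return A list: `p_fs`, `p_r2`, `sim_fs`, `sim_r2`.
#' @export
neutrality_pvalues <- function(fs_obs, r2_obs, n, S, n_sims = 10000L,
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (n_sims < 1000L) stop("n_sims must be >= 1000")
  sim_fs <- sim_r2 <- rep(NA_real_, n_sims)
  for (b in seq_len(n_sims)) {
    inc <- .coal_fixed_s(.coal_tree(n), S)
    sim_fs[b] <- .fs_from_incidence(inc)
    sim_r2[b] <- .r2_from_incidence(inc)
  }
  p_tail <- function(obs, sims) {
    if (is.na(obs)) return(NA_real_)
    sims <- sims[!is.na(sims)]
    (1 + sum(sims <= obs + 1e-12)) / (1 + length(sims))
  }
  list(p_fs = p_tail(fs_obs, sim_fs), p_r2 = p_tail(r2_obs, sim_r2),
       sim_fs = sim_fs, sim_r2 = sim_r2)
}
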