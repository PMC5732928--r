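# Shared fixture builders: everything is generated in code at test time.

# equifrequent allele-frequency list: n_loci loci x n_alleles alleles
equifreqs <- function(n_loci = 20L, n_alleles = 10L) {
  rep(list(stats::setNames(rep(1 / n_alleles, n_alleles),
                           seq_len(n_alleles))), n_loci)
}

# random genotype matrix with optional missingness (codes <= 999 so it
# round-trips through 3-digit GenePop encoding)
random_genotypes <- function(n = 10L, L = 4L, max_allele = 8L,
                             p_missing = 0) {
  a <- matrix(sample.int(max_allele, n * L, replace = TRUE), n, L)
  b <- matrix(sample.int(max_allele, n * L, replace = TRUE), n, L)
  if (p_missing > 0) {
    miss <- matrix(stats::runif(n * L) < p_missing, n, L)
    a[miss] <- NA_integer_; b[miss] <- NA_integer_
  }
  genotype_matrix(a, b)
}

# random equal-length alignment over ACGT
random_alignment <- function(n = 8L, L = 30L) {
  m <- matrix(sample(c("A", "C", "G", "T"), n * L, replace = TRUE), n, L)
  haplotype_alignment(m)
}

# exact conditional expectation of unbiased He given k alleles in n genes
# under the infinite-alleles model, by enumerating allele configurations
# (Ewens sampling formula conditioned on K = k)
ewens_conditional_he <- function(n, k) {
  parts_nk <- function(n, k, maxp = n) {
    if (k == 1L) return(if (n <= maxp) list(n) else list())
    out <- list()
    for (first in seq(min(n - k + 1L, maxp), ceiling(n / k))) {
      for (rest in parts_nk(n - first, k - 1L, first))
        out[[length(out) + 1L]] <- c(first, rest)
    }
    out
  }
  ps <- parts_nk(n, k)
  w <- vapply(ps, function(lam) {
    aj <- table(lam)
    exp(lgamma(n + 1) - sum(log(as.numeric(names(aj))) * aj) -
          sum(lgamma(aj + 1)))
  }, numeric(1))
  he <- vapply(ps, function(lam) n / (n - 1) * (1 - sum((lam / n)^2)),
               numeric(1))
  sum(w * he) / sum(w)
}

# independent quadratic-form oracles for haplotype and nucleotide diversity
oracle_hd <- function(hap_counts) {
  n <- sum(hap_counts)
  f <- hap_counts / n
  n / (n - 1) * (1 - sum(f^2))
}
oracle_pi <- function(seq_strings) {
  m <- do.call(rbind, strsplit(seq_strings, ""))
  n <- nrow(m)
  tot <- 0
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n))
    tot <- tot + sum(m[i, ] != m[j, ])
  tot / choose(n, 2) / ncol(m)
}
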