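#!/usr/bin/env Rscript
# 02 -- Nuclear within-population diversity.
#
# Per-site, per-locus A, rarefied Ar, Ho, unbiased He and F_IS; exact HWE
# tests (MCMC with reduced chain lengths; the package default mirrors the
# classic 1,000/100/10,000 settings) and Holm-Bonferroni decisions; LD
# permutation tests for the first few locus pairs in the largest site;
# private allele counts.

suppressPackageStartupMessages(library(riverkin))

gp <- read_genepop("results/data/broodstock.gen")
md <- read_metadata_csv("results/data/metadata.csv")
g <- gp$genotypes

tab <- diversity_table(g, md, rarefaction_g = "auto")
utils::write.csv(tab, "results/diversity_per_locus.csv", row.names = FALSE)
ov <- attr(tab, "overall")
utils::write.csv(ov, "results/diversity_overall.csv", row.names = FALSE)

cat("Per-site means (A / Ar / Ho / He / multilocus Fis):\n")
print(ov, row.names = FALSE, digits = 3)

# HWE per locus within the two large sites
sites <- md$site[match(g$ids, md$id)]
hwe_rows <- list()
for (s in c("PRJ", "MUR")) {
  sub <- subset_individuals(g, sites == s)
  for (j in seq_along(g$loci)) {
    res <- hwe_exact_mcmc(sub, j, dememorization = 1000, batches = 20,
                          iters_per_batch = 2000, seed = 100 + j)
    hwe_rows[[length(hwe_rows) + 1L]] <- data.frame(
      site = s, locus = g$loci[j], p = res$p, mc_se = res$se,
      untestable = res$untestable)
  }
}
hwe <- do.call(rbind, hwe_rows)
hwe$reject_holm <- holm_bonferroni(hwe$p, 0.05)
utils::write.csv(hwe, "results/hwe_tests.csv", row.names = FALSE)
cat(sprintf("\nHWE: %d of %d testable locus-site combinations rejected after
  Holm-Bonferroni correction\n",
            sum(hwe$reject_holm[!hwe$untestable]), sum(!hwe$untestable)))

# LD inside MUR for the first 10 locus pairs
mur <- subset_individuals(g, sites == "MUR")
pairs <- utils::combn(seq_along(g$loci), 2)[, 1:10]
ld <- apply(pairs, 2, function(pr) {
  ld_permutation_test(mur, pr[1], pr[2], n_perm = 499, seed = pr[1] * 100 +
                        pr[2])$p
})
ld_tab <- data.frame(locusA = g$loci[pairs[1, ]], locusB = g$loci[pairs[2, ]],
                     p = ld, reject_holm = holm_bonferroni(ld, 0.05))
utils::write.csv(ld_tab, "results/ld_tests.csv", row.names = FALSE)
cat(sprintf("LD (MUR, 10 pairs): %d rejected after Holm-Bonferroni\n",
            sum(ld_tab$reject_holm)))

priv <- private_alleles(g, md)
utils::write.csv(data.frame(site = names(priv), private_alleles = priv),
                 "results/private_alleles.csv", row.names = FALSE)
cat("Private alleles:", paste(names(priv), priv, sep = "=", collapse = ", "),
    "\n")
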