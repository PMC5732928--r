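#!/usr/bin/env Rscript
# 01 -- Build the synthetic study dataset.
#
# The real broodstock genotypes were never published, so every downstream
# script runs on a synthetic stand-in with the study's structure: 70
# individuals from five river sites (PSP 1, PRJ 24, PRE 5, POM 3, MUR 37)
# falling into three genetic clusters (PRJ; MUR; POM/PSP/PRE mixed), 20
# microsatellite loci, 44 females / 21 males / 5 of unknown sex (all in
# MUR), and a 791-bp control-region alignment with ~38 segregating sites
# and a strong transition bias.

suppressPackageStartupMessages(library(riverkin))

seed <- 20170196L
out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

# three drifted clusters, subsampled to the study's site sizes
sp <- sim_structured_pops(n_pops = 3, n_per_pop = 37, divergence = 0.6,
                          theta = 4, n_loci = 20, seed = seed)
keep <- c(1:24,            # cluster 1 -> PRJ (24)
          38:74,           # cluster 2 -> MUR (37)
          75:83)           # cluster 3 -> POM (3) + PSP (1) + PRE (5)
g <- subset_individuals(sp$genotypes, keep)
site <- c(rep("PRJ", 24), rep("MUR", 37),
          rep("POM", 3), "PSP", rep("PRE", 5))
ids <- sprintf("%s%02d", site, stats::ave(seq_along(site), site,
                                          FUN = seq_along))
g$ids <- ids; rownames(g$a1) <- rownames(g$a2) <- ids

# sexes: 44 F, 21 M, 5 U; the unknowns sit in MUR as in the study
set.seed(seed + 1)
sex <- rep("F", 70)
sex[sample(which(site != "MUR"), 7)] <- "M"
mur <- which(site == "MUR")
sex[sample(mur, 14)] <- "M"
u_idx <- sample(setdiff(mur, which(sex == "M")), 5)
sex[u_idx] <- "U"
stopifnot(sum(sex == "F") == 44, sum(sex == "M") == 21, sum(sex == "U") == 5)
md <- sample_metadata(ids, site, sex)

# control region: theta tuned so Watterson's E[S] ~ 38 over 791 bp
theta_mt <- 38 / sum(1 / (1:69))
aln <- sim_mtdna(70, 791, theta_mt, ts_bias = 34 / 7, seed = seed + 2)
aln$ids <- ids
rownames(aln$seq) <- ids

write_genepop(g, md, file.path(out, "broodstock.gen"),
              title = "synthetic broodstock microsatellites")
utils::write.csv(md, file.path(out, "metadata.csv"), row.names = FALSE)
write_fasta_alignment(aln, file.path(out, "mtcr_synthetic.fasta"))

cat("Synthetic dataset written to", out, "\n")
cat(sprintf("  %d individuals, %d loci; sites: %s\n",
            length(ids), length(g$loci),
            paste(names(table(site)), table(site), collapse = ", ")))
cat(sprintf("  mtDNA: %d bp, %d segregating sites, %d haplotypes\n",
            aln$L, segregating_sites(aln), aln$h))
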