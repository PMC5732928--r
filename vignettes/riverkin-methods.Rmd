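---
title: "Models and methods behind riverkin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind riverkin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

riverkin re-implements, as one coherent package, the analysis programme a
conservation-genetics study of a fragmented river fish typically runs:
within-population diversity, between-population differentiation,
demographic-history tests, individual clustering, haplotype networks, and
kinship-based mating advice. This vignette records the models, the
defaults, and the numerical decisions — especially where the published
methods leave genuine choices open. It states no empirical result that
the test suite or `scripts/acceptance.R` does not itself compute.

## The synthetic-data generator

Individual-level genotypes for studies of this kind are usually deposited
only as locus sequences and haplotypes, not as genotype tables, so the
package treats a simulator as first-class code. Its defaults encode the
study conditions the analyses assume:

* **Equilibrium microsatellites** (`sim_population_equilibrium`): per
  locus, a Kingman coalescent for 2n genes; mutations Poisson with rate
  θ/2 per unit branch length; allele states realized under IAM (every
  mutation a novel allele), SMM (±1 repeat with equal probability), or
  TPM. The TPM is realized per mutation — a single ±1 step with
  probability `p_single = 0.70`, otherwise an IAM-type novel allele —
  reading the classic "70% SMM / 30% IAM" mixture literally rather than
  as a geometric multi-step variant. Coalescent rather than forward
  simulation is used for equilibrium purely for speed; the forward
  Wright–Fisher phase is reserved for the post-crash period of
  `sim_bottleneck`, where the non-equilibrium dynamics are the point.
* **Pedigree pairs** (`sim_pedigree_pairs`): unrelated, half-sib,
  full-sib and parent–offspring pairs are built by explicit parental
  construction — founders drawn under Hardy–Weinberg from the supplied
  frequencies, offspring by Mendelian segregation — never by sampling
  IBD states directly from the (k0,k1,k2) coefficients. Founder gene
  copies carry hidden ancestry labels, so the realized IBD sharing is
  observable and is property-tested against the theoretical
  coefficients.
* **Structured populations** (`sim_structured_pops`): an ancestral
  equilibrium gene pool split into demes that drift independently
  (Wright–Fisher resampling of a 2N = 200-gene pool, no migration, no
  new mutation) for `divergence` units of 2N generations. Divergence 0
  leaves every deme sampling the ancestral pool, so panmixia is exact.
* **mtDNA** (`sim_mtdna`): a coalescent genealogy with finite-sites
  mutation — sites drawn uniformly per mutation, so repeat hits are
  possible — and a transition:transversion rate ratio defaulting to
  34:7, with an A-rich control-region base composition. θ is typically
  set from Watterson's expectation E[S] = θ·Σ1/i.

What the generator does *not* emulate: null alleles, allele-size binning
error, selection, migration, linkage. Passing tests therefore certify
the statistics and their calibration under the stated models, not
robustness to genotyping artefacts — the published workflow handles
those with a separate screening step that is explicitly out of scope
here.

## Numerical and statistical decisions

**Hardy–Weinberg exact test.** The Guo–Thompson chain runs on the
labeled-individual state space, where the Levene conditional
distribution is proportional to 2^(#heterozygotes). The Metropolis
ratio is that factor with a Hastings correction for proposal
multiplicity (a homozygote offers the same allele twice); the full
conditional table probability is tracked only as the test statistic
(two-sided "probability test" dialect: p = chain proportion of tables no
more probable than the observed one). Batch means give the Monte-Carlo
SE, and the chain is validated against complete enumeration for two
alleles.

**Jost's D.** Nei–Chesser corrected Hs and Ht; the multi-locus value is
the arithmetic mean of per-locus D (a harmonic-mean alternative was
considered and rejected as needlessly fragile for loci with D near 0).
Note the bias corrections make D slightly negative for identical finite
samples — of order 1/n — which is why tests assert near-zero rather than
exact zero there. The bootstrap null re-draws genotypes under pooled
allele frequencies with sample sizes preserved.

**AMOVA ϕ_ST.** Raw pairwise difference counts (no substitution-model
correction — none is specified in the workflows this mirrors), standard
two-level variance components, permutation of individuals among
populations, negative estimates reported as computed. Populations with a
single sequence join comparisons but contribute no within-group degrees
of freedom.

**Bottleneck test.** The equilibrium He distribution conditional on the
observed allele count is obtained by tuning θ (bisection on E[k]:
Ewens' closed form under IAM, a simulated estimate under SMM/TPM) and
rejection-sampling replicates with exactly k alleles; results are
memoised per (model, k, n) within a session. One deliberate deviation:
the one-tailed Wilcoxon signed-rank is centred at the conditional
*median* of that distribution, while the per-locus report keeps the
conventional mean-based DH and DH/sd columns. The conditional He
distribution is left-skewed, so mean-centred signs are positive with
probability ≈0.57–0.60 under equilibrium and the signed-rank test
rejects at roughly four times the nominal rate; median-centring restores
the nominal test size (verified by the 500-replicate calibration in the
acceptance suite) without costing the power that makes the test useful.
Conditional on k the models order as Heq(IAM) < Heq(TPM) < Heq(SMM) —
homoplasy means SMM needs more mutation pressure to show k alleles —
which is why IAM flags excess most readily.

**Fu's Fs and R2.** Fs uses the mean pairwise difference as θ̂ and the
Ewens tail probability S′ = Pr(K ≥ k_obs), computed in log space via
Stirling numbers of the first kind; Fs = ln(S′/(1−S′)), negative when
haplotypes are in excess. R2 counts singletons outgroup-free: a site
whose minor state occurs in exactly one sequence contributes one
singleton to that sequence, whichever state is ancestral. Significance
for both comes from constant-size coalescent replicates conditioned on
the observed number of segregating sites (fixed-S: mutations placed on
the genealogy proportionally to branch length); θ-conditioning was the
alternative and is not exposed because the fixed-S convention matches
the cited practice.

**DAPC.** Columns are centred/scaled, PCA-reduced, and LDA is run on the
a priori site labels. Membership probabilities are a softmax of negative
half squared Euclidean distances to group centroids in discriminant
space — a documented dialect; other implementations differ in detail
but agree wherever groups separate. The α-score (observed correct
reassignment minus its mean over 10 seeded label randomisations) picks
the retained PC count; candidates start at k−1 PCs because discriminating
k groups needs k−1 axes, and a single PC can otherwise win the noisy
score by chance and cost assignments.

**Neighbour-joining.** Saitou–Nei agglomeration via ape; negative branch
lengths are clamped to zero with the deficit moved to the sibling edge,
keeping path lengths as close to additive as the clamp allows.

**Median-joining networks.** ε = 0 by default. Nodes are observed
haplotypes over variable sites; iteratively, triplets with at least two
links in the current minimum-spanning network propose their sitewise-
majority median, retained when its star connection is strictly cheaper
than linking the triplet within the network; finally, median nodes whose
removal leaves the spanning cost unchanged are pruned. Sites with more
than two states take the majority with a deterministic fallback to the
first sequence's state and are flagged on the graph. A spanning network
keeps every tied alternative connection, so the guaranteed invariant is
that spanning the final node set costs no more than an MST over observed
haplotypes alone.

**Relatedness estimators.** The four classical moment estimators follow
their published per-locus forms and locus weightings (ratio of sums for
Queller–Goodnight and Li; information weights for Lynch–Ritland;
(k−1)-weights for Ritland), symmetrised over reference directions where
the raw formula is asymmetric. The Wang-type estimator models the
similarity-category probabilities (identical / hom–het sharing /
het–het sharing one / none) as linear in (k1, k2) and solves the
stacked moment equations by ordinary least squares across loci — a
weighting dialect that preserves unbiasedness, which is what the
calibration tests check. The dyadic ML estimator maximises the mixture
likelihood over IBD modes by EM (tolerance 1e-8 on the log-likelihood,
best of five seeded simplex starts), over (k0,k1,k2) or the nine
Jacquard coefficients; r̂ = k1/2 + k2 (equivalently 2Δ1 + Δ3 + Δ5 + Δ7
+ Δ8/2) and is bounded in [0,1] — which also gives it a small upward
bias for truly unrelated pairs. Genotyping-error accommodation is not
implemented (error rate fixed at 0). Reference allele frequencies
default to the full sample including the focal pair. A triadic
(three-individual) likelihood estimator is deliberately not provided;
the dyadic ML estimator is the likelihood-based advisor. Individual
inbreeding coefficients are exposed as the per-individual ML analogue
(`individual_inbreeding`), for ranking candidates only — no endogamy
threshold is asserted, because none is established for this setting.

**Mating advisor.** Thresholds are the standard theoretical category
values: r < 0.25 advisable, 0.25 ≤ r ≤ 0.5 marginal (closed interval,
per the "between 0.25 and 0.5" convention), r > 0.5 inadvisable. The
enumeration lists every female × male pair plus, for each unknown-sex
fish, a pair with every other individual — which double-lists
unknown–unknown pairs, reproducing the classic F·M + U·(N−1) arithmetic
(44·21 + 5·69 = 1,269); duplicates are flagged and `unique_pairs = TRUE`
gives the deduplicated count. The two-estimator consensus takes the more
severe category; the rule is stated here because consensus tables in the
field rarely state theirs.

## Problem sizes

The test suite and acceptance script use desk-scale sizes chosen to make
Monte-Carlo tolerances meaningful: 5,000 pairs per pedigree category for
estimator calibration (3 Monte-Carlo SE bounds), 500 equilibrium
datasets of 25 individuals × 15 loci for the bottleneck test size (with
1,000 conditional replicates per allele count, shared across loci), 20
seeded replicates of three 25-individual demes at divergence 1.0 (in 2N
generations) for structure recovery, and 1,000–5,000 coalescent
replicates for neutrality p-values. Exact-formula oracles (He, Ar, Hd,
π, D, ϕ_ST, R2, Fs, NJ on additive matrices, Steiner search on 3-site
toys) are checked to 1e-10 or better.

## Known limitations

* Moment estimators are unbounded; on few loci, single-pair estimates
  routinely leave [0,1]. Category means, not single pairs, are the
  calibrated quantity.
* Relatedness references computed from a structured sample conflate
  population-level allele sharing with pedigree kinship; mating
  categories on strongly structured broodstock are conservative
  (more pairs look related).
* The bottleneck test conditions on the allele count via a tuned θ;
  under SMM/TPM the conditional distribution retains a weak θ
  dependence that the median-centring absorbs at the calibration sizes
  tested, but extreme allele counts at tiny samples remain noisy.
* Median-joining with many multistate sites falls back to a
  deterministic majority recode; for deeply homoplasious alignments a
  quasi-median network would be more faithful.
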