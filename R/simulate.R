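#' Microsatellite mutation model specification
#'
#' Three classic models: `IAM` (every mutation creates a never-before-seen
#' allele), `SMM` (each mutation shifts the repeat count by +/-1 with equal
#' probability), and `TPM` (two-phase: each mutation is a single +/-1 step
#' with probability `p_single`, otherwise an IAM-type novel allele). The
#' default `p_single = 0.70` gives the common 70% SMM / 30% IAM two-phase
#' mixture.
#'
#' @param kind one of `"IAM"`, `"SMM"`, `"TPM"`.
#' @param p_single probability that a TPM mutation is a single step.
#' @return An object of class `mutation_model`.
#' @export
mutation_model <- function(kind = c("IAM", "SMM", "TPM"), p_single = 0.70) {
  kind <- match.arg(kind)
  if (p_single < 0 || p_single > 1) stop("p_single must lie in [0, 1]")
  structure(list(kind = kind, p_single = p_single), class = "mutation_model")
}

#' Pedigree relationship category
#'
#' Standard non-inbred relationship categories with their IBD-state
#' probabilities (k0, k1, k2) and expected relatedness r = k1/2 + k2:
#' unrelated `U` (1,0,0; r = 0), half-sib `HS` (1/2,1/2,0; r = 0.25),
#' full-sib `FS` (1/4,1/2,1/4; r = 0.5), parent-offspring `PO` (0,1,0;
#' r = 0.5).
#'
#' @param label one of `"U"`, `"HS"`, `"FS"`, `"PO"`.
#' @return A list with `label`, `k` (numeric length 3) and `r`.
#' @export
pedigree_category <- function(label = c("U", "HS", "FS", "PO")) {
  label <- match.arg(label)
  k <- switch(label,
              U  = c(1, 0, 0),
              HS = c(0.5, 0.5, 0),
              FS = c(0.25, 0.5, 0.25),
              PO = c(0, 1, 0))
  list(label = label, k = k, r = k[2] / 2 + k[3])
}

#' Simulate genotype pairs of a known pedigree relationship
#'
#' Pairs are generated by explicit parental construction: founders are drawn
#' from the supplied allele frequencies under Hardy-Weinberg, and offspring
#' are produced by Mendelian segregation according to the category's pedigree
#' (FS: two shared parents; HS: one shared parent; PO: a parent and its
#' offspring; U: independent draws). Founder gene copies carry hidden
#' ancestry labels, so realized identity-by-descent sharing is observable in
#' the returned `ibd` matrix.
#'
#' @param freqs list of per-locus named allele-frequency vectors (names are
#'   allele codes; each vector sums to 1).
#' @param category a [pedigree_category()] or its label.
#' @param n_pairs number of pairs to simulate.
#' @param seed integer RNG seed, or `NULL` to use the current RNG state.
#' @return A list with elements `x`, `y` (two [genotype_matrix()] objects,
#'   row i of each forming pair i), `ibd` (integer matrix pairs x loci of
#'   realized IBD allele-pair counts, 0/1/2), and `category`.
#' @export
sim_pedigree_pairs <- function(freqs, category, n_pairs, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.character(category)) category <- pedigree_category(category)
  if (n_pairs < 1L) stop("n_pairs must be >= 1")
  freqs <- .check_freqs(freqs)
  if (all(vapply(freqs, length, 1L) == 1L))
    warning("all loci monomorphic: pairs are uninformative")
  L <- length(freqs)
  x1 <- x2 <- y1 <- y2 <- matrix(NA_integer_, n_pairs, L)
  ibd <- matrix(0L, n_pairs, L)
  for (j in seq_len(L)) {
    al <- as.integer(names(freqs[[j]]))
    p <- unname(freqs[[j]])
    draw <- function() sample(al, n_pairs, replace = TRUE, prob = p)
    pick <- function(g1, g2) {       # Mendelian segregation
      takes1 <- stats::runif(n_pairs) < 0.5
      ifelse(takes1, g1, g2)
    }
    # founder genes with ancestry labels 1..6 (labels parallel the codes)
    switch(category$label,
      U = {
        x1[, j] <- draw(); x2[, j] <- draw()
        y1[, j] <- draw(); y2[, j] <- draw()
        # labels all distinct; ibd stays 0
      },
      PO = {
        # pair = (parent P, offspring of P x M)
        p1 <- draw(); p2 <- draw(); m1 <- draw(); m2 <- draw()
        sel_p <- stats::runif(n_pairs) < 0.5   # which of P's genes is passed
        sel_m <- stats::runif(n_pairs) < 0.5
        x1[, j] <- p1; x2[, j] <- p2
        y1[, j] <- ifelse(sel_p, p1, p2)
        y2[, j] <- ifelse(sel_m, m1, m2)
        ibd[, j] <- 1L
      },
      FS = {
        p1 <- draw(); p2 <- draw(); q1 <- draw(); q2 <- draw()
        sa <- stats::runif(n_pairs) < 0.5; sb <- stats::runif(n_pairs) < 0.5
        sc <- stats::runif(n_pairs) < 0.5; sd <- stats::runif(n_pairs) < 0.5
        x1[, j] <- ifelse(sa, p1, p2); x2[, j] <- ifelse(sb, q1, q2)
        y1[, j] <- ifelse(sc, p1, p2); y2[, j] <- ifelse(sd, q1, q2)
        ibd[, j] <- (sa == sc) + (sb == sd)
      },
      HS = {
        # shared parent P; other parents Q (for x) and R (for y)
        p1 <- draw(); p2 <- draw()
        q1 <- draw(); q2 <- draw(); r1 <- draw(); r2 <- draw()
        sa <- stats::runif(n_pairs) < 0.5; sc <- stats::runif(n_pairs) < 0.5
        x1[, j] <- ifelse(sa, p1, p2)
        x2[, j] <- ifelse(stats::runif(n_pairs) < 0.5, q1, q2)
        y1[, j] <- ifelse(sc, p1, p2)
        y2[, j] <- ifelse(stats::runif(n_pairs) < 0.5, r1, r2)
        ibd[, j] <- as.integer(sa == sc)
      })
  }
  loci <- names(freqs)
  if (is.null(loci)) loci <- paste0("loc", seq_len(L))
  list(x = genotype_matrix(x1, x2, ids = paste0("x", seq_len(n_pairs)),
                           loci = loci),
       y = genotype_matrix(y1, y2, ids = paste0("y", seq_len(n_pairs)),
                           loci = loci),
       ibd = ibd, category = category)
}

.check_freqs <- function(freqs) {
  if (!is.list(freqs)) stop("freqs must be a list of per-locus vectors")
  for (j in seq_along(freqs)) {
    p <- freqs[[j]]
    if (is.null(names(p))) names(freqs[[j]]) <- seq_along(p)
    if (abs(sum(p) - 1) > 1e-8)
      stop("allele frequencies at locus ", j, " do not sum to 1")
  }
  freqs
}

#' Simulate a mutation-drift-equilibrium microsatellite sample
#'
#' Per locus, a standard neutral coalescent genealogy is simulated for
#' `2 * n_individuals` genes, mutations are dropped as Poisson with rate
#' `theta/2` per unit branch length, and allele states are realized under
#' the mutation model. Loci are independent; genes are paired into diploid
#' individuals.
#'
#' @param n_individuals number of diploid individuals.
#' @param n_loci number of loci.
#' @param theta scaled mutation rate 4*N*mu per locus (> 0).
#' @param model a [mutation_model()].
#' @param seed integer RNG seed, or `NULL`.
#' @return A [genotype_matrix()].
#' @export
sim_population_equilibrium <- function(n_individuals, n_loci, theta,
                                       model = mutation_model("IAM"),
                                       seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (theta <= 0) stop("theta must be > 0")
  n_genes <- 2L * n_individuals
  a1 <- a2 <- matrix(NA_integer_, n_individuals, n_loci)
  for (j in seq_len(n_loci)) {
    genes <- .coal_microsat(.coal_tree(n_genes), theta, model)
    a1[, j] <- genes[seq(1L, n_genes, by = 2L)]
    a2[, j] <- genes[seq(2L, n_genes, by = 2L)]
  }
  genotype_matrix(a1, a2)
}

#' Simulate a recently bottlenecked microsatellite sample
#'
#' An equilibrium gene pool is simulated by coalescent, then propagated
#' forward by Wright-Fisher resampling at the reduced size
#' `pool_size * crash_factor` for `generations_since` generations (no new
#' mutation during the short post-crash phase), and finally
#' `n_individuals` diploids are sampled from the crashed pool. With
#' `crash_factor = 1` the forward phase is skipped and the result is an
#' equilibrium sample.
#'
#' @inheritParams sim_population_equilibrium
#' @param crash_factor ratio of post-crash to pre-crash size, in (0, 1].
#' @param generations_since generations since the crash (>= 1).
#' @param pool_size pre-crash diploid population size for the forward phase.
#' @return A [genotype_matrix()].
#' @export
sim_bottleneck <- function(n_individuals, n_loci, theta,
                           model = mutation_model("IAM"),
                           crash_factor, generations_since,
                           pool_size = 200L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (crash_factor <= 0 || crash_factor > 1) stop("crash_factor must be in (0, 1]")
  if (generations_since < 1L) stop("generations_since must be >= 1")
  if (crash_factor == 1) {
    return(sim_population_equilibrium(n_individuals, n_loci, theta, model))
  }
  n_crash <- as.integer(round(pool_size * crash_factor))
  if (n_crash < 2L) stop("reduced size < 2 (crash too severe for pool_size)")
  n_genes <- 2L * n_individuals
  a1 <- a2 <- matrix(NA_integer_, n_individuals, n_loci)
  for (j in seq_len(n_loci)) {
    pool <- .coal_microsat(.coal_tree(2L * pool_size), theta, model)
    pool <- sample(pool, 2L * n_crash, replace = FALSE)  # the crash itself
    for (g in seq_len(generations_since)) {
      pool <- sample(pool, 2L * n_crash, replace = TRUE)  # WF drift
    }
    genes <- sample(pool, n_genes, replace = TRUE)        # gamete sample
    a1[, j] <- genes[seq(1L, n_genes, by = 2L)]
    a2[, j] <- genes[seq(2L, n_genes, by = 2L)]
  }
  genotype_matrix(a1, a2)
}

#' Simulate an aligned mitochondrial sequence sample
#'
#' A coalescent genealogy is simulated for the sample; mutations are dropped
#' as Poisson(theta/2 per unit branch length) and placed on sites uniformly
#' (finite sites, so repeat hits are possible). Each mutation is a
#' transition with probability `ts_bias / (ts_bias + 1)`, else one of the
#' two transversions at random. The root sequence is drawn with the default
#' base composition of a vertebrate control region (A-rich).
#'
#' @param n_sequences number of sequences.
#' @param length alignment length in sites.
#' @param theta scaled mutation rate for the whole sequence.
#' @param ts_bias transition:transversion rate ratio (>= 0).
#' @param base_comp named numeric of root base probabilities (A, C, G, T).
#' @param seed integer RNG seed, or `NULL`.
#' @return A [haplotype_alignment()].
#' @export
sim_mtdna <- function(n_sequences, length, theta, ts_bias = 34 / 7,
                      base_comp = c(A = 0.34, C = 0.20, G = 0.21, T = 0.25),
                      seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (length < 1L) stop("length must be >= 1")
  if (ts_bias < 0) stop("ts_bias must be >= 0")
  bases <- c("A", "C", "G", "T")
  ts_partner <- c(A = "G", G = "A", C = "T", T = "C")
  tv_partner <- list(A = c("C", "T"), G = c("C", "T"),
                     C = c("A", "G"), T = c("A", "G"))
  root <- sample(bases, length, replace = TRUE,
                 prob = base_comp[bases] / sum(base_comp[bases]))
  if (n_sequences == 1L) {
    return(haplotype_alignment(matrix(root, 1L, length,
                                      dimnames = list("seq1", NULL))))
  }
  tree <- .coal_tree(n_sequences)
  n_nodes <- 2L * n_sequences - 1L
  nmut <- stats::rpois(n_nodes, theta / 2 * tree$elen)
  seqs <- vector("list", n_nodes)
  seqs[[n_nodes]] <- root
  p_ts <- ts_bias / (ts_bias + 1)
  for (v in seq(n_nodes - 1L, 1L)) {
    s <- seqs[[tree$parent[v]]]
    m <- nmut[v]
    if (m > 0L) {
      sites <- sample.int(length, m, replace = TRUE)
      for (k in seq_len(m)) {
        b <- s[sites[k]]
        s[sites[k]] <- if (stats::runif(1) < p_ts) ts_partner[[b]]
                       else sample(tv_partner[[b]], 1L)
      }
    }
    seqs[[v]] <- s
  }
  m <- do.call(rbind, seqs[seq_len(n_sequences)])
  rownames(m) <- paste0("seq", seq_len(n_sequences))
  haplotype_alignment(m)
}

#' Simulate diverged populations by pure drift from a common ancestor
#'
#' An ancestral equilibrium gene pool is simulated per locus; each deme then
#' drifts independently (Wright-Fisher resampling of its gene pool, no
#' migration, no new mutation) for `divergence * 2 * pool_size` generations,
#' after which `n_per_pop` diploids are sampled per deme.
#'
#' @param n_pops number of demes (>= 2).
#' @param n_per_pop diploid sample size per deme.
#' @param divergence drift time in units of 2N generations (>= 0).
#' @param theta scaled mutation rate of the ancestral population.
#' @param model a [mutation_model()].
#' @param n_loci number of independent loci.
#' @param pool_size diploid deme size for the drift phase.
#' @param seed integer RNG seed, or `NULL`.
#' @return A list with `genotypes` (a [genotype_matrix()]) and `metadata`
#'   (sites `deme1`, `deme2`, ...).
#' @export
sim_structured_pops <- function(n_pops, n_per_pop, divergence, theta,
                                model = mutation_model("IAM"),
                                n_loci = 20L, pool_size = 100L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (n_pops < 2L) stop("n_pops must be >= 2")
  if (divergence < 0) stop("divergence must be >= 0")
  n_gen <- as.integer(round(divergence * 2 * pool_size))
  n_tot <- n_pops * n_per_pop
  A1 <- A2 <- matrix(NA_integer_, n_tot, n_loci)
  for (j in seq_len(n_loci)) {
    # ancestral pool -> per-deme drift -> diploid sample
    anc <- .coal_microsat(.coal_tree(2L * pool_size), theta, model)
    for (d in seq_len(n_pops)) {
      pool <- anc  # divergence 0 leaves every deme drawing from the ancestor
      for (g in seq_len(n_gen)) pool <- sample(pool, 2L * pool_size, replace = TRUE)
      genes <- sample(pool, 2L * n_per_pop, replace = TRUE)
      rows <- (d - 1L) * n_per_pop + seq_len(n_per_pop)
      A1[rows, j] <- genes[seq(1L, 2L * n_per_pop, by = 2L)]
      A2[rows, j] <- genes[seq(2L, 2L * n_per_pop, by = 2L)]
    }
  }
  ids <- paste0("ind", seq_len(n_tot))
  sites <- rep(paste0("deme", seq_len(n_pops)), each = n_per_pop)
  list(genotypes = genotype_matrix(A1, A2, ids = ids),
       metadata = sample_metadata(ids, sites))
}

#' Ewens expected number of alleles in a sample
#'
#' Closed-form expectation under the infinite-alleles model:
#' `E[K] = sum_{i=0}^{n_genes-1} theta / (theta + i)`.
#'
#' @param theta scaled mutation rate.
#' @param n_genes sample size in genes.
#' @return Expected number of distinct alleles.
#' @export
ewens_expected_alleles <- function(theta, n_genes) {
  sum(theta / (theta + seq(0L, n_genes - 1L)))
}
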