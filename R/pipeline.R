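#' Run configuration for the full pipeline
#'
#' A flat list of inputs and stage parameters with an explicit master seed;
#' every stochastic stage receives its own RNG stream derived from the
#' master seed, so adding or removing a stage does not perturb the others.
#'
#' @param genotypes a [genotype_matrix()], or a GenePop path.
#' @param metadata a metadata data.frame, or a CSV path.
#' @param alignment a [haplotype_alignment()], a FASTA path, or `NULL` to
#'   skip the mitochondrial stages.
#' @param out_dir output directory (created if needed).
#' @param seed master seed.
#' @param n_perm permutations for phi_ST and LD tests.
#' @param n_bootstrap bootstrap replicates for Jost's D.
#' @param n_sims equilibrium replicates per locus for the bottleneck test
#'   and coalescent replicates for neutrality p-values.
#' @param rarefaction_g rarefaction gene count or `"auto"`.
#' @param p_single TPM single-step probability.
#' @return A list of class `run_config`.
#' @export
run_config <- function(genotypes, metadata, alignment = NULL,
                       out_dir = "riverkin-out", seed = 1L,
                       n_perm = 2000L, n_bootstrap = 500L, n_sims = 2000L,
                       rarefaction_g = "auto", p_single = 0.70) {
  structure(list(genotypes = genotypes, metadata = metadata,
                 alignment = alignment, out_dir = out_dir,
                 seed = as.integer(seed), n_perm = n_perm,
                 n_bootstrap = n_bootstrap, n_sims = n_sims,
                 rarefaction_g = rarefaction_g, p_single = p_single),
            class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Executes diversity -> differentiation -> clustering -> bottleneck ->
#' mtDNA -> kinship -> mating in order, writing per-stage CSV outputs and a
#' log to the configured output directory. A stage failure is recorded and
#' dependent stages are skipped; independent stages still run.
#'
#' @param config a [run_config()].
#' @return A list of stage results (invisibly also written to `out_dir`);
#'   element `log` records per-stage status and timing.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  g <- config$genotypes
  if (is.character(g)) g <- read_genepop(g)$genotypes
  meta <- config$metadata
  if (is.character(meta)) meta <- read_metadata_csv(meta)
  aln <- config$alignment
  if (is.character(aln)) aln <- read_fasta_alignment(aln)
  stage_seed <- function(i) (config$seed * 1000L + i * 97L) %% .Machine$integer.max
  results <- list()
  log <- list()
  run_stage <- function(name, fun) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(fun(), error = function(e) e)
    ok <- !inherits(res, "error")
    log[[name]] <<- list(ok = ok, seconds = proc.time()[["elapsed"]] - t0,
                         message = if (ok) "" else conditionMessage(res))
    if (ok) results[[name]] <<- res
    ok
  }
  write_csv <- function(df, file) {
    utils::write.csv(df, file.path(config$out_dir, file), row.names = FALSE)
  }

  run_stage("diversity", function() {
    set.seed(stage_seed(1L))
    tab <- diversity_table(g, meta, rarefaction_g = config$rarefaction_g)
    write_csv(tab, "diversity_per_locus.csv")
    write_csv(attr(tab, "overall"), "diversity_overall.csv")
    priv <- private_alleles(g, meta)
    write_csv(data.frame(site = names(priv), private_alleles = priv),
              "private_alleles.csv")
    list(table = tab, private = priv)
  })

  run_stage("differentiation", function() {
    set.seed(stage_seed(2L))
    pw <- pairwise_differentiation(g, meta, "dest",
                                   n_rep = config$n_bootstrap)
    write_csv(as.data.frame(pw$statistic), "pairwise_dest.csv")
    write_csv(as.data.frame(pw$p), "pairwise_dest_p.csv")
    pw
  })

  run_stage("clustering", function() {
    set.seed(stage_seed(3L))
    tab <- individual_allele_table(g)
    sites <- meta$site[match(g$ids, meta$id)]
    dap <- dapc_fit(tab, sites, n_pcs = "auto")
    write_csv(data.frame(id = g$ids, as.data.frame(dap$membership)),
              "dapc_membership.csv")
    tree <- nj_tree(as.matrix(stats::dist(tab)))
    ape::write.tree(tree, file.path(config$out_dir, "nj_tree.nwk"))
    list(dapc = dap, tree = tree)
  })

  run_stage("bottleneck", function() {
    set.seed(stage_seed(4L))
    sites <- meta$site[match(g$ids, meta$id)]
    rows <- lapply(unique(sites), function(s) {
      sub <- subset_individuals(g, sites == s)
      if (length(sub$ids) < 4L) return(NULL)
      cbind(site = s, bottleneck_all_models(sub, n_sims = config$n_sims,
                                            p_single = config$p_single))
    })
    tab <- do.call(rbind, rows)
    write_csv(tab, "bottleneck.csv")
    tab
  })

  if (!is.null(aln)) {
    run_stage("mtdna", function() {
      set.seed(stage_seed(5L))
      msum <- mtdna_summary(aln)
      fs <- fu_fs(aln); r2 <- r2_statistic(aln)
      pv <- neutrality_pvalues(fs, r2, msum$n, msum$S,
                               n_sims = max(1000L, config$n_sims))
      write_csv(data.frame(n = msum$n, S = msum$S, h = msum$h,
                           Hd = msum$Hd, Hd_sd = msum$Hd_sd, pi = msum$pi,
                           pi_sd = msum$pi_sd, Fs = fs, R2 = r2,
                           p_Fs = pv$p_fs, p_R2 = pv$p_r2),
                "mtdna_summary.csv")
      am <- amova_phist(aln, meta, n_perm = config$n_perm)
      write_csv(data.frame(phi_st = am$phi_st, p = am$p), "amova.csv")
      net <- median_joining_network(aln)
      list(summary = msum, fs = fs, r2 = r2, pvalues = pv, amova = am,
           network = net)
    })
  } else {
    log$mtdna <- list(ok = FALSE, seconds = 0,
                      message = "skipped: no mtDNA input")
  }

  kin_ok <- run_stage("kinship", function() {
    set.seed(stage_seed(6L))
    rel <- pairwise_relatedness(g, estimators = c("QG", "DyadML"))
    write_csv(rel, "relatedness_pairs.csv")
    rel
  })

  if (kin_ok) {
    run_stage("mating", function() {
      set.seed(stage_seed(7L))
      pairs <- enumerate_pairings(meta)
      plan <- classify_pairings(pairs, results$kinship,
                                method_a = "DyadML", method_b = "QG")
      rep <- mating_report(plan)
      write_csv(plan$pairs, "mating_plan.csv")
      write_csv(rep$summary, "mating_summary.csv")
      list(plan = plan, report = rep)
    })
  } else {
    log$mating <- list(ok = FALSE, seconds = 0,
                       message = "skipped: kinship stage failed")
  }

  results$log <- log
  status <- data.frame(
    stage = names(log),
    ok = vapply(log, `[[`, TRUE, "ok"),
    seconds = round(vapply(log, `[[`, 1.0, "seconds"), 2),
    message = vapply(log, `[[`, "", "message"))
  utils::write.csv(status, file.path(config$out_dir, "pipeline_log.csv"),
                   row.names = FALSE)
  invisible(results)
}
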