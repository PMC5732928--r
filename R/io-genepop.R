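#' Read a GenePop file
#'
#' Parses the classic GenePop dialect: a title line, one locus name per line
#' (or a single comma-separated line), then `POP`-delimited blocks of
#' `id , g1 g2 ...` sample lines with 2- or 3-digit allele encoding.
#' `"00"`/`"000"` (so `"0000"`/`"000000"` per call) encodes a missing call.
#'
#' Site labels are taken from the POP blocks: each individual is assigned the
#' ID of the last individual in its block as the block label unless
#' `pop_names` is given; blocks are labelled `pop1`, `pop2`, ... by default.
#'
#' @param path path to the `.gen` file.
#' @param pop_names optional character vector of block labels.
#' @return A list with elements `genotypes` (a [genotype_matrix()]) and
#'   `metadata` (site labels only; sex is `"U"`).
#' @export
read_genepop <- function(path, pop_names = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*$", lines)]
  if (length(lines) < 3L) stop("GenePop file too short")
  # locus names: lines 2..(first POP-1); a single comma-separated line allowed
  pop_idx <- grep("^\\s*pop\\s*$", lines, ignore.case = TRUE)
  if (length(pop_idx) == 0L) stop("no POP line found")
  locus_lines <- lines[2:(pop_idx[1] - 1L)]
  loci <- trimws(unlist(strsplit(locus_lines, ",")))
  loci <- loci[loci != ""]
  if (length(loci) == 0L) stop("no locus names found")

  n_pop <- length(pop_idx)
  if (is.null(pop_names)) pop_names <- paste0("pop", seq_len(n_pop))
  if (length(pop_names) != n_pop) stop("pop_names length != number of POP blocks")

  ids <- character(); sites <- character()
  A1 <- NULL; A2 <- NULL
  block_end <- c(pop_idx[-1] - 1L, length(lines))
  for (b in seq_len(n_pop)) {
    rng <- seq(pop_idx[b] + 1L, block_end[b])
    if (pop_idx[b] + 1L > block_end[b]) next
    for (li in rng) {
      line <- lines[li]
      parts <- strsplit(line, ",")[[1]]
      if (length(parts) < 2L)
        stop(sprintf("line %d: expected 'id , genotypes'", li))
      id <- trimws(parts[1])
      gts <- strsplit(trimws(paste(parts[-1], collapse = ",")), "\\s+")[[1]]
      gts <- gts[gts != ""]
      if (length(gts) != length(loci))
        stop(sprintf("line %d: %d genotypes for %d loci (ragged row)",
                     li, length(gts), length(loci)))
      w <- nchar(gts)
      if (any(w %% 2L != 0L))
        stop(sprintf("line %d: odd allele-string length", li))
      half <- w %/% 2L
      if (!all(half %in% c(2L, 3L)))
        stop(sprintf("line %d: allele encoding must be 2 or 3 digits", li))
      a1 <- as.integer(substr(gts, 1L, half))
      a2 <- as.integer(substr(gts, half + 1L, w))
      if (anyNA(a1) || anyNA(a2))
        stop(sprintf("line %d: non-numeric allele code", li))
      miss <- a1 == 0L | a2 == 0L
      a1[miss] <- NA_integer_; a2[miss] <- NA_integer_
      ids <- c(ids, id); sites <- c(sites, pop_names[b])
      A1 <- rbind(A1, a1); A2 <- rbind(A2, a2)
    }
  }
  if (anyDuplicated(ids)) {
    dup <- ids[duplicated(ids)][1]
    stop("duplicate individual ID: ", dup)
  }
  g <- genotype_matrix(A1, A2, ids = ids, loci = loci)
  list(genotypes = g, metadata = sample_metadata(ids, sites))
}

#' Write a GenePop file
#'
#' Writes 3-digit encoding by default; missing calls become `"000000"`.
#' Individuals are grouped into POP blocks by their metadata site, in order
#' of first appearance.
#'
#' @param g a [genotype_matrix()].
#' @param metadata metadata data.frame (site column used for POP blocks).
#' @param path output path.
#' @param title title line content.
#' @param digits allele-code width, 2 or 3.
#' @return `path`, invisibly.
#' @export
write_genepop <- function(g, metadata, path, title = "riverkin export",
                          digits = 3L) {
  if (!digits %in% c(2L, 3L)) stop("digits must be 2 or 3")
  if (any(g$a2 >= 10^digits, na.rm = TRUE))
    stop("allele codes too wide for ", digits, "-digit encoding")
  sites <- .sites_for(g, metadata)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(title, con)
  writeLines(g$loci, con)
  fmt <- function(a) {
    out <- formatC(a, width = digits, flag = "0")
    out[is.na(a)] <- strrep("0", digits)
    out
  }
  for (s in unique(sites)) {
    writeLines("POP", con)
    for (i in which(sites == s)) {
      gt <- paste0(fmt(g$a1[i, ]), fmt(g$a2[i, ]))
      writeLines(paste0(g$ids[i], " , ", paste(gt, collapse = " ")), con)
    }
  }
  invisible(path)
}

#' Holm-Bonferroni step-down multiple-testing decisions
#'
#' Sorts the p-values ascending and rejects `p_(i)` while
#' `p_(i) <= alpha / (m - i + 1)`, stopping at the first failure. Decisions
#' are returned in the input order.
#'
#' @param pvalues numeric vector of p-values in `[0, 1]`.
#' @param alpha family-wise error rate, in `(0, 1)`.
#' @return Logical vector, `TRUE` = reject, in input order.
#' @export
holm_bonferroni <- function(pvalues, alpha = 0.05) {
  if (length(pvalues) == 0L) return(logical(0))
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  m <- length(pvalues)
  ord <- order(pvalues)
  reject <- logical(m)
  for (i in seq_len(m)) {
    p <- pvalues[ord[i]]
    if (!is.na(p) && p <= alpha / (m - i + 1)) reject[ord[i]] <- TRUE
    else break
  }
  reject
}
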