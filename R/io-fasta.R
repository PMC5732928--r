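#' Aligned haplotype container
#'
#' Holds an alignment of equal-length DNA sequences, the collapse of
#' identical sequences into haplotypes, and the transition/transversion
#' classification of polymorphic sites. Sites with a gap (`-`) or `N` in any
#' sequence are excluded from polymorphism counting (complete deletion);
#' `usable_sites` marks the retained columns.
#'
#' Multi-state polymorphic sites are classified mutation-by-mutation: each
#' non-majority base at a site counts as one mutation, a transition if it is
#' an A<->G or C<->T exchange with the majority base, else a transversion.
#'
#' @param seqs character matrix (individuals x sites) over `{A,C,G,T,-,N}`,
#'   or a named character vector of sequence strings of equal length.
#' @param ids individual IDs (defaults to rownames / names).
#' @return An object of class `haplotype_alignment` with elements `ids`,
#'   `seq` (character matrix), `L`, `usable_sites` (logical),
#'   `haplotype` (integer index per individual, 1..h), `h`,
#'   `site_classes` (data.frame: site, n_states, transitions, transversions).
#' @export
haplotype_alignment <- function(seqs, ids = NULL) {
  if (is.character(seqs) && is.null(dim(seqs))) {
    if (length(seqs) == 0L) stop("empty alignment")
    L <- unique(nchar(seqs))
    if (length(L) != 1L) stop("sequences have unequal lengths")
    m <- do.call(rbind, strsplit(toupper(seqs), ""))
    rownames(m) <- if (is.null(ids)) names(seqs) else ids
    seqs <- m
  }
  seqs <- toupper(seqs)
  if (is.null(ids)) ids <- rownames(seqs)
  if (is.null(ids)) ids <- paste0("seq", seq_len(nrow(seqs)))
  ids <- as.character(ids)
  if (anyDuplicated(ids)) stop("duplicate sequence IDs")
  if (nrow(seqs) < 1L) stop("empty alignment")
  bad <- setdiff(unique(as.vector(seqs)), c("A", "C", "G", "T", "-", "N"))
  if (length(bad) > 0L)
    stop("invalid characters in alignment: ", paste(bad, collapse = " "))
  rownames(seqs) <- ids
  L <- ncol(seqs)
  usable <- apply(seqs, 2, function(col) all(col %in% c("A", "C", "G", "T")))
  # haplotypes: exact identity of the full sequence string
  strings <- apply(seqs, 1, paste, collapse = "")
  hap <- as.integer(factor(strings, levels = unique(strings)))
  site_classes <- .classify_sites(seqs[, usable, drop = FALSE], which(usable))
  structure(list(ids = ids, seq = seqs, L = L, usable_sites = usable,
                 haplotype = hap, h = max(hap), site_classes = site_classes),
            class = "haplotype_alignment")
}

.is_transition <- function(b1, b2) {
  (b1 == "A" & b2 == "G") | (b1 == "G" & b2 == "A") |
  (b1 == "C" & b2 == "T") | (b1 == "T" & b2 == "C")
}

.classify_sites <- function(seqs, site_pos) {
  rows <- list()
  for (j in seq_len(ncol(seqs))) {
    tab <- sort(table(seqs[, j]), decreasing = TRUE)
    if (length(tab) < 2L) next
    major <- names(tab)[1]
    others <- names(tab)[-1]
    ts <- sum(.is_transition(major, others))
    tv <- length(others) - ts
    rows[[length(rows) + 1L]] <-
      data.frame(site = site_pos[j], n_states = length(tab),
                 transitions = ts, transversions = tv)
  }
  if (length(rows) == 0L)
    return(data.frame(site = integer(), n_states = integer(),
                      transitions = integer(), transversions = integer()))
  do.call(rbind, rows)
}

#' @export
print.haplotype_alignment <- function(x, ...) {
  cat(sprintf(
    "haplotype_alignment: %d sequences x %d sites (%d usable), %d haplotypes\n",
    length(x$ids), x$L, sum(x$usable_sites), x$h))
  invisible(x)
}

#' Number of segregating (polymorphic) sites
#'
#' Counted over usable (gap/N-free) sites only.
#' @param aln a [haplotype_alignment()].
#' @return Integer count of polymorphic sites.
#' @export
segregating_sites <- function(aln) nrow(aln$site_classes)

#' Read an aligned FASTA file into a haplotype alignment
#'
#' @param path FASTA file path; sequences must be equal length.
#' @return A [haplotype_alignment()].
#' @export
read_fasta_alignment <- function(path) {
  dna <- ape::read.FASTA(path)
  if (length(dna) == 0L) stop("empty FASTA file")
  chr <- lapply(as.character(dna), function(s) toupper(s))
  lens <- lengths(chr)
  if (length(unique(lens)) != 1L) stop("sequences have unequal lengths")
  m <- do.call(rbind, chr)
  rownames(m) <- names(dna)
  haplotype_alignment(m)
}

#' Write a haplotype alignment to FASTA
#'
#' @param aln a [haplotype_alignment()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta_alignment <- function(aln, path) {
  con <- file(path, "w"); on.exit(close(con))
  for (i in seq_along(aln$ids)) {
    writeLines(paste0(">", aln$ids[i]), con)
    writeLines(paste(aln$seq[i, ], collapse = ""), con)
  }
  invisible(path)
}
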