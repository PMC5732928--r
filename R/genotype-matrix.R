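#' Diploid multilocus genotype matrix
#'
#' Container for codominant diploid genotypes (e.g. microsatellite fragment
#' sizes). Calls are stored as two integer matrices (`a1`, `a2`, individuals
#' in rows, loci in columns) with the pair canonicalised so that
#' `a1 <= a2`; a missing call has `NA` in both matrices.
#'
#' @param a1,a2 integer matrices of allele codes (positive integers), same
#'   dimensions; `NA` marks a missing call. Pair order is not meaningful.
#' @param ids character vector of individual identifiers (unique).
#' @param loci character vector of locus names (unique).
#' @return An object of class `genotype_matrix` with elements `ids`, `loci`,
#'   `a1`, `a2`.
#' @export
genotype_matrix <- function(a1, a2, ids = NULL, loci = NULL) {
  a1 <- as.matrix(a1); a2 <- as.matrix(a2)
  storage.mode(a1) <- "integer"; storage.mode(a2) <- "integer"
  if (!all(dim(a1) == dim(a2))) stop("a1 and a2 must have the same dimensions")
  if (nrow(a1) < 1L || ncol(a1) < 1L)
    stop("need at least 1 individual and 1 locus")
  if (is.null(ids)) ids <- paste0("ind", seq_len(nrow(a1)))
  if (is.null(loci)) loci <- paste0("loc", seq_len(ncol(a1)))
  ids <- as.character(ids); loci <- as.character(loci)
  if (anyDuplicated(ids)) stop("duplicate individual IDs")
  if (anyDuplicated(loci)) stop("duplicate locus names")
  if (length(ids) != nrow(a1)) stop("ids length mismatch")
  if (length(loci) != ncol(a1)) stop("loci length mismatch")
  # a call is a pair or wholly missing, never half-missing
  if (any(is.na(a1) != is.na(a2)))
    stop("half-missing calls are not allowed")
  if (any(a1 <= 0L, na.rm = TRUE) || any(a2 <= 0L, na.rm = TRUE))
    stop("allele codes must be positive integers")
  swap <- !is.na(a1) & a1 > a2
  if (any(swap)) {
    tmp <- a1[swap]; a1[swap] <- a2[swap]; a2[swap] <- tmp
  }
  dimnames(a1) <- dimnames(a2) <- list(ids, loci)
  structure(list(ids = ids, loci = loci, a1 = a1, a2 = a2),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d individuals x %d loci (%.1f%% missing)\n",
              length(x$ids), length(x$loci),
              100 * mean(is.na(x$a1))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) c(length(x$ids), length(x$loci))

#' Subset a genotype matrix by individuals
#'
#' @param g a [genotype_matrix()].
#' @param which logical, integer or character index of individuals to keep.
#' @return A `genotype_matrix` restricted to the selected individuals.
#' @export
subset_individuals <- function(g, which) {
  if (is.character(which)) which <- match(which, g$ids)
  genotype_matrix(g$a1[which, , drop = FALSE], g$a2[which, , drop = FALSE],
                  ids = g$ids[which], loci = g$loci)
}

#' Per-locus allele counts
#'
#' Counts allele copies at one locus over the non-missing calls.
#'
#' @param g a [genotype_matrix()].
#' @param locus locus name or index.
#' @return Named integer vector of allele copy counts (names are allele
#'   codes), in increasing allele order.
#' @export
allele_counts <- function(g, locus) {
  if (is.character(locus)) {
    j <- match(locus, g$loci)
    if (is.na(j)) stop("unknown locus: ", locus)
  } else j <- locus
  al <- c(g$a1[, j], g$a2[, j])
  al <- al[!is.na(al)]
  tab <- table(al)
  cnt <- as.integer(tab)
  names(cnt) <- names(tab)
  cnt[order(as.integer(names(cnt)))]
}

#' Per-locus allele frequency tables
#'
#' @param g a [genotype_matrix()].
#' @return Named list (one element per locus) of named numeric vectors of
#'   allele relative frequencies.
#' @export
allele_freqs <- function(g) {
  out <- lapply(seq_along(g$loci), function(j) {
    cnt <- allele_counts(g, j)
    cnt / sum(cnt)
  })
  names(out) <- g$loci
  out
}

#' Sample metadata table
#'
#' Per-individual site label and sex. Sex defaults to `"U"` (unknown).
#'
#' @param id character vector of individual IDs.
#' @param site character vector of site labels.
#' @param sex character vector in `{"F","M","U"}`; recycled `"U"` if omitted.
#' @return A data.frame with columns `id`, `site`, `sex`.
#' @export
sample_metadata <- function(id, site, sex = NULL) {
  id <- as.character(id); site <- as.character(site)
  if (length(site) != length(id)) stop("site length mismatch")
  if (is.null(sex)) sex <- rep("U", length(id))
  sex <- toupper(as.character(sex))
  sex[is.na(sex) | sex == ""] <- "U"
  if (!all(sex %in% c("F", "M", "U")))
    stop("sex must be one of F, M, U")
  if (anyDuplicated(id)) stop("duplicate individual IDs in metadata")
  data.frame(id = id, site = site, sex = sex, stringsAsFactors = FALSE)
}

#' Read a metadata CSV (columns id, site, sex)
#'
#' @param path file path; `sex` column is optional.
#' @return A metadata data.frame as from [sample_metadata()].
#' @export
read_metadata_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("id", "site") %in% names(df)))
    stop("metadata CSV needs columns id, site")
  sample_metadata(df$id, df$site, if ("sex" %in% names(df)) df$sex else NULL)
}

# internal: site label per individual of g, in g's order
.sites_for <- function(g, metadata) {
  m <- match(g$ids, metadata$id)
  if (anyNA(m)) stop("metadata missing individuals: ",
                     paste(g$ids[is.na(m)], collapse = ", "))
  metadata$site[m]
}
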