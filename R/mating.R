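#' Enumerate candidate broodstock pairings
#'
#' Lists every female x male pairing, plus, for each individual of unknown
#' sex, a pairing with every other individual. An unknown-unknown pair is
#' therefore listed once per unknown endpoint (twice in total); the total
#' count is `F*M + U*(N-1)`. Duplicated unknown-unknown listings are
#' flagged; `unique_pairs = TRUE` drops them (and the count becomes
#' `F*M + U*(F+M) + choose(U, 2)`).
#'
#' @param metadata metadata data.frame with `id` and `sex` columns.
#' @param unique_pairs drop the duplicate listing of unknown-unknown pairs.
#' @return A data.frame: `id1`, `id2`, `type` (`"FxM"` or `"U"`),
#'   `duplicate` (logical: the second listing of an unknown-unknown pair).
#' @export
enumerate_pairings <- function(metadata, unique_pairs = FALSE) {
  if (nrow(metadata) < 2L) stop("need >= 2 individuals")
  f <- metadata$id[metadata$sex == "F"]
  m <- metadata$id[metadata$sex == "M"]
  u <- metadata$id[metadata$sex == "U"]
  out <- list()
  if (length(f) > 0L && length(m) > 0L) {
    fm <- expand.grid(id1 = f, id2 = m, stringsAsFactors = FALSE)
    out[[1L]] <- data.frame(fm, type = "FxM", duplicate = FALSE,
                            stringsAsFactors = FALSE)
  }
  seen_uu <- character()
  for (ui in u) {
    others <- setdiff(metadata$id, ui)
    dup <- logical(length(others))
    uu <- others %in% u
    if (any(uu)) {
      key <- vapply(others[uu], function(o)
        paste(sort(c(ui, o)), collapse = "|"), "")
      dup[uu] <- key %in% seen_uu
      seen_uu <- c(seen_uu, key)
    }
    out[[length(out) + 1L]] <- data.frame(
      id1 = ui, id2 = others, type = "U", duplicate = dup,
      stringsAsFactors = FALSE)
  }
  pairs <- do.call(rbind, out)
  rownames(pairs) <- NULL
  if (unique_pairs) pairs <- pairs[!pairs$duplicate, , drop = FALSE]
  pairs
}

#' Classify candidate pairings by relatedness thresholds
#'
#' Category per method from the fixed thresholds -- `r < 0.25` advisable,
#' `0.25 <= r <= 0.5` marginal (closed interval), `r > 0.5` inadvisable --
#' and a consensus that takes the more severe of the two categories.
#'
#' @param pairs data.frame from [enumerate_pairings()].
#' @param relatedness data.frame with columns `id1`, `id2` and one column
#'   per method, covering every pair in either order.
#' @param method_a,method_b column names of the two estimators (advisor and
#'   cross-check).
#' @return A list of class `mating_plan`: `pairs` (with per-method r and
#'   category plus `consensus`), `methods`, `unevaluated` (count).
#' @export
classify_pairings <- function(pairs, relatedness, method_a = "DyadML",
                              method_b = "QG") {
  for (mth in c(method_a, method_b)) {
    if (!mth %in% names(relatedness))
      stop("relatedness table lacks method column: ", mth)
  }
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "|")
  rk <- key(relatedness$id1, relatedness$id2)
  idx <- match(key(pairs$id1, pairs$id2), rk)
  ra <- relatedness[[method_a]][idx]
  rb <- relatedness[[method_b]][idx]
  cat_a <- mating_category(ra)
  cat_b <- mating_category(rb)
  sev <- c(advisable = 1L, marginal = 2L, inadvisable = 3L)
  consensus <- factor(names(sev)[pmax(sev[cat_a], sev[cat_b])],
                      levels = names(sev))
  out <- cbind(pairs,
               data.frame(r_a = ra, r_b = rb, category_a = cat_a,
                          category_b = cat_b, consensus = consensus))
  n_uneval <- sum(is.na(ra) | is.na(rb))
  if (n_uneval > 0L)
    warning(n_uneval, " pairs unevaluated (missing relatedness)")
  structure(list(pairs = out, methods = c(method_a, method_b),
                 unevaluated = n_uneval),
            class = "mating_plan")
}

#' Mating category from a relatedness value
#'
#' @param r numeric relatedness values.
#' @return Factor with levels advisable, marginal, inadvisable (`NA` in,
#'   `NA` out).
#' @export
mating_category <- function(r) {
  out <- ifelse(is.na(r), NA_character_,
         ifelse(r < 0.25, "advisable",
         ifelse(r <= 0.5, "marginal", "inadvisable")))
  factor(out, levels = c("advisable", "marginal", "inadvisable"))
}

#' Mating plan summary report
#'
#' Per-category counts and percentages (one decimal) of the consensus
#' classification, plus a broodstock x broodstock category matrix.
#'
#' @param plan a [classify_pairings()] result, or a data.frame with columns
#'   `id1`, `id2` and `consensus` (factor of categories).
#' @return A list: `summary` (data.frame category/count/percent), `total`,
#'   `matrix` (character matrix of consensus categories).
#' @export
mating_report <- function(plan) {
  pairs <- if (inherits(plan, "mating_plan")) plan$pairs else plan
  evaluated <- pairs[!is.na(pairs$consensus), , drop = FALSE]
  total <- nrow(evaluated)
  lev <- levels(mating_category(numeric(0)))
  counts <- table(factor(evaluated$consensus, levels = lev))
  summary <- data.frame(category = lev,
                        count = as.integer(counts),
                        percent = round(100 * as.integer(counts) / total, 1))
  ids <- sort(unique(c(pairs$id1, pairs$id2)))
  mat <- matrix(NA_character_, length(ids), length(ids),
                dimnames = list(ids, ids))
  i <- match(evaluated$id1, ids); j <- match(evaluated$id2, ids)
  mat[cbind(i, j)] <- as.character(evaluated$consensus)
  mat[cbind(j, i)] <- as.character(evaluated$consensus)
  list(summary = summary, total = total, matrix = mat)
}
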