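#' Individual-by-allele dosage table
#'
#' Each individual's row holds, for every (locus, allele) column, the
#' fraction of its two gene copies carrying that allele (0, 0.5 or 1).
#' Missing calls are imputed with the column mean of the locus's columns
#' (row-mean-preserving, so imputed rows still sum to 1 per locus).
#'
#' @param g a [genotype_matrix()].
#' @return Numeric matrix, individuals x (locus, allele) columns, with
#'   column names `locus.allele`.
#' @export
individual_allele_table <- function(g) {
  blocks <- list()
  for (j in seq_along(g$loci)) {
    al <- sort(unique(c(g$a1[, j], g$a2[, j])))
    al <- al[!is.na(al)]
    if (length(al) == 0L) next
    m <- matrix(0, length(g$ids), length(al),
                dimnames = list(g$ids, paste0(g$loci[j], ".", al)))
    for (a in seq_along(al)) {
      m[, a] <- (ifelse(is.na(g$a1[, j]), 0, g$a1[, j] == al[a]) +
                 ifelse(is.na(g$a2[, j]), 0, g$a2[, j] == al[a])) / 2
    }
    miss <- is.na(g$a1[, j])
    if (any(miss)) {
      if (all(miss)) next
      colmean <- colMeans(m[!miss, , drop = FALSE])
      m[miss, ] <- matrix(colmean, sum(miss), length(al), byrow = TRUE)
    }
    blocks[[length(blocks) + 1L]] <- m
  }
  do.call(cbind, blocks)
}

#' Discriminant analysis of principal components (DAPC)
#'
#' Centres and scales the allele-dosage table, reduces it by PCA, retains
#' `n_pcs` components, and runs linear discriminant analysis on the a
#' priori group labels. Membership probabilities are softmax-normalised
#' negative half squared Euclidean distances to the group centroids in
#' discriminant space.
#'
#' With `n_pcs = "auto"`, the retained count maximises the mean alpha-score
#' over candidate counts `1..min(20, rank)`: alpha-score = (proportion of
#' individuals reassigned to their own group) minus (the mean of that
#' proportion under `n_rand` randomisations of the group labels).
#'
#' @param table matrix from [individual_allele_table()].
#' @param groups character/factor of a priori group labels, one per row.
#' @param n_pcs number of retained principal components, or `"auto"`.
#' @param n_rand label randomisations per candidate in the alpha-score.
#' @param seed integer RNG seed, or `NULL`.
#' @return A list of class `dapc_result`: `n_pcs`, `coords` (discriminant
#'   coordinates), `membership` (rows sum to 1), `assigned`, `groups`,
#'   `alpha_scores` (named by candidate PC count; `NULL` unless `"auto"`).
#' @export
dapc_fit <- function(table, groups, n_pcs = "auto", n_rand = 10L,
                     seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  groups <- as.factor(groups)
  if (length(groups) != nrow(table)) stop("groups length mismatch")
  if (nlevels(groups) < 2L) stop("need >= 2 groups")
  small <- table(groups) < 2L
  if (any(small))
    warning("groups with a single individual: ",
            paste(names(small)[small], collapse = ", "))
  sdv <- apply(table, 2, stats::sd)
  X <- scale(table[, sdv > 0, drop = FALSE])
  pca <- stats::prcomp(X, center = FALSE, scale. = FALSE)
  pos <- pca$sdev > 1e-8
  rank <- sum(pos)
  scores <- pca$x[, pos, drop = FALSE]
  alpha_scores <- NULL
  if (identical(n_pcs, "auto")) {
    # discriminating k groups needs k-1 axes, so scan from k-1 PCs upward
    cand <- seq(min(nlevels(groups) - 1L, rank), min(20L, rank))
    alpha_scores <- vapply(cand, function(np)
      .alpha_score(scores[, seq_len(np), drop = FALSE], groups, n_rand),
      numeric(1))
    names(alpha_scores) <- cand
    n_pcs <- cand[which.max(alpha_scores)]
  } else {
    if (n_pcs > rank) {
      warning("n_pcs exceeds rank (", rank, "); clipped")
      n_pcs <- rank
    }
  }
  fit <- .lda_membership(scores[, seq_len(n_pcs), drop = FALSE], groups)
  structure(list(n_pcs = n_pcs, coords = fit$coords,
                 membership = fit$membership,
                 assigned = fit$assigned, groups = groups,
                 alpha_scores = alpha_scores),
            class = "dapc_result")
}

# LDA + centroid-softmax membership on a reduced score matrix
.lda_membership <- function(S, groups) {
  lda <- suppressWarnings(MASS::lda(S, grouping = groups))
  coords <- S %*% lda$scaling
  cent <- apply(coords, 2, function(col) tapply(col, groups, mean))
  cent <- matrix(cent, nrow = nlevels(groups),
                 dimnames = list(levels(groups), colnames(coords)))
  d2 <- outer(rowSums(coords^2), rowSums(cent^2), "+") -
    2 * coords %*% t(cent)
  logw <- -0.5 * d2
  logw <- logw - apply(logw, 1, max)
  w <- exp(logw)
  membership <- w / rowSums(w)
  assigned <- factor(levels(groups)[max.col(membership, ties.method = "first")],
                     levels = levels(groups))
  list(coords = coords, membership = membership, assigned = assigned)
}

.alpha_score <- function(S, groups, n_rand) {
  obs <- mean(.lda_membership(S, groups)$assigned == groups)
  rnd <- vapply(seq_len(n_rand), function(b) {
    gr <- sample(groups)
    mean(.lda_membership(S, gr)$assigned == gr)
  }, numeric(1))
  obs - mean(rnd)
}

#' @export
print.dapc_result <- function(x, ...) {
  cat(sprintf("dapc_result: %d PCs retained, %d groups, %d individuals\n",
              x$n_pcs, nlevels(x$groups), nrow(x$membership)))
  cat(sprintf("  correct reassignment: %.1f%%\n",
              100 * mean(x$assigned == x$groups)))
  invisible(x)
}

#' Neighbour-joining tree on an inter-individual distance matrix
#'
#' Saitou-Nei agglomeration (via ape) with negative branch lengths clamped
#' to zero and the clamped length transferred to the sibling edge, keeping
#' tip-to-tip path lengths unchanged where possible.
#'
#' @param distances symmetric numeric matrix with zero diagonal (e.g.
#'   Euclidean distances between rows of [individual_allele_table()]).
#' @return An [ape::nj()] `phylo` tree (unrooted); for fewer than 3 leaves,
#'   a trivial tree.
#' @export
nj_tree <- function(distances) {
  distances <- as.matrix(distances)
  if (!isSymmetric(unname(distances), tol = 1e-8))
    stop("distance matrix must be symmetric")
  if (any(abs(diag(distances)) > 1e-12)) stop("diagonal must be zero")
  n <- nrow(distances)
  labs <- rownames(distances)
  if (is.null(labs)) labs <- paste0("t", seq_len(n))
  if (n < 3L) {
    tr <- list(edge = cbind(rep(n + 1L, n), seq_len(n)),
               edge.length = if (n == 2L) rep(distances[1, 2] / 2, 2) else 0,
               tip.label = labs, Nnode = 1L)
    class(tr) <- "phylo"
    return(tr)
  }
  rownames(distances) <- colnames(distances) <- labs
  tr <- ape::nj(stats::as.dist(distances))
  .clamp_negative_edges(tr)
}

# clamp negative branch lengths to 0, moving the deficit to the sibling
# edge under the same internal node
.clamp_negative_edges <- function(tr) {
  neg <- which(tr$edge.length < 0)
  for (e in neg) {
    len <- tr$edge.length[e]
    parent <- tr$edge[e, 1]
    sibs <- which(tr$edge[, 1] == parent)
    sibs <- setdiff(sibs, e)
    if (length(sibs) > 0) {
      tr$edge.length[sibs[1]] <- tr$edge.length[sibs[1]] + len
      if (tr$edge.length[sibs[1]] < 0) tr$edge.length[sibs[1]] <- 0
    }
    tr$edge.length[e] <- 0
  }
  tr
}
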