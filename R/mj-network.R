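#' Median-joining haplotype network
#'
#' Bandelt-style median-joining on the variable sites of the alignment:
#' iteratively (i) build the epsilon-relaxed minimum-spanning network over
#' the current node set, (ii) for every triplet of nodes mutually connected
#' by at least two links, compute the sitewise-majority median vector and
#' add it when it is novel and its star connection is cheaper than linking
#' the triplet within the current network, until no new medians arise;
#' finally prune median (inferred, unsampled) nodes whose removal does not
#' increase the total spanning cost. Sites with more than two observed
#' states are resolved by majority with a deterministic fallback to the
#' first sequence's state, and flagged.
#'
#' @param aln a [haplotype_alignment()].
#' @param epsilon relaxation parameter for the spanning network (default 0).
#' @return An [igraph::graph] with vertex attributes `name` (`H1`, ... for
#'   observed haplotypes, `mv1`, ... for inferred medians), `freq`
#'   (haplotype frequency; 0 for medians), `median` (logical), and edge
#'   attribute `weight` (number of mutational steps). The attribute
#'   `multistate_sites` on the graph lists flagged sites.
#' @export
median_joining_network <- function(aln, epsilon = 0) {
  n <- length(aln$ids)
  seqs <- aln$seq[, aln$usable_sites, drop = FALSE]
  # collapse to haplotypes, keep only variable columns
  hap_rows <- !duplicated(aln$haplotype)
  H <- seqs[hap_rows, , drop = FALSE]
  freq <- as.numeric(table(aln$haplotype))
  var_col <- apply(H, 2, function(col) length(unique(col)) > 1L)
  H <- H[, var_col, drop = FALSE]
  h <- nrow(H)
  if (h < 2L) stop("need >= 2 haplotypes")
  multistate <- which(apply(H, 2, function(col) length(unique(col)) > 2L))
  nodes <- H
  labels <- paste0("H", seq_len(h))
  is_median <- rep(FALSE, h)
  mv_counter <- 0L
  repeat {
    d <- .pairwise_diff_matrix(nodes)
    links <- .msn_links(d, epsilon)
    added <- FALSE
    adj <- matrix(FALSE, nrow(nodes), nrow(nodes))
    adj[links] <- TRUE; adj <- adj | t(adj)
    trips <- .linked_triplets(adj)
    for (t in seq_len(nrow(trips))) {
      u <- trips[t, 1]; v <- trips[t, 2]; w <- trips[t, 3]
      med <- .median_vector(nodes[u, ], nodes[v, ], nodes[w, ])
      if (.row_in(med, nodes)) next
      star <- sum(med != nodes[u, ]) + sum(med != nodes[v, ]) +
        sum(med != nodes[w, ])
      pairc <- sort(c(d[u, v], d[u, w], d[v, w]))
      if (star < pairc[1] + pairc[2]) {
        nodes <- rbind(nodes, med)
        mv_counter <- mv_counter + 1L
        labels <- c(labels, paste0("mv", mv_counter))
        is_median <- c(is_median, TRUE)
        added <- TRUE
      }
    }
    if (!added) break
  }
  # prune medians whose removal leaves the spanning cost unchanged
  repeat {
    d <- .pairwise_diff_matrix(nodes)
    cost_all <- .msn_cost(d)
    drop <- NA_integer_
    for (i in which(is_median)) {
      di <- d[-i, -i, drop = FALSE]
      if (.msn_cost(di) <= cost_all) { drop <- i; break }
    }
    if (is.na(drop)) break
    nodes <- nodes[-drop, , drop = FALSE]
    labels <- labels[-drop]
    is_median <- is_median[-drop]
  }
  d <- .pairwise_diff_matrix(nodes)
  links <- .msn_links(d, epsilon)
  gr <- igraph::graph_from_edgelist(
    cbind(labels[links[, 1]], labels[links[, 2]]), directed = FALSE)
  igraph::E(gr)$weight <- d[links]
  ord <- match(igraph::V(gr)$name, labels)
  igraph::V(gr)$freq <- ifelse(is_median[ord], 0, freq[pmin(ord, h)])
  igraph::V(gr)$median <- is_median[ord]
  gr <- igraph::set_graph_attr(gr, "multistate_sites", multistate)
  gr
}

# sitewise majority of three aligned vectors; ties (all distinct) fall back
# to the first vector's state
.median_vector <- function(u, v, w) {
  out <- u
  vw <- v == w
  out[vw] <- v[vw]  # if two agree they win; u==v or u==w already covered by u
  out
}

.row_in <- function(row, m) {
  any(apply(m, 1, function(r) all(r == row)))
}

# all (i,j,k) with at least two links among the three nodes
.linked_triplets <- function(adj) {
  n <- nrow(adj)
  out <- matrix(0L, 0L, 3L)
  if (n < 3L) return(out)
  cmb <- utils::combn(n, 3L)
  keep <- apply(cmb, 2, function(t) {
    sum(adj[t[1], t[2]], adj[t[1], t[3]], adj[t[2], t[3]]) >= 2L
  })
  t(cmb[, keep, drop = FALSE])
}

# epsilon-relaxed minimum spanning network: process distances in increasing
# order; add every link at the current distance joining components that
# were distinct before this distance class (plus epsilon tolerance classes)
.msn_links <- function(d, epsilon = 0) {
  n <- nrow(d)
  comp <- seq_len(n)
  links <- matrix(0L, 0L, 2L)
  dist_vals <- sort(unique(d[upper.tri(d)]))
  for (dv in dist_vals) {
    if (all(comp == comp[1])) break
    comp_before <- comp
    cand <- which(d == dv & upper.tri(d), arr.ind = TRUE)
    sel <- comp_before[cand[, 1]] != comp_before[cand[, 2]]
    # epsilon relaxation: also keep links within distance dv of already
    # connected components formed at this class (epsilon = 0: none extra)
    if (epsilon > 0) {
      near <- abs(d[cand] - dv) <= epsilon
      sel <- sel | near
    }
    cand <- cand[sel, , drop = FALSE]
    if (nrow(cand) == 0L) next
    links <- rbind(links, cand)
    for (r in seq_len(nrow(cand))) {
      ci <- comp[cand[r, 1]]; cj <- comp[cand[r, 2]]
      if (ci != cj) comp[comp == cj] <- ci
    }
  }
  links
}

.msn_cost <- function(d) {
  links <- .msn_links(d, 0)
  sum(d[links])
}
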