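# Internal coalescent machinery shared by the simulators.
#
# Trees are stored with tips 1..n and internal nodes n+1..2n-1 created in
# coalescence order, so a node's parent always has a larger index and the
# root is node 2n-1. Times are in units of 2N generations; mutations are
# dropped as Poisson(theta/2 * branch length).

# Simulate a Kingman coalescent genealogy for n genes.
# Returns list(parent, elen): parent pointer (0 at the root) and the length
# of the edge above each node.
.coal_tree <- function(n) {
  if (n < 2L) return(list(parent = 0L, elen = 0, n = 1L))
  n_nodes <- 2L * n - 1L
  parent <- integer(n_nodes)
  time <- numeric(n_nodes)
  active <- seq_len(n)
  nxt <- n + 1L
  t <- 0
  while (length(active) > 1L) {
    k <- length(active)
    t <- t + stats::rexp(1, k * (k - 1) / 2)
    pick <- sample.int(k, 2L)
    parent[active[pick]] <- nxt
    time[nxt] <- t
    active <- c(active[-pick], nxt)
    nxt <- nxt + 1L
  }
  elen <- numeric(n_nodes)
  has_par <- parent > 0L
  elen[has_par] <- time[parent[has_par]] - time[has_par]
  list(parent = parent, elen = elen, n = n)
}

# Realize microsatellite allele states on a genealogy under a mutation model.
# Returns integer allele codes for the n tips.
.coal_microsat <- function(tree, theta, model) {
  n <- tree$n
  if (n == 1L) return(if (model$kind == "IAM") 1L else 500L)
  n_nodes <- 2L * n - 1L
  nmut <- stats::rpois(n_nodes, theta / 2 * tree$elen)
  state <- integer(n_nodes)
  root <- n_nodes
  counter <- 1L   # fresh-allele counter (IAM / TPM large-jump component)
  if (model$kind == "IAM") {
    state[root] <- counter
  } else {
    state[root] <- 500L  # ladder origin; steps are +/-1 repeat units
  }
  for (v in seq(n_nodes - 1L, 1L)) {
    s <- state[tree$parent[v]]
    m <- nmut[v]
    if (m > 0L) {
      if (model$kind == "IAM") {
        counter <- counter + 1L
        s <- counter
      } else if (model$kind == "SMM") {
        s <- s + sum(sample(c(-1L, 1L), m, replace = TRUE))
      } else { # TPM: per-mutation mixture of single steps and fresh alleles
        for (k in seq_len(m)) {
          if (stats::runif(1) < model$p_single) {
            s <- s + sample(c(-1L, 1L), 1L)
          } else {
            counter <- counter + 1L
            s <- 1000L * counter + 500L  # fresh ladder, far from existing ones
          }
        }
      }
    }
    state[v] <- s
  }
  out <- state[seq_len(n)]
  if (model$kind == "IAM") out else pmax(out, 1L)
}

# Fixed-S mutation placement: drop exactly S mutations on the genealogy,
# each on an edge chosen with probability proportional to its length.
# Returns a n x S 0/1 incidence matrix (tip carries derived state).
.coal_fixed_s <- function(tree, S) {
  n <- tree$n
  inc <- matrix(0L, n, S)
  if (S == 0L || n < 2L) return(inc[, 0, drop = FALSE])
  n_nodes <- 2L * n - 1L
  # tip descendants of each node
  desc <- .tip_descendants(tree)
  edges <- sample.int(n_nodes - 1L, S, replace = TRUE,
                      prob = tree$elen[-n_nodes])
  for (j in seq_len(S)) inc[desc[[edges[j]]], j] <- 1L
  inc
}

# list: node index -> integer vector of tip indices below it (incl. itself)
.tip_descendants <- function(tree) {
  n <- tree$n
  n_nodes <- 2L * n - 1L
  desc <- vector("list", n_nodes)
  for (v in seq_len(n)) desc[[v]] <- v
  ch <- split(seq_len(n_nodes - 1L), tree$parent[-n_nodes])
  for (v in seq(n + 1L, n_nodes)) {
    desc[[v]] <- unlist(desc[ch[[as.character(v)]]], use.names = FALSE)
  }
  desc
}

# Watterson's theta scaling constant a_n = sum_{i=1}^{n-1} 1/i
.watterson_a <- function(n) sum(1 / seq_len(n - 1L))
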