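# Independent brute-force oracles and small generators used across the
# suite. The oracles enumerate over internal-state assignments and never
# share code with the implementation they check.

splitset <- function(tree) sort(names(bipartitions(tree)))

# random binary unrooted tree with the given labels
rand_tree <- function(n, labels = paste0("t", seq_len(n))) {
  ape::unroot(ape::rtree(n, tip.label = sample(labels)))
}

# random (possibly multifurcating) tree: contract a random subset of edges
rand_tree_poly <- function(n, labels = paste0("t", seq_len(n))) {
  tr <- rand_tree(n, labels)
  keys <- names(bipartitions(tr))
  if (length(keys) >= 1 && runif(1) < 0.6) {
    drop <- sample(seq_along(keys), sample.int(length(keys), 1))
    sides <- lapply(keys[-drop], function(k) strsplit(k, "\x1f")[[1]])
    tr <- superfine:::tree_from_splits(sides, tr$tip.label)
  }
  tr
}

tree_edges_undirected <- function(tree) {
  cbind(tree$edge[, 1], tree$edge[, 2])
}

# minimum number of 0<->1 changes over all internal assignments; '?'
# leaves are free (their pendant edge can always match its node)
brute_fitch <- function(tree, column) {
  ntip <- ape::Ntip(tree)
  nn <- tree$Nnode
  states_tip <- column[tree$tip.label]
  best <- Inf
  for (code in 0:(2^nn - 1)) {
    st <- c(states_tip, bitwAnd(bitwShiftR(code, 0:(nn - 1)), 1L))
    changes <- 0L
    for (i in seq_len(nrow(tree$edge))) {
      u <- tree$edge[i, 1]; v <- tree$edge[i, 2]
      if (is.na(st[u]) || is.na(st[v])) next
      changes <- changes + (st[u] != st[v])
    }
    best <- min(best, changes)
  }
  best
}

# exhaustive CFN likelihood: sum over all internal-state assignments, with
# a 1/2-1/2 root prior; '?' leaves marginalize out (their edge is skipped)
brute_cfn_loglik <- function(tree, column, rates) {
  ntip <- ape::Ntip(tree)
  nn <- tree$Nnode
  states_tip <- column[tree$tip.label]
  total <- 0
  for (r in rates) {
    lik <- 0
    for (code in 0:(2^nn - 1)) {
      st <- c(states_tip, bitwAnd(bitwShiftR(code, 0:(nn - 1)), 1L))
      p <- 0.5
      for (i in seq_len(nrow(tree$edge))) {
        u <- tree$edge[i, 1]; v <- tree$edge[i, 2]
        if (is.na(st[u]) || is.na(st[v])) next
        pd <- (1 - exp(-2 * tree$edge.length[i] * r)) / 2
        p <- p * if (st[u] != st[v]) pd else 1 - pd
      }
      lik <- lik + p
    }
    total <- total + lik / length(rates)
  }
  log(total)
}

# all binary unrooted topologies on the given labels
all_binary_trees <- function(labels) {
  stopifnot(length(labels) >= 4, length(labels) <= 7)
  trees <- phangorn::allTrees(length(labels), rooted = FALSE,
                              tip.label = labels)
  lapply(trees, ape::unroot)
}

# gamma-rate CFN character simulation (sites get independent gamma rates)
sim_gamma_chars <- function(tree, m, alpha) {
  ntip <- ape::Ntip(tree)
  nid <- ntip + tree$Nnode
  po <- ape::reorder.phylo(tree, "postorder")
  rates <- rgamma(m, shape = alpha, rate = alpha)
  states <- matrix(NA_integer_, nid, m)
  states[ntip + 1, ] <- rbinom(m, 1, 0.5)
  for (i in rev(seq_len(nrow(po$edge)))) {
    p <- po$edge[i, 1]; ch <- po$edge[i, 2]
    pflip <- (1 - exp(-2 * po$edge.length[i] * rates)) / 2
    states[ch, ] <- bitwXor(states[p, ], rbinom(m, 1, pflip))
  }
  out <- states[seq_len(ntip), , drop = FALSE]
  rownames(out) <- tree$tip.label
  out
}

# first `k` seeds whose synthetic profile is connected
connected_seeds <- function(k, first = 1L, ...) {
  out <- integer(0)
  s <- first
  while (length(out) < k) {
    sim <- suppressWarnings(make_profile(sim_design(seed = s, ...)))
    if (sim$connected) out <- c(out, s)
    s <- s + 1L
  }
  out
}
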