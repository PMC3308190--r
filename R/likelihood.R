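# Symmetric 2-state (CFN) likelihood with discrete-gamma rate variation:
# the MRL criterion engine. States are {0,1} with stationary frequencies
# (1/2, 1/2); branch lengths are expected substitutions per site, so the
# probability of a change across a branch of length t at relative rate r
# is (1 - exp(-2 r t)) / 2. The pruning recursions and branch-length
# sweeps run in compiled code (src/cfn.cpp).

#' Discrete-gamma rate categories
#'
#' Mean-1 gamma discretized into k equal-probability classes represented
#' by their class means, so the category rates always average 1. k = 1
#' reduces exactly to equal rates.
#'
#' @param alpha Shape parameter (> 0).
#' @param k Number of categories.
#' @export
gamma_rates <- function(alpha, k = 4L) {
  stopifnot(alpha > 0, k >= 1L)
  k <- as.integer(k)
  if (k == 1L) {
    rates <- 1
  } else {
    q <- stats::qgamma(seq(0, 1, length.out = k + 1L), shape = alpha,
                       rate = alpha)
    p <- stats::pgamma(q, shape = alpha + 1, rate = alpha)
    rates <- k * diff(p)
    rates <- rates / mean(rates)  # guard against tail round-off
  }
  structure(list(alpha = alpha, k = k, rates = rates), class = "gamma_rates")
}

# Align matrix rows to the tree's leaves; leaves missing from the matrix
# become all-'?'.
lik_states <- function(tree, matrix) {
  missing_taxa <- setdiff(matrix$taxa, tree$tip.label)
  if (length(missing_taxa)) {
    stop("matrix taxa absent from tree: ",
         paste(missing_taxa, collapse = ", "), call. = FALSE)
  }
  states <- matrix(NA_integer_, ape::Ntip(tree), ncol(matrix$states),
                   dimnames = list(tree$tip.label, NULL))
  states[matrix$taxa, ] <- matrix$states
  states
}

check_lengths <- function(tree) {
  if (is.null(tree$edge.length)) {
    stop("tree has no branch lengths", call. = FALSE)
  }
  if (any(tree$edge.length < 0)) {
    stop("negative branch length", call. = FALSE)
  }
  invisible(TRUE)
}

# Postorder inputs for the compiled kernel.
lik_data <- function(tree, states) {
  check_lengths(tree)
  po <- ape::reorder.phylo(tree, "postorder")
  list(edge = po$edge, elen = po$edge.length, ntip = ape::Ntip(tree),
       nnode = tree$Nnode, tips = states)
}

col_logliks <- function(tree, states, rates) {
  d <- lik_data(tree, states)
  cfn_col_loglik(d$edge, d$elen, d$ntip, d$nnode, d$tips, rates)
}

#' Log-likelihood of a single column at a fixed rate
#'
#' Felsenstein pruning under the symmetric 2-state model with a 1/2-1/2
#' root prior; '?' leaves contribute the partial (1,1). The result does
#' not depend on the traversal anchor.
#'
#' @param tree A \code{phylo} with non-negative branch lengths.
#' @param column States named by leaf label (0/1/NA or "0"/"1"/"?").
#' @param rate Positive relative rate multiplying all branch lengths.
#' @export
site_log_likelihood <- function(tree, column, rate = 1) {
  stopifnot(rate > 0)
  if (is.character(column)) {
    column[column == "?"] <- NA_character_
    column <- vapply(column, function(x) as.integer(x), 0L)
  }
  states <- matrix(NA_integer_, ape::Ntip(tree), 1L,
                   dimnames = list(tree$tip.label, NULL))
  hit <- intersect(names(column), tree$tip.label)
  states[hit, 1L] <- column[hit]
  as.numeric(col_logliks(tree, states, rate))
}

#' S2+Gamma log-likelihood of a tree on an MRP matrix
#'
#' Sum over columns of the log of the gamma-mixture likelihood (equal
#' category weights 1/k). This is the quantity the MRL criterion
#' maximizes.
#'
#' @param tree A \code{phylo} with branch lengths; polytomies allowed.
#' @param matrix An \code{mrp_matrix} whose taxa are all leaves of the tree.
#' @param gamma A \code{gamma_rates} object.
#' @export
tree_log_likelihood <- function(tree, matrix, gamma = gamma_rates(1, 4)) {
  sum(col_logliks(tree, lik_states(tree, matrix), gamma$rates))
}

#' Optimize branch lengths on a fixed topology
#'
#' Coordinate-wise univariate (golden-section) optimization cycling over
#' the edges until the log-likelihood improves by less than \code{tol} per
#' sweep. Each edge sees the exact likelihood at the current values of all
#' other edges, so the log-likelihood never decreases.
#'
#' @param tree A \code{phylo}; edges without lengths start at 0.1.
#' @param matrix An \code{mrp_matrix}.
#' @param gamma A \code{gamma_rates}.
#' @param tol Log-likelihood convergence tolerance per sweep.
#' @param max_sweeps Upper bound on the number of sweeps.
#' @param bounds Branch-length search interval.
#' @export
optimize_branch_lengths <- function(tree, matrix, gamma = gamma_rates(1, 4),
                                    tol = 1e-6, max_sweeps = 20L,
                                    bounds = c(1e-8, 20)) {
  if (is.null(tree$edge.length)) {
    tree$edge.length <- rep(0.1, nrow(tree$edge))
  }
  tree$edge.length <- pmax(tree$edge.length, bounds[1L])
  states <- lik_states(tree, matrix)
  d <- lik_data(tree, states)
  res <- cfn_opt_bl(d$edge, d$elen, d$ntip, d$nnode, d$tips, gamma$rates,
                    bounds[1L], bounds[2L], tol, as.integer(max_sweeps))
  key_in <- paste(d$edge[, 1L], d$edge[, 2L])
  key_out <- paste(tree$edge[, 1L], tree$edge[, 2L])
  tree$edge.length <- res$elen[match(key_out, key_in)]
  list(tree = tree, loglik = res$loglik)
}

#' Optimize the gamma shape parameter
#'
#' Maximizes the mixture likelihood over alpha (on the log scale) with the
#' topology and branch lengths fixed.
#'
#' @param tree A \code{phylo} with branch lengths.
#' @param matrix An \code{mrp_matrix}.
#' @param k Number of rate categories.
#' @param bounds Alpha search interval; a maximum on the boundary is
#'   flagged in the result (\code{at_bound}).
#' @export
optimize_alpha <- function(tree, matrix, k = 4L, bounds = c(0.02, 100)) {
  states <- lik_states(tree, matrix)
  f <- function(la) sum(col_logliks(tree, states, gamma_rates(exp(la), k)$rates))
  if (k == 1L) {
    return(list(gamma = gamma_rates(1, 1L), loglik = f(0), at_bound = FALSE))
  }
  opt <- stats::optimize(f, log(bounds), maximum = TRUE, tol = 1e-3)
  alpha <- exp(opt$maximum)
  at_bound <- min(alpha / bounds[1L], bounds[2L] / alpha) < 1.05
  list(gamma = gamma_rates(alpha, k), loglik = opt$objective,
       at_bound = at_bound)
}

# Alternate branch lengths and alpha a few times on a fixed topology.
fit_fixed_topology <- function(tree, matrix, k = 4L, rounds = 2L,
                               tol = 1e-4, max_sweeps = 10L, alpha0 = 1) {
  gamma <- gamma_rates(alpha0, k)
  fit <- optimize_branch_lengths(tree, matrix, gamma, tol = tol,
                                 max_sweeps = max_sweeps)
  at_bound <- FALSE
  for (r in seq_len(rounds - 1L)) {
    oa <- optimize_alpha(fit$tree, matrix, k)
    gamma <- oa$gamma; at_bound <- oa$at_bound
    fit <- optimize_branch_lengths(fit$tree, matrix, gamma, tol = tol,
                                   max_sweeps = max_sweeps)
  }
  list(tree = fit$tree, loglik = fit$loglik, gamma = gamma,
       at_bound = at_bound)
}

#' MRL score of a topology
#'
#' The S2+Gamma log-likelihood after optimizing branch lengths and the
#' gamma shape on the fixed topology -- the protocol used to score every
#' method's tree, whatever criterion produced it. Non-binary trees are
#' scored as-is (the pruning handles polytomies) and flagged.
#'
#' @param tree A \code{phylo} on (at least) the matrix taxa.
#' @param matrix An \code{mrp_matrix}.
#' @param k Number of gamma categories.
#' @param rounds Alternations of branch-length and shape optimization.
#' @param max_sweeps Branch-length sweeps per alternation.
#' @param tol Per-sweep log-likelihood convergence tolerance.
#' @return A list: \code{loglik} (the MRL score), \code{alpha},
#'   \code{tree} (with fitted lengths), \code{resolved}.
#' @export
mrl_score <- function(tree, matrix, k = 4L, rounds = 2L, max_sweeps = 10L,
                      tol = 1e-4) {
  tree$edge.length <- NULL
  fit <- fit_fixed_topology(tree, matrix, k, rounds, tol = tol,
                            max_sweeps = max_sweeps)
  list(loglik = fit$loglik, alpha = fit$gamma$alpha, tree = fit$tree,
       resolved = is_binary_unrooted(tree), alpha_at_bound = fit$at_bound)
}

# --- topology search -------------------------------------------------------

# NNI neighbors of a binary phylo, transferring branch lengths (the five
# lengths around the edge stay attached to their subtrees).
phylo_nni_neighbors <- function(tree) {
  ntip <- ape::Ntip(tree)
  out <- list()
  for (i in seq_len(nrow(tree$edge))) {
    u <- tree$edge[i, 1L]; v <- tree$edge[i, 2L]
    if (v <= ntip) next
    others <- which(tree$edge[, 1L] == u & tree$edge[, 2L] != v)
    if (!length(others)) next
    row_a <- others[1L]
    vkids <- which(tree$edge[, 1L] == v)
    for (row_c in vkids) {
      nt <- tree
      a <- nt$edge[row_a, 2L]; c2 <- nt$edge[row_c, 2L]
      nt$edge[row_a, 2L] <- c2
      nt$edge[row_c, 2L] <- a
      attr(nt, "order") <- NULL
      out[[length(out) + 1L]] <- ape::reorder.phylo(nt, "cladewise")
    }
  }
  out
}

#' Configuration for the heuristic ML search
#'
#' @param start Start-tree policy: the MP search result (default), a
#'   random-addition tree, or a supplied tree.
#' @param start_tree A \code{phylo}, required when \code{start = "given"}.
#' @param k Gamma categories used during the search and final scoring.
#' @param seed Integer seed for the whole trajectory.
#' @param max_rounds Upper bound on NNI improvement rounds.
#' @param mp Config of the MP search used for the default start.
#' @export
ml_config <- function(start = c("mp", "random", "given"), start_tree = NULL,
                      k = 4L, seed = NULL, max_rounds = 30L,
                      mp = mp_config(n_starts = 1L)) {
  start <- match.arg(start)
  list(start = start, start_tree = start_tree, k = as.integer(k),
       seed = seed, max_rounds = as.integer(max_rounds), mp = mp)
}

#' Heuristic maximum-likelihood (MRL) search
#'
#' NNI hill climbing from the start tree, scoring candidates at the
#' current branch lengths and shape and re-optimizing both after each
#' accepted move.
#'
#' @param matrix An \code{mrp_matrix} with >= 4 placeable taxa.
#' @param config An \code{ml_config}.
#' @return A list: \code{tree} (with optimized lengths), \code{loglik},
#'   \code{alpha}, \code{report}.
#' @export
ml_search <- function(matrix, config = ml_config()) {
  prep <- prepare_search_masks(matrix)
  if (length(prep$taxa) < 4L) {
    stop("ML search needs at least 4 placeable taxa", call. = FALSE)
  }
  sub <- mrp_matrix(matrix$states[prep$taxa, , drop = FALSE])
  with_seed(config$seed, {
    start <- switch(config$start,
      mp = {
        cfg <- config$mp
        cfg$seed <- sample.int(2^30, 1L)
        res <- suppressWarnings(mp_search(sub, cfg))
        res$trees[[1L]]
      },
      random = {
        g <- g_addition_tree(sample(prep$taxa), prep$masks)
        phylo_from_graph(g)
      },
      given = config$start_tree
    )
    if (!is_binary_unrooted(start)) {
      start <- random_refinement(start, seed = sample.int(2^30, 1L))
    }
    fit <- fit_fixed_topology(start, sub, config$k, rounds = 2L)
    tree <- fit$tree; gamma <- fit$gamma; ll <- fit$loglik
    for (round in seq_len(config$max_rounds)) {
      nbrs <- phylo_nni_neighbors(tree)
      scores <- vapply(nbrs, function(nt) {
        sum(col_logliks(nt, lik_states(nt, sub), gamma$rates))
      }, 0)
      if (!length(scores) || max(scores) <= ll + 1e-9) break
      cand <- nbrs[[which.max(scores)]]
      res <- optimize_branch_lengths(cand, sub, gamma, tol = 1e-4,
                                     max_sweeps = 5L)
      oa <- optimize_alpha(res$tree, sub, config$k)
      gamma <- oa$gamma
      res <- optimize_branch_lengths(res$tree, sub, gamma, tol = 1e-4,
                                     max_sweeps = 3L)
      if (res$loglik <= ll + 1e-9) break
      tree <- res$tree; ll <- res$loglik
    }
    final <- fit_fixed_topology(tree, sub, config$k, rounds = 2L)
    list(tree = final$tree, loglik = final$loglik,
         alpha = final$gamma$alpha,
         report = list(loglik = final$loglik, alpha = final$gamma$alpha,
                       ntax = length(prep$taxa), ncol = ncol(sub$states),
                       k = config$k))
  })
}
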