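# Reversible Fitch parsimony: column scoring by Hartigan's generalization
# (handles polytomies and missing states) and a heuristic MP search with
# random-addition starts, NNI/SPR hill climbing and an optional
# column-reweighting ratchet. This is the MRP criterion engine.

# --- core engine -----------------------------------------------------------
# Scores all columns at once on an arbitrary rooting; the minimum number of
# 0<->1 changes is invariant to the anchor because the root state is free.
# edges: 2-column integer matrix (parent, child) in postorder (every child's
# own edges appear before the edge above it). tip_row: for each node id, the
# row of `masks_tip` holding its state mask, or NA for internal nodes.
# Masks: 1 = {0}, 2 = {1}, 3 = {0,1} ('?').
fitch_edges <- function(edges, root, tip_row, masks_tip, weights = NULL) {
  ncol_ <- ncol(masks_tip)
  nid <- max(c(edges, root))
  k0 <- matrix(0L, nid, ncol_)
  k1 <- matrix(0L, nid, ncol_)
  nch <- integer(nid)
  cost <- numeric(ncol_)
  node_mask <- function(v) {
    if (!is.na(tip_row[v])) return(masks_tip[tip_row[v], ])
    kv0 <- k0[v, ]; kv1 <- k1[v, ]
    K <- pmax(kv0, kv1)
    cost <<- cost + (nch[v] - K)
    (kv0 == K) + 2L * (kv1 == K)
  }
  for (i in seq_len(nrow(edges))) {
    p <- edges[i, 1L]; ch <- edges[i, 2L]
    m <- node_mask(ch)
    k0[p, ] <- k0[p, ] + bitwAnd(m, 1L)
    k1[p, ] <- k1[p, ] + bitwShiftR(bitwAnd(m, 2L), 1L)
    nch[p] <- nch[p] + 1L
  }
  node_mask(root)
  if (is.null(weights)) sum(cost) else sum(cost * weights)
}

states_to_masks <- function(states) {
  m <- states + 1L
  m[is.na(m)] <- 3L
  storage.mode(m) <- "integer"
  m
}

phylo_post_edges <- function(tree) {
  po <- ape::reorder.phylo(tree, "postorder")
  list(edges = po$edge, root = ape::Ntip(tree) + 1L)
}

# Postorder edge list of a graph rooted at `root` (iterative DFS).
g_post_edges <- function(g, root) {
  parent <- integer(length(g$adj))
  order <- integer(0)
  stack <- root
  parent[root] <- -1L
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    order <- c(order, v)
    for (w in g$adj[[v]]) {
      if (w != parent[v]) {
        parent[w] <- v
        stack <- c(stack, w)
      }
    }
  }
  order <- rev(order)
  kids <- order[order != root]
  cbind(parent[kids], kids)
}

# Fitch score of a graph topology against a prepared mask matrix whose rows
# are named by taxon label.
g_fitch <- function(g, masks_tip, weights = NULL) {
  leaves <- g_leaves(g)
  internal <- g_internal(g)
  root <- if (length(internal)) internal[1L] else leaves[1L]
  tip_row <- rep(NA_integer_, length(g$adj))
  tip_row[leaves] <- match(g$label[leaves], rownames(masks_tip))
  edges <- g_post_edges(g, root)
  fitch_edges(edges, root, tip_row, masks_tip, weights)
}

# --- user-facing scoring ---------------------------------------------------

#' Fitch parsimony score of one column
#'
#' Minimum number of 0<->1 changes needed to explain the column on the
#' tree, minimized over all internal-state assignments; '?' leaves are
#' unconstrained. Polytomies are handled by Hartigan's generalization of
#' the Fitch sets.
#'
#' @param tree A \code{phylo} object.
#' @param column States named by leaf label: 0, 1 and NA (or the
#'   characters "0", "1", "?").
#' @export
fitch_column_score <- function(tree, column) {
  if (is.character(column)) {
    column[column == "?"] <- NA_character_
    column <- vapply(column, function(x) as.integer(x), 0L)
  }
  states <- matrix(NA_integer_, ape::Ntip(tree), 1L,
                   dimnames = list(tree$tip.label, NULL))
  hit <- intersect(names(column), tree$tip.label)
  states[hit, 1L] <- column[hit]
  pe <- phylo_post_edges(tree)
  tip_row <- c(seq_len(ape::Ntip(tree)), rep(NA_integer_, tree$Nnode))
  as.integer(fitch_edges(pe$edges, pe$root, tip_row, states_to_masks(states)))
}

#' Maximum-parsimony score of a tree on an MRP matrix
#'
#' Sum over columns of the Fitch column scores; the quantity reported by
#' the MRP criterion (the "MRP score"). Invariant to the traversal anchor.
#'
#' @param tree A \code{phylo} whose leaves include all matrix taxa.
#' @param matrix An \code{mrp_matrix}.
#' @param weights Optional per-column weights (used by the ratchet).
#' @export
mp_score <- function(tree, matrix, weights = NULL) {
  stopifnot(inherits(matrix, "mrp_matrix"))
  missing_taxa <- setdiff(matrix$taxa, tree$tip.label)
  if (length(missing_taxa)) {
    stop("matrix taxa absent from tree: ",
         paste(missing_taxa, collapse = ", "), call. = FALSE)
  }
  states <- matrix(NA_integer_, ape::Ntip(tree), ncol(matrix$states),
                   dimnames = list(tree$tip.label, NULL))
  states[matrix$taxa, ] <- matrix$states
  pe <- phylo_post_edges(tree)
  tip_row <- c(seq_len(ape::Ntip(tree)), rep(NA_integer_, tree$Nnode))
  sc <- fitch_edges(pe$edges, pe$root, tip_row, states_to_masks(states),
                    weights)
  if (is.null(weights)) as.integer(sc) else sc
}

# --- search ----------------------------------------------------------------

#' Configuration for the heuristic MP search
#'
#' @param n_starts Number of random-addition starting trees.
#' @param moves Hill-climbing move set: "NNI" or "SPR" (SPR implies NNI).
#' @param ratchet_rounds Rounds of column-reweighting perturbation per start.
#' @param ratchet_fraction Fraction of columns upweighted in each round.
#' @param max_trees Cap on the retained set of equally-best topologies.
#' @param seed Integer seed fixing the whole search trajectory.
#' @export
mp_config <- function(n_starts = 3L, moves = c("NNI", "SPR"),
                      ratchet_rounds = 0L, ratchet_fraction = 0.25,
                      max_trees = 100L, seed = NULL) {
  moves <- match.arg(moves)
  stopifnot(n_starts >= 1L, max_trees >= 1L,
            ratchet_fraction > 0, ratchet_fraction < 1)
  list(n_starts = as.integer(n_starts), moves = moves,
       ratchet_rounds = as.integer(ratchet_rounds),
       ratchet_fraction = ratchet_fraction,
       max_trees = as.integer(max_trees), seed = seed)
}

g_canonical_key <- function(g) {
  tr <- phylo_from_graph(g)
  paste(sort_c(split_keys(tr)), collapse = "|")
}

# Star graph on the given taxa.
g_star <- function(taxa) {
  g <- new_graph()
  res <- g_add_node(g); g <- res$g; center <- res$id
  for (x in taxa) {
    res <- g_add_node(g, x); g <- res$g
    g <- g_add_edge(g, center, res$id)
  }
  g
}

g_edge_list <- function(g) {
  out <- matrix(0L, 0L, 2L)
  for (v in which(g$active)) {
    for (w in g$adj[[v]]) if (w > v) out <- rbind(out, c(v, w))
  }
  out
}

# Insert leaf `label` into edge (u, v); returns the new graph.
g_insert_leaf <- function(g, u, v, label) {
  g <- g_del_edge(g, u, v)
  res <- g_add_node(g); g <- res$g; mid <- res$id
  res <- g_add_node(g, label); g <- res$g; tip <- res$id
  g <- g_add_edge(g, u, mid)
  g <- g_add_edge(g, mid, v)
  g <- g_add_edge(g, mid, tip)
  g
}

# Greedy random-addition tree: taxa added in `order`, each at the edge
# minimizing the Fitch score (ties to the first edge enumerated).
g_addition_tree <- function(order, masks_tip, weights = NULL) {
  g <- g_star(order[1:3])
  for (x in order[-(1:3)]) {
    edges <- g_edge_list(g)
    best <- NULL; best_sc <- Inf
    for (i in seq_len(nrow(edges))) {
      cand <- g_insert_leaf(g, edges[i, 1L], edges[i, 2L], x)
      sc <- g_fitch(cand, masks_tip, weights)
      if (sc < best_sc) { best_sc <- sc; best <- cand }
    }
    g <- best
  }
  g
}

# All NNI rearrangements of a binary graph, as a list of graphs.
g_nni_neighbors <- function(g) {
  out <- list()
  for (v in which(g$active)) {
    for (w in g$adj[[v]]) {
      if (w > v && is.na(g$label[v]) && is.na(g$label[w])) {
        a <- g$adj[[v]][g$adj[[v]] != w]
        cdd <- g$adj[[w]][g$adj[[w]] != v]
        for (c2 in cdd) {
          # swap a[2] with c2
          h <- g_del_edge(g, v, a[2L])
          h <- g_del_edge(h, w, c2)
          h <- g_add_edge(h, v, c2)
          h <- g_add_edge(h, w, a[2L])
          out[[length(out) + 1L]] <- h
        }
      }
    }
  }
  out
}

# SPR: prune the subtree hanging off `v` across edge (u, v) and regraft it
# into every other edge.
g_spr_neighbors <- function(g) {
  out <- list()
  edges <- g_edge_list(g)
  for (i in seq_len(nrow(edges))) {
    u <- edges[i, 1L]; v <- edges[i, 2L]
    for (sub_root in c(v, u)) {
      anchor <- if (sub_root == v) u else v
      comp <- g_component(g, sub_root, anchor)
      rest <- setdiff(which(g$active), comp)
      if (length(rest) < 3L) next
      h <- g_del_edge(g, anchor, sub_root)
      # pruning leaves `anchor` with degree 2: remember its neighbors and
      # splice; regraft positions enumerated on the pruned backbone
      h2 <- g_suppress_degree2_keep(h, comp)
      redges <- g_edge_list_subset(h2, setdiff(rest, which(!h2$active)))
      for (j in seq_len(nrow(redges))) {
        a <- redges[j, 1L]; b <- redges[j, 2L]
        if (!h2$active[a] || !h2$active[b]) next
        hh <- g_del_edge(h2, a, b)
        res <- g_add_node(hh); hh <- res$g; mid <- res$id
        hh <- g_add_edge(hh, a, mid)
        hh <- g_add_edge(hh, mid, b)
        hh <- g_add_edge(hh, mid, sub_root)
        out[[length(out) + 1L]] <- hh
      }
    }
  }
  out
}

g_suppress_degree2_keep <- function(g, keep) {
  repeat {
    changed <- FALSE
    for (v in which(g$active & is.na(g$label))) {
      if (v %in% keep) next
      if (g_degree(g, v) == 2L) {
        nb <- g$adj[[v]]
        g <- g_del_edge(g, v, nb[1L]); g <- g_del_edge(g, v, nb[2L])
        g <- g_add_edge(g, nb[1L], nb[2L])
        g$active[v] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  g
}

g_edge_list_subset <- function(g, nodes) {
  out <- matrix(0L, 0L, 2L)
  for (v in nodes) {
    if (!g$active[v]) next
    for (w in g$adj[[v]]) if (w > v && w %in% nodes) out <- rbind(out, c(v, w))
  }
  out
}

# Hill climbing under the move set; returns list(g, score, ties) where ties
# are equally-best graphs encountered in the final neighborhood.
g_hill_climb <- function(g, masks_tip, weights, moves,
                         constraint_keys = NULL) {
  score <- g_fitch(g, masks_tip, weights)
  repeat {
    nbrs <- g_nni_neighbors(g)
    if (moves == "SPR") nbrs <- c(nbrs, g_spr_neighbors(g))
    if (!is.null(constraint_keys)) {
      nbrs <- Filter(function(h) {
        all(constraint_keys %in% split_keys(phylo_from_graph(h)))
      }, nbrs)
    }
    if (!length(nbrs)) return(list(g = g, score = score, ties = list()))
    scores <- vapply(nbrs, g_fitch, 0, masks_tip = masks_tip,
                     weights = weights)
    best <- min(scores)
    if (best < score) {
      g <- nbrs[[which(scores == best)[1L]]]
      score <- best
    } else {
      ties <- nbrs[scores == score]
      return(list(g = g, score = score, ties = ties))
    }
  }
}

prepare_search_masks <- function(matrix) {
  obs <- rowSums(!is.na(matrix$states)) > 0L
  if (ncol(matrix$states) == 0L) obs <- rep(TRUE, length(matrix$taxa))
  if (any(!obs)) {
    warning("dropping taxa with no observed states (unplaceable): ",
            paste(matrix$taxa[!obs], collapse = ", "), call. = FALSE)
  }
  states <- matrix$states[obs, , drop = FALSE]
  list(masks = states_to_masks(states), taxa = matrix$taxa[obs])
}

#' Heuristic maximum-parsimony search
#'
#' Each start builds a random-addition greedy tree and hill-climbs under
#' the move set; optional ratchet rounds upweight a random column fraction,
#' re-search, restore weights and re-search. All distinct equally-best
#' topologies found are retained (up to \code{max_trees}).
#'
#' @param matrix An \code{mrp_matrix} with >= 4 taxa carrying observed
#'   states (all-'?' rows are dropped with a warning).
#' @param config An \code{mp_config}.
#' @return A list with \code{trees} (equally-best \code{phylo} topologies),
#'   \code{score} (best MP score) and \code{report}.
#' @export
mp_search <- function(matrix, config = mp_config()) {
  prep <- prepare_search_masks(matrix)
  if (length(prep$taxa) < 4L) {
    stop("MP search needs at least 4 placeable taxa", call. = FALSE)
  }
  with_seed(config$seed, {
    best_score <- Inf
    pool <- list(); pool_keys <- character(0)
    add_tree <- function(g, score) {
      if (score > best_score) return(invisible())
      if (score < best_score) {
        best_score <<- score
        pool <<- list(); pool_keys <<- character(0)
      }
      key <- g_canonical_key(g)
      if (!(key %in% pool_keys) && length(pool) < config$max_trees) {
        pool[[length(pool) + 1L]] <<- g
        pool_keys <<- c(pool_keys, key)
      }
      invisible()
    }
    ncol_ <- ncol(prep$masks)
    for (s in seq_len(config$n_starts)) {
      ord <- sample(prep$taxa)
      g <- g_addition_tree(ord, prep$masks)
      res <- g_hill_climb(g, prep$masks, NULL, config$moves)
      for (r in seq_len(config$ratchet_rounds)) {
        w <- rep(1, ncol_)
        w[sample(ncol_, max(1L, round(config$ratchet_fraction * ncol_)))] <- 3
        pert <- g_hill_climb(res$g, prep$masks, w, config$moves)
        res2 <- g_hill_climb(pert$g, prep$masks, NULL, config$moves)
        if (res2$score <= res$score) res <- res2
      }
      add_tree(res$g, res$score)
      for (t in res$ties) {
        if (g_fitch(t, prep$masks) == best_score) add_tree(t, best_score)
      }
    }
    trees <- lapply(pool, phylo_from_graph)
    list(trees = trees, score = as.integer(best_score),
         report = list(mp_score = as.integer(best_score),
                       ntax = length(prep$taxa), ncol = ncol_,
                       n_trees = length(trees)))
  })
}

#' Constrained maximum-parsimony search
#'
#' As \code{\link{mp_search}}, but every returned tree refines the given
#' constraint tree: starts are random refinements of the constraint and
#' hill-climbing moves that lose a constraint bipartition are rejected.
#'
#' @param matrix An \code{mrp_matrix}.
#' @param constraint A \code{phylo} on the matrix taxa.
#' @param config An \code{mp_config}.
#' @export
mp_search_constrained <- function(matrix, constraint, config = mp_config()) {
  prep <- prepare_search_masks(matrix)
  if (!setequal(constraint$tip.label, prep$taxa)) {
    stop("constraint leaf set must equal the (placeable) matrix taxon set",
         call. = FALSE)
  }
  ckeys <- split_keys(constraint)
  if (is_binary_unrooted(constraint)) {
    sc <- mp_score(constraint, matrix)
    return(list(trees = list(constraint), score = sc,
                report = list(mp_score = sc, ntax = length(prep$taxa),
                              ncol = ncol(prep$masks), n_trees = 1L)))
  }
  with_seed(config$seed, {
    best_score <- Inf; pool <- list(); pool_keys <- character(0)
    for (s in seq_len(config$n_starts)) {
      start <- random_refinement(constraint,
                                 seed = sample.int(2^30, 1L))
      g <- graph_from_phylo(start)
      res <- g_hill_climb(g, prep$masks, NULL, config$moves,
                          constraint_keys = ckeys)
      if (res$score <= best_score) {
        if (res$score < best_score) {
          best_score <- res$score; pool <- list(); pool_keys <- character(0)
        }
        key <- g_canonical_key(res$g)
        if (!(key %in% pool_keys) && length(pool) < config$max_trees) {
          pool[[length(pool) + 1L]] <- res$g
          pool_keys <- c(pool_keys, key)
        }
      }
    }
    list(trees = lapply(pool, phylo_from_graph),
         score = as.integer(best_score),
         report = list(mp_score = as.integer(best_score)))
  })
}
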