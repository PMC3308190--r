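# SuperFine refinement: every polytomy of the SCM tree is resolved
# independently by running a base supertree method (MRP or MRL) on
# label-reduced source trees. Each polytomy of degree d partitions the
# taxa into d blocks (the components of the SCM tree minus the node);
# source trees are relabeled by block and collapsed so each block label
# occurs at most once, the base method builds a tree on the labels, and
# that tree replaces the polytomy.

phylo_unrooted_degree <- function(tree, v) {
  sum(tree$edge[, 1L] == v) + sum(tree$edge[, 2L] == v)
}

#' Polytomies of a tree
#'
#' Internal nodes of unrooted degree >= 4, in ape node numbering.
#'
#' @param tree A \code{phylo}.
#' @export
polytomies <- function(tree) {
  ntip <- ape::Ntip(tree)
  nodes <- ntip + seq_len(tree$Nnode)
  nodes[vapply(nodes, function(v) phylo_unrooted_degree(tree, v), 0L) >= 4L]
}

#' Label taxa by the components of a tree minus a polytomy
#'
#' Every taxon is assigned the index (1..d) of the component of
#' \code{tree - v} that contains it, i.e. of the subtree hanging off one
#' of the d neighbors of \code{v}.
#'
#' @param tree A \code{phylo} containing all taxa (typically the SCM tree).
#' @param v Internal node id (ape numbering) with unrooted degree >= 4.
#' @return A list: \code{assign} (named integer vector taxon -> label),
#'   \code{blocks} (list of taxon vectors), \code{node}.
#' @export
label_taxa <- function(tree, v) {
  if (v <= ape::Ntip(tree) || phylo_unrooted_degree(tree, v) < 4L) {
    stop("node ", v, " is not a polytomy (unrooted degree >= 4)",
         call. = FALSE)
  }
  g <- graph_from_phylo(tree, suppress = FALSE)
  nbs <- g$adj[[v]]
  blocks <- lapply(nbs, function(w) {
    comp <- g_component(g, w, v)
    sort_c(g$label[comp][!is.na(g$label[comp])])
  })
  assign <- integer(0)
  for (i in seq_along(blocks)) {
    a <- rep(i, length(blocks[[i]]))
    names(a) <- blocks[[i]]
    assign <- c(assign, a)
  }
  list(assign = assign, blocks = blocks, node = v, neighbors = nbs)
}

#' Reduce a source tree to block labels
#'
#' Leaves are relabeled by their block label; whenever an internal node is
#' adjacent to several leaves carrying the same label, the duplicates are
#' removed (one leaf per label is kept and degree-2 nodes suppressed),
#' iterated to a fixed point. For labelings induced by a polytomy of the
#' SCM tree this leaves at most one leaf per label.
#'
#' @param tree A source \code{phylo}.
#' @param labels Named integer vector (taxon -> label) covering the leaves.
#' @return A \code{phylo} whose tips are label strings, or \code{NULL}
#'   when fewer than 4 distinct labels survive (uninformative).
#' @export
reduce_source_tree <- function(tree, labels) {
  if (!all(tree$tip.label %in% names(labels))) {
    stop("labels do not cover the tree's leaves", call. = FALSE)
  }
  g <- graph_from_phylo(tree)
  for (v in g_leaves(g)) {
    g$label[v] <- as.character(labels[[g$label[v]]])
  }
  if (length(unique(g$label[g_leaves(g)])) < 4L) return(NULL)
  repeat {
    changed <- FALSE
    for (v in g_internal(g)) {
      if (!g$active[v]) next
      nb <- g$adj[[v]]
      leaf_nb <- nb[!is.na(g$label[nb])]
      if (length(leaf_nb) < 2L) next
      labs <- g$label[leaf_nb]
      for (l in unique(labs[duplicated(labs)])) {
        dup <- leaf_nb[labs == l][-1L]
        for (w in dup) {
          g <- g_del_edge(g, v, w)
          g$active[w] <- FALSE
        }
        changed <- TRUE
      }
    }
    if (changed) g <- g_suppress_degree2(g) else break
  }
  leaves <- g_leaves(g)
  labs <- g$label[leaves]
  if (anyDuplicated(labs)) {
    # cannot arise from an SCM polytomy labeling; degrade gracefully
    warning("duplicate labels survived reduction; pruning extras",
            call. = FALSE)
    for (l in unique(labs[duplicated(labs)])) {
      for (w in leaves[labs == l][-1L]) {
        g <- g_del_edge(g, w, g$adj[[w]][1L])
        g$active[w] <- FALSE
      }
    }
    g <- g_suppress_degree2(g)
    leaves <- g_leaves(g)
  }
  if (length(leaves) < 4L) return(NULL)
  phylo_from_graph(g)
}

#' Resolve one polytomy with a base supertree method
#'
#' Runs the base method (MRP with greedy consensus of the equally best
#' trees, or MRL) on the label-reduced source trees of one polytomy.
#'
#' @param ctx A polytomy context from \code{\link{label_taxa}} plus the
#'   profile: a list with \code{assign} and \code{profile}.
#' @param base "mrp" or "mrl".
#' @param seed Integer seed for the base search.
#' @param starts Random-addition starts for the base MP search.
#' @return A \code{phylo} on (a subset of) the label strings, or
#'   \code{NULL} when no reduced source tree is informative.
#' @export
refine_polytomy <- function(ctx, base = c("mrp", "mrl"), seed = NULL,
                            starts = 1L) {
  base <- match.arg(base)
  reduced <- Filter(Negate(is.null),
                    lapply(ctx$profile$trees, reduce_source_tree,
                           labels = ctx$assign))
  if (!length(reduced)) return(NULL)
  rprof <- source_profile(reduced)
  cm <- encode_baum_ragan(rprof)
  if (ncol(cm$states) == 0L) return(NULL)
  if (base == "mrp") {
    res <- suppressWarnings(
      mp_search(cm, mp_config(n_starts = starts, seed = seed)))
    if (length(res$trees) > 1L) greedy_consensus(res$trees) else res$trees[[1L]]
  } else {
    suppressWarnings(ml_search(cm, ml_config(seed = seed)))$tree
  }
}

# Graft a resolution tree R (tips are label strings) in place of polytomy
# v in graph g. Block roots are looked up at graft time (earlier grafts at
# neighboring polytomies may have replaced the original neighbor nodes,
# but the taxon partition around v is unchanged).
graft_resolution <- function(g, v, assign, R) {
  if (is.null(R) || !length(split_keys(R))) return(g)
  cur <- g$adj[[v]]
  d <- max(assign)
  block_root <- rep(NA_integer_, d)
  for (w in cur) {
    comp <- g_component(g, w, v)
    taxon <- g$label[comp][!is.na(g$label[comp])][1L]
    block_root[assign[[taxon]]] <- w
  }
  for (w in cur) g <- g_del_edge(g, v, w)
  g$active[v] <- FALSE
  gr <- graph_from_phylo(R)
  map <- rep(NA_integer_, length(gr$adj))
  for (u in which(gr$active)) {
    if (!is.na(gr$label[u])) {
      map[u] <- block_root[as.integer(gr$label[u])]
    } else {
      res <- g_add_node(g); g <- res$g; map[u] <- res$id
    }
  }
  for (u in which(gr$active)) {
    for (w in gr$adj[[u]]) {
      if (w > u) g <- g_add_edge(g, map[u], map[w])
    }
  }
  present <- as.integer(gr$label[g_leaves(gr)])
  missing <- setdiff(seq_len(d), present)
  if (length(missing)) {
    # blocks unplaced by the base method rejoin at a single hub: the image
    # of the resolution's highest-degree internal node (deterministic)
    internals <- which(gr$active & is.na(gr$label))
    hub <- map[internals[which.max(vapply(internals, function(u)
      g_degree(gr, u), 0L))]]
    for (l in missing) g <- g_add_edge(g, hub, block_root[l])
  }
  g
}

#' SuperFine supertree estimation
#'
#' Computes the SCM tree of the profile, then refines each polytomy
#' independently with the base method on label-reduced source trees. The
#' output's bipartitions always contain the SCM tree's. Per-polytomy RNG
#' streams are derived from the seed and the polytomy's taxon partition,
#' so the processing order cannot affect the result.
#'
#' @param profile A \code{source_profile}.
#' @param base Base method for refinement: "mrp" or "mrl".
#' @param seed Integer seed.
#' @param starts Random-addition starts per base MP search.
#' @param polytomy_order Optional permutation of the polytomy indices
#'   (processing order; the output is invariant to it).
#' @return A list: \code{tree}, \code{scm} (the scm_tree result),
#'   \code{n_polytomies}, \code{refined}.
#' @export
superfine <- function(profile, base = c("mrp", "mrl"), seed = 1L,
                      starts = 1L, polytomy_order = NULL) {
  base <- match.arg(base)
  scm <- scm_tree(profile)
  polys <- polytomies(scm$tree)
  if (!length(polys)) {
    return(list(tree = scm$tree, scm = scm, n_polytomies = 0L, refined = 0L))
  }
  ord <- polytomy_order %||% seq_along(polys)
  stopifnot(setequal(ord, seq_along(polys)))
  ctxs <- vector("list", length(polys))
  for (i in ord) {
    lt <- label_taxa(scm$tree, polys[i])
    lt$profile <- profile
    ctxs[[i]] <- lt
  }
  g <- graph_from_phylo(scm$tree, suppress = FALSE)
  refined <- 0L
  for (i in ord) {
    ctx <- ctxs[[i]]
    pkey <- paste(sort_c(vapply(ctx$blocks, split_key, "")), collapse = "##")
    pseed <- as.integer((as.double(seed) * 7919 + hash31(pkey)) %% 2147483647)
    R <- refine_polytomy(ctx, base, seed = pseed, starts = starts)
    if (!is.null(R)) {
      g <- graft_resolution(g, ctx$node, ctx$assign, R)
      refined <- refined + 1L
    }
  }
  g <- g_suppress_degree2(g)
  list(tree = phylo_from_graph(g), scm = scm,
       n_polytomies = length(polys), refined = refined)
}
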