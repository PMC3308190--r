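# Strict Consensus Merger: pairwise merging of source trees on their
# shared taxa, with exclusive subtrees re-attached to the backbone.
# Conflicts between the two restrictions contract backbone edges
# ("disagreements"); a backbone edge that receives exclusive subtrees from
# BOTH trees is a "collision" and is also contracted, all colliding
# subtrees joining the resulting polytomy. Attachments that map to the
# same backbone node are not collisions.

# Decompose a tree relative to the shared taxon set X (rooted at the leaf
# holding the smallest shared taxon, so orientations agree across trees):
# contract every internal edge of the X-spanning structure whose X-split
# is non-trivial and absent from the backbone, then record, for every
# backbone element, the exclusive subtrees that hang there.
scm_decorate <- function(tree, X, backbone_keys) {
  g <- graph_from_phylo(tree)
  x0_lab <- sort_c(X)[1L]
  leaves <- g_leaves(g)
  root <- leaves[g$label[leaves] == x0_lab]

  rooted_info <- function(g, root) {
    n <- length(g$adj)
    parent <- rep(NA_integer_, n)
    order <- integer(0)
    stack <- root
    parent[root] <- 0L
    while (length(stack)) {
      v <- stack[length(stack)]; stack <- stack[-length(stack)]
      order <- c(order, v)
      for (w in g$adj[[v]]) {
        if (w != parent[v]) { parent[w] <- v; stack <- c(stack, w) }
      }
    }
    xbelow <- rep(list(character(0)), n)
    for (v in rev(order)) {
      own <- if (!is.na(g$label[v]) && g$label[v] %in% X) g$label[v] else NULL
      kidsets <- lapply(g$adj[[v]][g$adj[[v]] != parent[v]],
                        function(w) xbelow[[w]])
      xbelow[[v]] <- c(own, unlist(kidsets), character(0))
    }
    list(parent = parent, order = order, xbelow = xbelow)
  }

  info <- rooted_info(g, root)
  # contract spanning edges whose non-trivial X-split is not in the backbone
  find_map <- seq_along(g$adj)
  find <- function(v) {
    while (find_map[v] != v) v <- find_map[v]
    v
  }
  for (v in info$order) {
    p <- info$parent[v]
    if (p == 0L || is.na(p)) next
    nb <- length(info$xbelow[[v]])
    if (nb == 0L) next                       # exclusive-side edge: keep
    if (!is.na(g$label[v])) next             # pendant edge of a leaf: keep
    na_above <- length(X) - nb
    if (nb >= 2L && na_above >= 2L) {
      key <- split_key(canonical_side(info$xbelow[[v]], X))
      if (!(key %in% backbone_keys)) {
        rp <- find(p); rv <- find(v)
        g <- g_contract(g, rp, rv)
        find_map[rv] <- rp
      }
    }
  }
  info <- rooted_info(g, root)
  parent <- info$parent

  exclusive_at <- function(v) {
    kids <- g$adj[[v]][g$adj[[v]] != parent[v]]
    kids[vapply(kids, function(w) length(info$xbelow[[w]]) == 0L, TRUE)]
  }

  node_attach <- list()   # partition key -> list of subtree descriptors
  edge_attach <- list()   # edge id -> list of subdivider descriptors
  depth <- rep(NA_real_, length(g$adj))
  for (v in info$order) depth[v] <- if (parent[v] %in% c(0L)) 0 else depth[parent[v]] + 1

  for (v in info$order) {
    if (!g$active[v] || !is.na(g$label[v])) next
    if (length(info$xbelow[[v]]) == 0L) next          # inside an exclusive subtree
    kids <- g$adj[[v]][g$adj[[v]] != parent[v]]
    span_kids <- kids[vapply(kids, function(w) length(info$xbelow[[w]]) > 0L, TRUE)]
    sdeg <- length(span_kids) + 1L                     # +1 for the parent edge
    excl <- exclusive_at(v)
    if (!length(excl)) next
    subtrees <- lapply(excl, function(w) list(root = w, avoid = v))
    if (sdeg >= 3L) {
      blocks <- lapply(span_kids, function(w) info$xbelow[[w]])
      up <- setdiff(X, unlist(blocks))
      blocks <- c(blocks, list(up))
      pkey <- paste(sort_c(vapply(blocks, split_key, "")), collapse = "##")
      node_attach[[pkey]] <- c(node_attach[[pkey]], subtrees)
    } else {
      xb <- info$xbelow[[v]]
      eid <- if (length(xb) == 1L) {
        paste0("pendant:", xb)
      } else if (length(X) - length(xb) == 1L) {
        paste0("pendant:", setdiff(X, xb))
      } else {
        split_key(canonical_side(xb, X))
      }
      edge_attach[[eid]] <- c(edge_attach[[eid]],
                              list(list(subtrees = subtrees, depth = depth[v])))
    }
  }
  edge_attach <- lapply(edge_attach, function(lst) {
    lst[order(vapply(lst, function(e) e$depth, 0))]
  })
  list(g = g, node_attach = node_attach, edge_attach = edge_attach)
}

# Partition keys of the backbone's internal nodes and ids of its elements.
backbone_index <- function(B, X) {
  gB <- graph_from_phylo(B)
  leavesB <- g_leaves(gB)
  x0 <- leavesB[gB$label[leavesB] == sort_c(X)[1L]]
  n <- length(gB$adj)
  parent <- rep(NA_integer_, n); order <- integer(0); stack <- x0
  parent[x0] <- 0L
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    order <- c(order, v)
    for (w in gB$adj[[v]]) {
      if (w != parent[v]) { parent[w] <- v; stack <- c(stack, w) }
    }
  }
  xbelow <- rep(list(character(0)), n)
  for (v in rev(order)) {
    own <- if (!is.na(gB$label[v])) gB$label[v] else NULL
    xbelow[[v]] <- c(own, unlist(lapply(gB$adj[[v]][gB$adj[[v]] != parent[v]],
                                        function(w) xbelow[[w]])),
                     character(0))
  }
  node_key <- rep(NA_character_, n)
  for (v in order) {
    if (!is.na(gB$label[v])) next
    kids <- gB$adj[[v]][gB$adj[[v]] != parent[v]]
    blocks <- lapply(kids, function(w) xbelow[[w]])
    blocks <- c(blocks, list(setdiff(X, unlist(blocks))))
    blocks <- Filter(length, blocks)
    node_key[v] <- paste(sort_c(vapply(blocks, split_key, "")),
                         collapse = "##")
  }
  # edges, oriented parent -> child, with their ids
  edges <- list()
  for (v in order) {
    p <- parent[v]
    if (p == 0L || is.na(p)) next
    xb <- xbelow[[v]]
    eid <- if (length(xb) == 1L) {
      paste0("pendant:", xb)
    } else if (length(X) - length(xb) == 1L) {
      paste0("pendant:", setdiff(X, xb))
    } else {
      split_key(canonical_side(xb, X))
    }
    edges[[length(edges) + 1L]] <- list(u = p, v = v, id = eid)
  }
  list(g = gB, parent = parent, node_key = node_key, edges = edges)
}

#' Merge two trees by strict consensus on their shared taxa
#'
#' The backbone is the strict consensus of the two trees restricted to the
#' shared taxa X; each maximal subtree of tree-exclusive taxa re-attaches
#' at the backbone point (node or edge) corresponding to its attachment in
#' its own tree. Backbone edges receiving exclusive subtrees from both
#' trees (collisions) are contracted, all colliding subtrees joining the
#' resulting polytomy.
#'
#' @param t1,t2 \code{phylo} objects sharing at least 2 taxa.
#' @return A list: \code{tree} (on the union of the leaf sets) and
#'   \code{step} (a merge log with shared-taxon, collision and
#'   disagreement-contraction counts).
#' @export
pairwise_scm <- function(t1, t2) {
  X <- intersect(t1$tip.label, t2$tip.label)
  if (length(X) < 2L) {
    stop("trees share fewer than 2 taxa; cannot merge", call. = FALSE)
  }
  if (length(X) < 4L) {
    warning("merging on an overlap of only ", length(X),
            " taxa conveys little or no topology", call. = FALSE)
  }
  r1 <- restrict_tree(t1, X)
  r2 <- restrict_tree(t2, X)
  k1 <- split_keys(r1); k2 <- split_keys(r2)
  bkeys <- intersect(k1, k2)
  disagreements <- (length(k1) - length(bkeys)) + (length(k2) - length(bkeys))
  B <- tree_from_splits(lapply(bkeys, key_to_side), X)
  idx <- backbone_index(B, X)
  dec1 <- scm_decorate(t1, X, bkeys)
  dec2 <- scm_decorate(t2, X, bkeys)

  # assemble the merged tree
  gm <- new_graph()
  bmap <- rep(NA_integer_, length(idx$g$adj))  # backbone node -> gm node
  for (v in seq_along(idx$g$adj)) {
    if (!idx$g$active[v]) next
    res <- g_add_node(gm, idx$g$label[v])
    gm <- res$g; bmap[v] <- res$id
  }
  # collision pass: union-find over backbone nodes
  uf <- seq_along(idx$g$adj)
  uf_find <- function(v) { while (uf[v] != v) v <- uf[v]; v }
  attach1 <- dec1$edge_attach; attach2 <- dec2$edge_attach
  collided <- character(0)
  for (e in idx$edges) {
    p1 <- attach1[[e$id]]; p2 <- attach2[[e$id]]
    if (!is.null(p1) && !is.null(p2)) {
      leaf_u <- !is.na(idx$g$label[e$u]); leaf_v <- !is.na(idx$g$label[e$v])
      if (!leaf_u && !leaf_v) {
        # a true collision: the backbone split is lost
        collided <- c(collided, e$id)
        uf[uf_find(e$v)] <- uf_find(e$u)
      }
      # on a pendant edge the attachment points merge into one
      # subdividing node instead (no backbone split exists to lose)
    }
  }
  target_of <- function(v) bmap[uf_find(v)]

  attach_subtrees <- function(gm, src, descs, at) {
    for (d in descs) {
      gm <- g_graft(src, d$root, d$avoid, gm, at)
    }
    gm
  }

  for (e in idx$edges) {
    p1 <- attach1[[e$id]]; p2 <- attach2[[e$id]]
    u <- target_of(e$u); v <- target_of(e$v)
    if (!is.null(p1) && !is.null(p2)) {
      leaf_u <- !is.na(idx$g$label[e$u]); leaf_v <- !is.na(idx$g$label[e$v])
      at <- if (leaf_u || leaf_v) {
        # pendant edge: all attachment points merge into one subdivider
        res <- g_add_node(gm); gm <- res$g
        gm <- g_add_edge(gm, u, res$id)
        gm <- g_add_edge(gm, res$id, v)
        res$id
      } else {
        u  # endpoints merged by the collision
      }
      for (sd in p1) gm <- attach_subtrees(gm, dec1$g, sd$subtrees, at)
      for (sd in p2) gm <- attach_subtrees(gm, dec2$g, sd$subtrees, at)
    } else if (!is.null(p1) || !is.null(p2)) {
      chain <- if (!is.null(p1)) p1 else p2
      src <- if (!is.null(p1)) dec1$g else dec2$g
      prev <- u
      for (sd in chain) {
        res <- g_add_node(gm); gm <- res$g; mid <- res$id
        gm <- g_add_edge(gm, prev, mid)
        gm <- attach_subtrees(gm, src, sd$subtrees, mid)
        prev <- mid
      }
      gm <- g_add_edge(gm, prev, v)
    } else {
      gm <- g_add_edge(gm, u, v)
    }
  }
  # node attachments (never collisions)
  for (v in seq_along(idx$node_key)) {
    pk <- idx$node_key[v]
    if (is.na(pk)) next
    at <- target_of(v)
    if (!is.null(dec1$node_attach[[pk]])) {
      gm <- attach_subtrees(gm, dec1$g, dec1$node_attach[[pk]], at)
    }
    if (!is.null(dec2$node_attach[[pk]])) {
      gm <- attach_subtrees(gm, dec2$g, dec2$node_attach[[pk]], at)
    }
  }
  gm <- g_suppress_degree2(gm)
  out <- phylo_from_graph(gm)
  step <- list(shared = length(X), collisions = length(collided),
               disagreements = disagreements)
  list(tree = out, step = step)
}

#' Greedy merge order for a profile
#'
#' Repeatedly pairs the two current trees (including earlier merger
#' results) with the largest shared-taxon count; ties are broken by the
#' larger resulting union, then by the lowest item indices, making the
#' plan deterministic. The plan depends only on the leaf sets.
#'
#' @param profile A \code{source_profile}.
#' @return A list of steps; each has \code{i}, \code{j} (item indices,
#'   originals first, each merge appending a new item) and \code{overlap}.
#' @export
merge_order <- function(profile) {
  sets <- lapply(profile$trees, function(t) t$tip.label)
  alive <- seq_along(sets)
  plan <- list()
  while (length(alive) > 1L) {
    best <- NULL
    lex_gt <- function(a, b) {
      d <- which(a != b)
      length(d) > 0L && a[d[1L]] > b[d[1L]]
    }
    for (a in seq_along(alive)) {
      for (b in seq_len(a - 1L)) {
        i <- alive[b]; j <- alive[a]
        ov <- length(intersect(sets[[i]], sets[[j]]))
        un <- length(union(sets[[i]], sets[[j]]))
        cand <- c(ov, un, -i, -j)
        if (is.null(best) || lex_gt(cand, best$cand)) {
          best <- list(i = i, j = j, cand = cand)
        }
      }
    }
    if (best$cand[1] < 2L) {
      stop("profile is disconnected under >=2-taxon overlaps; isolated items: ",
           paste(alive, collapse = ", "), call. = FALSE)
    }
    sets[[length(sets) + 1L]] <- union(sets[[best$i]], sets[[best$j]])
    plan[[length(plan) + 1L]] <- list(i = best$i, j = best$j,
                                      overlap = best$cand[1],
                                      result = length(sets))
    alive <- c(setdiff(alive, c(best$i, best$j)), length(sets))
  }
  plan
}

#' Strict consensus merger tree of a profile
#'
#' Executes the greedy merge plan; the final tree contains all taxa of the
#' profile but is in general only partially resolved.
#'
#' @param profile A \code{source_profile}.
#' @return A list: \code{tree}, \code{steps} (per-merge logs) and
#'   \code{resolution} (internal edges present as a fraction of the n-3
#'   possible).
#' @export
scm_tree <- function(profile) {
  plan <- merge_order(profile)
  items <- profile$trees
  steps <- list()
  for (st in plan) {
    res <- suppressWarnings(pairwise_scm(items[[st$i]], items[[st$j]]))
    items[[st$result]] <- res$tree
    res$step$i <- st$i; res$step$j <- st$j
    steps[[length(steps) + 1L]] <- res$step
  }
  final <- if (length(plan)) items[[length(items)]] else items[[1L]]
  n <- ape::Ntip(final)
  resolution <- if (n > 3L) length(split_keys(final)) / (n - 3L) else 1
  list(tree = final, steps = steps, resolution = resolution)
}
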