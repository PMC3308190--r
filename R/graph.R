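# Minimal mutable-by-copy unrooted tree graph used internally by the
# tree-surgery algorithms (SCM merging, polytomy refinement, random
# refinement). Nodes are integer ids; leaves carry labels; topology only
# (branch lengths are not tracked through surgery).

new_graph <- function() {
  list(adj = list(), label = character(0), active = logical(0))
}

g_add_node <- function(g, label = NA_character_) {
  id <- length(g$adj) + 1L
  g$adj[[id]] <- integer(0)
  g$label[id] <- label
  g$active[id] <- TRUE
  list(g = g, id = id)
}

g_add_edge <- function(g, u, v) {
  g$adj[[u]] <- c(g$adj[[u]], v)
  g$adj[[v]] <- c(g$adj[[v]], u)
  g
}

g_del_edge <- function(g, u, v) {
  g$adj[[u]] <- g$adj[[u]][g$adj[[u]] != v]
  g$adj[[v]] <- g$adj[[v]][g$adj[[v]] != u]
  g
}

g_degree <- function(g, v) length(g$adj[[v]])

g_leaves <- function(g) which(g$active & !is.na(g$label))

g_internal <- function(g) which(g$active & is.na(g$label))

# Merge node v into node u: v's neighbors are reattached to u, v removed.
g_contract <- function(g, u, v) {
  for (w in g$adj[[v]]) {
    if (w != u) {
      g$adj[[w]] <- c(g$adj[[w]][g$adj[[w]] != v], u)
      g$adj[[u]] <- c(g$adj[[u]], w)
    }
  }
  g$adj[[u]] <- g$adj[[u]][g$adj[[u]] != v]
  g$adj[[v]] <- integer(0)
  g$active[v] <- FALSE
  g
}

# Splice out unlabeled degree-2 nodes and prune dangling unlabeled nodes.
g_suppress_degree2 <- function(g) {
  repeat {
    changed <- FALSE
    for (v in which(g$active & is.na(g$label))) {
      d <- g_degree(g, v)
      if (d == 2L) {
        nb <- g$adj[[v]]
        g <- g_del_edge(g, v, nb[1L])
        g <- g_del_edge(g, v, nb[2L])
        g <- g_add_edge(g, nb[1L], nb[2L])
        g$active[v] <- FALSE
        changed <- TRUE
      } else if (d <= 1L) {
        if (d == 1L) g <- g_del_edge(g, v, g$adj[[v]][1L])
        g$active[v] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  g
}

graph_from_phylo <- function(tree, suppress = TRUE) {
  n <- ape::Ntip(tree) + tree$Nnode
  g <- list(
    adj = rep(list(integer(0)), n),
    label = c(tree$tip.label, rep(NA_character_, tree$Nnode)),
    active = rep(TRUE, n)
  )
  for (i in seq_len(nrow(tree$edge))) {
    g <- g_add_edge(g, tree$edge[i, 1L], tree$edge[i, 2L])
  }
  if (suppress) g <- g_suppress_degree2(g)
  g
}

quote_label <- function(x) {
  ifelse(grepl("[][ ():;,'{}]", x),
         paste0("'", gsub("'", "''", x, fixed = TRUE), "'"),
         x)
}

g_newick <- function(g, v, parent) {
  if (!is.na(g$label[v])) return(quote_label(g$label[v]))
  kids <- g$adj[[v]][g$adj[[v]] != parent]
  paste0("(", paste(vapply(kids, function(k) g_newick(g, k, v), ""),
                    collapse = ","), ")")
}

phylo_from_graph <- function(g) {
  leaves <- g_leaves(g)
  internal <- g_internal(g)
  if (length(leaves) == 1L && !length(internal)) {
    return(one_tip_phylo(g$label[leaves]))
  }
  if (length(leaves) == 2L && !length(internal)) {
    txt <- paste0("(", quote_label(g$label[leaves[1L]]), ",",
                  quote_label(g$label[leaves[2L]]), ");")
    return(ape::read.tree(text = txt))
  }
  start <- internal[which.max(vapply(internal, function(v) g_degree(g, v), 0L))]
  kids <- g$adj[[start]]
  txt <- paste0("(", paste(vapply(kids, function(k) g_newick(g, k, start), ""),
                           collapse = ","), ");")
  ape::read.tree(text = txt)
}

one_tip_phylo <- function(label) {
  structure(list(edge = matrix(c(2L, 1L), 1L, 2L),
                 tip.label = label, Nnode = 1L),
            class = "phylo", order = "cladewise")
}

# Connected component of g containing `root` after removing edge (avoid, root);
# returns the node ids.
g_component <- function(g, root, avoid) {
  seen <- c(root)
  queue <- root
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    for (w in g$adj[[v]]) {
      if (w != avoid && !(w %in% seen)) {
        seen <- c(seen, w)
        queue <- c(queue, w)
      }
    }
  }
  seen
}

# Copy the subtree of `src` hanging off `root` (entered from `avoid`) into
# `dst`, attached at node `attach`. Returns the updated dst graph.
g_graft <- function(src, root, avoid, dst, attach) {
  copy_rec <- function(v, parent, attach_to, dst) {
    res <- g_add_node(dst, src$label[v])
    dst <- g_add_edge(res$g, attach_to, res$id)
    for (w in src$adj[[v]]) {
      if (w != parent) dst <- copy_rec(w, v, res$id, dst)
    }
    dst
  }
  copy_rec(root, avoid, attach, dst)
}
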