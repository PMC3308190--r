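# Unrooted tree data model: newick I/O, bipartitions, restriction,
# strict consensus, random refinement. Trees are ape "phylo" objects;
# the stored root is only a traversal anchor and never affects results,
# which are all defined on the unrooted topology.

#' Parse a newick string into an unrooted tree
#'
#' Accepts standard parenthetical newick with optional branch lengths,
#' single-quoted labels and polytomies. Degree-2 nodes (including a rooted
#' binary tree's root) are suppressed so the result represents an unrooted
#' topology. Internal node labels are parsed but ignored.
#'
#' @param text A single newick string (terminated by ';').
#' @return An object of class \code{phylo}.
#' @export
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  check_newick_syntax(text)
  bare <- sub(";\\s*$", "", trimws(text))
  if (grepl("^'?[^'(),:;]+'?(:[0-9.eE+-]+)?$", bare)) {
    lab <- gsub("^'|'(:.*)?$", "", sub(":.*$", "", bare))
    return(one_tip_phylo(lab))
  }
  tr <- tryCatch(ape::read.tree(text = text), error = function(e) NULL,
                 warning = function(w) NULL)
  if (is.null(tr)) stop("malformed newick string", call. = FALSE)
  tr$node.label <- NULL
  quoted <- grepl("^'.*'$", tr$tip.label)
  tr$tip.label[quoted] <- gsub("''", "'", sub("^'(.*)'$", "\\1",
                                              tr$tip.label[quoted]))
  if (anyDuplicated(tr$tip.label)) {
    stop("duplicate leaf label: ",
         paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = ", "),
         call. = FALSE)
  }
  tr <- ape::collapse.singles(tr)
  if (ape::Ntip(tr) > 2L && !ape::is.rooted(tr)) return(tr)
  if (ape::Ntip(tr) > 3L) tr <- ape::unroot(tr)
  tr
}

# Cheap structural scan so syntax errors carry a character offset.
check_newick_syntax <- function(text) {
  chars <- strsplit(text, "")[[1]]
  depth <- 0L; in_quote <- FALSE
  for (i in seq_along(chars)) {
    ch <- chars[i]
    if (ch == "'") in_quote <- !in_quote
    if (in_quote) next
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") {
      depth <- depth - 1L
      if (depth < 0L) {
        stop(sprintf("malformed newick: unmatched ')' at offset %d", i),
             call. = FALSE)
      }
    }
  }
  if (in_quote) stop("malformed newick: unterminated quote", call. = FALSE)
  if (depth != 0L) {
    stop(sprintf("malformed newick: %d unclosed '(' at end of string", depth),
         call. = FALSE)
  }
  if (!grepl(";\\s*$", trimws(text))) {
    stop(sprintf("malformed newick: missing ';' terminator at offset %d",
                 nchar(text)), call. = FALSE)
  }
  invisible(TRUE)
}

#' Write a tree as a newick string or file
#'
#' @param tree A \code{phylo} object.
#' @param file Optional path; when \code{NULL} the string is returned.
#' @export
write_newick <- function(tree, file = NULL) {
  txt <- ape::write.tree(tree)
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(txt)
}

# All non-trivial splits of a tree as canonical sides (see canonical_side).
# Returned in a deterministic preorder of the internal edges from the
# traversal anchor; names are canonical keys.
tree_splits <- function(tree, universe = NULL) {
  labs <- tree$tip.label
  if (is.null(universe)) universe <- labs
  if (!all(labs %in% universe)) {
    stop("tree contains leaves outside the stated taxon universe: ",
         paste(setdiff(labs, universe), collapse = ", "), call. = FALSE)
  }
  ntip <- ape::Ntip(tree)
  if (ntip < 4L || tree$Nnode < 2L) {
    out <- list()
    attr(out, "universe") <- universe
    return(out)
  }
  po <- ape::reorder.phylo(tree, "postorder")
  below <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip)) below[[i]] <- labs[i]
  for (i in seq_len(nrow(po$edge))) {
    p <- po$edge[i, 1L]; ch <- po$edge[i, 2L]
    below[[p]] <- c(below[[p]], below[[ch]])
  }
  root <- ntip + 1L
  pre <- ape::reorder.phylo(tree, "cladewise")
  sides <- list()
  for (i in seq_len(nrow(pre$edge))) {
    ch <- pre$edge[i, 2L]
    if (ch <= ntip || ch == root) next
    side <- below[[ch]]
    if (length(side) >= 2L && ntip - length(side) >= 2L) {
      cs <- canonical_side(side, universe)
      sides[[split_key(cs)]] <- cs
    }
  }
  attr(sides, "universe") <- universe
  sides
}

#' Non-trivial bipartitions of an unrooted tree
#'
#' Each internal edge induces one bipartition of the taxon universe,
#' returned in canonical form (the side not containing the reference
#' taxon, the byte-order minimum of the universe), so that the result is
#' independent of edge polarity and of the traversal anchor. Trivial
#' (pendant) edges are excluded.
#'
#' @param tree A \code{phylo} object.
#' @param universe Taxon universe; defaults to the tree's own leaf set.
#' @return A named list of character vectors (canonical sides).
#' @export
bipartitions <- function(tree, universe = NULL) {
  tree_splits(tree, universe)
}

split_keys <- function(tree) names(tree_splits(tree)) %||% character(0)

#' Restrict a tree to a taxon subset
#'
#' Returns the induced subtree on \code{subset} with degree-2 nodes
#' suppressed, so its bipartitions are exactly the non-trivial
#' restrictions of the input's bipartitions. Branch lengths, when
#' present, are summed through suppressed nodes.
#'
#' @param tree A \code{phylo} object.
#' @param subset Character vector of taxa (intersected with the leaves).
#' @export
restrict_tree <- function(tree, subset) {
  keep <- intersect(tree$tip.label, subset)
  if (!length(keep)) stop("restriction to an empty leaf set", call. = FALSE)
  if (length(keep) == 1L) return(one_tip_phylo(keep))
  if (length(keep) == ape::Ntip(tree)) return(tree)
  tr <- ape::keep.tip(tree, keep)
  if (length(keep) > 3L && ape::is.rooted(tr)) tr <- ape::unroot(tr)
  tr <- ape::collapse.singles(tr)
  tr
}

#' Strict consensus of trees on one leaf set
#'
#' The output tree's bipartition set is the intersection of the inputs'
#' bipartition sets.
#'
#' @param trees A list of \code{phylo} objects on identical leaf sets.
#' @export
strict_consensus <- function(trees) {
  stopifnot(length(trees) >= 1L)
  taxa <- sort_c(trees[[1L]]$tip.label)
  for (t in trees) {
    if (!identical(sort_c(t$tip.label), taxa)) {
      stop("strict consensus requires identical leaf sets", call. = FALSE)
    }
  }
  keys <- split_keys(trees[[1L]])
  for (t in trees[-1L]) keys <- intersect(keys, split_keys(t))
  tree_from_splits(lapply(keys, key_to_side), taxa)
}

# Build the unique tree whose non-trivial splits are `sides` (must be
# pairwise compatible). Sides are given over `taxa`; each is replaced by
# the side avoiding the reference taxon and the laminar family is
# assembled into a rooted hierarchy anchored at the reference.
tree_from_splits <- function(sides, taxa) {
  taxa <- sort_c(taxa)
  if (length(taxa) == 1L) return(one_tip_phylo(taxa))
  if (length(taxa) == 2L) {
    return(ape::read.tree(
      text = paste0("(", quote_label(taxa[1]), ",", quote_label(taxa[2]), ");")))
  }
  ref <- taxa[1L]
  clusters <- lapply(sides, function(s) {
    if (ref %in% s) setdiff(taxa, s) else s
  })
  clusters <- unique(lapply(clusters, sort_c))
  sizes <- vapply(clusters, length, 0L)
  clusters <- clusters[order(-sizes)]
  # laminar check (defensive: callers must pass compatible splits)
  for (i in seq_along(clusters)) {
    for (j in seq_len(i - 1L)) {
      a <- clusters[[i]]; b <- clusters[[j]]
      ov <- length(intersect(a, b))
      if (ov && ov < min(length(a), length(b))) {
        stop("incompatible splits passed to tree_from_splits", call. = FALSE)
      }
    }
  }
  # clusters are size-descending, so scanning with a `used` guard picks the
  # maximal sub-clusters at each level of the laminar hierarchy
  nwk <- function(members) {
    subs <- Filter(function(x) all(x %in% members) && length(x) < length(members),
                   clusters)
    parts <- character(0)
    used <- character(0)
    for (cl in subs) {
      if (length(intersect(cl, used))) next
      parts <- c(parts, nwk(cl))
      used <- c(used, cl)
    }
    parts <- c(parts, quote_label(setdiff(members, used)))
    paste0("(", paste(parts, collapse = ","), ")")
  }
  txt <- paste0(nwk(setdiff(taxa, ref)), ";")
  txt <- sub("^\\(", paste0("(", quote_label(ref), ","), txt)
  tr <- ape::read.tree(text = txt)
  ape::collapse.singles(tr)
}

is_binary_unrooted <- function(tree) {
  n <- ape::Ntip(tree)
  if (n < 4L) return(TRUE)
  length(tree_splits(tree)) == n - 3L
}

#' Randomly refine polytomies to a binary tree
#'
#' Each polytomy is resolved by repeatedly splitting its neighbor set into
#' two random parts of size >= 2 (binary recursion). The output's
#' bipartition set is a superset of the input's. This scheme is not
#' uniform over all possible resolutions.
#'
#' @param tree A \code{phylo} object with >= 4 leaves (binary input is
#'   returned unchanged).
#' @param seed Optional integer seed making the refinement reproducible.
#' @export
random_refinement <- function(tree, seed = NULL) {
  if (ape::Ntip(tree) < 4L || is_binary_unrooted(tree)) return(tree)
  with_seed(seed, {
    g <- graph_from_phylo(tree)
    queue <- Filter(function(v) g_degree(g, v) > 3L, g_internal(g))
    while (length(queue)) {
      v <- queue[[1L]]; queue <- queue[-1L]
      while (g_degree(g, v) > 3L) {
        nb <- g$adj[[v]]
        repeat {
          pick <- as.logical(stats::rbinom(length(nb), 1L, 0.5))
          if (sum(pick) >= 2L && sum(!pick) >= 2L) break
        }
        res <- g_add_node(g)
        g <- res$g; u <- res$id
        for (w in nb[pick]) {
          g <- g_del_edge(g, v, w)
          g <- g_add_edge(g, u, w)
        }
        g <- g_add_edge(g, u, v)
        if (g_degree(g, u) > 3L) queue <- c(queue, u)
      }
    }
    phylo_from_graph(g)
  })
}
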