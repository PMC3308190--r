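# Synthetic source-tree profiles with the structure of the simulation
# study: a binary model tree, several "clade-based" source trees (dense
# samples within clades of the model tree) and one "scaffold" source tree
# (a random sample of a stated proportion -- the scaffold density -- of
# all taxa), each optionally perturbed by estimation error.

#' Simulation design for a synthetic profile
#'
#' @param n_taxa Taxa in the model tree.
#' @param n_clade_trees Clade-based source trees per profile.
#' @param scaffold_density Proportion of taxa sampled by the scaffold
#'   tree, in (0, 1].
#' @param clade_size_range Admissible clade sizes; defaults to
#'   [max(4, n/20), max(8, n/4)].
#' @param error One of "none", "characters" (simulate \code{error_sites}
#'   binary characters on the source tree and re-estimate it by MP, so the
#'   error shrinks as \code{error_sites} grows) or "nni" (apply
#'   Poisson(rate * (n - 3)) random NNI moves).
#' @param error_sites Characters simulated per source tree in
#'   "characters" mode.
#' @param error_rate Expected NNI moves per internal edge in "nni" mode.
#' @param seed Integer seed.
#' @export
sim_design <- function(n_taxa = 500L, n_clade_trees = 15L,
                       scaffold_density = 1.0,
                       clade_size_range = NULL,
                       error = c("none", "characters", "nni"),
                       error_sites = 250L, error_rate = 0.1, seed = 1L) {
  error <- match.arg(error)
  stopifnot(scaffold_density > 0, scaffold_density <= 1,
            ceiling(scaffold_density * n_taxa) >= 4L, n_clade_trees >= 1L)
  if (is.null(clade_size_range)) {
    clade_size_range <- c(max(4L, floor(n_taxa / 20)),
                          max(8L, ceiling(n_taxa / 4)))
  }
  stopifnot(clade_size_range[1L] >= 4L,
            clade_size_range[2L] >= clade_size_range[1L])
  structure(list(n_taxa = as.integer(n_taxa),
                 n_clade_trees = as.integer(n_clade_trees),
                 scaffold_density = scaffold_density,
                 clade_size_range = as.integer(clade_size_range),
                 error = error, error_sites = as.integer(error_sites),
                 error_rate = error_rate, seed = seed),
            class = "sim_design")
}

#' Simulate a binary model tree
#'
#' Random (Yule-like random-addition) binary topology with independent
#' exponential branch lengths of mean 0.1 substitutions/site.
#'
#' @param n Number of leaves (labels t1..tn).
#' @param seed Integer seed.
#' @param mean_bl Mean branch length.
#' @export
simulate_model_tree <- function(n, seed = NULL, mean_bl = 0.1) {
  stopifnot(n >= 4L)
  with_seed(seed, {
    tr <- ape::rtree(n, tip.label = paste0("t", seq_len(n)))
    tr <- ape::unroot(tr)
    tr$edge.length <- stats::rexp(nrow(tr$edge), rate = 1 / mean_bl)
    tr
  })
}

model_clades <- function(model) {
  sp <- tree_splits(model)
  sides <- c(sp, lapply(sp, function(s) setdiff(model$tip.label, s)))
  unique(lapply(sides, sort_c))
}

#' Sample a clade-based source tree
#'
#' Chooses uniformly among the clades of the model tree (the components
#' obtained by removing one edge) whose size lies in the range, and
#' returns the model restricted to all of that clade's taxa (a dense
#' sample).
#'
#' @param model The model \code{phylo}.
#' @param size_range Two integers, the admissible clade sizes.
#' @param seed Integer seed.
#' @export
sample_clade_tree <- function(model, size_range, seed = NULL) {
  clades <- model_clades(model)
  sizes <- vapply(clades, length, 0L)
  ok <- which(sizes >= size_range[1L] & sizes <= size_range[2L])
  if (!length(ok)) {
    stop("no clade of the model tree has size in [", size_range[1L], ", ",
         size_range[2L], "]", call. = FALSE)
  }
  with_seed(seed, restrict_tree(model, clades[[sample(ok, 1L)]]))
}

#' Sample a scaffold source tree
#'
#' Restricts the model tree to ceiling(density * n) taxa drawn uniformly
#' without replacement across the whole tree.
#'
#' @param model The model \code{phylo}.
#' @param density Scaffold density in (0, 1].
#' @param seed Integer seed.
#' @export
sample_scaffold_tree <- function(model, density, seed = NULL) {
  stopifnot(density > 0, density <= 1)
  n <- ape::Ntip(model)
  m <- min(n, ceiling(density * n))
  with_seed(seed, restrict_tree(model, sample(model$tip.label, m)))
}

# Simulate m binary characters on a tree under the CFN model (equal rates).
simulate_cfn_characters <- function(tree, m) {
  check_lengths(tree)
  ntip <- ape::Ntip(tree)
  nid <- ntip + tree$Nnode
  po <- ape::reorder.phylo(tree, "postorder")
  states <- matrix(NA_integer_, nid, m)
  root <- ntip + 1L
  states[root, ] <- stats::rbinom(m, 1L, 0.5)
  for (i in rev(seq_len(nrow(po$edge)))) {
    p <- po$edge[i, 1L]; ch <- po$edge[i, 2L]
    pflip <- (1 - exp(-2 * po$edge.length[i])) / 2
    flip <- stats::rbinom(m, 1L, pflip)
    states[ch, ] <- bitwXor(states[p, ], flip)
  }
  out <- states[seq_len(ntip), , drop = FALSE]
  rownames(out) <- tree$tip.label
  out
}

#' Perturb a source tree with estimation error
#'
#' "characters" mode simulates binary characters on the tree under the
#' symmetric 2-state model and re-estimates the topology by heuristic MP,
#' so error arises naturally and shrinks with the number of sites. "nni"
#' mode applies Poisson(rate * (n - 3)) random NNI rearrangements.
#'
#' @param tree A binary \code{phylo} with branch lengths (for
#'   "characters").
#' @param mode "none", "characters" or "nni".
#' @param seed Integer seed.
#' @param sites Characters to simulate in "characters" mode.
#' @param rate Expected NNI moves per internal edge in "nni" mode.
#' @export
add_estimation_error <- function(tree, mode = c("none", "characters", "nni"),
                                 seed = NULL, sites = 250L, rate = 0.1) {
  mode <- match.arg(mode)
  if (mode == "none") return(tree)
  with_seed(seed, {
    if (mode == "characters") {
      chars <- simulate_cfn_characters(tree, sites)
      informative <- apply(chars, 2L, function(col) {
        min(sum(col == 0L), sum(col == 1L)) >= 2L
      })
      chars <- chars[, informative, drop = FALSE]
      if (ncol(chars) < 1L) return(random_refinement(
        tree_from_splits(list(), tree$tip.label),
        seed = sample.int(2^30, 1L)))
      cm <- mrp_matrix(chars)
      res <- suppressWarnings(
        mp_search(cm, mp_config(n_starts = 1L, seed = sample.int(2^30, 1L))))
      est <- res$trees[[1L]]
      if (!is_binary_unrooted(est)) {
        est <- random_refinement(est, seed = sample.int(2^30, 1L))
      }
      est
    } else {
      g <- graph_from_phylo(tree)
      n_moves <- stats::rpois(1L, rate * max(0L, ape::Ntip(tree) - 3L))
      for (mv in seq_len(n_moves)) {
        nbrs <- g_nni_neighbors(g)
        if (!length(nbrs)) break
        g <- nbrs[[sample.int(length(nbrs), 1L)]]
      }
      phylo_from_graph(g)
    }
  })
}

#' Generate a synthetic source-tree profile
#'
#' n_clade_trees clade-based trees plus one scaffold tree, each passed
#' through the estimation-error model. A warning is emitted when the
#' resulting profile is not connected under 2-taxon overlaps (too little
#' taxonomic overlap for a supertree analysis).
#'
#' @param design A \code{sim_design}.
#' @return A list: \code{profile} (a \code{source_profile}), \code{model}
#'   (the model tree) and \code{design}.
#' @export
make_profile <- function(design) {
  stopifnot(inherits(design, "sim_design"))
  with_seed(design$seed, {
    model <- simulate_model_tree(design$n_taxa,
                                 seed = sample.int(2^30, 1L))
    trees <- list()
    for (i in seq_len(design$n_clade_trees)) {
      # draw the sub-seeds eagerly: lazy evaluation must not make the
      # taxon sampling depend on the error mode
      s_clade <- sample.int(2^30, 1L)
      s_err <- sample.int(2^30, 1L)
      ct <- sample_clade_tree(model, design$clade_size_range, seed = s_clade)
      trees[[i]] <- add_estimation_error(ct, design$error, seed = s_err,
                                         sites = design$error_sites,
                                         rate = design$error_rate)
    }
    s_scaf <- sample.int(2^30, 1L)
    s_err <- sample.int(2^30, 1L)
    sc <- sample_scaffold_tree(model, design$scaffold_density, seed = s_scaf)
    trees[[design$n_clade_trees + 1L]] <-
      add_estimation_error(sc, design$error, seed = s_err,
                           sites = design$error_sites,
                           rate = design$error_rate)
    profile <- source_profile(trees)
    connected <- tryCatch({merge_order(profile); TRUE},
                          error = function(e) FALSE)
    if (!connected) {
      warning("profile has insufficient taxonomic overlap ",
              "(not connected under 2-taxon overlaps)", call. = FALSE)
    }
    list(profile = profile, model = model, design = design,
         connected = connected)
  })
}
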