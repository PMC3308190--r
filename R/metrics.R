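# Topological error rates (FN/FP), Robinson-Foulds distance, Sum-FN,
# p-ECR tree neighborhoods, and the score-versus-error rank-correlation
# protocol.

check_same_leaves <- function(t1, t2) {
  if (!setequal(t1$tip.label, t2$tip.label)) {
    stop("trees must have identical leaf sets", call. = FALSE)
  }
}

#' False negative (missing branch) rate
#'
#' Percentage of the reference tree's internal edges missing from the
#' estimate: 100 * |bip(true) \\ bip(est)| / |bip(true)|.
#'
#' @param true_tree,est_tree \code{phylo} objects on the same leaf set.
#' @export
fn_rate <- function(true_tree, est_tree) {
  check_same_leaves(true_tree, est_tree)
  kt <- split_keys(true_tree)
  if (!length(kt)) return(0)
  100 * length(setdiff(kt, split_keys(est_tree))) / length(kt)
}

#' False positive rate
#'
#' Percentage of the estimate's internal edges absent from the reference:
#' 100 * |bip(est) \\ bip(true)| / |bip(est)|; 0 when the estimate has no
#' internal edges. Never exceeds the FN rate when the reference is binary.
#'
#' @param true_tree,est_tree \code{phylo} objects on the same leaf set.
#' @export
fp_rate <- function(true_tree, est_tree) {
  check_same_leaves(true_tree, est_tree)
  ke <- split_keys(est_tree)
  if (!length(ke)) return(0)
  100 * length(setdiff(ke, split_keys(true_tree))) / length(ke)
}

#' Robinson-Foulds distance
#'
#' Size of the symmetric difference of the two bipartition sets.
#'
#' @param t1,t2 \code{phylo} objects on the same leaf set.
#' @export
rf_distance <- function(t1, t2) {
  check_same_leaves(t1, t2)
  k1 <- split_keys(t1); k2 <- split_keys(t2)
  length(setdiff(k1, k2)) + length(setdiff(k2, k1))
}

#' Error report for an estimated tree
#'
#' @param true_tree,est_tree \code{phylo} objects on the same leaf set.
#' @return A list with FN and FP rates (percent), the RF distance and the
#'   internal-edge counts of both trees.
#' @export
error_report <- function(true_tree, est_tree) {
  list(fn = fn_rate(true_tree, est_tree), fp = fp_rate(true_tree, est_tree),
       rf = rf_distance(true_tree, est_tree),
       n_edges_true = length(split_keys(true_tree)),
       n_edges_est = length(split_keys(est_tree)))
}

#' Sum-FN of a supertree against its source trees
#'
#' Percentage of the source trees' internal edges missing from the
#' supertree's restrictions: 100 * sum_t |bip(t) \\ bip(restrict(T,
#' leaves(t)))| / sum_t |bip(t)|. Identical (up to scale) to Sum-RF when
#' all trees are binary.
#'
#' @param profile A \code{source_profile}.
#' @param supertree A \code{phylo} whose leaves include every source taxon.
#' @export
sum_fn <- function(profile, supertree) {
  missing_taxa <- setdiff(profile$taxa, supertree$tip.label)
  if (length(missing_taxa)) {
    stop("source taxa absent from supertree: ",
         paste(missing_taxa, collapse = ", "), call. = FALSE)
  }
  miss <- 0L; tot <- 0L
  for (t in profile$trees) {
    kt <- split_keys(t)
    kr <- split_keys(restrict_tree(supertree, t$tip.label))
    miss <- miss + length(setdiff(kt, kr))
    tot <- tot + length(kt)
  }
  if (tot == 0L) return(0)
  100 * miss / tot
}

#' p-ECR move: contract p edges, then randomly refine
#'
#' Contracts p internal edges chosen uniformly without replacement, then
#' refines the resulting polytomies at random. A binary input yields a
#' binary output whose RF distance from the input is at most 2p.
#'
#' @param tree A \code{phylo}.
#' @param p Number of internal edges to contract (0..#internal edges).
#' @param seed Integer seed.
#' @export
p_ecr <- function(tree, p, seed = NULL) {
  keys <- split_keys(tree)
  if (p > length(keys)) {
    stop("p exceeds the number of internal edges (", length(keys), ")",
         call. = FALSE)
  }
  if (p == 0L) return(tree)
  with_seed(seed, {
    keep <- sample(keys, length(keys) - p)
    contracted <- tree_from_splits(lapply(keep, key_to_side),
                                   tree$tip.label)
    random_refinement(contracted, seed = sample.int(2^30, 1L))
  })
}

#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties (wraps
#' \code{stats::cor(method = "spearman")}).
#'
#' @param xs,ys Numeric vectors of equal length.
#' @export
spearman_rho <- function(xs, ys) {
  stopifnot(length(xs) == length(ys))
  stats::cor(xs, ys, method = "spearman")
}

#' Score-versus-error correlation experiment
#'
#' For each estimated supertree, generates \code{n_per_tree} p-ECR
#' neighbors with p uniform in [0, ceil(p_max_fraction * (n - 3))], then
#' scores every tree (originals plus neighbors) by MP score, MRL score and
#' Sum-FN, and computes the Spearman rank correlation of each score with
#' the missing branch (FN) rate against the true tree.
#'
#' Non-binary input supertrees are randomly refined first (seeded) so
#' error rates and scores are comparable across trees; set
#' \code{keep_polytomies = TRUE} to score them as they are.
#'
#' @param profile The source profile (defines the MRP matrix and Sum-FN).
#' @param true_tree The model tree, on the same taxa as the supertrees.
#' @param supertrees List of estimated supertrees on the profile's taxa.
#' @param n_per_tree Neighbors per supertree.
#' @param p_max_fraction Upper bound on p as a fraction of internal edges.
#' @param seed Integer seed.
#' @param keep_polytomies Keep unresolved supertrees unrefined.
#' @param mrl_sweeps Branch-length sweeps per alternation in MRL scoring.
#' @return A list: \code{table} (one row per scored tree) and \code{rho}
#'   (Spearman correlation of each score with the FN rate; the sign of
#'   the MRL log-likelihood and of Sum-FN are chosen so that a positive
#'   rho means "worse score, larger error").
#' @export
correlation_experiment <- function(profile, true_tree, supertrees,
                                   n_per_tree = 100L, p_max_fraction = 0.25,
                                   seed = 1L, keep_polytomies = FALSE,
                                   mrl_sweeps = 2L) {
  cm <- encode_baum_ragan(profile)
  with_seed(seed, {
    trees <- list()
    for (i in seq_along(supertrees)) {
      st <- supertrees[[i]]
      if (!keep_polytomies && !is_binary_unrooted(st)) {
        st <- random_refinement(st, seed = sample.int(2^30, 1L))
      }
      trees[[length(trees) + 1L]] <- st
      nkeys <- length(split_keys(st))
      pmax <- ceiling(p_max_fraction * nkeys)
      for (r in seq_len(n_per_tree)) {
        p <- sample.int(pmax + 1L, 1L) - 1L
        trees[[length(trees) + 1L]] <- p_ecr(st, p,
                                             seed = sample.int(2^30, 1L))
      }
    }
    fn <- vapply(trees, fn_rate, 0, true_tree = true_tree)
    mp <- vapply(trees, mp_score, 0L, matrix = cm)
    sfn <- vapply(trees, function(t) sum_fn(profile, t), 0)
    mrl <- vapply(trees, function(t) {
      # ranking needs the score's shape, not its converged tail: a loose
      # per-sweep tolerance keeps the 600-tree protocol fast
      mrl_score(t, cm, rounds = 2L, max_sweeps = mrl_sweeps,
                tol = 0.02)$loglik
    }, 0)
    tab <- data.frame(
      tree = seq_along(trees),
      origin = rep(seq_along(supertrees), each = n_per_tree + 1L),
      fn = fn, mp_score = mp, mrl_score = mrl, sum_fn = sfn)
    rho <- c(mp_score = spearman_rho(mp, fn),
             mrl_score = spearman_rho(-mrl, fn),
             sum_fn = spearman_rho(sfn, fn))
    list(table = tab, rho = rho)
  })
}
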