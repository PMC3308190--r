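# High-level drivers: one entry point dispatching over the supertree
# methods, and the scaled simulation experiment (methods x scaffold
# densities) mirroring the structure of the simulation study.

#' Estimate a supertree from a profile
#'
#' Dispatches over the implemented methods. MRP returns the greedy
#' consensus of the equally most-parsimonious trees found (or the strict
#' consensus / first tree on request); MRL returns the maximum-likelihood
#' tree; "scm" the strict consensus merger; the SuperFine variants refine
#' the SCM tree with the respective base method.
#'
#' @param profile A \code{source_profile}.
#' @param method One of "mrp", "mrl", "scm", "superfine_mrp",
#'   "superfine_mrl".
#' @param seed Integer seed.
#' @param starts Random-addition starts for MP searches.
#' @param consensus For "mrp": "greedy", "strict" or "none" (first best).
#' @param score Also report the MP score and MRL score of the estimate
#'   (adds an MRL optimization; off by default).
#' @return A list: \code{tree}, \code{method}, \code{report}.
#' @export
supertree <- function(profile,
                      method = c("mrp", "mrl", "scm", "superfine_mrp",
                                 "superfine_mrl"),
                      seed = 1L, starts = 2L,
                      consensus = c("greedy", "strict", "none"),
                      score = FALSE) {
  method <- match.arg(method)
  consensus <- match.arg(consensus)
  report <- list(method = method, ntax = length(profile$taxa))
  res <- switch(method,
    mrp = {
      cm <- encode_baum_ragan(profile)
      sr <- suppressWarnings(
        mp_search(cm, mp_config(n_starts = starts, seed = seed)))
      tree <- if (length(sr$trees) == 1L || consensus == "none") {
        sr$trees[[1L]]
      } else if (consensus == "greedy") {
        greedy_consensus(sr$trees)
      } else {
        strict_consensus(sr$trees)
      }
      report$mp_score <- sr$score
      report$n_best_trees <- length(sr$trees)
      tree
    },
    mrl = {
      cm <- encode_baum_ragan(profile)
      sr <- ml_search(cm, ml_config(seed = seed,
                                    mp = mp_config(n_starts = 1L)))
      report$mrl_score <- sr$loglik
      report$alpha <- sr$alpha
      sr$tree
    },
    scm = {
      sr <- scm_tree(profile)
      report$resolution <- sr$resolution
      sr$tree
    },
    superfine_mrp = {
      sr <- superfine(profile, "mrp", seed = seed, starts = starts)
      report$scm_resolution <- sr$scm$resolution
      report$n_polytomies <- sr$n_polytomies
      sr$tree
    },
    superfine_mrl = {
      sr <- superfine(profile, "mrl", seed = seed, starts = starts)
      report$scm_resolution <- sr$scm$resolution
      report$n_polytomies <- sr$n_polytomies
      sr$tree
    })
  n <- ape::Ntip(res)
  report$resolution <- length(split_keys(res)) / max(1L, n - 3L)
  if (score) {
    cm <- encode_baum_ragan(profile)
    report$mp_score <- mp_score(res, cm)
    ms <- mrl_score(res, cm)
    report$mrl_score <- ms$loglik
    report$alpha <- ms$alpha
  }
  list(tree = res, method = method, report = report)
}

#' Scaled density-trend experiment
#'
#' Generates one synthetic profile per (seed, scaffold density), runs the
#' requested methods, and reports FN/FP rates against the model tree --
#' the scaled analogue of the simulation study's accuracy-versus-density
#' comparison.
#'
#' @param n_taxa Model-tree size.
#' @param densities Scaffold densities to cover.
#' @param seeds Integer vector, one replicate per seed.
#' @param methods Methods to run (see \code{\link{supertree}}).
#' @param n_clade_trees Clade trees per profile.
#' @param clade_size_range Clade sizes; the scaled default [n/4, 5n/8]
#'   keeps profiles connected at small n.
#' @param error,error_sites,error_rate Estimation-error settings
#'   (see \code{\link{sim_design}}).
#' @return A data frame with one row per (seed, density, method);
#'   disconnected replicates are skipped, as in the underlying study
#'   design.
#' @export
density_experiment <- function(n_taxa = 32L, densities = c(0.2, 0.5, 1.0),
                               seeds = 1:5,
                               methods = c("mrp", "mrl", "scm",
                                           "superfine_mrp", "superfine_mrl"),
                               n_clade_trees = 6L,
                               clade_size_range = NULL,
                               error = "nni", error_sites = 250L,
                               error_rate = 0.1) {
  if (is.null(clade_size_range)) {
    clade_size_range <- c(max(4L, floor(n_taxa / 4)),
                          max(8L, ceiling(5 * n_taxa / 8)))
  }
  rows <- list()
  for (seed in seeds) {
    for (dens in densities) {
      sim <- suppressWarnings(make_profile(sim_design(
        n_taxa = n_taxa, n_clade_trees = n_clade_trees,
        scaffold_density = dens, clade_size_range = clade_size_range,
        error = error,
        error_sites = error_sites, error_rate = error_rate, seed = seed)))
      if (!sim$connected) next
      union_model <- restrict_tree(sim$model, sim$profile$taxa)
      for (m in methods) {
        est <- supertree(sim$profile, m, seed = seed)
        rows[[length(rows) + 1L]] <- data.frame(
          seed = seed, density = dens, method = m,
          fn = fn_rate(union_model, est$tree),
          fp = fp_rate(union_model, est$tree),
          resolution = est$report$resolution)
      }
    }
  }
  do.call(rbind, rows)
}
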