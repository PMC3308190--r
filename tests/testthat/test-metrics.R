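test_that("FN, FP and RF match hand-derived cases", {
  set.seed(2)
  tr <- rand_tree(8)
  expect_equal(fn_rate(tr, tr), 0)
  expect_equal(fp_rate(tr, tr), 0)
  expect_equal(rf_distance(tr, tr), 0L)

  star <- parse_newick(paste0("(", paste(tr$tip.label, collapse = ","), ");"))
  expect_equal(fn_rate(tr, star), 100)
  expect_equal(fp_rate(tr, star), 0)

  # 5-taxon trees differing in one of two internal edges
  a <- parse_newick("(((a,b),c),(d,e));")
  b <- parse_newick("(((a,b),d),(c,e));")
  expect_equal(fn_rate(a, b), 50)
  expect_equal(fp_rate(a, b), 50)
  expect_equal(rf_distance(a, b), 2L)

  q1 <- parse_newick("((a,b),(c,d));")
  q2 <- parse_newick("((a,c),(b,d));")
  expect_equal(rf_distance(q1, q2), 2L)

  expect_error(fn_rate(q1, parse_newick("((a,b),(c,e));")), "identical")
})

test_that("FN = FP for binary pairs; FP <= FN against a binary reference", {
  set.seed(14)
  for (i in 1:25) {
    n <- sample(5:20, 1)
    t1 <- rand_tree(n)
    t2 <- rand_tree(n, t1$tip.label)
    expect_equal(fn_rate(t1, t2), fp_rate(t1, t2))
    # contracted estimate: FP <= FN, and RF consistency
    est <- random_refinement(p_ecr(t2, min(2, n - 3), seed = i), seed = i)
    contracted <- superfine:::tree_from_splits(
      lapply(sample(names(bipartitions(t2)),
                    max(0, length(bipartitions(t2)) - 2)),
             function(k) strsplit(k, "\x1f")[[1]]),
      t1$tip.label)
    expect_lte(fp_rate(t1, contracted), fn_rate(t1, contracted))
    expect_equal(fp_rate(t2, contracted), 0)  # contraction of t2 itself
    # RF = FN counts + FP counts
    nt <- length(bipartitions(t1)); ne <- length(bipartitions(contracted))
    expect_equal(rf_distance(t1, contracted),
                 round(fn_rate(t1, contracted) / 100 * nt) +
                   round(fp_rate(t1, contracted) / 100 * ne))
  }
})

test_that("rf_distance agrees with an established implementation", {
  skip_if_not_installed("phangorn")
  set.seed(8)
  for (i in 1:15) {
    n <- sample(5:25, 1)
    t1 <- rand_tree(n)
    t2 <- rand_tree(n, t1$tip.label)
    expect_equal(rf_distance(t1, t2), as.integer(phangorn::RF.dist(t1, t2)))
  }
})

test_that("sum_fn: compatibility, binary Sum-RF identity, hand count", {
  set.seed(25)
  model <- rand_tree(12)
  prof <- source_profile(list(
    restrict_tree(model, sample(model$tip.label, 8)),
    restrict_tree(model, sample(model$tip.label, 7))))
  expect_equal(sum_fn(prof, model), 0)

  # binary sources and binary supertree: Sum-FN proportional to Sum-RF
  est <- rand_tree(12, model$tip.label)
  total_edges <- sum(vapply(prof$trees,
                            function(t) length(bipartitions(t)), 0L))
  sum_rf <- sum(vapply(prof$trees, function(t) {
    rf_distance(t, restrict_tree(est, t$tip.label))
  }, 0L))
  # restrictions of a binary tree are binary, so FN misses = RF/2
  expect_equal(sum_fn(prof, est), 100 * (sum_rf / 2) / total_edges)

  # one conflicting quartet among compatible sources
  q_ok <- restrict_tree(model, model$tip.label[1:4])
  labs <- q_ok$tip.label
  sides <- bipartitions(q_ok)[[1]]
  other <- setdiff(labs, sides)
  q_bad <- parse_newick(sprintf("((%s,%s),(%s,%s));",
                                sides[1], other[1], sides[2], other[2]))
  prof2 <- source_profile(list(prof$trees[[1]], prof$trees[[2]], q_bad))
  expect_equal(sum_fn(prof2, model), 100 * 1 / (total_edges + 1))

  expect_error(sum_fn(prof, restrict_tree(model, model$tip.label[1:6])),
               "absent")
})

test_that("p_ecr contracts then refines within the 2p RF bound", {
  set.seed(31)
  tr <- rand_tree(15)
  expect_identical(splitset(p_ecr(tr, 0)), splitset(tr))
  for (p in c(1, 3, 5)) {
    out <- p_ecr(tr, p, seed = p)
    expect_lte(rf_distance(tr, out), 2 * p)
    expect_length(bipartitions(out), ape::Ntip(tr) - 3L)
    expect_identical(splitset(p_ecr(tr, p, seed = p)), splitset(out))
  }
  expect_error(p_ecr(tr, 99), "exceeds")
})

test_that("spearman_rho matches the rank formula, with ties", {
  expect_equal(spearman_rho(1:5, c(10, 20, 30, 40, 50)), 1)
  expect_equal(spearman_rho(1:5, 5:1), -1)
  # hand computation: d = (-1, 1, -1, 1, 0), 1 - 6*4/120 = 0.8
  expect_equal(spearman_rho(1:5, c(2, 1, 4, 3, 5)), 0.8)
  # brute-force average ranks under ties
  set.seed(6)
  for (i in 1:10) {
    xs <- sample(1:4, 8, replace = TRUE)
    ys <- sample(1:4, 8, replace = TRUE)
    rx <- rank(xs); ry <- rank(ys)
    manual <- sum((rx - mean(rx)) * (ry - mean(ry))) /
      sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
    expect_equal(spearman_rho(xs, ys), manual)
  }
})

test_that("correlation_experiment scores originals plus neighbors", {
  set.seed(71)
  sim <- make_profile(sim_design(n_taxa = 12, n_clade_trees = 3,
                                 scaffold_density = 1.0, error = "none",
                                 seed = 5))
  truth <- restrict_tree(sim$model, sim$profile$taxa)
  sts <- list(truth, rand_tree(ape::Ntip(truth), truth$tip.label))
  ce <- correlation_experiment(sim$profile, truth, sts, n_per_tree = 5,
                               seed = 2, mrl_sweeps = 2)
  expect_equal(nrow(ce$table), 2 * (5 + 1))
  expect_named(ce$rho, c("mp_score", "mrl_score", "sum_fn"))
  expect_true(all(is.finite(ce$rho)))
  # identical inputs correlate perfectly with themselves
  expect_equal(spearman_rho(ce$table$fn, ce$table$fn), 1)
})
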