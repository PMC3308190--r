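test_that("two-leaf closed forms hold to 1e-12", {
  for (t in c(0.005, 0.1, 0.7, 3)) {
    tr <- ape::read.tree(text = sprintf("(a:%f,b:%f);", t / 2, t / 2))
    expect_equal(exp(site_log_likelihood(tr, c(a = 0L, b = 0L))),
                 (1 + exp(-2 * t)) / 4, tolerance = 1e-12)
    expect_equal(exp(site_log_likelihood(tr, c(a = 0L, b = 1L))),
                 (1 - exp(-2 * t)) / 4, tolerance = 1e-12)
  }
  # limits: t -> 0 gives 1/2 (same state) and 0 (different states)
  tr0 <- ape::read.tree(text = "(a:1e-9,b:1e-9);")
  expect_equal(exp(site_log_likelihood(tr0, c(a = 1L, b = 1L))), 0.5,
               tolerance = 1e-6)
  expect_lt(exp(site_log_likelihood(tr0, c(a = 0L, b = 1L))), 1e-8)
  expect_error(site_log_likelihood(ape::read.tree(text = "(a:-1,b:1);"),
                                   c(a = 0L, b = 0L)), "negative")
})

test_that("pruning equals exhaustive summation (with '?', polytomies, rates)", {
  set.seed(55)
  for (i in 1:80) {
    n <- sample(4:6, 1)
    tr <- rand_tree_poly(n, letters[1:n])
    tr$edge.length <- runif(nrow(tr$edge), 0.02, 2)
    col <- sample(c(0L, 1L, NA), n, replace = TRUE, prob = c(.4, .4, .2))
    names(col) <- tr$tip.label
    rate <- runif(1, 0.1, 3)
    expect_equal(site_log_likelihood(tr, col, rate),
                 brute_cfn_loglik(tr, col, rate), tolerance = 1e-10)
  }
})

test_that("gamma mixture: mean-one rates, k=1 equal rates, large-alpha limit", {
  g <- gamma_rates(0.37, 4)
  expect_equal(mean(g$rates), 1, tolerance = 1e-9)
  expect_true(all(diff(g$rates) >= 0))
  expect_identical(gamma_rates(5, 1)$rates, 1)

  set.seed(66)
  tr <- rand_tree(6, letters[1:6])
  tr$edge.length <- runif(nrow(tr$edge), 0.05, 1)
  cm <- encode_baum_ragan(source_profile(list(tr)))
  ll_inf <- tree_log_likelihood(tr, cm, gamma_rates(1e6, 4))
  ll_eq <- tree_log_likelihood(tr, cm, gamma_rates(1, 1))
  expect_equal(ll_inf, ll_eq, tolerance = 1e-6)

  # mixture agrees with averaging the single-rate likelihoods per column
  gg <- gamma_rates(0.6, 4)
  manual <- sum(apply(cm$states, 2, function(col) {
    names(col) <- cm$taxa
    log(mean(sapply(gg$rates, function(r)
      exp(site_log_likelihood(tr, col, r)))))
  }))
  expect_equal(tree_log_likelihood(tr, cm, gg), manual, tolerance = 1e-9)
})

test_that("all-'?' columns contribute zero log-likelihood", {
  tr <- rand_tree(5, letters[1:5])
  tr$edge.length <- rep(0.3, nrow(tr$edge))
  states <- matrix(NA_integer_, 5, 1, dimnames = list(letters[1:5], NULL))
  cm <- mrp_matrix(states)
  expect_equal(tree_log_likelihood(tr, cm), 0)
})

test_that("likelihood is invariant to anchor and leaf order", {
  set.seed(12)
  tr <- rand_tree(7, letters[1:7])
  tr$edge.length <- runif(nrow(tr$edge), 0.05, 1)
  cm <- encode_baum_ragan(source_profile(list(rand_tree(7, letters[1:7]))))
  g <- gamma_rates(0.8, 4)
  base <- tree_log_likelihood(tr, cm, g)
  rr <- ape::root(tr, outgroup = "d", resolve.root = TRUE)
  expect_equal(tree_log_likelihood(rr, cm, g), base, tolerance = 1e-9)
  perm <- ape::rotateConstr(tr, sample(tr$tip.label))
  expect_equal(tree_log_likelihood(perm, cm, g), base, tolerance = 1e-9)
})

test_that("branch-length optimization: closed form, bounds, monotonicity", {
  m <- 200; d <- 30
  states <- matrix(0L, 2, m, dimnames = list(c("a", "b"), NULL))
  states[2, seq_len(d)] <- 1L
  cm <- mrp_matrix(states)
  tr <- ape::read.tree(text = "(a:0.2,b:0.2);")
  fit <- optimize_branch_lengths(tr, cm, gamma_rates(1, 1))
  expect_equal(sum(fit$tree$edge.length), -log(1 - 2 * d / m) / 2,
               tolerance = 1e-5)

  # identical sequences: length collapses to the lower bound
  states0 <- matrix(0L, 2, m, dimnames = list(c("a", "b"), NULL))
  fit0 <- optimize_branch_lengths(tr, mrp_matrix(states0), gamma_rates(1, 1))
  expect_lt(sum(fit0$tree$edge.length), 1e-6)

  set.seed(3)
  tr8 <- rand_tree(8, letters[1:8])
  cm8 <- encode_baum_ragan(source_profile(list(rand_tree(8, letters[1:8]),
                                               rand_tree(8, letters[1:8]))))
  tr8$edge.length <- rep(0.1, nrow(tr8$edge))
  before <- tree_log_likelihood(tr8, cm8, gamma_rates(1, 4))
  fit8 <- optimize_branch_lengths(tr8, cm8, gamma_rates(1, 4))
  expect_gte(fit8$loglik, before)
  expect_equal(fit8$loglik, tree_log_likelihood(fit8$tree, cm8,
                                                gamma_rates(1, 4)),
               tolerance = 1e-8)
})

test_that("alpha optimization improves on alpha = 1 and recovers simulations", {
  set.seed(99)
  tr <- rand_tree(16)
  tr$edge.length <- runif(nrow(tr$edge), 0.1, 0.8)
  chars <- sim_gamma_chars(tr, 2000, alpha = 0.5)
  cm <- mrp_matrix(chars)
  fit <- optimize_branch_lengths(tr, cm, gamma_rates(1, 4), tol = 1e-3,
                                 max_sweeps = 6)
  oa <- optimize_alpha(fit$tree, cm, k = 4)
  ll1 <- tree_log_likelihood(fit$tree, cm, gamma_rates(1, 4))
  expect_gte(oa$loglik, ll1)
  expect_gt(oa$gamma$alpha, 0.25)
  expect_lt(oa$gamma$alpha, 1.0)
  expect_false(oa$at_bound)
})

test_that("ml_search: exhaustive 4-taxon optimum, recovery, determinism", {
  set.seed(17)
  states <- matrix(sample(c(0L, 1L), 4 * 12, replace = TRUE), 4, 12,
                   dimnames = list(letters[1:4], NULL))
  cm <- mrp_matrix(states)
  res <- ml_search(cm, ml_config(seed = 2))
  exhaustive <- vapply(all_binary_trees(letters[1:4]), function(t) {
    mrl_score(t, cm)$loglik
  }, 0)
  expect_equal(res$loglik, max(exhaustive), tolerance = 1e-3)

  tr <- rand_tree(8, letters[1:8])
  cm8 <- encode_baum_ragan(source_profile(list(tr)))
  r8 <- ml_search(cm8, ml_config(seed = 5))
  expect_identical(splitset(r8$tree), splitset(tr))

  r8b <- ml_search(cm8, ml_config(seed = 5))
  expect_identical(splitset(r8b$tree), splitset(r8$tree))
  expect_equal(r8b$loglik, r8$loglik)
})

test_that("mrl_score: local optimality, corruption monotonicity, polytomies", {
  set.seed(27)
  tr <- rand_tree(7, letters[1:7])
  cm <- encode_baum_ragan(source_profile(list(tr, rand_tree(7, letters[1:7]))))
  res <- ml_search(cm, ml_config(seed = 9))
  best <- mrl_score(res$tree, cm)$loglik
  for (nb in superfine:::phylo_nni_neighbors(res$tree)[1:4]) {
    expect_lte(mrl_score(nb, cm)$loglik, best + 1e-3)
  }

  # appending incompatible columns lowers the optimized score
  base <- mrl_score(tr, cm)$loglik
  bad <- matrix(sample(c(0L, 1L), 7 * 6, replace = TRUE), 7, 6,
                dimnames = list(letters[1:7], NULL))
  cm_bad <- mrp_matrix(cbind(cm$states, bad))
  expect_lt(mrl_score(tr, cm_bad)$loglik, base)

  star <- parse_newick(paste0("(", paste(letters[1:7], collapse = ","), ");"))
  sc <- mrl_score(star, cm)
  expect_false(sc$resolved)
  expect_lt(sc$loglik, base)
})
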