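test_that("label_taxa partitions the taxa by the polytomy's components", {
  star <- parse_newick("(a,b,c,d,e,f);")
  v <- polytomies(star)
  expect_length(v, 1L)
  lt <- label_taxa(star, v)
  expect_length(lt$blocks, 6L)
  expect_setequal(names(lt$assign), letters[1:6])
  expect_equal(sort(unname(lt$assign)), 1:6)

  bin <- rand_tree(8)
  expect_length(polytomies(bin), 0L)
  expect_error(label_taxa(bin, ape::Ntip(bin) + 1L), "polytomy")

  # one degree-4 node: blocks are the four hanging subtrees
  tr <- parse_newick("((a,b),(c,d),(e,f),g);")
  v <- polytomies(tr)
  lt <- label_taxa(tr, v[1])
  blocks <- lapply(lt$blocks, paste, collapse = ",")
  expect_setequal(unlist(blocks), c("a,b", "c,d", "e,f", "g"))
})

test_that("reduce_source_tree collapses duplicate labels correctly", {
  labels <- c(a1 = 1L, a2 = 1L, b1 = 2L, b2 = 2L)
  t_cherries <- parse_newick("((a1,a2),(b1,b2));")
  expect_null(reduce_source_tree(t_cherries, labels))  # 2 labels only

  one <- c(x = 1L, y = 1L, z = 1L, w = 1L)
  expect_null(reduce_source_tree(parse_newick("((x,y),(z,w));"), one))

  # five distinct labels, one duplicate pair as a cherry -> 5 leaves
  labs <- c(p = 1L, q = 2L, r = 3L, s = 4L, s2 = 4L, u = 5L)
  tr <- parse_newick("((p,q),(r,((s,s2),u)));")
  red <- reduce_source_tree(tr, labs)
  expect_equal(sort(red$tip.label), as.character(1:5))
  # the collapsed node keeps the cherry's position
  expect_true("4\x1f5" %in% names(bipartitions(red)))

  expect_error(reduce_source_tree(tr, labs[-1]), "cover")
})

test_that("reduction property: at most one leaf per label, at most d leaves", {
  set.seed(33)
  for (i in 1:20) {
    sim <- suppressWarnings(make_profile(sim_design(
      n_taxa = 18, n_clade_trees = 4, scaffold_density = 0.6,
      clade_size_range = c(5, 12), error = "nni", error_rate = 0.2,
      seed = i)))
    if (!sim$connected) next
    scm <- scm_tree(sim$profile)
    for (v in polytomies(scm$tree)) {
      lt <- label_taxa(scm$tree, v)
      d <- length(lt$blocks)
      for (t in sim$profile$trees) {
        red <- reduce_source_tree(t, lt$assign)
        if (is.null(red)) next
        expect_lte(ape::Ntip(red), d)
        expect_false(anyDuplicated(red$tip.label) > 0)
      }
    }
  }
})

test_that("refine_polytomy resolves a quartet context with either base", {
  # polytomy over 4 blocks; one informative reduced source tree
  scmtree <- parse_newick("((a1,a2),(b1,b2),(c1,c2),(d1,d2));")
  v <- polytomies(scmtree)[1]
  lt <- label_taxa(scmtree, v)
  src <- parse_newick("(((a1,a2),(b1,b2)),(c1,(d1,d2)));")
  lt$profile <- source_profile(list(src))
  r_mp <- refine_polytomy(lt, "mrp", seed = 1)
  r_ml <- refine_polytomy(lt, "mrl", seed = 1)
  expect_identical(splitset(r_mp), splitset(r_ml))
  # the reduced source is the quartet ab|cd on the labels
  lab <- function(x) lt$assign[[x]]
  expect_true(paste(sort(as.character(c(lab("c1"), lab("d1")))),
                    collapse = "\x1f") %in% names(bipartitions(r_mp)) ||
              paste(sort(as.character(c(lab("a1"), lab("b1")))),
                    collapse = "\x1f") %in% names(bipartitions(r_mp)))

  lt$profile <- source_profile(list(parse_newick("((z1,z2),(z3,z4));")))
  expect_error(refine_polytomy(lt, "mrp"), "cover")
})

test_that("superfine refines the SCM tree and keeps all its bipartitions", {
  set.seed(44)
  checked <- 0
  for (s in 1:8) {
    sim <- suppressWarnings(make_profile(sim_design(
      n_taxa = 20, n_clade_trees = 5, scaffold_density = 0.5,
      clade_size_range = c(5, 12), error = "nni", error_rate = 0.15,
      seed = s)))
    if (!sim$connected) next
    for (base in c("mrp", "mrl")) {
      sf <- superfine(sim$profile, base, seed = s)
      expect_true(all(splitset(sf$scm$tree) %in% splitset(sf$tree)))
      expect_setequal(sf$tree$tip.label, sim$profile$taxa)
    }
    checked <- checked + 1
    if (checked >= 3) break
  }
  expect_gte(checked, 1)
})

test_that("binary SCM passes through superfine unchanged", {
  t1 <- parse_newick("(((a,b),(c,d)),((e,f),(g,h)));")
  res <- superfine(source_profile(list(t1, t1)), "mrp", seed = 1)
  expect_identical(splitset(res$tree), splitset(t1))
  expect_equal(res$n_polytomies, 0L)
})

test_that("polytomy processing order does not change the output", {
  set.seed(58)
  done <- 0
  for (s in 1:10) {
    sim <- suppressWarnings(make_profile(sim_design(
      n_taxa = 20, n_clade_trees = 5, scaffold_density = 0.4,
      clade_size_range = c(5, 12), error = "nni", error_rate = 0.2,
      seed = s)))
    if (!sim$connected) next
    probe <- superfine(sim$profile, "mrp", seed = s)
    if (probe$n_polytomies < 2) next
    np <- probe$n_polytomies
    shuffled <- superfine(sim$profile, "mrp", seed = s,
                          polytomy_order = sample(np))
    expect_identical(splitset(shuffled$tree), splitset(probe$tree))
    done <- done + 1
    if (done >= 3) break
  }
  expect_gte(done, 1)
})

test_that("compatible profiles are recovered exactly end to end", {
  set.seed(61)
  sim <- make_profile(sim_design(n_taxa = 14, n_clade_trees = 4,
                                 scaffold_density = 1.0, error = "none",
                                 seed = 3))
  truth <- restrict_tree(sim$model, sim$profile$taxa)
  for (base in c("mrp", "mrl")) {
    sf <- superfine(sim$profile, base, seed = 2)
    expect_equal(fn_rate(truth, sf$tree), 0)
    expect_equal(fp_rate(truth, sf$tree), 0)
  }
})
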