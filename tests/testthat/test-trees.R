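test_that("parse_newick handles the basic dialect", {
  t1 <- parse_newick("((a,b),(c,d));")
  expect_s3_class(t1, "phylo")
  expect_equal(ape::Ntip(t1), 4L)
  expect_length(bipartitions(t1), 1L)

  star <- parse_newick("(a,b,c,d,e);")
  expect_length(bipartitions(star), 0L)

  tq <- parse_newick("(('He llo',b),(c,d));")
  expect_true("He llo" %in% tq$tip.label)

  expect_error(parse_newick("((a,b),(c,d);"), "unclosed")
  expect_error(parse_newick("((a,b)),(c,d));"), "offset")
  expect_error(parse_newick("((a,b),(c,d))"), "terminator")
  expect_error(parse_newick("((a,b),(a,d));"), "duplicate")
})

test_that("branch lengths survive a write/parse round trip", {
  t1 <- parse_newick("((a:1,b:2):0.5,c:1,d:1);")
  t2 <- parse_newick(write_newick(t1))
  expect_equal(sort(t2$edge.length), sort(t1$edge.length))
  expect_setequal(splitset(t1), splitset(t2))
})

test_that("parse/write round trip is bipartition-identical (200 random trees)", {
  set.seed(101)
  for (i in 1:200) {
    n <- sample(4:40, 1)
    tr <- rand_tree_poly(n)
    back <- parse_newick(write_newick(tr))
    expect_identical(splitset(back), splitset(tr))
  }
})

test_that("bipartitions: edge counts, canonical form, universe checks", {
  set.seed(7)
  for (i in 1:20) {
    n <- sample(4:25, 1)
    tr <- rand_tree(n)
    expect_length(bipartitions(tr), n - 3L)
    tp <- rand_tree_poly(n)
    expect_lte(length(bipartitions(tp)), n - 3L)
  }
  tr <- parse_newick("((a,b),(c,d),e);")
  sides <- lapply(bipartitions(tr), paste, collapse = ",")
  expect_setequal(unlist(sides), c("c,d,e", "c,d"))  # ab|cde and cd|abe
  expect_error(bipartitions(tr, universe = c("a", "b", "c")), "universe")
  # polarity independence: rotating the newick does not change the keys
  expect_identical(splitset(parse_newick("(e,(c,d),(b,a));")), splitset(tr))
})

test_that("restrict_tree gives the induced subtree", {
  tr <- parse_newick("((a,b),(c,d));")
  r <- restrict_tree(tr, c("a", "b", "c"))
  expect_length(bipartitions(r), 0L)
  expect_setequal(r$tip.label, c("a", "b", "c"))

  expect_identical(splitset(restrict_tree(tr, tr$tip.label)), splitset(tr))

  r2 <- restrict_tree(parse_newick("(((a,b),c),(d,e));"), c("a", "b", "d", "e"))
  expect_setequal(unlist(lapply(bipartitions(r2), paste, collapse = ",")),
                  "d,e")  # ab|de retained

  expect_error(restrict_tree(tr, c("zz")), "empty")
})

test_that("restrict commutes with bipartition restriction (random)", {
  set.seed(11)
  for (i in 1:30) {
    n <- sample(5:25, 1)
    tr <- rand_tree_poly(n)
    s <- sample(tr$tip.label, sample(3:n, 1))
    su <- sort(s, method = "radix")
    expected <- unique(unlist(Filter(Negate(is.null), lapply(
      bipartitions(tr), function(side) {
        a <- intersect(side, s)
        if (length(a) >= 2 && length(setdiff(s, a)) >= 2) {
          paste(sort(superfine:::canonical_side(a, su), method = "radix"),
                collapse = "\x1f")
        } else NULL
      }))))
    got <- names(bipartitions(restrict_tree(tr, s)))
    expect_setequal(if (is.null(got)) character(0) else got,
                    if (is.null(expected)) character(0) else expected)
  }
})

test_that("strict_consensus intersects bipartition sets", {
  t1 <- parse_newick("((a,b),c,(d,e));")
  expect_identical(splitset(strict_consensus(list(t1, t1))), splitset(t1))

  t3 <- parse_newick("((a,d),(b,e),c);")
  expect_length(bipartitions(strict_consensus(list(t1, t3))), 0L)

  # {ab|cde, abc|de} vs {ab|cde, abd|ce} -> only ab|cde
  u1 <- parse_newick("(((a,b),c),(d,e));")
  u2 <- parse_newick("(((a,b),d),(c,e));")
  sc <- strict_consensus(list(u1, u2))
  expect_setequal(unlist(lapply(bipartitions(sc), paste, collapse = ",")),
                  "c,d,e")
  expect_error(strict_consensus(list(t1, parse_newick("((a,b),(c,f));"))),
               "identical leaf sets")
  # output splits are pairwise compatible by construction (a tree exists)
  expect_s3_class(sc, "phylo")
})

test_that("random_refinement resolves to binary and refines the input", {
  set.seed(5)
  bin <- rand_tree(8)
  expect_identical(splitset(random_refinement(bin, seed = 1)), splitset(bin))

  star4 <- parse_newick("(a,b,c,d);")
  r <- random_refinement(star4, seed = 2)
  expect_length(bipartitions(r), 1L)

  big_star <- parse_newick(paste0("(", paste(paste0("x", 1:12),
                                             collapse = ","), ");"))
  r1 <- random_refinement(big_star, seed = 9)
  r2 <- random_refinement(big_star, seed = 9)
  expect_identical(splitset(r1), splitset(r2))
  expect_length(bipartitions(r1), 12 - 3)

  for (i in 1:15) {
    tr <- rand_tree_poly(sample(5:20, 1))
    rr <- random_refinement(tr, seed = i)
    expect_true(all(splitset(tr) %in% splitset(rr)))
    expect_length(bipartitions(rr), ape::Ntip(tr) - 3L)
  }
})

test_that("profile loading validates and aggregates taxa", {
  t1 <- parse_newick("((a,b),(c,d));")
  t2 <- parse_newick("((c,d),(e,f));")
  prof <- source_profile(list(t1, t2))
  expect_setequal(prof$taxa, letters[1:6])
  expect_error(source_profile(list(parse_newick("(a,b,c);"))), "4 leaves")

  f <- tempfile(fileext = ".nwk")
  write_profile(prof, f)
  back <- read_profile(f)
  expect_length(back$trees, 2L)
  expect_identical(splitset(back$trees[[1]]), splitset(t1))
})
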