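test_that("fitch_score handles trivial reductions", {
  same <- c(A = "ACGTACGT", B = "ACGTACGT", C = "ACGTACGT", D = "ACGTACGT")
  t1 <- ape::read.tree(text = "((A,B),(C,D));")
  expect_equal(fitch_score(t1, same), 0)

  # two taxa: Hamming distance over doubly-observed columns
  two <- c(X = "AAGT-C", Y = "ATGTAC")
  sr <- search_mp(two)
  expect_equal(sr$length, 1L)

  # gaps and N contribute no cost
  miss <- c(A = "A-N", B = "AAN", C = "A-T", D = "AAT")
  expect_equal(fitch_score(t1, miss), 0)

  expect_error(
    fitch_score(t1, c(A = "AA", B = "AA", C = "AA", E = "AA")),
    "do not match"
  )
})

test_that("the four-taxon hand example scores 3/3/4 across topologies", {
  aln <- c(A = "AAA", B = "AAT", C = "GAA", D = "GAT")
  expect_equal(fitch_score(ape::read.tree(text = "((A,B),(C,D));"), aln), 3)
  expect_equal(fitch_score(ape::read.tree(text = "((A,C),(B,D));"), aln), 3)
  expect_equal(fitch_score(ape::read.tree(text = "((A,D),(B,C));"), aln), 4)

  sr <- search_mp(aln, mode = "exhaustive")
  expect_equal(sr$length, 3L)
  expect_equal(sr$n_trees, 2L)
  splits <- vapply(sr$trees, function(t) {
    s <- same_topology(t, ape::read.tree(text = "((A,B),(C,D));"))
    if (s) "AB|CD" else if (same_topology(t, ape::read.tree(text = "((A,C),(B,D));"))) "AC|BD" else "other"
  }, "")
  expect_setequal(splits, c("AB|CD", "AC|BD"))
})

test_that("fitch_score equals unit-cost Sankoff on random alignments", {
  set.seed(23)
  for (i in 1:25) {
    aln <- random_alignment(5, 30)
    sr <- search_mp(aln, mode = "exhaustive")
    t <- sr$trees[[sample(sr$n_trees, 1)]]
    expect_equal(fitch_score(t, aln), oracle_sankoff(t, aln))
    # and on a deliberately suboptimal caterpillar
    cat5 <- ape::read.tree(text = "((((A,B),C),D),E);")
    expect_equal(fitch_score(cat5, aln), oracle_sankoff(cat5, aln))
  }
})

test_that("branch-and-bound equals exhaustive search and phangorn's optimum", {
  set.seed(59)
  for (n in 4:7) {
    for (i in 1:3) {
      aln <- random_alignment(n, 25, miss_prob = 0.08)
      ex <- search_mp(aln, mode = "exhaustive")
      bb <- search_mp(aln, mode = "branch_and_bound")
      expect_identical(ex$newick, bb$newick)
      expect_identical(ex$length, bb$length)
      expect_gte(ex$length, parsimony_lower_bound(aln))

      oracle <- oracle_optimal_set(aln)
      expect_equal(ex$length, oracle$length)
      expect_equal(ex$n_trees, length(oracle$trees))
    }
  }
  expect_error(search_mp(random_alignment(8, 10), mode = "exhaustive"), "at most 7")
})

test_that("taxon input order never changes the optimum", {
  set.seed(71)
  aln <- random_alignment(6, 40)
  sr1 <- search_mp(aln)
  sr2 <- search_mp(aln[sample(length(aln))])
  expect_identical(sr1$newick, sr2$newick)
  expect_identical(sr1$length, sr2$length)
})

test_that("newick output is canonical, rooted on the outgroup, and round-trips", {
  aln <- c(A = "AAA", B = "AAT", C = "GAA", D = "GAT")
  sr <- search_mp(aln, mode = "exhaustive")
  ab_cd <- sr$trees[[which(vapply(
    sr$trees, same_topology, logical(1),
    b = ape::read.tree(text = "((A,B),(C,D));")
  ))]]
  nwk <- to_newick(ab_cd, outgroup = "A", alignment = aln)
  reread <- ape::read.tree(text = nwk)
  expect_true(same_topology(reread, ape::read.tree(text = "((A,B),(C,D));")))
  # branch change counts sum to the parsimony length
  expect_equal(sum(reread$edge.length), 3)
  # byte-stable serialisation
  expect_identical(nwk, to_newick(ab_cd, outgroup = "A", alignment = aln))
  expect_error(to_newick(ab_cd, outgroup = "Z"), "unknown outgroup")

  # two-taxon convention: all changes attach to the non-outgroup side
  two <- search_mp(c(X = "AAAT", Y = "TTGT")) # three mismatched columns
  expect_identical(
    to_newick(two$trees[[1]], outgroup = "Y", alignment = c(X = "AAAT", Y = "TTGT")),
    "(X:3,Y:0);"
  )
})

test_that("per-branch changes from the deterministic assignment sum correctly", {
  set.seed(83)
  for (i in 1:5) {
    aln <- random_alignment(6, 30)
    sr <- search_mp(aln)
    t <- sr$trees[[1]]
    fc <- fitch_changes(t, aln, outgroup = "A")
    expect_equal(sum(fc$edge.length), sr$length)
    expect_equal(attr(fc, "parsimony_length"), sr$length)
  }
})

test_that("trees simulated at low divergence are recovered", {
  gen <- "(((A:0.05,B:0.05):0.05,(C:0.05,D:0.05):0.05):0.05,(E:0.05,F:0.05):0.05);"
  gen_tree <- ape::read.tree(text = gen)
  set.seed(90)
  root <- random_seq(600)
  wins <- 0
  for (s in 1:5) {
    leaves <- simulate_orthologs(root, gen, seed = 1000 + s)
    sr <- search_mp(leaves)
    if (sr$n_trees == 1 && same_topology(sr$trees[[1]], gen_tree)) wins <- wins + 1
  }
  expect_gte(wins, 4)
})
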