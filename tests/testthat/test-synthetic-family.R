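test_that("zero-mutation, untruncated copies reproduce the consensus exactly", {
  cfg <- simulation_config(
    seed = 7, n_loci = 5, consensus_length = 120,
    divergence = 0, indel_rate = 0, truncation_model = "none"
  )
  fam <- simulate_family(cfg)
  expect_length(fam$loci, 5)
  expect_true(all(fam$loci == fam$consensus$sequence))
  expect_true(all(fam$meta$trunc_offset == 0L))
})

test_that("identical seed and config give byte-identical outputs", {
  mot <- default_motifs()
  cfg <- simulation_config(
    seed = 42, n_loci = 20, divergence = 0.1, indel_rate = 0.01,
    embeddings = list(embedding_spec("Brn-2", 300, "-", locus_ids = 1:5)),
    random_orientation = TRUE
  )
  f1 <- simulate_family(cfg, mot)
  f2 <- simulate_family(cfg, mot)
  expect_identical(f1, f2)

  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_family(f1, d1)
  write_family(f2, d2)
  for (f in list.files(d1)) {
    expect_identical(
      readLines(file.path(d1, f)), readLines(file.path(d2, f)),
      label = paste("file", f)
    )
  }
})

test_that("pooled mismatch fraction matches the divergence rate", {
  cfg <- simulation_config(
    seed = 9, n_loci = 124, consensus_length = 570,
    divergence = 0.10, indel_rate = 0, truncation_model = "none"
  )
  fam <- simulate_family(cfg)
  cons <- strsplit(fam$consensus$sequence, "")[[1]]
  mism <- vapply(fam$loci, function(s) {
    sum(strsplit(s, "")[[1]] != cons)
  }, numeric(1))
  frac <- sum(mism) / (124 * 570)
  expect_gt(frac, 0.09)
  expect_lt(frac, 0.11)
})

test_that("mutate_sequence honours trivial and boundary contracts", {
  out <- mutate_sequence(strrep("ACGT", 10), divergence = 0)
  expect_identical(out$sequence, strrep("ACGT", 10))
  expect_identical(nrow(out$edits), 0L)
  expect_identical(out$map$locus, out$map$ref)

  expect_error(mutate_sequence("ACGT", divergence = 1), "\\[0, 1\\)")
  expect_error(mutate_sequence("", divergence = 0.1), "non-empty")
  expect_error(mutate_sequence("ACGT", 0.5, indel_rate = 0.6), "< 1")
})

test_that("substitution counts fall in the central 99% binomial range", {
  set.seed(101)
  seq10k <- random_seq(10000)
  out <- mutate_sequence(seq10k, divergence = 0.05)
  mism <- sum(strsplit(out$sequence, "")[[1]] != strsplit(seq10k, "")[[1]])
  bounds <- qbinom(c(0.005, 0.995), 10000, 0.05)
  expect_gte(mism, bounds[1])
  expect_lte(mism, bounds[2])
})

test_that("edit lists reconstruct the mutated sequence and the column map", {
  set.seed(5)
  for (rep in 1:10) {
    tmpl <- random_seq(300)
    out <- mutate_sequence(tmpl, divergence = 0.1, indel_rate = 0.03,
                           indel_mean_len = 2)
    expect_identical(apply_edits(tmpl, out$edits), out$sequence)

    # map consistency: non-substituted aligned columns carry identical bases
    tc <- strsplit(tmpl, "")[[1]]
    lc <- strsplit(out$sequence, "")[[1]]
    both <- !is.na(out$map$locus) & !is.na(out$map$ref)
    subs <- out$edits$ref_pos[out$edits$op == "sub"]
    keep <- both & !(out$map$ref %in% subs)
    expect_true(all(lc[out$map$locus[keep] + 1] == tc[out$map$ref[keep] + 1]))
    # both sides strictly increasing over aligned columns
    expect_true(all(diff(out$map$locus[!is.na(out$map$locus)]) > 0))
    expect_true(all(diff(out$map$ref[!is.na(out$map$ref)]) > 0))
  }
})

test_that("protected embedded instances survive mutation literally", {
  mot <- default_motifs()
  cfg <- simulation_config(
    seed = 13, n_loci = 60, divergence = 0.15, indel_rate = 0.02,
    embeddings = list(
      embedding_spec("Oct-1", 350, "+", locus_ids = 1:30),
      embedding_spec("Nkx6.1", 420, "-", locus_ids = 11:40)
    ),
    random_orientation = TRUE
  )
  fam <- simulate_family(cfg, mot)
  tr <- fam$truth[fam$truth$survives_truncation, ]
  expect_gt(nrow(tr), 0)
  for (i in seq_len(nrow(tr))) {
    got <- substr(
      fam$loci[[tr$locus_id[i]]], tr$locus_start[i] + 1, tr$locus_end[i]
    )
    want <- if (tr$locus_strand[i] == "+") {
      tr$embedded_sequence[i]
    } else {
      revcomp(tr$embedded_sequence[i])
    }
    expect_identical(got, want)
  }
})

test_that("truncation models set offsets and survival flags correctly", {
  mot <- default_motifs()
  # fixed offset 256 emulates copies retaining only the 3' half [256, 570)
  cfg <- simulation_config(
    seed = 3, n_loci = 10, divergence = 0, indel_rate = 0,
    truncation_model = "fixed_offset",
    embeddings = list(
      embedding_spec("S8", 100, "+", locus_ids = 1:10), # 5' of the cut
      embedding_spec("Oct-1", 400, "+", locus_ids = 1:10)
    )
  )
  expect_warning(fam <- simulate_family(cfg, mot), "truncated away")
  expect_true(all(fam$meta$trunc_offset == 256L))
  expect_true(all(nchar(fam$loci) == 570 - 256))
  tr <- fam$truth
  expect_true(all(!tr$survives_truncation[tr$motif_id == "S8"]))
  expect_true(all(tr$survives_truncation[tr$motif_id == "Oct-1"]))

  cfg2 <- simulation_config(
    seed = 3, n_loci = 200, truncation_model = "uniform_5prime",
    truncation_params = list(max_trunc = 100)
  )
  fam2 <- simulate_family(cfg2)
  expect_true(all(fam2$meta$trunc_offset >= 0 & fam2$meta$trunc_offset <= 100))
  expect_gt(length(unique(fam2$meta$trunc_offset)), 20)
})

test_that("ortholog simulation respects branch probabilities and seeds", {
  root <- strrep("ACGT", 150)
  leaves0 <- simulate_orthologs(root, "((A:0,B:0):0,(C:0,D:0):0);", seed = 2)
  expect_true(all(leaves0 == root))

  two <- simulate_orthologs(root, "(X:0,Y:0.2);", seed = 2)
  expect_identical(unname(two[["X"]]), root)
  expect_false(identical(two[["Y"]], root))

  expect_identical(
    simulate_orthologs(root, "((A:0.05,B:0.05):0.05,(C:0.05,D:0.05):0.05);", seed = 4),
    simulate_orthologs(root, "((A:0.05,B:0.05):0.05,(C:0.05,D:0.05):0.05);", seed = 4)
  )
  expect_error(simulate_orthologs(root, "((A:0.05,B", seed = 1), "Newick")
  expect_error(simulate_orthologs(root, "(A:0.5,B:1.5);", seed = 1), "\\[0, 1\\)")
})

test_that("leaf-root differences track the depth-compounded substitution rate", {
  # per-branch pass: P(same) evolves as s' = s (1 - p) + (1 - s) p / 3
  compound <- function(depth, p) {
    s <- 1
    for (i in seq_len(depth)) s <- s * (1 - p) + (1 - s) * p / 3
    1 - s
  }
  root <- {
    set.seed(77)
    random_seq(600)
  }
  nwk <- "(((A:0.05,B:0.05):0.05,(C:0.05,D:0.05):0.05):0.05,(E:0.05,F:0.05):0.05);"
  leaves <- simulate_orthologs(root, nwk, seed = 21)
  depth <- c(A = 3, B = 3, C = 3, D = 3, E = 2, F = 2)
  rc <- strsplit(root, "")[[1]]
  for (l in names(leaves)) {
    d <- sum(strsplit(leaves[[l]], "")[[1]] != rc)
    m <- compound(depth[[l]], 0.05)
    bounds <- qbinom(c(0.005, 0.995), 600, m)
    expect_gte(d, bounds[1])
    expect_lte(d, bounds[2])
  }
})
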