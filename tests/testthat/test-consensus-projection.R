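cons <- local({
  set.seed(90)
  sine_consensus(random_seq(570), domains = default_domain_layout())
})

identity_maps <- function(seqs) align_family(seqs, cons)

mk_hit <- function(locus_id, start, end, strand = "+", motif = "m1", score = 10) {
  data.frame(
    locus_id = locus_id, motif_id = motif, start = start, end = end,
    strand = strand, score = score, matched_sequence = "",
    stringsAsFactors = FALSE
  )
}

mk_proj <- function(locus_id, start, end, strand = "+", motif = "m1", score = 10) {
  data.frame(
    locus_id = locus_id, motif_id = motif,
    consensus_start = start, consensus_end = end, consensus_strand = strand,
    locus_start = start, locus_end = end, locus_strand = strand,
    score = score, aligned_column_fraction = 1, stringsAsFactors = FALSE
  )
}

test_that("projection through identity and offset maps is exact", {
  loci <- c(full = cons$sequence, half = substr(cons$sequence, 257, 570))
  maps <- identity_maps(loci)

  pr <- project_hits(mk_hit("full", 10, 18), maps)
  expect_equal(nrow(pr$projected), 1)
  expect_equal(pr$projected$consensus_start, 10L)
  expect_equal(pr$projected$consensus_end, 18L)
  expect_equal(pr$projected$consensus_strand, "+")

  # 3'-half truncated copy: locus [10,18) sits at consensus [266,274)
  pr2 <- project_hits(mk_hit("half", 10, 18, strand = "-"), maps)
  expect_equal(pr2$projected$consensus_start, 266L)
  expect_equal(pr2$projected$consensus_end, 274L)
  expect_equal(pr2$projected$consensus_strand, "-")
})

test_that("strand composition flips for reverse-stored loci", {
  loci <- c(rc = revcomp(cons$sequence))
  maps <- identity_maps(loci)
  expect_equal(maps$rc$orientation_used, "-")
  # a minus-strand hit on a minus-oriented copy is a plus site on the
  # consensus; stored interval [0,8) is consensus [562,570)
  pr <- project_hits(mk_hit("rc", 0, 8, strand = "-"), maps)
  expect_equal(pr$projected$consensus_strand, "+")
  expect_equal(pr$projected$consensus_start, 562L)
  pr2 <- project_hits(mk_hit("rc", 0, 8, strand = "+"), maps)
  expect_equal(pr2$projected$consensus_strand, "-")
})

test_that("poorly aligned hits are rejected with a reason and counts reconcile", {
  # locus with a 12-nt foreign insertion: hits covering it lose columns
  loci <- c(ins = paste0(
    substr(cons$sequence, 1, 40), "GGGGGGGGGGGG", substr(cons$sequence, 41, 80)
  ))
  maps <- align_family(loci, sine_consensus(gsub("G", "A", cons$sequence)))
  hits <- rbind(
    mk_hit("ins", 0, 8), # cleanly aligned
    mk_hit("ins", 42, 50), # mostly inside the insertion
    mk_hit("ins", 36, 44) # straddles: 4 of 8 columns aligned
  )
  pr <- project_hits(hits, maps, min_aligned_frac = 0.8)
  expect_equal(nrow(pr$projected) + nrow(pr$rejected), nrow(hits))
  expect_true(all(pr$rejected$reason %in%
    c("insufficient_alignment", "outside_alignment")))
  expect_gte(nrow(pr$rejected), 1)
  expect_true(all(pr$projected$aligned_column_fraction >= 0.8))
})

test_that("histograms count loci per position with per-locus deduplication", {
  h0 <- aggregate_histogram(mk_proj("x", 0, 8)[0, ], 570)
  expect_equal(nrow(h0$counts), 0)
  expect_equal(h0$mass, 0)

  h1 <- aggregate_histogram(mk_proj("l1", 100, 108), 570)
  expect_equal(nrow(h1$counts), 8)
  expect_true(all(h1$counts$n_loci == 1))
  expect_equal(h1$counts$position, 100:107)

  # two overlapping hits of one locus: positions 104..107 still count 1
  two <- rbind(mk_proj("l1", 100, 108), mk_proj("l1", 104, 112))
  h2 <- aggregate_histogram(two, 570)
  expect_true(all(h2$counts$n_loci == 1))
  expect_equal(h2$counts$position, 100:111)
  # mass equals the per-locus union length (12), not the summed lengths (16)
  expect_equal(h2$mass, 12)

  # distinct loci stack
  h3 <- aggregate_histogram(
    rbind(mk_proj("l1", 100, 108), mk_proj("l2", 104, 112)), 570
  )
  expect_equal(h3$counts$n_loci[h3$counts$position %in% 104:107], rep(2, 4))

  expect_error(aggregate_histogram(mk_proj("l1", 565, 575), 570), "beyond")
})

test_that("single-linkage clustering groups nearby starts and counts loci", {
  three <- rbind(
    mk_proj("l1", 100, 108), mk_proj("l2", 102, 110), mk_proj("l3", 104, 112)
  )
  cl <- cluster_shared_sites(three, tolerance = 5)
  expect_equal(nrow(cl), 1)
  expect_equal(cl$n_loci, 3)
  expect_equal(cl$loci, "l1,l2,l3")

  apart <- rbind(mk_proj("l1", 100, 108), mk_proj("l2", 120, 128))
  cl2 <- cluster_shared_sites(apart, tolerance = 5)
  expect_equal(nrow(cl2), 2)
  expect_equal(cl2$n_loci, c(1, 1))

  # chained linkage: 100-104-108 joins even though 100 and 108 are 8 apart
  chain <- rbind(
    mk_proj("l1", 100, 108), mk_proj("l2", 104, 112), mk_proj("l3", 108, 116)
  )
  expect_equal(nrow(cluster_shared_sites(chain, tolerance = 5)), 1)

  # strands and motifs never mix; a locus counts once per cluster
  mixed <- rbind(
    mk_proj("l1", 100, 108), mk_proj("l1", 101, 109),
    mk_proj("l2", 100, 108, strand = "-"),
    mk_proj("l3", 100, 108, motif = "m2")
  )
  cl3 <- cluster_shared_sites(mixed, tolerance = 5)
  expect_equal(nrow(cl3), 3)
  expect_equal(cl3$n_loci[cl3$motif_id == "m1" & cl3$consensus_strand == "+"], 1)
})

test_that("clusters partition the projected hits per motif and strand", {
  set.seed(8)
  pr <- do.call(rbind, lapply(1:60, function(i) {
    mk_proj(
      sprintf("l%02d", sample(20, 1)), s <- sample(550, 1), s + 8,
      strand = sample(c("+", "-"), 1),
      motif = sample(c("m1", "m2"), 1)
    )
  }))
  cl <- cluster_shared_sites(pr, tolerance = 5)
  expect_equal(sum(cl$n_hits), nrow(pr))
  # sorted by size then position
  expect_true(all(diff(cl$n_loci) <= 0))
})

test_that("embedded shared sites are recovered as the top cluster", {
  mot <- default_motifs()
  cfg <- simulation_config(
    seed = 30, n_loci = 124, divergence = 0.10, indel_rate = 0.005,
    embeddings = list(embedding_spec("Oct-1", 350, "+", locus_ids = 1:20))
  )
  fam <- simulate_family(cfg, mot)
  pwms <- lapply(mot, build_pwm, threshold_fraction = 0.95)
  hits <- scan_loci(pwms, fam$loci)
  maps <- align_family(fam$loci, fam$consensus)
  pr <- project_hits(hits, maps)
  cl <- cluster_shared_sites(pr$projected)
  top <- cl[cl$motif_id == "Oct-1", ][1, ]
  members <- strsplit(top$loci, ",")[[1]]
  embedded <- fam$truth$locus_id
  expect_gte(length(intersect(members, embedded)), 18)
  expect_lte(length(setdiff(members, embedded)), 2)
  expect_true(top$rep_start >= 345 && top$rep_start <= 355)
})

test_that("domain enrichment behaves at the analytic extremes", {
  whole <- sine_consensus(
    cons$sequence,
    domains = data.frame(label = "all", start = 0, end = 570)
  )
  pr <- rbind(mk_proj("l1", 10, 18), mk_proj("l2", 400, 408))
  en <- domain_enrichment(pr, whole, n_permutations = 200, seed = 1)
  expect_equal(en$observed, 2L)
  expect_equal(en$p_value, 1)

  # zero hits: observed 0 everywhere, p = 1
  en0 <- domain_enrichment(pr[0, ], cons, n_permutations = 200, seed = 1)
  expect_true(all(en0$observed == 0))
  expect_true(all(en0$p_value == 1))

  # 30 hits packed into the 150-nt Deu domain of a 570-nt consensus
  deu <- cons$domains[cons$domains$label == "Deu", ]
  starts <- seq(deu$start + 2, deu$end - 12, length.out = 30)
  packed <- do.call(rbind, lapply(seq_along(starts), function(i) {
    mk_proj(sprintf("l%02d", i), as.integer(starts[i]), as.integer(starts[i]) + 8)
  }))
  enD <- domain_enrichment(packed, cons, n_permutations = 10000, seed = 1)
  expect_lte(enD$p_value[enD$domain == "Deu"], 0.001)
  expect_equal(enD$observed[enD$domain == "Deu"], 30L)
  # observed counts over domains sum to the assignable hits
  expect_equal(sum(enD$observed), 30L)
  # expectation under uniform placement is near n * 150/570
  expect_equal(enD$expected[enD$domain == "Deu"], 30 * 150 / 570, tolerance = 0.05)

  expect_error(
    domain_enrichment(pr, sine_consensus(cons$sequence), 200, 1),
    "domain"
  )
  expect_error(domain_enrichment(pr, cons, n_permutations = 50), ">= 100")
})

test_that("reverse-complementing every locus leaves consensus-space results invariant", {
  mot <- default_motifs()
  cfg <- simulation_config(
    seed = 44, n_loci = 30, divergence = 0.08, indel_rate = 0.005,
    embeddings = list(embedding_spec("S8", 300, "-", locus_ids = 1:10))
  )
  fam <- simulate_family(cfg, mot)
  pwms <- lapply(mot, build_pwm, threshold_fraction = 0.9)

  run_once <- function(loci) {
    maps <- align_family(loci, fam$consensus)
    pr <- project_hits(scan_loci(pwms, loci), maps)
    list(
      hist = aggregate_histogram(pr$projected, fam$consensus$length),
      clusters = cluster_shared_sites(pr$projected)
    )
  }
  fwd <- run_once(fam$loci)
  rev <- run_once(setNames(revcomp(fam$loci), names(fam$loci)))
  expect_identical(fwd$hist$counts, rev$hist$counts)
  expect_identical(fwd$clusters$loci, rev$clusters$loci)
  expect_identical(fwd$clusters$rep_start, rev$clusters$rep_start)
})
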