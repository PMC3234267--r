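# Independent oracles used to validate the implementation. These deliberately
# re-derive results from first principles (explicit per-window rescoring, a
# fresh dynamic program, Sankoff instead of Fitch) and share no code with the
# package internals they check.

BASES <- c("A", "C", "G", "T")

random_seq <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")

toy_transfac <- function() {
  c(
    "ID  t1", "P0  A  C  G  T",
    "01  8  0  0  0  A", "02  8  0  0  0  A",
    "03  0  0  8  0  G", "04  0  0  0  8  T",
    "//",
    "ID  t2", "P0  A  C  G  T",
    "01  0  9  1  0  C", "02  6  2  1  1  A",
    "03  1  1  1  7  T", "04  0  0 10  0  G",
    "05  5  5  0  0  M",
    "//",
    "ID  t3", "P0  A  C  G  T",
    "01  2  2  2  2  N", "02  0  0  0  9  T",
    "03  9  0  0  0  A", "04  0  9  0  0  C",
    "05  0  0  9  0  G", "06  9  0  0  0  A",
    "//"
  )
}

# brute-force PWM scan: independently rescore every window of both strands
oracle_scan <- function(pwm, seq, both_strands = TRUE) {
  score_window <- function(w) {
    total <- 0
    for (j in seq_len(nchar(w))) {
      b <- substr(w, j, j)
      if (!b %in% BASES) {
        return(-Inf)
      }
      total <- total + pwm$log_odds[j, b]
    }
    total
  }
  rc_of <- function(s) {
    comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
    paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
  }
  n <- nchar(seq)
  L <- pwm$length
  rows <- list()
  if (n >= L) {
    for (i in 1:(n - L + 1)) {
      w <- substr(seq, i, i + L - 1)
      sc <- score_window(w)
      if (sc >= pwm$threshold) {
        rows[[length(rows) + 1]] <- data.frame(
          start = i - 1L, end = i - 1L + L, strand = "+", score = sc,
          stringsAsFactors = FALSE
        )
      }
      if (both_strands) {
        wrc <- rc_of(w)
        src <- score_window(wrc)
        if (src >= pwm$threshold) {
          rows[[length(rows) + 1]] <- data.frame(
            start = i - 1L, end = i - 1L + L, strand = "-", score = src,
            stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else data.frame(
    start = integer(0), end = integer(0), strand = character(0),
    score = numeric(0)
  )
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# independent affine semi-global DP (full locus vs consensus window; free
# consensus end gaps; gap of length k costs open + k * ext); returns the
# optimal score
oracle_semiglobal_score <- function(locus, cons, match = 1, mismatch = -1,
                                    open = -4, ext = -1) {
  x <- strsplit(locus, "")[[1]]
  y <- strsplit(cons, "")[[1]]
  n <- length(x)
  m <- length(y)
  s <- function(a, b) if (a == b && a %in% BASES) match else mismatch
  NEG <- -1e18
  Mm <- matrix(NEG, n + 1, m + 1)
  Gx <- matrix(NEG, n + 1, m + 1) # gap in consensus (locus char vs -)
  Gy <- matrix(NEG, n + 1, m + 1) # gap in locus (- vs consensus char)
  Mm[1, ] <- 0 # free consensus prefix before the locus starts
  for (i in 2:(n + 1)) {
    Gx[i, 1] <- max(Mm[i - 1, 1] + open + ext, Gx[i - 1, 1] + ext)
    for (j in 2:(m + 1)) {
      diagbest <- max(Mm[i - 1, j - 1], Gx[i - 1, j - 1], Gy[i - 1, j - 1])
      Mm[i, j] <- s(x[i - 1], y[j - 1]) + diagbest
      Gx[i, j] <- max(
        Mm[i - 1, j] + open + ext, Gy[i - 1, j] + open + ext,
        Gx[i - 1, j] + ext
      )
      Gy[i, j] <- max(
        Mm[i, j - 1] + open + ext, Gx[i, j - 1] + open + ext,
        Gy[i, j - 1] + ext
      )
    }
  }
  max(Mm[n + 1, ], Gx[n + 1, ]) # free consensus suffix
}

# unit-cost Sankoff dynamic programming over explicit state-cost vectors;
# gaps and N allow all four states at zero cost
oracle_sankoff <- function(tree, seqs) {
  seqs <- toupper(seqs)
  ntip <- length(tree$tip.label)
  nsite <- nchar(seqs[[1]])
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  root <- setdiff(unique(tree$edge[, 1]), tree$edge[, 2])
  leafcost <- function(base) {
    if (base %in% BASES) ifelse(BASES == base, 0, Inf) else rep(0, 4)
  }
  total <- 0L
  for (site in seq_len(nsite)) {
    cost <- function(node) {
      if (node <= ntip) {
        return(leafcost(substr(seqs[[tree$tip.label[node]]], site, site)))
      }
      cc <- rep(0, 4)
      for (ch in kids[[as.character(node)]]) {
        child <- cost(ch)
        cc <- cc + vapply(1:4, function(sst) {
          min(child + ifelse(seq_len(4) == sst, 0, 1))
        }, numeric(1))
      }
      cc
    }
    total <- total + min(cost(root))
  }
  total
}

random_alignment <- function(ntaxa, nsites, miss_prob = 0.05) {
  labs <- LETTERS[seq_len(ntaxa)]
  alphabet <- c(BASES, "-", "N")
  p <- c(rep((1 - miss_prob) / 4, 4), miss_prob / 2, miss_prob / 2)
  setNames(
    vapply(
      labs,
      function(l) paste(sample(alphabet, nsites, TRUE, prob = p), collapse = ""),
      ""
    ),
    labs
  )
}

# independent optimal-set oracle: phangorn's complete topology enumeration
# and Fitch implementation
oracle_optimal_set <- function(aln) {
  mat <- do.call(rbind, strsplit(toupper(unname(aln)), ""))
  rownames(mat) <- names(aln)
  pd <- phangorn::phyDat(mat, type = "DNA")
  trees <- phangorn::allTrees(length(aln), tip.label = names(aln))
  scores <- vapply(trees, function(t) phangorn::parsimony(t, pd), numeric(1))
  list(length = min(scores), trees = trees[scores == min(scores)])
}

default_motifs <- function() {
  read_transfac(system.file("extdata", "motifs_synthetic.transfac",
    package = "sinexapt"
  ))
}
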