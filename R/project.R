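#' Project motif hits into consensus coordinates
#'
#' Each raw hit (locus coordinates, locus-relative strand) is carried through
#' the locus's alignment map: the consensus interval is the span
#' `[min, max + 1)` of the consensus columns paired with the hit's locus
#' positions, and the consensus-relative strand is the locus strand composed
#' with the alignment orientation (a `-` hit on a `-`-oriented copy is a `+`
#' site on the consensus). Hits mapping too few of their columns are
#' rejected with a reason, so counts always reconcile
#' (`hits = projected + rejected`).
#'
#' @param hits a hit `data.frame` from [scan_sequence()]/[scan_loci()].
#' @param maps named list of `alignment_map` objects (one per locus in
#'   `hits`).
#' @param min_aligned_frac minimum fraction of hit columns that must map to
#'   consensus columns (default 0.8).
#' @return a list with `projected` (a `data.frame`: `locus_id`, `motif_id`,
#'   `consensus_start`, `consensus_end`, `consensus_strand`, `locus_start`,
#'   `locus_end`, `locus_strand`, `score`, `aligned_column_fraction`) and
#'   `rejected` (the unprojectable hits plus a `reason` column:
#'   `outside_alignment` or `insufficient_alignment`).
#' @export
project_hits <- function(hits, maps, min_aligned_frac = 0.8) {
  if (min_aligned_frac < 0 || min_aligned_frac > 1) {
    stop_input("min_aligned_frac must lie in [0, 1]")
  }
  proj <- list()
  rej <- list()
  for (r in seq_len(nrow(hits))) {
    h <- hits[r, ]
    map <- maps[[h$locus_id]]
    if (is.null(map)) stop_input("no alignment map for locus '", h$locus_id, "'")
    p <- project_one(h, map, min_aligned_frac)
    if (is.null(p$reason)) proj[[length(proj) + 1L]] <- p$row else {
      h$reason <- p$reason
      rej[[length(rej) + 1L]] <- h
    }
  }
  projected <- if (length(proj)) do.call(rbind, proj) else data.frame(
    locus_id = character(0), motif_id = character(0),
    consensus_start = integer(0), consensus_end = integer(0),
    consensus_strand = character(0), locus_start = integer(0),
    locus_end = integer(0), locus_strand = character(0),
    score = numeric(0), aligned_column_fraction = numeric(0)
  )
  rejected <- if (length(rej)) do.call(rbind, rej) else cbind(
    hits[0, , drop = FALSE],
    data.frame(reason = character(0))
  )
  rownames(projected) <- rownames(rejected) <- NULL
  list(projected = projected, rejected = rejected)
}

project_one <- function(h, map, min_aligned_frac) {
  if (h$locus_id != map$locus_id) {
    stop_input("hit locus '", h$locus_id, "' does not match map '", map$locus_id, "'")
  }
  L <- h$end - h$start
  pos <- h$start:(h$end - 1L)
  cols <- map_position(map, pos, frame = "stored")
  cols <- cols[!is.na(cols)]
  if (!length(cols)) {
    return(list(reason = "outside_alignment"))
  }
  frac <- length(cols) / L
  if (frac < min_aligned_frac) {
    return(list(reason = "insufficient_alignment"))
  }
  list(row = data.frame(
    locus_id = h$locus_id, motif_id = h$motif_id,
    consensus_start = min(cols), consensus_end = max(cols) + 1L,
    consensus_strand = compose_strand(h$strand, map$orientation_used),
    locus_start = h$start, locus_end = h$end, locus_strand = h$strand,
    score = h$score, aligned_column_fraction = frac,
    stringsAsFactors = FALSE
  ))
}

#' Per-position locus counts on the consensus, split by strand
#'
#' The family-wide binding-site landscape: for every motif, strand and
#' consensus position, the number of distinct loci whose projected hit
#' covers that position. A locus contributes at most 1 per position per
#' motif and strand even when it carries several overlapping hits, so the
#' histogram counts loci, not hits.
#'
#' @param projected the `projected` table from [project_hits()].
#' @param consensus_length consensus length in nt.
#' @return a `position_histogram` object: `counts` (long `data.frame`
#'   `motif`, `strand`, `position`, `n_loci`, non-zero positions only),
#'   `consensus_length`, and `mass` (total count mass, which equals the sum
#'   over motif, strand and locus of the per-locus covered-interval union
#'   lengths).
#' @export
aggregate_histogram <- function(projected, consensus_length) {
  if (nrow(projected) &&
    any(projected$consensus_end > consensus_length | projected$consensus_start < 0)) {
    stop_input("projected interval extends beyond the consensus")
  }
  rows <- list()
  if (nrow(projected)) {
    key <- interaction(
      projected$motif_id, projected$consensus_strand,
      drop = TRUE, sep = "\r"
    )
    for (k in levels(key)) {
      sub <- projected[key == k, , drop = FALSE]
      covered <- lapply(split(sub, sub$locus_id), function(s) {
        unique(unlist(mapply(
          function(a, b) a:(b - 1L), s$consensus_start, s$consensus_end,
          SIMPLIFY = FALSE
        )))
      })
      tab <- table(unlist(covered, use.names = FALSE))
      ms <- strsplit(k, "\r", fixed = TRUE)[[1]]
      rows[[length(rows) + 1L]] <- data.frame(
        motif = ms[1], strand = ms[2],
        position = as.integer(names(tab)), n_loci = as.integer(tab),
        stringsAsFactors = FALSE
      )
    }
  }
  counts <- if (length(rows)) do.call(rbind, rows) else data.frame(
    motif = character(0), strand = character(0),
    position = integer(0), n_loci = integer(0)
  )
  counts <- counts[order(counts$motif, counts$strand, counts$position), , drop = FALSE]
  rownames(counts) <- NULL
  structure(
    list(
      counts = counts, consensus_length = as.integer(consensus_length),
      mass = sum(counts$n_loci)
    ),
    class = "position_histogram"
  )
}

#' @export
print.position_histogram <- function(x, ...) {
  cat(
    "Position histogram over ", x$consensus_length, "-nt consensus: ",
    length(unique(x$counts$motif)), " motif(s), mass ", x$mass, "\n",
    sep = ""
  )
  invisible(x)
}

#' Cluster loci carrying binding sites at similar consensus locations
#'
#' Operationalises "the same site shared across loci": per motif and
#' consensus strand, projected hit start positions are single-linkage
#' clustered with linkage distance <= `tolerance` nt. Each cluster reports
#' its distinct member loci (a locus counts once however many hits it
#' contributes) and a representative interval (the modal projected interval,
#' ties to the leftmost).
#'
#' @param projected the `projected` table from [project_hits()].
#' @param tolerance single-linkage distance `w` in nt (default 5).
#' @return a `data.frame` of clusters: `motif_id`, `consensus_strand`,
#'   `rep_start`, `rep_end`, `n_loci`, `n_hits`, `loci` (comma-separated
#'   sorted ids), sorted by `n_loci` descending then position.
#' @export
cluster_shared_sites <- function(projected, tolerance = 5) {
  if (tolerance < 0) stop_input("tolerance must be >= 0")
  out <- list()
  if (nrow(projected)) {
    key <- interaction(
      projected$motif_id, projected$consensus_strand,
      drop = TRUE, sep = "\r"
    )
    for (k in levels(key)) {
      sub <- projected[key == k, , drop = FALSE]
      sub <- sub[order(sub$consensus_start, sub$locus_id), , drop = FALSE]
      brk <- c(0L, cumsum(diff(sub$consensus_start) > tolerance))
      for (g in split(sub, brk)) {
        iv <- paste(g$consensus_start, g$consensus_end)
        tab <- sort(table(iv), decreasing = TRUE)
        best <- names(tab)[tab == tab[1]]
        rep_iv <- as.integer(strsplit(sort(best)[1], " ")[[1]])
        out[[length(out) + 1L]] <- data.frame(
          motif_id = g$motif_id[1], consensus_strand = g$consensus_strand[1],
          rep_start = rep_iv[1], rep_end = rep_iv[2],
          n_loci = length(unique(g$locus_id)), n_hits = nrow(g),
          loci = paste(sort(unique(g$locus_id)), collapse = ","),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  res <- if (length(out)) do.call(rbind, out) else data.frame(
    motif_id = character(0), consensus_strand = character(0),
    rep_start = integer(0), rep_end = integer(0),
    n_loci = integer(0), n_hits = integer(0), loci = character(0)
  )
  res <- res[order(-res$n_loci, res$rep_start, res$motif_id, res$consensus_strand), ,
    drop = FALSE
  ]
  rownames(res) <- NULL
  res
}

#' Permutation test for concentration of sites in consensus domains
#'
#' Asks whether projected binding sites pile up in particular annotated
#' domains of the consensus (e.g. the Deu-domain) more than uniform
#' placement would produce. A hit is assigned to the domain containing its
#' interval midpoint. The null redraws each hit's start uniformly over all
#' consensus positions where it fits, `n_permutations` times; the one-sided
#' p-value per domain is `(1 + #{perm >= observed}) / (M + 1)`. p-values are
#' Benjamini-Hochberg adjusted across all motif x domain rows (exploratory).
#'
#' @param projected the `projected` table from [project_hits()].
#' @param consensus a [sine_consensus()] with non-empty domain annotation.
#' @param n_permutations `M` >= 100 (default 1000).
#' @param seed integer RNG seed.
#' @return a `domain_enrichment` `data.frame`: `motif_id`, `domain`,
#'   `observed`, `expected`, `p_value`, `q_value`, `n_hits`,
#'   `n_permutations`, `seed`.
#' @export
domain_enrichment <- function(projected, consensus, n_permutations = 1000L,
                              seed = 1L) {
  stopifnot(inherits(consensus, "sine_consensus"))
  dom <- consensus$domains
  if (is.null(dom) || nrow(dom) == 0) stop_input("consensus has no domain annotation")
  M <- as.integer(n_permutations)
  if (M < 100L) stop_input("n_permutations must be >= 100")
  set.seed(as.integer(seed))
  C <- consensus$length

  res <- list()
  for (m in sort(unique(projected$motif_id))) {
    sub <- projected[projected$motif_id == m, , drop = FALSE]
    lens <- sub$consensus_end - sub$consensus_start
    mids <- sub$consensus_start + lens %/% 2L
    nh <- nrow(sub)

    # null: per hit, uniform start over [0, C - L]; midpoint domain counts
    perm_counts <- matrix(0L, M, nrow(dom))
    if (nh > 0) {
      starts <- vapply(
        lens, function(L) sample.int(C - L + 1L, M, replace = TRUE) - 1L,
        integer(M)
      )
      perm_mids <- sweep(starts, 2, lens %/% 2L, "+")
      for (d in seq_len(nrow(dom))) {
        perm_counts[, d] <- rowSums(
          perm_mids >= dom$start[d] & perm_mids < dom$end[d]
        )
      }
    }

    for (d in seq_len(nrow(dom))) {
      obs <- sum(mids >= dom$start[d] & mids < dom$end[d])
      expd <- if (nh == 0) 0 else sum(vapply(lens, function(L) {
        fl <- L %/% 2L
        lo <- max(0L, dom$start[d] - fl)
        hi <- min(C - L, dom$end[d] - 1L - fl)
        if (hi < lo) 0 else (hi - lo + 1) / (C - L + 1)
      }, numeric(1)))
      p <- (1 + sum(perm_counts[, d] >= obs)) / (M + 1)
      res[[length(res) + 1L]] <- data.frame(
        motif_id = m, domain = dom$label[d], observed = obs,
        expected = expd, p_value = p, q_value = NA_real_,
        n_hits = nh, n_permutations = M, seed = as.integer(seed),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- if (length(res)) do.call(rbind, res) else data.frame(
    motif_id = character(0), domain = character(0), observed = integer(0),
    expected = numeric(0), p_value = numeric(0), q_value = numeric(0),
    n_hits = integer(0), n_permutations = integer(0), seed = integer(0)
  )
  out$q_value <- p.adjust(out$p_value, method = "BH")
  rownames(out) <- NULL
  class(out) <- c("domain_enrichment", "data.frame")
  out
}

version_comment <- function() {
  paste0("# sinexapt ", as.character(packageVersion("sinexapt")))
}

write_tsv_report <- function(d, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(version_comment(), con)
  write.table(d, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write pipeline tables
#'
#' `write_projected_bed()` emits projected hits as BED-like text in
#' consensus space (`consensus_name start end locus_id|motif_id score
#' strand`, 0-based half-open); the other writers emit tab-separated reports
#' with a header row and a leading `# sinexapt <version>` comment.
#'
#' @param projected,histogram,clusters,enrichment pipeline result tables.
#' @param consensus_name name for the BED chrom column.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_projected_bed <- function(projected, path, consensus_name = "consensus") {
  bed <- data.frame(
    chrom = consensus_name,
    start = projected$consensus_start, end = projected$consensus_end,
    name = paste0(projected$locus_id, "|", projected$motif_id),
    score = round(projected$score, 4), strand = projected$consensus_strand
  )
  write.table(bed, path,
    sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}

#' @rdname write_projected_bed
#' @export
write_histogram <- function(histogram, path) {
  write_tsv_report(histogram$counts, path)
}

#' @rdname write_projected_bed
#' @export
write_clusters <- function(clusters, path) {
  write_tsv_report(clusters, path)
}

#' @rdname write_projected_bed
#' @export
write_enrichment <- function(enrichment, path) {
  write_tsv_report(as.data.frame(enrichment), path)
}
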