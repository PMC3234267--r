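#' Configure a synthetic SINE family simulation
#'
#' Describes how a SINE-family consensus is amplified into a set of diverged,
#' variably 5'-truncated genomic copies, optionally carrying embedded
#' transcription-factor motif instances at shared consensus positions. The
#' defaults emulate an amniote tRNA-derived family: a 570-nt four-domain
#' consensus copied into 124 loci at moderate divergence.
#'
#' @param seed integer RNG seed; the seed plus the configuration fully
#'   determine every output byte.
#' @param n_loci number of copies to generate (>= 1).
#' @param consensus_length consensus length in nt.
#' @param domain_layout domain `data.frame` (`label`,`start`,`end`); defaults
#'   to [default_domain_layout()] scaled to `consensus_length`.
#' @param divergence per-site substitution probability in `[0, 1)`.
#' @param indel_rate per-site indel-initiation probability in `[0, 1)`;
#'   `divergence + indel_rate` must be below 1.
#' @param indel_mean_len mean indel length in nt (geometric lengths, >= 1).
#' @param truncation_model one of `"none"`, `"uniform_5prime"` (retained
#'   start uniform on `[0, max_trunc]`), `"fixed_offset"` (all copies start
#'   at `offset`; 256 gives copies retaining the 3' half `[256, 570)` of a
#'   570-nt consensus).
#' @param truncation_params list: `max_trunc` for `uniform_5prime` (default
#'   half the consensus), `offset` for `fixed_offset` (default 256).
#' @param embeddings list of [embedding_spec()] objects.
#' @param protect_embedded if `TRUE` (default) embedded motif instances are
#'   shielded from substitutions and indels, so downstream recovery tests
#'   measure pipeline error rather than simulation noise.
#' @param random_orientation if `TRUE`, each copy is stored on a random
#'   strand; default `FALSE` (all stored as `+`).
#' @param consensus_seq optional explicit consensus sequence; by default a
#'   uniform-random sequence of `consensus_length` nt is drawn from the seed.
#' @return a validated `sim_config` list.
#' @seealso [simulate_family()]
#' @export
simulation_config <- function(seed = 1L,
                              n_loci = 124L,
                              consensus_length = 570L,
                              domain_layout = NULL,
                              divergence = 0.10,
                              indel_rate = 0.005,
                              indel_mean_len = 2,
                              truncation_model = c("uniform_5prime", "none", "fixed_offset"),
                              truncation_params = list(),
                              embeddings = list(),
                              protect_embedded = TRUE,
                              random_orientation = FALSE,
                              consensus_seq = NULL) {
  truncation_model <- match.arg(truncation_model)
  n_loci <- as.integer(n_loci)
  consensus_length <- as.integer(consensus_length)
  if (is.na(n_loci) || n_loci < 1L) stop_input("n_loci must be >= 1")
  if (!is.null(consensus_seq)) consensus_length <- nchar(consensus_seq)
  if (consensus_length < 1L) stop_input("consensus_length must be positive")
  if (divergence < 0 || divergence >= 1) stop_input("divergence must lie in [0, 1)")
  if (indel_rate < 0 || indel_rate >= 1) stop_input("indel_rate must lie in [0, 1)")
  if (divergence + indel_rate >= 1) stop_input("divergence + indel_rate must be < 1")
  if (indel_mean_len < 1) stop_input("indel_mean_len must be >= 1")
  if (is.null(domain_layout)) domain_layout <- default_domain_layout(consensus_length)
  if (sum(domain_layout$end - domain_layout$start) > consensus_length) {
    stop_input("domain layout exceeds consensus_length")
  }
  if (truncation_model == "uniform_5prime") {
    truncation_params$max_trunc <- as.integer(
      truncation_params$max_trunc %||% (consensus_length %/% 2L)
    )
    if (truncation_params$max_trunc < 0 || truncation_params$max_trunc >= consensus_length) {
      stop_input("max_trunc must lie in [0, consensus_length)")
    }
  } else if (truncation_model == "fixed_offset") {
    truncation_params$offset <- as.integer(truncation_params$offset %||% 256L)
    if (truncation_params$offset < 0 || truncation_params$offset >= consensus_length) {
      stop_input("fixed offset must lie in [0, consensus_length)")
    }
  }
  for (e in embeddings) {
    if (!inherits(e, "embedding_spec")) stop_input("embeddings must be embedding_spec objects")
    if (any(e$locus_ids < 1L | e$locus_ids > n_loci)) {
      stop_input("embedding locus_ids out of range 1..n_loci")
    }
  }
  structure(
    list(
      seed = as.integer(seed), n_loci = n_loci,
      consensus_length = consensus_length, domain_layout = domain_layout,
      divergence = divergence, indel_rate = indel_rate,
      indel_mean_len = indel_mean_len,
      truncation_model = truncation_model, truncation_params = truncation_params,
      embeddings = embeddings, protect_embedded = isTRUE(protect_embedded),
      random_orientation = isTRUE(random_orientation),
      consensus_seq = consensus_seq
    ),
    class = "sim_config"
  )
}

#' Specify an embedded motif instance
#'
#' Models exaptation-era binding sites: the same motif instance placed at one
#' consensus position in a chosen subset of copies, on either strand relative
#' to the consensus. One ancestral instance sequence is drawn per embedding
#' and shared by all carrier loci (the copies inherit the site; divergence is
#' applied afterwards, unless the site is protected).
#'
#' @param motif_id name matching a motif in the matrix set passed to
#'   [simulate_family()].
#' @param consensus_position 0-based consensus offset of the instance start.
#' @param strand `"+"` or `"-"` relative to the consensus.
#' @param locus_ids integer indices (1-based) of the carrier loci.
#' @param sampling `"consensus_string"` (per-column argmax of the count
#'   matrix, ties broken A<C<G<T) or `"pfm_sample"` (one random draw from the
#'   per-column frequencies).
#' @return an `embedding_spec` object.
#' @export
embedding_spec <- function(motif_id, consensus_position, strand = "+",
                           locus_ids, sampling = c("consensus_string", "pfm_sample")) {
  sampling <- match.arg(sampling)
  locus_ids <- unique(as.integer(locus_ids))
  if (length(locus_ids) == 0) stop_input("locus_ids must be non-empty")
  if (!strand %in% c("+", "-")) stop_input("strand must be '+' or '-'")
  structure(
    list(
      motif_id = as.character(motif_id),
      consensus_position = as.integer(consensus_position),
      strand = strand, locus_ids = locus_ids, sampling = sampling
    ),
    class = "embedding_spec"
  )
}

#' Mutate a sequence with substitutions and indels, keeping the column map
#'
#' Applies, in one pass over the template, (i) indel initiations (per-site
#' probability `indel_rate`; geometric lengths with mean `indel_mean_len`;
#' deletions and insertions equiprobable; inserted bases uniform over
#' `A,C,G,T`) and (ii) independent per-site substitutions (probability
#' `divergence`, uniform over the three other bases; no back-mutation within
#' a pass, so the expected mismatch fraction equals `divergence` exactly).
#' Positions listed in `protect` (0-based template coordinates) are immune:
#' never substituted or deleted, and deletions running into them stop;
#' insertions never fall between two protected positions.
#'
#' Draws come from R's current RNG stream; seed the stream (or use the
#' seeded wrappers [simulate_family()] / [simulate_orthologs()]) for
#' reproducibility.
#'
#' @param seq template nucleotide string over `A,C,G,T`.
#' @param divergence,indel_rate per-site probabilities in `[0, 1)`, summing
#'   below 1.
#' @param indel_mean_len mean indel length (>= 1).
#' @param protect integer vector of protected template positions (0-based).
#' @return a list with
#'   `sequence` (the mutated string),
#'   `map` (a `data.frame` of alignment columns `locus`/`ref`, 0-based, `NA`
#'   on the gapped side; both sides strictly increasing, no all-gap column),
#'   and `edits` (a `data.frame` of `op` in `sub`,`del`,`ins`, `ref_pos`
#'   0-based, `bases`) sufficient to reconstruct `sequence` from `seq` via
#'   [apply_edits()].
#' @examples
#' set.seed(1)
#' m <- mutate_sequence(strrep("ACGT", 25), divergence = 0.1)
#' identical(apply_edits(strrep("ACGT", 25), m$edits), m$sequence)
#' @export
mutate_sequence <- function(seq, divergence, indel_rate = 0,
                            indel_mean_len = 2, protect = integer(0)) {
  if (!nzchar(seq)) stop_input("sequence must be non-empty")
  if (grepl("[^ACGT]", seq)) stop_input("sequence must be over A,C,G,T")
  if (divergence < 0 || divergence >= 1) stop_input("divergence must lie in [0, 1)")
  if (indel_rate < 0 || indel_rate >= 1) stop_input("indel_rate must lie in [0, 1)")
  if (divergence + indel_rate >= 1) stop_input("divergence + indel_rate must be < 1")
  if (indel_mean_len < 1) stop_input("indel_mean_len must be >= 1")

  chars <- seq_to_chars(seq)
  n <- length(chars)
  protected <- logical(n)
  protected[protect + 1L] <- TRUE

  # --- indel events ---------------------------------------------------------
  deleted <- logical(n)
  ins_after <- vector("list", n) # bases inserted immediately after position i
  if (indel_rate > 0) {
    ev <- which(runif(n) < indel_rate & !protected)
    for (i in ev) {
      if (deleted[i]) next
      len <- rgeom(1L, 1 / indel_mean_len) + 1L
      if (runif(1L) < 0.5) { # deletion, stops at protected positions
        j <- i
        while (j <= n && len > 0L && !protected[j] && !deleted[j]) {
          deleted[j] <- TRUE
          j <- j + 1L
          len <- len - 1L
        }
      } else {
        # insertion after i; i is unprotected, so this never splits a
        # protected interval
        ins_after[[i]] <- c(ins_after[[i]], sample(DNA_BASES, len, replace = TRUE))
      }
    }
  }

  # --- substitutions --------------------------------------------------------
  out_chars <- chars
  sub_at <- integer(0)
  if (divergence > 0) {
    sub_at <- which(runif(n) < divergence & !deleted & !protected)
    if (length(sub_at)) {
      shift <- sample.int(3L, length(sub_at), replace = TRUE)
      old <- match(chars[sub_at], DNA_BASES)
      out_chars[sub_at] <- DNA_BASES[((old - 1L + shift) %% 4L) + 1L]
    }
  }

  # --- assemble columns and edit list ---------------------------------------
  has_ins <- !vapply(ins_after, is.null, logical(1))
  if (!any(deleted) && !any(has_ins)) {
    loc_col <- seq_len(n) - 1L
    ref_col <- loc_col
    loc_chars <- out_chars
  } else {
    cols <- vector("list", n)
    lp <- 0L
    for (i in seq_len(n)) {
      lc <- if (deleted[i]) NA_integer_ else {
        lp <- lp + 1L
        lp - 1L
      }
      rc <- i - 1L
      if (has_ins[i]) {
        k <- length(ins_after[[i]])
        lc <- c(lc, lp + 0:(k - 1L))
        rc <- c(rc, rep(NA_integer_, k))
        lp <- lp + k
      }
      cols[[i]] <- cbind(lc, rc)
    }
    cols <- do.call(rbind, cols)
    loc_col <- cols[, 1]
    ref_col <- cols[, 2]
    keepc <- !is.na(loc_col)
    loc_chars <- character(sum(keepc))
    src <- ifelse(is.na(ref_col[keepc]), NA_integer_, ref_col[keepc] + 1L)
    loc_chars[!is.na(src)] <- out_chars[src[!is.na(src)]]
    ins_flat <- unlist(ins_after[has_ins], use.names = FALSE)
    loc_chars[is.na(src)] <- ins_flat
  }

  edits <- rbind(
    if (length(sub_at)) {
      data.frame(
        op = "sub", ref_pos = sub_at - 1L, bases = out_chars[sub_at],
        stringsAsFactors = FALSE
      )
    },
    if (any(deleted)) {
      data.frame(
        op = "del", ref_pos = which(deleted) - 1L, bases = "",
        stringsAsFactors = FALSE
      )
    },
    {
      ii <- which(!vapply(ins_after, is.null, logical(1)))
      if (length(ii)) {
        data.frame(
          op = "ins", ref_pos = ii - 1L,
          bases = vapply(ins_after[ii], paste, "", collapse = ""),
          stringsAsFactors = FALSE
        )
      }
    }
  )
  if (is.null(edits)) {
    edits <- data.frame(op = character(0), ref_pos = integer(0), bases = character(0))
  }

  list(
    sequence = chars_to_seq(loc_chars),
    map = data.frame(locus = loc_col, ref = ref_col),
    edits = edits[order(edits$ref_pos, edits$op), , drop = FALSE]
  )
}

#' Reconstruct a mutated sequence from its edit list
#'
#' Inverse check for [mutate_sequence()]: applies `sub`, `del` and `ins`
#' records (0-based `ref_pos`; insertions go immediately after `ref_pos`) to
#' the reference.
#'
#' @param ref reference nucleotide string.
#' @param edits edit `data.frame` as returned by [mutate_sequence()].
#' @return the reconstructed sequence string.
#' @export
apply_edits <- function(ref, edits) {
  chars <- seq_to_chars(ref)
  n <- length(chars)
  keep <- rep(TRUE, n)
  ins_after <- vector("list", n)
  for (r in seq_len(nrow(edits))) {
    op <- edits$op[r]
    i <- edits$ref_pos[r] + 1L
    if (op == "sub") {
      chars[i] <- edits$bases[r]
    } else if (op == "del") {
      keep[i] <- FALSE
    } else if (op == "ins") {
      ins_after[[i]] <- c(ins_after[[i]], seq_to_chars(edits$bases[r]))
    } else {
      stop_input("unknown edit op: ", op)
    }
  }
  out <- character(0)
  for (i in seq_len(n)) {
    if (keep[i]) out <- c(out, chars[i])
    if (!is.null(ins_after[[i]])) out <- c(out, ins_after[[i]])
  }
  chars_to_seq(out)
}

motif_counts_of <- function(m) {
  if (inherits(m, "motif_counts")) m$counts else if (inherits(m, "pwm")) m$counts else {
    stop_input("motifs must be motif_counts or pwm objects")
  }
}

draw_instance <- function(counts, sampling) {
  if (sampling == "consensus_string") {
    chars_to_seq(DNA_BASES[apply(counts, 1, which.max)])
  } else {
    chars_to_seq(apply(counts, 1, function(cc) sample(DNA_BASES, 1L, prob = cc / sum(cc))))
  }
}

#' Simulate a diverged, truncated SINE family with ground truth
#'
#' Amplifies the consensus into `n_loci` copies. Per copy, the order of
#' events mirrors retroposition followed by neutral decay: the consensus is
#' copied, any embedded motif instances for that copy are placed, the copy is
#' 5'-truncated per the truncation model, and finally substitutions and
#' indels are applied (skipping protected embedded intervals when
#' `protect_embedded`). Identical seed and configuration give byte-identical
#' results.
#'
#' @param config a [simulation_config()] object.
#' @param motifs named list of motif count matrices ([read_transfac()]) or
#'   PWMs; required when `config$embeddings` is non-empty.
#' @return a `sine_family` object: list with
#'   `loci` (named character vector of stored sequences),
#'   `meta` (`data.frame`: `locus_id`, `trunc_offset`, `orientation`,
#'   `length`),
#'   `truth` (one row per (locus, embedding): `locus_id`, `motif_id`,
#'   `consensus_start`, `consensus_end`, `strand` (consensus-relative),
#'   `embedded_sequence`, `survives_truncation`, plus the realised
#'   stored-locus interval `locus_start`, `locus_end`, `locus_strand`,
#'   `NA` when the site was truncated away),
#'   `maps` (per locus the true locus/consensus column map, 0-based, in the
#'   pre-orientation `+` frame),
#'   `consensus` ([sine_consensus()]) and `config`.
#'   A warning is raised for any embedding truncated away in every carrier.
#' @examples
#' cfg <- simulation_config(seed = 7, n_loci = 5, consensus_length = 80,
#'                          divergence = 0, indel_rate = 0,
#'                          truncation_model = "none")
#' fam <- simulate_family(cfg)
#' all(fam$loci == fam$consensus$sequence)
#' @export
simulate_family <- function(config, motifs = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)

  cons_seq <- config$consensus_seq %||%
    chars_to_seq(sample(DNA_BASES, config$consensus_length, replace = TRUE))
  consensus <- sine_consensus(cons_seq, domains = config$domain_layout)
  C <- consensus$length

  # one ancestral instance per embedding, shared by all carriers
  inst <- lapply(config$embeddings, function(e) {
    if (is.null(motifs) || is.null(motifs[[e$motif_id]])) {
      stop_input("embedding references unknown motif '", e$motif_id, "'")
    }
    s <- draw_instance(motif_counts_of(motifs[[e$motif_id]]), e$sampling)
    if (e$consensus_position + nchar(s) > C) {
      stop_input("embedding for '", e$motif_id, "' extends past the consensus end")
    }
    s
  })

  loci <- character(config$n_loci)
  ids <- sprintf("locus_%03d", seq_len(config$n_loci))
  meta <- data.frame(
    locus_id = ids, trunc_offset = 0L, orientation = "+",
    length = 0L, stringsAsFactors = FALSE
  )
  maps <- vector("list", config$n_loci)
  truth <- list()
  cons_chars <- seq_to_chars(consensus$sequence)

  for (k in seq_len(config$n_loci)) {
    orient <- if (config$random_orientation && runif(1L) < 0.5) "-" else "+"
    tau <- switch(config$truncation_model,
      none = 0L,
      uniform_5prime = sample.int(config$truncation_params$max_trunc + 1L, 1L) - 1L,
      fixed_offset = config$truncation_params$offset
    )

    template <- cons_chars
    carried <- which(vapply(
      config$embeddings, function(e) k %in% e$locus_ids, logical(1)
    ))
    protect <- integer(0)
    for (j in carried) {
      e <- config$embeddings[[j]]
      s <- if (e$strand == "+") inst[[j]] else revcomp(inst[[j]])
      L <- nchar(s)
      template[(e$consensus_position + 1L):(e$consensus_position + L)] <- seq_to_chars(s)
      if (config$protect_embedded && e$consensus_position >= tau) {
        protect <- c(protect, (e$consensus_position - tau) + 0:(L - 1L))
      }
    }

    retained <- chars_to_seq(template[(tau + 1L):C])
    mut <- mutate_sequence(
      retained, config$divergence, config$indel_rate,
      config$indel_mean_len, protect
    )
    map <- mut$map
    map$consensus <- map$ref + tau
    map$ref <- NULL
    llen <- nchar(mut$sequence)

    loci[k] <- if (orient == "-") revcomp(mut$sequence) else mut$sequence
    meta$trunc_offset[k] <- tau
    meta$orientation[k] <- orient
    meta$length[k] <- llen
    maps[[k]] <- map

    for (j in carried) {
      e <- config$embeddings[[j]]
      L <- nchar(inst[[j]])
      survives <- e$consensus_position >= tau
      ls <- le <- NA_integer_
      lstr <- NA_character_
      if (survives) {
        cols <- map$locus[!is.na(map$consensus) &
          map$consensus >= e$consensus_position &
          map$consensus < e$consensus_position + L]
        cols <- cols[!is.na(cols)]
        if (length(cols)) {
          ls <- min(cols)
          le <- max(cols) + 1L
          if (orient == "-") {
            t0 <- llen - le
            le <- llen - ls
            ls <- t0
          }
          lstr <- compose_strand(e$strand, orient)
        }
      }
      truth[[length(truth) + 1L]] <- data.frame(
        locus_id = ids[k], motif_id = e$motif_id,
        consensus_start = e$consensus_position,
        consensus_end = e$consensus_position + L,
        strand = e$strand, embedded_sequence = inst[[j]],
        survives_truncation = survives,
        locus_start = ls, locus_end = le, locus_strand = lstr,
        stringsAsFactors = FALSE
      )
    }
  }

  truth <- if (length(truth)) do.call(rbind, truth) else data.frame(
    locus_id = character(0), motif_id = character(0),
    consensus_start = integer(0), consensus_end = integer(0),
    strand = character(0), embedded_sequence = character(0),
    survives_truncation = logical(0), locus_start = integer(0),
    locus_end = integer(0), locus_strand = character(0)
  )

  for (j in seq_along(config$embeddings)) {
    e <- config$embeddings[[j]]
    tr <- truth[truth$motif_id == e$motif_id &
      truth$consensus_start == e$consensus_position, ]
    if (nrow(tr) && !any(tr$survives_truncation)) {
      warning(
        "embedding '", e$motif_id, "' at consensus position ",
        e$consensus_position, " was truncated away in every carrier locus",
        call. = FALSE
      )
    }
  }

  names(loci) <- ids
  names(maps) <- ids
  structure(
    list(
      loci = loci, meta = meta, truth = truth, maps = maps,
      consensus = consensus, config = config
    ),
    class = "sine_family"
  )
}

#' @export
print.sine_family <- function(x, ...) {
  cat(
    "Synthetic SINE family: ", length(x$loci), " loci, consensus ",
    x$consensus$length, " nt\n", sep = ""
  )
  cat(
    "  divergence ", x$config$divergence, ", indel rate ",
    x$config$indel_rate, ", truncation ", x$config$truncation_model, "\n",
    sep = ""
  )
  if (nrow(x$truth)) {
    surv <- sum(x$truth$survives_truncation)
    cat(
      "  embeddings: ", length(x$config$embeddings), " (",
      surv, "/", nrow(x$truth), " locus instances survive truncation)\n",
      sep = ""
    )
  }
  invisible(x)
}

#' Write a simulated family to disk
#'
#' Emits `loci.fasta` (headers `locus_<k>|trunc=<o>|orient=<+/->`),
#' `consensus.fasta`, `domains.tsv`, `truth.tsv` (tab-separated, header row)
#' and `config.yaml` (full parameter echo) into `outdir`. All coordinates are
#' 0-based half-open.
#'
#' @param family a `sine_family`.
#' @param outdir output directory (created if missing).
#' @return `outdir`, invisibly.
#' @export
write_family <- function(family, outdir) {
  stopifnot(inherits(family, "sine_family"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  seqs <- family$loci
  names(seqs) <- sprintf(
    "%s|trunc=%d|orient=%s",
    family$meta$locus_id, family$meta$trunc_offset, family$meta$orientation
  )
  write_fasta(seqs, file.path(outdir, "loci.fasta"))
  write_fasta(
    setNames(family$consensus$sequence, family$consensus$name),
    file.path(outdir, "consensus.fasta")
  )
  write_domain_table(family$consensus$domains, file.path(outdir, "domains.tsv"))
  write.table(
    family$truth, file.path(outdir, "truth.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  cfg <- family$config
  cfg$domain_layout <- NULL
  cfg$embeddings <- lapply(cfg$embeddings, unclass)
  yaml::write_yaml(unclass(cfg), file.path(outdir, "config.yaml"))
  invisible(outdir)
}

#' Evolve a root sequence along a tree (substitutions only)
#'
#' Generates orthologous leaf sequences by recursive application of the
#' per-site substitution process down a binary tree whose branch lengths are
#' per-branch substitution probabilities.
#'
#' @param root_seq root nucleotide string over `A,C,G,T`.
#' @param tree an ape `phylo` object or a Newick string; must be binary, with
#'   branch lengths in `[0, 1)` interpreted as substitution probabilities.
#' @param seed integer RNG seed.
#' @return named character vector of leaf sequences (tip-label order).
#' @examples
#' simulate_orthologs(strrep("ACGT", 5), "((A:0,B:0):0,(C:0,D:0):0);", seed = 1)
#' @export
simulate_orthologs <- function(root_seq, tree, seed = 1L) {
  if (is.character(tree)) {
    tree <- tryCatch(
      suppressWarnings(ape::read.tree(text = tree)),
      error = function(e) NULL
    )
    if (is.null(tree) || !inherits(tree, "phylo")) {
      stop_input("malformed Newick tree")
    }
  }
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) stop_input("tree must carry branch lengths")
  if (any(tree$edge.length < 0 | tree$edge.length >= 1)) {
    stop_input("branch lengths must be substitution probabilities in [0, 1)")
  }
  if (!ape::is.binary(tree)) stop_input("tree must be binary")

  set.seed(as.integer(seed))
  tree <- ape::reorder.phylo(tree, "cladewise")
  nnode <- max(tree$edge)
  seqs <- vector("list", nnode)
  root <- unique(tree$edge[!(tree$edge[, 1] %in% tree$edge[, 2]), 1])
  seqs[[root]] <- root_seq
  for (i in seq_len(nrow(tree$edge))) {
    par <- tree$edge[i, 1]
    child <- tree$edge[i, 2]
    p <- tree$edge.length[i]
    seqs[[child]] <- if (p == 0) seqs[[par]] else {
      mutate_sequence(seqs[[par]], divergence = p)$sequence
    }
  }
  setNames(
    unlist(seqs[seq_along(tree$tip.label)]),
    tree$tip.label
  )
}
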