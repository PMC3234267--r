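#' Validate a character alignment for parsimony analysis
#'
#' @param seqs named character vector of equal-length aligned sequences over
#'   `A,C,G,T,-,N` (case-insensitive). At least two taxa; unique labels.
#' @return a `character_alignment` object (named, upper-cased).
#' @export
character_alignment <- function(seqs) {
  if (inherits(seqs, "character_alignment")) {
    return(seqs)
  }
  if (is.null(names(seqs)) || any(!nzchar(names(seqs)))) {
    stop_input("alignment sequences must be named by taxon")
  }
  if (anyDuplicated(names(seqs))) stop_input("taxon labels must be unique")
  if (length(seqs) < 2) stop_input("alignment needs at least 2 taxa")
  seqs <- toupper(seqs)
  if (length(unique(nchar(seqs))) != 1) stop_input("sequences must have equal length")
  if (any(grepl("[^ACGTN-]", seqs))) {
    stop_input("alignment alphabet is A,C,G,T,-,N")
  }
  structure(seqs, class = "character_alignment")
}

# bit encoding A=1 C=2 G=4 T=8; gap and N are missing (all four bases)
encode_alignment <- function(aln) {
  aln <- character_alignment(aln)
  code <- c(A = 1L, C = 2L, G = 4L, T = 8L, N = 15L, "-" = 15L)
  M <- do.call(rbind, lapply(unname(aln), function(s) code[seq_to_chars(s)]))
  rownames(M) <- names(aln)
  key <- apply(M, 2, paste, collapse = ",")
  first <- !duplicated(key)
  list(
    patterns = M[, first, drop = FALSE],
    weights = as.integer(table(key)[key[first]]),
    taxa = names(aln), n_sites = ncol(M)
  )
}

low_bit <- function(x) bitwAnd(x, -x)

# Fitch length of an undirected binary tree given as an edge matrix over
# node ids (tips 1..ntip in pattern-row order); vectorised over site patterns
fitch_edges <- function(edges, tipM, weights) {
  nnode <- max(edges)
  adj <- vector("list", nnode)
  for (i in seq_len(nrow(edges))) {
    u <- edges[i, 1]
    v <- edges[i, 2]
    adj[[u]] <- c(adj[[u]], v)
    adj[[v]] <- c(adj[[v]], u)
  }
  ntip <- nrow(tipM)
  total <- 0L
  down <- function(node, parent) {
    if (node <= ntip) {
      return(tipM[node, ])
    }
    s <- NULL
    for (x in adj[[node]]) {
      if (x == parent) next
      cs <- down(x, node)
      if (is.null(s)) {
        s <- cs
      } else {
        a <- bitwAnd(s, cs)
        z <- a == 0L
        total <<- total + sum(weights[z])
        s <- ifelse(z, bitwOr(s, cs), a)
      }
    }
    s
  }
  root_nb <- adj[[1]][1]
  s <- down(root_nb, 1L)
  z <- bitwAnd(s, tipM[1, ]) == 0L
  total + sum(weights[z])
}

phylo_taxon_check <- function(tree, enc) {
  if (!setequal(tree$tip.label, enc$taxa)) {
    stop_input("tree taxa do not match alignment taxa")
  }
}

#' Fitch parsimony length of a tree
#'
#' Unit-cost small parsimony: the minimum number of substitutions the
#' alignment requires on the given tree, summed over sites. Gaps and `N` are
#' treated as missing data (the leaf state set is all four bases, costing
#' nothing by themselves).
#'
#' @param tree an ape `phylo` (binary; rooted or unrooted) whose tip labels
#'   match the alignment taxa.
#' @param alignment a [character_alignment()] (or named character vector).
#' @return integer parsimony length.
#' @examples
#' aln <- c(A = "AAA", B = "AAT", C = "GAA", D = "GAT")
#' fitch_score(ape::read.tree(text = "((A,B),(C,D));"), aln)
#' @export
fitch_score <- function(tree, alignment) {
  stopifnot(inherits(tree, "phylo"))
  enc <- encode_alignment(alignment)
  phylo_taxon_check(tree, enc)
  tipM <- enc$patterns[match(tree$tip.label, enc$taxa), , drop = FALSE]
  fitch_edges(tree$edge, tipM, enc$weights)
}

#' Per-branch substitution counts from one deterministic Fitch assignment
#'
#' Runs the Fitch downpass and a deterministic traceback (ambiguities broken
#' in base order A < C < G < T; the root state prefers the outgroup side, so
#' changes attach away from the outgroup) and attributes each inferred
#' substitution to its branch.
#'
#' @param tree a rooted binary `phylo` (root the unrooted search result with
#'   [to_newick()] or `ape::root()` first), or unrooted with `outgroup`.
#' @param alignment a [character_alignment()].
#' @param outgroup optional tip label to root on.
#' @return the (rooted) `phylo` with `edge.length` set to per-branch change
#'   counts and attribute `parsimony_length` (their sum).
#' @export
fitch_changes <- function(tree, alignment, outgroup = NULL) {
  stopifnot(inherits(tree, "phylo"))
  enc <- encode_alignment(alignment)
  phylo_taxon_check(tree, enc)
  if (!is.null(outgroup)) {
    if (!outgroup %in% tree$tip.label) stop_input("unknown outgroup '", outgroup, "'")
    tree <- ape::root(unroot_safe(tree), outgroup = outgroup, resolve.root = TRUE)
  } else if (!ape::is.rooted(tree)) {
    tree <- ape::root(tree, outgroup = tree$tip.label[1], resolve.root = TRUE)
    outgroup <- tree$tip.label[1]
  }
  tree$edge.length <- NULL
  ntip <- length(tree$tip.label)
  tipM <- enc$patterns[match(tree$tip.label, enc$taxa), , drop = FALSE]
  w <- enc$weights
  np <- length(w)

  tree <- ape::reorder.phylo(tree, "postorder")
  nnode <- ntip + tree$Nnode
  sets <- matrix(0L, nnode, np)
  sets[seq_len(ntip), ] <- tipM
  seen <- logical(nnode)
  for (i in seq_len(nrow(tree$edge))) {
    par <- tree$edge[i, 1]
    ch <- tree$edge[i, 2]
    cs <- sets[ch, ]
    if (!seen[par]) {
      sets[par, ] <- cs
      seen[par] <- TRUE
    } else {
      a <- bitwAnd(sets[par, ], cs)
      z <- a == 0L
      sets[par, ] <- ifelse(z, bitwOr(sets[par, ], cs), a)
    }
  }

  root <- tree$edge[nrow(tree$edge), 1]
  rs <- sets[root, ]
  if (!is.null(outgroup)) {
    og <- match(outgroup, tree$tip.label)
    pref <- bitwAnd(rs, sets[og, ])
    rs <- ifelse(pref != 0L, pref, rs)
  }
  state <- matrix(0L, nnode, np)
  state[root, ] <- low_bit(rs)
  changes <- numeric(nrow(tree$edge))
  for (i in rev(seq_len(nrow(tree$edge)))) { # preorder
    par <- tree$edge[i, 1]
    ch <- tree$edge[i, 2]
    keep <- bitwAnd(state[par, ], sets[ch, ]) != 0L
    state[ch, ] <- ifelse(keep, state[par, ], low_bit(sets[ch, ]))
    changes[i] <- sum(w[!keep])
  }
  tree$edge.length <- changes
  attr(tree, "parsimony_length") <- sum(changes)
  tree
}

#' Column-wise lower bound on the parsimony length
#'
#' Each site needs at least (number of distinct observed bases - 1) changes
#' on any tree; the sum over sites bounds every topology from below.
#'
#' @param alignment a [character_alignment()].
#' @return integer lower bound.
#' @export
parsimony_lower_bound <- function(alignment) {
  enc <- encode_alignment(alignment)
  per_pattern <- apply(enc$patterns, 2, function(col) {
    obs <- unique(col[col != 15L])
    states <- unique(unlist(lapply(obs, function(x) {
      which(bitwAnd(x, c(1L, 2L, 4L, 8L)) != 0L)
    })))
    max(0L, length(states) - 1L)
  })
  sum(per_pattern * enc$weights)
}

# --- topology enumeration / search ------------------------------------------

add_taxon_edges <- function(edges, edge_idx, leaf, internal) {
  u <- edges[edge_idx, 1]
  v <- edges[edge_idx, 2]
  edges[edge_idx, ] <- c(u, internal)
  rbind(edges, c(internal, v), c(internal, leaf))
}

edges_to_phylo <- function(edges, labels) {
  ntip <- length(labels)
  if (ntip == 2) {
    return(structure(
      list(
        edge = matrix(c(3L, 1L, 3L, 2L), 2, 2, byrow = TRUE),
        tip.label = labels, Nnode = 1L
      ),
      class = "phylo"
    ))
  }
  nnode <- max(edges)
  adj <- vector("list", nnode)
  for (i in seq_len(nrow(edges))) {
    u <- edges[i, 1]
    v <- edges[i, 2]
    adj[[u]] <- c(adj[[u]], v)
    adj[[v]] <- c(adj[[v]], u)
  }
  newid <- integer(nnode)
  newid[seq_len(ntip)] <- seq_len(ntip)
  nxt <- ntip
  emat <- matrix(0L, 0, 2)
  walk <- function(node, parent) {
    if (node > ntip) {
      nxt <<- nxt + 1L
      newid[node] <<- nxt
    }
    for (x in adj[[node]]) {
      if (x == parent) next
      walk(x, node)
      emat <<- rbind(emat, c(newid[node], newid[x]))
    }
  }
  root <- adj[[1]][1] # internal node next to tip 1: becomes the basal node
  walk(root, 1L)
  emat <- rbind(emat, c(newid[root], 1L))
  structure(
    list(edge = emat, tip.label = labels, Nnode = nnode - ntip),
    class = "phylo"
  )
}

#' Exact maximum-parsimony tree search
#'
#' Finds *all* minimum-length unrooted binary topologies by stepwise-addition
#' enumeration: exhaustive for up to 7 taxa, or branch-and-bound (pruning on
#' the monotone partial-tree Fitch length) for up to 12. Both modes return
#' the identical optimal set wherever both apply. Topologies are reported in
#' canonical sorted-Newick order; taxon input order never affects the
#' result.
#'
#' @param alignment a [character_alignment()] (or named character vector).
#' @param mode `"branch_and_bound"` (default) or `"exhaustive"`.
#' @return an `mp_search` object: `trees` (list of unrooted `phylo`),
#'   `newick` (canonical topology strings, sorted), `length` (optimal
#'   parsimony length), `n_trees`, `n_taxa`, `mode`.
#' @examples
#' aln <- c(A = "AAA", B = "AAT", C = "GAA", D = "GAT")
#' search_mp(aln)
#' @export
search_mp <- function(alignment, mode = c("branch_and_bound", "exhaustive")) {
  mode <- match.arg(mode)
  enc <- encode_alignment(alignment)
  n <- length(enc$taxa)
  limit <- if (mode == "exhaustive") 7L else 12L
  if (n > limit) {
    stop_input(
      "search_mp '", mode, "' handles at most ", limit, " taxa (got ", n,
      "); use mode = 'branch_and_bound'",
      if (mode == "branch_and_bound") " or a heuristic search tool" else ""
    )
  }

  taxa <- sort(enc$taxa) # label invariance: addition order fixed by labels
  tipM <- enc$patterns[match(taxa, enc$taxa), , drop = FALSE]
  w <- enc$weights

  if (n == 2) {
    # two taxa: length is the mismatch count over doubly-observed columns
    best <- sum(w[bitwAnd(tipM[1, ], tipM[2, ]) == 0L])
    found <- list(list(edges = matrix(c(1L, 2L), 1, 2), score = best))
  } else {
    base_edges <- matrix(c(n + 1L, 1L, n + 1L, 2L, n + 1L, 3L), 3, 2, byrow = TRUE)
    found <- list()
    best <- Inf
    prune <- mode == "branch_and_bound"
    rec <- function(edges, k, internal) {
      sc <- fitch_edges(edges, tipM, w)
      if (prune && sc > best) {
        return()
      }
      if (k > n) {
        if (sc <= best) {
          best <<- min(best, sc)
          found[[length(found) + 1L]] <<- list(edges = edges, score = sc)
        }
        return()
      }
      for (e in seq_len(nrow(edges))) {
        rec(add_taxon_edges(edges, e, k, internal), k + 1L, internal + 1L)
      }
    }
    rec(base_edges, 4L, n + 2L)
    best <- min(vapply(found, `[[`, numeric(1), "score"))
  }

  keep <- Filter(function(f) f$score == best, found)
  trees <- lapply(keep, function(f) edges_to_phylo(f$edges, taxa))
  nwk <- vapply(trees, canonical_topology_string, "")
  o <- order(nwk)
  structure(
    list(
      trees = trees[o], newick = nwk[o], length = as.integer(best),
      n_trees = length(trees), n_taxa = n, mode = mode
    ),
    class = "mp_search"
  )
}

#' @export
print.mp_search <- function(x, ...) {
  cat(
    "Maximum-parsimony search (", x$mode, "): ", x$n_taxa, " taxa, length ",
    x$length, ", ", x$n_trees, " optimal topolog",
    if (x$n_trees == 1) "y" else "ies", "\n",
    sep = ""
  )
  for (s in x$newick) cat(" ", s, "\n")
  invisible(x)
}

# canonical (rooting- and rotation-invariant) string of an unrooted topology:
# re-root on the alphabetically first tip, then sorted-subtree serialisation
canonical_topology_string <- function(tree) {
  t <- unroot_safe(tree)
  if (length(t$tip.label) > 2) {
    t <- ape::root(t, outgroup = sort(t$tip.label)[1], resolve.root = TRUE)
    t$edge.length <- NULL
  }
  to_newick(t)
}

#' Canonical Newick serialisation with optional outgroup rooting
#'
#' Writes a byte-stable Newick string: subtrees are ordered by their
#' smallest descendant taxon label at every node. With an `outgroup` the
#' tree is rooted on the outgroup branch; with an `alignment`, branch
#' annotations are the per-branch Fitch change counts of
#' [fitch_changes()] (all changes attach away from the outgroup at the
#' root).
#'
#' @param tree a `phylo`.
#' @param outgroup optional tip label ("used as an outgroup" display
#'   rooting).
#' @param alignment optional [character_alignment()] for change-count branch
#'   lengths.
#' @return a Newick string ending in `;`.
#' @examples
#' aln <- c(A = "AAA", B = "AAT", C = "GAA", D = "GAT")
#' sr <- search_mp(aln)
#' to_newick(sr$trees[[1]], outgroup = "A", alignment = aln)
#' @export
to_newick <- function(tree, outgroup = NULL, alignment = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (!is.null(outgroup) && !outgroup %in% tree$tip.label) {
    stop_input("unknown outgroup '", outgroup, "'")
  }
  if (!is.null(alignment)) {
    tree <- fitch_changes(tree, alignment, outgroup = outgroup)
  } else if (!is.null(outgroup)) {
    tree <- ape::root(ape::unroot(tree), outgroup = outgroup, resolve.root = TRUE)
    tree$edge.length <- NULL
  }
  ntip <- length(tree$tip.label)
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  fmt_len <- function(x) {
    if (x == as.integer(x)) sprintf("%d", as.integer(x)) else sprintf("%g", x)
  }
  rec <- function(node, elen) {
    suffix <- if (!is.null(tree$edge.length) && !is.na(elen)) {
      paste0(":", fmt_len(elen))
    } else {
      ""
    }
    if (node <= ntip) {
      return(list(
        str = paste0(tree$tip.label[node], suffix),
        key = tree$tip.label[node]
      ))
    }
    ch <- kids[[as.character(node)]]
    parts <- lapply(ch, function(e) {
      rec(tree$edge[e, 2], if (is.null(tree$edge.length)) NA else tree$edge.length[e])
    })
    keys <- vapply(parts, `[[`, "", "key")
    o <- order(keys)
    list(
      str = paste0(
        "(", paste(vapply(parts[o], `[[`, "", "str"), collapse = ","), ")",
        suffix
      ),
      key = min(keys)
    )
  }
  root <- setdiff(unique(tree$edge[, 1]), tree$edge[, 2])
  paste0(rec(root, NA)$str, ";")
}

#' Compare two trees by their unrooted split sets
#'
#' @param a,b `phylo` objects over the same taxa.
#' @return `TRUE` when the non-trivial bipartitions agree.
#' @export
same_topology <- function(a, b) {
  identical(
    canonical_topology_string(unroot_safe(a)),
    canonical_topology_string(unroot_safe(b))
  )
}

unroot_safe <- function(t) {
  t$edge.length <- NULL
  t$node.label <- NULL
  if (length(t$tip.label) > 2 && ape::is.rooted(t)) ape::unroot(t) else t
}
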