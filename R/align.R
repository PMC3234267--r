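#' Alignment scoring parameters
#'
#' Affine-gap scores for the locus-to-consensus semi-global alignment. A gap
#' of length k costs `gap_open + k * gap_extend`. Defaults: match +1,
#' mismatch -1, gap open -4, gap extend -1. `N` scores as a mismatch against
#' everything.
#'
#' @param match,mismatch,gap_open,gap_extend numeric scores (penalties
#'   negative).
#' @return an `alignment_params` list.
#' @export
alignment_params <- function(match = 1, mismatch = -1, gap_open = -4, gap_extend = -1) {
  if (gap_open > 0 || gap_extend > 0) stop_input("gap penalties must be <= 0")
  structure(
    list(
      match = match, mismatch = mismatch,
      gap_open = gap_open, gap_extend = gap_extend
    ),
    class = "alignment_params"
  )
}

align_substitution_matrix <- function(params) {
  b <- c(DNA_BASES, "N")
  m <- matrix(params$mismatch, 5, 5, dimnames = list(b, b))
  diag(m)[1:4] <- params$match # N-N is still a mismatch
  m
}

#' Align a locus to the family consensus (truncation-tolerant)
#'
#' Semi-global dynamic programming: the whole locus is aligned, end gaps on
#' the consensus side are free (so 5'- or 3'-truncated copies align to the
#' consensus interval they actually retain), and internal gaps carry affine
#' costs. Both orientations of the locus are aligned and the higher-scoring
#' one kept (ties favour `+`). The result is a bidirectional locus/consensus
#' position map.
#'
#' @param locus_seq locus nucleotide string over `A,C,G,T,N`.
#' @param consensus a [sine_consensus()] object (or plain sequence string).
#' @param locus_id identifier carried into the map.
#' @param params an [alignment_params()] object.
#' @param try_reverse also try the reverse complement (default `TRUE`).
#' @return an `alignment_map`: `locus_id`, `orientation_used` (`+`/`-`),
#'   `score`, `columns` (a `data.frame` of aligned columns `locus` /
#'   `consensus`, 0-based, `NA` on the gapped side; locus coordinates are in
#'   the *oriented* frame, i.e. of the reverse complement when
#'   `orientation_used == "-"`), `locus_length`, `consensus_length` and
#'   `aligned_fraction` (fraction of locus positions paired with a consensus
#'   column).
#' @examples
#' cons <- sine_consensus(strrep("ACGT", 20))
#' m <- align_to_consensus(substr(cons$sequence, 41, 80), cons, "half")
#' m$aligned_fraction
#' map_position(m, 0) # 0-based locus position 0 -> consensus position 40
#' @export
align_to_consensus <- function(locus_seq, consensus, locus_id = "locus",
                               params = alignment_params(), try_reverse = TRUE) {
  if (is.character(consensus)) consensus <- sine_consensus(consensus)
  stopifnot(inherits(consensus, "sine_consensus"))
  locus_seq <- toupper(locus_seq)
  if (!nzchar(locus_seq)) stop_input("locus sequence is empty")
  if (grepl("[^ACGTN]", locus_seq)) stop_input("locus sequence must be over A,C,G,T,N")

  mat <- align_substitution_matrix(params)
  one <- function(s) {
    Biostrings::pairwiseAlignment(
      pattern = s, subject = consensus$sequence, type = "global-local",
      substitutionMatrix = mat,
      gapOpening = -params$gap_open, gapExtension = -params$gap_extend
    )
  }

  fwd <- one(locus_seq)
  orientation <- "+"
  aln <- fwd
  used_seq <- locus_seq
  if (try_reverse) {
    rc <- revcomp(locus_seq)
    rev <- one(rc)
    if (Biostrings::score(rev) > Biostrings::score(fwd)) {
      aln <- rev
      orientation <- "-"
      used_seq <- rc
    }
  }

  pstr <- seq_to_chars(as.character(Biostrings::pattern(aln)))
  sstr <- seq_to_chars(as.character(Biostrings::subject(aln)))
  sstart <- Biostrings::start(Biostrings::subject(aln)) # 1-based consensus
  lp <- cumsum(pstr != "-") - 1L
  lp[pstr == "-"] <- NA_integer_
  rp <- (sstart - 1L) + cumsum(sstr != "-") - 1L
  rp[sstr == "-"] <- NA_integer_
  columns <- data.frame(locus = lp, consensus = rp)

  llen <- nchar(locus_seq)
  structure(
    list(
      locus_id = locus_id, orientation_used = orientation,
      score = Biostrings::score(aln), columns = columns,
      locus_length = llen, consensus_length = consensus$length,
      aligned_fraction = sum(!is.na(columns$locus) & !is.na(columns$consensus)) / llen,
      params = params
    ),
    class = "alignment_map"
  )
}

#' @export
print.alignment_map <- function(x, ...) {
  cat(
    "Alignment map '", x$locus_id, "': orientation ", x$orientation_used,
    ", score ", x$score, ", aligned fraction ",
    sprintf("%.3f", x$aligned_fraction), "\n",
    sep = ""
  )
  invisible(x)
}

#' Map a locus position to consensus coordinates (and back)
#'
#' `map_position()` returns the consensus column paired with a locus
#' position, or `NA` (the unaligned flag) when the position sits in a
#' locus-only insertion or outside the aligned span; `map_position_inverse()`
#' is the symmetric consensus-to-locus lookup. Positions are 0-based.
#'
#' @param map an `alignment_map`.
#' @param pos integer vector of 0-based positions (locus positions for
#'   `map_position`, consensus positions for the inverse).
#' @param frame for `map_position`: `"stored"` (default) interprets `pos` on
#'   the locus sequence as stored; `"oriented"` interprets it in the aligned
#'   frame (identical unless `orientation_used == "-"`). The inverse lookup
#'   returns positions in the same frame.
#' @return integer vector of mapped positions, `NA` where unaligned.
#' @export
map_position <- function(map, pos, frame = c("stored", "oriented")) {
  frame <- match.arg(frame)
  stopifnot(inherits(map, "alignment_map"))
  if (any(pos < 0 | pos >= map$locus_length)) {
    stop_input("locus position out of range [0, ", map$locus_length, ")")
  }
  opos <- if (frame == "stored" && map$orientation_used == "-") {
    map$locus_length - 1L - pos
  } else {
    pos
  }
  cc <- map$columns
  aligned <- cc[!is.na(cc$locus), , drop = FALSE]
  aligned$consensus[match(opos, aligned$locus)]
}

#' @rdname map_position
#' @export
map_position_inverse <- function(map, pos, frame = c("stored", "oriented")) {
  frame <- match.arg(frame)
  stopifnot(inherits(map, "alignment_map"))
  if (any(pos < 0 | pos >= map$consensus_length)) {
    stop_input("consensus position out of range [0, ", map$consensus_length, ")")
  }
  cc <- map$columns
  aligned <- cc[!is.na(cc$consensus), , drop = FALSE]
  lp <- aligned$locus[match(pos, aligned$consensus)]
  if (frame == "stored" && map$orientation_used == "-") {
    ifelse(is.na(lp), NA_integer_, map$locus_length - 1L - lp)
  } else {
    lp
  }
}

#' Align every locus of a set to the consensus
#'
#' @param loci named character vector of locus sequences.
#' @param consensus a [sine_consensus()].
#' @param params an [alignment_params()].
#' @param try_reverse try both orientations (default `TRUE`).
#' @return named list of `alignment_map` objects.
#' @export
align_family <- function(loci, consensus, params = alignment_params(),
                         try_reverse = TRUE) {
  maps <- lapply(names(loci), function(id) {
    align_to_consensus(loci[[id]], consensus, id, params, try_reverse)
  })
  setNames(maps, names(loci))
}

#' Export alignment maps as a tab-separated column list
#'
#' Long format `locus_id  orientation  locus_pos  consensus_pos` (0-based;
#' `.` marks the gapped side), one row per alignment column.
#'
#' @param maps list of `alignment_map` objects.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_alignment_maps <- function(maps, path) {
  rows <- lapply(maps, function(m) {
    data.frame(
      locus_id = m$locus_id, orientation = m$orientation_used,
      locus_pos = ifelse(is.na(m$columns$locus), ".", m$columns$locus),
      consensus_pos = ifelse(is.na(m$columns$consensus), ".", m$columns$consensus),
      stringsAsFactors = FALSE
    )
  })
  write.table(
    do.call(rbind, rows), path,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}
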