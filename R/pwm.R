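#' Read TRANSFAC-format nucleotide count matrices
#'
#' Parses the public TRANSFAC flat dialect: records separated by `//`, an
#' optional `ID`/`NA`/`AC` header, a `P0  A  C  G  T` column header and
#' numbered count rows (`01  8  0  0  0  A`), one row per motif position.
#'
#' @param path path to a matrix file, or a character vector of lines via
#'   `text`.
#' @param text optional character scalar/vector with the file content.
#' @return a named list of `motif_counts` objects (fields `motif_id`,
#'   `accession`, `counts`: an L x 4 matrix with columns `A,C,G,T`).
#'   An empty input yields an empty list. Malformed records (missing `P0`
#'   header, ragged or negative rows) raise a parse error naming the line.
#' @examples
#' m <- read_transfac(text = c(
#'   "ID  toy", "P0  A  C  G  T",
#'   "01  8  0  0  0  A", "02  8  0  0  0  A",
#'   "03  0  0  8  0  G", "04  0  0  0  8  T", "//"))
#' m$toy$counts
#' @export
read_transfac <- function(path = NULL, text = NULL) {
  lines <- if (!is.null(text)) {
    unlist(strsplit(text, "\n", fixed = TRUE))
  } else {
    readLines(path, warn = FALSE)
  }
  n <- length(lines)
  out <- list()
  rec_start <- 1L
  flush <- function(from, to) {
    block <- lines[from:to]
    keys <- sub("\\s.*$", "", trimws(block))
    # preamble / trailer blocks (VV version line, CC comments) carry no matrix
    if (all(keys %in% c("", "VV", "CC", "XX"))) {
      return(NULL)
    }
    parse_transfac_record(block, offset = from - 1L)
  }
  i <- 1L
  while (i <= n) {
    if (trimws(lines[i]) == "//") {
      if (i > rec_start) {
        m <- flush(rec_start, i - 1L)
        if (!is.null(m)) out[[m$motif_id]] <- m
      }
      rec_start <- i + 1L
    }
    i <- i + 1L
  }
  if (rec_start <= n) {
    m <- flush(rec_start, n)
    if (!is.null(m)) out[[m$motif_id]] <- m
  }
  out
}

parse_transfac_record <- function(block, offset = 0L) {
  err <- function(line_local, msg) {
    stop_input("TRANSFAC parse error at line ", offset + line_local, ": ", msg)
  }
  p0 <- grep("^P0\\b", trimws(block))
  if (!length(p0)) err(1L, "missing 'P0  A  C  G  T' header")
  p0 <- p0[1]
  hdr <- strsplit(trimws(block[p0]), "\\s+")[[1]]
  if (!identical(hdr[2:5], c("A", "C", "G", "T"))) {
    err(p0, "P0 header must list columns A C G T")
  }

  motif_id <- accession <- NA_character_
  for (j in seq_len(p0 - 1L)) {
    f <- strsplit(trimws(block[j]), "\\s+")[[1]]
    if (!length(f)) next
    if (f[1] == "AC" && length(f) > 1) accession <- f[2]
    if (f[1] %in% c("ID", "NA") && length(f) > 1 && is.na(motif_id)) {
      motif_id <- f[2]
    }
    if (f[1] == "NA" && length(f) > 1) motif_id <- f[2]
  }
  if (is.na(motif_id)) motif_id <- accession
  if (is.na(motif_id)) err(1L, "record has no ID/NA/AC identifier line")

  rows <- list()
  for (j in (p0 + 1L):length(block)) {
    ln <- trimws(block[j])
    if (!nzchar(ln)) next
    f <- strsplit(ln, "\\s+")[[1]]
    if (!grepl("^[0-9]+$", f[1])) break # XX, CC or other trailing fields
    if (length(f) < 5L) err(j, "count row has fewer than 4 count fields")
    cc <- suppressWarnings(as.numeric(f[2:5]))
    if (anyNA(cc)) err(j, "non-numeric count")
    if (any(cc < 0)) err(j, "negative count")
    rows[[length(rows) + 1L]] <- cc
  }
  if (length(rows) < 4L) err(p0, "motif must have at least 4 positions")
  counts <- do.call(rbind, rows)
  colnames(counts) <- DNA_BASES
  rownames(counts) <- NULL
  if (any(rowSums(counts) <= 0)) {
    err(p0, "every motif position needs at least one positive count")
  }
  structure(
    list(motif_id = motif_id, accession = accession, counts = counts),
    class = "motif_counts"
  )
}

#' @export
print.motif_counts <- function(x, ...) {
  cat(
    "Motif count matrix '", x$motif_id, "' (", nrow(x$counts),
    " positions", if (!is.na(x$accession)) paste0(", ", x$accession), ")\n",
    sep = ""
  )
  cat(" consensus:", chars_to_seq(DNA_BASES[apply(x$counts, 1, which.max)]), "\n")
  invisible(x)
}

#' Build a log-odds position weight matrix
#'
#' Per position, base probabilities are `(count + eps) / (N + 4 eps)` and the
#' score is `log2(p / background)` in bits. The detection threshold is set
#' relative to the achievable score range:
#' `threshold = min_score + f * (max_score - min_score)`.
#'
#' @param counts a `motif_counts` object (or bare L x 4 count matrix).
#' @param pseudocount per-base pseudocount `eps` (> 0; default 0.25).
#' @param background base composition `A,C,G,T` (strictly positive, summing
#'   to 1; default uniform).
#' @param threshold_fraction `f` in `[0, 1]`; `f = 1` accepts only windows
#'   matching the per-position optimum.
#' @return a `pwm` object: `motif_id`, `accession`, `counts`, `log_odds`
#'   (L x 4, bits), `background`, `pseudocount`, `threshold_fraction`,
#'   `min_score`, `max_score`, `threshold`, `length`.
#' @examples
#' m <- read_transfac(text = c(
#'   "ID  toy", "P0  A  C  G  T",
#'   "01  8  0  0  0  A", "02  8  0  0  0  A",
#'   "03  0  0  8  0  G", "04  0  0  0  8  T", "//"))
#' build_pwm(m$toy, threshold_fraction = 1)
#' @export
build_pwm <- function(counts, pseudocount = 0.25,
                      background = c(0.25, 0.25, 0.25, 0.25),
                      threshold_fraction = 0.8) {
  if (is.matrix(counts)) {
    counts <- structure(
      list(
        motif_id = "motif", accession = NA_character_,
        counts = `colnames<-`(counts, DNA_BASES)
      ),
      class = "motif_counts"
    )
  }
  stopifnot(inherits(counts, "motif_counts"))
  if (pseudocount <= 0) stop_input("pseudocount must be > 0")
  if (length(background) != 4 || any(background <= 0)) {
    stop_input("background must be 4 strictly positive probabilities")
  }
  background <- background / sum(background)
  if (threshold_fraction < 0 || threshold_fraction > 1) {
    stop_input("threshold_fraction must lie in [0, 1]")
  }
  cc <- counts$counts
  p <- (cc + pseudocount) / (rowSums(cc) + 4 * pseudocount)
  lo <- log2(sweep(p, 2, background, "/"))
  max_score <- sum(apply(lo, 1, max))
  min_score <- sum(apply(lo, 1, min))
  structure(
    list(
      motif_id = counts$motif_id, accession = counts$accession,
      counts = cc, log_odds = lo, background = background,
      pseudocount = pseudocount, threshold_fraction = threshold_fraction,
      min_score = min_score, max_score = max_score,
      threshold = min_score + threshold_fraction * (max_score - min_score),
      length = nrow(cc)
    ),
    class = "pwm"
  )
}

#' @export
print.pwm <- function(x, ...) {
  cat(
    "PWM '", x$motif_id, "': ", x$length, " positions, score range [",
    sprintf("%.2f", x$min_score), ", ", sprintf("%.2f", x$max_score),
    "] bits, threshold ", sprintf("%.2f", x$threshold),
    " (f = ", x$threshold_fraction, ")\n",
    sep = ""
  )
  invisible(x)
}

# per-window + strand scores; windows containing N score -Inf
pwm_window_scores <- function(pwm, chars) {
  L <- pwm$length
  n <- length(chars)
  if (n < L) {
    return(numeric(0))
  }
  code <- match(chars, DNA_BASES) # NA for N
  nw <- n - L + 1L
  scores <- numeric(nw)
  lo <- cbind(pwm$log_odds, -Inf) # 5th column: N
  code[is.na(code)] <- 5L
  for (j in seq_len(L)) {
    scores <- scores + lo[j, code[j:(j + nw - 1L)]]
  }
  scores
}

#' Scan a sequence for above-threshold PWM matches on both strands
#'
#' Scores every length-L window on the forward strand and, when
#' `both_strands`, on the reverse complement; windows containing `N` are
#' disqualified. Hits (score >= threshold) are reported in forward-strand
#' coordinates of the input sequence, sorted by (start, strand). A sequence
#' shorter than the motif yields an empty hit table.
#'
#' @param pwm a [build_pwm()] object.
#' @param seq nucleotide string over `A,C,G,T,N`.
#' @param both_strands scan the reverse complement too (default `TRUE`).
#' @param locus_id identifier recorded in the output.
#' @return a `data.frame` of hits: `locus_id`, `motif_id`, `start`, `end`
#'   (0-based half-open on the input sequence), `strand` (relative to the
#'   input sequence), `score` (bits), `matched_sequence` (as read on the hit
#'   strand).
#' @examples
#' m <- read_transfac(text = c(
#'   "ID  toy", "P0  A  C  G  T",
#'   "01  8  0  0  0  A", "02  8  0  0  0  A",
#'   "03  0  0  8  0  G", "04  0  0  0  8  T", "//"))
#' scan_sequence(build_pwm(m$toy, threshold_fraction = 1), "ACTT")
#' @export
scan_sequence <- function(pwm, seq, both_strands = TRUE, locus_id = "seq") {
  stopifnot(inherits(pwm, "pwm"))
  seq <- toupper(seq)
  if (grepl("[^ACGTN]", seq)) stop_input("sequence must be over A,C,G,T,N")
  chars <- seq_to_chars(seq)
  n <- length(chars)
  L <- pwm$length

  empty <- data.frame(
    locus_id = character(0), motif_id = character(0),
    start = integer(0), end = integer(0), strand = character(0),
    score = numeric(0), matched_sequence = character(0),
    stringsAsFactors = FALSE
  )
  if (n < L) {
    return(empty)
  }

  hit_rows <- function(scores, strand, scan_chars) {
    idx <- which(scores >= pwm$threshold)
    if (!length(idx)) {
      return(NULL)
    }
    start0 <- if (strand == "+") idx - 1L else n - (idx - 1L) - L
    data.frame(
      locus_id = locus_id, motif_id = pwm$motif_id,
      start = start0, end = start0 + L, strand = strand,
      score = scores[idx],
      matched_sequence = vapply(
        idx, function(i) chars_to_seq(scan_chars[i:(i + L - 1L)]), ""
      ),
      stringsAsFactors = FALSE
    )
  }

  res <- hit_rows(pwm_window_scores(pwm, chars), "+", chars)
  if (both_strands) {
    comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
    rc <- unname(rev(comp[chars]))
    res <- rbind(res, hit_rows(pwm_window_scores(pwm, rc), "-", rc))
  }
  if (is.null(res)) {
    return(empty)
  }
  res <- res[order(res$start, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Scan a set of loci with a set of PWMs
#'
#' @param pwms named list of [build_pwm()] objects.
#' @param loci named character vector of locus sequences.
#' @param both_strands scan both strands (default `TRUE`).
#' @return one combined hit `data.frame` (see [scan_sequence()]).
#' @export
scan_loci <- function(pwms, loci, both_strands = TRUE) {
  res <- list()
  for (id in names(loci)) {
    for (p in pwms) {
      res[[length(res) + 1L]] <- scan_sequence(
        p, loci[[id]],
        both_strands = both_strands, locus_id = id
      )
    }
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
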