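#' Construct a SINE consensus with domain annotation
#'
#' The consensus (master) sequence of a SINE family, together with an ordered
#' set of non-overlapping, labelled domain intervals. The canonical amniote
#' tRNA-derived family layout has four domains: a 5S rRNA-derived promoter, a
#' tRNA-derived region, a Deu-domain and a 3' tail.
#'
#' @param sequence nucleotide string over `A,C,G,T` (optionally `N`).
#' @param domains a `data.frame` with columns `label`, `start`, `end`
#'   (0-based half-open), non-overlapping and in increasing order; labels
#'   unique. `NULL` for an unannotated consensus.
#' @param name consensus name used in FASTA/BED output.
#' @return an object of class `sine_consensus` with fields `name`,
#'   `sequence`, `length`, `domains`.
#' @examples
#' cons <- sine_consensus(strrep("ACGT", 10),
#'   domains = data.frame(label = c("head", "tail"), start = c(0, 20), end = c(20, 40)))
#' cons
#' @export
sine_consensus <- function(sequence, domains = NULL, name = "consensus") {
  sequence <- toupper(as.character(sequence)[1])
  if (is.na(sequence) || nchar(sequence) == 0) stop_input("consensus sequence is empty")
  if (grepl("[^ACGTN]", sequence)) stop_input("consensus sequence contains non-ACGTN characters")
  n <- nchar(sequence)
  if (!is.null(domains)) {
    domains <- as.data.frame(domains)
    need <- c("label", "start", "end")
    if (!all(need %in% names(domains))) {
      stop_input("domains must have columns label, start, end")
    }
    domains <- domains[, need]
    domains$label <- as.character(domains$label)
    domains$start <- as.integer(domains$start)
    domains$end <- as.integer(domains$end)
    if (anyDuplicated(domains$label)) stop_input("domain labels must be unique")
    if (any(domains$start < 0 | domains$end > n | domains$start >= domains$end)) {
      stop_input("domain intervals must be non-empty and lie within [0, ", n, ")")
    }
    o <- order(domains$start)
    domains <- domains[o, , drop = FALSE]
    if (nrow(domains) > 1 && any(domains$start[-1] < domains$end[-nrow(domains)])) {
      stop_input("domain intervals must not overlap")
    }
    rownames(domains) <- NULL
  }
  structure(
    list(name = name, sequence = sequence, length = n, domains = domains),
    class = "sine_consensus"
  )
}

#' @export
print.sine_consensus <- function(x, ...) {
  cat("SINE consensus '", x$name, "': ", x$length, " nt\n", sep = "")
  if (!is.null(x$domains)) {
    for (i in seq_len(nrow(x$domains))) {
      d <- x$domains[i, ]
      cat(sprintf("  %-14s [%d, %d)\n", d$label, d$start, d$end))
    }
  } else {
    cat("  (no domain annotation)\n")
  }
  invisible(x)
}

#' Default four-domain layout of the simulated family consensus
#'
#' The family modelled here has a 570-nt consensus with, in order, a
#' 5S-promoter, a tRNA-derived region, a Deu-domain and a 3' tail. Only the
#' total length and the domain order are established for the real family; the
#' individual domain lengths used here (60, 120, 150, 240 nt) are package
#' defaults chosen to give a mid-consensus Deu-domain of realistic size.
#'
#' @param consensus_length total consensus length in nt; the default layout
#'   is scaled proportionally (rounded, last domain absorbs the remainder)
#'   when this is not 570.
#' @return a domain `data.frame` suitable for [sine_consensus()].
#' @export
default_domain_layout <- function(consensus_length = 570L) {
  lens <- c("5S_promoter" = 60L, "tRNA" = 120L, "Deu" = 150L, "tail3p" = 240L)
  if (consensus_length != 570L) {
    lens[] <- pmax(1L, as.integer(round(lens / 570 * consensus_length)))
    lens[length(lens)] <- consensus_length - sum(lens[-length(lens)])
    if (lens[length(lens)] < 1L) stop_input("consensus_length too short for four domains")
  }
  ends <- cumsum(lens)
  data.frame(
    label = names(lens),
    start = c(0L, ends[-length(ends)]),
    end = as.integer(ends),
    stringsAsFactors = FALSE
  )
}

#' Read / write a domain annotation table
#'
#' Tab-separated `label  start  end` (0-based half-open) with a header row.
#'
#' @param path file path.
#' @return `read_domain_table()` returns a domain `data.frame`;
#'   `write_domain_table()` returns `path` invisibly.
#' @export
read_domain_table <- function(path) {
  d <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("label", "start", "end") %in% names(d))) {
    stop_input("domain table must have header 'label\tstart\tend': ", path)
  }
  d
}

#' @rdname read_domain_table
#' @param domains a domain `data.frame`.
#' @export
write_domain_table <- function(domains, path) {
  write.table(domains, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read/write FASTA as plain named character vectors
#'
#' Thin wrappers over Biostrings FASTA I/O returning upper-case plain
#' character vectors named by record id.
#'
#' @param path file path.
#' @return `read_fasta()`: named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(toupper(as.character(x)), names(x))
}

#' @rdname read_fasta
#' @param seqs named character vector of sequences.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(unlist(seqs))
  names(x) <- names(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
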