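#' Build the virtual-primer read store
#'
#' Stores reads in a hash-table k-mer index: every exact 10-mer of every read
#' is indexed on both strands, which supports exact, one-mismatch
#' (pigeonhole over the two 10-mer halves of a 20-bp primer) and
#' IUPAC-ambiguous primer search. Pairing information is deliberately not
#' kept. Reads shorter than 20 bases cannot contain a primer and are skipped
#' with a warning.
#'
#' @param reads a [read_set()], or a character vector of read sequences.
#' @param ids optional id filter: only reads whose id is in `ids` are stored
#'   (the read partition used upstream of the method is left to the caller).
#' @return an object of class `read_store`.
#' @export
build_store <- function(reads, ids = NULL) {
  if (is.character(reads)) {
    reads <- read_set(id = paste0("r", seq_along(reads)), bases = reads,
                      quals = vapply(nchar(reads),
                                     function(n) strrep("I", n), ""))
  }
  if (!is.null(ids)) reads <- reads[reads$id %in% ids, , drop = FALSE]
  too_short <- nchar(reads$bases) < 20L
  if (any(too_short)) {
    warning(sum(too_short), " read(s) shorter than 20 bases skipped")
  }
  kept <- reads[!too_short, , drop = FALSE]
  ptr <- cpp_store_build(kept$bases, 20L)
  structure(list(ptr = ptr, reads = kept, n_skipped = sum(too_short)),
            class = "read_store")
}

#' @export
print.read_store <- function(x, ...) {
  cat(sprintf("<read_store: %d reads (%d skipped), 10-mer index, both strands>\n",
              nrow(x$reads), x$n_skipped))
  invisible(x)
}

#' Construct a virtual primer
#'
#' A 20-base terminal search key. Round-1 primers come straight from the
#' assembler's contigs and carry no ambiguity codes; later rounds may.
#'
#' @param seq 20-character IUPAC string.
#' @param end `"five_prime"` or `"three_prime"`.
#' @param round round number (>= 1).
#' @return object of class `virtual_primer`.
#' @export
virtual_primer <- function(seq, end = c("three_prime", "five_prime"),
                           round = 1L) {
  seq <- toupper(seq)
  end <- match.arg(end)
  if (nchar(seq) != 20L) stop("virtual primer must be 20 bases, got ",
                              nchar(seq))
  if (!.iupac_ok(seq)) stop("non-IUPAC character in primer")
  if (round == 1L && grepl("[^ACGTN]", seq)) {
    stop("round-1 primers must not contain ambiguity codes")
  }
  structure(list(seq = seq, end = end, round = as.integer(round)),
            class = "virtual_primer")
}

#' Find all reads containing a virtual primer
#'
#' Locates every (read, strand, offset) at which the primer matches with at
#' most `max_mismatch` mismatching positions under IUPAC matching ('N' in a
#' read matches nothing). Candidates come from exact hash lookups of the
#' primer's two 10-mer halves (ambiguous positions expanded, at most 16 keys
#' per half); the pigeonhole principle guarantees no <=1-mismatch occurrence
#' is missed. Each (read, strand, offset) is reported once.
#'
#' @param store a [build_store()] result.
#' @param primer a [virtual_primer()] or a 20-character string.
#' @param max_mismatch 0 or 1.
#' @return data.frame with columns `read` (id), `strand` (+1/-1), `offset`
#'   (0-based position of the primer in the strand-oriented read), and
#'   `mismatches`.
#' @export
find_primer_hits <- function(store, primer, max_mismatch = 0L) {
  stopifnot(inherits(store, "read_store"), max_mismatch %in% c(0L, 1L))
  pseq <- if (inherits(primer, "virtual_primer")) primer$seq else
    toupper(primer)
  if (nchar(pseq) != 20L) stop("primer length must be 20, got ", nchar(pseq))
  h <- cpp_find_primer(store$ptr, pseq, as.integer(max_mismatch))
  data.frame(read = store$reads$id[h$read], strand = h$strand,
             offset = h$offset, mismatches = h$mismatches,
             read_idx = h$read, stringsAsFactors = FALSE)
}

# strand-oriented read sequences for a hit table (minus-strand hits get the
# reverse complement, so primer coordinates run left to right)
oriented_reads <- function(store, hits) {
  cpp_oriented_seq(store$ptr, hits$read_idx, hits$strand)
}
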