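#' @useDynLib vpseq, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# IUPAC nucleotide sets as 4-bit masks (A=1, C=2, G=4, T=8). The six two-base
# codes are the only ones the tool ever writes; three/four-base codes are
# accepted on input.
.IUPAC_MASK <- c(
  A = 1L, C = 2L, G = 4L, T = 8L,
  M = 3L, R = 5L, S = 6L, V = 7L, W = 9L, Y = 10L, H = 11L, K = 12L,
  D = 13L, B = 14L, N = 15L
)

.AMBIG2 <- c(R = "AG", Y = "CT", K = "GT", M = "AC", S = "CG", W = "AT")

.iupac_ok <- function(seq) {
  !grepl(paste0("[^", paste(names(.IUPAC_MASK), collapse = ""), "]"), seq)
}

#' Reverse complement of IUPAC nucleotide strings
#'
#' Complements every IUPAC code correctly (R<->Y, K<->M, S and W self-
#' complementary, N->N) and reverses.
#'
#' @param seq character vector of sequences over the IUPAC alphabet.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(seq) {
  bad <- !.iupac_ok(toupper(seq))
  if (any(bad)) {
    stop("non-IUPAC character in sequence: ",
         paste(utils::head(seq[bad], 3), collapse = ", "))
  }
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
}

#' Does a read base satisfy an IUPAC pattern character?
#'
#' Vectorized over both arguments. A pattern character matches when the read
#' base lies in the nucleotide set it denotes; an 'N' in a read matches
#' nothing (so undetermined read bases never feed a consensus).
#'
#' @param pattern_char IUPAC character(s) (primer/contig side).
#' @param read_char read character(s), each one of A, C, G, T, N.
#' @return logical vector.
#' @export
iupac_match <- function(pattern_char, read_char) {
  p <- .IUPAC_MASK[toupper(pattern_char)]
  r <- c(A = 1L, C = 2L, G = 4L, T = 8L)[toupper(read_char)]
  r[is.na(r)] <- 0L
  if (anyNA(p)) stop("non-IUPAC pattern character")
  unname(bitwAnd(p, r) > 0L)
}

#' Create a read set
#'
#' Columnar container for sequencing reads: parallel vectors of ids, base
#' strings and Phred+33 quality strings.
#'
#' @param id,bases,quals character vectors of equal length; `quals[i]` must
#'   have the same number of characters as `bases[i]`.
#' @return a `read_set` (data.frame with columns id, bases, quals).
#' @export
read_set <- function(id = character(), bases = character(),
                     quals = character()) {
  stopifnot(length(id) == length(bases), length(bases) == length(quals))
  if (any(!nzchar(id))) stop("read ids must be non-empty")
  bases <- toupper(bases)
  bad <- nchar(bases) != nchar(quals)
  if (any(bad)) {
    stop("bases/quality length mismatch for read ", id[which(bad)[1]])
  }
  structure(
    data.frame(id = as.character(id), bases = bases,
               quals = as.character(quals), stringsAsFactors = FALSE),
    class = c("read_set", "data.frame")
  )
}

#' Decode a Phred+33 quality string to integer scores
#' @param qual character vector of quality strings.
#' @return list of integer vectors (one per string).
#' @export
phred_to_int <- function(qual) {
  lapply(qual, function(q) utf8ToInt(q) - 33L)
}

#' Encode integer Phred scores as a Phred+33 string
#' @param q integer vector of scores (0..93).
#' @return single quality string.
#' @export
int_to_phred <- function(q) {
  intToUtf8(as.integer(q) + 33L)
}

#' Read a FASTQ file
#'
#' Strict four-line-record Phred+33 reader. Bases are uppercased; a record
#' whose quality string length differs from its bases is a format error that
#' names the record.
#'
#' @param path FASTQ file.
#' @return a [read_set()].
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ln <- readLines(path)
  if (length(ln) == 0) return(read_set())
  if (length(ln) %% 4 != 0) {
    stop("malformed FASTQ (", path, "): line count not a multiple of 4")
  }
  hd <- ln[seq(1, length(ln), by = 4)]
  sq <- toupper(ln[seq(2, length(ln), by = 4)])
  qu <- ln[seq(4, length(ln), by = 4)]
  if (any(substr(hd, 1, 1) != "@")) {
    i <- which(substr(hd, 1, 1) != "@")[1]
    stop("malformed FASTQ record at line ", (i - 1) * 4 + 1, ": ", hd[i])
  }
  id <- sub("^@", "", hd)
  bad <- nchar(sq) != nchar(qu)
  if (any(bad)) {
    stop("FASTQ record '", id[which(bad)[1]],
         "': bases and qualities differ in length")
  }
  read_set(id = id, bases = sq, quals = qu)
}

#' Write a read set as FASTQ (Phred+33)
#' @param reads a [read_set()].
#' @param path output file.
#' @export
write_fastq <- function(reads, path) {
  out <- if (nrow(reads) > 0) {
    paste0("@", reads$id, "\n", reads$bases, "\n+\n", reads$quals)
  } else {
    character(0)
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(out, con, sep = "\n")
  invisible(path)
}

#' Read a FASTA file as a named character vector
#' @param path FASTA file.
#' @return named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path, format = "fasta")
  out <- toupper(as.character(x))
  names(out) <- names(x)
  out
}

#' Write sequences as FASTA (70-column wrap)
#' @param seqs named character vector.
#' @param path output file.
#' @export
write_fasta <- function(seqs, path) {
  force(seqs)
  x <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(x, path, format = "fasta", width = 70L)
  invisible(path)
}

#' Construct a contig with provenance
#'
#' A contig records which span of its bases is the original (pre-extension)
#' sequence; elongated bases lie outside `core_span`.
#'
#' @param id contig id.
#' @param bases IUPAC sequence.
#' @param core_span integer length-2 vector, half-open 0-based `[start, end)`;
#'   defaults to the whole sequence.
#' @return object of class `vp_contig`.
#' @export
contig <- function(id, bases, core_span = c(0L, nchar(bases))) {
  bases <- toupper(bases)
  if (!.iupac_ok(bases)) stop("contig ", id, ": non-IUPAC character")
  s <- as.integer(core_span[1]); e <- as.integer(core_span[2])
  if (!(s >= 0 && s < e && e <= nchar(bases))) {
    stop("contig ", id, ": invalid core_span")
  }
  structure(list(id = id, bases = bases, core_span = c(s, e)),
            class = "vp_contig")
}

#' @export
print.vp_contig <- function(x, ...) {
  cat(sprintf("<vp_contig %s: %d bp, core %d-%d, +%d 5', +%d 3'>\n",
              x$id, nchar(x$bases), x$core_span[1], x$core_span[2],
              x$core_span[1], nchar(x$bases) - x$core_span[2]))
  invisible(x)
}

core_seq <- function(ctg) {
  substr(ctg$bases, ctg$core_span[1] + 1L, ctg$core_span[2])
}
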