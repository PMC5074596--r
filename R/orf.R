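.STOPS <- c("TAA", "TAG", "TGA")

#' ORF classifier parameters
#'
#' @param nterm_prox_aa a protein alignment starting within this many amino
#'   acids of the subject N-terminus counts as start evidence.
#' @param min_utr5 if positive, an in-frame ATG with at least this many
#'   nucleotides of open 5' sequence upstream counts as start evidence even
#'   without an upstream in-frame stop. Disabled (0) by default: without an
#'   upstream stop, a 5'-truncated CDS fragment would otherwise classify as
#'   full-length through any internal ATG.
#' @return list of class `orf_params`.
#' @export
orf_params <- function(nterm_prox_aa = 15L, min_utr5 = 0L) {
  structure(list(nterm_prox_aa = as.integer(nterm_prox_aa),
                 min_utr5 = as.integer(min_utr5)), class = "orf_params")
}

#' Construct a protein-alignment hit (blastx-style)
#'
#' Query coordinates are 1-based on the contig; `qstart > qend` denotes a
#' minus-frame hit. Subject coordinates are amino acids.
#'
#' @param query contig id.
#' @param qstart,qend aligned query span (nt).
#' @param sstart,send aligned subject span (aa).
#' @param evalue,bitscore alignment statistics.
#' @return list of class `protein_hit`.
#' @export
protein_hit <- function(query, qstart, qend, sstart, send, evalue = 0,
                        bitscore = 0) {
  stopifnot(evalue >= 0)
  structure(list(query = query, qstart = as.integer(qstart),
                 qend = as.integer(qend), sstart = as.integer(sstart),
                 send = as.integer(send), evalue = evalue,
                 bitscore = bitscore), class = "protein_hit")
}

#' Read BLAST tabular (outfmt-6) hits, keeping the best hit per query
#'
#' Standard 12 columns: qseqid sseqid pident length mismatch gapopen qstart
#' qend sstart send evalue bitscore. Best hit = lowest e-value, ties broken
#' by highest bitscore.
#'
#' @param path tab-separated hits file (comment lines starting `#` skipped).
#' @return named list of [protein_hit()], one per query.
#' @export
read_blast_hits <- function(path) {
  tb <- utils::read.table(path, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE)
  if (ncol(tb) < 12) stop("expected 12 tab-separated columns in ", path)
  names(tb)[1:12] <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                       "gapopen", "qstart", "qend", "sstart", "send",
                       "evalue", "bitscore")
  tb <- tb[order(tb$qseqid, tb$evalue, -tb$bitscore), ]
  tb <- tb[!duplicated(tb$qseqid), ]
  out <- lapply(seq_len(nrow(tb)), function(i) {
    protein_hit(tb$qseqid[i], tb$qstart[i], tb$qend[i], tb$sstart[i],
                tb$send[i], tb$evalue[i], tb$bitscore[i])
  })
  names(out) <- tb$qseqid
  out
}

# in-frame codon starts (1-based) in seq for frame offset fo (0..2)
.codons_at <- function(seq, fo) {
  L <- nchar(seq)
  if (L - 2L < 1L + fo) return(character(0))
  starts <- seq.int(1L + fo, L - 2L, by = 3L)
  substring(seq, starts, starts + 2L)
}

# maximal open (stop-free) codon segments for one frame offset;
# returns data.frame: first/last codon index, left/right bounded by a stop
.open_segments <- function(codons) {
  n <- length(codons)
  is_stop <- codons %in% .STOPS
  bounds <- c(0L, which(is_stop), n + 1L)
  segs <- list()
  for (i in seq_len(length(bounds) - 1L)) {
    a <- bounds[i] + 1L
    b <- bounds[i + 1L] - 1L
    if (a > b) next
    segs[[length(segs) + 1L]] <- data.frame(
      from = a, to = b,
      left_stop = bounds[i] > 0L,
      right_stop = bounds[i + 1L] <= n)
  }
  if (length(segs) == 0) {
    return(data.frame(from = integer(), to = integer(),
                      left_stop = logical(), right_stop = logical()))
  }
  do.call(rbind, segs)
}

#' Classify the ORF completeness of a contig
#'
#' With a protein hit, the classifier works in the hit's reading frame:
#' the 3' end is complete iff an in-frame stop codon occurs at or after the
#' aligned query end; the 5' end is complete iff an in-frame ATG lies at or
#' before the aligned query start and either an in-frame stop sits upstream
#' of that ATG or the alignment starts within `nterm_prox_aa` residues of
#' the subject N-terminus. Without a hit, all six frames are scanned for
#' maximal stop-free segments; the candidate with the longest potential
#' coding stretch is classified: start evidence requires an in-frame ATG
#' with an upstream in-frame stop (or, if `min_utr5 > 0`, that much open 5'
#' sequence), stop evidence requires the segment to end at a stop codon.
#'
#' @param ctg a [contig()], or a single (optionally named) sequence string.
#' @param hit optional [protein_hit()] for this contig.
#' @param params an [orf_params()].
#' @return list of class `orf_call`: `contig`, `class` (one of
#'   `full_length`, `five_prime_partial`, `three_prime_partial`,
#'   `internal`), `frame` (+1..+3 / -1..-3), `start`, `stop` (1-based
#'   offsets in the oriented sequence, NA when absent), `evidence`.
#' @export
classify_orf <- function(ctg, hit = NULL, params = orf_params()) {
  if (inherits(ctg, "vp_contig")) {
    id <- ctg$id; seq <- ctg$bases
  } else {
    id <- names(ctg) %||% "contig"; seq <- toupper(as.character(ctg))
  }
  if (nchar(seq) < 3) stop("contig shorter than one codon")
  if (!is.null(hit)) return(.classify_with_hit(id, seq, hit, params))
  best <- NULL
  for (strand in c(1L, -1L)) {
    s <- if (strand == 1L) seq else revcomp(seq)
    for (fo in 0:2) {
      codons <- .codons_at(s, fo)
      segs <- .open_segments(codons)
      for (k in seq_len(nrow(segs))) {
        seg <- segs[k, ]
        idx <- seg$from:seg$to
        atg <- idx[codons[idx] == "ATG"]
        cand_from <- if (length(atg)) atg[1] else seg$from
        # coding stretch from the (first) ATG, or the whole open segment
        # for ATG-less fragments; a terminating stop codon counts
        cds_len <- (seg$to - cand_from + 1L) * 3L +
          if (seg$right_stop) 3L else 0L
        ev <- as.integer(length(atg) > 0) + as.integer(seg$right_stop)
        # featureless open frames (no ATG, no stop) only stand when nothing
        # with coding evidence exists anywhere
        if (is.null(best) || (ev > 0) > (best$ev > 0) ||
            ((ev > 0) == (best$ev > 0) &&
             (cds_len > best$cds_len ||
              (cds_len == best$cds_len && ev > best$ev)))) {
          best <- list(strand = strand, fo = fo, seg = seg,
                       atg = if (length(atg)) atg[1] else NA_integer_,
                       cds_len = cds_len, ev = ev, seqlen = nchar(s))
        }
      }
    }
  }
  if (is.null(best)) {
    return(structure(list(contig = id, class = "internal", frame = 1L,
                          start = NA_integer_, stop = NA_integer_,
                          evidence = "longest_orf"), class = "orf_call"))
  }
  start_nt <- if (!is.na(best$atg)) best$fo + (best$atg - 1L) * 3L + 1L else
    NA_integer_
  stop_nt <- if (best$seg$right_stop) best$fo + best$seg$to * 3L + 1L else
    NA_integer_
  has_start <- !is.na(best$atg) &&
    (best$seg$left_stop ||
       (params$min_utr5 > 0L && (start_nt - 1L) >= params$min_utr5))
  has_stop <- best$seg$right_stop
  cls <- if (has_start && has_stop) "full_length"
    else if (has_start) "three_prime_partial"
    else if (has_stop) "five_prime_partial"
    else "internal"
  structure(list(contig = id, class = cls,
                 frame = best$strand * (best$fo + 1L),
                 start = start_nt, stop = stop_nt, evidence = "longest_orf"),
            class = "orf_call")
}

.classify_with_hit <- function(id, seq, hit, params) {
  L <- nchar(seq)
  minus <- hit$qstart > hit$qend
  if (minus) {
    s <- revcomp(seq)
    qs <- L - hit$qstart + 1L
    qe <- L - hit$qend + 1L
  } else {
    s <- seq
    qs <- hit$qstart
    qe <- hit$qend
  }
  fo <- (qs - 1L) %% 3L
  codons <- .codons_at(s, fo)
  starts_nt <- fo + (seq_along(codons) - 1L) * 3L + 1L
  is_stop <- codons %in% .STOPS
  # 3' side: an in-frame stop whose codon begins at or after the last
  # aligned codon's end
  stop_after <- which(is_stop & starts_nt >= qe - 2L)
  has_stop <- length(stop_after) > 0
  stop_nt <- if (has_stop) starts_nt[stop_after[1]] else NA_integer_
  # 5' side: first in-frame ATG of the open region containing the alignment
  # start
  before <- which(starts_nt <= qs)
  stops_before <- before[is_stop[before]]
  region_from <- if (length(stops_before)) max(stops_before) + 1L else 1L
  atg_idx <- before[codons[before] == "ATG" & seq_along(codons)[before] >=
                      region_from]
  has_atg <- length(atg_idx) > 0
  start_nt <- if (has_atg) starts_nt[atg_idx[1]] else NA_integer_
  start_evidence <- has_atg &&
    (length(stops_before) > 0 || hit$sstart <= params$nterm_prox_aa ||
       (params$min_utr5 > 0L && has_atg && (start_nt - 1L) >= params$min_utr5))
  cls <- if (start_evidence && has_stop) "full_length"
    else if (start_evidence) "three_prime_partial"
    else if (has_stop) "five_prime_partial"
    else "internal"
  structure(list(contig = id, class = cls,
                 frame = (if (minus) -1L else 1L) * (fo + 1L),
                 start = start_nt, stop = stop_nt,
                 evidence = "alignment_guided"), class = "orf_call")
}

#' Tally ORF-completeness classes
#'
#' @param calls list of [classify_orf()] results.
#' @return data.frame of counts per class plus the full-length fraction
#'   (attribute `fraction_full_length`, also a column).
#' @export
completeness_table <- function(calls) {
  classes <- c("full_length", "five_prime_partial", "three_prime_partial",
               "internal")
  got <- vapply(calls, function(x) x$class, "")
  counts <- vapply(classes, function(cl) sum(got == cl), 0L)
  frac <- if (length(got)) unname(counts["full_length"]) / length(got) else 0
  out <- data.frame(class = classes, count = unname(counts),
                    stringsAsFactors = FALSE)
  attr(out, "fraction_full_length") <- frac
  out
}
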