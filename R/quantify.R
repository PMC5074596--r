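#' Assign reads to contigs with quality-aware fractional counting
#'
#' Each read is matched against the contigs (both strands, full containment)
#' allowing at most one penalized mismatch, where a mismatch at a read
#' position with quality below `qmin` carries no penalty. A read matching
#' `k > 1` contigs contributes `1/k` of a fragment to each; unmatched reads
#' are uncounted. Candidate placements are seeded from the read's exact
#' 10-mers (every 10 bases plus the final window) against the contig k-mer
#' index.
#'
#' @param reads a [read_set()].
#' @param contigs named character vector of contig sequences, or a
#'   prebuilt contig store from [build_store()].
#' @param max_mismatch penalized-mismatch budget.
#' @param qmin Phred score below which mismatches are free.
#' @return named numeric vector of fractional fragment counts per contig,
#'   with attribute `n_assigned` (number of reads placed).
#' @export
assign_reads <- function(reads, contigs, max_mismatch = 1L, qmin = 20L) {
  if (inherits(contigs, "read_store")) {
    store <- contigs
    nm <- store$reads$id
  } else {
    nm <- names(contigs) %||% paste0("contig", seq_along(contigs))
    store <- build_store(read_set(
      id = nm, bases = as.character(contigs),
      quals = vapply(nchar(contigs), function(n) strrep("I", n), "")))
  }
  counts <- stats::setNames(numeric(length(nm)), nm)
  if (nrow(reads) == 0) {
    attr(counts, "n_assigned") <- 0L
    return(counts)
  }
  hits <- cpp_map_reads(store$ptr, reads$bases, reads$quals,
                        as.integer(max_mismatch), as.integer(qmin))
  if (nrow(hits) > 0) {
    k <- table(hits$read)
    w <- 1 / as.numeric(k[as.character(hits$read)])
    add <- tapply(w, nm[hits$contig], sum)
    counts[names(add)] <- counts[names(add)] + as.numeric(add)
  }
  attr(counts, "n_assigned") <- length(unique(hits$read))
  counts
}

#' Fragments per kilobase of transcript per million mapped fragments
#'
#' @param count fragments assigned to the contig.
#' @param contig_len contig length in bp.
#' @param total_assigned total assigned fragments in the sample.
#' @return FPKM value: `1e9 * count / (contig_len * total_assigned)`.
#' @export
fpkm <- function(count, contig_len, total_assigned) {
  if (any(total_assigned == 0)) stop("total_assigned must be positive")
  if (any(contig_len <= 0)) stop("contig_len must be positive")
  1e9 * count / (contig_len * total_assigned)
}

#' Classify differential expression between two samples
#'
#' Contigs with FPKM at or below `min_fpkm` in both samples are
#' `not_expressed`; otherwise the log2 ratio
#' `log2((fpkm_a + eps) / (fpkm_b + eps))` is compared against
#' `+/- log_cut` (strict inequalities).
#'
#' @param fpkm_a,fpkm_b FPKM in samples A and B (vectorized).
#' @param min_fpkm expression floor.
#' @param log_cut absolute log2-ratio cutoff.
#' @param eps pseudo-FPKM avoiding log of zero.
#' @return character vector: `up_in_A`, `up_in_B`, `not_DE`, or
#'   `not_expressed`.
#' @export
de_classify <- function(fpkm_a, fpkm_b, min_fpkm = 0.1, log_cut = 2.0,
                        eps = 0.01) {
  lr <- log2((fpkm_a + eps) / (fpkm_b + eps))
  out <- ifelse(fpkm_a <= min_fpkm & fpkm_b <= min_fpkm, "not_expressed",
         ifelse(lr > log_cut, "up_in_A",
         ifelse(lr < -log_cut, "up_in_B", "not_DE")))
  out
}

#' GO-term enrichment score between two gene sets
#'
#' `log2( ((n_a + pseudo)/total_a) / ((n_b + pseudo)/total_b) )`, the
#' pseudo-count (0.05) rescuing zero numerators. Positive scores mean the
#' term is enriched in set A; swapping the sets negates the score.
#'
#' @param n_a,n_b genes in set A / set B annotated with the term
#'   (vectorized).
#' @param total_a,total_b sizes of the annotated gene sets.
#' @param pseudo numerator pseudo-count.
#' @return enrichment score(s) in log2 units.
#' @export
enrich_score <- function(n_a, n_b, total_a, total_b, pseudo = 0.05) {
  if (any(total_a <= 0) || any(total_b <= 0)) {
    stop("set totals must be positive")
  }
  log2(((n_a + pseudo) / total_a) / ((n_b + pseudo) / total_b))
}

#' Per-term enrichment table from a contig-to-GO annotation
#'
#' @param annot data.frame with columns `id` (contig) and `go` (term), one
#'   term per row.
#' @param set_a,set_b character vectors of contig ids (e.g. tissue-specific
#'   gene sets).
#' @param pseudo numerator pseudo-count.
#' @return data.frame with per-term counts and the enrichment score in both
#'   orientations (`score_ab`, `score_ba = -score_ab`).
#' @export
enrich_table <- function(annot, set_a, set_b, pseudo = 0.05) {
  a <- annot[annot$id %in% set_a, ]
  b <- annot[annot$id %in% set_b, ]
  total_a <- length(unique(a$id))
  total_b <- length(unique(b$id))
  if (total_a == 0 || total_b == 0) {
    stop("both sets must contain annotated contigs")
  }
  terms <- sort(unique(annot$go))
  n_a <- vapply(terms, function(t) length(unique(a$id[a$go == t])), 0L)
  n_b <- vapply(terms, function(t) length(unique(b$id[b$go == t])), 0L)
  s <- enrich_score(n_a, n_b, total_a, total_b, pseudo)
  data.frame(go = terms, n_a = n_a, n_b = n_b, total_a = total_a,
             total_b = total_b, score_ab = s, score_ba = -s,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Two-sample expression table (counts, FPKM, DE class)
#'
#' @param contigs named character vector of contig sequences.
#' @param reads_a,reads_b [read_set()]s for the two samples.
#' @param ... passed to [de_classify()].
#' @return data.frame with per-contig fragment counts, FPKM values, log2
#'   ratio and DE class.
#' @export
expression_table <- function(contigs, reads_a, reads_b, ...) {
  ca <- assign_reads(reads_a, contigs)
  cb <- assign_reads(reads_b, contigs)
  len <- nchar(contigs)
  ta <- sum(ca); tb <- sum(cb)
  fa <- if (ta > 0) fpkm(ca, len, ta) else ca * 0
  fb <- if (tb > 0) fpkm(cb, len, tb) else cb * 0
  eps <- list(...)$eps %||% 0.01
  data.frame(id = names(contigs), length = len,
             count_a = as.numeric(ca), count_b = as.numeric(cb),
             fpkm_a = as.numeric(fa), fpkm_b = as.numeric(fb),
             log2_ratio = log2((as.numeric(fa) + eps) /
                                 (as.numeric(fb) + eps)),
             de_class = de_classify(as.numeric(fa), as.numeric(fb), ...),
             row.names = NULL, stringsAsFactors = FALSE)
}
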