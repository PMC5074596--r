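#' Read-cleaning parameters
#'
#' Controls PCR-duplicate detection (identical 10-base prefix plus strictly
#' more than 90% whole-read identity) and quality-driven trimming (start at
#' the first run of five Phred scores above 30; stop when the cumulative
#' fraction of accurately called bases drops to 0.5).
#'
#' @param dup_prefix_len prefix length that must be identical (bp).
#' @param dup_similarity whole-read identity that must be strictly exceeded.
#' @param start_run_len length of the quality run opening base calling.
#' @param start_q Phred score the run must strictly exceed.
#' @param accurate_q Phred score at or above which a base counts as
#'   accurately called.
#' @param stop_fraction base calling stops once the running accurate fraction
#'   is at or below this value.
#' @param min_len minimum surviving read length (shorter reads are dropped;
#'   reads below the duplicate-prefix length cannot enter any index).
#' @return list of class `clean_params`.
#' @export
clean_params <- function(dup_prefix_len = 10L, dup_similarity = 0.90,
                         start_run_len = 5L, start_q = 30L,
                         accurate_q = 30L, stop_fraction = 0.5,
                         min_len = 10L) {
  stopifnot(dup_prefix_len > 0, dup_similarity > 0, dup_similarity <= 1,
            start_run_len > 0, start_q > 0, accurate_q > 0,
            stop_fraction > 0, stop_fraction <= 1)
  structure(list(dup_prefix_len = as.integer(dup_prefix_len),
                 dup_similarity = dup_similarity,
                 start_run_len = as.integer(start_run_len),
                 start_q = as.integer(start_q),
                 accurate_q = as.integer(accurate_q),
                 stop_fraction = stop_fraction,
                 min_len = as.integer(min_len)),
            class = "clean_params")
}

.identity_min_len <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  if (n == 0) return(0)
  av <- utf8ToInt(substr(a, 1, n))
  bv <- utf8ToInt(substr(b, 1, n))
  sum(av == bv) / n
}

#' Are two reads PCR duplicates?
#'
#' True iff the first `dup_prefix_len` bases are identical and the positional
#' identity over the shorter read's length strictly exceeds
#' `dup_similarity`. No alignment is attempted: fixed-length Illumina reads
#' are compared position by position.
#'
#' @param a,b single rows of a [read_set()] (or lists with `$bases`).
#' @param p a [clean_params()].
#' @return logical scalar.
#' @export
is_pcr_duplicate <- function(a, b, p = clean_params()) {
  ab <- a$bases; bb <- b$bases
  k <- p$dup_prefix_len
  if (nchar(ab) < k || nchar(bb) < k) return(FALSE)
  if (substr(ab, 1, k) != substr(bb, 1, k)) return(FALSE)
  .identity_min_len(ab, bb) > p$dup_similarity
}

#' Remove PCR duplicates from a read set
#'
#' Reads are bucketed by their `dup_prefix_len`-base prefix; within a bucket
#' a read is dropped iff it duplicates an earlier retained read. The first
#' occurrence is always kept, and the operation is idempotent.
#'
#' @param reads a [read_set()].
#' @param p a [clean_params()].
#' @return the deduplicated [read_set()], with attribute `n_dropped`.
#' @export
dedupe <- function(reads, p = clean_params()) {
  n <- nrow(reads)
  if (n <= 1) return(reads)
  keep <- rep(TRUE, n)
  pref <- substr(reads$bases, 1, p$dup_prefix_len)
  buckets <- split(seq_len(n), pref)
  for (idx in buckets) {
    if (length(idx) < 2) next
    kept <- idx[1]
    for (i in idx[-1]) {
      dup <- FALSE
      for (j in kept) {
        if (is_pcr_duplicate(reads[i, ], reads[j, ], p)) { dup <- TRUE; break }
      }
      if (dup) keep[i] <- FALSE else kept <- c(kept, i)
    }
  }
  out <- reads[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- n - nrow(out)
  out
}

#' Quality-trim one read
#'
#' Base calling runs 5' to 3': it starts at the first position opening a run
#' of `start_run_len` qualities strictly above `start_q`, and stops just
#' before the first position at which the cumulative fraction of bases with
#' quality `>= accurate_q` (counted from the start position) falls to
#' `stop_fraction` or below. Reads with no start window, or trimmed below
#' `min_len`, are dropped.
#'
#' @param r one row of a [read_set()] (or list with `$id`, `$bases`,
#'   `$quals`).
#' @param p a [clean_params()].
#' @return a one-row [read_set()], or `NULL` when the read is dropped.
#' @export
trim_read <- function(r, p = clean_params()) {
  q <- utf8ToInt(r$quals) - 33L
  n <- length(q)
  if (n < p$start_run_len) return(NULL)
  good <- q > p$start_q
  # first index s with start_run_len consecutive TRUEs
  run <- 0L; s <- NA_integer_
  for (i in seq_len(n)) {
    run <- if (good[i]) run + 1L else 0L
    if (run == p$start_run_len) { s <- i - p$start_run_len + 1L; break }
  }
  if (is.na(s)) return(NULL)
  acc <- cumsum(q[s:n] >= p$accurate_q)
  frac <- acc / seq_along(acc)
  bad <- which(frac <= p$stop_fraction)
  e <- if (length(bad)) s + bad[1] - 2L else n  # last kept index
  if (e - s + 1L < p$min_len) return(NULL)
  read_set(id = r$id,
           bases = substr(r$bases, s, e),
           quals = substr(r$quals, s, e))
}

#' Clean a read set: deduplicate then quality-trim
#'
#' @param reads a [read_set()].
#' @param p a [clean_params()].
#' @param verbose log counts of dropped reads.
#' @return cleaned [read_set()] with attributes `n_duplicates` and
#'   `n_low_quality`.
#' @export
clean_reads <- function(reads, p = clean_params(), verbose = FALSE) {
  dd <- dedupe(reads, p)
  n_dup <- attr(dd, "n_dropped") %||% 0L
  kept <- vector("list", nrow(dd))
  for (i in seq_len(nrow(dd))) kept[[i]] <- trim_read(dd[i, ], p)
  keep <- !vapply(kept, is.null, logical(1))
  out <- if (any(keep)) do.call(rbind, kept[keep]) else read_set()
  out <- structure(out, class = c("read_set", "data.frame"))
  rownames(out) <- NULL
  attr(out, "n_duplicates") <- n_dup
  attr(out, "n_low_quality") <- nrow(dd) - nrow(out)
  if (verbose) {
    message(sprintf("clean_reads: %d in, %d duplicates, %d low-quality, %d out",
                    nrow(reads), n_dup, nrow(dd) - nrow(out), nrow(out)))
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
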