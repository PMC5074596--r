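# Independent reference implementations used as oracles. They share no code
# with the package internals beyond trivial primitives.

IUPAC_SET <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), K = c("G", "T"), M = c("A", "C"),
  S = c("C", "G"), W = c("A", "T"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

rand_reads <- function(n, len_range = c(20, 120), qual_range = c(2, 41)) {
  lens <- sample(len_range[1]:len_range[2], n, replace = TRUE)
  read_set(
    id = paste0("r", seq_len(n)),
    bases = vapply(lens, rand_dna, ""),
    quals = vapply(lens, function(l)
      int_to_phred(sample(qual_range[1]:qual_range[2], l, replace = TRUE)),
      ""))
}

# --- brute-force primer scan (every offset, every strand) ------------------

.pat_mask <- vapply(IUPAC_SET, function(b)
  sum(c(A = 1L, C = 2L, G = 4L, T = 8L)[b]), 0L)

bf_primer_hits <- function(reads, primer, max_mm) {
  pm <- unname(.pat_mask[strsplit(toupper(primer), "")[[1]]])
  L <- length(pm)
  rows <- list()
  for (i in seq_len(nrow(reads))) {
    for (strand in c(1L, -1L)) {
      s <- if (strand == 1L) reads$bases[i] else revcomp(reads$bases[i])
      n <- nchar(s)
      if (n < L) next
      rm_ <- c(A = 1L, C = 2L, G = 4L, T = 8L)[strsplit(s, "")[[1]]]
      rm_[is.na(rm_)] <- 0L
      idx <- outer(0:(n - L), seq_len(L), `+`)
      mm <- rowSums(matrix(bitwAnd(pm[col(idx)], rm_[idx]) == 0L,
                           nrow(idx)))
      hit <- which(mm <= max_mm)
      for (h in hit) {
        rows[[length(rows) + 1L]] <- data.frame(
          read = reads$id[i], strand = strand, offset = h - 1L,
          mismatches = mm[h], stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(read = character(), strand = integer(),
                      offset = integer(), mismatches = integer(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

hit_key <- function(h) {
  sort(paste(h$read, h$strand, h$offset, h$mismatches))
}

# --- brute-force PCR-duplicate marking (all pairs) -------------------------

bf_dedupe_keep <- function(reads, p = clean_params()) {
  n <- nrow(reads)
  keep <- logical(n)
  for (i in seq_len(n)) {
    dup <- FALSE
    for (j in seq_len(i - 1L)) {
      if (!keep[j]) next
      a <- reads$bases[i]; b <- reads$bases[j]
      if (nchar(a) < p$dup_prefix_len || nchar(b) < p$dup_prefix_len) next
      if (substr(a, 1, p$dup_prefix_len) != substr(b, 1, p$dup_prefix_len))
        next
      L <- min(nchar(a), nchar(b))
      av <- strsplit(substr(a, 1, L), "")[[1]]
      bv <- strsplit(substr(b, 1, L), "")[[1]]
      if (sum(av == bv) / L > p$dup_similarity) { dup <- TRUE; break }
    }
    keep[i] <- !dup
  }
  keep
}

# --- literal restatement of the trimming rule ------------------------------

bf_trim_span <- function(q, p = clean_params()) {
  n <- length(q)
  s <- NA_integer_
  if (n >= p$start_run_len) {
    for (i in seq_len(n - p$start_run_len + 1L)) {
      if (all(q[i:(i + p$start_run_len - 1L)] > p$start_q)) { s <- i; break }
    }
  }
  if (is.na(s)) return(NULL)
  good <- 0L
  e <- n
  for (i in s:n) {
    good <- good + as.integer(q[i] >= p$accurate_q)
    if (good / (i - s + 1L) <= p$stop_fraction) { e <- i - 1L; break }
  }
  if (e - s + 1L < p$min_len) return(NULL)
  c(s, e)
}

# --- direct evaluation of the three-branch calling rule --------------------

bf_call_base <- function(counts, prev, p_thr = 0.8, n = 20) {
  post <- (counts[c("A", "C", "G", "T")] + n / 4) / (sum(counts) + n)
  if (max(post) >= p_thr) return(c("A", "C", "G", "T")[which.max(post)])
  sets <- list(R = c("A", "G"), Y = c("C", "T"), K = c("G", "T"),
               M = c("A", "C"), S = c("C", "G"), W = c("A", "T"))
  cp <- vapply(sets, function(b) {
    if (all(counts[b] > 0)) sum(post[b]) else 0  # both alleles observed
  }, 0)
  if (max(cp) >= p_thr && prev %in% c("A", "C", "G", "T")) {
    return(names(sets)[which.max(cp)])
  }
  NA_character_
}

# --- partition comparison (label-invariant) --------------------------------

same_partition <- function(a, b) {
  stopifnot(length(a) == length(b))
  n <- length(a)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if ((a[i] == a[j]) != (b[i] == b[j])) return(FALSE)
    }
  }
  TRUE
}

# random symmetric distance matrix with zero diagonal, generic entries
rand_dist <- function(n) {
  d <- matrix(0, n, n)
  d[upper.tri(d)] <- runif(n * (n - 1) / 2, 0.05, 1)
  d <- d + t(d)
  dimnames(d) <- list(letters[seq_len(n)], letters[seq_len(n)])
  d
}
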