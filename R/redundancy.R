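# substitution matrix over the IUPAC alphabet: +1 when the base sets
# intersect, -1 otherwise; built once
.iupac_submat <- local({
  m <- NULL
  function() {
    if (is.null(m)) {
      al <- names(.IUPAC_MASK)
      mm <- outer(.IUPAC_MASK[al], .IUPAC_MASK[al],
                  function(a, b) ifelse(bitwAnd(a, b) > 0L, 1, -1))
      dimnames(mm) <- list(al, al)
      storage.mode(mm) <- "double"
      m <<- mm
    }
    m
  }
})

# effective overlap of a vs b: the score of the best overlap (end-gap-free)
# alignment, floored at zero. For a clean overlap this equals the number of
# matched positions; mismatches and gaps inside the overlap discount it, so
# spurious micro-overlaps between unrelated sequences stay near zero.
.overlap_matches <- function(a, b) {
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::BString(a), Biostrings::BString(b), type = "overlap",
    substitutionMatrix = .iupac_submat(), gapOpening = 0, gapExtension = 2,
    scoreOnly = TRUE)
  max(pa, 0)
}

#' Pairwise contig distance on the unit interval
#'
#' `1 - M / min(len_a, len_b)`, where `M` is the effective overlap — the
#' score of the best end-gap-free (overlap) alignment of the two sequences,
#' taken over both relative orientations (match +1, mismatch -1, gap -2;
#' overlapping IUPAC sets count as matches; negative scores floor at 0).
#' Identical sequences score 0, a fragment fully contained in a longer
#' contig scores 0, and sequences with no real overlap score near 1.
#'
#' @param a,b sequences (strings) or [contig()]s.
#' @return distance in `[0, 1]`.
#' @export
pair_distance <- function(a, b) {
  sa <- if (inherits(a, "vp_contig")) a$bases else toupper(a)
  sb <- if (inherits(b, "vp_contig")) b$bases else toupper(b)
  if (!nzchar(sa) || !nzchar(sb)) stop("empty sequence")
  m <- max(.overlap_matches(sa, sb), .overlap_matches(sa, revcomp(sb)))
  d <- 1 - m / min(nchar(sa), nchar(sb))
  min(max(d, 0), 1)
}

# candidate pairs: contigs sharing at least one exact 20-mer (either strand)
.candidate_pairs <- function(seqs) {
  n <- length(seqs)
  if (n < 2) return(data.frame(i = integer(), j = integer()))
  env <- new.env(hash = TRUE, parent = emptyenv())
  add <- function(key, i) {
    cur <- env[[key]]
    env[[key]] <- if (is.null(cur)) i else c(cur, i)
  }
  for (i in seq_len(n)) {
    s <- seqs[i]
    L <- nchar(s)
    if (L < 20L) next
    for (t in c(s, revcomp(s))) {
      km <- unique(substring(t, 1:(L - 19L), 20:L))
      for (k in km) add(k, i)
    }
  }
  seen <- new.env(hash = TRUE, parent = emptyenv())
  pairs <- list()
  for (key in ls(env)) {
    ids <- unique(env[[key]])
    if (length(ids) < 2) next
    cmb <- utils::combn(sort(ids), 2)
    for (c1 in seq_len(ncol(cmb))) {
      tag <- paste(cmb[1, c1], cmb[2, c1])
      if (is.null(seen[[tag]])) {
        seen[[tag]] <- TRUE
        pairs[[length(pairs) + 1L]] <- cmb[, c1]
      }
    }
  }
  if (!length(pairs)) return(data.frame(i = integer(), j = integer()))
  m <- do.call(rbind, pairs)
  data.frame(i = m[, 1], j = m[, 2])
}

.union_find <- function(n) {
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  list(find = find,
       union = function(a, b) {
         ra <- find(a); rb <- find(b)
         if (ra != rb) parent[ra] <<- rb
       })
}

#' Detect redundant contigs and asymmetric fragment pairs
#'
#' Computes [pair_distance()] for every pair of contigs sharing at least one
#' exact 20-mer, single-linkage clusters pairs at distance `<= d_max`, and
#' picks the longest member of each cluster as representative. When a
#' post-extension sequence set is also supplied, pairs whose distance
#' exceeds `d_max` before extension but drops to `<= d_max` after are
#' reported as `asymmetric_fragments` — non-overlapping 5' and 3' fragments
#' of one transcript united by elongation.
#'
#' @param contigs named character vector of sequences.
#' @param d_max redundancy distance threshold.
#' @param post optional named character vector of the same contigs after
#'   extension (names must match).
#' @return list with `pairs` (id_a, id_b, distance, relation), `clusters`
#'   (id -> cluster), `representatives`, and, when `post` is given,
#'   `asymmetric` (the flagged pairs with pre/post distances).
#' @export
find_redundant <- function(contigs, d_max = 0.05, post = NULL) {
  nm <- names(contigs) %||% paste0("contig", seq_along(contigs))
  names(contigs) <- nm
  cand <- .candidate_pairs(unname(contigs))
  pairs <- NULL
  if (nrow(cand) > 0) {
    d <- vapply(seq_len(nrow(cand)), function(r) {
      pair_distance(contigs[[cand$i[r]]], contigs[[cand$j[r]]])
    }, 0)
    la <- nchar(contigs[cand$i]); lb <- nchar(contigs[cand$j])
    relation <- ifelse(d == 0 & la == lb, "identical",
                ifelse(d <= d_max & la != lb, "contained",
                ifelse(d <= d_max, "overlapping", "unrelated")))
    pairs <- data.frame(id_a = nm[cand$i], id_b = nm[cand$j], distance = d,
                        relation = relation, stringsAsFactors = FALSE)
  } else {
    pairs <- data.frame(id_a = character(), id_b = character(),
                        distance = numeric(), relation = character(),
                        stringsAsFactors = FALSE)
  }
  uf <- .union_find(length(contigs))
  if (nrow(cand) > 0) {
    for (r in which(pairs$distance <= d_max)) uf$union(cand$i[r], cand$j[r])
  }
  roots <- vapply(seq_along(contigs), uf$find, 0L)
  cluster <- match(roots, unique(roots))
  reps <- vapply(split(seq_along(contigs), cluster), function(ix) {
    nm[ix[which.max(nchar(contigs[ix]))]]
  }, "")
  out <- list(pairs = pairs,
              clusters = data.frame(id = nm, cluster = cluster,
                                    stringsAsFactors = FALSE),
              representatives = unname(reps))
  if (!is.null(post)) {
    if (!all(nm %in% names(post))) stop("post is missing some contig ids")
    cand2 <- .candidate_pairs(unname(post[nm]))
    asym <- list()
    for (r in seq_len(nrow(cand2))) {
      i <- cand2$i[r]; j <- cand2$j[r]
      d_post <- pair_distance(post[[nm[i]]], post[[nm[j]]])
      if (d_post > d_max) next
      d_pre <- pair_distance(contigs[[i]], contigs[[j]])
      if (d_pre > d_max) {
        asym[[length(asym) + 1L]] <- data.frame(
          id_a = nm[i], id_b = nm[j], distance_pre = d_pre,
          distance_post = d_post, relation = "asymmetric_fragments",
          stringsAsFactors = FALSE)
      }
    }
    out$asymmetric <- if (length(asym)) do.call(rbind, asym) else
      data.frame(id_a = character(), id_b = character(),
                 distance_pre = numeric(), distance_post = numeric(),
                 relation = character(), stringsAsFactors = FALSE)
  }
  out
}
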