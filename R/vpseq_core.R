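#' Extension engine parameters
#'
#' @param p_threshold minimum posterior probability for calling a base or a
#'   two-base ambiguity code (inclusive).
#' @param pseudo_n pseudo-count regularizing the posterior; split as
#'   `pseudo_n/4` per base. With the defaults, a unanimous column needs
#'   depth >= 55 before a base is callable.
#' @param primer_len virtual-primer length (bp).
#' @param round1_mismatch mismatch budget for round-1 primer search (the
#'   allowance that recruits reads carrying a sequencing error or variant).
#' @param later_mismatch mismatch budget for later rounds, whose primers
#'   instead carry IUPAC ambiguity codes.
#' @param max_rounds safety cap on extension rounds.
#' @return list of class `vp_params`.
#' @export
vp_params <- function(p_threshold = 0.8, pseudo_n = 20L, primer_len = 20L,
                      round1_mismatch = 1L, later_mismatch = 0L,
                      max_rounds = 100L) {
  stopifnot(p_threshold > 0.5, p_threshold <= 1, pseudo_n >= 0,
            primer_len == 20L, round1_mismatch %in% c(0L, 1L),
            later_mismatch %in% c(0L, 1L), max_rounds >= 1)
  structure(list(p_threshold = p_threshold, pseudo_n = as.integer(pseudo_n),
                 primer_len = as.integer(primer_len),
                 round1_mismatch = as.integer(round1_mismatch),
                 later_mismatch = as.integer(later_mismatch),
                 max_rounds = as.integer(max_rounds)),
            class = "vp_params")
}

#' Posterior probability of a nucleotide at an extension position
#'
#' With counts `N(nt | i)` over the reads piled on position `i` and total
#' depth `N(i)`, the posterior is `(N(nt|i) + n/4) / (N(i) + n)` with
#' pseudo-count `n`. For a two-base ambiguity code the posterior is the sum
#' of its two component-base posteriors. At depth 0 every base has posterior
#' 1/4.
#'
#' @param counts named numeric vector with elements A, C, G, T.
#' @param nt a base (A/C/G/T) or a two-base code (R/Y/K/M/S/W).
#' @param pseudo_n pseudo-count (default 20).
#' @return posterior probability.
#' @export
posterior <- function(counts, nt, pseudo_n = 20L) {
  counts <- counts[c("A", "C", "G", "T")]
  depth <- sum(counts)
  nt <- toupper(nt)
  if (nt %in% c("A", "C", "G", "T")) {
    return(unname((counts[nt] + pseudo_n / 4) / (depth + pseudo_n)))
  }
  comp <- .AMBIG2[nt]
  if (is.na(comp)) stop("nt must be a base or a two-base ambiguity code")
  b <- strsplit(comp, "")[[1]]
  unname(sum(counts[b] + pseudo_n / 4) / (depth + pseudo_n))
}

#' Call the consensus character for one extension position
#'
#' Branch order: (1) if the maximum posterior over A/C/G/T reaches
#' `p_threshold`, call that base; (2) otherwise, if the maximum posterior
#' over the six two-base codes reaches `p_threshold` *and* the previously
#' called character is an unambiguous base, call that code (successive
#' ambiguity codes are forbidden — low-complexity / contamination guard);
#' (3) otherwise no call, and elongation stops. A two-base code represents
#' two observed alleles, so it is only eligible when both of its component
#' bases are actually present in the pile-up — otherwise the pseudo-count
#' share of an unobserved base could promote a unanimous column below the
#' calling depth into a spurious ambiguity call. Ties break
#' lexicographically (A<C<G<T; R<Y<K<M<S<W).
#'
#' @param counts named numeric vector with elements A, C, G, T.
#' @param previous_base the adjacent already-determined character.
#' @param params a [vp_params()].
#' @return single character, or `NA_character_` for no call.
#' @export
call_base <- function(counts, previous_base, params = vp_params()) {
  counts <- as.numeric(counts[c("A", "C", "G", "T")])
  n <- params$pseudo_n
  depth <- sum(counts)
  post <- (counts + n / 4) / (depth + n)
  if (max(post) >= params$p_threshold) {
    return(c("A", "C", "G", "T")[which.max(post)])
  }
  codes <- c("R", "Y", "K", "M", "S", "W")
  # component indices into (A,C,G,T)
  comp <- list(R = c(1, 3), Y = c(2, 4), K = c(3, 4),
               M = c(1, 2), S = c(2, 3), W = c(1, 4))
  cpost <- vapply(comp, function(ix) {
    if (all(counts[ix] > 0)) sum(post[ix]) else 0
  }, 0)
  if (max(cpost) >= params$p_threshold &&
      toupper(previous_base) %in% c("A", "C", "G", "T")) {
    return(codes[which.max(cpost)])
  }
  NA_character_
}

# pile overhanging read bases and call outward from one end; works in the
# orientation where extension is rightward (3'); returns the called string
# and a per-position trace
.extend_right <- function(bases, store, max_mismatch, params) {
  L <- nchar(bases)
  primer <- substr(bases, L - params$primer_len + 1L, L)
  hits <- find_primer_hits(store, primer, max_mismatch)
  trace0 <- data.frame(position = integer(), A = integer(), C = integer(),
                       G = integer(), T = integer(), depth = integer(),
                       p_max = numeric(), call = character(),
                       stringsAsFactors = FALSE)
  if (nrow(hits) == 0) {
    return(list(added = "", n_hits = 0L, primer = primer, trace = trace0))
  }
  rd <- oriented_reads(store, hits)
  ov <- substr(rd, hits$offset + params$primer_len + 1L, nchar(rd))
  ov <- ov[nzchar(ov)]
  if (length(ov) == 0) {
    return(list(added = "", n_hits = nrow(hits), primer = primer,
                trace = trace0))
  }
  maxov <- max(nchar(ov))
  prev <- substr(bases, L, L)
  added <- character(0)
  trace <- vector("list", maxov)
  for (i in seq_len(maxov)) {
    ch <- substr(ov, i, i)
    counts <- c(A = sum(ch == "A"), C = sum(ch == "C"),
                G = sum(ch == "G"), T = sum(ch == "T"))
    call <- call_base(counts, prev, params)
    post <- (counts + params$pseudo_n / 4) / (sum(counts) + params$pseudo_n)
    trace[[i]] <- data.frame(position = i, A = counts[["A"]],
                             C = counts[["C"]], G = counts[["G"]],
                             T = counts[["T"]], depth = sum(counts),
                             p_max = max(post),
                             call = ifelse(is.na(call), "NO_CALL", call),
                             stringsAsFactors = FALSE)
    if (is.na(call)) break
    added <- c(added, call)
    prev <- call
  }
  trace <- do.call(rbind, trace[!vapply(trace, is.null, logical(1))])
  list(added = paste(added, collapse = ""), n_hits = nrow(hits),
       primer = primer, trace = trace)
}

#' One elongation round at one contig end
#'
#' Takes the terminal 20 bases as the virtual primer, recruits reads from
#' the store (both strands; minus-strand hits contribute the read's reverse
#' complement), anchors each primer occurrence at the contig terminus, piles
#' the overhanging read bases into per-position profiles, and calls bases
#' outward until no call can be made. The 5' end is handled as 3' extension
#' of the reverse-complemented contig, so both ends behave symmetrically.
#'
#' @param ctg a [contig()] or a plain sequence string.
#' @param end `"five_prime"` or `"three_prime"`.
#' @param store a [build_store()] result.
#' @param max_mismatch primer-search mismatch budget for this round.
#' @param params a [vp_params()].
#' @return list with `added` (new bases, contig orientation), `n_hits`,
#'   `primer` and the per-position `trace`.
#' @export
extend_once <- function(ctg, end = c("three_prime", "five_prime"), store,
                        max_mismatch = 0L, params = vp_params()) {
  end <- match.arg(end)
  bases <- if (inherits(ctg, "vp_contig")) ctg$bases else toupper(ctg)
  if (nchar(bases) < params$primer_len) {
    stop("contig shorter than the primer length")
  }
  if (end == "three_prime") {
    .extend_right(bases, store, max_mismatch, params)
  } else {
    res <- .extend_right(revcomp(bases), store, max_mismatch, params)
    res$added <- if (nzchar(res$added)) revcomp(res$added) else ""
    res
  }
}

#' Elongate a contig to convergence
#'
#' Repeats rounds of 5'-then-3' extension, redesigning the terminal 20-mer
#' primers (which may now contain ambiguity codes) after every round, until
#' a full round adds no base to either end or `max_rounds` is reached. Round
#' 1 allows `round1_mismatch` mismatches in primer search; later rounds use
#' `later_mismatch`. The input sequence is preserved verbatim as a
#' contiguous substring of the output, recorded in `core_span`.
#'
#' @param ctg a [contig()], or a single (optionally named) sequence string.
#' @param store a [build_store()] result.
#' @param params a [vp_params()].
#' @return list with `contig` (the elongated [contig()]) and `report`
#'   (class `vp_report`: totals plus a per-round log of primer, hit count
#'   and bases added).
#' @export
vpseq_extend <- function(ctg, store, params = vp_params()) {
  if (!inherits(ctg, "vp_contig")) {
    id <- names(ctg) %||% "contig"
    ctg <- contig(id, as.character(ctg))
  }
  bases <- ctg$bases
  orig_len <- nchar(bases)
  add5_total <- 0L
  add3_total <- 0L
  log <- list()
  rounds <- 0L
  for (round in seq_len(params$max_rounds)) {
    rounds <- round
    budget <- if (round == 1L) params$round1_mismatch else
      params$later_mismatch
    r5 <- extend_once(bases, "five_prime", store, budget, params)
    if (nzchar(r5$added)) bases <- paste0(r5$added, bases)
    r3 <- extend_once(bases, "three_prime", store, budget, params)
    if (nzchar(r3$added)) bases <- paste0(bases, r3$added)
    a5 <- nchar(r5$added)
    a3 <- nchar(r3$added)
    add5_total <- add5_total + a5
    add3_total <- add3_total + a3
    log[[length(log) + 1L]] <- data.frame(
      round = round, end = c("five_prime", "three_prime"),
      primer = c(r5$primer, r3$primer), hits = c(r5$n_hits, r3$n_hits),
      bases_added = c(a5, a3), stringsAsFactors = FALSE)
    if (a5 + a3 == 0L) break
  }
  new_core <- ctg$core_span + add5_total
  out <- contig(ctg$id, bases, core_span = new_core)
  added_seq <- paste0(substr(bases, 1, add5_total),
                      substr(bases, orig_len + add5_total + 1L, nchar(bases)))
  report <- structure(list(
    contig = ctg$id, rounds = rounds, added5 = add5_total,
    added3 = add3_total,
    ambiguity_count = nchar(gsub("[^RYKMSW]", "", added_seq)),
    log = do.call(rbind, log)), class = "vp_report")
  list(contig = out, report = report)
}

#' @export
print.vp_report <- function(x, ...) {
  cat(sprintf("<vp_report %s: %d round(s), +%d bp 5', +%d bp 3', %d ambiguity code(s)>\n",
              x$contig, x$rounds, x$added5, x$added3, x$ambiguity_count))
  invisible(x)
}

#' Elongate a set of contigs independently
#'
#' Applies [vpseq_extend()] to each contig in input order. Contigs are
#' independent: permuting the input permutes the output identically. A
#' failure on one contig is logged and the rest are still processed.
#'
#' @param contigs named character vector of sequences, or list of
#'   [contig()]s.
#' @param store a [build_store()] result.
#' @param params a [vp_params()].
#' @return list of `list(contig, report)` as from [vpseq_extend()].
#' @export
batch_extend <- function(contigs, store, params = vp_params()) {
  if (is.character(contigs)) {
    nm <- names(contigs) %||% paste0("contig", seq_along(contigs))
    contigs <- Map(contig, nm, contigs)
  }
  out <- vector("list", length(contigs))
  names(out) <- vapply(contigs, function(c) c$id, "")
  for (i in seq_along(contigs)) {
    out[[i]] <- tryCatch(vpseq_extend(contigs[[i]], store, params),
                         error = function(e) {
                           warning("contig ", contigs[[i]]$id, " failed: ",
                                   conditionMessage(e))
                           list(contig = contigs[[i]], report = NULL)
                         })
  }
  out
}
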