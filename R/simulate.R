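#' Synthetic transcriptome configuration
#'
#' Defines the study conditions the extension engine is validated under:
#' transcripts with a planted complete ORF (an in-frame upstream stop, ATG,
#' stop-free codons, stop codon and UTRs), optional heterozygous 50/50
#' biallelic sites, uniformly placed error-bearing reads (including clipped
#' transcript-terminal fragments, as fragmentation at transcript ends
#' produces), and contigs truncated at both ends.
#'
#' @param n_transcripts number of transcripts.
#' @param len_range transcript length range in bp.
#' @param gc GC fraction of the background composition.
#' @param coverage per-transcript fold coverage (recycled).
#' @param read_len read length in bp.
#' @param error_rate per-base substitution error rate.
#' @param het_rate per-bp probability of a biallelic 50/50 site.
#' @param trunc length-2 vector: bases removed from the 5' and 3' contig
#'   ends.
#' @param utr5_range,utr3_range UTR length ranges (bp); the 5' UTR carries
#'   an in-frame stop just upstream of the ATG.
#' @param seed integer seed fixing every downstream draw.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_transcripts = 50L, len_range = c(900L, 3000L),
                       gc = 0.44, coverage = 200, read_len = 101L,
                       error_rate = 0.001, het_rate = 0.0005,
                       trunc = c(150L, 150L),
                       utr5_range = c(60L, 140L), utr3_range = c(80L, 250L),
                       seed = 1L) {
  stopifnot(n_transcripts >= 1, len_range[1] >= 200,
            len_range[2] >= len_range[1], gc > 0, gc < 1,
            all(coverage >= 0), read_len >= 30,
            error_rate >= 0, error_rate <= 1, het_rate >= 0, het_rate <= 1,
            trunc[1] >= 0, trunc[2] >= 0)
  if (read_len > len_range[1]) {
    stop("read length exceeds the shortest transcript length")
  }
  structure(list(n_transcripts = as.integer(n_transcripts),
                 len_range = as.integer(len_range), gc = gc,
                 coverage = coverage, read_len = as.integer(read_len),
                 error_rate = error_rate, het_rate = het_rate,
                 trunc = as.integer(trunc),
                 utr5_range = as.integer(utr5_range),
                 utr3_range = as.integer(utr3_range),
                 seed = as.integer(seed)),
            class = "sim_config")
}

# sample one integer from [a, b] (safe when a == b, unlike sample())
.sample_range <- function(a, b) {
  if (a >= b) return(a)
  sample(a:b, 1L)
}

.SENSE_CODONS <- local({
  b <- c("A", "C", "G", "T")
  all <- as.vector(outer(outer(b, b, paste0), b, paste0))
  setdiff(all, c("TAA", "TAG", "TGA"))
})

.rand_bases <- function(n, gc) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# one transcript: 5' UTR (with planted in-frame stop directly upstream of
# the ATG), ATG, sense codons, stop, 3' UTR
.make_transcript <- function(len, cfg) {
  u5 <- .sample_range(cfg$utr5_range[1], cfg$utr5_range[2])
  u3 <- .sample_range(cfg$utr3_range[1], cfg$utr3_range[2])
  n_codons <- max(30L, (len - u5 - u3 - 6L) %/% 3L)
  cds <- paste(c("ATG", sample(.SENSE_CODONS, n_codons, replace = TRUE),
                 sample(c("TAA", "TAG", "TGA"), 1)), collapse = "")
  utr5 <- paste0(.rand_bases(u5 - 3L, cfg$gc), sample(c("TAA", "TAG", "TGA"), 1))
  utr3 <- .rand_bases(u3, cfg$gc)
  seq <- paste0(utr5, cds, utr3)
  list(seq = seq, utr5 = u5, cds_start = u5 + 1L,
       cds_end = u5 + nchar(cds))
}

.plant_het <- function(seq, rate) {
  n <- nchar(seq)
  sites <- which(stats::runif(n) < rate)
  if (!length(sites)) {
    return(list(allele_b = seq, sites = integer(0), alt = character(0)))
  }
  ref <- strsplit(seq, "")[[1]]
  alt <- vapply(sites, function(i) {
    sample(setdiff(c("A", "C", "G", "T"), ref[i]), 1)
  }, "")
  bv <- ref
  bv[sites] <- alt
  list(allele_b = paste(bv, collapse = ""), sites = sites, alt = alt)
}

# reads from one allele: starts uniform over [2 - R, L] then clipped to the
# transcript, so fragments overhanging an end yield shorter terminal reads
.draw_reads <- function(template, n_reads, cfg, prefix) {
  L <- nchar(template)
  R <- cfg$read_len
  if (n_reads == 0) return(read_set())
  starts <- sample((2L - R):L, n_reads, replace = TRUE)
  from <- pmax(starts, 1L)
  to <- pmin(starts + R - 1L, L)
  len <- to - from + 1L
  keep <- len >= 20L
  from <- from[keep]; to <- to[keep]; len <- len[keep]
  if (!length(from)) return(read_set())
  bases <- substring(template, from, to)
  strand <- sample(c(TRUE, FALSE), length(from), replace = TRUE)
  bases[strand] <- revcomp(bases[strand])
  if (cfg$error_rate > 0) {
    nerr <- stats::rbinom(length(bases), len, cfg$error_rate)
    for (i in which(nerr > 0)) {
      bv <- strsplit(bases[i], "")[[1]]
      pos <- sample(len[i], nerr[i])
      bv[pos] <- vapply(bv[pos], function(b) {
        sample(setdiff(c("A", "C", "G", "T"), b), 1)
      }, "")
      bases[i] <- paste(bv, collapse = "")
    }
  }
  quals <- .qual_strings(len)
  read_set(id = paste0(prefix, "_", seq_along(bases)), bases = bases,
           quals = quals)
}

# realistic Phred strings: high-quality core, decaying 3' tail
.qual_strings <- function(lens) {
  R <- max(lens)
  profile <- pmin(40L, pmax(25L, 40L - pmax(0L, seq_len(R) - (R - 15L))))
  vapply(lens, function(l) int_to_phred(profile[seq_len(l)]), "")
}

#' Generate a synthetic transcriptome dataset with gold standard
#'
#' @param cfg a [sim_config()].
#' @return list of class `sim_dataset`: `templates` (named vector, allele
#'   A), `alleles_b`, `contigs` (truncated allele-A sequences), `reads`
#'   (a [read_set()], both alleles pooled), and `gold` (per-transcript
#'   truth: truncation coordinates, het sites, ORF coordinates, read
#'   counts).
#' @export
simulate_dataset <- function(cfg = sim_config()) {
  set.seed(cfg$seed)
  n <- cfg$n_transcripts
  cov <- rep_len(cfg$coverage, n)
  templates <- character(n)
  alleles_b <- character(n)
  contigs <- character(n)
  gold <- vector("list", n)
  reads <- vector("list", 2L * n)
  for (i in seq_len(n)) {
    len <- .sample_range(cfg$len_range[1], cfg$len_range[2])
    tr <- .make_transcript(len, cfg)
    het <- .plant_het(tr$seq, cfg$het_rate)
    templates[i] <- tr$seq
    alleles_b[i] <- het$allele_b
    L <- nchar(tr$seq)
    t5 <- min(cfg$trunc[1], max(0L, L - 20L))
    t3 <- min(cfg$trunc[2], max(0L, L - t5 - 20L))
    contigs[i] <- substr(tr$seq, t5 + 1L, L - t3)
    n_reads <- as.integer(round(cov[i] * L / cfg$read_len))
    na <- stats::rbinom(1, n_reads, 0.5)
    id <- sprintf("tx%03d", i)
    reads[[2L * i - 1L]] <- .draw_reads(tr$seq, na, cfg,
                                        paste0(id, "a"))
    reads[[2L * i]] <- .draw_reads(het$allele_b, n_reads - na, cfg,
                                   paste0(id, "b"))
    gold[[i]] <- list(id = id, length = L, trunc5 = t5, trunc3 = t3,
                      cds_start = tr$cds_start, cds_end = tr$cds_end,
                      het_sites = het$sites, het_alt = het$alt,
                      n_reads = n_reads)
  }
  ids <- vapply(gold, `[[`, "", "id")
  names(templates) <- names(alleles_b) <- names(contigs) <- ids
  all_reads <- do.call(rbind, reads)
  all_reads <- structure(all_reads, class = c("read_set", "data.frame"))
  rownames(all_reads) <- NULL
  structure(list(templates = templates, alleles_b = alleles_b,
                 contigs = contigs, reads = all_reads, gold = gold,
                 config = cfg),
            class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat(sprintf("<sim_dataset: %d transcripts, %d reads, seed %d>\n",
              length(x$templates), nrow(x$reads), x$config$seed))
  invisible(x)
}

#' Write a simulated dataset to disk
#'
#' @param sim a [simulate_dataset()] result.
#' @param outdir output directory (created if needed).
#' @return invisibly, the paths written (templates/alleles/contigs FASTA,
#'   reads FASTQ, gold-standard JSON).
#' @export
write_sim_dataset <- function(sim, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- file.path(outdir, c("templates.fasta", "alleles_b.fasta",
                           "contigs.fasta", "reads.fastq", "gold.json"))
  write_fasta(sim$templates, p[1])
  write_fasta(sim$alleles_b, p[2])
  write_fasta(sim$contigs, p[3])
  write_fastq(sim$reads, p[4])
  jsonlite::write_json(sim$gold, p[5], auto_unbox = TRUE, digits = NA)
  invisible(p)
}

#' Reload a simulated dataset written by [write_sim_dataset()]
#'
#' Reads are not reloaded (evaluation does not need them).
#'
#' @param dir directory holding the dataset files.
#' @return a `sim_dataset`-like list with `templates`, `alleles_b`,
#'   `contigs` and `gold`.
#' @export
read_sim_dataset <- function(dir) {
  gold_raw <- jsonlite::fromJSON(file.path(dir, "gold.json"),
                                 simplifyDataFrame = FALSE,
                                 simplifyVector = FALSE)
  gold <- lapply(gold_raw, function(g) {
    g$het_sites <- as.integer(unlist(g$het_sites))
    g$het_alt <- as.character(unlist(g$het_alt))
    g
  })
  structure(list(templates = read_fasta(file.path(dir, "templates.fasta")),
                 alleles_b = read_fasta(file.path(dir, "alleles_b.fasta")),
                 contigs = read_fasta(file.path(dir, "contigs.fasta")),
                 reads = NULL, gold = gold, config = NULL),
            class = "sim_dataset")
}

#' Parse extended contigs (with `core=` headers) back into contig objects
#'
#' The FASTA headers written by the pipeline carry
#' `core=<start>-<end> added5=<n> added3=<n>`; this reconstructs
#' [contig()] objects with their provenance for evaluation.
#'
#' @param path FASTA of extended contigs.
#' @return named list of [contig()]s.
#' @export
read_extended_fasta <- function(path) {
  seqs <- read_fasta(path)
  out <- lapply(seq_along(seqs), function(i) {
    hdr <- names(seqs)[i]
    id <- sub("\\s.*$", "", hdr)
    m <- regmatches(hdr, regexec("core=(\\d+)-(\\d+)", hdr))[[1]]
    span <- if (length(m) == 3) as.integer(m[2:3]) else
      c(0L, nchar(seqs[[i]]))
    contig(id, seqs[[i]], core_span = span)
  })
  names(out) <- vapply(out, function(c) c$id, "")
  out
}

# is the emitted character compatible with the true allele set at a site?
.base_ok <- function(emitted, truth_set) {
  m <- .IUPAC_MASK[emitted]
  t <- sum(.IUPAC_MASK[truth_set])
  !is.na(m) && bitwAnd(m, t) == t  # emitted set contains every true allele
}

#' Score elongated contigs against the simulation truth
#'
#' For every contig: the fraction of truncated bases recovered, per-base
#' identity of the elongated spans to the template (an ambiguity code is
#' correct iff its set contains the true allele(s) at that site), the
#' het-site code accuracy, and the ORF class before/after extension.
#'
#' @param results list from [batch_extend()] (names = transcript ids).
#' @param sim the [simulate_dataset()] that produced the inputs.
#' @return list with `per_contig` (data.frame) and `summary` (means).
#' @export
evaluate_extension <- function(results, sim) {
  ids <- vapply(sim$gold, `[[`, "", "id")
  if (!all(names(results) %in% ids)) {
    stop("result ids not in gold standard: ",
         paste(setdiff(names(results), ids), collapse = ", "))
  }
  rows <- vector("list", length(results))
  het_total <- 0L
  het_correct <- 0L
  for (k in seq_along(results)) {
    id <- names(results)[k]
    g <- sim$gold[[match(id, ids)]]
    tpl <- sim$templates[[id]]
    alt <- sim$alleles_b[[id]]
    ctg <- results[[k]]$contig
    a5 <- ctg$core_span[1]
    a3 <- nchar(ctg$bases) - ctg$core_span[2]
    rec5 <- min(a5, g$trunc5)
    rec3 <- min(a3, g$trunc3)
    trunc_total <- g$trunc5 + g$trunc3
    recovery <- if (trunc_total == 0) 1 else (rec5 + rec3) / trunc_total
    # added spans, template coordinates
    added_pos <- integer(0)
    added_chr <- character(0)
    if (a5 > 0) {
      span <- substr(ctg$bases, 1L, a5)
      pos <- (g$trunc5 - a5 + 1L):g$trunc5
      keep <- pos >= 1
      added_pos <- c(added_pos, pos[keep])
      added_chr <- c(added_chr, strsplit(span, "")[[1]][keep])
    }
    if (a3 > 0) {
      span <- substr(ctg$bases, ctg$core_span[2] + 1L, nchar(ctg$bases))
      first <- g$length - g$trunc3 + 1L
      pos <- first:(first + a3 - 1L)
      keep <- pos <= g$length
      added_pos <- c(added_pos, pos[keep])
      added_chr <- c(added_chr, strsplit(span, "")[[1]][keep])
    }
    n_ok <- 0L
    for (m in seq_along(added_pos)) {
      p <- added_pos[m]
      truth <- unique(c(substr(tpl, p, p), substr(alt, p, p)))
      ok <- .base_ok(added_chr[m], truth)
      if (ok) n_ok <- n_ok + 1L
      if (length(truth) == 2L) {
        het_total <- het_total + 1L
        code <- names(.AMBIG2)[match(paste(sort(truth), collapse = ""),
                                     .AMBIG2)]
        if (!is.na(code) && added_chr[m] == code) {
          het_correct <- het_correct + 1L
        }
      }
    }
    identity <- if (length(added_pos)) n_ok / length(added_pos) else 1
    cls_before <- classify_orf(stats::setNames(sim$contigs[id], id))$class
    cls_after <- classify_orf(ctg)$class
    rows[[k]] <- data.frame(
      id = id, trunc5 = g$trunc5, trunc3 = g$trunc3, added5 = a5,
      added3 = a3, recovery = recovery, identity = identity,
      class_before = cls_before, class_after = cls_after,
      stringsAsFactors = FALSE)
  }
  per_contig <- do.call(rbind, rows)
  summary <- list(
    mean_recovery = mean(per_contig$recovery),
    mean_identity = mean(per_contig$identity),
    full_length_before = mean(per_contig$class_before == "full_length"),
    full_length_after = mean(per_contig$class_after == "full_length"),
    het_sites_scored = het_total,
    het_code_accuracy = if (het_total > 0) het_correct / het_total else
      NA_real_)
  list(per_contig = per_contig, summary = summary)
}
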