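# small CDS helpers: sense codons only, no internal ATG unless asked
codons_no_atg <- setdiff(vpseq:::.SENSE_CODONS, "ATG")
mk_cds <- function(n) paste(sample(codons_no_atg, n, replace = TRUE),
                            collapse = "")

test_that("codon-scan fallback classifies by start and stop evidence", {
  # upstream in-frame TGA, ATG, TAA: complete at both ends
  call <- classify_orf(c(x = "CCCTGAATGAAACCCTAAGG"))
  expect_equal(call$class, "full_length")
  expect_equal(call$evidence, "longest_orf")

  set.seed(51)
  # upstream stop + ATG but the frame stays open to the contig end
  open3 <- paste0("CC", "TGA", "ATG", mk_cds(60))
  expect_equal(classify_orf(c(x = open3))$class, "three_prime_partial")

  # stop present but no ATG with an upstream stop: 5' incomplete
  open5 <- paste0(mk_cds(60), "TAA", "CCGGCCGGCC")
  expect_equal(classify_orf(c(x = open5))$class, "five_prime_partial")

  # the reverse complement classifies identically (all six frames scanned)
  full <- paste0("CCAC", "TAA", "ATG", mk_cds(80), "TGA", "CCGGAAGGTT")
  expect_equal(classify_orf(c(x = full))$class, "full_length")
  expect_equal(classify_orf(c(x = revcomp(full)))$class, "full_length")
})

test_that("an internal ATG without upstream stop is not start evidence
           unless the UTR-length rule is enabled", {
  set.seed(52)
  frag <- paste0(mk_cds(40), "ATG", mk_cds(60), "TAA", "CC")
  expect_equal(classify_orf(c(x = frag))$class, "five_prime_partial")
  permissive <- orf_params(min_utr5 = 30L)
  expect_equal(classify_orf(c(x = frag), params = permissive)$class,
               "full_length")
})

test_that("alignment-guided classification uses the hit frame and subject
           N-terminus proximity", {
  set.seed(53)
  cds <- paste0("ATG", mk_cds(50), "TAA")
  utr5 <- "CCACCGGTTACC"  # 12 nt, no in-frame stop
  seq <- paste0(utr5, cds, "GGACCGGAAT")
  qs <- nchar(utr5) + 1L
  qe <- nchar(utr5) + nchar(cds) - 3L
  # subject alignment starting at residue 1: start evidence without an
  # upstream stop
  h1 <- protein_hit("x", qs, qe, 1, 51)
  expect_equal(classify_orf(c(x = seq), hit = h1)$class, "full_length")
  # mid-subject alignment: no start evidence
  h2 <- protein_hit("x", qs, qe, 120, 170)
  expect_equal(classify_orf(c(x = seq), hit = h2)$class,
               "five_prime_partial")
  # mid-CDS fragment, mid-subject alignment, no ATG, no stop: internal
  frag <- mk_cds(60)
  h3 <- protein_hit("x", 1, nchar(frag), 100, 159)
  expect_equal(classify_orf(c(x = frag), hit = h3)$class, "internal")
  # no stop before the contig end: 3' partial
  open3 <- paste0(utr5, "ATG", mk_cds(50))
  h4 <- protein_hit("x", qs, nchar(open3), 1, 51)
  expect_equal(classify_orf(c(x = open3), hit = h4)$class,
               "three_prime_partial")
})

test_that("mirroring the contig and the hit preserves the class", {
  set.seed(54)
  cds <- paste0("ATG", mk_cds(40), "TAA")
  seq <- paste0("CCGGTT", cds, "AACCGGTT")
  L <- nchar(seq)
  qs <- 7L
  qe <- 6L + nchar(cds) - 3L
  fwd <- classify_orf(c(x = seq), hit = protein_hit("x", qs, qe, 1, 41))
  rev <- classify_orf(c(x = revcomp(seq)),
                      hit = protein_hit("x", L - qs + 1L, L - qe + 1L,
                                        1, 41))
  expect_equal(rev$class, fwd$class)
  expect_equal(rev$frame < 0, TRUE)
})

test_that("completeness_table counts classes and the full-length fraction", {
  calls <- list(
    structure(list(class = "full_length"), class = "orf_call"),
    structure(list(class = "full_length"), class = "orf_call"),
    structure(list(class = "internal"), class = "orf_call"))
  tb <- completeness_table(calls)
  expect_equal(tb$count[tb$class == "full_length"], 2L)
  expect_equal(attr(tb, "fraction_full_length"), 2 / 3)
  tb0 <- completeness_table(list())
  expect_equal(sum(tb0$count), 0L)
  expect_equal(attr(tb0, "fraction_full_length"), 0)
})

test_that("best hit per query is chosen by e-value then bitscore", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "c1\ts1\t90\t100\t5\t0\t10\t309\t1\t100\t1e-50\t200",
    "c1\ts2\t80\t100\t5\t0\t10\t309\t1\t100\t1e-30\t150",
    "c2\ts3\t70\t90\t9\t0\t200\t10\t1\t60\t1e-10\t90"), f)
  hits <- read_blast_hits(f)
  expect_equal(hits$c1$evalue, 1e-50)
  expect_true(hits$c2$qstart > hits$c2$qend)  # minus-frame hit retained
})
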