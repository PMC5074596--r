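mk_read <- function(bases, quals = strrep("I", nchar(bases)), id = "r") {
  read_set(id = id, bases = bases, quals = quals)
}

# a copy of `base` with exactly n_mm mismatches at positions > 10
mutate_after_prefix <- function(base, n_mm) {
  bv <- strsplit(base, "")[[1]]
  pos <- sample(11:length(bv), n_mm)
  bv[pos] <- vapply(bv[pos], function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
  paste(bv, collapse = "")
}

test_that("PCR-duplicate rule: identical prefix plus strict >90% identity", {
  set.seed(21)
  a <- mk_read(rand_dna(100))
  expect_true(is_pcr_duplicate(a, a))
  b8 <- mk_read(mutate_after_prefix(a$bases, 8))   # 92/100 identical
  expect_true(is_pcr_duplicate(a, b8))
  b10 <- mk_read(mutate_after_prefix(a$bases, 10)) # exactly 90/100
  expect_false(is_pcr_duplicate(a, b10))
  # identical tails but different prefixes are never duplicates
  c1 <- mk_read(paste0("AAAAAAAAAA", substr(a$bases, 11, 100)))
  c2 <- mk_read(paste0("CCCCCCCCCC", substr(a$bases, 11, 100)))
  expect_false(is_pcr_duplicate(c1, c2))
})

test_that("dedupe keeps first occurrences, is idempotent, matches the
           all-pairs oracle", {
  set.seed(22)
  r <- mk_read(rand_dna(100), id = "a")
  dup <- read_set(id = c("a", "b"), bases = rep(r$bases, 2),
                  quals = rep(r$quals, 2))
  expect_equal(dedupe(dup)$id, "a")

  # random reads with a planted duplicate structure
  base <- rand_dna(100)
  pool_bases <- c(replicate(10, mutate_after_prefix(base, sample(0:12, 1))),
                  vapply(1:40, function(i) rand_dna(sample(30:100, 1)), ""))
  pool <- read_set(
    id = paste0("r", 1:50),
    bases = pool_bases,
    quals = vapply(nchar(pool_bases), function(n) strrep("I", n), ""))
  got <- dedupe(pool)
  expect_identical(got$id, pool$id[bf_dedupe_keep(pool)])
  expect_identical(dedupe(got)$id, got$id)
})

test_that("trimming starts at the first high-quality run and stops on the
           cumulative accurate fraction", {
  q40 <- mk_read(rand_dna(50), int_to_phred(rep(40, 50)))
  expect_identical(trim_read(q40)$bases, q40$bases)

  # first window of five quals > 30 begins at (0-based) index 2
  q <- c(10, 10, rep(35, 5), rep(40, 43))
  r <- mk_read(rand_dna(50), int_to_phred(q))
  expect_identical(trim_read(r)$bases, substr(r$bases, 3, 50))

  expect_null(trim_read(mk_read(rand_dna(50), int_to_phred(rep(10, 50)))))
  # a run of five exactly at Q30 is not a start (strict >)
  expect_null(trim_read(mk_read(rand_dna(5), int_to_phred(rep(30, 5)))))

  # once low-quality bases drag the running fraction to 0.5 the read ends
  q <- c(rep(40, 10), rep(10, 50))
  r <- mk_read(rand_dna(60), int_to_phred(q))
  tr <- trim_read(r)
  expect_identical(tr$bases, substr(r$bases, 1, 19))
})

test_that("trim output is a contiguous substring starting with five quals
           above the threshold (oracle over random reads)", {
  set.seed(23)
  p <- clean_params()
  reads <- rand_reads(300, len_range = c(5, 120))
  for (i in seq_len(nrow(reads))) {
    q <- phred_to_int(reads$quals[i])[[1]]
    span <- bf_trim_span(q, p)
    tr <- trim_read(reads[i, ], p)
    if (is.null(span)) {
      expect_null(tr)
    } else {
      expect_identical(tr$bases,
                       substr(reads$bases[i], span[1], span[2]))
      qq <- phred_to_int(tr$quals)[[1]]
      expect_true(all(qq[1:5] > p$start_q))
    }
  }
})
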