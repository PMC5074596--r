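test_that("fpkm closed forms and guards", {
  expect_identical(fpkm(100, 1000, 1e6), 100)
  expect_identical(fpkm(0, 1000, 1e6), 0)
  expect_error(fpkm(1, 1000, 0), "positive")
  expect_error(fpkm(1, 0, 1e6), "positive")
  # linearity: doubling count and total together leaves FPKM unchanged
  expect_equal(fpkm(200, 1000, 2e6), fpkm(100, 1000, 1e6))
})

test_that("reads are assigned with fractional splitting and quality-blind
           mismatches", {
  set.seed(71)
  c1 <- rand_dna(400)
  c2 <- rand_dna(400)
  contigs <- c(c1 = c1, c2 = c2, c2copy = c2)
  inside <- substr(c1, 50, 150)
  flip <- function(b) setdiff(c("A", "C", "G", "T"), b)[1]
  mm2 <- {  # c1[201..300] with guaranteed mismatches at the first two bases
    bv <- strsplit(substr(c1, 201, 300), "")[[1]]
    bv[1:2] <- vapply(bv[1:2], flip, "")
    paste(bv, collapse = "")
  }
  reads <- read_set(
    id = c("unique", "multi", "lowq_mm", "highq_mm", "alien"),
    bases = c(inside, substr(c2, 100, 200), mm2, mm2, rand_dna(101)),
    quals = c(strrep("I", 101), strrep("I", 101),
              paste0("++", strrep("I", 98)),        # Q10 at the mismatches
              strrep("I", 100),
              strrep("I", 101)))
  counts <- assign_reads(reads, contigs)
  expect_equal(unname(counts["c1"]), 2)        # unique + lowq_mm
  expect_equal(unname(counts["c2"]), 0.5)      # multi split across copies
  expect_equal(unname(counts["c2copy"]), 0.5)
  expect_equal(sum(counts), attr(counts, "n_assigned"))
  expect_equal(attr(counts, "n_assigned"), 3L)
})

test_that("mismatches above the quality floor consume the single-mutation
           budget", {
  set.seed(72)
  c1 <- rand_dna(300)
  mut2 <- function(s) {
    bv <- strsplit(s, "")[[1]]
    bv[c(10, 60)] <- vapply(bv[c(10, 60)], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
    paste(bv, collapse = "")
  }
  reads <- read_set(id = c("one_mm", "two_mm"),
                    bases = c({
                      bv <- strsplit(substr(c1, 50, 150), "")[[1]]
                      bv[30] <- setdiff(c("A", "C", "G", "T"), bv[30])[1]
                      paste(bv, collapse = "")
                    }, mut2(substr(c1, 50, 150))),
                    quals = rep(strrep("I", 101), 2))
  counts <- assign_reads(reads, c(c1 = c1))
  expect_equal(unname(counts["c1"]), 1)  # one high-quality mismatch passes
})

test_that("differential classes follow the FPKM floor and log-ratio cuts", {
  expect_equal(de_classify(10, 300), "up_in_B")
  expect_equal(de_classify(0.05, 0.05), "not_expressed")
  expect_equal(de_classify(7, 7), "not_DE")
  expect_equal(de_classify(300, 10), "up_in_A")
  # relabeling samples swaps the directional classes
  set.seed(73)
  fa <- runif(50, 0, 50); fb <- runif(50, 0, 50)
  ab <- de_classify(fa, fb)
  ba <- de_classify(fb, fa)
  swap <- c(up_in_A = "up_in_B", up_in_B = "up_in_A", not_DE = "not_DE",
            not_expressed = "not_expressed")
  expect_identical(unname(swap[ab]), ba)
})

test_that("enrichment score closed forms and antisymmetry", {
  expect_equal(enrich_score(10, 10, 100, 100), 0)
  expect_equal(enrich_score(5, 0, 50, 50), log2(5.05 / 0.05))
  expect_equal(log2(5.05 / 0.05), 6.658, tolerance = 1e-3)
  set.seed(74)
  for (i in 1:20) {
    na <- sample(0:40, 1); nb <- sample(0:40, 1)
    ta <- sample(40:100, 1); tb <- sample(40:100, 1)
    expect_equal(enrich_score(na, nb, ta, tb),
                 -enrich_score(nb, na, tb, ta))
  }
  expect_error(enrich_score(1, 1, 0, 10), "positive")
})

test_that("enrich_table reports both orientations over an annotation", {
  annot <- data.frame(id = c("g1", "g1", "g2", "g3", "g4"),
                      go = c("GO:1", "GO:2", "GO:1", "GO:2", "GO:2"))
  tb <- enrich_table(annot, set_a = c("g1", "g2"), set_b = c("g3", "g4"))
  expect_equal(tb$score_ab, -tb$score_ba)
  r1 <- tb[tb$go == "GO:1", ]
  expect_equal(r1$n_a, 2L)
  expect_equal(r1$n_b, 0L)
  expect_equal(r1$score_ab, log2((2.05 / 2) / (0.05 / 2)))
})
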