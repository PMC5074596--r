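test_that("posterior closed forms and normalization", {
  z <- c(A = 0, C = 0, G = 0, T = 0)
  for (b in c("A", "C", "G", "T")) expect_equal(posterior(z, b), 0.25)
  expect_equal(posterior(c(A = 100, C = 0, G = 0, T = 0), "A"), 105 / 120)
  cc <- c(A = 30, C = 0, G = 30, T = 0)
  expect_equal(posterior(cc, "A"), 35 / 80)
  expect_equal(posterior(cc, "R"), 70 / 80)
  set.seed(41)
  for (i in 1:50) {
    counts <- setNames(sample(0:500, 4, replace = TRUE),
                       c("A", "C", "G", "T"))
    s <- sum(vapply(c("A", "C", "G", "T"),
                    function(b) posterior(counts, b), 0))
    expect_equal(s, 1)
  }
})

test_that("call_base branch order, ambiguity ban and the unanimous depth
           boundary", {
  expect_equal(call_base(c(A = 100, C = 0, G = 0, T = 0), "T"), "A")
  het <- c(A = 30, C = 0, G = 30, T = 0)
  expect_equal(call_base(het, "T"), "R")
  expect_true(is.na(call_base(het, "R")))  # no successive ambiguity codes
  # (N + 5)/(N + 20) >= 0.8 <=> N >= 55
  expect_true(is.na(call_base(c(A = 54, C = 0, G = 0, T = 0), "T")))
  expect_equal(call_base(c(A = 55, C = 0, G = 0, T = 0), "T"), "A")
})

test_that("the unanimous calling depth follows (p*n - n/4)/(1 - p) for any
           threshold", {
  n <- 20
  for (p in c(0.6, 0.7, 0.8, 0.9)) {
    params <- vp_params(p_threshold = p)
    nmin <- ceiling(round((p * n - n / 4) / (1 - p), 9))
    below <- c(A = nmin - 1, C = 0, G = 0, T = 0)
    at <- c(A = nmin, C = 0, G = 0, T = 0)
    expect_true(is.na(call_base(below, "T", params)))
    expect_equal(call_base(at, "T", params), "A")
  }
})

test_that("call_base matches the brute-force rule evaluation on a grid", {
  grid <- expand.grid(A = c(0, 5, 30, 60, 120), C = c(0, 30, 60),
                      G = c(0, 30, 120), T = c(0, 5, 60))
  for (prev in c("A", "T", "R", "W")) {
    for (r in seq_len(nrow(grid))) {
      counts <- unlist(grid[r, ])
      got <- call_base(counts, prev)
      ref <- bf_call_base(counts, prev)
      expect_identical(got, ref,
                       info = paste(paste(counts, collapse = ","), prev))
    }
  }
})

test_that("one extension round recovers missing terminal bases from
           error-free reads", {
  set.seed(43)
  cfg <- sim_config(n_transcripts = 1, len_range = c(600, 600),
                    coverage = 300, error_rate = 0, het_rate = 0,
                    trunc = c(0, 60), seed = 43)
  sim <- simulate_dataset(cfg)
  store <- build_store(sim$reads)
  res <- extend_once(sim$contigs[[1]], "three_prime", store,
                     max_mismatch = 1)
  tpl <- sim$templates[[1]]
  expect_gt(nchar(res$added), 0)
  expect_lte(nchar(res$added), 81)  # read length 101 minus the primer
  expect_identical(res$added,
                   substr(tpl, 541, 540 + nchar(res$added)))
  # no recruiting reads: nothing appended
  empty_store <- build_store(strrep("ACGT", 30))
  res0 <- extend_once(sim$contigs[[1]], "three_prime", empty_store, 1)
  expect_identical(res0$added, "")
})

test_that("vpseq_extend reaches a fixpoint, preserves the input contig
           verbatim, and reports per-round logs", {
  set.seed(44)
  cfg <- sim_config(n_transcripts = 2, len_range = c(900, 1200),
                    coverage = 200, error_rate = 0, het_rate = 0,
                    trunc = c(150, 150), seed = 44)
  sim <- simulate_dataset(cfg)
  store <- build_store(sim$reads)
  r <- vpseq_extend(setNames(sim$contigs[1], names(sim$contigs)[1]), store)
  ctg <- r$contig
  expect_identical(vpseq:::core_seq(ctg), sim$contigs[[1]])
  expect_identical(ctg$bases, sim$templates[[1]])
  expect_gte(r$report$rounds, 2)  # 150 bp needs > 1 round at 81 bp max
  expect_equal(r$report$added5 + r$report$added3,
               nchar(ctg$bases) - nchar(sim$contigs[[1]]))
  # running extension on its own output adds nothing
  r2 <- vpseq_extend(ctg, store)
  expect_identical(r2$contig$bases, ctg$bases)
  expect_equal(r2$report$added5 + r2$report$added3, 0)
  # unmatched contig: unchanged, a single round
  lone <- setNames(strrep("TTAGGCAT", 30), "lone")
  r3 <- vpseq_extend(lone, store)
  expect_identical(r3$contig$bases, unname(lone))
  expect_equal(r3$report$rounds, 1)
})

test_that("heterozygous 50/50 sites are called as the correct two-base code
           with unambiguous neighbors", {
  set.seed(45)
  cfg <- sim_config(n_transcripts = 3, len_range = c(900, 1200),
                    coverage = 200, error_rate = 0, het_rate = 0.004,
                    trunc = c(120, 120), seed = 45)
  sim <- simulate_dataset(cfg)
  store <- build_store(sim$reads)
  res <- batch_extend(sim$contigs, store)
  ev <- evaluate_extension(res, sim)
  expect_gt(ev$summary$het_sites_scored, 0)
  expect_equal(ev$summary$het_code_accuracy, 1)
  for (r in res) {
    expect_false(grepl("[RYKMSW]{2}", r$contig$bases))
  }
})

test_that("batch extension is order-independent and never shortens", {
  set.seed(46)
  cfg <- sim_config(n_transcripts = 3, len_range = c(900, 1000),
                    coverage = 150, error_rate = 0, het_rate = 0,
                    trunc = c(60, 60), seed = 46)
  sim <- simulate_dataset(cfg)
  store <- build_store(sim$reads)
  res <- batch_extend(sim$contigs, store)
  expect_length(res, 3)
  lens_in <- nchar(sim$contigs)
  lens_out <- vapply(res, function(r) nchar(r$contig$bases), 0)
  expect_true(all(lens_out >= lens_in))
  perm <- c(3, 1, 2)
  res_p <- batch_extend(sim$contigs[perm], store)
  expect_identical(vapply(res_p, function(r) r$contig$bases, ""),
                   vapply(res, function(r) r$contig$bases, "")[perm])
})
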