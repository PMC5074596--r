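test_that("the generator is reproducible from its seed and honors per-
           transcript coverage", {
  cfg <- sim_config(n_transcripts = 3, len_range = c(900, 1200),
                    coverage = c(0, 60, 60), error_rate = 0.001,
                    het_rate = 0.001, seed = 9)
  s1 <- simulate_dataset(cfg)
  s2 <- simulate_dataset(cfg)
  expect_identical(s1$templates, s2$templates)
  expect_identical(s1$reads, s2$reads)
  expect_false(any(startsWith(s1$reads$id, "tx001")))  # coverage 0
  expect_true(any(startsWith(s1$reads$id, "tx002")))
})

test_that("realized coverage tracks the request at deep coverage", {
  cfg <- sim_config(n_transcripts = 4, len_range = c(900, 1500),
                    coverage = 120, error_rate = 0, het_rate = 0, seed = 10)
  sim <- simulate_dataset(cfg)
  realized <- sum(nchar(sim$reads$bases)) / sum(nchar(sim$templates))
  expect_equal(realized, 120, tolerance = 0.1)
})

test_that("planted ORFs classify as full length on untruncated templates", {
  cfg <- sim_config(n_transcripts = 8, len_range = c(900, 2000),
                    coverage = 1, seed = 11)
  sim <- simulate_dataset(cfg)
  for (id in names(sim$templates)) {
    call <- classify_orf(setNames(sim$templates[id], id))
    expect_equal(call$class, "full_length")
    g <- sim$gold[[match(id, vapply(sim$gold, `[[`, "", "id"))]]
    expect_equal(call$start, g$cds_start)
  }
})

test_that("truncated contigs are substrings of their templates with
           consistent coordinates", {
  cfg <- sim_config(n_transcripts = 5, len_range = c(900, 1300),
                    coverage = 1, trunc = c(150, 150), seed = 12)
  sim <- simulate_dataset(cfg)
  for (i in seq_along(sim$gold)) {
    g <- sim$gold[[i]]
    expect_identical(sim$contigs[[i]],
                     substr(sim$templates[[i]], g$trunc5 + 1,
                            g$length - g$trunc3))
  }
})

test_that("evaluation scores perfect, absent and het-aware recovery
           correctly", {
  cfg <- sim_config(n_transcripts = 2, len_range = c(900, 1000),
                    coverage = 1, trunc = c(100, 100), het_rate = 0,
                    seed = 13)
  sim <- simulate_dataset(cfg)
  ids <- names(sim$contigs)
  # hand-built "results": transcript 1 fully recovered, transcript 2 not
  # extended at all
  full <- contig(ids[1], sim$templates[[1]],
                 core_span = c(100, nchar(sim$templates[[1]]) - 100))
  stub <- contig(ids[2], sim$contigs[[2]])
  res <- setNames(list(list(contig = full), list(contig = stub)), ids)
  ev <- evaluate_extension(res, sim)
  expect_equal(ev$per_contig$recovery, c(1, 0))
  expect_equal(ev$per_contig$identity, c(1, 1))
  # a wrong base in the recovered span is charged to identity
  bv <- strsplit(sim$templates[[1]], "")[[1]]
  bv[50] <- setdiff(c("A", "C", "G", "T"), bv[50])[1]
  wrong <- contig(ids[1], paste(bv, collapse = ""),
                  core_span = c(100, nchar(sim$templates[[1]]) - 100))
  ev2 <- evaluate_extension(setNames(list(list(contig = wrong)), ids[1]),
                            sim)
  expect_equal(ev2$per_contig$identity, 1 - 1 / 200)
  expect_error(evaluate_extension(setNames(list(list(contig = full)), "zz"),
                                  sim), "zz")
})

test_that("datasets write to disk as FASTA/FASTQ/JSON and read back", {
  cfg <- sim_config(n_transcripts = 2, len_range = c(900, 1000),
                    coverage = 5, seed = 14)
  sim <- simulate_dataset(cfg)
  dir <- withr::local_tempdir()
  write_sim_dataset(sim, dir)
  expect_identical(read_fasta(file.path(dir, "templates.fasta")),
                   sim$templates)
  back <- read_fastq(file.path(dir, "reads.fastq"))
  expect_identical(back$bases, sim$reads$bases)
  gold <- jsonlite::read_json(file.path(dir, "gold.json"))
  expect_equal(length(gold), 2L)
  back2 <- read_sim_dataset(dir)
  expect_identical(back2$templates, sim$templates)
  expect_identical(back2$alleles_b, sim$alleles_b)
  expect_equal(back2$gold[[1]]$trunc5, sim$gold[[1]]$trunc5)
})

test_that("impossible configurations are rejected", {
  expect_error(sim_config(read_len = 1000, len_range = c(900, 950)),
               "read length")
})
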