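test_that("markov_from_gc builds the stated base probabilities", {
  m <- markov_from_gc(0.5, order = 0)
  expect_equal(unname(m$transition[1, ]), rep(0.25, 4))
  m2 <- markov_from_gc(0.5764, order = 2)
  expect_equal(nrow(m2$transition), 16L)
  expect_equal(sum(m2$transition[1, c("C", "G")]), 0.5764)
  expect_equal(unname(rowSums(m2$transition)), rep(1, 16))
  # skew splits GC mass asymmetrically but preserves total GC
  ms <- markov_from_gc(0.6, order = 1, skew = 0.2)
  expect_equal(unname(ms$transition[1, "G"]), 0.6 / 2 * 1.2)
  expect_equal(sum(ms$transition[1, c("C", "G")]), 0.6)
  # default donor vs background GC gap exceeds 0.2
  expect_gt(0.5764 - 0.35, 0.2)
  expect_error(markov_from_gc(1.2), "between 0 and 1")
  expect_error(markov_from_gc(0.5, order = 3), "order")
})

test_that("fit_markov recovers transition structure", {
  # strict alternation
  m <- fit_markov(strrep("AC", 200), order = 1)
  expect_gt(m$transition["A", "C"], 0.98)
  expect_gt(m$transition["C", "A"], 0.98)
  # order-0 fit returns observed GC
  s <- strrep("GGCC", 30)
  m0 <- fit_markov(s, order = 0)
  expect_equal(sum(m0$transition[1, c("C", "G")]),
               genome_stats(s)$gc_fraction, tolerance = 0.02)
  expect_error(fit_markov("ACGT", order = 2), "too short")
})

test_that("fit -> simulate -> refit recovers the transition matrix", {
  set.seed(61)
  src <- random_dna(8000, gc = 0.6)
  m1 <- fit_markov(src, order = 1)
  sim <- simulate_markov(m1, 100000, seed = 62)
  m2 <- fit_markov(sim, order = 1)
  expect_lt(max(abs(m1$transition - m2$transition)), 0.02)
})

test_that("simulation is seed-deterministic and seed-sensitive", {
  m <- markov_from_gc(0.5764, order = 2)
  a <- simulate_markov(m, 5000, seed = 7)
  b <- simulate_markov(m, 5000, seed = 7)
  expect_identical(a, b)
  c <- simulate_markov(m, 5000, seed = 8)
  ham <- mean(strsplit(a, "")[[1]] != strsplit(c, "")[[1]])
  expect_gt(ham, 0.3)
  expect_equal(nchar(simulate_markov(m, 1, seed = 1)), 1L)
  # the generic simulate() method produces nsim sequences from one seed
  two <- simulate(m, nsim = 2, seed = 9, L = 100)
  expect_length(two, 2L)
  expect_false(two[1] == two[2])
})

test_that("realized GC concentrates around the model GC", {
  m <- markov_from_gc(0.5764, order = 2)
  gcs <- vapply(1:20, function(s)
    genome_stats(simulate_markov(m, 40452, seed = s))$gc_fraction,
    numeric(1))
  expect_true(all(abs(gcs - 0.5764) < 0.02))
  # a genuinely context-dependent model also hits its stationary GC
  set.seed(63)
  mh <- fit_markov(random_dna(20000, gc = 0.4), order = 2)
  g <- simulate_markov(mh, 50000, seed = 64)
  expect_equal(genome_stats(g)$gc_fraction, 0.4, tolerance = 0.03)
})

test_that("make_chimera places inserts exactly and emits matching truth", {
  ch <- make_chimera(seed = 1)
  expect_equal(ch$record$length, 40452L)
  expect_equal(ch$truth$start, 28000L)
  expect_equal(ch$truth$end, 34000L)
  # the inserted segment is GC-poor relative to the backbone
  ins <- substr(ch$record$seq, 28001, 34000)
  rest <- paste0(substr(ch$record$seq, 1, 28000),
                 substr(ch$record$seq, 34001, 40452))
  expect_lt(genome_stats(ins)$gc_fraction, 0.40)
  expect_gt(genome_stats(rest)$gc_fraction, 0.53)
  # toy ORFs tile the genome in 600 bp steps with unique ids
  expect_equal(ch$features$end - ch$features$start,
               rep(600L, nrow(ch$features)))
  expect_false(anyDuplicated(ch$features$feature_id) > 0)

  # zero inserts -> pure background
  ch0 <- make_chimera(insert_spans = list(), seed = 2)
  expect_equal(nrow(ch0$truth), 0L)
  expect_gt(genome_stats(ch0$record)$gc_fraction, 0.55)

  # two disjoint inserts recorded in order
  ch2 <- make_chimera(insert_spans = list(c(30000L, 3000L), c(5000L, 3000L)),
                      seed = 3)
  expect_equal(ch2$truth$start, c(5000L, 30000L))
  expect_equal(ch2$truth$end, c(8000L, 33000L))
  expect_error(make_chimera(insert_spans = list(c(1000L, 3000L),
                                                c(2000L, 500L))),
               "overlap")
  expect_error(make_chimera(insert_spans = list(c(39000L, 3000L))),
               "outside")
})

test_that("chimera determinism holds end to end", {
  a <- make_chimera(seed = 5)
  b <- make_chimera(seed = 5)
  expect_identical(a$record$seq, b$record$seq)
  expect_identical(a$truth$start, b$truth$start)
})

test_that("chimera outputs round-trip through the writers", {
  dir <- withr::local_tempdir()
  ch <- make_chimera(L = 6000L, insert_spans = list(c(2000L, 1000L)),
                     seed = 6)
  paths <- write_chimera(ch, file.path(dir, "sim"))
  expect_true(all(file.exists(paths)))
  rec <- read_fasta(paths[1])
  expect_identical(rec$seq, ch$record$seq)
  feats <- read_features(paths[3], "tsv", record = rec)
  expect_equal(feats$start, ch$features$start)
  expect_equal(feats$end, ch$features$end)
})
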