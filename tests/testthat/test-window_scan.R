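test_that("window partitioning matches the stated scheme", {
  w <- make_windows(40452, 10000, 1000)
  expect_equal(nrow(w), 41L)
  expect_equal(w$start, seq(0L, 40000L, by = 1000L))
  expect_equal(w$end, pmin(w$start + 10000L, 40452L))

  w2 <- make_windows(10000, 10000, 1000)
  expect_equal(nrow(w2), 10L)
  expect_equal(w2$end[1] - w2$start[1], 10000L)
  expect_true(all(w2$end[-1] - w2$start[-1] < 10000L))

  expect_equal(nrow(make_windows(10000, 10000, 1000,
                                 include_truncated = FALSE)), 1L)
  expect_error(make_windows(1000, 10, 20), "window >= step")
  expect_error(make_windows(0, 10, 5), "L must be")
})

test_that("windows cover every base between 1 and ceiling(window/step) times", {
  for (L in c(437L, 5000L, 12345L)) {
    w <- make_windows(L, 1000, 250)
    expect_equal(nrow(w), ceiling(L / 250))
    cov <- integer(L)
    for (i in seq_len(nrow(w)))
      cov[(w$start[i] + 1):w$end[i]] <- cov[(w$start[i] + 1):w$end[i]] + 1L
    expect_true(all(cov >= 1L))
    expect_true(all(cov <= ceiling(1000 / 250)))
    expect_equal(sort(unique(w$start %% 250)), 0L)
  }
})

test_that("a genome equal to one window correlates with itself at exactly 1", {
  g <- random_dna(5000, gc = 0.58)
  p <- window_profile(g, window = 5000, step = 1000)
  expect_identical(p$windows$r[1], 1.0)
  p1 <- window_profile(g, window = 10000, step = 1000)  # window > genome
  expect_equal(nrow(p1$windows), 5L)
  expect_identical(p1$windows$r[1], 1.0)
})

test_that("profiles are deterministic for identical input", {
  g <- random_dna(30000, gc = 0.55)
  p1 <- window_profile(g)
  p2 <- window_profile(g)
  expect_identical(p1$windows, p2$windows)
  expect_identical(p1$genome_signature$z, p2$genome_signature$z)
})

test_that("uniform-composition genomes show no low full-window correlations", {
  mins <- vapply(1:5, function(s) {
    g <- simulate_markov(markov_from_gc(0.5764, 2), 40000, seed = 400 + s)
    p <- window_profile(g)
    full <- with(p$windows, end - start == 10000L)
    min(p$windows$r[full])
  }, numeric(1))
  expect_true(all(mins >= 0.8))
})

test_that("anomaly calling flags a constructed dip and merges regions", {
  # constant profile: MAD = 0, cut = median, nothing strictly below
  quiet <- fake_profile(rep(0.99, 40))
  a0 <- call_anomalies(quiet)
  expect_equal(nrow(a0$regions), 0L)

  # one dip among 40 quiet windows -> exactly that window's span
  r <- rep(0.97, 41) + seq(-0.002, 0.002, length.out = 41)
  r[15] <- 0.5
  prof <- fake_profile(r)
  a1 <- call_anomalies(prof)
  expect_equal(nrow(a1$regions), 1L)
  expect_equal(a1$regions$start, prof$windows$start[15])
  expect_equal(a1$regions$end, prof$windows$end[15])
  expect_equal(a1$regions$min_r, 0.5)

  # two dips further apart than one step stay separate regions
  r2 <- rep(0.97, 41) + seq(-0.002, 0.002, length.out = 41)
  r2[c(5, 30)] <- 0.4
  a2 <- call_anomalies(fake_profile(r2))
  expect_equal(nrow(a2$regions), 2L)

  # adjacent dips merge
  r3 <- rep(0.97, 41) + seq(-0.002, 0.002, length.out = 41)
  r3[10:13] <- 0.4
  a3 <- call_anomalies(fake_profile(r3))
  expect_equal(nrow(a3$regions), 1L)
  expect_equal(a3$regions$start, fake_profile(r3)$windows$start[10])
  expect_equal(a3$regions$end, fake_profile(r3)$windows$end[13])
})

test_that("lowering a fixed threshold never increases flagged windows", {
  set.seed(77)
  r <- 0.9 + rnorm(41, sd = 0.05)
  prof <- fake_profile(r)
  spans <- vapply(seq(0.99, 0.7, by = -0.01), function(th) {
    a <- call_anomalies(prof, threshold = th)
    sum(a$regions$end - a$regions$start)
  }, numeric(1))
  expect_true(all(diff(spans) <= 0))
})

test_that("feature scores take the minimum r over overlapping windows", {
  r <- rep(0.97, 41) + seq(-0.002, 0.002, length.out = 41)
  r[15] <- 0.5  # window [14000, 24000)
  prof <- fake_profile(r)
  feats <- data.frame(feature_id = c("inside", "outside"),
                      start = c(15000L, 30000L), end = c(15600L, 30600L),
                      strand = "+")
  a <- call_anomalies(prof, feats)
  expect_equal(a$features$min_r[a$features$feature_id == "inside"], 0.5)
  expect_true(a$features$flagged[a$features$feature_id == "inside"])
  expect_false(a$features$flagged[a$features$feature_id == "outside"])
  # every flagged feature overlaps a flagged region
  for (i in which(a$features$flagged)) {
    f <- feats[feats$feature_id == a$features$feature_id[i], ]
    expect_true(any(a$regions$start < f$end & a$regions$end > f$start))
  }
})

test_that("missing and short-window correlations are never flagged", {
  r <- rep(0.97, 41) + seq(-0.002, 0.002, length.out = 41)
  r[41] <- NA  # truncated terminal window, undefined
  prof <- fake_profile(r, L = 40452L)
  a <- call_anomalies(prof)
  expect_equal(nrow(a$regions), 0L)
  expect_error(call_anomalies(fake_profile(rep(NA_real_, 5))),
               "degenerate")
  # a deep dip in a truncated window is ignored at default min_len,
  # caught with min_len = 0
  r2 <- rep(0.97, 41) + seq(-0.002, 0.002, length.out = 41)
  r2[41] <- 0.2
  prof2 <- fake_profile(r2, L = 40452L)
  expect_equal(nrow(call_anomalies(prof2)$regions), 0L)
  expect_equal(nrow(call_anomalies(prof2, min_len = 0)$regions), 1L)
})

test_that("the chimera insert is recovered as the lowest-correlation region", {
  hits <- 0L
  for (s in 1:5) {
    ch <- make_chimera(seed = 500 + s)
    p <- window_profile(ch$record)
    i <- which.min(p$windows$r)
    hits <- hits + (p$windows$start[i] < default_truth_end &&
                      p$windows$end[i] > default_truth_start)
    a <- call_anomalies(p, ch$features)
    inside <- ch$features$start >= default_truth_start &
      ch$features$end <= default_truth_end
    flagged <- a$features$flagged
    # all truth ORFs flagged; flagged ORFs within one window of truth
    expect_true(all(flagged[inside]))
    expect_true(all(ch$features$start[flagged] < default_truth_end + 10000 &
                      ch$features$end[flagged] > default_truth_start - 10000))
  }
  expect_equal(hits, 5L)
})
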