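test_that("partition_windows cuts equal windows and discards the remainder", {
  p <- segmentation_params()
  w <- partition_windows(make_seq_gc(100000, 40), p)
  expect_equal(nrow(w), 4L)
  expect_equal(w$end - w$start, rep(25000L, 4))

  w2 <- partition_windows(make_seq_gc(110000, 40), p)
  expect_equal(nrow(w2), 4L)            # trailing 10 kb discarded
  expect_equal(max(w2$end), 100000L)

  w3 <- partition_windows(strrep("G", 25000), p)
  expect_equal(w3$gc_percent, 100)

  expect_warning(w4 <- partition_windows(strrep("A", 10000), p),
                 "shorter than one window")
  expect_equal(nrow(w4), 0L)
})

test_that("gap-rich windows are flagged invalid and break segments", {
  p <- segmentation_params(window_size = 1000L)
  s <- paste0(make_seq_gc(1000, 40), strrep("N", 1000), make_seq_gc(1000, 40))
  w <- partition_windows(s, p)
  expect_equal(w$valid, c(TRUE, FALSE, TRUE))
  segs <- segment_chromosome(w, p)
  expect_equal(nrow(segs), 2L)          # not bridged across the gap
  expect_equal(segs$size, c(1000, 1000))
})

test_that("greedy segmentation merges by running mean within threshold", {
  p <- segmentation_params()
  segs <- segment_chromosome(make_windows(c(40, 40, 40, 40)), p)
  expect_equal(nrow(segs), 1L)
  expect_equal(segs$gc_percent, 40)
  expect_equal(segs$size, 4 * 25000)

  segs2 <- segment_chromosome(make_windows(c(40, 40, 60, 60)), p)
  expect_equal(nrow(segs2), 2L)
  expect_equal(segs2$n_windows, c(2L, 2L))
  expect_equal(segs2$gc_percent, c(40, 60))

  # running-mean semantics: 41 joins {40} (diff 1), 42 joins {40,41}
  # (diff from mean 40.5 is 1.5, inclusive), 43 breaks (diff 1.75)
  segs3 <- segment_chromosome(make_windows(c(40, 41, 42, 43)), p)
  expect_equal(segs3$n_windows, c(3L, 1L))
  expect_equal(segs3$gc_percent, c(41, 43))

  expect_equal(nrow(segment_chromosome(make_windows(numeric(0)), p)), 0L)
  expect_equal(nrow(segment_chromosome(make_windows(c(40, 50),
                                                    valid = FALSE), p)), 0L)
})

test_that("segmentation matches the brute-force oracle on random cases", {
  set.seed(42)
  for (rep in 1:300) {
    n <- sample(1:12, 1)
    gcs <- sample(c(30, 35, 40, 45, 50, 55, 60), n, replace = TRUE)
    thr <- sample(c(1.5, 4, 7, 11, 16), 1)
    p <- segmentation_params(merge_threshold = thr)
    got <- segment_chromosome(make_windows(gcs), p)
    want <- oracle_segment(gcs, thr)
    expect_equal(got$n_windows, want$sizes)
    expect_equal(got$gc_percent, want$means)
  }
})

test_that("raising the merge threshold never increases segment count", {
  set.seed(7)
  for (rep in 1:40) {
    gcs <- runif(20, 30, 60)
    counts <- vapply(c(0.5, 1.5, 3, 6, 12, 30), function(thr) {
      nrow(segment_chromosome(make_windows(gcs),
                              segmentation_params(merge_threshold = thr)))
    }, 0L)
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("segments conserve windows and length-weighted mean GC", {
  set.seed(11)
  for (rep in 1:30) {
    gcs <- runif(25, 20, 70)
    valid <- runif(25) > 0.1
    w <- make_windows(gcs)
    w$valid <- valid
    segs <- segment_chromosome(w, segmentation_params(merge_threshold = 3))
    expect_equal(sum(segs$n_windows), sum(valid))
    expect_equal(sum(segs$size), sum(valid) * 25000)
    # no overlap, ordered
    if (nrow(segs) > 1) {
      expect_true(all(segs$start[-1] >= segs$end[-nrow(segs)]))
    }
    if (any(valid)) {
      expect_equal(sum(segs$gc_percent * segs$size) / sum(segs$size),
                   mean(gcs[valid]), tolerance = 1e-9)
    }
  }
})

test_that("segment names follow the <chrom><Gg><index> convention", {
  expect_equal(name_segment(3, "Saccharomyces cerevisiae", 2), "3Sc2")
  expect_equal(name_segment(1, "Plasmodium vivax", 1), "1Pv1")
  expect_error(name_segment(2, "Ostreococcus", 1), "genus and species")
})

test_that("heterogeneity is the sample sd of valid window GC", {
  expect_equal(heterogeneity(make_windows(c(40, 40, 40))), 0)
  expect_equal(heterogeneity(make_windows(c(40, 60))), sqrt(200))
  expect_error(heterogeneity(make_windows(40)), "at least 2")
  w <- make_windows(c(40, 60, 80))
  w$valid[3] <- FALSE
  expect_equal(heterogeneity(w), sqrt(200))
})

test_that("window-size comparison recovers the same families at 25 and 100 kb", {
  spec <- genome_spec(
    list(family_spec(38, 0.5, segment_length_mean = 500000,
                     segment_length_sd = 200000),
         family_spec(46, 0.5, segment_length_mean = 500000,
                     segment_length_sd = 200000)),
    n_chromosomes = 1L, chromosome_length = 20000000L,
    window_noise_sd = 1, seed = 19L)
  sim <- simulate_genome(spec)
  cmp <- compare_window_sizes(sim$assembly[[1]],
                              sizes = c(25000L, 100000L))
  expect_gte(cmp[["25000"]]$heterogeneity, cmp[["100000"]]$heterogeneity)
  # the two dominant modes agree across window sizes and with the truth;
  # coarse windows straddling family boundaries may add minor
  # intermediate mass, so comparison is on the two heaviest families
  top2 <- function(fam) {
    sort(fam$mean_gc[order(fam$relative_amount,
                           decreasing = TRUE)][1:2])
  }
  fam25 <- detect_families(cmp[["25000"]]$profile)
  fam100 <- detect_families(cmp[["100000"]]$profile)
  expect_gte(nrow(fam25), 2L)
  expect_gte(nrow(fam100), 2L)
  expect_true(all(abs(top2(fam25) - top2(fam100)) <= 0.5))
  expect_true(all(abs(top2(fam25) - c(38, 46)) <= 0.5))
})
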