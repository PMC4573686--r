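# Coverage tracks, windowed identity, coverage-identity correlation.

test_that("coverage from hits counts interval membership and conserves mass", {
  h <- data.frame(t_start = c(0L, 50L), t_end = c(100L, 150L))
  cov <- coverage_from_hits(h, 200L)
  expect_equal(length(cov), 200L)
  expect_equal(cov[1], 1L)
  expect_equal(cov[60], 2L)
  expect_equal(cov[151], 0L)
  expect_equal(sum(cov), sum(h$t_end - h$t_start))
  expect_equal(coverage_from_hits(h[0, ], 50L), integer(50))
  expect_error(coverage_from_hits(data.frame(t_start = -1L, t_end = 10L), 50L),
               "outside")
})

test_that("windowed identity localizes divergence", {
  a <- rand_dna(8000, seed = 71)
  it <- windowed_identity(a, a, window = 1000, step = 500)
  expect_equal(length(it$identity), ceiling(8000 / 500))
  expect_true(all(it$identity == 1))
  # every 10th base substituted: interior windows around 0.9
  ch <- strsplit(a, "", fixed = TRUE)[[1]]
  ix <- seq(10, 8000, 10)
  ch[ix] <- chartr("ACGT", "CGTA", ch[ix])
  b <- paste(ch, collapse = "")
  it2 <- windowed_identity(a, b, window = 1000, step = 500)
  expect_true(all(abs(it2$identity[2:13] - 0.9) < 0.02))
  # a planted 500 bp divergent block is the minimum-identity window
  set.seed(71)
  blk_start <- 4000L
  ch2 <- strsplit(a, "", fixed = TRUE)[[1]]
  ch2[(blk_start + 1):(blk_start + 500)] <-
    sample(c("A", "C", "G", "T"), 500, TRUE)
  b2 <- paste(ch2, collapse = "")
  it3 <- windowed_identity(a, b2, window = 1000, step = 500)
  wmin <- which.min(it3$identity)
  wlo <- (wmin - 1) * 500
  expect_true(wlo < blk_start + 500 && wlo + 1000 > blk_start)
})

test_that("coverage-identity correlation flags degenerate input and random nulls", {
  it <- windowed_identity(rand_dna(5000, seed = 72), rand_dna(5000, seed = 72),
                          window = 500, step = 250)
  flat <- rep(10L, 5000)
  r <- correlate_coverage_identity(flat, it)
  expect_true(r$degenerate)
  expect_equal(r$pearson, 0)
  # permuted identity against random coverage: |r| small
  set.seed(72)
  it$identity <- runif(length(it$identity), 0.8, 1)
  cov <- as.integer(rpois(5000, 30))
  r2 <- correlate_coverage_identity(cov, it)
  expect_lt(abs(r2$pearson), 0.35)
  expect_error(correlate_coverage_identity(rep(1L, 10), it), "different lengths")
})

test_that("read recruitment drops where the reference diverges, giving positive correlation", {
  # heterologous reference at ~5% divergence with a planted 70%-identity
  # block; reads recruited at the 80% threshold thin out over the block
  g <- rand_dna(16000, seed = 73)
  set.seed(73)
  ref <- plastidkit:::mutate_seq(g, 0.05, c(0, 0, 1))$seq
  ch <- strsplit(ref, "", fixed = TRUE)[[1]]
  blk <- 8001:11000
  flip <- sample(blk, round(0.3 * length(blk)))
  ch[flip] <- chartr("ACGT", "CGTA", ch[flip])
  ref <- paste(ch, collapse = "")
  cfg <- mini_config(seed = 73)
  lr <- simulate_long_reads(g, coverage = 25, config = cfg)
  wl <- classify_reads(lr$reads, ref)
  kept <- extract_by_whitelist(lr$reads, wl)
  hits <- map_set(kept, target = paste0(g, substr(g, 1, 6000)))
  hits$t_end <- pmin(hits$t_end, 16000L)
  cov <- coverage_from_hits(hits[hits$t_start < 16000, ], 16000L)
  it <- windowed_identity(g, ref, window = 1000, step = 500)
  r <- correlate_coverage_identity(cov, it)
  expect_gte(r$pearson, 0.5)
})

test_that("dual linearization keeps the coordinate contract in the interior", {
  g <- rand_dna(6000, seed = 74)
  cfg <- mini_config(seed = 74, read_error_rate = 0)
  lr <- simulate_long_reads(g, coverage = 8, config = cfg)
  tr <- circular_coverage(lr$reads, g, end_window = 500)
  expect_equal(tr$length, 6000L)
  mid <- 1500:4500
  # interior positions come from the primary linearization untouched
  expect_equal(tr$values[mid], tr$naive[mid])
  # zero reads give a zero track
  tr0 <- circular_coverage(lr$reads[0, ], g, end_window = 500)
  expect_true(all(tr0$values == 0))
})
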