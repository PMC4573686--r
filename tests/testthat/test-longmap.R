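# Minimizer index and approximate mapper.

test_that("minimizer index is canonical and has the expected density", {
  s <- rand_dna(10000, seed = 21)
  mz <- plastidkit:::minimizers_cpp(s, 15L, 10L)
  dens <- nrow(mz) / nchar(s)
  expect_gt(dens, (2 / 11) / 2)
  expect_lt(dens, (2 / 11) * 2)
  # a sequence and its reverse complement share the canonical k-mer multiset
  mz_rc <- plastidkit:::minimizers_cpp(revcomp(s), 15L, 10L)
  expect_equal(sort(mz$key), sort(mz_rc$key))
  # a sequence of length k indexes exactly one k-mer
  one <- plastidkit:::minimizers_cpp(rand_dna(15, seed = 1), 15L, 10L)
  expect_equal(nrow(one), 1L)
  expect_error(index_reference("ACGT", k = 15), "shorter than k")
})

test_that("exact substrings map with identity 1 at the correct interval and strand", {
  g <- rand_dna(20000, seed = 22)
  idx <- index_reference(g)
  h <- map_read(substr(g, 5001, 7000), idx)
  expect_equal(nrow(h), 1L)
  expect_equal(h$t_start, 5000L)
  expect_equal(h$t_end, 7000L)
  expect_equal(h$strand, "+")
  expect_equal(h$identity, 1)
  h2 <- map_read(revcomp(substr(g, 5001, 7000)), idx)
  expect_equal(h2$strand, "-")
  expect_equal(h2$identity, 1)
  expect_equal(h2$t_start, 5000L)
  # unrelated sequence does not map
  expect_equal(nrow(map_read(rand_dna(2000, seed = 23), idx)), 0L)
})

test_that("mapping a noisy read matches an exhaustive alignment oracle", {
  g <- rand_dna(20000, seed = 24)
  idx <- index_reference(g)
  set.seed(24)
  for (r in 1:5) {
    s0 <- sample(1000:15000, 1)
    read <- plastidkit:::mutate_seq(substr(g, s0 + 1, s0 + 3000), 0.11)$seq
    h <- map_read(read, idx)
    expect_equal(nrow(h), 1L)
    # interval overlaps >= 95% of the truth
    ov <- min(h$t_end, s0 + 3000) - max(h$t_start, s0)
    expect_gt(ov / 3000, 0.95)
    # identity within 0.03 of full (unbanded) DP against the true window
    margin <- 400L
    win <- substr(g, max(1, s0 - margin), min(nchar(g), s0 + 3000 + margin))
    n <- nchar(read); m <- nchar(win)
    oracle <- plastidkit:::align_band_cpp(read, win, TRUE, -m, m)
    st <- plastidkit:::ops_stats_cpp(oracle$ops)
    oid <- st[["n_match"]] / nchar(oracle$ops)
    expect_lt(abs(h$identity - oid), 0.03)
  }
})

test_that("map_set is batch-invariant and deterministic", {
  g <- rand_dna(15000, seed = 25)
  set.seed(25)
  reads <- data.frame(
    id = sprintf("r%02d", 1:20),
    seq = vapply(1:20, function(i) {
      s0 <- sample(1000:10000, 1)
      plastidkit:::mutate_seq(substr(g, s0, s0 + 1500), 0.11)$seq
    }, ""), stringsAsFactors = FALSE)
  idx <- index_reference(g)
  all_at_once <- map_set(reads, index = idx)
  one_by_one <- do.call(rbind, lapply(1:20, function(i)
    map_set(reads[i, , drop = FALSE], index = idx)))
  rownames(one_by_one) <- NULL
  expect_equal(all_at_once, one_by_one)
  expect_equal(map_set(reads, index = idx), all_at_once)
  expect_equal(nrow(map_set(reads[0, ], index = idx)), 0L)
})

test_that("simulated reads map back onto their true intervals", {
  cfg <- sim_config(seed = 26)
  g <- rand_dna(20000, seed = 26)
  lr <- simulate_long_reads(g, n_reads = 100, config = cfg)
  wrap <- max(nchar(lr$reads$seq))
  ext <- paste0(g, substr(g, 1, wrap))
  idx <- index_reference(ext)
  hits <- map_set(lr$reads, index = idx)
  best <- hits[!duplicated(hits$read_id), ]
  jac <- vapply(seq_len(nrow(lr$truth)), function(i) {
    tr <- lr$truth[i, ]
    h <- best[best$read_id == tr$id, ]
    if (nrow(h) == 0) return(0)
    inter <- max(0, min(h$t_end, tr$end) - max(h$t_start, tr$start))
    inter / (max(h$t_end, tr$end) - min(h$t_start, tr$start))
  }, 0)
  expect_gte(mean(jac >= 0.9), 0.98)
})
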