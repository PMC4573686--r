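# Circularity, inverted repeats, quadripartite partition, rotation, SSC flip.

test_that("overlapping ends are detected, trimmed, and absent from random contigs", {
  S <- rand_dna(60000, seed = 41)
  contig <- paste0(S, substr(S, 1, 5000))
  r <- check_circularity(contig, min_overlap = 1000)
  expect_true(r$is_circular)
  expect_equal(r$overlap_len, 5000L)
  expect_identical(r$trimmed_seq, S)
  # trimming is complete: no residual overlap
  expect_false(check_circularity(r$trimmed_seq, min_overlap = 1000)$is_circular)
  expect_false(check_circularity(S, min_overlap = 1000)$is_circular)
})

test_that("circularity detection tolerates errors in the duplicated region", {
  S <- rand_dna(60000, seed = 42)
  set.seed(42)
  dup <- plastidkit:::mutate_seq(substr(S, 1, 5000), 0.01)$seq
  r <- check_circularity(paste0(S, dup), min_overlap = 1000)
  expect_true(r$is_circular)
  expect_lt(abs(nchar(r$trimmed_seq) - nchar(S)), 60)
})

test_that("inverted repeats are recovered exactly on noise-free plastomes", {
  cfg <- mini_config(seed = 43)
  p <- make_plastome(cfg)
  ir <- find_inverted_repeats(p$seq, circular = FALSE, min_len = 1000)
  expect_equal(as.integer(ir$a), c(8300L, 10800L))
  expect_equal(as.integer(ir$b), c(12500L, 15000L))
  expect_equal(ir$identity, 1)
  expect_null(find_inverted_repeats(rand_dna(150000, seed = 44), min_len = 1000))
})

test_that("inverted repeat boundaries survive scattered mutations", {
  cfg <- mini_config(seed = 45)
  p <- make_plastome(cfg)
  set.seed(45)
  irb <- substr(p$seq, 12501, 15000)
  mut <- paste0(substr(p$seq, 1, 12500),
                plastidkit:::mutate_seq(irb, 0.005, c(0, 0, 1))$seq)
  ir <- find_inverted_repeats(mut, circular = FALSE, min_len = 1000,
                              min_identity = 0.98)
  expect_false(is.null(ir))
  expect_lt(max(abs(ir$a - c(8300, 10800))), 50)
  expect_lt(max(abs(ir$b - c(12500, 15000))), 50)
  expect_gte(ir$identity, 0.98)
})

test_that("quadripartite partition is canonical and rotation-invariant", {
  cfg <- mini_config(seed = 46)
  p <- make_plastome(cfg)
  pq <- partition_quadripartite(p$seq, find_inverted_repeats(p$seq, min_len = 1000))
  lens <- pq$regions$end - pq$regions$start
  # boundaries are defined up to chance continuation of the repeat into the
  # flanks, so allow a few bp of jitter
  expect_lt(max(abs(lens - c(8300, 2500, 1700, 2500))), 8)
  probe <- substr(p$seq, 1, 50)
  for (off in c(4000, 9000, 13500)) {
    rot <- plastidkit:::rotate_seq(p$seq, off)
    pq2 <- partition_quadripartite(rot, find_inverted_repeats(rot, min_len = 1000))
    expect_identical(pq2$seq, pq$seq)
  }
  hit <- regexpr(probe, paste0(pq$seq, substr(pq$seq, 1, 100)), fixed = TRUE)
  drift <- (as.integer(hit) - 1) %% nchar(p$seq)
  expect_true(drift <= 8 || drift >= nchar(p$seq) - 8)
})

test_that("equal-length single-copy segments demand explicit labels", {
  set.seed(47)
  u1 <- rand_dna(3000)
  ira <- rand_dna(1500)
  u2 <- rand_dna(3000)
  seq <- paste0(u1, ira, u2, revcomp(ira))
  ir <- find_inverted_repeats(seq, circular = FALSE, min_len = 500)
  expect_error(partition_quadripartite(seq, ir), "equal length")
})

test_that("rotate_to_start handles offsets, anchors, strands and ambiguity", {
  cfg <- mini_config(seed = 48)
  p <- make_plastome(cfg)
  expect_identical(rotate_to_start(p, 0L)$seq, p$seq)
  r1 <- rotate_to_start(p, 1000L)
  expect_identical(rotate_to_start(r1, nchar(p$seq) - 1000L)$seq, p$seq)
  anchor <- substr(p$seq, 1001, 1500)
  r2 <- rotate_to_start(p, anchor)
  expect_identical(r2$seq, r1$seq)
  # anchor on the '-' strand reverse complements the molecule first
  r3 <- rotate_to_start(p, revcomp(anchor))
  expect_identical(substr(r3$seq, 1, 500), revcomp(anchor))
  # an anchor inside an inverted repeat maps twice
  ir_anchor <- substr(p$seq, 9001, 9500)
  expect_error(rotate_to_start(p, ir_anchor), "ambiguous")
})

test_that("flip_ssc is an involution that conserves length and repairs a misoriented SSC", {
  cfg <- mini_config(seed = 49)
  truth <- make_plastome(cfg)
  bad <- flip_ssc(truth)
  expect_equal(nchar(bad$seq), nchar(truth$seq))
  expect_false(identical(bad$seq, truth$seq))
  expect_identical(flip_ssc(bad)$seq, truth$seq)
  # reverse complementing conserves the A+T and C+G totals
  tab <- function(s) {
    t <- table(factor(strsplit(s, "", fixed = TRUE)[[1]],
                      levels = c("A", "C", "G", "T")))
    c(at = t[["A"]] + t[["T"]], cg = t[["C"]] + t[["G"]])
  }
  expect_equal(tab(bad$seq), tab(truth$seq))
  expect_error(flip_ssc(plastome(rand_dna(1000, seed = 1))), "SSC")
})
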