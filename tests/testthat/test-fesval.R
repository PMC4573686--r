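# Mate-pair geometry, consistency classification, SSC-flip diagnosis.

test_that("pair geometry distance is start-to-start on the circle", {
  L <- 149722
  g <- pair_geometry(list(t_start = 70072, strand = "+"),
                     list(t_start = 107500, strand = "-"), L)
  expect_equal(g$distance, 37428)
  expect_equal(g$orientation_class, "convergent")
  # invariant under joint rotation of both mates
  for (off in c(1, 50000, 120000)) {
    g2 <- pair_geometry(list(t_start = (70072 + off) %% L, strand = "+"),
                        list(t_start = (107500 + off) %% L, strand = "-"), L)
    expect_equal(g2$distance, 37428)
  }
  # same-strand mates are tandem; far-apart opposite mates divergent
  expect_equal(pair_geometry(list(t_start = 100, strand = "+"),
                             list(t_start = 4e4, strand = "+"), L)$orientation_class,
               "tandem")
  expect_equal(pair_geometry(list(t_start = 100, strand = "+"),
                             list(t_start = 70000, strand = "-"), L)$orientation_class,
               "divergent")
  expect_error(pair_geometry(list(t_start = 1, strand = "+", target_id = "x"),
                             list(t_start = 2, strand = "-", target_id = "y"), L),
               "different targets")
})

test_that("validation of a correct assembly is consistent; distances track the insert", {
  cfg <- sim_config(seed = 61)
  p <- make_plastome(cfg)
  fes <- simulate_fes_pairs(p, 40, cfg)
  rep <- validate_assembly(fes$reads, p)
  scored <- rep$n_consistent + rep$n_inconsistent
  expect_gt(scored, 10)
  expect_gte(rep$n_consistent / scored, 0.95)
  expect_equal(rep$n_unplaced, 0L)
  # median reported distance ~ median insert minus one mate length
  d <- rep$pairs$distance[!is.na(rep$pairs$distance)]
  expected <- stats::median(fes$truth$insert_len) - cfg$fes_read_len
  expect_lt(abs(stats::median(d) - expected) / expected, 0.02)
  # empty input
  rep0 <- validate_assembly(
    data.frame(clone = character(0), fw_start = integer(0),
               fw_strand = character(0), rv_start = integer(0),
               rv_strand = character(0), stringsAsFactors = FALSE), p)
  expect_equal(rep0$n_consistent + rep0$n_inconsistent, 0L)
})

test_that("a flipped SSC produces the same-strand LSC-SSC signature and is diagnosed", {
  cfg <- sim_config(seed = 62)
  truth <- make_plastome(cfg)
  fes <- simulate_fes_pairs(truth, 50, cfg)
  flipped <- flip_ssc(truth)
  rep <- validate_assembly(fes$reads, flipped)
  pr <- rep$pairs
  span <- !is.na(pr$consistent) & !pr$ambiguous &
    xor(pr$region_fw == "SSC", pr$region_rv == "SSC")
  expect_gt(sum(span), 3)
  expect_gte(mean(!pr$consistent[span]), 0.95)
  # the misoriented mates map on the same strand (tandem), the published
  # signature of a flipped single-copy region
  expect_gte(mean(pr$orientation_class[span] == "tandem"), 0.9)
  diag <- diagnose_ssc_flip(rep, flipped)
  expect_true(diag$flip_recommended)
  expect_lt(diag$evidence$inconsistent_after, diag$evidence$inconsistent_before)
  # and the repair restores the truth exactly
  expect_identical(flip_ssc(flipped)$seq, truth$seq)
  # a correct assembly is never flipped
  rep_ok <- validate_assembly(fes$reads, truth)
  expect_false(diagnose_ssc_flip(rep_ok, truth)$flip_recommended)
})

test_that("no SSC-spanning pairs means insufficient evidence, not a flip", {
  cfg <- mini_config(seed = 63)
  p <- make_plastome(cfg)
  pairs <- data.frame(clone = c("c1", "c2"),
                      fw_start = c(100L, 2000L), fw_strand = "+",
                      rv_start = c(4700L, 6600L), rv_strand = "-",
                      stringsAsFactors = FALSE)
  rep <- validate_assembly(pairs, p, insert_window = c(3000, 7000))
  diag <- diagnose_ssc_flip(rep, p)
  expect_false(diag$flip_recommended)
  expect_match(diag$note, "insufficient evidence")
})
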