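# Synthetic data generator: plastome structure, read statistics, FES
# geometry, background/NUPT bookkeeping, determinism.

test_that("simulated plastome has the configured quadripartite layout", {
  cfg <- sim_config(seed = 2)
  p <- make_plastome(cfg)
  expect_equal(nchar(p$seq), 150000L)
  r <- p$regions
  expect_equal(r$region, c("LSC", "IRa", "SSC", "IRb"))
  ira <- substr(p$seq, r$start[2] + 1, r$end[2])
  irb <- substr(p$seq, r$start[4] + 1, r$end[4])
  expect_equal(revcomp(ira), irb)
  # degenerate: no inverted repeat
  p0 <- make_plastome(mini_config(seed = 3, ir_len = 0L))
  expect_null(p0$regions)
  expect_null(find_inverted_repeats(p0$seq, min_len = 500))
})

test_that("read lengths match the configured mean and N50", {
  cfg <- sim_config(seed = 4, read_error_rate = 0)
  g <- rand_dna(150000, seed = 4)
  lr <- simulate_long_reads(g, n_reads = 6000, config = cfg)
  lens <- nchar(lr$reads$seq)
  expect_lt(abs(mean(lens) - 3213) / 3213, 0.05)
  sl <- sort(lens, decreasing = TRUE)
  n50 <- sl[which(cumsum(sl) >= sum(sl) / 2)[1]]
  expect_lt(abs(n50 - 4713) / 4713, 0.10)
})

test_that("error-free reads are exact (possibly wrapped/reverse-complemented) substrings", {
  cfg <- mini_config(seed = 5, read_error_rate = 0)
  p <- make_plastome(cfg)
  lr <- simulate_long_reads(p, n_reads = 30, config = cfg)
  doubled <- paste0(p$seq, p$seq)
  for (i in seq_len(30)) {
    tr <- lr$truth[i, ]
    tmpl <- substr(doubled, tr$start + 1, tr$end)
    if (tr$strand == "-") tmpl <- revcomp(tmpl)
    expect_identical(lr$reads$seq[i], tmpl)
  }
})

test_that("coverage requests produce the expected total bases and error rate", {
  cfg <- sim_config(seed = 6)
  g <- rand_dna(150000, seed = 6)
  lr <- simulate_long_reads(g, coverage = 10, config = cfg)
  expect_lt(abs(sum(nchar(lr$reads$seq)) - 1.5e6) / 1.5e6, 0.05)
  # planted error operations per template base approximate the configured rate
  rate <- sum(lr$truth$n_errors) / sum(lr$truth$end - lr$truth$start)
  expect_lt(abs(rate - 0.11) / 0.11, 0.10)
})

test_that("read starts are uniform on the circle", {
  cfg <- mini_config(seed = 7, read_error_rate = 0)
  g <- rand_dna(15000, seed = 7)
  lr <- simulate_long_reads(g, n_reads = 20000, config = cfg)
  h <- table(cut(lr$truth$start, breaks = seq(0, 15000, length.out = 101),
                 include.lowest = TRUE))
  expect_gt(stats::chisq.test(as.vector(h))$p.value, 0.01)
})

test_that("FES pair construction gives the documented circular geometry", {
  cfg <- sim_config(seed = 8, fes_insert_mean = 40000, fes_insert_sd = 0,
                    fes_error_rate = 0)
  g <- rand_dna(150000, seed = 8)
  fes <- simulate_fes_pairs(g, 40, cfg)
  L <- nchar(g)
  doubled <- paste0(g, g)
  for (i in seq_len(40)) {
    tr <- fes$truth[i, ]
    fw <- fes$reads$seq[2 * i - 1]
    rv <- fes$reads$seq[2 * i]
    expect_identical(fw, substr(doubled, tr$insert_start + 1,
                                tr$insert_start + 700))
    rv_start <- tr$insert_start + tr$insert_len - 700
    expect_identical(rv, revcomp(substr(doubled, rv_start + 1, rv_start + 700)))
    # start-to-start circular distance = insert - read length, wrap included
    d <- (rv_start - tr$insert_start) %% L
    expect_equal(d, tr$insert_len - 700)
  }
  expect_equal(nrow(simulate_fes_pairs(g, 0, cfg)$reads), 0L)
})

test_that("nuclear background records NUPT truth and respects nupt_count", {
  cfg <- mini_config(seed = 9, nuclear_len = 60000L, nupt_count = 0L)
  p <- make_plastome(cfg)
  bg0 <- simulate_background(cfg, p)
  expect_equal(nrow(bg0$truth), 0L)
  cfg3 <- mini_config(seed = 9, nuclear_len = 60000L, nupt_count = 3L)
  bg3 <- simulate_background(cfg3, p, nupt_len_range = c(2000L, 4000L))
  expect_equal(nrow(bg3$truth), 3L)
  expect_equal(nchar(bg3$genome), 60000L)
  for (i in 1:3) {
    frag <- substr(bg3$genome, bg3$truth$start[i] + 1, bg3$truth$end[i])
    src <- substr(p$seq, bg3$truth$src_start[i] + 1, bg3$truth$src_end[i])
    d <- mean(strsplit(frag, "")[[1]] != strsplit(src, "")[[1]])
    expect_lt(d, 0.12)
    expect_gt(d, 0.01)
  }
})

test_that("simulation is reproducible and streams are independent per operation", {
  cfg <- mini_config(seed = 11)
  a <- simulate_long_reads(make_plastome(cfg), n_reads = 20, config = cfg)
  b <- simulate_long_reads(make_plastome(cfg), n_reads = 20, config = cfg)
  expect_identical(a, b)
  # FES output does not depend on whether reads were simulated before
  p <- make_plastome(cfg)
  f1 <- simulate_fes_pairs(p, 10, cfg)
  invisible(simulate_long_reads(p, n_reads = 5, config = cfg))
  f2 <- simulate_fes_pairs(p, 10, cfg)
  expect_identical(f1, f2)
})
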