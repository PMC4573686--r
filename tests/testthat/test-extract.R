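# Whitelist construction, threshold semantics, extraction summary.

test_that("classification threshold is inclusive at min_identity", {
  reads <- data.frame(id = c("m1/1/0_100", "m1/2/0_100", "m1/3/0_100"),
                      seq = strrep("A", 100), stringsAsFactors = FALSE)
  hits <- data.frame(read_id = reads$id, target_id = "ref",
                     t_start = 0L, t_end = 100L, q_start = 0L, q_end = 100L,
                     q_len = 100L, strand = "+",
                     identity = c(0.79, 0.80, 0.85),
                     n_match = c(79L, 80L, 85L), n_cols = 100L,
                     ops = NA_character_, stringsAsFactors = FALSE)
  wl <- classify_reads(reads, hits = hits)
  expect_equal(wl, c("m1/2", "m1/3"))
  # raising the threshold never enlarges the whitelist
  wl2 <- classify_reads(reads, hits = hits,
                        config = extract_config(min_identity = 0.84))
  expect_true(all(wl2 %in% wl))
  expect_equal(wl2, "m1/3")
})

test_that("whitelist extraction operates at polymerase-read granularity", {
  pool <- data.frame(
    id = c("m1/8/0_100", "m1/8/150_300", "m1/9/0_50", "plain-read"),
    seq = c("ACGT", "GGCC", "TTAA", "CCGG"), stringsAsFactors = FALSE)
  out <- extract_by_whitelist(pool, "m1/8")
  expect_equal(out$id, c("m1/8/0_100", "m1/8/150_300"))
  expect_equal(nrow(extract_by_whitelist(pool, character(0))), 0L)
  all_keys <- consolidate_whitelist(polymerase_key(pool$id))
  expect_equal(extract_by_whitelist(pool, all_keys), pool)
  # idempotence on its own output
  expect_equal(extract_by_whitelist(out, "m1/8"), out)
})

test_that("extraction summary arithmetic and edge cases", {
  s <- summarize_extraction(n_subreads = 10L, n_bases = 300000,
                            pool_bases = 1e6, config = extract_config())
  expect_equal(s$fold_coverage, 2.0)
  expect_equal(s$fraction_of_pool, 0.3)
  z <- summarize_extraction(extracted = data.frame(id = character(0),
                                                   seq = character(0)),
                            pool_bases = 100)
  expect_equal(z$n_subreads, 0L)
  expect_equal(z$n_bases, 0)
  expect_equal(z$fold_coverage_int, 0L)
  expect_error(summarize_extraction(n_subreads = 1L, n_bases = 200,
                                    pool_bases = 100), "pool_bases")
})

test_that("reads from a moderately diverged NUPT pass the plastid filter", {
  # the documented contamination mode: a nuclear insertion at 5% divergence
  # from the plastome still recruits reads at the 80% identity threshold
  cfg <- mini_config(seed = 31)
  p <- make_plastome(cfg)
  set.seed(31)
  nupt <- plastidkit:::mutate_seq(substr(p$seq, 2001, 7000), 0.05, c(0, 0, 1))$seq
  lr <- simulate_long_reads(nupt, n_reads = 10, config = cfg, circular = FALSE,
                            movie = "sim_nupt", source = "nupt")
  wl <- classify_reads(lr$reads, p$seq)
  expect_gte(length(wl), 9L)
})
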