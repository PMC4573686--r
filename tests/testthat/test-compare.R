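# Anchored global alignment, difference calling, read arbitration.

test_that("identical sequences align all-match; single events are typed correctly", {
  a <- rand_dna(30000, seed = 91)
  aln <- global_align_anchored(a, a)
  expect_equal(aln$score, 0L)
  expect_equal(nrow(call_differences(aln, a, a)), 0L)
  # one substitution
  ch <- strsplit(a, "", fixed = TRUE)[[1]]
  ch[15000] <- setdiff(c("A", "C", "G", "T"), ch[15000])[1]
  b <- paste(ch, collapse = "")
  d <- call_differences(global_align_anchored(a, b), a, b)
  expect_equal(nrow(d), 1L)
  expect_equal(d$kind, "substitution")
  expect_equal(d$len, 1L)
  expect_equal(d$pos_a, 15000)
  # one 61 bp block absent from b: a single insertion_in_A run
  b2 <- paste0(substr(a, 1, 9000), substr(a, 9062, nchar(a)))
  d2 <- call_differences(global_align_anchored(a, b2), a, b2)
  expect_equal(nrow(d2), 1L)
  expect_equal(d2$kind, "insertion_in_A")
  expect_equal(d2$len, 61L)
})

test_that("swapping the assemblies transposes the difference list", {
  pair <- reconstruct_assembly_pair(seed = 92, genome_len = 40000,
                                    edits = data.frame(
                                      pos_a = c(5000L, 12000L, 22000L, 31000L),
                                      kind = c("insertion_in_A", "substitution",
                                               "deletion_in_A", "substitution"),
                                      len = c(7L, 1L, 4L, 2L),
                                      region = NA_character_))
  a <- pair$seq_a; b <- pair$seq_b
  dab <- call_differences(global_align_anchored(a, b), a, b)
  dba <- call_differences(global_align_anchored(b, a), b, a)
  expect_equal(nrow(dab), nrow(dba))
  swap <- c(insertion_in_A = "deletion_in_A", deletion_in_A = "insertion_in_A",
            substitution = "substitution")
  expect_equal(unname(swap[dab$kind]), dba$kind)
  expect_equal(dab$pos_a, dba$pos_b)
  expect_equal(dab$pos_b, dba$pos_a)
  expect_equal(dab$allele_a, dba$allele_b)
})

test_that("applying called differences to B reconstructs A exactly", {
  for (s in c(93, 94)) {
    a <- rand_dna(12000, seed = s)
    set.seed(s)
    b <- plastidkit:::mutate_seq(a, 0.03)$seq
    d <- call_differences(global_align_anchored(a, b), a, b)
    expect_identical(apply_differences(d, b), a)
  }
})

test_that("anchored alignment equals exhaustive dynamic programming", {
  set.seed(95)
  for (r in 1:4) {
    n <- sample(2000:5000, 1)
    a <- rand_dna(n)
    b <- plastidkit:::mutate_seq(a, 0.05)$seq
    g1 <- global_align_anchored(a, b)
    g2 <- global_align_exact(a, b)
    expect_equal(g1$score, g2$score)
    expect_equal(call_differences(g1, a, b)[, 1:6],
                 call_differences(g2, a, b)[, 1:6])
  }
})

test_that("arbitration assigns verdicts by spanning-read haplotype counts", {
  a <- rand_dna(4000, seed = 96)
  # b carries AAAAAA where a (and all reads) carry TTTTTT: the homopolymer
  # miscall scenario resolved by accurate spanning reads
  ch <- strsplit(a, "", fixed = TRUE)[[1]]
  ch[2001:2006] <- c("T", "T", "T", "T", "T", "T")
  a <- paste(ch, collapse = "")
  chb <- ch
  chb[2001:2006] <- c("A", "A", "A", "A", "A", "A")
  b <- paste(chb, collapse = "")
  d <- call_differences(global_align_anchored(a, b), a, b)
  expect_equal(nrow(d), 1L)
  set.seed(96)
  reads <- data.frame(id = sprintf("fes%02d", 1:6),
                      seq = vapply(1:6, function(i) {
                        s0 <- sample(1500:1900, 1)
                        substr(a, s0, s0 + 600)
                      }, ""), stringsAsFactors = FALSE)
  arb <- arbitrate_with_fes(d, reads, a, b)
  expect_equal(arb$verdict, "A")
  expect_gte(arb$support_a, 3L)
  expect_equal(arb$support_b, 0L)
  # a 2 vs 2 split stays ambiguous (tie and below the informative minimum)
  reads_b <- reads
  reads_b$seq[1:3] <- vapply(1:3, function(i) {
    s0 <- c(1600, 1700, 1800)[i]
    substr(b, s0, s0 + 600)
  }, "")
  arb2 <- arbitrate_with_fes(d, reads_b[1:4, ], a, b, min_informative = 5L)
  expect_equal(arb2$verdict, "ambiguous")
})
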