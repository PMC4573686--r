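# Shared fixtures: small-scale configurations keep the unit tests fast; the
# full-size study conditions are exercised in test-acceptance.R.

rand_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# a ~15 kb plastome with the same 83:25:17 proportions as the full molecule
mini_config <- function(seed = 1L, lsc_len = 8300L, ir_len = 2500L,
                        ssc_len = 1700L, ...) {
  sim_config(lsc_len = lsc_len, ir_len = ir_len, ssc_len = ssc_len,
             fes_insert_mean = 5000, fes_insert_sd = 400,
             fes_read_len = 400L, seed = seed, ...)
}

# plant `n_err` substitutions into seq at positions `pos` (or random)
plant_substitutions <- function(seq, n_err, seed = 1L, margin = 100L) {
  set.seed(seed)
  L <- nchar(seq)
  pos <- sort(sample(seq(margin, L - margin), n_err))
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  for (p in pos) ch[p] <- setdiff(c("A", "C", "G", "T"), ch[p])[sample(3, 1)]
  list(seq = paste(ch, collapse = ""), pos = pos)
}
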