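# Internal helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of DNA strings
#'
#' @param x character vector of DNA sequences (ACGTN, case preserved).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x))
  revcomp_cpp(x)
}

# rotate a linearized circular sequence so that 0-based position `offset`
# becomes position 0
rotate_seq <- function(seq, offset) {
  L <- nchar(seq)
  offset <- ((offset %% L) + L) %% L
  if (offset == 0) return(seq)
  paste0(substr(seq, offset + 1, L), substr(seq, 1, offset))
}

# random DNA of length n (uses the current RNG stream)
random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

assert_dna <- function(seq, what = "sequence") {
  bad <- grepl("[^ACGTNacgtn]", seq)
  if (any(bad)) {
    stop(sprintf("%s contains characters outside {A,C,G,T,N} (first offender: record %d)",
                 what, which(bad)[1]), call. = FALSE)
  }
  invisible(TRUE)
}

# Inject errors into a sequence: per-base error probability `rate`, split
# into insertion/deletion/substitution by `mix` (sums to 1). Insertions add a
# random base in front of the affected position. Returns the mutated string
# and the number of edit operations applied.
mutate_seq <- function(seq, rate, mix = c(ins = 5 / 11, del = 3 / 11, sub = 3 / 11)) {
  if (rate <= 0) return(list(seq = seq, n_edits = 0L))
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(chars)
  err <- which(runif(n) < rate)
  if (length(err) == 0) return(list(seq = seq, n_edits = 0L))
  type <- sample(c("ins", "del", "sub"), length(err), replace = TRUE, prob = mix)
  out <- chars
  del <- err[type == "del"]
  if (length(del)) out[del] <- ""
  sub <- err[type == "sub"]
  if (length(sub)) {
    cur <- match(chars[sub], DNA_BASES)
    cur[is.na(cur)] <- 1L
    out[sub] <- DNA_BASES[((cur - 1L + sample(1:3, length(sub), replace = TRUE)) %% 4L) + 1L]
  }
  ins <- err[type == "ins"]
  if (length(ins)) {
    out[ins] <- paste0(sample(DNA_BASES, length(ins), replace = TRUE), out[ins])
  }
  list(seq = paste(out, collapse = ""), n_edits = length(err))
}

# scoped seeding: every stochastic operation draws from a stream derived from
# (seed, op tag) so that simulating more of one data type does not perturb
# the others
op_seed <- function(seed, tag) {
  offs <- c(plastome = 101L, reads = 202L, fes = 303L, background = 404L,
            misc = 505L)
  o <- offs[[tag]]
  if (is.null(o)) o <- 999L
  set.seed((as.integer(seed) %% 1000000L) * 1000L + o)
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
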