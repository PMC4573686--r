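# Reconstruction experiment: re-create a pair of assemblies that disagree by
# a published list of differences (types, lengths and positions in the first
# assembly), then verify that the comparison stage recovers the list. The
# edit list between the long-read sugar beet chloroplast assembly (cp_2320)
# and the earlier short-read assembly ships with the package.

#' The published cp_2320 vs short-read assembly difference list
#'
#' 23 differences: positions in cp_2320 coordinates, event type relative to
#' cp_2320 (insertions are bases present only in cp_2320, deletions bases
#' present only in the short-read assembly), lengths in bp, and the
#' quadripartite region each difference falls in.
#'
#' @return data.frame with columns `pos_a`, `kind`, `len`, `region`.
#' @export
load_difference_table <- function() {
  read.delim(system.file("extdata", "cp2320_vs_illumina_differences.tsv",
                         package = "plastidkit"),
             stringsAsFactors = FALSE)
}

#' Build a synthetic assembly pair carrying a given difference list
#'
#' Assembly A is a seeded random sequence of `genome_len` bp; assembly B is
#' derived by applying the edit list (interpreted in A coordinates):
#' insertions in A are omitted from B, deletions in A become random extra
#' bases in B, substitutions become bases differing position-wise from A.
#' Substituted and inserted content is drawn so that every edited base
#' differs from its counterpart, keeping each event a single contiguous
#' alignment run.
#'
#' @param seed integer seed.
#' @param edits data.frame as [load_difference_table()] (the default).
#' @param genome_len length of assembly A (default 149,722 bp, the size of
#'   the finished cp_2320 molecule).
#' @return list with `seq_a`, `seq_b`, `edits`.
#' @export
reconstruct_assembly_pair <- function(seed = 1L, edits = load_difference_table(),
                                      genome_len = 149722L) {
  set.seed(as.integer(seed) %% .Machine$integer.max)
  a <- random_dna(genome_len)
  achars <- strsplit(a, "", fixed = TRUE)[[1]]
  ed <- edits[order(edits$pos_a), , drop = FALSE]
  stopifnot(all(ed$pos_a + ed$len <= genome_len))
  # pick a base avoiding `hard` always and `soft` (ordered by priority) as
  # far as the 4-letter alphabet allows
  pick_base <- function(hard, soft = character(0)) {
    avoid <- unique(c(hard, soft))
    while (length(setdiff(DNA_BASES, avoid)) == 0) avoid <- avoid[-length(avoid)]
    cand <- setdiff(DNA_BASES, avoid)
    cand[sample.int(length(cand), 1)]
  }
  near <- function(p, off) {
    q <- p + off
    achars[q[q >= 1 & q <= genome_len]]
  }
  pieces <- character(0)
  cur <- 1L
  for (i in seq_len(nrow(ed))) {
    p <- ed$pos_a[i]; l <- ed$len[i]; k <- ed$kind[i]
    pieces <- c(pieces, substr(a, cur, p - 1L))
    if (k == "substitution") {
      # differ from the substituted base and, where possible, from the
      # background within a +-2 shift window, so the event cannot be
      # re-expressed as a cheaper gap arrangement
      sub <- vapply(seq_len(l), function(j)
        pick_base(achars[p + j - 1L],
                  near(p + j - 1L, c(-1L, 1L, -2L, 2L))), "")
      pieces <- c(pieces, paste(sub, collapse = ""))
      cur <- p + l
    } else if (k == "insertion_in_A") {
      cur <- p + l                     # B omits these bases
    } else if (k == "deletion_in_A") {
      # extra bases in B: differ from the local background (+-2 around the
      # gap point) and avoid homopolymer continuation within the insert
      ins <- character(l)
      for (j in seq_len(l)) {
        ins[j] <- pick_base(character(0),
                            c(near(p, c(-1L, 0L, 1L, -2L, 2L)),
                              if (j > 1) ins[j - 1]))
      }
      pieces <- c(pieces, paste(ins, collapse = ""))
      cur <- p
    } else stop("unknown edit kind: ", k)
  }
  pieces <- c(pieces, substr(a, cur, genome_len))
  list(seq_a = a, seq_b = paste(pieces, collapse = ""), edits = ed)
}

#' Run the full difference-recovery experiment
#'
#' Builds the assembly pair of [reconstruct_assembly_pair()], aligns the two
#' sequences with the anchored global aligner and calls differences.
#'
#' @param seed integer seed.
#' @param ... passed to [reconstruct_assembly_pair()].
#' @return list with `diffs` (called differences) and the generated pair.
#' @export
difference_recovery_experiment <- function(seed = 1L, ...) {
  pair <- reconstruct_assembly_pair(seed, ...)
  aln <- global_align_anchored(pair$seq_a, pair$seq_b)
  diffs <- call_differences(aln, pair$seq_a, pair$seq_b)
  list(diffs = diffs, pair = pair, alignment = aln)
}
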