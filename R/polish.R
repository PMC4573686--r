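# Majority-vote pileup consensus polishing: reads are projected onto
# assembly columns through their alignments; each column emits the plurality
# base (ties keep the assembly base), deletions win when they are the
# plurality, and an insertion string between two columns is emitted when
# more than half of the reads spanning that junction carry exactly it.
# This is a deliberately simple consensus model: no realignment and no
# quality weighting.

#' Pileup consensus polishing
#'
#' @param assembly DNA string to polish.
#' @param reads data.frame of reads.
#' @param hits optional precomputed hits of `reads` against `assembly`
#'   (mapped internally when NULL).
#' @param min_coverage columns covered by fewer reads are left unchanged
#'   and flagged (default 5).
#' @param support_threshold support fraction below which a position is
#'   flagged low-support (default 0.5).
#' @param min_identity mapping floor when mapping internally.
#' @return list of class `polish_result`: `polished_seq`, `n_changes`,
#'   `support` (per input position, fraction of covering reads agreeing
#'   with the emitted base), `low_support_positions`,
#'   `low_coverage_positions` (1-based input coordinates).
#' @export
pileup_consensus <- function(assembly, reads, hits = NULL, min_coverage = 5L,
                             support_threshold = 0.5, min_identity = 0.60) {
  assembly <- toupper(assembly)
  L <- nchar(assembly)
  if (is.null(hits)) hits <- map_set(reads, target = assembly,
                                     min_identity = min_identity)
  if (nrow(hits) > 0 && any(is.na(hits$ops)))
    stop("pileup requires hits with alignment detail (ops)", call. = FALSE)
  if (nrow(hits) == 0) {
    return(structure(list(polished_seq = assembly, n_changes = 0L,
                          support = rep(NA_real_, L),
                          low_support_positions = integer(0),
                          low_coverage_positions = seq_len(L)),
                     class = "polish_result"))
  }
  # oriented query sequences matching the ops
  rseq <- stats::setNames(reads$seq, reads$id)
  oq <- toupper(rseq[hits$read_id])
  flip <- hits$strand == "-"
  if (any(flip)) oq[flip] <- revcomp(oq[flip])
  pu <- pileup_cpp(L, hits$t_start, hits$ops, unname(oq))
  counts <- pu$counts
  coverage <- rowSums(counts)
  achars <- strsplit(assembly, "", fixed = TRUE)[[1]]
  aidx <- match(achars, DNA_BASES)      # NA for N
  # prefer the assembly base on ties
  adj <- counts + 0
  sel <- !is.na(aidx)
  adj[cbind(which(sel), aidx[sel])] <- adj[cbind(which(sel), aidx[sel])] + 0.4
  winner <- max.col(adj, ties.method = "first")
  emit <- c(DNA_BASES, "")[winner]
  low_cov <- which(coverage < min_coverage)
  emit[low_cov] <- achars[low_cov]
  support <- ifelse(coverage > 0,
                    counts[cbind(seq_len(L), winner)] / coverage, NA_real_)
  support[low_cov] <- NA_real_
  low_support <- which(!is.na(support) & support < support_threshold)
  # insertion consensus: plurality exact string carried by > 50% of the
  # reads spanning the junction; ties break toward no insertion
  ins_prefix <- rep("", L + 1L)
  if (length(pu$ins_pos)) {
    jc <- pu$jcov
    df <- data.frame(pos = pu$ins_pos, str = pu$ins_str, cnt = pu$ins_cnt,
                     stringsAsFactors = FALSE)
    df <- df[df$pos >= 1 & df$pos <= L - 1, , drop = FALSE] # interior junctions
    for (p in unique(df$pos)) {
      sub <- df[df$pos == p, ]
      jcov <- jc[p + 1L]
      if (jcov < min_coverage) next
      best <- which(sub$cnt == max(sub$cnt))
      if (length(best) != 1) next
      if (sub$cnt[best] > 0.5 * jcov) ins_prefix[p + 1L] <- sub$str[best]
    }
  }
  polished <- paste0(paste0(ins_prefix[seq_len(L)], emit, collapse = ""),
                     ins_prefix[L + 1L])
  n_changes <- sum(emit != achars) + sum(nchar(ins_prefix))
  structure(list(polished_seq = polished, n_changes = as.integer(n_changes),
                 support = support, low_support_positions = low_support,
                 low_coverage_positions = low_cov),
            class = "polish_result")
}

#' @export
print.polish_result <- function(x, ...) {
  cat(sprintf("polished %d bp, %d change(s), %d low-coverage position(s)\n",
              nchar(x$polished_seq), x$n_changes,
              length(x$low_coverage_positions)))
  invisible(x)
}

#' Iterated polishing to a fixed point
#'
#' Re-maps and re-polishes until no changes are made or `rounds` is
#' exhausted.
#'
#' @param assembly DNA string.
#' @param reads data.frame of reads.
#' @param rounds maximum rounds (>= 1).
#' @param ... passed to [pileup_consensus()].
#' @return the final `polish_result` with an extra `changes_per_round`
#'   integer vector.
#' @export
iterate_polish <- function(assembly, reads, rounds = 2L, ...) {
  if (rounds < 1) stop("rounds must be >= 1", call. = FALSE)
  cur <- toupper(assembly)
  changes <- integer(0)
  res <- NULL
  for (r in seq_len(rounds)) {
    res <- pileup_consensus(cur, reads, ...)
    changes <- c(changes, res$n_changes)
    if (res$n_changes == 0L) break
    cur <- res$polished_seq
  }
  res$changes_per_round <- changes
  res
}
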