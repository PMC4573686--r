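# Whole-molecule comparison of two assemblies: anchored global alignment,
# difference segmentation and classification, and per-difference arbitration
# by mapped high-accuracy reads.

#' Anchored global alignment of two assemblies
#'
#' k-mers occurring exactly once in each sequence define candidate anchors;
#' a longest collinear (strictly increasing) chain of them is selected and
#' the inter-anchor segments are aligned by banded exact dynamic
#' programming, giving a true global alignment. Unique anchors avoid false
#' anchoring inside large inverted repeats (where k-mers occur twice and
#' hence produce no anchors); the repeats are covered by the banded DP of
#' the enclosing segment. Circular molecules must be rotated to a shared
#' origin by the caller first.
#'
#' @param seq_a,seq_b DNA strings.
#' @param k anchor k-mer size (default 21).
#' @param spacing minimum spacing between used anchors (bp, default 32).
#' @param max_anchors anchors are thinned evenly to at most this many.
#' @return list of class `global_alignment`: `ops` (column string over
#'   M/X/I/D, I = consumes `seq_a` only), `score` (total unit-cost edit
#'   distance), `n_anchors`, `a_len`, `b_len`.
#' @export
global_align_anchored <- function(seq_a, seq_b, k = 21L, spacing = 32L,
                                  max_anchors = 20000L) {
  a <- toupper(seq_a); b <- toupper(seq_b)
  n <- nchar(a); m <- nchar(b)
  stopifnot(n > 0, m > 0)
  an <- shared_unique_kmers_cpp(a, b, as.integer(k))
  if (nrow(an) > 1) {
    keep <- c(TRUE, diff(an$pos_a) >= spacing)
    an <- an[keep, , drop = FALSE]
    if (nrow(an) > max_anchors) {
      an <- an[unique(as.integer(seq(1, nrow(an), length.out = max_anchors))), ,
               drop = FALSE]
    }
    li <- lis_cpp(an$pos_b)
    an <- an[li, , drop = FALSE]
    # enforce non-overlap in both coordinates
    keep <- rep(TRUE, nrow(an))
    last_a <- -1e18; last_b <- -1e18
    for (i in seq_len(nrow(an))) {
      if (an$pos_a[i] >= last_a + k && an$pos_b[i] >= last_b + k) {
        last_a <- an$pos_a[i]; last_b <- an$pos_b[i]
      } else keep[i] <- FALSE
    }
    an <- an[keep, , drop = FALSE]
  }
  if (nrow(an) == 0) {
    if ((n + 1) * (m + 1) > 2.5e8)
      stop("no shared unique anchors and sequences too large for exact DP; ",
           "reduce input size", call. = FALSE)
    al <- banded_global(a, b, band = max(n, m))
    return(structure(list(ops = al$ops, score = al$dist, n_anchors = 0L,
                          a_len = n, b_len = m), class = "global_alignment"))
  }
  segs <- character(nrow(an) * 2L + 1L)
  score <- 0L
  prev_a <- 0L; prev_b <- 0L
  si <- 0L
  for (i in seq_len(nrow(an))) {
    pa <- an$pos_a[i]; pb <- an$pos_b[i]
    sa <- substr(a, prev_a + 1L, pa)
    sb <- substr(b, prev_b + 1L, pb)
    si <- si + 1L
    if (identical(sa, sb)) {
      segs[si] <- strrep("M", nchar(sa))
    } else {
      al <- banded_global(sa, sb)
      if (is.null(al)) stop("inter-anchor alignment failed", call. = FALSE)
      segs[si] <- al$ops
      score <- score + al$dist
    }
    si <- si + 1L
    segs[si] <- strrep("M", k)
    prev_a <- pa + k; prev_b <- pb + k
  }
  sa <- substr(a, prev_a + 1L, n)
  sb <- substr(b, prev_b + 1L, m)
  si <- si + 1L
  if (identical(sa, sb)) {
    segs[si] <- strrep("M", nchar(sa))
  } else {
    al <- banded_global(sa, sb)
    if (is.null(al)) stop("inter-anchor alignment failed", call. = FALSE)
    segs[si] <- al$ops
    score <- score + al$dist
  }
  structure(list(ops = paste(segs[seq_len(si)], collapse = ""),
                 score = score, n_anchors = nrow(an), a_len = n, b_len = m),
            class = "global_alignment")
}

#' Exact global alignment (reference implementation)
#'
#' Full unit-cost dynamic programming over the entire pair, without
#' anchoring or banding. Quadratic in memory; intended as an independent
#' check of [global_align_anchored()] at moderate sizes.
#'
#' @param seq_a,seq_b DNA strings (product of lengths limited).
#' @return a `global_alignment`.
#' @export
global_align_exact <- function(seq_a, seq_b) {
  a <- toupper(seq_a); b <- toupper(seq_b)
  n <- nchar(a); m <- nchar(b)
  if ((n + 1) * (m + 1) > 2.5e8)
    stop("inputs too large for exact DP", call. = FALSE)
  al <- align_band_cpp(a, b, FALSE, -n, m)
  structure(list(ops = al$ops, score = al$dist, n_anchors = 0L,
                 a_len = n, b_len = m), class = "global_alignment")
}

#' @export
print.global_alignment <- function(x, ...) {
  st <- ops_stats_cpp(x$ops)
  cat(sprintf("global alignment: %d x %d bp, %d columns, distance %d (%d anchors)\n",
              x$a_len, x$b_len, nchar(x$ops), x$score, x$n_anchors))
  cat(sprintf("  match %d, mismatch %d, ins(A) %d, del(A) %d\n",
              st[["n_match"]], st[["n_mismatch"]], st[["n_ins"]], st[["n_del"]]))
  invisible(x)
}

#' Call differences between two globally aligned assemblies
#'
#' Differences are maximal runs of non-match columns, split into minimal
#' typed events left-to-right (a run mixing mismatches and both gap
#' directions yields one event per homogeneous stretch). Indels are
#' left-aligned: an event is shifted left through matching flanks while the
#' shifted allele is unchanged (the standard normalization in homopolymer
#' context), keeping at least one matching column between events. Reported
#' positions are 1-based: the first involved base of the assembly that has
#' bases at the event, and the position just after the left flank on the
#' assembly that does not.
#'
#' @param aln a `global_alignment` of `seq_a` vs `seq_b`.
#' @param seq_a,seq_b the aligned sequences.
#' @param plastome optional `plastome` (in `seq_a` coordinates) for region
#'   labels.
#' @return data.frame with one row per difference: `kind` (substitution /
#'   insertion_in_A / deletion_in_A), `pos_a`, `pos_b` (1-based), `len`,
#'   `allele_a`, `allele_b`, `region`, plus empty arbitration columns
#'   `support_a`, `support_b`, `support_ambiguous`, `verdict`.
#' @export
call_differences <- function(aln, seq_a, seq_b, plastome = NULL) {
  a <- toupper(seq_a); b <- toupper(seq_b)
  opsv <- strsplit(aln$ops, "", fixed = TRUE)[[1]]
  r <- rle(opsv)
  events <- list()
  ai <- 0L; bi <- 0L  # bases consumed so far
  for (j in seq_along(r$values)) {
    op <- r$values[j]; l <- r$lengths[j]
    if (op == "M") { ai <- ai + l; bi <- bi + l; next }
    if (op == "X") {
      events[[length(events) + 1L]] <- list(
        kind = "substitution", len = l, a0 = ai, b0 = bi,
        allele_a = substr(a, ai + 1L, ai + l),
        allele_b = substr(b, bi + 1L, bi + l))
      ai <- ai + l; bi <- bi + l
    } else if (op == "I") {
      events[[length(events) + 1L]] <- list(
        kind = "insertion_in_A", len = l, a0 = ai, b0 = bi,
        allele_a = substr(a, ai + 1L, ai + l), allele_b = "")
      ai <- ai + l
    } else if (op == "D") {
      events[[length(events) + 1L]] <- list(
        kind = "deletion_in_A", len = l, a0 = ai, b0 = bi,
        allele_a = "", allele_b = substr(b, bi + 1L, bi + l))
      bi <- bi + l
    }
  }
  # left-align indels through matching flanks
  prev_end_a <- -1L  # exclusive end (0-based) of the previous event in a
  prev_end_b <- -1L
  for (i in seq_along(events)) {
    ev <- events[[i]]
    if (ev$kind != "substitution") {
      s <- ev$a0; t <- ev$b0; l <- ev$len
      seq_ref <- if (ev$kind == "insertion_in_A") a else b
      p <- if (ev$kind == "insertion_in_A") s else t
      shift <- 0L
      # shift left while the flanking base equals the last allele base;
      # shifting may bring the event adjacent to (but not into) the
      # previous one, which makes the placement canonical regardless of
      # where an equal-score alignment path put it
      while (s - shift > prev_end_a + 1L && t - shift > prev_end_b + 1L &&
             p - shift >= 1L &&
             substr(seq_ref, p - shift, p - shift) ==
             substr(seq_ref, p - shift + l, p - shift + l)) {
        shift <- shift + 1L
      }
      if (shift > 0L) {
        ev$a0 <- s - shift; ev$b0 <- t - shift
        if (ev$kind == "insertion_in_A")
          ev$allele_a <- substr(a, ev$a0 + 1L, ev$a0 + l)
        else
          ev$allele_b <- substr(b, ev$b0 + 1L, ev$b0 + l)
        events[[i]] <- ev
      }
    }
    a_cons <- if (ev$kind == "deletion_in_A") 0L else ev$len
    b_cons <- if (ev$kind == "insertion_in_A") 0L else ev$len
    prev_end_a <- ev$a0 + a_cons - 1L
    prev_end_b <- ev$b0 + b_cons - 1L
  }
  n <- length(events)
  out <- data.frame(
    kind = vapply(events, `[[`, "", "kind"),
    pos_a = vapply(events, function(e) e$a0 + 1L, 1L),
    pos_b = vapply(events, function(e) e$b0 + 1L, 1L),
    len = vapply(events, `[[`, 1L, "len"),
    allele_a = vapply(events, `[[`, "", "allele_a"),
    allele_b = vapply(events, `[[`, "", "allele_b"),
    stringsAsFactors = FALSE)
  out$region <- if (!is.null(plastome)) region_of(plastome, out$pos_a - 1L)
                else rep(NA_character_, n)
  out$support_a <- rep(NA_integer_, n)
  out$support_b <- rep(NA_integer_, n)
  out$support_ambiguous <- rep(NA_integer_, n)
  out$verdict <- rep(NA_character_, n)
  out
}

#' Reconstruct assembly A by applying its differences to assembly B
#'
#' Edit-script soundness helper: applying the output of
#' [call_differences()] (A vs B) to B must reproduce A exactly.
#'
#' @param diffs data.frame from [call_differences()].
#' @param seq_b assembly B.
#' @return the reconstructed assembly A.
#' @export
apply_differences <- function(diffs, seq_b) {
  b <- toupper(seq_b)
  d <- diffs[order(diffs$pos_b), , drop = FALSE]
  pieces <- character(0)
  cur <- 1L
  for (i in seq_len(nrow(d))) {
    k <- d$kind[i]; pb <- d$pos_b[i]; l <- d$len[i]
    pieces <- c(pieces, substr(b, cur, pb - 1L))
    if (k == "substitution") {
      pieces <- c(pieces, d$allele_a[i]); cur <- pb + l
    } else if (k == "insertion_in_A") {
      pieces <- c(pieces, d$allele_a[i]); cur <- pb
    } else { # deletion_in_A: skip B's extra bases
      cur <- pb + l
    }
  }
  pieces <- c(pieces, substr(b, cur, nchar(b)))
  paste(pieces, collapse = "")
}

# oriented-query substring of a hit covering target interval [t_lo, t_hi)
# (0-based); NULL when the hit does not fully span it
project_query_substring <- function(hit, t_lo, t_hi) {
  if (hit$t_start > t_lo || hit$t_end < t_hi) return(NULL)
  opsv <- strsplit(hit$ops, "", fixed = TRUE)[[1]]
  cons_t <- opsv %in% c("M", "X", "D")
  cons_q <- opsv %in% c("M", "X", "I")
  tpos <- hit$t_start + cumsum(cons_t) - ifelse(cons_t, 1L, 0L) # t index of col
  qpos <- cumsum(cons_q) - ifelse(cons_q, 1L, 0L)               # 0-based q index
  sel <- which(cons_t & tpos >= t_lo & tpos < t_hi)
  if (length(sel) == 0) return("")
  c1 <- sel[1]; c2 <- sel[length(sel)]
  # include insertions strictly inside the interval
  q_from <- qpos[c1]                              # works for M/X and D columns
  q_to <- qpos[c2] + ifelse(cons_q[c2], 1L, 0L)
  # insertions between c1..c2 are inside [q_from, q_to) automatically
  if (q_to <= q_from) return("")
  substr(hit$oriented_seq, q_from + 1L, q_to)
}

#' Arbitrate differences with high-accuracy reads
#'
#' Each read whose mapping spans a difference locus with at least
#' `flank` matching bp on both sides is assigned to allele A, allele B or
#' ambiguous by exact comparison of its spanning substring against the two
#' local haplotypes. The verdict is the majority allele when at least
#' `min_informative` reads are informative, otherwise ambiguous.
#'
#' @param diffs data.frame from [call_differences()].
#' @param fes_reads data.frame of high-accuracy reads (mapped single-end).
#' @param assembly_a,assembly_b the two assemblies.
#' @param flank bp of context on each side (default 10).
#' @param min_informative minimum informative reads for a verdict
#'   (default 3).
#' @return `diffs` with `support_a`, `support_b`, `support_ambiguous` and
#'   `verdict` (`"A"`, `"B"` or `"ambiguous"`) filled in.
#' @export
arbitrate_with_fes <- function(diffs, fes_reads, assembly_a, assembly_b,
                               flank = 10L, min_informative = 3L) {
  a <- toupper(assembly_a); b <- toupper(assembly_b)
  hits <- map_set(fes_reads, target = a, min_identity = 0.7)
  if (nrow(hits) > 0) {
    rseq <- stats::setNames(toupper(fes_reads$seq), fes_reads$id)
    oseq <- rseq[hits$read_id]
    flip <- hits$strand == "-"
    oseq[flip] <- revcomp(oseq[flip])
    hits$oriented_seq <- unname(oseq)
  }
  for (i in seq_len(nrow(diffs))) {
    la <- nchar(diffs$allele_a[i])
    lb <- nchar(diffs$allele_b[i])
    a_lo <- diffs$pos_a[i] - 1L - flank
    a_hi <- diffs$pos_a[i] - 1L + la + flank
    b_lo <- diffs$pos_b[i] - 1L - flank
    b_hi <- diffs$pos_b[i] - 1L + lb + flank
    if (a_lo < 0 || b_lo < 0 || a_hi > nchar(a) || b_hi > nchar(b)) {
      diffs$verdict[i] <- "ambiguous"
      next
    }
    hap_a <- substr(a, a_lo + 1L, a_hi)
    hap_b <- substr(b, b_lo + 1L, b_hi)
    sa <- 0L; sb <- 0L; samb <- 0L
    if (nrow(hits) > 0) {
      span <- hits[hits$t_start <= a_lo & hits$t_end >= a_hi, , drop = FALSE]
      for (j in seq_len(nrow(span))) {
        sub <- project_query_substring(span[j, ], a_lo, a_hi)
        if (is.null(sub)) next
        if (identical(sub, hap_a)) sa <- sa + 1L
        else if (identical(sub, hap_b)) sb <- sb + 1L
        else samb <- samb + 1L
      }
    }
    diffs$support_a[i] <- sa
    diffs$support_b[i] <- sb
    diffs$support_ambiguous[i] <- samb
    diffs$verdict[i] <- if (sa + sb >= min_informative && sa != sb) {
      if (sa > sb) "A" else "B"
    } else "ambiguous"
  }
  diffs
}

#' Write a difference table as TSV
#'
#' Columns mirror the usual finishing-report layout: positions in both
#' assemblies (1-based), type, length, verdict and region.
#' @param diffs data.frame from [call_differences()].
#' @param path output file.
#' @export
write_difference_report <- function(diffs, path) {
  write.table(diffs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
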