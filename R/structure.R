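# Physical structure of an assembled organelle contig: circularity,
# inverted-repeat discovery, quadripartite partitioning, canonical rotation
# and SSC inversion.

#' Plastome container
#'
#' A linearized circular sequence plus (optionally) its quadripartite
#' partition. Regions tile `[0, len)` in order LSC, IRa, SSC, IRb with
#' 0-based half-open coordinates; IRa is the repeat copy adjacent to the
#' right end of the LSC after canonical rotation.
#'
#' @param seq DNA string.
#' @param circular logical.
#' @param regions NULL or a data.frame with columns region/start/end.
#' @export
plastome <- function(seq, circular = TRUE, regions = NULL) {
  assert_dna(seq, "plastome sequence")
  seq <- toupper(seq)
  if (!is.null(regions)) {
    stopifnot(all(c("region", "start", "end") %in% names(regions)),
              nrow(regions) == 4)
    regions <- regions[match(c("LSC", "IRa", "SSC", "IRb"), regions$region), ]
    if (any(is.na(regions$region)))
      stop("regions must be labeled LSC, IRa, SSC, IRb", call. = FALSE)
    L <- nchar(seq)
    ok <- regions$start[1] == 0 &&
      all(regions$end[-4] == regions$start[-1]) && regions$end[4] == L
    if (!ok) stop("regions must tile [0, len) in order LSC, IRa, SSC, IRb",
                  call. = FALSE)
    la <- regions$end[2] - regions$start[2]
    lb <- regions$end[4] - regions$start[4]
    if (abs(la - lb) > max(20, 0.02 * la))
      warning("IRa and IRb lengths differ by more than 2%")
    if ((regions$end[1] - regions$start[1]) <
        (regions$end[3] - regions$start[3]))
      stop("LSC must not be shorter than SSC", call. = FALSE)
  }
  structure(list(seq = seq, circular = circular, regions = regions),
            class = "plastome")
}

#' @export
print.plastome <- function(x, ...) {
  cat(sprintf("plastome: %d bp, %s\n", nchar(x$seq),
              if (x$circular) "circular" else "linear"))
  if (!is.null(x$regions)) {
    r <- x$regions
    cat(sprintf("  %-4s %8d..%-8d (%d bp)\n", r$region, r$start + 1, r$end,
                r$end - r$start), sep = "")
  } else cat("  no quadripartite partition recorded\n")
  invisible(x)
}

region_of <- function(plastome, pos0) {
  if (is.null(plastome$regions)) return(rep(NA_character_, length(pos0)))
  r <- plastome$regions
  idx <- findInterval(pos0, r$start)
  out <- r$region[pmax(idx, 1L)]
  out[pos0 < 0 | pos0 >= nchar(plastome$seq)] <- NA_character_
  out
}

#' Check a linear contig for overlapping (circular) ends
#'
#' A circular molecule assembled into a linear string duplicates its start
#' at the end. The check seeds with a prefix of the contig, fit-aligns it
#' against the tail, and verifies the implied suffix-prefix overlap with a
#' full alignment at `<= max_error` alignment error. On success the suffix
#' copy is trimmed.
#'
#' @param contig DNA string.
#' @param min_overlap smallest overlap considered (bp).
#' @param max_error maximum alignment error fraction in the overlap.
#' @param max_search how far from the end the overlap may start (default:
#'   half the contig).
#' @return list with `is_circular`, `overlap_len`, `trimmed_seq`.
#' @export
check_circularity <- function(contig, min_overlap = 500L, max_error = 0.05,
                              max_search = NULL) {
  contig <- toupper(contig)
  L <- nchar(contig)
  stopifnot(L > 2 * min_overlap)
  max_search <- as.integer(max_search %||% min(floor(L / 2), 50000L))
  seed_len <- min(1000L, min_overlap)
  seed <- substr(contig, 1, seed_len)
  tail_off <- L - max_search
  tl <- substr(contig, tail_off + 1L, L)
  hit <- fit_align(seed, tl)
  not_circ <- list(is_circular = FALSE, overlap_len = 0L, trimmed_seq = contig)
  if (is.null(hit) || hit$identity < 1 - max_error - 0.05) return(not_circ)
  ov_start <- tail_off + hit$b_start      # 0-based start of the suffix copy
  ov_len <- L - ov_start
  if (ov_len < min_overlap) return(not_circ)
  # verify the full overlap: suffix copy vs prefix
  sfx <- substr(contig, ov_start + 1L, L)
  pfx <- substr(contig, 1, min(L, ov_len + max(50L, ceiling(0.2 * ov_len))))
  ver <- fit_align(sfx, pfx)
  if (is.null(ver)) return(not_circ)
  err <- 1 - ver$identity
  if (err > max_error || ver$b_start > max(20, 0.05 * ov_len)) return(not_circ)
  list(is_circular = TRUE, overlap_len = as.integer(ov_len),
       trimmed_seq = substr(contig, 1, ov_start))
}

# greedy outward extension of an inverted-repeat candidate: step a left /
# b right (or a right / b left) while local identity holds, then trim back
# until the kept extension ends in `clean` consecutive matching columns
# (chance matches beyond the true boundary rarely run that long).
extend_ir <- function(chars, rc_chars, a, b, dir, min_identity, L,
                      clean = 10L) {
  mvec <- logical(0)
  steps <- 0L
  last_match <- 0L
  repeat {
    a2 <- a + dir$da; b2 <- b + dir$db
    if (a2 < 1L || a2 > L || b2 < 1L || b2 > L) break
    if (dir$da > 0 && a2 >= b2) break   # keep intervals disjoint
    m <- chars[a2] == rc_chars[b2]
    steps <- steps + 1L
    mvec[steps] <- m
    if (m) last_match <- steps
    a <- a2; b <- b2
    if (steps - last_match > 25L) break
  }
  # largest prefix ending in `clean` consecutive matches
  keep <- 0L
  if (steps >= clean) {
    run <- 0L
    for (t in seq_len(steps)) {
      run <- if (mvec[t]) run + 1L else 0L
      if (run >= clean) keep <- t
    }
  }
  backtrack <- steps - keep
  list(a = a - dir$da * backtrack, b = b - dir$db * backtrack)
}

#' Find the large inverted repeat pair of a plastome
#'
#' Self-comparison via canonical minimizers: positions whose k-mers match in
#' opposite orientation cluster on an anti-diagonal (`pos_a + pos_b`
#' constant) when a true inverted repeat is present. The dominant cluster is
#' extended greedily to maximal length and verified by banded alignment of
#' one copy against the reverse complement of the other. Circular inputs are
#' additionally searched in a half-rotated frame so a repeat split by the
#' linearization point is still found.
#'
#' @param seq DNA string.
#' @param circular logical.
#' @param min_len minimum repeat length (bp, >= 100).
#' @param min_identity minimum identity between the copies.
#' @param k,w minimizer parameters.
#' @return NULL, or a list with 0-based half-open intervals `a` and `b`
#'   (a before b in the given linearization), their `identity`, and
#'   `wrapped` if the detection used the rotated frame.
#' @export
find_inverted_repeats <- function(seq, circular = TRUE, min_len = 1000L,
                                  min_identity = 0.95, k = 15L, w = 10L) {
  stopifnot(min_len >= 100)
  seq <- toupper(seq)
  cand <- ir_candidate(seq, min_len, k, w)
  if (circular) {
    L <- nchar(seq)
    off <- floor(L / 2)
    cand2 <- ir_candidate(rotate_seq(seq, off), min_len, k, w)
    len1 <- if (is.null(cand)) 0 else cand$a[2] - cand$a[1]
    len2 <- if (is.null(cand2)) 0 else cand2$a[2] - cand2$a[1]
    if (len2 > len1 && !is.null(cand2)) {
      # map back to original coordinates; an interval crossing the original
      # cut is kept unwrapped as [start, start + len) with end possibly > L
      la <- cand2$a[2] - cand2$a[1]
      lb <- cand2$b[2] - cand2$b[1]
      as <- (cand2$a[1] + off) %% L
      bs <- (cand2$b[1] + off) %% L
      cand <- list(a = c(as, as + la), b = c(bs, bs + lb),
                   identity = cand2$identity, wrapped = TRUE)
      if (cand$a[1] > cand$b[1]) cand[c("a", "b")] <- cand[c("b", "a")]
    }
  }
  if (is.null(cand)) return(NULL)
  if (cand$identity < min_identity) return(NULL)
  if ((cand$a[2] - cand$a[1]) < min_len) return(NULL)
  cand
}

ir_candidate <- function(seq, min_len, k, w) {
  L <- nchar(seq)
  mz <- minimizers_cpp(seq, k, w)
  if (nrow(mz) < 4) return(NULL)
  # opposite-strand matches of the same canonical k-mer
  sp <- split(seq_len(nrow(mz)), mz$key)
  sp <- sp[vapply(sp, length, 1L) >= 2]
  pa <- integer(0); pb <- integer(0)
  for (ix in sp) {
    f <- ix[mz$fwd[ix]]
    r <- ix[!mz$fwd[ix]]
    if (length(f) == 0 || length(r) == 0) next
    g <- expand.grid(f = f, r = r)
    lo <- pmin(mz$pos[g$f], mz$pos[g$r])
    hi <- pmax(mz$pos[g$f], mz$pos[g$r])
    keep <- hi - lo >= k
    pa <- c(pa, lo[keep]); pb <- c(pb, hi[keep])
  }
  if (length(pa) < 4) return(NULL)
  s <- pa + pb
  o <- order(s)
  s <- s[o]; pa <- pa[o]; pb <- pb[o]
  grp <- cumsum(c(1L, as.integer(diff(s) > 64L)))
  cnt <- tabulate(grp)
  # pick the anti-diagonal cluster covering the longest extent
  best <- NULL; best_len <- 0
  for (g in which(cnt >= 4)) {
    i <- grp == g
    ext <- max(pa[i]) + k - min(pa[i])
    if (ext > best_len) { best_len <- ext; best <- which(i) }
  }
  if (is.null(best) || best_len < min_len * 0.5) return(NULL)
  # re-phase on the modal anti-diagonal and extend from a central seed pair,
  # stepping both copies together so the pairing stays exact
  sb <- s[best]
  mode_s <- as.integer(names(sort(table(sb), decreasing = TRUE))[1])
  cand <- best[sb == mode_s]
  if (length(cand) == 0) cand <- best
  seed <- cand[which.min(abs(pa[cand] - stats::median(pa[cand])))]
  spa <- pa[seed]; spb <- pb[seed]
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  comp <- chartr("ACGT", "TGCA", chars)
  # A k-mer [spa, spa+k) pairs with revcomp of B k-mer [spb, spb+k)
  el <- extend_ir(chars, comp, spa + 1L, spb + k, list(da = -1L, db = +1L), 0.9, L)
  er <- extend_ir(chars, comp, spa + k, spb + 1L, list(da = +1L, db = -1L), 0.9, L)
  a0 <- el$a - 1L; b1 <- el$b
  a1 <- er$a; b0 <- er$b - 1L
  if (a1 - a0 < min_len || b1 - b0 < min_len || a1 > b0) return(NULL)
  # verify identity of the two copies
  sa <- substr(seq, a0 + 1L, a1)
  sb_rc <- revcomp(substr(seq, b0 + 1L, b1))
  al <- banded_global(sa, sb_rc)
  if (is.null(al)) return(NULL)
  st <- ops_stats_cpp(al$ops)
  list(a = c(a0, a1), b = c(b0, b1),
       identity = st[["n_match"]] / nchar(al$ops), wrapped = FALSE)
}

#' Partition a plastome sequence into its quadripartite regions
#'
#' The two segments between the inverted repeats are labeled by size (the
#' larger is the LSC); the linearization is rotated so the order is LSC,
#' IRa, SSC, IRb with the LSC starting at position 0.
#'
#' @param seq DNA string.
#' @param ir_pair result of [find_inverted_repeats()].
#' @return a `plastome` with regions set (sequence possibly rotated).
#' @export
partition_quadripartite <- function(seq, ir_pair) {
  if (is.null(ir_pair)) stop("no inverted repeat pair supplied", call. = FALSE)
  seq <- toupper(seq)
  L <- nchar(seq)
  a <- ir_pair$a; b <- ir_pair$b
  gap1 <- (b[1] - a[2]) %% L   # between A end and B start
  gap2 <- (a[1] - b[2]) %% L   # between B end and A start (wraps)
  if (gap1 == gap2)
    stop("inter-repeat segments have equal length; supply explicit labels",
         call. = FALSE)
  if (gap1 <= 0 || gap2 <= 0)
    stop("inverted repeats overlap after rotation; structural error",
         call. = FALSE)
  if (gap1 > gap2) {
    # segment after A is the LSC: rotate so it starts at 0;
    # then order is LSC, (B copy), SSC, (A copy)
    off <- a[2] %% L
    lsc_len <- gap1; ssc_len <- gap2
    ira_len <- b[2] - b[1]; irb_len <- a[2] - a[1]
  } else {
    off <- b[2] %% L
    lsc_len <- gap2; ssc_len <- gap1
    ira_len <- a[2] - a[1]; irb_len <- b[2] - b[1]
  }
  rseq <- rotate_seq(seq, off)
  regions <- data.frame(
    region = c("LSC", "IRa", "SSC", "IRb"),
    start = cumsum(c(0L, lsc_len, ira_len, ssc_len)),
    end = cumsum(c(lsc_len, ira_len, ssc_len, irb_len)),
    stringsAsFactors = FALSE)
  plastome(rseq, circular = TRUE, regions = regions)
}

#' Rotate a plastome to a canonical start
#'
#' `anchor` is either a 0-based offset or an anchor sequence (e.g. the first
#' 500 bp of a reference) that must map uniquely at identity >= 0.9. An
#' anchor mapping on the '-' strand reverse complements the whole molecule
#' first. Anchors inside an inverted repeat map twice and raise an error.
#'
#' @param plastome a `plastome`.
#' @param anchor integer offset or DNA string.
#' @return the rotated `plastome`.
#' @export
rotate_to_start <- function(plastome, anchor) {
  stopifnot(inherits(plastome, "plastome"))
  L <- nchar(plastome$seq)
  if (is.numeric(anchor)) {
    off <- as.integer(anchor) %% L
  } else {
    idx <- index_reference(plastome$seq)
    hits <- map_read(data.frame(id = "anchor", seq = toupper(anchor),
                                stringsAsFactors = FALSE),
                     idx, min_identity = 0.9, max_hits = 4L)
    if (nrow(hits) == 0) stop("anchor does not map at identity >= 0.9",
                              call. = FALSE)
    top <- hits[hits$identity >= max(hits$identity) - 0.02, , drop = FALSE]
    if (nrow(top) > 1) {
      stop("anchor maps ambiguously at positions ",
           paste(top$t_start + 1, collapse = ", "),
           " (is it inside an inverted repeat?)", call. = FALSE)
    }
    if (top$strand[1] == "-") {
      plastome <- revcomp_plastome(plastome)
      idx <- index_reference(plastome$seq)
      hits <- map_read(data.frame(id = "anchor", seq = toupper(anchor),
                                  stringsAsFactors = FALSE),
                       idx, min_identity = 0.9, max_hits = 1L)
      top <- hits[1, , drop = FALSE]
    }
    off <- top$t_start[1]
  }
  out <- plastome
  out$seq <- rotate_seq(plastome$seq, off)
  out$regions <- shift_regions(plastome$regions, off, L)
  out
}

shift_regions <- function(regions, off, L) {
  if (is.null(regions) || off == 0) return(regions)
  r <- regions
  r$start <- (r$start - off) %% L
  r$end <- ((r$end - off - 1L) %% L) + 1L
  if (any(r$start > r$end - 1L & (r$end - r$start) != 0)) {
    # a region now wraps the origin; drop coordinates rather than lie
    return(NULL)
  }
  o <- order(r$start)
  r <- r[o, ]
  rownames(r) <- NULL
  if (r$start[1] != 0) return(NULL)
  if (!identical(r$region, c("LSC", "IRa", "SSC", "IRb"))) return(NULL)
  r
}

revcomp_plastome <- function(p) {
  L <- nchar(p$seq)
  out <- p
  out$seq <- revcomp(p$seq)
  if (!is.null(p$regions)) {
    r <- p$regions
    ns <- L - r$end; ne <- L - r$start
    r$start <- ns; r$end <- ne
    # order reverses; labels keep their identity but IRa/IRb swap roles
    r$region <- c(LSC = "LSC", SSC = "SSC", IRa = "IRb", IRb = "IRa")[r$region]
    r <- r[order(r$start), ]
    rownames(r) <- NULL
    out$regions <- if (r$start[1] == 0 &&
                       identical(sort(r$region),
                                 sort(c("LSC", "IRa", "SSC", "IRb")))) r else NULL
    # after reverse complement the order is IRb',SSC,IRa',LSC; rotate to LSC
    if (!is.null(out$regions) &&
        !identical(out$regions$region, c("LSC", "IRa", "SSC", "IRb"))) {
      lsc_start <- out$regions$start[out$regions$region == "LSC"]
      out$seq <- rotate_seq(out$seq, lsc_start)
      out$regions <- shift_regions(out$regions, lsc_start, L)
    }
  }
  out
}

#' Invert the small single copy region in place
#'
#' Replaces the SSC interval by its reverse complement; all region
#' boundaries and the total length are unchanged. The operation is an
#' involution. This is the repair applied when mate-pair validation shows
#' the SSC was assembled in the wrong orientation.
#'
#' @param plastome a `plastome` with quadripartite regions.
#' @return the modified `plastome`.
#' @export
flip_ssc <- function(plastome) {
  stopifnot(inherits(plastome, "plastome"))
  if (is.null(plastome$regions)) stop("no SSC defined: partition the plastome first",
                                      call. = FALSE)
  r <- plastome$regions
  s <- r$start[r$region == "SSC"]; e <- r$end[r$region == "SSC"]
  out <- plastome
  seq <- out$seq
  substr(seq, s + 1L, e) <- revcomp(substr(seq, s + 1L, e))
  out$seq <- seq
  out
}
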