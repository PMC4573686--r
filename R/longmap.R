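# Approximate mapper for long error-rich reads and short accurate reads:
# canonical minimizer seeding, diagonal clustering ("chaining"), and banded
# fit alignment of the whole read against the implied target window.
# Circularity is not handled here; callers rotate or wrap-extend the target.

#' Build a minimizer index over a reference sequence
#'
#' @param seq reference DNA string.
#' @param k k-mer size (>= 11 for mapping use; default 15).
#' @param w minimizer window (default 10).
#' @return object of class `minimizer_index`.
#' @export
index_reference <- function(seq, k = 15L, w = 10L) {
  seq <- toupper(seq)
  if (nchar(seq) < k) stop("reference shorter than k", call. = FALSE)
  mz <- minimizers_cpp(seq, as.integer(k), as.integer(w))
  o <- order(mz$key, mz$pos)
  key <- mz$key[o]
  r <- rle(key)
  structure(list(seq = seq, k = as.integer(k), w = as.integer(w),
                 ukey = r$values,
                 start = cumsum(c(1L, r$lengths))[seq_along(r$values)],
                 len = r$lengths, pos = mz$pos[o], fwd = mz$fwd[o]),
            class = "minimizer_index")
}

# look up query minimizer keys; returns target pos/fwd per match plus the
# query row index
lookup_minimizers <- function(index, keys) {
  ix <- findInterval(keys, index$ukey)
  hit <- ix >= 1L & index$ukey[pmax(ix, 1L)] == keys
  qrow <- integer(0); tpos <- integer(0); tfwd <- logical(0)
  wh <- which(hit)
  if (length(wh)) {
    reps <- index$len[ix[wh]]
    qrow <- rep(wh, reps)
    take <- unlist(lapply(ix[wh], function(u)
      seq(index$start[u], length.out = index$len[u])), use.names = FALSE)
    tpos <- index$pos[take]
    tfwd <- index$fwd[take]
  }
  list(qrow = qrow, tpos = tpos, tfwd = tfwd)
}

# widest half-band (beyond the |m - n| offset) that fits the DP memory
# budget of the C kernel
max_half_band <- function(n, m, budget = 1.8e8) {
  wmax <- floor(budget / (3 * (n + 1)))
  max(16L, as.integer(floor((wmax - abs(m - n) - 1) / 2)))
}

# fit-align query into target window with automatic band widening
fit_align <- function(query, window, slack = NULL, max_band_frac = 0.6) {
  n <- nchar(query); m <- nchar(window)
  if (n == 0 || m == 0) return(NULL)
  cap <- max_half_band(n, m)
  s2 <- min(as.integer(slack %||% max(32L, round(0.06 * n))), cap)
  smax <- min(as.integer(ceiling(max_band_frac * n)), cap)
  repeat {
    dmin <- min(0L, m - n) - s2
    dmax <- max(0L, m - n) + s2
    al <- tryCatch(align_band_cpp(query, window, TRUE, dmin, dmax),
                   error = function(e) list(ok = FALSE))
    if (isTRUE(al$ok)) {
      drift <- ops_max_drift_cpp(al$ops)
      if (drift < s2 - 4L || s2 >= smax) break
    } else if (s2 >= smax) {
      return(NULL)
    }
    s2 <- min(s2 * 2L, smax)
  }
  if (!isTRUE(al$ok)) return(NULL)
  st <- ops_stats_cpp(al$ops)
  list(ops = al$ops, dist = al$dist, b_start = al$b_start, b_end = al$b_end,
       n_match = st[["n_match"]], n_cols = nchar(al$ops),
       identity = st[["n_match"]] / nchar(al$ops))
}

# alignment cost parameters of the C kernel (match 0; see src/core.cpp)
AFFINE_COSTS <- c(mismatch = 4L, gap_open = 3L, gap_extend = 4L)

# banded global alignment with automatic widening (both sequences consumed)
banded_global <- function(a, b, band = NULL) {
  n <- nchar(a); m <- nchar(b)
  gap_cost <- function(l) AFFINE_COSTS[["gap_open"]] +
    AFFINE_COSTS[["gap_extend"]] * l
  if (n == 0 && m == 0) return(list(ops = "", dist = 0L))
  if (n == 0) return(list(ops = strrep("D", m), dist = gap_cost(m)))
  if (m == 0) return(list(ops = strrep("I", n), dist = gap_cost(n)))
  cap <- max_half_band(n, m)
  bw <- min(as.integer(band %||% max(64L, 2L * abs(m - n) + 32L)), cap)
  bmax <- min(max(n, m), cap)
  repeat {
    al <- tryCatch(align_band_cpp(a, b, FALSE, min(0L, m - n) - bw,
                                  max(0L, m - n) + bw),
                   error = function(e) list(ok = FALSE))
    if (isTRUE(al$ok)) {
      drift <- ops_max_drift_cpp(al$ops)
      if (drift < bw + abs(m - n) - 4L || bw >= bmax) break
    } else if (bw >= bmax) {
      return(NULL)
    }
    bw <- min(bw * 2L, bmax)
  }
  if (!isTRUE(al$ok)) return(NULL)
  list(ops = al$ops, dist = al$dist)
}

#' Map one read against an indexed reference
#'
#' Minimizer anchors are grouped by strand and diagonal; the best cluster(s)
#' define a target window into which the whole read is fit-aligned with a
#' banded unit-cost alignment. Hits below the floor identity (default 0.60)
#' are suppressed; the biological identity threshold is applied downstream
#' by the extraction step.
#'
#' @param read one-row data.frame (id, seq) or a character sequence.
#' @param index a [index_reference()] result.
#' @param min_chain_anchors minimum anchors in a cluster.
#' @param min_identity floor identity for reported hits.
#' @param max_hits report up to this many chains (default 1, the best).
#' @param target_id name used in the hits table.
#' @return hits data.frame (possibly empty); `q_start`/`q_end` are in
#'   oriented-query coordinates (reverse complement frame for '-' hits).
#' @export
map_read <- function(read, index, min_chain_anchors = 3L, min_identity = 0.60,
                     max_hits = 1L, target_id = "ref") {
  if (is.character(read)) read <- data.frame(id = "read", seq = read,
                                             stringsAsFactors = FALSE)
  q <- toupper(read$seq[1])
  n <- nchar(q)
  k <- index$k
  if (n < k) return(empty_hits())
  qm <- minimizers_cpp(q, k, index$w)
  if (nrow(qm) == 0) return(empty_hits())
  lk <- lookup_minimizers(index, qm$key)
  if (length(lk$qrow) == 0) return(empty_hits())
  qpos <- qm$pos[lk$qrow]
  qfwd <- qm$fwd[lk$qrow]
  rel_fwd <- qfwd == lk$tfwd
  qo <- ifelse(rel_fwd, qpos, n - k - qpos)  # oriented-query coordinate
  diag <- lk$tpos - qo
  T_len <- nchar(index$seq)
  gap <- max(64L, round(0.12 * n))
  clusters <- list()
  for (strand in c("+", "-")) {
    sel <- if (strand == "+") rel_fwd else !rel_fwd
    if (sum(sel) < min_chain_anchors) next
    d <- diag[sel]; tp <- lk$tpos[sel]; qp <- qo[sel]
    o <- order(d)
    d <- d[o]; tp <- tp[o]; qp <- qp[o]
    grp <- cumsum(c(1L, as.integer(diff(d) > gap)))
    for (g in unique(grp)) {
      i <- grp == g
      cnt <- sum(i)
      if (cnt < min_chain_anchors) next
      span <- diff(range(d[i]))
      clusters[[length(clusters) + 1L]] <- list(
        strand = strand, count = cnt, score = cnt - floor(span / 100),
        t_lo = min(tp[i] - qp[i]), t_hi = max(tp[i] - qp[i]) + n,
        n_uniq_q = length(unique(qp[i])))
    }
  }
  if (length(clusters) == 0) return(empty_hits())
  sc <- vapply(clusters, `[[`, 0, "score")
  tl <- vapply(clusters, `[[`, 0, "t_lo")
  ord <- order(-sc, tl)
  clusters <- clusters[ord][seq_len(min(max_hits, length(clusters)))]
  out <- list()
  for (cl in clusters) {
    slack <- max(48L, round(0.04 * n))
    t_lo <- max(0L, as.integer(cl$t_lo) - slack)
    t_hi <- min(T_len, as.integer(cl$t_hi) + slack)
    if (t_hi - t_lo < k) next
    oq <- if (cl$strand == "+") q else revcomp(q)
    al <- fit_align(oq, substr(index$seq, t_lo + 1L, t_hi))
    if (is.null(al) || al$identity < min_identity) next
    out[[length(out) + 1L]] <- data.frame(
      read_id = read$id[1], target_id = target_id,
      t_start = t_lo + al$b_start, t_end = t_lo + al$b_end,
      q_start = 0L, q_end = n, q_len = n, strand = cl$strand,
      identity = al$identity, n_match = al$n_match, n_cols = al$n_cols,
      ops = al$ops, stringsAsFactors = FALSE)
  }
  if (length(out) == 0) return(empty_hits())
  res <- do.call(rbind, out)
  res <- res[order(-(res$identity * (res$t_end - res$t_start))), ]
  rownames(res) <- NULL
  res
}

#' Map a set of reads
#'
#' Concatenation of per-read [map_read()] results in input order; the result
#' is independent of any batching of the input.
#'
#' @param reads data.frame of reads (id, seq).
#' @param target reference DNA string, or NULL when `index` is given.
#' @param index optional prebuilt [index_reference()].
#' @param ... passed to [map_read()].
#' @export
map_set <- function(reads, target = NULL, index = NULL, ...) {
  if (is.null(index)) {
    stopifnot(!is.null(target))
    index <- index_reference(target)
  }
  if (nrow(reads) == 0) return(empty_hits())
  res <- lapply(seq_len(nrow(reads)), function(i)
    map_read(reads[i, , drop = FALSE], index, ...))
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
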