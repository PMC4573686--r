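# Circular-aware coverage via dual linearization, windowed inter-assembly
# identity, and coverage-identity correlation.

#' Per-base coverage from a hits table
#'
#' @param hits hits data.frame (0-based half-open `t_start`/`t_end`).
#' @param genome_len track length (bp).
#' @return integer vector of length `genome_len`; `values[i]` is the number
#'   of hits whose target interval contains position i.
#' @export
coverage_from_hits <- function(hits, genome_len) {
  if (nrow(hits) == 0) return(integer(genome_len))
  if (any(hits$t_start < 0 | hits$t_end > genome_len))
    stop("hit interval outside [0, genome_len)", call. = FALSE)
  cov <- IRanges::coverage(IRanges::IRanges(start = hits$t_start + 1L,
                                            end = hits$t_end),
                           width = genome_len)
  as.integer(cov)
}

#' Circular-aware coverage by dual linearization
#'
#' Reads are mapped twice: against the assembly as given, and against the
#' assembly rotated by half its length (linearized at the opposite point of
#' the circle). Reads spanning the original cut map poorly in the first
#' linearization; the final track therefore takes its first and last
#' `end_window` positions from the (de-rotated) second mapping.
#'
#' @param reads data.frame of reads.
#' @param assembly DNA string (linearized circular molecule).
#' @param end_window bp replaced at each end (default 7000).
#' @param min_identity mapping floor passed to the mapper.
#' @return list of class `coverage_track`: `values` (final merged track),
#'   `naive` (single-linearization track), `length`, `end_window`.
#' @export
circular_coverage <- function(reads, assembly, end_window = 7000L,
                              min_identity = 0.60) {
  assembly <- toupper(assembly)
  L <- nchar(assembly)
  stopifnot(L > 2 * end_window)
  hits_a <- map_set(reads, target = assembly, min_identity = min_identity)
  track_a <- coverage_from_hits(hits_a, L)
  off <- floor(L / 2)
  rot <- rotate_seq(assembly, off)
  hits_b <- map_set(reads, target = rot, min_identity = min_identity)
  track_b_rot <- coverage_from_hits(hits_b, L)
  # de-rotate: position i (0-based) of the original assembly sits at
  # (i - off) mod L in the rotated frame
  i0 <- seq_len(L) - 1L
  track_b <- track_b_rot[((i0 - off) %% L) + 1L]
  values <- track_a
  head_ix <- seq_len(end_window)
  tail_ix <- (L - end_window + 1L):L
  values[head_ix] <- track_b[head_ix]
  values[tail_ix] <- track_b[tail_ix]
  structure(list(values = values, naive = track_a, length = L,
                 end_window = as.integer(end_window)),
            class = "coverage_track")
}

#' Windowed identity between two assemblies
#'
#' Computes (or reuses) a global alignment and reports, per window of the
#' first assembly's coordinates, matches / alignment columns among columns
#' whose first-assembly position falls in the window. Columns consuming
#' only the second assembly are attributed to the preceding position of the
#' first.
#'
#' @param seq_a,seq_b DNA strings.
#' @param window,step window size and stride in bp of `seq_a`.
#' @param aln optional precomputed [global_align_anchored()] result.
#' @return list of class `identity_track`: `identity` (one value per
#'   window, NA where no columns), `window`, `step`, `length`.
#' @export
windowed_identity <- function(seq_a, seq_b, window = 1000L, step = 500L,
                              aln = NULL) {
  if (is.null(aln)) aln <- global_align_anchored(toupper(seq_a), toupper(seq_b))
  n_a <- aln$a_len
  opsv <- strsplit(aln$ops, "", fixed = TRUE)[[1]]
  consumes_a <- opsv %in% c("M", "X", "I")
  apos <- cumsum(consumes_a)          # 1-based a position after the column
  abin <- pmax(apos, 1L)              # attribute b-only columns to current pos
  match_per_base <- integer(n_a)
  cols_per_base <- integer(n_a)
  tb <- tabulate(abin, nbins = n_a)
  cols_per_base <- tb
  mt <- tabulate(abin[opsv == "M"], nbins = n_a)
  match_per_base <- mt
  n_win <- ceiling(n_a / step)
  cm <- cumsum(c(0L, cols_per_base))
  mm <- cumsum(c(0L, match_per_base))
  ident <- rep(NA_real_, n_win)
  for (i in seq_len(n_win)) {
    s <- (i - 1L) * step
    e <- min(s + window, n_a)
    ncols <- cm[e + 1L] - cm[s + 1L]
    if (ncols > 0) ident[i] <- (mm[e + 1L] - mm[s + 1L]) / ncols
  }
  structure(list(identity = ident, window = as.integer(window),
                 step = as.integer(step), length = n_a),
            class = "identity_track")
}

#' Correlate coverage with inter-assembly identity
#'
#' Pearson (and Spearman rank) correlation of window-mean coverage against
#' window identity over the same molecule. When either track has zero
#' variance the correlation is undefined and reported as 0 with
#' `degenerate = TRUE`.
#'
#' @param cov a `coverage_track` (or plain numeric per-base vector).
#' @param ident an `identity_track`.
#' @return list with `pearson`, `spearman`, `n_windows`, `degenerate`.
#' @export
correlate_coverage_identity <- function(cov, ident) {
  values <- if (inherits(cov, "coverage_track")) cov$values else cov
  if (length(values) != ident$length)
    stop("coverage and identity tracks cover different lengths", call. = FALSE)
  n_win <- length(ident$identity)
  covw <- numeric(n_win)
  cs <- cumsum(c(0, values))
  for (i in seq_len(n_win)) {
    s <- (i - 1L) * ident$step
    e <- min(s + ident$window, length(values))
    covw[i] <- (cs[e + 1L] - cs[s + 1L]) / max(e - s, 1L)
  }
  keep <- !is.na(ident$identity)
  x <- covw[keep]; y <- ident$identity[keep]
  if (length(x) < 3 || stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(pearson = 0, spearman = 0, n_windows = length(x),
                degenerate = TRUE))
  }
  list(pearson = cor(x, y), spearman = cor(x, y, method = "spearman"),
       n_windows = length(x), degenerate = FALSE)
}

#' Write a coverage track as bedGraph (0-based half-open)
#'
#' @param track `coverage_track` or numeric vector.
#' @param path output file.
#' @param name molecule name.
#' @export
write_bedgraph <- function(track, path, name = "assembly") {
  values <- if (inherits(track, "coverage_track")) track$values else track
  r <- rle(values)
  e <- cumsum(r$lengths)
  s <- c(0L, head(e, -1))
  write.table(data.frame(name, s, e, r$values), path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
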