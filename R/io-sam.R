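# Minimal SAM subset: import and export of mapping records. Only the fields
# the workflow needs are honoured (header @SQ lengths, FLAG bits 0x4/0x10,
# RNAME, POS, CIGAR, optional NM tag). Exported records use =/X/I/D CIGAR ops
# so that import -> export -> import is lossless for the alignment detail.
#
# Internal mapping records ("hits") are data.frames with columns
#   read_id, target_id, t_start, t_end   (0-based half-open target interval)
#   q_start, q_end, q_len                (oriented-query coordinates)
#   strand ('+'/'-'), identity, n_match, n_cols, ops
# where `ops` is a string over M (match), X (mismatch), I (query-only) and
# D (target-only) columns; the oriented query is the reverse complement of
# the read when strand == '-'. Identity is matches / alignment columns with
# columns = matches + mismatches + inserted + deleted bases.

empty_hits <- function() {
  data.frame(read_id = character(0), target_id = character(0),
             t_start = integer(0), t_end = integer(0),
             q_start = integer(0), q_end = integer(0), q_len = integer(0),
             strand = character(0), identity = numeric(0),
             n_match = integer(0), n_cols = integer(0), ops = character(0),
             stringsAsFactors = FALSE)
}

parse_cigar <- function(cigar) {
  m <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
  if (length(m) == 0 || paste(m, collapse = "") != cigar)
    stop("unparseable CIGAR: ", cigar, call. = FALSE)
  list(len = as.integer(sub("[MIDNSHP=X]$", "", m)),
       op = sub("^[0-9]+", "", m))
}

#' Import mappings from a minimal SAM file
#'
#' Unmapped records (FLAG 0x4) are skipped; positions are converted to the
#' package's 0-based half-open convention; strand comes from FLAG 0x10.
#' Identity is computed from the CIGAR (directly for `=`/`X` CIGARs,
#' otherwise from the NM tag); records without either carry `NA` identity.
#'
#' @param path SAM file with header.
#' @return a hits data.frame (see package conventions).
#' @export
read_mappings_sam <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "@")]
  rec <- lines[!startsWith(lines, "@") & nzchar(lines)]
  sq <- hdr[startsWith(hdr, "@SQ")]
  sq_len <- integer(0)
  if (length(sq)) {
    sn <- sub(".*\\tSN:([^\t]+).*", "\\1", sq)
    ln <- suppressWarnings(as.integer(sub(".*\\tLN:([0-9]+).*", "\\1", sq)))
    sq_len <- stats::setNames(ln, sn)
  }
  out <- vector("list", length(rec))
  for (i in seq_along(rec)) {
    f <- strsplit(rec[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 11) stop("truncated SAM record at line ", i, call. = FALSE)
    flag <- as.integer(f[2])
    if (bitwAnd(flag, 4L) != 0L) next
    rname <- f[3]
    if (!(rname %in% names(sq_len)) || is.na(sq_len[[rname]]))
      stop("missing @SQ length for reference '", rname, "'", call. = FALSE)
    cig <- parse_cigar(f[6])
    ref_len <- sum(cig$len[cig$op %in% c("M", "D", "N", "=", "X")])
    qcons <- sum(cig$len[cig$op %in% c("M", "I", "=", "X")])
    clip_l <- if (cig$op[1] == "S") cig$len[1] else 0L
    clip_r <- if (tail(cig$op, 1) == "S") tail(cig$len, 1) else 0L
    t_start <- as.integer(f[4]) - 1L
    nm <- NA_integer_
    if (length(f) > 11) {
      nmf <- grep("^NM:i:", f[12:length(f)], value = TRUE)
      if (length(nmf)) nm <- as.integer(sub("^NM:i:", "", nmf[1]))
    }
    n_ins <- sum(cig$len[cig$op == "I"])
    n_del <- sum(cig$len[cig$op == "D"])
    m_cols <- sum(cig$len[cig$op %in% c("M", "=", "X")])
    has_eqx <- any(cig$op %in% c("=", "X")) && !any(cig$op == "M")
    if (has_eqx) {
      n_mm <- sum(cig$len[cig$op == "X"])
      opchars <- rep(cig$op, cig$len)
      opchars <- opchars[opchars %in% c("=", "X", "I", "D")]
      ops <- paste(chartr("=", "M", opchars), collapse = "")
    } else if (!is.na(nm)) {
      n_mm <- nm - n_ins - n_del
      ops <- NA_character_
    } else {
      n_mm <- NA_integer_
      ops <- NA_character_
    }
    n_cols <- m_cols + n_ins + n_del
    n_match <- if (is.na(n_mm)) NA_integer_ else m_cols - n_mm
    q_len <- clip_l + qcons + clip_r
    out[[i]] <- data.frame(
      read_id = f[1], target_id = rname, t_start = t_start,
      t_end = t_start + ref_len, q_start = clip_l, q_end = clip_l + qcons,
      q_len = q_len, strand = if (bitwAnd(flag, 16L)) "-" else "+",
      identity = if (is.na(n_match)) NA_real_ else n_match / n_cols,
      n_match = n_match, n_cols = n_cols, ops = ops,
      stringsAsFactors = FALSE)
  }
  out <- out[!vapply(out, is.null, TRUE)]
  if (length(out) == 0) return(empty_hits())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

ops_to_cigar <- function(ops, clip_l = 0L, clip_r = 0L) {
  r <- rle(strsplit(chartr("M", "=", ops), "", fixed = TRUE)[[1]])
  body <- paste0(r$lengths, r$values, collapse = "")
  paste0(if (clip_l > 0) paste0(clip_l, "S") else "",
         body,
         if (clip_r > 0) paste0(clip_r, "S") else "")
}

#' Export mappings to a minimal SAM file
#'
#' @param hits hits data.frame.
#' @param path output path.
#' @param target_lengths named integer vector of reference lengths for the
#'   `@SQ` header lines.
#' @export
write_mappings_sam <- function(hits, path, target_lengths) {
  stopifnot(!is.null(names(target_lengths)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unknown", con)
  writeLines(sprintf("@SQ\tSN:%s\tLN:%d", names(target_lengths),
                     as.integer(target_lengths)), con)
  if (nrow(hits) > 0) {
    cig <- character(nrow(hits))
    nm <- integer(nrow(hits))
    for (i in seq_len(nrow(hits))) {
      h <- hits[i, ]
      if (is.na(h$ops)) {
        mlen <- h$q_end - h$q_start
        cig[i] <- ops_to_cigar(strrep("M", mlen), h$q_start, h$q_len - h$q_end)
      } else {
        cig[i] <- ops_to_cigar(h$ops, h$q_start, h$q_len - h$q_end)
      }
      nm[i] <- h$n_cols - h$n_match
    }
    writeLines(sprintf("%s\t%d\t%s\t%d\t255\t%s\t*\t0\t0\t*\t*\tNM:i:%d",
                       hits$read_id,
                       ifelse(hits$strand == "-", 16L, 0L),
                       hits$target_id, hits$t_start + 1L, cig, nm), con)
  }
  invisible(path)
}
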