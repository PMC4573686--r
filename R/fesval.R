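# Mate-pair (fosmid-end sequence) validation of assembly element order and
# orientation: circular pair geometry, consistency classification, and
# diagnosis of a misoriented small single copy region.

#' Circular geometry of a mate pair
#'
#' Distance convention: start of the '-' mate minus start of the '+' mate,
#' modulo the genome length, with both starts the leftmost (smallest)
#' coordinate of the respective mapping. A pair is convergent when the
#' strands are opposite and that distance falls within the insert window;
#' mates on the same strand are tandem; the remaining opposite-strand pairs
#' are divergent.
#'
#' @param hit_fw,hit_rv one-row hits (need `t_start`, `strand`,
#'   `target_id`).
#' @param genome_len circumference of the molecule (bp).
#' @param insert_window numeric length-2, plausible distance range (bp).
#' @return list with `distance` and `orientation_class`.
#' @export
pair_geometry <- function(hit_fw, hit_rv, genome_len,
                          insert_window = c(25000, 50000)) {
  if (!is.null(hit_fw$target_id) && !is.null(hit_rv$target_id) &&
      !identical(hit_fw$target_id[1], hit_rv$target_id[1]))
    stop("mates map to different targets", call. = FALSE)
  s_fw <- hit_fw$t_start[1]; s_rv <- hit_rv$t_start[1]
  st_fw <- hit_fw$strand[1]; st_rv <- hit_rv$strand[1]
  if (st_fw == st_rv) {
    d <- min((s_rv - s_fw) %% genome_len, (s_fw - s_rv) %% genome_len)
    return(list(distance = d, orientation_class = "tandem"))
  }
  plus <- if (st_fw == "+") s_fw else s_rv
  minus <- if (st_fw == "+") s_rv else s_fw
  d <- (minus - plus) %% genome_len
  cls <- if (d >= insert_window[1] && d <= insert_window[2]) "convergent"
         else "divergent"
  list(distance = d, orientation_class = cls)
}

#' Validate an assembly with long-insert mate pairs
#'
#' Mates are mapped (via the internal mapper, on a wrap-extended
#' linearization so pairs spanning the origin behave like any other pair),
#' paired by the `<clone>-fw` / `<clone>-rv` naming convention, and
#' classified. A pair is consistent when convergent with a distance inside
#' the insert window. Mates whose best placement lies inside an inverted
#' repeat are flagged ambiguous (the two copies are interchangeable) and
#' tallied separately, as are pairs with an unmapped mate.
#'
#' @param reads data.frame of FES reads (`id` ending in `-fw`/`-rv`), or a
#'   precomputed pairs data.frame (columns clone, fw_start, fw_strand,
#'   rv_start, rv_strand).
#' @param plastome a `plastome` (regions optional).
#' @param insert_window plausible start-to-start distance range (bp).
#' @param min_identity mapping identity floor for placing a mate.
#' @return list of class `fes_validation`: `pairs` (per-pair table),
#'   `n_consistent`, `n_inconsistent`, `n_ambiguous`, `n_unplaced`,
#'   `inconsistent_by_region_pair`.
#' @export
validate_assembly <- function(reads, plastome, insert_window = c(25000, 50000),
                              min_identity = 0.8) {
  stopifnot(inherits(plastome, "plastome"))
  L <- nchar(plastome$seq)
  if (!is.null(reads$id)) {
    wrap <- min(2000L, floor(L / 10))
    ext <- paste0(plastome$seq, substr(plastome$seq, 1, wrap))
    idx <- index_reference(ext)
    hits <- map_set(reads, index = idx, min_identity = min_identity)
    hits$t_start <- hits$t_start %% L
    clone <- sub("-(fw|rv)$", "", reads$id)
    role <- sub("^.*-(fw|rv)$", "\\1", reads$id)
    clones <- unique(clone)
    pairs <- data.frame(clone = clones, fw_start = NA_integer_,
                        fw_strand = NA_character_, rv_start = NA_integer_,
                        rv_strand = NA_character_, stringsAsFactors = FALSE)
    best <- hits[!duplicated(hits$read_id), ] # map_read returns best first
    rownames(best) <- best$read_id
    for (i in seq_along(clones)) {
      fid <- reads$id[clone == clones[i] & role == "fw"][1]
      rid <- reads$id[clone == clones[i] & role == "rv"][1]
      if (!is.na(fid) && fid %in% rownames(best)) {
        pairs$fw_start[i] <- best[fid, "t_start"]
        pairs$fw_strand[i] <- best[fid, "strand"]
      }
      if (!is.na(rid) && rid %in% rownames(best)) {
        pairs$rv_start[i] <- best[rid, "t_start"]
        pairs$rv_strand[i] <- best[rid, "strand"]
      }
    }
  } else {
    pairs <- reads
  }
  classify_pairs(pairs, plastome, insert_window)
}

classify_pairs <- function(pairs, plastome, insert_window) {
  L <- nchar(plastome$seq)
  n <- nrow(pairs)
  pairs$distance <- rep(NA_real_, n)
  pairs$orientation_class <- rep(NA_character_, n)
  pairs$region_fw <- region_of(plastome, pairs$fw_start)
  pairs$region_rv <- region_of(plastome, pairs$rv_start)
  pairs$ambiguous <- pairs$region_fw %in% c("IRa", "IRb") |
    pairs$region_rv %in% c("IRa", "IRb")
  pairs$consistent <- rep(NA, n)
  for (i in seq_len(n)) {
    if (is.na(pairs$fw_start[i]) || is.na(pairs$rv_start[i])) next
    g <- pair_geometry(list(t_start = pairs$fw_start[i], strand = pairs$fw_strand[i]),
                       list(t_start = pairs$rv_start[i], strand = pairs$rv_strand[i]),
                       L, insert_window)
    pairs$distance[i] <- g$distance
    pairs$orientation_class[i] <- g$orientation_class
    pairs$consistent[i] <- g$orientation_class == "convergent"
  }
  placed <- !is.na(pairs$consistent)
  scored <- placed & !pairs$ambiguous
  inc <- pairs[scored & !pairs$consistent, , drop = FALSE]
  by_region <- if (nrow(inc)) {
    key <- apply(cbind(inc$region_fw, inc$region_rv), 1,
                 function(x) paste(sort(x), collapse = "-"))
    as.list(table(key))
  } else list()
  structure(list(
    pairs = pairs,
    n_consistent = sum(scored & pairs$consistent),
    n_inconsistent = sum(scored & !pairs$consistent),
    n_ambiguous = sum(placed & pairs$ambiguous),
    n_unplaced = sum(!placed),
    inconsistent_by_region_pair = by_region,
    insert_window = insert_window), class = "fes_validation")
}

#' @export
print.fes_validation <- function(x, ...) {
  cat(sprintf("FES validation: %d consistent, %d inconsistent, %d IR-ambiguous, %d unplaced\n",
              x$n_consistent, x$n_inconsistent, x$n_ambiguous, x$n_unplaced))
  if (length(x$inconsistent_by_region_pair)) {
    cat("  inconsistent by region pair:\n")
    for (k in names(x$inconsistent_by_region_pair))
      cat(sprintf("    %s: %d\n", k, x$inconsistent_by_region_pair[[k]]))
  }
  invisible(x)
}

#' Diagnose a misoriented small single copy region
#'
#' Re-evaluates every pair against a virtually SSC-flipped assembly without
#' re-mapping: mates inside the SSC have their position mirrored and strand
#' inverted, mates elsewhere are untouched. A flip is recommended iff the
#' inconsistent count strictly decreases and the post-flip consistency of
#' SSC-involving pairs reaches at least the pre-flip consistency of pairs
#' not touching the SSC. Pairs with an inverted-repeat mate carry no
#' orientation information (the copies are interchangeable) and are
#' excluded from the evidence.
#'
#' @param report a `fes_validation` from [validate_assembly()].
#' @param plastome the `plastome` the report was computed on (regions
#'   required).
#' @return list with `flip_recommended`, `evidence` (counts before/after),
#'   and `note` when evidence is insufficient.
#' @export
diagnose_ssc_flip <- function(report, plastome) {
  stopifnot(inherits(report, "fes_validation"), inherits(plastome, "plastome"))
  if (is.null(plastome$regions))
    stop("plastome has no quadripartite partition", call. = FALSE)
  r <- plastome$regions
  s <- r$start[r$region == "SSC"]; e <- r$end[r$region == "SSC"]
  pairs <- report$pairs
  placed <- !is.na(pairs$consistent)
  eligible <- placed & !pairs$ambiguous
  in_ssc_fw <- pairs$region_fw == "SSC"
  in_ssc_rv <- pairs$region_rv == "SSC"
  ssc_involved <- eligible & (in_ssc_fw | in_ssc_rv)
  if (!any(ssc_involved)) {
    return(list(flip_recommended = FALSE,
                note = "insufficient evidence: no confidently placed pair touches the SSC",
                evidence = NULL))
  }
  flipped <- pairs
  mirror <- function(pos) s + (e - pos) - 1L
  flip_strand <- function(st) ifelse(st == "+", "-", "+")
  fsel <- which(in_ssc_fw & placed)
  flipped$fw_start[fsel] <- mirror(pairs$fw_start[fsel])
  flipped$fw_strand[fsel] <- flip_strand(pairs$fw_strand[fsel])
  rsel <- which(in_ssc_rv & placed)
  flipped$rv_start[rsel] <- mirror(pairs$rv_start[rsel])
  flipped$rv_strand[rsel] <- flip_strand(pairs$rv_strand[rsel])
  after <- classify_pairs(flipped[, c("clone", "fw_start", "fw_strand",
                                      "rv_start", "rv_strand")],
                          plastome, report$insert_window)
  non_ssc <- eligible & !(in_ssc_fw | in_ssc_rv)
  cons_non_ssc_before <- if (any(non_ssc))
    mean(pairs$consistent[non_ssc]) else 1
  after_pairs <- after$pairs
  cons_ssc_after <- mean(after_pairs$consistent[ssc_involved], na.rm = TRUE)
  dec <- after$n_inconsistent < report$n_inconsistent
  list(flip_recommended = isTRUE(dec && cons_ssc_after >= cons_non_ssc_before),
       evidence = list(
         inconsistent_before = report$n_inconsistent,
         inconsistent_after = after$n_inconsistent,
         ssc_pairs = sum(ssc_involved),
         consistency_ssc_after = cons_ssc_after,
         consistency_non_ssc_before = cons_non_ssc_before),
       note = NULL)
}

#' Export a FES validation report as a TSV table
#'
#' Positions are written 1-based, mirroring how mate positions are usually
#' tabulated in finishing reports.
#' @param report `fes_validation`.
#' @param path output file.
#' @export
write_fes_report <- function(report, path) {
  p <- report$pairs
  out <- data.frame(clone = p$clone,
                    position_fw = p$fw_start + 1L, orientation_fw = p$fw_strand,
                    position_rv = p$rv_start + 1L, orientation_rv = p$rv_strand,
                    distance = p$distance, located_on_fw = p$region_fw,
                    located_on_rv = p$region_rv,
                    consistent = p$consistent, stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
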