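# Build the chloroplast read whitelist from a whole-genome read pool by
# mapping against a heterologous plastome reference, and summarize the
# extraction.

#' Extraction configuration
#'
#' @param min_identity minimal mapping identity for a subread to count as
#'   plastid-like (inclusive threshold; default 0.80).
#' @param expected_genome_size expected chloroplast genome size in bp used
#'   for fold-coverage reporting (default 150,000).
#' @export
extract_config <- function(min_identity = 0.80, expected_genome_size = 150000L) {
  stopifnot(min_identity > 0, min_identity < 1, expected_genome_size > 0)
  structure(list(min_identity = min_identity,
                 expected_genome_size = as.integer(expected_genome_size)),
            class = "extract_config")
}

#' Classify reads against a plastome reference and build the whitelist
#'
#' A subread contributes its polymerase-read key to the whitelist iff it has
#' at least one mapping with identity >= `min_identity` (inclusive). Keys
#' are consolidated at the `movie/hole` level, so sibling subreads of a
#' matching hole are pulled in by [extract_by_whitelist()].
#'
#' @param reads data.frame of reads (id, seq).
#' @param reference heterologous plastome DNA string.
#' @param config an [extract_config()].
#' @param hits optional precomputed hits table (skips mapping).
#' @param circular_reference treat the reference as a circular molecule
#'   (default TRUE): it is wrap-extended before mapping so reads spanning
#'   its linearization point are not penalized.
#' @param ... passed to the mapper.
#' @return character vector whitelist of polymerase-read keys.
#' @export
classify_reads <- function(reads, reference = NULL, config = extract_config(),
                           hits = NULL, circular_reference = TRUE, ...) {
  if (is.null(hits)) {
    stopifnot(nzchar(reference))
    reference <- toupper(reference)
    if (circular_reference && nrow(reads) > 0) {
      wrap <- min(nchar(reference), max(nchar(reads$seq)))
      reference <- paste0(reference, substr(reference, 1, wrap))
    }
    hits <- map_set(reads, target = reference, ...)
  }
  if (nrow(hits) == 0) return(character(0))
  ok <- hits$identity >= config$min_identity
  ids <- unique(hits$read_id[ok])
  if (length(ids) == 0) return(character(0))
  consolidate_whitelist(ids)
}

#' Extract all subreads whose polymerase read is whitelisted
#'
#' @param reads data.frame of reads.
#' @param wl whitelist (character vector of `movie/hole` keys).
#' @return the matching subset of `reads`, input order preserved.
#' @export
extract_by_whitelist <- function(reads, wl) {
  if (nrow(reads) == 0 || length(wl) == 0) return(reads[0, , drop = FALSE])
  keep <- polymerase_key(reads$id) %in% wl
  out <- reads[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Summarize an extraction
#'
#' @param extracted data.frame of extracted reads (or NULL when passing
#'   counts directly).
#' @param pool_bases total bases in the read pool the extraction drew from.
#' @param config an [extract_config()].
#' @param n_subreads,n_bases direct counts (used when `extracted` is NULL).
#' @return list of class `extract_summary` with `n_subreads`, `n_bases`,
#'   `fold_coverage` (full precision), `fold_coverage_int` (truncated, as
#'   reported in text), and `fraction_of_pool`.
#' @export
summarize_extraction <- function(extracted = NULL, pool_bases = NA_real_,
                                 config = extract_config(),
                                 n_subreads = NULL, n_bases = NULL) {
  if (!is.null(extracted)) {
    n_subreads <- nrow(extracted)
    n_bases <- if (n_subreads) sum(nchar(extracted$seq)) else 0
  }
  stopifnot(!is.null(n_subreads), !is.null(n_bases))
  if (!is.na(pool_bases) && pool_bases < n_bases)
    stop("pool_bases smaller than extracted bases", call. = FALSE)
  fold <- n_bases / config$expected_genome_size
  structure(list(
    n_subreads = n_subreads, n_bases = n_bases,
    fold_coverage = fold, fold_coverage_int = as.integer(floor(fold)),
    fraction_of_pool = if (is.na(pool_bases)) NA_real_ else n_bases / pool_bases),
    class = "extract_summary")
}

#' @export
print.extract_summary <- function(x, ...) {
  cat(sprintf("extracted %d subreads, %.0f bases (%d-fold coverage)\n",
              x$n_subreads, x$n_bases, x$fold_coverage_int))
  if (!is.na(x$fraction_of_pool))
    cat(sprintf("  %.2f%% of the supplied pool\n", 100 * x$fraction_of_pool))
  invisible(x)
}

#' Total sequencing yield from read count and mean length
#'
#' Dataset-scale arithmetic helper: `n_reads * mean_length` bases.
#' @param n_reads number of reads.
#' @param mean_length mean read length (bp).
#' @export
sequencing_yield <- function(n_reads, mean_length) n_reads * mean_length
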