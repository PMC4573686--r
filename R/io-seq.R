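# FASTA/FASTQ input and output. Reads are carried through the package as a
# plain data.frame with columns id, seq, qual (qual NA when absent), which
# keeps the simulator truth exact and the C-level aligners string-based.
# Biostrings does the actual file parsing and writing.

#' Read sequences from FASTA or FASTQ
#'
#' @param path input file.
#' @param format `"fasta"` or `"fastq"` (default: guessed from the
#'   extension, falling back to fasta).
#' @return data.frame with columns `id`, `seq` and `qual` (NA for FASTA).
#'   Sequences are uppercased and restricted to A,C,G,T,N.
#' @export
read_sequences <- function(path, format = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(format)) {
    format <- if (grepl("\\.f(ast)?q(\\.gz)?$", path, ignore.case = TRUE))
      "fastq" else "fasta"
  }
  format <- match.arg(format, c("fasta", "fastq"))
  if (format == "fasta") {
    x <- Biostrings::readBStringSet(path, format = "fasta")
    recs <- data.frame(id = names(x), seq = toupper(as.character(x)),
                       qual = rep(NA_character_, length(x)),
                       stringsAsFactors = FALSE)
  } else {
    x <- tryCatch(
      Biostrings::readBStringSet(path, format = "fastq", with.qualities = TRUE),
      error = function(e) stop("malformed FASTQ in '", path, "': ",
                               conditionMessage(e), call. = FALSE))
    q <- as.character(S4Vectors::mcols(x)$qualities)
    recs <- data.frame(id = names(x), seq = toupper(as.character(x)),
                       qual = q, stringsAsFactors = FALSE)
    bad <- nchar(recs$qual) != nchar(recs$seq)
    if (any(bad)) {
      stop(sprintf("FASTQ record '%s': quality length (%d) != sequence length (%d)",
                   recs$id[which(bad)[1]], nchar(recs$qual[which(bad)[1]]),
                   nchar(recs$seq[which(bad)[1]])), call. = FALSE)
    }
  }
  rownames(recs) <- NULL
  if (nrow(recs) > 0) {
    if (any(!nzchar(recs$seq)))
      stop("empty sequence in record '", recs$id[!nzchar(recs$seq)][1], "'",
           call. = FALSE)
    assert_dna(recs$seq, "input sequence")
  }
  recs
}

#' Write sequences to FASTA or FASTQ
#'
#' FASTA output wraps at `width` columns; FASTQ uses Sanger Phred+33
#' qualities (records without qualities get a flat placeholder).
#'
#' @param records data.frame with columns `id`, `seq` and optionally `qual`.
#' @param path output file.
#' @param format `"fasta"` or `"fastq"`.
#' @param width line width for FASTA wrapping.
#' @export
write_sequences <- function(records, path, format = c("fasta", "fastq"),
                            width = 80L) {
  format <- match.arg(format)
  stopifnot(is.data.frame(records), all(c("id", "seq") %in% names(records)))
  if (format == "fasta") {
    x <- Biostrings::BStringSet(records$seq)
    names(x) <- records$id
    Biostrings::writeXStringSet(x, path, format = "fasta", width = width)
  } else {
    qual <- records$qual
    if (is.null(qual)) qual <- rep(NA_character_, nrow(records))
    qual <- ifelse(is.na(qual),
                   vapply(nchar(records$seq),
                          function(n) strrep("I", n), ""),
                   qual)
    if (any(nchar(qual) != nchar(records$seq)))
      stop("quality length != sequence length", call. = FALSE)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste0("@", records$id, "\n", records$seq, "\n+\n", qual), con)
  }
  invisible(path)
}
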