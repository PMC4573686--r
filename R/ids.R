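# PacBio-style read identifiers and polymerase-read whitelists.
#
# A SMRT instrument emits one polymerase read per ZMW hole; adapters split it
# into subreads named `<movie>/<hole>/<qstart>_<qend>` with a 0-based
# half-open query interval. Whitelisting happens at the polymerase-read level
# (`<movie>/<hole>`): once any subread of a hole looks plastid-like, all
# subreads of that hole are kept.

#' Parse PacBio-style subread identifiers
#'
#' @param raw character vector of identifiers of the form
#'   `movie/hole/qstart_qend` (the movie name may itself contain `_` or `/`).
#' @return a data.frame with columns `movie`, `hole`, `qstart`, `qend`
#'   (`qstart` 0-based inclusive, `qend` exclusive).
#' @examples
#' parse_subread_id("m1/8/0_3213")
#' @export
parse_subread_id <- function(raw) {
  stopifnot(is.character(raw), length(raw) >= 1)
  m <- regmatches(raw, regexec("^(.*)/([0-9]+)/([0-9]+)_([0-9]+)$", raw))
  bad <- vapply(m, length, 1L) != 5L
  if (any(bad)) {
    r <- raw[bad][1]
    part <- if (!grepl("/", r)) "movie/hole separator"
            else if (!grepl("_[0-9]+$", r)) "qstart_qend suffix"
            else "hole number"
    stop(sprintf("malformed subread id '%s': cannot parse %s", r, part),
         call. = FALSE)
  }
  movie <- vapply(m, `[`, "", 2L)
  if (any(movie == "")) {
    stop(sprintf("malformed subread id '%s': empty movie name",
                 raw[movie == ""][1]), call. = FALSE)
  }
  out <- data.frame(
    movie = movie,
    hole = as.integer(vapply(m, `[`, "", 3L)),
    qstart = as.integer(vapply(m, `[`, "", 4L)),
    qend = as.integer(vapply(m, `[`, "", 5L)),
    stringsAsFactors = FALSE
  )
  if (any(out$qend <= out$qstart)) {
    i <- which(out$qend <= out$qstart)[1]
    stop(sprintf("malformed subread id '%s': qend (%d) must exceed qstart (%d)",
                 raw[i], out$qend[i], out$qstart[i]), call. = FALSE)
  }
  out
}

#' Format parsed subread identifiers back to strings
#'
#' Inverse of [parse_subread_id()]; round-trips exactly.
#' @param parsed data.frame as returned by [parse_subread_id()].
#' @export
format_subread_id <- function(parsed) {
  sprintf("%s/%d/%d_%d", parsed$movie, parsed$hole, parsed$qstart, parsed$qend)
}

#' Polymerase-read key of a read identifier
#'
#' Returns `movie/hole` for PacBio-style ids; identifiers that do not follow
#' the subread convention are used verbatim as their own key.
#' @param ids character vector of read identifiers.
#' @export
polymerase_key <- function(ids) {
  ok <- grepl("^.*/[0-9]+/[0-9]+_[0-9]+$", ids)
  out <- ids
  if (any(ok)) out[ok] <- sub("/[0-9]+_[0-9]+$", "", ids[ok])
  out
}

#' Consolidate subread identifiers into a polymerase-read whitelist
#'
#' Multiple subreads of the same hole collapse to a single whitelist entry.
#' The result is a sorted unique character vector, so consolidation is
#' idempotent and order-insensitive.
#'
#' @param subread_ids character vector of subread identifiers (or a parsed
#'   data.frame from [parse_subread_id()]).
#' @return character vector of unique `movie/hole` keys, sorted.
#' @export
consolidate_whitelist <- function(subread_ids) {
  if (is.data.frame(subread_ids)) {
    keys <- sprintf("%s/%d", subread_ids$movie, subread_ids$hole)
  } else {
    if (length(subread_ids) == 0) return(character(0))
    keys <- polymerase_key(subread_ids)
  }
  sort(unique(keys))
}

#' Read / write whitelist files (one polymerase-read key per line)
#'
#' @param path file path.
#' @export
read_whitelist <- function(path) {
  x <- readLines(path)
  sort(unique(x[nzchar(x)]))
}

#' @rdname read_whitelist
#' @param keys character vector of keys.
#' @export
write_whitelist <- function(keys, path) {
  writeLines(sort(unique(keys)), path)
  invisible(path)
}
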