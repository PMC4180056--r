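# Sequence records: a named DNA string plus N-run annotation.
# Internal coordinates are 0-based half-open everywhere.

ALLOWED_INPUT <- "ACGTNURYSWKMBDHV"

#' Create a normalized sequence record
#'
#' Uppercases the sequence, maps `U` to `T`, maps IUPAC ambiguity codes other
#' than `N` to `N`, and annotates runs of `N`. Characters outside the IUPAC
#' nucleotide alphabet are a hard error.
#'
#' @param id Record identifier (first whitespace-delimited token is used).
#' @param seq DNA string.
#' @return An object of class `seq_record`: a list with elements `id`, `seq`,
#'   `length` and `n_runs` (two-column matrix of 0-based half-open intervals).
#' @export
seq_record <- function(id, seq) {
  stopifnot(is.character(id), length(id) == 1L, is.character(seq), length(seq) == 1L)
  id <- strsplit(trimws(id), "\\s+")[[1]][1]
  if (is.na(id) || !nzchar(id)) stop("record has an empty identifier")
  s <- toupper(seq)
  bad <- gsub(sprintf("[%s]", ALLOWED_INPUT), "", s)
  if (nzchar(bad))
    stop(sprintf("record '%s' contains invalid characters: %s", id,
                 paste(unique(strsplit(bad, "")[[1]]), collapse = " ")))
  s <- chartr("U", "T", s)
  s <- gsub("[RYSWKMBDHV]", "N", s)
  if (!nzchar(s)) stop(sprintf("record '%s' has an empty sequence", id))
  structure(list(id = id, seq = s, length = nchar(s), n_runs = n_runs(s)),
            class = "seq_record")
}

# 0-based half-open intervals of N runs in a normalized sequence.
n_runs <- function(seq) {
  m <- gregexpr("N+", seq)[[1]]
  if (m[1] == -1L)
    return(matrix(integer(0), ncol = 2, dimnames = list(NULL, c("start", "end"))))
  start <- as.integer(m) - 1L
  end <- start + attr(m, "match.length")
  cbind(start = start, end = end)
}

#' @export
print.seq_record <- function(x, ...) {
  cat(sprintf("<seq_record> %s  %d bp  (%d N runs)\n",
              x$id, x$length, nrow(x$n_runs)))
  invisible(x)
}

as_records <- function(x) {
  if (inherits(x, "seq_record")) return(list(x))
  if (is.character(x)) {
    ids <- names(x)
    if (is.null(ids)) ids <- sprintf("seq%d", seq_along(x))
    return(mapply(seq_record, ids, x, SIMPLIFY = FALSE, USE.NAMES = FALSE))
  }
  stopifnot(is.list(x))
  x
}

record_ids <- function(records) vapply(records, `[[`, character(1), "id")

record_seqs <- function(records) {
  s <- vapply(records, `[[`, character(1), "seq")
  names(s) <- record_ids(records)
  s
}

find_record <- function(records, id) {
  i <- match(id, record_ids(records))
  if (is.na(i)) stop(sprintf("no record with id '%s'", id))
  records[[i]]
}

#' Reverse complement
#'
#' @param seq Character vector of DNA strings over `{A,C,G,T,N}`.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(seq) cpp_revcomp(seq)
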