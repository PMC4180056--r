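# FASTA input/output, assembly statistics, and scaffold splitting.

#' Read a FASTA file into normalized sequence records
#'
#' Records come back in file order. Sequences are uppercased, IUPAC ambiguity
#' codes other than N are mapped to N, and ids are the first
#' whitespace-delimited token of each header. Empty sequences and duplicate
#' ids are hard errors naming the offending record.
#'
#' @param path Path to a FASTA file.
#' @return List of [seq_record()] objects.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop(sprintf("FASTA file '%s' does not exist", path))
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop(sprintf("malformed FASTA '%s': %s",
                                                   path, conditionMessage(e))))
  if (length(set) == 0L) stop(sprintf("FASTA '%s' contains no records", path))
  ids <- vapply(strsplit(trimws(names(set)), "\\s+"), `[`, character(1), 1)
  empty <- which(Biostrings::width(set) == 0L)
  if (length(empty) > 0L)
    stop(sprintf("record '%s' in '%s' has an empty sequence", ids[empty[1]], path))
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L)
    stop(sprintf("duplicate record id '%s' in '%s'", dup[1], path))
  seqs <- as.character(set)
  mapply(seq_record, ids, seqs, SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

#' Write sequence records to a FASTA file
#'
#' @param records List of [seq_record()] objects.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 70L) {
  records <- as_records(records)
  set <- Biostrings::BStringSet(record_seqs(records))
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Assembly summary statistics
#'
#' N50 is the standard definition: the length L such that sequences of
#' length at least L contain at least half of the total assembly bases.
#'
#' @param records List of [seq_record()] objects.
#' @return List with `n_sequences`, `total_length`, `n50`, `min_length`,
#'   `max_length`.
#' @export
compute_stats <- function(records) {
  records <- as_records(records)
  if (length(records) == 0L) stop("cannot compute statistics of an empty assembly")
  len <- sort(vapply(records, `[[`, integer(1), "length"), decreasing = TRUE)
  total <- sum(as.double(len))
  n50 <- len[which(cumsum(as.double(len)) >= total / 2)[1]]
  list(n_sequences = length(len), total_length = total, n50 = as.integer(n50),
       min_length = min(len), max_length = max(len))
}

#' Split oversized sequences into contiguous pieces
#'
#' Every output piece is at most `target_len` bases; the pieces of one input
#' are contiguous, non-overlapping and cover it exactly. Piece ids encode the
#' original id and 0-based offset (`id|offset`) so intervals on pieces can be
#' lifted back with [lift_intervals()].
#'
#' @param records List of [seq_record()] objects.
#' @param target_len Maximum piece length (>= 1).
#' @return List with `records` (the pieces) and `mapping` (data frame
#'   `piece_id`, `origin_id`, `offset`, `piece_length`, `origin_length`).
#' @export
split_long_sequences <- function(records, target_len) {
  records <- as_records(records)
  stopifnot(target_len >= 1)
  pieces <- list()
  map <- list()
  for (rec in records) {
    if (rec$length <= target_len) {
      pieces[[length(pieces) + 1L]] <- rec
      map[[length(map) + 1L]] <- data.frame(
        piece_id = rec$id, origin_id = rec$id, offset = 0L,
        piece_length = rec$length, origin_length = rec$length,
        stringsAsFactors = FALSE)
      next
    }
    offs <- seq.int(0L, rec$length - 1L, by = target_len)
    for (off in offs) {
      len <- min(target_len, rec$length - off)
      pid <- sprintf("%s|%d", rec$id, off)
      pieces[[length(pieces) + 1L]] <-
        seq_record(pid, substr(rec$seq, off + 1L, off + len))
      map[[length(map) + 1L]] <- data.frame(
        piece_id = pid, origin_id = rec$id, offset = as.integer(off),
        piece_length = as.integer(len), origin_length = rec$length,
        stringsAsFactors = FALSE)
    }
  }
  list(records = pieces, mapping = do.call(rbind, map))
}

#' Lift piece-local intervals back to original coordinates
#'
#' @param intervals Data frame with columns `piece_id`, `start`, `end`
#'   (0-based half-open, piece-local).
#' @param mapping Mapping data frame from [split_long_sequences()].
#' @return The intervals with `origin_id` and original-coordinate
#'   `start`/`end` columns.
#' @export
lift_intervals <- function(intervals, mapping) {
  i <- match(intervals$piece_id, mapping$piece_id)
  if (anyNA(i))
    stop(sprintf("unknown piece id '%s'", intervals$piece_id[which(is.na(i))[1]]))
  data.frame(origin_id = mapping$origin_id[i],
             start = intervals$start + mapping$offset[i],
             end = intervals$end + mapping$offset[i],
             stringsAsFactors = FALSE)
}
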