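# Novel-sequence candidates: extraction of unaligned regions, parsing of
# BLAST tabular and RepeatMasker evidence, interval subtraction and the
# contamination screen.
#
# A candidate carries two coordinate systems: `start`/`end` on the
# originating contig or scaffold, and `local_start`/`local_end` within the
# originally extracted candidate. Mask files (BLAST/RepeatMasker run on the
# exported candidate FASTA) are in original-candidate-local coordinates and
# reference candidates by id, so subtraction is idempotent.

empty_candidates <- function() {
  data.frame(candidate_id = character(0), query_id = character(0),
             start = integer(0), end = integer(0),
             local_start = integer(0), local_end = integer(0),
             origin_id = character(0), origin_length = integer(0),
             anchor_chrom = character(0), anchor_pos = integer(0),
             anchor_side = character(0), stringsAsFactors = FALSE)
}

candidate_len <- function(candidates) candidates$end - candidates$start

#' Extract unaligned regions as novel-sequence candidates
#'
#' The complement of the final aligned blocks within each query is clipped
#' of pure-N runs and filtered to pieces at least `min_novel_len` long
#' (novel sequences are operationally >= 100 bp). Each candidate records its
#' originating sequence, its nearest flanking aligned block as an anchor
#' (`chrom`, reference position, side; `unplaced` when the query has no
#' aligned block), and the bases dropped by N-clipping and the length filter
#' are tallied for exact bookkeeping.
#'
#' @param alignment Result of [align_queries()].
#' @param queries The list of [seq_record()] queries that were aligned.
#' @param min_novel_len Minimum candidate length (default 100).
#' @return List with `candidates` (data frame, see above) and `dropped`
#'   (data frame `query_id`, `n_bases`, `short_bases`).
#' @export
extract_candidates <- function(alignment, queries, min_novel_len = 100L) {
  queries <- as_records(queries)
  qids <- record_ids(queries)
  cand <- list()
  dropped <- list()
  for (qi in seq_along(queries)) {
    rec <- queries[[qi]]
    b <- alignment$blocks[alignment$blocks$query_id == rec$id, , drop = FALSE]
    runs <- unaligned_runs(b, rec$length)
    n_dropped <- 0L
    short_dropped <- 0L
    for (i in seq_len(nrow(runs))) {
      s <- runs$start[i]; e <- runs$end[i]
      # split the run at N bases; N bases themselves are dropped
      nr <- rec$n_runs
      nr <- nr[nr[, "end"] > s & nr[, "start"] < e, , drop = FALSE]
      nr[, "start"] <- pmax(nr[, "start"], s)
      nr[, "end"] <- pmin(nr[, "end"], e)
      n_dropped <- n_dropped + sum(nr[, "end"] - nr[, "start"])
      run_r <- IRanges::IRanges(s + 1L, e)
      if (nrow(nr) > 0L)
        run_r <- IRanges::setdiff(run_r, IRanges::IRanges(nr[, "start"] + 1L, nr[, "end"]))
      for (j in seq_along(run_r)) {
        ps <- IRanges::start(run_r)[j] - 1L
        pe <- IRanges::end(run_r)[j]
        if (pe - ps < min_novel_len) {
          short_dropped <- short_dropped + (pe - ps)
          next
        }
        anchor <- candidate_anchor(b, ps, pe)
        cand[[length(cand) + 1L]] <- data.frame(
          candidate_id = sprintf("%s:%d-%d", rec$id, ps + 1L, pe),
          query_id = rec$id, start = ps, end = pe,
          local_start = 0L, local_end = pe - ps,
          origin_id = rec$id, origin_length = rec$length,
          anchor_chrom = anchor$chrom, anchor_pos = anchor$pos,
          anchor_side = anchor$side, stringsAsFactors = FALSE)
      }
    }
    dropped[[length(dropped) + 1L]] <- data.frame(
      query_id = rec$id, n_bases = n_dropped, short_bases = short_dropped,
      stringsAsFactors = FALSE)
  }
  list(candidates = if (length(cand)) do.call(rbind, cand) else empty_candidates(),
       dropped = do.call(rbind, dropped))
}

candidate_anchor <- function(blocks, s, e) {
  if (is.null(blocks) || nrow(blocks) == 0L)
    return(list(chrom = NA_character_, pos = NA_integer_, side = "unplaced"))
  left <- blocks[blocks$q_end <= s, , drop = FALSE]
  right <- blocks[blocks$q_start >= e, , drop = FALSE]
  dl <- if (nrow(left)) s - max(left$q_end) else Inf
  dr <- if (nrow(right)) min(right$q_start) - e else Inf
  if (is.infinite(dl) && is.infinite(dr))
    return(list(chrom = NA_character_, pos = NA_integer_, side = "unplaced"))
  if (dl <= dr) {
    i <- which.max(left$q_end)
    list(chrom = left$chrom[i], pos = left$r_end[i], side = "left")
  } else {
    i <- which.min(right$q_start)
    list(chrom = right$chrom[i], pos = right$r_start[i], side = "right")
  }
}

#' Parse BLAST tabular output (outfmt 6)
#'
#' Twelve whitespace/tab-delimited columns: qseqid sseqid pident length
#' mismatch gapopen qstart qend sstart send evalue bitscore. BLAST's 1-based
#' inclusive query coordinates are converted to 0-based half-open;
#' reverse-strand subject hits (sstart > send) are accepted unchanged.
#' Malformed lines are an error naming the line number.
#'
#' @param path Path to the tabular file.
#' @return Data frame `query_id`, `start`, `end` (query-local), `subject_id`,
#'   `identity`, `evalue`.
#' @export
parse_blast_tab <- function(path) {
  if (!file.exists(path)) stop(sprintf("BLAST file '%s' does not exist", path))
  lines <- readLines(path)
  keep <- which(nzchar(trimws(lines)) & !startsWith(trimws(lines), "#"))
  out <- vector("list", length(keep))
  for (i in seq_along(keep)) {
    f <- strsplit(trimws(lines[keep[i]]), "[ \t]+")[[1]]
    if (length(f) != 12L)
      stop(sprintf("line %d of '%s': expected 12 columns, found %d",
                   keep[i], path, length(f)))
    qs <- as.integer(f[7]); qe <- as.integer(f[8])
    if (is.na(qs) || is.na(qe))
      stop(sprintf("line %d of '%s': non-numeric query coordinates", keep[i], path))
    out[[i]] <- data.frame(query_id = f[1],
                           start = min(qs, qe) - 1L, end = max(qs, qe),
                           subject_id = f[2], identity = as.numeric(f[3]),
                           evalue = as.numeric(f[11]), stringsAsFactors = FALSE)
  }
  if (length(out) == 0L)
    return(data.frame(query_id = character(0), start = integer(0),
                      end = integer(0), subject_id = character(0),
                      identity = numeric(0), evalue = numeric(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Parse RepeatMasker .out annotation
#'
#' Standard layout: three header lines then whitespace-delimited rows with
#' the query name in column 5, 1-based inclusive query interval in columns
#' 6-7 and the repeat class/family in column 11 (recorded verbatim).
#' Intervals come back 0-based half-open.
#'
#' @param path Path to the .out file.
#' @return Data frame `query_id`, `start`, `end`, `repeat_class`.
#' @export
parse_repeatmasker_out <- function(path) {
  if (!file.exists(path)) stop(sprintf("RepeatMasker file '%s' does not exist", path))
  lines <- readLines(path)
  body <- lines[-seq_len(min(3L, length(lines)))]
  body <- body[nzchar(trimws(body))]
  out <- vector("list", length(body))
  for (i in seq_along(body)) {
    f <- strsplit(trimws(body[i]), "[ \t]+")[[1]]
    if (length(f) < 11L)
      stop(sprintf("line %d of '%s' body: expected >= 11 columns, found %d",
                   i, path, length(f)))
    out[[i]] <- data.frame(query_id = f[5],
                           start = as.integer(f[6]) - 1L, end = as.integer(f[7]),
                           repeat_class = f[11], stringsAsFactors = FALSE)
  }
  if (length(out) == 0L)
    return(data.frame(query_id = character(0), start = integer(0),
                      end = integer(0), repeat_class = character(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

# Subtract one set of masks (original-candidate-local coordinates) from the
# candidates, then refilter on min_novel_len. Shared engine for the homology,
# repeat and contamination filters.
subtract_masks <- function(candidates, masks, min_novel_len, filter_name) {
  if (nrow(candidates) == 0L || nrow(masks) == 0L)
    return(list(candidates = candidates,
                trail = data.frame(candidate_id = character(0), filter = character(0),
                                   bases_removed = numeric(0), stringsAsFactors = FALSE),
                dropped_bases = 0,
                by_source = data.frame(source = character(0), bases_removed = numeric(0),
                                       stringsAsFactors = FALSE)))
  unknown <- setdiff(unique(masks$query_id), candidates$candidate_id)
  if (length(unknown) > 0L) {
    warning(sprintf("masks reference unknown candidate id(s): %s; skipped",
                    paste(utils::head(unknown, 3), collapse = ", ")), call. = FALSE)
    masks <- masks[!(masks$query_id %in% unknown), , drop = FALSE]
  }
  trail <- list()
  dropped <- 0
  by_source <- list()
  pieces <- list()
  for (cid in unique(candidates$candidate_id)) {
    rows <- candidates[candidates$candidate_id == cid, , drop = FALSE]
    base0 <- rows$start[1] - rows$local_start[1]  # contig coord of local 0
    cur <- IRanges::IRanges(rows$local_start + 1L, rows$local_end)
    m <- masks[masks$query_id == cid, , drop = FALSE]
    removed <- 0
    if (nrow(m) > 0L) {
      mr <- IRanges::reduce(IRanges::IRanges(m$start + 1L, m$end))
      removed <- sum(IRanges::width(IRanges::intersect(cur, mr)))
      if (!is.null(m$source)) {
        ov <- IRanges::intersect(cur, mr)
        # apportion removed bases to sources by per-source overlap
        for (src in unique(m$source)) {
          sr <- IRanges::reduce(IRanges::IRanges(m$start[m$source == src] + 1L,
                                                 m$end[m$source == src]))
          by_source[[length(by_source) + 1L]] <- data.frame(
            source = src,
            bases_removed = sum(IRanges::width(IRanges::intersect(cur, sr))),
            stringsAsFactors = FALSE)
        }
      }
      cur <- IRanges::setdiff(cur, mr)
    }
    if (removed > 0)
      trail[[length(trail) + 1L]] <- data.frame(
        candidate_id = cid, filter = filter_name, bases_removed = removed,
        stringsAsFactors = FALSE)
    for (j in seq_along(cur)) {
      ls <- IRanges::start(cur)[j] - 1L
      le <- IRanges::end(cur)[j]
      if (le - ls < min_novel_len) {
        dropped <- dropped + (le - ls)
        next
      }
      # carry metadata from the overlapping input piece
      src_row <- rows[rows$local_start < le & rows$local_end > ls, , drop = FALSE][1, ]
      p <- src_row
      p$local_start <- ls
      p$local_end <- le
      p$start <- base0 + ls
      p$end <- base0 + le
      pieces[[length(pieces) + 1L]] <- p
    }
  }
  out <- if (length(pieces)) do.call(rbind, pieces) else empty_candidates()
  rownames(out) <- NULL
  list(candidates = out,
       trail = if (length(trail)) do.call(rbind, trail) else
         data.frame(candidate_id = character(0), filter = character(0),
                    bases_removed = numeric(0), stringsAsFactors = FALSE),
       dropped_bases = dropped,
       by_source = if (length(by_source)) do.call(rbind, by_source) else
         data.frame(source = character(0), bases_removed = numeric(0),
                    stringsAsFactors = FALSE))
}

#' Subtract homology/repeat masks and re-apply the length filter
#'
#' BLAST-derived masks are applied only at sequence identity at or above
#' `identity_ceiling` (novel sequences are defined as < 90% identical to the
#' reference, so hits of >= 90% identity are evidence of known sequence);
#' masks without an identity column (RepeatMasker) are always applied. After
#' interval subtraction the `min_novel_len` filter is re-applied and the
#' removal is recorded in the filter trail.
#'
#' @param candidates Candidate data frame from [extract_candidates()].
#' @param masks Data frame with `query_id` (candidate id), `start`, `end` in
#'   original-candidate-local coordinates, optionally `identity`.
#' @param min_novel_len Minimum candidate length after filtering.
#' @param identity_ceiling Identity threshold (percent) for BLAST masks.
#' @param filter_name Label recorded in the filter trail.
#' @return List with `candidates`, `trail` (`candidate_id`, `filter`,
#'   `bases_removed`) and `dropped_bases` (bases lost to refiltering).
#' @export
subtract_and_refilter <- function(candidates, masks, min_novel_len = 100L,
                                  identity_ceiling = 90, filter_name = "mask") {
  if (!is.null(masks$identity))
    masks <- masks[is.na(masks$identity) | masks$identity >= identity_ceiling,
                   , drop = FALSE]
  res <- subtract_masks(candidates, masks, min_novel_len, filter_name)
  res[c("candidates", "trail", "dropped_bases")]
}

#' Screen candidates for contaminant sequence
#'
#' Contaminant hits (parsed BLAST/RepeatMasker masks labelled with a
#' `source` organism) are subtracted like any other mask; removed bases are
#' tallied per contaminant source for the run report. With no masks the
#' candidates pass through unchanged.
#'
#' @param candidates Candidate data frame.
#' @param contaminant_masks Mask data frame with a `source` column.
#' @param min_novel_len Minimum candidate length after filtering.
#' @return List with `candidates`, `removed` (data frame `source`,
#'   `bases_removed`), `trail` and `dropped_bases`.
#' @export
contamination_screen <- function(candidates, contaminant_masks = NULL,
                                 min_novel_len = 100L) {
  if (is.null(contaminant_masks) || nrow(contaminant_masks) == 0L)
    return(list(candidates = candidates,
                removed = data.frame(source = character(0), bases_removed = numeric(0),
                                     stringsAsFactors = FALSE),
                trail = data.frame(candidate_id = character(0), filter = character(0),
                                   bases_removed = numeric(0), stringsAsFactors = FALSE),
                dropped_bases = 0))
  if (is.null(contaminant_masks$source))
    stop("contaminant masks must carry a 'source' column")
  res <- subtract_masks(candidates, contaminant_masks, min_novel_len, "contamination")
  removed <- stats::aggregate(bases_removed ~ source, data = res$by_source, FUN = sum)
  list(candidates = res$candidates, removed = removed, trail = res$trail,
       dropped_bases = res$dropped_bases)
}

#' Export candidates as FASTA/BED/TSV
#'
#' FASTA headers carry the originating sequence, the 1-based inclusive
#' interval on it, and the anchor. The BED is 0-based half-open on the
#' originating sequence.
#'
#' @param candidates Candidate data frame.
#' @param queries The query [seq_record()] list (for sequence extraction).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_candidates_fasta <- function(candidates, queries, path) {
  queries <- as_records(queries)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(candidates))) {
    rec <- find_record(queries, candidates$query_id[i])
    seq <- substr(rec$seq, candidates$start[i] + 1L, candidates$end[i])
    anchor <- if (candidates$anchor_side[i] == "unplaced") "unplaced" else
      sprintf("%s:%d:%s", candidates$anchor_chrom[i],
              candidates$anchor_pos[i] + 1L, candidates$anchor_side[i])
    writeLines(sprintf(">%s %s:%d-%d anchor=%s", candidates$candidate_id[i],
                       candidates$origin_id[i], candidates$start[i] + 1L,
                       candidates$end[i], anchor), con)
    writeLines(gsub("(.{70})", "\\1\n", seq), con)
  }
  invisible(path)
}

#' @rdname write_candidates_fasta
#' @export
write_candidates_bed <- function(candidates, path) {
  bed <- data.frame(candidates$query_id, candidates$start, candidates$end,
                    candidates$candidate_id)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
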