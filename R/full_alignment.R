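# Phase 3: full-density alignment of the four query groups, base-level
# extension, overlap resolution and final per-query alignments.

min_block_of <- function(config) {
  if (!is.null(config$min_block_len)) config$min_block_len else 2L * config$k
}

#' Full-density scan of one query against one chromosome index
#'
#' Same chaining-by-intersection logic as [gapped_scan()] but with all
#' indexed k-mers (no seed subsetting, gap 0): consecutive seeds within a
#' chain are `k` apart and the index must be unfiltered. Raw chains of any
#' length are returned; callers extend them with [extend_blocks()] and then
#' apply the phase-3 minimum block length.
#'
#' @param query A [seq_record()].
#' @param index An unfiltered `kmer_index` of the target chromosome.
#' @param orient `"+"` or `"-"`.
#' @param config Configuration carrying `k`.
#' @return Data frame of regions as in [gapped_scan()], query coordinates in
#'   the original query frame, with attribute `lookups`.
#' @export
full_scan <- function(query, index, orient = "+", config) {
  stopifnot(orient %in% c("+", "-"))
  if (index$delta != 1L) stop("full_scan requires an unfiltered index")
  seq <- if (orient == "-") revcomp(query$seq) else query$seq
  res <- cpp_scan(index$ptr, seq, period = config$k, min_span = config$k)
  r <- res$regions
  out <- region_frame(index$chrom_id, orient, r$q_start, r$q_end, r$r_start, r$n_seeds)
  if (orient == "-") out <- flip_query_coords(out, query$length)
  attr(out, "lookups") <- res$lookups
  out
}

#' Extend alignment blocks by direct base comparison
#'
#' Each block is grown base-by-base to the left and right while query and
#' reference bases are equal (N never matches), stopping at the first
#' mismatch or a sequence end. Both coordinates move together (blocks are
#' gap-free).
#'
#' @param blocks Data frame with `q_start`, `q_end`, `r_start`, `r_end`
#'   (coordinates in the frame of `query`).
#' @param query Query sequence string (reverse-complemented already if the
#'   blocks came from a reverse-orientation scan).
#' @param chrom Reference chromosome sequence string.
#' @return The blocks with updated coordinates.
#' @export
extend_blocks <- function(blocks, query, chrom) {
  if (nrow(blocks) == 0L) return(blocks)
  ext <- cpp_extend_blocks(query, chrom, blocks$q_start, blocks$q_end, blocks$r_start)
  blocks$q_start <- ext$q_start
  blocks$q_end <- ext$q_end
  blocks$r_start <- ext$r_start
  blocks$r_end <- ext$r_end
  blocks$span <- ext$q_end - ext$q_start
  blocks
}

#' Resolve query-interval overlaps between blocks
#'
#' Blocks are processed by decreasing length, equal lengths in a seeded
#' random order; each block keeps only the parts of its query interval not
#' covered by already-kept blocks, and pieces trimmed below `min_len` are
#' dropped. Reference coordinates follow the trimming (gap-free blocks).
#'
#' @param blocks Data frame of blocks on one query.
#' @param rng_seed Integer seed for the random tie-break.
#' @param min_len Minimum surviving piece length.
#' @return Non-overlapping blocks sorted by `q_start`.
#' @export
resolve_overlaps <- function(blocks, rng_seed = 1L, min_len = 1L) {
  if (nrow(blocks) == 0L) return(blocks)
  len <- blocks$q_end - blocks$q_start
  shuffle <- with_local_seed(rng_seed, sample.int(nrow(blocks)))
  ord <- order(-len, shuffle)
  kept <- IRanges::IRanges()
  out <- list()
  for (i in ord) {
    b <- blocks[i, , drop = FALSE]
    r <- IRanges::IRanges(start = b$q_start + 1L, end = b$q_end)
    free <- IRanges::setdiff(r, kept)
    free <- free[IRanges::width(free) >= min_len]
    if (length(free) == 0L) next
    kept <- IRanges::reduce(c(kept, free))
    for (j in seq_along(free)) {
      piece <- b
      d <- IRanges::start(free)[j] - 1L - b$q_start
      piece$q_start <- IRanges::start(free)[j] - 1L
      piece$q_end <- IRanges::end(free)[j]
      piece$r_start <- b$r_start + d
      piece$r_end <- piece$r_start + (piece$q_end - piece$q_start)
      piece$span <- piece$q_end - piece$q_start
      out[[length(out) + 1L]] <- piece
    }
  }
  out <- do.call(rbind, out)
  out[order(out$q_start), , drop = FALSE]
}

# Run the RNG-dependent expression under a local seed, restoring global state.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Derive a per-query sub-seed below 2^31 from the run seed; deterministic and
# independent of processing order.
sub_seed <- function(rng_seed, key) {
  h <- sum(utf8ToInt(key) * seq_along(utf8ToInt(key)))
  as.integer((as.double(rng_seed) * 7919 + h) %% .Machine$integer.max)
}

# Align one query to one (chrom, orient) target: full scan, extension,
# minimum-length filter, overlap resolution. Returns blocks in the original
# query frame plus the aligned-base total.
align_one_target <- function(query, chrom_rec, index, orient, config) {
  seq <- if (orient == "-") revcomp(query$seq) else query$seq
  res <- cpp_scan(index$ptr, seq, period = config$k, min_span = config$k)
  r <- res$regions
  blocks <- region_frame(chrom_rec$id, orient, r$q_start, r$q_end, r$r_start, r$n_seeds)
  blocks <- extend_blocks(blocks, seq, chrom_rec$seq)
  blocks <- blocks[blocks$span >= min_block_of(config), , drop = FALSE]
  if (nrow(blocks) > 0L)
    blocks <- resolve_overlaps(blocks, sub_seed(config$rng_seed %||% 1L, query$id),
                               min_block_of(config))
  if (orient == "-" && nrow(blocks) > 0L)
    blocks <- flip_query_coords(blocks, query$length)
  blocks <- blocks[order(blocks$q_start), , drop = FALSE]
  list(chrom = chrom_rec$id, orient = orient, blocks = blocks,
       aligned_bases = if (nrow(blocks)) sum(blocks$span) else 0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Choose the best alignment among per-target results
#'
#' The alignment with the most aligned bases wins; ties are broken
#' deterministically by reference chromosome order, forward before reverse.
#'
#' @param results List of per-target results (each with `chrom`, `orient`,
#'   `aligned_bases`, `blocks`).
#' @param chrom_order Character vector giving the reference chromosome order.
#' @return The winning result (or NULL for an empty list).
#' @export
best_alignment <- function(results, chrom_order) {
  if (length(results) == 0L) return(NULL)
  score <- vapply(results, `[[`, numeric(1), "aligned_bases")
  ci <- match(vapply(results, `[[`, character(1), "chrom"), chrom_order)
  oi <- match(vapply(results, `[[`, character(1), "orient"), c("+", "-"))
  ord <- order(-score, ci, oi)
  results[[ord[1]]]
}

# Align a set of queries each against its own list of targets, loading one
# full-density chromosome index at a time. targets: data frame query_id,
# chrom, orient. Returns a named list of best results per query.
align_to_targets <- function(queries, targets, reference, config) {
  queries <- as_records(queries)
  qids <- record_ids(queries)
  chrom_order <- record_ids(reference)
  partial <- stats::setNames(vector("list", length(queries)), qids)
  for (chrom_rec in reference) {
    rows <- targets[targets$chrom == chrom_rec$id, , drop = FALSE]
    if (nrow(rows) == 0L) next
    idx <- build_index(chrom_rec, config$k)
    for (i in seq_len(nrow(rows))) {
      qid <- rows$query_id[i]
      qi <- match(qid, qids)
      if (is.na(qi)) next
      res <- align_one_target(queries[[qi]], chrom_rec, idx, rows$orient[i], config)
      partial[[qid]] <- c(partial[[qid]], list(res))
    }
  }
  lapply(partial, best_alignment, chrom_order = chrom_order)
}

unaligned_runs <- function(blocks, query_len) {
  cov <- IRanges::IRanges()
  if (!is.null(blocks) && nrow(blocks) > 0L)
    cov <- IRanges::reduce(IRanges::IRanges(blocks$q_start + 1L, blocks$q_end))
  gaps <- IRanges::setdiff(IRanges::IRanges(1L, query_len), cov)
  data.frame(start = IRanges::start(gaps) - 1L, end = IRanges::end(gaps))
}

#' Classify queries after alignment
#'
#' Queries aligned to their assigned chromosomes for at most half their
#' length are `misassigned`; queries with no assignment are `unassigned`;
#' all others are `assigned`. Within the final alignments, maximal unaligned
#' runs longer than `fp_cutoff` (default 2500 bp) are false-positive
#' novel-sequence candidates — typically chimeric joins — to be excised and
#' re-aligned against all targets.
#'
#' @param per_query Data frame with `query_id`, `length`, `aligned_bases`.
#' @param assigned_ids Query ids that received a phase-2 assignment.
#' @param fp_cutoff Minimum length of a false-positive candidate run.
#' @param blocks Data frame of final blocks (for run extraction).
#' @return List with `labels` (data frame `query_id`, `group`) and `fp`
#'   (data frame `query_id`, `start`, `end` of runs longer than the cutoff).
#' @export
classify_queries <- function(per_query, assigned_ids, fp_cutoff = 2500,
                             blocks = NULL) {
  group <- ifelse(!(per_query$query_id %in% assigned_ids), "unassigned",
                  ifelse(per_query$aligned_bases / per_query$length > 0.5,
                         "assigned", "misassigned"))
  fp <- list()
  if (!is.null(blocks)) {
    for (i in seq_len(nrow(per_query))) {
      qid <- per_query$query_id[i]
      b <- blocks[blocks$query_id == qid, , drop = FALSE]
      runs <- unaligned_runs(b, per_query$length[i])
      runs <- runs[runs$end - runs$start > fp_cutoff, , drop = FALSE]
      if (nrow(runs) > 0L)
        fp[[length(fp) + 1L]] <- cbind(query_id = qid, runs,
                                       stringsAsFactors = FALSE)
    }
  }
  fp <- if (length(fp) > 0L) do.call(rbind, fp) else
    data.frame(query_id = character(0), start = integer(0), end = integer(0),
               stringsAsFactors = FALSE)
  list(labels = data.frame(query_id = per_query$query_id, group = group,
                           stringsAsFactors = FALSE),
       fp = fp)
}

result_blocks <- function(results) {
  out <- list()
  for (qid in names(results)) {
    res <- results[[qid]]
    if (is.null(res) || nrow(res$blocks) == 0L) next
    b <- res$blocks
    b$query_id <- qid
    out[[length(out) + 1L]] <- b
  }
  if (length(out) == 0L)
    return(data.frame(chrom = character(0), orient = character(0),
                      q_start = integer(0), q_end = integer(0),
                      r_start = integer(0), r_end = integer(0),
                      n_seeds = integer(0), span = integer(0),
                      query_id = character(0), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

all_targets_for <- function(qids, chrom_ids) {
  expand.grid(query_id = qids, chrom = chrom_ids, orient = c("+", "-"),
              stringsAsFactors = FALSE)
}

#' Phase 3: align the four query groups and produce final alignments
#'
#' Assigned queries are aligned at full seed density to each of their
#' assigned targets and reduced to the best alignment. Queries aligned for
#' at most half their length are re-aligned (with the unassigned queries)
#' against all chromosome-orientation targets. Finally, unaligned runs
#' longer than `fp_cutoff` are excised as false-positive candidates,
#' re-aligned against all targets, and any recovered blocks are merged back
#' into the owning query's alignment.
#'
#' @param queries List of [seq_record()] queries.
#' @param reference List of [seq_record()] chromosomes.
#' @param assignments Assignment data frame from [assign_queries()].
#' @param config A [pipeline_config()].
#' @return List with `blocks` (all final blocks; column `source` is
#'   `"primary"` or `"fp_realign"`), `per_query` (`query_id`, `length`,
#'   `group`, `aligned_bases`, `coverage`), and `fp` (the excised runs with
#'   the bases each recovered on re-alignment).
#' @export
align_queries <- function(queries, reference, assignments, config) {
  queries <- as_records(queries)
  reference <- as_records(reference)
  qids <- record_ids(queries)
  qlen <- stats::setNames(vapply(queries, `[[`, integer(1), "length"), qids)
  chrom_ids <- record_ids(reference)
  assigned_ids <- unique(assignments$query_id)

  # round 1: assigned queries to their assigned targets
  t1 <- assignments[assignments$query_id %in% qids,
                    c("query_id", "chrom", "orient"), drop = FALSE]
  res <- align_to_targets(queries[match(unique(t1$query_id), qids)], t1,
                          reference, config)
  aligned_bases <- stats::setNames(numeric(length(qids)), qids)
  for (qid in names(res))
    aligned_bases[qid] <- if (!is.null(res[[qid]])) res[[qid]]$aligned_bases else 0

  per_query <- data.frame(query_id = qids, length = unname(qlen[qids]),
                          aligned_bases = unname(aligned_bases[qids]),
                          stringsAsFactors = FALSE)
  cls <- classify_queries(per_query, assigned_ids, config$fp_cutoff %||% 2500)
  group <- stats::setNames(cls$labels$group, cls$labels$query_id)

  # round 2: unassigned and misassigned queries against all targets
  redo <- qids[group[qids] %in% c("unassigned", "misassigned")]
  if (length(redo) > 0L) {
    t2 <- all_targets_for(redo, chrom_ids)
    res2 <- align_to_targets(queries[match(redo, qids)], t2, reference, config)
    for (qid in redo) {
      res[[qid]] <- res2[[qid]]
      aligned_bases[qid] <- if (!is.null(res2[[qid]])) res2[[qid]]$aligned_bases else 0
    }
  }

  blocks <- result_blocks(res)
  blocks$source <- rep("primary", nrow(blocks))

  # round 3: excise large unaligned runs (chimera suspects) and re-align them
  per_query$aligned_bases <- unname(aligned_bases[qids])
  cls3 <- classify_queries(per_query, assigned_ids, config$fp_cutoff %||% 2500,
                           blocks = blocks)
  fp <- cls3$fp
  fp$recovered_bases <- rep(0, length.out = nrow(fp))
  if (nrow(fp) > 0L) {
    subq <- list()
    for (i in seq_len(nrow(fp))) {
      qid <- fp$query_id[i]
      rec <- queries[[match(qid, qids)]]
      sid <- sprintf("%s|fp|%d", qid, fp$start[i])
      subq[[length(subq) + 1L]] <-
        seq_record(sid, substr(rec$seq, fp$start[i] + 1L, fp$end[i]))
    }
    # all-N excised runs cannot be scanned; drop them from re-alignment
    ok <- !vapply(subq, function(r) all(r$n_runs[, "end"] - r$n_runs[, "start"] == r$length) &&
                    nrow(r$n_runs) == 1L, logical(1))
    subq <- subq[ok]
    if (length(subq) > 0L) {
      t3 <- all_targets_for(record_ids(subq), chrom_ids)
      res3 <- align_to_targets(subq, t3, reference, config)
      for (sid in names(res3)) {
        r3 <- res3[[sid]]
        if (is.null(r3) || nrow(r3$blocks) == 0L) next
        parts <- strsplit(sid, "|", fixed = TRUE)[[1]]
        qid <- parts[1]
        off <- as.integer(parts[3])
        b <- r3$blocks
        b$q_start <- b$q_start + off
        b$q_end <- b$q_end + off
        b$query_id <- qid
        b$source <- "fp_realign"
        blocks <- rbind(blocks, b)
        fi <- which(fp$query_id == qid & fp$start == off)
        fp$recovered_bases[fi] <- r3$aligned_bases
        aligned_bases[qid] <- aligned_bases[qid] + r3$aligned_bases
        group[qid] <- if (group[qid] == "assigned") "assigned" else group[qid]
      }
    }
  }

  per_query$aligned_bases <- unname(aligned_bases[qids])
  per_query$group <- unname(group[qids])
  per_query$group[per_query$query_id %in% fp$query_id &
                    per_query$group == "assigned"] <- "assigned"
  per_query$coverage <- per_query$aligned_bases / per_query$length
  blocks <- blocks[order(blocks$query_id, blocks$q_start), , drop = FALSE]
  rownames(blocks) <- NULL
  list(blocks = blocks, per_query = per_query, fp = fp)
}
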