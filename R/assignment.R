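# Phase 2: chromosome/orientation assignment with gapped seeds, maximal
# unique match chaining, anchor-distance pruning and a Gaussian outlier test.

region_frame <- function(chrom, orient, q_start, q_end, r_start, n_seeds) {
  data.frame(chrom = rep(chrom, length(q_start)),
             orient = rep(orient, length(q_start)),
             q_start = q_start, q_end = q_end,
             r_start = r_start, r_end = r_start + (q_end - q_start),
             n_seeds = n_seeds, span = q_end - q_start,
             stringsAsFactors = FALSE)
}

# Map query coordinates scanned on the reverse complement back to the
# original query frame.
flip_query_coords <- function(regions, query_len) {
  qs <- query_len - regions$q_end
  qe <- query_len - regions$q_start
  regions$q_start <- qs
  regions$q_end <- qe
  regions
}

#' Gapped-seed scan of one query against one chromosome index
#'
#' Scans the query (reverse-complemented first for `orient = "-"`) left to
#' right. A chain starts at the first base whose seed has indexed positions
#' and grows by intersecting the surviving reference-location set with the
#' next seed's positions shifted by `k + gap`, skipping `k + gap` bases on
#' both query and reference per match. A maximal unique aligned region is
#' emitted when the surviving set is unique and the chain span reaches
#' `min_mum_len`; scanning restarts at the base after the chain, so each
#' query base is examined at most once per orientation.
#'
#' @param query A [seq_record()].
#' @param index A `kmer_index` filtered with [filter_index()] for `config`.
#' @param orient `"+"` or `"-"`.
#' @param config A [seed_config()].
#' @return Data frame of aligned regions (`chrom`, `orient`, `q_start`,
#'   `q_end`, `r_start`, `r_end`, `n_seeds`, `span`; query coordinates in
#'   the original query frame) with attribute `lookups`, the number of seed
#'   lookups performed.
#' @export
gapped_scan <- function(query, index, orient = "+", config) {
  stopifnot(orient %in% c("+", "-"))
  seq <- if (orient == "-") revcomp(query$seq) else query$seq
  res <- cpp_scan(index$ptr, seq, period = config$k + config$gap,
                  min_span = config$min_mum_len)
  r <- res$regions
  out <- region_frame(index$chrom_id, orient, r$q_start, r$q_end, r$r_start, r$n_seeds)
  if (orient == "-") out <- flip_query_coords(out, query$length)
  attr(out, "lookups") <- res$lookups
  out
}

#' Prune spurious aligned regions around the longest anchor
#'
#' Within one chromosome and orientation the longest region is the anchor of
#' the true alignment (ties: smallest `r_start`); a region is retained iff
#' the absolute difference between its reference start and the anchor's is
#' at most `D`. The anchor itself is always retained.
#'
#' @param regions Regions from [gapped_scan()], one chromosome+orientation.
#' @param D Distance threshold in bases (default 1e6).
#' @return The retained regions, in input order.
#' @export
prune_spurious <- function(regions, D = 1e6) {
  if (nrow(regions) == 0L) return(regions)
  if (length(unique(paste(regions$chrom, regions$orient))) > 1L)
    stop("prune_spurious expects regions from a single chromosome and orientation")
  anchor <- which(regions$span == max(regions$span))
  anchor <- anchor[which.min(regions$r_start[anchor])]
  keep <- abs(regions$r_start - regions$r_start[anchor]) <= D
  regions[keep, , drop = FALSE]
}

#' Alignment score of a set of regions
#'
#' The score is the total number of aligned bases, i.e. the sum of region
#' spans.
#'
#' @param regions Data frame of (pruned) regions.
#' @return Integer score.
#' @export
score_regions <- function(regions) {
  if (nrow(regions) == 0L) return(0L)
  as.integer(sum(regions$span))
}

#' Assign targets from a vector of per-slot alignment scores
#'
#' The per-query scores (one per chromosome-orientation slot; 48 for a
#' 24-chromosome reference) are modelled as Gaussian chance matches: with
#' `mu` and `sigma` the mean and population standard deviation over all
#' slots, a slot is assigned iff `sigma > 0` and
#' `(score - mu) / sigma >= z_crit`. The default `z_crit = 2.326` is the
#' one-sided standard-normal quantile for p = 0.01. With `leave_one_out =
#' TRUE`, `mu` and `sigma` for each slot are computed from the other slots.
#'
#' @param scores Named numeric vector of slot scores (names `"chrom|+"` /
#'   `"chrom|-"`).
#' @param z_crit Critical z value.
#' @param leave_one_out Exclude the candidate slot from its own mu/sigma.
#' @return List with `mu`, `sigma`, `z` (per-slot z scores) and `assigned`
#'   (character vector of assigned slot names; empty when `sigma == 0`).
#' @export
assign_targets <- function(scores, z_crit = 2.326, leave_one_out = FALSE) {
  n <- length(scores)
  if (n < 2L) stop("need at least two score slots")
  if (leave_one_out) {
    mu <- (sum(scores) - scores) / (n - 1)
    sigma <- sqrt(pmax(0, (sum(scores^2) - scores^2) / (n - 1) - mu^2))
  } else {
    mu <- mean(scores)
    sigma <- sqrt(mean((scores - mu)^2))
  }
  mu_s <- rep(mu, length.out = n)
  sig_s <- rep(sigma, length.out = n)
  z <- ifelse(sig_s > 0, (scores - mu_s) / sig_s, NA_real_)
  names(z) <- names(scores)
  assigned <- names(scores)[!is.na(z) & z >= z_crit]
  list(mu = mu, sigma = sigma, z = z, assigned = assigned)
}

slot_names <- function(chrom_ids) {
  as.vector(t(outer(chrom_ids, c("+", "-"), paste, sep = "|")))
}

split_slot <- function(slots) {
  parts <- strsplit(slots, "|", fixed = TRUE)
  data.frame(chrom = vapply(parts, `[`, character(1), 1),
             orient = vapply(parts, `[`, character(1), 2),
             stringsAsFactors = FALSE)
}

#' Score all queries against all chromosome-orientation slots
#'
#' Builds (or filters) one gapped-seed index per chromosome at a time,
#' scans every query in both orientations, prunes each slot's regions around
#' its anchor and records the per-slot alignment score. Queries shorter than
#' `min_mum_len` are skipped (scored 0 everywhere).
#'
#' @param queries List of [seq_record()] queries.
#' @param reference List of [seq_record()] chromosomes.
#' @param config A [seed_config()].
#' @return Numeric matrix of scores, queries in rows, slots in columns.
#' @export
score_queries <- function(queries, reference, config) {
  queries <- as_records(queries)
  reference <- as_records(reference)
  chroms <- record_ids(reference)
  scores <- matrix(0, nrow = length(queries), ncol = 2L * length(chroms),
                   dimnames = list(record_ids(queries), slot_names(chroms)))
  scan_q <- which(vapply(queries, `[[`, integer(1), "length") >= config$min_mum_len)
  for (chrom in reference) {
    idx <- filter_index(build_index(chrom, config$k), config)
    for (qi in scan_q) {
      for (orient in c("+", "-")) {
        regions <- gapped_scan(queries[[qi]], idx, orient, config)
        regions <- prune_spurious(regions, config$prune_dist)
        scores[qi, paste(chrom$id, orient, sep = "|")] <- score_regions(regions)
      }
    }
  }
  scores
}

#' Phase 2: assign each query a candidate chromosome and orientation
#'
#' @inheritParams score_queries
#' @param z_crit Critical z value for [assign_targets()].
#' @param leave_one_out Passed to [assign_targets()].
#' @return List with `scores` (the score matrix) and `assignments`, a data
#'   frame (`query_id`, `chrom`, `orient`, `score`, `z`) with one row per
#'   assigned slot; queries absent from it are unassigned.
#' @export
assign_queries <- function(queries, reference, config, z_crit = 2.326,
                           leave_one_out = FALSE) {
  queries <- as_records(queries)
  scores <- score_queries(queries, reference, config)
  rows <- list()
  for (qi in seq_len(nrow(scores))) {
    a <- assign_targets(scores[qi, ], z_crit, leave_one_out)
    if (length(a$assigned) == 0L) next
    sl <- split_slot(a$assigned)
    rows[[length(rows) + 1L]] <- data.frame(
      query_id = rownames(scores)[qi], chrom = sl$chrom, orient = sl$orient,
      score = unname(scores[qi, a$assigned]), z = unname(a$z[a$assigned]),
      stringsAsFactors = FALSE)
  }
  assignments <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(query_id = character(0), chrom = character(0),
               orient = character(0), score = numeric(0), z = numeric(0),
               stringsAsFactors = FALSE)
  list(scores = scores, assignments = assignments)
}
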