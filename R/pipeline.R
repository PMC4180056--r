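# End-to-end pipeline: index -> assign -> align -> extract (-> filter),
# with a structured run log and exact base bookkeeping.

#' Pipeline configuration
#'
#' Extends [seed_config()] with the phase-3 and post-filter parameters. The
#' defaults mirror the recommended human-scale settings: k = 12, gap = 84,
#' 6 seed sets (delta 16), minimum MUM length 200, anchor-pruning distance
#' 1e6, false-positive cutoff 2.5 kb, minimum novel length 100 bp, identity
#' ceiling 90%, z threshold 2.326 (one-sided p = 0.01).
#'
#' @inheritParams seed_config
#' @param min_block_len Phase-3 minimum block length after extension
#'   (default `2 * k`; far below `min_mum_len` for sensitivity, above `k`
#'   to avoid noise).
#' @param fp_cutoff Minimum length of an unaligned run treated as a
#'   false-positive (chimera) candidate and re-aligned genome-wide.
#' @param min_novel_len Minimum reported novel-candidate length.
#' @param identity_ceiling BLAST identity threshold (percent) above which a
#'   hit masks candidate bases.
#' @param z_crit Critical z value for the assignment outlier test.
#' @param rng_seed Seed for all random tie-breaks; recorded in the run log.
#' @param split_target_len Optional: split assembly sequences longer than
#'   this before alignment (candidate coordinates are lifted back).
#' @return An object of classes `pipeline_config` and `seed_config`.
#' @export
pipeline_config <- function(k = 12L, gap = 84L, sets = 6L, min_mum_len = 200L,
                            prune_dist = 1e6, min_block_len = 2L * k,
                            fp_cutoff = 2500L, min_novel_len = 100L,
                            identity_ceiling = 90, z_crit = 2.326,
                            rng_seed = 1L, split_target_len = NULL) {
  base <- seed_config(k, gap, sets, min_mum_len, prune_dist)
  cfg <- c(unclass(base),
           list(min_block_len = as.integer(min_block_len),
                fp_cutoff = as.integer(fp_cutoff),
                min_novel_len = as.integer(min_novel_len),
                identity_ceiling = identity_ceiling, z_crit = z_crit,
                rng_seed = as.integer(rng_seed),
                split_target_len = split_target_len))
  structure(cfg, class = c("pipeline_config", "seed_config"))
}

load_if_path <- function(x) if (is.character(x) && length(x) == 1L) read_fasta(x) else as_records(x)

#' Run the full pipeline
#'
#' Index construction, chromosome assignment, query alignment and
#' novel-candidate extraction, with optional post-filtering from parsed
#' BLAST/RepeatMasker/contaminant masks. One chromosome index is held in
#' memory at a time. Base bookkeeping is exact: for every query, aligned
#' bases + candidate bases + filtered (N/short/subtracted) bases equal the
#' query length, and the run aborts if not.
#'
#' @param reference Reference FASTA path or list of [seq_record()].
#' @param assembly Assembly FASTA path or list of [seq_record()].
#' @param config A [pipeline_config()].
#' @param blast_masks,rm_masks,contaminant_masks Optional parsed mask data
#'   frames (see [parse_blast_tab()], [parse_repeatmasker_out()]); applied
#'   to candidates in that order.
#' @param out_dir Optional directory for TSV/BED/FASTA/JSON artifacts.
#' @return List with `assignments`, `scores`, `alignment`, `candidates`,
#'   `filter_trail`, `contamination`, `tallies` and `log`.
#' @export
run_pipeline <- function(reference, assembly, config = pipeline_config(),
                         blast_masks = NULL, rm_masks = NULL,
                         contaminant_masks = NULL, out_dir = NULL) {
  reference <- load_if_path(reference)
  assembly <- load_if_path(assembly)
  split_map <- NULL
  if (!is.null(config$split_target_len)) {
    sp <- split_long_sequences(assembly, config$split_target_len)
    assembly <- sp$records
    split_map <- sp$mapping
  }

  ph2 <- assign_queries(assembly, reference, config, z_crit = config$z_crit)
  aln <- align_queries(assembly, reference, ph2$assignments, config)
  ext <- extract_candidates(aln, assembly, config$min_novel_len)

  total_bases <- sum(vapply(assembly, `[[`, integer(1), "length"))
  aligned_bases <- sum(aln$blocks$span)
  cand0_bases <- sum(candidate_len(ext$candidates))
  dropped_bases <- sum(ext$dropped$n_bases) + sum(ext$dropped$short_bases)
  if (aligned_bases + cand0_bases + dropped_bases != total_bases)
    stop(sprintf("bookkeeping violation: %d aligned + %d candidate + %d filtered != %d total",
                 aligned_bases, cand0_bases, dropped_bases, total_bases))

  candidates <- ext$candidates
  trail <- list()
  removed_report <- NULL
  if (!is.null(blast_masks)) {
    f <- subtract_and_refilter(candidates, blast_masks, config$min_novel_len,
                               config$identity_ceiling, "blast")
    candidates <- f$candidates
    trail[[length(trail) + 1L]] <- f$trail
    dropped_bases <- dropped_bases + f$dropped_bases
  }
  if (!is.null(rm_masks)) {
    f <- subtract_and_refilter(candidates, rm_masks, config$min_novel_len,
                               config$identity_ceiling, "repeatmasker")
    candidates <- f$candidates
    trail[[length(trail) + 1L]] <- f$trail
    dropped_bases <- dropped_bases + f$dropped_bases
  }
  if (!is.null(contaminant_masks)) {
    f <- contamination_screen(candidates, contaminant_masks, config$min_novel_len)
    candidates <- f$candidates
    trail[[length(trail) + 1L]] <- f$trail
    removed_report <- f$removed
    dropped_bases <- dropped_bases + f$dropped_bases
  }
  trail <- if (length(trail)) do.call(rbind, trail) else
    data.frame(candidate_id = character(0), filter = character(0),
               bases_removed = numeric(0), stringsAsFactors = FALSE)

  # lift candidate coordinates back to the original scaffolds
  if (!is.null(split_map) && nrow(candidates) > 0L) {
    lifted <- lift_intervals(data.frame(piece_id = candidates$query_id,
                                        start = candidates$start,
                                        end = candidates$end), split_map)
    candidates$origin_id <- lifted$origin_id
    candidates$start <- lifted$start
    candidates$end <- lifted$end
    candidates$origin_length <-
      split_map$origin_length[match(candidates$query_id, split_map$piece_id)]
  }

  group_bases <- function(g) {
    i <- aln$per_query$group == g
    c(n = sum(i), bases = sum(aln$per_query$length[i]))
  }
  tallies <- list(
    total_bases = total_bases,
    assigned = group_bases("assigned"),
    unassigned = group_bases("unassigned"),
    misassigned = group_bases("misassigned"),
    fp_candidate = c(n = nrow(aln$fp),
                     bases = sum(aln$fp$end - aln$fp$start)),
    aligned_bases = aligned_bases,
    candidate_bases_initial = cand0_bases,
    candidate_bases_final = sum(candidate_len(candidates)),
    filtered_bases = dropped_bases + sum(trail$bases_removed))
  stopifnot(tallies$aligned_bases + tallies$candidate_bases_final +
              tallies$filtered_bases == tallies$total_bases)

  log <- list(parameters = unclass(config)[setdiff(names(config), "split_target_len")],
              rng_seed = config$rng_seed, tallies = tallies,
              contamination = removed_report)

  res <- list(assignments = ph2$assignments, scores = ph2$scores,
              alignment = aln, candidates = candidates, filter_trail = trail,
              contamination = removed_report, tallies = tallies, log = log,
              queries = assembly)
  if (!is.null(out_dir)) write_pipeline_outputs(res, out_dir)
  res
}

write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(res$assignments, file.path(out_dir, "assignments.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(res$alignment$blocks, file.path(out_dir, "blocks.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_candidates_bed(res$candidates, file.path(out_dir, "candidates.bed"))
  write_candidates_fasta(res$candidates, res$queries,
                         file.path(out_dir, "candidates.fasta"))
  jsonlite::write_json(res$log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA, null = "null", force = TRUE)
  invisible(out_dir)
}
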