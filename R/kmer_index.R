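# Phase 1: per-chromosome k-mer hash indexes and the gapped-seed subset scheme.

#' Seed configuration for the gapped-seed assignment phase
#'
#' Seeds within one set are `k + gap` bases apart; `sets` offset sets are
#' loaded, so consecutive sets start `delta = (k + gap) / sets` bases apart
#' and the retained reference positions are exactly the multiples of `delta`.
#' `delta` between 10 and 20 gives the best time/sensitivity trade-off, and a
#' `k` that is a multiple of 3 (the codon size) is preferred. At least three
#' seeds should fit inside a minimum-length match, i.e.
#' `3k + 2*gap <= min_mum_len`; this is advisory and only warned about
#' (the recommended human-scale defaults themselves violate it slightly).
#'
#' @param k Seed length (2-16; 8-16 recommended).
#' @param gap Bases skipped between consecutive seeds within a set.
#' @param sets Number of offset seed sets; must divide `k + gap`.
#' @param min_mum_len Minimum chain span (bases) for a maximal unique match
#'   to be retained in the assignment phase. Should exceed 25 since most of a
#'   mammalian genome is unique at 25 bp.
#' @param prune_dist Anchor-distance pruning threshold `D` in bases.
#' @return An object of class `seed_config`.
#' @export
seed_config <- function(k = 12L, gap = 84L, sets = 6L, min_mum_len = 200L,
                        prune_dist = 1e6) {
  k <- as.integer(k); gap <- as.integer(gap); sets <- as.integer(sets)
  if (k < 2L || k > 16L) stop("k must be between 2 and 16")
  if (gap < 0L) stop("gap must be non-negative")
  if (sets < 1L) stop("sets must be at least 1")
  if ((k + gap) %% sets != 0L)
    stop(sprintf("(k + gap) = %d is not divisible by sets = %d", k + gap, sets))
  if (min_mum_len < k) stop("min_mum_len must be at least k")
  if (3L * k + 2L * gap > min_mum_len)
    warning(sprintf(paste0("three seeds span %d bp which exceeds min_mum_len = %d; ",
                           "assignments may rest on two-seed chains"),
                    3L * k + 2L * gap, min_mum_len), call. = FALSE)
  structure(list(k = k, gap = gap, sets = sets, delta = (k + gap) %/% sets,
                 min_mum_len = as.integer(min_mum_len),
                 prune_dist = as.numeric(prune_dist)),
            class = "seed_config")
}

#' @export
print.seed_config <- function(x, ...) {
  cat(sprintf("<seed_config> k=%d gap=%d sets=%d delta=%d min_mum_len=%d prune_dist=%g\n",
              x$k, x$gap, x$sets, x$delta, x$min_mum_len, x$prune_dist))
  invisible(x)
}

#' Encode k-mers as base-4 integers
#'
#' `A=0, C=1, G=2, T=3`; the code of a k-mer is the positional base-4 value,
#' a bijection over N-free k-mers. K-mers containing `N` get `NA` (the
#' sentinel); other characters are an error.
#'
#' @param kmer Character vector of k-mers (k <= 16).
#' @return Numeric vector of codes in `[0, 4^k)`, `NA` for N-containing k-mers.
#' @export
encode_kmer <- function(kmer) {
  if (any(nchar(kmer) > 16L)) stop("k-mers longer than 16 bases are not supported")
  cpp_encode_kmers(kmer)
}

#' Build the k-mer index of one chromosome
#'
#' Maps every N-free k-mer window of the chromosome to its ascending list of
#' 0-based start positions, built with a rolling hash in one left-to-right
#' pass.
#'
#' @param chrom A [seq_record()] (or plain string) for one chromosome.
#' @param k Seed length.
#' @return An object of class `kmer_index`.
#' @export
build_index <- function(chrom, k = 12L) {
  if (is.character(chrom)) chrom <- seq_record("chrom", chrom)
  k <- as.integer(k)
  if (k < 2L || k > 16L) stop("k must be between 2 and 16")
  if (chrom$length < k)
    warning(sprintf("chromosome '%s' (%d bp) is shorter than k = %d; index is empty",
                    chrom$id, chrom$length, k), call. = FALSE)
  new_kmer_index(cpp_build_index(chrom$seq, k, chrom$id))
}

new_kmer_index <- function(ptr) {
  s <- cpp_index_summary(ptr)
  structure(list(ptr = ptr, k = s$k, chrom_id = s$chrom_id, delta = s$delta),
            class = "kmer_index")
}

#' @export
print.kmer_index <- function(x, ...) {
  s <- index_summary(x)
  cat(sprintf("<kmer_index> %s  k=%d delta=%d  %.0f codes, %.0f positions\n",
              s$chrom_id, s$k, s$delta, s$n_codes, s$n_positions))
  invisible(x)
}

#' Index summary (k, delta, chromosome id, code and position counts)
#' @param index A `kmer_index`.
#' @return List of summary fields.
#' @export
index_summary <- function(index) cpp_index_summary(index$ptr)

#' Look up the reference positions of one k-mer
#' @param index A `kmer_index`.
#' @param kmer A single k-mer string of the index's k.
#' @return Ascending integer vector of 0-based positions (empty if absent or
#'   the k-mer contains N).
#' @export
index_positions <- function(index, kmer) cpp_index_lookup(index$ptr, kmer)

#' Restrict an index to the gapped-seed position subset
#'
#' Retains a position `p` iff `p %% delta == 0`. The retained positions
#' decompose into exactly `sets` residue classes mod `(k + gap)`, class `j`
#' starting at `j * delta`, with consecutive seeds within a class
#' `k + gap` apart.
#'
#' @param index An unfiltered `kmer_index`.
#' @param config A [seed_config()] (or a bare integer delta).
#' @return A filtered `kmer_index`.
#' @export
filter_index <- function(index, config) {
  delta <- if (inherits(config, "seed_config")) config$delta else as.integer(config)
  if (delta < 1L) stop("delta must be at least 1")
  new_kmer_index(cpp_filter_index(index$ptr, delta))
}

#' Save an index to disk / load it back, optionally seed-filtered
#'
#' The on-disk format is a small documented binary: magic bytes, version, k,
#' delta, chromosome id, then per-code position arrays — one file per
#' chromosome. Loading with a `seed_config` materializes only the seed-subset
#' positions (multiples of delta).
#'
#' @param index A `kmer_index`.
#' @param path File path.
#' @return `save_index`: `path` invisibly. `load_index`: a `kmer_index`.
#' @export
save_index <- function(index, path) {
  cpp_save_index(index$ptr, path)
  invisible(path)
}

#' @rdname save_index
#' @param subset_filter Optional [seed_config()]; if supplied only positions
#'   divisible by its delta are loaded.
#' @param k Optional expected k; a mismatch with the file header is an error.
#' @export
load_index <- function(path, subset_filter = NULL, k = NULL) {
  delta <- if (is.null(subset_filter)) 1L else subset_filter$delta
  idx <- new_kmer_index(cpp_load_index(path, as.integer(delta)))
  if (!is.null(k) && idx$k != k)
    stop(sprintf("index file '%s' has k = %d, expected %d", path, idx$k, k))
  idx
}

#' Gapped-seed position predicate and enumeration
#'
#' `seed_positions` returns the predicate retaining position `p` iff
#' `p %% delta == 0`; `seed_position_set` enumerates the retained 0-based
#' positions below `upto`.
#'
#' @param config A [seed_config()].
#' @return A predicate function of integer positions.
#' @export
seed_positions <- function(config) {
  delta <- config$delta
  function(p) (p %% delta) == 0L
}

#' @rdname seed_positions
#' @param upto Exclusive upper bound on positions.
#' @export
seed_position_set <- function(config, upto) {
  if (upto < 1) return(integer(0))
  seq.int(0L, upto - 1L, by = config$delta)
}
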