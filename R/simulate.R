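# Seeded simulator: reference genomes and derived de novo assemblies with
# known ground truth, so every pipeline stage is testable without downloads.

#' Simulation configuration
#'
#' The defaults describe a small but structurally realistic world: a
#' 10-chromosome reference of 50-200 kb, ~60 contigs of 0.5-5 kb carrying 1%
#' substitutions and sparse short indels, 50 implanted novel insertions of
#' 100-2000 bp (random sequence, rejection-sampled so that neither strand
#' shares a 2k-mer with the reference), a couple of multi-copy repeat
#' families, occasional N gaps, and small fractions of chimeric
#' (two-chromosome) contigs and contigs drawn from an unrelated contaminant
#' "organism".
#'
#' @param seed Integer seed; the entire simulation is reproducible from it.
#' @param n_chroms Number of reference chromosomes.
#' @param chrom_lengths Chromosome lengths in bases.
#' @param n_contigs Number of assembly contigs.
#' @param contig_length_dist `(min, max)` contig length.
#' @param snp_rate Per-base substitution probability.
#' @param indel_rate Per-base indel probability; `max_indel_len` caps each
#'   event's length.
#' @param max_indel_len Maximum indel length.
#' @param novel_insertion_count Number of implanted novel insertions.
#' @param novel_length_dist `(min, max)` insertion length.
#' @param repeat_family_count Number of repeat motifs implanted in the
#'   reference; each is copied `repeat_copy_number` times
#'   (`repeat_unit_len` bases each).
#' @param repeat_copy_number Copies per repeat family.
#' @param repeat_unit_len Length of each repeat motif.
#' @param n_gap_rate Per-base probability that an N gap (10-50 bases)
#'   starts.
#' @param chimera_rate Fraction of contigs fusing segments of two
#'   chromosomes (`chimera_segment_len` each).
#' @param chimera_segment_len `(min, max)` chimeric segment length.
#' @param contaminant_fraction Fraction of contigs drawn from the
#'   contaminant genome (`contaminant_length` bases).
#' @param contaminant_length Contaminant genome length.
#' @param k Aligner seed length; the insertion novelty check runs at `2k`
#'   (the phase-3 minimum block length), since isolated shared k-mers are
#'   statistically unavoidable and cannot seed a reportable block.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_chroms = 10L,
                       chrom_lengths = round(seq(50e3, 200e3, length.out = n_chroms)),
                       n_contigs = 60L, contig_length_dist = c(500L, 5000L),
                       snp_rate = 0.01, indel_rate = 5e-4, max_indel_len = 10L,
                       novel_insertion_count = 50L,
                       novel_length_dist = c(100L, 2000L),
                       repeat_family_count = 2L, repeat_copy_number = 3L,
                       repeat_unit_len = 500L,
                       n_gap_rate = 2e-4, chimera_rate = 0.05,
                       chimera_segment_len = c(3000L, 5000L),
                       contaminant_fraction = 0.05, contaminant_length = 50e3,
                       k = 12L) {
  cfg <- list(seed = as.integer(seed), n_chroms = as.integer(n_chroms),
              chrom_lengths = as.integer(chrom_lengths),
              n_contigs = as.integer(n_contigs),
              contig_length_dist = as.integer(contig_length_dist),
              snp_rate = snp_rate, indel_rate = indel_rate,
              max_indel_len = as.integer(max_indel_len),
              novel_insertion_count = as.integer(novel_insertion_count),
              novel_length_dist = as.integer(novel_length_dist),
              repeat_family_count = as.integer(repeat_family_count),
              repeat_copy_number = as.integer(repeat_copy_number),
              repeat_unit_len = as.integer(repeat_unit_len),
              n_gap_rate = n_gap_rate, chimera_rate = chimera_rate,
              chimera_segment_len = as.integer(chimera_segment_len),
              contaminant_fraction = contaminant_fraction,
              contaminant_length = as.integer(contaminant_length),
              k = as.integer(k))
  rates <- c(cfg$snp_rate, cfg$indel_rate, cfg$n_gap_rate, cfg$chimera_rate,
             cfg$contaminant_fraction)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
  if (any(cfg$chrom_lengths < 1L) || any(cfg$contig_length_dist < 1L) ||
      any(cfg$novel_length_dist < 1L))
    stop("lengths must be positive")
  if (length(cfg$chrom_lengths) != cfg$n_chroms)
    stop("chrom_lengths must have n_chroms entries")
  structure(cfg, class = "sim_config")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

runif_int <- function(n, lo, hi) as.integer(floor(runif(n, lo, hi + 1)))

# Substitutions and indels applied to a character-split contig.
mutate_seq <- function(chars, snp_rate, indel_rate, max_indel_len) {
  L <- length(chars)
  n_ind <- stats::rbinom(1, L, indel_rate)
  if (n_ind > 0) {
    at <- sort(sample.int(L, n_ind), decreasing = TRUE)
    for (p in at) {
      l <- runif_int(1, 1, max_indel_len)
      if (runif(1) < 0.5) {  # deletion
        chars <- chars[-(p:min(L, p + l - 1))]
      } else {               # insertion
        chars <- append(chars, sample(c("A", "C", "G", "T"), l, replace = TRUE),
                        after = p)
      }
      L <- length(chars)
    }
  }
  hit <- which(runif(L) < snp_rate)
  for (p in hit) {
    chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
  }
  chars
}

# TRUE when no novelty-k-mer of seq (either strand) occurs in the reference.
# The novelty check runs at 2k (the phase-3 minimum block length): random
# sequence unavoidably shares isolated k-mers with a megabase-scale
# reference, but those cannot seed a reportable block; absence of shared
# 2k-mers is the guarantee that matters and is achievable by rejection.
kmer_clean <- function(seq, ref_index_novelty) {
  cpp_count_hits(ref_index_novelty$ptr, seq) == 0 &&
    cpp_count_hits(ref_index_novelty$ptr, revcomp(seq)) == 0
}

#' Simulate a reference genome and a derived de novo assembly
#'
#' Fully reproducible from `config$seed`. Novel insertions are random
#' sequence verified absent from the reference at the 2k-mer level on both
#' strands, with boundary bases chosen to differ from the flanking contig
#' bases so the implanted interval is exactly the unalignable run. Ground
#' truth covers every contig: its source (reference interval and
#' orientation, chimeric parts, or contaminant) and the implanted novel
#' intervals in final contig coordinates.
#'
#' @param config A [sim_config()].
#' @return List with `reference` and `assembly` (lists of [seq_record()]),
#'   `contaminant` (the contaminant genome record) and `truth` (list of
#'   data frames `sources` and `novel`).
#' @export
simulate_genome <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  with_local_seed(config$seed, simulate_genome_impl(config))
}

simulate_genome_impl <- function(cfg) {
  k <- cfg$k
  # reference with implanted repeat families
  ref_seqs <- lapply(cfg$chrom_lengths, random_dna)
  names(ref_seqs) <- sprintf("chr%d", seq_len(cfg$n_chroms))
  if (cfg$repeat_family_count > 0L) {
    for (f in seq_len(cfg$repeat_family_count)) {
      motif <- random_dna(cfg$repeat_unit_len)
      for (cp in seq_len(cfg$repeat_copy_number)) {
        ci <- sample.int(cfg$n_chroms, 1)
        pos <- runif_int(1, 1, nchar(ref_seqs[[ci]]) - cfg$repeat_unit_len)
        substr(ref_seqs[[ci]], pos, pos + cfg$repeat_unit_len - 1L) <- motif
      }
    }
  }
  reference <- mapply(seq_record, names(ref_seqs), ref_seqs,
                      SIMPLIFY = FALSE, USE.NAMES = FALSE)
  contaminant <- seq_record("contaminant", random_dna(cfg$contaminant_length))

  # one concatenated index at 2k for the insertion novelty check
  ref_cat <- paste(unlist(ref_seqs), collapse = "N")
  ref_idx <- new_kmer_index(cpp_build_index(ref_cat, 2L * k, "refcat"))

  # contigs
  sources <- list()
  contigs <- list()
  type <- sample(c("contaminant", "chimera", "reference"), cfg$n_contigs,
                 replace = TRUE,
                 prob = c(cfg$contaminant_fraction, cfg$chimera_rate,
                          1 - cfg$contaminant_fraction - cfg$chimera_rate))
  for (i in seq_len(cfg$n_contigs)) {
    cid <- sprintf("ctg%03d", i)
    if (type[i] == "contaminant") {
      len <- runif_int(1, cfg$contig_length_dist[1], cfg$contig_length_dist[2])
      len <- min(len, cfg$contaminant_length)
      s <- runif_int(1, 0, cfg$contaminant_length - len)
      chars <- strsplit(substr(contaminant$seq, s + 1L, s + len), "")[[1]]
      sources[[length(sources) + 1L]] <- data.frame(
        contig_id = cid, label = "contaminant", chrom = NA_character_,
        ref_start = s, ref_end = s + len, orient = NA_character_,
        stringsAsFactors = FALSE)
    } else if (type[i] == "chimera") {
      cis <- sample.int(cfg$n_chroms, 2)
      chars <- character(0)
      for (part in 1:2) {
        plen <- runif_int(1, cfg$chimera_segment_len[1], cfg$chimera_segment_len[2])
        plen <- min(plen, cfg$chrom_lengths[cis[part]] - 1L)
        s <- runif_int(1, 0, cfg$chrom_lengths[cis[part]] - plen)
        seg <- substr(ref_seqs[[cis[part]]], s + 1L, s + plen)
        orient <- sample(c("+", "-"), 1)
        if (orient == "-") seg <- revcomp(seg)
        chars <- c(chars, strsplit(seg, "")[[1]])
        sources[[length(sources) + 1L]] <- data.frame(
          contig_id = cid, label = "chimera", chrom = names(ref_seqs)[cis[part]],
          ref_start = s, ref_end = s + plen, orient = orient,
          stringsAsFactors = FALSE)
      }
      chars <- mutate_seq(chars, cfg$snp_rate, cfg$indel_rate, cfg$max_indel_len)
    } else {
      len <- runif_int(1, cfg$contig_length_dist[1], cfg$contig_length_dist[2])
      ci <- sample.int(cfg$n_chroms, 1)
      len <- min(len, cfg$chrom_lengths[ci] - 1L)
      s <- runif_int(1, 0, cfg$chrom_lengths[ci] - len)
      seg <- substr(ref_seqs[[ci]], s + 1L, s + len)
      orient <- sample(c("+", "-"), 1)
      if (orient == "-") seg <- revcomp(seg)
      chars <- strsplit(seg, "")[[1]]
      sources[[length(sources) + 1L]] <- data.frame(
        contig_id = cid, label = "reference", chrom = names(ref_seqs)[ci],
        ref_start = s, ref_end = s + len, orient = orient,
        stringsAsFactors = FALSE)
      chars <- mutate_seq(chars, cfg$snp_rate, cfg$indel_rate, cfg$max_indel_len)
    }
    contigs[[cid]] <- chars
  }

  # novel insertions into reference-derived contigs with >= 200 bp flanks
  flank <- 200L
  novel <- list()
  novel_by_contig <- stats::setNames(vector("list", length(contigs)), names(contigs))
  host_pool <- names(contigs)[type == "reference"]
  for (ins in seq_len(cfg$novel_insertion_count)) {
    ilen <- runif_int(1, cfg$novel_length_dist[1], cfg$novel_length_dist[2])
    hosts <- host_pool[vapply(host_pool, function(h) length(contigs[[h]]),
                              integer(1)) >= 2L * flank + 1L]
    if (length(hosts) == 0L)
      stop("no contig long enough to host a novel insertion; enlarge contigs")
    ok <- FALSE
    for (try in 1:50) {
      host <- if (length(hosts) > 1L) sample(hosts, 1) else hosts
      L <- length(contigs[[host]])
      pos <- runif_int(1, flank, L - flank)  # insert between pos and pos+1
      clash <- FALSE
      for (iv in novel_by_contig[[host]])
        if (pos >= iv[1] - flank && pos <= iv[2] + flank) clash <- TRUE
      if (!clash) { ok <- TRUE; break }
    }
    if (!ok) stop("could not place a novel insertion; too many for the assembly size")
    left_c <- contigs[[host]][pos]
    right_c <- contigs[[host]][pos + 1L]
    repeat {
      iseq <- random_dna(ilen)
      if (substr(iseq, 1, 1) != right_c && substr(iseq, ilen, ilen) != left_c &&
          kmer_clean(iseq, ref_idx)) break
    }
    contigs[[host]] <- append(contigs[[host]], strsplit(iseq, "")[[1]], after = pos)
    # shift previously recorded intervals right of the insertion point
    novel_by_contig[[host]] <- lapply(novel_by_contig[[host]], function(iv)
      if (iv[1] >= pos) iv + ilen else iv)
    novel_by_contig[[host]] <- c(novel_by_contig[[host]], list(c(pos, pos + ilen)))
  }
  for (cid in names(novel_by_contig)) {
    for (iv in novel_by_contig[[cid]])
      novel[[length(novel) + 1L]] <- data.frame(
        contig_id = cid, start = iv[1], end = iv[2], length = iv[2] - iv[1],
        stringsAsFactors = FALSE)
  }

  # N gaps (outside novel intervals so truth stays exact)
  if (cfg$n_gap_rate > 0) {
    for (cid in names(contigs)) {
      if (type[match(cid, names(contigs))] == "contaminant") next
      L <- length(contigs[[cid]])
      n_gaps <- stats::rbinom(1, L, cfg$n_gap_rate)
      for (g in seq_len(n_gaps)) {
        glen <- runif_int(1, 10, 50)
        if (L <= glen + 2L) next
        pos <- runif_int(1, 1, L - glen)
        inside_novel <- any(vapply(novel_by_contig[[cid]], function(iv)
          pos + glen > iv[1] && pos <= iv[2], logical(1)))
        if (inside_novel) next
        contigs[[cid]][pos:(pos + glen - 1L)] <- "N"
      }
    }
  }

  assembly <- lapply(names(contigs), function(cid)
    seq_record(cid, paste(contigs[[cid]], collapse = "")))
  sources <- do.call(rbind, sources)
  novel <- if (length(novel)) do.call(rbind, novel) else
    data.frame(contig_id = character(0), start = integer(0), end = integer(0),
               length = integer(0), stringsAsFactors = FALSE)
  list(reference = reference, assembly = assembly, contaminant = contaminant,
       truth = list(sources = sources, novel = novel), config = cfg)
}
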