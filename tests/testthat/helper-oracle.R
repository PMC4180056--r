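# Shared fixtures and the independent brute-force oracle used to check the
# seed-chain scanner. The oracle never touches the package's scanning code:
# it enumerates maximal exact runs on every query/reference diagonal and
# checks uniqueness by substring counting.

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

# substitute bases at the given 1-based positions (always to a different base)
mutate_at <- function(seq, pos) {
  ch <- strsplit(seq, "")[[1]]
  for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
  paste(ch, collapse = "")
}

# occurrences of `sub` in `ref`, overlaps allowed, capped at 2
count_occ <- function(ref, sub) {
  n <- 0L
  from <- 1L
  repeat {
    i <- regexpr(sub, substring(ref, from), fixed = TRUE)
    if (i == -1L) break
    n <- n + 1L
    if (n > 1L) break
    from <- from + i
  }
  n
}

# Brute-force maximal unique exact matches of length >= min_len between a
# query and a reference: maximal equal runs per diagonal whose substring
# occurs exactly once in the reference. 0-based half-open coordinates.
oracle_mums <- function(ref, query, min_len) {
  R <- strsplit(ref, "")[[1]]
  Q <- strsplit(query, "")[[1]]
  Lr <- length(R)
  Lq <- length(Q)
  out <- list()
  for (d in (-(Lq - 1L)):(Lr - 1L)) {
    qlo <- max(0L, -d)
    qhi <- min(Lq - 1L, Lr - 1L - d)
    if (qhi < qlo) next
    qs <- qlo:qhi
    eq <- Q[qs + 1L] == R[qs + d + 1L] & Q[qs + 1L] != "N"
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in which(r$values & r$lengths >= min_len)) {
      q0 <- qs[starts[j]]
      q1 <- qs[ends[j]] + 1L
      if (count_occ(ref, substr(query, q0 + 1L, q1)) == 1L)
        out[[length(out) + 1L]] <- data.frame(q_start = q0, q_end = q1,
                                              r_start = q0 + d)
    }
  }
  if (length(out) == 0L)
    return(data.frame(q_start = integer(0), q_end = integer(0),
                      r_start = integer(0)))
  out <- do.call(rbind, out)
  out[order(out$q_start, out$r_start), , drop = FALSE]
}

# Random sequence of length `len` sharing no `k2`-mer (either strand) with
# any of `ref_seqs`, checked independently with Biostrings; boundary bases
# forced to differ from the given flanking characters so implanted intervals
# are exactly the unalignable run.
make_clean_insert <- function(len, ref_seqs, left_c = "", right_c = "", k2 = 24L) {
  subjects <- lapply(ref_seqs, Biostrings::DNAString)
  repeat {
    s <- rand_dna(len)
    if (nzchar(right_c) && substr(s, 1, 1) == right_c) next
    if (nzchar(left_c) && substr(s, len, len) == left_c) next
    windows <- substring(s, 1:(len - k2 + 1L), k2:len)
    pd <- Biostrings::PDict(Biostrings::DNAStringSet(
      c(windows, as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(windows))))))
    hits <- sum(vapply(subjects, function(x)
      sum(Biostrings::countPDict(pd, x)), numeric(1)))
    if (hits == 0) return(s)
  }
}

# full-density alignment blocks (scan + extension + length filter) of a
# query against one reference chromosome, both orientations not needed for
# the oracle check which uses forward only
full_blocks_forward <- function(ref_rec, query_rec, config) {
  idx <- build_index(ref_rec, config$k)
  raw <- full_scan(query_rec, idx, "+", config)
  ext <- extend_blocks(raw, query_rec$seq, ref_rec$seq)
  ext <- ext[ext$span >= config$min_block_len, , drop = FALSE]
  ext <- ext[order(ext$q_start, ext$r_start), , drop = FALSE]
  rownames(ext) <- NULL
  ext
}

quiet_config <- function(...) suppressWarnings(pipeline_config(...))

# quiet zero-gap single-set seed configuration for scanning tests
scan_config <- function(...) {
  args <- list(...)
  defaults <- list(k = 12, gap = 0, sets = 1, min_mum_len = 150, prune_dist = 1e6)
  defaults[names(args)] <- args
  suppressWarnings(do.call(seed_config, defaults))
}

# internal region constructor, convenient for hand-built fixtures
region_frame <- novasm:::region_frame

# minimal candidate row for filter/viewer tests
mk_cand <- function(id, qid, start, end) {
  data.frame(candidate_id = id, query_id = qid, start = start, end = end,
             local_start = 0L, local_end = end - start, origin_id = qid,
             origin_length = 5000L, anchor_chrom = NA_character_,
             anchor_pos = NA_integer_, anchor_side = "unplaced",
             stringsAsFactors = FALSE)
}
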