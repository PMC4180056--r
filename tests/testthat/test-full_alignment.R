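test_that("full_scan + extension recovers an exact copy completely", {
  set.seed(81)
  ref <- seq_record("chr1", rand_dna(6000))
  q <- seq_record("q", substr(ref$seq, 1501, 1900))
  cfg <- quiet_config()
  idx <- build_index(ref, cfg$k)
  raw <- full_scan(q, idx, "+", cfg)
  expect_equal(nrow(raw), 1L)
  ext <- extend_blocks(raw, q$seq, ref$seq)
  expect_equal(ext$q_start, 0L)
  expect_equal(ext$q_end, 400L)
  expect_equal(ext$r_start, 1500L)
  expect_equal(ext$r_end, 1900L)
})

test_that("full_scan equals the gapped scanner run at zero gap on in-phase input", {
  set.seed(83)
  ref <- seq_record("chr1", rand_dna(6000))
  q <- seq_record("q", substr(ref$seq, 2401, 2800))  # ref offset 2400, in phase
  g0 <- scan_config()                                 # k = 12, gap 0, one set
  gapped <- gapped_scan(q, filter_index(build_index(ref, g0$k), g0), "+", g0)
  full <- full_scan(q, build_index(ref, g0$k), "+", quiet_config())
  full <- full[full$span >= g0$min_mum_len, , drop = FALSE]
  expect_equal(gapped, full, ignore_attr = TRUE)
})

test_that("a novel insertion splits the alignment into flanking blocks", {
  set.seed(87)
  ref <- seq_record("chr1", rand_dna(8000))
  left <- substr(ref$seq, 2001, 2800)
  right <- substr(ref$seq, 2801, 3600)
  ins <- make_clean_insert(500, list(ref$seq),
                           left_c = substr(left, 800, 800),
                           right_c = substr(right, 1, 1))
  q <- seq_record("q", paste0(left, ins, right))
  cfg <- quiet_config()
  blocks <- full_blocks_forward(ref, q, cfg)
  expect_equal(nrow(blocks), 2L)
  # the unaligned gap is exactly the implanted insertion
  expect_equal(blocks$q_end[1], 800L)
  expect_equal(blocks$q_start[2], 1300L)
  expect_equal(blocks$r_end[1], blocks$r_start[2])
})

test_that("extend_blocks grows to the first mismatch and never through N", {
  ref <- "GGGGACGTACGTACGTGGGG"
  qry <- "GGGGACGTACGTACGTGGGG"
  b <- data.frame(q_start = 7L, q_end = 13L, r_start = 7L, r_end = 13L, span = 6L)
  e <- extend_blocks(b, qry, ref)
  expect_equal(e$q_start, 0L)
  expect_equal(e$q_end, 20L)
  # mismatch immediately adjacent: unchanged
  qry2 <- paste0("T", substr(ref, 2, 19), "A")
  e2 <- extend_blocks(data.frame(q_start = 1L, q_end = 19L, r_start = 1L,
                                 r_end = 19L, span = 18L), qry2, ref)
  expect_equal(e2$q_start, 1L)
  expect_equal(e2$q_end, 19L)
  # N never matches
  qryN <- paste0("GGGN", substr(ref, 5, 20))
  e3 <- extend_blocks(data.frame(q_start = 7L, q_end = 13L, r_start = 7L,
                                 r_end = 13L, span = 6L), qryN, ref)
  expect_equal(e3$q_start, 4L)
})

test_that("resolve_overlaps trims by length priority with seeded ties", {
  b <- region_frame("c", "+", q_start = c(0L, 250L), q_end = c(300L, 400L),
                    r_start = c(1000L, 5000L), n_seeds = c(5L, 3L))
  out <- resolve_overlaps(b, rng_seed = 1, min_len = 24L)
  expect_equal(out$q_start, c(0L, 300L))
  expect_equal(out$q_end, c(300L, 400L))
  # the trimmed piece's reference interval shifts with it
  expect_equal(out$r_start[2], 5000L + 50L)
  # disjoint blocks unchanged
  d <- region_frame("c", "+", q_start = c(0L, 500L), q_end = c(100L, 600L),
                    r_start = c(0L, 900L), n_seeds = c(1L, 1L))
  expect_equal(resolve_overlaps(d, 1, 24L)$q_start, c(0L, 500L))
  # equal-length full overlap: exactly one survives, fixed by the seed
  t1 <- region_frame("c", "+", q_start = c(0L, 0L), q_end = c(100L, 100L),
                     r_start = c(10L, 700L), n_seeds = c(1L, 1L))
  s1 <- resolve_overlaps(t1, 99, 24L)
  s2 <- resolve_overlaps(t1, 99, 24L)
  expect_equal(nrow(s1), 1L)
  expect_equal(s1, s2)
})

test_that("best_alignment maximizes aligned bases with deterministic ties", {
  mk <- function(chrom, orient, bases) list(chrom = chrom, orient = orient,
                                            aligned_bases = bases, blocks = NULL)
  chroms <- c("chr1", "chr2", "chr3")
  r <- best_alignment(list(mk("chr2", "-", 400), mk("chr1", "+", 900)), chroms)
  expect_equal(r$chrom, "chr1")
  tie <- best_alignment(list(mk("chr3", "-", 500), mk("chr3", "+", 500),
                             mk("chr2", "-", 500)), chroms)
  expect_equal(tie$chrom, "chr2")
  expect_equal(tie$orient, "-")
  tie2 <- best_alignment(list(mk("chr3", "-", 500), mk("chr3", "+", 500)), chroms)
  expect_equal(tie2$orient, "+")
  expect_null(best_alignment(list(), chroms))
})

test_that("classify_queries applies the half-length and fp-cutoff rules", {
  pq <- data.frame(query_id = c("a", "b", "c"), length = c(1000L, 8000L, 4000L),
                   aligned_bases = c(400L, 5000L, 4000L), stringsAsFactors = FALSE)
  blocks <- rbind(
    region_frame("chr1", "+", 0L, 2500L, 0L, 5L),       # b: [0,2500)
    region_frame("chr1", "+", 5500L, 8000L, 9000L, 5L), # b: [5500,8000): 3000 bp gap
    region_frame("chr2", "+", 0L, 1000L, 0L, 2L),       # c: [0,1000)
    region_frame("chr2", "+", 3000L, 4000L, 3000L, 2L)) # c: 2000 bp gap
  blocks$query_id <- c("b", "b", "c", "c")
  cls <- classify_queries(pq, assigned_ids = c("a", "b", "c"), fp_cutoff = 2500,
                          blocks = blocks)
  expect_equal(cls$labels$group, c("misassigned", "assigned", "assigned"))
  # only the 3000 bp run exceeds the 2.5 kb cutoff
  expect_equal(cls$fp$query_id, "b")
  expect_equal(cls$fp$start, 2500L)
  expect_equal(cls$fp$end, 5500L)
  # unassigned routing
  cls2 <- classify_queries(pq, assigned_ids = c("b"), fp_cutoff = 2500)
  expect_equal(cls2$labels$group, c("unassigned", "assigned", "unassigned"))
})

test_that("a chimeric scaffold is excised, re-aligned and not called novel", {
  set.seed(91)
  ref <- lapply(1:8, function(i) seq_record(sprintf("chr%d", i), rand_dna(20000)))
  partA <- substr(ref[[2]]$seq, 3001, 7000)
  partB <- revcomp(substr(ref[[5]]$seq, 9001, 13000))
  scaf <- seq_record("scaffold1", paste0(partA, partB))
  cfg <- quiet_config(rng_seed = 5)
  res <- run_pipeline(ref, list(scaf), cfg)
  expect_equal(nrow(res$alignment$fp), 1L)
  fp_blocks <- res$alignment$blocks[res$alignment$blocks$source == "fp_realign", ]
  expect_true(all(fp_blocks$chrom == "chr5"))
  expect_true(all(fp_blocks$orient == "-"))
  expect_gt(res$alignment$fp$recovered_bases, 3500)
  expect_equal(nrow(res$candidates), 0L)
  expect_gt(res$tallies$aligned_bases / res$tallies$total_bases, 0.99)
})

test_that("base bookkeeping is conserved end to end, insertions recovered", {
  # scaled down from the acceptance fixture (3 small replicates) to keep the
  # suite fast; the acceptance test runs the stated 50-insertion world
  for (r in 1:3) {
    sim <- simulate_genome(sim_config(
      seed = 100 + r, n_chroms = 4, chrom_lengths = rep(40e3, 4),
      n_contigs = 15, novel_insertion_count = 6, contig_length_dist = c(600, 4000)))
    res <- run_pipeline(sim$reference, sim$assembly, quiet_config(rng_seed = r))
    t <- res$tallies
    expect_equal(t$aligned_bases + t$candidate_bases_final + t$filtered_bases,
                 t$total_bases, ignore_attr = TRUE)
    # implanted novel bases recovered in candidates
    hit <- 0
    for (i in seq_len(nrow(sim$truth$novel))) {
      tr <- sim$truth$novel[i, ]
      cc <- res$candidates[res$candidates$query_id == tr$contig_id, , drop = FALSE]
      if (nrow(cc) == 0L) next
      hit <- hit + sum(IRanges::width(IRanges::intersect(
        IRanges::IRanges(cc$start + 1L, cc$end),
        IRanges::IRanges(tr$start + 1L, tr$end))))
    }
    expect_gte(hit / sum(sim$truth$novel$length), 0.95)
  }
})
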