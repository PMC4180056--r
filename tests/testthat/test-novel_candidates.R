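# Hand-built alignment results for extraction tests.
fake_alignment <- function(blocks) list(blocks = blocks)

test_that("extract_candidates takes the aligned complement with the length rule", {
  q <- seq_record("q1", rand_dna(1000))
  blocks <- region_frame("chr1", "+", q_start = c(0L, 900L), q_end = c(400L, 1000L),
                         r_start = c(5000L, 9000L), n_seeds = c(3L, 1L))
  blocks$query_id <- "q1"
  ext <- extract_candidates(fake_alignment(blocks), list(q), 100L)
  expect_equal(nrow(ext$candidates), 1L)
  expect_equal(ext$candidates$start, 400L)
  expect_equal(ext$candidates$end, 900L)
  expect_equal(ext$candidates$origin_length, 1000L)
  # anchor: nearest flanking block (left, at its reference end)
  expect_equal(ext$candidates$anchor_side, "left")
  expect_equal(ext$candidates$anchor_chrom, "chr1")
  expect_equal(ext$candidates$anchor_pos, 5400L)
  # exact bookkeeping: 500 candidate bases, nothing dropped
  expect_equal(ext$dropped$n_bases + ext$dropped$short_bases, 0L)
})

test_that("short runs and all-N runs are dropped but tallied", {
  set.seed(101)
  q99 <- seq_record("q99", rand_dna(1000))
  blocks <- region_frame("chr1", "+", q_start = c(0L, 599L), q_end = c(500L, 1000L),
                         r_start = c(0L, 599L), n_seeds = c(1L, 1L))
  blocks$query_id <- "q99"
  ext <- extract_candidates(fake_alignment(blocks), list(q99), 100L)
  expect_equal(nrow(ext$candidates), 0L)       # 99 bp run < 100
  expect_equal(ext$dropped$short_bases, 99L)
  # an all-N unaligned run disappears into the N tally
  qn <- seq_record("qn", paste0(rand_dna(300), strrep("N", 200), rand_dna(300)))
  bn <- region_frame("chr1", "+", q_start = c(0L, 500L), q_end = c(300L, 800L),
                     r_start = c(0L, 500L), n_seeds = c(1L, 1L))
  bn$query_id <- "qn"
  extn <- extract_candidates(fake_alignment(bn), list(qn), 100L)
  expect_equal(nrow(extn$candidates), 0L)
  expect_equal(extn$dropped$n_bases[extn$dropped$query_id == "qn"], 200L)
  # a wholly unaligned query anchors as unplaced
  qu <- seq_record("qu", rand_dna(400))
  extu <- extract_candidates(fake_alignment(blocks[0, ]), list(qu), 100L)
  expect_equal(extu$candidates$anchor_side, "unplaced")
  expect_equal(extu$candidates$start, 0L)
  expect_equal(extu$candidates$end, 400L)
})

test_that("parse_blast_tab converts coordinates and flags malformed lines", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "c1\tchr1\t98.0\t200\t4\t0\t1\t200\t5000\t5199\t1e-100\t360",
    "c2\tchr2\t91.5\t150\t8\t1\t11\t160\t9000\t8851\t1e-50\t180"), f)
  hits <- parse_blast_tab(f)
  expect_equal(hits$start, c(0L, 10L))
  expect_equal(hits$end, c(200L, 160L))
  expect_equal(hits$identity, c(98.0, 91.5))
  # reverse-strand subject (sstart > send) accepted, query interval unaffected
  expect_equal(hits$subject_id[2], "chr2")
  writeLines("c1\tchr1\t98.0\t200\t4\t0\t1\t200\t5000\t5199\t1e-100", f)
  expect_error(parse_blast_tab(f), "line 1.*expected 12 columns")
})

test_that("parse_repeatmasker_out skips headers and converts coordinates", {
  f <- withr::local_tempfile(fileext = ".out")
  writeLines(c(
    "   SW   perc perc perc  query     position in query    matching repeat",
    "score   div. del. ins.  sequence  begin end (left)     repeat class/family",
    "",
    "  463   12.1  0.0  0.0  cand1     102   250  (750)  +  AluYa5  SINE/Alu   1 149 (0) 1",
    "  300    8.0  1.1  0.0  cand2       1    80  (120)  C  L1MC    LINE/L1    1  80 (0) 2"), f)
  masks <- parse_repeatmasker_out(f)
  expect_equal(masks$query_id, c("cand1", "cand2"))
  expect_equal(masks$start, c(101L, 0L))
  expect_equal(masks$end, c(250L, 80L))
  expect_equal(masks$repeat_class, c("SINE/Alu", "LINE/L1"))
  # headers only -> empty
  writeLines(c("h1", "h2", ""), f)
  expect_equal(nrow(parse_repeatmasker_out(f)), 0L)
})

test_that("subtract_and_refilter splits, refilters and respects the identity ceiling", {
  cands <- mk_cand("c1", "q1", 0L, 1000L)
  masks <- data.frame(query_id = "c1", start = 200L, end = 300L, identity = 99)
  res <- subtract_and_refilter(cands, masks, 100L, 90, "blast")
  expect_equal(res$candidates$local_start, c(0L, 300L))
  expect_equal(res$candidates$local_end, c(200L, 1000L))
  expect_equal(res$trail$bases_removed, 100)
  expect_equal(res$dropped_bases, 0)
  # remainder below the length floor is dropped and tallied
  c2 <- mk_cand("c2", "q2", 0L, 150L)
  res2 <- subtract_and_refilter(c2, data.frame(query_id = "c2", start = 0L,
                                               end = 60L, identity = 95), 100L, 90)
  expect_equal(nrow(res2$candidates), 0L)
  expect_equal(res2$dropped_bases, 90)
  # below the ceiling the hit is not evidence of known sequence
  res3 <- subtract_and_refilter(cands, data.frame(query_id = "c1", start = 200L,
                                                  end = 300L, identity = 85), 100L, 90)
  expect_equal(res3$candidates$local_end, 1000L)
  expect_equal(nrow(res3$trail), 0L)
  # unknown candidate ids are skipped with a warning
  expect_warning(
    subtract_and_refilter(cands, data.frame(query_id = "ghost", start = 0L,
                                            end = 10L, identity = 99), 100L, 90),
    "unknown candidate")
})

test_that("subtraction is idempotent and keeps exact base accounts", {
  set.seed(103)
  cands <- rbind(mk_cand("c1", "q1", 100L, 1100L), mk_cand("c2", "q2", 0L, 700L))
  masks <- data.frame(query_id = c("c1", "c1", "c2"),
                      start = c(50L, 600L, 650L), end = c(220L, 780L, 700L),
                      identity = c(95, 99, 97))
  res1 <- subtract_and_refilter(cands, masks, 100L, 90, "blast")
  res2 <- subtract_and_refilter(res1$candidates, masks, 100L, 90, "blast")
  expect_equal(res2$candidates, res1$candidates)
  expect_equal(sum(res2$trail$bases_removed), 0)
  # input bases == output + removals + refilter drops
  expect_equal(sum(candidate_len <- cands$end - cands$start),
               sum(res1$candidates$end - res1$candidates$start) +
                 sum(res1$trail$bases_removed) + res1$dropped_bases)
})

test_that("independent masks commute: BLAST-then-repeat equals repeat-then-BLAST", {
  set.seed(107)
  for (rep in 1:5) {
    n <- sample(2:4, 1)
    cands <- do.call(rbind, lapply(seq_len(n), function(i)
      mk_cand(sprintf("c%d", i), sprintf("q%d", i), 0L, sample(500:1500, 1))))
    rmask <- function() {
      id <- sample(cands$candidate_id, 1)
      L <- cands$local_end[cands$candidate_id == id]
      s <- sample.int(L - 50L, 1)
      data.frame(query_id = id, start = s - 1L,
                 end = min(L, s + sample(30:200, 1)), identity = 99)
    }
    blast <- do.call(rbind, replicate(3, rmask(), simplify = FALSE))
    rm_m <- do.call(rbind, replicate(3, rmask(), simplify = FALSE))
    ab <- subtract_and_refilter(subtract_and_refilter(cands, blast, 100L, 90)$candidates,
                                rm_m, 100L, 90)
    ba <- subtract_and_refilter(subtract_and_refilter(cands, rm_m, 100L, 90)$candidates,
                                blast, 100L, 90)
    expect_equal(ab$candidates[order(ab$candidates$candidate_id,
                                     ab$candidates$local_start), ],
                 ba$candidates[order(ba$candidates$candidate_id,
                                     ba$candidates$local_start), ],
                 ignore_attr = TRUE)
  }
})

test_that("contamination_screen removes and tallies by source", {
  cands <- rbind(mk_cand("c1", "q1", 0L, 500L), mk_cand("c2", "q2", 0L, 800L))
  masks <- data.frame(query_id = c("c1", "c2"), start = c(0L, 100L),
                      end = c(500L, 250L), source = c("EBV", "zebrafish"))
  res <- contamination_screen(cands, masks, 100L)
  # fully covered candidate removed outright
  expect_false("c1" %in% res$candidates$candidate_id)
  expect_equal(res$removed$bases_removed[res$removed$source == "EBV"], 500)
  expect_equal(res$removed$bases_removed[res$removed$source == "zebrafish"], 150)
  # partial hit: partial subtraction plus refilter
  c2 <- res$candidates[res$candidates$candidate_id == "c2", ]
  expect_equal(c2$local_start, c(0L, 250L))
  # no contaminant file: identity pass-through
  pass <- contamination_screen(cands, NULL, 100L)
  expect_equal(pass$candidates, cands)
})

test_that("candidate FASTA/BED exports round-trip the intervals", {
  set.seed(109)
  q <- seq_record("ctg1", rand_dna(600))
  cands <- mk_cand("ctg1:101-350", "ctg1", 100L, 350L)
  fa <- withr::local_tempfile(fileext = ".fa")
  bed <- withr::local_tempfile(fileext = ".bed")
  write_candidates_fasta(cands, list(q), fa)
  back <- read_fasta(fa)
  expect_equal(back[[1]]$seq, substr(q$seq, 101, 350))
  expect_equal(back[[1]]$id, "ctg1:101-350")
  write_candidates_bed(cands, bed)
  b <- read.table(bed, sep = "\t")
  expect_equal(b$V2, 100L)
  expect_equal(b$V3, 350L)
})
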