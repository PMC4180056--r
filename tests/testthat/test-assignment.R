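test_that("gapped_scan recovers an exact unique copy as one maximal region", {
  set.seed(51)
  ref <- seq_record("chr1", rand_dna(5000))
  # copy starts at a multiple of delta so the chain starts at query base 0
  q <- seq_record("q", substr(ref$seq, 1201, 1600))
  cfg <- scan_config()
  idx <- filter_index(build_index(ref, cfg$k), cfg)
  r <- gapped_scan(q, idx, "+", cfg)
  expect_equal(nrow(r), 1L)
  # chain covers whole k-mers only: [0, 12 * floor(400/12)) = [0, 396)
  expect_equal(r$q_start, 0L)
  expect_equal(r$q_end, 396L)
  expect_equal(r$r_start, 1200L)
  expect_equal(r$span, r$r_end - r$r_start)
  expect_equal(score_regions(r), 396L)
})

test_that("gapped_scan around a substitution matches the brute-force oracle", {
  set.seed(53)
  ref <- seq_record("chr1", rand_dna(5000))
  qseq <- substr(ref$seq, 1201, 1600)
  qseq <- mutate_at(qseq, 201)   # one substitution at bp 201 (1-based)
  q <- seq_record("q", qseq)
  cfg <- scan_config()
  idx <- filter_index(build_index(ref, cfg$k), cfg)
  r <- gapped_scan(q, idx, "+", cfg)
  # oracle: maximal unique exact runs with the same seed spacing (k = 12,
  # delta = 12): a chain emitted by the scanner covers whole seeds of a run,
  # starting at the first in-phase clean seed
  mums <- oracle_mums(ref$seq, q$seq, cfg$min_mum_len)
  expect_equal(nrow(r), nrow(mums))
  for (i in seq_len(nrow(r))) {
    expect_gte(r$q_start[i], mums$q_start[i])
    expect_lte(r$q_end[i], mums$q_end[i])
    expect_equal(r$r_start[i] - r$q_start[i], mums$r_start[i] - mums$q_start[i])
    expect_lt(r$q_start[i] - mums$q_start[i], cfg$k + cfg$gap)
  }
})

test_that("a two-copy tandem repeat never reaches uniqueness", {
  set.seed(59)
  unit <- rand_dna(600)
  ref <- seq_record("chr1", paste0(rand_dna(996), unit, unit, rand_dna(1000)))
  q <- seq_record("q", substr(unit, 101, 500))
  cfg <- scan_config()
  idx <- filter_index(build_index(ref, cfg$k), cfg)
  expect_equal(nrow(gapped_scan(q, idx, "+", cfg)), 0L)
})

test_that("each query base is examined at most once per orientation", {
  set.seed(61)
  ref <- seq_record("chr1", rand_dna(20000))
  cfg <- suppressWarnings(seed_config(k = 12, gap = 84, sets = 6))
  idx <- filter_index(build_index(ref, cfg$k), cfg)
  for (rep in 1:5) {
    s <- sample(1:15000, 1)
    qseq <- mutate_at(substr(ref$seq, s, s + 999), sample(1000, 10))
    q <- seq_record("q", qseq)
    r <- gapped_scan(q, idx, "+", cfg)
    expect_lte(attr(r, "lookups"), q$length)
  }
})

test_that("prune_spurious keeps the anchor and its neighborhood", {
  regions <- region_frame("chr1", "+",
                          q_start = c(0L, 400L, 800L),
                          q_end = c(300L, 560L, 1000L),
                          r_start = c(5e6, 5.4e6, 9e6), n_seeds = c(3L, 2L, 2L))
  kept <- prune_spurious(regions, 1e6)
  expect_equal(kept$r_start, c(5e6, 5.4e6))
  one <- prune_spurious(regions[2, , drop = FALSE], 1e6)
  expect_equal(nrow(one), 1L)
  expect_equal(prune_spurious(regions[0, , drop = FALSE], 1e6), regions[0, ])
})

test_that("anchor ties break to the smallest r_start, invariant to input order", {
  regions <- region_frame("chr1", "+",
                          q_start = c(0L, 0L, 0L),
                          q_end = c(200L, 200L, 150L),
                          r_start = c(8e6, 2e6, 2.5e6), n_seeds = c(2L, 2L, 1L))
  a <- prune_spurious(regions, 1e6)
  b <- prune_spurious(regions[c(2, 3, 1), , drop = FALSE], 1e6)
  expect_setequal(a$r_start, b$r_start)
  # leftmost equal-longest (2e6) anchors; 8e6 is beyond D, 2.5e6 within
  expect_setequal(a$r_start, c(2e6, 2.5e6))
  # pruning properties: subset, anchor retained, score non-increasing
  expect_true(all(a$r_start %in% regions$r_start))
  expect_lte(score_regions(a), score_regions(regions))
})

test_that("score_regions totals aligned bases", {
  r <- region_frame("c", "+", c(0L, 200L), c(150L, 290L), c(0L, 500L), c(2L, 1L))
  expect_equal(score_regions(r), 240L)
  expect_equal(score_regions(r[0, ]), 0L)
})

test_that("assign_targets implements the Gaussian outlier rule", {
  # 47 zeros and one 1000: arithmetic oracle for mu/sigma/z
  scores <- stats::setNames(c(rep(0, 47), 1000), slot_names <- paste0("s", 1:48))
  mu <- sum(scores) / 48
  sigma <- sqrt(mean((scores - mu)^2))
  a <- assign_targets(scores, 2.326)
  expect_equal(a$mu, mu)
  expect_equal(a$sigma, sigma)
  expect_equal(unname(a$z[48]), (1000 - mu) / sigma)
  expect_equal(round(a$z[[48]], 2), 6.86)
  expect_equal(a$assigned, "s48")
  # all-equal scores: sigma 0, unassigned
  b <- assign_targets(stats::setNames(rep(7, 48), slot_names))
  expect_equal(b$assigned, character(0))
  # a slot at the mean of Gaussian noise is never an outlier
  set.seed(67)
  noise <- stats::setNames(c(rnorm(47, 100, 10), 100), slot_names)
  expect_false("s48" %in% assign_targets(noise, 2.326)$assigned)
  # leave-one-out variant excludes the candidate slot from its own baseline
  loo_scores <- stats::setNames(c(rnorm(47, 100, 10), 1000), slot_names)
  loo <- assign_targets(loo_scores, 2.326, leave_one_out = TRUE)
  expect_equal(unname(loo$mu[48]), mean(loo_scores[1:47]))
  expect_true("s48" %in% loo$assigned)
})

test_that("orientation symmetry: reverse-complementing a query flips the slots", {
  set.seed(71)
  ref <- lapply(1:3, function(i) seq_record(sprintf("chr%d", i), rand_dna(8000)))
  cfg <- scan_config(min_mum_len = 120)
  q <- seq_record("q", substr(ref[[2]]$seq, 3001, 3600))
  qr <- seq_record("q", revcomp(q$seq))
  s1 <- score_queries(list(q), ref, cfg)
  s2 <- score_queries(list(qr), ref, cfg)
  flip <- sub("\\+$", "MINUS", colnames(s1))
  flip <- sub("\\-$", "+", flip)
  flip <- sub("MINUS$", "-", flip)
  expect_equal(unname(s1[1, ]), unname(s2[1, flip]))
  expect_gt(s1[1, "chr2|+"], 0)
})

test_that("assign_queries routes short queries to unassigned without scanning", {
  set.seed(73)
  # a one-hot score among 2n slots has z = sqrt(2n - 1), so the p = 0.01
  # outlier rule needs at least 7 slots to be satisfiable at all
  ref <- lapply(1:6, function(i) seq_record(sprintf("chr%d", i), rand_dna(4000)))
  cfg <- scan_config(min_mum_len = 150)
  short <- seq_record("tiny", substr(ref[[1]]$seq, 101, 200))  # 100 < 150
  good <- seq_record("good", substr(ref[[1]]$seq, 1001, 1500))
  res <- assign_queries(list(short, good), ref, cfg)
  expect_false("tiny" %in% res$assignments$query_id)
  expect_true(all(res$scores["tiny", ] == 0))
  hit <- res$assignments[res$assignments$query_id == "good", ]
  expect_equal(hit$chrom, "chr1")
  expect_equal(hit$orient, "+")
})
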