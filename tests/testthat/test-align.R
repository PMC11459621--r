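test_that("sw_local reproduces oracle-derived scores on worked examples", {
  s <- scoring_scheme()
  expect_identical(sw_local("ACGTACGTAC", "ACGTACGTAC", s)$score, 50L)
  # with mismatch = 0, extending through the G as a mismatch (7 matches,
  # 35) beats bridging it with a 1-nt gap (8 matches - 6 = 34); the R DP
  # oracle agrees
  expect_identical(sw_local("AAAATTTT", "AAAAGTTTT", s)$score, 35L)
  expect_identical(oracle_sw_score("AAAATTTT", "AAAAGTTTT"), 35)
  expect_identical(
    sw_local("TTTT", "TCTC", scoring_scheme(bisulfite_mode = "CT"))$score,
    20L)
  expect_identical(sw_local("ACGTACGTAC", "ACGTTCGTAC", s)$score, 45L)
})

test_that("bisulfite wildcards are asymmetric", {
  ct <- scoring_scheme(bisulfite_mode = "CT")
  expect_identical(sw_local("T", "C", ct)$score, 5L)   # read T on ref C
  expect_identical(sw_local("C", "T", ct)$score, 0L)   # not the reverse
  ga <- scoring_scheme(bisulfite_mode = "GA")
  expect_identical(sw_local("A", "G", ga)$score, 5L)
  expect_identical(sw_local("G", "A", ga)$score, 0L)
  expect_identical(sw_local("N", "N", ct)$score, 0L)   # N never matches
})

test_that("sw_local matches the brute-force DP oracle on random pairs", {
  set.seed(31)
  for (k in 1:80) {
    q <- random_dna(sample(5:50, 1L))
    t <- random_dna(sample(5:50, 1L))
    mode <- sample(c("off", "CT", "GA"), 1L)
    mm <- sample(c(0L, -3L), 1L)  # a negative mismatch exercises gap paths
    got <- sw_local(q, t, scoring_scheme(mismatch = mm,
                                         bisulfite_mode = mode))$score
    expect_identical(as.numeric(got),
                     oracle_sw_score(q, t, mismatch = mm, mode = mode))
  }
})

test_that("appending bases never decreases the local score", {
  set.seed(57)
  s <- scoring_scheme()
  for (k in 1:40) {
    q <- random_dna(sample(10:40, 1L))
    t <- random_dna(sample(10:40, 1L))
    base <- sw_local(q, t, s)$score
    grown <- sw_local(paste0(q, random_dna(5L)),
                      paste0(t, random_dna(5L)), s)$score
    expect_gte(grown, base)
  }
})

test_that("co-optimal alignments resolve to the smallest target offset", {
  s <- scoring_scheme()
  res <- sw_local("ACGT", "TTACGTTTACGTT", s)
  expect_identical(res$score, 20L)
  expect_identical(res$t_off, 2L)
})

test_that("anchor_align recovers a unique planted anchor on both strands", {
  set.seed(12)
  ctg <- random_dna(5000L)
  ref <- reference_set(c(chr = ctg))
  params <- pipeline_params()
  anchor <- substr(ctg, 1001L, 1050L)
  pl <- anchor_align(anchor, ref, params)
  expect_identical(nrow(pl), 1L)
  expect_identical(pl$start0, 1000L)
  expect_identical(pl$strand, "+")
  expect_identical(pl$score, 250L)
  expect_identical(pl$n_candidates, 1L)

  pl_rc <- anchor_align(revcomp(anchor), ref, params)
  expect_identical(pl_rc$start0, 1000L)
  expect_identical(pl_rc$strand, "-")

  expect_identical(nrow(anchor_align(random_dna(50L), ref, params)), 0L)
})

test_that("anchor placements are capped at max_hits over a repeat array", {
  set.seed(13)
  unit <- random_dna(50L)
  ref <- reference_set(c(rep = paste(vapply(1:25, function(i) {
    paste0(unit, random_dna(30L))
  }, character(1L)), collapse = "")))
  pl <- anchor_align(unit, ref, pipeline_params())
  expect_identical(nrow(pl), 20L)
  expect_true(all(pl$score == 250L))
  expect_identical(pl$n_candidates[1L], 25L)
  expect_identical(pl$start0, seq(0L, by = 80L, length.out = 20L))
})

test_that("position_r1 places simulated Read1 at truth inside the 1 kb window", {
  cfg <- exact_sim_config(n_pairs = 40L, genome_length = 15000L)
  sim <- simulate_gps(cfg)
  params <- pipeline_params()
  pre <- preprocess_pairs(sim$pairs, params)
  pv <- sim$provenance[match(pre$pairs$id, sim$provenance$id), ]
  hit <- 0L
  for (i in seq_len(min(15L, nrow(pre$pairs)))) {
    pl2 <- anchor_align(pre$boundaries$anchor[i], sim$ref, params)
    expect_gte(nrow(pl2), 1L)
    pp <- position_r1(pre$pairs$r1_seq[i], pl2, sim$ref, params)
    expect_identical(pp$status, "placed")
    expect_lte(pp$pair_distance, params$max_pair_distance)
    truth_start <- if (pp$frag_strand == "+") pv$frag_start[i] else
      pv$frag_end[i] - nchar(pre$pairs$r1_seq[i])
    expect_identical(pp$r1_aln_start0, truth_start)
    expect_identical(pp$frag_strand, pv$strand[i])
    hit <- hit + 1L
  }
  expect_gte(hit, 10L)

  # with mismatches scoring 0, even an unrelated read accrues ~5/16 chance
  # matches per diagonal position, so rejection needs a stringent score
  # floor (the true read still clears it at ~5 x read length)
  set.seed(77)
  strict <- pipeline_params(min_sw_score = 600)
  pl2 <- anchor_align(pre$boundaries$anchor[1L], sim$ref, params)
  bad <- position_r1(random_dna(150L), pl2, sim$ref, strict)
  expect_identical(bad$status, "low_score")
  good <- position_r1(pre$pairs$r1_seq[1L], pl2, sim$ref, strict)
  expect_identical(good$status, "placed")
})

test_that("trim_paired finds the first conversion scanning 3'->5'", {
  params <- pipeline_params()
  ref <- reference_set(c(chr = strrep("C", 200L)))
  # converted everywhere up to read coord 119, retained-C block after
  row <- make_placed_row("p", "chr", paste0(strrep("T", 120L),
                                            strrep("C", 30L)), 0L)
  tr <- trim_paired(row, ref, boundary = 40L, params)
  expect_identical(tr$r1_keep, 120L)
  expect_identical(tr$r2_keep, 40L)

  # fully converted: terminal base is the first conversion -> no trimming
  row2 <- make_placed_row("p2", "chr", strrep("T", 150L), 0L)
  expect_identical(trim_paired(row2, ref, 40L, params)$r1_keep, 150L)

  # no conversion anywhere: whole read potentially patched
  row3 <- make_placed_row("p3", "chr", strrep("C", 150L), 0L)
  expect_identical(trim_paired(row3, ref, 40L, params)$r1_keep, 0L)

  # window without any reference C: no over-cut evidence, keep whole read
  ref_a <- reference_set(c(chr = strrep("A", 200L)))
  row4 <- make_placed_row("p4", "chr", strrep("A", 150L), 0L)
  expect_identical(trim_paired(row4, ref_a, 40L, params)$r1_keep, 150L)

  # minus-strand fragment: aligned query is revcomp(R1); the read's 3' end
  # sits at low aligned coordinates and conversion is A over reference G
  ref_g <- reference_set(c(chr = strrep("G", 200L)))
  row5 <- make_placed_row("p5", "chr",
                          paste0(strrep("G", 5L), strrep("A", 145L)), 0L,
                          frag_strand = "-")
  expect_identical(trim_paired(row5, ref_g, 40L, params)$r1_keep, 145L)
})

test_that("align_pairs matches simulator truth end-to-end", {
  cfg <- exact_sim_config(n_pairs = 150L, genome_length = 15000L)
  sim <- simulate_gps(cfg)
  params <- pipeline_params()
  pre <- preprocess_pairs(sim$pairs, params)
  pl <- align_pairs(pre$pairs, pre$boundaries, sim$ref, params)
  expect_identical(nrow(pl), nrow(pre$pairs))
  placed <- pl[pl$status == "placed", ]
  expect_gte(nrow(placed), 0.95 * nrow(pl))
  tr <- merge(placed, sim$provenance, by = "id")
  ok <- ifelse(tr$frag_strand == "+", tr$r1_aln_start0 == tr$frag_start,
               tr$r1_aln_end0 == tr$frag_end)
  expect_true(all(ok))
  expect_true(all(tr$pair_distance <= params$max_pair_distance))
  expect_true(all(tr$frag_strand != tr$r2_strand))   # inward-facing mates
  # R2 keep-span equals the preprocessing boundary
  b <- pre$boundaries[match(tr$id, pre$boundaries$id), ]
  expect_identical(tr$r2_keep, b$boundary)
  # trimmed R1 never reaches into the 5mC patch
  pp <- ifelse(tr$strand == "+", tr$patch_right, tr$patch_left)
  frag_len <- tr$frag_end - tr$frag_start
  expect_true(all(tr$r1_keep <= frag_len - pp))
})

test_that("anchor alignments can be imported from SAM in place of seeding", {
  cfg <- exact_sim_config(n_pairs = 60L, genome_length = 12000L)
  sim <- simulate_gps(cfg)
  params <- pipeline_params()
  pre <- preprocess_pairs(sim$pairs, params)
  pl <- align_pairs(pre$pairs, pre$boundaries, sim$ref, params)
  sam <- withr::local_tempfile(fileext = ".sam")
  write_pairs_sam(pl, pre$pairs, sim$ref, sam)
  ## keep only the Read2 (anchor) records as an external anchor SAM
  lines <- readLines(sam)
  is_r2 <- !startsWith(lines, "@") &
    bitwAnd(as.integer(vapply(strsplit(lines, "\t"), function(f) {
      if (startsWith(f[1L], "@")) "0" else f[2L]
    }, character(1L))), 128L) > 0L
  writeLines(c(lines[startsWith(lines, "@")], lines[is_r2]), sam)
  pl2 <- align_pairs(pre$pairs, pre$boundaries, sim$ref, params,
                     anchor_sam = sam)
  placed <- pl$status == "placed"
  expect_identical(pl2$status[placed], pl$status[placed])
  expect_identical(pl2$r1_aln_start0[placed], pl$r1_aln_start0[placed])
  expect_identical(pl2$r2_start0[placed], pl$r2_start0[placed])
})
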