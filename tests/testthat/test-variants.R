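# constructed scenario: a het site at pos 60 (ref A / alt T) inside the
# protected anchors, and a CpG at pos 10 covered by the groups' Read1s
make_asm_fixture <- function(n_alt = 5L, n_ref = 5L, meth_alt = 5L,
                             meth_ref = 1L, extra_base = NULL) {
  ctg <- paste0(strrep("A", 10L), "CG", strrep("A", 38L), "A",
                strrep("A", 49L))  # pos 60 is A
  ref <- reference_set(c(chr = ctg))
  mk <- function(id, allele, meth) {
    anchor <- substr(ctg, 51L, 80L)
    substr(anchor, 10L, 10L) <- allele          # anchor covers pos 50..79
    r1 <- substr(ctg, 1L, 30L)
    substr(r1, 11L, 11L) <- if (meth) "C" else "T"
    row <- make_placed_row(id, "chr", r1, 0L, anchor_query = anchor,
                           r2_start0 = 50L)
    row
  }
  rows <- list()
  for (i in seq_len(n_alt)) {
    rows[[length(rows) + 1L]] <- mk(paste0("alt", i), "T", i <= meth_alt)
  }
  for (i in seq_len(n_ref)) {
    rows[[length(rows) + 1L]] <- mk(paste0("ref", i), "A", i <= meth_ref)
  }
  if (!is.null(extra_base)) {
    rows[[length(rows) + 1L]] <- mk("odd1", extra_base, TRUE)
  }
  pl <- do.call(rbind, rows)
  class(pl) <- c("gps_placements", "data.frame")
  list(ref = ref, placements = pl)
}

test_that("variant candidates emerge from protected segments only", {
  fx <- make_asm_fixture()
  params <- pipeline_params()
  v <- call_variant_candidates(fx$placements, fx$ref, params)
  expect_identical(nrow(v), 1L)
  expect_identical(v$pos0, 59L)
  expect_identical(v$ref_base, "A")
  expect_identical(v$alt_base, "T")
  expect_identical(v$coverage, 10L)
  expect_identical(v$alt_count, 5L)
})

test_that("allele grouping partitions covering pairs and ignores other bases", {
  fx <- make_asm_fixture(extra_base = "N")
  v <- call_variant_candidates(fx$placements, fx$ref, pipeline_params())
  grp <- group_pairs_by_allele(v[1L, ], fx$placements, fx$ref)
  expect_setequal(grp$with_alt, paste0("alt", 1:5))
  expect_setequal(grp$without_alt, paste0("ref", 1:5))
  expect_false("odd1" %in% c(grp$with_alt, grp$without_alt))
  expect_length(intersect(grp$with_alt, grp$without_alt), 0L)

  # a site nobody covers yields empty groups
  far <- data.frame(contig = "chr", pos0 = 5L, ref_base = "A",
                    alt_base = "T", coverage = 0L, alt_count = 0L)
  grp0 <- group_pairs_by_allele(far, fx$placements, fx$ref)
  expect_length(grp0$with_alt, 0L)
  expect_length(grp0$without_alt, 0L)
})

test_that("ASM flags respect the 70 pp / 5x thresholds", {
  params <- pipeline_params()
  # 100 % vs 20 % at 5x/5x -> diff 80, ASM
  fx <- make_asm_fixture(meth_alt = 5L, meth_ref = 1L)
  v <- call_variant_candidates(fx$placements, fx$ref, params)
  rec <- asm_scan(v, fx$placements, fx$ref, params)
  cg <- rec[rec$cyt_pos0 == 10L, ]
  expect_identical(nrow(cg), 1L)
  expect_equal(cg$level_with_alt, 100)
  expect_equal(cg$level_without_alt, 20)
  expect_equal(cg$diff, 80)
  expect_true(cg$is_asm)

  # 80 % vs 20 % -> diff 60, below the threshold
  fx2 <- make_asm_fixture(meth_alt = 4L, meth_ref = 1L)
  v2 <- call_variant_candidates(fx2$placements, fx2$ref, params)
  rec2 <- asm_scan(v2, fx2$placements, fx2$ref, params)
  expect_false(any(rec2$is_asm))

  # coverage 4 in one group -> cytosine not emitted at all
  fx3 <- make_asm_fixture(n_ref = 4L, meth_ref = 0L)
  v3 <- call_variant_candidates(fx3$placements, fx3$ref, params)
  rec3 <- asm_scan(v3, fx3$placements, fx3$ref, params)
  expect_identical(nrow(rec3[rec3$cyt_pos0 == 10L, ]), 0L)
})

test_that("swapping ref and alt labels swaps groups but not the ASM verdict", {
  params <- pipeline_params()
  fx <- make_asm_fixture()
  v <- call_variant_candidates(fx$placements, fx$ref, params)
  swapped <- v
  swapped$ref_base <- v$alt_base
  swapped$alt_base <- v$ref_base
  g1 <- group_pairs_by_allele(v[1L, ], fx$placements, fx$ref)
  g2 <- group_pairs_by_allele(swapped[1L, ], fx$placements, fx$ref)
  expect_setequal(g1$with_alt, g2$without_alt)
  expect_setequal(g1$without_alt, g2$with_alt)
  r1 <- asm_scan(v, fx$placements, fx$ref, params)
  r2 <- asm_scan(swapped, fx$placements, fx$ref, params)
  expect_equal(r1$diff, r2$diff)
  expect_identical(r1$is_asm, r2$is_asm)
})

test_that("planted variants and ASM loci are recovered from simulation", {
  cfg <- exact_sim_config(n_pairs = 9000L, genome_length = 30000L,
                          n_het_snv = 5L, n_asm_loci = 1L,
                          lambda_fraction = 0, seed = 21L)
  sim <- simulate_gps(cfg)
  params <- pipeline_params()
  pre <- preprocess_pairs(sim$pairs, params)
  pl <- align_pairs(pre$pairs, pre$boundaries, sim$ref, params)
  v <- call_variant_candidates(pl, sim$ref, params)
  truth <- sim$variants
  # every call is a planted site (no false positives without errors) and
  # most planted sites are recovered at balanced allele fractions
  expect_true(all(paste(v$contig, v$pos0, v$alt_base) %in%
                  paste(truth$contig, truth$pos0, truth$alt_base)))
  found <- paste(truth$contig, truth$pos0) %in% paste(v$contig, v$pos0)
  expect_gte(sum(found), 4L)
  frac <- v$alt_count / v$coverage
  se3 <- 3 * sqrt(0.25 / v$coverage)
  expect_true(all(abs(frac - 0.5) <= se3))

  rec <- asm_scan(v, pl, sim$ref, params)
  asm_site <- truth$pos0[truth$is_asm_locus]
  hit <- rec[rec$pos0 == asm_site & rec$is_asm, ]
  expect_gte(nrow(hit), 1L)
  expect_true(all(abs(hit$cyt_pos0 - asm_site) <= cfg$asm_window + 1L))
  neutral <- truth$pos0[!truth$is_asm_locus]
  expect_false(any(rec$is_asm[rec$pos0 %in% neutral]))
})
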