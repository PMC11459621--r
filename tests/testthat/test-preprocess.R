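test_that("quality filter applies the 70 % qualified-base rule per mate", {
  params <- pipeline_params()
  q_ok <- strrep(rawToChar(as.raw(35L + 33L)), 150L)            # all Q35
  mixed <- function(n_hi, n_lo) {
    paste0(strrep(rawToChar(as.raw(40L + 33L)), n_hi),
           strrep(rawToChar(as.raw(2L + 33L)), n_lo))
  }
  pairs <- gps_pairs(
    c("hi", "border", "low", "empty"),
    r1_seq = c(strrep("A", 150L), strrep("A", 150L), strrep("A", 150L), ""),
    r2_seq = c(strrep("A", 150L), strrep("A", 150L), strrep("A", 150L),
               "ACGT"),
    r1_qual = c(q_ok, mixed(120L, 30L), mixed(90L, 60L), ""),
    r2_qual = c(q_ok, mixed(120L, 30L), q_ok, "IIII"))
  res <- quality_filter(pairs, params)
  expect_identical(res$keep, c(TRUE, TRUE, FALSE, FALSE))
  expect_identical(res$reason, c("ok", "ok", "low_quality", "empty"))
})

test_that("deduplication keeps first occurrence, is idempotent, conserves tuples", {
  pairs <- gps_pairs(c("a", "b", "c", "d"),
                     c("ACGT", "ACGT", "ACGT", "ACGT"),
                     c("TTTT", "TTTT", "TTTA", "TTTT"),
                     rep("IIII", 4L), rep("IIII", 4L))
  out <- deduplicate_pairs(pairs)
  expect_identical(out$id, c("a", "c"))
  expect_identical(attr(out, "dropped"), c("b", "d"))
  again <- deduplicate_pairs(out)
  expect_identical(again$id, out$id)
  expect_setequal(paste(out$r1_seq, out$r2_seq),
                  unique(paste(pairs$r1_seq, pairs$r2_seq)))
})

test_that("boundary detection matches its worked examples", {
  params <- pipeline_params()
  b <- detect_r2_boundary(
    c(paste0(strrep("A", 33L), "TG", "TTTTT"),
      paste0("TG", strrep("A", 20L)),
      "CGCGCGCG"), params)
  expect_identical(b$boundary, c(35L, 2L, NA_integer_))
  expect_identical(b$reason, c("ok", "too_short", "no_boundary"))
  expect_identical(b$anchor[1L], paste0(strrep("A", 33L), "TG"))
})

test_that("boundary detection agrees with the exhaustive scan oracle", {
  set.seed(101)
  params <- pipeline_params()
  n_reads <- 1000L
  seqs <- vapply(seq_len(n_reads), function(i) {
    random_dna(sample(1:80, 1L), alphabet = c("A", "C", "G", "T", "N"),
               prob = c(0.24, 0.24, 0.24, 0.24, 0.04))
  }, character(1L))
  got <- detect_r2_boundary(seqs, params)
  for (i in seq_len(n_reads)) {
    exp <- oracle_boundary(seqs[i], params$min_anchor_len)
    expect_identical(got$reason[i], exp$reason)
    if (!is.na(exp$boundary)) expect_identical(got$boundary[i], exp$boundary)
  }
  # structural invariants: anchor is a literal prefix; the suffix past the
  # boundary contains no AG/TG/GG; short anchors always discarded
  kept <- which(!got$discarded)
  for (i in kept) {
    expect_identical(got$anchor[i], substr(seqs[i], 1L, got$boundary[i]))
    suffix <- substr(seqs[i], got$boundary[i] + 1L, nchar(seqs[i]))
    expect_false(grepl("[ATG]G", suffix))
    expect_gte(got$boundary[i], params$min_anchor_len)
  }
})

test_that("boundary on simulated reads never exceeds the true patch extent", {
  cfg <- exact_sim_config(n_pairs = 200L, genome_length = 12000L)
  sim <- simulate_gps(cfg)
  pv <- sim$provenance
  b <- detect_r2_boundary(sim$pairs$r2_seq[match(pv$id, sim$pairs$id)],
                          pipeline_params())
  pp <- ifelse(pv$strand == "+", pv$patch_right, pv$patch_left)
  ok <- !b$discarded
  expect_true(all(b$boundary[ok] <= pp[ok]))
})

test_that("incorporation length follows the non-CpG boundary rules", {
  fwd <- "AATGATACGGCGAC"
  idx <- "CAAGCAGAAGACGG"
  # orientation A: patch at the 3' end; only non-CpG Cs live in the final
  # 40 nt, the 5'-most of them 40 nt from the 3' end
  conv <- strrep("TGTA", 20L)                       # no C, G preceded by T
  patch <- paste0("CA", strrep("TACA", 9L), "AT")   # 40 nt, Cs at non-CpG
  clone <- paste0(fwd, conv, patch, revcomp(idx))
  res <- estimate_incorporation_length(clone, fwd, idx)
  expect_identical(res$orientation, "A")
  expect_identical(res$length, 40L)
  expect_false(res$resolved_by_ref)

  # orientation B: patch at the 5' end, boundary at the last non-CpG G
  patch_b <- paste0("TG", strrep("TAGA", 9L), "TG") # 40 nt, last G at 40
  conv_b <- strrep("ACTA", 20L)                     # no non-CpG G
  clone_b <- paste0(idx, patch_b, conv_b, revcomp(fwd))
  res_b <- estimate_incorporation_length(clone_b, fwd, idx)
  expect_identical(res_b$orientation, "B")
  expect_identical(res_b$length, 40L)

  # fully converted insert: no evidence of a patch
  res0 <- estimate_incorporation_length(paste0(fwd, conv, revcomp(idx)),
                                        fwd, idx)
  expect_identical(res0$length, 0L)

  expect_error(estimate_incorporation_length("ACGTACGT", fwd, idx),
               "primer not found")
})

test_that("a reference resolves artifactual distal boundary candidates", {
  fwd <- "AATGATACGGCGAC"
  idx <- "CAAGCAGAAGACGG"
  # reference insert: unmethylated non-CpG Cs everywhere except a true
  # 30 nt patch at the 3' end
  set.seed(5)
  ref_insert <- paste0(strrep("CATT", 15L), strrep("CAAT", 7L), "CC")
  n <- nchar(ref_insert)
  true_patch <- 30L
  conv_part <- chartr("C", "T", substr(ref_insert, 1L, n - true_patch))
  read_insert <- paste0(conv_part, substring(ref_insert, n - true_patch + 1L))
  # artifact: a spurious non-CpG C far 5' of the patch
  substr(read_insert, 3L, 3L) <- "C"
  clone <- paste0(fwd, read_insert, revcomp(idx))
  naive <- estimate_incorporation_length(clone, fwd, idx)
  expect_gt(naive$length, true_patch)     # artifact inflates the estimate
  fixed <- estimate_incorporation_length(clone, fwd, idx, ref = ref_insert)
  expect_identical(fixed$length, true_patch)
  expect_true(fixed$resolved_by_ref)
})

test_that("preprocessing accounts for every pair exactly once", {
  cfg <- exact_sim_config(n_pairs = 250L, genome_length = 15000L)
  sim <- simulate_gps(cfg)
  pre <- preprocess_pairs(sim$pairs, pipeline_params())
  expect_identical(nrow(pre$accounting), nrow(sim$pairs))
  expect_true(all(pre$accounting$fate %in%
    c("passed", "dropped_qc", "dropped_duplicate", "dropped_no_boundary",
      "dropped_short_anchor")))
  expect_identical(sum(pre$accounting$fate == "passed"), nrow(pre$pairs))
  expect_true(all(diff(unname(pre$counts)) <= 0))  # monotone counters
})
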