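## Quality filtering, exact duplicate removal, Read2 treatment-boundary
## detection, and the Sanger-clone incorporation-length estimator.

#' Pipeline parameters
#'
#' Defaults follow the protocol's quoted values: Phred cutoff 35 with at
#' least 70 % qualified bases per mate, anchors shorter than 35 nt
#' discarded, up to 20 reported anchor alignments, mate pairing within
#' 1 kb, Smith-Waterman scoring 5/0/-6, and ASM thresholds of a 70
#' percentage-point difference at 5x coverage per allele group.
#'
#' @param qc_qual_cutoff Phred score a base must reach to count as
#'   qualified.
#' @param qc_min_fraction Minimum fraction of qualified bases per mate.
#' @param min_anchor_len Minimum Read2 anchor length (nt); shorter anchors
#'   are discarded.
#' @param max_hits Maximum number of anchor placements reported per read.
#' @param max_pair_distance Maximum R1-R2 distance on the reference (bp).
#' @param min_sw_score Minimum Smith-Waterman score for a reported
#'   placement (100 corresponds to 20 matched bases).
#' @param asm_min_diff Minimum absolute methylation difference between
#'   allele groups (percentage points).
#' @param asm_min_cov Minimum read coverage per allele group.
#' @param trim_default_len Nominal usable Read1 length (nt); recorded for
#'   configuration compatibility, the alignment-based trimmer in
#'   [trim_paired()] supersedes it.
#' @param min_alt_count,min_alt_fraction Candidate-variant filters applied
#'   by [call_variant_candidates()].
#' @param sw_match,sw_mismatch,sw_gap Smith-Waterman scores (match bonus,
#'   mismatch score, per-base gap penalty).
#' @param seed_k Exact seed k-mer length used by the built-in anchor
#'   aligner.
#' @param strict_noncpg_trim When `TRUE`, the Read1 boundary scan in
#'   [trim_paired()] counts only non-CpG conversions as evidence.
#' @param seed Integer seed for any stochastic step.
#' @return A validated list of class `gps_params`.
#' @export
pipeline_params <- function(qc_qual_cutoff = 35L, qc_min_fraction = 0.70,
                            min_anchor_len = 35L, max_hits = 20L,
                            max_pair_distance = 1000L, min_sw_score = 100,
                            asm_min_diff = 70, asm_min_cov = 5L,
                            trim_default_len = 100L, min_alt_count = 2L,
                            min_alt_fraction = 0.1, sw_match = 5L,
                            sw_mismatch = 0L, sw_gap = -6L, seed_k = 20L,
                            strict_noncpg_trim = FALSE, seed = 1L) {
  p <- list(qc_qual_cutoff = as.integer(qc_qual_cutoff),
            qc_min_fraction = qc_min_fraction,
            min_anchor_len = as.integer(min_anchor_len),
            max_hits = as.integer(max_hits),
            max_pair_distance = as.integer(max_pair_distance),
            min_sw_score = min_sw_score, asm_min_diff = asm_min_diff,
            asm_min_cov = as.integer(asm_min_cov),
            trim_default_len = as.integer(trim_default_len),
            min_alt_count = as.integer(min_alt_count),
            min_alt_fraction = min_alt_fraction,
            sw_match = as.integer(sw_match),
            sw_mismatch = as.integer(sw_mismatch),
            sw_gap = as.integer(sw_gap), seed_k = as.integer(seed_k),
            strict_noncpg_trim = isTRUE(strict_noncpg_trim),
            seed = as.integer(seed))
  if (p$qc_min_fraction < 0 || p$qc_min_fraction > 1) {
    stop("qc_min_fraction must lie in [0,1]")
  }
  nonneg <- c("qc_qual_cutoff", "min_anchor_len", "max_hits",
              "max_pair_distance", "min_sw_score", "asm_min_diff",
              "asm_min_cov", "trim_default_len", "min_alt_count")
  bad <- vapply(p[nonneg], function(v) v < 0, logical(1L))
  if (any(bad)) stop("negative threshold: ", names(bad)[bad][1L])
  structure(p, class = "gps_params")
}

#' Quality-filter read pairs
#'
#' A pair is kept iff for both mates the fraction of bases at or above
#' `qc_qual_cutoff` is at least `qc_min_fraction`; a zero-length mate drops
#' the pair.
#'
#' @param pairs A [gps_pairs()] table.
#' @param params A [pipeline_params()].
#' @return A `data.frame` with one row per pair: `id`, `keep`, `reason`
#'   (`"ok"`, `"low_quality"` or `"empty"`).
#' @export
quality_filter <- function(pairs, params = pipeline_params()) {
  frac_ok <- function(qual) {
    vapply(qual, function(s) {
      n <- nchar(s)
      if (n == 0L) return(NA_real_)
      sum(utf8ToInt(s) - 33L >= params$qc_qual_cutoff) / n
    }, numeric(1L), USE.NAMES = FALSE)
  }
  f1 <- frac_ok(pairs$r1_qual)
  f2 <- frac_ok(pairs$r2_qual)
  empty <- is.na(f1) | is.na(f2)
  keep <- !empty & f1 >= params$qc_min_fraction & f2 >= params$qc_min_fraction
  reason <- ifelse(empty, "empty", ifelse(keep, "ok", "low_quality"))
  data.frame(id = pairs$id, keep = keep, reason = reason,
             stringsAsFactors = FALSE)
}

#' Remove exact sequencing duplicates
#'
#' Among pairs with identical `(r1_seq, r2_seq)` tuples exactly the first
#' occurrence (in input order) survives; output order is the input order of
#' survivors.  Keys on sequence identity, not on alignment coordinates,
#' matching duplicate removal on pasted sequence lines.
#'
#' @param pairs A [gps_pairs()] table.
#' @return The deduplicated [gps_pairs()] table, with the ids of removed
#'   rows in `attr(, "dropped")`.
#' @export
deduplicate_pairs <- function(pairs) {
  dup <- duplicated(paste(pairs$r1_seq, pairs$r2_seq, sep = "\r"))
  out <- pairs[!dup, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("gps_pairs", "data.frame")
  attr(out, "dropped") <- pairs$id[dup]
  out
}

#' Detect the T4 treatment boundary on Read2
#'
#' Scans each read 5'->3' for the last `5'-[A/T/G]G-3'` dinucleotide (a
#' guanine not preceded by C, i.e. a retained non-CpG cytosine on the
#' read's strand).  The boundary index is one past that G, which is
#' included in the anchor; reads with no such dinucleotide, or an anchor
#' shorter than `min_anchor_len`, are discarded with a reason.
#'
#' @param r2_seq Character vector of Read2 sequences.
#' @param params A [pipeline_params()].
#' @return A `data.frame`: `boundary` (0-based index one past the anchor,
#'   `NA` if none), `anchor` (the protected prefix, `NA` if discarded),
#'   `discarded`, `reason` (`"ok"`, `"no_boundary"`, `"too_short"`).
#' @export
detect_r2_boundary <- function(r2_seq, params = pipeline_params()) {
  r2_seq <- as.character(r2_seq)
  hits <- gregexpr("(?=[ATG]G)", r2_seq, perl = TRUE)
  last <- vapply(hits, function(h) {
    if (h[1L] == -1L) NA_integer_ else as.integer(h[length(h)])
  }, integer(1L))
  boundary <- last + 1L                 # 0-based, one past the included G
  reason <- ifelse(is.na(boundary), "no_boundary",
                   ifelse(boundary < params$min_anchor_len, "too_short",
                          "ok"))
  discarded <- reason != "ok"
  anchor <- ifelse(discarded, NA_character_,
                   substr(r2_seq, 1L, boundary))
  data.frame(boundary = boundary, anchor = anchor, discarded = discarded,
             reason = reason, stringsAsFactors = FALSE)
}

.find_all_fixed <- function(hay, needle) {
  h <- gregexpr(needle, hay, fixed = TRUE)[[1L]]
  if (h[1L] == -1L) integer() else as.integer(h)
}

#' Estimate the 5mC incorporation length from a Sanger clone
#'
#' Reconstructs the T4 patch length from a cloned pre-amplification library
#' fragment.  The insert is delimited by the forward PCR primer and the
#' reverse complement of the index primer (orientation A) or the index
#' primer and the reverse complement of the forward primer (orientation B).
#' In orientation A the patch sits at the insert's 3' end and its length is
#' counted from the 3' end to the last non-CpG C encountered scanning
#' 3'->5' (inclusive); in orientation B the patch sits at the 5' end and
#' the length runs from the 5' end to the last non-CpG G scanning 5'->3'
#' (inclusive).  When a reference sequence is supplied, the insert is
#' aligned to it and boundary candidates lying beyond positions whose
#' C-to-T (or G-to-A) mismatch proves bisulfite conversion are discarded,
#' which resolves sequencing artifacts at the distal end.
#'
#' @param clone_seq Sanger read of the clone.
#' @param primer_fwd,primer_idx The two PCR primer sequences.
#' @param ref Optional reference sequence covering the insert.
#' @return A list: `length` (nt), `orientation` (`"A"` or `"B"`),
#'   `resolved_by_ref`.
#' @export
estimate_incorporation_length <- function(clone_seq, primer_fwd, primer_idx,
                                          ref = NULL) {
  clone_seq <- toupper(clone_seq)
  primer_fwd <- toupper(primer_fwd)
  primer_idx <- toupper(primer_idx)

  locate <- function(p5, p3) {
    a <- .find_all_fixed(clone_seq, p5)
    b <- .find_all_fixed(clone_seq, p3)
    if (!length(a) || !length(b)) return(NULL)
    s <- a[1L] + nchar(p5)            # 1-based first insert base
    e <- b[b >= s]                     # primer must follow the insert
    if (!length(e)) return(NULL)
    c(s, e[1L] - 1L)                   # 1-based inclusive insert span
  }
  span <- locate(primer_fwd, revcomp(primer_idx))
  orientation <- "A"
  if (is.null(span)) {
    span <- locate(primer_idx, revcomp(primer_fwd))
    orientation <- "B"
  }
  if (is.null(span)) stop("primer not found in clone sequence")
  if (span[2L] < span[1L]) stop("insert empty")
  insert <- substr(clone_seq, span[1L], span[2L])
  n <- nchar(insert)
  b <- charToRaw(insert)
  ## context uses the clone continuation so terminal bases are classified
  nxt <- if (span[2L] < nchar(clone_seq)) {
    charToRaw(substr(clone_seq, span[2L] + 1L, span[2L] + 1L))
  } else charToRaw("N")
  prv <- if (span[1L] > 1L) {
    charToRaw(substr(clone_seq, span[1L] - 1L, span[1L] - 1L))
  } else charToRaw("N")
  follower <- c(b[-1L], nxt)
  preceder <- c(prv, b[-n])
  noncpg_c <- which(b == charToRaw("C") & follower != charToRaw("G")) # 1-based
  noncpg_g <- which(b == charToRaw("G") & preceder != charToRaw("C"))

  naive_len <- function(cpos, gpos) {
    if (orientation == "A") {
      if (!length(cpos)) 0L else n - min(cpos) + 1L
    } else {
      if (!length(gpos)) 0L else max(gpos)
    }
  }
  len <- naive_len(noncpg_c, noncpg_g)
  resolved <- FALSE
  if (!is.null(ref)) {
    ref <- toupper(ref)
    aln <- sw_local(insert, ref, scoring_scheme())
    cols <- .cigar_columns(aln$cigar)
    q <- cols$q + aln$q_off + 1L                 # 1-based insert coords
    t <- cols$t + aln$t_off + 1L                 # 1-based ref coords
    rb <- charToRaw(ref)
    qb <- b[q]
    tb <- rb[t]
    tnext <- rb[pmin(t + 1L, length(rb))]
    tprev <- rb[pmax(t - 1L, 1L)]
    if (orientation == "A") {
      ## read T over reference non-CpG C proves conversion 5' of the patch
      ev <- q[qb == charToRaw("T") & tb == charToRaw("C") &
                tnext != charToRaw("G")]
      if (length(ev)) {
        keep <- noncpg_c[noncpg_c > max(ev)]
        new_len <- if (!length(keep)) 0L else n - min(keep) + 1L
        if (new_len != len) resolved <- TRUE
        len <- new_len
      }
    } else {
      ## read A over reference non-CpG G proves conversion 3' of the patch
      ev <- q[qb == charToRaw("A") & tb == charToRaw("G") &
                tprev != charToRaw("C")]
      if (length(ev)) {
        keep <- noncpg_g[noncpg_g < min(ev)]
        new_len <- if (!length(keep)) 0L else max(keep)
        if (new_len != len) resolved <- TRUE
        len <- new_len
      }
    }
  }
  list(length = as.integer(len), orientation = orientation,
       resolved_by_ref = resolved)
}

#' Run the full preprocessing stage
#'
#' Quality filter, exact duplicate removal and Read2 boundary detection, in
#' the pipeline's order, with per-pair accounting.
#'
#' @param pairs A [gps_pairs()] table.
#' @param params A [pipeline_params()].
#' @return A list: `pairs` (surviving pairs with a usable anchor),
#'   `boundaries` (their boundary annotations, with `id`), `accounting`
#'   (`id`, `fate` in `dropped_qc / dropped_duplicate / dropped_no_boundary
#'   / dropped_short_anchor / passed`), `counts` (stage counters).
#' @export
preprocess_pairs <- function(pairs, params = pipeline_params()) {
  qc <- quality_filter(pairs, params)
  fate <- setNames(rep("passed", nrow(pairs)), pairs$id)
  fate[!qc$keep] <- "dropped_qc"
  kept <- pairs[qc$keep, , drop = FALSE]
  class(kept) <- c("gps_pairs", "data.frame")

  dd <- deduplicate_pairs(kept)
  fate[attr(dd, "dropped")] <- "dropped_duplicate"

  bnd <- detect_r2_boundary(dd$r2_seq, params)
  fate[dd$id[bnd$reason == "no_boundary"]] <- "dropped_no_boundary"
  fate[dd$id[bnd$reason == "too_short"]] <- "dropped_short_anchor"

  ok <- !bnd$discarded
  out_pairs <- dd[ok, , drop = FALSE]
  rownames(out_pairs) <- NULL
  class(out_pairs) <- c("gps_pairs", "data.frame")
  boundaries <- cbind(data.frame(id = dd$id[ok], stringsAsFactors = FALSE),
                      bnd[ok, , drop = FALSE])
  rownames(boundaries) <- NULL
  counts <- c(pairs_in = nrow(pairs), qc_pass = nrow(kept),
              dedup_out = nrow(dd), boundary_ok = nrow(out_pairs))
  list(pairs = out_pairs, boundaries = boundaries,
       accounting = data.frame(id = pairs$id, fate = unname(fate[pairs$id]),
                               stringsAsFactors = FALSE),
       counts = counts)
}
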