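## Anchor-guided alignment: Smith-Waterman core, exact-seed anchor
## placement, Read1 positioning within 1 kb of each anchor, and trimming of
## both mates to their treatment-consistent spans.

.MODE_INT <- c(off = 0L, CT = 1L, GA = 2L)

#' Smith-Waterman scoring scheme
#'
#' The protocol's scoring: +5 per matching base, 0 for a mismatch, -6 per
#' gapped base (linear).  In `CT` mode a read T over a reference C scores
#' as a match (bisulfite conversion on the plus strand); in `GA` mode a
#' read A over a reference G does (minus strand).  The wildcards are
#' asymmetric: the reverse pairings do not match.
#'
#' @param match Match bonus.
#' @param mismatch Mismatch score.
#' @param gap_per_base Per-base gap score (negative).
#' @param bisulfite_mode One of `"off"`, `"CT"`, `"GA"`.
#' @return A list of class `gps_scoring`.
#' @export
scoring_scheme <- function(match = 5L, mismatch = 0L, gap_per_base = -6L,
                           bisulfite_mode = c("off", "CT", "GA")) {
  bisulfite_mode <- match.arg(bisulfite_mode)
  structure(list(match = as.integer(match), mismatch = as.integer(mismatch),
                 gap_per_base = as.integer(gap_per_base),
                 bisulfite_mode = bisulfite_mode), class = "gps_scoring")
}

.scheme_from_params <- function(params, mode = "off") {
  scoring_scheme(params$sw_match, params$sw_mismatch, params$sw_gap, mode)
}

#' Smith-Waterman local alignment
#'
#' Maximal-scoring local alignment of `query` against `target` under a
#' [scoring_scheme()], with all DP cells floored at zero.  Co-optimal
#' alignments are resolved deterministically: smallest target offset, then
#' smallest query offset, then fewest gapped bases.
#'
#' @param query,target Non-empty DNA strings.
#' @param scheme A [scoring_scheme()].
#' @return A list: `score`, `q_off`, `t_off`, `q_end`, `t_end` (0-based
#'   half-open offsets of the aligned region), `cigar` (`M`/`I`/`D` over
#'   the aligned region), `ngaps`.
#' @export
sw_local <- function(query, target, scheme = scoring_scheme()) {
  stopifnot(nchar(query) > 0L, nchar(target) > 0L)
  cpp_sw_local(toupper(query), toupper(target), scheme$match,
               scheme$mismatch, scheme$gap_per_base,
               .MODE_INT[[scheme$bisulfite_mode]])
}

## SW-verify candidate starts for one oriented query on one contig
.verify_candidates <- function(query, starts, contig, contig_seq, strand,
                               params, pad = 8L) {
  out <- vector("list", length(starts))
  qlen <- nchar(query)
  clen <- nchar(contig_seq)
  for (k in seq_along(starts)) {
    s <- starts[k]
    ws <- max(0L, s - pad)
    we <- min(clen, s + qlen + pad)
    if (we - ws < params$seed_k) next
    res <- cpp_sw_local(query, substr(contig_seq, ws + 1L, we),
                        params$sw_match, params$sw_mismatch, params$sw_gap,
                        0L)
    if (res$score < params$min_sw_score) next
    out[[k]] <- list(contig = contig, start0 = ws + res$t_off,
                     end0 = ws + res$t_end, strand = strand,
                     score = res$score, cigar = res$cigar,
                     qoff = res$q_off, qend = res$q_end, query = query)
  }
  out[!vapply(out, is.null, logical(1L))]
}

## rank, deduplicate and truncate candidate placement rows (plain lists —
## the hot path avoids data.frame construction per pair)
.rank_rows <- function(rows, params) {
  if (!length(rows)) return(rows)
  contig <- vapply(rows, `[[`, character(1L), "contig")
  start0 <- vapply(rows, `[[`, integer(1L), "start0")
  strand <- vapply(rows, `[[`, character(1L), "strand")
  score <- vapply(rows, function(r) as.numeric(r$score), numeric(1L))
  ## deduplicate identical placements found from different seeds
  o <- order(contig, start0, strand, -score)
  keep <- o[!duplicated(paste(contig[o], start0[o], strand[o]))]
  o2 <- keep[order(-score[keep], contig[keep], start0[keep],
                   match(strand[keep], c("+", "-")))]
  nc <- sum(score[o2] == score[o2[1L]])
  rows <- rows[utils::head(o2, params$max_hits)]
  for (k in seq_along(rows)) rows[[k]]$n_candidates <- nc
  rows
}

.placement_df <- function(rows, params) {
  rows <- .rank_rows(rows, params)
  if (!length(rows)) {
    return(data.frame(contig = character(), start0 = integer(),
                      end0 = integer(), strand = character(),
                      score = integer(), cigar = character(),
                      qoff = integer(), qend = integer(),
                      query = character(), n_candidates = integer(),
                      stringsAsFactors = FALSE))
  }
  df <- data.table::setDF(data.table::rbindlist(rows))
  rownames(df) <- NULL
  df
}

#' Align a Read2 anchor to the reference
#'
#' Candidate locations are found by exact k-mer seeding (`seed_k`-mers from
#' the anchor's start, middle and end, both strands), then scored with
#' [sw_local()] without bisulfite wildcards.  Placements scoring at least
#' `min_sw_score` are returned best-first, truncated at `max_hits`.
#' `start0`/`end0` are always in plus-strand reference coordinates; strand
#' `"-"` means the reverse complement of the anchor matched.
#'
#' @param anchor_seq The protected Read2 prefix.
#' @param ref A [reference_set()].
#' @param params A [pipeline_params()].
#' @return A `data.frame` of placements: `contig, start0, end0, strand,
#'   score, cigar, qoff, qend, query, n_candidates`.
#' @export
anchor_align <- function(anchor_seq, ref, params = pipeline_params()) {
  anchor_seq <- toupper(anchor_seq)
  rc <- revcomp(anchor_seq)
  rows <- list()
  for (nm in names(ref$contigs)) {
    cs <- ref$contigs[[nm]]
    hits <- cpp_seed_hits(c(anchor_seq, rc), cs, params$seed_k)
    rows <- c(rows,
              .verify_candidates(anchor_seq, hits[[1L]], nm, cs, "+", params),
              .verify_candidates(rc, hits[[2L]], nm, cs, "-", params))
  }
  .placement_df(rows, params)
}

## core of position_r1/trim_paired; `placements` is a list of row-lists
## (fast path for the align_pairs loop)
.position_r1_core <- function(r1_seq, r1_rc, placements, ref, params) {
  n <- length(placements)
  scores <- numeric(n)
  res_list <- vector("list", n)
  wstarts <- integer(n)
  frag_strand <- character(n)
  for (i in seq_len(n)) {
    p <- placements[[i]]
    cs <- ref$contigs[[p$contig]]
    clen <- nchar(cs)
    if (p$strand == "-") {
      ## anchor on minus strand: fragment is plus; window extends leftward
      ws <- max(0L, p$end0 - params$max_pair_distance)
      we <- p$end0
      q <- r1_seq; mode <- 1L; frag_strand[i] <- "+"
    } else {
      ws <- p$start0
      we <- min(clen, p$start0 + params$max_pair_distance)
      q <- r1_rc; mode <- 2L; frag_strand[i] <- "-"
    }
    if (we <= ws) { scores[i] <- -Inf; next }
    res <- cpp_sw_local(q, substr(cs, ws + 1L, we), params$sw_match,
                        params$sw_mismatch, params$sw_gap, mode)
    scores[i] <- res$score
    res_list[[i]] <- res
    wstarts[i] <- ws
  }
  best <- max(scores)
  if (best < params$min_sw_score) return(list(status = "low_score"))
  if (sum(scores == best) > 1L) return(list(status = "ambiguous"))
  i <- which.max(scores)
  p <- placements[[i]]
  res <- res_list[[i]]
  r1_aln_start0 <- wstarts[i] + res$t_off
  r1_aln_end0 <- wstarts[i] + res$t_end
  list(status = "placed", contig = p$contig, frag_strand = frag_strand[i],
       r2_strand = p$strand, r2_start0 = p$start0, r2_end0 = p$end0,
       r2_score = p$score, r2_cigar = p$cigar, r2_qoff = p$qoff,
       r2_qend = p$qend, anchor_query = p$query,
       anchor_len = nchar(p$query), n_candidates = p$n_candidates,
       r1_query = if (frag_strand[i] == "+") r1_seq else r1_rc,
       r1_len = nchar(r1_seq), r1_aln_start0 = r1_aln_start0,
       r1_aln_end0 = r1_aln_end0, r1_score = res$score,
       r1_cigar = res$cigar, r1_qoff = res$q_off, r1_qend = res$q_end,
       pair_distance = max(r1_aln_end0, p$end0) - min(r1_aln_start0,
                                                      p$start0))
}

#' Position Read1 relative to its mate's anchor placements
#'
#' For each anchor placement a reference window extending
#' `max_pair_distance` bp in the inward direction is extracted and Read1 is
#' aligned with [sw_local()] in the bisulfite mode implied by the fragment
#' strand (`CT` for plus-strand fragments; `GA` via the reverse complement
#' for minus-strand fragments).  The placement pair with the maximal Read1
#' score wins; ties across windows are reported as ambiguous, scores below
#' `min_sw_score` as low-score.
#'
#' @param r1_seq The Read1 sequence.
#' @param r2_placements Placements from [anchor_align()] (at least one row).
#' @param ref A [reference_set()].
#' @param params A [pipeline_params()].
#' @return A one-row `data.frame` (a paired placement) with
#'   `status = "placed"`, or a one-row `data.frame` whose `status` is
#'   `"ambiguous"` or `"low_score"`.
#' @export
position_r1 <- function(r1_seq, r2_placements, ref,
                        params = pipeline_params()) {
  stopifnot(nrow(r2_placements) >= 1L)
  r1_seq <- toupper(r1_seq)
  rows <- lapply(seq_len(nrow(r2_placements)), function(i) {
    as.list(r2_placements[i, ])
  })
  core <- .position_r1_core(r1_seq, revcomp(r1_seq), rows, ref, params)
  data.table::setDF(data.table::rbindlist(list(core), fill = TRUE))
}

.trim_core <- function(pp, ref, boundary, params) {
  rb <- charToRaw(ref$contigs[[pp$contig]])
  cols <- .cigar_columns(pp$r1_cigar)
  qpos <- cols$q + pp$r1_qoff
  tpos <- cols$t + pp$r1_aln_start0
  refb <- rb[tpos + 1L]
  qb <- charToRaw(pp$r1_query)[qpos + 1L]
  rawC <- charToRaw("C"); rawG <- charToRaw("G")
  rawT <- charToRaw("T"); rawA <- charToRaw("A")
  len <- pp$r1_len
  if (pp$frag_strand == "+") {
    informative <- refb == rawC
    if (params$strict_noncpg_trim) {
      nxt <- rb[pmin(tpos + 2L, length(rb))]
      informative <- informative & nxt != rawG
    }
    if (!any(informative)) {
      k <- len                       # no reference C: no over-cut evidence
    } else {
      ev <- informative & qb == rawT
      k <- if (!any(ev)) 0L else max(qpos[ev]) + 1L
    }
  } else {
    informative <- refb == rawG
    if (params$strict_noncpg_trim) {
      prv <- rb[pmax(tpos, 1L)]
      informative <- informative & prv != rawC
    }
    if (!any(informative)) {
      k <- len
    } else {
      ev <- informative & qb == rawA
      ## aligned query is revcomp(R1): original 3'->5' scan is ascending q
      k <- if (!any(ev)) 0L else len - min(qpos[ev])
    }
  }
  list(r1_keep = as.integer(k), r2_keep = as.integer(boundary))
}

#' Trim a paired placement to its treatment-consistent spans
#'
#' Read2's keep-span is its protected prefix `[0, boundary)` — the
#' converted tail is insufficiently cut material, unusable for variants.
#' Read1 is scanned 3'->5' along its alignment for the first bisulfite
#' conversion (read T over reference C for plus-strand fragments, read A
#' over reference G for minus); everything 3' of that first conversion is
#' potentially 5mC-patched and is trimmed.  A read with no conversion
#' anywhere is wholly unusable (`r1_keep = 0`); a read whose alignment
#' covers no reference cytosine carries no over-cut evidence and is kept
#' whole.
#'
#' @param paired_placement A one-row placed result from [position_r1()].
#' @param ref A [reference_set()].
#' @param boundary The Read2 boundary from [detect_r2_boundary()].
#' @param params A [pipeline_params()].
#' @return The paired placement with `r1_keep` and `r2_keep` columns set
#'   (keep-spans are `[0, k)` in original read coordinates).
#' @export
trim_paired <- function(paired_placement, ref, boundary,
                        params = pipeline_params()) {
  stopifnot(identical(paired_placement$status, "placed"))
  tr <- .trim_core(paired_placement, ref, boundary, params)
  paired_placement$r1_keep <- tr$r1_keep
  paired_placement$r2_keep <- tr$r2_keep
  paired_placement
}

#' Align all preprocessed pairs
#'
#' Batch driver: seeds every anchor against every contig, SW-verifies the
#' candidates, positions each Read1 inside its mate's 1 kb window and trims
#' both mates.  Optionally ingests externally produced anchor alignments
#' from a SAM file instead of the built-in seeder.
#'
#' @param pairs Surviving pairs from [preprocess_pairs()].
#' @param boundaries Their boundary annotations (same order, with `id`).
#' @param ref A [reference_set()].
#' @param params A [pipeline_params()].
#' @param anchor_sam Optional path to a SAM file of anchor alignments.
#' @return A `data.frame` of class `gps_placements`, one row per pair, with
#'   `status` in `placed / unanchored / ambiguous / low_score` and, for
#'   placed rows, the full paired-placement fields including keep-spans.
#' @export
align_pairs <- function(pairs, boundaries, ref, params = pipeline_params(),
                        anchor_sam = NULL) {
  stopifnot(nrow(pairs) == nrow(boundaries))
  n <- nrow(pairs)
  anchors <- boundaries$anchor
  rc_anchors <- revcomp(anchors)
  r1_rc <- revcomp(pairs$r1_seq)

  sam_by_id <- NULL
  hits_f <- hits_r <- NULL
  if (!is.null(anchor_sam)) {
    sam <- read_anchor_sam(anchor_sam, ref)
    sam_rows <- lapply(seq_len(nrow(sam)), function(k) {
      list(contig = sam$contig[k], start0 = sam$start0[k],
           end0 = sam$end0[k], strand = sam$strand[k],
           score = if (is.na(sam$score[k])) params$min_sw_score else
             sam$score[k],
           cigar = sam$cigar[k], qoff = sam$qoff[k], qend = sam$qend[k],
           query = sam$seq[k])
    })
    sam_by_id <- split(sam_rows, sam$id)
  } else {
    hits_f <- lapply(names(ref$contigs), function(nm) {
      cpp_seed_hits(anchors, ref$contigs[[nm]], params$seed_k)
    })
    hits_r <- lapply(names(ref$contigs), function(nm) {
      cpp_seed_hits(rc_anchors, ref$contigs[[nm]], params$seed_k)
    })
    names(hits_f) <- names(hits_r) <- names(ref$contigs)
  }

  rows <- vector("list", n)
  for (i in seq_len(n)) {
    if (!is.null(sam_by_id)) {
      pl <- sam_by_id[[pairs$id[i]]]
      if (is.null(pl) || !length(pl)) {
        rows[[i]] <- list(id = pairs$id[i], status = "unanchored")
        next
      }
      for (k in seq_along(pl)) pl[[k]]$n_candidates <- length(pl)
    } else {
      cand <- list()
      for (nm in names(ref$contigs)) {
        cs <- ref$contigs[[nm]]
        cand <- c(cand,
                  .verify_candidates(anchors[i], hits_f[[nm]][[i]], nm, cs,
                                     "+", params),
                  .verify_candidates(rc_anchors[i], hits_r[[nm]][[i]], nm,
                                     cs, "-", params))
      }
      pl <- .rank_rows(cand, params)
      if (!length(pl)) {
        rows[[i]] <- list(id = pairs$id[i], status = "unanchored")
        next
      }
    }
    core <- .position_r1_core(pairs$r1_seq[i], r1_rc[i], pl, ref, params)
    if (!identical(core$status, "placed")) {
      rows[[i]] <- c(list(id = pairs$id[i]), core)
      next
    }
    tr <- .trim_core(core, ref, boundaries$boundary[i], params)
    rows[[i]] <- c(list(id = pairs$id[i]), core, tr)
  }
  out <- data.table::setDF(data.table::rbindlist(rows, fill = TRUE))
  class(out) <- c("gps_placements", "data.frame")
  out
}
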