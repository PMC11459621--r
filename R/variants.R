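## Candidate variant calling from protected Read2 segments, and
## allele-specific methylation detection by contrasting Read1 methylation
## between allele groups.

## one row per aligned protected Read2 base: id, contig, pos0, base
.r2_base_table <- function(placements, ref) {
  pl <- placements[placements$status == "placed", , drop = FALSE]
  acc <- vector("list", nrow(pl))
  for (i in seq_len(nrow(pl))) {
    p <- pl[i, ]
    cols <- .cigar_columns(p$r2_cigar)
    if (!length(cols$q)) next
    qpos <- cols$q + p$r2_qoff
    tpos <- cols$t + p$r2_start0
    base <- substring(p$anchor_query, qpos + 1L, qpos + 1L)
    acc[[i]] <- list(id = p$id, contig = p$contig, pos0 = tpos, base = base)
  }
  acc <- acc[!vapply(acc, is.null, logical(1L))]
  if (!length(acc)) {
    return(data.table::data.table(id = character(), contig = character(),
                                  pos0 = integer(), base = character()))
  }
  data.table::rbindlist(acc)
}

#' Call candidate variant sites from protected Read2 segments
#'
#' Piles up the aligned protected-prefix bases (bases beyond the Read2
#' treatment boundary never contribute) and reports one record per
#' `(site, alt_base)` when the alternate allele is seen at least
#' `min_alt_count` times and at a fraction of at least `min_alt_fraction`
#' of the A/C/G/T coverage.
#'
#' @param placements Placements from [align_pairs()].
#' @param ref A [reference_set()].
#' @param params A [pipeline_params()].
#' @return A `data.frame` of variant sites: `contig, pos0, ref_base,
#'   alt_base, coverage, alt_count`, sorted by position.
#' @export
call_variant_candidates <- function(placements, ref,
                                    params = pipeline_params()) {
  tbl <- .r2_base_table(placements, ref)
  empty <- data.frame(contig = character(), pos0 = integer(),
                      ref_base = character(), alt_base = character(),
                      coverage = integer(), alt_count = integer(),
                      stringsAsFactors = FALSE)
  if (!nrow(tbl)) return(empty)
  tbl <- tbl[tbl$base %in% .BASES, ]
  if (!nrow(tbl)) return(empty)
  cnt <- tbl[, list(n = .N), by = c("contig", "pos0", "base")]
  cov <- cnt[, list(coverage = sum(n)), by = c("contig", "pos0")]
  cnt <- merge(cnt, cov, by = c("contig", "pos0"))
  cnt <- as.data.frame(cnt)
  refb <- vapply(seq_len(nrow(cnt)), function(i) {
    substr(ref$contigs[[cnt$contig[i]]], cnt$pos0[i] + 1L, cnt$pos0[i] + 1L)
  }, character(1L))
  keep <- cnt$base != refb & cnt$n >= params$min_alt_count &
    cnt$n / cnt$coverage >= params$min_alt_fraction
  out <- data.frame(contig = cnt$contig[keep], pos0 = cnt$pos0[keep],
                    ref_base = refb[keep], alt_base = cnt$base[keep],
                    coverage = cnt$coverage[keep], alt_count = cnt$n[keep],
                    stringsAsFactors = FALSE)
  out <- out[order(out$contig, out$pos0, out$alt_base), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Partition pairs by the allele their protected base carries
#'
#' A pair joins the alt group iff its protected Read2 base at the site
#' equals `alt_base`, the ref group iff it equals `ref_base`; any other
#' base (including N) or no protected coverage joins neither.  The groups
#' are disjoint.
#'
#' @param site A one-row variant site (from [call_variant_candidates()]).
#' @param placements Placements from [align_pairs()].
#' @param ref A [reference_set()].
#' @return A list with character vectors `with_alt` and `without_alt` of
#'   pair ids.
#' @export
group_pairs_by_allele <- function(site, placements, ref) {
  tbl <- .r2_base_table(placements, ref)
  .group_from_table(site, tbl)
}

.group_from_table <- function(site, tbl) {
  at <- tbl[tbl$contig == site$contig & tbl$pos0 == site$pos0, ]
  with_alt <- unique(at$id[at$base == site$alt_base])
  without_alt <- unique(at$id[at$base == site$ref_base])
  both <- intersect(with_alt, without_alt)
  list(with_alt = setdiff(with_alt, both),
       without_alt = setdiff(without_alt, both))
}

#' Scan variant sites for allele-specific methylation
#'
#' For each site the pairs are partitioned by allele and the methylation
#' pileup is run separately on the two groups' trimmed Read1 spans.  Every
#' cytosine covered at least `asm_min_cov` times in both groups yields a
#' record; it is flagged ASM when additionally the absolute level
#' difference reaches `asm_min_diff` percentage points.
#'
#' @param sites Variant sites from [call_variant_candidates()].
#' @param placements Placements from [align_pairs()].
#' @param ref A [reference_set()].
#' @param params A [pipeline_params()].
#' @return A `data.frame` of ASM records, one per `(site, cytosine)`:
#'   variant columns, `cyt_pos0`, `cyt_strand`, per-group levels and
#'   coverages, `diff`, `is_asm`; sorted by site then cytosine.
#' @export
asm_scan <- function(sites, placements, ref, params = pipeline_params()) {
  empty <- data.frame(contig = character(), pos0 = integer(),
                      ref_base = character(), alt_base = character(),
                      coverage = integer(), alt_count = integer(),
                      cyt_pos0 = integer(), cyt_strand = character(),
                      level_with_alt = numeric(), cov_with_alt = integer(),
                      level_without_alt = numeric(),
                      cov_without_alt = integer(), diff = numeric(),
                      is_asm = logical(), stringsAsFactors = FALSE)
  if (is.null(sites) || !nrow(sites)) return(empty)
  tbl <- .r2_base_table(placements, ref)
  pl <- placements[placements$status == "placed", , drop = FALSE]
  out <- vector("list", nrow(sites))
  for (s in seq_len(nrow(sites))) {
    site <- sites[s, ]
    grp <- .group_from_table(site, tbl)
    if (!length(grp$with_alt) || !length(grp$without_alt)) next
    mw <- pileup_methylation(pl[pl$id %in% grp$with_alt, , drop = FALSE],
                             ref)
    mo <- pileup_methylation(pl[pl$id %in% grp$without_alt, , drop = FALSE],
                             ref)
    if (!nrow(mw) || !nrow(mo)) next
    mw$cov <- mw$count_meth + mw$count_unmeth
    mo$cov <- mo$count_meth + mo$count_unmeth
    m <- merge(mw[mw$cov >= params$asm_min_cov,
                  c("contig", "pos0", "strand", "level_percent", "cov")],
               mo[mo$cov >= params$asm_min_cov,
                  c("contig", "pos0", "strand", "level_percent", "cov")],
               by = c("contig", "pos0", "strand"),
               suffixes = c("_with", "_without"))
    if (!nrow(m)) next
    diff <- abs(m$level_percent_with - m$level_percent_without)
    out[[s]] <- data.frame(
      contig = site$contig, pos0 = site$pos0, ref_base = site$ref_base,
      alt_base = site$alt_base, coverage = site$coverage,
      alt_count = site$alt_count, cyt_pos0 = m$pos0, cyt_strand = m$strand,
      level_with_alt = m$level_percent_with, cov_with_alt = m$cov_with,
      level_without_alt = m$level_percent_without,
      cov_without_alt = m$cov_without, diff = diff,
      is_asm = diff >= params$asm_min_diff &
        m$cov_with >= params$asm_min_cov &
        m$cov_without >= params$asm_min_cov,
      stringsAsFactors = FALSE)
  }
  out <- out[!vapply(out, is.null, logical(1L))]
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  res <- res[order(res$contig, res$pos0, res$alt_base, res$cyt_pos0,
                   res$cyt_strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}
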