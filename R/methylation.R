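## Per-cytosine methylation pileup from trimmed Read1 spans, and spike-in
## conversion-efficiency estimation.

#' Per-cytosine methylation pileup
#'
#' Only Read1 bases inside the trimmed keep-span contribute — Read2's
#' protected prefix is artificially methylated by the 5mC patch and never
#' enters the pileup.  At a reference cytosine on the fragment strand (C on
#' plus, G on minus, in plus-strand reference coordinates) a read C (resp.
#' G) counts as methylated and a read T (resp. A) as unmethylated; any
#' other base is ignored.  The methylation level is
#' `100 * count_meth / (count_meth + count_unmeth)`, the ratio of retained
#' cytosines to all cytosine-plus-thymine observations.  Sites with no
#' contributing base are omitted.
#'
#' @param placements Placements from [align_pairs()] (rows with
#'   `status != "placed"` are ignored).
#' @param ref A [reference_set()].
#' @param merge_strands When `TRUE`, the two strand records of a CpG dyad
#'   are merged onto the plus-strand C position (strand `"*"`); non-CpG
#'   records are left strand-resolved.
#' @return A `data.frame` of methylation records: `contig, pos0, strand,
#'   context, count_meth, count_unmeth, level_percent`, sorted by
#'   `(contig, pos0, strand)`.
#' @export
pileup_methylation <- function(placements, ref, merge_strands = FALSE) {
  pl <- placements[placements$status == "placed", , drop = FALSE]
  missing_ctg <- setdiff(unique(pl$contig), names(ref$contigs))
  if (length(missing_ctg)) {
    stop("placement references unknown contig '", missing_ctg[1L], "'")
  }
  rawC <- charToRaw("C"); rawG <- charToRaw("G")
  rawT <- charToRaw("T"); rawA <- charToRaw("A")
  rb <- lapply(ref$contigs, charToRaw)

  ctg <- character(0); pos <- integer(0); std <- character(0)
  meth <- logical(0)
  acc <- vector("list", nrow(pl))
  for (i in seq_len(nrow(pl))) {
    p <- pl[i, ]
    if (p$r1_keep == 0L) next
    cols <- .cigar_columns(p$r1_cigar)
    qpos <- cols$q + p$r1_qoff
    tpos <- cols$t + p$r1_aln_start0
    refb <- rb[[p$contig]][tpos + 1L]
    qb <- charToRaw(p$r1_query)[qpos + 1L]
    if (p$frag_strand == "+") {
      inkeep <- qpos < p$r1_keep
      site <- refb == rawC
      m <- qb == rawC; u <- qb == rawT
      strand <- "+"
    } else {
      inkeep <- qpos >= p$r1_len - p$r1_keep
      site <- refb == rawG
      m <- qb == rawG; u <- qb == rawA
      strand <- "-"
    }
    sel <- inkeep & site & (m | u)
    if (!any(sel)) next
    acc[[i]] <- list(contig = p$contig, pos0 = tpos[sel], strand = strand,
                     meth = m[sel])
  }
  acc <- acc[!vapply(acc, is.null, logical(1L))]
  if (!length(acc)) {
    return(data.frame(contig = character(), pos0 = integer(),
                      strand = character(), context = character(),
                      count_meth = integer(), count_unmeth = integer(),
                      level_percent = numeric()))
  }
  dt <- data.table::rbindlist(acc)
  agg <- dt[, list(count_meth = sum(meth), count_unmeth = sum(!meth)),
            by = c("contig", "pos0", "strand")]
  agg <- as.data.frame(agg)

  ## context from the reference dinucleotide
  ctx <- character(nrow(agg))
  for (nm in unique(agg$contig)) {
    sel <- agg$contig == nm
    b <- rb[[nm]]
    p0 <- agg$pos0[sel]
    plus <- agg$strand[sel] == "+"
    nxt <- ifelse(p0 + 2L <= length(b), as.integer(b[p0 + 2L]), NA_integer_)
    prv <- ifelse(p0 >= 1L, as.integer(b[p0]), NA_integer_)
    ctx[sel] <- ifelse(plus,
                       ifelse(!is.na(nxt) & nxt == as.integer(rawG),
                              "CpG", "nonCpG"),
                       ifelse(!is.na(prv) & prv == as.integer(rawC),
                              "CpG", "nonCpG"))
  }
  agg$context <- ctx
  if (merge_strands) {
    key_pos <- ifelse(agg$context == "CpG" & agg$strand == "-",
                      agg$pos0 - 1L, agg$pos0)
    key_std <- ifelse(agg$context == "CpG", "*", agg$strand)
    dtm <- data.table::data.table(contig = agg$contig, pos0 = key_pos,
                                  strand = key_std, context = agg$context,
                                  count_meth = agg$count_meth,
                                  count_unmeth = agg$count_unmeth)
    agg <- as.data.frame(dtm[, list(count_meth = sum(count_meth),
                                    count_unmeth = sum(count_unmeth)),
                             by = c("contig", "pos0", "strand", "context")])
  }
  agg$level_percent <- 100 * agg$count_meth /
    (agg$count_meth + agg$count_unmeth)
  agg <- agg[order(agg$contig, agg$pos0, agg$strand),
             c("contig", "pos0", "strand", "context", "count_meth",
               "count_unmeth", "level_percent")]
  rownames(agg) <- NULL
  agg
}

#' Estimate bisulfite conversion efficiency from the spike-in control
#'
#' The control contig is fully unmethylated, so every retained cytosine on
#' it is a conversion failure: efficiency is
#' `100 * sum(count_unmeth) / sum(count_meth + count_unmeth)` over all
#' control-contig records.
#'
#' @param records Methylation records from [pileup_methylation()].
#' @param ref A [reference_set()] whose `control` names the spike-in
#'   contig(s).
#' @return Conversion efficiency in percent.
#' @export
conversion_efficiency <- function(records, ref) {
  if (!length(ref$control)) {
    stop("reference has no control contig; conversion efficiency undefined")
  }
  ctl <- records[records$contig %in% ref$control, , drop = FALSE]
  if (!nrow(ctl)) {
    stop("no methylation records on control contig(s) ",
         paste(ref$control, collapse = ", "),
         "; conversion efficiency undefined")
  }
  100 * sum(ctl$count_unmeth) /
    sum(ctl$count_meth + ctl$count_unmeth)
}
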