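## Shared primitive types and readers/writers for FASTA, FASTQ, TSV reports
## and minimal SAM.  Internal coordinates are 0-based half-open everywhere;
## conversion to 1-based happens only at SAM emission.

#' Reference sequence set
#'
#' Container for a set of reference contigs plus the names of contigs that
#' are unmethylated spike-in controls (lambda DNA, spiked at 0.1 % wt/wt in
#' the library protocol so conversion efficiency can be estimated).
#'
#' @param contigs Named character vector of uppercase DNA sequences over
#'   `A,C,G,T,N`.
#' @param control Character vector of contig names flagged as unmethylated
#'   control (must be a subset of `names(contigs)`).
#' @return An object of class `gps_reference` with elements `contigs` and
#'   `control`.
#' @export
reference_set <- function(contigs, control = character()) {
  nm <- names(contigs)
  if (is.null(nm) || any(!nzchar(nm))) {
    stop("every contig must have a non-empty name")
  }
  if (anyDuplicated(nm)) {
    stop("duplicate contig name: ", nm[duplicated(nm)][1L])
  }
  if (any(grepl("[[:space:]]", nm))) {
    stop("contig names must not contain whitespace")
  }
  contigs <- toupper(contigs)
  bad <- grepl("[^ACGTN]", contigs)
  if (any(bad)) {
    stop("non-IUPAC character in contig '", nm[bad][1L], "'")
  }
  if (!all(control %in% nm)) {
    stop("control contig not present: ",
         paste(setdiff(control, nm), collapse = ", "))
  }
  structure(list(contigs = contigs, control = control),
            class = "gps_reference")
}

#' @export
print.gps_reference <- function(x, ...) {
  cat("GPS reference set:", length(x$contigs), "contig(s)\n")
  for (nm in names(x$contigs)) {
    cat(sprintf("  %s  %d bp%s\n", nm, nchar(x$contigs[[nm]]),
                if (nm %in% x$control) "  [control]" else ""))
  }
  invisible(x)
}

#' Read a reference FASTA file
#'
#' Sequences are uppercased on read; duplicate record names, empty files and
#' non-IUPAC characters are reported as format errors naming the offending
#' record.  Gzip-compressed files are handled transparently.
#'
#' @param path Path to a FASTA file.
#' @param control Character vector of contig names to flag as unmethylated
#'   spike-in controls.
#' @return A [reference_set()].
#' @export
read_fasta <- function(path, control = character()) {
  seqs <- tryCatch(Biostrings::readBStringSet(path),
                   error = function(e) stop("cannot read FASTA '", path,
                                            "': ", conditionMessage(e)))
  if (length(seqs) == 0L) stop("FASTA file '", path, "' contains no records")
  nm <- sub("[[:space:]].*$", "", names(seqs))
  reference_set(setNames(as.character(seqs), nm), control = control)
}

#' Write a reference FASTA file
#'
#' @param ref A [reference_set()].
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(ref, path, width = 70L) {
  stopifnot(inherits(ref, "gps_reference"))
  x <- Biostrings::BStringSet(ref$contigs)
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

#' Construct a table of read pairs
#'
#' One sequenced fragment per row: Read1 is the bisulfite-converted mate,
#' Read2 starts with the 5mC-protected prefix.  Sequences are stored as
#' sequenced (5'->3') with Phred+33 quality strings of matching length.
#'
#' @param id Character vector of pair ids.
#' @param r1_seq,r2_seq DNA sequences over `A,C,G,T,N`.
#' @param r1_qual,r2_qual Phred+33 quality strings, same lengths as the
#'   sequences.
#' @return A `data.frame` of class `gps_pairs`.
#' @export
gps_pairs <- function(id, r1_seq, r2_seq, r1_qual, r2_qual) {
  df <- data.frame(id = as.character(id), r1_seq = as.character(r1_seq),
                   r2_seq = as.character(r2_seq),
                   r1_qual = as.character(r1_qual),
                   r2_qual = as.character(r2_qual),
                   stringsAsFactors = FALSE)
  bad <- which(nchar(df$r1_seq) != nchar(df$r1_qual) |
               nchar(df$r2_seq) != nchar(df$r2_qual))
  if (length(bad)) {
    stop("sequence/quality length mismatch at record ", bad[1L])
  }
  class(df) <- c("gps_pairs", "data.frame")
  df
}

## strip mate suffixes "/1", "/2", " 1...", " 2..." from FASTQ ids
.strip_mate_suffix <- function(x) {
  x <- sub("[[:space:]].*$", "", x)
  sub("/[12]$", "", x)
}

.read_fastq_records <- function(path) {
  lines <- readLines(path)
  if (length(lines) && !nzchar(lines[length(lines)])) {
    lines <- lines[-length(lines)]
  }
  if (length(lines) %% 4L != 0L) {
    stop("FASTQ file '", path, "' is truncated (", length(lines),
         " lines, not a multiple of 4)")
  }
  n <- length(lines) %/% 4L
  i <- seq_len(n)
  ids <- lines[4L * i - 3L]
  if (n && any(substr(ids, 1L, 1L) != "@")) {
    stop("malformed FASTQ record ", which(substr(ids, 1L, 1L) != "@")[1L],
         " in '", path, "' (missing '@')")
  }
  list(id = substring(ids, 2L), seq = toupper(lines[4L * i - 2L]),
       qual = lines[4L * i])
}

#' Read a pair of record-synchronized FASTQ files
#'
#' Mates are matched by record order; mate suffixes (`/1`, `/2` or a
#' space-separated comment) are stripped to form the pair id.  Gzip input is
#' handled transparently.  Unequal record counts and sequence/quality length
#' mismatches are format errors carrying the record index.
#'
#' @param path_r1,path_r2 Paths to the Read1 and Read2 FASTQ files.
#' @return A [gps_pairs()] table.
#' @export
read_fastq_pairs <- function(path_r1, path_r2) {
  a <- .read_fastq_records(path_r1)
  b <- .read_fastq_records(path_r2)
  if (length(a$id) != length(b$id)) {
    stop("mate files out of sync: ", length(a$id), " records in '", path_r1,
         "' but ", length(b$id), " in '", path_r2, "'")
  }
  bad <- which(nchar(a$seq) != nchar(a$qual) | nchar(b$seq) != nchar(b$qual))
  if (length(bad)) {
    stop("sequence/quality length mismatch at record ", bad[1L])
  }
  gps_pairs(.strip_mate_suffix(a$id), a$seq, b$seq, a$qual, b$qual)
}

.open_write <- function(path) {
  if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
}

#' Write a table of read pairs as two FASTQ files
#'
#' @param pairs A [gps_pairs()] table.
#' @param path_r1,path_r2 Output paths (a `.gz` suffix enables compression).
#' @return The two paths, invisibly.
#' @export
write_fastq_pairs <- function(pairs, path_r1, path_r2) {
  w <- function(path, id, seq, qual, mate) {
    con <- .open_write(path)
    on.exit(close(con))
    txt <- paste0("@", id, "/", mate, "\n", seq, "\n+\n", qual)
    writeLines(txt, con)
  }
  w(path_r1, pairs$id, pairs$r1_seq, pairs$r1_qual, 1L)
  w(path_r2, pairs$id, pairs$r2_seq, pairs$r2_qual, 2L)
  invisible(c(path_r1, path_r2))
}

#' Reverse complement
#'
#' @param x Character vector of DNA sequences (`N` maps to `N`).
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) cpp_revcomp(as.character(x))

.write_tsv <- function(df, path, format_cols = NULL) {
  con <- file(path, "wb")
  on.exit(close(con))
  out <- df
  if (!is.null(format_cols)) {
    for (cl in names(format_cols)) {
      out[[cl]] <- sprintf(format_cols[[cl]], out[[cl]])
    }
  }
  writeLines(paste(colnames(out), collapse = "\t"), con)
  if (nrow(out)) {
    writeLines(do.call(paste, c(lapply(out, as.character), sep = "\t")), con)
  }
  invisible(path)
}

#' Write a per-cytosine methylation report
#'
#' Tab-separated with header `contig, start, strand, context, count_meth,
#' count_unmeth, level_percent`; `start` is 0-based.
#'
#' @param records Methylation records from [pileup_methylation()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_methylation_report <- function(records, path) {
  df <- data.frame(contig = character(), start = integer(),
                   strand = character(), context = character(),
                   count_meth = integer(), count_unmeth = integer(),
                   level_percent = numeric())
  if (!is.null(records) && nrow(records)) {
    df <- data.frame(contig = records$contig, start = records$pos0,
                     strand = records$strand, context = records$context,
                     count_meth = records$count_meth,
                     count_unmeth = records$count_unmeth,
                     level_percent = records$level_percent)
  }
  .write_tsv(df, path, format_cols = c(level_percent = "%.1f"))
}

#' Write a candidate-variant report
#'
#' Columns: `contig, pos0, ref_base, alt_base, coverage, alt_count` with
#' 0-based positions.
#'
#' @param sites Variant sites from [call_variant_candidates()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_variant_report <- function(sites, path) {
  cols <- c("contig", "pos0", "ref_base", "alt_base", "coverage", "alt_count")
  if (is.null(sites) || !nrow(sites)) {
    sites <- data.frame(contig = character(), pos0 = integer(),
                        ref_base = character(), alt_base = character(),
                        coverage = integer(), alt_count = integer())
  }
  .write_tsv(sites[, cols], path)
}

#' Write an allele-specific methylation report
#'
#' Variant columns followed by the tested cytosine (0-based position and
#' strand), per-group methylation levels and coverages, the absolute level
#' difference in percentage points, and the ASM flag.
#'
#' @param records ASM records from [asm_scan()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_asm_report <- function(records, path) {
  cols <- c("contig", "pos0", "ref_base", "alt_base", "coverage", "alt_count",
            "cyt_pos0", "cyt_strand", "level_with_alt", "cov_with_alt",
            "level_without_alt", "cov_without_alt", "diff", "is_asm")
  if (is.null(records) || !nrow(records)) {
    records <- data.frame(contig = character(), pos0 = integer(),
                          ref_base = character(), alt_base = character(),
                          coverage = integer(), alt_count = integer(),
                          cyt_pos0 = integer(), cyt_strand = character(),
                          level_with_alt = numeric(), cov_with_alt = integer(),
                          level_without_alt = numeric(),
                          cov_without_alt = integer(), diff = numeric(),
                          is_asm = logical())
  }
  .write_tsv(records[, cols], path,
             format_cols = c(level_with_alt = "%.1f",
                             level_without_alt = "%.1f", diff = "%.1f"))
}

## CIGAR helpers ------------------------------------------------------------

.parse_cigar <- function(cigar) {
  if (!nzchar(cigar)) return(list(len = integer(), op = character()))
  len <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1L]])
  op <- regmatches(cigar, gregexpr("[MIDS]", cigar))[[1L]]
  if (length(len) != length(op)) stop("malformed CIGAR: ", cigar)
  list(len = len, op = op)
}

## expand a CIGAR into parallel query/target offsets of its M columns,
## both 0-based relative to the alignment start
.cigar_columns <- function(cigar) {
  cg <- .parse_cigar(cigar)
  q <- 0L; t <- 0L
  qs <- vector("list", length(cg$op)); ts <- vector("list", length(cg$op))
  for (k in seq_along(cg$op)) {
    n <- cg$len[k]
    if (cg$op[k] == "M") {
      qs[[k]] <- q + seq_len(n) - 1L
      ts[[k]] <- t + seq_len(n) - 1L
      q <- q + n; t <- t + n
    } else if (cg$op[k] == "I") {
      q <- q + n
    } else if (cg$op[k] == "D") {
      t <- t + n
    } else if (cg$op[k] == "S") {
      q <- q + n
    }
  }
  list(q = unlist(qs, use.names = FALSE), t = unlist(ts, use.names = FALSE))
}

.cigar_tspan <- function(cigar) {
  cg <- .parse_cigar(cigar)
  sum(cg$len[cg$op %in% c("M", "D")])
}

## Minimal SAM --------------------------------------------------------------

#' Write placed pairs as a minimal SAM file
#'
#' Emits one record per placed mate with proper-pair flags, 1-based `POS`
#' and a CIGAR derived from the alignment path (unaligned read ends are
#' soft-clipped).  `SEQ`/`QUAL` are stored in reference-forward orientation
#' per the SAM convention.
#'
#' @param placements Placements from [align_pairs()].
#' @param pairs The [gps_pairs()] table the placements came from (source of
#'   quality strings).
#' @param ref A [reference_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pairs_sam <- function(placements, pairs, ref, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unknown", con)
  for (nm in names(ref$contigs)) {
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", nm, nchar(ref$contigs[[nm]])), con)
  }
  pl <- placements[placements$status == "placed", , drop = FALSE]
  if (!nrow(pl)) return(invisible(path))
  qual <- setNames(pairs$r1_qual, pairs$id)
  qual2 <- setNames(pairs$r2_qual, pairs$id)

  clip_cigar <- function(cigar, qoff, qend, qlen) {
    pre <- if (qoff > 0L) sprintf("%dS", qoff) else ""
    post <- if (qlen - qend > 0L) sprintf("%dS", qlen - qend) else ""
    paste0(pre, cigar, post)
  }
  lines <- character(2L * nrow(pl))
  for (i in seq_len(nrow(pl))) {
    p <- pl[i, ]
    r1_rev <- p$frag_strand == "-"
    r2_rev <- p$r2_strand == "-"
    f1 <- bitwOr(bitwOr(1L + 2L + 64L, if (r1_rev) 16L else 0L),
                 if (r2_rev) 32L else 0L)
    f2 <- bitwOr(bitwOr(1L + 2L + 128L, if (r2_rev) 16L else 0L),
                 if (r1_rev) 32L else 0L)
    q1 <- qual[[p$id]]
    if (r1_rev) q1 <- paste(rev(strsplit(q1, "")[[1L]]), collapse = "")
    q2 <- substr(qual2[[p$id]], 1L, p$anchor_len)
    if (r2_rev) q2 <- paste(rev(strsplit(q2, "")[[1L]]), collapse = "")
    tlen <- p$pair_distance
    lines[2L * i - 1L] <- paste(p$id, f1, p$contig, p$r1_aln_start0 + 1L, 60L,
      clip_cigar(p$r1_cigar, p$r1_qoff, p$r1_qend, p$r1_len), "=",
      p$r2_start0 + 1L, if (r1_rev) -tlen else tlen, p$r1_query, q1,
      sep = "\t")
    lines[2L * i] <- paste(p$id, f2, p$contig, p$r2_start0 + 1L, 60L,
      clip_cigar(p$r2_cigar, p$r2_qoff, p$r2_qend, p$anchor_len), "=",
      p$r1_aln_start0 + 1L, if (r2_rev) -tlen else tlen, p$anchor_query, q2,
      sep = "\t")
  }
  writeLines(lines, con)
  invisible(path)
}

#' Import anchor alignments from a SAM file
#'
#' Ingests externally produced Read2 anchor alignments verbatim (minimal
#' parser: `QNAME FLAG RNAME POS CIGAR SEQ` plus the optional `AS:i` score
#' tag).  Unmapped records are skipped.
#'
#' @param path Path to a SAM file.
#' @param ref A [reference_set()]; records naming a missing contig are an
#'   error.
#' @return A `data.frame` with one row per alignment: `id, contig, start0,
#'   end0, strand, score, cigar, qoff, qend, qlen`.
#' @export
read_anchor_sam <- function(path, ref) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  out <- list()
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    flag <- as.integer(f[2L])
    if (bitwAnd(flag, 4L) > 0L) next
    if (!(f[3L] %in% names(ref$contigs))) {
      stop("SAM record references unknown contig '", f[3L], "'")
    }
    score <- NA_real_
    as_tag <- grep("^AS:i:", f, value = TRUE)
    if (length(as_tag)) score <- as.numeric(sub("^AS:i:", "", as_tag[1L]))
    cg <- .parse_cigar(f[6L])
    qlen <- sum(cg$len[cg$op %in% c("M", "I", "S")])
    lead <- if (length(cg$op) && cg$op[1L] == "S") cg$len[1L] else 0L
    tail_s <- if (length(cg$op) && cg$op[length(cg$op)] == "S") {
      cg$len[length(cg$op)]
    } else 0L
    core <- f[6L]
    core <- sub("^[0-9]+S", "", core)
    core <- sub("[0-9]+S$", "", core)
    out[[length(out) + 1L]] <- data.frame(
      id = f[1L], contig = f[3L], start0 = as.integer(f[4L]) - 1L,
      end0 = as.integer(f[4L]) - 1L + .cigar_tspan(core),
      strand = if (bitwAnd(flag, 16L) > 0L) "-" else "+",
      score = score, cigar = core, qoff = lead, qend = qlen - tail_s,
      qlen = qlen, seq = f[10L], stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    return(data.frame(id = character(), contig = character(),
                      start0 = integer(), end0 = integer(),
                      strand = character(), score = numeric(),
                      cigar = character(), qoff = integer(), qend = integer(),
                      qlen = integer(), seq = character()))
  }
  do.call(rbind, out)
}
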