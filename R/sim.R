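## GPS library simulator: reference + methylome generation, heterozygous
## allele/ASM planting, and paired-read emission with per-read ground truth.

#' Simulation configuration
#'
#' Defaults follow the library protocol: sheared fragments of 200-500 bp
#' (mode near 330 bp), 36-150 nt excised and 5mC-patched per 3' end by T4
#' DNA polymerase, 150 bp paired-end reads, 0.1 % unmethylated lambda
#' spike-in, and bisulfite conversion efficiency of 99.5 %.
#'
#' @param genome_length Length of the main contig (bp).
#' @param gc_fraction GC content of the simulated contigs.
#' @param n_pairs Number of (non-duplicate) fragments to sequence.
#' @param frag_len_mean,frag_len_sd Normal law for fragment length, clipped
#'   to `frag_len_bounds`.
#' @param frag_len_bounds Inclusive fragment-length bounds (bp).
#' @param t4_excision_bounds Inclusive bounds of the per-3'-end patch length
#'   (nt); patch lengths are uniform over this range.
#' @param conversion_rate Probability that an unmethylated cytosine is
#'   bisulfite-converted to T.
#' @param meth_protection_failure Probability that a methylated cytosine
#'   converts anyway.
#' @param seq_error_rate Per-base substitution error probability.
#' @param read_length Read length (nt).
#' @param lambda_fraction Probability that a fragment is drawn from the
#'   unmethylated control contig.
#' @param lambda_length Length of the control contig (bp).
#' @param n_het_snv Number of heterozygous SNVs to plant.
#' @param n_asm_loci Number of planted SNVs whose surrounding CpGs are
#'   allele-specifically methylated (must be `<= n_het_snv`).
#' @param asm_window Half-width (bp) of the CpG window linked to an ASM
#'   locus.
#' @param snv_spacing Minimum distance between planted SNVs (bp).
#' @param meth_model Per-CpG methylation-probability law: either
#'   `list(type = "binary", p_meth = p)` (probability exactly 0 or 1) or
#'   `list(type = "beta", weights, shape1, shape2)` (mixture of Beta
#'   components).
#' @param noncpg_meth Methylation probability at non-CpG cytosines.
#' @param duplicate_fraction Expected fraction of pairs re-emitted as exact
#'   sequencing duplicates.
#' @param base_quality Constant Phred quality assigned to emitted bases.
#' @param seed Integer seed; a fixed seed makes all outputs byte-identical.
#' @return A validated list of class `gps_sim_config`.
#' @export
sim_config <- function(genome_length = 100000L, gc_fraction = 0.42,
                       n_pairs = 10000L, frag_len_mean = 330,
                       frag_len_sd = 60, frag_len_bounds = c(200L, 500L),
                       t4_excision_bounds = c(36L, 150L),
                       conversion_rate = 0.995,
                       meth_protection_failure = 0.005,
                       seq_error_rate = 0.001, read_length = 150L,
                       lambda_fraction = 0.001, lambda_length = 48502L,
                       n_het_snv = 0L, n_asm_loci = 0L, asm_window = 300L,
                       snv_spacing = 2000L,
                       meth_model = list(type = "beta",
                                         weights = c(0.3, 0.7),
                                         shape1 = c(1, 8), shape2 = c(8, 1)),
                       noncpg_meth = 0, duplicate_fraction = 0.02,
                       base_quality = 37L, seed = 1L) {
  cfg <- list(genome_length = as.integer(genome_length),
              gc_fraction = gc_fraction, n_pairs = as.integer(n_pairs),
              frag_len_mean = frag_len_mean, frag_len_sd = frag_len_sd,
              frag_len_bounds = as.integer(frag_len_bounds),
              t4_excision_bounds = as.integer(t4_excision_bounds),
              conversion_rate = conversion_rate,
              meth_protection_failure = meth_protection_failure,
              seq_error_rate = seq_error_rate,
              read_length = as.integer(read_length),
              lambda_fraction = lambda_fraction,
              lambda_length = as.integer(lambda_length),
              n_het_snv = as.integer(n_het_snv),
              n_asm_loci = as.integer(n_asm_loci),
              asm_window = as.integer(asm_window),
              snv_spacing = as.integer(snv_spacing),
              meth_model = meth_model, noncpg_meth = noncpg_meth,
              duplicate_fraction = duplicate_fraction,
              base_quality = as.integer(base_quality),
              seed = as.integer(seed))
  probs <- c(gc_fraction = cfg$gc_fraction,
             conversion_rate = cfg$conversion_rate,
             meth_protection_failure = cfg$meth_protection_failure,
             seq_error_rate = cfg$seq_error_rate,
             lambda_fraction = cfg$lambda_fraction,
             noncpg_meth = cfg$noncpg_meth,
             duplicate_fraction = cfg$duplicate_fraction)
  bad <- probs < 0 | probs > 1
  if (any(bad)) {
    stop("probability out of [0,1]: ", paste(names(probs)[bad],
                                             collapse = ", "))
  }
  if (cfg$frag_len_bounds[1L] < 2L ||
      cfg$frag_len_bounds[1L] > cfg$frag_len_bounds[2L]) {
    stop("invalid frag_len_bounds")
  }
  if (cfg$t4_excision_bounds[1L] < 1L ||
      cfg$t4_excision_bounds[2L] >= cfg$frag_len_bounds[1L]) {
    stop("t4_excision_bounds must lie within [1, min fragment length)")
  }
  if (cfg$lambda_fraction > 0 && cfg$lambda_length < cfg$frag_len_bounds[2L]) {
    stop("lambda_length must be at least the maximum fragment length")
  }
  if (cfg$n_asm_loci > cfg$n_het_snv) {
    stop("n_asm_loci must not exceed n_het_snv")
  }
  structure(cfg, class = "gps_sim_config")
}

.draw_meth_probs <- function(n, model) {
  if (n == 0L) return(numeric())
  if (identical(model$type, "binary")) {
    as.numeric(runif(n) < model$p_meth)
  } else if (identical(model$type, "beta")) {
    comp <- sample.int(length(model$weights), n, replace = TRUE,
                       prob = model$weights)
    rbeta(n, model$shape1[comp], model$shape2[comp])
  } else {
    stop("unknown meth_model type: ", model$type)
  }
}

.random_contig <- function(len, gc) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(.BASES, len, replace = TRUE, prob = p), collapse = "")
}

#' Generate a simulated reference and its true methylome
#'
#' Creates one main contig plus one unmethylated control contig (the lambda
#' spike-in stand-in) with i.i.d. bases at the configured GC.  Every
#' reference cytosine (C on the plus strand, G on the minus strand) gets a
#' truth entry: CpG-context cytosines draw a methylation probability from
#' `meth_model`, shared across the two strands of a CpG dyad; non-CpG
#' cytosines get `noncpg_meth`; control-contig entries are all 0.
#'
#' @param config A [sim_config()].
#' @return A list with `ref` (a [reference_set()]) and `methylome` (a
#'   `data.frame`: `contig, pos0, strand, context, prob_ref, prob_alt`;
#'   the two probability columns differ only after [plant_alleles()]).
#' @export
generate_reference <- function(config) {
  stopifnot(inherits(config, "gps_sim_config"))
  set.seed(config$seed)
  contigs <- c(sim1 = .random_contig(config$genome_length,
                                     config$gc_fraction))
  control <- character()
  if (config$lambda_fraction > 0) {
    contigs <- c(contigs,
                 lambda = .random_contig(config$lambda_length,
                                         config$gc_fraction))
    control <- "lambda"
  }
  ref <- reference_set(contigs, control = control)

  meth <- list()
  for (nm in names(ref$contigs)) {
    b <- charToRaw(ref$contigs[[nm]])
    isC <- b == charToRaw("C")
    isG <- b == charToRaw("G")
    cpgC <- which(isC[-length(b)] & isG[-1L])           # 1-based C of CpG
    posC <- which(isC)                                   # all + strand
    posG <- which(isG)                                   # all - strand
    ctxC <- ifelse(posC %in% cpgC, "CpG", "nonCpG")
    ctxG <- ifelse(posG %in% (cpgC + 1L), "CpG", "nonCpG")
    if (nm %in% ref$control) {
      pC <- numeric(length(posC)); pG <- numeric(length(posG))
    } else {
      dyad <- .draw_meth_probs(length(cpgC), config$meth_model)
      names(dyad) <- as.character(cpgC)
      pC <- ifelse(ctxC == "CpG", dyad[as.character(posC)],
                   config$noncpg_meth)
      pG <- ifelse(ctxG == "CpG", dyad[as.character(posG - 1L)],
                   config$noncpg_meth)
    }
    meth[[nm]] <- data.frame(
      contig = nm,
      pos0 = c(posC, posG) - 1L,
      strand = rep(c("+", "-"), c(length(posC), length(posG))),
      context = c(ctxC, ctxG),
      prob_ref = as.numeric(c(pC, pG)), prob_alt = as.numeric(c(pC, pG)),
      stringsAsFactors = FALSE)
  }
  methylome <- do.call(rbind, meth)
  methylome <- methylome[order(methylome$contig, methylome$pos0,
                               methylome$strand), ]
  rownames(methylome) <- NULL
  list(ref = ref, methylome = methylome)
}

#' Plant heterozygous SNVs and allele-specific methylation loci
#'
#' Places `n_het_snv` heterozygous substitutions on the main contig, at
#' least `snv_spacing` apart.  Sites are restricted to A/T positions with an
#' A<->T substitution so that no CpG is created or destroyed and the variant
#' is unaffected by bisulfite conversion on either strand.  The first
#' `n_asm_loci` sites become ASM loci: CpG truth entries within
#' `asm_window` bp get probability 1 on the alt haplotype and 0 on the ref
#' haplotype.  Remaining sites are methylation-neutral controls.
#'
#' @param ref A [reference_set()].
#' @param methylome Methylome truth from [generate_reference()].
#' @param config A [sim_config()].
#' @return A list: `methylome` (updated), `variants` (`contig, pos0,
#'   ref_base, alt_base, is_asm_locus`) and `asm` (per-locus linked
#'   cytosines with per-allele probabilities).
#' @export
plant_alleles <- function(ref, methylome, config) {
  set.seed(config$seed + 1L)
  empty_var <- data.frame(contig = character(), pos0 = integer(),
                          ref_base = character(), alt_base = character(),
                          is_asm_locus = logical(), stringsAsFactors = FALSE)
  empty_asm <- data.frame(site_pos0 = integer(), cyt_pos0 = integer(),
                          cyt_strand = character(), prob_ref = numeric(),
                          prob_alt = numeric(), stringsAsFactors = FALSE)
  if (config$n_het_snv == 0L) {
    return(list(methylome = methylome, variants = empty_var, asm = empty_asm))
  }
  main <- setdiff(names(ref$contigs), ref$control)[1L]
  seq <- ref$contigs[[main]]
  L <- nchar(seq)
  margin <- max(600L, config$asm_window + 50L)
  b <- charToRaw(seq)
  cand <- which(b == charToRaw("A") | b == charToRaw("T")) - 1L  # 0-based
  cand <- cand[cand >= margin & cand < L - margin]
  ## sites on a jittered grid: guarantees the spacing whenever the genome
  ## admits it, unlike random sequential packing
  n <- config$n_het_snv
  step <- (L - 2 * margin) / n
  slack <- floor((step - config$snv_spacing) / 2)
  if (!length(cand) || slack < 0) {
    stop("genome too small to place ", n, " heterozygous sites at ",
         config$snv_spacing, " bp spacing")
  }
  centers <- margin + as.integer(round((seq_len(n) - 0.5) * step)) +
    as.integer(floor(runif(n, -slack, slack + 1)))
  chosen <- vapply(centers, function(p) cand[which.min(abs(cand - p))],
                   integer(1L))
  chosen <- sample(chosen)   # random order: ASM loci are a random subset
  if (anyDuplicated(chosen) || any(abs(diff(sort(chosen))) <
                                   config$snv_spacing)) {
    stop("genome too small to place ", n, " heterozygous sites at ",
         config$snv_spacing, " bp spacing")
  }
  ref_base <- substring(seq, chosen + 1L, chosen + 1L)
  alt_base <- ifelse(ref_base == "A", "T", "A")
  is_asm <- seq_along(chosen) <= config$n_asm_loci

  variants <- data.frame(contig = main, pos0 = chosen, ref_base = ref_base,
                         alt_base = alt_base, is_asm_locus = is_asm,
                         stringsAsFactors = FALSE)
  asm <- empty_asm
  for (k in which(is_asm)) {
    sel <- methylome$contig == main & methylome$context == "CpG" &
      abs(methylome$pos0 - chosen[k]) <= config$asm_window
    methylome$prob_alt[sel] <- 1
    methylome$prob_ref[sel] <- 0
    if (any(sel)) {
      asm <- rbind(asm, data.frame(site_pos0 = chosen[k],
                                   cyt_pos0 = methylome$pos0[sel],
                                   cyt_strand = methylome$strand[sel],
                                   prob_ref = 0, prob_alt = 1,
                                   stringsAsFactors = FALSE))
    }
  }
  list(methylome = methylome, variants = variants, asm = asm)
}

.comp_lut <- local({
  lut <- as.raw(0:255)
  from <- charToRaw("ACGTNacgtn")
  to <- charToRaw("TGCANtgcan")
  lut[as.integer(from) + 1L] <- to
  lut
})

.revcomp_raw <- function(x) rev(.comp_lut[as.integer(x) + 1L])

## per-contig, per-strand, per-haplotype methylation probability lookup
## vectors (position 0-based + 1 -> probability; NA off cytosines)
.meth_lookup <- function(methylome, contig, len) {
  m <- methylome[methylome$contig == contig, , drop = FALSE]
  out <- list(plus_ref = rep(NA_real_, len), plus_alt = rep(NA_real_, len),
              minus_ref = rep(NA_real_, len), minus_alt = rep(NA_real_, len))
  p <- m$strand == "+"
  out$plus_ref[m$pos0[p] + 1L] <- m$prob_ref[p]
  out$plus_alt[m$pos0[p] + 1L] <- m$prob_alt[p]
  out$minus_ref[m$pos0[!p] + 1L] <- m$prob_ref[!p]
  out$minus_alt[m$pos0[!p] + 1L] <- m$prob_alt[!p]
  out
}

#' Simulate GPS read pairs with ground truth
#'
#' For each fragment: haplotype and strand are drawn uniformly; the length
#' from a clipped normal law; one patch length per 3' end uniformly from
#' `t4_excision_bounds`.  Within the patch at the sequenced strand's 3' end
#' every cytosine is protected; outside it each cytosine converts to T with
#' probability `conversion_rate` when its per-molecule methylation Bernoulli
#' draw is unmethylated and `meth_protection_failure` when methylated.
#' Read1 is the first `read_length` nt of the converted strand; Read2 is the
#' reverse complement of its last `read_length` nt, so Read2 begins inside
#' the protected patch.  Substitution errors are applied at
#' `seq_error_rate`; a duplicate fraction re-emits byte-identical pairs;
#' fragments come from the control contig with probability
#' `lambda_fraction`.
#'
#' @param ref A [reference_set()].
#' @param methylome Methylome truth (after [plant_alleles()] if alleles are
#'   wanted).
#' @param truth Output of [plant_alleles()] (its `variants` define the alt
#'   haplotype), or `NULL` for no variants.
#' @param config A [sim_config()].
#' @return A list: `pairs` (a [gps_pairs()] table) and `provenance` (one row
#'   per emitted pair: fragment coordinates, strand, haplotype, patch
#'   lengths, lambda/duplicate flags).
#' @export
simulate_pairs <- function(ref, methylome, truth, config) {
  stopifnot(inherits(config, "gps_sim_config"))
  set.seed(config$seed + 2L)
  n <- config$n_pairs
  rl <- config$read_length
  main <- setdiff(names(ref$contigs), ref$control)[1L]
  ctrl <- if (length(ref$control)) ref$control[1L] else NA_character_
  variants <- if (is.null(truth)) NULL else truth$variants

  ## per-contig precomputation
  prep <- list()
  for (nm in names(ref$contigs)) {
    raw_ref <- charToRaw(ref$contigs[[nm]])
    raw_alt <- raw_ref
    if (!is.null(variants) && nrow(variants)) {
      v <- variants[variants$contig == nm, , drop = FALSE]
      if (nrow(v)) raw_alt[v$pos0 + 1L] <- charToRaw(paste(v$alt_base,
                                                           collapse = ""))
    }
    prep[[nm]] <- list(raw = list(ref = raw_ref, alt = raw_alt),
                       len = length(raw_ref),
                       meth = .meth_lookup(methylome, nm, length(raw_ref)))
  }

  is_lambda <- if (!is.na(ctrl)) runif(n) < config$lambda_fraction else
    rep(FALSE, n)
  contig <- ifelse(is_lambda, ctrl, main)
  hap <- ifelse(is_lambda, "ref", c("ref", "alt")[sample.int(2L, n,
                                                             replace = TRUE)])
  strand <- c("+", "-")[sample.int(2L, n, replace = TRUE)]
  clen <- vapply(prep[contig], `[[`, integer(1L), "len")
  fl <- pmin(pmax(as.integer(round(rnorm(n, config$frag_len_mean,
                                         config$frag_len_sd))),
                  config$frag_len_bounds[1L]), config$frag_len_bounds[2L])
  fl <- pmin(fl, clen)
  fstart <- as.integer(floor(runif(n) * (clen - fl + 1)))  # 0-based
  tb <- config$t4_excision_bounds
  p_left <- as.integer(floor(runif(n) * (tb[2L] - tb[1L] + 1))) + tb[1L]
  p_right <- as.integer(floor(runif(n) * (tb[2L] - tb[1L] + 1))) + tb[1L]

  rawC <- charToRaw("C"); rawT <- charToRaw("T")
  alt_of <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
                 G = c("A", "C", "T"), T = c("A", "C", "G"),
                 N = c("A", "C", "G", "T"))
  add_errors <- function(readraw) {
    len <- length(readraw)
    ne <- rbinom(1L, len, config$seq_error_rate)
    if (ne > 0L) {
      at <- sample.int(len, ne)
      for (p in at) {
        cur <- rawToChar(readraw[p])
        readraw[p] <- charToRaw(sample(alt_of[[cur]], 1L))
      }
    }
    readraw
  }

  r1 <- character(n); r2 <- character(n)
  for (i in seq_len(n)) {
    pc <- prep[[contig[i]]]
    L <- fl[i]; st <- fstart[i]
    frag <- pc$raw[[hap[i]]][(st + 1L):(st + L)]
    if (strand[i] == "-") frag <- .revcomp_raw(frag)
    ## patch at the sequenced strand's 3' end
    pp <- if (strand[i] == "+") p_right[i] else p_left[i]
    ci <- which(frag == rawC) - 1L                       # 0-based in frag
    if (length(ci)) {
      refpos <- if (strand[i] == "+") st + ci else st + L - 1L - ci
      lut <- if (strand[i] == "+") {
        if (hap[i] == "ref") pc$meth$plus_ref else pc$meth$plus_alt
      } else {
        if (hap[i] == "ref") pc$meth$minus_ref else pc$meth$minus_alt
      }
      m <- lut[refpos + 1L]
      m[is.na(m)] <- 0
      meth_state <- runif(length(ci)) < m
      pconv <- ifelse(meth_state, config$meth_protection_failure,
                      config$conversion_rate)
      conv <- (runif(length(ci)) < pconv) & (ci < L - pp)
      if (any(conv)) frag[ci[conv] + 1L] <- rawT
    }
    k <- min(rl, L)
    r1raw <- add_errors(frag[seq_len(k)])
    r2raw <- add_errors(.revcomp_raw(frag[(L - k + 1L):L]))
    r1[i] <- rawToChar(r1raw)
    r2[i] <- rawToChar(r2raw)
  }

  id <- sprintf("sim%06d", seq_len(n))
  prov <- data.frame(id = id, contig = contig, haplotype = hap,
                     frag_start = fstart, frag_end = fstart + fl,
                     strand = strand, patch_left = p_left,
                     patch_right = p_right, is_lambda = is_lambda,
                     is_duplicate = FALSE, dup_of = NA_character_,
                     stringsAsFactors = FALSE)

  n_dup <- if (n > 0L) rbinom(1L, n, config$duplicate_fraction) else 0L
  if (n_dup > 0L) {
    src <- sample.int(n, n_dup, replace = TRUE)
    dup_id <- sprintf("%s_dup%d", id[src], seq_len(n_dup))
    id <- c(id, dup_id)
    r1 <- c(r1, r1[src])
    r2 <- c(r2, r2[src])
    dprov <- prov[src, , drop = FALSE]
    dprov$id <- dup_id
    dprov$is_duplicate <- TRUE
    dprov$dup_of <- prov$id[src]
    prov <- rbind(prov, dprov)
    rownames(prov) <- NULL
  }

  qchar <- rawToChar(as.raw(config$base_quality + 33L))
  pairs <- gps_pairs(id, r1, r2, strrep(qchar, nchar(r1)),
                     strrep(qchar, nchar(r2)))
  list(pairs = pairs, provenance = prov)
}

#' Simulate a complete GPS library
#'
#' Runs [generate_reference()], [plant_alleles()] and [simulate_pairs()]
#' under one configuration, optionally writing the FASTQ pair, the
#' reference FASTA and the truth tables to disk.  A fixed seed makes every
#' output byte-identical across runs.
#'
#' @param config A [sim_config()].
#' @param out_prefix Optional path prefix; when given, writes
#'   `<prefix>_R1.fastq`, `<prefix>_R2.fastq`, `<prefix>_ref.fa` and
#'   `<prefix>_truth_*.tsv`.
#' @return A list: `ref`, `methylome`, `variants`, `asm`, `pairs`,
#'   `provenance`, `config`.
#' @export
simulate_gps <- function(config, out_prefix = NULL) {
  g <- generate_reference(config)
  al <- plant_alleles(g$ref, g$methylome, config)
  sim <- simulate_pairs(g$ref, al$methylome, al, config)
  out <- list(ref = g$ref, methylome = al$methylome, variants = al$variants,
              asm = al$asm, pairs = sim$pairs, provenance = sim$provenance,
              config = config)
  if (!is.null(out_prefix)) {
    write_fasta(g$ref, paste0(out_prefix, "_ref.fa"))
    write_fastq_pairs(sim$pairs, paste0(out_prefix, "_R1.fastq"),
                      paste0(out_prefix, "_R2.fastq"))
    .write_tsv(sim$provenance, paste0(out_prefix, "_truth_provenance.tsv"))
    .write_tsv(al$methylome, paste0(out_prefix, "_truth_methylome.tsv"))
    .write_tsv(al$variants, paste0(out_prefix, "_truth_variants.tsv"))
    .write_tsv(al$asm, paste0(out_prefix, "_truth_asm.tsv"))
  }
  out
}
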