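## End-to-end orchestration: configuration, stage accounting, outputs and a
## machine-readable run manifest.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full GPS pipeline
#'
#' Executes (simulate ->) preprocess -> align -> methylation ->
#' variants/ASM and writes all reports plus a JSON run manifest into
#' `out_dir`.  The configuration is a list (or path to a YAML file) with
#' sections `sim` (fields of [sim_config()]; presence triggers simulation),
#' `params` (fields of [pipeline_params()]) and `io` (`r1`, `r2`, `ref`,
#' optional `control` contig names and `anchor_sam`).  With a fixed seed
#' the whole run is byte-deterministic.
#'
#' @param config A list or path to a YAML configuration file.
#' @param out_dir Output directory (created if needed).
#' @param seed Optional integer overriding the configured seed.
#' @return Invisibly, a list with the in-memory results (`ref`, `pairs`,
#'   `placements`, `methylation`, `variants`, `asm`, `sim`) and the
#'   `manifest`.
#' @export
run_pipeline <- function(config, out_dir, seed = NULL) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  params_args <- config$params %||% list()
  if (!is.null(seed)) params_args$seed <- seed
  params <- do.call(pipeline_params, params_args)

  sim <- NULL
  if (!is.null(config$sim)) {
    sim_args <- config$sim
    if (!is.null(seed)) sim_args$seed <- seed
    simcfg <- do.call(sim_config, sim_args)
    if (simcfg$n_pairs == 0L) stop("simulation requested with n_pairs = 0")
    sim <- simulate_gps(simcfg, out_prefix = file.path(out_dir, "sim"))
    ref <- sim$ref
    pairs <- sim$pairs
  } else {
    io <- config$io %||% list()
    if (is.null(io$r1) || is.null(io$r2) || is.null(io$ref)) {
      stop("config needs either a `sim` section or io$r1/io$r2/io$ref")
    }
    ref <- read_fasta(io$ref, control = io$control %||% character())
    pairs <- read_fastq_pairs(io$r1, io$r2)
  }
  if (!nrow(pairs)) stop("no input pairs")

  pre <- preprocess_pairs(pairs, params)
  if (!nrow(pre$pairs)) {
    stop("no pairs survive preprocessing (quality filter / duplicate ",
         "removal / boundary detection)")
  }
  pl <- align_pairs(pre$pairs, pre$boundaries, ref, params,
                    anchor_sam = config$io$anchor_sam)

  fate <- setNames(pre$accounting$fate, pre$accounting$id)
  aligned_fate <- ifelse(pl$status == "placed", "placed",
                         paste0("unplaced_", pl$status))
  fate[pl$id] <- aligned_fate
  placed <- sum(pl$status == "placed")

  meth <- pileup_methylation(pl, ref)
  write_methylation_report(meth, file.path(out_dir, "meth.tsv"))
  conv <- tryCatch(conversion_efficiency(meth, ref),
                   error = function(e) NULL)
  if (!is.null(conv)) {
    jsonlite::write_json(list(conversion_efficiency_percent = conv),
                         file.path(out_dir, "conversion.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  vars <- call_variant_candidates(pl, ref, params)
  write_variant_report(vars, file.path(out_dir, "variants.tsv"))
  asm <- asm_scan(vars, pl, ref, params)
  write_asm_report(asm, file.path(out_dir, "asm.tsv"))
  write_pairs_sam(pl, pre$pairs, ref, file.path(out_dir, "aligned.sam"))

  keep_cols <- intersect(c("id", "status", "contig", "frag_strand",
                           "r2_strand", "r2_start0", "r2_end0", "anchor_len",
                           "r2_keep", "r1_aln_start0", "r1_aln_end0",
                           "r1_keep", "r1_score", "r2_score",
                           "pair_distance", "n_candidates"), colnames(pl))
  .write_tsv(as.data.frame(pl)[, keep_cols], file.path(out_dir, "pairs.tsv"))

  counters <- c(pairs_in = nrow(pairs), qc_pass = pre$counts[["qc_pass"]],
                dedup_out = pre$counts[["dedup_out"]],
                boundary_ok = pre$counts[["boundary_ok"]], placed = placed)
  manifest <- list(
    package = "gpsmeth",
    version = as.character(utils::packageVersion("gpsmeth")),
    seed = if (!is.null(seed)) seed else
      (config$sim$seed %||% params$seed),
    config = config,
    counters = as.list(counters),
    fates = as.list(table(unname(fate))),
    files = list(methylation = "meth.tsv", variants = "variants.tsv",
                 asm = "asm.tsv", sam = "aligned.sam", pairs = "pairs.tsv"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(ref = ref, pairs = pairs, preprocess = pre,
                 placements = pl, methylation = meth,
                 conversion_efficiency = conv, variants = vars, asm = asm,
                 sim = sim, accounting = fate, manifest = manifest))
}
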