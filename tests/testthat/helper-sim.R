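# Shared small simulation fixtures, built in code.

# an error-free, fully deterministic chemistry: binary methylome, complete
# conversion, no sequencing error
exact_sim_config <- function(n_pairs = 400L, genome_length = 20000L,
                             seed = 7L,
                             meth_model = list(type = "binary",
                                               p_meth = 0.5),
                             lambda_fraction = 0.01,
                             lambda_length = 3000L, ...) {
  sim_config(genome_length = genome_length, n_pairs = n_pairs,
             meth_model = meth_model,
             conversion_rate = 1, meth_protection_failure = 0,
             seq_error_rate = 0, lambda_fraction = lambda_fraction,
             lambda_length = lambda_length, seed = seed, ...)
}

# a tiny hand-made aligned placement row for constructed-case tests:
# a plus-strand fragment whose R1 aligns full-length and ungapped
make_placed_row <- function(id, contig, r1_query, start0, frag_strand = "+",
                            r1_keep = nchar(r1_query),
                            anchor_query = NULL, r2_start0 = NA_integer_) {
  alen <- if (is.null(anchor_query)) 0L else nchar(anchor_query)
  data.frame(
    id = id, status = "placed", contig = contig, frag_strand = frag_strand,
    r2_strand = if (frag_strand == "+") "-" else "+",
    r2_start0 = r2_start0, r2_end0 = r2_start0 + alen, r2_score = 5 * alen,
    r2_cigar = if (alen) sprintf("%dM", alen) else "",
    r2_qoff = 0L, r2_qend = alen,
    anchor_query = if (is.null(anchor_query)) "" else anchor_query,
    anchor_len = alen, n_candidates = 1L, r1_query = r1_query,
    r1_len = nchar(r1_query), r1_aln_start0 = start0,
    r1_aln_end0 = start0 + nchar(r1_query), r1_score = 5 * nchar(r1_query),
    r1_cigar = sprintf("%dM", nchar(r1_query)), r1_qoff = 0L,
    r1_qend = nchar(r1_query), pair_distance = NA_integer_,
    r1_keep = r1_keep, r2_keep = alen, stringsAsFactors = FALSE)
}
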