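# Independent oracles, coded without reference to the package internals.

# plain-R textbook local-alignment DP, score only
oracle_sw_score <- function(q, t, match = 5, mismatch = 0, gap = -6,
                            mode = "off") {
  qc <- strsplit(q, "")[[1L]]
  tc <- strsplit(t, "")[[1L]]
  nq <- length(qc); nt <- length(tc)
  S <- matrix(0, nq + 1L, nt + 1L)
  best <- 0
  for (i in seq_len(nq)) {
    for (j in seq_len(nt)) {
      m <- if (qc[i] == "N" || tc[j] == "N") FALSE
      else qc[i] == tc[j] ||
        (mode == "CT" && tc[j] == "C" && qc[i] == "T") ||
        (mode == "GA" && tc[j] == "G" && qc[i] == "A")
      S[i + 1L, j + 1L] <- max(0, S[i, j] + if (m) match else mismatch,
                               S[i, j + 1L] + gap, S[i + 1L, j] + gap)
      best <- max(best, S[i + 1L, j + 1L])
    }
  }
  best
}

# exhaustive dinucleotide scan for the Read2 boundary rule
oracle_boundary <- function(seq, min_len = 35L) {
  n <- nchar(seq)
  last <- NA_integer_
  if (n >= 2L) {
    for (i in 2:n) {
      di <- substr(seq, i - 1L, i)
      if (di %in% c("AG", "TG", "GG")) last <- i  # 1-based G position
    }
  }
  if (is.na(last)) {
    list(boundary = NA_integer_, reason = "no_boundary")
  } else if (last < min_len) {
    list(boundary = last, reason = "too_short")
  } else {
    list(boundary = last, reason = "ok")
  }
}

random_dna <- function(n, alphabet = c("A", "C", "G", "T"),
                       prob = NULL) {
  paste(sample(alphabet, n, replace = TRUE, prob = prob), collapse = "")
}
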