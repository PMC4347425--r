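# Independent oracles used by the unit and acceptance tests.

# Brute-force longest-ORF search: enumerate every ATG on both strands and
# walk codon-by-codon to the first stop (or the end). Deliberately written
# as a per-ATG enumeration, unlike the per-frame scan in the package.
orf_oracle <- function(seq, both_strands = TRUE) {
  n <- nchar(seq)
  stops <- c("TAA", "TAG", "TGA")
  best <- NULL
  strands <- if (both_strands) c("+", "-") else "+"
  for (strand in strands) {
    s <- if (strand == "+") seq else reverse_complement(seq)
    for (st in seq_len(n - 2L)) {
      if (substr(s, st, st + 2L) != "ATG") next
      starts <- seq(st, n - 2L, by = 3L)
      cods <- substring(s, starts, starts + 2L)
      stop_idx <- which(cods %in% stops)
      if (length(stop_idx) > 0L) {
        len_nt <- 3L * stop_idx[1L]
        has_stop <- TRUE
      } else {
        len_nt <- 3L * length(cods)
        has_stop <- FALSE
      }
      if (strand == "+") {
        start0 <- st - 1L
      } else {
        start0 <- n - (st - 1L) - len_nt
      }
      cand <- list(start = start0, end = start0 + len_nt, strand = strand,
                   length_nt = len_nt, has_stop = has_stop)
      if (is.null(best) || cand$length_nt > best$length_nt ||
          (cand$length_nt == best$length_nt &&
             (cand$start < best$start ||
                (cand$start == best$start && cand$strand == "+" &&
                   best$strand == "-")))) {
        best <- cand
      }
    }
  }
  best
}

# Full Smith-Waterman score over both strands via Biostrings, matching the
# package's scoring (match +1, mismatch -2, gap open -3, gap extend -1;
# Biostrings expresses the same affine cost as gapOpening = 2,
# gapExtension = 1).
sw_oracle_score <- function(query, target) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2,
                                                  baseOnly = TRUE)
  fwd <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(query), Biostrings::DNAString(target),
    type = "local", substitutionMatrix = mat,
    gapOpening = 2, gapExtension = 1)
  rev <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(reverse_complement(query)),
    Biostrings::DNAString(target),
    type = "local", substitutionMatrix = mat,
    gapOpening = 2, gapExtension = 1)
  max(Biostrings::score(fwd), Biostrings::score(rev))
}

# Random planted-homology alignment instance: a query mutated to a given
# identity and embedded in random background, on a random strand.
random_alignment_instance <- function(i, identity = NULL,
                                      qlen_range = c(150, 300),
                                      tlen_range = c(800, 2000)) {
  withr::with_seed(10000L + i, {
    qlen <- sample(qlen_range[1]:qlen_range[2], 1L)
    tlen <- sample(tlen_range[1]:tlen_range[2], 1L)
    if (is.null(identity)) identity <- sample(c(85, 88, 92, 96, 100), 1L)
    strand <- sample(c("+", "-"), 1L)
    q <- simulate_genome(qlen, id = "q")[[1L]]
    backbone <- simulate_genome(tlen, id = "t")
    mut <- mutate_to_identity(q, identity)
    planted <- plant_gene(backbone, mut$seq, 1, strand)
    list(query = q, target = planted$genome, identity = identity,
         strand = strand)
  })
}
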