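# Functional / pseudogene curation of OR genes.
#
# An OR is called a pseudogene when it has no ORF, when its longest ORF is
# shorter than the coding-length threshold (900 nt by default, stop codon
# included), or when its annotation flags a frameshift. A curated override
# list can force individual genes to functional status while retaining the
# original reasons (the OR14L1P-style exception: 293 aa, all family motifs
# present, only slightly N-terminally short).

#' Default OR-family motif set
#'
#' Consensus patterns characteristic of the OR family, scanned with one
#' mismatch allowed each: the MAYDRYVAIC region around the TM3/DRY box, the
#' KAFSTCASH region of TM6, and the PMLNPFIY region containing the NPxxY-like
#' motif. The set is data, not code: supply your own data frame with columns
#' `name`, `pattern`, `max_mismatch`, `rel_pos` to change it. `rel_pos` is
#' the canonical position of the motif start as a fraction of protein length
#' (used by the simulator when planting motifs).
#'
#' @return A data frame with columns `name`, `pattern`, `max_mismatch`,
#'   `rel_pos`.
#' @export
or_default_motifs <- function() {
  data.frame(
    name = c("DRY_box", "TM6_KAFSTC", "NPxxY"),
    pattern = c("MAYDRYVAIC", "KAFSTCASH", "PMLNPFIY"),
    max_mismatch = c(1L, 1L, 1L),
    rel_pos = c(0.38, 0.77, 0.92)
  )
}

#' Scan a protein for OR-family motifs
#'
#' Each pattern is slid along the protein and matches when the Hamming
#' distance at some offset is at most `max_mismatch`.
#'
#' @param prot Protein string.
#' @param motifs Motif table as in [or_default_motifs()].
#' @return A list with `per_motif` (data frame: `name`, `pattern`, `matched`,
#'   `position` 0-based start or NA, `mismatches`) and `all_present`.
#' @export
scan_or_motifs <- function(prot, motifs = or_default_motifs()) {
  if (!is.character(prot) || length(prot) != 1L || is.na(prot) ||
      nchar(prot) == 0L) {
    stop("protein sequence must be a non-empty string")
  }
  if (!is.data.frame(motifs) || nrow(motifs) == 0L) {
    stop("motif set must be a non-empty data frame")
  }
  pchars <- strsplit(prot, "")[[1L]]
  n <- length(pchars)
  rows <- lapply(seq_len(nrow(motifs)), function(i) {
    pat <- strsplit(motifs$pattern[i], "")[[1L]]
    m <- length(pat)
    best_pos <- NA_integer_
    best_mm <- m + 1L
    if (n >= m) {
      for (off in 0:(n - m)) {
        mm <- sum(pchars[off + seq_len(m)] != pat)
        if (mm < best_mm) {
          best_mm <- mm
          best_pos <- off
          if (mm == 0L) break
        }
      }
    }
    matched <- best_mm <= motifs$max_mismatch[i]
    data.frame(name = motifs$name[i], pattern = motifs$pattern[i],
               matched = matched,
               position = if (matched) best_pos else NA_integer_,
               mismatches = if (matched) best_mm else NA_integer_)
  })
  per_motif <- do.call(rbind, rows)
  list(per_motif = per_motif, all_present = all(per_motif$matched))
}

#' Classify one OR gene as functional or pseudogene
#'
#' Status follows the longest-ORF length against `min_coding_nt`:
#' pseudogene if and only if the coding region is absent or shorter than the
#' threshold (a gene of exactly `min_coding_nt` is functional), or if the
#' annotation carries a frameshift flag. `include_stop` controls whether the
#' stop codon counts toward the coding length (default yes). Overrides force
#' `functional` while retaining the reasons and setting `overridden = TRUE`.
#'
#' @param gene Nucleotide string.
#' @param gene_id Identifier.
#' @param min_coding_nt Coding-length threshold in nucleotides (default 900).
#' @param overrides Optional data frame with columns `gene_id`,
#'   `justification`.
#' @param frameshift_annotated Logical annotation-level frameshift flag.
#' @param include_stop Count the stop codon inside the coding length?
#' @param motifs Motif set scanned on the ORF translation (for the report
#'   only; motifs do not gate the status).
#' @return A list of class `curation_decision`: `gene_id`, `status`,
#'   `coding_length_nt`, `reasons`, `overridden`, `justification`,
#'   `motif_report`.
#' @export
classify_or_gene <- function(gene, gene_id, min_coding_nt = 900L,
                             overrides = NULL, frameshift_annotated = FALSE,
                             include_stop = TRUE,
                             motifs = or_default_motifs()) {
  if (min_coding_nt <= 0L) stop("min_coding_nt must be positive")
  if (!nzchar(gene)) stop(gene_id, ": empty sequence")
  orf <- find_longest_orf(gene)
  reasons <- character(0)
  if (is.null(orf)) {
    coding_len <- 0L
    reasons <- "no_orf"
    motif_report <- NULL
  } else {
    coding_len <- orf$length_nt
    if (!include_stop && orf$has_stop) coding_len <- coding_len - 3L
    if (coding_len < min_coding_nt) reasons <- "short_orf"
    motif_report <- scan_or_motifs(orf_translation(gene), motifs)
  }
  if (isTRUE(frameshift_annotated)) {
    reasons <- c(reasons, "frameshift_annotation")
  }
  overridden <- FALSE
  justification <- NA_character_
  if (length(reasons) > 0L && !is.null(overrides) &&
      gene_id %in% overrides$gene_id) {
    overridden <- TRUE
    justification <- overrides$justification[match(gene_id,
                                                   overrides$gene_id)]
  }
  status <- if (length(reasons) == 0L || overridden) {
    "functional"
  } else {
    "pseudogene"
  }
  structure(list(gene_id = gene_id, status = status,
                 coding_length_nt = coding_len, reasons = reasons,
                 overridden = overridden, justification = justification,
                 motif_report = motif_report),
            class = "curation_decision")
}

#' Curate a set of OR genes
#'
#' @param genes Named character vector of nucleotide sequences.
#' @param min_coding_nt Threshold, see [classify_or_gene()].
#' @param overrides Optional override data frame (`gene_id`,
#'   `justification`).
#' @param frameshift_ids Character vector of gene ids whose annotation flags
#'   a frameshift.
#' @param include_stop See [classify_or_gene()].
#' @param motifs Motif set.
#' @return Data frame: `gene_id`, `status`, `coding_length_nt`, `reasons`
#'   (comma-joined), `overridden`, `all_motifs_present`.
#' @export
curate_or_set <- function(genes, min_coding_nt = 900L, overrides = NULL,
                          frameshift_ids = character(0), include_stop = TRUE,
                          motifs = or_default_motifs()) {
  if (is.null(names(genes)) || any(names(genes) == "")) {
    stop("all genes must be named")
  }
  rows <- lapply(names(genes), function(id) {
    d <- classify_or_gene(genes[[id]], id, min_coding_nt = min_coding_nt,
                          overrides = overrides,
                          frameshift_annotated = id %in% frameshift_ids,
                          include_stop = include_stop, motifs = motifs)
    data.frame(gene_id = d$gene_id, status = d$status,
               coding_length_nt = d$coding_length_nt,
               reasons = paste(d$reasons, collapse = ","),
               overridden = d$overridden,
               all_motifs_present = if (is.null(d$motif_report)) NA
                                    else d$motif_report$all_present)
  })
  do.call(rbind, rows)
}

#' Read an override list
#'
#' Tab-separated file with columns `gene_id` and `justification`.
#'
#' @param path File path.
#' @return Data frame.
#' @export
read_override_list <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene_id", "justification") %in% names(df))) {
    stop("override list needs columns gene_id and justification")
  }
  df
}
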