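# Sequence containers are plain named character vectors (id -> residues);
# FASTA input/output goes through Biostrings.

DNA_ALPHABET <- c("A", "C", "G", "T", "N")
STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Validate a nucleotide sequence
#'
#' Checks that a sequence contains only A, C, G, T or N (case-insensitive)
#' and reports the position of the first offending character otherwise.
#'
#' @param x A single character string.
#' @param id Identifier used in error messages.
#' @return The sequence, upper-cased, invisibly usable downstream.
#' @keywords internal
check_nuc <- function(x, id = "sequence") {
  if (!is.character(x) || length(x) != 1L || is.na(x)) {
    stop(id, ": a nucleotide sequence must be a single character string")
  }
  x <- toupper(x)
  bad <- regexpr("[^ACGTN]", x)
  if (bad > 0L) {
    stop(sprintf("%s: invalid character '%s' at position %d",
                 id, substr(x, bad, bad), bad))
  }
  x
}

#' Reverse complement of a nucleotide sequence
#'
#' @param x A single nucleotide string over A, C, G, T, N.
#' @return The reverse complement, upper case.
#' @examples
#' reverse_complement("ATGC")
#' @export
reverse_complement <- function(x) {
  x <- check_nuc(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Read sequences from a FASTA file
#'
#' @param path Path to a (possibly multi-record) FASTA file.
#' @param type `"dna"` or `"protein"`.
#' @return A named character vector, names taken from the first word of each
#'   FASTA header.
#' @export
read_fasta <- function(path, type = c("dna", "protein")) {
  type <- match.arg(type)
  set <- if (type == "dna") {
    Biostrings::readDNAStringSet(path)
  } else {
    Biostrings::readAAStringSet(path)
  }
  out <- as.character(set)
  names(out) <- vapply(strsplit(names(set), "\\s+"), `[`, "", 1L)
  if (anyDuplicated(names(out))) {
    stop("duplicate record ids in ", path)
  }
  out
}

#' Write sequences to a FASTA file
#'
#' Records are wrapped at 60 columns. A write followed by [read_fasta()]
#' preserves ids and residues byte-exactly.
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param type `"dna"` or `"protein"`.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, type = c("dna", "protein")) {
  type <- match.arg(type)
  if (is.null(names(seqs)) || any(names(seqs) == "")) {
    stop("all sequences must be named")
  }
  set <- if (type == "dna") {
    Biostrings::DNAStringSet(seqs)
  } else {
    Biostrings::AAStringSet(seqs)
  }
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' Translate a nucleotide sequence in a given frame
#'
#' Standard genetic code; a trailing partial codon is dropped; stop codons
#' are rendered as `*`; codons containing N translate to `X` (and N-containing
#' codons never act as start or stop elsewhere in the package).
#'
#' @param nuc Nucleotide string over A, C, G, T, N.
#' @param frame Frame offset, 0, 1 or 2.
#' @return A single protein string.
#' @examples
#' translate_seq("ATGGCT")       # "MA"
#' translate_seq("CATGGC", 1)    # "MG"
#' @export
translate_seq <- function(nuc, frame = 0L) {
  nuc <- check_nuc(nuc)
  if (!frame %in% 0:2) stop("frame must be 0, 1 or 2")
  if (nchar(nuc) - frame < 3L) stop("sequence too short to translate")
  codons <- codon_split(nuc, frame)
  paste(codon_translate(codons), collapse = "")
}

# split into complete codons starting at 0-based offset `frame`
codon_split <- function(nuc, frame = 0L) {
  n <- nchar(nuc)
  n_codons <- (n - frame) %/% 3L
  if (n_codons < 1L) return(character(0))
  starts <- frame + 3L * (seq_len(n_codons) - 1L) + 1L
  substring(nuc, starts, starts + 2L)
}

codon_translate <- function(codons) {
  code <- Biostrings::GENETIC_CODE
  aa <- unname(code[codons])
  aa[is.na(aa)] <- "X" # codons containing N
  aa
}

#' Find the longest open reading frame
#'
#' Scans all six frames (three if `both_strands = FALSE`) for ATG-to-stop
#' spans. An ORF runs from an ATG to the first in-frame stop codon; when no
#' stop follows, it extends to the end of the sequence and is flagged
#' (`has_stop = FALSE`). The stop codon is counted inside `length_nt`, so a
#' 293-residue protein plus its stop spans 882 nt. Ties on length are broken
#' in favour of the earlier start, then the forward strand.
#'
#' Coordinates are 0-based half-open on the forward strand of the input; a
#' minus-strand ORF is reported with its reverse-complement hit re-mapped to
#' forward offsets.
#'
#' @param nuc Nucleotide string.
#' @param both_strands Search the reverse complement too? Default `TRUE`.
#' @return A list with `start`, `end`, `strand`, `frame`, `length_nt`,
#'   `length_aa`, `has_stop`, or `NULL` when no ATG-initiated span exists.
#' @examples
#' find_longest_orf("AAATGGCTTAAAA")  # start 2, end 11, 9 nt, 2 aa
#' @export
find_longest_orf <- function(nuc, both_strands = TRUE) {
  nuc <- check_nuc(nuc)
  n <- nchar(nuc)
  if (n < 3L) stop("sequence shorter than one codon")
  strands <- if (both_strands) c("+", "-") else "+"
  cand <- list()
  for (strand in strands) {
    s <- if (strand == "+") nuc else reverse_complement(nuc)
    for (frame in 0:2) {
      codons <- codon_split(s, frame)
      if (length(codons) == 0L) next
      atg <- which(codons == "ATG")
      if (length(atg) == 0L) next
      stops <- which(codons %in% STOP_CODONS)
      for (a in atg) {
        nxt <- stops[stops >= a]
        if (length(nxt) > 0L) {
          last <- nxt[1L]
          has_stop <- TRUE
        } else {
          last <- length(codons)
          has_stop <- FALSE
        }
        len_codons <- last - a + 1L
        start_local <- frame + 3L * (a - 1L)
        end_local <- start_local + 3L * len_codons
        if (strand == "+") {
          start <- start_local; end <- end_local
        } else {
          start <- n - end_local; end <- n - start_local
        }
        cand[[length(cand) + 1L]] <- list(
          start = start, end = end, strand = strand, frame = frame,
          length_nt = 3L * len_codons,
          length_aa = if (has_stop) len_codons - 1L else len_codons,
          has_stop = has_stop
        )
      }
    }
  }
  if (length(cand) == 0L) return(NULL)
  len <- vapply(cand, `[[`, 0L, "length_nt")
  st <- vapply(cand, `[[`, 0L, "start")
  minus <- vapply(cand, `[[`, "", "strand") == "-"
  ord <- order(-len, st, minus)
  cand[[ord[1L]]]
}

#' Tabulate the longest ORF of each sequence
#'
#' @param seqs Named character vector of nucleotide sequences.
#' @param both_strands Passed to [find_longest_orf()].
#' @return A data frame with one row per sequence: `seq_id`, `strand`,
#'   `start`, `end`, `length_nt`, `length_aa`, `has_stop` (NA rows where no
#'   ORF exists).
#' @export
orf_report <- function(seqs, both_strands = TRUE) {
  rows <- lapply(names(seqs), function(id) {
    orf <- find_longest_orf(seqs[[id]], both_strands = both_strands)
    if (is.null(orf)) {
      data.frame(seq_id = id, strand = NA_character_, start = NA_integer_,
                 end = NA_integer_, length_nt = 0L, length_aa = 0L,
                 has_stop = NA)
    } else {
      data.frame(seq_id = id, strand = orf$strand, start = orf$start,
                 end = orf$end, length_nt = orf$length_nt,
                 length_aa = orf$length_aa, has_stop = orf$has_stop)
    }
  })
  do.call(rbind, rows)
}

#' Translate the longest ORF of a gene
#'
#' Convenience used by curation and the identity matrix: extracts the longest
#' ORF and returns its translation without the trailing stop.
#'
#' @param nuc Nucleotide string.
#' @return Protein string, or `NA_character_` when no ORF exists.
#' @export
orf_translation <- function(nuc) {
  orf <- find_longest_orf(nuc)
  if (is.null(orf)) return(NA_character_)
  s <- if (orf$strand == "+") nuc else reverse_complement(nuc)
  n <- nchar(nuc)
  loc_start <- if (orf$strand == "+") orf$start else n - orf$end
  cds <- substr(s, loc_start + 1L, loc_start + orf$length_nt)
  aa <- paste(codon_translate(codon_split(cds)), collapse = "")
  sub("\\*$", "", aa)
}
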