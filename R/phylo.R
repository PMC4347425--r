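# Pairwise amino-acid identity and distance-based phylogeny.
#
# Identity convention: after dropping columns gapped in both sequences of a
# pair and stripping terminal-gap columns, identity is 100 * identical
# columns / remaining columns, so internal gap columns count against
# identity. Distances are (100 - identity) / 100 and trees are built by
# neighbor joining (ape), with bootstrap support from column resampling of
# an alignment.

# identity of one aligned pair given as two equal-length strings
aln_identity <- function(a, b) {
  av <- strsplit(a, "")[[1L]]
  bv <- strsplit(b, "")[[1L]]
  if (length(av) != length(bv)) stop("aligned sequences differ in length")
  keep <- !(av == "-" & bv == "-")
  av <- av[keep]; bv <- bv[keep]
  if (length(av) == 0L) return(NA_real_)
  gap <- av == "-" | bv == "-"
  core <- which(!gap)
  if (length(core) == 0L) return(0)
  idx <- core[1L]:core[length(core)] # strip terminal-gap columns
  100 * sum(av[idx] == bv[idx] & av[idx] != "-") / length(idx)
}

#' Pairwise percent-identity matrix of proteins
#'
#' `pairwise_global` mode aligns each pair with Needleman-Wunsch (affine
#' gaps, BLOSUM62) via Biostrings and applies the identity rule above;
#' `from_msa` mode applies the same rule per pair on an already-aligned set
#' (equal-length strings with `-` gaps). Each unordered pair is aligned
#' once, so the matrix is exactly symmetric; the diagonal is 100.
#'
#' @param prots Named character vector of protein sequences (aligned rows
#'   in `from_msa` mode).
#' @param mode `"pairwise_global"` or `"from_msa"`.
#' @param gap_opening,gap_extension Affine gap penalties for global
#'   alignment (Biostrings convention, positive costs).
#' @return Square numeric matrix of percentages with the ids as dimnames.
#' @examples
#' pairwise_identity_matrix(c(a = "ACDEFGHIK", b = "ACDEFGHIR"))
#' @export
pairwise_identity_matrix <- function(prots,
                                     mode = c("pairwise_global", "from_msa"),
                                     gap_opening = 10, gap_extension = 0.5) {
  mode <- match.arg(mode)
  n <- length(prots)
  if (n < 2L) stop("at least two sequences required")
  if (is.null(names(prots)) || any(names(prots) == "")) {
    stop("all sequences must be named")
  }
  if (anyDuplicated(names(prots))) stop("duplicate sequence ids")
  if (any(!nzchar(gsub("-", "", prots)))) stop("empty sequence supplied")
  if (mode == "from_msa" && length(unique(nchar(prots))) != 1L) {
    stop("from_msa mode requires equal-length aligned sequences")
  }
  m <- matrix(100, n, n, dimnames = list(names(prots), names(prots)))
  if (mode == "pairwise_global") {
    data(list = "BLOSUM62", package = "Biostrings",
         envir = environment())
    submat <- get("BLOSUM62", envir = environment())
  }
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (mode == "from_msa") {
        id <- aln_identity(prots[[i]], prots[[j]])
      } else {
        pa <- Biostrings::pairwiseAlignment(
          Biostrings::AAString(prots[[i]]),
          Biostrings::AAString(prots[[j]]),
          type = "global", substitutionMatrix = submat,
          gapOpening = gap_opening, gapExtension = gap_extension)
        id <- aln_identity(
          as.character(Biostrings::alignedPattern(pa)),
          as.character(Biostrings::alignedSubject(pa)))
      }
      m[i, j] <- id
      m[j, i] <- id
    }
  }
  m
}

#' Convert an identity matrix to a distance matrix
#'
#' @param identity Percent-identity matrix.
#' @return `(100 - identity) / 100`, a dissimilarity in \[0, 1\].
#' @export
identity_to_distance <- function(identity) {
  (100 - identity) / 100
}

#' Neighbor-joining tree from a distance matrix
#'
#' Canonical neighbor joining (via \pkg{ape}); exact on additive distances.
#' Negative branch lengths are clamped to zero, with the raw lengths kept in
#' the `edge.length.raw` attribute.
#'
#' @param dist Symmetric numeric matrix with zero diagonal and labels as
#'   dimnames.
#' @return An unrooted `phylo` tree.
#' @export
build_nj_tree <- function(dist) {
  if (!is.matrix(dist) || nrow(dist) != ncol(dist)) {
    stop("dist must be a square matrix")
  }
  if (max(abs(dist - t(dist))) > 1e-8) stop("dist must be symmetric")
  if (any(abs(diag(dist)) > 1e-8)) stop("dist must have a zero diagonal")
  tree <- ape::nj(dist)
  raw <- tree$edge.length
  tree$edge.length <- pmax(raw, 0)
  attr(tree, "edge.length.raw") <- raw
  tree
}

#' Bootstrap support for the identity-distance NJ tree
#'
#' Builds the full-data tree from an alignment (identity -> distance -> NJ),
#' then resamples alignment columns with replacement `n_reps` times,
#' rebuilds a tree per replicate, and annotates each internal node of the
#' full tree with the percentage of replicates containing its bipartition.
#' Columns that end up all-gap for a pair are handled by the identity rule
#' (dropped for that pair). Seeded and reproducible.
#'
#' @param msa Named character vector of equal-length aligned proteins.
#' @param n_reps Number of bootstrap replicates (default 100).
#' @param seed Integer seed (optional).
#' @return The full-data `phylo` tree with `node.label` set to supports in
#'   \[0, 100\] (the root label is empty) and attributes `n_reps`, `seed`.
#' @export
bootstrap_support <- function(msa, n_reps = 100L, seed = NULL) {
  if (n_reps < 1L) stop("n_reps must be at least 1")
  if (length(unique(nchar(msa))) != 1L) {
    stop("msa must contain equal-length aligned sequences")
  }
  ncol <- unique(nchar(msa))
  if (ncol < 1L) stop("alignment has no columns")
  full <- build_nj_tree(identity_to_distance(
    pairwise_identity_matrix(msa, mode = "from_msa")))
  chars <- do.call(rbind, strsplit(msa, ""))
  run <- function() {
    reps <- vector("list", n_reps)
    for (r in seq_len(n_reps)) {
      cols <- sample.int(ncol, ncol, replace = TRUE)
      boot <- apply(chars[, cols, drop = FALSE], 1L, paste, collapse = "")
      names(boot) <- names(msa)
      reps[[r]] <- build_nj_tree(identity_to_distance(
        pairwise_identity_matrix(boot, mode = "from_msa")))
    }
    reps
  }
  reps <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  counts <- ape::prop.clades(full, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  support <- round(100 * counts / n_reps, 1)
  full$node.label <- as.character(support)
  attr(full, "n_reps") <- n_reps
  attr(full, "seed") <- seed
  full
}

#' Write a support-annotated tree to Newick
#'
#' @param tree `phylo` tree (supports in `node.label`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tree_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Write an identity matrix as a tab-separated table
#'
#' Square table with a header row and a leading label column.
#'
#' @param m Identity matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_identity_matrix <- function(m, path) {
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
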