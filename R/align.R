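# Seed-and-extend local alignment, BLAT-style in spirit: exact k-mer seeds
# locate candidate diagonals, candidate regions get a full local
# dynamic-programming pass with affine gaps (the C++ kernel in
# src/seedextend.cpp), and hits at or above a minimum score are reported.

#' Default alignment parameters
#'
#' Match +1, mismatch -2, gap open -3, gap extend -1, k-mer size 11, minimum
#' reported score 30, diagonal band padding 50. Loosely modelled on the
#' defaults of k-mer seeded genome aligners for same-species to
#' close-species DNA searches. When a primary pass at `k` finds no hit, the
#' search re-seeds once at `fallback_k` (default 8, the smallest allowed
#' seed) so weakly conserved counterparts lacking an exact long k-mer are
#' still found.
#'
#' @return A named list.
#' @export
align_params <- function(k = 11L, match = 1, mismatch = -2, gap_open = -3,
                         gap_extend = -1, min_score = 30, band_pad = 50L,
                         fallback_k = 8L) {
  if (k < 8L || fallback_k < 8L) stop("k must be at least 8")
  if (k > 15L) stop("k must be at most 15")
  if (fallback_k > k) stop("fallback_k cannot exceed k")
  if (gap_open > 0 || gap_extend > 0 || mismatch > 0) {
    stop("mismatch and gap scores must be non-positive")
  }
  list(k = as.integer(k), match = match, mismatch = mismatch,
       gap_open = gap_open, gap_extend = gap_extend, min_score = min_score,
       band_pad = as.integer(band_pad), fallback_k = as.integer(fallback_k))
}

# one strand of one contig: seeds -> diagonal clusters -> merged target
# windows -> local DP per window
align_one <- function(qseq, tseq, params) {
  seeds <- cpp_seed_hits(qseq, tseq, params$k)
  if (nrow(seeds) == 0L) return(NULL)
  diag <- seeds[, "tpos"] - seeds[, "qpos"]
  ord <- order(diag, seeds[, "tpos"])
  diag <- diag[ord]
  tpos <- seeds[ord, "tpos"]
  qlen <- nchar(qseq)
  tlen <- nchar(tseq)
  # cluster on the diagonal (split where it jumps more than the band
  # padding), then within a cluster on target position (split across
  # tandem copies)
  brk <- which(diff(diag) > params$band_pad)
  starts <- c(1L, brk + 1L)
  ends <- c(brk, length(diag))
  windows <- list()
  for (ci in seq_along(starts)) {
    idx <- starts[ci]:ends[ci]
    o2 <- idx[order(tpos[idx])]
    tp <- tpos[o2]
    sub_brk <- which(diff(tp) > qlen)
    sub_starts <- c(1L, sub_brk + 1L)
    sub_ends <- c(sub_brk, length(tp))
    for (si in seq_along(sub_starts)) {
      sidx <- o2[sub_starts[si]:sub_ends[si]]
      d_lo <- min(diag[sidx]); d_hi <- max(diag[sidx])
      w_start <- max(0L, d_lo - params$band_pad)
      w_end <- min(tlen, d_hi + qlen + params$band_pad)
      windows[[length(windows) + 1L]] <- c(w_start, w_end)
    }
  }
  # merge overlapping windows so each target region is aligned once
  wm <- do.call(rbind, windows)
  wm <- wm[order(wm[, 1L]), , drop = FALSE]
  merged <- list()
  cur <- wm[1L, ]
  for (i in seq_len(nrow(wm))[-1L]) {
    if (wm[i, 1L] <= cur[2L]) {
      cur[2L] <- max(cur[2L], wm[i, 2L])
    } else {
      merged[[length(merged) + 1L]] <- cur
      cur <- wm[i, ]
    }
  }
  merged[[length(merged) + 1L]] <- cur
  hits <- list()
  for (w in merged) {
    hit <- cpp_sw(qseq, substr(tseq, w[1L] + 1L, w[2L]),
                  params$match, params$mismatch, params$gap_open,
                  params$gap_extend)
    if (hit$score >= params$min_score) {
      hit$t_start <- hit$t_start + w[1L]
      hit$t_end <- hit$t_end + w[1L]
      hits[[length(hits) + 1L]] <- hit
    }
  }
  if (length(hits) == 0L) return(NULL)
  df <- do.call(rbind, lapply(hits, as.data.frame))
  unique(df)
}

#' Seed-and-extend local alignment of a query against target contigs
#'
#' Exact k-mer seeds are grouped into diagonal clusters; each cluster's
#' region of the target is aligned to the query by full local dynamic
#' programming with affine gaps, so within a seeded region the reported
#' score is the Smith-Waterman optimum. Both strands are searched; a
#' minus-strand hit carries forward-strand query coordinates with
#' `strand == "-"` meaning the query matches the reverse complement of the
#' target span. Deterministic for fixed inputs and parameters.
#'
#' @param query Nucleotide string.
#' @param targets Named character vector of target contigs (a single
#'   unnamed string is accepted and named `"target"`).
#' @param params See [align_params()].
#' @param query_id Identifier stored in the hits.
#' @return A data frame of hits sorted by score (ties: more matches, then
#'   smaller `t_start`): `query_id`, `target_id`, `strand`, `q_start`,
#'   `q_end`, `t_start`, `t_end`, `matches`, `aligned_cols`, `gap_cols`,
#'   `score`. Zero rows when nothing reaches `min_score`.
#' @export
seed_and_extend_align <- function(query, targets, params = align_params(),
                                  query_id = "query") {
  query <- check_nuc(query, query_id)
  if (nchar(query) < params$k) {
    stop("query shorter than the seed size k = ", params$k)
  }
  if (length(targets) == 0L) stop("no target contigs supplied")
  if (is.null(names(targets))) {
    if (length(targets) == 1L) names(targets) <- "target"
    else stop("multi-contig targets must be named")
  }
  qlen <- nchar(query)
  qrc <- reverse_complement(query)
  search_pass <- function(p) {
    rows <- list()
    for (tid in names(targets)) {
      tseq <- check_nuc(targets[[tid]], tid)
      for (strand in c("+", "-")) {
        qseq <- if (strand == "+") query else qrc
        hits <- align_one(qseq, tseq, p)
        if (is.null(hits)) next
        if (strand == "-") {
          qs <- qlen - hits$q_end
          qe <- qlen - hits$q_start
          hits$q_start <- qs
          hits$q_end <- qe
        }
        hits$query_id <- query_id
        hits$target_id <- tid
        hits$strand <- strand
        rows[[length(rows) + 1L]] <- hits
      }
    }
    rows
  }
  rows <- search_pass(params)
  fb <- params$fallback_k
  if (length(rows) == 0L && !is.null(fb) && fb < params$k &&
      qlen >= fb) {
    params$k <- fb
    rows <- search_pass(params)
  }
  cols <- c("query_id", "target_id", "strand", "q_start", "q_end",
            "t_start", "t_end", "matches", "aligned_cols", "gap_cols",
            "score")
  if (length(rows) == 0L) {
    out <- data.frame(query_id = character(0), target_id = character(0),
                      strand = character(0), q_start = integer(0),
                      q_end = integer(0), t_start = integer(0),
                      t_end = integer(0), matches = integer(0),
                      aligned_cols = integer(0), gap_cols = integer(0),
                      score = numeric(0))
    return(out)
  }
  out <- do.call(rbind, rows)[, cols]
  out <- out[order(-out$score, -out$matches, out$t_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Identity and coverage of the best hit
#'
#' The best hit is the highest score, ties broken by more matches, then the
#' smaller target start. Identity is `100 * matches / aligned_cols` of the
#' best hit, with gap columns counting against identity
#' (`mode = "all_columns"`, the default) or excluded
#' (`mode = "match_mismatch"`). Coverage is the aligned fraction of the
#' query from the single best hit: `100 * (q_end - q_start) / query_len`.
#'
#' @param hits Hit data frame from [seed_and_extend_align()].
#' @param query_len Query length in nucleotides.
#' @param mode Identity denominator convention.
#' @return List: `identity_pct`, `coverage_pct`, `best_hit` (one-row data
#'   frame or `NULL`). An empty hit list yields `(0, 0)`.
#' @export
summarize_best_hit <- function(hits, query_len,
                               mode = c("all_columns", "match_mismatch")) {
  mode <- match.arg(mode)
  if (query_len <= 0) stop("query_len must be positive")
  if (is.null(hits) || nrow(hits) == 0L) {
    return(list(identity_pct = 0, coverage_pct = 0, best_hit = NULL))
  }
  ord <- order(-hits$score, -hits$matches, hits$t_start)
  best <- hits[ord[1L], , drop = FALSE]
  denom <- if (mode == "all_columns") {
    best$aligned_cols
  } else {
    best$aligned_cols - best$gap_cols
  }
  list(identity_pct = 100 * best$matches / denom,
       coverage_pct = 100 * (best$q_end - best$q_start) / query_len,
       best_hit = best)
}
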