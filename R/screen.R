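# Cross-species presence/absence screening and lineage classification.
#
# A query OR is "present" in a species when its best local hit against that
# species' genome reaches both the identity and the coverage threshold
# (70% / 70% by default, both inclusive). Queries absent from chimpanzee,
# dog, mouse and rat are human-only; present in chimpanzee but absent from
# dog, mouse and rat are human+chimpanzee-only; anything else is shared.

SCREEN_SPECIES <- c("chimpanzee", "dog", "mouse", "rat")

#' Presence call from identity and coverage
#'
#' Inclusive on both axes: a hit at exactly the thresholds is present.
#'
#' @param identity_pct,coverage_pct Percentages of the best hit.
#' @param id_threshold,cov_threshold Thresholds in (0, 100], default 70.
#' @return Logical (vectorized over the first two arguments).
#' @examples
#' call_presence(70, 70)   # TRUE: boundary is inclusive
#' call_presence(69.9, 99) # FALSE
#' @export
call_presence <- function(identity_pct, coverage_pct, id_threshold = 70,
                          cov_threshold = 70) {
  if (id_threshold <= 0 || id_threshold > 100 ||
      cov_threshold <= 0 || cov_threshold > 100) {
    stop("thresholds must lie in (0, 100]")
  }
  identity_pct >= id_threshold & coverage_pct >= cov_threshold
}

#' Lineage category from per-species presence
#'
#' @param present Named logical vector over exactly the species
#'   `chimpanzee`, `dog`, `mouse`, `rat`.
#' @return `"human_only"` (absent in all four), `"human_chimp_only"`
#'   (present in chimpanzee, absent in dog, mouse and rat) or `"shared"`.
#' @export
classify_lineage <- function(present) {
  if (!setequal(names(present), SCREEN_SPECIES) ||
      length(present) != length(SCREEN_SPECIES)) {
    stop("presence calls required for exactly: ",
         paste(SCREEN_SPECIES, collapse = ", "))
  }
  present <- present[SCREEN_SPECIES]
  if (any(is.na(present))) stop("presence calls must not be NA")
  if (!any(present)) {
    "human_only"
  } else if (present[["chimpanzee"]] && !present[["dog"]] &&
             !present[["mouse"]] && !present[["rat"]]) {
    "human_chimp_only"
  } else {
    "shared"
  }
}

#' Run the full lineage screen
#'
#' Aligns every query against every species genome, summarizes the best hit
#' per (query, species), makes presence calls, classifies lineages and
#' derives the selected set: queries restricted to human (or human plus
#' chimpanzee) that are not curated pseudogenes (unless overridden).
#'
#' @param queries Named character vector of query OR nucleotide sequences.
#' @param genomes Named list over the four screen species; each element a
#'   named character vector of contigs.
#' @param curation Curation data frame from [curate_or_set()] covering every
#'   query.
#' @param params Alignment parameters, see [align_params()].
#' @param id_threshold,cov_threshold Presence thresholds (default 70/70).
#' @param identity_mode Identity denominator, see [summarize_best_hit()].
#' @return List: `calls` (data frame `query_id`, `species`,
#'   `best_identity_pct`, `best_coverage_pct`, `present`), `lineage`
#'   (`query_id`, `category`), `selected` (character vector of query ids),
#'   `counts` (category counts), `failures` (per-species failures, if any).
#' @export
run_lineage_screen <- function(queries, genomes, curation,
                               params = align_params(), id_threshold = 70,
                               cov_threshold = 70,
                               identity_mode = "all_columns") {
  if (length(genomes) == 0L) stop("no genomes supplied")
  if (!setequal(names(genomes), SCREEN_SPECIES)) {
    stop("genomes required for exactly: ",
         paste(SCREEN_SPECIES, collapse = ", "))
  }
  if (is.null(names(queries)) || any(names(queries) == "")) {
    stop("all queries must be named")
  }
  if (!all(names(queries) %in% curation$gene_id)) {
    stop("curation decisions missing for some queries")
  }
  calls <- list()
  failures <- list()
  lineage_rows <- list()
  for (qid in names(queries)) {
    qlen <- nchar(queries[[qid]])
    present <- setNames(rep(NA, length(SCREEN_SPECIES)), SCREEN_SPECIES)
    for (sp in SCREEN_SPECIES) {
      res <- tryCatch({
        hits <- seed_and_extend_align(queries[[qid]], genomes[[sp]],
                                      params = params, query_id = qid)
        summarize_best_hit(hits, qlen, mode = identity_mode)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        failures[[length(failures) + 1L]] <-
          data.frame(query_id = qid, species = sp,
                     message = conditionMessage(res))
        next
      }
      present[[sp]] <- call_presence(res$identity_pct, res$coverage_pct,
                                     id_threshold, cov_threshold)
      calls[[length(calls) + 1L]] <-
        data.frame(query_id = qid, species = sp,
                   best_identity_pct = res$identity_pct,
                   best_coverage_pct = res$coverage_pct,
                   present = present[[sp]])
    }
    if (any(is.na(present))) {
      lineage_rows[[length(lineage_rows) + 1L]] <-
        data.frame(query_id = qid, category = "incomplete")
    } else {
      lineage_rows[[length(lineage_rows) + 1L]] <-
        data.frame(query_id = qid, category = classify_lineage(present))
    }
  }
  calls <- do.call(rbind, calls)
  lineage <- do.call(rbind, lineage_rows)
  restricted <- lineage$query_id[lineage$category %in%
                                   c("human_only", "human_chimp_only")]
  pseudo <- curation$gene_id[curation$status == "pseudogene"]
  selected <- setdiff(restricted, pseudo)
  counts <- as.data.frame(table(category = lineage$category),
                          stringsAsFactors = FALSE)
  names(counts) <- c("category", "n")
  list(calls = calls, lineage = lineage, selected = selected,
       counts = counts,
       failures = if (length(failures)) do.call(rbind, failures) else NULL)
}
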