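# End-to-end orchestration: curate -> homology screen -> identity/phylogeny
# -> (optional) plate quantification, with a self-describing run directory.
# Every output table starts with comment lines echoing the thresholds that
# produced it, and a manifest maps each file to the stage that wrote it.

#' Default run configuration
#'
#' All thresholds of the pipeline in one list: coding-length threshold for
#' curation (900 nt, stop codon included), presence thresholds (70% identity
#' and 70% coverage, inclusive), hit threshold (3e5 AU, strict), QC
#' threshold (transfection fraction 0.70, inclusive), alignment parameters
#' and bootstrap settings.
#'
#' @param seed Integer seed used by every seeded stage.
#' @return A named list understood by [run_end_to_end()].
#' @export
default_run_config <- function(seed = 1L) {
  list(min_coding_nt = 900L, include_stop = TRUE,
       id_threshold = 70, cov_threshold = 70,
       hit_threshold = HIT_THRESHOLD_AU, qc_min = 0.70,
       align = align_params(), identity_mode = "all_columns",
       bootstrap_reps = 100L, seed = as.integer(seed))
}

#' Validate a run configuration
#'
#' Rejects out-of-range thresholds before any computation.
#'
#' @param config Configuration list.
#' @return The config, invisibly, or an error.
#' @export
validate_run_config <- function(config) {
  need <- c("min_coding_nt", "id_threshold", "cov_threshold",
            "hit_threshold", "qc_min", "align", "seed")
  missing <- setdiff(need, names(config))
  if (length(missing)) {
    stop("config missing fields: ", paste(missing, collapse = ", "))
  }
  if (config$min_coding_nt <= 0) stop("min_coding_nt must be positive")
  for (f in c("id_threshold", "cov_threshold")) {
    if (config[[f]] <= 0 || config[[f]] > 100) {
      stop(f, " must lie in (0, 100]")
    }
  }
  if (config$hit_threshold <= 0) stop("hit_threshold must be positive")
  if (config$qc_min < 0 || config$qc_min > 1) {
    stop("qc_min must lie in [0, 1]")
  }
  invisible(config)
}

# tab-separated writer with a self-describing comment header
write_stage_table <- function(df, path, header = character(0)) {
  con <- file(path, "w")
  on.exit(close(con))
  for (h in header) writeLines(paste0("# ", h), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

config_header <- function(config, keys) {
  vapply(keys, function(k) paste0(k, ": ", config[[k]]), "")
}

#' Run the full pipeline
#'
#' Stages: curation of the query OR genes, cross-species homology screen,
#' identity matrix and bootstrap NJ tree of the selected set, and, when
#' plate data are supplied, screen quantification. All tables, the Newick
#' tree, a results-style summary and a manifest are written under
#' `out_dir`. Fails (stops) when any stage fails.
#'
#' @param queries Named character vector of query OR nucleotide sequences
#'   (or a FASTA path).
#' @param genomes Named list of species genomes (named character vectors of
#'   contigs, or FASTA paths), over chimpanzee, dog, mouse, rat.
#' @param out_dir Output directory (created if needed).
#' @param config Configuration from [default_run_config()].
#' @param overrides Optional curation override data frame.
#' @param frameshift_ids Gene ids with annotation-level frameshifts.
#' @param plates Optional list with `wells` and `qc` (as produced by
#'   [simulate_plate_dataset()] or read with [read_plate_table()]).
#' @return Invisibly, a list with the in-memory results of every stage.
#' @export
run_end_to_end <- function(queries, genomes, out_dir,
                           config = default_run_config(),
                           overrides = NULL,
                           frameshift_ids = character(0),
                           plates = NULL) {
  validate_run_config(config)
  if (is.character(queries) && length(queries) == 1L &&
      file.exists(queries)) {
    queries <- read_fasta(queries, "dna")
  }
  genomes <- lapply(genomes, function(g) {
    if (is.character(g) && length(g) == 1L && file.exists(g)) {
      read_fasta(g, "dna")
    } else {
      g
    }
  })
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()
  note <- function(file, stage) {
    manifest[[length(manifest) + 1L]] <<- data.frame(file = file,
                                                     stage = stage)
  }

  message("[curate] ", length(queries), " query genes")
  curation <- curate_or_set(queries, min_coding_nt = config$min_coding_nt,
                            overrides = overrides,
                            frameshift_ids = frameshift_ids,
                            include_stop = config$include_stop)
  write_stage_table(curation, file.path(out_dir, "curation.tsv"),
                    config_header(config, c("min_coding_nt",
                                            "include_stop", "seed")))
  note("curation.tsv", "curate")

  message("[screen] aligning against ", length(genomes), " genomes")
  screen <- run_lineage_screen(queries, genomes, curation,
                               params = config$align,
                               id_threshold = config$id_threshold,
                               cov_threshold = config$cov_threshold,
                               identity_mode = config$identity_mode)
  hdr <- config_header(config, c("id_threshold", "cov_threshold", "seed"))
  write_stage_table(screen$calls, file.path(out_dir, "screen_calls.tsv"),
                    hdr)
  note("screen_calls.tsv", "screen")
  write_stage_table(screen$lineage, file.path(out_dir, "lineage.tsv"), hdr)
  note("lineage.tsv", "screen")
  write_stage_table(screen$counts, file.path(out_dir,
                                             "lineage_counts.tsv"), hdr)
  note("lineage_counts.tsv", "screen")

  identity <- NULL
  tree <- NULL
  if (length(screen$selected) >= 2L) {
    message("[phylo] ", length(screen$selected), " selected genes")
    prots <- vapply(screen$selected, function(id)
      orf_translation(queries[[id]]), "")
    identity <- pairwise_identity_matrix(prots, mode = "pairwise_global")
    write_identity_matrix(identity, file.path(out_dir,
                                              "identity_matrix.tsv"))
    note("identity_matrix.tsv", "phylo")
    if (length(screen$selected) < 3L) {
      # a tree needs at least three taxa; the matrix alone is reported
    } else if (length(unique(nchar(prots))) == 1L) {
      tree <- bootstrap_support(prots, n_reps = config$bootstrap_reps,
                                seed = config$seed)
    } else {
      tree <- build_nj_tree(identity_to_distance(identity))
    }
    if (!is.null(tree)) {
      write_tree_newick(tree, file.path(out_dir, "tree.nwk"))
      note("tree.nwk", "phylo")
    }
  }

  quant <- NULL
  if (!is.null(plates)) {
    message("[quantify] ", length(unique(plates$wells$plate_id)),
            " plates")
    quant <- quantify_plate_dataset(plates$wells, qc = plates$qc,
                                    qc_min = config$qc_min)
    hits <- hit_table(quant$responses, threshold = config$hit_threshold)
    summary <- summarize_screen(hits)
    qhdr <- config_header(config, c("hit_threshold", "qc_min", "seed"))
    write_stage_table(quant$responses,
                      file.path(out_dir, "responses.tsv"), qhdr)
    note("responses.tsv", "quantify")
    write_stage_table(hits, file.path(out_dir, "hits.tsv"), qhdr)
    note("hits.tsv", "quantify")
    quant$hits <- hits
    quant$summary <- summary
  }

  summary_lines <- c(
    sprintf("queries: %d", length(queries)),
    sprintf("functional: %d", sum(curation$status == "functional")),
    sprintf("pseudogenes: %d", sum(curation$status == "pseudogene")),
    sprintf("human_only: %d",
            sum(screen$lineage$category == "human_only")),
    sprintf("human_chimp_only: %d",
            sum(screen$lineage$category == "human_chimp_only")),
    sprintf("selected: %d", length(screen$selected)))
  if (!is.null(quant)) {
    summary_lines <- c(summary_lines,
      sprintf("odorants_responding: %d",
              quant$summary$n_odorants_responding),
      sprintf("odorants_hit_at_10uM: %d",
              quant$summary$n_odorants_hit_at_10uM),
      sprintf("ors_hit_at_10uM: %d", quant$summary$n_ors_hit_at_10uM))
  }
  writeLines(summary_lines, file.path(out_dir, "summary.txt"))
  note("summary.txt", "summary")
  write.table(do.call(rbind, manifest), file.path(out_dir, "manifest.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  invisible(list(curation = curation, screen = screen,
                 identity = identity, tree = tree, quant = quant,
                 config = config, out_dir = out_dir))
}
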