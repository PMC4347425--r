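# Seeded simulators for every input the pipeline consumes, each paired with
# a ground-truth record so recovery tests can compare pipeline output with
# planted truth rather than with re-runs of the pipeline.

with_seed_opt <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(seed, expr)
}

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N", "P",
          "Q", "R", "S", "T", "V", "W", "Y")

# one random synonymous codon per amino acid
reverse_translate <- function(aa) {
  code <- Biostrings::GENETIC_CODE
  vapply(aa, function(a) {
    opts <- names(code)[code == a]
    opts[sample.int(length(opts), 1L)]
  }, "", USE.NAMES = FALSE)
}

#' Simulate an OR-like gene
#'
#' A single-exon, single-ORF gene: ATG, random sense codons, a stop codon,
#' with the configured family motifs planted at their canonical relative
#' positions. The default length of 310 codons (stop included) gives a 930
#' nt coding region, comfortably above the 900 nt functional threshold.
#'
#' @param length_codons Total codons including start and stop (default 310).
#' @param motifs Motif table (see [or_default_motifs()]); planted exactly.
#' @param seed Integer seed.
#' @param id Sequence id.
#' @return Named character vector of length one (the gene).
#' @export
simulate_or_gene <- function(length_codons = 310L,
                             motifs = or_default_motifs(), seed = NULL,
                             id = "ORsim") {
  n_aa <- length_codons - 1L # protein length, stop excluded
  longest <- max(nchar(motifs$pattern))
  if (n_aa < longest + 2L) stop("gene too short to place the motifs")
  with_seed_opt(seed, {
    prot <- c("M", sample(AA20, n_aa - 1L, replace = TRUE))
    for (i in seq_len(nrow(motifs))) {
      pat <- strsplit(motifs$pattern[i], "")[[1L]]
      pos <- max(2L, min(n_aa - length(pat) + 1L,
                         round(motifs$rel_pos[i] * n_aa)))
      prot[pos:(pos + length(pat) - 1L)] <- pat
    }
    codons <- reverse_translate(prot)
    codons[1L] <- "ATG"
    gene <- paste(c(codons, sample(STOP_CODONS, 1L)), collapse = "")
    setNames(gene, id)
  })
}

#' Mutate a gene to a target nucleotide identity
#'
#' Substitutions (no indels) at uniformly random positions, each to a
#' different base, until the positional identity to the source equals the
#' target within rounding. The realized identity is reported, not the
#' requested one.
#'
#' @param gene Nucleotide string.
#' @param target_identity_pct Target identity in (0, 100].
#' @param seed Integer seed.
#' @return List: `seq`, `realized_identity_pct`, `n_substitutions`.
#' @export
mutate_to_identity <- function(gene, target_identity_pct, seed = NULL) {
  if (target_identity_pct <= 0 || target_identity_pct > 100) {
    stop("target identity must lie in (0, 100]")
  }
  gene <- check_nuc(gene)
  n <- nchar(gene)
  d <- round(n * (1 - target_identity_pct / 100))
  with_seed_opt(seed, {
    chars <- strsplit(gene, "")[[1L]]
    pos <- sample.int(n, d)
    for (p in pos) {
      chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1L)
    }
    list(seq = paste(chars, collapse = ""),
         realized_identity_pct = 100 * (n - d) / n, n_substitutions = d)
  })
}

#' Simulate a random genome contig
#'
#' @param length_nt Contig length.
#' @param seed Integer seed.
#' @param id Contig id.
#' @return Named character vector of length one.
#' @export
simulate_genome <- function(length_nt, seed = NULL, id = "contig1") {
  with_seed_opt(seed, {
    setNames(paste(sample(c("A", "C", "G", "T"), length_nt,
                          replace = TRUE), collapse = ""), id)
  })
}

#' Plant a gene (or its prefix) into a genome
#'
#' Inserts the first `coverage_fraction` of the gene at a uniformly random
#' position, on the requested strand (minus strand inserts the reverse
#' complement). Truncation models a partial counterpart.
#'
#' @param genome Named character vector of one contig.
#' @param gene Nucleotide string.
#' @param coverage_fraction Fraction of the gene planted, in (0, 1].
#' @param strand `"+"` or `"-"`.
#' @param seed Integer seed.
#' @return List: `genome` (with the insert), `truth` (data frame:
#'   `insert_pos`, `strand`, `fragment_nt`, `realized_coverage_pct`).
#' @export
plant_gene <- function(genome, gene, coverage_fraction = 1, strand = "+",
                       seed = NULL) {
  if (coverage_fraction <= 0 || coverage_fraction > 1) {
    stop("coverage_fraction must lie in (0, 1]")
  }
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  gene <- check_nuc(gene)
  gl <- nchar(gene)
  frag_len <- max(1L, round(gl * coverage_fraction))
  frag <- substr(gene, 1L, frag_len)
  if (strand == "-") frag <- reverse_complement(frag)
  gseq <- genome[[1L]]
  with_seed_opt(seed, {
    pos <- sample.int(nchar(gseq) + 1L, 1L) - 1L # 0-based insert offset
    out <- paste0(substr(gseq, 1L, pos), frag,
                  substr(gseq, pos + 1L, nchar(gseq)))
    list(genome = setNames(out, names(genome)[1L]),
         truth = data.frame(insert_pos = pos, strand = strand,
                            fragment_nt = frag_len,
                            realized_coverage_pct = 100 * frag_len / gl))
  })
}

#' Simulate an OR gene family with planted pseudogene lesions
#'
#' Generates `n` OR-like genes; the first `n_pseudo` carry one lesion each,
#' cycling through frameshift (single-nucleotide deletion) and premature
#' stop, placed between codons 80 and 150 so the longest surviving ORF is
#' well below the 900 nt threshold. A frameshift is re-drawn until the
#' shifted frame stops within 50 codons, which the generator checks by
#' direct codon inspection of its own product.
#'
#' @param n Number of genes (default 20).
#' @param n_pseudo Number of lesioned genes (default 5).
#' @param length_codons Gene length in codons (default 310, a 930 nt ORF).
#' @param seed Integer seed.
#' @return List: `genes` (named character vector), `truth` (data frame:
#'   `gene_id`, `lesion`, `true_status`).
#' @export
simulate_or_family <- function(n = 20L, n_pseudo = 5L, length_codons = 310L,
                               seed = NULL) {
  if (n_pseudo > n) stop("n_pseudo cannot exceed n")
  with_seed_opt(seed, {
    genes <- character(0)
    truth <- list()
    lesions <- rep(c("frameshift", "premature_stop"),
                   length.out = n_pseudo)
    for (i in seq_len(n)) {
      id <- sprintf("ORsim%02d", i)
      g <- simulate_or_gene(length_codons = length_codons, id = id)[[1L]]
      lesion <- if (i <= n_pseudo) lesions[i] else "none"
      if (lesion == "premature_stop") {
        cod <- sample(80:150, 1L)
        substr(g, 3L * cod + 1L, 3L * cod + 3L) <- sample(STOP_CODONS, 1L)
      } else if (lesion == "frameshift") {
        repeat {
          cod <- sample(80:150, 1L)
          p <- 3L * cod + 1L # delete one nt at the start of codon cod + 1
          cand <- paste0(substr(g, 1L, p - 1L),
                         substr(g, p + 1L, nchar(g)))
          # require an in-frame stop within 50 codons after the shift
          tail_codons <- codon_split(substr(cand, p, nchar(cand)))
          if (any(tail_codons[seq_len(min(50L, length(tail_codons)))] %in%
                    STOP_CODONS)) {
            g <- cand
            break
          }
        }
      }
      genes[id] <- g
      truth[[i]] <- data.frame(
        gene_id = id, lesion = lesion,
        true_status = if (lesion == "none") "functional" else "pseudogene")
    }
    list(genes = genes, truth = do.call(rbind, truth))
  })
}

#' Simulate a reporter-plate screen dataset
#'
#' One odorant per plate. Each plate carries, for every OR construct, wells
#' with the odorant at each concentration plus no-odorant (basal) wells,
#' matching empty-vector wells, and GFP transfection-control wells. Well
#' fluorescence is the condition mean plus seeded Gaussian noise. For true
#' agonists the effect size is scaled by a saturating concentration factor:
#' 0.6 / 0.9 / 1.0 of the effect at 10 / 100 / 1000 uM for potent agonists
#' and 0 / 0.5 / 1.0 for weak ones.
#'
#' The truth record carries, per OR x odorant pair, the agonist flag and the
#' potency class implied by the generator's own parameters (the lowest
#' concentration whose noiseless response exceeds `truth_threshold`),
#' computed in closed form, never by running the quantification.
#'
#' @param or_names Character vector of OR names.
#' @param odorants Character vector of odorant names (one plate each).
#' @param agonists Data frame `or_name`, `odorant`, `potency`
#'   (`"potent"`/`"weak"`), `effect_AU`; or NULL for no agonists.
#' @param rho_tagged Tag states simulated per OR (default untagged only).
#' @param basal_or_AU,basal_empty_AU Mean basal fluorescence of OR and
#'   empty-vector wells (defaults 2e5 and 1e5 AU).
#' @param noise_sd_AU Gaussian well noise (default 3e4 AU, one tenth of the
#'   hit threshold).
#' @param n_replicates Replicates per condition (default 2).
#' @param concentrations Tested concentrations in uM.
#' @param saturation List with `potent` and `weak` factors per
#'   concentration.
#' @param gfp_fraction Simulated transfection efficiency per plate.
#' @param truth_threshold Threshold used to derive the true potency class.
#' @param seed Integer seed.
#' @return List: `wells` (well-record data frame), `qc` (`plate_id`,
#'   `gfp_fraction`), `truth` (per OR x odorant: `or_name`, `odorant`,
#'   `is_true_agonist`, `effect_AU`, `true_lowest_effective_uM`,
#'   `true_potency_class`), `params`.
#' @export
simulate_plate_dataset <- function(or_names, odorants, agonists = NULL,
                                   rho_tagged = FALSE,
                                   basal_or_AU = 2e5, basal_empty_AU = 1e5,
                                   noise_sd_AU = 3e4, n_replicates = 2L,
                                   concentrations = c(10, 100, 1000),
                                   saturation = list(
                                     potent = c(0.6, 0.9, 1.0),
                                     weak = c(0, 0.5, 1.0)),
                                   gfp_fraction = 0.85,
                                   truth_threshold = HIT_THRESHOLD_AU,
                                   seed = NULL) {
  if (noise_sd_AU < 0) stop("noise_sd_AU must be non-negative")
  if (!is.null(agonists) && nrow(agonists) > 0) {
    if (any(agonists$effect_AU < 0)) stop("effect sizes must be non-negative")
    if (!all(agonists$potency %in% names(saturation))) {
      stop("unknown potency class in the agonist map")
    }
  }
  for (f in saturation) {
    if (length(f) != length(concentrations)) {
      stop("saturation factors must match the concentration axis")
    }
  }
  conc_axis <- c(0, concentrations)
  with_seed_opt(seed, {
    # empty-vector wells: plate x concentration (incl. basal) x replicate
    empty <- expand.grid(replicate = seq_len(n_replicates),
                         concentration_uM = conc_axis,
                         plate_odorant = odorants,
                         stringsAsFactors = FALSE)
    empty$construct <- "empty_vector"
    empty$or_name <- NA_character_
    empty$rho_tagged <- NA
    empty$mu <- basal_empty_AU
    # OR wells: plate x OR x tag x concentration x replicate
    orw <- expand.grid(replicate = seq_len(n_replicates),
                       concentration_uM = conc_axis,
                       rho_tagged = rho_tagged,
                       or_name = or_names,
                       plate_odorant = odorants,
                       stringsAsFactors = FALSE)
    orw$construct <- "OR"
    orw$mu <- basal_or_AU
    if (!is.null(agonists) && nrow(agonists) > 0) {
      key <- paste(orw$or_name, orw$plate_odorant, sep = "\r")
      akey <- paste(agonists$or_name, agonists$odorant, sep = "\r")
      hitrow <- match(key, akey)
      has <- !is.na(hitrow) & orw$concentration_uM > 0
      if (any(has)) {
        ci <- match(orw$concentration_uM[has], concentrations)
        sat <- mapply(function(p, i) saturation[[p]][i],
                      agonists$potency[hitrow[has]], ci)
        orw$mu[has] <- orw$mu[has] +
          agonists$effect_AU[hitrow[has]] * sat
      }
    }
    gfp <- expand.grid(replicate = 1:2, concentration_uM = 0,
                       plate_odorant = odorants, stringsAsFactors = FALSE)
    gfp$construct <- "gfp_control"
    gfp$or_name <- NA_character_
    gfp$rho_tagged <- NA
    gfp$mu <- 0
    cols <- c("plate_odorant", "construct", "or_name", "rho_tagged",
              "concentration_uM", "replicate", "mu")
    wells <- rbind(empty[, cols], orw[, cols], gfp[, cols])
    wells <- wells[order(wells$plate_odorant), , drop = FALSE]
    wells$plate_id <- paste0("plate_", wells$plate_odorant)
    wells$odorant <- ifelse(wells$concentration_uM > 0,
                            wells$plate_odorant, NA_character_)
    # well ids cycle A1..H12 within each plate
    idx <- stats::ave(seq_len(nrow(wells)), wells$plate_id,
                      FUN = seq_along)
    well_ids <- paste0(rep(LETTERS[1:8], each = 12), rep(1:12, times = 8))
    wells$well <- well_ids[((idx - 1L) %% 96L) + 1L]
    wells$fluorescence_AU <- wells$mu +
      if (noise_sd_AU > 0) stats::rnorm(nrow(wells), 0, noise_sd_AU) else 0
    wells <- wells[, c("plate_id", "well", "construct", "or_name",
                       "rho_tagged", "odorant", "concentration_uM",
                       "replicate", "fluorescence_AU")]
    rownames(wells) <- NULL
    # truth per OR x odorant, potency class from the generator's own model
    truth <- expand.grid(or_name = or_names, odorant = odorants,
                         stringsAsFactors = FALSE)
    truth$is_true_agonist <- FALSE
    truth$effect_AU <- 0
    truth$true_lowest_effective_uM <- NA_real_
    truth$true_potency_class <- "none"
    if (!is.null(agonists) && nrow(agonists) > 0) {
      akey <- paste(agonists$or_name, agonists$odorant, sep = "\r")
      tkey <- paste(truth$or_name, truth$odorant, sep = "\r")
      m <- match(tkey, akey)
      for (i in which(!is.na(m))) {
        ag <- agonists[m[i], ]
        resp <- ag$effect_AU * saturation[[ag$potency]]
        eff <- concentrations[resp > truth_threshold]
        truth$is_true_agonist[i] <- TRUE
        truth$effect_AU[i] <- ag$effect_AU
        if (length(eff)) {
          lec <- min(eff)
          truth$true_lowest_effective_uM[i] <- lec
          truth$true_potency_class[i] <-
            c(`10` = "high", `100` = "mid", `1000` = "low")[[
              as.character(lec)]]
        }
      }
    }
    qc <- data.frame(plate_id = paste0("plate_", odorants),
                     gfp_fraction = gfp_fraction)
    list(wells = wells, qc = qc, truth = truth,
         params = list(basal_or_AU = basal_or_AU,
                       basal_empty_AU = basal_empty_AU,
                       noise_sd_AU = noise_sd_AU,
                       n_replicates = n_replicates,
                       concentrations = concentrations,
                       saturation = saturation, seed = seed))
  })
}

#' Simulate a protein family on a star phylogeny
#'
#' Each tip is the ancestor with every site substituted independently with
#' probability `rate` (to a uniformly random different residue). Useful for
#' identity-matrix calibration: two tips agree at a site only when neither
#' mutated or both mutated to the same residue, so the expected pairwise
#' identity is `(1 - rate)^2 + rate^2 / 19` per site.
#'
#' @param n_tips Number of tips.
#' @param length_aa Protein length.
#' @param rate Per-site substitution probability on each branch.
#' @param seed Integer seed.
#' @return List: `prots` (named character), `expected_identity_pct`.
#' @export
simulate_star_proteins <- function(n_tips = 10L, length_aa = 300L,
                                   rate = 0.2, seed = NULL) {
  with_seed_opt(seed, {
    anc <- sample(AA20, length_aa, replace = TRUE)
    prots <- vapply(seq_len(n_tips), function(i) {
      tip <- anc
      mut <- stats::runif(length_aa) < rate
      tip[mut] <- vapply(tip[mut], function(a)
        sample(setdiff(AA20, a), 1L), "", USE.NAMES = FALSE)
      paste(tip, collapse = "")
    }, "")
    names(prots) <- sprintf("tip%02d", seq_len(n_tips))
    p_same <- (1 - rate)^2 + rate^2 / 19
    list(prots = prots, expected_identity_pct = 100 * p_same)
  })
}
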