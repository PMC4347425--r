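# Quantification of the heterologous odorant screen.
#
# The response statistic is a background double subtraction on condition
# means: R = [F(OR + odorant) - F(empty vector + odorant)]
#            - [F(OR, no odorant) - F(empty vector, no odorant)],
# in arbitrary fluorescence units (AU) of the CRE reporter readout. A
# response is a hit when R exceeds 3e5 AU (strict inequality). Negative
# responses are retained, never clipped. Rho-tagged and untagged constructs
# are distinct conditions and are never pooled.

#' Default hit threshold in arbitrary fluorescence units
#' @export
HIT_THRESHOLD_AU <- 3e5

#' Background-double-subtraction response
#'
#' All four terms are condition means (over replicates) in AU. Any missing
#' (NA) term makes the response NA -- a cell with a missing condition is
#' not evaluable, never zero.
#'
#' @param f_or_od OR construct with odorant.
#' @param f_empty_od Empty vector with odorant.
#' @param f_or_basal OR construct without odorant.
#' @param f_empty_basal Empty vector without odorant.
#' @return Response in AU (vectorized; may be negative).
#' @examples
#' compute_response(8e5, 1e5, 2e5, 1e5)  # 6e5
#' @export
compute_response <- function(f_or_od, f_empty_od, f_or_basal,
                             f_empty_basal) {
  (f_or_od - f_empty_od) - (f_or_basal - f_empty_basal)
}

#' Hit call at a fixed threshold
#'
#' Strict inequality: a response exactly at the threshold is not a hit.
#'
#' @param r_au Response in AU.
#' @param threshold Positive threshold (default `3e5`).
#' @return Logical (NA responses stay NA).
#' @examples
#' call_hit(3.0e5)  # FALSE: boundary is strict
#' call_hit(3.1e5)  # TRUE
#' @export
call_hit <- function(r_au, threshold = HIT_THRESHOLD_AU) {
  if (threshold <= 0) stop("threshold must be positive")
  r_au > threshold
}

#' Replicate mean and standard error
#'
#' @param x Numeric vector of replicate values (n >= 1).
#' @return List: `mean`, `sem` (sample sd / sqrt(n); NA when n = 1), `n`.
#' @export
aggregate_replicates <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 1L) stop("at least one replicate required")
  list(mean = mean(x), sem = if (n >= 2L) sd(x) / sqrt(n) else NA_real_,
       n = n)
}

#' Normalize responses as percent of maximum
#'
#' Each value is scaled by 100 / max over the set (the dose-response
#' display convention: percent of the maximum response across a chosen set
#' of receptors). Negative values stay negative. Refused when the maximum
#' is not positive.
#'
#' @param r Numeric responses.
#' @return Percentages.
#' @export
normalize_profile <- function(r) {
  mx <- max(r, na.rm = TRUE)
  if (!is.finite(mx) || mx <= 0) {
    stop("normalization refused: no positive response in the set")
  }
  100 * r / mx
}

#' Lowest effective concentration and potency class
#'
#' @param is_hit Named logical vector of hit flags; names are tested
#'   concentrations in micromolar.
#' @param classes Mapping from concentration to class; default 10 -> high,
#'   100 -> mid, 1000 -> low.
#' @return List: `lowest_effective_uM` (NA when no hit), `potency_class`
#'   (`"high"`, `"mid"`, `"low"` or `"none"`).
#' @export
lowest_effective_concentration <- function(is_hit,
                                           classes = c(`10` = "high",
                                                       `100` = "mid",
                                                       `1000` = "low")) {
  if (length(is_hit) == 0L) stop("no concentration evaluated")
  conc <- as.numeric(names(is_hit))
  hit_conc <- conc[!is.na(is_hit) & is_hit]
  if (length(hit_conc) == 0L) {
    return(list(lowest_effective_uM = NA_real_, potency_class = "none"))
  }
  lec <- min(hit_conc)
  cls <- classes[[as.character(lec)]]
  if (is.null(cls)) cls <- "other"
  list(lowest_effective_uM = lec, potency_class = cls)
}

#' Plate quality control on transfection efficiency
#'
#' @param gfp_fraction GFP-positive fraction in \[0, 1\].
#' @param min_fraction Pass threshold, inclusive (default 0.70).
#' @return List: `gfp_transfection_fraction`, `pass`.
#' @examples
#' qc_plate(0.70)$pass  # TRUE: boundary is inclusive
#' @export
qc_plate <- function(gfp_fraction, min_fraction = 0.70) {
  if (is.na(gfp_fraction) || gfp_fraction < 0 || gfp_fraction > 1) {
    stop("gfp_fraction must lie in [0, 1]")
  }
  list(gfp_transfection_fraction = gfp_fraction,
       pass = gfp_fraction >= min_fraction)
}

#' Quantify a plate dataset into a response table
#'
#' For every (OR, tag state, odorant, concentration) cell on a plate, the
#' four F terms are computed as condition means over replicates and combined
#' by [compute_response()]. The standard error is taken over per-replicate
#' responses (replicates paired by index across the four conditions) when at
#' least two full replicates exist. Plates failing transfection QC are
#' excluded with a logged reason.
#'
#' @param wells Data frame of well records with columns `plate_id`, `well`,
#'   `construct` (`"OR"`, `"empty_vector"`, `"gfp_control"`), `or_name`,
#'   `rho_tagged`, `odorant`, `concentration_uM` (0 = no odorant),
#'   `replicate`, `fluorescence_AU`.
#' @param qc Optional data frame `plate_id`, `gfp_fraction` used for plate
#'   QC.
#' @param qc_min Inclusive QC threshold (default 0.70).
#' @return List: `responses` (data frame `or_name`, `rho_tagged`, `odorant`,
#'   `concentration_uM`, `R_AU`, `n_replicates`, `sem_AU`, `evaluable`),
#'   `qc_log` (per-plate pass/fail), `excluded_plates`.
#' @export
quantify_plate_dataset <- function(wells, qc = NULL, qc_min = 0.70) {
  need <- c("plate_id", "construct", "or_name", "rho_tagged", "odorant",
            "concentration_uM", "replicate", "fluorescence_AU")
  if (!all(need %in% names(wells))) {
    stop("well table missing columns: ",
         paste(setdiff(need, names(wells)), collapse = ", "))
  }
  excluded <- character(0)
  qc_log <- NULL
  if (!is.null(qc)) {
    qc_log <- do.call(rbind, lapply(seq_len(nrow(qc)), function(i) {
      q <- qc_plate(qc$gfp_fraction[i], qc_min)
      data.frame(plate_id = qc$plate_id[i],
                 gfp_fraction = q$gfp_transfection_fraction, pass = q$pass)
    }))
    excluded <- qc_log$plate_id[!qc_log$pass]
    wells <- wells[!(wells$plate_id %in% excluded), , drop = FALSE]
  }
  wells <- wells[wells$construct != "gfp_control", , drop = FALSE]
  acc <- list(or = character(0), tag = logical(0), od = character(0),
              conc = numeric(0), r = numeric(0), n = integer(0),
              sem = numeric(0), ev = logical(0))
  add <- function(or, tag, od, conc, r, n, sem, ev) {
    acc$or[length(acc$or) + 1L] <<- or
    acc$tag[length(acc$tag) + 1L] <<- tag
    acc$od[length(acc$od) + 1L] <<- od
    acc$conc[length(acc$conc) + 1L] <<- conc
    acc$r[length(acc$r) + 1L] <<- r
    acc$n[length(acc$n) + 1L] <<- n
    acc$sem[length(acc$sem) + 1L] <<- sem
    acc$ev[length(acc$ev) + 1L] <<- ev
  }
  for (pid in unique(wells$plate_id)) {
    pw <- wells[wells$plate_id == pid, , drop = FALSE]
    empty <- pw[pw$construct == "empty_vector", , drop = FALSE]
    orw <- pw[pw$construct == "OR", , drop = FALSE]
    odorants <- unique(pw$odorant[pw$concentration_uM > 0])
    odorants <- odorants[!is.na(odorants)]
    combos <- unique(orw[, c("or_name", "rho_tagged")])
    for (ci in seq_len(nrow(combos))) {
      or <- combos$or_name[ci]
      tag <- combos$rho_tagged[ci]
      sel_or <- orw$or_name == or & orw$rho_tagged == tag
      f_or_basal_v <- orw$fluorescence_AU[sel_or & orw$concentration_uM == 0]
      f_eb_v <- empty$fluorescence_AU[empty$concentration_uM == 0]
      for (od in odorants) {
        concs <- sort(unique(pw$concentration_uM[
          pw$odorant %in% od & pw$concentration_uM > 0]))
        for (conc in concs) {
          f_oo_v <- orw$fluorescence_AU[sel_or & orw$odorant %in% od &
                                          orw$concentration_uM == conc]
          f_eo_v <- empty$fluorescence_AU[empty$odorant %in% od &
                                            empty$concentration_uM == conc]
          evaluable <- length(f_oo_v) > 0 && length(f_eo_v) > 0 &&
            length(f_or_basal_v) > 0 && length(f_eb_v) > 0
          if (!evaluable) {
            add(or, tag, od, conc, NA_real_, 0L, NA_real_, FALSE)
            next
          }
          r <- compute_response(mean(f_oo_v), mean(f_eo_v),
                                mean(f_or_basal_v), mean(f_eb_v))
          n_full <- min(length(f_oo_v), length(f_eo_v),
                        length(f_or_basal_v), length(f_eb_v))
          sem <- NA_real_
          if (n_full >= 2L) {
            r_rep <- compute_response(f_oo_v[seq_len(n_full)],
                                      f_eo_v[seq_len(n_full)],
                                      f_or_basal_v[seq_len(n_full)],
                                      f_eb_v[seq_len(n_full)])
            sem <- sd(r_rep) / sqrt(n_full)
          }
          add(or, tag, od, conc, r, n_full, sem, TRUE)
        }
      }
    }
  }
  responses <- if (length(acc$or)) {
    data.frame(or_name = acc$or, rho_tagged = acc$tag, odorant = acc$od,
               concentration_uM = acc$conc, R_AU = acc$r,
               n_replicates = acc$n, sem_AU = acc$sem, evaluable = acc$ev)
  } else {
    NULL
  }
  list(responses = responses, qc_log = qc_log,
       excluded_plates = excluded)
}

#' Hit and potency table from a response table
#'
#' @param responses Response table from [quantify_plate_dataset()].
#' @param threshold Hit threshold in AU, strict (default `3e5`).
#' @return Data frame per (OR, tag, odorant): hit flags per concentration
#'   (`hit_10`, `hit_100`, `hit_1000` where tested), `lowest_effective_uM`,
#'   `potency_class`.
#' @export
hit_table <- function(responses, threshold = HIT_THRESHOLD_AU) {
  keys <- unique(responses[, c("or_name", "rho_tagged", "odorant")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    sel <- responses$or_name == keys$or_name[i] &
      responses$rho_tagged == keys$rho_tagged[i] &
      responses$odorant == keys$odorant[i]
    sub <- responses[sel, , drop = FALSE]
    is_hit <- setNames(call_hit(sub$R_AU, threshold),
                       sub$concentration_uM)
    lec <- lowest_effective_concentration(is_hit)
    out <- data.frame(or_name = keys$or_name[i],
                      rho_tagged = keys$rho_tagged[i],
                      odorant = keys$odorant[i],
                      lowest_effective_uM = lec$lowest_effective_uM,
                      potency_class = lec$potency_class)
    for (conc in c(10, 100, 1000)) {
      col <- paste0("hit_", conc)
      out[[col]] <- if (as.character(conc) %in% names(is_hit)) {
        unname(is_hit[[as.character(conc)]])
      } else {
        NA
      }
    }
    out
  })
  do.call(rbind, rows)
}

#' Screen-level summary counts
#'
#' @param hits Hit table from [hit_table()].
#' @return List: `n_odorants_responding` (odorants with at least one
#'   responding OR at any concentration), `n_odorants_hit_at_10uM`,
#'   `n_ors_hit_at_10uM` (tag states pooled by OR name for counting only),
#'   `tuning_breadth` (data frame `or_name`, `rho_tagged`, `n_odorants`).
#' @export
summarize_screen <- function(hits) {
  any_hit <- !is.na(hits$lowest_effective_uM)
  hit10 <- !is.na(hits$hit_10) & hits$hit_10
  breadth_keys <- unique(hits[, c("or_name", "rho_tagged")])
  breadth <- do.call(rbind, lapply(seq_len(nrow(breadth_keys)), function(i) {
    sel <- hits$or_name == breadth_keys$or_name[i] &
      hits$rho_tagged == breadth_keys$rho_tagged[i]
    data.frame(or_name = breadth_keys$or_name[i],
               rho_tagged = breadth_keys$rho_tagged[i],
               n_odorants = sum(any_hit[sel]))
  }))
  list(n_odorants_responding = length(unique(hits$odorant[any_hit])),
       n_odorants_hit_at_10uM = length(unique(hits$odorant[hit10])),
       n_ors_hit_at_10uM = length(unique(hits$or_name[hit10])),
       tuning_breadth = breadth)
}

#' Read a plate table
#'
#' Tab-separated file with the well-record columns of
#' [quantify_plate_dataset()].
#'
#' @param path File path.
#' @return Data frame.
#' @export
read_plate_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if ("rho_tagged" %in% names(df)) df$rho_tagged <- as.logical(df$rho_tagged)
  df
}
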