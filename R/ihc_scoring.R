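#' IHC combined score for a single core
#'
#' The combined score (H-score style) of one tissue-microarray core is the
#' product of the staining intensity category and the percentage of
#' positively stained tumor cells, giving a range of 0--300.
#'
#' @param intensity integer staining intensity: 0 (negative), 1 (weak),
#'   2 (moderate) or 3 (strong). Vectorized; `NA` propagates.
#' @param density percentage of positively stained tumor cells, in
#'   \[0, 100\]. Vectorized; `NA` propagates.
#' @return numeric vector of combined scores in \[0, 300\].
#' @examples
#' core_score(3, 100)  # 300, the maximum
#' core_score(2, 40)   # 80
#' @export
core_score <- function(intensity, density) {
  ok <- is.na(intensity) | intensity %in% c(0, 1, 2, 3)
  if (!all(ok))
    abort("`intensity` must be 0, 1, 2 or 3", "ihcmet_param_error")
  okd <- is.na(density) | (is.numeric(density) & density >= 0 & density <= 100)
  if (!is.numeric(density) || !all(okd))
    abort("`density` must be in [0, 100]", "ihcmet_param_error")
  as.numeric(intensity) * as.numeric(density)
}

#' Per-tumor mean score over multiple cores
#'
#' When several cores were sampled from one tumor, the tumor-level score of
#' a marker is the arithmetic mean of the evaluable core scores. Cores with
#' missing readings are dropped, never zero-imputed; a marker with zero
#' evaluable cores is non-evaluable and returns `NA` (distinct from a true
#' score of 0).
#'
#' @param scores numeric vector of per-core combined scores (`NA` =
#'   non-evaluable core).
#' @return mean score, or `NA_real_` if no core is evaluable.
#' @export
tumor_score <- function(scores) {
  if (!is.numeric(scores) || length(scores) == 0L)
    abort("`scores` must be a non-empty numeric vector", "ihcmet_param_error")
  if (all(is.na(scores))) return(NA_real_)
  mean(scores, na.rm = TRUE)
}

#' Positivity call from a combined score
#'
#' Positive IHC staining is defined as a combined score at or above the
#' cutoff (default 1, i.e. any detectable staining).
#'
#' @param mean_score numeric score(s) in \[0, 300\]; `NA` propagates.
#' @param cutoff positivity cutoff on the combined-score scale (default 1).
#' @return logical vector.
#' @export
is_positive <- function(mean_score, cutoff = 1) {
  if (!is.numeric(mean_score) ||
      any(mean_score < 0 | mean_score > 300, na.rm = TRUE))
    abort("`mean_score` must be in [0, 300]", "ihcmet_param_error")
  mean_score >= cutoff
}

#' Metabolic phenotype from marker positivity
#'
#' Classifies a tumor from its GLUT1, PCK1 and PCK2 positivity flags:
#' \describe{
#'   \item{glycolytic}{GLUT1 positive, PCK1 and PCK2 negative}
#'   \item{gluconeogenic}{GLUT1 negative, PCK1 or PCK2 positive}
#'   \item{mixed}{GLUT1 positive and PCK1 or PCK2 positive}
#'   \item{unspecified}{all three negative}
#' }
#' The four classes partition all 8 flag combinations. A tumor with any
#' non-evaluable flag (`NA`) is not classified (`NA` returned); such samples
#' are reported separately, not counted in phenotype tallies.
#'
#' @param glut1_pos,pck1_pos,pck2_pos logical vectors of positivity flags.
#' @return factor with levels glycolytic, gluconeogenic, mixed, unspecified.
#' @export
classify_phenotype <- function(glut1_pos, pck1_pos, pck2_pos) {
  n <- length(glut1_pos)
  if (length(pck1_pos) != n || length(pck2_pos) != n)
    abort("flag vectors must have equal length", "ihcmet_param_error")
  if (!is.logical(glut1_pos) || !is.logical(pck1_pos) || !is.logical(pck2_pos))
    abort("flags must be logical", "ihcmet_param_error")
  pck_any <- pck1_pos | pck2_pos
  out <- rep(NA_character_, n)
  out[glut1_pos & !pck_any] <- "glycolytic"
  out[!glut1_pos & pck_any] <- "gluconeogenic"
  out[glut1_pos & pck_any] <- "mixed"
  out[!glut1_pos & !pck1_pos & !pck2_pos] <- "unspecified"
  # strict evaluability: any non-evaluable flag excludes the sample, even
  # when two flags would suffice logically (e.g. GLUT1- with one PCK+)
  out[is.na(glut1_pos) | is.na(pck1_pos) | is.na(pck2_pos)] <- NA_character_
  factor(out, levels = PHENOTYPES)
}

#' Combined PCK1 + PCK2 score
#'
#' Sum of the tumor-level PCK1 and PCK2 mean scores (range 0--600); a proxy
#' for total PEPCK abundance. Non-evaluable if either marker is.
#'
#' @param pck1_mean,pck2_mean numeric tumor-level mean scores.
#' @return numeric vector in \[0, 600\]; `NA` where either input is `NA`.
#' @export
combined_pck_score <- function(pck1_mean, pck2_mean) {
  if (any(pck1_mean < 0 | pck1_mean > 300, na.rm = TRUE) ||
      any(pck2_mean < 0 | pck2_mean > 300, na.rm = TRUE))
    abort("mean scores must be in [0, 300]", "ihcmet_param_error")
  pck1_mean + pck2_mean
}

#' Score a long-format cohort table
#'
#' Aggregates a per-core cohort table (one row per patient, marker and core)
#' to tumor level: mean combined score, positivity call per marker, combined
#' PCK1/2 score and metabolic phenotype.
#'
#' @param cohort data.frame with columns `patient_id`, `histology`, `site`,
#'   `t_stage`, `grade`, `gender`, `age`, `marker`, `core_index`,
#'   `intensity`, `density`. `NA` intensity or density marks a
#'   non-evaluable core.
#' @param cutoff positivity cutoff on the combined score (default 1).
#' @return data.frame, one row per patient, with `score_<marker>`,
#'   `pos_<marker>` columns, `combined_pck`, and `phenotype`.
#' @export
score_cohort <- function(cohort, cutoff = 1) {
  need <- c("patient_id", "marker", "intensity", "density")
  if (!all(need %in% names(cohort)))
    abort(paste("cohort table must contain",
                paste(need, collapse = ", ")), "ihcmet_format_error")
  cohort$.score <- core_score(cohort$intensity, cohort$density)
  agg <- aggregate(.score ~ patient_id + marker, data = cohort,
                   FUN = tumor_score, na.action = stats::na.pass)
  wide <- stats::reshape(agg, idvar = "patient_id", timevar = "marker",
                         direction = "wide")
  names(wide) <- sub("^\\.score\\.", "score_", names(wide))
  for (m in MARKERS) {
    sc <- paste0("score_", m)
    if (!sc %in% names(wide)) wide[[sc]] <- NA_real_
    wide[[paste0("pos_", m)]] <- is_positive(wide[[sc]], cutoff)
  }
  wide$combined_pck <- combined_pck_score(wide$score_PCK1, wide$score_PCK2)
  wide$phenotype <- classify_phenotype(wide$pos_GLUT1, wide$pos_PCK1,
                                       wide$pos_PCK2)
  covars <- intersect(c("histology", "site", "t_stage", "grade", "gender",
                        "age"), names(cohort))
  if (length(covars)) {
    meta <- unique(cohort[, c("patient_id", covars), drop = FALSE])
    if (anyDuplicated(meta$patient_id))
      abort("inconsistent per-patient covariates", "ihcmet_format_error")
    wide <- merge(meta, wide, by = "patient_id", sort = TRUE)
  }
  attr(wide, "cutoff") <- cutoff
  wide
}

#' Cohort positivity and phenotype summary
#'
#' Produces a Table-1-style per-marker positivity summary and a phenotype
#' frequency table, stratified by the given columns. Percentages are
#' rounded half-up to integers; raw fractions are also returned (printed
#' rounding in the literature is not always recoverable). An empty stratum
#' is emitted with n = 0 and `NA` (never 0) percentages. Phenotype
#' fractions are over samples evaluable for all three classifying markers;
#' the count of unclassifiable samples is reported alongside.
#'
#' @param scored output of [score_cohort()].
#' @param by character vector of stratification columns (default
#'   `"histology"`; use `c("histology","site")` for primary/metastasis
#'   splits).
#' @return list with data.frames `positivity` and `phenotype`.
#' @export
cohort_summary <- function(scored, by = "histology") {
  if (nrow(scored) < 1L)
    abort("need at least one sample", "ihcmet_param_error")
  by <- intersect(by, names(scored))
  strata <- if (length(by)) interaction(scored[by], drop = FALSE, sep = "/")
            else factor(rep("all", nrow(scored)))
  pos_rows <- list(); phe_rows <- list()
  for (s in levels(strata)) {
    idx <- which(strata == s)
    for (m in MARKERS) {
      sc <- scored[[paste0("score_", m)]][idx]
      ev <- sum(!is.na(sc))
      np <- sum(scored[[paste0("pos_", m)]][idx], na.rm = TRUE)
      frac <- if (ev > 0) np / ev else NA_real_
      pos_rows[[length(pos_rows) + 1L]] <- data.frame(
        stratum = s, marker = m, n_evaluable = ev, n_positive = np,
        fraction = frac,
        percent = if (ev > 0) round_half_up(100 * frac) else NA_real_)
    }
    ph <- scored$phenotype[idx]
    n_class <- sum(!is.na(ph))
    tab <- table(ph[!is.na(ph)])
    phe_rows[[length(phe_rows) + 1L]] <- data.frame(
      stratum = s, phenotype = PHENOTYPES,
      n = as.integer(tab[PHENOTYPES]),
      fraction = if (n_class > 0) as.numeric(tab[PHENOTYPES]) / n_class
                 else NA_real_,
      n_classifiable = n_class,
      n_unclassifiable = sum(is.na(ph)))
  }
  list(positivity = do.call(rbind, pos_rows),
       phenotype = do.call(rbind, phe_rows))
}
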