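# Modified Dutch Lipid Clinic Network (DLCN) scoring.
#
# The modified criteria usable with biobank questionnaire data carry four
# items: first-degree relative with coronary/vascular disease (1 point),
# personal premature coronary artery disease (2), personal premature
# cerebral or peripheral vascular disease (1), and banded pre-treatment
# LDL-C (0/1/3/5/8 points), for a maximum total of 12. Tendon xanthoma,
# corneal arcus and genetic-test items of the full DLCN need clinical data a
# biobank questionnaire lacks and are deliberately absent.

#' Correction factor implied by a fractional LDL-C reduction
#'
#' Lipid-lowering therapy reduces observed LDL-C; dividing by the retained
#' fraction recovers the estimated pre-treatment level. A 30% reduction
#' corresponds to a multiplicative correction factor of 1/(1 - 0.30) = 1.43.
#'
#' @param reduction proportion of LDL-C removed by treatment, in [0, 1).
#' @return multiplicative correction factor (>= 1).
#' @examples
#' correction_factor_from_reduction(0.30)  # 1.43
#' @export
correction_factor_from_reduction <- function(reduction) {
  assert_proportion(reduction, "reduction")
  if (any(reduction >= 1)) stop_domain("`reduction` must be < 1")
  1 / (1 - reduction)
}

#' Default medication correction-factor map
#'
#' Returns the built-in map from medication class to the multiplicative
#' factor applied to on-treatment LDL-C. The only universally applicable
#' entry is the factor 1.43 for an unspecified cholesterol-lowering
#' medication (an estimated 30% LDL-C reduction); study-specific maps for
#' named statin/dose classes can be supplied via [read_correction_factors()].
#'
#' @return data.frame with columns `med_class`, `factor`.
#' @export
default_correction_factors <- function() {
  data.frame(med_class = "unspecified", factor = 1.43,
             stringsAsFactors = FALSE)
}

#' Read a correction-factor map from delimited text
#'
#' @param path two-column delimited file with header `med_class`, `factor`.
#' @return validated data.frame usable as the `factors` argument elsewhere.
#' @export
read_correction_factors <- function(path) {
  df <- read_tsv(path)
  if (!all(c("med_class", "factor") %in% names(df))) {
    stop_domain("correction-factor file needs columns `med_class`, `factor`")
  }
  df$factor <- as.numeric(df$factor)
  if (any(is.na(df$factor)) || any(df$factor < 1)) {
    stop_domain("all correction factors must be numeric and >= 1")
  }
  if (!"unspecified" %in% df$med_class) {
    stop_domain("correction-factor map must include an `unspecified` default")
  }
  if (anyDuplicated(df$med_class)) {
    stop_domain("duplicated med_class in correction-factor map")
  }
  df
}

lookup_factor <- function(med_class, factors) {
  med_class[is.na(med_class) | med_class == ""] <- "unspecified"
  idx <- match(med_class, factors$med_class)
  f <- factors$factor[idx]
  f[is.na(f)] <- factors$factor[match("unspecified", factors$med_class)]
  f
}

#' Correct observed LDL-C for lipid-lowering treatment
#'
#' Participants on treatment have their observed LDL-C multiplied by the
#' correction factor of their medication class (default 1.43 for
#' unspecified medication); untreated participants are returned unchanged.
#'
#' @param observed observed LDL-C in mmol/L (vectorized). `NA` marks a
#'   missing measurement and propagates (see [classify_cohort()] exclusion).
#' @param on_med logical, on lipid-lowering therapy.
#' @param med_class character medication class, or `NA`/"unspecified".
#' @param factors correction-factor map (see [default_correction_factors()]).
#' @return corrected LDL-C in mmol/L, always >= `observed` when factors >= 1.
#' @examples
#' correct_ldl(4.2, TRUE, "unspecified")  # 6.006
#' @export
correct_ldl <- function(observed, on_med, med_class = "unspecified",
                        factors = default_correction_factors()) {
  if (any(observed < 0, na.rm = TRUE)) stop_domain("LDL-C must be >= 0")
  n <- length(observed)
  on_med <- rep_len(on_med, n)
  med_class <- rep_len(as.character(med_class), n)
  if (any(is.na(factors$factor)) || any(factors$factor < 1)) {
    stop_domain("all correction factors must be >= 1")
  }
  f <- ifelse(on_med, lookup_factor(med_class, factors), 1)
  observed * f
}

#' DLCN points for a (corrected) LDL-C level
#'
#' Bands are contiguous half-open intervals so no value falls in a gap
#' between printed band edges: `[4.0, 5.0)` scores 1, `[5.0, 6.5)` scores 3,
#' `[6.5, 8.5)` scores 5 and `[8.5, Inf)` scores 8; below 4.0 scores 0.
#'
#' @param ldl_corrected corrected LDL-C in mmol/L (vectorized, must be >= 0).
#' @return integer points in \{0, 1, 3, 5, 8\}.
#' @export
ldl_points <- function(ldl_corrected) {
  if (any(ldl_corrected < 0, na.rm = TRUE)) {
    stop_domain("LDL-C must be >= 0")
  }
  pts <- integer(length(ldl_corrected))
  pts[ldl_corrected >= 4.0] <- 1L
  pts[ldl_corrected >= 5.0] <- 3L
  pts[ldl_corrected >= 6.5] <- 5L
  pts[ldl_corrected >= 8.5] <- 8L
  pts[is.na(ldl_corrected)] <- NA_integer_
  pts
}

#' Classify a DLCN score into an FH diagnosis class
#'
#' Definite FH for a score above 8 (or at 8 and above when
#' `definite_at_8 = TRUE`), probable for 6–8, possible for 3–5, unlikely
#' below 3.
#'
#' @param score integer DLCN score in \[0, 12\] (vectorized).
#' @param definite_at_8 logical; move the definite boundary down so a score
#'   of exactly 8 is definite rather than probable.
#' @return factor with levels `definite`, `probable`, `possible`, `unlikely`.
#' @export
classify_dlcn <- function(score, definite_at_8 = FALSE) {
  assert_flag(definite_at_8, "definite_at_8")
  if (any(score < 0 | score > 12, na.rm = TRUE)) {
    stop_domain("DLCN score must lie in [0, 12]")
  }
  definite_min <- if (definite_at_8) 8L else 9L
  cls <- ifelse(score >= definite_min, "definite",
         ifelse(score >= 6, "probable",
         ifelse(score >= 3, "possible", "unlikely")))
  factor(cls, levels = fh_classes())
}

#' @rdname classify_dlcn
#' @export
fh_classes <- function() c("definite", "probable", "possible", "unlikely")

#' Score one or more participants with the modified DLCN criteria
#'
#' @param pheno phenotype data.frame with at least columns `id`,
#'   `ldl_observed`, `on_med`, `med_class`, `first_degree_cvd`,
#'   `premature_cad`, `premature_cerebro_peripheral` (see
#'   [simulate_cohort()] for the full documented layout).
#' @param factors correction-factor map.
#' @param definite_at_8 see [classify_dlcn()].
#' @return data.frame with one row per input row: `id`, `ldl_corrected`,
#'   itemized points (`points_family`, `points_cad`, `points_vascular`,
#'   `points_ldl`), total `score` and `fh_class`. Rows with missing LDL-C
#'   have `NA` score and class (callers decide exclusion policy;
#'   [classify_cohort()] excludes them).
#' @export
dlcn_score <- function(pheno, factors = default_correction_factors(),
                       definite_at_8 = FALSE) {
  req <- c("id", "ldl_observed", "on_med", "med_class", "first_degree_cvd",
           "premature_cad", "premature_cerebro_peripheral")
  miss <- setdiff(req, names(pheno))
  if (length(miss)) {
    stop_domain("phenotype table lacks columns: ", paste(miss, collapse = ", "))
  }
  ldl_c <- correct_ldl(pheno$ldl_observed, pheno$on_med, pheno$med_class,
                       factors)
  p_fam <- ifelse(pheno$first_degree_cvd, 1L, 0L)
  p_cad <- ifelse(pheno$premature_cad, 2L, 0L)
  p_vas <- ifelse(pheno$premature_cerebro_peripheral, 1L, 0L)
  p_ldl <- ldl_points(ldl_c)
  score <- p_fam + p_cad + p_vas + p_ldl
  data.frame(
    id = pheno$id,
    ldl_corrected = ldl_c,
    points_family = p_fam,
    points_cad = p_cad,
    points_vascular = p_vas,
    points_ldl = p_ldl,
    score = score,
    fh_class = classify_dlcn(score, definite_at_8),
    stringsAsFactors = FALSE
  )
}

#' Classify a whole cohort, with exclusion bookkeeping
#'
#' Participants lacking an LDL-C measurement cannot be scored and are
#' excluded (never imputed), mirroring standard practice for
#' biobank lipid phenotyping.
#'
#' @inheritParams dlcn_score
#' @return list with `results` (per-participant [dlcn_score()] rows for
#'   included participants), `class_counts` (named integer vector over the
#'   four classes, summing to the number included), `excluded_ids`
#'   (participants without LDL-C) and `n_included`.
#' @export
classify_cohort <- function(pheno, factors = default_correction_factors(),
                            definite_at_8 = FALSE) {
  if (nrow(pheno) == 0L) {
    return(list(results = dlcn_score(pheno[0, , drop = FALSE], factors),
                class_counts = setNames(integer(4), fh_classes()),
                excluded_ids = character(0), n_included = 0L))
  }
  excluded <- is.na(pheno$ldl_observed)
  res <- dlcn_score(pheno[!excluded, , drop = FALSE], factors, definite_at_8)
  counts <- table(factor(res$fh_class, levels = fh_classes()))
  list(results = res,
       class_counts = setNames(as.integer(counts), fh_classes()),
       excluded_ids = as.character(pheno$id[excluded]),
       n_included = nrow(res))
}

#' Is a cardiovascular event premature?
#'
#' Sex-specific cutoffs: an event before age 55 in men or before age 60 in
#' women counts as premature. Cutoffs are configurable.
#'
#' @param event_age age at event, years.
#' @param sex "male" or "female" (vectorized with `event_age`).
#' @param male_cutoff,female_cutoff exclusive upper age bounds.
#' @return logical vector.
#' @export
is_premature <- function(event_age, sex, male_cutoff = 55, female_cutoff = 60) {
  sex <- as.character(sex)
  if (!all(sex %in% c("male", "female"))) {
    stop_domain("`sex` must be 'male' or 'female'")
  }
  cutoff <- ifelse(sex == "male", male_cutoff, female_cutoff)
  event_age < cutoff
}
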