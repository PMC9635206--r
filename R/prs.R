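# Weighted LDL-C SNP score and the polygenic-inheritance assessment.
#
# The score is the raw weighted sum of LDL-raising effect-allele dosages
# (weights = per-allele GWAS effect sizes); it is not divided by the number
# of SNPs or alleles, which matches general-population score distributions
# with means below 1. A `normalize` option divides by the number of SNPs
# actually scored for users who want a per-SNP average.

#' Read a PRS weight table
#'
#' Tab-delimited with columns `rsid`, `chrom`, `pos`, `effect_allele`,
#' `other_allele`, `beta`. rsIDs must be unique, effect and other alleles
#' must differ, and strand-ambiguous pairs (A/T, C/G) are rejected with an
#' explicit error because they cannot be disambiguated without strand
#' information.
#'
#' @param path weight-table file.
#' @return validated data.frame.
#' @export
read_prs_weights <- function(path) {
  w <- read_tsv(path)
  validate_prs_weights(w)
}

#' @rdname read_prs_weights
#' @param weights in-memory weight table to validate.
#' @export
validate_prs_weights <- function(weights) {
  req <- c("rsid", "chrom", "pos", "effect_allele", "other_allele", "beta")
  miss <- setdiff(req, names(weights))
  if (length(miss)) {
    stop_domain("weight table lacks columns: ", paste(miss, collapse = ", "))
  }
  if (anyDuplicated(weights$rsid)) {
    stop_domain("duplicated rsID in weight table")
  }
  if (any(weights$effect_allele == weights$other_allele)) {
    stop_domain("effect allele must differ from other allele")
  }
  amb <- paste0(weights$effect_allele, weights$other_allele) %in%
    c("AT", "TA", "CG", "GC")
  if (any(amb)) {
    stop_domain("strand-ambiguous (A/T, C/G) SNPs rejected: ",
                paste(weights$rsid[amb], collapse = ", "))
  }
  weights$beta <- as.numeric(weights$beta)
  if (anyNA(weights$beta)) stop_domain("non-numeric beta in weight table")
  weights
}

#' Effect-allele dosage from an ALT dosage
#'
#' @param dosage_alt integer 0/1/2 count of the ALT allele (`NA` missing).
#' @param effect_allele,ref,alt site alleles; the effect allele may be
#'   either REF or ALT.
#' @return integer count of effect-allele copies.
#' @export
allele_dosage <- function(dosage_alt, effect_allele, ref, alt) {
  if (effect_allele == alt) {
    as.integer(dosage_alt)
  } else if (effect_allele == ref) {
    as.integer(2L - dosage_alt)
  } else {
    stop_domain(sprintf(
      "effect allele %s matches neither REF %s nor ALT %s",
      effect_allele, ref, alt))
  }
}

#' Compute per-participant LDL-C SNP scores
#'
#' score = sum over resolvable SNPs of effect-allele dosage times beta.
#' SNPs entirely absent from the genotype set are skipped for all
#' participants with a logged notice. Per-sample missing genotypes are, by
#' default, imputed as twice the cohort effect-allele frequency (the
#' standard expected-dosage imputation) and flagged; `missing = "strict"`
#' drops those SNPs from the affected participants' sums instead.
#'
#' @param geno an [fh_genotypes()] object.
#' @param weights validated PRS weight table.
#' @param missing `"impute"` (default) or `"strict"`.
#' @param normalize divide each score by the number of SNPs scored.
#' @return data.frame with `id`, `score`, `n_missing_snps`, `imputed`.
#' @export
compute_prs <- function(geno, weights, missing = c("impute", "strict"),
                        normalize = FALSE) {
  missing <- match.arg(missing)
  weights <- validate_prs_weights(weights)
  n <- n_samples(geno)
  ids <- rownames(geno$dosage)
  score <- rep(0, n)
  n_miss <- rep(0L, n)
  imputed <- rep(FALSE, n)
  n_used <- 0L
  for (i in seq_len(nrow(weights))) {
    j <- which(geno$variants$id == weights$rsid[i])
    if (length(j) == 0L) {
      key <- variant_key(weights$chrom[i], weights$pos[i],
                         weights$other_allele[i], weights$effect_allele[i])
      j <- match(key, geno$variants$key)
      if (is.na(j)) j <- integer(0)
    }
    if (length(j) == 0L) {
      message("PRS SNP absent from genotypes, skipped: ", weights$rsid[i])
      next
    }
    j <- j[1]
    d <- allele_dosage(geno$dosage[, j], weights$effect_allele[i],
                       geno$variants$ref[j], geno$variants$alt[j])
    miss_i <- is.na(d)
    n_miss <- n_miss + as.integer(miss_i)
    if (any(miss_i)) {
      if (missing == "impute") {
        af <- mean(d[!miss_i]) / 2
        if (is.nan(af)) af <- 0
        d[miss_i] <- 2 * af
        imputed <- imputed | miss_i
      } else {
        d[miss_i] <- 0
      }
    }
    score <- score + d * weights$beta[i]
    n_used <- n_used + 1L
  }
  if (normalize && n_used > 0L) score <- score / n_used
  data.frame(id = ids, score = score, n_missing_snps = n_miss,
             imputed = imputed, stringsAsFactors = FALSE)
}

#' Bottom-quartile threshold of a score distribution
#'
#' The 25th percentile (or another `q`) by linear interpolation between
#' order statistics (quantile type 7).
#'
#' @param scores numeric vector of at least four scores.
#' @param q quantile, default 0.25.
#' @return the threshold value.
#' @examples
#' bottom_quartile_threshold(c(0.4, 0.6, 0.8, 1.0))  # 0.55
#' @export
bottom_quartile_threshold <- function(scores, q = 0.25) {
  scores <- scores[!is.na(scores)]
  if (length(scores) < 4L) {
    stop_domain("at least four scores are needed for a quartile threshold")
  }
  unname(quantile(scores, probs = q, type = 7))
}

#' Polygenic-inheritance assessment
#'
#' Computes (i) the fraction of mutation-negative definite-or-probable FH
#' participants whose SNP score exceeds the bottom quartile of the
#' unlikely-FH score distribution (scores in the top three quartiles
#' suggest a polygenic rather than monogenic cause), (ii) group score
#' summaries (mean, SD) for definite-or-probable / possible / unlikely, and
#' (iii) a one-way ANOVA across those three groups. Groups without members
#' are omitted with a notice.
#'
#' @param scores data.frame from [compute_prs()] (`id`, `score`).
#' @param dlcn_results per-participant DLCN results (`id`, `fh_class`).
#' @param mut_positive named logical vector from [mutation_positive()].
#' @param q quantile defining the threshold, default 0.25.
#' @return list with `threshold`, `fraction_above`, `n_mut_negative_case`,
#'   `group_summaries`, `anova`.
#' @export
polygenic_assessment <- function(scores, dlcn_results, mut_positive,
                                 q = 0.25) {
  cls <- as.character(dlcn_results$fh_class)[match(scores$id,
                                                   dlcn_results$id)]
  group <- ifelse(cls %in% c("definite", "probable"), "definite_or_probable",
           ifelse(cls == "possible", "possible",
           ifelse(cls == "unlikely", "unlikely", NA_character_)))
  groups <- list(
    definite_or_probable = scores$score[!is.na(group) &
                                          group == "definite_or_probable"],
    possible = scores$score[!is.na(group) & group == "possible"],
    unlikely = scores$score[!is.na(group) & group == "unlikely"]
  )
  empty <- vapply(groups, function(g) length(g) == 0L, TRUE)
  if (any(empty)) {
    message("empty score group(s) omitted: ",
            paste(names(groups)[empty], collapse = ", "))
    groups <- groups[!empty]
  }
  threshold <- if (!is.null(groups$unlikely)) {
    bottom_quartile_threshold(groups$unlikely, q)
  } else NA_real_
  mp <- mut_positive[scores$id]
  mp[is.na(mp)] <- FALSE
  case_neg <- !is.na(group) & group == "definite_or_probable" & !mp
  fraction_above <- if (any(case_neg) && !is.na(threshold)) {
    mean(scores$score[case_neg] > threshold)
  } else NA_real_
  anova <- if (length(groups) >= 2 &&
               all(vapply(groups, length, 1L) >= 2)) {
    one_way_anova(groups)
  } else NULL
  list(threshold = threshold,
       fraction_above = fraction_above,
       n_mut_negative_case = sum(case_neg),
       group_summaries = data.frame(
         group = names(groups),
         n = vapply(groups, length, 1L),
         mean = vapply(groups, mean, 1),
         sd = vapply(groups, sd, 1),
         stringsAsFactors = FALSE),
       anova = anova)
}
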