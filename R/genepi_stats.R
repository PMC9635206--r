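# Genetic-epidemiology statistics: prevalence, odds ratios with Woolf
# intervals, 2x2 chi-square, one-way ANOVA, and the comorbidity cross-tabs
# behind the screening report.

#' Prevalence with a one-in-N representation
#'
#' @param k number of cases (>= 0).
#' @param n total number screened (> 0).
#' @return list with `k`, `n`, `proportion` = k/n, `percent`,
#'   `one_in_n` = round(n/k) (NA when k = 0) and a `label` like "1:125".
#' @examples
#' prevalence(49, 6140)  # 0.8%, "1:125"
#' @export
prevalence <- function(k, n) {
  if (length(k) != 1L || length(n) != 1L || is.na(k) || is.na(n)) {
    stop_domain("`k` and `n` must be single numbers")
  }
  if (n <= 0) stop_domain("`n` must be > 0")
  if (k < 0 || k > n) stop_domain("`k` must lie in [0, n]")
  one_in_n <- if (k > 0) round_half_up(n / k) else NA_real_
  list(k = k, n = n,
       proportion = k / n,
       percent = 100 * k / n,
       one_in_n = one_in_n,
       label = if (k > 0) sprintf("1:%d", as.integer(one_in_n)) else NA_character_)
}

as_table_2x2 <- function(a, b = NULL, c = NULL, d = NULL) {
  if (is.null(b)) {
    x <- as.numeric(a)
    if (length(x) != 4L) stop_domain("2x2 table needs exactly four cells")
  } else {
    x <- as.numeric(c(a, b, c, d))
  }
  if (any(is.na(x)) || any(x < 0)) stop_domain("2x2 cells must be >= 0")
  if (sum(x) <= 0) stop_domain("2x2 table must have a positive grand total")
  setNames(x, c("a", "b", "c", "d"))
}

#' Odds ratio with a Woolf (log-scale) confidence interval
#'
#' Cells follow the exposed-case (`a`), exposed-noncase (`b`),
#' unexposed-case (`c`), unexposed-noncase (`d`) layout, so
#' OR = (a d)/(b c). The confidence interval is
#' exp(log OR ± z * sqrt(1/a + 1/b + 1/c + 1/d)). Any zero cell triggers the
#' Haldane–Anscombe correction (+0.5 to every cell), reported via the
#' `corrected` flag.
#'
#' @param a,b,c,d non-negative cell counts; alternatively pass a length-4
#'   vector (a, b, c, d) as `a`.
#' @param conf_level confidence level, default 0.95.
#' @return list with `or`, `ci_low`, `ci_high`, `conf_level`, `corrected`.
#' @examples
#' odds_ratio_woolf(6, 43, 4, 5753)  # OR ~ 201, CI ~ (55, 736)
#' @export
odds_ratio_woolf <- function(a, b = NULL, c = NULL, d = NULL,
                             conf_level = 0.95) {
  t <- as_table_2x2(a, b, c, d)
  corrected <- any(t == 0)
  if (corrected) t <- t + 0.5
  or <- (t["a"] * t["d"]) / (t["b"] * t["c"])
  se <- sqrt(sum(1 / t))
  z <- qnorm(1 - (1 - conf_level) / 2)
  list(or = unname(or),
       ci_low = unname(exp(log(or) - z * se)),
       ci_high = unname(exp(log(or) + z * se)),
       conf_level = conf_level,
       corrected = corrected)
}

#' Pearson chi-square test on a 2x2 table
#'
#' No continuity correction by default; set `correct = TRUE` for Yates.
#' A zero row or column margin makes the statistic undefined and returns
#' `NA` for both statistic and p-value.
#'
#' @inheritParams odds_ratio_woolf
#' @param correct apply Yates continuity correction.
#' @return list with `statistic`, `p_value`, `df` (= 1).
#' @export
chi_square_2x2 <- function(a, b = NULL, c = NULL, d = NULL, correct = FALSE) {
  t <- as_table_2x2(a, b, c, d)
  m <- matrix(t, nrow = 2, byrow = TRUE)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    return(list(statistic = NA_real_, p_value = NA_real_, df = 1L))
  }
  ht <- suppressWarnings(chisq.test(m, correct = correct))
  list(statistic = unname(ht$statistic), p_value = unname(ht$p.value),
       df = 1L)
}

#' Classical one-way ANOVA
#'
#' Between/within mean-square F with (k - 1, N - k) degrees of freedom,
#' assuming equal variances (the classical ANOVA, not Welch).
#'
#' @param groups list of >= 2 numeric vectors, each of length >= 2.
#' @return list with `f`, `p_value`, `df_between`, `df_within` and a
#'   `group_summaries` data.frame (n, mean, sd per group).
#' @export
one_way_anova <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) {
    stop_domain("`groups` must be a list of at least two numeric vectors")
  }
  if (any(vapply(groups, length, 1L) < 2L)) {
    stop_domain("every group needs at least two observations")
  }
  labels <- names(groups) %||% paste0("group", seq_along(groups))
  labels[labels == ""] <- paste0("group", which(labels == ""))
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(labels, vapply(groups, length, 1L)), levels = labels)
  ht <- oneway.test(values ~ g, var.equal = TRUE)
  f <- unname(ht$statistic)
  p <- unname(ht$p.value)
  if (is.nan(f)) {  # zero within- and between-group variance
    f <- 0
    p <- 1
  }
  list(f = f, p_value = p,
       df_between = unname(ht$parameter[1]),
       df_within = unname(ht$parameter[2]),
       group_summaries = data.frame(
         group = labels,
         n = vapply(groups, length, 1L),
         mean = vapply(groups, mean, 1),
         sd = vapply(groups, sd, 1),
         stringsAsFactors = FALSE))
}

#' Comorbidity cross-tabulation by FH class
#'
#' Counts and percentages of a logical phenotype flag within each DLCN
#' class, plus a pooled definite-or-probable column. Percentages are
#' rounded half away from zero to integers for report parity with clinical
#' tables; raw proportions are retained.
#'
#' @param dlcn_results per-participant results from [dlcn_score()] /
#'   [classify_cohort()].
#' @param pheno phenotype table containing `id` and the flag column.
#' @param field name of a logical column in `pheno`.
#' @return data.frame with one row per class (plus `definite_or_probable`):
#'   `group`, `n`, `count`, `proportion`, `percent`.
#' @export
comorbidity_crosstab <- function(dlcn_results, pheno, field) {
  if (!field %in% names(pheno)) {
    stop_domain(sprintf("unknown phenotype field `%s`", field))
  }
  flag <- as.logical(pheno[[field]])[match(dlcn_results$id, pheno$id)]
  if (anyNA(match(dlcn_results$id, pheno$id))) {
    stop_domain("all DLCN result ids must be present in the phenotype table")
  }
  cls <- factor(dlcn_results$fh_class, levels = fh_classes())
  groups <- c(as.list(setNames(fh_classes(), fh_classes())),
              list(definite_or_probable = c("definite", "probable")))
  rows <- lapply(names(groups), function(gname) {
    in_g <- cls %in% groups[[gname]]
    n <- sum(in_g)
    k <- sum(flag[in_g], na.rm = TRUE)
    prop <- if (n > 0) k / n else NA_real_
    data.frame(group = gname, n = n, count = k, proportion = prop,
               percent = if (n > 0) round_half_up(100 * prop) else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
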