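# End-to-end orchestration: simulate or ingest, DLCN, carriers/penetrance,
# SV consensus, PRS, statistics. Stages communicate through documented
# plain-text files under the output directory so each stage can be re-run
# in isolation; the run report is serialized as JSON with a configuration
# hash for provenance.

#' Build a pipeline configuration
#'
#' Either a `simulate` block (arguments for [fh_sim_params()]) or a set of
#' `inputs` paths (`phenotypes`, `vcf`, `annotations`, `prs_weights`,
#' `sv_caller_a`, `sv_caller_b`, `genes`) must be supplied, not neither.
#'
#' @param out_dir output directory for stage files and the report.
#' @param simulate optional named list passed to [fh_sim_params()].
#' @param inputs optional named list of input file paths.
#' @param factors_path optional correction-factor file; defaults to the
#'   built-in map.
#' @param definite_at_8 DLCN boundary switch (see [classify_dlcn()]).
#' @param sv_threshold reciprocal-overlap threshold for SV consensus.
#' @param sv_min_size,sv_max_size SV size bounds in bases.
#' @param prs_quantile quantile for the polygenic bottom-quartile rule.
#' @param seed master seed (overrides any seed inside `simulate`).
#' @param quiet suppress stage log lines.
#' @return list of class `fh_pipeline_config`.
#' @export
fh_pipeline_config <- function(out_dir,
                               simulate = NULL,
                               inputs = NULL,
                               factors_path = NULL,
                               definite_at_8 = FALSE,
                               sv_threshold = 0.8,
                               sv_min_size = 50,
                               sv_max_size = 1e7,
                               prs_quantile = 0.25,
                               seed = 1L,
                               quiet = FALSE) {
  if (is.null(simulate) && is.null(inputs)) {
    stop_domain("config needs either a `simulate` block or `inputs` paths")
  }
  if (!is.null(inputs)) {
    req <- c("phenotypes", "vcf", "annotations", "prs_weights",
             "sv_caller_a", "sv_caller_b", "genes")
    miss <- setdiff(req, names(inputs))
    if (length(miss)) {
      stop_domain("`inputs` lacks paths: ", paste(miss, collapse = ", "))
    }
  }
  structure(list(out_dir = out_dir, simulate = simulate, inputs = inputs,
                 factors_path = factors_path, definite_at_8 = definite_at_8,
                 sv_threshold = sv_threshold, sv_min_size = sv_min_size,
                 sv_max_size = sv_max_size, prs_quantile = prs_quantile,
                 seed = as.integer(seed), quiet = quiet),
            class = "fh_pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys mirror the arguments of
#'   [fh_pipeline_config()].
#' @return an `fh_pipeline_config` object.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(fh_pipeline_config, y)
}

config_hash <- function(config) {
  canon <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA,
                            null = "null")
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(as.character(canon), tf)
  unname(tools::md5sum(tf))
}

stage_log <- function(quiet, stage, ...) {
  if (!quiet) message(sprintf("[%s] %s", stage, paste0(...)))
}

#' Run the full FH screening pipeline
#'
#' Executes all stages in order (simulate/ingest, DLCN classification,
#' carrier detection and penetrance, SV consensus and gene disruption, PRS
#' and polygenic assessment, epidemiology statistics), writes every stage
#' output under `config$out_dir`, and returns the run report (also written
#' as `report.json`). Deterministic given the seed and inputs.
#'
#' @param config an [fh_pipeline_config()] (or path to a YAML config).
#' @return the run report, an `fh_run_report` list.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  if (!inherits(config, "fh_pipeline_config")) {
    stop_domain("`config` must come from fh_pipeline_config()")
  }
  quiet <- isTRUE(config$quiet)
  out_dir <- config$out_dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  # stage: inputs ------------------------------------------------------
  if (!is.null(config$simulate)) {
    stage_log(quiet, "simulate", "generating synthetic cohort")
    sim_args <- config$simulate
    sim_args$seed <- config$seed
    params <- do.call(fh_sim_params, sim_args)
    bundle <- simulate_cohort(params)
    manifest <- write_cohort(bundle, file.path(out_dir, "cohort"))
    pheno <- bundle$phenotypes
    geno <- bundle$genotypes
    ann <- validate_annotations(bundle$annotations)
    weights <- bundle$prs_weights
    sv_a <- bundle$sv_calls$a
    sv_b <- bundle$sv_calls$b
    genes <- bundle$genes
  } else {
    stage_log(quiet, "ingest", "reading input files")
    pheno <- read_phenotypes(config$inputs$phenotypes)
    geno <- read_genotypes(config$inputs$vcf)
    ann <- load_annotations(config$inputs$annotations)
    weights <- read_prs_weights(config$inputs$prs_weights)
    sv_a <- read_sv_calls(config$inputs$sv_caller_a, caller = "caller_a")
    sv_b <- read_sv_calls(config$inputs$sv_caller_b, caller = "caller_b")
    genes <- read_gene_bed(config$inputs$genes)
    manifest <- unlist(config$inputs)
  }
  factors <- if (is.null(config$factors_path)) default_correction_factors()
             else read_correction_factors(config$factors_path)

  # stage: dlcn --------------------------------------------------------
  stage_log(quiet, "dlcn", "scoring cohort")
  cls <- classify_cohort(pheno, factors, config$definite_at_8)
  write_tsv(cls$results, file.path(out_dir, "dlcn_results.tsv"))
  prev <- prevalence(sum(cls$class_counts[c("definite", "probable")]),
                     cls$n_included)

  # stage: carriers ----------------------------------------------------
  stage_log(quiet, "carriers", "cross-referencing pathogenic variants")
  summaries <- carrier_status(geno, ann)
  summaries <- estimated_penetrance(summaries, cls$results)
  mut_pos <- mutation_positive(summaries, rownames(geno$dosage))
  carrier_table <- summaries[, setdiff(names(summaries),
                                       c("het_ids", "hom_ids"))]
  write_tsv(carrier_table, file.path(out_dir, "carrier_summaries.tsv"))

  # stage: sv consensus ------------------------------------------------
  stage_log(quiet, "sv", "merging caller call sets")
  sv_a_f <- sv_size_filter(sv_a, config$sv_min_size, config$sv_max_size)
  sv_b_f <- sv_size_filter(sv_b, config$sv_min_size, config$sv_max_size)
  consensus <- merge_callers(sv_a_f, sv_b_f, config$sv_threshold)
  write_tsv(consensus, file.path(out_dir, "sv_consensus.tsv"))
  multi <- multi_sample_consensus(consensus, config$sv_threshold)
  write_tsv(multi, file.path(out_dir, "sv_consensus_multisample.tsv"))
  disruptions <- gene_disruption(
    consensus, genes[genes$gene %in% c("LDLR", "PCSK9", "APOB"), ,
                     drop = FALSE])
  write_tsv(disruptions, file.path(out_dir, "sv_gene_disruption.tsv"))

  # stage: prs ---------------------------------------------------------
  stage_log(quiet, "prs", "computing LDL-C SNP scores")
  scores <- compute_prs(geno, weights)
  write_tsv(scores, file.path(out_dir, "prs_scores.tsv"))
  poly <- polygenic_assessment(scores, cls$results, mut_pos,
                               q = config$prs_quantile)

  # stage: stats -------------------------------------------------------
  stage_log(quiet, "stats", "prevalence, odds ratios and cross-tabs")
  case_ids <- cls$results$id[cls$results$fh_class %in%
                               c("definite", "probable")]
  unlikely_ids <- cls$results$id[cls$results$fh_class == "unlikely"]
  a <- sum(mut_pos[case_ids]); b <- length(case_ids) - a
  cc <- sum(mut_pos[unlikely_ids]); d <- length(unlikely_ids) - cc
  or_ldlr <- if (length(case_ids) > 0 && length(unlikely_ids) > 0) {
    odds_ratio_woolf(a, b, cc, d)
  } else NULL
  crosstab_fields <- intersect(
    c("premature_cad", "metabolic_syndrome", "diabetes", "hypertension",
      "obesity", "smoker", "parental_mi"),
    names(pheno))
  crosstabs <- lapply(setNames(crosstab_fields, crosstab_fields),
                      function(f) comorbidity_crosstab(cls$results, pheno, f))

  report <- structure(list(
    n_included = cls$n_included,
    n_excluded = length(cls$excluded_ids),
    class_counts = as.list(cls$class_counts),
    prevalence = prev[c("k", "n", "proportion", "percent", "one_in_n",
                        "label")],
    carrier_summaries = carrier_table,
    or_pathogenic_carrier = or_ldlr,
    sv = list(n_caller_a = nrow(sv_a), n_caller_b = nrow(sv_b),
              n_consensus = nrow(consensus),
              n_multisample = nrow(multi),
              n_gene_disruptions = nrow(disruptions)),
    prs = list(threshold = poly$threshold,
               fraction_above = poly$fraction_above,
               n_mut_negative_case = poly$n_mut_negative_case,
               group_summaries = poly$group_summaries,
               anova = if (!is.null(poly$anova))
                 poly$anova[c("f", "p_value", "df_between", "df_within")]
               else NULL),
    comorbidity_crosstabs = crosstabs,
    provenance = list(seed = config$seed,
                      config_hash = config_hash(config),
                      package_version = as.character(
                        utils::packageVersion("fhburden"))),
    manifest = as.list(manifest)
  ), class = "fh_run_report")
  json <- jsonlite::toJSON(unclass(report), auto_unbox = TRUE, digits = NA,
                           pretty = TRUE, null = "null", dataframe = "rows")
  writeLines(as.character(json), file.path(out_dir, "report.json"))
  report
}
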