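# Curated-variant carrier detection and estimated clinical penetrance.
#
# Estimated clinical penetrance is the fraction of a variant's carriers
# classified definite, probable or possible FH by the DLCN criteria. For
# dominant genes carriers of any zygosity count; for recessive genes both
# numerator and denominator are restricted to homozygotes.

fh_dominant_genes <- c("LDLR", "APOB", "PCSK9")
fh_recessive_genes <- c("LDLRAP1", "ABCG5", "ABCG8", "LIPA")

#' Validate a pathogenicity annotation table
#'
#' Checks required columns, unique variant keys, and inheritance modes.
#' For the seven canonical FH genes the mode must agree with the gene list
#' (*LDLR*/*APOB*/*PCSK9* dominant; *LDLRAP1*/*ABCG5*/*ABCG8*/*LIPA*
#' recessive). Variant keys are normalized (shared prefix/suffix trimming)
#' so they match VCF-derived keys.
#'
#' @param ann data.frame with columns `gene`, `chrom`, `pos`, `ref`, `alt`,
#'   `classification`, `mode` (plus optional `rsid`, `cdna`, `protein`,
#'   `source`, `phenotype`, `max_af`).
#' @return the validated table with a normalized `key` column added.
#' @export
validate_annotations <- function(ann) {
  req <- c("gene", "chrom", "pos", "ref", "alt", "classification", "mode")
  miss <- setdiff(req, names(ann))
  if (length(miss)) {
    stop_domain("annotation table lacks columns: ",
                paste(miss, collapse = ", "))
  }
  if (nrow(ann) == 0L) {
    ann$key <- character(0)
    return(ann)
  }
  if (!all(ann$mode %in% c("dominant", "recessive"))) {
    stop_domain("annotation mode must be 'dominant' or 'recessive'")
  }
  bad_dom <- ann$gene %in% fh_dominant_genes & ann$mode != "dominant"
  bad_rec <- ann$gene %in% fh_recessive_genes & ann$mode != "recessive"
  if (any(bad_dom | bad_rec)) {
    stop_domain("inheritance mode inconsistent with FH gene list for: ",
                paste(unique(ann$gene[bad_dom | bad_rec]), collapse = ", "))
  }
  nv <- normalize_variant(ann$chrom, ann$pos, ann$ref, ann$alt)
  ann$chrom <- nv$chrom; ann$pos <- nv$pos
  ann$ref <- nv$ref; ann$alt <- nv$alt
  ann$key <- nv$key
  if (anyDuplicated(ann$key)) {
    stop_domain("duplicated variant key in annotation table: ",
                paste(unique(ann$key[duplicated(ann$key)]), collapse = ", "))
  }
  ann
}

#' Load a pathogenicity annotation table from delimited text
#'
#' @param path tab-delimited annotation file.
#' @return validated annotation data.frame (see [validate_annotations()]).
#' @export
load_annotations <- function(path) {
  if (!file.exists(path)) stop_domain("annotation file not found: ", path)
  validate_annotations(read_tsv(path))
}

#' Carrier status of annotated variants in a cohort
#'
#' For every annotated variant, finds heterozygous and homozygous carriers
#' in the genotype set, and computes the cohort allele count and allele
#' frequency. Missing genotypes are excluded from the frequency denominator
#' (standard allele-number convention). Annotated variants absent from the
#' VCF yield a zero-carrier summary with a logged notice, not an error.
#'
#' @param geno an [fh_genotypes()] object (e.g. from [read_genotypes()]).
#' @param ann validated annotation table.
#' @return data.frame, one row per annotation: `key`, `gene`, `mode`,
#'   `classification`, `n_het`, `n_hom`, `allele_count`, `allele_number`,
#'   `allele_frequency`, `in_vcf`, plus list-columns `het_ids`, `hom_ids`.
#' @export
carrier_status <- function(geno, ann) {
  ann <- validate_annotations(ann)
  rows <- lapply(seq_len(nrow(ann)), function(i) {
    key <- ann$key[i]
    j <- match(key, geno$variants$key)
    if (is.na(j)) {
      message("annotated variant absent from VCF: ", key)
      het <- character(0); hom <- character(0)
      an <- 2L * nrow(geno$dosage)
    } else {
      d <- geno$dosage[, j]
      het <- rownames(geno$dosage)[!is.na(d) & d == 1L]
      hom <- rownames(geno$dosage)[!is.na(d) & d == 2L]
      an <- 2L * sum(!is.na(d))
    }
    ac <- length(het) + 2L * length(hom)
    data.frame(key = key, gene = ann$gene[i], mode = ann$mode[i],
               classification = ann$classification[i],
               n_het = length(het), n_hom = length(hom),
               allele_count = ac, allele_number = an,
               allele_frequency = if (an > 0) ac / an else NA_real_,
               in_vcf = !is.na(j),
               het_ids = I(list(het)), hom_ids = I(list(hom)),
               stringsAsFactors = FALSE)
  })
  if (!length(rows)) {
    return(data.frame(key = character(0), gene = character(0),
                      mode = character(0), classification = character(0),
                      n_het = integer(0), n_hom = integer(0),
                      allele_count = integer(0), allele_number = integer(0),
                      allele_frequency = numeric(0), in_vcf = logical(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

carrier_ids <- function(summary_row, mode = summary_row$mode) {
  het <- summary_row$het_ids[[1]]
  hom <- summary_row$hom_ids[[1]]
  if (identical(mode, "recessive")) hom else c(het, hom)
}

#' Estimated clinical penetrance per variant
#'
#' Numerator: carriers classified definite, probable or possible FH.
#' Denominator: all carriers for dominant variants; homozygotes only for
#' recessive variants. A zero denominator yields an undefined-penetrance
#' marker (`NA` with `penetrance_defined = FALSE`), distinct from an
#' estimated penetrance of zero.
#'
#' @param summaries output of [carrier_status()].
#' @param dlcn_results per-participant DLCN results covering every carrier
#'   (columns `id`, `fh_class`).
#' @return `summaries` with `penetrance_num`, `penetrance_den`,
#'   `penetrance` and `penetrance_defined` columns added.
#' @export
estimated_penetrance <- function(summaries, dlcn_results) {
  affected_ids <- dlcn_results$id[
    dlcn_results$fh_class %in% c("definite", "probable", "possible")]
  num <- integer(nrow(summaries))
  den <- integer(nrow(summaries))
  for (i in seq_len(nrow(summaries))) {
    ids <- carrier_ids(summaries[i, ])
    missing_class <- setdiff(ids, dlcn_results$id)
    if (length(missing_class)) {
      stop_domain("carriers lack a DLCN class: ",
                  paste(missing_class, collapse = ", "))
    }
    den[i] <- length(ids)
    num[i] <- sum(ids %in% affected_ids)
  }
  summaries$penetrance_num <- num
  summaries$penetrance_den <- den
  summaries$penetrance <- ifelse(den > 0, num / den, NA_real_)
  summaries$penetrance_defined <- den > 0
  summaries
}

#' Flag mutation-positive participants
#'
#' A participant is mutation-positive iff they carry at least one variant
#' whose classification is in `classes` (default pathogenic/likely
#' pathogenic) in one of the genes of `gene_set`, at any zygosity for
#' dominant genes. Used to split mutation-positive from mutation-negative
#' FH individuals for the polygenic-score analysis.
#'
#' @param summaries output of [carrier_status()].
#' @param sample_ids character vector of all participant ids to flag.
#' @param gene_set genes to consider (default the dominant FH genes).
#' @param classes classifications that count as pathogenic.
#' @return named logical vector over `sample_ids`.
#' @export
mutation_positive <- function(summaries, sample_ids,
                              gene_set = fh_dominant_genes,
                              classes = c("P", "LP", "P/LP")) {
  out <- setNames(rep(FALSE, length(sample_ids)), sample_ids)
  keep <- summaries$gene %in% gene_set &
    summaries$classification %in% classes
  for (i in which(keep)) {
    ids <- c(summaries$het_ids[[i]], summaries$hom_ids[[i]])
    out[intersect(ids, sample_ids)] <- TRUE
  }
  out
}
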