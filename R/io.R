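# File formats: VCF genotypes (read via vcfR, written by a small
# format-correct text writer), BED gene intervals (read via rtracklayer,
# converted to 1-based inclusive coordinates), and tab-delimited SV call
# sets and phenotype tables.

#' Construct a genotype container
#'
#' The in-memory genotype representation is a variant metadata table plus a
#' samples-by-variants matrix of ALT-allele dosages (0/1/2, `NA` = missing
#' genotype). Column names are normalized `chrom:pos:ref:alt` keys.
#'
#' @param variants data.frame with columns `chrom`, `pos` (1-based), `id`
#'   (rsID or "."), `ref`, `alt`.
#' @param dosage integer matrix, samples in rows (rownames = sample ids),
#'   variants in columns.
#' @return object of class `fh_genotypes`.
#' @export
fh_genotypes <- function(variants, dosage) {
  stopifnot(is.data.frame(variants), is.matrix(dosage),
            nrow(variants) == ncol(dosage),
            nrow(dosage) == 0L || !is.null(rownames(dosage)))
  if (is.null(rownames(dosage))) rownames(dosage) <- character(0)
  variants$key <- variant_key(variants$chrom, variants$pos,
                              variants$ref, variants$alt)
  colnames(dosage) <- variants$key
  structure(list(variants = variants, dosage = dosage),
            class = "fh_genotypes")
}

#' @export
print.fh_genotypes <- function(x, ...) {
  cat(sprintf("<fh_genotypes> %d samples x %d variants\n",
              nrow(x$dosage), ncol(x$dosage)))
  invisible(x)
}

#' Number of samples / variants in a genotype container
#' @param geno an `fh_genotypes` object.
#' @return integer.
#' @export
n_samples <- function(geno) nrow(geno$dosage)

dosage_to_gt <- function(d) {
  gt <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")[as.character(d)]
  gt[is.na(d)] <- "./."
  gt
}

gt_to_dosage <- function(gt) {
  # GT like 0/1, 1|1, ./.; counts of allele "1" (callers must pre-split
  # multiallelics or use read_genotypes(), which splits).
  gt <- sub(":.*", "", gt)
  out <- rep(NA_integer_, length(gt))
  ok <- !is.na(gt) & grepl("^[0-9.]([/|][0-9.])?$", gt)
  alleles <- strsplit(gt[ok], "[/|]")
  out[ok] <- vapply(alleles, function(a) {
    if (any(a == ".")) return(NA_integer_)
    sum(a == "1")
  }, 1L)
  out
}

#' Write genotypes as a VCF v4.2 file
#'
#' Emits a minimal GT-only VCF (FORMAT "GT"), one sample column per row of
#' the dosage matrix, sorted by chromosome and position.
#'
#' @param geno `fh_genotypes` object.
#' @param path output path (plain text `.vcf`).
#' @return the path, invisibly.
#' @export
write_vcf <- function(geno, path) {
  v <- geno$variants
  ord <- order(v$chrom, v$pos)
  v <- v[ord, , drop = FALSE]
  dos <- geno$dosage[, ord, drop = FALSE]
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=fhburden",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(dos)), collapse = "\t")
  )
  body <- vapply(seq_len(nrow(v)), function(i) {
    paste(c(v$chrom[i], v$pos[i], v$id[i] %||% ".", v$ref[i], v$alt[i],
            ".", "PASS", ".", "GT", dosage_to_gt(dos[, i])),
          collapse = "\t")
  }, "")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read genotypes from a VCF file
#'
#' Parses a VCF via \pkg{vcfR}, splits multi-allelic records into biallelic
#' ALT-specific dosages, and normalizes variant keys (shared prefix/suffix
#' trimming) so they match annotation tables.
#'
#' @param path VCF file (plain or bgzipped).
#' @return an [fh_genotypes()] object.
#' @export
read_genotypes <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
  gt_raw <- vcfR::extract.gt(vcf, element = "GT")
  samples <- colnames(gt_raw)
  var_rows <- list()
  dos_cols <- list()
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    gts <- sub(":.*", "", gt_raw[i, ])
    alleles <- strsplit(gts, "[/|]")
    for (ai in seq_along(alts)) {
      d <- vapply(alleles, function(a) {
        if (length(a) == 0L || any(is.na(a)) || any(a == ".")) {
          return(NA_integer_)
        }
        sum(a == as.character(ai))
      }, 1L)
      d[is.na(gts)] <- NA_integer_
      nv <- normalize_variant(fix$CHROM[i], as.integer(fix$POS[i]),
                              fix$REF[i], alts[ai])
      var_rows[[length(var_rows) + 1L]] <- data.frame(
        chrom = nv$chrom, pos = nv$pos,
        id = fix$ID[i] %||% ".", ref = nv$ref, alt = nv$alt,
        stringsAsFactors = FALSE)
      dos_cols[[length(dos_cols) + 1L]] <- d
    }
  }
  variants <- do.call(rbind, var_rows)
  dosage <- do.call(cbind, dos_cols)
  rownames(dosage) <- samples
  fh_genotypes(variants, dosage)
}

#' Read gene intervals from a BED file
#'
#' BED is 0-based half-open; intervals are converted to the package's
#' 1-based inclusive convention on read.
#'
#' @param path BED file with at least chrom/start/end/name columns.
#' @return data.frame with `gene`, `chrom`, `start`, `end` (1-based
#'   inclusive).
#' @export
read_gene_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  df <- as.data.frame(gr)
  data.frame(gene = if ("name" %in% names(df)) df$name else
               paste0("region", seq_len(nrow(df))),
             chrom = as.character(df$seqnames),
             start = df$start,   # GRanges is already 1-based inclusive
             end = df$end,
             stringsAsFactors = FALSE)
}

#' Write gene intervals as BED
#'
#' @param genes data.frame with `gene`, `chrom`, `start`, `end` in 1-based
#'   inclusive coordinates; written as 0-based half-open BED.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_gene_bed <- function(genes, path) {
  bed <- data.frame(chrom = genes$chrom, start = genes$start - 1L,
                    end = genes$end, name = genes$gene)
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

sv_required_cols <- c("sample", "chrom", "start", "end", "type", "caller")

#' Read a structural-variant call set
#'
#' Accepts either a tab-delimited table with columns
#' `sample, chrom, start, end, type, caller` (1-based inclusive
#' coordinates), or a VCF with `SVTYPE` and `END` INFO keys. Breakend (BND)
#' records are excluded with a message reporting the count.
#'
#' @param path input file.
#' @param caller caller label; required for VCF input, used to fill a
#'   missing `caller` column for tabular input.
#' @param sample sample id for VCF input lacking per-record sample columns
#'   (single-sample SV VCFs); ignored for tabular input.
#' @return data.frame of SV calls with the six required columns; `length`
#'   is computed as `end - start + 1`.
#' @export
read_sv_calls <- function(path, caller = NULL, sample = NULL) {
  first <- readLines(path, n = 1L)
  if (startsWith(first, "##fileformat=VCF")) {
    if (is.null(caller)) stop_domain("VCF SV input needs a `caller` label")
    vcf <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- as.data.frame(vcfR::getFIX(vcf, getINFO = TRUE),
                         stringsAsFactors = FALSE)
    svtype <- vcfR::extract.info(vcf, "SVTYPE")
    end <- as.integer(vcfR::extract.info(vcf, "END"))
    keep <- !is.na(svtype) & svtype != "BND"
    n_bnd <- sum(svtype == "BND", na.rm = TRUE)
    if (n_bnd > 0) message(sprintf("excluded %d BND record(s)", n_bnd))
    smp <- sample %||% colnames(vcf@gt)[-1][1]
    if (is.null(smp) || is.na(smp)) smp <- "sample1"
    calls <- data.frame(sample = smp,
                        chrom = fix$CHROM[keep],
                        start = as.integer(fix$POS[keep]),
                        end = end[keep],
                        type = svtype[keep],
                        caller = caller,
                        stringsAsFactors = FALSE)
  } else {
    calls <- read_tsv(path)
    if (!is.null(caller) && !"caller" %in% names(calls)) {
      calls$caller <- caller
    }
    miss <- setdiff(sv_required_cols, names(calls))
    if (length(miss)) {
      stop_domain("SV table lacks columns: ", paste(miss, collapse = ", "))
    }
  }
  calls$start <- as.integer(calls$start)
  calls$end <- as.integer(calls$end)
  if (any(calls$end < calls$start)) stop_domain("SV calls need end >= start")
  calls$length <- calls$end - calls$start + 1L
  calls[, c(sv_required_cols, "length")]
}

#' Read a cohort phenotype table
#'
#' @param path tab-delimited phenotype table as written by [write_cohort()].
#' @return data.frame with logical flag columns restored.
#' @export
read_phenotypes <- function(path) {
  df <- read_tsv(path)
  logical_cols <- intersect(
    c("on_med", "first_degree_cvd", "premature_cad",
      "premature_cerebro_peripheral", "self_reported_hc", "obesity",
      "metabolic_syndrome", "diabetes", "hypertension", "smoker",
      "parental_mi"),
    names(df))
  for (cl in logical_cols) df[[cl]] <- as.logical(df[[cl]])
  df$id <- as.character(df$id)
  df
}
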