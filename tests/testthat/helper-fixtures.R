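# Shared fixtures, built in code.

# Minimal phenotype row(s) with every field the DLCN scorer needs.
make_pheno <- function(id = "p1", ldl = 3.0, on_med = FALSE,
                       med_class = NA_character_, family = FALSE,
                       cad = FALSE, vascular = FALSE) {
  data.frame(id = id, age = 45L, sex = "female", ldl_observed = ldl,
             on_med = on_med, med_class = med_class,
             first_degree_cvd = family, premature_cad = cad,
             premature_cerebro_peripheral = vascular,
             self_reported_hc = FALSE, obesity = FALSE,
             metabolic_syndrome = FALSE, diabetes = FALSE,
             hypertension = FALSE, smoker = FALSE, parental_mi = FALSE,
             stringsAsFactors = FALSE)
}

# Genotype container with given per-variant het/hom carrier counts among n
# samples. Carriers are stacked without overlap: variant j's carriers start
# after variant j-1's (het before hom within a variant).
make_genotypes <- function(n, het = integer(0), hom = integer(0),
                           genes = NULL) {
  k <- length(het)
  if (length(hom) == 0L) hom <- rep(0L, k)
  ids <- sprintf("s%04d", seq_len(n))
  dosage <- matrix(0L, nrow = n, ncol = k, dimnames = list(ids, NULL))
  offset <- 0L
  for (j in seq_len(k)) {
    if (het[j] > 0) dosage[offset + seq_len(het[j]), j] <- 1L
    if (hom[j] > 0) dosage[offset + het[j] + seq_len(hom[j]), j] <- 2L
    offset <- offset + het[j] + hom[j]
  }
  variants <- data.frame(
    chrom = "chr19",
    pos = 11090000L + 100L * seq_len(k),
    id = sprintf("rsx%d", seq_len(k)),
    ref = "A", alt = "G", stringsAsFactors = FALSE)
  fh_genotypes(variants, dosage)
}

make_annotations <- function(geno, gene = "LDLR", mode = "dominant",
                             classification = "P") {
  v <- geno$variants
  data.frame(gene = gene, chrom = v$chrom, pos = v$pos, ref = v$ref,
             alt = v$alt, rsid = v$id, classification = classification,
             mode = mode, stringsAsFactors = FALSE)
}

# DLCN results table assigning fixed classes to ids.
make_dlcn <- function(ids, classes) {
  data.frame(id = ids, fh_class = factor(classes, levels = fh_classes()),
             stringsAsFactors = FALSE)
}

sv_call <- function(sample = "s1", chrom = "chr1", start, end, type = "DEL",
                    caller = "caller_a") {
  data.frame(sample = sample, chrom = chrom, start = start, end = end,
             type = type, caller = caller, stringsAsFactors = FALSE)
}

# Central 99% binomial interval by direct pmf summation (independent
# oracle: lo = largest k with P(X < k) <= 0.005, hi = smallest k with
# P(X <= k) >= 0.995).
central_binom_interval <- function(size, prob, level = 0.99) {
  alpha <- (1 - level) / 2
  cdf <- cumsum(dbinom(0:size, size, prob))
  lo <- max(which(c(0, cdf[-length(cdf)]) <= alpha)) - 1L
  hi <- min(which(cdf >= 1 - alpha)) - 1L
  c(lo, hi)
}
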