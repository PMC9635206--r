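# Synthetic biobank generator.
#
# Real cohort genotype/phenotype data of the kind this package analyses is
# access-controlled, so the generator builds a cohort with the same
# statistical structure: log-normal baseline LDL-C with mild age/sex
# shifts, a common-variant polygenic contribution, rare planted
# dominant/recessive pathogenic variants with specified penetrance and
# effect size, lipid-lowering treatment that masks true LDL-C by a fixed
# fractional reduction, noisy questionnaire fields, and two jittered
# structural-variant call sets around a shared set of true events. Full
# ground truth is retained for parameter-recovery tests.

#' Approximate genomic intervals of the seven FH-relevant genes
#'
#' Dominant FH genes (*LDLR*, *APOB*, *PCSK9*) and recessive ones
#' (*LDLRAP1*, *ABCG5*, *ABCG8*, *LIPA*). Coordinates are approximate
#' GRCh38 gene spans, 1-based inclusive; they serve as simulation and
#' SV-annotation anchors, not as an authoritative gene model.
#'
#' @return data.frame with `gene`, `chrom`, `start`, `end`, `mode`.
#' @export
fh_gene_intervals <- function() {
  data.frame(
    gene  = c("LDLR", "APOB", "PCSK9", "LDLRAP1", "ABCG5", "ABCG8", "LIPA"),
    chrom = c("chr19", "chr2", "chr1", "chr1", "chr2", "chr2", "chr10"),
    start = c(11089362, 21001429, 55039475, 25543500, 43812472, 43838887,
              89213569),
    end   = c(11133820, 21044073, 55064852, 25590000, 43838865, 43878700,
              89252000),
    mode  = c("dominant", "dominant", "dominant", "recessive", "recessive",
              "recessive", "recessive"),
    stringsAsFactors = FALSE
  )
}

#' Default planted pathogenic variants
#'
#' A small catalogue of rare variants mirroring the structure of a
#' ClinVar-style pathogenic/likely-pathogenic FH table: four dominant
#' *LDLR* variants with allele counts of order 1–6 per ~6,000 genomes and
#' penetrances spanning 0–1, plus recessive sitosterolemia alleles in
#' *ABCG5*/*ABCG8*. Positions within the gene spans are synthetic;
#' frequencies are allele frequencies used for Hardy–Weinberg planting.
#'
#' @param n_reference cohort size used to convert target allele counts into
#'   allele frequencies (default 6140).
#' @return data.frame, one row per variant.
#' @export
default_planted_variants <- function(n_reference = 6140) {
  ac <- c(6, 3, 1, 1, 27, 6)
  data.frame(
    chrom = c("chr19", "chr19", "chr19", "chr19", "chr2", "chr2"),
    pos = c(11102500, 11105800, 11111200, 11120400, 43820000, 43860000),
    ref = c("A", "A", "A", "T", "C", "G"),
    alt = c("C", "G", "G", "G", "T", "A"),
    rsid = c("rs1064793799", "rs771019366", "rs758194385", "rs879254809",
             "rs199689137", "rs137852988"),
    gene = c("LDLR", "LDLR", "LDLR", "LDLR", "ABCG5", "ABCG8"),
    mode = c("dominant", "dominant", "dominant", "dominant", "recessive",
             "recessive"),
    frequency = ac / (2 * n_reference),
    penetrance = c(0.83, 0.67, 1.0, 0.0, 1.0, 1.0),
    ldl_effect = c(3.0, 3.0, 3.0, 3.0, 2.5, 2.5),
    classification = c("P", "P/LP", "LP", "LP", "P", "P/LP"),
    cdna = c("c.313+3A>C", "c.269A>G", "c.1691A>G", "c.1154T>G",
             "c.1336C>T", "c.1720G>A"),
    protein = c(".", "p.Asp90Gly", "p.Asn564Ser", "p.Leu385Arg",
                "p.Arg446Ter", "p.Gly574Arg"),
    source = "ClinVar",
    phenotype = c(rep("Familial Hypercholesterolemia", 4),
                  "Sitosterolemia 1", "Sitosterolemia 2"),
    stringsAsFactors = FALSE
  )
}

#' Default (illustrative) LDL-C SNP score weights
#'
#' Eleven common LDL-raising SNPs with effect alleles, allele frequencies
#' and per-allele betas (mmol/L per allele). The rsIDs come from the
#' standard 12-SNP LDL-C panel minus the *HFE* SNP; alleles and betas are
#' illustrative values calibrated once so the synthetic general-population
#' score distribution has mean near 0.76 and SD near 0.2. They are not the
#' published GWAS weights, which live in supplementary material; supply a
#' real table via [read_prs_weights()] for production use. No
#' strand-ambiguous (A/T or C/G) allele pairs are used.
#'
#' @return data.frame with `rsid`, `chrom`, `pos`, `effect_allele`,
#'   `other_allele`, `frequency`, `beta`.
#' @export
default_prs_snps <- function() {
  data.frame(
    rsid = c("rs629301", "rs1367117", "rs4299376", "rs1564348", "rs1800961",
             "rs3757354", "rs11220462", "rs8017377", "rs6511720",
             "rs429358", "rs7412"),
    chrom = c("chr1", "chr2", "chr2", "chr6", "chr20", "chr6", "chr11",
              "chr14", "chr19", "chr19", "chr19"),
    pos = c(109275684, 21044073, 43845437, 160578860, 44413724, 16127245,
            126243952, 24407084, 11091630, 44908684, 44908822),
    effect_allele = c("T", "A", "G", "C", "C", "C", "A", "A", "G", "C", "C"),
    other_allele  = c("G", "G", "T", "T", "T", "T", "G", "G", "T", "T", "T"),
    frequency = c(0.25, 0.30, 0.30, 0.20, 0.05, 0.35, 0.15, 0.45, 0.88,
                  0.15, 0.10),
    beta = c(0.145, 0.102, 0.085, 0.068, 0.187, 0.068, 0.119, 0.060,
             0.170, 0.136, 0.255),
    stringsAsFactors = FALSE
  )
}

#' Simulation parameters for the synthetic biobank
#'
#' Defaults emulate the cohort structure the analysis assumes: about 6,140
#' adults, 57% female, ~13% on lipid-lowering therapy with a true 30%
#' LDL-C reduction masked by treatment, log-normal baseline LDL-C with mild
#' age/sex shifts plus a common-variant polygenic contribution, rare
#' planted pathogenic variants, and 2% symmetric misreport noise on
#' questionnaire fields.
#'
#' @param n_participants cohort size (>= 0).
#' @param seed master RNG seed; per-component substreams are derived from
#'   it so adding a component does not perturb the others.
#' @param age_range integer (min, max) age in years.
#' @param female_fraction proportion female.
#' @param ldl_mean,ldl_sd mean and SD of baseline log LDL-C (log mmol/L).
#' @param treatment_fraction proportion on lipid-lowering therapy.
#' @param true_treatment_reduction fractional LDL-C reduction in treated
#'   participants (observed = true x (1 - reduction)).
#' @param planted_variants data.frame as in [default_planted_variants()];
#'   allele frequencies must lie in (0, 0.5].
#' @param prs_snps data.frame as in [default_prs_snps()]; effect-allele
#'   frequencies in (0, 1).
#' @param selfreport_noise symmetric misreport (flip) probability for
#'   questionnaire-derived fields.
#' @param geno_missing_rate per-genotype missingness rate in the emitted
#'   VCF (default 0).
#' @param n_sv_events number of true structural-variant events planted
#'   across the cohort (each observed by each caller with
#'   `sv_detect_prob`, with small breakpoint jitter).
#' @param sv_detect_prob per-caller detection probability of a true SV.
#' @return validated list of class `fh_sim_params`.
#' @export
fh_sim_params <- function(n_participants = 6140,
                          seed = 1L,
                          age_range = c(18L, 88L),
                          female_fraction = 0.569,
                          ldl_mean = 0.84,
                          ldl_sd = 0.38,
                          treatment_fraction = 0.134,
                          true_treatment_reduction = 0.30,
                          planted_variants = default_planted_variants(),
                          prs_snps = default_prs_snps(),
                          selfreport_noise = 0.02,
                          geno_missing_rate = 0,
                          n_sv_events = 40,
                          sv_detect_prob = 0.9) {
  if (length(n_participants) != 1L || is.na(n_participants) ||
      n_participants < 0 || n_participants != floor(n_participants)) {
    stop_domain("`n_participants` must be a non-negative integer")
  }
  assert_proportion(female_fraction, "female_fraction")
  assert_proportion(treatment_fraction, "treatment_fraction")
  assert_proportion(true_treatment_reduction, "true_treatment_reduction")
  assert_proportion(selfreport_noise, "selfreport_noise")
  assert_proportion(geno_missing_rate, "geno_missing_rate")
  assert_proportion(sv_detect_prob, "sv_detect_prob")
  if (length(age_range) != 2L || age_range[1] <= 0 ||
      age_range[2] < age_range[1]) {
    stop_domain("`age_range` must be (min, max) with 0 < min <= max")
  }
  if (nrow(planted_variants) > 0) {
    f <- planted_variants$frequency
    if (any(is.na(f)) || any(f <= 0) || any(f > 0.5)) {
      stop_domain("planted variant allele frequencies must lie in (0, 0.5]")
    }
    if (!all(planted_variants$mode %in% c("dominant", "recessive"))) {
      stop_domain("planted variant mode must be 'dominant' or 'recessive'")
    }
    assert_proportion(planted_variants$penetrance, "penetrance")
  }
  if (nrow(prs_snps) > 0) {
    f <- prs_snps$frequency
    if (any(is.na(f)) || any(f <= 0) || any(f >= 1)) {
      stop_domain("PRS effect-allele frequencies must lie in (0, 1)")
    }
    amb <- paste0(prs_snps$effect_allele, prs_snps$other_allele) %in%
      c("AT", "TA", "CG", "GC")
    if (any(amb)) {
      stop_domain("strand-ambiguous (A/T, C/G) PRS SNPs are not allowed: ",
                  paste(prs_snps$rsid[amb], collapse = ", "))
    }
  }
  structure(list(
    n_participants = as.integer(n_participants),
    seed = as.integer(seed),
    age_range = as.integer(age_range),
    female_fraction = female_fraction,
    ldl_mean = ldl_mean, ldl_sd = ldl_sd,
    treatment_fraction = treatment_fraction,
    true_treatment_reduction = true_treatment_reduction,
    planted_variants = planted_variants,
    prs_snps = prs_snps,
    selfreport_noise = selfreport_noise,
    geno_missing_rate = geno_missing_rate,
    n_sv_events = n_sv_events,
    sv_detect_prob = sv_detect_prob
  ), class = "fh_sim_params")
}

flip_noise <- function(x, p) {
  if (p <= 0 || length(x) == 0L) return(x)
  xor(x, runif(length(x)) < p)
}

#' Simulate a synthetic biobank cohort
#'
#' Generates phenotypes, small-variant genotypes (planted pathogenic
#' variants plus PRS SNPs, both in Hardy–Weinberg proportions at their
#' stated frequencies), a pathogenicity annotation table, a PRS weight
#' table, two structural-variant call sets, gene intervals, and full ground
#' truth. Deterministic given `params$seed`.
#'
#' @param params an [fh_sim_params()] object.
#' @return list of class `fh_cohort` with elements `phenotypes`,
#'   `genotypes` ([fh_genotypes()]), `annotations`, `prs_weights`,
#'   `sv_calls` (list `a`, `b`), `genes`, `truth` (list `ldl`, `variants`)
#'   and `params`.
#' @export
simulate_cohort <- function(params = fh_sim_params()) {
  if (!inherits(params, "fh_sim_params")) {
    stop_domain("`params` must come from fh_sim_params()")
  }
  n <- params$n_participants
  seeds <- component_seeds(params$seed)
  ids <- if (n > 0) sprintf("QB%05d", seq_len(n)) else character(0)

  # demographics -------------------------------------------------------
  demo <- with_seed(seeds[["demographics"]], {
    sex <- ifelse(runif(n) < params$female_fraction, "female", "male")
    age <- sample(seq(params$age_range[1], params$age_range[2]), n,
                  replace = TRUE)
    list(sex = sex, age = age)
  })

  # genotypes (Hardy-Weinberg planting) --------------------------------
  pv <- params$planted_variants
  ps <- params$prs_snps
  geno <- with_seed(seeds[["variants"]], {
    planted <- if (nrow(pv) > 0 && n > 0) {
      matrix(vapply(pv$frequency, function(f) rbinom(n, 2L, f), integer(n)),
             nrow = n, ncol = nrow(pv))
    } else matrix(integer(0), nrow = n, ncol = nrow(pv))
    prs <- if (nrow(ps) > 0 && n > 0) {
      matrix(vapply(ps$frequency, function(f) rbinom(n, 2L, f), integer(n)),
             nrow = n, ncol = nrow(ps))
    } else matrix(integer(0), nrow = n, ncol = nrow(ps))
    list(planted = planted, prs = prs)
  })

  # baseline LDL-C -----------------------------------------------------
  ldl_base <- with_seed(seeds[["ldl"]], {
    mu <- params$ldl_mean + 0.003 * (demo$age - 40) +
      ifelse(demo$sex == "male", 0.02, 0)
    rlnorm(n, meanlog = mu, sdlog = params$ldl_sd)
  })

  # PRS effect alleles: columns of geno$prs count ALT dosage; the effect
  # allele is the ALT allele of the simulated site by construction.
  prs_contrib <- if (nrow(ps) > 0 && n > 0) {
    as.vector(geno$prs %*% ps$beta)
  } else rep(0, n)

  # penetrance of planted variants -------------------------------------
  pen <- with_seed(seeds[["penetrance"]], {
    m <- matrix(FALSE, nrow = n, ncol = nrow(pv))
    if (nrow(pv) > 0 && n > 0) {
      for (j in seq_len(nrow(pv))) {
        carrier <- if (pv$mode[j] == "dominant") geno$planted[, j] >= 1L
                   else geno$planted[, j] == 2L
        m[carrier, j] <- runif(sum(carrier)) < pv$penetrance[j]
      }
    }
    m
  })
  variant_effect <- if (nrow(pv) > 0 && n > 0) {
    as.vector(pen %*% pv$ldl_effect)
  } else rep(0, n)

  ldl_true <- ldl_base + prs_contrib + variant_effect

  # treatment masking --------------------------------------------------
  treated <- with_seed(seeds[["treatment"]], {
    k <- round(n * params$treatment_fraction)
    out <- rep(FALSE, n)
    if (k > 0) {
      w <- exp(0.8 * pmin(ldl_true, 12))
      out[sample.int(n, k, prob = w)] <- TRUE
    }
    out
  })
  ldl_observed <- ifelse(treated,
                         ldl_true * (1 - params$true_treatment_reduction),
                         ldl_true)

  # questionnaire / comorbidity fields ---------------------------------
  fields <- with_seed(seeds[["comorbidity"]], {
    lc <- ldl_true - 3.2  # centred LDL
    ac <- demo$age - 40   # centred age
    list(
      first_degree_cvd = runif(n) < 0.14,
      premature_cad = runif(n) < plogis(-6.3 + 0.5 * ldl_true),
      premature_cerebro_peripheral = runif(n) < plogis(-8.2 + 0.3 * ldl_true),
      parental_mi = runif(n) < plogis(qlogis(0.13) + 0.25 * lc),
      obesity = runif(n) < plogis(qlogis(0.10) + 0.15 * lc + 0.01 * ac),
      metabolic_syndrome = runif(n) < plogis(qlogis(0.15) + 0.45 * lc +
                                               0.02 * ac),
      diabetes = runif(n) < plogis(qlogis(0.16) + 0.35 * lc + 0.03 * ac),
      hypertension = runif(n) < plogis(qlogis(0.15) + 0.30 * lc + 0.03 * ac),
      smoker = runif(n) < 0.15
    )
  })
  selfrep <- with_seed(seeds[["selfreport"]], {
    p <- params$selfreport_noise
    list(
      self_reported_hc = flip_noise((ldl_true >= 4.9) | treated, p),
      first_degree_cvd = flip_noise(fields$first_degree_cvd, p),
      premature_cad = flip_noise(fields$premature_cad, p),
      premature_cerebro_peripheral =
        flip_noise(fields$premature_cerebro_peripheral, p),
      parental_mi = flip_noise(fields$parental_mi, p)
    )
  })

  phenotypes <- data.frame(
    id = ids,
    age = demo$age,
    sex = demo$sex,
    ldl_observed = ldl_observed,
    on_med = treated,
    med_class = ifelse(treated, "unspecified", NA_character_),
    first_degree_cvd = selfrep$first_degree_cvd,
    premature_cad = selfrep$premature_cad,
    premature_cerebro_peripheral = selfrep$premature_cerebro_peripheral,
    self_reported_hc = selfrep$self_reported_hc,
    obesity = fields$obesity,
    metabolic_syndrome = fields$metabolic_syndrome,
    diabetes = fields$diabetes,
    hypertension = fields$hypertension,
    smoker = fields$smoker,
    parental_mi = selfrep$parental_mi,
    stringsAsFactors = FALSE
  )

  # genotype container (planted + PRS variants) ------------------------
  variants <- rbind(
    if (nrow(pv) > 0) data.frame(chrom = pv$chrom, pos = pv$pos,
                                 id = pv$rsid, ref = pv$ref, alt = pv$alt,
                                 role = "planted",
                                 stringsAsFactors = FALSE),
    if (nrow(ps) > 0) data.frame(chrom = ps$chrom, pos = ps$pos,
                                 id = ps$rsid, ref = ps$other_allele,
                                 alt = ps$effect_allele, role = "prs",
                                 stringsAsFactors = FALSE)
  )
  dosage <- cbind(geno$planted, geno$prs)
  if (is.null(variants)) {
    variants <- data.frame(chrom = character(0), pos = integer(0),
                           id = character(0), ref = character(0),
                           alt = character(0), role = character(0),
                           stringsAsFactors = FALSE)
    dosage <- matrix(integer(0), nrow = n, ncol = 0)
  }
  rownames(dosage) <- ids
  dosage <- with_seed(seeds[["missing"]], {
    if (params$geno_missing_rate > 0 && length(dosage) > 0) {
      dosage[runif(length(dosage)) < params$geno_missing_rate] <- NA_integer_
    }
    dosage
  })
  genotypes <- fh_genotypes(variants, dosage)

  annotations <- if (nrow(pv) > 0) {
    data.frame(gene = pv$gene, chrom = pv$chrom, pos = pv$pos, ref = pv$ref,
               alt = pv$alt, rsid = pv$rsid, cdna = pv$cdna,
               protein = pv$protein, source = pv$source,
               classification = pv$classification, mode = pv$mode,
               phenotype = pv$phenotype, max_af = NA_real_,
               stringsAsFactors = FALSE)
  } else {
    data.frame(gene = character(0), chrom = character(0), pos = integer(0),
               ref = character(0), alt = character(0), rsid = character(0),
               cdna = character(0), protein = character(0),
               source = character(0), classification = character(0),
               mode = character(0), phenotype = character(0),
               max_af = numeric(0), stringsAsFactors = FALSE)
  }

  genes <- fh_gene_intervals()
  sv_calls <- with_seed(seeds[["sv"]], simulate_sv_calls(params, ids, genes))

  truth_variants <- if (nrow(pv) > 0 && n > 0) {
    do.call(rbind, lapply(seq_len(nrow(pv)), function(j) {
      data.frame(id = ids,
                 key = variant_key(pv$chrom[j], pv$pos[j], pv$ref[j],
                                   pv$alt[j]),
                 gene = pv$gene[j], mode = pv$mode[j],
                 dosage = geno$planted[, j],
                 carrier = if (pv$mode[j] == "dominant")
                   geno$planted[, j] >= 1L else geno$planted[, j] == 2L,
                 penetrant = pen[, j],
                 stringsAsFactors = FALSE)
    }))
  } else {
    data.frame(id = character(0), key = character(0), gene = character(0),
               mode = character(0), dosage = integer(0), carrier = logical(0),
               penetrant = logical(0), stringsAsFactors = FALSE)
  }

  structure(list(
    phenotypes = phenotypes,
    genotypes = genotypes,
    annotations = annotations,
    prs_weights = ps[, c("rsid", "chrom", "pos", "effect_allele",
                         "other_allele", "beta")],
    sv_calls = sv_calls,
    genes = genes,
    truth = list(
      ldl = data.frame(id = ids, ldl_true = ldl_true, treated = treated,
                       ldl_observed = ldl_observed,
                       stringsAsFactors = FALSE),
      variants = truth_variants
    ),
    params = params
  ), class = "fh_cohort")
}

# Two jittered call sets around shared true SV events, plus caller-specific
# false positives and deliberately out-of-size-range calls that exercise
# the downstream size filter. One whole-gene PCSK9 duplication is always
# planted when the cohort is non-empty.
simulate_sv_calls <- function(params, ids, genes) {
  empty <- data.frame(sample = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      type = character(0), caller = character(0),
                      stringsAsFactors = FALSE)
  if (length(ids) == 0L) return(list(a = empty, b = empty))
  chroms <- c("chr1", "chr2", "chr5", "chr10", "chr19")
  k <- params$n_sv_events
  events <- data.frame(
    sample = sample(ids, k, replace = TRUE),
    chrom = sample(chroms, k, replace = TRUE),
    start = as.integer(round(runif(k, 1e6, 2e8))),
    len = as.integer(round(exp(runif(k, log(1e3), log(5e5))))),
    type = sample(c("DEL", "DUP", "INV"), k, replace = TRUE),
    stringsAsFactors = FALSE
  )
  # whole-gene PCSK9 duplication in one participant
  pcsk9 <- genes[genes$gene == "PCSK9", ]
  events <- rbind(events, data.frame(
    sample = sample(ids, 1), chrom = pcsk9$chrom,
    start = 54828792L, len = 55862308L - 54828792L + 1L, type = "DUP",
    stringsAsFactors = FALSE))
  observe <- function(caller, forced_last = TRUE) {
    seen <- runif(nrow(events)) < params$sv_detect_prob
    if (forced_last) seen[nrow(events)] <- TRUE
    e <- events[seen, , drop = FALSE]
    jit_s <- as.integer(round(runif(nrow(e), -20, 20)))
    jit_e <- as.integer(round(runif(nrow(e), -20, 20)))
    start <- pmax(1L, e$start + jit_s)
    end <- pmax(start, e$start + e$len - 1L + jit_e)
    fp_n <- 8L
    fp <- data.frame(
      sample = sample(ids, fp_n, replace = TRUE),
      chrom = sample(chroms, fp_n, replace = TRUE),
      start = as.integer(round(runif(fp_n, 1e6, 2e8))),
      len = as.integer(round(exp(runif(fp_n, log(100), log(1e5))))),
      type = sample(c("DEL", "DUP"), fp_n, replace = TRUE),
      stringsAsFactors = FALSE)
    extreme <- data.frame(
      sample = sample(ids, 2, replace = TRUE),
      chrom = c("chr5", "chr5"),
      start = as.integer(round(runif(2, 1e6, 5e7))),
      len = c(40L, 12000000L),  # below and above the size cut-offs
      type = c("DEL", "DUP"),
      stringsAsFactors = FALSE)
    out <- rbind(
      data.frame(sample = e$sample, chrom = e$chrom, start = start,
                 end = end, type = e$type, stringsAsFactors = FALSE),
      data.frame(sample = fp$sample, chrom = fp$chrom, start = fp$start,
                 end = fp$start + fp$len - 1L, type = fp$type,
                 stringsAsFactors = FALSE),
      data.frame(sample = extreme$sample, chrom = extreme$chrom,
                 start = extreme$start, end = extreme$start + extreme$len - 1L,
                 type = extreme$type, stringsAsFactors = FALSE))
    out$caller <- caller
    out[order(out$sample, out$chrom, out$start), ]
  }
  list(a = observe("caller_a"), b = observe("caller_b"))
}

#' Write a simulated cohort bundle to disk
#'
#' Serializes every component as documented plain-text formats: phenotype
#' table and truth tables (tab-delimited), genotypes (VCF v4.2, GT-only),
#' pathogenicity annotations, PRS weights and two SV call sets
#' (tab-delimited), and gene intervals (BED). Re-reading the files with the
#' package readers reproduces the in-memory values.
#'
#' @param bundle an `fh_cohort` from [simulate_cohort()].
#' @param out_dir output directory (created if absent).
#' @return named character vector of written paths (the file manifest).
#' @export
write_cohort <- function(bundle, out_dir) {
  if (!inherits(bundle, "fh_cohort")) {
    stop_domain("`bundle` must come from simulate_cohort()")
  }
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", out_dir)
  }
  p <- function(f) file.path(out_dir, f)
  manifest <- c(
    phenotypes = p("phenotypes.tsv"),
    genotypes = p("genotypes.vcf"),
    annotations = p("annotations.tsv"),
    prs_weights = p("prs_weights.tsv"),
    sv_caller_a = p("sv_calls_caller_a.tsv"),
    sv_caller_b = p("sv_calls_caller_b.tsv"),
    genes = p("genes.bed"),
    truth_ldl = p("truth_ldl.tsv"),
    truth_variants = p("truth_variants.tsv")
  )
  write_tsv(bundle$phenotypes, manifest[["phenotypes"]])
  write_vcf(bundle$genotypes, manifest[["genotypes"]])
  write_tsv(bundle$annotations, manifest[["annotations"]])
  write_tsv(bundle$prs_weights, manifest[["prs_weights"]])
  write_tsv(bundle$sv_calls$a, manifest[["sv_caller_a"]])
  write_tsv(bundle$sv_calls$b, manifest[["sv_caller_b"]])
  write_gene_bed(bundle$genes, manifest[["genes"]])
  write_tsv(bundle$truth$ldl, manifest[["truth_ldl"]])
  write_tsv(bundle$truth$variants, manifest[["truth_variants"]])
  manifest
}
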