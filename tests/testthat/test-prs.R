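test_that("effect-allele dosage handles effect = REF and effect = ALT", {
  expect_equal(allele_dosage(1L, "G", ref = "A", alt = "G"), 1L)
  expect_equal(allele_dosage(2L, "A", ref = "A", alt = "G"), 0L)
  expect_equal(allele_dosage(0L, "A", ref = "A", alt = "G"), 2L)
  expect_error(allele_dosage(1L, "T", ref = "A", alt = "G"),
               "matches neither REF")
})

test_that("weight tables are validated, ambiguous SNPs rejected", {
  w <- default_prs_snps()[, c("rsid", "chrom", "pos", "effect_allele",
                              "other_allele", "beta")]
  expect_silent(validate_prs_weights(w))
  w2 <- w; w2$rsid[2] <- w2$rsid[1]
  expect_error(validate_prs_weights(w2), "duplicated")
  w3 <- w; w3$effect_allele[1] <- "A"; w3$other_allele[1] <- "T"
  expect_error(validate_prs_weights(w3), "ambiguous")
  w4 <- w; w4$other_allele[1] <- w4$effect_allele[1]
  expect_error(validate_prs_weights(w4), "differ")
})

make_prs_fixture <- function(dosages, betas, effect_is_alt = TRUE) {
  k <- length(betas)
  n <- nrow(dosages)
  ids <- sprintf("s%02d", seq_len(n))
  rownames(dosages) <- ids
  variants <- data.frame(chrom = "chr1", pos = 1000L + seq_len(k),
                         id = sprintf("rs%d", seq_len(k)),
                         ref = "A", alt = "G", stringsAsFactors = FALSE)
  geno <- fh_genotypes(variants, dosages)
  weights <- data.frame(rsid = variants$id, chrom = variants$chrom,
                        pos = variants$pos,
                        effect_allele = if (effect_is_alt) "G" else "A",
                        other_allele = if (effect_is_alt) "A" else "G",
                        beta = betas, stringsAsFactors = FALSE)
  list(geno = geno, weights = weights)
}

test_that("scores are the weighted sum of effect-allele dosages", {
  fx <- make_prs_fixture(matrix(c(0L, 2L, 1L,
                                  0L, 2L, 0L), nrow = 2, byrow = TRUE),
                         betas = c(0.1, 0.1, 0.3))
  s <- compute_prs(fx$geno, fx$weights)
  expect_equal(s$score, c(0 * 0.1 + 2 * 0.1 + 1 * 0.3,
                          0 * 0.1 + 2 * 0.1 + 0 * 0.3))
  # all dosages zero -> score zero
  fx0 <- make_prs_fixture(matrix(0L, nrow = 2, ncol = 3),
                          betas = c(0.1, 0.1, 0.3))
  expect_equal(compute_prs(fx0$geno, fx0$weights)$score, c(0, 0))
  # single SNP, dosage 2, beta 0.1 -> 0.2
  fx1 <- make_prs_fixture(matrix(2L, nrow = 1, ncol = 1), betas = 0.1)
  expect_equal(compute_prs(fx1$geno, fx1$weights)$score, 0.2)
})

test_that("scores are linear in betas and invariant to SNP order", {
  set.seed(71)
  dos <- matrix(sample(0:2, 60, replace = TRUE), nrow = 10)
  betas <- runif(6, 0.01, 0.3)
  fx <- make_prs_fixture(dos, betas)
  s1 <- compute_prs(fx$geno, fx$weights)$score
  wdouble <- fx$weights; wdouble$beta <- 2 * wdouble$beta
  expect_equal(compute_prs(fx$geno, wdouble)$score, 2 * s1)
  perm <- sample(nrow(fx$weights))
  expect_equal(compute_prs(fx$geno, fx$weights[perm, ])$score, s1)
})

test_that("SNPs missing from the genotype set are skipped with a notice", {
  fx <- make_prs_fixture(matrix(1L, nrow = 2, ncol = 2), betas = c(0.1, 0.2))
  extra <- rbind(fx$weights,
                 data.frame(rsid = "rs1800562", chrom = "chr6",
                            pos = 26092913L, effect_allele = "G",
                            other_allele = "A", beta = 0.5))
  expect_message(s <- compute_prs(fx$geno, extra), "rs1800562")
  expect_equal(s$score, compute_prs(fx$geno, fx$weights)$score)
})

test_that("per-sample missing genotypes impute to 2xAF and are flagged", {
  dos <- matrix(c(2L, 2L, 0L, NA_integer_), nrow = 4, ncol = 1)
  fx <- make_prs_fixture(dos, betas = 1)
  s <- compute_prs(fx$geno, fx$weights)
  # cohort effect AF among observed = (2+2+0)/6 = 2/3; imputed dosage 4/3
  expect_equal(s$score[4], 4 / 3)
  expect_true(s$imputed[4])
  expect_equal(s$n_missing_snps, c(0L, 0L, 0L, 1L))
  strict <- compute_prs(fx$geno, fx$weights, missing = "strict")
  expect_equal(strict$score[4], 0)
  expect_false(strict$imputed[4])
})

test_that("cohort mean score matches the HWE expectation", {
  b <- simulate_cohort(fh_sim_params(n_participants = 2000, seed = 73))
  s <- compute_prs(b$genotypes, b$prs_weights)
  snps <- default_prs_snps()
  expected <- sum(2 * snps$frequency * snps$beta)
  se <- sd(s$score) / sqrt(nrow(s))
  expect_lt(abs(mean(s$score) - expected), 3 * se)
})

test_that("bottom-quartile threshold interpolates order statistics", {
  expect_equal(bottom_quartile_threshold(c(0.4, 0.6, 0.8, 1.0)), 0.55)
  expect_equal(bottom_quartile_threshold(rep(0.7, 10)), 0.7)
  expect_equal(bottom_quartile_threshold(c(0, 0, 0, 100)), 0)
  expect_error(bottom_quartile_threshold(c(1, 2, 3)), "at least four")
})

test_that("at most a quarter of scores sit at or below the threshold", {
  set.seed(79)
  for (i in 1:20) {
    x <- rnorm(sample(50:500, 1), mean = 0.76, sd = 0.19)
    thr <- bottom_quartile_threshold(x)
    # within interpolation granularity of one order statistic
    expect_lte(mean(x < thr), 0.25 + 1 / length(x))
    expect_gte(mean(x <= thr), 0.25 - 1 / length(x))
  }
})

test_that("polygenic assessment reports fraction, groups and ANOVA", {
  set.seed(83)
  n <- c(49, 334, 5757)
  ids <- sprintf("p%04d", seq_len(sum(n)))
  classes <- rep(c("probable", "possible", "unlikely"), n)
  scores <- data.frame(
    id = ids,
    score = c(rnorm(n[1], 0.87, 0.16), rnorm(n[2], 0.82, 0.16),
              rnorm(n[3], 0.76, 0.19)),
    stringsAsFactors = FALSE)
  dlcn <- make_dlcn(ids, classes)
  mp <- setNames(rep(FALSE, length(ids)), ids)
  pa <- polygenic_assessment(scores, dlcn, mp)
  gs <- pa$group_summaries
  expect_equal(gs$n, n)
  # planted group-mean ordering recovered
  expect_gt(gs$mean[gs$group == "definite_or_probable"],
            gs$mean[gs$group == "possible"])
  expect_gt(gs$mean[gs$group == "possible"],
            gs$mean[gs$group == "unlikely"])
  expect_lt(pa$anova$p_value, 0.01)
  expect_true(pa$fraction_above >= 0 && pa$fraction_above <= 1)
  expect_equal(pa$n_mut_negative_case, 49L)

  # mutation-positive cases are excluded from the polygenic fraction
  mp[ids[1:49]] <- TRUE
  pa2 <- polygenic_assessment(scores, dlcn, mp)
  expect_equal(pa2$n_mut_negative_case, 0L)
  expect_true(is.na(pa2$fraction_above))
})

test_that("all mutation-negative cases above threshold give fraction 1", {
  ids <- sprintf("p%02d", 1:24)
  classes <- c(rep("probable", 4), rep("unlikely", 20))
  scores <- data.frame(id = ids,
                       score = c(rep(5, 4), seq(0.1, 2, length.out = 20)),
                       stringsAsFactors = FALSE)
  mp <- setNames(rep(FALSE, 24), ids)
  pa <- polygenic_assessment(scores, make_dlcn(ids, classes), mp)
  expect_equal(pa$fraction_above, 1.0)
})

test_that("group mean shifts at study scale are detected reliably", {
  # 200 seeded replicates at the study's group sizes; ANOVA should reject
  # at alpha = 0.01 in at least 95% of them
  n <- c(49, 334, 5757)
  rejections <- vapply(1:200, function(r) {
    set.seed(8000 + r)
    groups <- list(rnorm(n[1], 0.87, 0.16), rnorm(n[2], 0.82, 0.16),
                   rnorm(n[3], 0.76, 0.19))
    one_way_anova(groups)$p_value < 0.01
  }, TRUE)
  expect_gte(mean(rejections), 0.95)
})
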