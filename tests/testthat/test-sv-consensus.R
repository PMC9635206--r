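test_that("reciprocal overlap handles identity, disjoint and partial cases", {
  a <- list(chrom = "chr1", start = 101, end = 200, type = "DEL")
  expect_equal(reciprocal_overlap(a, a), 1.0)
  b <- list(chrom = "chr1", start = 151, end = 250, type = "DEL")
  expect_equal(reciprocal_overlap(a, b), 0.5)
  expect_equal(reciprocal_overlap(a, list(chrom = "chr1", start = 300,
                                          end = 400, type = "DEL")), 0)
  # contract: different chromosome or type scores zero
  expect_equal(reciprocal_overlap(a, list(chrom = "chr2", start = 101,
                                          end = 200, type = "DEL")), 0)
  expect_equal(reciprocal_overlap(a, list(chrom = "chr1", start = 101,
                                          end = 200, type = "DUP")), 0)
})

test_that("reciprocal overlap is symmetric", {
  set.seed(53)
  for (i in 1:40) {
    a <- list(chrom = "chr1", start = sample(1000, 1),
              end = sample(1000:3000, 1), type = "DEL")
    b <- list(chrom = "chr1", start = sample(1000, 1),
              end = sample(1000:3000, 1), type = "DEL")
    expect_equal(reciprocal_overlap(a, b), reciprocal_overlap(b, a))
    ro <- reciprocal_overlap(a, b)
    expect_true(ro >= 0 && ro <= 1)
  }
})

test_that("size filter keeps calls within [50 bp, 10 Mb] inclusive", {
  calls <- rbind(
    sv_call(start = 1000, end = 1039),                    # 40 bp: out
    sv_call(start = 1000, end = 1049),                    # 50 bp: in
    sv_call(start = 54828792, end = 55862308, type = "DUP"),  # 1.03 Mb: in
    sv_call(start = 1e6, end = 1e6 + 1e7 - 1, type = "DUP"),  # 10 Mb: in
    sv_call(start = 1e6, end = 1e6 + 11e6, type = "DUP"))     # 11 Mb: out
  kept <- sv_size_filter(calls)
  expect_equal(nrow(kept), 3L)
  expect_equal(kept$end - kept$start + 1,
               c(50, 1033517, 1e7))
})

test_that("caller merging requires strictly more than the threshold", {
  a <- sv_call(start = 1000, end = 1999)
  # identical call in both callers -> one consensus record
  cons <- merge_callers(a, sv_call(start = 1000, end = 1999,
                                   caller = "caller_b"))
  expect_equal(nrow(cons), 1L)
  expect_equal(cons$start, 1000L)
  expect_equal(cons$end, 1999L)
  expect_equal(cons$overlap, 1.0)

  # overlap exactly 0.8 is NOT merged: [1,1000] vs [201,1200]
  b <- sv_call(start = 201, end = 1200, caller = "caller_b")
  expect_equal(nrow(merge_callers(sv_call(start = 1, end = 1000), b)), 0L)
  # nudging one breakpoint above 0.8 merges
  b2 <- sv_call(start = 200, end = 1199, caller = "caller_b")
  expect_equal(nrow(merge_callers(sv_call(start = 1, end = 1000), b2)), 1L)

  # one caller empty -> empty consensus
  expect_equal(nrow(merge_callers(a, a[0, ])), 0L)
  expect_equal(nrow(merge_callers(a[0, ], a)), 0L)

  # type and sample must match
  expect_equal(nrow(merge_callers(a, sv_call(start = 1000, end = 1999,
                                             type = "DUP"))), 0L)
  expect_equal(nrow(merge_callers(a, sv_call(sample = "s2", start = 1000,
                                             end = 1999))), 0L)
})

test_that("consensus breakpoints average the two callers, rounded half up", {
  a <- sv_call(start = 1000, end = 2000)
  b <- sv_call(start = 1001, end = 2002, caller = "caller_b")
  cons <- merge_callers(a, b)
  expect_equal(cons$start, 1001L)  # (1000+1001)/2 = 1000.5 -> 1001
  expect_equal(cons$end, 2001L)    # (2000+2002)/2 = 2001
})

test_that("merge output size never exceeds the smaller call set", {
  set.seed(59)
  for (i in 1:20) {
    na <- sample(1:6, 1); nb <- sample(1:6, 1)
    A <- do.call(rbind, lapply(seq_len(na), function(j) {
      s <- sample(1e5, 1)
      sv_call(start = s, end = s + sample(500:5000, 1))
    }))
    B <- do.call(rbind, lapply(seq_len(nb), function(j) {
      s <- sample(1e5, 1)
      sv_call(start = s, end = s + sample(500:5000, 1), caller = "caller_b")
    }))
    expect_lte(nrow(merge_callers(A, B)), min(na, nb))
  }
})

test_that("merging a consensus set with itself reproduces the intervals", {
  set.seed(61)
  A <- do.call(rbind, lapply(1:8, function(j) {
    s <- j * 10000 + sample(0:50, 1)
    sv_call(start = s, end = s + sample(500:5000, 1))
  }))
  B <- A
  B$caller <- "caller_b"
  B$start <- B$start + sample(-20:20, nrow(B), replace = TRUE)
  B$end <- B$end + sample(-20:20, nrow(B), replace = TRUE)
  cons <- merge_callers(A, B)
  for (thr in c(0.5, 0.8, 0.95)) {
    again <- merge_callers(cons, cons, threshold = thr)
    expect_equal(again[, c("sample", "chrom", "start", "end", "type")],
                 cons[, c("sample", "chrom", "start", "end", "type")],
                 ignore_attr = TRUE)
  }
})

# Brute-force oracle: enumerate all matchings between the two call sets and
# maximize (number of pairs, then total overlap). Independent of the greedy
# implementation.
brute_force_match <- function(A, B, threshold = 0.8) {
  ro <- outer(seq_len(nrow(A)), seq_len(nrow(B)), Vectorize(function(i, j) {
    reciprocal_overlap(A[i, ], B[j, ])
  }))
  best <- list(count = 0L, total = 0)
  recurse <- function(i, used_b, count, total) {
    if (i > nrow(A)) {
      if (count > best$count ||
          (count == best$count && total > best$total + 1e-12)) {
        best <<- list(count = count, total = total)
      }
      return(invisible())
    }
    recurse(i + 1L, used_b, count, total)  # leave call i unmatched
    for (j in seq_len(nrow(B))) {
      if (!used_b[j] && ro[i, j] > threshold) {
        used_b[j] <- TRUE
        recurse(i + 1L, used_b, count + 1L, total + ro[i, j])
        used_b[j] <- FALSE
      }
    }
  }
  recurse(1L, logical(nrow(B)), 0L, 0)
  best
}

test_that("greedy matching equals brute-force optimum on small instances", {
  set.seed(67)
  for (rep in 1:25) {
    # well-separated true events observed by both callers with jitter
    n_ev <- sample(2:4, 1)
    ev_start <- cumsum(sample(20000:40000, n_ev))
    ev_len <- sample(500:5000, n_ev, replace = TRUE)
    obs <- function(caller) {
      seen <- runif(n_ev) < 0.85
      if (!any(seen)) seen[1] <- TRUE
      do.call(rbind, lapply(which(seen), function(e) {
        sv_call(start = ev_start[e] + sample(-30:30, 1),
                end = ev_start[e] + ev_len[e] + sample(-30:30, 1),
                caller = caller)
      }))
    }
    A <- obs("caller_a"); B <- obs("caller_b")
    cons <- merge_callers(A, B)
    oracle <- brute_force_match(A, B)
    expect_equal(nrow(cons), oracle$count)
    expect_equal(sum(cons$overlap), oracle$total, tolerance = 1e-10)
  }
})

test_that("gene disruption is any-overlap on inclusive intervals", {
  genes <- fh_gene_intervals()
  pcsk9 <- genes[genes$gene == "PCSK9", ]
  cons <- data.frame(sample = "s1", chrom = "chr1",
                     start = 54828792L, end = 55862308L, type = "DUP",
                     stringsAsFactors = FALSE)
  hits <- gene_disruption(cons, genes)
  expect_true("PCSK9" %in% hits$gene)
  expect_true(hits$whole_gene[hits$gene == "PCSK9"])

  # different chromosome: no hit
  off <- cons; off$chrom <- "chr9"
  expect_equal(nrow(gene_disruption(off, genes)), 0L)

  # abutting but not overlapping: no hit; one-base overlap: hit
  abut <- data.frame(sample = "s1", chrom = pcsk9$chrom,
                     start = pcsk9$end + 1L, end = pcsk9$end + 1000L,
                     type = "DEL", stringsAsFactors = FALSE)
  expect_equal(nrow(gene_disruption(abut, genes)), 0L)
  touch <- abut; touch$start <- pcsk9$end
  expect_equal(nrow(gene_disruption(touch, genes)), 1L)
})

test_that("multi-sample consensus clusters recurrent calls", {
  per_sample <- do.call(rbind, lapply(1:3, function(i) {
    data.frame(sample = paste0("s", i), chrom = "chr2",
               start = 5000L + i, end = 15000L + i, type = "DEL",
               stringsAsFactors = FALSE)
  }))
  lone <- data.frame(sample = "s4", chrom = "chr2", start = 9e6L,
                     end = 9.01e6L, type = "DEL", stringsAsFactors = FALSE)
  multi <- multi_sample_consensus(rbind(per_sample, lone))
  expect_equal(nrow(multi), 2L)
  rec <- multi[multi$n_samples == 3, ]
  expect_equal(rec$start, 5002L)   # median of 5001..5003
  expect_equal(rec$samples, "s1,s2,s3")
})
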