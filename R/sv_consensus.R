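# Dual-caller structural-variant consensus by reciprocal overlap.
#
# All internal arithmetic is on 1-based inclusive coordinates (VCF
# convention); BED input is converted on read. Two calls merge when they
# share sample, chromosome and SV type and their reciprocal overlap is
# strictly greater than the threshold (default 0.8).

#' Reciprocal overlap of two SV calls
#'
#' min(overlap/length(a), overlap/length(b)) on inclusive coordinates;
#' 0 when the calls are disjoint, on different chromosomes, or of
#' different SV types.
#'
#' @param a,b SV calls: lists or one-row data.frames with `chrom`, `start`,
#'   `end`, `type`.
#' @return fraction in \[0, 1\].
#' @examples
#' a <- list(chrom = "chr1", start = 101, end = 200, type = "DEL")
#' b <- list(chrom = "chr1", start = 151, end = 250, type = "DEL")
#' reciprocal_overlap(a, b)  # 0.5
#' @export
reciprocal_overlap <- function(a, b) {
  if (!identical(as.character(a$chrom), as.character(b$chrom)) ||
      !identical(as.character(a$type), as.character(b$type))) {
    return(0)
  }
  ovl <- min(a$end, b$end) - max(a$start, b$start) + 1
  if (ovl <= 0) return(0)
  min(ovl / (a$end - a$start + 1), ovl / (b$end - b$start + 1))
}

# vectorized overlap of one call against many rows (same chrom/type assumed)
.ro_vec <- function(start, end, starts, ends) {
  ovl <- pmin(end, ends) - pmax(start, starts) + 1
  len_a <- end - start + 1
  len_b <- ends - starts + 1
  out <- pmin(ovl / len_a, ovl / len_b)
  out[ovl <= 0] <- 0
  out
}

#' Filter SV calls by size
#'
#' Keeps calls whose inclusive length lies within `[min_size, max_size]`
#' (defaults 50 bp and 10 Mb); input order is preserved.
#'
#' @param calls SV call data.frame with `start`, `end`.
#' @param min_size,max_size inclusive length bounds in bases.
#' @return filtered data.frame.
#' @export
sv_size_filter <- function(calls, min_size = 50, max_size = 1e7) {
  len <- calls$end - calls$start + 1
  calls[len >= min_size & len <= max_size, , drop = FALSE]
}

#' Merge two callers' SV calls into per-individual consensus calls
#'
#' For every sample/chromosome/type group, pairs of calls (one from each
#' caller) with reciprocal overlap strictly greater than `threshold` are
#' matched greedily: candidate pairs are ranked by larger overlap, then
#' smaller start, and each call is used at most once. The representative
#' consensus interval averages the two start positions and the two end
#' positions (rounded half up).
#'
#' @param calls_a,calls_b SV call data.frames (columns
#'   `sample, chrom, start, end, type`), one per caller.
#' @param threshold reciprocal-overlap threshold; merging requires strict
#'   `> threshold`.
#' @return data.frame of consensus calls with `sample`, `chrom`, `start`,
#'   `end`, `type`, `callers`, `overlap`, and the contributing intervals
#'   (`start_a`, `end_a`, `start_b`, `end_b`).
#' @export
merge_callers <- function(calls_a, calls_b, threshold = 0.8) {
  empty <- data.frame(sample = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      type = character(0), callers = character(0),
                      overlap = numeric(0), start_a = integer(0),
                      end_a = integer(0), start_b = integer(0),
                      end_b = integer(0), stringsAsFactors = FALSE)
  if (nrow(calls_a) == 0L || nrow(calls_b) == 0L) return(empty)
  ga <- interaction(calls_a$sample, calls_a$chrom, calls_a$type, drop = TRUE)
  out <- list()
  for (g in intersect(levels(ga),
                      levels(interaction(calls_b$sample, calls_b$chrom,
                                         calls_b$type, drop = TRUE)))) {
    A <- calls_a[ga == g, , drop = FALSE]
    B <- calls_b[interaction(calls_b$sample, calls_b$chrom, calls_b$type,
                             drop = TRUE) == g, , drop = FALSE]
    # candidate pairs above threshold
    pairs <- expand.grid(ia = seq_len(nrow(A)), ib = seq_len(nrow(B)))
    pairs$ro <- .ro_vec(A$start[pairs$ia], A$end[pairs$ia],
                        B$start[pairs$ib], B$end[pairs$ib])
    pairs <- pairs[pairs$ro > threshold, , drop = FALSE]
    if (nrow(pairs) == 0L) next
    pairs <- pairs[order(-pairs$ro, pmin(A$start[pairs$ia],
                                         B$start[pairs$ib])), , drop = FALSE]
    used_a <- logical(nrow(A)); used_b <- logical(nrow(B))
    for (r in seq_len(nrow(pairs))) {
      ia <- pairs$ia[r]; ib <- pairs$ib[r]
      if (used_a[ia] || used_b[ib]) next
      used_a[ia] <- TRUE; used_b[ib] <- TRUE
      out[[length(out) + 1L]] <- data.frame(
        sample = A$sample[ia], chrom = A$chrom[ia],
        start = as.integer(floor((A$start[ia] + B$start[ib]) / 2 + 0.5)),
        end = as.integer(floor((A$end[ia] + B$end[ib]) / 2 + 0.5)),
        type = A$type[ia],
        callers = paste(sort(unique(c(
          if ("caller" %in% names(A)) A$caller[ia] else "caller_a",
          if ("caller" %in% names(B)) B$caller[ib] else "caller_b"))),
          collapse = ","),
        overlap = pairs$ro[r],
        start_a = A$start[ia], end_a = A$end[ia],
        start_b = B$start[ib], end_b = B$end[ib],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  res[order(res$sample, res$chrom, res$start), , drop = FALSE]
}

#' Cluster per-individual consensus calls across samples
#'
#' Builds a multi-sample consensus set: per chromosome and type,
#' single-linkage clusters under the same strict reciprocal-overlap rule,
#' with the cluster representative taken as the median start and end.
#'
#' @param consensus output of [merge_callers()] (possibly concatenated over
#'   samples).
#' @param threshold reciprocal-overlap threshold (strict `>`).
#' @return data.frame with `chrom`, `start`, `end`, `type`, `n_samples`,
#'   `samples` (comma-separated member list).
#' @export
multi_sample_consensus <- function(consensus, threshold = 0.8) {
  if (nrow(consensus) == 0L) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), type = character(0),
                      n_samples = integer(0), samples = character(0),
                      stringsAsFactors = FALSE))
  }
  out <- list()
  grp <- interaction(consensus$chrom, consensus$type, drop = TRUE)
  for (g in levels(grp)) {
    X <- consensus[grp == g, , drop = FALSE]
    n <- nrow(X)
    cluster <- seq_len(n)
    if (n > 1) {
      for (i in seq_len(n - 1)) {
        ro <- .ro_vec(X$start[i], X$end[i],
                      X$start[(i + 1):n], X$end[(i + 1):n])
        for (j in which(ro > threshold)) {
          jj <- i + j
          old <- cluster[jj]; new <- cluster[i]
          cluster[cluster == old] <- new
        }
      }
    }
    for (cl in unique(cluster)) {
      m <- X[cluster == cl, , drop = FALSE]
      out[[length(out) + 1L]] <- data.frame(
        chrom = m$chrom[1],
        start = as.integer(floor(median(m$start) + 0.5)),
        end = as.integer(floor(median(m$end) + 0.5)),
        type = m$type[1],
        n_samples = length(unique(m$sample)),
        samples = paste(sort(unique(m$sample)), collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  res[order(res$chrom, res$start), , drop = FALSE]
}

#' Gene-disruption table for consensus SVs
#'
#' An SV disrupts a gene iff their intervals (both 1-based inclusive)
#' intersect by at least one base, regardless of SV type.
#'
#' @param consensus consensus SV data.frame (`sample`, `chrom`, `start`,
#'   `end`, `type`).
#' @param genes gene interval data.frame (`gene`, `chrom`, `start`, `end`),
#'   e.g. from [read_gene_bed()] or [fh_gene_intervals()].
#' @return data.frame of hits: `sample`, `gene`, `type`, `sv_start`,
#'   `sv_end`, `whole_gene` (SV spans the full gene interval).
#' @export
gene_disruption <- function(consensus, genes) {
  hits <- list()
  for (i in seq_len(nrow(consensus))) {
    same <- genes$chrom == consensus$chrom[i] &
      genes$start <= consensus$end[i] & genes$end >= consensus$start[i]
    for (j in which(same)) {
      hits[[length(hits) + 1L]] <- data.frame(
        sample = if ("sample" %in% names(consensus))
          consensus$sample[i] else NA_character_,
        gene = genes$gene[j],
        type = consensus$type[i],
        sv_start = consensus$start[i],
        sv_end = consensus$end[i],
        whole_gene = consensus$start[i] <= genes$start[j] &&
          consensus$end[i] >= genes$end[j],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(hits)) {
    return(data.frame(sample = character(0), gene = character(0),
                      type = character(0), sv_start = integer(0),
                      sv_end = integer(0), whole_gene = logical(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, hits)
}
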