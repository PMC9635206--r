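# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Round half away from zero
#'
#' Base `round()` uses banker's rounding; report tables here follow the
#' convention of rounding halves away from zero (47.5 -> 48), matching how
#' clinical percentages are usually printed.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

stop_domain <- function(...) stop(..., call. = FALSE)

assert_proportion <- function(x, name) {
  if (!is.numeric(x) || any(is.na(x)) || any(x < 0) || any(x > 1)) {
    stop_domain(sprintf("`%s` must be a proportion in [0, 1]", name))
  }
  invisible(x)
}

assert_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x)) {
    stop_domain(sprintf("`%s` must be TRUE or FALSE", name))
  }
  invisible(x)
}

# Deterministic per-component substreams from one master seed. Seeds are
# drawn once in a fixed order, so appending a new component name keeps the
# streams of existing components unchanged.
.component_names <- c(
  "demographics", "ldl", "variants", "penetrance", "treatment",
  "selfreport", "comorbidity", "prs", "sv", "missing", "reserved1",
  "reserved2"
)

component_seeds <- function(seed) {
  stopifnot(is.numeric(seed), length(seed) == 1L, !is.na(seed))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed) %% .Machine$integer.max)
  setNames(sample.int(.Machine$integer.max - 1L, length(.component_names)),
           .component_names)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

variant_key <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

# Minimal representation of a chrom/pos/ref/alt key: shared suffix then
# shared prefix bases are trimmed (position advanced past trimmed prefix).
# Full left-alignment needs a reference genome and is out of scope; trimming
# handles the padded representations that VCF splitting produces.
normalize_variant <- function(chrom, pos, ref, alt) {
  pos <- as.integer(pos)
  for (i in seq_along(ref)) {
    r <- strsplit(ref[i], "")[[1]]
    a <- strsplit(alt[i], "")[[1]]
    while (length(r) > 1L && length(a) > 1L && r[length(r)] == a[length(a)]) {
      r <- r[-length(r)]
      a <- a[-length(a)]
    }
    while (length(r) > 1L && length(a) > 1L && r[1L] == a[1L]) {
      r <- r[-1L]
      a <- a[-1L]
      pos[i] <- pos[i] + 1L
    }
    ref[i] <- paste(r, collapse = "")
    alt[i] <- paste(a, collapse = "")
  }
  list(chrom = chrom, pos = pos, ref = ref, alt = alt,
       key = variant_key(chrom, pos, ref, alt))
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE, ...)
}
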