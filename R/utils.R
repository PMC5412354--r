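#' Round half away from zero
#'
#' Decimal rounding with ties going up (0.5 -> 1), matching how coverage and
#' recall figures are conventionally printed in sequencing reports. Base R's
#' `round()` uses banker's rounding, which would print 73.75 as 73.7.
#'
#' @param x numeric vector
#' @param digits number of decimal places
#' @return rounded numeric vector
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

## Run an expression with a temporary RNG state. All exported stochastic
## operations funnel through this so a caller-supplied seed fully determines
## the result without clobbering the session RNG.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  expr
}

## Deterministic sub-seed for a named pipeline stage. Kept below 2^31 - 1 so
## it is always a valid R integer seed.
derive_seed <- function(base_seed, stage, index = 0L) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(base_seed) * 10007 + h * 101 + index) %% 2147483647)
}

assert_scalar_number <- function(x, name, min = -Inf, max = Inf,
                                 allow_min = TRUE, allow_max = TRUE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (allow_min) x >= min else x > min) &&
    (if (allow_max) x <= max else x < max)
  if (!ok) {
    stop(sprintf("invalid parameter '%s': must be a number in %s%s, %s%s",
                 name, if (allow_min) "[" else "(", min, max,
                 if (allow_max) "]" else ")"), call. = FALSE)
  }
  invisible(x)
}

assert_count <- function(x, name, min = 0L) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    x == as.integer(x) && x >= min
  if (!ok) stop(sprintf("invalid parameter '%s': must be an integer >= %d",
                        name, min), call. = FALSE)
  invisible(as.integer(x))
}

BASES <- c("A", "C", "G", "T")

## integer encoding A=1 C=2 G=3 T=4 used throughout the simulator and caller
encode_bases <- function(chars) match(chars, BASES)

decode_bases <- function(ints) BASES[ints]

seq_to_int <- function(s) encode_bases(strsplit(s, "", fixed = TRUE)[[1]])

int_to_seq <- function(v) paste(BASES[v], collapse = "")

revcomp_int <- function(v) rev(5L - v)

## canonical ordering used for all variant tables and emitted VCFs
order_variants <- function(df, chrom_levels) {
  order(match(df$chrom, chrom_levels), df$pos, df$ref, df$alt)
}

variant_key <- function(df) paste(df$chrom, df$pos, df$ref, df$alt, sep = ":")

#' Classify variants as SNPs or indels
#'
#' @param ref,alt character vectors of reference and alternate alleles
#' @return character vector with values `"snp"` or `"indel"`
#' @export
variant_class <- function(ref, alt) {
  ifelse(nchar(ref) == 1L & nchar(alt) == 1L, "snp", "indel")
}
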