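#' Recall and precision of a call set against a truth set
#'
#' Per-class (SNP / indel) evaluation with site-and-allele matching of
#' left-normalized variants: a call is a true positive when (chromosome,
#' position, ref, alt) matches a truth record, and additionally the
#' genotype when `require_genotype` is set. No distance-window matching is
#' attempted — normalization is the equivalence rule.
#'
#' @param calls,truth variant tables (`chrom`, `pos`, `ref`, `alt`,
#'   `class`; `genotype` needed when `require_genotype`)
#' @param require_genotype also require genotype concordance (default
#'   `FALSE`, mirroring how recall is counted in rarefaction analyses)
#' @return data.frame of class `benchmark_result`, one row per variant
#'   class: `true_positives`, `false_negatives`, `false_positives`,
#'   `recall`, `precision` (percent, 2 decimals; precision is `NA` when
#'   the class has no calls)
#' @export
match_and_score <- function(calls, truth, require_genotype = FALSE) {
  key <- function(df) {
    k <- variant_key(df)
    if (require_genotype) paste(k, df$genotype, sep = ":") else k
  }
  ## sortedness contract: chromosome blocks contiguous, positions
  ## non-decreasing within each block (matching itself is key-based)
  is_sorted <- function(df) {
    if (nrow(df) < 2L) return(TRUE)
    r <- rle(df$chrom)
    !anyDuplicated(r$values) &&
      all(tapply(df$pos, factor(df$chrom, levels = r$values),
                 function(p) !is.unsorted(p)))
  }
  for (nm in c("calls", "truth")) {
    df <- get(nm)
    if (!is_sorted(df)) {
      warning("unsorted ", nm, " input; sorting")
      assign(nm, df[order(df$chrom, df$pos, df$ref, df$alt), , drop = FALSE])
    }
  }
  out <- lapply(c("snp", "indel"), function(cls) {
    tr <- truth[truth$class == cls, , drop = FALSE]
    cl <- calls[calls$class == cls, , drop = FALSE]
    tp <- sum(key(cl) %in% key(tr))
    fp <- nrow(cl) - tp
    fn <- nrow(tr) - sum(key(tr) %in% key(cl))
    data.frame(
      variant_class = cls,
      true_positives = tp, false_negatives = fn, false_positives = fp,
      recall = if (nrow(tr)) round_half_up(100 * tp / (tp + fn), 2)
               else NA_real_,
      precision = if (nrow(cl)) round_half_up(100 * tp / (tp + fp), 2)
                  else NA_real_,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  class(out) <- c("benchmark_result", "data.frame")
  out
}

#' Write a benchmark result as TSV
#'
#' @param result a `benchmark_result`
#' @param path output file
#' @export
write_benchmark_tsv <- function(result, path) {
  utils::write.table(result, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
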