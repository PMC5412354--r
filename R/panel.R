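#' Build a synthetic capture-panel world
#'
#' Generates a reference sequence and exon/target geometry emulating a
#' multi-gene diagnostic capture panel (by default 27 genes, mirroring the
#' size of commercial hereditary-neuropathy panels). Each gene lives on its
#' own chromosome (`panel_chr1`, `panel_chr2`, ...) so there is no inter-gene
#' mapping ambiguity. Targets are the exons padded by `pad_bp` on each side
#' and merged, reproducing the exon +/- 100 bp calling restriction used in
#' clinical panel pipelines.
#'
#' Coordinates follow the field conventions: intervals are held as 1-based
#' closed [`GenomicRanges::GRanges`] in memory; on disk BED is 0-based
#' half-open (handled by \pkg{rtracklayer}) and VCF is 1-based.
#'
#' @param n_genes number of genes (one chromosome each)
#' @param exons_per_gene number of exons per gene
#' @param exon_len exon length in bp (>= 10)
#' @param pad_bp padding added to each exon side before merging (default 100)
#' @param exon_gap distance between consecutive exon ends/starts; gaps smaller
#'   than `2 * pad_bp` cause padded exons to merge
#' @param margin reference sequence kept beyond the outermost pads, so that
#'   read pairs near target edges never run off the chromosome
#' @param seed integer seed controlling the random reference sequence
#' @return an object of class `panel_world`: a list with `genes` (data.frame),
#'   `exons` and `targets` (`GRanges`, `targets` = padded & merged),
#'   `reference` (`DNAStringSet`), `pad_bp`, and `target_bp` (total padded
#'   target length)
#' @examples
#' pw <- build_panel(n_genes = 2, exons_per_gene = 3, exon_len = 150, seed = 1)
#' pw$target_bp
#' @export
build_panel <- function(n_genes = 27, exons_per_gene = 5, exon_len = 200,
                        pad_bp = 100, exon_gap = 500, margin = 600, seed = 1) {
  assert_count(n_genes, "n_genes", min = 1L)
  assert_count(exons_per_gene, "exons_per_gene", min = 1L)
  assert_count(exon_len, "exon_len", min = 10L)
  assert_count(pad_bp, "pad_bp", min = 0L)
  assert_count(exon_gap, "exon_gap", min = 1L)
  assert_count(margin, "margin", min = 0L)

  chrom <- paste0("panel_chr", seq_len(n_genes))
  gene <- sprintf("GENE%02d", seq_len(n_genes))
  ## exon i starts at margin + pad + (i-1)*(exon_len + exon_gap)  (1-based)
  first <- margin + pad_bp + 1L
  starts0 <- first + (seq_len(exons_per_gene) - 1L) * (exon_len + exon_gap)
  chrom_len <- max(starts0) + exon_len - 1L + pad_bp + margin

  exons <- GenomicRanges::GRanges(
    seqnames = rep(chrom, each = exons_per_gene),
    ranges = IRanges::IRanges(start = rep(starts0, times = n_genes),
                              width = exon_len),
    gene = rep(gene, each = exons_per_gene),
    seqlengths = stats::setNames(rep(chrom_len, n_genes), chrom)
  )
  padded <- GenomicRanges::trim(exons + pad_bp)
  targets <- GenomicRanges::reduce(padded)

  reference <- with_seed(seed, {
    Biostrings::DNAStringSet(stats::setNames(vapply(
      seq_len(n_genes),
      function(i) paste(sample(BASES, chrom_len, replace = TRUE), collapse = ""),
      character(1)), chrom))
  })

  pw <- structure(list(
    genes = data.frame(gene = gene, chrom = chrom, chrom_len = chrom_len,
                       stringsAsFactors = FALSE),
    exons = exons,
    targets = targets,
    reference = reference,
    pad_bp = as.integer(pad_bp),
    target_bp = sum(GenomicRanges::width(targets))
  ), class = "panel_world")
  ## cached integer encoding and target mask: the caller and the
  ## down-sampling grid touch these hundreds of times
  pw$ref_int <- lapply(as.list(as.character(reference)), seq_to_int)
  pw$target_mask <- panel_target_mask(pw)
  pw
}

#' @export
print.panel_world <- function(x, ...) {
  cat(sprintf("panel_world: %d genes, %d exons, padded target %d bp (pad %d bp)\n",
              nrow(x$genes), length(x$exons), x$target_bp, x$pad_bp))
  invisible(x)
}

#' Write the panel reference as FASTA
#'
#' @param panel a `panel_world`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_panel_fasta <- function(panel, path) {
  Biostrings::writeXStringSet(panel$reference, filepath = path)
  invisible(path)
}

#' Write the padded target intervals as BED
#'
#' Emits the merged padded intervals (0-based half-open on disk).
#'
#' @inheritParams write_panel_fasta
#' @export
write_targets_bed <- function(panel, path) {
  rtracklayer::export(panel$targets, path, format = "BED")
  invisible(path)
}

#' Read target intervals from a BED file
#'
#' @param path BED file
#' @return a `GRanges` of targets (1-based in memory)
#' @export
read_targets_bed <- function(path) {
  rtracklayer::import(path, format = "BED")
}

## per-chromosome integer-coded reference, cached on the panel object
panel_ref_int <- function(panel) {
  panel$ref_int %||% lapply(as.list(as.character(panel$reference)), seq_to_int)
}

## offsets mapping (chrom, pos) -> single global coordinate space
panel_offsets <- function(panel) {
  lens <- panel$genes$chrom_len
  stats::setNames(c(0, cumsum(as.numeric(lens)))[seq_along(lens)],
                  panel$genes$chrom)
}

## logical vector over the global coordinate space flagging on-target bases
panel_target_mask <- function(panel) {
  if (!is.null(panel$target_mask)) return(panel$target_mask)
  off <- panel_offsets(panel)
  total <- sum(panel$genes$chrom_len)
  mask <- logical(total)
  tg <- panel$targets
  ch <- as.character(GenomicRanges::seqnames(tg))
  st <- GenomicRanges::start(tg); en <- GenomicRanges::end(tg)
  for (i in seq_along(tg)) {
    mask[(off[[ch[i]]] + st[i]):(off[[ch[i]]] + en[i])] <- TRUE
  }
  mask
}
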