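#' Left-normalize a variant against the reference
#'
#' Shifts an indel to its leftmost equivalent position and trims shared
#' bases, keeping one shared leading reference base as the VCF anchor for
#' indels. SNPs are reduced to single differing bases. This is the standard
#' normalization applied before any variant matching, so that equivalent
#' representations compare equal.
#'
#' @param pos 1-based position
#' @param ref,alt allele strings
#' @param refseq_int integer-coded chromosome sequence (see internals) or a
#'   character chromosome string
#' @return list with `pos`, `ref`, `alt`
#' @export
normalize_variant <- function(pos, ref, alt, refseq_int) {
  pos <- as.integer(pos)
  if (is.character(refseq_int)) refseq_int <- seq_to_int(refseq_int)
  r <- seq_to_int(ref)
  a <- seq_to_int(alt)
  if (identical(r, a)) stop("ref and alt alleles are identical", call. = FALSE)
  ## trim shared trailing bases; extend left when an allele empties
  repeat {
    nr <- length(r); na <- length(a)
    if (nr > 0 && na > 0 && r[nr] == a[na]) {
      r <- r[-nr]; a <- a[-na]
      if (length(r) == 0L || length(a) == 0L) {
        if (pos <= 1L) stop("cannot left-normalize past start of chromosome",
                            call. = FALSE)
        pos <- pos - 1L
        r <- c(refseq_int[pos], r)
        a <- c(refseq_int[pos], a)
      }
    } else break
  }
  ## trim shared leading bases while both alleles keep >= 2 bases
  while (length(r) > 1L && length(a) > 1L && r[1] == a[1]) {
    r <- r[-1]; a <- a[-1]; pos <- pos + 1L
  }
  list(pos = pos, ref = int_to_seq(r), alt = int_to_seq(a))
}

#' Plant ground-truth variants in a synthetic panel
#'
#' Draws non-overlapping SNP and small-indel positions inside the padded
#' target intervals, producing a left-normalized, sorted truth set. Counts
#' default to the scale of a proband's on-target call set from a
#' high-coverage gene panel (162 SNPs, 42 indels).
#'
#' Indels are insertions or deletions with equal probability, with lengths
#' uniform over `indel_len_range`. Variants are separated by at least
#' `min_spacing` bp and kept away from interval edges so that a planted
#' indel plus its normalization shift stays on target.
#'
#' @param panel a `panel_world` from [build_panel()]
#' @param n_snps,n_indels number of SNPs / indels to plant
#' @param indel_len_range integer length range for indels (inserted or
#'   deleted bases)
#' @param min_spacing minimal distance between planted variant anchors
#' @param seed integer seed
#' @return data.frame of class `planted_variants` with columns `chrom`,
#'   `pos`, `ref`, `alt`, `class`, `id`, sorted by position
#' @export
plant_variants <- function(panel, n_snps = 162, n_indels = 42,
                           indel_len_range = c(1L, 10L), min_spacing = 30L,
                           seed = 1) {
  stopifnot(inherits(panel, "panel_world"))
  assert_count(n_snps, "n_snps"); assert_count(n_indels, "n_indels")
  assert_count(min_spacing, "min_spacing", min = 1L)
  stopifnot(length(indel_len_range) == 2L, indel_len_range[1] >= 1L,
            indel_len_range[2] >= indel_len_range[1])
  max_ilen <- as.integer(indel_len_range[2])
  edge <- max_ilen + 2L

  tg <- panel$targets
  ch <- as.character(GenomicRanges::seqnames(tg))
  st <- GenomicRanges::start(tg); en <- GenomicRanges::end(tg)
  ## candidate anchor positions, away from interval edges
  cand_ch <- character(0); cand_pos <- integer(0)
  for (i in seq_along(tg)) {
    lo <- st[i] + edge; hi <- en[i] - edge
    if (hi >= lo) {
      cand_ch <- c(cand_ch, rep(ch[i], hi - lo + 1L))
      cand_pos <- c(cand_pos, lo:hi)
    }
  }
  n_total <- n_snps + n_indels
  if (n_total == 0L) {
    out <- data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      class = character(0), id = character(0),
                      stringsAsFactors = FALSE)
    class(out) <- c("planted_variants", "data.frame")
    return(out)
  }

  refint <- panel_ref_int(panel)
  with_seed(seed, {
    ## greedy spaced sampling of anchor positions
    ord <- sample.int(length(cand_pos))
    chosen <- integer(0)
    occupied <- new.env(hash = TRUE)
    for (k in ord) {
      key_ch <- cand_ch[k]
      slot <- cand_pos[k] %/% min_spacing
      near <- vapply(c(slot - 1L, slot, slot + 1L), function(s) {
        v <- occupied[[paste(key_ch, s)]]
        !is.null(v) && any(abs(v - cand_pos[k]) < min_spacing)
      }, logical(1))
      if (any(near)) next
      kk <- paste(key_ch, slot)
      occupied[[kk]] <- c(occupied[[kk]], cand_pos[k])
      chosen <- c(chosen, k)
      if (length(chosen) >= n_total) break
    }
    if (length(chosen) < n_total) {
      stop(sprintf(
        "capacity error: target space holds only %d variants at spacing %d (requested %d)",
        length(chosen), min_spacing, n_total), call. = FALSE)
    }
    vch <- cand_ch[chosen]; vpos <- cand_pos[chosen]
    is_indel <- c(rep(FALSE, n_snps), rep(TRUE, n_indels))

    ref <- character(n_total); alt <- character(n_total); pos <- vpos
    for (j in seq_len(n_total)) {
      rs <- refint[[match(vch[j], panel$genes$chrom)]]
      if (!is_indel[j]) {
        rb <- rs[vpos[j]]
        ab <- sample(setdiff(1:4, rb), 1L)
        ref[j] <- BASES[rb]; alt[j] <- BASES[ab]
      } else {
        len <- sample(indel_len_range[1]:indel_len_range[2], 1L)
        if (stats::runif(1) < 0.5) {        # deletion
          r0 <- rs[vpos[j]:(vpos[j] + len)]
          nv <- normalize_variant(vpos[j], int_to_seq(r0),
                                  BASES[r0[1]], rs)
        } else {                            # insertion
          ins <- sample.int(4L, len, replace = TRUE)
          rb <- rs[vpos[j]]
          nv <- normalize_variant(vpos[j], BASES[rb],
                                  int_to_seq(c(rb, ins)), rs)
        }
        pos[j] <- nv$pos; ref[j] <- nv$ref; alt[j] <- nv$alt
      }
    }
    out <- data.frame(chrom = vch, pos = pos, ref = ref, alt = alt,
                      class = variant_class(ref, alt),
                      stringsAsFactors = FALSE)
    out <- out[order_variants(out, panel$genes$chrom), , drop = FALSE]
    out$id <- sprintf("var%04d", seq_len(nrow(out)))
    rownames(out) <- NULL
    class(out) <- c("planted_variants", "data.frame")
    out
  })
}

## ---- VCF I/O -------------------------------------------------------------
## The emitter writes a fixed-layout VCF v4.2 body directly (QUAL/GT/DP
## only); parsing is delegated to VariantAnnotation::readVcf.

#' Write a variant table as VCF v4.2
#'
#' @param variants data.frame with `chrom`, `pos`, `ref`, `alt`, optionally
#'   `qual`, `depth`
#' @param path output file
#' @param panel a `panel_world`, used for contig headers and sorting order
#' @param genotypes optional character matrix (variants x samples) with
#'   values `hom_ref`, `het`, `hom_alt`; written as GT (plus DP when `depth`
#'   present)
#' @return `path`, invisibly
#' @export
write_vcf <- function(variants, path, panel, genotypes = NULL) {
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s,length=%d>", panel$genes$chrom,
                   panel$genes$chrom_len),
           "##source=paneldepth")
  fmt_cols <- ""
  samples <- character(0)
  if (!is.null(genotypes)) {
    genotypes <- as.matrix(genotypes)
    stopifnot(nrow(genotypes) == nrow(variants))
    samples <- colnames(genotypes) %||% paste0("S", seq_len(ncol(genotypes)))
    hdr <- c(hdr,
             '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
             '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth at site">')
  }
  hdr <- c(hdr, paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                        "FILTER", "INFO",
                        if (length(samples)) c("FORMAT", samples)),
                      collapse = "\t"))
  if (nrow(variants) > 0) {
    o <- order_variants(variants, panel$genes$chrom)
    variants <- variants[o, , drop = FALSE]
    qual <- variants$qual %||% rep(".", nrow(variants))
    qual <- ifelse(is.na(qual), ".", format(qual, trim = TRUE, digits = 10))
    id <- variants$id %||% rep(".", nrow(variants))
    body <- paste(variants$chrom, variants$pos, id, variants$ref,
                  variants$alt, qual, "PASS", ".", sep = "\t")
    if (length(samples)) {
      genotypes <- genotypes[o, , drop = FALSE]
      gt_code <- c(hom_ref = "0/0", het = "0/1", hom_alt = "1/1")
      gm <- matrix(gt_code[genotypes], nrow = nrow(variants))
      if (!is.null(variants$depth)) {
        gm[] <- paste0(gm, ":", rep(as.integer(round(variants$depth)),
                                    ncol(gm)))
        fmt <- "GT:DP"
      } else fmt <- "GT"
      body <- paste(body, fmt, apply(gm, 1L, paste, collapse = "\t"),
                    sep = "\t")
    }
    writeLines(c(hdr, body), path)
  } else writeLines(hdr, path)
  invisible(path)
}

#' Read a VCF into the package's variant-table form
#'
#' Thin wrapper around [VariantAnnotation::readVcf()]. Multi-allelic records
#' are expanded to one row per alternate allele.
#'
#' @param path VCF file
#' @return data.frame with columns `chrom`, `pos`, `ref`, `alt`, `class`,
#'   `qual`, `id` and, when present, a `genotypes` attribute
#'   (variants x samples character matrix)
#' @export
read_vcf <- function(path) {
  v <- VariantAnnotation::readVcf(path)
  v <- VariantAnnotation::expand(v)
  rr <- SummarizedExperiment::rowRanges(v)
  out <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(rr)),
    pos = GenomicRanges::start(rr),
    ref = as.character(VariantAnnotation::ref(v)),
    alt = as.character(VariantAnnotation::alt(v)),
    qual = VariantAnnotation::qual(v),
    stringsAsFactors = FALSE
  )
  out$class <- variant_class(out$ref, out$alt)
  ids <- names(rr)
  out$id <- if (!is.null(ids)) ids else rep(NA_character_, nrow(out))
  rownames(out) <- NULL
  gt <- VariantAnnotation::geno(v)$GT
  if (!is.null(gt)) {
    code <- c("0/0" = "hom_ref", "0/1" = "het", "1/0" = "het",
              "1/1" = "hom_alt", "0|0" = "hom_ref", "0|1" = "het",
              "1|0" = "het", "1|1" = "hom_alt")
    gm <- matrix(code[gt], nrow = nrow(gt), dimnames = dimnames(gt))
    rownames(gm) <- NULL
    attr(out, "genotypes") <- gm
  }
  out
}
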