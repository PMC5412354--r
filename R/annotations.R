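#' Worked-example annotated variant table (two diagnosed families)
#'
#' The nine annotated variant rows from the package's worked example: the
#' post-frequency-filter shortlists of two hereditary-neuropathy probands
#' (case 1, consanguineous recessive family; case 2, dominant family with
#' incomplete penetrance), with their database frequencies, pathogenicity
#' predictor outputs and genotypes. Genotype quality and site depth are
#' set to comfortably passing values (the source pipelines apply QC before
#' this table is formed).
#'
#' @param case `1`, `2` or `"both"`
#' @return an `annotated_variants` data.frame
#' @export
worked_example_variants <- function(case = "both") {
  df <- data.frame(
    case = c(1L, 1L, 1L, 1L, 2L, 2L, 2L, 2L, 2L),
    chrom = c("chr1", "chr7", "chr11", "chr11",
              "chr1", "chr1", "chr1", "chr8", "chr11"),
    pos = c(156109095L, 75932279L, 9861208L, 95595177L,
            10342522L, 10397567L, 156109095L, 75272419L, 9990017L),
    ref = c("GA", "G", "G", "A", "G", "A", "GA", "C", "G"),
    alt = c("G", "A", "C", "G", "A", "G", "G", "T", "A"),
    gene = c("LMNA", "HSPB1", "SBF2", "MTMR2",
             "KIF1B", "KIF1B", "LMNA", "GDAP1", "SBF2"),
    transcript = c("NM_170707", "NM_001540", "NM_030962", "NM_016156",
                   "NM_015074", "NM_015074", "NM_170707", "NM_018972",
                   "NM_030962"),
    hgvs_c = c("cDNA.2405_2405delA", "c.250G>A", "c.3292C>G", "c.447T>C",
               "c.1227G>A", "c.3260A>G", "cDNA.2405_2405delA", "c.358C>T",
               "c.1471C>T"),
    hgvs_p = c(NA, "p.G84R", "p.L1098V", "p.Y149Y",
               "p.T409T", "p.Y1087C", NA, "p.R120W", "p.L491F"),
    function_class = c("utr_indel", "nonsynonymous_snp",
                       "nonsynonymous_snp", "synonymous_snp",
                       "synonymous_snp", "nonsynonymous_snp", "utr_indel",
                       "nonsynonymous_snp", "nonsynonymous_snp"),
    genotype = c("het", "hom_alt", "het", "het",
                 "het", "het", "het", "het", "het"),
    genotype_quality = 99,
    site_depth = 200,
    maf_exac = c(NA, NA, 0.0209, 2.527e-5, 0.0328, 0.0325, NA, NA, NA),
    subpopmaf_eas = c(NA, NA, NA, NA, 0.08, NA, NA, NA, NA),
    mt_label = c("disease_causing", "disease_causing", "polymorphism",
                 "disease_causing", "polymorphism", "polymorphism",
                 "disease_causing", "disease_causing", "disease_causing"),
    mt_p = c(0.999, 0.999, 0.054, 1, 2.98e-17, 5.41e-11, 0.999, 0.999,
             0.999),
    kgg_label = c("no_prediction", "disease_causing",
                  "non_disease_causing", "no_prediction", "filtered",
                  "non_disease_causing", "no_prediction", "disease_causing",
                  "non_disease_causing"),
    kgg_p = c(NA, 0.681, 3.46e-4, NA, NA, 0.039, NA, 0.500, 0.044),
    homopolymer_indel = c(TRUE, FALSE, FALSE, FALSE,
                          FALSE, FALSE, TRUE, FALSE, FALSE),
    multiallelic = c(TRUE, FALSE, FALSE, FALSE,
                     FALSE, FALSE, TRUE, FALSE, FALSE),
    stringsAsFactors = FALSE)
  if (!identical(case, "both")) df <- df[df$case == case, , drop = FALSE]
  rownames(df) <- NULL
  annotated_variants(df)
}

#' Observed segregation genotypes for the two worked-example families
#'
#' Genotypes of the causal variant across the genotyped relatives:
#' family 1 (AR) — both parents heterozygous, the two affected sibs
#' homozygous, three unaffected sibs homozygous-reference; family 2 (AD) —
#' affected proband and affected paternal aunt heterozygous, the
#' unaffected father a heterozygous carrier, the mother
#' homozygous-reference.
#'
#' @param case `1` or `2`
#' @return named character vector of genotypes by member id
#' @export
worked_example_segregation <- function(case) {
  if (case == 1) {
    c("I-1" = "het", "I-2" = "het", "II-1" = "hom_alt", "II-2" = "hom_alt",
      "II-3" = "hom_ref", "II-4" = "hom_ref", "II-5" = "hom_ref")
  } else {
    c("I-1" = "het", "I-2" = "het", "I-3" = "hom_ref", "II-1" = "het")
  }
}

#' Generate a synthetic annotated variant table with one causal variant
#'
#' Emulates the output of annotation + prediction tooling on a proband's
#' filtered variant list: `n_benign` background variants plus one planted
#' causal variant. Benign variants draw ensemble disease probabilities
#' from `Beta(1, 10)` (rarely above 0.5) and a mix of frequency profiles
#' (some common enough to fail the frequency filters); the causal variant
#' is a rare nonsynonymous change with ensemble probability from
#' `Beta(8, 2)` and a genotype matching the inheritance model (homozygous
#' under AR, heterozygous under AD).
#'
#' @param n_benign number of background variants
#' @param model `"AR"` or `"AD"` (or a [pedigree()])
#' @param seed integer seed
#' @return an `annotated_variants` table; the causal row has
#'   `gene == "CAUSAL1"` and attribute `causal_id` gives its `variant_id`
#' @export
synth_annotations <- function(n_benign = 30, model = "AR", seed = 1) {
  if (inherits(model, "pedigree")) model <- model$inheritance_model
  model <- match.arg(model, c("AR", "AD"))
  with_seed(seed, {
    n <- n_benign
    common <- stats::runif(n) < 0.4          # these should fail frequency
    maf <- ifelse(common, stats::runif(n, 0.05, 0.5),
                  ifelse(stats::runif(n) < 0.3, NA, stats::runif(n, 0, 0.04)))
    subpop <- ifelse(!common & stats::runif(n) < 0.1,
                     stats::runif(n, 0.05, 0.2), NA)
    fclass <- sample(FUNCTION_CLASSES, n, replace = TRUE,
                     prob = c(0.35, 0.3, 0.05, 0.1, 0.2))
    kgg_p <- ifelse(fclass %in% c("nonsynonymous_snp", "splice_site"),
                    stats::rbeta(n, 1, 10), NA)
    geno <- sample(c("het", "hom_alt"), n, replace = TRUE,
                   prob = c(0.7, 0.3))
    gq <- ifelse(stats::runif(n) < 0.05, stats::runif(n, 5, 19),
                 stats::runif(n, 30, 99))
    dp <- ifelse(stats::runif(n) < 0.05, sample(1:3, n, replace = TRUE),
                 sample(20:300, n, replace = TRUE))
    benign <- data.frame(
      chrom = paste0("chr", sample(1:22, n, replace = TRUE)),
      pos = sample.int(2e8, n),
      ref = sample(BASES, n, replace = TRUE),
      alt = sample(BASES, n, replace = TRUE),
      gene = sprintf("BG%03d", seq_len(n)),
      transcript = sprintf("NM_%06d", sample.int(999999, n)),
      hgvs_c = sprintf("c.%d%s>%s", sample.int(3000, n),
                       sample(BASES, n, TRUE), sample(BASES, n, TRUE)),
      hgvs_p = NA_character_,
      function_class = fclass,
      genotype = geno,
      genotype_quality = round(gq, 1),
      site_depth = dp,
      maf_exac = maf,
      subpopmaf_eas = subpop,
      mt_label = ifelse(stats::runif(n) < 0.15, "disease_causing",
                        "polymorphism"),
      mt_p = stats::runif(n),
      kgg_label = NA_character_,
      kgg_p = kgg_p,
      homopolymer_indel = FALSE,
      multiallelic = FALSE,
      stringsAsFactors = FALSE)
    ## same-base draws would be malformed records; re-draw alt
    same <- benign$ref == benign$alt
    benign$alt[same] <- vapply(benign$ref[same], function(b)
      sample(setdiff(BASES, b), 1L), character(1))
    causal <- data.frame(
      chrom = "chr7", pos = 75932279L, ref = "G", alt = "A",
      gene = "CAUSAL1", transcript = "NM_000001",
      hgvs_c = "c.250G>A", hgvs_p = "p.G84R",
      function_class = "nonsynonymous_snp",
      genotype = if (model == "AR") "hom_alt" else "het",
      genotype_quality = 99, site_depth = 200,
      maf_exac = NA_real_, subpopmaf_eas = NA_real_,
      mt_label = "disease_causing", mt_p = 0.999,
      kgg_label = NA_character_, kgg_p = stats::rbeta(1, 8, 2),
      homopolymer_indel = FALSE, multiallelic = FALSE,
      stringsAsFactors = FALSE)
    out <- annotated_variants(rbind(benign, causal))
    attr(out, "causal_id") <- out$variant_id[nrow(out)]
    out
  })
}
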