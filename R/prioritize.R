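## Annotated-variant tables are plain data.frames with a documented column
## dictionary (see `annotated_variants()`); population frequencies live in
## `maf_<db>` columns (overall) and `subpopmaf_<pop>` columns
## (sub-population maxima are taken across these).

FUNCTION_CLASSES <- c("nonsynonymous_snp", "synonymous_snp", "splice_site",
                      "utr_indel", "other")
MT_LABELS <- c("disease_causing", "polymorphism", "no_prediction")
KGG_LABELS <- c("disease_causing", "non_disease_causing", "no_prediction",
                "filtered")

#' Validate / construct an annotated variant table
#'
#' Column dictionary: variant identity (`chrom`, `pos`, `ref`, `alt`,
#' `gene`, `transcript`, `hgvs_c`, `hgvs_p`), `function_class` (one of
#' nonsynonymous_snp, synonymous_snp, splice_site, utr_indel, other),
#' `genotype` (`het` / `hom_alt`), `genotype_quality` (Phred),
#' `site_depth`, overall population frequencies in `maf_<database>`
#' columns, sub-population frequencies in `subpopmaf_<population>` columns
#' (`NA` = no data), predictor outputs `mt_label`/`mt_p` (pathogenicity
#' classifier label and its probability of correctness) and
#' `kgg_label`/`kgg_p` (Mendelian disease-causing ensemble label and
#' disease probability), optional `known_id`, and artifact flags
#' `homopolymer_indel`, `multiallelic`.
#'
#' @param df data.frame following the dictionary above
#' @return the validated data.frame, classed `annotated_variants`
#' @export
annotated_variants <- function(df) {
  req <- c("gene", "hgvs_c", "function_class", "genotype",
           "genotype_quality", "site_depth", "mt_label", "mt_p",
           "kgg_label", "kgg_p")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  stopifnot(all(df$function_class %in% FUNCTION_CLASSES),
            all(df$genotype %in% c("het", "hom_alt")),
            all(df$mt_label %in% MT_LABELS | is.na(df$mt_label)),
            all(df$kgg_label %in% KGG_LABELS | is.na(df$kgg_label)),
            all(df$genotype_quality >= 0, na.rm = TRUE))
  fr <- unlist(df[grepl("^(maf_|subpopmaf_)", names(df))])
  stopifnot(all(fr >= 0 & fr <= 1, na.rm = TRUE))
  if (is.null(df$variant_id))
    df$variant_id <- paste(df$gene, df$hgvs_c, sep = ":")
  class(df) <- unique(c("annotated_variants", class(df)))
  df
}

#' Quality-control and frequency thresholds for the filter cascade
#'
#' Defaults follow standard clinical-pipeline settings: genotype quality
#' >= 20, site depth >= 4, and exclusion of variants with allele frequency
#' >= 0.05 in any overall or sub-population database.
#'
#' @param min_genotype_quality Phred genotype-quality floor (inclusive)
#' @param min_depth site-depth floor (inclusive)
#' @param max_overall_maf overall-frequency exclusion boundary (a variant
#'   at or above this frequency fails)
#' @param max_subpop_maf sub-population frequency exclusion boundary
#' @return object of class `qc_thresholds`
#' @export
qc_thresholds <- function(min_genotype_quality = 20, min_depth = 4,
                          max_overall_maf = 0.05, max_subpop_maf = 0.05) {
  for (v in c("min_genotype_quality", "min_depth", "max_overall_maf",
              "max_subpop_maf"))
    assert_scalar_number(get(v), v, min = 0)
  structure(list(min_genotype_quality = min_genotype_quality,
                 min_depth = min_depth, max_overall_maf = max_overall_maf,
                 max_subpop_maf = max_subpop_maf),
            class = "qc_thresholds")
}

row_max <- function(df, cols) {
  if (!length(cols)) return(rep(NA_real_, nrow(df)))
  m <- as.matrix(df[cols])
  mx <- unname(suppressWarnings(apply(m, 1L, max, na.rm = TRUE)))
  mx[!is.finite(mx)] <- NA_real_
  mx
}

#' Overall population-frequency filter
#'
#' Fails a variant if its frequency in any overall database (`maf_*`
#' column) is at or above the boundary; absent data never fails (a variant
#' with no frequency record is a candidate rare variant by definition).
#'
#' @param v `annotated_variants` table
#' @param t [qc_thresholds()]
#' @return character vector `"pass"` / `"fail"`
#' @export
frequency_filter <- function(v, t = qc_thresholds()) {
  mx <- row_max(v, grep("^maf_", names(v), value = TRUE))
  ifelse(!is.na(mx) & mx >= t$max_overall_maf, "fail", "pass")
}

#' Sub-population frequency filter
#'
#' Fails a variant whose maximum frequency across sub-population columns
#' (`subpopmaf_*`) reaches the boundary — catching alleles that are rare
#' overall but common in one ancestry.
#'
#' @inheritParams frequency_filter
#' @return character vector `"pass"` / `"fail"`
#' @export
subpop_frequency_filter <- function(v, t = qc_thresholds()) {
  mx <- row_max(v, grep("^subpopmaf_", names(v), value = TRUE))
  ifelse(!is.na(mx) & mx >= t$max_subpop_maf, "fail", "pass")
}

#' Genotype quality control
#'
#' Passes a variant iff genotype quality and site depth are at or above
#' their (inclusive) floors.
#'
#' @inheritParams frequency_filter
#' @return character vector `"pass"` / `"fail"`
#' @export
genotype_qc <- function(v, t = qc_thresholds()) {
  unname(ifelse(v$genotype_quality >= t$min_genotype_quality &
                  v$site_depth >= t$min_depth, "pass", "fail"))
}

#' Predictor consensus level
#'
#' `"strong"` when the Mendelian ensemble predictor labels the variant
#' disease-causing (or, if only its probability is available, when
#' `kgg_p >= 0.5` — the boundary is inclusive); `"weak"` when only the
#' general pathogenicity classifier calls it disease-causing; `"none"`
#' otherwise.
#'
#' @param v `annotated_variants` table
#' @return character vector in `c("strong", "weak", "none")`
#' @export
predictor_consensus <- function(v) {
  kgg <- v$kgg_label
  derived <- is.na(kgg) & !is.na(v$kgg_p)
  kgg[derived] <- ifelse(v$kgg_p[derived] >= 0.5, "disease_causing",
                         "non_disease_causing")
  strong <- !is.na(kgg) & kgg == "disease_causing"
  weak <- !strong & !is.na(v$mt_label) & v$mt_label == "disease_causing"
  ifelse(strong, "strong", ifelse(weak, "weak", "none"))
}

#' Inheritance-mode shortlist
#'
#' Under AR only homozygous variants are compatible (optionally, pairs of
#' heterozygous variants in the same gene as compound-heterozygote
#' candidates); under AD any carried variant qualifies.
#'
#' @param v `annotated_variants` table
#' @param model `"AR"` or `"AD"` (or a [pedigree()], whose model is used)
#' @param compound_het also keep AR gene-level het pairs (off by default)
#' @return logical vector: compatible with the inheritance model
#' @export
inheritance_filter <- function(v, model, compound_het = FALSE) {
  if (inherits(model, "pedigree")) model <- model$inheritance_model
  model <- match.arg(model, c("AR", "AD"))
  if (nrow(v) == 0L) return(logical(0))
  if (model == "AD") return(v$genotype %in% c("het", "hom_alt"))
  ok <- v$genotype == "hom_alt"
  if (compound_het) {
    het_genes <- table(v$gene[v$genotype == "het"])
    ok <- ok | (v$genotype == "het" & v$gene %in%
                  names(het_genes)[het_genes >= 2L])
  }
  ok
}

#' Known-mutation table lookup
#'
#' Exact match on (gene, coding HGVS); absence is not a failure, merely no
#' annotation.
#'
#' @param v `annotated_variants` table
#' @param known_table data.frame with columns `gene`, `hgvs_c`, `id`
#' @return character vector of known-mutation ids (`NA` when unlisted)
#' @export
known_mutation_lookup <- function(v, known_table = known_mutations()) {
  i <- match(paste(v$gene, v$hgvs_c), paste(known_table$gene,
                                            known_table$hgvs_c))
  known_table$id[i]
}

#' Bundled known-mutation mini-table
#'
#' The two hereditary-neuropathy mutations relevant to the worked
#' examples, keyed by gene and coding change.
#'
#' @return data.frame with `gene`, `hgvs_c`, `id`
#' @export
known_mutations <- function() {
  data.frame(gene = c("HSPB1", "GDAP1"),
             hgvs_c = c("c.250G>A", "c.358C>T"),
             id = c("CM084860", "CM032927"),
             stringsAsFactors = FALSE)
}

#' Run the full variant-prioritization cascade
#'
#' Ordered verdict trail per variant: overall frequency, sub-population
#' frequency, genotype QC, functional class (diagnosis-eligible =
#' nonsynonymous or splice-site; synonymous and UTR variants are retained
#' in the report but flagged), predictor consensus, inheritance
#' compatibility. The final candidates are the variants passing every
#' mandatory filter with strong predictor consensus and a genotype
#' compatible with the inheritance model, ranked by consensus then by the
#' ensemble disease probability. Indels at the end of a homopolymer run
#' with multi-allelic pileups are flagged as suspected artifacts.
#'
#' @param v `annotated_variants` table
#' @param model `"AR"`, `"AD"`, or a [pedigree()]
#' @param thresholds [qc_thresholds()]
#' @param known_table known-mutation data.frame (see [known_mutations()])
#' @param compound_het passed to [inheritance_filter()]
#' @return object of class `shortlist_report`: list with `trail` (one row
#'   per variant x filter: verdict and reason), `variants` (input plus
#'   derived columns), `shortlist` (variants passing the mandatory
#'   filters), `candidates` (final ranked candidates), `model`
#' @export
run_cascade <- function(v, model, thresholds = qc_thresholds(),
                        known_table = known_mutations(),
                        compound_het = FALSE) {
  v <- annotated_variants(as.data.frame(v, stringsAsFactors = FALSE))
  if (inherits(model, "pedigree")) model <- model$inheritance_model
  model <- match.arg(model, c("AR", "AD"))
  n <- nrow(v)

  freq <- frequency_filter(v, thresholds)
  subpop <- subpop_frequency_filter(v, thresholds)
  qc <- genotype_qc(v, thresholds)
  eligible <- v$function_class %in% c("nonsynonymous_snp", "splice_site")
  consensus <- predictor_consensus(v)
  inherit_ok <- inheritance_filter(v, model, compound_het)
  artifact <- variant_class(v$ref %||% "A", v$alt %||% "A") == "indel" &
    isTRUE_vec(v$homopolymer_indel) & isTRUE_vec(v$multiallelic)

  mx_overall <- row_max(v, grep("^maf_", names(v), value = TRUE))
  mx_subpop <- row_max(v, grep("^subpopmaf_", names(v), value = TRUE))
  trail <- rbind(
    data.frame(variant_id = v$variant_id, filter = "frequency",
               verdict = freq,
               reason = ifelse(is.na(mx_overall), "no frequency data",
                               sprintf("max overall MAF %.4g", mx_overall))),
    data.frame(variant_id = v$variant_id, filter = "subpop_frequency",
               verdict = subpop,
               reason = ifelse(is.na(mx_subpop), "no sub-population data",
                               sprintf("max sub-population MAF %.4g",
                                       mx_subpop))),
    data.frame(variant_id = v$variant_id, filter = "genotype_qc",
               verdict = qc,
               reason = sprintf("GQ %.3g, depth %.3g", v$genotype_quality,
                                v$site_depth)),
    data.frame(variant_id = v$variant_id, filter = "functional_class",
               verdict = ifelse(eligible, "pass", "not_applicable"),
               reason = v$function_class),
    data.frame(variant_id = v$variant_id, filter = "predictor_consensus",
               verdict = ifelse(consensus == "strong", "pass",
                                ifelse(consensus == "weak",
                                       "not_applicable", "fail")),
               reason = sprintf("consensus %s (ensemble p=%s)", consensus,
                                ifelse(is.na(v$kgg_p), "NA",
                                       format(v$kgg_p, digits = 3)))),
    data.frame(variant_id = v$variant_id, filter = "inheritance",
               verdict = ifelse(inherit_ok, "pass", "fail"),
               reason = sprintf("%s under %s model", v$genotype, model)))
  trail$verdict <- as.character(trail$verdict)

  v$consensus <- consensus
  v$known_id <- known_mutation_lookup(v, known_table)
  v$suspected_artifact <- artifact
  mandatory <- freq == "pass" & subpop == "pass" & qc == "pass"
  shortlist <- v[mandatory, , drop = FALSE]
  cand <- v[mandatory & eligible & consensus == "strong" & inherit_ok, ,
            drop = FALSE]
  if (nrow(cand)) {
    ## candidates are all strong-consensus; rank by ensemble probability
    cand <- cand[order(-ifelse(is.na(cand$kgg_p), -Inf, cand$kgg_p)), ,
                 drop = FALSE]
  }
  structure(list(trail = trail, variants = v, shortlist = shortlist,
                 candidates = cand, model = model,
                 thresholds = thresholds),
            class = "shortlist_report")
}

isTRUE_vec <- function(x) if (is.null(x)) FALSE else !is.na(x) & x

#' @export
print.shortlist_report <- function(x, ...) {
  cat(sprintf("prioritization cascade (%s model): %d variants in, %d shortlisted, %d candidate(s)\n",
              x$model, nrow(x$variants), nrow(x$shortlist),
              nrow(x$candidates)))
  if (nrow(x$candidates)) {
    d <- x$candidates
    cat("candidates:\n")
    for (i in seq_len(nrow(d))) {
      cat(sprintf("  %s %s (%s, %s; ensemble p=%s%s)\n", d$gene[i],
                  d$hgvs_c[i], d$function_class[i], d$genotype[i],
                  format(d$kgg_p[i], digits = 3),
                  ifelse(is.na(d$known_id[i]), "",
                         paste0("; known ", d$known_id[i]))))
    }
  }
  invisible(x)
}

#' Pedigree segregation check for one variant
#'
#' Verifies Mendelian transmission of the observed genotypes and their
#' compatibility with the pedigree's inheritance model. Under AR every
#' affected member must be homozygous-alternate (with carrier parents);
#' under AD every affected member must carry the allele, and unaffected
#' carriers downgrade the verdict to consistency under incomplete
#' penetrance rather than inconsistency.
#'
#' @param genotypes named character vector (member id -> `hom_ref`, `het`,
#'   `hom_alt`) for at least two members
#' @param ped a [pedigree()]
#' @return one of `"consistent"`, `"consistent_with_incomplete_penetrance"`,
#'   `"inconsistent"`
#' @export
segregation_check <- function(genotypes, ped) {
  stopifnot(inherits(ped, "pedigree"), length(genotypes) >= 2L)
  mem <- ped$members
  ids <- intersect(mem$id, names(genotypes))
  g <- genotypes[ids]
  ## Mendelian transmission among genotyped trios
  n_alt <- c(hom_ref = 0L, het = 1L, hom_alt = 2L)
  can_give <- list(hom_ref = 0L, het = 0:1, hom_alt = 1L)
  for (id in ids) {
    k <- match(id, mem$id)
    f <- mem$father[k]; m <- mem$mother[k]
    fa <- if (!is.na(f) && f %in% ids) can_give[[g[f]]] else 0:1
    mo <- if (!is.na(m) && m %in% ids) can_give[[g[m]]] else 0:1
    if (!n_alt[[g[id]]] %in% outer(fa, mo, `+`)) return("inconsistent")
  }
  aff <- ids[mem$affected[match(ids, mem$id)] == "yes"]
  unaff <- ids[mem$affected[match(ids, mem$id)] == "no"]
  if (ped$inheritance_model == "AR") {
    if (any(g[aff] != "hom_alt")) return("inconsistent")
    if (any(g[unaff] == "hom_alt")) return("inconsistent")
    "consistent"
  } else {
    if (any(g[aff] == "hom_ref")) return("inconsistent")
    if (any(g[unaff] != "hom_ref"))
      "consistent_with_incomplete_penetrance"
    else "consistent"
  }
}

#' Write the shortlist report as TSV
#'
#' @param report a `shortlist_report`
#' @param path output file
#' @export
write_shortlist_tsv <- function(report, path) {
  utils::write.table(report$variants, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Read / write annotated variant TSV
#'
#' @param path TSV file following the [annotated_variants()] dictionary
#' @return an `annotated_variants` data.frame
#' @export
read_annotated_tsv <- function(path) {
  annotated_variants(utils::read.delim(path, stringsAsFactors = FALSE,
                                       na.strings = c("NA", "")))
}

#' @rdname read_annotated_tsv
#' @param v an `annotated_variants` table
#' @export
write_annotated_tsv <- function(v, path) {
  utils::write.table(v, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}
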