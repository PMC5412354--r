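#' Run configuration for the end-to-end experiment
#'
#' One serializable object holding every parameter of the canned
#' panel-depth experiment. All stage seeds are derived deterministically
#' from the single top-level `seed`.
#'
#' @param seed top-level integer seed
#' @param n_genes,exons_per_gene,exon_len,pad_bp panel geometry (see
#'   [build_panel()])
#' @param n_snps,n_indels planted truth-set size
#' @param mean_target_coverage,error_rate,capture_cv sequencing regime
#'   (see [simulate_reads()])
#' @param fractions,replicates down-sampling grid (see [grid_config()])
#' @param qual_threshold caller confidence threshold
#' @param inheritance_model `"AR"` or `"AD"` family for the prioritization
#'   stage
#' @param outdir output directory
#' @param plot also write a rarefaction plot (PDF; never load-bearing)
#' @return object of class `run_config`
#' @export
run_config <- function(seed = 1, n_genes = 27, exons_per_gene = 5,
                       exon_len = 200, pad_bp = 100, n_snps = 162,
                       n_indels = 42, mean_target_coverage = 213.4,
                       error_rate = 0.005, capture_cv = 0.75,
                       fractions = seq(1, 0.05, by = -0.05),
                       replicates = 10, qual_threshold = 50,
                       inheritance_model = "AR", outdir = "paneldepth_run",
                       plot = TRUE) {
  cfg <- list(seed = as.integer(seed), n_genes = n_genes,
              exons_per_gene = exons_per_gene, exon_len = exon_len,
              pad_bp = pad_bp, n_snps = n_snps, n_indels = n_indels,
              mean_target_coverage = mean_target_coverage,
              error_rate = error_rate, capture_cv = capture_cv,
              fractions = fractions, replicates = replicates,
              qual_threshold = qual_threshold,
              inheritance_model = inheritance_model,
              outdir = outdir, plot = isTRUE(plot))
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  allowed <- c("seed", "n_genes", "exons_per_gene", "exon_len", "pad_bp",
               "n_snps", "n_indels", "mean_target_coverage", "error_rate",
               "capture_cv", "fractions", "replicates", "qual_threshold",
               "inheritance_model", "outdir", "plot")
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown))
    stop("validation error: unknown config key(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  missing <- setdiff(allowed, names(cfg))
  if (length(missing))
    stop("validation error: missing config key(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  cfg$seed <- assert_count(cfg$seed, "seed")
  assert_count(cfg$n_genes, "n_genes", min = 1L)
  assert_scalar_number(cfg$mean_target_coverage, "mean_target_coverage",
                       min = 0, allow_min = FALSE)
  assert_scalar_number(cfg$error_rate, "error_rate", min = 0, max = 0.25,
                       allow_max = FALSE)
  if (!cfg$inheritance_model %in% c("AR", "AD"))
    stop("validation error: inheritance_model must be AR or AD",
         call. = FALSE)
  stopifnot(all(cfg$fractions > 0), all(cfg$fractions <= 1))
  structure(cfg, class = "run_config")
}

#' Read / write a run configuration (JSON)
#'
#' @param path JSON file
#' @return a `run_config`
#' @export
read_run_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  validate_run_config(cfg)
}

#' @rdname read_run_config
#' @param cfg a `run_config`
#' @export
write_run_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Run the complete panel-depth experiment
#'
#' Wires every stage together: synthesize the panel world (reference,
#' targets, truth variants, pedigree genotypes), simulate proband reads,
#' call variants at full coverage, benchmark against the planted truth,
#' run the down-sampling rarefaction grid with C95 brackets and
#' per-causal-variant minimal callable fractions, and run the
#' prioritization cascade on a synthetic annotation table. All artifacts
#' are written under `config$outdir`; a manifest records seeds, stage
#' timings and the variant counts after every stage. Rerunning with an
#' identical configuration reproduces every emitted table byte for byte.
#'
#' @param config a [run_config()]
#' @return (invisibly) a list with all in-memory stage results and
#'   `manifest`
#' @export
replicate_experiment <- function(config = run_config()) {
  config <- validate_run_config(config)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  out <- function(...) file.path(config$outdir, ...)
  manifest <- list(package_version = as.character(utils::packageVersion("paneldepth")),
                   seed = config$seed, stages = list())
  log_lines <- character(0)
  note <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, msg)
    message(msg)
  }
  timed <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
           call. = FALSE))
    manifest$stages[[stage]] <<- list(seed = derive_seed(config$seed, stage),
                                      elapsed_s = round(proc.time()[["elapsed"]] - t0, 2))
    res
  }

  panel <- timed("panel", build_panel(
    n_genes = config$n_genes, exons_per_gene = config$exons_per_gene,
    exon_len = config$exon_len, pad_bp = config$pad_bp,
    seed = derive_seed(config$seed, "panel")))
  write_panel_fasta(panel, out("reference.fasta"))
  write_targets_bed(panel, out("targets.bed"))
  note("panel: %d genes, padded target %d bp", config$n_genes,
       panel$target_bp)

  truth <- timed("variants", plant_variants(
    panel, n_snps = config$n_snps, n_indels = config$n_indels,
    seed = derive_seed(config$seed, "variants")))
  ped <- if (config$inheritance_model == "AR") case1_pedigree()
         else case2_pedigree()
  causal_id <- if (nrow(truth)) truth$id[match("snp", truth$class)] else NULL
  geno <- timed("pedigree", assign_pedigree_genotypes(
    truth, ped, causal_variant_id = causal_id,
    seed = derive_seed(config$seed, "pedigree")))
  proband <- attr(geno, "proband_id")
  truth$depth <- NULL
  write_vcf(truth, out("truth.vcf"), panel, genotypes = t(geno))
  write_ped(ped, out("family.ped"))
  note("truth: %d SNPs + %d indels; proband %s",
       sum(truth$class == "snp"), sum(truth$class == "indel"), proband)

  rs <- timed("reads", simulate_reads(
    panel, truth, genotypes = geno[proband, ],
    mean_target_coverage = config$mean_target_coverage,
    error_rate = config$error_rate, capture_cv = config$capture_cv,
    member_id = proband, seed = derive_seed(config$seed, "reads")))
  covm <- coverage_metrics(rs, panel)
  note("reads: %d pairs; realized mean coverage %.1fx (>=50x: %.2f%%)",
       nrow(rs$reads) / 2, covm$mean_target_coverage, covm$pct_ge_50x)

  model <- caller_model(error_rate = config$error_rate,
                        qual_threshold = config$qual_threshold)
  calls <- timed("call", call_variants(rs, panel, model))
  write_vcf(calls, out("calls.vcf"), panel,
            genotypes = matrix(calls$genotype, ncol = 1,
                               dimnames = list(NULL, proband)))
  note("calls: %d variants (%d SNPs, %d indels) at QUAL >= %g",
       nrow(calls), sum(calls$class == "snp"), sum(calls$class == "indel"),
       config$qual_threshold)

  ## truth restricted to alleles the proband actually carries
  carried <- truth[geno[proband, truth$id] != "hom_ref", , drop = FALSE]
  bench <- timed("benchmark", match_and_score(calls, carried))
  write_benchmark_tsv(bench, out("benchmark.tsv"))
  note("benchmark: SNV recall %.2f%% / precision %.2f%%; indel recall %.2f%%",
       bench$recall[1], bench$precision[1], bench$recall[2])

  grid <- grid_config(fractions = config$fractions,
                      replicates = config$replicates,
                      base_seed = derive_seed(config$seed, "grid"))
  rar <- timed("rarefaction", run_grid(rs, panel, model, grid,
                                       mean_target_coverage = covm$mean_target_coverage))
  write_rarefaction_tsv(rar, out("rarefaction.tsv"))
  c95 <- list(snp = estimate_c95(rar, "snp"),
              indel = estimate_c95(rar, "indel"))
  c95_df <- do.call(rbind, lapply(c95, function(b)
    data.frame(variant_class = b$variant_class,
               lower_coverage = b$lower_coverage %||% NA_integer_,
               upper_coverage = b$upper_coverage %||% NA_integer_,
               crossed = b$crossed)))
  utils::write.table(c95_df, out("c95.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  for (cls in c("snp", "indel")) {
    b <- c95[[cls]]
    if (b$crossed)
      note("C_%s95 bracket: %dx - %dx", cls, b$lower_coverage,
           b$upper_coverage)
    else note("C_%s95: 95%% threshold not crossed", cls)
  }
  if (isTRUE(config$plot)) {
    tryCatch({
      grDevices::pdf(out("rarefaction.pdf"), width = 7, height = 5)
      plot_rarefaction(rar)
      grDevices::dev.off()
    }, error = function(e) note("plot skipped: %s", conditionMessage(e)))
  }

  ## minimal callable fraction for the causal variant
  min_frac <- NULL
  if (!is.null(causal_id)) {
    ci <- match(variant_key(truth[truth$id == causal_id, ]),
                variant_key(rar$pseudo_truth))
    if (!is.na(ci)) {
      min_frac <- min_fraction_all_replicates(ci, rar)
      note("causal variant callable in all replicates from fraction %s (%.1fx; site depth %.1fx)",
           format(min_frac$fraction), min_frac$effective_coverage,
           min_frac$mean_site_depth)
    }
  }

  ann <- timed("prioritize", synth_annotations(
    model = config$inheritance_model,
    seed = derive_seed(config$seed, "prioritize")))
  report <- run_cascade(ann, config$inheritance_model)
  write_shortlist_tsv(report, out("shortlist.tsv"))
  note("cascade: %d in, %d shortlisted, %d candidate(s)", nrow(ann),
       nrow(report$shortlist), nrow(report$candidates))

  manifest$config <- unclass(config)
  manifest$coverage <- unclass(covm)
  manifest$counts <- list(
    truth_snps = sum(truth$class == "snp"),
    truth_indels = sum(truth$class == "indel"),
    calls_snps = sum(calls$class == "snp"),
    calls_indels = sum(calls$class == "indel"),
    shortlisted = nrow(report$shortlist),
    candidates = nrow(report$candidates))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  writeLines(log_lines, out("run.log"))

  invisible(list(panel = panel, truth = truth, pedigree = ped,
                 genotypes = geno, reads = rs, coverage = covm,
                 calls = calls, benchmark = bench, rarefaction = rar,
                 c95 = c95, min_fraction_causal = min_frac,
                 shortlist = report, manifest = manifest))
}
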