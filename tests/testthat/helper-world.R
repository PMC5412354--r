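# Shared fixtures, built once per test run and memoized. The "full world"
# mirrors the default experiment (27-gene / 54 kb panel at ~213x); smaller
# worlds keep unit tests fast.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

tiny_panel <- function() memo("tiny_panel",
  build_panel(n_genes = 3, exons_per_gene = 3, exon_len = 150, pad_bp = 50,
              exon_gap = 400, seed = 11))

# mid-sized world for read-level statistics (~21 kb padded target)
mid_world <- function() memo("mid_world", {
  pw <- build_panel(n_genes = 7, exons_per_gene = 5, exon_len = 200,
                    pad_bp = 100, seed = 21)
  v <- plant_variants(pw, n_snps = 60, n_indels = 15, seed = 22)
  ped <- case1_pedigree()
  g <- assign_pedigree_genotypes(v, ped, causal_variant_id = v$id[1],
                                 seed = 23)
  pro <- attr(g, "proband_id")
  rs <- simulate_reads(pw, v, genotypes = g[pro, ],
                       mean_target_coverage = 120, error_rate = 0.005,
                       member_id = pro, seed = 24)
  list(panel = pw, variants = v, ped = ped, genotypes = g, proband = pro,
       reads = rs, model = caller_model(error_rate = 0.005))
})

# the stated full-scale world: 27 genes, 162 SNPs + 42 indels, 213.4x
full_world <- function() memo("full_world", {
  pw <- build_panel(seed = 101)
  v <- plant_variants(pw, n_snps = 162, n_indels = 42, seed = 102)
  ped <- case1_pedigree()
  g <- assign_pedigree_genotypes(v, ped, causal_variant_id = v$id[1],
                                 seed = 103)
  pro <- attr(g, "proband_id")
  rs <- simulate_reads(pw, v, genotypes = g[pro, ],
                       mean_target_coverage = 213.4, error_rate = 0.005,
                       member_id = pro, seed = 104)
  list(panel = pw, variants = v, ped = ped, genotypes = g, proband = pro,
       reads = rs, model = caller_model(error_rate = 0.005))
})

# full down-sampling grid over the full world (the expensive fixture;
# built at most once per run)
full_grid <- function() memo("full_grid", {
  w <- full_world()
  covm <- coverage_metrics(w$reads, w$panel)
  rar <- run_grid(w$reads, w$panel, w$model,
                  grid_config(base_seed = 7), covm$mean_target_coverage)
  list(world = w, coverage = covm, rar = rar)
})

# hand-built read set: reads placed at given starts on the reference
# haplotype (no variants, no errors); read_len may differ from the
# simulator default
manual_read_set <- function(panel, chrom, starts, read_len) {
  haps <- paneldepth:::build_member_haplotypes(panel, NULL, NULL, 1)
  n <- length(starts)
  reads <- data.frame(pair_id = seq_len(n), mate = 1L, chrom = chrom,
                      hap = 1L, hap_start = as.integer(starts),
                      stringsAsFactors = FALSE)
  structure(list(reads = reads,
                 errors = data.frame(row = integer(0), offset = integer(0),
                                     d = integer(0)),
                 slips = NULL, haps = haps, read_len = as.integer(read_len),
                 member_id = "M1", mean_target_coverage = NA,
                 error_rate = 0, cache = new.env(parent = emptyenv())),
            class = "read_set")
}
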