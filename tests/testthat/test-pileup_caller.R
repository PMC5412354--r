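test_that("pileup counts every on-target base exactly once", {
  pw <- build_panel(n_genes = 1, exons_per_gene = 1, exon_len = 300,
                    pad_bp = 0, seed = 61)
  a <- GenomicRanges::start(pw$targets)[1]
  ## ten identical reference reads over one window
  rs <- manual_read_set(pw, pw$genes$chrom[1], rep(a, 10), read_len = 50)
  pu <- build_pileup(rs, pw)
  covered <- pu$pos >= a & pu$pos < a + 50
  expect_true(all(pu$depth[covered] == 10))
  expect_true(all(pu$depth[!covered] == 0))
  ## all support on the reference base
  refc <- paneldepth:::seq_to_int(as.character(pw$reference[[1]]))
  for (p in which(covered)) {
    ref_letter <- c("A", "C", "G", "T")[refc[pu$pos[p]]]
    expect_equal(pu[[ref_letter]][p], 10)
  }
  ## empty read selection gives an all-zero pileup
  expect_true(all(paneldepth:::pileup_counts(rs, pw, integer(0)) == 0))
})

test_that("genotype_site matches the brute-force likelihood oracle (depth <= 12)", {
  model <- caller_model(error_rate = 0.01)
  for (d in 1:12) {
    for (a in 0:d) {
      got <- paneldepth:::genotype_counts(d - a, a, model)
      want <- genotype_oracle(d - a, a, e = 0.01)
      expect_equal(unname(c(got$post_hom_ref, got$post_het,
                            got$post_hom_alt)),
                   want$posterior, tolerance = 1e-9)
      expect_equal(got$qual, want$qual, tolerance = 1e-9)
      expect_identical(got$genotype, want$genotype)
    }
  }
})

test_that("genotype_site handles canonical columns and edge cases", {
  model <- caller_model(error_rate = 0.01)
  ## pure alternate support: hom_alt, qual from direct evaluation
  col <- c(A = 0, C = 0, G = 0, T = 10)
  g <- genotype_site(col, model, ref_base = "A")
  o <- genotype_oracle(0, 10, 0.01)
  expect_identical(g$genotype, "hom_alt")
  expect_equal(g$qual, o$qual, tolerance = 1e-9)
  ## pure reference support: confidently hom_ref, not emittable
  g <- genotype_site(c(A = 10, C = 0, G = 0, T = 0), model, "A")
  expect_identical(g$genotype, "hom_ref")
  expect_gt(g$posterior[["hom_ref"]], 0.998)
  expect_equal(g$posterior[["hom_ref"]],
               genotype_oracle(10, 0, 0.01)$posterior[1], tolerance = 1e-9)
  ## balanced support: het wins by symmetry
  g <- genotype_site(c(A = 5, C = 0, G = 5, T = 0), model, "A")
  expect_identical(g$genotype, "het")
  expect_identical(g$alt_base, "G")
  ## alt tie broken alphabetically
  g <- genotype_site(c(A = 6, C = 3, G = 3, T = 0), model, "A")
  expect_identical(g$alt_base, "C")
  ## zero depth: no-call signal
  expect_warning(g <- genotype_site(c(A = 0, C = 0, G = 0, T = 0),
                                    model, "A"), "no-call")
  expect_null(g)
})

test_that("confidence is monotone in depth at fixed allele balance", {
  model <- caller_model(error_rate = 0.01)
  quals <- vapply(seq(2, 80, by = 2), function(d)
    paneldepth:::genotype_counts(d / 2, d / 2, model)$qual, numeric(1))
  expect_true(all(diff(quals) >= -1e-9))
  ## hom_alt support likewise
  quals2 <- vapply(1:60, function(d)
    paneldepth:::genotype_counts(0, d, model)$qual, numeric(1))
  expect_true(all(diff(quals2) >= -1e-9))
})

test_that("minimum alt count for qual >= 50 matches analytic recomputation", {
  e <- 0.01
  model <- caller_model(error_rate = e, qual_threshold = 50)
  for (d in c(10, 20, 40, 60)) {
    ## analytic scan with the oracle, independent of the vectorized path
    amin_oracle <- NA
    for (a in 0:d) {
      if (genotype_oracle(d - a, a, e)$qual >= 50) { amin_oracle <- a; break }
    }
    quals <- vapply(0:d, function(a)
      paneldepth:::genotype_counts(d - a, a, model)$qual, numeric(1))
    amin <- (0:d)[which(quals >= 50)[1]]
    expect_identical(amin, amin_oracle)
  }
})

test_that("hom variants become reliably callable at lower depth than hets", {
  ## minimal depth at which qual >= 50 and a non-ref genotype is reached in
  ## >= 95% of replicate binomial draws
  model <- caller_model(error_rate = 0.01, qual_threshold = 50)
  min_reliable_depth <- function(p_alt) {
    set.seed(99)
    for (d in 1:60) {
      alt <- stats::rbinom(400, d, p_alt)
      g <- paneldepth:::genotype_counts(d - alt, alt, model)
      if (mean(g$qual >= 50 & g$genotype != "hom_ref") >= 0.95) return(d)
    }
    Inf
  }
  d_hom <- min_reliable_depth(1 - 0.01)
  d_het <- min_reliable_depth(0.5)
  expect_lte(d_hom, d_het)
  expect_gt(d_het, d_hom)   # the gap itself mirrors hom 5.4x vs het 16.4x
})

test_that("call_variants recovers planted variants and respects the contract", {
  w <- mid_world()
  calls <- call_variants(w$reads, w$panel, w$model)
  carried <- w$variants[w$genotypes[w$proband, w$variants$id] != "hom_ref", ]
  res <- match_and_score(calls, carried)
  expect_gte(res$recall[res$variant_class == "snp"], 99)
  expect_gte(res$recall[res$variant_class == "indel"], 90)
  expect_gte(res$precision[res$variant_class == "snp"], 99)

  ## calls sorted, on-target, above threshold
  expect_true(all(calls$qual >= w$model$qual_threshold))
  gr <- GenomicRanges::GRanges(calls$chrom,
                               IRanges::IRanges(calls$pos, calls$pos))
  expect_true(all(IRanges::overlapsAny(gr, w$panel$targets)))
  o <- paneldepth:::order_variants(calls, w$panel$genes$chrom)
  expect_identical(o, seq_len(nrow(calls)))

  ## an unreachable threshold silences the caller
  strict <- caller_model(error_rate = 0.005, qual_threshold = Inf)
  expect_identical(nrow(call_variants(w$reads, w$panel, strict)), 0L)

  ## calls are VCF-writable and re-readable
  p <- file.path(withr::local_tempdir(), "calls.vcf")
  write_vcf(calls, p, w$panel,
            genotypes = matrix(calls$genotype, ncol = 1,
                               dimnames = list(NULL, w$proband)))
  back <- read_vcf(p)
  expect_identical(back[c("chrom", "pos", "ref", "alt")],
                   as.data.frame(calls)[c("chrom", "pos", "ref", "alt")])
  expect_equal(back$qual, calls$qual)
})

test_that("variants planted outside the padded targets are never called", {
  pw <- build_panel(n_genes = 1, exons_per_gene = 2, exon_len = 150,
                    pad_bp = 50, exon_gap = 500, seed = 71)
  ## hand-plant a variant in the unpadded gap between the two exons
  e1_end <- GenomicRanges::end(pw$targets)[1]
  e2_start <- GenomicRanges::start(pw$targets)[2]
  gap_pos <- e1_end + 150L
  stopifnot(gap_pos < e2_start - 50L)
  refc <- paneldepth:::seq_to_int(as.character(pw$reference[[1]]))
  off_target <- data.frame(
    chrom = pw$genes$chrom[1], pos = gap_pos,
    ref = c("A", "C", "G", "T")[refc[gap_pos]],
    alt = c("C", "G", "T", "A")[refc[gap_pos]],
    class = "snp", id = "off1", stringsAsFactors = FALSE)
  rs <- simulate_reads(pw, off_target, genotypes = c(off1 = "hom_alt"),
                       mean_target_coverage = 150, error_rate = 0,
                       capture_cv = 0, seed = 72)
  calls <- call_variants(rs, pw, caller_model(error_rate = 0.005))
  expect_false(any(calls$pos == gap_pos))
})
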