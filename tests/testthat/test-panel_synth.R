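test_that("panel geometry matches an independent interval-union oracle", {
  pw <- build_panel(n_genes = 27, exons_per_gene = 5, exon_len = 200,
                    pad_bp = 100, seed = 1)
  expect_equal(nrow(pw$genes), 27)
  expect_equal(length(pw$exons), 27 * 5)

  ## recompute the padded target length from the emitted BED with a
  ## sort-and-scan union oracle, per chromosome
  bed <- file.path(withr::local_tempdir(), "targets.bed")
  write_targets_bed(pw, bed)
  raw <- read.table(bed, sep = "\t", stringsAsFactors = FALSE)
  expect_true(all(raw[[2]] >= 0))                    # 0-based starts on disk
  by_chr <- split(raw, raw[[1]])
  oracle_total <- sum(vapply(by_chr, function(d)
    union_length_oracle(d[[2]] + 1L, d[[3]]), integer(1)))
  expect_identical(oracle_total, pw$target_bp)
  ## spaced exons with 100 bp pads: no merging, every exon contributes
  ## exon_len + 2 * pad
  expect_identical(pw$target_bp, 27L * 5L * (200L + 200L))

  ## round trip through rtracklayer preserves the intervals
  back <- read_targets_bed(bed)
  expect_equal(GenomicRanges::start(back), GenomicRanges::start(pw$targets))
  expect_equal(GenomicRanges::end(back), GenomicRanges::end(pw$targets))
})

test_that("close exons merge through their pads; degenerate panels work", {
  ## exons 150 bp apart with 100 bp pads must merge into one interval
  pw <- build_panel(n_genes = 2, exons_per_gene = 2, exon_len = 200,
                    pad_bp = 100, exon_gap = 150, seed = 2)
  expect_equal(length(pw$targets), 2)                # one block per gene
  expect_equal(unique(GenomicRanges::width(pw$targets)),
               100L + 200L + 150L + 200L + 100L)

  one <- build_panel(n_genes = 1, exons_per_gene = 1, exon_len = 100,
                     pad_bp = 0, seed = 3)
  expect_equal(length(one$targets), 1)
  expect_identical(one$target_bp, 100L)

  expect_error(build_panel(n_genes = 0), "n_genes")
  expect_error(build_panel(exon_len = 5), "exon_len")
})

test_that("panel world is deterministic for a fixed seed and FASTA-writable", {
  a <- build_panel(n_genes = 2, seed = 5)
  b <- build_panel(n_genes = 2, seed = 5)
  expect_identical(as.character(a$reference), as.character(b$reference))
  fa <- file.path(withr::local_tempdir(), "ref.fasta")
  write_panel_fasta(a, fa)
  back <- Biostrings::readDNAStringSet(fa)
  expect_identical(as.character(back), as.character(a$reference))
})

test_that("planted variants honor counts, normalization and determinism", {
  pw <- tiny_panel()
  v <- plant_variants(pw, n_snps = 25, n_indels = 8, seed = 4)
  expect_equal(sum(v$class == "snp"), 25)
  expect_equal(sum(v$class == "indel"), 8)
  expect_true(all(v$ref != v$alt))
  ## snp <=> both alleles length 1
  expect_identical(v$class == "snp", nchar(v$ref) == 1 & nchar(v$alt) == 1)
  ## every variant lies inside a padded interval
  gr <- GenomicRanges::GRanges(v$chrom, IRanges::IRanges(v$pos, v$pos))
  expect_true(all(IRanges::overlapsAny(gr, pw$targets)))
  ## already left-normalized: renormalizing is a no-op
  for (i in which(v$class == "indel")) {
    ci <- match(v$chrom[i], pw$genes$chrom)
    nv <- normalize_variant(v$pos[i], v$ref[i], v$alt[i],
                            as.character(pw$reference[[ci]]))
    expect_identical(nv, list(pos = v$pos[i], ref = v$ref[i],
                              alt = v$alt[i]))
  }
  expect_identical(v, plant_variants(pw, n_snps = 25, n_indels = 8,
                                     seed = 4))
  expect_error(plant_variants(pw, n_snps = 5000, n_indels = 0, seed = 1),
               "capacity")
})

test_that("truth VCF round-trips through a standard parser", {
  pw <- tiny_panel()
  v <- plant_variants(pw, n_snps = 10, n_indels = 5, seed = 6)
  g <- assign_pedigree_genotypes(v, case1_pedigree(),
                                 causal_variant_id = v$id[1], seed = 7)
  dir <- withr::local_tempdir()
  p1 <- file.path(dir, "truth.vcf")
  write_vcf(v, p1, pw, genotypes = t(g))
  back <- read_vcf(p1)
  cols <- c("chrom", "pos", "ref", "alt", "class")
  expect_identical(back[cols], as.data.frame(v)[cols])
  expect_identical(attr(back, "genotypes"),
                   matrix(t(g), ncol = nrow(g),
                          dimnames = list(NULL, rownames(g))))

  ## byte-identical emission for identical inputs
  p2 <- file.path(dir, "truth2.vcf")
  write_vcf(v, p2, pw, genotypes = t(g))
  expect_identical(readLines(p1), readLines(p2))

  ## empty truth set: valid header-only VCF
  p3 <- file.path(dir, "empty.vcf")
  write_vcf(v[0, ], p3, pw)
  expect_equal(nrow(read_vcf(p3)), 0)
})

test_that("left-normalization shifts indels to canonical leftmost form", {
  refseq <- "GATTTTC"
  ## deleting one T of the TTTT run, given right-shifted: anchors at the A
  nv <- normalize_variant(3, "TT", "T", refseq)
  expect_identical(nv, list(pos = 2L, ref = "AT", alt = "A"))
  ## inserting one T, given at the run's right end: same anchor
  nv <- normalize_variant(5, "T", "TT", refseq)
  expect_identical(nv, list(pos = 2L, ref = "A", alt = "AT"))
  ## SNP given with shared context collapses to the single differing base
  nv <- normalize_variant(3, "TTT", "TGT", refseq)
  expect_identical(nv, list(pos = 4L, ref = "T", alt = "G"))
  expect_error(normalize_variant(3, "TT", "TT", refseq), "identical")

  ## property: normalization preserves the edited sequence
  set.seed(42)
  for (i in 1:50) {
    ref0 <- paste(sample(c("A", "C", "G", "T"), 40, replace = TRUE),
                  collapse = "")
    pos <- sample(5:30, 1)
    len <- sample(1:4, 1)
    if (runif(1) < 0.5) {                  # deletion with sloppy context
      ref <- substr(ref0, pos, pos + len)
      alt <- substr(ref0, pos, pos)
    } else {                               # insertion
      ref <- substr(ref0, pos, pos)
      alt <- paste0(ref, paste(sample(c("A", "C", "G", "T"), len,
                                      replace = TRUE), collapse = ""))
    }
    nv <- normalize_variant(pos, ref, alt, ref0)
    expect_identical(apply_variant_oracle(ref0, nv$pos, nv$ref, nv$alt),
                     apply_variant_oracle(ref0, pos, ref, alt))
  }
})

test_that("pedigree genotype assignment is Mendelian and model-consistent", {
  pw <- tiny_panel()
  v <- plant_variants(pw, n_snps = 12, n_indels = 4, seed = 8)
  ped <- case1_pedigree()
  for (s in 1:5) {
    g <- assign_pedigree_genotypes(v, ped, causal_variant_id = v$id[3],
                                   seed = s)
    ## exhaustive transmission check across all members x variants
    expect_identical(nrow(check_mendelian(g, ped)), 0L)
    ## AR causal variant: affected hom_alt, obligate-carrier parents het,
    ## unaffected sibs never hom_alt
    causal <- g[, v$id[3]]
    expect_true(all(causal[c("II-1", "II-2")] == "hom_alt"))
    expect_true(all(causal[c("I-1", "I-2")] == "het"))
    expect_true(all(causal[c("II-3", "II-4", "II-5")] %in%
                      c("het", "hom_ref")))
    ## proband anchored as carrier of every variant
    expect_true(all(g[attr(g, "proband_id"), ] != "hom_ref"))
  }

  ## AD with incomplete penetrance: affected carry the allele; the
  ## carrier father may be unaffected
  ped2 <- case2_pedigree()
  g2 <- assign_pedigree_genotypes(v, ped2, causal_variant_id = v$id[1],
                                  proband_id = "II-1", seed = 9)
  expect_identical(nrow(check_mendelian(g2, ped2)), 0L)
  causal2 <- g2[, v$id[1]]
  expect_true(all(causal2[c("I-1", "II-1")] != "hom_ref"))

  expect_error(assign_pedigree_genotypes(v, ped, causal_variant_id = "nope"),
               "causal_variant_id")
})

test_that("check_mendelian flags an impossible transmission", {
  pw <- tiny_panel()
  v <- plant_variants(pw, n_snps = 3, n_indels = 0, seed = 10)
  ped <- case1_pedigree()
  g <- assign_pedigree_genotypes(v, ped, causal_variant_id = NULL, seed = 11)
  g["I-1", 1] <- "hom_ref"; g["I-2", 1] <- "hom_ref"
  g["II-3", 1] <- "hom_alt"
  bad <- check_mendelian(g, ped)
  expect_true(any(bad$member == "II-3" & bad$variant == colnames(g)[1]))
})

test_that("pedigree validation and PED round trip", {
  expect_error(pedigree(data.frame(id = "A", sex = "M", father = "B",
                                   mother = NA, affected = "no")),
               "unresolved")
  cyc <- data.frame(id = c("A", "B"), sex = "M",
                    father = c("B", "A"), mother = NA, affected = "no")
  expect_error(pedigree(cyc), "cycle")
  expect_error(pedigree(case1_pedigree()$members, "AR", penetrance = 0.5),
               "penetrance")

  ped <- case2_pedigree()
  p <- file.path(withr::local_tempdir(), "fam.ped")
  write_ped(ped, p)
  back <- read_ped(p, "AD", penetrance = 0.8)
  expect_identical(back$members, ped$members)

  ## a lone unaffected founder stays hom_ref with no causal override
  solo <- pedigree(data.frame(id = "F1", sex = "F", father = NA,
                              mother = NA, affected = "no"), "AR")
  pw <- tiny_panel()
  v <- plant_variants(pw, n_snps = 2, n_indels = 0, seed = 12)
  g <- assign_pedigree_genotypes(v, solo, proband_id = "F1", hom_frac = 0,
                                 seed = 13)
  expect_true(all(g %in% c("het", "hom_alt")))   # anchored proband carries
})

test_that("simulated reads hit the requested coverage and error structure", {
  w <- mid_world()
  pw <- w$panel
  expect_gt(pw$target_bp, 10000)
  covm <- coverage_metrics(w$reads, pw)
  ## realized mean on-target coverage within 5% of request (>= 10 kb target)
  expect_lt(abs(covm$mean_target_coverage - 120) / 120, 0.05)

  ## error-free reads from a reference-only member match the reference
  small <- build_panel(n_genes = 1, exons_per_gene = 2, exon_len = 150,
                       seed = 31)
  rs0 <- simulate_reads(small, NULL, mean_target_coverage = 8,
                        error_rate = 0, capture_cv = 0, seed = 32)
  seqs <- paneldepth:::read_sequences(rs0, small)
  refc <- as.character(small$reference[[1]])
  for (i in seq_along(seqs)) {
    st <- rs0$reads$hap_start[i]
    expect_identical(seqs[i], substr(refc, st, st + 99))
  }

  ## determinism
  rs_a <- simulate_reads(small, NULL, mean_target_coverage = 8,
                         error_rate = 0.01, seed = 33)
  rs_b <- simulate_reads(small, NULL, mean_target_coverage = 8,
                         error_rate = 0.01, seed = 33)
  expect_identical(rs_a$reads, rs_b$reads)
  expect_identical(rs_a$errors, rs_b$errors)

  ## mates always come in pairs
  expect_true(all(table(w$reads$reads$pair_id) == 2))

  expect_error(simulate_reads(small, mean_target_coverage = 0), "coverage")
  expect_error(simulate_reads(small, mean_target_coverage = 10,
                              error_rate = 0.3), "error_rate")
})

test_that("heterozygous sites show binomial allele balance in the pileup", {
  pw <- build_panel(n_genes = 1, exons_per_gene = 1, exon_len = 400,
                    seed = 41)
  v <- plant_variants(pw, n_snps = 1, n_indels = 0, seed = 42)
  g <- stats::setNames("het", v$id)
  rs <- simulate_reads(pw, v, genotypes = g, mean_target_coverage = 200,
                       error_rate = 0, capture_cv = 0, seed = 43)
  pu <- build_pileup(rs, pw)
  row <- pu[pu$pos == v$pos, ]
  d <- row$depth
  alt_frac <- row[[v$alt]] / d
  expect_gt(d, 120)
  ## 3-sigma binomial bound around 1/2
  expect_lt(abs(alt_frac - 0.5), 3 * sqrt(0.25 / d))
})

test_that("FASTQ output is well-formed and pairs align by name", {
  small <- build_panel(n_genes = 1, exons_per_gene = 1, exon_len = 200,
                       seed = 51)
  rs <- simulate_reads(small, NULL, mean_target_coverage = 10,
                       error_rate = 0.01, seed = 52)
  prefix <- file.path(withr::local_tempdir(), "reads")
  paths <- write_fastq(rs, small, prefix)
  r1 <- Biostrings::readDNAStringSet(paths[1], format = "fastq")
  r2 <- Biostrings::readDNAStringSet(paths[2], format = "fastq")
  expect_equal(length(r1), nrow(rs$reads) / 2)
  expect_equal(length(r1), length(r2))
  expect_identical(names(r1), names(r2))          # same pair order
  expect_true(all(Biostrings::width(r1) == 100))
  af <- Biostrings::alphabetFrequency(r1)
  expect_true(all(rowSums(af[, c("A", "C", "G", "T")]) == 100))
})
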