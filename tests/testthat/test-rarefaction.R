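test_that("pair subsampling is deterministic, pair-safe and binomial", {
  w <- mid_world()
  rs <- w$reads
  expect_identical(subsample_reads(rs, 1.0, seed = 1)$reads, rs$reads)
  s1 <- subsample_reads(rs, 0.3, seed = 5)
  s2 <- subsample_reads(rs, 0.3, seed = 5)
  expect_identical(s1$reads, s2$reads)
  ## mates never split
  expect_true(all(table(s1$reads$pair_id) == 2))
  ## kept-pair count within the 99.9% binomial interval
  n_pairs <- nrow(rs$reads) / 2
  kept <- nrow(subsample_reads(rs, 0.05, seed = 6)$reads) / 2
  bounds <- qbinom(c(5e-4, 1 - 5e-4), n_pairs, 0.05)
  expect_gte(kept, bounds[1]); expect_lte(kept, bounds[2])
  ## errors stay attached to their reads after subsampling
  if (nrow(s1$errors)) {
    expect_true(all(s1$errors$row >= 1 & s1$errors$row <= nrow(s1$reads)))
  }
  expect_error(subsample_reads(rs, 0), "fraction")
  expect_error(subsample_reads(rs, 1.2), "fraction")
})

test_that("recall counting matches keys and flags empty truth", {
  truth <- data.frame(chrom = "c1", pos = c(10L, 20L, 30L),
                      ref = c("A", "C", "GT"), alt = c("G", "T", "G"),
                      class = c("snp", "snp", "indel"),
                      stringsAsFactors = FALSE)
  expect_identical(compute_recall(truth, truth, "snp"),
                   list(count = 2L, recall = 1))
  calls <- truth[c(1, 3), ]
  r <- compute_recall(calls, truth, "snp")
  expect_identical(r$count, 1L)
  expect_equal(r$recall, 0.5)
  ## genotype differences are ignored by design
  calls$genotype <- "het"; truth$genotype <- "hom_alt"
  expect_identical(compute_recall(calls, truth, "indel")$count, 1L)
  expect_warning(r <- compute_recall(calls, truth[truth$class == "snp", ],
                                     "indel"), "undefined")
  expect_true(is.na(r$recall))
})

test_that("effective coverage rounds half-up to one decimal", {
  expect_equal(effective_coverage(1.0, 184.2), 184.2)
  expect_equal(effective_coverage(0.5, 100.1), 50.1)  # 50.05 rounds up
  expect_error(effective_coverage(0, 100))
})

test_that("the grid contract holds on a small world", {
  w <- mid_world()
  grid <- grid_config(fractions = c(1.0, 0.6, 0.3, 0.1), replicates = 3,
                      base_seed = 17)
  rar <- run_grid(w$reads, w$panel, w$model, grid)
  pts <- rar$points
  expect_setequal(unique(pts$class), c("snp", "indel"))
  expect_identical(nrow(pts), 8L)                       # 4 fractions x 2
  ## full-coverage recall is 100% by construction (pseudo-truth bias)
  full <- pts[pts$fraction == 1, ]
  expect_true(all(full$mean_recall_pct == 100))
  expect_true(all(full$sd_count == 0))
  ## replicate arrays have the declared shape
  expect_identical(dim(rar$detail[[1]]$present),
                   c(nrow(rar$pseudo_truth), 3L))
  ## stochastic monotonicity: recall non-increasing as fraction decreases,
  ## within 2 pooled SDs
  for (cls in c("snp", "indel")) {
    p <- pts[pts$class == cls, ]
    p <- p[order(-p$fraction), ]
    n_truth <- sum(rar$pseudo_truth$class == cls)
    for (i in seq_len(nrow(p) - 1)) {
      slack <- 2 * (p$sd_count[i] + p$sd_count[i + 1]) / n_truth * 100
      expect_gte(p$mean_recall_pct[i], p$mean_recall_pct[i + 1] - slack)
    }
  }
  ## exact replicate reproducibility with the same base seed
  rar2 <- run_grid(w$reads, w$panel, w$model, grid)
  expect_identical(rar$points, rar2$points)
})

test_that("C95 brackets come from adjacent grid fractions", {
  mkpts <- function(recall_by_fraction) {
    data.frame(class = "snp", fraction = as.numeric(names(recall_by_fraction)),
               effective_coverage = NA_real_,
               mean_count = NA_real_, sd_count = NA_real_,
               mean_recall_pct = unname(recall_by_fraction))
  }
  fr <- seq(1, 0.05, by = -0.05)
  ## crossing between 0.20 and 0.25 at mean coverage 213.4 -> (43, 53)
  rec <- setNames(ifelse(fr >= 0.25, 97, 80), fr)
  b <- estimate_c95(mkpts(rec), "snp", mean_target_coverage = 213.4)
  expect_true(b$crossed)
  expect_identical(b$lower_coverage, 43L)
  expect_identical(b$upper_coverage, 53L)
  expect_equal(b$upper_fraction - b$lower_fraction, 0.05, tolerance = 1e-9)

  ## all points above threshold: not crossed, boundary reported
  rec_hi <- setNames(rep(99, length(fr)), fr)
  b <- estimate_c95(mkpts(rec_hi), "snp", mean_target_coverage = 213.4)
  expect_false(b$crossed)
  expect_true(is.na(b$lower_coverage))
  expect_equal(b$upper_fraction, 0.05)

  ## never reaches threshold
  rec_lo <- setNames(rep(50, length(fr)), fr)
  b <- estimate_c95(mkpts(rec_lo), "snp", mean_target_coverage = 213.4)
  expect_false(b$crossed)
  expect_true(is.na(b$upper_coverage))

  ## noisy double crossing: highest crossing wins, with a warning
  rec_noisy <- setNames(ifelse(fr >= 0.5, 97,
                               ifelse(abs(fr - 0.3) < 1e-9, 96, 80)), fr)
  expect_warning(b <- estimate_c95(mkpts(rec_noisy), "snp",
                                   mean_target_coverage = 213.4),
                 "more than once")
  expect_equal(b$lower_fraction, 0.45)
  expect_equal(b$upper_fraction, 0.5)
})

test_that("minimal all-replicate fraction follows its definition", {
  truth <- data.frame(chrom = "c1", pos = c(5L, 9L), ref = "A", alt = "G",
                      class = "snp", stringsAsFactors = FALSE)
  mkdetail <- function(fraction, present_rows) {
    list(fraction = fraction,
         present = matrix(present_rows, nrow = 2, byrow = TRUE),
         site_depth = matrix(rep(round(100 * fraction), 6), nrow = 2))
  }
  fake <- structure(list(
    pseudo_truth = truth,
    detail = list(
      mkdetail(1.0, c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE)),
      mkdetail(0.10, c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE)),
      mkdetail(0.05, c(TRUE, FALSE, TRUE, TRUE, TRUE, TRUE))),
    mean_target_coverage = 213.4,
    grid = grid_config(fractions = c(1, 0.1, 0.05), replicates = 3)),
    class = "rarefaction_result")
  ## variant 1: absent once at 0.05, present in all replicates above -> 0.10
  r <- min_fraction_all_replicates(1, fake)
  expect_equal(r$fraction, 0.10)
  expect_equal(r$effective_coverage, 21.3)
  expect_equal(r$mean_site_depth, 10)
  ## variant 2: fails a replicate at 0.10 -> only 1.0 qualifies upward
  r2 <- min_fraction_all_replicates(2, fake)
  expect_equal(r2$fraction, 1.0)
  ## unknown variant errors
  expect_error(min_fraction_all_replicates(
    data.frame(chrom = "cX", pos = 1L, ref = "A", alt = "C"), fake),
    "not present")
})

test_that("coverage metrics reproduce hand-computed depth profiles", {
  pw <- build_panel(n_genes = 1, exons_per_gene = 1, exon_len = 200,
                    pad_bp = 0, seed = 81)
  a <- GenomicRanges::start(pw$targets)[1]
  ch <- pw$genes$chrom[1]
  ## uniform 10x: ten reads exactly tiling the 200 bp target
  rs <- manual_read_set(pw, ch, rep(a, 10), read_len = 200)
  m <- coverage_metrics(rs, pw)
  expect_equal(m$mean_target_coverage, 10)
  expect_equal(m$pct_ge_2x, 100)
  expect_equal(m$pct_ge_10x, 100)
  expect_equal(m$pct_ge_50x, 0)
  ## half the target at 60x, half at 4x
  rs2 <- manual_read_set(pw, ch, c(rep(a, 60), rep(a + 100, 4)),
                         read_len = 100)
  m2 <- coverage_metrics(rs2, pw)
  expect_equal(m2$mean_target_coverage, 32)
  expect_equal(m2$pct_ge_2x, 100)
  expect_equal(m2$pct_ge_10x, 50)
  expect_equal(m2$pct_ge_50x, 50)
  expect_true(m2$pct_ge_2x >= m2$pct_ge_10x,
              m2$pct_ge_10x >= m2$pct_ge_50x)
})
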