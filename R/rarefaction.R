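#' Down-sampling grid configuration
#'
#' The fraction grid of the depth-rarefaction experiment: descending from
#' 1.00 to 0.05 in steps of 0.05, with 10 replicate subsamples per
#' fraction. Replicate `r` uses seed `base_seed + r`, so the same replicate
#' index draws the same uniforms at every fraction (nested subsets — a
#' common-random-numbers scheme that smooths the recall curves without
#' biasing their level).
#'
#' @param fractions descending fractions in (0, 1]
#' @param replicates replicate subsamples per fraction
#' @param base_seed integer seed
#' @return object of class `grid_config`
#' @export
grid_config <- function(fractions = seq(1, 0.05, by = -0.05),
                        replicates = 10L, base_seed = 1L) {
  stopifnot(all(fractions > 0), all(fractions <= 1),
            !is.unsorted(rev(fractions), strictly = TRUE))
  assert_count(replicates, "replicates", min = 1L)
  structure(list(fractions = round(fractions, 10), replicates = as.integer(replicates),
                 base_seed = as.integer(base_seed)),
            class = "grid_config")
}

#' Randomly subsample a read set by fraction
#'
#' Each read pair is kept independently with probability `fraction`; mates
#' are never split. Emulates per-read downsampling in expectation while
#' sparing the caller any orphan-mate logic.
#'
#' @param rs a `read_set`
#' @param fraction keep probability in (0, 1]
#' @param seed integer seed (deterministic subset for a fixed seed)
#' @return a `read_set` containing the kept pairs
#' @export
subsample_reads <- function(rs, fraction, seed = 1) {
  assert_scalar_number(fraction, "fraction", min = 0, max = 1,
                       allow_min = FALSE)
  if (fraction == 1) return(rs)
  rows <- subsample_rows(rs, fraction, seed)
  out <- rs
  out$cache <- new.env(parent = emptyenv())   # cached indices are row-bound
  out$reads <- rs$reads[rows, , drop = FALSE]
  rownames(out$reads) <- NULL
  remap <- integer(nrow(rs$reads)); remap[rows] <- seq_along(rows)
  keep_err <- remap[rs$errors$row] > 0L
  out$errors <- rs$errors[keep_err, , drop = FALSE]
  out$errors$row <- remap[out$errors$row]
  if (!is.null(rs$slips)) {
    keep_sl <- remap[rs$slips$row] > 0L
    out$slips <- rs$slips[keep_sl, , drop = FALSE]
    out$slips$row <- remap[out$slips$row]
  }
  out
}

## row indices of the kept pairs (cheap path used inside the grid)
subsample_rows <- function(rs, fraction, seed) {
  pairs <- unique(rs$reads$pair_id)
  u <- with_seed(seed, stats::runif(length(pairs)))
  kept <- pairs[u < fraction]
  which(rs$reads$pair_id %in% kept)
}

#' Effective coverage of a subsampling fraction
#'
#' @param fraction subsampling fraction
#' @param mean_target_coverage full-data mean target coverage
#' @return `fraction * mean_target_coverage`, rounded half-up to 1 decimal
#' @examples
#' effective_coverage(0.05, 213.4)  # 10.7
#' @export
effective_coverage <- function(fraction, mean_target_coverage) {
  stopifnot(all(fraction > 0), all(mean_target_coverage > 0))
  round_half_up(fraction * mean_target_coverage, 1)
}

#' Count recovered variants against a pseudo-truth set
#'
#' Matching is on (chromosome, position, ref, alt) of left-normalized
#' alleles; genotype is deliberately ignored (the rarefaction experiment
#' counts variants recovered, not genotype concordance).
#'
#' @param calls,pseudo_truth variant tables (`chrom`, `pos`, `ref`, `alt`,
#'   `class`)
#' @param class `"snp"` or `"indel"`
#' @return list with `count` (recovered) and `recall` (proportion; `NA`
#'   with a warning when the pseudo-truth holds no variant of the class)
#' @export
compute_recall <- function(calls, pseudo_truth, class = c("snp", "indel")) {
  class <- match.arg(class)
  tr <- pseudo_truth[pseudo_truth$class == class, , drop = FALSE]
  cl <- calls[calls$class == class, , drop = FALSE]
  if (nrow(tr) == 0L) {
    warning("undefined recall: pseudo-truth has no ", class, " records")
    return(list(count = 0L, recall = NA_real_))
  }
  n <- sum(variant_key(tr) %in% variant_key(cl))
  list(count = n, recall = n / nrow(tr))
}

#' Run the full down-sampling rarefaction grid
#'
#' Calls variants on the complete read set once (the pseudo-truth set),
#' then re-calls on random pair subsets over the fraction grid, recording
#' per-replicate recovered-variant counts per class. Summaries are printed
#' to 1 decimal (half-up), matching the conventional mean +/- SD
#' presentation of rarefaction tables.
#'
#' @param rs full `read_set`
#' @param panel the `panel_world`
#' @param model a [caller_model()]
#' @param grid a [grid_config()]
#' @param mean_target_coverage measured full-data coverage; computed with
#'   [coverage_metrics()] when omitted
#' @return object of class `rarefaction_result`: list with `points`
#'   (data.frame: class, fraction, effective_coverage, mean_count,
#'   sd_count, mean_recall_pct), `pseudo_truth`, `detail` (per-fraction
#'   presence/site-depth arrays), `mean_target_coverage`, `grid`
#' @export
run_grid <- function(rs, panel, model = caller_model(),
                     grid = grid_config(), mean_target_coverage = NULL) {
  stopifnot(inherits(grid, "grid_config"))
  if (is.null(mean_target_coverage)) {
    mean_target_coverage <- coverage_metrics(rs, panel)$mean_target_coverage
  }
  truth <- call_variants(rs, panel, model)
  if (nrow(truth) == 0L)
    stop("full-coverage call set is empty; nothing to rarefy", call. = FALSE)
  tkey <- variant_key(truth)
  toff <- panel_offsets(panel)
  tglob <- unname(toff[truth$chrom]) + truth$pos

  nf <- length(grid$fractions); nr <- grid$replicates
  detail <- vector("list", nf)
  rows_cache <- NULL
  points <- list()
  for (fi in seq_len(nf)) {
    f <- grid$fractions[fi]
    present <- matrix(FALSE, nrow = nrow(truth), ncol = nr)
    sdepth <- matrix(0L, nrow = nrow(truth), ncol = nr)
    for (r in seq_len(nr)) {
      rows <- if (f == 1) seq_len(nrow(rs$reads))
              else subsample_rows(rs, f, grid$base_seed + r)
      cnts <- pileup_counts(rs, panel, rows)
      calls <- call_variants(rs, panel, model, rows = rows, counts = cnts)
      present[, r] <- tkey %in% variant_key(calls)
      ## site depth at the truth positions under this subsample
      cm <- matrix(cnts, nrow = 4L)
      sdepth[, r] <- as.integer(colSums(cm)[tglob])
    }
    detail[[fi]] <- list(fraction = f, present = present, site_depth = sdepth)
    for (cls in c("snp", "indel")) {
      sel <- truth$class == cls
      if (!any(sel)) next
      cnt <- colSums(present[sel, , drop = FALSE])
      points[[length(points) + 1L]] <- data.frame(
        class = cls, fraction = f,
        effective_coverage = effective_coverage(f, mean_target_coverage),
        mean_count = round_half_up(mean(cnt), 1),
        sd_count = round_half_up(stats::sd(cnt), 1),
        mean_recall_pct = round_half_up(100 * mean(cnt) / sum(sel), 1),
        stringsAsFactors = FALSE)
    }
  }
  structure(list(points = do.call(rbind, points), pseudo_truth = truth,
                 detail = detail, mean_target_coverage = mean_target_coverage,
                 grid = grid),
            class = "rarefaction_result")
}

#' @export
print.rarefaction_result <- function(x, ...) {
  cat(sprintf("rarefaction over %d fractions x %d replicates (mean coverage %.1f)\n",
              length(x$grid$fractions), x$grid$replicates,
              x$mean_target_coverage))
  print(utils::head(x$points, 8), row.names = FALSE)
  invisible(x)
}

#' Bracket the coverage needed to recover 95% of a variant class
#'
#' Returns the C95 bracket: the lower bound is the (integer-rounded)
#' effective coverage of the largest-coverage grid point whose mean recall
#' is still below 95%, the upper bound that of the adjacent grid point
#' above it. When the curve crosses 95% more than once (replicate noise),
#' the highest crossing wins and a warning is logged. When the curve never
#' crosses, `crossed` is `FALSE` and the available boundary is reported.
#'
#' @param result a `rarefaction_result` (or its `points` data.frame)
#' @param variant_class `"snp"` or `"indel"`
#' @param threshold_pct recall threshold (default 95)
#' @param mean_target_coverage full-data mean coverage; taken from the
#'   `rarefaction_result` when omitted. Bracket endpoints are
#'   `round(fraction * mean_target_coverage)` on the unrounded product —
#'   rounding the 1-decimal effective coverage a second time would shift
#'   some endpoints by one fold
#' @return object of class `c95_bracket`: list with `variant_class`,
#'   `lower_coverage`, `upper_coverage` (integer-rounded folds),
#'   `lower_fraction`, `upper_fraction`, `crossed`
#' @export
estimate_c95 <- function(result, variant_class = c("snp", "indel"),
                         threshold_pct = 95, mean_target_coverage = NULL) {
  variant_class <- match.arg(variant_class)
  if (inherits(result, "rarefaction_result")) {
    pts <- result$points
    mean_target_coverage <- mean_target_coverage %||%
      result$mean_target_coverage
  } else pts <- result
  if (is.null(mean_target_coverage))
    stop("mean_target_coverage is required with a plain points table",
         call. = FALSE)
  pts <- pts[pts$class == variant_class, , drop = FALSE]
  pts <- pts[order(pts$fraction), , drop = FALSE]
  if (nrow(pts) < 1L) stop("no grid points for class ", variant_class,
                           call. = FALSE)
  below <- pts$mean_recall_pct < threshold_pct
  n_cross <- sum(diff(as.integer(below)) != 0L)
  if (n_cross > 1L)
    warning("recall curve crosses ", threshold_pct,
            "% more than once; using the highest crossing")
  mk <- function(lower_f, upper_f, crossed) {
    structure(list(
      variant_class = variant_class,
      lower_coverage = if (is.na(lower_f)) NA_integer_ else
        as.integer(round_half_up(lower_f * mean_target_coverage, 0)),
      upper_coverage = if (is.na(upper_f)) NA_integer_ else
        as.integer(round_half_up(upper_f * mean_target_coverage, 0)),
      lower_fraction = lower_f, upper_fraction = upper_f,
      crossed = crossed), class = "c95_bracket")
  }
  if (!any(below)) {
    ## even the smallest grid coverage reaches the threshold
    return(mk(NA_real_, min(pts$fraction), FALSE))
  }
  lower_f <- max(pts$fraction[below])        # highest crossing
  if (lower_f == max(pts$fraction)) {
    ## never reaches the threshold
    return(mk(lower_f, NA_real_, FALSE))
  }
  upper_f <- min(pts$fraction[pts$fraction > lower_f])
  mk(lower_f, upper_f, TRUE)
}

#' @export
print.c95_bracket <- function(x, ...) {
  if (x$crossed) {
    cat(sprintf("C_%s95: %dx < C95 < %dx (fractions %.2f-%.2f)\n",
                x$variant_class, x$lower_coverage, x$upper_coverage,
                x$lower_fraction, x$upper_fraction))
  } else {
    cat(sprintf("C_%s95: 95%% threshold not crossed within the grid\n",
                x$variant_class))
  }
  invisible(x)
}

#' Minimal fraction at which a variant is called in every replicate
#'
#' For one pseudo-truth variant, finds the smallest grid fraction from
#' which upward the variant is recovered in all replicates, and reports the
#' corresponding effective coverage together with the mean replicate read
#' depth at the variant site at that fraction.
#'
#' @param variant one row of the pseudo-truth table (or an index into it)
#' @param result a `rarefaction_result`
#' @return list with `fraction`, `effective_coverage`, `mean_site_depth`
#'   (1 decimal); all `NA` when no fraction recovers the variant in every
#'   replicate
#' @export
min_fraction_all_replicates <- function(variant, result) {
  stopifnot(inherits(result, "rarefaction_result"))
  truth <- result$pseudo_truth
  i <- if (is.numeric(variant)) as.integer(variant)
       else match(variant_key(variant), variant_key(truth))
  if (is.na(i) || i < 1L || i > nrow(truth))
    stop("variant not present in the pseudo-truth set", call. = FALSE)
  fr <- vapply(result$detail, function(d) d$fraction, numeric(1))
  all_rep <- vapply(result$detail, function(d) all(d$present[i, ]), logical(1))
  ord <- order(fr)
  fr <- fr[ord]; all_rep <- all_rep[ord]
  ## smallest fraction from which upward every replicate recovers it
  ok_up <- rev(cumprod(rev(all_rep))) == 1
  if (!any(ok_up)) {
    return(list(fraction = NA_real_, effective_coverage = NA_real_,
                mean_site_depth = NA_real_))
  }
  fmin <- fr[which(ok_up)[1]]
  d <- result$detail[[ord[which(ok_up)[1]]]]
  list(fraction = fmin,
       effective_coverage = effective_coverage(fmin,
                                               result$mean_target_coverage),
       mean_site_depth = round_half_up(mean(d$site_depth[i, ]), 1))
}

#' Coverage metrics over the padded targets
#'
#' Per-base read depth over the padded target intervals, summarized the way
#' capture-panel QC reports print it: mean target coverage (1 decimal) and
#' the percentage of target bases at or above 2x, 10x and 50x (2 decimals).
#'
#' @param rs a `read_set`
#' @param panel the `panel_world`
#' @return object of class `coverage_metrics`: list with
#'   `mean_target_coverage`, `pct_ge_2x`, `pct_ge_10x`, `pct_ge_50x`
#' @export
coverage_metrics <- function(rs, panel) {
  if (sum(GenomicRanges::width(panel$targets)) == 0L)
    stop("invalid parameter: empty target set", call. = FALSE)
  cm <- matrix(pileup_counts(rs, panel), nrow = 4L)
  depth <- colSums(cm)[panel_target_mask(panel)]
  structure(list(
    mean_target_coverage = round_half_up(mean(depth), 1),
    pct_ge_2x = round_half_up(100 * mean(depth >= 2), 2),
    pct_ge_10x = round_half_up(100 * mean(depth >= 10), 2),
    pct_ge_50x = round_half_up(100 * mean(depth >= 50), 2)),
    class = "coverage_metrics")
}

#' @export
print.coverage_metrics <- function(x, ...) {
  cat(sprintf("mean target coverage %.1fx (>=2x: %.2f%%, >=10x: %.2f%%, >=50x: %.2f%%)\n",
              x$mean_target_coverage, x$pct_ge_2x, x$pct_ge_10x, x$pct_ge_50x))
  invisible(x)
}

#' Write the rarefaction table as TSV
#'
#' @param result a `rarefaction_result`
#' @param path output file
#' @export
write_rarefaction_tsv <- function(result, path) {
  utils::write.table(result$points, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
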