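#' Plot rarefaction curves
#'
#' Mean percent of pseudo-truth variants recovered versus effective
#' coverage, one curve per variant class, with +/- 1 SD error bars and a
#' dashed line at the 95% recovery threshold.
#'
#' @param result a `rarefaction_result`
#' @param threshold_pct where to draw the dashed threshold line
#' @export
plot_rarefaction <- function(result, threshold_pct = 95) {
  pts <- result$points
  cols <- c(snp = "#D55E00", indel = "#0072B2")
  graphics::plot(NA, xlim = range(pts$effective_coverage),
                 ylim = c(0, 105), xlab = "effective coverage (x)",
                 ylab = "% of pseudo-truth variants recovered")
  for (cls in unique(pts$class)) {
    p <- pts[pts$class == cls, ]
    p <- p[order(p$effective_coverage), ]
    n_truth <- sum(result$pseudo_truth$class == cls)
    sd_pct <- 100 * p$sd_count / n_truth
    graphics::lines(p$effective_coverage, p$mean_recall_pct,
                    type = "b", pch = 19, col = cols[[cls]])
    graphics::arrows(p$effective_coverage, p$mean_recall_pct - sd_pct,
                     p$effective_coverage, p$mean_recall_pct + sd_pct,
                     angle = 90, code = 3, length = 0.02,
                     col = cols[[cls]])
  }
  graphics::abline(h = threshold_pct, lty = 2, col = "blue")
  graphics::legend("bottomright", legend = names(cols), col = cols,
                   pch = 19, bty = "n")
  invisible(result)
}
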