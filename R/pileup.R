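#' Caller model parameters
#'
#' The diploid genotype model used by the pileup caller: a single global
#' per-read error rate `e`, a prior over the three genotypes, and a
#' Phred-scaled confidence threshold. Per-read allele likelihoods are
#' `P(alt | hom_ref) = e/3`, `P(alt | het) = (1-e)/2 + e/6`,
#' `P(alt | hom_alt) = 1-e` (and symmetrically for reference-supporting
#' reads). The emitted confidence is `-10 log10 P(hom_ref | data)`, capped
#' at `qual_cap`.
#'
#' @param error_rate per-read error probability `e`, in (0, 0.25)
#' @param genotype_prior prior over (hom_ref, het, hom_alt); flat by
#'   default, which maximizes sensitivity (the clinical setting here favors
#'   sensitivity and defers specificity to downstream filters)
#' @param qual_threshold minimum Phred-scaled confidence for an emitted
#'   call (default 50)
#' @param qual_cap upper bound on reported confidence (default 1000)
#' @param min_alt_reads minimum alternate-read observations for a site to
#'   be considered a candidate (default 2)
#' @return object of class `caller_model`
#' @export
caller_model <- function(error_rate = 0.005,
                         genotype_prior = c(1, 1, 1) / 3,
                         qual_threshold = 50, qual_cap = 1000,
                         min_alt_reads = 2L) {
  assert_scalar_number(error_rate, "error_rate", min = 0, max = 0.25,
                       allow_min = FALSE, allow_max = FALSE)
  stopifnot(length(genotype_prior) == 3L, all(genotype_prior > 0),
            abs(sum(genotype_prior) - 1) < 1e-8)
  ## Inf is a legitimate threshold (silences the caller entirely)
  stopifnot(is.numeric(qual_threshold), length(qual_threshold) == 1L,
            !is.na(qual_threshold), qual_threshold >= 0)
  assert_scalar_number(qual_cap, "qual_cap", min = 0)
  structure(list(error_rate = error_rate,
                 genotype_prior = as.numeric(genotype_prior),
                 qual_threshold = qual_threshold, qual_cap = qual_cap,
                 min_alt_reads = as.integer(min_alt_reads)),
            class = "caller_model")
}

## ---- fast pileup core ----------------------------------------------------
## Base counts over a single global coordinate space (4 x total length,
## flattened). Reads are counted through their haplotype coordinate maps;
## stored substitution errors are then applied as sparse count moves.
## A per-read-base index is computed once per read set and cached, so a
## subsampled pileup (the inner loop of the rarefaction grid) reduces to a
## single masked tabulate() pass.

pileup_index <- function(rs, panel) {
  if (!is.null(rs$cache) && !is.null(rs$cache$pidx)) return(rs$cache$pidx)
  R <- rs$read_len
  off <- panel_offsets(panel)
  total <- sum(panel$genes$chrom_len)
  idx_list <- list(); row_list <- list()
  for (ci in seq_len(nrow(panel$genes))) {
    ch <- panel$genes$chrom[ci]
    for (h in 1:2) {
      sel <- which(rs$reads$chrom == ch & rs$reads$hap == h)
      if (!length(sel)) next
      hp <- rs$haps[[ci]][[h]]
      hpos <- rep(rs$reads$hap_start[sel], each = R) +
        rep.int(0:(R - 1L), length(sel))
      base <- hp$seq[hpos]
      rpos <- hp$ref_of_hap[hpos]
      ok <- !is.na(rpos)
      idx_list[[length(idx_list) + 1L]] <-
        as.integer((off[[ch]] + rpos[ok] - 1L) * 4L + base[ok])
      row_list[[length(row_list) + 1L]] <- rep(sel, each = R)[ok]
    }
  }
  ## substitution errors as sparse count moves (original -> substituted)
  er <- rs$errors
  err_row <- integer(0); err_orig <- integer(0); err_sub <- integer(0)
  if (nrow(er)) {
    ci_of <- match(rs$reads$chrom[er$row], panel$genes$chrom)
    hap_of <- rs$reads$hap[er$row]
    ehp <- rs$reads$hap_start[er$row] + er$offset - 1L
    orig <- integer(nrow(er)); erp <- integer(nrow(er))
    for (ci in unique(ci_of)) for (h in 1:2) {
      s <- which(ci_of == ci & hap_of == h)
      if (!length(s)) next
      hp <- rs$haps[[ci]][[h]]
      orig[s] <- hp$seq[ehp[s]]
      erp[s] <- hp$ref_of_hap[ehp[s]]
    }
    keep <- !is.na(erp)
    gpos <- (unname(off[rs$reads$chrom[er$row[keep]]]) + erp[keep] - 1L) * 4L
    err_row <- er$row[keep]
    err_orig <- as.integer(gpos + orig[keep])
    err_sub <- as.integer(gpos + (((orig[keep] - 1L + er$d[keep]) %% 4L) + 1L))
  }
  pidx <- list(idx = unlist(idx_list, use.names = FALSE),
               row = unlist(row_list, use.names = FALSE),
               err_row = err_row, err_orig = err_orig, err_sub = err_sub,
               nbins = 4L * total)
  if (!is.null(rs$cache)) rs$cache$pidx <- pidx
  pidx
}

pileup_counts <- function(rs, panel, rows = NULL) {
  p <- pileup_index(rs, panel)
  if (is.null(rows)) {
    counts <- tabulate(p$idx, nbins = p$nbins)
    if (length(p$err_row)) {
      counts <- counts - tabulate(p$err_orig, nbins = p$nbins) +
        tabulate(p$err_sub, nbins = p$nbins)
    }
    return(counts)
  }
  rowset <- logical(nrow(rs$reads)); rowset[rows] <- TRUE
  counts <- tabulate(p$idx[rowset[p$row]], nbins = p$nbins)
  if (length(p$err_row)) {
    em <- rowset[p$err_row]
    if (any(em)) {
      counts <- counts - tabulate(p$err_orig[em], nbins = p$nbins) +
        tabulate(p$err_sub[em], nbins = p$nbins)
    }
  }
  counts
}

## alternate/reference support counts for every candidate indel allele
## carried by the member's haplotypes (plus any slip artifacts), with the
## minimum flank requirement `mf` on both sides of the event
indel_observations <- function(rs, panel, rows = NULL, mf = 3L) {
  R <- rs$read_len
  rows <- rows %||% seq_len(nrow(rs$reads))
  rowset <- logical(nrow(rs$reads)); rowset[rows] <- TRUE

  ## collect candidate indel alleles across haplotypes
  cands <- list()
  for (ci in seq_len(nrow(panel$genes))) {
    for (h in 1:2) {
      vs <- rs$haps[[ci]][[h]]$vars
      if (nrow(vs)) {
        iv <- vs[nchar(vs$ref) != nchar(vs$alt), , drop = FALSE]
        if (nrow(iv)) cands[[length(cands) + 1L]] <-
          iv[, c("chrom", "pos", "ref", "alt")]
      }
    }
  }
  if (!is.null(rs$slips) && any(rowset[rs$slips$row])) {
    sl <- rs$slips[rowset[rs$slips$row], c("chrom", "pos", "ref", "alt")]
    cands[[length(cands) + 1L]] <- unique(sl)
  }
  if (!length(cands)) {
    return(data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      alt_count = integer(0), ref_count = integer(0),
                      stringsAsFactors = FALSE))
  }
  cands <- unique(do.call(rbind, cands))

  ## cached per-(chrom, haplotype) read groups and coordinate fills
  cc <- rs$cache
  if (is.null(cc)) cc <- new.env(parent = emptyenv())
  if (is.null(cc$grp)) {
    cc$grp <- split(seq_len(nrow(rs$reads)),
                    paste(rs$reads$chrom, rs$reads$hap))
    cc$fills <- lapply(rs$haps, function(by_h) lapply(by_h, function(hp)
      list(nxt = fill_next(hp$ref_of_hap), prv = fill_prev(hp$ref_of_hap))))
  }

  alt_count <- integer(nrow(cands)); ref_count <- integer(nrow(cands))
  for (k in seq_len(nrow(cands))) {
    ci <- match(cands$chrom[k], panel$genes$chrom)
    p <- cands$pos[k]
    rlen <- nchar(cands$ref[k]); alen <- nchar(cands$alt[k])
    for (h in 1:2) {
      hp <- rs$haps[[ci]][[h]]
      g <- cc$grp[[paste(cands$chrom[k], h)]]
      sel <- g[rowset[g]]
      if (!length(sel)) next
      vs <- hp$vars
      carries <- nrow(vs) > 0 &&
        any(vs$pos == p & vs$ref == cands$ref[k] & vs$alt == cands$alt[k])
      hs <- rs$reads$hap_start[sel]
      if (carries) {
        anchor <- vs$hap_anchor[vs$pos == p & vs$ref == cands$ref[k] &
                                vs$alt == cands$alt[k]][1]
        evt_end <- anchor + (alen - 1L)      # last alt base in hap coords
        n_obs <- sum(hs <= anchor - mf & hs + R - 1L >= evt_end + mf)
        alt_count[k] <- alt_count[k] + n_obs
      } else {
        ## reference-supporting spanning reads on this haplotype
        span_a <- p - mf; span_b <- p + rlen - 1L + mf
        fl <- cc$fills[[ci]][[h]]
        r_start <- fl$nxt[hs]
        r_end <- fl$prv[pmin(hs + R - 1L, length(fl$prv))]
        n_obs <- sum(!is.na(r_start) & !is.na(r_end) &
                     r_start <= span_a & r_end >= span_b)
        ref_count[k] <- ref_count[k] + n_obs
      }
    }
    ## slip artifacts: per-read observations override the haplotype route
    if (!is.null(rs$slips)) {
      sl_n <- sum(rowset[rs$slips$row] & rs$slips$chrom == cands$chrom[k] &
                  rs$slips$pos == p & rs$slips$ref == cands$ref[k] &
                  rs$slips$alt == cands$alt[k])
      if (sl_n > 0) {
        alt_count[k] <- alt_count[k] + sl_n
        ref_count[k] <- max(0L, ref_count[k] - sl_n)
      }
    }
  }
  cbind(cands, data.frame(alt_count = alt_count, ref_count = ref_count))
}

#' Pileup over the padded target regions
#'
#' Counts every on-target base of every read exactly once (substitution
#' errors included), returning one row per target position plus an
#' `indels` attribute with alternate/reference support for candidate
#' indel alleles.
#'
#' @param rs a `read_set`
#' @param panel the `panel_world` the reads come from
#' @return data.frame with columns `chrom`, `pos`, `A`, `C`, `G`, `T`,
#'   `depth`; attribute `indels`
#' @export
build_pileup <- function(rs, panel) {
  counts <- pileup_counts(rs, panel)
  cm <- matrix(counts, nrow = 4L)
  mask <- panel_target_mask(panel)
  off <- panel_offsets(panel)
  gpos <- which(mask)
  chrom_idx <- findInterval(gpos - 1L, unname(off))
  out <- data.frame(
    chrom = panel$genes$chrom[chrom_idx],
    pos = as.integer(gpos - unname(off)[chrom_idx]),
    A = cm[1L, gpos], C = cm[2L, gpos], G = cm[3L, gpos], T = cm[4L, gpos],
    stringsAsFactors = FALSE)
  out$depth <- out$A + out$C + out$G + out$T
  attr(out, "indels") <- indel_observations(rs, panel)
  out
}

## ---- genotype likelihood model -------------------------------------------

## vectorized three-genotype posterior from reference/alternate support
genotype_counts <- function(ref_count, alt_count, model) {
  e <- model$error_rate
  lp <- log(model$genotype_prior)
  p_alt <- c(e / 3, (1 - e) / 2 + e / 6, 1 - e)
  p_ref <- c(1 - e, (1 - e) / 2 + e / 6, e / 3)
  ll <- sapply(1:3, function(g)
    ref_count * log(p_ref[g]) + alt_count * log(p_alt[g]) + lp[g])
  ll <- matrix(ll, ncol = 3L)
  mx <- apply(ll, 1L, max)
  post <- exp(ll - mx)
  post <- post / rowSums(post)
  qual <- -10 * log10(post[, 1L])
  qual[!is.finite(qual) | qual > model$qual_cap] <- model$qual_cap
  gt <- c("hom_ref", "het", "hom_alt")[max.col(post, ties.method = "first")]
  data.frame(post_hom_ref = post[, 1L], post_het = post[, 2L],
             post_hom_alt = post[, 3L], qual = qual, genotype = gt,
             stringsAsFactors = FALSE)
}

#' Genotype a single pileup column
#'
#' Picks the highest-count non-reference base as the alternate allele (ties
#' broken alphabetically), evaluates the three diploid genotype likelihoods
#' and returns the posterior with the Phred-scaled confidence
#' `-10 log10 P(hom_ref | data)`.
#'
#' @param column one row of [build_pileup()] output (fields `A`, `C`, `G`,
#'   `T`, `depth`), or a named count vector
#' @param model a [caller_model()]
#' @param ref_base the reference base at the site
#' @return list with `posterior` (named 3-vector), `qual`, `genotype`,
#'   `alt_base`, `ref_count`, `alt_count`; or `NULL` (no-call) at depth 0
#' @export
genotype_site <- function(column, model, ref_base) {
  cnt <- c(A = as.integer(column[["A"]]), C = as.integer(column[["C"]]),
           G = as.integer(column[["G"]]), T = as.integer(column[["T"]]))
  if (sum(cnt) == 0L) {
    warning("no-call: zero depth")
    return(NULL)
  }
  stopifnot(ref_base %in% BASES)
  ref_count <- cnt[[ref_base]]
  alts <- cnt[setdiff(BASES, ref_base)]
  alt_base <- names(alts)[which.max(alts)]   # which.max: first max, A<C<G<T
  g <- genotype_counts(ref_count, alts[[alt_base]], model)
  list(posterior = c(hom_ref = g$post_hom_ref, het = g$post_het,
                     hom_alt = g$post_hom_alt),
       qual = g$qual, genotype = g$genotype, alt_base = alt_base,
       ref_count = ref_count, alt_count = alts[[alt_base]])
}

#' Call variants from a read set
#'
#' Pileup-based diploid calling restricted to the padded target intervals:
#' candidate SNV sites (at least `min_alt_reads` non-reference
#' observations) and candidate indel alleles are genotyped under the
#' [caller_model()]; calls with a non-reference genotype and confidence at
#' or above the threshold are emitted, left-normalized and sorted.
#'
#' @param rs a `read_set`
#' @param panel the `panel_world`
#' @param model a [caller_model()]
#' @param rows internal: restrict to these read rows (used by the
#'   down-sampler)
#' @param counts internal: precomputed [pileup_counts()] for these rows
#' @return data.frame of class `variant_calls`: `chrom`, `pos`, `ref`,
#'   `alt`, `class`, `genotype`, `qual`, `depth`
#' @export
call_variants <- function(rs, panel, model = caller_model(), rows = NULL,
                          counts = NULL) {
  stopifnot(inherits(model, "caller_model"))
  counts <- counts %||% pileup_counts(rs, panel, rows)
  total <- sum(panel$genes$chrom_len)
  cm <- matrix(counts, nrow = 4L)
  refint <- panel_ref_int(panel)
  refb_g <- unlist(refint, use.names = FALSE)
  off <- unname(panel_offsets(panel))
  depth_g <- colSums(cm)
  ref_cnt_g <- cm[cbind(refb_g, seq_len(total))]
  nonref <- as.integer(depth_g) - ref_cnt_g
  mask <- panel_target_mask(panel)

  cand <- which(nonref >= model$min_alt_reads & mask)
  snv <- NULL
  if (length(cand)) {
    sub <- cm[, cand, drop = FALSE]
    sub[cbind(refb_g[cand], seq_along(cand))] <- -1L
    alt_idx <- max.col(t(sub), ties.method = "first")
    alt_cnt <- sub[cbind(alt_idx, seq_along(cand))]
    keep <- alt_cnt >= model$min_alt_reads
    if (any(keep)) {
      cand <- cand[keep]; alt_idx <- alt_idx[keep]; alt_cnt <- alt_cnt[keep]
      g <- genotype_counts(ref_cnt_g[cand], alt_cnt, model)
      emit <- g$genotype != "hom_ref" & g$qual >= model$qual_threshold
      if (any(emit)) {
        ci <- findInterval(cand[emit] - 1L, off)
        snv <- data.frame(
          chrom = panel$genes$chrom[ci],
          pos = as.integer(cand[emit] - off[ci]),
          ref = BASES[refb_g[cand[emit]]],
          alt = BASES[alt_idx[emit]],
          genotype = g$genotype[emit],
          qual = round(g$qual[emit], 2),
          depth = as.integer(depth_g[cand[emit]]),
          stringsAsFactors = FALSE)
      }
    }
  }

  iob <- indel_observations(rs, panel, rows)
  ind <- NULL
  if (nrow(iob)) {
    keep <- iob$alt_count >= model$min_alt_reads
    iob <- iob[keep, , drop = FALSE]
    if (nrow(iob)) {
      g <- genotype_counts(iob$ref_count, iob$alt_count, model)
      emit <- g$genotype != "hom_ref" & g$qual >= model$qual_threshold
      ## on-target restriction on the anchored position
      ci <- match(iob$chrom, panel$genes$chrom)
      on_t <- mask[off[ci] + iob$pos]
      emit <- emit & on_t
      if (any(emit)) {
        ind <- data.frame(
          chrom = iob$chrom[emit], pos = iob$pos[emit],
          ref = iob$ref[emit], alt = iob$alt[emit],
          genotype = g$genotype[emit],
          qual = round(g$qual[emit], 2),
          depth = iob$alt_count[emit] + iob$ref_count[emit],
          stringsAsFactors = FALSE)
        ## re-normalize defensively (planted alleles are already normalized)
        for (k in seq_len(nrow(ind))) {
          nv <- normalize_variant(ind$pos[k], ind$ref[k], ind$alt[k],
                                  refint[[match(ind$chrom[k],
                                                panel$genes$chrom)]])
          ind$pos[k] <- nv$pos; ind$ref[k] <- nv$ref; ind$alt[k] <- nv$alt
        }
      }
    }
  }

  out <- rbind(snv, ind)
  if (is.null(out)) {
    out <- data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      genotype = character(0), qual = numeric(0),
                      depth = integer(0), stringsAsFactors = FALSE)
  }
  out$class <- variant_class(out$ref, out$alt)
  out <- out[order_variants(out, panel$genes$chrom),
             c("chrom", "pos", "ref", "alt", "class", "genotype",
               "qual", "depth")]
  rownames(out) <- NULL
  class(out) <- c("variant_calls", "data.frame")
  out
}
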