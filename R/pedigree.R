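#' Construct a pedigree
#'
#' @param members data.frame with columns `id`, `sex` (`"M"`, `"F"` or
#'   `"U"`), `father`, `mother` (member ids or `NA` for founders) and
#'   `affected` (`"yes"`, `"no"`, `"unknown"`)
#' @param inheritance_model `"AR"` or `"AD"`
#' @param penetrance probability that a genotype-positive individual is
#'   affected; must be 1 under AR, may be below 1 under AD (incomplete
#'   penetrance)
#' @return object of class `pedigree`
#' @export
pedigree <- function(members, inheritance_model = c("AR", "AD"),
                     penetrance = 1.0) {
  inheritance_model <- match.arg(inheritance_model)
  req <- c("id", "sex", "father", "mother", "affected")
  if (!all(req %in% names(members)))
    stop("members must have columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  members <- as.data.frame(members, stringsAsFactors = FALSE)
  if (anyDuplicated(members$id)) stop("duplicate member ids", call. = FALSE)
  stopifnot(all(members$sex %in% c("M", "F", "U")),
            all(members$affected %in% c("yes", "no", "unknown")))
  for (col in c("father", "mother")) {
    p <- members[[col]]
    bad <- !is.na(p) & !(p %in% members$id)
    if (any(bad)) stop("unresolved ", col, " reference: ",
                       paste(p[bad], collapse = ", "), call. = FALSE)
  }
  assert_scalar_number(penetrance, "penetrance", min = 0, max = 1)
  if (inheritance_model == "AR" && penetrance != 1)
    stop("penetrance must be 1.0 under the AR model", call. = FALSE)
  ## cycle check: members must admit a founder-first ordering
  ord <- pedigree_order(members)
  if (is.null(ord)) stop("pedigree contains an ancestry cycle", call. = FALSE)
  structure(list(members = members, inheritance_model = inheritance_model,
                 penetrance = penetrance, order = ord),
            class = "pedigree")
}

## topological order (founders first); NULL if cyclic
pedigree_order <- function(members) {
  ids <- members$id
  placed <- character(0)
  remaining <- seq_along(ids)
  while (length(remaining)) {
    ready <- remaining[vapply(remaining, function(i) {
      f <- members$father[i]; m <- members$mother[i]
      (is.na(f) || f %in% placed) && (is.na(m) || m %in% placed)
    }, logical(1))]
    if (!length(ready)) return(NULL)
    placed <- c(placed, ids[ready])
    remaining <- setdiff(remaining, ready)
  }
  placed
}

#' @export
print.pedigree <- function(x, ...) {
  cat(sprintf("pedigree: %d members, model %s, penetrance %.2f\n",
              nrow(x$members), x$inheritance_model, x$penetrance))
  print(x$members, row.names = FALSE)
  invisible(x)
}

#' Two-generation consanguineous family with recessive disease
#'
#' A seven-member pedigree: consanguineous parents (both carriers), five
#' children of whom two (the proband `II-2` and an elder sister `II-1`)
#' are affected, three unaffected. Used as the default family for the
#' autosomal recessive analysis.
#'
#' @return a `pedigree` (AR, full penetrance)
#' @export
case1_pedigree <- function() {
  m <- data.frame(
    id = c("I-1", "I-2", "II-1", "II-2", "II-3", "II-4", "II-5"),
    sex = c("M", "F", "F", "M", "M", "F", "M"),
    father = c(NA, NA, "I-1", "I-1", "I-1", "I-1", "I-1"),
    mother = c(NA, NA, "I-2", "I-2", "I-2", "I-2", "I-2"),
    affected = c("no", "no", "yes", "yes", "no", "no", "no"),
    stringsAsFactors = FALSE)
  pedigree(m, "AR", penetrance = 1.0)
}

#' Small dominant family with an unaffected carrier
#'
#' Four genotyped members: the affected proband (`II-1`), her clinically
#' unaffected father (`I-2`, a carrier — incomplete penetrance), an affected
#' paternal aunt (`I-1`) and the non-carrier mother (`I-3`). Used as the
#' default family for the autosomal dominant analysis.
#'
#' @param penetrance penetrance of the dominant allele (default 0.8)
#' @return a `pedigree` (AD)
#' @export
case2_pedigree <- function(penetrance = 0.8) {
  m <- data.frame(
    id = c("I-1", "I-2", "I-3", "II-1"),
    sex = c("F", "M", "F", "F"),
    father = c(NA, NA, NA, "I-2"),
    mother = c(NA, NA, NA, "I-3"),
    affected = c("yes", "no", "no", "yes"),
    stringsAsFactors = FALSE)
  pedigree(m, "AD", penetrance = penetrance)
}

#' Assign Mendelian-consistent genotypes for planted variants
#'
#' Produces a members-by-variants genotype matrix. The proband is anchored
#' as a carrier of every planted variant (the truth set represents the
#' proband's own call set); parents and other relatives are filled in by
#' Mendelian gene dropping. The causal variant is overridden to match the
#' pedigree's inheritance model: under AR all affected members are
#' `hom_alt` with obligate-carrier parents; under AD all affected members
#' carry at least one alternate allele (unaffected carriers are permitted
#' when penetrance < 1).
#'
#' @param variants `planted_variants` table
#' @param ped a [pedigree()]
#' @param causal_variant_id id of the causal variant (or `NULL` for none)
#' @param proband_id member anchored as carrier of all variants; defaults
#'   to the first affected member
#' @param hom_frac probability that a non-causal variant is homozygous in
#'   the proband (0.5 by default: a consanguineous proband runs long
#'   stretches of homozygosity)
#' @param carrier_parents under AR, force both parents of affected members
#'   to be carriers (obligate); disabling this raises a consistency error
#'   when an affected child requires carrier parents
#' @param seed integer seed
#' @return character matrix (members x variants) with values `hom_ref`,
#'   `het`, `hom_alt`; attribute `proband_id`
#' @export
assign_pedigree_genotypes <- function(variants, ped, causal_variant_id = NULL,
                                      proband_id = NULL, hom_frac = 0.5,
                                      carrier_parents = TRUE, seed = 1) {
  stopifnot(inherits(ped, "pedigree"))
  mem <- ped$members
  ids <- mem$id
  if (is.null(proband_id)) {
    aff <- ids[mem$affected == "yes"]
    proband_id <- if (length(aff)) aff[1] else ids[1]
  }
  if (!proband_id %in% ids) stop("unknown proband_id", call. = FALSE)
  if (!is.null(causal_variant_id) && !causal_variant_id %in% variants$id)
    stop("causal_variant_id not found in variants", call. = FALSE)

  nv <- nrow(variants)
  G <- matrix("hom_ref", nrow = length(ids), ncol = nv,
              dimnames = list(ids, variants$id))
  if (nv == 0L) return(structure(G, proband_id = proband_id))

  G <- with_seed(seed, {
    for (j in seq_len(nv)) {
      G[, j] <- assign_one_variant(mem, ids, proband_id, hom_frac)
    }
    if (!is.null(causal_variant_id)) {
      G[, causal_variant_id] <-
        assign_causal_variant(ped, ids, carrier_parents)
    }
    G
  })
  bad <- check_mendelian(G, ped)
  if (nrow(bad)) {
    stop(sprintf(
      "consistency error: genotype of %s at %s impossible given parents",
      bad$member[1], bad$variant[1]), call. = FALSE)
  }
  structure(G, proband_id = proband_id)
}

## one non-causal variant: proband carrier, ancestors compatible, sibs dropped
assign_one_variant <- function(mem, ids, proband_id, hom_frac) {
  g <- stats::setNames(rep(NA_character_, length(ids)), ids)
  pro <- proband_id
  g[pro] <- if (stats::runif(1) < hom_frac) "hom_alt" else "het"
  ## walk up: make parents compatible with each set child
  for (id in rev(pedigree_order(mem))) {
    if (is.na(g[id]) || g[id] == "hom_ref") next
    i <- match(id, ids)
    f <- mem$father[i]; m <- mem$mother[i]
    if (is.na(f) || is.na(m)) next
    if (g[id] == "hom_alt") {
      for (p in c(f, m)) if (is.na(g[p]) || g[p] == "hom_ref") g[p] <- "het"
    } else {
      carriers <- c(f, m)[!is.na(g[c(f, m)]) & g[c(f, m)] != "hom_ref"]
      if (!length(carriers)) {
        p <- sample(c(f, m), 1L)
        g[p] <- "het"
        other <- setdiff(c(f, m), p)
        if (is.na(g[other])) g[other] <- "hom_ref"
      }
    }
  }
  ## founders not yet set are reference; drop alleles down to the rest
  for (id in pedigree_order(mem)) {
    if (!is.na(g[id])) next
    i <- match(id, ids)
    f <- mem$father[i]; m <- mem$mother[i]
    if (is.na(f) && is.na(m)) { g[id] <- "hom_ref"; next }
    g[id] <- mendel_draw(g[f], g[m])
  }
  g[ids]
}

## random child genotype given parent genotypes
mendel_draw <- function(gf, gm) {
  alt_from <- function(gp) switch(gp,
    hom_ref = 0, het = stats::rbinom(1, 1, 0.5), hom_alt = 1)
  n_alt <- alt_from(gf) + alt_from(gm)
  c("hom_ref", "het", "hom_alt")[n_alt + 1L]
}

## causal-variant genotypes obeying the pedigree's inheritance model
assign_causal_variant <- function(ped, ids, carrier_parents) {
  mem <- ped$members
  g <- stats::setNames(rep(NA_character_, length(ids)), ids)
  aff <- ids[mem$affected == "yes"]
  if (ped$inheritance_model == "AR") {
    g[aff] <- "hom_alt"
    for (id in aff) {
      i <- match(id, ids)
      f <- mem$father[i]; m <- mem$mother[i]
      for (p in c(f, m)) {
        if (is.na(p)) next
        if (!carrier_parents && is.na(g[p]))
          stop("consistency error: AR causal variant requires carrier parents",
               call. = FALSE)
        if (is.na(g[p]) || g[p] == "hom_ref")
          g[p] <- if (mem$affected[match(p, ids)] == "yes") "hom_alt" else "het"
      }
    }
    ## unaffected relatives: Mendelian draw conditional on not hom_alt
    for (id in pedigree_order(mem)) {
      if (!is.na(g[id])) next
      i <- match(id, ids)
      f <- mem$father[i]; m <- mem$mother[i]
      if (is.na(f) || is.na(m)) { g[id] <- "hom_ref"; next }
      repeat {
        cand <- mendel_draw(g[f], g[m])
        if (cand != "hom_alt" || mem$affected[i] != "no") break
      }
      g[id] <- cand
    }
  } else {                                   # AD
    g[aff] <- "het"
    ## every affected non-founder needs a carrier parent; prefer a lineage
    ## already containing carriers (pushes the allele through e.g. an
    ## affected aunt's side)
    for (id in pedigree_order(mem)) {
      i <- match(id, ids)
      if (is.na(g[id]) || g[id] == "hom_ref") next
      f <- mem$father[i]; m <- mem$mother[i]
      if (is.na(f) && is.na(m)) next
      pc <- c(f, m)
      if (!any(!is.na(g[pc]) & g[pc] != "hom_ref")) {
        g[pc[1]] <- "het"                    # unaffected carrier is allowed
      }
    }
    for (id in ids) if (is.na(g[id])) g[id] <- "hom_ref"
  }
  g[ids]
}

#' Exhaustive Mendelian-transmission check
#'
#' Verifies every (member, variant) genotype against the member's parents:
#' a child's genotype must be reachable by drawing one allele from each
#' recorded parent.
#'
#' @param genotypes members x variants character matrix
#' @param ped a [pedigree()]
#' @return data.frame of violations (`member`, `variant`); zero rows when
#'   the assignment is fully Mendelian-consistent
#' @export
check_mendelian <- function(genotypes, ped) {
  mem <- ped$members
  ids <- rownames(genotypes)
  viol_m <- character(0); viol_v <- character(0)
  can_give <- list(hom_ref = 0L, het = 0:1, hom_alt = 1L)
  n_alt <- c(hom_ref = 0L, het = 1L, hom_alt = 2L)
  for (i in seq_along(ids)) {
    k <- match(ids[i], mem$id)
    f <- mem$father[k]; m <- mem$mother[k]
    if (is.na(f) && is.na(m)) next
    for (j in seq_len(ncol(genotypes))) {
      child <- n_alt[[genotypes[i, j]]]
      fa <- if (is.na(f)) 0:1 else can_give[[genotypes[f, j]]]
      mo <- if (is.na(m)) 0:1 else can_give[[genotypes[m, j]]]
      if (!child %in% outer(fa, mo, `+`)) {
        viol_m <- c(viol_m, ids[i])
        viol_v <- c(viol_v, colnames(genotypes)[j])
      }
    }
  }
  data.frame(member = viol_m, variant = viol_v, stringsAsFactors = FALSE)
}

#' Write a pedigree as a PED-style TSV
#'
#' Columns: family id, member id, father, mother, sex (1 = male, 2 = female,
#' 0 = unknown), phenotype (2 = affected, 1 = unaffected, 0 = unknown).
#'
#' @param ped a [pedigree()]
#' @param path output file
#' @param family family identifier written in column 1
#' @export
write_ped <- function(ped, path, family = "FAM1") {
  m <- ped$members
  d <- data.frame(
    family = family, id = m$id,
    father = ifelse(is.na(m$father), "0", m$father),
    mother = ifelse(is.na(m$mother), "0", m$mother),
    sex = c(M = 1L, F = 2L, U = 0L)[m$sex],
    phenotype = c(yes = 2L, no = 1L, unknown = 0L)[m$affected],
    stringsAsFactors = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a PED-style TSV
#'
#' @param path PED file written by [write_ped()] (or any 6-column
#'   whitespace-separated PED)
#' @param inheritance_model,penetrance passed to [pedigree()] (PED files do
#'   not carry the inheritance model)
#' @return a `pedigree`
#' @export
read_ped <- function(path, inheritance_model = "AR", penetrance = 1.0) {
  d <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                         col.names = c("family", "id", "father", "mother",
                                       "sex", "phenotype"))
  m <- data.frame(
    id = as.character(d$id),
    sex = c("U", "M", "F")[d$sex + 1L],
    father = ifelse(d$father == "0", NA_character_, as.character(d$father)),
    mother = ifelse(d$mother == "0", NA_character_, as.character(d$mother)),
    affected = c("unknown", "no", "yes")[d$phenotype + 1L],
    stringsAsFactors = FALSE)
  pedigree(m, inheritance_model, penetrance)
}
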