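# Independent oracles used across the suite. These deliberately avoid the
# package's own vectorized code paths.

# interval-union oracle: total length of the union of [start, end] (1-based,
# closed) intervals, by sort-and-scan
union_length_oracle <- function(start, end) {
  o <- order(start)
  start <- start[o]; end <- end[o]
  total <- 0L; cur_s <- start[1]; cur_e <- end[1]
  for (i in seq_along(start)[-1]) {
    if (start[i] <= cur_e + 1L) {
      cur_e <- max(cur_e, end[i])
    } else {
      total <- total + (cur_e - cur_s + 1L)
      cur_s <- start[i]; cur_e <- end[i]
    }
  }
  total + (cur_e - cur_s + 1L)
}

# brute-force genotype-likelihood oracle: sequential per-read products, no
# closed-form powers, flat prior unless given
genotype_oracle <- function(ref_count, alt_count, e, prior = c(1, 1, 1) / 3,
                            qual_cap = 1000) {
  p_ref <- c(1 - e, (1 - e) / 2 + e / 6, e / 3)
  p_alt <- c(e / 3, (1 - e) / 2 + e / 6, 1 - e)
  lik <- prior
  for (g in 1:3) {
    for (i in seq_len(ref_count)) lik[g] <- lik[g] * p_ref[g]
    for (i in seq_len(alt_count)) lik[g] <- lik[g] * p_alt[g]
  }
  post <- lik / sum(lik)
  qual <- -10 * log10(post[1])
  if (!is.finite(qual) || qual > qual_cap) qual <- qual_cap
  list(posterior = post, qual = qual,
       genotype = c("hom_ref", "het", "hom_alt")[which.max(post)])
}

# apply a variant to a chromosome string: the equivalence oracle for
# left-normalization (two representations are equivalent iff the edited
# sequences are identical)
apply_variant_oracle <- function(refseq, pos, ref, alt) {
  stopifnot(substr(refseq, pos, pos + nchar(ref) - 1L) == ref)
  paste0(substr(refseq, 1L, pos - 1L), alt,
         substr(refseq, pos + nchar(ref), nchar(refseq)))
}
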