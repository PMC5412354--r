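---
title: "paneldepth: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{paneldepth: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`paneldepth` studies two linked questions about targeted gene-panel
sequencing in a Mendelian-diagnostics setting: (1) how recall of SNPs and
small indels decays as sequencing depth is reduced, summarized by the
coverage bracket at which 95 % of variants are still recovered; and (2) how
an annotated variant list is reduced to a single diagnostic candidate by a
cascade of frequency, quality, predictor and inheritance filters, validated
by pedigree segregation. Because real patient reads are not distributable,
the package carries a synthetic panel world whose statistical structure
matches what the analysis assumes. This vignette explains each model, its
parameters and defaults, the numerical choices, and what the synthetic
world does and does not establish.

## The synthetic panel world

`build_panel()` creates one chromosome per gene (`panel_chr1`, ...),
default 27 genes with 5 exons of 200 bp each — the scale of a commercial
hereditary-neuropathy panel. Targets are exons padded by `pad_bp = 100` on
each side and merged; the default geometry yields a 54 kb padded target.
Exon spacing (`exon_gap = 500`) keeps pads from merging by default, and a
`margin` of 600 bp of extra reference beyond the outermost pads guarantees
that read pairs near target edges stay on the chromosome. Intervals are
1-based closed `GRanges` in memory, 0-based half-open BED on disk
(`rtracklayer` handles the shift), and VCF positions are 1-based with the
usual anchored-indel convention.

`plant_variants()` defaults to 162 SNPs and 42 indels — the size of a
proband's on-target, confidence-filtered call set from a deep gene-panel
run. Indels are insertions or deletions with equal probability, 1–10 bp
long, planted at least 30 bp apart and away from interval edges, and
left-normalized at creation so that truth and calls share one canonical
representation.

`assign_pedigree_genotypes()` anchors the proband as a carrier of every
planted variant (the truth set *is* the proband's call set) and fills the
rest of the family by Mendelian gene dropping. The default probability that
a non-causal variant is homozygous in the proband is 0.5: the bundled
recessive family is consanguineous, and probands from such families carry
long runs of homozygosity, so a high homozygote fraction is the realistic
choice. The causal variant is overridden to the inheritance model: under AR
all affected members become `hom_alt` with obligate-carrier parents; under
AD every affected member carries the allele and unaffected carriers are
permitted (incomplete penetrance). Every assignment is verified by an
exhaustive transmission check (`check_mendelian()`).

`simulate_reads()` generates paired-end 100 bp reads with:

* **capture non-uniformity**: each target interval draws a gamma depth
  multiplier with mean 1 and coefficient of variation `capture_cv`. The
  default 0.75 was chosen analytically, before any simulation, so that at a
  mean of ~213× roughly 10 % of target bases fall below 50×
  (`P(gamma < 50/213) ≈ 0.095` at shape `1/0.75²`), reproducing the
  long lower tail that capture chemistry produces in real panels. The
  realized profile (≥2×: ~99.9 %, ≥10×: ~98.9 %, ≥50×: ~90 %) matches the
  QC metrics a clinical panel run reports at this depth.
* **coverage calibration**: per-interval read-pair counts are set from the
  exact expected on-target yield of the placement rule (fragment start
  uniform over a window that makes the fragment overlap the interval), so
  realized mean coverage tracks the request to ~1 % — well inside the 5 %
  contract for targets ≥ 10 kb.
* **diploid sampling**: each fragment picks one of the member's two
  haplotypes with probability 1/2, so heterozygous sites show binomial
  allele balance per fragment, not per read.
* **errors**: i.i.d. per-base substitutions at `error_rate` (default
  0.005, a typical post-trimming short-read rate; the library insert —
  mean 250 bp, SD 25 — and the error profile are conventions, since
  instrument settings vary, and both are exposed in the configuration).
  An optional `homopolymer_slip` rate plants spurious 1 bp deletions at
  the ends of reference homopolymer runs ≥ 6 bp, emulating the classic
  poly-A artifact that downstream prioritization flags.

Reads are held as an internal read table carrying true placements (the
package deliberately contains no aligner); FASTQ export encodes the
placement in read names, the convention read simulators use.

## The pileup caller

The caller substitutes an explicit, minimal model for the black-box
pipeline a production lab would run; the downstream analyses depend only on
which calls clear a Phred-50 confidence threshold, not on caller internals.
Per-read allele probabilities given the three diploid genotypes are

| genotype | P(read shows alt) | P(read shows ref) |
|---|---|---|
| hom_ref | e/3 | 1 − e |
| het | (1−e)/2 + e/6 | (1−e)/2 + e/6 |
| hom_alt | 1 − e | e/3 |

with a single global error rate `e` (base qualities are not modeled
separately — the simulation controls `e` exactly). Reads showing a third
base contribute equally to all three genotypes and cancel in the
posterior. The prior is flat by default: in a diagnostic setting the caller
is tuned for sensitivity and specificity is delegated to the QUAL
threshold and downstream filters. The emitted confidence is
`QUAL = −10·log₁₀ P(hom_ref | data)`, capped at `qual_cap = 1000` to avoid
infinities when the posterior underflows; likelihoods are evaluated in log
space. Candidate SNV sites need `min_alt_reads = 2` supporting reads;
whether the 50-point threshold applies to the site QUAL or to genotype
quality is ambiguous in common usage, and this package applies it to the
variant QUAL. Multi-allelic pileups resolve to the highest-count alternate,
ties broken alphabetically.

Indels are genotyped with the same three-genotype model on
alternate-versus-reference *spanning* reads: a read supports an indel
allele only if it covers the event with at least 3 bp of flank on each
side, and reference support is counted the same way on non-carrier
haplotypes. Calls are left-normalized and restricted to the padded targets.

The caller is verified against a brute-force oracle (sequential per-read
products, no closed forms) on every pileup of depth ≤ 12, and its
calibration — the minimal alternate count reaching QUAL ≥ 50 at a given
depth — is recomputed analytically in the tests.

## Down-sampling rarefaction

`run_grid()` calls variants once on the full read set (the *pseudo-truth*
set), then re-calls on random subsets over fractions 1.00 down to 0.05 in
steps of 0.05 with 10 replicates each. The subsampling unit is the read
pair — mates are never split, which spares the caller orphan-mate logic and
has identical fraction semantics in expectation to per-read thinning.
Replicate `r` uses seed `base_seed + r` at every fraction, so subsets are
nested across fractions (common random numbers); this smooths the recall
curves without biasing their level. Recall matches on (chromosome,
position, ref, alt) and deliberately ignores genotype — the question is
whether the variant is still *seen*, not whether its genotype is
concordant.

Summaries follow report conventions: means and SDs of recovered counts to
1 decimal (ties rounding up), recall percentages to 1 decimal, effective
coverage = fraction × mean target coverage to 1 decimal. The C95 bracket
takes the largest-coverage grid point still below 95 % recall and the
adjacent point above it; endpoints are the *unrounded* product
`fraction × mean coverage` rounded half-up to integers (rounding the
1-decimal effective coverage a second time would shift some endpoints by
one fold). If replicate noise produces multiple crossings the highest one
wins with a warning; curves that never cross report `crossed = FALSE` with
the available boundary. `min_fraction_all_replicates()` reports the
smallest fraction from which upward a variant is recovered in every
replicate, with the mean replicate depth at its site.

Two properties of this design deserve emphasis. First, recall at fraction
1.0 is 100 % *by construction* — the pseudo-truth set is the fraction-1.0
call set, so the curves are optimistic at the high end and no asymptotic
total-variant extrapolation is attempted. Second, the synthetic C95
brackets land lower (≈ 21–32× for SNPs at default settings) than the
40–60× a realignment-based production pipeline reports on real data: the
bespoke caller sees true read placements and a single known error rate, so
it loses variants later than a pipeline that must also survive mapping
ambiguity, indel realignment and base-quality noise. The machinery —
grids, brackets, per-variant minimal fractions — is exactly comparable; the
absolute bracket values are a property of the caller and world, and a green
test establishes the *relationships* (monotone decay, indel recall below
SNP recall, hom variants callable shallower than hets), not the real-data
coverage numbers.

## Variant prioritization and segregation

The cascade consumes an annotated variant table (the column dictionary is
documented on `annotated_variants()`); it does not re-implement annotation
or pathogenicity predictors — ensemble outputs are input columns, the way a
lab consumes them. Filters, in order: overall population frequency (fail
iff any database frequency ≥ 0.05; absent data passes — a variant with no
frequency record is a rare-variant candidate by definition), maximum
sub-population frequency (same boundary), genotype QC (GQ ≥ 20 and
depth ≥ 4, inclusive), functional class (nonsynonymous and splice-site
variants are diagnosis-eligible; synonymous and UTR variants stay in the
report, flagged), predictor consensus (*strong* iff the Mendelian ensemble
labels the variant disease-causing, with probability ≥ 0.5 inclusive when
only the probability is given — 0.500 is on record as a disease-causing
label; *weak* if only the general pathogenicity classifier says so), and
inheritance compatibility (AR keeps homozygotes, optionally same-gene het
pairs as compound-het candidates — off by default; AD keeps any carrier).
The mandatory filters commute, so the shortlist is their intersection and
order is presentational; the final candidates need strong consensus plus
inheritance compatibility and are ranked by ensemble probability (the
ranking rule for two strong candidates is a convention of this package).
Indels at the end of a ≥ 6 bp homopolymer with multi-allelic pileups are
flagged `suspected_artifact`. `segregation_check()` verifies Mendelian
transmission and model compatibility, returning
`consistent_with_incomplete_penetrance` (rather than inconsistent) when an
unaffected AD carrier is observed.

The synthetic annotation generator (`synth_annotations()`) draws benign
ensemble probabilities from Beta(1, 10) and causal ones from Beta(8, 2),
with 40 % of benign variants common enough to fail the frequency filter and
5 % failing QC; under these defaults the planted causal variant is
recovered as the sole candidate in well over 95 % of simulations, which the
acceptance suite checks over 100 seeded runs. The generator emulates the
*distributional shape* of annotation output, not any particular
predictor's behavior.

## Benchmarking

`match_and_score()` evaluates calls against a truth set per variant class
with left-normalized exact site+allele matching (no distance windows —
normalization is the documented equivalence rule), optionally requiring
genotype concordance. Precision is undefined (NA) for a class with no
calls. On default synthetic data at 200× / e = 0.005 the caller clears the
external-validation-style bars (SNV recall ≥ 96 %, precision ≥ 99 %, indel
recall ≥ 85 %); clearing them on *synthetic* data validates the pipeline's
internal consistency, not its performance on real reads.

## Reproducibility and numerical conventions

Every stochastic operation takes an explicit seed; the orchestrator
(`replicate_experiment()`) derives per-stage seeds deterministically from
one top-level seed and records them in a manifest, and two runs with the
same configuration reproduce every emitted table byte for byte. Rounding of
reported values is half-up at the stated precision (`round_half_up()`),
because that is how coverage and recall figures are conventionally
printed; internal computations are never rounded. Genotype posteriors are
computed in log space with a max-subtraction, and the Phred cap handles
posterior underflow. Degenerate inputs have defined behavior: zero-depth
sites are no-calls, empty truth classes give NA recall with a warning,
empty variant sets produce valid header-only VCFs, and a single-fraction
grid degenerates to the 100 % point.

## Known limitations

No aligner, so FASTQ re-import relies on placement-encoding read names; no
duplicate marking, base-quality recalibration, haplotype assembly, or
structural/copy-number variation — the analysis is limited to SNVs and
small indels, as any pileup-based approach is. Capture bias is modeled at
interval granularity (no GC-dependence within intervals). The caller's
error model is a single global substitution rate. Predictor internals and
population databases are emulated, not queried. These boundaries are
deliberate: each one either requires data that cannot ship with a package
or machinery (alignment, assembly) that would dominate the codebase
without changing the depth-requirement and prioritization questions the
package exists to answer.
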