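---
title: "Methods: EST-based miRNA discovery and validation analytics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: EST-based miRNA discovery and validation analytics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirseedscan)
```

This vignette is the package's account of the science it implements:
the models and procedures, the parameters that matter and their
defaults, the numerical choices, what the synthetic-data generators do
and do not emulate, and the known limitations.

## The discovery model

Plant miRNAs are deeply conserved, so a new species' miRNAs can be
mined by homology: a mature miRNA from any plant that aligns almost
perfectly to a transcribed sequence, in a context that folds back on
itself, is a strong candidate. The package implements that chain at
desk scale.

**Preprocessing.** `trim_polyAT()` removes terminal poly-A (3′) and
poly-T (5′) runs of at least `min_run` bases, tolerating one
interrupting base per 10 bases of run; trimming iterates until stable,
so it is idempotent. `mask_low_complexity()` is a DUST-style masker:
each window of width `window` (default 64) is scored by
$\sum_t c_t(c_t-1)/2 \,/\, (k-1)$ over its triplet counts $c_t$
($k$ = number of triplets), and windows scoring strictly above
`threshold` (default 2) are soft-masked. Masked bases are excluded from
seed matching but remain available inside extensions, mirroring
soft-masking semantics in sequence search. `assemble_greedy()` is a
deliberately simple overlap-layout assembler (merge the longest
suffix–prefix overlap ≥ `min_overlap` = 30 at identity ≥
`min_identity` = 0.95, repeat): full assemblers add quality awareness
and chimera handling that do not change what the downstream homology
scan sees at the scales this package targets. Contaminant screening is
an exact 16-mer match against a user-supplied set, replacing
web-service vector screens.

**Homology scan.** `scan_homologs()` seeds on exact words of length 7
(the word size conventional for short-query nucleotide BLAST) on both
strands and extends each seed ungapped across the full mature length.
A hit requires no gaps, at most `max_mismatch` = 3 mismatches and at
least `min_len` = 18 nt aligned. No e-value is computed: with these
caps any reported hit would pass a permissive e-value screen anyway,
so the mismatch cap is the effective filter. The scan is guaranteed to
agree with an exhaustive Hamming slide whenever a true locus retains
one exact 7-mer — with ≤ 3 mismatches over ≥ 18 nt this holds unless
the mismatches are spread adversarially; the generators place
mutations so an intact terminal 7-mer always survives, and the
property suite checks set-identity against the brute-force oracle.
Whether the full mature must align or only an 18-nt core is exposed
via `min_len`; the default treats the full mature footprint as the
locus, consistent with the observed mature+100 precursor lengths.

**Precursor extraction and folding.** `extract_precursor()` takes 50
nt either side of the hit on the hit strand; candidates whose flanks
truncate below 20 nt are rejected. Absent truncation the precursor
length is mature + 100 (20-nt matures give 120-nt precursors, 21-nt
give 121). `fold_hairpin()` is a pluggable contract: the built-in
engine is a simplified nearest-neighbour model — only stacked pairs
contribute energy (GC 1.5, AU 1.0, GU 0.5 kcal/mol per pair, a stack
scoring the sum of its two pairs), minimum hairpin loop 3, no dangles
— solved exactly by dynamic programming in C++, with ties broken
toward fewer pairs. The external engine shells out to RNAfold at its
default 37 °C parameters. The built-in model's energies are coarser
than a full Turner model (it overestimates stability of long helices
and ignores loop penalties), but every downstream statistic takes MFE
as an input, so engine choice cannot affect the hairpin-statistic
arithmetic; the two engines provably agree on designed perfect
inverted repeats, which the tests exercise.

**Hairpin statistics.** For a precursor of length $L$ with fold energy
MFE: $\mathrm{GC\%} = 100(G+C)/L$, $\mathrm{AU\%} = 100 -
\mathrm{GC\%}$, $\mathrm{AMFE} = 100\,\mathrm{MFE}/L$ and
$\mathrm{MFEI} = \mathrm{AMFE}/\mathrm{GC\%}$ with GC% as the
percentage number. Values are kept at full precision; display rounding
is two decimals, half away from zero, and test comparisons use an
absolute tolerance of 0.005. One published AMFE cell in the reference
candidate set is internally inconsistent with its own MFE and length
(and one MFEI cell is off-rounded); only self-consistent cells are
used as golden values.

**Classification and curation.** `triplet_features()` encodes each
interior position by the paired/unpaired status of its 3-window
(brackets of either orientation count as paired — the original triplet
encoding does not distinguish arm) crossed with the middle base: 32
frequencies summing to 1. The published pre-trained SVM for this
encoding is not redistributable, so `train_classifier()` fits a
linear-kernel SVM on generator output (planted hairpins vs
mononucleotide shuffles); this preserves the stage's mechanics and
testability, and held-out accuracy on generator data exceeds 0.9.
`exclude_coding()` replaces BLASTx/Rfam screens with two documented
rules: any ORF of ≥ 60 codons in any of the six frames, or any exact
16-mer shared with a supplied rRNA/tRNA/snRNA set, drops the
candidate. `curate()` makes the usual manual rules programmatic:
mature wholly in one arm (no base in a terminal loop, no self-pairing
across the loop), mature/star mismatches (counted as unpaired mature
bases) ≤ 6, no multibranch junction inside the mature, AU% in
[30, 70], |MFEI| ≥ 0.5. The |MFEI| default is 0.5 rather than the 0.85
often quoted, because accepted candidates in the motivating lineage
reach only ≈ 0.61; curation is monotone in all thresholds.

## Target scoring

`score_site()` aligns a mature antiparallel to a transcript window
(window length within ±1 of the mature): each mismatch costs 1, each
G:U wobble 0.5, each gap 2, all doubled at miRNA positions
2–`seed_end` (default 13) from the 5′ end. The minimal-penalty global
alignment over ≤ 1 gap is found by a small three-state DP and equals
exhaustive enumeration (a tested invariant). The defaults (cutoff 3.0,
seed 2–13, ≤ 1 gap) follow the published scheme of the widely used
plant target server, since no explicit parameter panel is otherwise
stated; they are all configurable. `call_mode()` applies the
central-complementarity convention: a mismatch or gap at positions
10–11 blocks slicing, giving a translational-repression call; wobbles
do not. Target-site accessibility energy is not scored — a stated
fidelity limitation.

## Enrichment

`hypergeom_tail()` computes $P(X \ge k)$ for
$X \sim \mathrm{Hyper}(N, K, n)$ by log-sum-exp over `lchoose` terms,
stable for large counts; it matches the exact distribution to 1e−12
over an $N \le 60$ grid. `bh_adjust()` is the Benjamini–Hochberg
step-up within one family. `enrich()` tests only terms with ≥ 1 study
hit and takes the BH family size from the tested terms, matching
common GO-tool behaviour. The significance default is $\alpha = 0.05$;
the source text prints "0.05%", almost certainly a typo for 5%, and
the literal 0.0005 remains available through `alpha`. No GO-graph
propagation is performed.

## Expression analytics

`normalization_factor()` implements geometric-mean multi-reference
normalization: per reference gene, a sample's relative quantity is
$2^{-\Delta Ct}$ against that gene's across-sample mean; the sample
factor is the geometric mean across references. Replicates are
summarised by mean Ct before ΔCt and the replicate ΔCt SD propagates
to a log2-scale SE — standard 2^-ΔΔCt practice. Because the reference
panels named for the different assays in the motivating study
contradict each other between methods and figure legends, the module
accepts any reference panel per assay rather than hard-coding one.
`fold_change_ddct()` returns $2^{-\Delta\Delta Ct}$ against a
calibrator sample and is invariant to a common Ct shift within a
sample.

RA-PCR compares three amplicons per transcript (5′ of, spanning, and
3′ of the putative cleavage site). Since reverse transcription cannot
cross a cleaved site, cleavage depletes the site-spanning region
relative to the 3′ region: `rapcr_reduction()` reports
$(1 - q_{mid}/q_{3'}) \times 100$ with the 3′ region as denominator,
invariant to common rescaling; `call_cleavage()` calls a transcript
cleaved only when every stage shows reduction above the threshold
(default 0). The 5′ region is reported descriptively but not used in
calls, as its accumulation is empirically too variable to be
diagnostic. `mirna_target_correlation()` reports Spearman (default) or
Pearson correlation across ≥ 3 stages with a sign call at |r| > 0.5.

## HPLC quantification

`fit_calibration()` is OLS of peak area on standard concentration
(5/10/20/40/50 ppm five-point series); the intercept is retained —
forcing the origin would be an uncited assumption — and $r^2$ is
reported for QC. `quantify()` inverts the line and applies the
extraction arithmetic $\mu g/g = \mathrm{ppm} \times V_{ml} \times
\mathrm{dilution} / m_g$ with defaults of 0.125 g flour and 6 ml
extract; areas below the intercept clip to 0 with a warning.
`profile_totals()` sums the three aglycones. Replicates default to
mean-of-3 before totals.

## Phylogeny

`p_distance()` uses pairwise deletion of gap/N columns; the distance
model is deliberately the p-distance, the simplest defensible default
when the original analysis does not state its model.
`neighbor_joining()` wraps the Saitou–Nei agglomeration and
post-processes negative branch lengths by clamping to zero and moving
the deficit to a sister edge, preserving path lengths through the
parent; NJ is exact on additive matrices, which the tests exploit by
generating random 5–8-taxon trees. `bootstrap_support()` resamples
alignment columns, rebuilds the NJ tree per replicate, and reports the
percentage of replicates containing each original bipartition;
alignment itself is out of scope (inputs must be pre-aligned). The
conventional replicate count is 1000; the test suite and acceptance
script use 50–100 replicates, which the package treats as its chosen
problem size for routine verification since support estimates enter
only through determinism and strong-signal checks there.

## Synthetic data: what it does and does not emulate

The generators produce every input the pipeline consumes, with ground
truth serialised alongside:

- `gen_est_corpus()`: 300–800-nt uniform-base background units; planted
  units embed a reference mature (mutated per a stated spectrum, final
  7-mer kept intact) followed by an 8-nt loop and the reverse
  complement of the planted copy, so the extracted precursor folds
  arm-to-arm; 30% of units get 15-nt poly-A tails. Defaults (200
  units, 10 plantings) are the package's standing desk-scale study
  condition.
- `gen_hairpin_precursor()`: the mature+100 construction with an exact
  number of unpairable star positions (mutations chosen so the star
  base can neither WC- nor GU-pair its mature partner).
- `gen_expression_tables()`: 2 genotypes × 4 stages × 3 replicates;
  reference genes constant up to noise (default SD 0.1 Ct, a typical
  technical-replicate spread); target Ct = calibrator Ct − log2(fold);
  RA-PCR mid-region Ct inflated by −log2(1 − reduction/100) for
  cleaved transcripts (planted cleavage fraction 0.7, reductions
  drawn 55–95%).
- `gen_annotation()`: multinomial background terms; the planted term
  carried by study genes at `odds` × the 5% background rate.
- `gen_hplc()`: standards on the planted line plus noise; sample areas
  obtained by inverting the quantification arithmetic. The built-in
  concentration profile rises over 35–65 DAF with 65-DAF totals of
  606.36 and 1382.51 µg/g for the low- and high-isoflavone genotype;
  the split across the three aglycones is synthetic.

What the generators do **not** emulate: EST basecalling error
profiles, realistic codon/GC structure of background transcripts,
amplification-efficiency differences between qPCR assays, correlated
replicate noise, or chromatogram peak-shape effects. Passing tests
therefore demonstrate that the algorithms are implemented correctly
and recover planted parameters under idealised noise — not that the
pipeline's biological error rates on real EST corpora match those of
the full-scale web-tool chain it mirrors. Corpus-scale counts from the
original analysis depend on external database state and are out of
scope.

## Numerical choices and degenerate inputs

- Fold DP ties break toward fewer pairs; unpairable sequences return
  an all-dot structure with MFE 0.
- MFEI requires GC% > 0; zero-GC precursors raise an error.
- Display rounding is half-away-from-zero at 2 decimals; tests compare
  at 0.005 absolute.
- The expectation DP uses exact arithmetic on penalties in units of
  0.5, so equality tests against enumeration are safe at 1e−9.
- `hypergeom_tail(k = 0, ...)` is exactly 1; inconsistent counts raise
  domain errors rather than returning NaN.
- Constant expression series yield NA correlations with an explicit
  "none" sign call.
- All-identical alignments produce arbitrary topologies; bootstrap
  output is flagged `degenerate`.
- Every generator seeds its own RNG from the caller's seed; identical
  seeds give byte-identical outputs.

## Problem sizes

Routine verification runs at the package's chosen desk scale: 200-unit
corpora with 10 plantings for discovery recovery; ≤ 50-unit instances
for oracle identity; 200 genes for expression recovery; 500 null
replicates for the BH flag rate; 100 random trees for NJ recovery;
50–100 bootstrap replicates. These sizes are stated here as the
package's own defaults for reproducible checking.
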