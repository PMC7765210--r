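---
title: "Mining and characterizing a plant lipoxygenase gene family"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining and characterizing a plant lipoxygenase gene family}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(loxfamily)
```

## The problem

Plant lipoxygenases (LOXs, EC 1.13.11.12) are non-heme iron dioxygenases
that oxygenate linoleic/linolenic acid at carbon 9 (9-LOX) or carbon 13
(13-LOX); the 13-LOX branch feeds jasmonic acid (JA) and methyl jasmonate
(MeJA) synthesis. Annotating the LOX complement of a newly sequenced
genome is a decision problem: keyword and homology searches over-call, so a
candidate is accepted as a *bona fide* LOX only if it carries

1. a PLAT/LH2 β-sandwich domain,
2. a complete catalytic LOX domain, and
3. the conserved 38-residue 5-histidine signature
   His-(X)<sub>4</sub>-His-(X)<sub>4</sub>-His-(X)<sub>17</sub>-His-(X)<sub>8</sub>-His
   inside the LOX domain.

`loxfamily` implements this rule and everything downstream of it —
physicochemical properties, subfamily classification, exon/intron
structure, tandem/segmental duplication detection, distance-based
phylogeny, and 2^−ΔΔCt qPCR statistics — as testable functions, exercised
end to end on synthetic genomes with known ground truth. The model system
is the nine-member family of the greater duckweed *Spirodela polyrhiza*
(2 × 9-LOX, 7 × 13-LOX), whose published per-gene summary and
domain-coordinate tables ship with the package (`lox_gene_table()`,
`lox_domain_table()`) as reference inputs.

## The decision rule and its parameters

`scan_candidates()` runs two position-frequency profile motifs (PLAT,
100 aa; LOX, 470 aa) plus the exact 5-His pattern scanner over each
candidate protein, and `bona_fide_filter()` applies the rule. Parameters
that matter:

* **Profile threshold** — default 0.6 × the consensus (maximal) log-odds
  score, in bits. At the packaged 0.7 match probability per consensus
  column this leaves a margin of several hundred bits between a 10%-mutated
  domain copy and a truncated or absent one, so the decision is effectively
  noise-free at desk scale. Real genomes should instead supply HMMER /
  InterProScan intervals via `read_domain_table()`; the packaged profiles
  are a desk-scale stand-in, because the contribution here is the decision
  rule, not the scanner.
* **Minimum complete-LOX width** — 450 aa. The narrowest published LOX
  interval in the reference family is 492 aa (SpLOX8), and the rejected
  putatives lack most of the catalytic domain, so any cutoff in roughly
  350–490 aa draws the same line; 450 leaves headroom on both sides.
* **5-His geometry** — fixed: the signature spans exactly 38 residues with
  His at relative positions 1, 6, 11, 29, 38. All nine published
  5-histidine intervals have width 38 and lie inside their LOX intervals,
  which the package enforces as a validation check
  (`check_5his_containment()`).

Subfamily assignment is nearest-reference classification by global
alignment percent identity against a labeled panel (ties broken by
similarity, then reference id). 13-LOX members are sub-typed: type II iff
an N-terminal plastid transit peptide is predicted. No predictor or cutoff
is published for the reference family, so the package uses a transparent
compositional heuristic over the N-terminal 60 residues: Ser+Thr ≥ 25%,
Asp+Glu ≤ 8%, and basic-minus-acidic residue count ≥ 0. The net-charge
floor is 0, not +1: transit peptides must not be net acidic, but a neutral
Ser/Thr-rich leader still qualifies (an all-Ser leader is the canonical
positive control). All three thresholds are arguments.

## Sequence comparison

`global_align()` is Needleman–Wunsch with affine gaps, delegated to
`Biostrings::pairwiseAlignment` (a gap of length L costs open + L·extend)
with EMBOSS-style defaults: BLOSUM62, gap 12/2 for proteins; +5/−4, gap
16/4 for nucleotides. Identity is identical columns over the full
alignment length; similarity is columns with a positive substitution
score; ambiguity codes count as mismatches. The engine is checked in the
tests against exhaustive enumeration of all alignments on short pairs.

Duplication classification follows the published operational rules:
tandem arrays are clusters of 2–5 genes on one scaffold whose total span
stays within 100 kb, grown greedily along the coordinate-sorted gene list
with a 70% protein-identity floor for joining (below the smallest published
tandem-pair identity, 75.77%, and well above background); remaining pairs
with similarity > 90% are segmental calls, with tandem membership taking
precedence. The >90% rule is applied to protein similarity — the published
criterion does not say nucleotide or protein — with the matrix switchable.
Intervening non-family genes are ignored (pure coordinate-window rule).

Intron phases are recomputed from CDS lengths (cumulative coding length of
upstream exons mod 3, 5′→3′ on the coding strand); the GFF3 phase column
is read but never trusted.

## Phylogeny

The published family tree was a maximum-likelihood JTT tree; reproducing
its 63-taxon topology is out of scope. The package's contract is
topology-level: subfamilies must separate into clades. It uses
Poisson-corrected distances (d = −ln(1 − p), pairwise deletion of gap
columns; an error if p = 1) with Saitou–Nei neighbor joining (`ape::nj`;
negative branch estimates clamped to zero and counted). Bootstrap support
resamples alignment columns with replacement under a fixed seed (default
1000 replicates, reduced in the bundled analyses for speed) and reports
the percentage of replicates containing each bipartition of the full-data
tree.

The multiple alignment behind the distances is a deterministic
**center-star** construction: the sequence with the highest summed pairwise
identity is the center, every other sequence is aligned to it pairwise
with the same global engine, and gap patterns are merged on the center
("once a gap, always a gap"). This was chosen over a guide-tree
progressive aligner because it satisfies the same contract (equal-length
rows, de-gapping restores inputs, indels placed by the pairwise optimum)
with no profile–profile scoring, and is exactly reproducible. It is not a
general-purpose MSA: for the intended inputs — a single family at moderate
divergence — the center-star approximation is comfortably sufficient for
distance estimation.

## Expression statistics

`delta_delta_ct()` implements the Livak 2^−ΔΔCt method with
multi-reference normalization: per sample, ΔCt = Ct(target) − mean
Ct(references) (the arithmetic mean of Cts equals the geometric mean of
quantities); per condition × timepoint group, ΔΔCt = mean ΔCt −
mean ΔCt(control at the same timepoint); fold = 2^−ΔΔCt. Statistics run on
the ΔCt scale, where Gaussian noise in Ct stays Gaussian; folds are
reported on the ratio scale. A target undetected in the control group is
flagged `not_expressed`, mirroring the cycle-ceiling convention (no signal
at 45 cycles), rather than silently dropped.

`anova_dunnett()` pairs the standard one-way ANOVA F test with Dunnett's
many-to-one comparisons. Adjusted p-values come from the null distribution
of the maximum absolute Dunnett t, estimated by seeded Monte Carlo
(default 10^5 draws) with the exact correlation structure (shared control
mean, shared pooled variance). The Monte Carlo error on an adjusted p is
about ±0.002 at 10^5 draws; the tests cross-check against the closed-form
single-step adjustment in `multcomp` and verify family-wise error
calibration (0.05 ± 0.02 over 1000 null simulations). Significance
categories use the conventional `*`/`**`/`***`/`****` thresholds at 0.05,
0.01, 0.001, 0.0001.

Trajectory classification is deliberately coarse: culture-aging profiles
over day 14/21/28 are monotone-up, peak-mid, monotone-down or static
(strict inequalities, ties to static); treatment time courses are
upregulated / downregulated / static / mixed from the per-timepoint
adjusted p and fold direction.

## What the synthetic generator emulates — and what it does not

`generate_genome_bundle()` is the package's stand-in for downloaded
assemblies. Its defaults *are* the study conditions: nine true family
members split 2:7 between subfamilies, six of seven 13-LOX with a transit
peptide, six decoys each violating exactly one clause of the bona-fide
rule, and two tandem clusters (sizes 2 and 3) within 20 kb and 40 kb
spans. Sequence backgrounds are i.i.d. uniform — the simplest null that
keeps false motif hits rare and quantifiable. Subfamily archetypes are two
fixed 60-aa blocks at >40% mutual divergence, copied into members at a 10%
per-site substitution rate. Tandem-cluster members descend from a shared
per-cluster ancestor at half that rate, reflecting their recent common
origin and producing within-cluster identities in the 80–90% band the
published arrays show; unrelated family members sit near 60–75%, so the
70% tandem floor separates the two regimes. Gene models have 2–8 exons
with 80–400 bp introns; CDSs are reverse-translated with uniformly random
synonymous codons; qPCR tables draw Ct = baseline − log2(fold) + N(0, sd)
with reference genes unaffected by treatment.

What it does **not** emulate: codon usage bias, repeats and intergenic
structure, UTRs, alternative transcripts, paralog families outside the
planted one, amplification-efficiency differences between primer pairs,
and between-run qPCR batch effects. Passing the end-to-end suites
therefore shows the *decision logic and arithmetic* are correct under
clean, planted truth — not that the packaged toy profiles would annotate a
real genome; for that, real domain scans are the supported input path.
One seed drives every file in a bundle; the same config and seed are
byte-identical.

## Numerical choices

* pI by bisection of the Henderson–Hasselbalch net charge on pH ∈ [0, 14],
  iterated to interval convergence (< 10^−7 pH) rather than stopping at the
  charge tolerance alone, which on long chains can stop visibly short of
  the root; the tests pin the result to a 10^−5-grid search oracle.
  EMBOSS-style pKa constants are packaged and swappable — constant-set
  choice moves pI by about ±0.2, which is why reproducing published pI
  values from real sequences is a tolerance check (±0.3), not a golden
  test. Molecular weight uses average residue masses plus one water.
* Alignment traceback determinism is inherited from the engine; all
  randomized procedures (generator, bootstrap, Dunnett Monte Carlo) take
  explicit seeds and restore the caller's RNG state.
* Degenerate inputs are contracts, not crashes: empty candidate sets,
  headers-only reports, single-exon genes (no introns), zero subfamily
  counts (ratio reported as undefined), saturated Poisson distances and
  zero within-group variance are all explicit errors or flagged results.

## Problem sizes in the bundled analyses

The shipped analysis scripts and test suites run at desk scale, chosen so
a full pass stays comfortable on one CPU: 15-gene genomes on 4 × 800 kb
scaffolds, 10–20 generator seeds for the recall/precision and
tandem-recovery sweeps, 200 simulated qPCR datasets for fold-recovery,
1000 null simulations against a 2 × 10^5-draw Dunnett critical value, and
200 bootstrap replicates in the analysis tree (the function default
remains 1000). These sizes are statements about the demonstrations, not
limits of the code.

## Known limitations

* The profile motifs are toy stand-ins; no Forward/Viterbi pHMM scoring.
* The transit-peptide heuristic separates the generator's type I/II
  archetypes perfectly but is not a validated predictor for real proteins.
* No Ka/Ks dating, synteny/collinearity detection, or
  amplification-efficiency (Pfaffl) correction.
* Center-star alignment degrades for deeply divergent or length-variable
  families; it is fit for purpose here, not a MUSCLE replacement.
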