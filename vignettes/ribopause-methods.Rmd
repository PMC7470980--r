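---
title: "Models and methods behind ribopause"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ribopause}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ribopause)
```

## The problem

When a bacterial toxin inactivates one species of aminoacyl-tRNA — for
example a GNAT-family acetyltransferase that blocks charged Gly-tRNA —
ribosomes stall whenever the corresponding codon enters the A-site.
Ribosome profiling (Ribo-seq) makes this visible genome-wide: footprint
3'-end density piles up at the affected codons, and because stalled
ribosomes drop off prematurely, total density declines towards the 3' end
of coding regions. `ribopause` implements the codon-level analysis of that
signal: 3'-end densities, A-site offset calibration, pause scores, and a
compositional test for the along-ORF density shift, together with a
footprint simulator that generates data with exactly this structure and an
RNA mass module for the orthogonal mass-spectrometry readout
(aminoacylation +57 Da for glycine, N-acetylation +42 Da, on the tRNA
3'-terminal RNase T1 fragment).

## Density and filters

Ribosome density is the per-nucleotide count of footprint **3' ends**,
normalised to reads per million uniquely mapped (RPM). The pipeline starts
from aligned footprint records (contig, 3'-end position, strand, length);
trimming and alignment are upstream concerns and out of scope.

Filters follow standard bacterial Ribo-seq practice:

* reads of 15–40 nt (inclusive) are retained;
* ORFs shorter than 170 nt, or with mean raw footprint count below 1 per
  codon (0.33 per nt), are excluded;
* the first 50 nt after the start codon and the last 20 nt before the stop
  are trimmed from every analysis window.

Two choices here were genuinely open. The per-codon density floor is
applied to **raw counts**, not RPM — a threshold of "1 per codon" is only
meaningful pre-normalisation, and this makes inclusion decisions invariant
to library depth (a property the test suite asserts). Second, the floor is
evaluated over the full ORF, before end-trimming, since inclusion is a
property of the gene, not of the trimmed window. Footprints whose 3' end
falls inside two overlapping same-strand ORFs are counted for both, and the
double-counting is reported in the filter report; attribution of shared
reads is a policy, not something the data decide.

Coordinates are 0-based half-open internally (BED-like), 1-based inclusive
in files meant for human reading; sequences are always stored on the coding
strand.

## A-site offset calibration

A footprint's A-site codon sits a fixed distance upstream of its 3' end
(11 nt for the MNase-generated libraries this models). The offset is
calibrated from the start-anchored metagene profile: with the ORFs aligned
at their start codons, 3'-end density is zero upstream of the offset and
begins exactly at it, so the calibrator scores each candidate offset by the
density at that position minus the mean over the three positions upstream,
and returns the maximum. The contrast is deliberately one nucleotide wide:
3'-end pileups recur with codon periodicity, so any window of three or more
nucleotides ties across neighbouring candidates and cannot resolve the
onset. Ties (if any) go to the smaller candidate for determinism. A flat
profile — no step larger than half the overall mean — is an error advising
a manual offset, rather than a silently arbitrary pick.

The stop-anchored profile serves as a reading-frame consistency check. ORF-
local density tracks end at the stop codon, so footprints whose 3' ends
project past it are truncated, and the 3'-most position carrying density
constrains the offset only modulo 3; the calibrator checks this congruence
and warns on disagreement. The toeprint utility is the same idea for primer
extension data: reverse transcriptase stalls 13 nt downstream of the first
nucleotide of the A-site codon of an arrested ribosome.

## Pause scores

The pause score at a nucleotide is its density divided by the mean density
over the gene's trimmed window, so scores average to exactly 1 over every
window and are dimensionless and depth-invariant. Using the trimmed window
(not the full ORF) as the denominator keeps the mean-one identity on the
positions actually analysed. A codon occurrence is scored by the mean of
the three per-nucleotide scores at its offset-shifted positions; occurrences
whose shifted positions leave the window are skipped and counted. Codon
scores aggregate to amino-acid scores by occurrence-weighted means. The
genome-wide table uses all included ORFs by default; a `top_n` argument
restricts it to the densest genes when a per-gene view is wanted.

## Compositional comparison of along-ORF profiles

Each window is cut into 10 contiguous segments; the segment shares of
window density form a 10-part composition (summing to 100). Window length
modulo 10 leaves up to 9 spare nucleotides, which are assigned one each to
the 3'-most bins — deterministic, and biased (if at all) against the
direction of the effect being tested, since extra 3' nucleotides can only
dampen an apparent 3' decline. Compositions carry only relative
information, so:

* central tendency is the part-wise geometric mean, re-closed to 100;
* inference happens after the isometric log-ratio (ilr) transform, which
  maps the 10-simplex isometrically onto R^9, where ordinary multivariate
  statistics apply.

The default ilr basis is the pivot (sequential binary partition) basis in
bin order, recorded as `pivot-1` in every output; a Helmert basis is
provided because Hotelling's T² must be — and is asserted to be, at 1e-8 —
invariant under any orthonormal basis change. Zero parts (a bin with no
footprints) are handled by multiplicative simple replacement: zeros become
65% of that composition's smallest nonzero part (floored at 1e-6), nonzero
parts shrink proportionally, and the vector re-closes. This is standard
compositional practice for count zeros; the replacement is per-ORF, so one
sparse gene cannot perturb another's coordinates.

Conditions are compared with a paired Hotelling's T² on the per-ORF ilr
differences: T² = n·d̄ᵀS⁻¹d̄, F = T²(n−p)/(p(n−1)) on (p, n−p) degrees of
freedom with p = 9. Fewer than 10 paired ORFs, or a singular difference
covariance, are errors (the message suggests fewer bins). Mardia's
multivariate skewness and kurtosis statistics are reported as an advisory
normality check on the ilr coordinates — advisory because the exact
goodness-of-fit procedure behind compositional-normality tests varies
between implementations, and because the paired test's calibration is
checked directly by simulation anyway; the check never gates the pipeline.

## The simulator

The simulator is first-class, tested code: it defines the statistical
structure every downstream stage is validated against.

For ORF *o* and sense codon *k* (0-based; the start codon is codon 0), the
expected footprint count with A-site at codon *k* is proportional to
`dwell(codon_k) × (1 − q)^k`: codon-specific dwell times multiplied by
memoryless per-codon survival, the simplest model that produces a monotone
3'-ward decline. Counts are Poisson; each footprint's 3' end is placed
`offset` nt (default 11) downstream of its A-site codon's first nucleotide,
with an optional ±1 nt jitter flag for calibration-robustness experiments;
lengths are drawn from a rounded Gaussian (mean 25 nt, sd 3 nt) truncated
to 15–40 nt — the admissible range is all the data constrain, so the shape
is a stand-in. A truth table records every read's A-site codon for
parameter-recovery tests.

Under this model the expected mean A-site pause score of a codon class with
dwell multiplier *m* and genomic frequency *f* has the closed form
`m / (f·m + 1 − f)` (the pause score normalises by the gene mean, whose
expectation is `f·m + 1 − f` times the baseline). With *m* = 5 and
*f* = 0.1 this is 3.571, and the recovered value at a million footprints is
asserted to match within sampling error. Likewise `q = 0.005` over 200
codons implies a density ratio of 0.995²⁰⁰ ≈ 0.367 — the "one third of
ribosomes reach the ORF end" regime.

ORFs begin with ATG, end with TAA, contain no internal stops, and are laid
head-to-tail with 60 nt random spacers on one contig, on the plus strand by
default (`both_strands` exercises the minus-strand arithmetic). The
standard two-condition fixture pairs a "toxin" library (Gly dwell ×5,
q = 0.004) against a "control" library (Ser dwell ×2, q = 0, mimicking the
hungry-serine artefact of unstressed bacterial Ribo-seq); the pipeline run
on it calibrates the offset to 11 nt, puts Gly and Ser at the top of the
respective amino-acid tables, and rejects the paired compositional null.

What the simulator deliberately omits: sequencing error, alignment
ambiguity and multimapping, UMI/duplicate structure, nuclease sequence
bias, per-length offset variation, and any 5'-end assignment mode. Passing
tests therefore certify the analysis logic under the stated generative
model, not robustness to every artefact of real libraries.

## RNA fragment masses

RNase T1 cleaves 3' of unmodified guanosine; the digestion model cuts after
every unprotected G, leaves a 3' linear phosphate on upstream fragments
(the hydrolysed cyclic intermediate; a flag keeps 2',3'-cyclic ends,
−18.015 Da) and a 5'-OH downstream, and preserves the molecule's native 3'
terminus on the last fragment. `protected_positions` models modified
guanosines or missed cleavages — the diagnostic tRNA 3'-terminal fragment
UUUCCCGCUCCA contains an internal G that evidently survives digestion.

Masses are computed from elemental formulas with standard average atomic
weights — MALDI-TOF in linear mode measures average mass — with a
monoisotopic mode available. MH⁺ = Σ nucleosides + (n−1) × 61.97
(phosphodiester bridge) + terminal adjustments + adducts + 1.008. A printed
T in an RNA sequence is read as unmodified U: this reproduces the observed
fragment mass (≈3669 Da, matching the printed m/z 3670 within the 1 Da
measurement accuracy), whereas ribothymidine would add 14 Da and does not.
Aminoacylation adds the amino-acid residue mass (glycyl: C₂H₃NO =
57.05 Da), N-acetylation adds C₂H₂O = 42.04 Da and is only valid on an
aminoacylated fragment, and peptidyl-tRNA hydrolase treatment returns the
fragment to its unmodified mass exactly. Peak matching assigns each
observed m/z to the nearest theoretical candidate within a 1 Da tolerance,
ties to the lower mass.

## Problem sizes and numerical choices

The simulation-based checks run at sizes chosen to make their statistical
assertions sharp while staying desk-scale: offset recovery uses 20
replicates of 20 ORFs at 20,000 footprints across generating offsets
9–13 nt; the pause-score recovery uses 100 ORFs of 150–250 codons at 10⁶
footprints; the test-calibration study uses 500 null and 200 alternative
replicates of 50 ORFs at 37,500 footprints (≈5 footprints per codon, five
times the inclusion floor). Sampling-error tolerances are 3σ bands derived
from the replicate structure itself (per-ORF means for the pause score,
binomial for rejection rates), never ad-hoc constants. All randomness flows
from explicit integer seeds; identical seeds give byte-identical outputs,
including written files.

## Known limitations

* A single global 3'-end offset is used for all read lengths; libraries
  with strong length-dependent offsets would need per-length calibration.
* The drop-off model is memoryless; site-specific abortive events would
  produce step-like, not geometric, declines.
* The compositional test addresses the global along-ORF density shape
  only; it is not a per-gene differential test.
* The mass module covers MH⁺ ions of T1 fragments with at most aminoacyl +
  acetyl adducts; it does not parse spectrum files or model isotope
  envelopes.
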