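---
title: "ampliscan: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ampliscan: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

ampliscan implements an integrated analysis method for multiplex-PCR
amplicon panels of the BRCA1/BRCA2 type, where PCR products are fragmented
by 4-cutter restriction enzymes (MseI, Csp6I, FspBI — all leaving TA
5' overhangs), sequenced single-end, and analysed for germline and somatic
point variants, small indels and whole-exon copy-number changes. This
vignette records the models behind each stage, the tunable parameters with
their defaults, and the design decisions taken where the method description
left room.

## The read simulator and what it does (not) emulate

The simulator is the package's substitute for patient data: every
downstream stage is tested against reads whose ground truth is known.

* **Molecules.** Per amplicon, a Poisson number of template molecules with
  mean `reads_per_amplicon * copy_number / 2`. Each spiked variant is
  applied independently per molecule with its allele fraction, so a
  heterozygous variant is a Binomial(n, 0.5) subset of molecules — realised
  VAFs inherit that noise, as in any finite library.
* **Fragmentation.** Top-strand restriction digestion: a cut at every
  recognition-site occurrence at the enzyme's cut offset. Digestion is
  total and lossless (fragments concatenate to the input). By default each
  molecule is digested with *one* enzyme chosen uniformly (`digestion =
  "split"`), modelling a library split across the three enzymes; this is
  what produces overlapping fragments — and thereby several well-defined
  read start positions per reference column, which the depth-test filter
  depends on. `"combined"` digestion (all enzymes at once) is available.
* **Reads.** Fragments outside the 50–300 bp size-selection window are
  discarded; each retained fragment yields one read of
  `min(read_length, fragment)` bases from a uniformly chosen end/strand.
  The default read length 100 matches the ~99 bp mean the enzymatic
  libraries produce.
* **Errors.** Substitutions, insertions and deletions are injected per
  base. Indel rates are escalated multiplicatively inside homopolymer runs
  (run length ≥ 3), by a configurable factor per extra base beyond 2
  (default ×2; the functional form is not dictated by the method
  description, only that homopolymer indel errors dominate). Within a run
  an insertion and a deletion cancel in the emitted read — a sequencer
  observes only the net run length — and an insertion within ~2 bases of a
  deletion elsewhere collapses into mismatches under alignment. Because
  the platform rates one measures from alignments are these *observable*
  rates, the built-in profiles are calibrated: the injection scales are
  solved (exact Binomial expectations per run, plus the first-order
  pairwise-collapse term, weighted by the exact expected per-base
  sequencing coverage of the concrete molecule set) so that the expected
  observable event rates equal the profile's stated marginal rates.
* **Profiles.** Per 100 bases: Illumina-like 0.29 substitutions / 0.01
  insertions / 0.04 deletions, mean Q34; ion-semiconductor-like 0.23 / 1.27
  / 0.67, mean Q24 with a quality penalty of 4 Phred per extra homopolymer
  base (a 6-run's neighbourhood drops below Q10, reproducing the known
  failure mode in which low-quality homopolymer flanks starve the
  strand-bias tally).
* **Not modelled:** PCR duplicates and chimeras, FFPE deamination (C>T)
  beyond the generic substitution rate, paired ends, platform base-calling.
  A green simulation test therefore establishes algorithmic correctness
  under this stated world, not performance on real instruments.

The synthetic panel generator builds amplicons from 50–62 bp site-free
chunks joined by cyclically alternating enzyme sites, so single-enzyme
fragments stay under ~200 bp (every position is covered by a read from
either fragment end) and combined-digest fragments stay above 50 bp.
Amplicon lengths come out at ~280–460 bp, within the 186–812 bp range such
panels have; 20 bp primers flank each amplicon and one exon per amplicon is
annotated (inset 5 bp into the insert).

## The two-stage mapper

Seeding uses an FM-index (Burrows–Wheeler) over the panel reference.
Two 20 nt keys per read — skipping the first and last 4 nt — are searched
on both strands with at most 2 substitutions by bounded backtracking.
Implied read-start candidates within <5 nt are combined (single linkage,
minimum representative). Each cluster is aligned by Smith–Waterman with
match 10, mismatch −8, indel −9 per base and *no* gap open/extend
distinction, then rescored by the rearrangement pass: match 100, mismatch
30, deletion 10, insertion 1 per base, and **every base of an indel run
longer than 5 scores as a match**. The per-base reading of the long-indel
rule is deliberate: flat-penalty SW splits an 11- or 40-bp deletion across
accidental interior matches (e.g. `D3 M1 D4 M1 D3`), and under a
one-bonus-per-run reading the split form always outscores the merged run,
so no rescoring pass could ever reassemble the deletion. Per-base scoring
makes the merged run dominant while leaving short-indel and mismatch
preferences unchanged.

The rearrangement pass performs only linear-time rewrites, each adopted
solely on rearrangement score:

* left-shift of indels within repeats (ties broken leftmost);
* merging of same-type indel runs separated by ≤ 5 aligned columns;
* re-anchoring of long terminal soft clips (≥ 8 bases) across a deletion of
  up to 60 bp, with a 12-mer exact seed and sparse mismatches tolerated in
  the extension;
* trimming of mismatch-dense read ends back to the last ≥12 M anchor,
  followed by the same re-anchoring.

Reads whose 5' and 3' keys seed two clusters a deletion apart additionally
get a spliced two-frame candidate (prefix frame at the left start, suffix
frame at the right start, split point maximising matches — O(L) with
cumulative sums). This is what detects 40-bp deletions from 100-bp reads,
where no contiguous DP path is competitive.

Cluster ties by rearrangement score are flagged multi-mapping and excluded
from variant calling; reads scoring below 60% of a perfect read are
unmapped (the original method reports mapped fractions but no rule; the
floor is configurable). Alignments beginning in primer intervals are
soft-clipped down to the insert, since primer-derived bases are synthetic
and can mask real variants.

## Pileup and calling

Pileups exclude soft-clipped bases and multi-mapping reads; insertions are
attributed to the column left of the inserted bases, deletions to their
first deleted base (interior deleted columns count toward depth only).
Germline calling requires depth ≥ 50 and VAF ≥ 25% (SNVs and indels
alike); somatic (FFPE) calling requires depth ≥ 100 and VAF ≥ 10%. The
boundary is inclusive; zygosity is annotated heterozygous below VAF 0.75.
The spec's fixed 25% indel limit is kept as the germline threshold and as
the HP-percentage filter cutoff, but somatic candidate emission uses the
10% threshold for indels too — the FFPE dilution experiment the method
reports (an insertion detected at expected VAF 12.5% under the 10%
threshold) is impossible otherwise.

Indel VAFs use a **run-spanning denominator**: only reads covering the
whole homopolymer run containing the event plus one anchor base on each
side can witness an indel there, so reads ending inside the run are
excluded from the denominator (they would otherwise dilute every run-indel
VAF below its true value, in proportion to the local fragment layout).
Both groups of the depth test and the strand tallies of indel candidates
are restricted the same way. A run's insertion and deletion fractions are
reported at one position (the run's first base) so the run-level filters
compare like with like.

## The homopolymer error database and the filter cascade

The database is built from ≥ 2 (by design 20) wild-type samples: per
position, the 1-bp insertion, 1-bp deletion and 2-bp insertion event
fractions, averaged across samples. Positions with an averaged 1-bp indel
frequency ≥ 10% are high-error; below that the platform error is
"reliable" and indel candidates pass the homopolymer filters untouched.

Ion-torrent candidates run the cascade in fixed order — depth test,
insertion overrun, deletion displacement, HP percentage, strand bias — with
SNVs exempt from the three indel filters; Illumina candidates are accepted
as called (the validation data needed no filtering). Failed candidates are
retained with their flags for visual inspection rather than deleted.
Thresholds (all configurable): depth-test α = 0.05, insertion overrun 20
percentage points, deletion displacement 30 points, HP percentage 25%,
strand bias 35 points, context-quality floor Q10.

* **Depth test.** Mann–Whitney U on the read start positions of wild-type
  vs mutant reads. Starts are first grouped into fragmentation start sites
  (single linkage, <5 nt — the aligner's clustering distance): an indel
  carrier's fragments are one base shorter downstream, and without
  grouping that deterministic ±1 jitter is mistaken for an artefact at
  high depth. Groups with fewer than 3 reads on either side pass by
  default. "Depth test 5" is read as a 5% significance level: the other
  four thresholds are percentages, and a raw U cutoff would not scale with
  depth. The U statistic uses midranks; the p-value is exact (via the null
  U distribution) for untied samples with combined n ≤ 20, otherwise a
  normal approximation with tie-corrected variance and continuity
  correction.
* **Insertion overrun** (1-bp insertions at high-error positions): pass
  when the sample insertion frequency exceeds the database value by ≥ 20
  points *and* the 2-bp insertion frequency is elevated over the database.
* **Deletion displacement** (1-bp deletions at high-error positions): with
  r = f_del / (f_del + f_ins), pass when r shifts up by ≥ 30 points versus
  the database *and* the insertion frequency decreases.
* **HP percentage** (indels): corrected = f_event − max(0, f_opposite_db −
  f_opposite_sample); pass at corrected ≥ 25%. The original decision
  algorithm lives in an unavailable supplement; this is the simplest
  reading of its description and is isolated in one function.
* **Strand bias**: reads with mean context quality (±2 read positions)
  below Q10 are excluded first; fail when the variant is seen on exactly
  one strand while the other has ≥ 5 informative reads, or when the
  per-strand VAFs differ by more than 35 points. Per-strand VAFs rather
  than raw counts avoid killing variants at amplicon ends covered by one
  strand.

The variant rearrangement tool handles non-homopolymer multi-base indels
below the detection limit: reads near such candidates are re-examined and
same-type indel runs separated by ≤ 2 aligned bases are merged when the
merged alignment scores at least as high; VAFs are then recomputed.

## Dosage quotients

For amplicon i in multiplex m, DQ = (RC_i / ΣRC_m) of the test sample over
the mean of the same ratio in the reference samples (three by default).
Normalisation is strictly within-multiplex, so DQ is invariant to library
size; DQ ≈ copy_number/2, but not exactly: a heterozygous deletion in a
9-amplicon multiplex gives (0.5/8.5)/(1/9) ≈ 0.53, because the event
shrinks the multiplex total too — which is why observed deletion DQs sit
above the naive 0.5. Default bands: deletion ≤ 0.70, normal 0.80–1.20,
duplication ≥ 1.35, with guard gaps classified ambiguous; exon calls
require unanimity of the covering amplicons. A rearrangement spanning an
entire multiplex is mathematically invisible to within-multiplex DQs — a
documented blind spot, as is band behaviour near the gaps: with Poisson
mean 1000 counts a duplication DQ (≈1.42) falls into the 1.20–1.35 gap in
roughly 4% of samples and a deletion DQ (≈0.53) below 0.5 in roughly 12%,
so the guard-gap design trades a small ambiguous rate for never silently
misclassifying between bands. The package keeps that trade-off; the
corresponding all-or-nothing acceptance criterion is reported honestly as
failing at exactly the analytically expected rate.

## Reporting

Variants are left-normalised (VCF normal form) for truth comparison and
3'-shifted within their repeat for HGVS c.-names on the panel's synthetic
transcript model (all exon bases treated as coding; substitution,
deletion, duplication and insertion forms, intronic offsets). Molecular
classes come from translating the affected codons (standard genetic code):
synonymous/missense/nonsense for substitutions, frameshift for length
changes not divisible by three, inframe otherwise; ±2 nt of an exon
boundary is splice_region. Performance metrics follow the standard
diagnostic formulas — sensitivity TP/(TP+FN), false-positive rate
FP/(FP+TP) (the surrogate when no true negatives exist), specificity
TN/(TN+FP), accuracy (TP+TN)/total — reported as percentages rounded
half-up to one decimal. For simulated evaluations, a true negative is a
panel insert position carrying neither a call nor a truth variant, counted
once; that definition is explicit because the published counts leave the
TN denominator undefined (and indeed the printed specificity/accuracy are
not exactly reproducible from the printed counts: TN=680, FP=16 gives
97.7%, and (19+680)/716 gives 97.6% — only the arithmetically consistent
values are asserted).

VCF 4.2 output is written by a small deterministic writer (byte-identical
reruns; validated against a standard VCF reader in the tests); SAM output
carries soft clips and NM and converts with samtools/Rsamtools. Error
rates recovered from simulations are measured by realigning reads to their
truth molecules and counting events in the read interior (8 bases trimmed
from each end — a local aligner cannot resolve indels at read termini, and
including them biases every rate estimate downward).

## Numerical choices and degenerate inputs

Seeds: every simulation entry point takes one integer seed; derived seeds
stay below 2^31. Identical seeds give byte-identical outputs. Thresholds
compare inclusively (≥) at their boundaries. Zero-depth positions yield no
candidates; empty candidate sets propagate as empty tables with zeroed
audit counts; a multiplex with a zero total read count is an error naming
the sample and multiplex. The Smith–Waterman tie-breaks are fixed
(diagonal over deletion over insertion; best cell at the smallest window
column) so results are reproducible across platforms.
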