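---
title: "Methods: miRNA discovery, target prediction and degradome validation in fruitmir"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: miRNA discovery, target prediction and degradome validation in fruitmir}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## Scope and model

fruitmir reimplements, as a tested pipeline, the computational workflow used
to characterise miRNAs in plant (peach fruit) small-RNA sequencing libraries:

1. **Read cleaning and accounting.** Raw reads pass a fixed cascade —
   low quality, 3' adaptor null, insert null, 5' adaptor contaminant,
   shorter than 18 nt, poly(A), clean — in which every read lands in exactly
   one category, so the category counts partition the high-quality total and
   `clean = high_quality - sum(contaminants)` holds by construction.
2. **Annotation cascade.** Clean reads are collapsed to unique tags with
   redundant counts, mapped perfectly to the genome on both strands, and
   classified by a precedence order (miRNA > rRNA > tRNA > snRNA > snoRNA >
   repeat > exon > intron > unannotated).
3. **Known miRNAs.** Tags are assigned to miRBase-style mature sequences by
   same-length comparison with at most 2 substitutions; families are the
   `miR` + number prefix; conservation across species databases is called
   identical / variant / absent (the `++` / `+` / blank rendering).
4. **Novel miRNAs.** Unannotated genome-mapped tags seed hairpin candidates
   that must satisfy nine structural criteria (below).
5. **Targets.** Transcripts are scanned with the six plant complementarity
   rules with G:U wobble = 0.5 mismatches and a duplex-MFE ratio filter.
6. **Degradome validation.** Cleavage is called where the degradome 5'-end
   density peaks exactly opposite miRNA nucleotides 10–11.
7. **Expression.** Relative expression from Ct tables by 2^-ddCt.

## The nine novel-miRNA criteria

A candidate precursor is accepted only if all of the following hold
(defaults in `novel_criteria()`):

| criterion | default | meaning |
|---|---|---|
| mature_len | 18–25 nt | mature tag length |
| ref_len | 20–23 nt | reference (dominant) tag length |
| max_ref_copies | ≤ 20 | genomic loci of the mature tag |
| mfe | ≤ −18 kcal/mol | precursor minimum free energy |
| loop_space | ≤ 300 nt | distance between miRNA and miRNA* |
| min_paired | ≥ 16 | miRNA/miRNA* base pairs |
| max_bulge | ≤ 4 nt | longest unpaired run in the duplex |
| max_asymmetry | ≤ 4 nt | strand difference of unpaired duplex nt |
| flank | ≥ 20 nt | precursor flank beyond the duplex |

plus a read-support floor of 5 reads for the mature tag.

Both length windows measure the same object (the dominant mature tag): the
conventional criterion set distinguishes a miRNA "sequence" from a miRNA
"reference sequence" without pinning down the difference, so the two
windows are kept as separate, separately configurable checks. A consequence
is that a mature outside 18–25 nt necessarily also violates the 20–23 nt
window; the simulator's `mature_len` decoy therefore co-fails `ref_len` by
entailment. The copy-number criterion is read as a repeat-likeness cap on
the number of genomic loci of the mature tag, exposed as
`max_ref_copies`; this interpretation is a documented package choice.

**Folding.** All folding is nearest-neighbor thermodynamic MFE folding
(RNAfold); duplex energies for the target rules use intermolecular
hybridisation (RNAduplex) with no intramolecular structure. DNA is the
on-disk alphabet, RNA the in-model alphabet, converted at module
boundaries.

**Precursor excision.** Hits of unannotated tags are clustered into loci
(gap ≤ 200 nt, a documented choice bounded by the loop-space criterion);
for each locus a ladder of windows around the dominant tag (mature tried on
both arms, extensions up to 360 nt so over-long miRNA/miRNA* spacings are
observed and rejected rather than never excised) is folded, the duplex is
located, and the precursor is then *trimmed to duplex ± 20 nt flank and
refolded*. Trimming makes the judged object — and in particular its MFE —
a property of the precursor itself rather than of the search-window size.
Among window hypotheses the one pairing the most mature bases wins, then
criteria passed, then compactness.

**Star inference.** miRNA* is the pairing partner of the mature region with
the canonical 2-nt 3' overhang of Dicer processing applied to the partner
span. Duplex metrics, however, are measured on the structure itself:
`paired_bases` counts mature positions paired outside the mature region,
`max_bulge` the longest interior unpaired run on either strand,
`asymmetry` the difference of interior unpaired counts, `loop_space` the
gap between the mature region and its partner span. A hairpin whose two
arms are exact reverse complements is rediscoverable from the opposite
strand; overlapping opposite-strand twins are resolved in favour of the
better-supported candidate.

## The six target rules

With miRNA positions numbered 5'→3' from 1 and sites ungapped (site length
= miRNA length; the six rules are purely positional, with no bulge rule —
a documented narrowing of the original bulge-allowing heuristic):

1. total mismatch score ≤ 4.0 (G:U wobble = 0.5);
2. longest run of adjacent mismatches ≤ 2;
3. no adjacent mismatches within positions 2–12;
4. no mismatch at positions 10–11;
5. mismatch score over positions 1–12 ≤ 2.5;
6. duplex MFE ≥ 75% of the MFE of the miRNA bound to its perfect
   complement — the standard MFE-ratio reading of the 75% energy
   criterion, configurable via `min_mfe_ratio`.

Wobbles score half a mismatch but, being pairs, break mismatch adjacency
for rules 2–3 by default (`gu_breaks_adjacency = FALSE` gives the strict
reading). Rule 2 is read as a run-length cap. The scanner vectorises rules
1–5 over every window and evaluates the energy rule only on survivors; the
test suite proves it equal to a per-window oracle.

## Degradome conventions

Cleavage leaves the 3' fragment's 5' end opposite miRNA nucleotides 10–11:
for a site at `[s, e]` with `e` pairing miRNA nucleotide 1, the expected
position is `e − 9`. Density is 5'-end counts of sense-matched, exactly
mapped reads. Peak categories follow the conventional 0–4 scheme, frozen
here for testability: 0 unique maximum (> 1), 1 tied maximum (> 1),
2 above the median of the transcript's *nonzero* counts, 3 at/below that
median (> 1), 4 singleton. The nonzero-count median is used because
degradome densities are sparse; a median over all positions would be 0 for
almost every transcript and collapse categories 2 and 3. No peak p-values
are computed.

## 2^-ddCt

Per replicate, dCt = Ct(target) − Ct(reference); replicates are paired by
index, dCt is averaged per sample, ddCt subtracts the calibrator mean and
expression is 2^−ddCt. The SE is the replicate SE of dCt propagated to the
expression scale (delta method), matching mean ± SE bar-plot presentation.
Replicates are treated as exchangeable; no amplification-efficiency
correction is applied.

## What the simulator emulates — and what it does not

`simulation_spec()` defaults encode the published library conditions: read
classes at the printed proportions (≈ 0.5% low quality, 0.04 / 0.02 /
0.18% adapter artefacts, 2.26% short, ≈ 0.001% poly(A), rRNA 14.05%, tRNA
4.42%, snRNA 0.07%, snoRNA 0.02%, exon/intron at their printed sense +
antisense sums, known miRNA 21.9%, and an unannotated remainder near 50%),
a length distribution peaked at 21 nt (0.38) with a 24-nt secondary mode
(0.30), and a 5'-U bias of 0.8 for mature miRNAs (the printed 21-nt U
fraction is 0.82). Genome scale (3 × 50 kb scaffolds, 20,000 reads) is the
package's default desk-scale study size; it exercises every code path while
keeping a full run in minutes. Reads carry constant high quality; planted
hairpins receive a deterministic equal split of the mature-read budget so
each clears the 5-read floor.

Planted hairpins are built from a sampled stem: pass hairpins carry two
G:U wobbles (so the arms are not exact reverse complements and the mature
cannot re-map antisense), decoys introduce exactly one controlled defect —
an out-of-window length, > 20 genomic copies, a weak low-GC stem for the
MFE decoy, a 310-nt loop, six isolated mismatches (15 pairs), paired 5-nt
bulges on both strands (bulge 5, asymmetry 0), 3+2-nt deletions on one
strand (asymmetry 5, bulges ≤ 3), or a scaffold-edge placement that clips
the flank. Every planted object is verified by the package's own
predicates (fold, duplex metrics, criteria; target rules; cleavage
positions) before emission, with bounded resampling.

The simulator does **not** emulate sequencing error, quality-score
variation, isomiR 5'/3' heterogeneity, RNA editing, repeat-family
structure, or expression-correlated biases. Passing recovery tests
therefore demonstrates correctness of the analysis logic under the stated
statistical structure, not robustness to real-library noise.

## Numerical and design choices

- Percentages print with half-up rounding at 2 decimals
  (`round_half_up()`), since published tables round 97.4975→97.50; R's
  default banker's rounding would disagree at the printed precision.
- "Low quality" (mean Phred < 20 or > 10% N) is the conventional
  definition; published accountings report the raw vs high-quality
  difference without itemising it.
- Adapter matching uses a 6-nt 3'-adapter seed (leftmost match) and an
  8-nt 5'-adapter suffix; poly(A) means ≥ 80% A after trimming. All are
  configurable.
- Known-miRNA category matching tolerates 1 substitution ("perfect match
  or one mismatch"); genome mapping is exact ("perfectly mapped").
- The annotation precedence order is configuration, not inference:
  published workflows remove ncRNA classes before miRNA alignment yet
  tabulate miRNA as a sibling category, which is internally ambiguous; the
  default order reproduces a consistent partition. Published category
  tables fold unmapped reads into "unannotated"; `classify_tags()` does
  the same in its summary while keeping mapped/unmapped distinct per tag.
- Tag-to-known assignment takes the fewest-mismatch hit, ties broken by
  lexicographic id; both exact-sequence and family-aggregated counts are
  reported (`identify_known()`, `family_counts()`).
- Degenerate inputs: empty read sets, zero depth, all-zero densities and
  empty candidate lists all return valid empty objects; a mature region
  that pairs nothing is a duplex-undefined rejection, not an error.
- Monotonicity: tightening any of the nine thresholds can only shrink the
  prediction set; the suite re-judges a fixed candidate set under
  tightened criteria (re-excision cannot rescue a candidate that a
  stricter threshold rejects, since excision already maximises pairing).

## Problem sizes used by tests and the acceptance script

Tests run the full stack on a 3 × 50 kb genome with 10 criterion-satisfying
hairpins and 9 single-violation decoys at 8,000 reads (the pipeline test
uses 2 × 20 kb / 4,000 reads); the scan-vs-oracle check uses 50 miRNAs
against transcripts up to 2.5 kb. These are the package's chosen
desk-scale study conditions; genome-scale inputs run through the same code
paths unchanged.

## Known limitations

- Ungapped target duplexes exclude genuine bulged target sites.
- Star coordinates at precursor edges are clipped rather than discarded.
- The excision search assumes the dominant tag is the mature arm; loci
  where the star out-accumulates the mature are reported with arms
  swapped.
- Known-miRNA matching has no indel tolerance.
- Cleavage calls carry no statistical significance, only peak categories.
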