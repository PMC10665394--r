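---
title: "Mining and validating cysteine-rich venom toxins: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining and validating cysteine-rich venom toxins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(venomine)
```

## The problem

Spider venom glands express large repertoires of short, disulfide-rich
toxins. Within a family, toxins differ by single residue substitutions, so
a transcriptome built from single-pass EST reads must be analysed *read by
read*: assembling near-identical transcripts into contigs would merge real
isoforms into consensus artifacts. Each read is therefore treated as an
independent transcript. What makes per-read mining feasible is that mature
toxins carry an almost invariant skeleton of cysteines whose spacing
pattern — not the sequence itself — identifies a toxin precursor even in a
noisy single-pass read.

`venomine` implements that strategy end to end: six-frame translation and
ORF detection, cysteine-framework motif search, precursor segmentation,
mature-variant enumeration, family/subfamily organisation, and validation
of the predictions against observed peptide-spectrum matches from
multi-protease digests of the venom.

## The SRDA model and the pattern language

A protein is encoded as the ordered sequence of its cysteines (`C`),
inter-cysteine spacer lengths (a number), and the translation stop (`.`).
Adjacent cysteines produce adjacent `C` tokens; a zero-length spacer is
never emitted. `X` (an untranslatable codon) counts toward spacer lengths
and never encodes as a cysteine.

Search formulas are token sequences over `C`, exact spacers, `#`, `*`, `.`
and a constrained spacer `n (n≠v)`. Three semantic decisions deserve
justification because the symbols admit narrower readings:

* **`*` spans cysteines.** A gap that could not absorb `C` tokens would
  make the eight-cysteine formula (`Cys#2`) disjoint from the six-cysteine
  one (`Cys#1`); in practice the two give almost identical result sets,
  which is only possible if `*` absorbs the extra `C1C` tokens. The package
  therefore lets `*` match any run of cysteine/spacer tokens (it never
  crosses a stop). A direct consequence, asserted in the tests, is the
  containment: every `Cys#2` match is a `Cys#1` match.
* **`#` includes digit zero.** `#` stands for any digit 0–9, but a
  zero-length spacer is not a token; digit zero therefore means "the last
  cysteine sits directly before the stop", and `#` is allowed to match
  emptily exactly in that position.
* **Literals are token-level.** `C16C` must not satisfy `C6C`; an exact
  spacer matches one whole spacer token, never a digit substring. This is
  why matching operates on tokens rather than on the serialised line with
  regular expressions.

Matching is attempted on full frame translations, not only on ORFs,
because the partial motifs target reads truncated before a start codon or
stop. A frame translation usually contains several stop codons; since no
motif can span a stop (`*` stops at `.`, `.` must match the terminal
stop), the frame is split into stop-terminated segments that are encoded
and matched independently. Overlapping matches within one encoding are
de-duplicated leftmost-shortest.

Classification is precedence-ordered: motifs are tried in the table order
`Cys#1 … partCys#2`, each across all six frames, and the first motif that
matches claims the read. Every read therefore contributes to at most one
motif's *impact*, and impacts sum to the toxin-candidate count. Extended
and partial hits are flagged as requiring external homology verification,
mirroring the downstream BLAST check that this package deliberately leaves
out of scope. Ties across frames report the lowest frame number.

### Anchoring the precursor ORF

A coincidental cysteine arrangement in a non-coding frame can satisfy a
motif — the general `Cys#3` is particularly permissive because its first
spacer is only constrained to differ from six. Classification (which
counts reads) is unaffected, but precursor annotation must not segment a
spurious frame. Annotation therefore re-anchors at the ORF level: each ORF
of a classified read is tested against the motif list on its own
translation (with its terminal stop), and among motif-bearing ORFs the one
whose motif ranks earliest in precedence wins, with complete-before-
partial, protein length and frame number as tie-breaks. General-framework
ORFs thus always outrank fragments that only satisfy an extended or
partial motif.

## Precursor segmentation

The segmentation partitions the precursor: signal peptide
`[0, signal_end)`, propeptide `[signal_end, mature_start)` (possibly
empty), mature chain `[mature_start, end)`.

* **Signal peptidase site.** The package ships a deliberately simple
  hydrophobicity heuristic: candidate cut sites 15–35 score
  `0.7 · normalised Kyte–Doolittle mean` of the 8 upstream residues plus
  0.15 for a small residue (A, G, S, C, T) at each of the −1 and −3
  positions, accepted above 0.45. It is a stand-in intended for synthetic
  and screening use; analyses of real data should ingest consolidated
  external predictions (TSV of `id`, `cleavage_site`), which always
  override the heuristic.
* **Start codon.** The initiator Met is the one whose distance *d* to the
  cleavage site satisfies 20 ≤ d ≤ 27, minimising *d*; both bounds are
  treated as inclusive. When no Met falls in the window the nearest Met
  with 15 ≤ d ≤ 35 is used — a deliberate widening so that slightly
  shorter or longer signal peptides do not spuriously demote a complete
  precursor to partial. With no candidate at all the sequence is partial.
* **Propeptide.** Toxin propeptides end in a processing quadruplet
  `XXKR`/`XXRR`. The region between signal end and the *first mature
  cysteine* is scanned and the most C-terminal quadruplet wins — mature
  chains are cysteine-rich, so the processing site must precede the first
  half-cystine, and the protease acts at the site closest to the mature
  chain. Ambiguous residues (`X`) disqualify a quadruplet. Without a
  quadruplet the mature chain starts at the signal end (no propeptide).
* **C-terminal variants.** Carboxypeptidases remove C-terminal basic
  residues and peptidylglycine alpha-amidating monooxygenase converts a
  C-terminal Gly into an amide on the preceding residue. Variant
  enumeration emits the full sequence, up to `trim_depth = 2` single K/R
  trims (two covers the canonical `…G-K-R` cassette while keeping the
  variant list small; configurable), and an amidated variant for every
  Gly-terminated intermediate. Amidation is a boolean flag on the variant
  — a mass shift of −0.984 Da for the proteomics layer — never a sequence
  character.

Clones encoding identical precursor proteins collapse to one entry whose
transcript count later feeds subfamily dominance.

## Families and subfamilies

Families are defined purely by the mature cysteine count (6C, 8C, 9C,
10C; anything else is `other`); an odd count implies an unbound cysteine
and is flagged. Within a family, subfamilies are single-linkage clusters
of pairwise global-alignment identity (Needleman–Wunsch, match +1,
mismatch 0, gap −1; identity = matches / alignment length including end
gaps). The 0.70 default threshold is an exposed calibration knob — the
grouping criterion behind published subfamily counts is not a fixed
constant of the method. Identity is computed on mature chains only, since
families are defined on mature toxins. Single linkage is implemented as
connected components, which makes the partition trivially invariant to
input order; output ordering is fixed (size descending, then smallest
member id). A subfamily's dominant sequence is its unique transcript-count
maximum; a tie means no dominant sequence.

For per-position summaries a small center-star aligner is bundled (center
= highest summed identity; pairwise alignments merged gap-wise). It is
adequate for residue frequency matrices and information content — a
full progressive aligner is explicitly not a goal. Information content per
column is `log2 20 − (H + (20−1)/(2 ln 2 · n))`, clamped at zero, with
gaps excluded from the entropy and counted separately.

## Proteomic validation

* **Protease rules.** Trypsin cuts C-terminal to K/R and, by default, not
  before proline; Lys-C after K; Glu-C after E (D can be added for
  ammonium-bicarbonate conditions); Asp-N before D. The proline rule and
  Glu-C specificity are configuration switches because both vary with
  protocol and neither choice is universal.
* **Digestion.** All peptides spanning at most four missed cleavages are
  enumerated; zero-missed peptides partition the protein — a property the
  tests verify against a substring-enumeration oracle.
* **Uniqueness.** Peptides are pooled over the database and parents are
  recorded at the *toxin-group* level: isoforms of one toxin share
  peptides without destroying uniqueness, which is what lets one isoform
  per group be selected while its peptides still count as unique.
  Isoleucine and leucine are indistinguishable by mass, so I/L are
  collapsed by default. Uniqueness statistics use a minimum length of 5;
  observed peptides are accepted at any length.
* **FDR.** The filter returns the largest target set of the form
  `score ≥ t` whose decoy/target ratio does not exceed α (ties at the
  threshold included). The accepted set is invariant to input order and
  monotone in α.
* **Identification.** Replicates are merged by union. An observed peptide
  is matched within its protease's theoretical digest; amidation is the
  one modification that must agree — a PSM flagged as C-terminally
  amidated may only match the C-terminal peptide of an amidated variant,
  and an unflagged PSM may not. One consequence: the free-acid form of an
  amidated variant's C-terminal peptide has no theoretical counterpart and
  is excluded from identification, but it *is* counted as amidation
  counter-evidence (below). Unmatched observed peptides are logged, never
  silently dropped. A toxin group is `unique_identified` with ≥ 1 unique
  observed peptide, `group_evidence_only` with only shared ones. Among
  isoforms, unique-peptide evidence wins, then unique-peptide coverage,
  then all-peptide coverage, then id.
* **Coverage.** The union of all matched occurrences of the peptides in
  the toxin sequence, divided by its length; overlaps count once, and
  `coverage_all ≥ coverage_unique` always holds.
* **Amidation evidence.** For each group the C-terminal peptides of its
  amidated variants define the amidation site. Accepted PSMs with those
  sequences are counted by flag: amidated only → `confirmed_unique` if the
  site peptide maps to this group alone, else
  `confirmed_nonunique_group`; both forms → `ambiguous`; free acid only →
  `not_amidated`; nothing observed → `undefined`. Counting is
  sequence-based on purpose, so the free-acid counterpart contributes even
  though it is not an identification.

## The synthetic study

The generator produces the conditions the pipeline assumes, with ground
truth attached to every artifact:

* **Reads.** Precursor proteins are built as signal peptide (18–25
  residues: Met, a basic residue, a Leu/Val/Ile/Phe core, ending `ALA`),
  propeptide (8–16 residues of E/D/Q/N/P filler ending `XXKR`/`XXRR`),
  and a mature chain drawn to satisfy a chosen framework, optionally
  extended by a `GR`/`GKR` amidation cassette (probabilities 0.8/0.1/0.1
  `none`/`GR`/`GKR`, matching the roughly one-fifth of toxins with
  predicted amidation). Proteins are reverse-translated with uniform
  synonymous codons (no stage downstream is codon-aware), framed by an
  in-frame upstream stop, padded with random UTRs to a log-normal length
  (median 457 nt, sdlog 0.35) and placed on a random strand. Family
  proportions default to 0.25/0.54/0.01/0.20 for 6C/8C/9C/10C, the
  relative sizes of the four families in the data the package models.
* **Planted spacings.** Non-fixed inter-cysteine spacers avoid the values
  1 and 6 so that only the intended literal tokens of the planted motif
  can match, and the post-cysteine tail plus cassette stays within the
  single digit that `#` tolerates. One homolog pair shares its C-terminal
  half (mutations restricted to the N-terminal 40%), providing group-level
  non-unique C-terminal evidence.
* **Unambiguity by construction.** Padding is redrawn until the planted
  precursor is the only motif-bearing ORF on the read. Spurious
  *motif-free* Met-to-end fragments remain — they are a property of real
  single-pass reads — but a synthetic read never carries two competing
  cysteine frameworks. Error reads (one indel or an in-read stop) are
  exempt from recovery guarantees.
* **PSMs.** Present toxins contribute their venom form's digestion
  products for all four proteases (zero-missed always, higher missed
  cleavage states with probability 0.3, emission floor 6 residues);
  target scores are N(10, 1) and reversed-sequence decoys N(10 − 6, 1) —
  the simplest model under which target-decoy FDR behaviour is
  analytically predictable. C-terminal peptides carry flags dictated by
  each toxin's planted amidation category.
* **Self-validation.** Before returning, the generator re-runs the
  pipeline on its own output (ORF recovery per read; FDR filtering,
  identification and amidation categorisation per study) and regenerates
  on any mismatch, so a returned study is guaranteed internally
  consistent.

What passing these tests shows: the implementation of every rule is
correct on data that satisfies the model's assumptions exactly. What it
does not show: robustness to base-calling error profiles, codon usage,
chimeric clones, or homology structure of real venom transcriptomes — the
generator has no chromatogram error model, no real sequence homology and
no spectra; observed peptides are emitted directly rather than searched
from spectra.

## Numerical choices and degenerate inputs

Coordinates are 0-based and half-open throughout; `.` is the internal
stop symbol, `*` belongs to the pattern language only. Encodings of
sequences with internal stops are truncated at the first stop and
flagged. Empty FASTA files yield empty tables, not errors; a protein too
short for a signal peptide yields a no-signal result, not an exception; a
mature region without cysteines is flagged and left without a propeptide.
Matching uses a dynamic program over tokens that returns minimal match
ends, so reported hits are deterministic. The FDR filter scans observed
scores only, which makes its threshold exact on ties.

Problem sizes used by the test suite and the acceptance script — a
300-read study (240 toxin, 40 motif-free, 20 error reads from 15 planted
toxins), 500 random encodings against the brute-force matcher oracle,
1000 random proteins for the digestion partition property, 50 replicates
of the FDR model at 500 targets + 500 decoys, and 50 homolog-rich
databases for the multi-enzyme comparison — were chosen so the whole
suite completes in a few minutes on one CPU while keeping every estimate
well away from its acceptance margin.

## Known limitations

* The built-in signal predictor is a heuristic stand-in; real analyses
  should supply external predictions.
* Extended/partial motif hits are only flagged for homology verification;
  no BLAST step is included.
* The center-star aligner is for frequency summaries, not
  publication-quality alignments.
* Spectral search, mass-tolerance matching and quantification are out of
  scope: the validator consumes post-search PSM tables.
* Disulfide connectivity is never predicted; the 9C "unbound cysteine"
  flag is a parity argument only.
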