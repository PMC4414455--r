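---
title: "Identifying stress-responsive plant miRNAs from two small-RNA libraries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying stress-responsive plant miRNAs from two small-RNA libraries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirstress)
```

## The problem this package addresses

A common design in plant stress transcriptomics sequences two small-RNA
libraries — one control, one treated (here labelled CK and Cd, for a
cadmium-exposure study design) — from a species without a reference
genome, using a de novo assembled transcriptome as the only sequence
reference. From roughly 10^7 49-nt reads per library one wants to know:
which reads are miRNAs rather than rRNA/tRNA/snoRNA degradation
fragments; which miRNAs are conserved family members versus novel,
species-specific ones; which transcripts they target; and which of them
respond to the treatment. `mirstress` implements that entire workflow as
testable R functions, plus a seeded generator of synthetic two-library
datasets so every stage can be validated against a known ground truth
without any external download.

## Pipeline stages and their models

### Read cleaning and tag collapsing

Reads are filtered in a fixed order (each read is counted once, at the
first failing rule): low quality (> 10% of bases under Phred 20, or any
N), 5' adapter contaminants (first 8 nt matching the 5' adapter tail with
at most one mismatch), 3' adapter trimming, poly(A) inserts, and a
15–30 nt length window. Two rules deserve comment:

* Reads with no recognizable 3' adapter are discarded. In a single-end
  small-RNA protocol the insert boundary is unknowable without the
  adapter, so keeping such reads would quantify sequences of unknown
  3' ends. Counted under `no_insert` together with adapter-adapter
  ligation products.
* The quality rule is a choice: published studies typically say only
  "low-quality tags were filtered". The 10%-below-Q20 rule with an
  absolute ban on N is the common Illumina small-RNA default and keeps
  the unique-tag space free of ambiguity codes.

Clean inserts are collapsed to unique *tags* with per-library counts.
All sequence handling is in the DNA alphabet; reports render U, as is
conventional for miRNAs. Tag order (descending total count, ties
alphabetical) is fixed so that seeded runs are byte-reproducible.

### Annotation priority

Each unique tag receives exactly one category by a total priority order:
ncRNA (with GenBank-sourced records consulted before Rfam, and the
subtype — rRNA, tRNA, snRNA, snoRNA — taken from the matched record) >
known miRNA > other reference > unannotated. Matching is exact substring
on the sense strand: adapter-ligated small-RNA reads are directional, and
the upstream mapping step already kept only perfect matches. The
genome-dependent repeat/exon/intron classes of genome-based pipelines
collapse here into a single optional `other_reference` class, because no
genome exists for this kind of study; this preserves the priority
semantics without inventing annotations.

### Conserved miRNAs

Tags are matched to known mature miRNAs allowing up to two substitutions
(no indels; the shorter sequence slid to its best offset, length
difference at most 2 nt). Substitution-only matching is deliberate:
the "within two mismatches" convention of tag-based pipelines is a
Hamming bound, and indels between a tag and a mature miRNA are better
modelled as the terminal trims the isomiR machinery handles. Matched tags
are clustered per reference; the member with the dominant read count is
taken as the true sequence (ties: alphabetically smallest member, for
determinism), and expression is the sum over members that pass the class
rule, re-checked against the matched reference.

### Novel miRNA prediction

Unannotated tags mapping perfectly to transcripts seed a hairpin search:
windows `[pos - flank, tag_end + 20)` and `[pos - 20, tag_end + flank)`
(default flank 150 nt, both orientations — a transcript may contain a
precursor in either sense) are folded, and a candidate is accepted when
all of the following hold: mature 18–26 nt wholly within one arm; at
least 16 mature bases paired; at most 4 unpaired with at most 2
consecutive; the terminal loop does not overlap the mature; MFE ≤ −18
kcal/mol; MFEI ≤ −0.5; precursor 68–300 nt. These thresholds follow the
plant-miRNA (Mireap-style) convention; all are configuration fields.
Candidates sharing a locus are merged under the dominant tag.

An accepted hairpin whose mature matches a known miRNA — by sequence
(within 2 substitutions, ±2 nt) or by position (a known mature occurs
verbatim in the precursor overlapping at least half the candidate's
mature span) — is reported as a *conserved pre-miRNA locus*, not a novel
call. The positional clause matters in practice: a 3-nt-trimmed isomiR
of a known miRNA is outside the ±2 sequence tolerance, yet folding its
locus yields the known precursor; without the clause such loci inflate
the novel list.

Novel expression sums cluster members with at most 3 nt of deviation in
total, confined to the outermost 3 nt of each end, and no internal
substitution; length differences (trims/extensions) count toward the end
budget.

5p/3p arm pairs are detected from the canonical Dicer duplex geometry:
a second expressed tag on the opposite arm whose span matches the
2-nt 3'-overhang duplex within ±1 nt. On either arm the expected star
span is `[partner(mature_end − 2), partner(mature_start) + 2]`, with
partners of unpaired mature bases extrapolated from the nearest paired
base assuming a locally regular helix. IsomiRs are every tag aligning
exactly within the precursor and overlapping at least half of the mature
span; offsets are signed, positive meaning trimmed relative to the
canonical mature at that end, negative extended.

### The folding energy model

No RNA folding library is available in this R environment, so the
package ships its own Zuker-style minimum-free-energy dynamic program
(in C++): Watson–Crick plus G:U pairs, minimum hairpin loop 3 nt,
sequence-dependent stacking increments, size-dependent hairpin / bulge /
interior loop penalties with Jacobson–Stockmayer extrapolation, an
affine multiloop cost, and a 30-nt cap on interior loop size. The ten
Watson–Crick stack parameters are the standard nearest-neighbor values;
wobble stacks use class approximations (one G:U next to a C-G-class
pair: −1.4; next to an A-U-class pair: −1.0; two G:U: −0.5 kcal/mol),
with strand-reversal symmetry enforced exactly. The precursor criteria
depend only on MFE *ranking*, not on absolute free energies, so modest
parameter approximations are immaterial — but the model is required to
be internally consistent: the same parameter set drives `fold_rna()`,
the intermolecular `duplex_mfe()` (no intramolecular pairs, plus a
4.1 kcal/mol helix initiation), and `eval_structure()`, the independent
loop-decomposition evaluator the test suite uses to score exhaustively
enumerated structures. Ties in energy are broken toward more base pairs
and then the 5'-most pairing, so folding is deterministic.

### Target prediction

Plant miRNAs pair near-perfectly with their targets, so scanning is by
complementarity scoring rather than seed-match heuristics: each aligned
miRNA position contributes 0 (Watson–Crick), 0.5 (G:U wobble — displayed
`o`, explicitly not a mismatch) or 1.0 (mismatch, `x`); penalties double
over the seed span (miRNA positions 2–13 from the 5' end); at most one
single-nucleotide bulge on either strand costs 2.0. The expectation is
the penalty sum, and sites with expectation ≤ 3.0 (default) are
reported, overlapping windows reduced to the best scorer, each site
annotated with its duplex hybridization MFE. The seed span and all
penalties are configuration fields, since the literature varies slightly
in the seed definition.

### Differential expression

Counts are normalized to transcripts per million against the total
miRNA-matching reads of each library (not total clean reads — the
composition of the non-miRNA fraction differs between libraries and
would distort the normalization). Significance of a per-miRNA count
difference between the two unreplicated libraries uses the
Audic–Claverie posterior predictive test; `p(y|x)` is evaluated exactly
through its negative-binomial form `dnbinom(y, size = x + 1, prob =
N1/(N1+N2))`, in log space, so counts up to 10^6 are safe. The two-sided
p-value doubles the smaller inclusive tail; because that construction
treats the observed point asymmetrically under a swap of the libraries,
it is evaluated in both orientations and the smaller value taken —
making the test exactly symmetric (via the identity
`P_swap(K ≤ x) = 1 − P(Y ≤ y)`) while leaving the textbook cases
(`p(0|0)` with equal totals, equal counts at the mode) unchanged.

Calls require raw `p < 0.05` *and* at least a 1.5-fold change; stars
mark `P < 0.05` / `P < 0.01`. No multiple-testing correction enters the
calls (single-pair designs are conventionally reported on raw P), but a
Benjamini–Hochberg column is emitted for reference. A 0.01-TPM floor
keeps fold changes of library-specific miRNAs finite; miRNAs with zero
counts in exactly one library are flagged `CK_only` / `Cd_only`.

## The synthetic world

`simulate_truth()` / `simulate_dataset()` state the world the pipeline
assumes, with defaults chosen once:

* 20 conserved + 10 novel planted pre-miRNA hairpins (stems 30–45 bp,
  loops 8–14 nt, 0–2 single-nucleotide bulges, stem GC 0.55), matures
  20–22 nt placed wholly in one arm.
* Per-miRNA counts negative-binomial, means log-uniform on 20–2000 reads
  (the span between "under 10 reads" and the dominant families in real
  libraries), dispersion 0.1; Poisson is the dispersion → 0 limit used
  by the exact round-trip tests.
* Treatment effects: 2 up- and 4 down-regulated miRNAs at 4-fold, one
  CK-only and two Cd-only miRNAs — mirroring the preponderance of
  down-regulation and library-specific expression such studies report.
* 30% of clean reads are ncRNA fragments, 20% of each miRNA's reads are
  isomiR variants (1–3 nt terminal trims or extensions within the
  precursor), and 10% of depth is deliberately bad reads (adapter-only,
  poly(A), short inserts, low quality, 5' contaminants) in equal
  proportions.
* Every insert carries the Illumina TruSeq small-RNA 3' adapter; reads
  are truncated at 49 nt; all randomness flows through one seed.

What the generator does *not* emulate: position-dependent sequencing
error profiles (only clean bases plus discrete bad-read classes),
RNA-edited or 3'-tailed isomiRs, chimeric reads, expression correlation
between family members, and multi-locus miRNA families on distinct
precursors. A green synthetic run therefore establishes the
correctness of the algorithms on data satisfying the model assumptions,
not robustness to every artefact of a real sequencer.

One behaviour of the stated world is worth knowing when reading
differential-expression output: with dispersion 0.1 the two libraries
differ by genuine overdispersion that the Audic–Claverie test (which
models only sampling noise) cannot distinguish from treatment effects,
so highly expressed null miRNAs can reach significance at modest fold
changes — the same phenomenon that makes real unreplicated designs
overcall. The planted 4-fold effects are recovered on top of that
background; the type-I calibration tests run at dispersion 0 (Poisson),
where the test's nominal level is meaningful.

## Numerical and design choices

* Energies are compared with an absolute tolerance of 10^-6 kcal/mol in
  the folder's tie-breaking and the oracle tests; all loop tables are
  precomputed to length 600.
* `fold_rna()` accepts 5–600 nt (the hairpin-criteria range is enforced
  by `predict_novel()`, not the folder), `duplex_mfe()` any pair of
  sequences ≥ 2 nt.
* The 15–30 nt computational filter and the 14–30 nt length-distribution
  plot range are both kept, as is conventional even though gel size
  selection is narrower.
* Coordinates are 0-based half-open everywhere in code and output
  files.
* The CLI layer is a thin Rscript (`inst/scripts/mirstress-pipeline.R`)
  over `simulate_dataset()` and `run_pipeline()`; the configuration is a
  JSON object mirroring `pipeline_config()` (no YAML parser is assumed),
  echoed at run time for provenance.

## Limitations

* Without a genome, precursors can only be found for miRNAs whose loci
  are represented in the assembled transcriptome; conserved miRNAs
  without a recovered precursor are still quantified but carry no
  hairpin, star or isomiR information.
* The folding model is a single-temperature MFE model: no suboptimal
  ensembles, no pseudoknots, no dangling-end or terminal-mismatch terms.
* The Audic–Claverie test models sampling variability only; with one
  library per condition, biological variability is unidentifiable and
  significant calls should be read accordingly.
* Target prediction is sequence-only; it does not model target-site
  accessibility or translational repression.
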