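---
title: "Screening for membrane-bound RING-finger ubiquitin ligases: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening for membrane-bound RING-finger ubiquitin ligases: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ringscreen)
```

## The screening problem

Endoplasmic-reticulum-associated degradation (ERAD) disposes of unfolded ER
proteins through the ubiquitin–proteasome system. The E3 ubiquitin ligases
known to drive ERAD — HRD1/SYVN1 being the archetype — share two structural
features: a canonical RING-finger domain and one or more transmembrane
segments anchoring them in the ER membrane. `ringscreen` implements an
in-silico screen built on exactly those two criteria, together with the
regulatory and expression analyses used to prioritise candidates: scanning
upstream DNA for ER-stress response elements, and quantifying ER-stress
induction of candidate genes from qPCR time courses.

## The RING-finger matcher

The canonical RING coordinates two Zn²⁺ ions with eight residues. We encode
it as a variable-gap pattern over the protein sequence:

```
C-X2-C-X9-39-C-X1-3-H-X2-3-C/H-X2-C-X9-39-C-X2-C
```

eight coordination slots with bounded spacers between them. The fifth slot
decides the subtype of each match: His gives the two-His **C3H2C3** form,
Cys the one-His **C3HC4** form. `find_ring_motifs()` enumerates *every*
distinct coordination tuple by depth-first search over candidate slot
positions (candidates visited in ascending order, so output order is
lexicographic and deterministic). Design choices worth knowing:

* **All matches are enumerated; screening uses "≥ 1 match per protein".**
  Overlapping assignments carry real information (a protein can satisfy both
  subtypes through different tuples), but tables need one canonical row per
  gene: `best_match()` takes the lexicographically smallest tuple (leftmost,
  then shortest spacers), and a protein whose match set spans both subtypes
  is flagged in a `notes` column.
* **Ambiguity codes** (`X`, `B`, `Z`, `U`) never satisfy a coordination
  slot but are legal spacer fillers; a `*` stop character truncates the
  scanned sequence at its position. Sequences are uppercased on ingest.
  This mirrors a conservative literal search over database dumps.
* The matcher is checked against an independent brute-force oracle (a
  join-then-filter enumeration of all candidate tuples) on hundreds of
  random sequences in the test suite.

Non-goals: the RINGv/C4HC3 pattern of the MARCH family, RING-C2, HECT and
U-box domains are outside this pattern by construction.

## Transmembrane counting

The screen's second criterion is membrane anchoring. When TMHMM v2 output
is available, `parse_tmhmm()` uses it verbatim (declared helix counts are
cross-checked against the helix lines; disagreement is an error naming the
protein). For self-contained work the package provides a classical
Kyte–Doolittle sliding-window predictor, `predict_tm()`: residues whose
centred 19-residue window mean reaches 1.6 are marked, maximal marked runs
are extended by half a window, merged when closer than 5 residues, and kept
when at least 15 residues long. These are textbook settings for a
first-pass hydropathy scan; we make no claim that they reproduce TMHMM on
real proteins — the synthetic generator closes that loop instead (below).
Two deliberate behaviours: N-terminal hydrophobic stretches (signal
peptides) **count** as helices, since HRD1's six membrane spans include its
signal peptide; and parsed output takes precedence over prediction when
both exist, reproducing the original tool choice.

## Upstream element scanning

ER-stress transcription is driven by ATF6 binding ERSE-I
(`CCAAT-N9-CCACG/A`) and ERSE-II (`ATTGG-N-CCACG`), and by spliced XBP1
binding UPRE (`TGACGTGG/A`). `scan_upstream()` matches these IUPAC
consensi exactly (no position-weight scoring, matching the original exact
search; near-consensus variants are a documented limitation).
Coordinate conventions, declared rather than inferred:

* Regions read 5′→3′ on the gene's sense strand; the TSS is +1, the last
  upstream base −1, and there is no position 0.
* A hit's position is the **5′-most base of the matched substring on the
  sense strand**, for either orientation.
* Both strands are scanned by default — reverse-orientation hits are real
  (they are reported with a `-r` label suffix, e.g. `UPRE-r`) — and an `N`
  in the input matches only element `N` slots, so gapped assemblies cannot
  fabricate hits.
* The default window is 5000 nt, enough to contain the deepest planted
  element in the shipped design (−4801).

`extract_upstream()` maps a genome plus TSS table into such regions: for a
`+` gene bases `[tss − window, tss − 1]`, for a `−` gene the reverse
complement of `[tss + 1, tss + window]`, truncated at contig edges. The
TSS base itself is excluded on both strands.

## The screen pipeline

`run_screen()` composes the stages: a candidate is a protein with at least
one RING match and at least one transmembrane helix. Output is one row per
candidate (subtype of the canonical match, helix count, protein length,
serialized upstream hits such as `ERSE-I,-506;UPRE,-2303`) plus a summary
(total, subtype split, helix-count range). Missing transmembrane data for a
motif-positive protein is a hard error — silent drops would bias the
counts. The screen is a pure filter: shuffling the proteome or injecting
motif-free decoys cannot change the candidate set, and the tests assert
this.

## qPCR quantification and calls

`delta_delta_ct()` implements comparative Ct: per sample,
ΔCt = mean Ct(target) − mean Ct(reference); ΔΔCt subtracts the calibrator's
ΔCt; fold = 2^−ΔΔCt. Replicates are aggregated as mean Ct *before*
differencing (standard practice; stated explicitly because protocols often
leave it implicit), with replicate-level folds against the calibrator mean
retained for dispersion.

Tissue distribution is summarised by the tau specificity index,
τ = Σ(1 − x/x_max)/(n − 1) over per-tissue levels: 0 for uniform, 1 for
single-tissue expression. The qualitative classes use τ ≥ 0.95 for
*specific* (single tissue) and τ ≥ 0.85 for *selective* (limited tissues);
no numeric criterion exists in the source analyses, so these defaults were
chosen once to reproduce the qualitative calls on synthetic emulations
(e.g. a kidney-only profile at fold 50 over ~1 background) and are
configurable. With pooled-RNA tissue panels there is no replication, so
tissue classification is descriptive, not inferential.

ER-stress responsiveness follows the original statistical recipe: per gene
and stressor (thapsigargin, tunicamycin), one-way ANOVA of replicate ΔCt
across timepoint groups including the untreated control, then two-sided
pairwise comparisons of each timepoint against control with Bonferroni
correction (raw p × number of comparisons, capped at 1). The factor
structure was not fully specified in the source, so we use one-way ANOVA
per condition with timepoints as groups. A gene is *responsive* only when
**both** stressors show at least one timepoint with adjusted p < α and
fold > 1 — requiring induction, not just change, under two mechanistically
distinct stressors. Zero within-group variance (possible in noiseless
synthetic data) degenerates to exact p ∈ {0, 1} with a warning.
`viability()` covers the crystal-violet assay arithmetic (OD590 over
vehicle control, optionally relative to mock).

## The synthetic study design

No sequence accessions accompany the original screen, so reproducing it
from live databases is not a stable target (database drift, isoform
choice, predictor versioning). Instead, `fixture_spec()` transcribes the
published candidate tables into a generative design: 37 genes with their
subtype (19 C3H2C3, 18 C3HC4), transmembrane count (1–12) and protein
length, the eight genes with upstream elements at their reported positions
(one in reverse orientation), 200 motif-free decoys, and a 5000-nt window.

The generators are **self-verifying by rejection sampling**, using the same
pipeline code they are tested against (the only second implementations are
the deliberately independent brute-force test oracles):

* `make_motif_protein()` plants one minimal-spacer RING of the requested
  subtype in a hydrophilic background (drawn from polar/charged residues,
  excluding Cys/His so the planted tuple is the unique match) plus
  21-residue hydrophobic stretches separated by ≥ 23 background residues
  (so window-extended helices stay distinct under the merge rule), the
  first stretch N-terminal like a signal peptide; drafts are redrawn until
  the motif subtype and helix count verify, and an infeasible length/count
  combination errors out after a bounded number of tries.
* `make_promoter()` draws a uniform-composition background, redraws until
  it is free of all three elements on both strands, then writes random
  instantiations of the planted consensi and verifies the scan returns
  exactly the planted hits.
* `make_ct_table()` sets Ct(target) = 25 − log2(true fold) + N(0, sd), a
  constant reference gene, and an automatically added calibrator sample,
  so noiseless tables recover folds exactly and noisy ones are unbiased on
  the log2 scale.

What passing these tests shows — and does not show. Planted recovery
demonstrates that the pipeline's logic is correct end to end: the filters
compose, coordinates and strands are handled exactly, counts are conserved.
It does not demonstrate that the hydropathy predictor matches TMHMM on real
proteins, nor that real RefSeq/Ensembl sequences yield the published gene
list; uniform background composition, motif-free decoys and well-separated
hydrophobic stretches are idealisations of real proteomes and promoters.

## Numerical and testing choices

Deterministic behaviour everywhere: given a seed, generators are
byte-reproducible; the matcher and scanner are seed-free and
order-deterministic. Problem sizes in the shipped tests were chosen to
exercise the claims at meaningful scale while staying quick: the full
37-gene + 200-decoy fixture for screen recovery, 100–200 random instances
per oracle-equivalence property, 1000 null replications for the type-I
bound on the responsiveness call (the both-stressor requirement makes the
realised false-call rate far below the nominal 5%), and 500 noisy draws
for log2-fold bias (< 0.05 at sd 0.2, n = 4).

## Limitations

* Exact consensus matching only for elements; variant ER-stress elements
  escape the scan, as they did the original search.
* The hydropathy predictor is a stand-alone desk-scale method, not a
  reimplementation of TMHMM's HMM; orientation (inside/outside topology)
  is out of scope.
* Isoform collapse is the caller's responsibility: the screen operates per
  sequence, and which database isoform represents a gene materially
  affects transmembrane counts.
* Whether published element positions count from the element's 5′ or 3′
  end, anchored at TSS or ATG, is not stated in the source; our convention
  (5′-most base, TSS = +1) is declared and used consistently for planting
  and scanning, so recovery is exact within the package.
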