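---
title: "Screening for arylmalonate decarboxylases: model, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening for arylmalonate decarboxylases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amdscreen)
```

## The screening model

Arylmalonate decarboxylases (AMDases) are hard to annotate from overall
sequence similarity because they sit inside the aspartate/glutamate
racemase superfamily, whose members share the same fold and much of the
active site. What separates a true AMDase from a racemase is positional:
AMDases carry Gly74 and a single catalytic Cys188 (the proton donor that
sets the product's configuration), while racemases carry a second Cys at
position 74. `amdscreen` therefore screens candidates in coordinates,
not in aggregate similarity: every rule is anchored to the residue
numbering of a reference AMDase, and a candidate is mapped onto that
numbering before any rule is applied.

The screen is a conjunction of stages; a candidate must clear all of
them to be called `amdase_candidate`.

**Pre-filter.** A Smith–Waterman local alignment against the reference
provides the score for a Karlin–Altschul E-value,
$E = K\,m\,n\,e^{-\lambda S}$, and a Needleman–Wunsch global alignment
provides the percent identity. Thresholds are $E \le 10^{-44}$ and
identity $\ge 43\%$, both inclusive. Percent identity is computed over
global-alignment columns with terminal-gap columns removed from the
denominator. We chose the global alignment for the identity (and the
local alignment only for the score) because a local hit can shrink to a
short high-identity segment: a shuffled sequence can show a 50%-identity
local fragment while its full-length identity is near the random
baseline. The trimmed-global denominator is the deterministic quantity
closest to a full-length BLAST hit identity; whether the original screen
computed identity over the hit or the full length is not documented, so
this choice is flagged here as ours.

**Criterion filter.** Twelve reference-anchored criteria: the large
binding pocket (P14, P15), the dioxyanion hole (T75, S76, Y126, G189),
the hydrophobic pocket (L40, V43, Y48, V156, M159), the stereochemistry
pair G74 + C188, and two octamer motifs, `LMGTSLSF` at 72–79 and
`ILLSCGGL` at 184–191. "Similar physicochemical properties" is not a
defined residue grouping, so we operationalize it as a substitution-
matrix cutoff: a non-strict position passes when BLOSUM62(observed,
required) ≥ 1 (configurable). G74 and C188 accept identity only,
including where they fall inside the octamers. A Cys observed at
position 74 raises the racemase flag. Octamer criteria are evaluated
per position through the same identity-or-similarity rule, which keeps
them consistent with the degenerate patterns that cover the same spans.

**Degenerate patterns.** Six gapless patterns with `x` wildcards cover
the reference spans 10–23, 37–48, 66–82, 119–126, 151–159 and 182–191.
Starred catalytic positions (P14, P15, L40, V43, Y48, G74, T75, S76,
Y126, V156, M159, C188, G189) require identity; other specific
positions use the similarity rule; `x` matches anything, including the
ambiguity code X. Each pattern is searched within ±5 residues
(`spanSlack`) of the candidate coordinate its span maps to, which
tolerates small indels while keeping the match positional. Among
admissible placements the one with the most exact matches wins, ties to
the smallest start.

Two details of the pattern tables deserve a note, because the printed
sources are not perfectly self-consistent. First, the 151–159 pattern is
implemented as `LxIxxVxxM`: position 159 is listed as methionine in the
criterion table and the pattern's starred positions must agree with the
criteria, so the pattern ends in M rather than a second V. Second, the
182–191 pattern (`DALLISCGxL`) disagrees with the 184–191 octamer
(`ILLSCGGL`) at positions 184 and 186 (L/I swapped); both are satisfied
simultaneously because L and I are similar under the BLOSUM62 ≥ 1 rule,
so the reference takes the octamer literally and the pattern passes by
similarity. No residue that is strict in either table is affected.

**Strictness resolution.** The criterion stage treats only G74 and C188
as strict; the pattern stage treats all starred positions as strict.
A conservative mutation at another catalytic position (say Y126→F,
BLOSUM62 = 3) therefore scores "similar" in the criterion report but
still causes the overall screen to reject the candidate through the
pattern stage. This split keeps the criterion report informative (it
distinguishes "conservatively substituted" from "wrong") while the
final call remains strict at every catalytic residue.

**Final call.** `amdase_candidate` requires the pre-filter, all 12
criteria and all 6 patterns. `racemase_like` is called when Cys is
observed at position 74 and every remaining requirement passes once
position 74 is wildcarded — i.e. the candidate is exactly a racemase-
configured member of the superfamily, not a generally degraded
sequence. Everything else is `reject`, with the failing stage recorded.

## The profile HMM

The family alignment is compiled into a Durbin-style profile HMM with
match, insert and delete states per consensus column. Columns with gap
fraction strictly below 0.5 become match states (the HMMER-like rule).
Emissions are observed counts plus background-proportional pseudocounts
with weight 1; transitions are counted from each member's implied state
path and Laplace-smoothed. The background is uniform (1/20) by default
— the training families here are small and synthetic, and a uniform
null keeps scores reproducible without external frequency tables; an
empirical background is available as an option. These are deliberately
simple, fully documented priors: scores are **not** bit-identical to
HMMER's Dirichlet-mixture models, and the package does not read or
write genuine HMMER3 files.

Scoring is global (candidates are full-length proteins of similar
length; no local/glocal modes). The reported score is the log-odds of
the sequence against the background in bits; forward sums all paths,
Viterbi takes the best path with a deterministic match > insert >
delete tie-break. The ambiguity code X emits at the background rate
(log-odds contribution zero). Both recursions are checked against an
exhaustive path-enumeration oracle on tiny models in the test suite.

No operating threshold is documented for the original screen, so the
default bit threshold is calibrated as the minimum training-member
self-score minus 2 bits: every training member is then a hit, with a
small margin for close relatives. The margin is a package choice and
should be re-calibrated for real families.

Logo statistics per match column follow the conventions of HMM logo
renderers: information content is the relative entropy of the match
emission against the background (0 bits when they coincide, log2(20) ≈
4.32 bits for a one-hot emission under the uniform background);
occupancy is the fraction of members with a residue in the column;
insert probability is the fraction of members inserting after the
column; insert length is the mean insertion length among inserters.

## Classification into eight clusters

Known AMDases group into eight clusters defined jointly by sequence
relatedness and by the transporter genes next to the *amd* gene:
TTT-I…V (tripartite tricarboxylate transporters — orphan periplasmic
receptor genes in I–III, full TctA/B/C operons in IV–V), one ABC
cluster, and TRAP-I/II. The package reproduces this layer with two
deliberate simplifications:

* **Neighbor joining instead of maximum likelihood.** The tree only
  mediates "which anchor is nearest", not publication phylogenetics, so
  a deterministic distance method suffices. Distances are
  1 − fractional identity from global alignments; taxa are sorted
  lexicographically before agglomeration, which makes the topology
  independent of input order; negative NJ branch estimates are clamped
  to zero and flagged. Bootstrap support is not computed — confidence
  is reported as the patristic distance to the chosen anchor.
* **Keyword detection instead of orthology.** Transporter families are
  called by case-insensitive keyword match over product annotations
  (editable TSV ruleset, because annotation vocabularies drift), with
  the matching gene and keyword recorded as evidence.

Assignment: the candidate takes the cluster of its nearest anchored
leaf whose family is compatible with the candidate's neighborhood
(anchors are user-supplied exemplars, at least one per cluster in use).
If no anchor is compatible, the neighborhood family wins the coarse
label (TTT/ABC/TRAP) and the subdivision is reported unresolved. The
rule that separates TTT-I from TTT-II/III in the original survey is not
stated beyond tree topology; nearest-anchor assignment is our
reconstruction of it, and it is exercised against the synthetic
archetypes, not against the original strains. The neighborhood window
defaults to 10 genes on each side of *amd*, roughly the span of the
published neighborhood diagrams; it is configurable.

## The synthetic benchmark

The generator provides the study conditions for all tests and for the
acceptance script; it shares no code with the screener, so agreement
between generated truth and verdicts is a real check.

* **Reference**: 240 residues; every motif placed at its printed
  coordinate; unconstrained positions drawn uniformly from the 20
  residues (no composition is documented, so uniform is the neutral
  choice). The reference is synthetic and named accordingly; the
  documentation explains how to substitute the real KU1201 sequence.
* **Family**: 50 members by default (the benchmark size used in the
  acceptance checks); substitutions at unconstrained sites at rate
  0.15 per site — divergent enough that members differ at dozens of
  positions (pairwise identities around 75–90%) while remaining far
  above the 43% pre-filter floor; one short indel (length 1–3) in 25%
  of members, confined to the inter-motif zones 92–115 and 196–235 so
  that motif coordinates, and hence ground truth, stay unambiguous.
* **Decoys**: racemase decoys are family members with G74→C and nothing
  else changed; unrelated decoys are uniform-composition sequences of
  matched length.
* **Neighborhoods and metadata**: one GFF3 contig per cluster
  archetype with the diagnostic gene content described above, an
  MR/MLE gene in 61% of archetypes, and a metadata table whose
  marginals mirror the published survey (25/34/4 genes over 16/6/3
  genera across Alpha-/Beta-/Gamma-proteobacteria; 23 Variovorax and 7
  Alcaligenes strains; 32% soil and 16% unstated isolation sources,
  allocated by largest remainder so percentages always total 100).

What passing these benchmarks does **not** show: the generator mutates
sites independently and uniformly, with no phylogenetic correlation, no
realistic residue composition, no domain rearrangements and no
annotation noise in the product strings. Real screening hits will sit
closer to the thresholds than the synthetic family does, and real
neighborhoods will contain partially or wrongly annotated transporter
genes. The discrimination rates measured here are a correctness check
of the machinery, not a sensitivity/specificity estimate for database
screening.

## Numerical and edge-case choices

* Coordinates are 1-based inclusive throughout (GFF3 and residue
  numbering convention).
* The ambiguity code X is accepted on input, scores 0 against every
  residue (so it can never reach the similarity cutoff of 1), fails any
  strict position, matches only `x` wildcards, and emits at the
  background rate in the HMM — uniformly conservative handling.
* Reference positions aligned to a candidate gap score "unaligned" and
  fail their criterion, rather than being skipped: the all-12
  requirement stays a conjunction over all twelve.
* Pairwise alignment and traceback are delegated to Biostrings'
  `pairwiseAlignment` (deterministic); gap of length L costs
  11 + L·1, the BLAST protein defaults. Alignment scores are verified
  against an exhaustive enumeration oracle for short sequences.
* HMM probability invariants (emissions and outgoing transitions sum
  to 1 within 1e-9) are enforced by the class validity method and
  property-tested on random builds.
* Problem sizes in the routine test run are deliberately modest (family
  sizes 4–8 for unit tests, 50 for the benchmark; enumeration oracles
  up to 8 residues and 4 match states); they are chosen to make the
  oracles exact and the suite quick to iterate, and the benchmark
  conditions are fixed once in the generator defaults.

## Known limitations

* The "analyzed and evaluated manually" step that sat between the
  original BLAST screen and the criterion filter has no computational
  definition and is not implemented.
* HMM scores carry no E-value calibration; only bit scores and the
  self-score-derived threshold are provided.
* The cluster subdivision rule is a reconstruction (see above), and
  cluster labels for real candidates depend on the anchors the user
  supplies.
* GC-content comparison is provided per gene against a user-supplied
  genome average; the package does not compute genome-wide GC itself.
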