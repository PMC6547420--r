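---
title: "Methods: IES boundary analysis with iesbound"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: IES boundary analysis with iesbound}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iesbound)
```

## The problem

Ciliates such as *Tetrahymena thermophila* carry two nuclei: a germline
micronucleus (MIC) with the complete genome and a somatic macronucleus
(MAC) from which thousands of internal eliminated sequences (IESs) are
excised during development. Most IESs are deleted reproducibly, but the
exact breakpoints vary — within a strain, and between independently
developed strains. This package implements a complete analysis chain for
asking *how tightly IES boundaries are controlled and what sequence
features control them*:

1. **Breakpoint refinement** — base-exact deletion ends from clipped-read
   (split-read) pileups around coarse structural-variant calls.
2. **Cataloguing** — junction normalization, length/N filtering, and
   clustering of deletion forms into IES loci across strains.
3. **Boundary variation** — a per-locus variation statistic, its class
   histogram, and cross-tabulations against a flagged locus subset.
4. **Flanking regulatory sequence (FRS) discovery** — inverted-repeat
   (IR) k-mer pairs in the two 100-bp flanks at near-equal distances from
   the two ends, selected by positional concentricity.
5. **PWM classification** — G-rich versus C-rich IR arrangements from
   position-weight-matrix scans, and a single FRS assignment per locus.
6. **Mutant contrast** — loci whose boundaries are tight in wild type but
   inflate in a boundary-control mutant (a LIA3-knockout-like genotype).

Every stage is exercised end to end on a deterministic synthetic MIC
generator with full truth tables, so the statistical machinery can be
validated without any sequencing data.

## Coordinates and junction normalization

All intervals are 0-based, half-open `[A, B)` internally; the A-end and
B-end are the 5' and 3' ends of the deleted segment in MIC orientation.
Because excision junctions frequently carry a terminal direct repeat
(microhomology), the same MAC product can be written as several MIC
intervals. `normalize_junction()` makes the representation canonical by
sliding the interval left while the base preceding A equals the last
deleted base, which places the retained microhomology copy at the A-end:

```{r}
normalize_junction(3, 10, "ACGGATTTGGACG")
```

The rejoined MAC product is invariant under this shift — a property the
test suite checks on a thousand random junctions — and the shift is
idempotent. The microhomology length is the longest shared prefix of the
deleted segment and the sequence that follows it.

## Breakpoint refinement

Clipped-read pileups localize junctions at base resolution. For each
(strain, contig) profile the refinement threshold is the arithmetic mean
of clip counts over positions with at least one clipped read; positions
below the mean are treated as noise. Within a 200-bp window centred on
each predicted end (read as ±100 bp; the width is a parameter because
other window conventions are defensible), the position with the highest
surviving count becomes the refined end, with ties broken by distance to
the prediction and then by the smaller coordinate. When several positions
tie at the maximal count, all of them are retained and expanded into
alternative `(A, B)` pairs — this is how intra-strain alternative
deletion forms enter the catalogue. Whether the threshold mean should
include zero-count positions is not decidable from first principles;
both modes exist and the nonzero mean is the default, computed per
(strain, contig) so coverage differences between strains do not couple.

## Cataloguing and variation

Deletions shorter than 100 bp are removed, as are calls with an unknown
base (N) within 5 bp inside either end or within the 5 flanking bases —
a small symmetric guard around each junction, configurable because the
appropriate extent depends on assembly quality. Forms within or among
strains sharing at least 1 bp of overlap belong to one IES locus;
clustering is single-linkage on the half-open-overlap graph, so abutting
intervals stay separate and a chain of pairwise overlaps merges.

The boundary difference between two forms is `|A1-A2| + |B1-B2|` — a
metric — and a locus's **maximum boundary variation** is the maximum over
all form pairs, intra-strain forms included. Variations are binned into
the classes 0, 1–10, …, 91–100, >100 (closed bins), and `ratio_cells()` /
`enrichment_cells()` carry the reporting arithmetic (half-up rounding at
two decimals, so printed tables can be reproduced cell by cell).

## FRS discovery by positional concentricity

For each locus, the 100 bp upstream of the A-end and the reverse
complement of the 100 bp downstream of the B-end are extracted; both
processed flanks then end at their junction, and a genomic inverted
repeat appears as a literal k-mer match between them. All pentamer pairs
whose distances to the respective ends differ by at most 10 bp are
collected; distances run from the junction to the motif copy's
IES-proximal base (0 = abutting). The measuring point is a convention —
any fixed choice shifts all distances by a constant — and the proximal
base is used consistently. Distances are computed against a designated
reference strain's form (default `CU427`; the lexicographically smallest
form when that strain has several).

A k-mer group is a candidate FRS when its left-distance distribution is
tight and recurrent: interquartile range ≤ 10 bp (linear-interpolation
quantiles, `stats::quantile(type = 7)`; the type is exposed) and at
least 3 contributing pairs. Groups sharing a core (N in a core pattern
matches any base) can be pooled with `group_by_core()`, which recomputes
the statistics on the pooled distance vector. Direct repeats are
searched identically but with the downstream flank in genome
orientation, providing the orientation control.

## PWM scanning and FRS typing

`build_pwm()` turns aligned motif instances into per-position log2-odds
against a uniform background with pseudocount 1. A window's similarity
is min–max normalized, `(score − s_min) / (s_max − s_min)`, which makes
0 and 1 attainable and the "75% similarity" threshold independent of the
instance set's background; the comparison is inclusive. The alternative
reading (fraction of the maximal score) changes with the background term
and cannot reach 0, which is why min–max was chosen; an AT-weighted
background is available as an option since the genomes in question are
~75% AT. A G-rich IR is called when both processed flanks contain a
same-orientation hit at matched distances (≤ 10 bp difference); scanning
with the reverse-complement matrix yields the C-rich arrangement. When
both types qualify at one locus, the one with the lesser distance
difference wins, ties to G-rich. The PWM is a configurable input (a
plain-text A/C/G/T count matrix via `read_pfm()`), not a package
constant, because the instance sets behind published logos are usually
not reproducible numerically.

## The mutant contrast

A locus — considered only when every wild-type and every mutant strain
contributes a form — is *mutant-affected* when its wild-type maximum
variation is ≤ 100 bp (a stringent 20-bp cap is an option) and pooling
the mutant forms raises the maximum by ≥ 100 bp. The increase is
inclusive by default with a strict `>` variant, since both conventions
appear in common usage; the flagged set grows monotonically as the
increase threshold drops, and the pooled maximum can never be below the
wild-type maximum. Enrichment of G-/C-rich IRs among flagged versus
background loci is tabulated per strain and under "at least one strain"
/ "all strains" aggregations over the per-strain assignments. The
background is the considered loci minus the flagged set, and the
denominator used is printed alongside.

## What the simulator emulates — and what it does not

`sim_config()` defaults are the package's reference study conditions,
chosen once:

| parameter | default | rationale |
|---|---|---|
| contigs | 2 × 1 Mb | enough loci for stable statistics at desk scale |
| GC | 0.25 | AT-rich MIC-like background |
| planted IESs | 200, 120–300 bp | above the 100-bp filter with margin for jitter |
| IR motif | `AAAAAGGGGG` at 45 ± 3 bp | the polypurine arrangement seen ~45 bp from deletion ends |
| microhomology | 0–4 bp | typical junction direct-repeat lengths |
| WT boundary jitter | ±5 bp | microheterogeneity mostly within 20 bp per locus |
| mutant jitter | ±150 bp at motif loci | produces ≥100-bp variation increases |
| skip fraction | 0.02/strain | a few percent of loci not shared by all strains |
| intra-strain duplicates | 0.05 | a small population of alternative forms |
| clip signal | floor 10 + Poisson(20) | junction pileups well above background |
| clip noise | rate 10⁻³, counts 1–2 | sparse low-count background, so the mean threshold separates signal |
| candidate displacement | ±50 bp | inside the ±100-bp refinement window |

Microhomology is planted by copying the first `m` deleted bases to the
position immediately after the IES, making both junction representations
valid; the emitted truth interval is kept canonical so left-alignment
recovers it exactly. One master seed drives everything, with per-strain
substreams derived by hashing, so adding a strain never changes another
strain's draws. Jitter that would shrink a form below 100 bp is
resampled.

The generator works at the clip-count level: there are no reads, no
quality scores, no alignment ambiguity, no repetitive sequence, and the
background noise is homogeneous Poisson — a modeling choice exposed in
the configuration, since real pileup noise is structured. Passing tests
therefore demonstrate that the statistical machinery is correct under
the stated evidence model, not that any particular aligner/SV-caller
stack would produce such evidence from real libraries.

## Problem sizes and numerical choices

The test suite validates each operation against independent brute-force
oracles (exhaustive window enumeration, double-loop pair search,
connected components, direct matrix arithmetic) on hundreds of random
small instances, and runs the full pipeline on the reference conditions
(2 × 1 Mb, 200 loci; 500 loci for the mutant contrast) in well under a
minute each. PWM-typing recovery is asserted on the planted reference
intervals, where the planted geometry bounds the distance difference by
construction; on jittered catalogued forms the same quantity additionally
absorbs both ends' boundary jitter, which is reported but not asserted to
a fixed percentage. Ratios and percentages round half-up at two decimals
everywhere, matching the print convention of the tables this layout
mirrors.

## Known limitations

- Breakpoint refinement keeps all tied maxima; with constant-coverage
  evidence this can expand nearby alternative ends into cross products.
  Real pileups rarely tie, and junction re-verification is approximated
  by requiring both ends to clear the threshold.
- The concentricity statistic summarizes left-flank distances (the
  right-flank distribution is computed and reported alongside, not
  folded into selection).
- The N-guard width, window semantics, quantile type and similarity
  normalization are all conventions with defensible alternatives; each
  is a parameter rather than a hard-coded choice.
- No G-quadruplex or protein-binding modeling: the package classifies
  sequence arrangements only.
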