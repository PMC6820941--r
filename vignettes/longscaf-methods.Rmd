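---
title: "Scaffolding contigs with long reads: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scaffolding contigs with long reads: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(longscaf)
```

## The problem and the model

Draft assemblies of long-read data are fragmented mostly where the genome
repeats itself: a contig representing a collapsed repeat can be linked to
several different flanking contigs, and a scaffolder that trusts every
link will produce chimeric joins. `longscaf` treats repeat detection as a
first-class step. Reads aligned across several contigs define *local
scaffolds* — per-read ordered, oriented contig lists with read-axis gaps
— and a contig's positions within those lists reveal whether it behaves
like a single-copy sequence (stable neighbours) or a repeat (many
distinct neighbours). Only the single-copy ("unique") contigs enter the
global ordering problem; repeat-like ("ambiguous") contigs are
re-inserted afterwards at the junctions the reads support.

The global ordering itself is a weighted scaffold graph over unique
contigs. Each edge carries a relative orientation type (the four ways two
oriented sequences can abut: 3'–5', 5'–3', 5'–5', 3'–3'), a gap estimate,
and a confidence weight. The weight is an *alignment-length* statistic —
the largest, over supporting reads, of the smaller of the two endpoint
alignment spans — rather than a bare read count, on the view that a long
alignment is stronger evidence than several marginal ones. Cleaning the
graph is formulated as two optimisation problems solved once over the
whole graph: a binary orientation assignment maximising the total weight
of edges whose orientation constraint can hold, and a position assignment
maximising total big-M slack (equivalently, minimising weighted absolute
positional residuals). Edges losing either stage, and all but the
heaviest edge at any contig end, are discarded, leaving simple paths.

### Assumptions

* Alignments, not raw reads, are the input; the aligner's MAPQ is
  meaningful (multi-mapping reads get low MAPQ).
* Read error shows up as clipped/shifted alignment endpoints and missing
  records, not as systematic strand bias.
* Gaps between adjacent contigs are small relative to read length, so
  reads regularly span junctions.
* Exact repeats are collapsed by the assembler into single contigs; the
  classifier also catches near-exact repeats long enough to recruit
  conflicting neighbours.

## Parameters

| name | meaning | unit | default |
|------|---------|------|---------|
| `s_m` | minimum MAPQ (strict) | – | 20 |
| `l_m` | minimum alignment span on both axes (strict) | bp | 100 |
| `alpha` | maximum endpoint displacement during revision (strict) | bp | 150 |
| `L_r` | minimum read length (strict) | bp | 500 |
| `L_c` | minimum contig length (strict) | bp | 200 |
| `L_ca` | ambiguity length cutoff | bp | 1000 |
| `t` | shared terminal contigs required to merge scaffolds | contigs | 2 |
| `delta` | positional residual above which an edge is spurious | bp | 1000 |
| `containment_fraction` | coverage for containment removal | fraction | 0.95 |

`s_m`, `l_m` and `alpha` are the method's core reliability thresholds
and keep their published defaults. `L_r`, `L_c`, `L_ca` and `t` are
deliberately left to the user by the method; the shipped defaults are
conservative choices for bacterial-scale drafts: `L_r = 500` and
`L_c = 200` keep everything a modern long-read run produces while
guaranteeing `l_m < L_c` (below that no alignment could pass the span
criterion); `L_ca = 1000` treats sub-kilobase contigs as unplaceable by
graph evidence alone; `t = 2` requires two shared terminal contigs
because merging on a single shared contig joins scaffolds on evidence
the contradiction-removal stages never audited. `delta = 1000` is loose
against gap-estimate noise (a few hundred bp under heavy jitter) yet far
below the kilobase-scale disagreement a genuinely misplaced edge
produces. All are strict inequalities where the criteria are phrased as
"greater/smaller than".

## Coordinate conventions and the revision step

All coordinates are 0-based inclusive intervals; SAM input is converted
at the boundary (clip-aware, reverse-strand query offsets mapped back to
the read's original orientation so each read defines one axis).

Revision extends an alignment to the nearer sequence end on each side,
moving **both** axes by the same amount: `ext_left = min(sr, sc)`,
`ext_right = min(LEN(lr)-1-er, LEN(c)-1-ec)`. Writing it as a single
shared extension per side (rather than pinning one axis and recomputing
the other from a length difference) keeps the step idempotent, keeps
every revised coordinate inside its sequence, and makes the eight
interval invariants checked by the tests hold exactly — the
displacement compared against `alpha` is then identical on both axes of
each side. This is the package's resolution of an endpoint-versus-length
ambiguity in the usual inclusive-interval presentation of the formulas,
where the shared boundary position would otherwise be counted twice
(shifting one revised endpoint by a single base and breaking
idempotence).

Degenerate inputs: alignments whose jittered endpoints collapse are
clamped to keep `sr < er` and `sc < ec`; reads whose records are all
filtered simply produce no local scaffold; an empty alignment set yields
singleton scaffolds for every contig.

## The two optimisation stages

*Orientation.* With `η ∈ {0,1}` per edge and `o ∈ {0,1}` per vertex, the
program maximises `Σ w·η` subject to `η ≤ o_i + o_j ≤ 2 - η` for
opposite-strand edge types and `η - 1 ≤ o_i - o_j ≤ 1 - η` for
same-strand types. `η = 1` activates the constraint, so `η = 0` marks an
edge spurious; the textual condition "`o_i ≠ o_j`" selects the first
constraint through the edge's *type* (5'–5' / 3'–3'), since the `o` are
free variables. Because the optimal `η` is determined by `o` (an edge is
kept iff its constraint holds), the program reduces to a maximum-weight
consistent orientation search, solved exactly per connected component by
branch-and-bound over vertex orientations with the remaining-weight upper
bound; one vertex per component is anchored to break the global flip
symmetry (a scaffold and its reverse-complement are the same object).
Components beyond `max_component` vertices would fall back to spanning
tree propagation plus hill climbing, with a warning; at the problem sizes
targeted here the exact search always runs. The tests verify equality
with exhaustive enumeration over all `2^n` assignments on random graphs.

*Positions.* For each edge, directed so `u` precedes `v` under the solved
orientations, `L(φ-1) ≤ p_v - p_u - len(u) - g ≤ L(1-φ)` with
`φ ∈ [0,1]` and `L` one more than the component's total contig plus
absolute-gap length, so the band is non-binding at `φ = 0` and the
optimal `φ` equals `1 - |residual|/L`. Maximising `Σ w·φ` is therefore a
weighted least-absolute-deviation problem in the positions: forest
components are solved in closed form (zero residual); components with
cycles go through a simplex solve, with a deterministic spanning-tree
fallback should the solver not converge. Edges whose final residual
exceeds `delta` are removed. The stages run strictly in the order
orientation → positions → per-end pruning → cycle breaking, each
consuming the previous stage's surviving edges.

Tie-breaking is deterministic throughout: equal spans at a read end and
equal-weight edges at a vertex end resolve by contig id; equal-size
orientation classes by summed weight then a fixed type order; cycle
breaking removes the minimum-weight edge. Identical inputs give
byte-identical outputs.

## What the simulator emulates — and what it does not

The generator produces a random genome, cuts it into contigs separated
by short unsequenced gaps (20–200 bp, single-copy segments at least
2 kb so they sit above `L_ca`), assigns each contig a random strand,
optionally plants exact repeat copies collapsed into one contig placed
several times in the truth layout, and emits alignment records directly:
reads sampled uniformly from both strands (6–12 kb, matching typical
long-read N50s), one record per sufficiently overlapped placement, with
endpoint jitter bounded by `coord_noise`, record dropout with probability
`p_missing`, and full MAPQ. The presets fix the validation conditions:
`clean` (100 kb, 20 contigs, 20x, no noise), `noisy` (jitter 100 bp —
below `alpha` — and 10% dropout), `repeat` (three copies of a 2 kb
unit).

Read-level base error is abstracted entirely into endpoint jitter,
dropout and MAPQ: there is no base-calling error model, no chimeric
reads, no heterozygosity, and repeats are exact rather than diverged.
Passing the preset suites therefore shows the *algorithmic* chain —
revision, classification, graph cleaning, generation — recovers layouts
under bounded coordinate noise; it does not certify behaviour on real
base-space artefacts (which the upstream aligner, not this package,
absorbs).

## Design choices where the method leaves room

* Secondary/supplementary alignments are retained as candidates; the
  MAPQ criterion removes typical multi-mappers.
* Containment removal consumes optional contig-vs-contig alignments
  rather than recomputing them, with "completely contained"
  operationalised as ≥ 95% coverage inside a strictly longer contig.
* The coarse-scaffold deletion rule is generalised to every adjacent
  pair, requires orientation-consistent witnesses, and accepts witnesses
  in either read direction (a read traversing the region backwards is
  the same physical evidence).
* Neighbour distinctness in classification is by contig identity, not
  orientation; a contig recurring within one read contributes one census
  entry per occurrence.
* Gap estimates may be negative (contig overlap) and propagate signed
  end to end; FASTA rendering clamps each gap to at least one `N` while
  the layout TSV keeps the signed value.
* Ambiguous-path insertion copies its gaps from the maximum-weight
  supporting read; end extension adds at most one run per end per pass,
  to a fixpoint capped at 10 passes; merging averages the overlap's gap
  estimates.
* Contigs placed nowhere (never aligned, or ambiguous but never
  inserted) are emitted as singleton scaffolds so output conserves the
  input contig set.

## Known limitations

* Under simultaneous dropout and jitter, a read that skipped a short
  contig can survive the (strict) coarse-scaffold deletion inequality
  when the true inter-contig gaps are smaller than the jitter; its
  skip-edge can then outweigh the short contig's own edges at end
  pruning, leaving that contig as a singleton. This is the method's
  stated trade-off between its weighting and its pruning rule, visible
  in a minority of noisy-preset seeds.
* The orientation stage is exact only per component up to
  `max_component` vertices; beyond that a heuristic engages (never at
  the scales exercised here).
* Gaps are filled with `N`: no read-sequence gap filling and no
  consensus polishing.
* Runtime scales with the local-scaffold set; the implementation targets
  desk-scale validation (the test suites use 30–100 kb genomes) and
  bacterial-scale inputs, not mammalian genomes.
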