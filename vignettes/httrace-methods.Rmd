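---
title: "Detecting and dating horizontal transposon transfer with httrace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and dating horizontal transposon transfer with httrace}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Transposable elements are usually inherited vertically, so a TE family's
distribution across a clade should mirror the host phylogeny. Horizontal
transposon transfer (HTT) leaves three diagnostic signatures instead: a
patchy taxonomic distribution among close relatives, cross-species
sequence identity far in excess of what the hosts' divergence time
allows, and discordance between the TE tree and the species tree.
`httrace` implements the full analysis chain that turns genome
assemblies into HTT calls: consensus curation, panel screening,
copy profiling, two independent dating methods, event inference on a
dated host tree, tree-discordance statistics, and gene-context
annotation of insertions. The motivating application is the repeated
transfer of LINE retrotransposons (RTE, Rex1 and Proto2 superfamilies)
into marine elapid snakes after their transition from land; the package
encodes that seven-species study system (`elapid_timetree()`,
`sea_snake_presence()`) and reproduces its headline result of nine
independent transfer events.

## The similarity engine

Every stage rests on one local DNA search (`search_hits()`). Exact
word seeds (hash index, both strands by reverse-complementing the
query) are clustered by diagonal; each cluster passes a cheap ungapped
X-drop extension filter and then receives a banded affine-gap local
alignment (Smith–Waterman within the band, traceback included). When
the whole problem is small the engine runs the exact unbanded local DP,
so scores on short pairs equal the full Smith–Waterman optimum — the
test suite verifies exact score agreement with an independent
dynamic-programming oracle on hundreds of random homologous pairs.

Two presets mirror the two search regimes the analysis needs:

* `default` — word 28, reward 1, penalty −2, gap 2+2L. Megablast-like
  within-species searching; the values are this package's own documented
  defaults, not a claim of bit-compatibility with any external tool.
* `relaxed` — word 10, reward +3, penalty −4, gap open 30 / extend 6,
  e-value 2×10⁻⁵, dust-style seed masking. The expected per-column
  score stays positive down to ≈57 % identity, which is what a
  cross-phylum screen for 65–75 %-identity relatives of a family needs.

E-values use the Karlin–Altschul formula with λ solved numerically from
the uniform-base-frequency constraint and a fixed K = 0.1; the e-value
is a ranking/threshold device here, not a calibrated genome-wide
statistic. Any non-ACGT character is scored as a mismatch, never as a
match, which biases identity estimates conservatively. Percent identity
counts gap columns in the denominator, the convention of tabular hit
formats, so printed identities are comparable with published tables.

## Consensus curation ("search, extend, align, trim")

`seat_iterate()` refines a seed consensus against a genome by repeated
rounds of: search; keep the 25 best hits of ≥ 1,000 bp by score; extend
each hit by 1,000 bp per side (3,000 bp in cross-species mode, where
homology boundaries are less predictable); extract, reverse-complementing
minus-strand hits; align; trim; and call a majority consensus
(ties broken A<C<G<T; a column is emitted only at ≥ 50 % occupancy).
Iteration stops when successive consensi reach 99 % identity or after
10 rounds. A family with exactly one qualifying copy returns that copy
verbatim, flagged `single_copy`.

The multiple alignment is a center-star: the center is the sequence
with the greatest summed best-local-hit score against the others, and
every sequence is aligned to the center with an affine-gap **local**
alignment. Two deliberate choices depart from the textbook construction
and are worth stating plainly:

* Rows align to the center locally, not end-to-end. Extended copies
  carry ±1 kb of unrelated flanking genome; an end-to-end path would be
  forced to drag one sequence's flank through the other, inflating the
  consensus. Local alignment clips both flanks, and the occupancy trim
  removes whatever the center itself contributes.
* Unaligned segments get private gap columns in the merged alignment —
  insertions from different rows are never stacked into shared columns.
  Stacking unrelated flanks would manufacture high-occupancy columns of
  non-homologous sequence (we observed exactly this failure mode); the
  price is that a genuinely shared insertion relative to the center is
  also split per row, which matters little with the default
  substitution-only simulator and low indel rates in recent TE copies.

Flank trimming drops columns from each end until a 10-column window
holds ≥ 50 % occupancy throughout (inclusive), and removes internal
columns under 20 % occupancy. The original study performed this step by
eye in an alignment editor; the occupancy rule is a deterministic,
parameterized surrogate for the same intent (the published description
is "remove nonhomologous regions", not an algorithm).

Subfamily splitting clusters aligned rows by average linkage on
pairwise identity and cuts at 94 % — the same threshold as redundancy
removal, consistent with subfamilies observed to sit at ≈90 % identity
from each other. Clusters of ≥ 2 rows become subfamilies named H1, H2,
… by size; singletons join their nearest cluster. The convergence
criterion (99 % identity between successive consensi) is likewise a
surrogate for a by-eye judgement and is exposed in `seat_params()`.

## Screening and presence calls

`screen_genome()` collects hits of ≥ 1,000 bp; `call_presence()` makes
the three-state call: **present_similar** with at least one such hit at
≥ 75 % identity; **present_divergent** with more than one such hit all
below 75 %; **absent** otherwise. A single sub-75 % hit is deliberately
not evidence of presence (isolated fragments are too often spurious).
Overlapping hits are merged per locus before counting, resolving the
"more than one sequence" ambiguity in favour of distinct loci. Identity
for the 75 % rule is the best single hit's identity, the simplest
reading of the published threshold. Reciprocal verification
re-searches each candidate region against the whole family library and
drops regions that match a different family better, which eliminates
cross-assignment between related subfamilies.

Transcript support uses ≥ 95 % identity, with 500 bp separating a
`supported` call from `fragment_only`; the fragment boundary is not
stated in the source analysis and is exposed as a parameter.

## Two clocks and their reconciliation

Copy divergence (`copy_divergence()`) is read directly from each copy's
best alignment to its consensus as substitutions per site (raw
p-distance by default, matching "mean substitutions per site";
Jukes–Cantor correction optional and never smaller). The
substitution-rate clock converts divergence to time as
T = d̄ / r × g, with defaults r = 1.25×10⁻⁸ per site per generation
and g = 10 years. The division is by the per-generation rate directly,
with no ploidy factor — this matches the calculator the rate estimate
was published with, and is the largest interpretive risk in the
chain, so it is stated here prominently. Both the SD over copies and
the SE of the mean are reported, since which of the two the published
uncertainties represent is not stated.

Gain parsimony (`infer_gain_events()`) uses a no-loss model: a gain on
a branch forces presence in every descendant tip, so the minimal
explanation of a presence pattern is one gain on the stem of each
maximal all-present clade. Each event is dated to the interval
[crown age, stem age] of its clade. The test suite proves exact
equivalence with a brute-force minimal-gain search over all 2⁷ presence
patterns on the seven-taxon study tree. `present_divergent` counts as
absent for event inference by default (the events of interest concern
high-identity, recently transferred families); a flag reverses this.
`consistency()` marks an event consistent when the clock interval
(mean ± SD) overlaps the branch interval.

On the encoded study matrix the result is nine events: one each for
the three families shared by all three sea snakes, one for the family
shared by the Emydocephalus–Aipysurus clade, one for the family
restricted to *Aipysurus laevis*, and two each for the two Rex1
subfamilies found in *Aipysurus* and *Hydrophis* but not
*Emydocephalus* — those must be independent gains because the three sea
snakes' topology places *Emydocephalus* inside the clade the other two
would otherwise share. The event count is a topological statement and
does not depend on the node ages chosen for the tree; the ages
(root 30 Ma, *Laticauda* split 25 Ma, sea-snake crown 10 Ma,
Emydocephalus–Aipysurus 5 Ma) follow published divergence-time
estimates for the group and only position the event intervals.

## Profiles and the truncation statistic

`build_profile()` maps all fragments of a family onto its consensus:
depth per consensus position plus per-fragment divergence. LINE
replication by target-primed reverse transcription routinely aborts,
producing copies missing 5′ sequence, so a LINE-typical family shows
3′-biased coverage. The statistic is the mean depth over the 3′
quartile of consensus positions divided by the 5′ quartile;
`truncation_call()` fires at ≥ 2.0 (inclusive). The threshold is this
package's quantification of a qualitative published observation. The
simulator's truncation model (keep a 3′ fraction f ~ Uniform(0.05, 1)
with probability `truncation_p`) yields expected ratios well above 2
at `truncation_p` near 1, and flat profiles stay near 1.

## Gene context and flank validation

`intersect_insertions()` assigns each insertion exactly one category by
the priority coding_exon > 5′ UTR > 3′ UTR > in_transcript >
upstream(≤ 5,000 bp, inclusive, strand-aware) > intergenic; the most
functionally specific overlap wins. Upstream distances are measured to
the 5′ UTR start, falling back to the transcript start when no UTR is
annotated (logged). `validate_flanks()` guards against assembly
chimeras: the 2-kb flanks of an insertion are located in independent
comparison assemblies; if both flanks co-locate on one contig within
twice the expected span in at least one comparison the insertion is
`contiguous`, if they land on different contigs in *every* comparison
it is `split` (disregarded), otherwise `unresolved`.

## Tree discordance

`filter_intact()` keeps elements with ≥ 80 % coverage of both the
endonuclease and reverse transcriptase domains, so trees are built from
alignable, full-ORF sequence. `block_trim()` is a relaxed block filter
(occupancy ≥ 50 %, runs of ≥ 5 kept columns). Trees are built by
neighbor-joining on p- or JC-distances over shared non-gap columns —
a deliberate desk-scale choice; a maximum-likelihood program can be
substituted externally, and the discordance conclusions are
topology-level. `discordance_stat()` collapses duplicate-host tips
(keeping the tip nearest its host-group centroid), relabels by host,
and reports the normalized Robinson–Foulds distance to the pruned
species tree plus each TE tip's nearest neighbour's host — under HTT a
recipient's nearest neighbour is the donor lineage's TE, not its own
host's vertical elements.

## The simulator and what passing tests mean

`simulate_panel()` is the package's ground-truth instrument. Host
backgrounds are i.i.d. uniform DNA at 41 % GC evolved along the dated
tree under Jukes–Cantor at 1.25×10⁻⁹ substitutions/site/year (the
default clock expressed per year); the model is substitution-only by
default because the analysis chain reads divergence from substitutions
per site. Vertical families are present in every tip with a stated
per-copy divergence; an HTT family is present exactly in the tips below
its origin branch, with per-copy divergence rate × origin time — the
realization inserts the copies at the tips with that divergence, which
preserves every contract the downstream analyses consume (the truth
matrix, the coverage shape, and the expected copy-to-consensus
divergence) without tracking insertion coordinates through ancestral
genomes. Copies are placed non-overlapping with ≥ 300 bp spacing
(nesting is deliberately absent), truncated and stranded as described,
and every copy has an exact truth record. All randomness flows from one
seed; regeneration is byte-identical.

What the simulator does **not** emulate bounds what green tests mean:
real repeat landscapes (satellites, LTR nests, segmental duplications),
indel accumulation, sequencing error, assembly collapse of young
near-identical copies, and GC/rate heterogeneity along the genome. The
property tests therefore demonstrate that the chain is correct and
well-calibrated under its own model assumptions, not that those
assumptions hold for any particular real assembly.

## Problem sizes and numerical choices

The shipped tests and the acceptance script run the chain at desk
scale, chosen as the smallest sizes at which the statistical properties
are meaningful: 150-kb simulated backgrounds for the worked panel,
25-kb backgrounds across 20 seeded screening panels, 25-copy curation
of a 3-kb family (d = 0.08, half the copies truncated), 50-copy age
recovery at 4–16 Ma, and 100-pair alignment-oracle comparisons.
Deterministic tie-breaks appear wherever a choice is otherwise
arbitrary: consensus ties in base order, redundancy ties drop the
lexicographically later id, subfamily names order by cluster size, and
the center of the star alignment is chosen on name-sorted input so row
order never changes a result. Degenerate inputs error loudly rather
than degrade: non-ultrametric trees for dating, empty alignments after
trimming, zero qualifying curation hits, families with no copies.

## Known limitations

* The e-value is uncalibrated for gapped alignments (fixed K); use
  scores or identities for fine ranking.
* The no-loss gain parsimony is conservative by construction: a true
  loss in one species inflates the event count. This mirrors the
  published analysis's choice and is the reason its event count is
  called a conservative estimate.
* NJ trees carry no support values; the discordance statistic is
  topology-only.
* The center-star MSA is a desk-scale tool; for publication-grade
  repeat phylogenies an external aligner remains preferable.
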