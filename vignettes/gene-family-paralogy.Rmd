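---
title: "Resolving gene-family paralogy: methods and design notes"
author: "paralogr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resolving gene-family paralogy: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paralogr)
```

# Scope

`paralogr` implements the comparative-genomics toolkit needed to resolve a
small gene family that descends from one ancestral gene through rounds of
whole-genome duplication (the vertebrate 1R/2R scenario): which modern
members are sisters, which introns are homologous, which genomic
neighborhoods still witness the duplications, and which database matches
are full-length homologs rather than single-domain hits. Four independent
lines of evidence are implemented — exon–intron architecture, distance
phylogeny, synteny, and alignment coverage — plus a ground-truthed
simulator that generates labeled inputs for all of them.

The package deliberately *consumes* multiple sequence alignments and
pairwise hit tables rather than producing them: alignment construction
(MAFFT and friends) and database search (BLAST) are external concerns with
their own mature tooling.

# Exon–intron architecture

A `gene_model` stores the ordered coding exons of a protein-coding gene as
0-based half-open genomic intervals in transcription order, together with
the CDS (including its stop codon, as in RefSeq annotation practice; the
protein is therefore `cds_len/3 - 1` residues) and the translated protein.

**Intron phase** is computed by the modulo-of-exon-lengths rule: if
`cds_offset` coding nucleotides precede an intron, its phase is
`cds_offset mod 3` — phase 0 introns fall between codons, phase 1/2
introns split a codon after its first/second position. Phase is a strong
homology signal because it is invariant under sequence divergence: an
intron can only keep its phase or be lost, it cannot drift.

**Anchoring.** To compare introns across genes they are projected onto a
shared protein alignment. Each intron is anchored to residue
`floor(cds_offset / 3)` — the residue whose codon contains the splice
point; for phase 0 this is the residue immediately 3' of the splice. This
single deterministic rule makes projection unambiguous; the alternative
(anchoring phase-0 introns to the 5' residue) merely shifts every phase-0
column by one and carries no extra information.

**Projection and conservation.** `residue_to_column()` maps an ungapped
residue index through the gaps of that gene's alignment row;
`intron_conservation()` then groups projected introns by column: a column
carried by two or more genes with one common phase is a *shared site*, a
column whose carriers disagree in phase is a *phase conflict*. Matching is
by exact column equality — no ±1-column sliding — because determinism
matters more here than rescuing marginal alignments, and near-miss sites
are visible in the report anyway as adjacent singletons.

**Spliced mapping.** When gene models are not annotated, `spliced_map()`
reconstructs exon intervals by greedy left-to-right exact matching of the
CDS against a genomic slice, treating every intron as canonical `GT...AG`.
At a mismatch it prefers the splice donor giving the longest current exon,
then the shortest intron; candidate chains are verified recursively so the
returned chain always re-concatenates to the CDS exactly. Mismatch
tolerance and non-canonical splice sites (GC–AG, AT–AC) are out of scope.
Note that a random intron interior can by chance contain an alternative
consistent `GT...AG` chain; the mapping is then still a valid exact
spliced alignment, just not bitwise the generating one — downstream
consumers should rely on the CDS-reconstruction invariant, not on interval
identity.

# Alignment filters and information content

Two filters are applied before distance computation, mirroring common
practice in distance phylogenetics:

* `complete_deletion()` removes every column containing a gap (`-`) or
  missing data (`X`, `?`), so all pairwise distances use exactly the same
  sites.
* `gap_fraction_filter()` drops sequences responsible for more than a
  threshold share (default 0.20) of the alignment's gap characters. The
  phrase "a row introducing more than 20% of the total gaps" admits two
  readings — the row's share of *all* gap characters in the MSA (default,
  `mode = "msa_share"`), or the row's own gap fraction
  (`mode = "row_fraction"`). Both are implemented; the MSA-share reading
  is the default as the closest literal interpretation, and no claim is
  made that it is the only sensible one.

`column_information_bits()` scores per-column conservation as
`log2(20) - H` with `H` the Shannon entropy of the residue frequencies;
the ceiling for proteins is `log2(20) ≈ 4.32` bits (the familiar "4.3
bits" y-axis of sequence logos). The optional small-sample correction
subtracts the approximation `19 / (2 ln(2) n)`. Gap and missing characters
are excluded from the counts; the corrected value is returned as computed
(it can go negative for tiny samples) rather than clipped.

# Distance phylogeny

**Model.** Pairwise distances are maximum-likelihood branch lengths under
the JTT amino-acid model: the published Jones–Taylor–Thornton (1992)
exchangeabilities and equilibrium frequencies, assembled into a reversible
rate matrix normalized to one expected substitution per site. Among-site
rate heterogeneity uses Yang's discrete-Gamma approximation with
equal-probability categories (default K = 5) whose rates are the
conditional category means; the shape parameter is exposed as
`gamma_shape` (typical empirical values for vertebrate protein families
lie between 1 and 2.5). Invariant-site mixtures are deliberately not
implemented for distances: +I is aliased with low Gamma shapes at pairwise
scale and would complicate the likelihood for no measurable gain here.

The pairwise likelihood only depends on the 20×20 table of aligned residue
pairs, so one evaluation costs `O(20^3)` regardless of alignment length.
Optimization is Brent search on `t ∈ [1e-9, 10]` to tolerance `1e-6`
(compiled); an estimate at the upper bound is flagged `saturated`. The
test suite verifies the optimizer against an independently assembled
grid-search of the same likelihood (step `1e-4`) and against an external
JTT implementation.

**Neighbor joining** is the classical Saitou–Nei algorithm. Two numerical
choices are pinned down because they affect bit-reproducibility: Q-ties
are broken toward the lowest (row, column) index pair, and negative
branch-length estimates are clamped to zero (the count is reported in an
attribute, not silently discarded). NJ is exact on additive matrices,
which the tests exploit as an oracle.

**Bootstrap.** Column bootstrap with the same number of columns, tree
rebuilt per replicate, support of each original internal edge = percent of
replicates containing its bipartition. Replicate `r` is seeded with
`seed + r`, which makes individual replicates reproducible in isolation.
Degenerate replicates (all rows identical after resampling) carry no
signal; they are skipped with a warning but remain in the denominator, so
support is conservative. The package default is 1000 replicates; the
package's own acceptance checks use 200 to keep a 50-simulation sweep
inside a few minutes, a size at which support estimates have a standard
error below 3.5 points.

**Midpoint rooting** places the root halfway along the longest
leaf-to-leaf path, found by the two-pass farthest-leaf method (exact on
trees). With highly asymmetric outgroup-free families this is the standard
rooting choice. If the midpoint falls exactly on an internal node the tree
is rooted at that node (yielding a trifurcating root) rather than
inventing a zero-length edge.

# Synteny

`extract_neighborhood()` collects up to `k = 4` protein-coding genes per
side of a focal gene, skipping RNA genes (which do not count toward `k`)
and stopping at a `window = 500` kb boundary-to-boundary distance.
Distances are measured between nearest gene boundaries, not midpoints —
a determinate reading of "distance from the locus".

Neighborhood comparison works on *family labels*, not gene identifiers,
because orthologous flankers carry species- and paralog-specific symbols
(`Sox6` vs `Sox13`). The default normalization uppercases the symbol and
strips one paralog suffix: a single trailing letter when it follows a
digit (`Pik3c2a → PIK3C2`), otherwise the trailing digit run
(`Sox13 → SOX`). This rule is intentionally minimal; irregular
nomenclature is handled by an explicit symbol→family map, which overrides
the rule per symbol. `conserved_blocks()` reports the families present on
both sides and a Jaccard score of the two family sets. The score is an
artifact-level formalization — synteny figures in the literature are
qualitative — and gene order/strand are recorded but not required to
match, since real conserved blocks survive local inversions.

# Homology coverage classification

`coverage_profile()` merges a query's hit intervals (query-anchored, as
alignment diagrams conventionally are) into disjoint covered segments.
`classify_homology()` applies, in order: no hits or best E-value above
`1e-20` → `none`; coverage above 60% → `full_length`; at least 80% of the
covered length inside the PH domain → `PH_only`; inside the
coiled-coil/C-terminal region → `CC_or_Cterm_only`; otherwise
`partial_other`. The 60% coverage and `1e-20` E-value thresholds are the
conventional full-length-homology criteria for this kind of survey; the
80% within-domain fraction is this package's own operationalization of
"alignment restricted to the domain" and is exposed as `domain_frac`.
Classification is monotone: adding hits can only move a label toward
`full_length`.

# The simulator and what it does (not) emulate

`simulate_family()` generates one ancestral gene and applies two rounds of
duplication, producing members `m1..m4` with true tree
`((m1,m2),(m3,m4))`. Defaults define the reference scenario:

| parameter | default | rationale |
|---|---|---|
| `protein_length` | 300 aa | typical multi-domain protein scale |
| `n_introns` | 8 | typical vertebrate gene |
| `duplication_depths` | 0.4, 0.25 subst/site | deep pre-vertebrate split, shallower second round |
| `terminal_depth` | 0.15 subst/site | post-duplication divergence |
| `gamma_shape` | none | uniform rates unless heterogeneity is under study |
| `intron_loss_rate` | 0 /branch | architecture conserved unless perturbed |
| `intron_gain_rate` | 0 /branch | gains are rare in vertebrates |
| `flankers_per_side` | 4 | matches the neighborhood rule |
| `neighbor_retention_p` | 0.7 | visible but incomplete neighborhood decay |

Sequences evolve by per-site sampling from the exact JTT transition
matrices; the ancestor is drawn from JTT equilibrium so the closed-form
expected divergence holds exactly (the tests use this). Intron events are
applied per branch: each intron lost with probability `intron_loss_rate`,
`Poisson(intron_gain_rate)` gains at random coding offsets — at most one
intron per codon, so projected anchors stay unique. Every event is logged
with the intron's homology label, making downstream conservation calls
exactly checkable. Neighborhoods decay by independent per-flanker
retention at each duplication; flanker families are synthetic unique
tokens (`FAM001`…), sidestepping symbol-normalization ambiguity in truth
checks.

**Limitations.** No indels are simulated, so the true alignment of a
simulated family is the trivial positional one and the gap-handling code
paths are exercised with hand-built fixtures instead; no codon-level
model (CDS sequences are re-reverse-translated per member, so synonymous
structure is not meaningful); no rate variation across lineages; the
teleost-specific third round is representable by composing an extra
duplication but has no dedicated mode. Passing recovery tests on
simulated families therefore demonstrates correctness of the machinery
under the stated model, not robustness to alignment error, indel-rich
regions, or compositional bias in real data.

# Problem sizes used in the package's own checks

The bundled checks run, per invocation: 100 random additive matrices
(4–10 leaves) for NJ consistency; 30 trees (≤12 leaves) for midpoint
rooting against exhaustive search; 50 random pairs for the distance grid
oracle; 50 simulated families with 200-replicate bootstraps for scenario
recovery; 20 seeded families for intron-event agreement; and 200
neighborhood duplications for the `8p²` decay expectation. These sizes
give Monte-Carlo standard errors comfortably below the decision
thresholds while keeping a full run in the low minutes on one core.

# Worked example

```{r example, eval = FALSE}
tru <- simulate_family(simulation_config(seed = 1))
aln <- tru$alignment

## phylogeny with support, midpoint-rooted
tree <- bootstrap_support(aln, phylo_config(n_bootstrap = 200, seed = 1))
rooted <- midpoint_root(tree)

## intron conservation across the family
introns <- do.call(rbind, lapply(tru$members, `[[`, "introns"))
cons <- intron_conservation(project_introns(aln, introns))

## synteny between the two deepest paralogs
conserved_blocks(tru$members$m1$neighborhood,
                 tru$members$m4$neighborhood)
```
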