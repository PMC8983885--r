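# paralogr

Comparative-genomics tools for resolving **gene-family paralogy**: given a
small family of genes descended from one ancestor through rounds of
(whole-genome) duplication — the classic vertebrate 1R/2R situation — which
members are sister paralogs, which introns are homologous, which genomic
neighborhoods still record the duplications, and which database matches are
genuine full-length homologs? The package is aimed at molecular
evolutionists doing family-scale analyses (a handful to a few hundred
sequences), not genome-wide pipelines.

It combines four independent lines of evidence behind one consistent API:

1. **Exon–intron architecture.** Intron phase by the modulo rule
   (`phase = cds_offset mod 3`; 0 = between codons, 1/2 = codon split after
   the first/second position), extraction from gene models (GFF3 + genome,
   or spliced mapping of a CDS onto a genomic slice with canonical `GT…AG`
   introns), and projection of intron anchors onto a protein multiple
   sequence alignment to score position+phase conservation and phase
   conflicts.
2. **Distance phylogeny.** Maximum-likelihood pairwise distances under the
   JTT model, optionally with discrete-Γ rate heterogeneity
   (`P(t) = Σ_k 1/K · exp(Q r_k t)`, Yang's equal-probability categories),
   classical Saitou–Nei neighbor joining
   (`Q(i,j) = (n−2) d(i,j) − Σ_k d(i,k) − Σ_k d(j,k)`, deterministic tie
   rule), column bootstrap with per-edge bipartition support, and midpoint
   rooting on the longest leaf-to-leaf path.
3. **Synteny.** Neighborhoods of up to four protein-coding flankers per
   side within 500 kb (RNA genes skipped), gene symbols normalized to
   family labels (`Sox6`/`Sox13` → `SOX`), and conserved blocks scored by
   the Jaccard index of the two family sets.
4. **Homology coverage.** Query-anchored coverage profiles merged from
   BLAST-tabular hits, classified as `full_length` (coverage > 60%, best
   E ≤ 1e−20), `PH_only`, `CC_or_Cterm_only`, `partial_other`, or `none`.

A ground-truthed **simulator** (`simulate_family()`) generates families
under the two-round duplication scenario — JTT sequence evolution, intron
gain/loss with a full event log, lineage-specific gene loss, decaying
neighborhoods — so every stage can be validated against known truth without
any external downloads.

## Worked example

```r
library(paralogr)

tru <- simulate_family(simulation_config(seed = 1))
aln <- tru$alignment                     # 4 rows x 300 columns

round(jtt_distance_matrix(aln), 3)
#>       m1    m2    m3    m4
#> m1 0.000 0.774 1.677 1.683
#> m2 0.774 0.000 1.645 1.761
#> m3 1.677 1.645 0.000 0.828
#> m4 1.683 1.761 0.828 0.000

tree <- bootstrap_support(aln, phylo_config(n_bootstrap = 200, seed = 1))
ape::write.tree(midpoint_root(tree))
#> ((m1:0.376,m2:0.399)100:0.468,(m3:0.383,m4:0.445):0.422);

introns <- do.call(rbind, lapply(tru$members, `[[`, "introns"))
intron_conservation(project_introns(aln, introns))
#> intron_conservation: 8 intron-bearing columns ( 8 shared, 0 phase conflicts )

conserved_blocks(tru$members$m1$neighborhood, tru$members$m4$neighborhood)
#> synteny_block m1 vs m4 : score 0.4286 with 3 shared families
```

Reading the output: the distance matrix already separates the two sister
pairs (m1–m2 and m3–m4 are each other's closest relatives at ~0.8
substitutions/site, cross-pair distances ~1.7); the midpoint-rooted NJ tree
recovers the true `((m1,m2),(m3,m4))` topology with 100% bootstrap support
on its internal edge; all 8 ancestral introns are conserved in position and
phase across the family (no intron events were simulated); and the m1/m4
neighborhoods still share 3 of their flanker families after two rounds of
decay at the default retention probability 0.7.

`run_pipeline(pipeline_config(seed = 1), "run1")` executes all stages into
a run directory with a determinism manifest; a thin command-line front end
with the same stages lives in `inst/cli/paralogr.R`.

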