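# aridEvol

Branch-specific gene gain, positive selection and heat-stress
expression analyses for cactophilic *Drosophila*.

## The problem

Comparative genomics of the *repleta* species group asks where, on the
species phylogeny, bursts of evolutionary change happened as flies
adapted to cactus hosts and hot, desiccating environments. The
quantities of interest are per-branch rates: how many orthogroups
(gene families spanning ≥ 2 species) arose on each internal branch,
how many species-specific duplicates (inparalogues) arose on each
terminal branch, and how many genes show positive selection — each
normalised by the branch's presumptively neutral silent-site length
*L<sub>i</sub>* (substitutions per 4-fold degenerate site). For an
event class with counts *c<sub>i</sub>*, the expected count under a
single global rate is

    E_i = L_i * (Σ c) / (Σ L),    excess_i = c_i − E_i

and Σ excess = 0 by construction. A second question is whether genes
that generate inparalogues are more likely to be positively selected:
per species, the proportions x/n in both strata are compared with
exact Clopper–Pearson 95% intervals and a Fisher exact test. The
transcriptomic arm calls heat-responsive genes (BH-adjusted p < 0.05
and |log2FC| > 1 versus the pre-exposure control at ≥ 2 of 7
post-control time points), clusters standardised trajectories by
fuzzy c-means with the cluster number chosen by the partition
coefficient, and tests whether shared differential-expression
responses between two species exceed the independence expectation
E = (a+both)(b+both)/N.

The package implements all of this — a three-criterion
orthologue/inparalogue/gene-birth classifier (reciprocal-best
similarity, synteny, symmetric sister grouping), Dollo origin-branch
mapping, 4-fold-site JC distances with non-negative least-squares
branch lengths, NG86 Ka/Ks, the four-criterion phylogenomic locus
filter, Louvain GO-set construction with Lin semantic-similarity edge
weights and hypergeometric set enrichment, and the full heat-shock
pipeline — together with a synthetic-data generator that produces
every input with known ground truth. It is aimed at researchers who
want to reuse the inference machinery, or to study its statistical
behaviour under controlled conditions.

## Worked example

The numbered scripts under `analysis/` run the whole workflow on
synthetic data at study scale (seeded, deterministic):

```sh
Rscript analysis/01_simulate.R      # data + ground truth under results/data/
Rscript analysis/02_orthology.R
Rscript analysis/03_branch_rates.R
Rscript analysis/04_go_sets.R
Rscript analysis/05_heat_response.R
```

Step 2 classifies 11,337 genes and prints the confusion against the
generator's truth — 100% of the 630 planted inparalogues and all 108
gene births are recovered, with 1.8% of true orthologues
conservatively demoted to inparalogues (the rate of synteny-breaking
relocations in the generator):

```
             called
truth         birth inparalogue orthologue
  birth         108           0          0
  inparalogue     0         630          0
  orthologue     0          190      10409
```

Step 3 fits silent branch lengths from 200 simulated alignments and
prints the origination excesses; the planted high-rate `cactus_use`
branch carries the large positive excess (+328 orthogroups here),
exactly the signature the analysis is designed to expose. Step 5
prints the heat-shock arm:

```
Dhyd: 857 heat-responsive genes
Dbuz: 821 heat-responsive genes
Shared DE: 129 observed vs 67.6 expected under independence (1.91-fold)
Partition coefficient selects c = 8 clusters
```

against planted values of 825/804 DE genes, a 1.94-fold shared
excess, and 8 trajectory clusters.

In-paper quantities are one-liners:

```r
library(aridEvol)
round(100 * clopper_pearson(95, 1237), 2)   #  6.26  9.31
overlap_independence(123, 702, 681, 10443)$expected_both  # 63.52
fullsib_inbreeding_coefficient(17)          # 0.974 (> 0.7)
```

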