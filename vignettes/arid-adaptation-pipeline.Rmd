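---
title: "Methods: branch-specific gene gain, selection and heat-stress expression analyses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: branch-specific gene gain, selection and heat-stress expression analyses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

# Scope

`aridEvol` implements the inference machinery of a comparative
genomics and transcriptomics analysis of arid adaptation in
cactophilic *Drosophila* (the *repleta* species group): orthology
classification and origin-branch mapping of gene families, silent-site
branch lengths from 4-fold degenerate sites, per-branch event rates
and excesses, the duplication-selection association, GO-term set
construction and enrichment, and a heat-shock time-course
differential-expression and fuzzy-clustering analysis. A first-class
synthetic-data module generates every input with known ground truth,
so the whole pipeline is testable end to end without any external
data. The numbered scripts under `analysis/` run the workflow; every
computational step lives in the package and is unit-tested.

What the package deliberately does *not* do: genome assembly and
annotation, maximum-likelihood tree inference and dating, the
branch-site likelihood test itself (selection calls are consumed as
flags or simulated), read-level RNA-seq processing, batch correction
against real batch structure, and ontology compression services.

# The species tree and the synthetic genome model

The fixed study topology (`repleta_tree()`) carries five *repleta*
group species — *D. aldrichi* (`Dald`), *D. mojavensis* (`Dmoj`),
*D. buzzatii* (`Dbuz`), *D. hydei* (`Dhyd`), *D. repleta* (`Drep`) —
plus a *D. virilis*-like near outgroup and a *D. melanogaster*-like
far outgroup. Internal branches are named for the events on them:
`ancestral_repleta`, `cactus_use`, `cactus_specialisation`,
`mulleri_complex`. Branch lengths are silent-site lengths
(substitutions per 4-fold degenerate site); the defaults (0.25, 0.10,
0.06, 0.05 on the internal branches; 0.10-0.22 on the repleta
terminals) were chosen once as plausible magnitudes for a 10-15 My
radiation and are *not* fitted to any published tree. Two outgroups
are used rather than one because pairwise distances cannot place a
root: with a single outgroup the repleta stem would be confounded with
the outgroup's own branch, whereas with two it is an internal branch
of the unrooted tree and therefore estimable.

`simulate_gene_families()` draws orthogroup origination events per
branch as Poisson(rate × silent length). The default per-branch birth
rates reproduce, in expectation, the published per-branch origination
counts (265, 394, 194 and 22 orthogroups on the four internal
branches); terminal duplication rates are proportional to the
published per-species inparalogue counts, scaled to the generator's
family count (1,000 root families by default). Gene loss after
origination defaults to 0 (Dollo-clean presence patterns), because the
origin-branch assignment rule implicitly assumes a single origin; a
configurable `loss_prob` exists to probe the robustness of that
assignment.

Genomes are collinear by construction: all species inherit one
ancestral gene order, split into five scaffolds, and each gene is
relocated with probability 0.02 per species. This is what gives the
synteny criterion its signal and its noise. Inparalogues insert
adjacent to their template with probability 0.7 (else uniformly).

Two generative assumptions matter for interpretation:

* **Duplicate copies evolve faster.** Each inparalogue carries a fixed
  divergence penalty (`dup_penalty`, default 0.05 silent units) on top
  of its age. Without some rate asymmetry, template and copy are
  statistically exchangeable (both descend from the duplication point)
  and no distance-based rule could tell them apart. The penalty
  encodes the standard expectation that redundant young duplicates
  accumulate substitutions faster.
* **Similarity scores are minus expected distances plus Gaussian noise**
  (sd 0.01). Real pipelines consume alignment scores; the package
  accepts any symmetric score table, and tests exercise the
  classifier through this generative stand-in.

Positive-selection flags are Bernoulli per branch; on terminal
branches the probability is multiplied by `selection_enrichment_dup`
(default 1.8) for genes that generated inparalogues. This plants the
duplication-selection association that the Table-2-style analysis is
meant to detect, at roughly the odds ratio visible in the published
proportions.

# Orthology classification

`classify_orthology()` applies three criteria:

1. *Similarity*: reciprocal best-scoring cross-species hit.
2. *Synteny*: at least one of the `w = 5` nearest scaffold neighbours
   (either side) has a best hit within `w` gene-order positions of the
   gene's partner. No published window parameterisation exists for the
   original classifier, so this window rule is an explicit stand-in;
   both `w` and the support threshold are configurable.
3. *Symmetric sister grouping*: when several same-species copies share
   one best partner, the candidate with the smallest signed mean
   excess of its third-species distances over the partner's wins. The
   signed mean (rather than an absolute difference) is important: the
   species-path component of the distance is common to all candidates
   of one species, so it cancels, leaving only duplication excess plus
   paired noise. An absolute-difference statistic would be confounded
   by non-clock rate variation among species. The verdicts are
   aggregated over all partner species before deciding, so one noisy
   comparison cannot flip a classification.

A gene meeting every applicable criterion (with reciprocal-best
similarity) is an orthologue; a gene with detectable cross-species
similarity failing one or two criteria is an inparalogue (template =
best-scoring same-species orthologue); a gene with no similarity edge
at all is a gene birth. Orthogroups are connected components of
accepted orthologue pairs; if a component retains two members of one
species, only the best-supported copy stays an orthologue — a
conservative rule that, as in the original study, pushes some true
orthologues into the inparalogue class (about 2% under the default
generator, dominated by the 2% relocation rate defeating the synteny
criterion).

Origin branches follow the Dollo rule: the stem of the smallest clade
containing all member species; families spanning both sides of the
root map to the root stem.

# Silent-site branch lengths and Ka/Ks

4-fold degenerate columns are third positions whose codon prefix is
4-fold degenerate in *every* sequence (strict intersection), avoiding
columns whose degeneracy class differs between species. Pairwise
silent distances use the Jukes-Cantor correction
`d = -(3/4) ln(1 - (4/3) p)`; pairs with `p >= 3/4` are flagged
saturated and dropped. Branch lengths are fitted by non-negative
least squares (`pracma::lsqnonneg`) on the fixed topology — a
deterministic, testable choice made because the original work does not
state how its silent lengths were computed; the two root-adjacent
branches are merged during the fit (only their sum is identifiable
from distances) and the fitted sum is split equally, with the pair
reported in an attribute so consumers can exclude it.

Numerical behaviour worth knowing: under the simulator's kappa = 2
mutation kernel the JC correction under-corrects deep paths by ~4% at
silent distance 1.9, and short internal branches (0.05-0.06) carry
sampling error of order 5-10% of their own length at 200 genes x 300
codons. Branch-length recovery is therefore assessed as the
normalised total error `sum(|est - true|) / sum(true)` over
identifiable branches (observed ~3-4% at that problem size), not
per-branch, where the shortest branches would be noise-dominated.

`ng86_kaks()` is the classical Nei-Gojobori (1986) estimator:
per-position synonymous site fractions averaged over the two
sequences (mutations to stop codons count as nonsynonymous sites),
differences averaged over all minimal substitution pathways excluding
those through stop codons (with a fall-back to all pathways if every
one is blocked), Jukes-Cantor correction of both proportions, ratio
undefined at `Ks = 0`. The test suite checks it against an independent
pathway-enumeration oracle over every sense-codon pair.

The phylogenomic locus filter applies, in order: no inparalogues in
the orthogroup; no member-vs-reference pair with Ka/Ks > 1 (a pair
with Ka > 0 and Ks = 0 — an unbounded ratio — also fails); protein
length > 200 aa unless all members are within five residues of each
other; and all lengths within 1.5 raw median absolute deviations of
the median. The MAD bound is floored at one residue: for
near-identical length sets the raw MAD collapses to zero and a
literal reading would reject orthogroups differing by a single
residue, which the length-window exception clearly intends to keep.

# Branch rates, excesses and the association test

For each event class (orthogroups arising, inparalogues,
inparalogue-generating orthogroups, selected genes) the expected count
under a single global rate is `E_i = L_i * sum(c) / sum(L)` and the
excess is `c_i - E_i`; excesses sum to zero by construction, which the
tests assert to 1e-9. The original analysis judges disproportion by
eye from plots; this implementation adds Poisson tail probabilities at
mean `E_i` as a formalisation, documented as an addition.

The duplication-selection association uses exact Clopper-Pearson
intervals (beta-quantile form, checked against tail-inversion
bisection to 1e-10) and a two-sided Fisher exact test per species.
Percentages are rounded to two decimals with round-half-even. The
shared-DE overlap statistic reports the expected shared count under
independence, the fold excess, and the standard Pearson chi-squared on
the implied 2x2 (df = 1, no continuity correction); the corresponding
published chi-squared value is not reproducible from the printed
counts by the standard formula, and the package makes no attempt to
guess the original computation.

# GO sets and enrichment

The ontology graph keeps `is_a` edges only; annotations are
ancestor-closed before anything else happens. Information content is
`-ln(n(term or descendants) / n(root))` with a 0.5-gene pseudo-count
for unannotated terms. Parent-child edge weights use the Lin
similarity `2 IC(parent) / (IC(parent) + IC(child))` (the parent is
the pair's most informative common ancestor, so the general Lin
formula reduces to this); Lin was chosen as a bounded, standard
IC-based measure, the original work naming only "semantic
similarities". Louvain community detection (weighted, via `igraph`,
seeded and deterministically relabelled by smallest member term) gives
mutually exclusive sets; re-running it inside each set gives nested
subsets. Set labels take the member term with the largest closed
annotation count, ties to the smallest id. Set counts are checked
only as properties (exclusivity, coverage, reproducibility), never as
fixed numbers: they depend on the ontology release and clustering
seeds, which the original study does not state.

Enrichment is a hypergeometric upper tail per set (a gene counts
toward a set if any closed term lies in it), BH-corrected across sets,
significant at q < 0.05. Representation metrics report absolute and
percentage involvement per subset, analysing only subsets of more than
ten genes and display-flagging those with more than ten genes or more
than 5% involved in any analysis — all strict inequalities.

# Heat-shock expression analysis

The design is 8 time points (pre-exposure control T0, mid- and
post-exposure, five recovery points) x 3 replicates, two species.
Genes need a total of more than 50 reads to enter. Normalisation is
TMM (via `edgeR`); expression is log2 CPM with pseudo-count 0.5.
Differential expression against T0 uses per-gene linear models with
empirical-Bayes moderated t-statistics (`limma`) — a documented
simplification of the original voom + ComBat route, since synthetic
data has no real batch structure — with BH correction applied jointly
across all gene x time-point tests (per-time-point scope available).
A gene is heat-responsive with adjusted p < 0.05 and |log2FC| > 1 at
two or more post-control time points, any sign; whether the original
criterion required a consistent sign is not stated, and the sign-free
reading is the implemented one.

DE genes' per-time-point mean profiles are z-scored per gene, pooled
across the two species, and clustered by fuzzy c-means (fuzzifier
m = 2, Euclidean distance, centroid-shift tolerance 1e-6, best of 5
seeded restarts by objective). The implementation is in the package
because the monotone-objective invariant is asserted per run and the
restart/tolerance policy must be deterministic; an independent
`e1071::cmeans` fit serves as a cross-check in the tests. The cluster
number is chosen by the fuzzy partition coefficient
(`mean(rowSums(U^2))`, 1 when crisp, 1/c when uniform) over c = 4..20,
ties to the smaller c. Core genes have membership > 0.5; genes never
exceeding 0.5 are reported unclustered. Discriminating genes of a
cluster are core genes of the over-represented species whose 1:1
orthologue is not a core gene of the same cluster in the other
species (genes without orthologues qualify); the top members are the
ten highest-membership discriminating genes with a stable id
tie-break.

The expression simulator draws negative-binomial counts (dispersion
0.05) whose DE genes follow one of eight standardised trajectory
templates on the log2 scale with amplitude 2 (up to 4-fold changes);
the default DE split (123 shared, 702 and 681 species-specific genes
out of 10,443) mirrors the study's published counts, so the planted
fold-excess of shared responses is ~1.94. What the generator does
*not* emulate: batch effects, library-preparation artefacts,
count-level correlation between genes, isoform structure, or
species-specific trajectory shapes for shared DE genes — so passing
tests demonstrate the machinery's correctness and calibration on
idealised counts, not robustness to those real-data pathologies.

# Problem sizes and determinism

All randomness flows through explicit integer seeds; the pipeline
writes a manifest of per-file checksums, and rerunning with the same
seed reproduces them byte for byte. The test suite uses these problem
sizes, chosen as the smallest at which the statistical behaviour under
test is stable: classifier recovery at 300 families; branch-length
recovery at 200 genes x 300 codons; rate-excess recovery over 20
seeds at 1,000 families; cluster-number selection over 20 seeds at
~300 pooled DE profiles; DE error control at 1,000 genes. The
`analysis/` workflow runs the same machinery at the full study scale
(1,000 families, 10,443-gene expression matrices).

# Known limitations

* The synteny and sister-symmetry criteria are distance-based
  stand-ins for a full synteny engine and gene-tree inference; their
  parameterisation is documented but not derived from the original
  tool.
* JC-corrected 4-fold distances under-correct deep divergences under
  transition-biased mutation; at the default tree depth this is a ~4%
  effect absorbed mostly by the outgroup branches.
* Fisher exact p-values are conservative on small 2x2 tables; the
  uniformity property holds at study-scale tables (~10,000 genes).
* The Louvain modularity optimum is only verified exhaustively on
  small graphs; on large graphs the usual local-optimum caveats
  apply.
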