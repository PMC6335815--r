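#!/usr/bin/env Rscript

## Step 1 -- generate the synthetic study data with known ground truth:
## gene families born along the repleta phylogeny, inparalogue
## duplications with synteny structure, positive-selection flags, a toy
## GO ontology with a planted enrichment, and two-species heat-shock
## count matrices with a planted shared/species-specific DE split.

source("analysis/00_config.R")
dir.create(DATA_DIR, recursive = TRUE, showWarnings = FALSE)

cfg <- study_config()
sim <- simulate_gene_families(cfg)

write_gene_positions(sim$genes, file.path(DATA_DIR, "gene_positions.tsv"))
aridEvol:::write_tsv(sim$selection,
                     file.path(DATA_DIR, "selection_flags.tsv"))
aridEvol:::write_tsv(sim$families, file.path(DATA_DIR, "families.tsv"))
write_newick(cfg$tree, file.path(DATA_DIR, "species_tree.nwk"))

edges <- similarity_from_truth(sim)
aridEvol:::write_tsv(edges, file.path(DATA_DIR, "similarity.tsv"))

gosim <- simulate_go_annotations(cfg$go, seed = cfg$seed)
writeLines(gosim$obo_text, file.path(DATA_DIR, "ontology.obo"))
aridEvol:::write_tsv(gosim$annotations,
                     file.path(DATA_DIR, "go_annotations.tsv"))
writeLines(gosim$truth$study_genes,
           file.path(DATA_DIR, "go_study_genes.txt"))

ex <- simulate_expression(cfg$expression, seed = cfg$seed)
write_counts(ex$Dhyd$counts, file.path(DATA_DIR, "counts_Dhyd.tsv"))
write_counts(ex$Dbuz$counts, file.path(DATA_DIR, "counts_Dbuz.tsv"))
aridEvol:::write_tsv(ex$truth, file.path(DATA_DIR, "expression_truth.tsv"))

cat(sprintf(
  "Simulated %d genes in %d families (%d inparalogues, %d births),\n",
  nrow(sim$genes), nrow(sim$families),
  sum(sim$genes$class == "inparalogue"),
  sum(sim$genes$class == "birth")))
cat(sprintf("%d similarity edges, %d GO terms, 2 x %d-gene count matrices.\n",
            nrow(edges), nrow(gosim$obo$terms), nrow(ex$Dhyd$counts)))
cat("Outputs under", DATA_DIR, "\n")
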