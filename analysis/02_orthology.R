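#!/usr/bin/env Rscript

## Step 2 -- classify every gene as orthologue, inparalogue or gene
## birth with the three-criterion rule, build orthogroups, and assign
## each orthogroup's origin branch on the species tree. Compares the
## classification with the simulation truth.

source("analysis/00_config.R")

genes <- aridEvol:::read_tsv(file.path(DATA_DIR, "gene_positions.tsv"))
edges <- aridEvol:::read_tsv(file.path(DATA_DIR, "similarity.tsv"))
tree <- read_newick(file.path(DATA_DIR, "species_tree.nwk"))

om <- classify_orthology(genes, edges, tree)
write_orthology(om, file.path(RESULTS, "orthology_map.tsv"))
saveRDS(om, file.path(RESULTS, "orthology_map.rds"))

## agreement with the generator's truth
truth <- simulate_gene_families(study_config())$genes
cls <- om$genes$category[match(truth$gene_id, om$genes$gene_id)]
conf <- table(truth = truth$class, called = cls)
print(conf)
inp <- truth$class == "inparalogue"
cat(sprintf("Inparalogue recovery: %.1f%%; birth recovery: %.1f%%\n",
            100 * mean(cls[inp] == "inparalogue"),
            100 * mean(cls[truth$class == "birth"] == "birth")))

ov <- pairwise_event_overlap(split(
  om$genes$orthogroup_id[om$genes$category == "inparalogue" &
                           !is.na(om$genes$orthogroup_id)],
  om$genes$species[om$genes$category == "inparalogue" &
                     !is.na(om$genes$orthogroup_id)]))
aridEvol:::write_tsv(as.data.frame(ov$jaccard),
                     file.path(RESULTS, "inparalogue_overlap_jaccard.tsv"))
cat("Jaccard overlap of inparalogue-generating orthogroups between",
    "terminal branches written.\n")
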