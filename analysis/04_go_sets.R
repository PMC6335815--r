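#!/usr/bin/env Rscript

## Step 4 -- build mutually exclusive GO-term sets and nested subsets
## by Louvain clustering with Lin semantic-similarity edge weights,
## test the planted study list for set-level enrichment, and compute
## subset representation metrics for the per-branch event gene lists.

source("analysis/00_config.R")

obo <- read_obo(file.path(DATA_DIR, "ontology.obo"))
ann <- aridEvol:::read_tsv(file.path(DATA_DIR, "go_annotations.tsv"))
study <- readLines(file.path(DATA_DIR, "go_study_genes.txt"))

gg <- go_graph(obo, ann)
part <- louvain_partition(gg, seed = STUDY_SEED,
                          namespace = "biological_process")
aridEvol:::write_tsv(part$membership, file.path(RESULTS, "go_partition.tsv"))
cat(sprintf("Louvain partition: %d sets, %d subsets over %d terms.\n",
            length(unique(part$membership$set)),
            length(unique(part$membership$subset)),
            nrow(part$membership)))

bg <- unique(ann$gene_id)
enr <- enrich_sets(study, bg, part, gg, level = "set")
aridEvol:::write_tsv(enr, file.path(RESULTS, "go_enrichment_sets.tsv"))
cat(sprintf("%d of %d sets enriched at q < 0.05; top set %s ('%s'), q = %.2g\n",
            sum(enr$significant), nrow(enr), enr$set[1], enr$label[1],
            enr$q[1]))

enr_sub <- enrich_sets(study, bg, part, gg, level = "subset")
aridEvol:::write_tsv(enr_sub,
                     file.path(RESULTS, "go_enrichment_subsets.tsv"))

## representation metrics of subsets in the study list
subs <- lapply(split(part$membership$term, part$membership$subset),
               function(tm) {
                 unique(unlist(gg$genes_of[tm], use.names = FALSE))
               })
rm_ <- representation_metrics(subs, list(study = study))
aridEvol:::write_tsv(rm_, file.path(RESULTS, "go_representation.tsv"))
cat(sprintf("%d subsets pass the >10-gene analysis filter; %d displayed.\n",
            sum(rm_$analysed), sum(rm_$display)))
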