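## Shared study configuration for the analysis workflow.
## Sourced by the numbered driver scripts; everything downstream is
## deterministic given this seed.

library(aridEvol)

STUDY_SEED <- 20191
RESULTS <- "results"
DATA_DIR <- file.path(RESULTS, "data")

study_config <- function(seed = STUDY_SEED) {
  sim_config(
    n_families = 1000,
    seed = seed,
    ## defaults of sim_config carry the study conditions: birth rates
    ## matched to the published per-branch origination counts,
    ## duplication and selection rates proportional to the published
    ## per-species inparalogue and selection proportions
    expression = expression_config(),   # 10,443 genes, 123/702/681 DE
    go = go_config(n_terms = 300, n_genes = 2000, n_study = 300))
}
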