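#' Run the synthetic end-to-end pipeline
#'
#' Executes the enabled stages in dependency order on synthetic data:
#' `simulate` (gene families, coordinates, selection flags),
#' `orthology` (three-criterion classification), `seqevol` (codon
#' alignments for a subsample of orthogroups, 4-fold silent distances,
#' non-negative least-squares branch lengths), `rates` (branch-event
#' table with expected counts and excesses, duplication-selection
#' association), `go` (toy ontology, Louvain sets, planted-enrichment
#' test) and `heat` (two-species count simulation, DE calls, pooled
#' fuzzy c-means, cluster report, shared-DE overlap statistic). Tables
#' are written under `outdir` together with a manifest (seed,
#' parameter fingerprint, per-file checksums). The run is
#' deterministic given the config seed.
#'
#' @param config a [sim_config()].
#' @param outdir output directory (created if needed).
#' @param stages character vector of stages to run.
#' @param seqevol_families number of orthogroups to simulate codon
#'   alignments for in the `seqevol` stage.
#' @param fcm_c cluster number used by the `heat` stage.
#' @return (invisibly) a list of in-memory stage results plus the
#'   manifest.
#' @export
run_pipeline <- function(config = sim_config(),
                         outdir = tempfile("aridevol_run_"),
                         stages = c("simulate", "orthology", "seqevol",
                                    "rates", "go", "heat"),
                         seqevol_families = 50, fcm_c = 8) {
  known <- c("simulate", "orthology", "seqevol", "rates", "go", "heat")
  bad <- setdiff(stages, known)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  deps <- list(orthology = "simulate", seqevol = "simulate",
               rates = c("simulate", "orthology"),
               heat = character(), go = character())
  for (st in stages) {
    need <- setdiff(deps[[st]] %||% character(), stages)
    if (length(need)) {
      stop(sprintf("stage '%s' requires stage(s): %s", st,
                   paste(need, collapse = ", ")))
    }
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  res <- list()
  files <- character()

  if ("simulate" %in% stages) {
    sim <- simulate_gene_families(config)
    res$sim <- sim
    f1 <- file.path(outdir, "gene_positions.tsv")
    write_gene_positions(sim$genes, f1)
    f2 <- file.path(outdir, "selection_flags.tsv")
    write_tsv(sim$selection, f2)
    f3 <- file.path(outdir, "species_tree.nwk")
    write_newick(config$tree, f3)
    files <- c(files, f1, f2, f3)
  }

  if ("orthology" %in% stages) {
    edges <- similarity_from_truth(res$sim)
    res$orthology <- classify_orthology(
      res$sim$genes[, c("gene_id", "species", "scaffold", "order_index")],
      edges, config$tree)
    f <- file.path(outdir, "orthology_map.tsv")
    write_orthology(res$orthology, f)
    files <- c(files, f)
  }

  if ("seqevol" %in% stages) {
    alns <- simulate_codon_sequences(res$sim,
                                     max_families = seqevol_families)
    full <- alns[vapply(alns, length, 0L) ==
                   length(config$tree$tip.label)]
    sm <- export_supermatrix(full)
    cols <- fourfold_degenerate_columns(sm$matrix)
    dmat <- jc_silent_distance(sm$matrix, cols)
    res$branch_lengths <- ls_branch_lengths(config$tree, dmat)
    f <- file.path(outdir, "silent_branch_lengths.tsv")
    write_tsv(data.frame(branch = names(res$branch_lengths),
                         silent_length = as.numeric(res$branch_lengths)),
              f)
    files <- c(files, f)
  }

  if ("rates" %in% stages) {
    lengths <- if (!is.null(res$branch_lengths)) res$branch_lengths else NULL
    tab <- tabulate_branch_events(res$orthology, res$sim$selection,
                                  config$tree, lengths = lengths)
    res$branch_events <- branch_event_excess(tab)
    f1 <- file.path(outdir, "branch_events.tsv")
    write_tsv(res$branch_events, f1)
    ## duplication-selection association over terminal branches
    sel <- res$sim$selection
    sel <- sel[!is.na(sel$species), ]
    og <- res$orthology$genes
    tmpl <- og$template_id[og$category == "inparalogue"]
    flags <- data.frame(species = sel$species,
                        has_inparalogue = sel$gene_id %in% tmpl,
                        is_selected = sel$selected == 1)
    res$association <- association_table(flags)
    f2 <- file.path(outdir, "association_table.tsv")
    write_tsv(res$association, f2)
    files <- c(files, f1, f2)
  }

  if ("go" %in% stages) {
    gosim <- simulate_go_annotations(config$go, seed = config$seed)
    gg <- go_graph(gosim$obo, gosim$annotations)
    part <- louvain_partition(gg, seed = config$seed)
    enr <- enrich_sets(gosim$truth$study_genes,
                       unique(gosim$annotations$gene_id), part, gg)
    res$go <- list(graph = gg, partition = part, enrichment = enr,
                   truth = gosim$truth)
    f1 <- file.path(outdir, "go_partition.tsv")
    write_tsv(part$membership, f1)
    f2 <- file.path(outdir, "go_enrichment.tsv")
    write_tsv(enr, f2)
    files <- c(files, f1, f2)
  }

  if ("heat" %in% stages) {
    ex <- simulate_expression(config$expression, seed = config$seed)
    sps <- setdiff(names(ex), "truth")
    prof <- list(); meta <- list(); de_res <- list()
    for (sp in sps) {
      cnt <- filter_low_expression(ex[[sp]]$counts)
      dr <- de_call(cnt)
      de_res[[sp]] <- dr
      de_genes <- names(dr$de)[dr$de]
      if (length(de_genes) >= 2) {
        pr <- standardize_profiles(dr$time_means[de_genes, , drop = FALSE])
        prof[[sp]] <- pr
        meta[[sp]] <- data.frame(gene_id = rownames(pr), species = sp,
                                 stringsAsFactors = FALSE)
      }
    }
    pooled <- do.call(rbind, prof)
    pmeta <- do.call(rbind, meta)
    fit <- fuzzy_cmeans(pooled, fcm_c, seed = config$seed)
    orths <- data.frame(gene_a = ex$truth$gene_id,
                        gene_b = ex$truth$gene_id)  # shared universe ids
    rep_out <- cluster_report(fit, pmeta, orths)
    deA <- names(de_res[[sps[1]]]$de)[de_res[[sps[1]]]$de]
    deB <- names(de_res[[sps[2]]]$de)[de_res[[sps[2]]]$de]
    universe <- union(rownames(de_res[[sps[1]]]$logcpm),
                      rownames(de_res[[sps[2]]]$logcpm))
    both <- length(intersect(deA, deB))
    res$overlap <- overlap_independence(
      both, length(deA) - both, length(deB) - both, length(universe))
    res$heat <- list(de = de_res, fcm = fit, report = rep_out,
                     truth = ex$truth)
    f1 <- file.path(outdir, "cluster_summary.tsv")
    write_tsv(rep_out$summary, f1)
    f2 <- file.path(outdir, "de_overlap.tsv")
    write_tsv(as.data.frame(res$overlap), f2)
    files <- c(files, f1, f2)
  }

  fingerprint <- paste0(config$seed, ":", config$n_families, ":",
                        paste(stages, collapse = "+"))
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  attr(manifest, "seed") <- config$seed
  attr(manifest, "fingerprint") <- fingerprint
  write_tsv(cbind(manifest, seed = config$seed),
            file.path(outdir, "manifest.tsv"))
  res$manifest <- manifest
  invisible(res)
}
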