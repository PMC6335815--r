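#' The eight canonical heat-response trajectory templates
#'
#' Standardised (mean 0, sd 1) expression shapes over the 8 time
#' points of the heat-shock design (pre-exposure control, mid- and
#' post-exposure, five recovery points). The shapes mirror the major
#' response patterns seen in heat-shock time courses: late
#' downregulation after initial upregulation (1), upregulation then
#' stable (2), upregulation with gradual return (3), bimodal
#' upregulation (4), upregulation with slow decline (5), ongoing
#' upregulation with mid-recovery downregulation (6), initial
#' downregulation with early recovery (7) and initial downregulation
#' with late recovery (8).
#'
#' @return 8 x 8 matrix (clusters x time points), rows standardised.
#' @export
expression_templates <- function() {
  raw <- rbind(
    c(0, 2, 2.2, 2.0, 1.8, 1.5, 0.5, -1.5),   # 1 up, late down
    c(0, 1.8, 2.2, 2.1, 2.0, 2.0, 1.9, 1.9),  # 2 up then stable
    c(0, 2.2, 2.0, 1.5, 1.0, 0.6, 0.3, 0.1),  # 3 up, gradual return
    c(0, 2.0, 1.2, 0.4, 0.2, 0.8, 1.8, 2.2),  # 4 bimodal up
    c(0, 1.5, 2.2, 2.0, 1.6, 1.2, 0.9, 0.7),  # 5 up, slow decline
    c(0, 1.0, 1.8, 2.4, 2.6, 1.2, 0.4, 0.6),  # 6 up, mid-recovery down
    c(0, -2.0, -2.2, -1.2, -0.3, 0.0, 0.1, 0.1), # 7 down, early recovery
    c(0, -1.6, -2.2, -2.1, -1.8, -1.2, -0.4, 0.4)) # 8 down, late recovery
  t(apply(raw, 1, function(x) (x - mean(x)) / sd(x)))
}

#' Expression-simulation settings
#'
#' Defaults mirror the study conditions of the two-species heat-shock
#' experiment: 10,443 1:1 orthologous genes, a planted differential
#' expression split of 123 shared / 702 species-A-only / 681
#' species-B-only genes, 8 trajectory clusters, negative-binomial
#' counts with dispersion 0.05 over 8 time points x 3 replicates.
#'
#' @param n_genes genes per species (1:1 orthologous universe).
#' @param de_shared,de_a_only,de_b_only planted DE gene counts.
#' @param templates cluster-template matrix (rows = clusters,
#'   standardised over the 8 time points).
#' @param cluster_weights relative probability of each cluster label
#'   for a DE gene.
#' @param amplitude log2 peak deviation applied to the standardised
#'   template (2 = up to 4-fold changes).
#' @param nb_dispersion negative-binomial dispersion (> 0).
#' @param baseline_meanlog,baseline_sdlog lognormal parameters of the
#'   per-gene baseline mean count.
#' @param libsize_range per-sample library scaling factor range.
#' @param n_reps replicates per time point.
#' @return list of class `expression_config`.
#' @export
expression_config <- function(n_genes = 10443, de_shared = 123,
                              de_a_only = 702, de_b_only = 681,
                              templates = expression_templates(),
                              cluster_weights = rep(1, 8),
                              amplitude = 2, nb_dispersion = 0.05,
                              baseline_meanlog = log(30),
                              baseline_sdlog = 1,
                              libsize_range = c(0.75, 1.25),
                              n_reps = 3) {
  if (nb_dispersion <= 0) stop("nb_dispersion must be > 0")
  if (de_shared + de_a_only + de_b_only > n_genes) {
    stop("DE gene counts exceed n_genes")
  }
  structure(list(n_genes = n_genes, de_shared = de_shared,
                 de_a_only = de_a_only, de_b_only = de_b_only,
                 templates = templates,
                 cluster_weights = cluster_weights,
                 amplitude = amplitude, nb_dispersion = nb_dispersion,
                 baseline_meanlog = baseline_meanlog,
                 baseline_sdlog = baseline_sdlog,
                 libsize_range = libsize_range, n_reps = n_reps),
            class = "expression_config")
}

#' Simulate two-species heat-shock count matrices with planted truth
#'
#' Generates negative-binomial counts for two species over
#' 8 time points x `n_reps` replicates on a shared 1:1 orthologous
#' gene universe. Non-DE genes are flat; DE genes follow their
#' assigned cluster template on the log2 scale
#' (`mu_t = baseline * 2^(amplitude * template_t)`). Shared DE genes
#' carry the same template in both species; species-specific DE genes
#' are flat in the other species. Library sizes vary within the
#' configured range.
#'
#' @param config an [expression_config()].
#' @param seed integer seed.
#' @param species labels of the two species.
#' @return list per species with `counts` (genes x 24 matrix, columns
#'   `T0_rep1` ... `T7_rep3`), plus `truth` (data.frame gene_id,
#'   de_label in none/shared/a_only/b_only, cluster_a, cluster_b).
#' @export
simulate_expression <- function(config = expression_config(), seed = 1L,
                                species = c("Dhyd", "Dbuz")) {
  stopifnot(inherits(config, "expression_config"))
  set.seed(seed)
  ng <- config$n_genes
  genes <- sprintf("og%05d", seq_len(ng))
  lab <- rep("none", ng)
  pick <- sample.int(ng, config$de_shared + config$de_a_only +
                       config$de_b_only)
  lab[pick[seq_len(config$de_shared)]] <- "shared"
  lab[pick[config$de_shared + seq_len(config$de_a_only)]] <- "a_only"
  lab[pick[config$de_shared + config$de_a_only +
             seq_len(config$de_b_only)]] <- "b_only"

  K <- nrow(config$templates)
  pw <- config$cluster_weights / sum(config$cluster_weights)
  clus <- sample.int(K, ng, replace = TRUE, prob = pw)
  cluster_a <- ifelse(lab %in% c("shared", "a_only"), clus, NA)
  cluster_b <- ifelse(lab %in% c("shared", "b_only"), clus, NA)

  baseline <- rlnorm(ng, config$baseline_meanlog, config$baseline_sdlog)
  tp <- 8; nr <- config$n_reps
  cols <- paste0("T", rep(0:(tp - 1), each = nr), "_rep",
                 rep(seq_len(nr), tp))

  sim_one <- function(cluster_vec) {
    lib <- runif(tp * nr, config$libsize_range[1], config$libsize_range[2])
    mu_t <- matrix(rep(baseline, tp), ng, tp)
    de <- !is.na(cluster_vec)
    if (any(de)) {
      shape <- config$templates[cluster_vec[de], , drop = FALSE]
      mu_t[de, ] <- baseline[de] * 2^(config$amplitude * shape)
    }
    mu <- mu_t[, rep(seq_len(tp), each = nr)] *
      matrix(lib, ng, tp * nr, byrow = TRUE)
    cnt <- matrix(rnbinom(length(mu), mu = mu,
                          size = 1 / config$nb_dispersion), ng)
    dimnames(cnt) <- list(genes, cols)
    cnt
  }
  counts_a <- sim_one(cluster_a)
  counts_b <- sim_one(cluster_b)
  truth <- data.frame(gene_id = genes, de_label = lab,
                      cluster_a = cluster_a, cluster_b = cluster_b,
                      stringsAsFactors = FALSE)
  out <- list(list(counts = counts_a), list(counts = counts_b))
  names(out) <- species
  out$truth <- truth
  out
}
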