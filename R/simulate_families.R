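#' Simulation configuration for the synthetic repleta-group data
#'
#' Collects every tunable of the synthetic-data generator with defaults
#' that mirror the study conditions of the real analysis: the fixed
#' 5-taxon repleta topology plus outgroup with silent-site branch
#' lengths, per-internal-branch orthogroup birth rates whose expected
#' event counts match the published per-branch origination counts
#' (265 / 394 / 194 / 22), terminal duplication rates proportional to
#' the published per-species inparalogue counts (scaled to the
#' generator's family count), and per-branch positive-selection
#' probabilities in the 2-5% range observed for the terminal branches.
#'
#' @param n_families number of gene families born at the root (present
#'   in all taxa barring loss).
#' @param tree species tree; default [repleta_tree()].
#' @param birth_rate named per-branch orthogroup birth rates (events per
#'   unit silent length). Branches not named get rate 0.
#' @param duplication_rate named per-terminal duplication rates (events
#'   per unit silent length).
#' @param singleton_rate per-terminal rate of de novo gene births
#'   (genes with no homology signal).
#' @param selection_prob named per-branch probability that a gene
#'   (lineage) is flagged positively selected on that branch.
#' @param selection_enrichment_dup multiplicative enrichment of the
#'   terminal selection probability for genes that generated
#'   inparalogues on that branch (the planted duplication-selection
#'   association; 1 = independence).
#' @param loss_prob per-species probability that a family member is
#'   lost after origination (0 = Dollo-clean presence patterns).
#' @param p_adjacent probability a new inparalogue inserts adjacent to
#'   its template (drives the synteny signal); else uniform placement.
#' @param dup_penalty extra silent divergence carried by a duplicate
#'   copy relative to its template (new copies evolve faster; this is
#'   what lets reciprocal-best similarity find the template).
#' @param rearrange_prob per-gene probability of relocation within its
#'   scaffold (degrades synteny).
#' @param n_scaffolds scaffolds per genome (ancestral order is split
#'   into this many contiguous blocks, conserved across species).
#' @param noise_sd standard deviation of Gaussian noise added to
#'   pairwise sequence distances when deriving similarity scores.
#' @param codon_length codons per simulated gene (>= 10).
#' @param omega named per-branch dN/dS for codon simulation (scalar is
#'   recycled to all branches).
#' @param kappa transition/transversion rate ratio of the mutation
#'   kernel.
#' @param expression expression-simulation settings; see
#'   [expression_config()].
#' @param go GO-simulation settings; see [go_config()].
#' @param seed integer seed; all generator randomness flows through it.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_families = 1000,
                       tree = repleta_tree(),
                       birth_rate = c(ancestral_repleta = 1060,
                                      cactus_use = 3940,
                                      cactus_specialisation = 3233,
                                      mulleri_complex = 440),
                       duplication_rate = c(Dald = 1120, Dmoj = 600,
                                            Dbuz = 970, Dhyd = 825,
                                            Drep = 545),
                       singleton_rate = 50,
                       selection_prob = c(Dald = 0.045, Dmoj = 0.031,
                                          Dbuz = 0.035, Dhyd = 0.048,
                                          Drep = 0.034,
                                          ancestral_repleta = 0.02,
                                          cactus_use = 0.02,
                                          cactus_specialisation = 0.02,
                                          mulleri_complex = 0.02),
                       selection_enrichment_dup = 1.8,
                       loss_prob = 0,
                       p_adjacent = 0.7,
                       dup_penalty = 0.05,
                       rearrange_prob = 0.02,
                       n_scaffolds = 5,
                       noise_sd = 0.01,
                       codon_length = 300,
                       omega = 0.1,
                       kappa = 2,
                       expression = expression_config(),
                       go = go_config(),
                       seed = 1L) {
  stopifnot(inherits(tree, "phylo"))
  if (any(tree$edge.length < 0)) stop("negative branch length in tree")
  if (sum(tree$edge.length) <= 0) stop("zero-length tree")
  if (codon_length < 10) stop("codon_length must be >= 10")
  if (any(birth_rate < 0) || any(duplication_rate < 0) ||
      singleton_rate < 0) stop("rates must be >= 0")
  if (any(selection_prob < 0 | selection_prob > 1)) {
    stop("selection_prob must be in [0, 1]")
  }
  if (loss_prob < 0 || loss_prob > 1) stop("loss_prob must be in [0, 1]")
  if (any(omega < 0)) stop("omega must be >= 0")
  cfg <- list(n_families = n_families, tree = ensure_node_labels(tree),
              birth_rate = birth_rate,
              duplication_rate = duplication_rate,
              singleton_rate = singleton_rate,
              selection_prob = selection_prob,
              selection_enrichment_dup = selection_enrichment_dup,
              loss_prob = loss_prob, p_adjacent = p_adjacent,
              dup_penalty = dup_penalty,
              rearrange_prob = rearrange_prob,
              n_scaffolds = n_scaffolds, noise_sd = noise_sd,
              codon_length = codon_length, omega = omega, kappa = kappa,
              expression = expression, go = go, seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate gene families on the species tree
#'
#' Gene families are born at the root (`n_families` of them) and along
#' each branch with a Poisson(`rate x silent length`) number of
#' origination events; a family born on branch *b* has one member in
#' every species descending from *b* (optionally thinned by
#' `loss_prob`). Terminal duplication events then create inparalogue
#' copies, placed adjacent to their template with probability
#' `p_adjacent` (else uniformly), and every gene receives
#' scaffold/order coordinates on a genome whose ancestral gene order is
#' conserved across species up to a per-gene relocation probability.
#' Positive-selection flags are drawn per branch, with the terminal
#' probability multiplied by `selection_enrichment_dup` for genes that
#' generated inparalogues (the planted duplication-selection
#' association).
#'
#' @param config a [sim_config()].
#' @return list with elements
#'   * `genes`: data.frame (gene_id, species, scaffold, order_index,
#'     family, class, origin_branch, template_id, age, extra)
#'   * `selection`: data.frame (gene_id, species, branch, selected)
#'     covering terminal branches at gene level and internal branches at
#'     family level (gene_id = family representative lineage),
#'   * `families`: data.frame (family, origin_branch, n_species),
#'   * `config`: the input config.
#' @export
simulate_gene_families <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  tree <- config$tree
  bt <- branch_table(tree)
  tips <- tree$tip.label

  ## --- family origination -------------------------------------------------
  fam_origin <- rep("root", config$n_families)
  for (i in seq_len(nrow(bt))) {
    b <- bt$branch[i]
    r <- if (b %in% names(config$birth_rate)) config$birth_rate[[b]] else 0
    if (r > 0) {
      k <- rpois(1, r * bt$length[i])
      fam_origin <- c(fam_origin, rep(b, k))
    }
  }
  nfam <- length(fam_origin)
  fam_id <- sprintf("OG%05d", seq_len(nfam))

  species_of_branch <- function(b) {
    if (b == "root") tips else unlist(bt$species[bt$branch == b])
  }
  fam_species <- lapply(fam_origin, species_of_branch)
  if (config$loss_prob > 0) {
    fam_species <- lapply(fam_species, function(s) {
      keep <- runif(length(s)) >= config$loss_prob
      s[keep]
    })
  }

  ## --- ancestral gene order and scaffolds ---------------------------------
  anc_rank <- sample.int(nfam)                 # ancestral order of families
  scaf_breaks <- ceiling(seq_len(nfam) / ceiling(nfam / config$n_scaffolds))
  scaf_of_rank <- sprintf("scaf%02d", scaf_breaks)

  genes_list <- vector("list", length(tips))
  names(genes_list) <- tips
  term_len <- setNames(bt$length[bt$terminal], bt$branch[bt$terminal])

  for (sp in tips) {
    present <- vapply(fam_species, function(s) sp %in% s, logical(1))
    fams <- which(present)
    if (!length(fams)) { genes_list[[sp]] <- NULL; next }
    rank <- anc_rank[fams]
    df <- data.frame(
      gene_id = sprintf("%s_g%05d", sp, seq_along(fams)),
      species = sp,
      scaffold = scaf_of_rank[rank],
      pos = as.numeric(rank),
      family = fam_id[fams],
      class = "orthologue",
      origin_branch = fam_origin[fams],
      template_id = NA_character_,
      age = 0, extra = 0,
      stringsAsFactors = FALSE)

    ## relocations (synteny noise)
    mv <- runif(nrow(df)) < config$rearrange_prob
    if (any(mv)) df$pos[mv] <- runif(sum(mv), 0, nfam + 1)

    ## terminal duplications -> inparalogues
    L <- term_len[[sp]]
    dr <- if (sp %in% names(config$duplication_rate)) {
      config$duplication_rate[[sp]]
    } else 0
    ndup <- if (dr > 0) rpois(1, dr * L) else 0
    if (ndup > 0) {
      tmpl_rows <- sample.int(nrow(df), ndup, replace = TRUE)
      ages <- runif(ndup, 0.005, L)
      dup <- df[tmpl_rows, ]
      dup$gene_id <- sprintf("%s_d%05d", sp, seq_len(ndup))
      dup$class <- "inparalogue"
      dup$template_id <- df$gene_id[tmpl_rows]
      dup$age <- ages
      dup$extra <- config$dup_penalty
      adj <- runif(ndup) < config$p_adjacent
      eps <- runif(ndup, 1e-4, 1e-2)
      dup$pos <- ifelse(adj, df$pos[tmpl_rows] + eps, runif(ndup, 0, nfam + 1))
      if (any(!adj)) {
        dup$scaffold[!adj] <- sample(unique(df$scaffold), sum(!adj),
                                     replace = TRUE)
      }
      df <- rbind(df, dup)
    }

    ## de novo gene births (no homology signal)
    nb <- if (config$singleton_rate > 0) {
      rpois(1, config$singleton_rate * L)
    } else 0
    if (nb > 0) {
      birth <- data.frame(
        gene_id = sprintf("%s_b%05d", sp, seq_len(nb)),
        species = sp,
        scaffold = sample(scaf_of_rank[anc_rank], nb, replace = TRUE),
        pos = runif(nb, 0, nfam + 1),
        family = NA_character_, class = "birth",
        origin_branch = sp, template_id = NA_character_,
        age = 0, extra = 0, stringsAsFactors = FALSE)
      df <- rbind(df, birth)
    }

    ## 0-based order index within scaffold
    df <- df[order(df$scaffold, df$pos), ]
    df$order_index <- stats::ave(df$pos, df$scaffold,
                                 FUN = function(p) rank(p) - 1L)
    genes_list[[sp]] <- df
  }
  genes <- do.call(rbind, genes_list)
  rownames(genes) <- NULL
  genes$pos <- NULL

  ## --- selection flags ----------------------------------------------------
  sel <- list()
  has_dup <- genes$gene_id %in% genes$template_id[genes$class == "inparalogue"]
  for (i in seq_len(nrow(bt))) {
    b <- bt$branch[i]
    p <- if (b %in% names(config$selection_prob)) {
      config$selection_prob[[b]]
    } else 0
    if (p == 0) next
    if (bt$terminal[i]) {
      rows <- which(genes$species == b & genes$class == "orthologue")
      if (!length(rows)) next
      pr <- ifelse(has_dup[rows],
                   pmin(1, p * config$selection_enrichment_dup), p)
      sel[[b]] <- data.frame(gene_id = genes$gene_id[rows],
                             species = b, branch = b,
                             selected = as.integer(runif(length(rows)) < pr),
                             stringsAsFactors = FALSE)
    } else {
      ## family-level flags on internal branches: families present on b
      under <- unlist(bt$species[i])
      fams <- unique(genes$family[genes$class == "orthologue" &
                                  genes$species %in% under])
      fams <- fams[!is.na(fams)]
      origin <- setNames(fam_origin, fam_id)[fams]
      ## a family is "on" branch b if it originated on b or rootward of b
      onb <- vapply(fams, function(f) {
        ob <- origin[[f]]
        ob == "root" || all(under %in% species_of_branch(ob))
      }, logical(1))
      fams <- fams[onb]
      if (!length(fams)) next
      sel[[b]] <- data.frame(gene_id = fams, species = NA_character_,
                             branch = b,
                             selected = as.integer(runif(length(fams)) < p),
                             stringsAsFactors = FALSE)
    }
  }
  selection <- if (length(sel)) do.call(rbind, sel) else
    data.frame(gene_id = character(), species = character(),
               branch = character(), selected = integer())
  rownames(selection) <- NULL

  families <- data.frame(family = fam_id, origin_branch = fam_origin,
                         n_species = lengths(fam_species),
                         stringsAsFactors = FALSE)
  list(genes = genes, selection = selection, families = families,
       config = config)
}

#' Pairwise similarity scores implied by the simulated truth
#'
#' For synthetic data the similarity score of a gene pair is minus its
#' expected silent sequence distance: cross-species pairs within a
#' family get the patristic tree distance plus any duplicate-copy
#' divergence penalties; a copy and its template are separated by the
#' copy's age plus the duplication penalty. Gaussian noise (`noise_sd`)
#' is added to every pair. Genes in different families (and de novo
#' births) share no edge.
#'
#' @param sim output of [simulate_gene_families()].
#' @return data.frame (gene_a, gene_b, score) with `score = -distance`;
#'   symmetric by convention (each pair listed once).
#' @export
similarity_from_truth <- function(sim) {
  cfg <- sim$config
  genes <- sim$genes
  set.seed(cfg$seed + 7919L)
  pd <- ape::cophenetic.phylo(cfg$tree)
  fams <- split(which(!is.na(genes$family)),
                genes$family[!is.na(genes$family)])
  out <- vector("list", length(fams))
  k <- 0L
  for (f in fams) {
    n <- length(f)
    if (n < 2) next
    idx <- t(utils::combn(n, 2))
    i <- f[idx[, 1]]; j <- f[idx[, 2]]
    spi <- genes$species[i]; spj <- genes$species[j]
    base <- pd[cbind(spi, spj)]
    d <- base + genes$extra[i] + genes$extra[j] +
      genes$age[i] + genes$age[j]
    ## copy vs its own template: distance is just the copy's divergence
    tpl_ij <- !is.na(genes$template_id[i]) & genes$template_id[i] == genes$gene_id[j]
    tpl_ji <- !is.na(genes$template_id[j]) & genes$template_id[j] == genes$gene_id[i]
    own <- tpl_ij | tpl_ji
    d[own] <- (genes$age[i] + genes$age[j] + genes$extra[i] +
               genes$extra[j])[own]
    d <- pmax(0, d + rnorm(length(d), 0, cfg$noise_sd))
    k <- k + 1L
    out[[k]] <- data.frame(gene_a = genes$gene_id[i],
                           gene_b = genes$gene_id[j],
                           score = -d, stringsAsFactors = FALSE)
  }
  if (k == 0L) {
    return(data.frame(gene_a = character(), gene_b = character(),
                      score = numeric()))
  }
  res <- do.call(rbind, out[seq_len(k)])
  rownames(res) <- NULL
  res
}

#' Orthology map implied directly by the simulated truth
#'
#' Bypasses the classifier: builds the [classify_orthology()]-shaped
#' orthology map straight from the generator's labels. Used for
#' parameter-recovery studies of the branch-rate machinery where the
#' classifier itself is not under test.
#'
#' @param sim output of [simulate_gene_families()].
#' @return an `orthology_map` (see [classify_orthology()]).
#' @export
orthology_from_truth <- function(sim) {
  genes <- sim$genes
  per_gene <- data.frame(
    gene_id = genes$gene_id, species = genes$species,
    category = ifelse(genes$class == "orthologue", "orthologue",
                      ifelse(genes$class == "inparalogue", "inparalogue",
                             "birth")),
    orthogroup_id = ifelse(genes$class == "birth", NA_character_,
                           genes$family),
    origin_branch = ifelse(genes$class == "birth", NA_character_,
                           genes$origin_branch),
    template_id = genes$template_id, stringsAsFactors = FALSE)
  ortho <- per_gene[per_gene$category == "orthologue", ]
  ogs <- split(ortho, ortho$orthogroup_id)
  orthogroups <- data.frame(
    orthogroup_id = names(ogs),
    origin_branch = vapply(ogs, function(g) g$origin_branch[1], ""),
    n_species = vapply(ogs, function(g) length(unique(g$species)), 0L),
    stringsAsFactors = FALSE)
  orthogroups$species <- I(lapply(ogs, function(g) unique(g$species)))
  orthogroups$members <- I(lapply(ogs, function(g) g$gene_id))
  rownames(orthogroups) <- NULL
  structure(list(genes = per_gene, orthogroups = orthogroups),
            class = "orthology_map")
}
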