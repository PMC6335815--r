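## Codon machinery shared by the simulator and the Ka/Ks code.
## Nucleotides are coded 1:4 = A, C, G, T; codons are indexed
## 16*(b1-1) + 4*(b2-1) + b3 in 1:64.

.NUC <- c("A", "C", "G", "T")

#' @keywords internal
codon_aa_table <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      gc <- Biostrings::GENETIC_CODE
      codons <- as.vector(outer(outer(.NUC, .NUC, paste0), .NUC, paste0))
      ## outer() fills b1 fastest; rebuild in b1-major order explicitly
      idx <- expand.grid(b3 = 1:4, b2 = 1:4, b1 = 1:4)
      codons <- paste0(.NUC[idx$b1], .NUC[idx$b2], .NUC[idx$b3])
      ord <- 16 * (idx$b1 - 1) + 4 * (idx$b2 - 1) + idx$b3
      aa <- character(64)
      aa[ord] <- unname(gc[codons])
      tab <<- aa
    }
    tab
  }
})

#' @keywords internal
codon_idx <- function(b1, b2, b3) 16L * (b1 - 1L) + 4L * (b2 - 1L) + b3

## transition partners: A<->G, C<->T
.TRANSITION <- c(3L, 4L, 1L, 2L)
.TRANSVERSIONS <- list(c(2L, 4L), c(1L, 3L), c(2L, 4L), c(1L, 3L))

#' Evolve a coding sequence along one branch
#'
#' Per-site multinomial replacement model: proposals arrive at rate `d`
#' per nucleotide site (Poisson), a proposal is a transition with
#' probability `kappa / (kappa + 2)` and otherwise one of the two
#' transversions; synonymous proposals are always accepted,
#' nonsynonymous ones with probability `omega`, and proposals creating
#' a stop codon are rejected. At a 4-fold degenerate third position all
#' proposals are accepted, so `d` is the expected number of silent
#' substitutions per 4-fold site.
#'
#' @param seq integer vector (1:4 codes) of length divisible by 3.
#' @param d branch silent length (>= 0).
#' @param omega dN/dS acceptance probability for nonsynonymous
#'   proposals.
#' @param kappa transition/transversion rate ratio.
#' @return evolved integer sequence.
#' @keywords internal
evolve_codon_seq <- function(seq, d, omega, kappa = 2) {
  if (d <= 0) return(seq)
  aa <- codon_aa_table()
  n <- length(seq)
  k <- rpois(1L, d * n)
  if (k == 0L) return(seq)
  sites <- sample.int(n, k, replace = TRUE)
  p_ts <- kappa / (kappa + 2)
  is_ts <- runif(k) < p_ts
  tv_pick <- sample.int(2L, k, replace = TRUE)
  u_acc <- runif(k)
  for (e in seq_len(k)) {
    s <- sites[e]
    old <- seq[s]
    new <- if (is_ts[e]) .TRANSITION[old] else .TRANSVERSIONS[[old]][tv_pick[e]]
    cp <- (s - 1L) %/% 3L
    o1 <- 3L * cp
    b <- seq[(o1 + 1L):(o1 + 3L)]
    pos <- s - o1
    bn <- b; bn[pos] <- new
    aan <- aa[codon_idx(bn[1L], bn[2L], bn[3L])]
    if (aan == "*") next
    aao <- aa[codon_idx(b[1L], b[2L], b[3L])]
    if (aan == aao || u_acc[e] < omega) seq[s] <- new
  }
  seq
}

#' @keywords internal
random_root_seq <- function(codon_length) {
  aa <- codon_aa_table()
  sense <- which(aa != "*")
  cods <- sample(sense, codon_length, replace = TRUE)
  b1 <- (cods - 1L) %/% 16L + 1L
  b2 <- ((cods - 1L) %/% 4L) %% 4L + 1L
  b3 <- (cods - 1L) %% 4L + 1L
  as.integer(rbind(b1, b2, b3))
}

#' Simulate codon alignments for the simulated orthogroups
#'
#' For each gene family an ancestral sequence of `codon_length` sense
#' codons is drawn at the family's origin node and evolved down the
#' species tree with [evolve_codon_seq()], so synonymous divergence
#' between two tips tracks the silent path length separating them and
#' nonsynonymous divergence is scaled by the per-branch `omega`.
#' Alignments are gap-free with no internal stop codons.
#'
#' @param sim output of [simulate_gene_families()].
#' @param families optional character vector of family ids to simulate
#'   (default: all families spanning >= 2 species).
#' @param max_families optional cap on the number of families (first
#'   `max_families` after sorting by id).
#' @return named list: family id -> named character vector
#'   (species -> codon sequence).
#' @export
simulate_codon_sequences <- function(sim, families = NULL,
                                     max_families = NULL) {
  cfg <- sim$config
  if (cfg$codon_length < 10) stop("codon_length must be >= 10")
  set.seed(cfg$seed + 104729L)
  tree <- reorder(cfg$tree, "cladewise")   # parents precede children
  bt <- branch_table(tree)
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  omega <- cfg$omega
  if (is.null(names(omega))) {
    omega <- setNames(rep(omega[1], nrow(bt)), bt$branch)
  }

  fam <- sim$families
  if (is.null(families)) families <- fam$family[fam$n_species >= 2]
  families <- sort(families)
  if (!is.null(max_families)) families <- head(families, max_families)

  memb <- split(sim$genes$species[sim$genes$class == "orthologue"],
                sim$genes$family[sim$genes$class == "orthologue"])
  origin <- setNames(fam$origin_branch, fam$family)

  ## origin branch id -> tree node carrying the ancestral sequence
  node_of_branch <- c(setNames(tree$edge[, 2], bt$branch), root = root)

  out <- vector("list", length(families))
  names(out) <- families
  for (f in families) {
    anc_node <- node_of_branch[[origin[[f]]]]
    seqs <- vector("list", ntip + tree$Nnode)
    seqs[[anc_node]] <- random_root_seq(cfg$codon_length)
    for (i in seq_len(nrow(tree$edge))) {
      par <- tree$edge[i, 1]; chl <- tree$edge[i, 2]
      if (is.null(seqs[[par]])) next
      om <- omega[[bt$branch[i]]]
      seqs[[chl]] <- evolve_codon_seq(seqs[[par]], tree$edge.length[i],
                                      om, cfg$kappa)
    }
    sp <- memb[[f]]
    tip_idx <- match(sp, tree$tip.label)
    aln <- vapply(tip_idx, function(ti) paste(.NUC[seqs[[ti]]],
                                              collapse = ""), "")
    names(aln) <- sp
    out[[f]] <- aln
  }
  out
}
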