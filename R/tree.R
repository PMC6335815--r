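#' The default repleta-group species tree
#'
#' Returns the fixed rooted 7-taxon topology used throughout the
#' pipeline: five *repleta* group species plus two outgroup reference
#' species (a *D. virilis*-like near outgroup in the same subgenus and
#' a *D. melanogaster*-like far outgroup), with named internal
#' branches and silent-site branch lengths (substitutions per 4-fold
#' degenerate site).
#'
#' Internal branch names follow the biological events on them:
#' `ancestral_repleta` (stem of the five repleta species),
#' `cactus_use` (stem of the four cactus-using species after
#' *D. repleta* split off), `cactus_specialisation` (stem of the three
#' cactus specialists after *D. hydei* split off) and `mulleri_complex`
#' (stem of *D. aldrichi* + *D. mojavensis*). The second outgroup
#' makes the `ancestral_repleta` stem identifiable from pairwise
#' distances (with a single outgroup it would be confounded with the
#' outgroup's own branch; see [ls_branch_lengths()]).
#'
#' @param lengths optional named numeric vector of silent branch lengths
#'   (names are branch ids, i.e. tip labels and internal node labels);
#'   defaults are the generator's study conditions.
#' @return an [ape::phylo] object with node labels on internal nodes.
#' @export
repleta_tree <- function(lengths = NULL) {
  nwk <- paste0(
    "(Dmel:0.90,(Dvir:0.50,(Drep:0.22,(Dhyd:0.20,(Dbuz:0.14,",
    "(Dald:0.12,Dmoj:0.10)mulleri_complex:0.05)",
    "cactus_specialisation:0.06)cactus_use:0.10)",
    "ancestral_repleta:0.25)drosophila_subgenus:0.15)root;")
  tr <- ape::read.tree(text = nwk)
  if (!is.null(lengths)) {
    bt <- branch_table(tr)
    miss <- setdiff(names(lengths), bt$branch)
    if (length(miss)) stop("unknown branch id(s): ", paste(miss, collapse = ", "))
    for (b in names(lengths)) {
      tr$edge.length[bt$edge_row[bt$branch == b]] <- lengths[[b]]
    }
  }
  tr
}

#' Branch table of a rooted, node-labelled tree
#'
#' Each branch is identified by the node it subtends: the tip label for
#' terminal branches, the internal node label for internal branches.
#' Unnamed internal nodes are auto-named `node<preorder index>` with a
#' warning.
#'
#' @param tree an [ape::phylo] object.
#' @return data.frame with columns `branch`, `length`, `terminal`
#'   (logical), `edge_row` (row of `tree$edge`), `species` (list column:
#'   tip labels descending from the branch).
#' @export
branch_table <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  tree <- ensure_node_labels(tree)
  ntip <- length(tree$tip.label)
  child <- tree$edge[, 2]
  lab <- character(length(child))
  term <- child <= ntip
  lab[term] <- tree$tip.label[child[term]]
  lab[!term] <- tree$node.label[child[!term] - ntip]
  desc <- lapply(child, function(nd) {
    if (nd <= ntip) tree$tip.label[nd]
    else ape::extract.clade(tree, nd)$tip.label
  })
  data.frame(branch = lab, length = tree$edge.length,
             terminal = child <= ntip,
             edge_row = seq_along(child),
             species = I(desc), stringsAsFactors = FALSE)
}

#' @keywords internal
ensure_node_labels <- function(tree) {
  nn <- tree$Nnode
  if (is.null(tree$node.label)) tree$node.label <- rep("", nn)
  empty <- is.na(tree$node.label) | tree$node.label == ""
  if (any(empty)) {
    warning("unnamed internal node(s) auto-named by preorder index")
    tree$node.label[empty] <- paste0("node", which(empty))
  }
  tree
}

#' Origin branch of a set of species (smallest-clade stem)
#'
#' Single-origin (Dollo) rule: the branch on which a gene family arose
#' is the stem branch of the smallest clade containing every member
#' species. A family spanning taxa on both sides of the root maps to
#' the root stem, reported as `"root"`.
#'
#' @param species character vector of member tip labels (>= 1).
#' @param tree species tree ([ape::phylo], node-labelled).
#' @return branch id (character scalar).
#' @export
mrca_branch <- function(species, tree) {
  tree <- ensure_node_labels(tree)
  species <- unique(species)
  bad <- setdiff(species, tree$tip.label)
  if (length(bad)) stop("species not in tree: ", paste(bad, collapse = ", "))
  ntip <- length(tree$tip.label)
  if (length(species) == 1L) return(species)
  nd <- ape::getMRCA(tree, species)
  if (nd == ntip + 1L) return("root")
  tree$node.label[nd - ntip]
}

#' Patristic (path) distance between two tips, in silent length
#' @keywords internal
tip_distance <- function(tree, a, b) {
  d <- ape::cophenetic.phylo(tree)
  d[a, b]
}

#' Write a tree to newick, keeping internal node labels
#' @param tree phylo object
#' @param path file path
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read a newick tree, auto-naming unnamed internal nodes
#' @param path file path
#' @return phylo with complete node labels
#' @export
read_newick <- function(path) {
  ensure_node_labels(ape::read.tree(path))
}
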