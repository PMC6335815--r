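#' GO-simulation settings
#'
#' @param n_terms number of terms (>= 1) excluding the root.
#' @param max_depth maximum depth of the DAG below the root.
#' @param n_genes size of the annotated gene universe.
#' @param terms_per_gene integer range (min, max) of direct leaf
#'   annotations per gene.
#' @param planted_block_size number of leaf terms in the planted
#'   enriched block (a subtree).
#' @param planted_enrichment odds multiplier with which study-list
#'   genes draw their annotations from the planted block.
#' @param n_study size of the study gene list carrying the planted
#'   enrichment.
#' @return list of class `go_config`.
#' @export
go_config <- function(n_terms = 150, max_depth = 5, n_genes = 1000,
                      terms_per_gene = c(1, 3),
                      planted_block_size = 8,
                      planted_enrichment = 5, n_study = 200) {
  stopifnot(n_terms >= 1, max_depth >= 1, n_genes >= 1)
  structure(list(n_terms = n_terms, max_depth = max_depth,
                 n_genes = n_genes, terms_per_gene = terms_per_gene,
                 planted_block_size = planted_block_size,
                 planted_enrichment = planted_enrichment,
                 n_study = n_study), class = "go_config")
}

#' Simulate a toy GO DAG with planted enrichment
#'
#' Builds a rooted is_a DAG (`n_terms` terms arranged in levels up to
#' `max_depth`, each term with 1-2 parents on the level above),
#' annotates genes to leaf terms, and plants an enrichment: genes of a
#' designated study list draw their annotations from one leaf block
#' (a subtree) with `planted_enrichment`-fold odds relative to the
#' background. Ground truth (block terms, study genes) is returned for
#' recovery tests.
#'
#' @param config a [go_config()].
#' @param seed integer seed.
#' @return list with `obo` (list terms/edges, as [read_obo()]),
#'   `obo_text` (character vector of OBO v1.2 lines), `annotations`
#'   (data.frame gene_id, term), and `truth` (list: block_terms,
#'   block_root, study_genes).
#' @export
simulate_go_annotations <- function(config = go_config(), seed = 1L) {
  stopifnot(inherits(config, "go_config"))
  set.seed(seed)
  nt <- config$n_terms
  ids <- c("GO:0000000", sprintf("GO:%07d", seq_len(nt)))
  depth <- integer(nt + 1)                 # root at depth 0
  parents <- vector("list", nt + 1)
  ## assign depths: roughly geometric growth down to max_depth
  lev <- pmin(config$max_depth,
              1 + findInterval(seq_len(nt) / nt,
                               seq_len(config$max_depth) /
                                 config$max_depth,
                               left.open = TRUE))
  depth[-1] <- sort(lev)
  for (i in seq_len(nt) + 1) {
    cand <- which(depth == depth[i] - 1)
    np <- if (length(cand) > 1) sample(1:2, 1) else 1
    parents[[i]] <- ids[sample(cand, min(np, length(cand)))]
  }
  edges <- do.call(rbind, lapply(seq_len(nt) + 1, function(i) {
    data.frame(child = ids[i], parent = parents[[i]],
               stringsAsFactors = FALSE)
  }))
  terms <- data.frame(id = ids,
                      name = c("biological_process root",
                               sprintf("process term %d", seq_len(nt))),
                      namespace = "biological_process",
                      stringsAsFactors = FALSE)

  ## leaves = terms that are nobody's parent
  leaves <- setdiff(ids, edges$parent)
  if (!length(leaves)) leaves <- ids[-1]

  ## planted block: the leaf descendants of one internal term (a
  ## coherent subtree, so the block stays together under clustering)
  ch <- split(edges$child, edges$parent)
  leaf_desc <- function(tm) {
    seen <- character(); queue <- tm
    while (length(queue)) {
      x <- queue[1]; queue <- queue[-1]
      kids <- ch[[x]]
      if (is.null(kids)) seen <- c(seen, x) else queue <- c(queue, kids)
    }
    unique(seen)
  }
  internals <- setdiff(intersect(ids, edges$parent), ids[1])
  sizes <- vapply(internals, function(tm) length(leaf_desc(tm)), 0L)
  ok <- internals[sizes >= 2]
  if (length(ok)) {
    pickt <- ok[which.min(abs(sizes[match(ok, internals)] -
                                config$planted_block_size))]
    block <- sort(leaf_desc(pickt))
  } else {
    block <- sort(sample(leaves, min(config$planted_block_size,
                                     length(leaves))))
  }
  bsize <- length(block)

  genes <- sprintf("gene%05d", seq_len(config$n_genes))
  study <- sort(sample(genes, min(config$n_study, config$n_genes)))
  frac_block <- bsize / length(leaves)
  w_study <- min(0.9, config$planted_enrichment * frac_block)

  ann <- list()
  tl <- config$terms_per_gene
  for (g in genes) {
    k <- sample(tl[1]:tl[2], 1)
    if (g %in% study) {
      from_block <- runif(k) < w_study
      tm <- character(k)
      tm[from_block] <- sample(block, sum(from_block), replace = TRUE)
      tm[!from_block] <- sample(leaves, sum(!from_block), replace = TRUE)
    } else {
      tm <- sample(leaves, k, replace = TRUE)
    }
    ann[[g]] <- unique(tm)
  }
  annotations <- data.frame(
    gene_id = rep(genes, lengths(ann)),
    term = unlist(ann, use.names = FALSE), stringsAsFactors = FALSE)

  obo <- list(terms = terms, edges = edges)
  list(obo = obo, obo_text = obo_lines(obo), annotations = annotations,
       truth = list(block_terms = block, study_genes = study))
}

#' Serialise an ontology to OBO v1.2 text
#' @param obo list with `terms` and `edges` (as from [read_obo()]).
#' @return character vector of lines.
#' @export
obo_lines <- function(obo) {
  hdr <- c("format-version: 1.2", "")
  pl <- split(obo$edges$parent, obo$edges$child)
  body <- unlist(lapply(seq_len(nrow(obo$terms)), function(i) {
    t <- obo$terms[i, ]
    p <- pl[[t$id]]
    isa <- if (length(p)) paste0("is_a: ", p) else character()
    c("[Term]", paste0("id: ", t$id), paste0("name: ", t$name),
      paste0("namespace: ", t$namespace), isa, "")
  }))
  c(hdr, body)
}
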