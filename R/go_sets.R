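#' Read an OBO v1.2 ontology (is_a edges only)
#'
#' Minimal reader for the `[Term]` stanzas of an OBO v1.2 file:
#' `id`, `name`, `namespace` and `is_a` lines (trailing `! comments`
#' stripped). Obsolete terms are skipped. The is_a graph must be
#' acyclic.
#'
#' @param path path to an OBO file.
#' @return list with `terms` (data.frame id, name, namespace) and
#'   `edges` (data.frame child, parent).
#' @export
read_obo <- function(path) {
  lines <- readLines(path)
  cur <- NULL; in_term <- FALSE; lineno <- 0
  flush <- function(cur) {
    if (is.null(cur$id)) stop("OBO term stanza without id near line ", lineno)
    cur
  }
  terms <- list(); edges <- list()
  for (ln in lines) {
    lineno <- lineno + 1
    ln <- sub("\\s*!.*$", "", trimws(ln))
    if (ln == "[Term]") {
      if (in_term && !is.null(cur) && !isTRUE(cur$obsolete)) {
        terms[[length(terms) + 1]] <- flush(cur)
      }
      cur <- list(is_a = character()); in_term <- TRUE
      next
    }
    if (grepl("^\\[", ln)) {           # other stanza type
      if (in_term && !is.null(cur) && !isTRUE(cur$obsolete)) {
        terms[[length(terms) + 1]] <- flush(cur)
      }
      in_term <- FALSE; cur <- NULL; next
    }
    if (!in_term || ln == "") next
    kv <- regmatches(ln, regexec("^([a-z_]+):\\s*(.*)$", ln))[[1]]
    if (length(kv) != 3) stop(sprintf("malformed OBO line %d: '%s'",
                                      lineno, ln))
    key <- kv[2]; val <- kv[3]
    if (key == "id") cur$id <- val
    else if (key == "name") cur$name <- val
    else if (key == "namespace") cur$namespace <- val
    else if (key == "is_a") cur$is_a <- c(cur$is_a, sub("\\s.*$", "", val))
    else if (key == "is_obsolete" && val == "true") cur$obsolete <- TRUE
  }
  if (in_term && !is.null(cur) && !isTRUE(cur$obsolete)) {
    terms[[length(terms) + 1]] <- flush(cur)
  }
  tdf <- data.frame(
    id = vapply(terms, function(t) t$id, ""),
    name = vapply(terms, function(t) t$name %||% t$id, ""),
    namespace = vapply(terms, function(t) t$namespace %||% "", ""),
    stringsAsFactors = FALSE)
  ed <- do.call(rbind, lapply(terms, function(t) {
    if (!length(t$is_a)) return(NULL)
    data.frame(child = t$id, parent = t$is_a, stringsAsFactors = FALSE)
  }))
  if (is.null(ed)) ed <- data.frame(child = character(),
                                    parent = character())
  if (nrow(ed)) {
    g <- igraph::graph_from_data_frame(ed, directed = TRUE)
    if (!igraph::is_dag(g)) stop("OBO is_a graph contains a cycle")
  }
  list(terms = tdf, edges = ed)
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build a GO graph with ancestor-closed annotations
#'
#' Combines an ontology (terms + is_a edges) with gene-to-term
#' annotations, propagating every annotation to all ancestors so that
#' a gene annotated to a term counts for the whole path to the root,
#' and computes per-term annotated-gene sets and information content.
#'
#' @param obo output of [read_obo()] (or a list with `terms`/`edges`).
#' @param annotations data.frame (gene_id, term).
#' @param ic_pseudo pseudo-count (genes) used for the information
#'   content of terms with zero annotations.
#' @return object of class `go_graph`.
#' @export
go_graph <- function(obo, annotations, ic_pseudo = 0.5) {
  terms <- obo$terms
  edges <- obo$edges
  bad <- setdiff(annotations$term, terms$id)
  if (length(bad)) stop("annotation to unknown term: ",
                        paste(head(bad, 3), collapse = ", "))
  parents <- split(edges$parent, edges$child)
  children <- split(edges$child, edges$parent)
  ## reverse-topological order (children before parents)
  if (nrow(edges)) {
    g <- igraph::graph_from_data_frame(edges, directed = TRUE,
                                       vertices = terms$id)
    ord <- names(igraph::topo_sort(g, mode = "out"))
  } else ord <- terms$id
  direct <- lapply(split(annotations$gene_id, annotations$term), unique)
  closed <- direct[terms$id]
  names(closed) <- terms$id
  closed[vapply(closed, is.null, TRUE)] <- list(character())
  for (tm in ord) {
    for (ch in children[[tm]] %||% character()) {
      closed[[tm]] <- union(closed[[tm]], closed[[ch]])
    }
  }
  n_total <- length(unique(annotations$gene_id))
  n_ann <- vapply(closed, length, 0L)
  ic <- ifelse(n_ann > 0, -log(n_ann / n_total),
               -log(ic_pseudo / n_total))
  structure(list(terms = terms, edges = edges, parents = parents,
                 children = children, genes_of = closed,
                 n_ann = setNames(n_ann, terms$id),
                 ic = setNames(ic, terms$id), n_genes = n_total),
            class = "go_graph")
}

#' Information content of a term
#'
#' `IC = -log(n_annotated(term or descendants) / n_annotated(root))`,
#' with a configured pseudo-count for unannotated terms (set when the
#' graph is built).
#'
#' @param graph a [go_graph()].
#' @param term term id.
#' @return non-negative IC.
#' @export
information_content <- function(graph, term) {
  if (!term %in% graph$terms$id) stop("unknown term: ", term)
  unname(graph$ic[[term]])
}

#' Lin semantic-similarity weights on is_a edges
#'
#' For a parent-child is_a pair the parent is the most informative
#' common ancestor, so the Lin similarity reduces to
#' `2 IC(parent) / (IC(parent) + IC(child))`, bounded in `[0, 1]`;
#' edges from a zero-IC parent (the root) get weight 0.
#'
#' @param graph a [go_graph()].
#' @return data.frame (child, parent, weight).
#' @export
edge_weights <- function(graph) {
  ed <- graph$edges
  icp <- graph$ic[ed$parent]
  icc <- graph$ic[ed$child]
  w <- ifelse(icp <= 0, 0, 2 * icp / (icp + icc))
  data.frame(child = ed$child, parent = ed$parent, weight = unname(w),
             stringsAsFactors = FALSE)
}

#' Louvain partition of the GO graph into sets and nested subsets
#'
#' Runs weighted Louvain community detection on the undirected is_a
#' graph with semantic-similarity edge weights, producing mutually
#' exclusive, jointly exhaustive term sets; Louvain is then re-applied
#' inside each set's induced subgraph to produce nested subsets.
#' Deterministic for a fixed seed.
#'
#' @param graph a [go_graph()].
#' @param weights optional data.frame (child, parent, weight); default
#'   [edge_weights()].
#' @param resolution Louvain resolution parameter.
#' @param seed integer seed.
#' @param namespace optional namespace filter (e.g.
#'   `"biological_process"`); only terms of that namespace are
#'   clustered.
#' @return object of class `go_partition`: data.frame `membership`
#'   (term, set, subset) plus `set_label`/`subset_label` named vectors
#'   (dominant-term names, see [label_partition()]).
#' @export
louvain_partition <- function(graph, weights = NULL, resolution = 1,
                              seed = 1L, namespace = NULL) {
  terms <- graph$terms
  if (!is.null(namespace)) terms <- terms[terms$namespace == namespace, ]
  if (!nrow(terms)) stop("empty graph after namespace filter")
  w <- weights %||% edge_weights(graph)
  w <- w[w$child %in% terms$id & w$parent %in% terms$id, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    w[, c("child", "parent")], directed = FALSE,
    vertices = data.frame(name = sort(terms$id)))
  igraph::E(g)$weight <- w$weight + 1e-9    # strictly positive weights
  set.seed(seed)
  cl <- igraph::cluster_louvain(g, resolution = resolution)
  memb <- igraph::membership(cl)
  ## relabel sets deterministically by smallest member term id
  sets <- split(names(memb), as.integer(memb))
  sets <- sets[order(vapply(sets, min, ""))]
  set_id <- sprintf("S%02d", seq_along(sets))
  df <- do.call(rbind, lapply(seq_along(sets), function(k) {
    data.frame(term = sets[[k]], set = set_id[k],
               stringsAsFactors = FALSE)
  }))
  ## subsets: Louvain within each set
  df$subset <- NA_character_
  for (k in seq_along(sets)) {
    m <- sets[[k]]
    if (length(m) == 1L) {
      df$subset[df$set == set_id[k]] <- paste0(set_id[k], ".1")
      next
    }
    sg <- igraph::induced_subgraph(g, m)
    set.seed(seed + k)
    scl <- igraph::cluster_louvain(sg, resolution = resolution)
    sm <- igraph::membership(scl)
    subs <- split(names(sm), as.integer(sm))
    subs <- subs[order(vapply(subs, min, ""))]
    for (j in seq_along(subs)) {
      df$subset[df$term %in% subs[[j]]] <- sprintf("%s.%d", set_id[k], j)
    }
  }
  rownames(df) <- NULL
  part <- structure(list(membership = df), class = "go_partition")
  label_partition(part, graph)
}

#' Label partition sets and subsets by their dominant term
#'
#' The label of a set (or subset) is the name of its member term with
#' the greatest (ancestor-closed) annotation count; ties break to the
#' lexicographically smallest term id.
#'
#' @param partition a `go_partition`.
#' @param graph the [go_graph()] the partition was built from.
#' @return the partition with `set_label` and `subset_label` filled.
#' @export
label_partition <- function(partition, graph) {
  df <- partition$membership
  if (!nrow(df)) stop("empty partition")
  nm <- setNames(graph$terms$name, graph$terms$id)
  dominant <- function(terms) {
    cnt <- graph$n_ann[terms]
    cand <- terms[cnt == max(cnt)]
    unname(nm[min(cand)])
  }
  partition$set_label <- vapply(split(df$term, df$set), dominant, "")
  partition$subset_label <- vapply(split(df$term, df$subset), dominant, "")
  partition
}

#' Set-level hypergeometric enrichment
#'
#' A gene counts towards a set if any of its (ancestor-closed) terms
#' belongs to the set. Per set: hypergeometric upper-tail p for the
#' study-list count, Benjamini-Hochberg q across sets, significance at
#' q < 0.05.
#'
#' @param study character vector of study gene ids (subset of
#'   `background`).
#' @param background character vector of background gene ids.
#' @param partition a `go_partition`.
#' @param graph the [go_graph()].
#' @param level `"set"` or `"subset"`.
#' @return data.frame (set, label, k, n, K, N, p, q, significant)
#'   sorted by p.
#' @export
enrich_sets <- function(study, background, partition, graph,
                        level = c("set", "subset")) {
  level <- match.arg(level)
  if (!length(study)) stop("empty study gene list")
  if (!all(study %in% background)) stop("study genes must be a subset of background")
  df <- partition$membership
  key <- df[[level]]
  labels <- if (level == "set") partition$set_label else partition$subset_label
  study <- unique(study); background <- unique(background)
  N <- length(background); n <- length(study)
  out <- lapply(split(df$term, key), function(terms) {
    genes <- unique(unlist(graph$genes_of[terms], use.names = FALSE))
    K <- sum(background %in% genes)
    k <- sum(study %in% genes)
    p <- if (K == 0) 1 else phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(k = k, n = n, K = K, N = N, p = p)
  })
  res <- do.call(rbind, out)
  res <- data.frame(set = names(out), label = unname(labels[names(out)]),
                    res, stringsAsFactors = FALSE)
  res$q <- p.adjust(res$p, method = "BH")
  res$significant <- res$q < 0.05
  res <- res[order(res$p, res$set), ]
  rownames(res) <- NULL
  res
}

#' Subset representation metrics for event gene lists
#'
#' For each GO subset and each analysis (event gene list): the
#' absolute number of subset genes involved in the events and the
#' percentage of the subset they represent. Only subsets with more
#' than `min_size` genes are analysed; a subset is display-flagged
#' when, in any analysis, more than `display_n` genes or more than
#' `display_pct` percent are involved.
#'
#' @param subset_genes named list: subset id -> character vector of
#'   member genes (against the species' full gene set).
#' @param event_lists named list: analysis -> character vector of
#'   event genes.
#' @param min_size analysis filter (strict), default 10.
#' @param display_n,display_pct display thresholds (strict).
#' @return data.frame (subset, analysis, size, n, pct, analysed,
#'   display).
#' @export
representation_metrics <- function(subset_genes, event_lists,
                                   min_size = 10, display_n = 10,
                                   display_pct = 5) {
  rows <- list()
  for (sub in names(subset_genes)) {
    sg <- unique(subset_genes[[sub]])
    size <- length(sg)
    for (an in names(event_lists)) {
      nn <- length(intersect(sg, event_lists[[an]]))
      rows[[length(rows) + 1]] <- data.frame(
        subset = sub, analysis = an, size = size, n = nn,
        pct = if (size > 0) 100 * nn / size else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  res$analysed <- res$size > min_size
  disp <- tapply(res$n > display_n | res$pct > display_pct, res$subset, any)
  res$display <- res$analysed & disp[res$subset]
  rownames(res) <- NULL
  res
}
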