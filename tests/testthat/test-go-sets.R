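## small hand-built ontology: root -> {m1, m2}; m1 -> {l1, l2}; m2 -> {l3}
toy_obo <- function() {
  list(terms = data.frame(
    id = c("GO:1", "GO:2", "GO:3", "GO:4", "GO:5", "GO:6"),
    name = c("root", "meta one", "meta two", "leaf a", "leaf b", "leaf c"),
    namespace = "biological_process", stringsAsFactors = FALSE),
    edges = data.frame(child = c("GO:2", "GO:3", "GO:4", "GO:5", "GO:6"),
                       parent = c("GO:1", "GO:1", "GO:2", "GO:2", "GO:3"),
                       stringsAsFactors = FALSE))
}

toy_ann <- function() {
  ## 10 genes: 5 on leaf a, 3 on leaf b, 2 on leaf c
  data.frame(gene_id = sprintf("g%02d", 1:10),
             term = c(rep("GO:4", 5), rep("GO:5", 3), rep("GO:6", 2)),
             stringsAsFactors = FALSE)
}

test_that("information content follows the closed form on a toy DAG", {
  gg <- go_graph(toy_obo(), toy_ann())
  expect_equal(information_content(gg, "GO:1"), 0)      # root
  ## GO:2 covers 8 of 10 genes; GO:4 covers 5 of 10 -> IC = ln 2
  expect_equal(information_content(gg, "GO:2"), -log(0.8))
  expect_equal(information_content(gg, "GO:4"), log(2))
  expect_error(information_content(gg, "GO:99"), "unknown")
  ## a term covering every gene has IC 0
  ann_all <- rbind(toy_ann(),
                   data.frame(gene_id = sprintf("g%02d", 1:10),
                              term = "GO:6"))
  gg2 <- go_graph(toy_obo(), ann_all)
  expect_equal(information_content(gg2, "GO:3"), 0)
})

test_that("Lin edge weights are bounded and hit the boundary cases", {
  gg <- go_graph(toy_obo(), toy_ann())
  w <- edge_weights(gg)
  expect_true(all(w$weight >= 0 & w$weight <= 1))
  ## root edges have weight 0
  expect_true(all(w$weight[w$parent == "GO:1"] == 0))
  ## equal-IC edge has weight 1: GO:6 (2 genes) under GO:3 (2 genes)
  expect_equal(w$weight[w$child == "GO:6"], 1)
  ## the closed form: IC 1 and 3 -> 2*1/(1+3) = 0.5
  expect_equal(2 * 1 / (1 + 3), 0.5)
})

test_that("Louvain separates disconnected cliques and beats singletons", {
  ## two 4-cliques, no cross edges, encoded as a toy ontology-like graph
  ids <- sprintf("GO:%02d", 1:8)
  ed <- do.call(rbind, lapply(list(1:4, 5:8), function(blk) {
    cmb <- t(combn(blk, 2))
    data.frame(child = ids[cmb[, 1]], parent = ids[cmb[, 2]],
               stringsAsFactors = FALSE)
  }))
  gg <- list(terms = data.frame(id = ids, name = ids,
                                namespace = "biological_process"),
             edges = ed)
  ann <- data.frame(gene_id = sprintf("g%d", 1:8), term = ids)
  graph <- go_graph(gg, ann)
  part <- louvain_partition(graph, seed = 1)
  m <- part$membership
  expect_equal(length(unique(m$set)), 2)
  expect_equal(length(unique(m$set[m$term %in% ids[1:4]])), 1)
  expect_equal(length(unique(m$set[m$term %in% ids[5:8]])), 1)
})

test_that("Louvain at a fixed seed is reproducible and exhaustive/exclusive", {
  g <- simulate_go_annotations(go_config(n_terms = 60, n_genes = 200),
                               seed = 12)
  gg <- go_graph(g$obo, g$annotations)
  p1 <- louvain_partition(gg, seed = 4)
  p2 <- louvain_partition(gg, seed = 4)
  expect_identical(p1$membership, p2$membership)
  m <- p1$membership
  ## mutually exclusive and jointly exhaustive over clustered terms
  expect_false(anyDuplicated(m$term) > 0)
  expect_setequal(m$term, gg$terms$id)
  ## every subset nests inside exactly one set
  expect_true(all(vapply(split(m$set, m$subset),
                         function(s) length(unique(s)) == 1, TRUE)))
})

test_that("set labels take the dominant term with lexicographic ties", {
  gg <- go_graph(toy_obo(), toy_ann())
  part <- structure(list(membership = data.frame(
    term = c("GO:2", "GO:4", "GO:5"), set = "S01", subset = "S01.1",
    stringsAsFactors = FALSE)), class = "go_partition")
  lab <- label_partition(part, gg)
  expect_equal(unname(lab$set_label["S01"]), "meta one")  # 8 genes
  ## tie between GO:3 (2 genes) and GO:6 (2 genes) -> smaller id wins
  part2 <- structure(list(membership = data.frame(
    term = c("GO:3", "GO:6"), set = "S01", subset = "S01.1",
    stringsAsFactors = FALSE)), class = "go_partition")
  lab2 <- label_partition(part2, gg)
  expect_equal(unname(lab2$set_label["S01"]), "meta two")
  expect_error(label_partition(structure(list(membership =
    data.frame(term = character(), set = character(),
               subset = character())), class = "go_partition"), gg))
})

test_that("set enrichment equals the exact hypergeometric tail", {
  gg <- go_graph(toy_obo(), toy_ann())
  part <- louvain_partition(gg, seed = 1)
  bg <- sprintf("g%02d", 1:10)
  ## study = background -> all p = 1
  enr_all <- enrich_sets(bg, bg, part, gg)
  expect_true(all(enr_all$p == 1))
  expect_error(enrich_sets(character(), bg, part, gg), "empty")
  expect_error(enrich_sets(c(bg, "gX"), bg, part, gg), "subset")

  ## toy numbers against direct summation: N=100, K=20, n=10, k=8
  p_direct <- oracle_hyper_tail(8, 20, 10, 100)
  expect_equal(phyper(7, 20, 80, 10, lower.tail = FALSE), p_direct,
               tolerance = 1e-12)

  ## a study list drawn from the genes of one set enriches that set
  m <- part$membership
  sets <- split(m$term, m$set)
  target <- names(sets)[vapply(sets, function(tm) "GO:4" %in% tm, TRUE)]
  enr <- enrich_sets(sprintf("g%02d", 1:5), bg, part, gg)
  expect_equal(enr$set[1], target)
  ## BH q is monotone in p
  expect_true(all(diff(enr$q[order(enr$p)]) >= -1e-12))
})

test_that("representation metrics apply the strict reporting filters", {
  subs <- list(small = sprintf("s%d", 1:10),      # exactly 10 -> excluded
               big = sprintf("b%d", 1:100),
               mid = sprintf("m%d", 1:20))
  events <- list(a1 = c(sprintf("b%d", 1:6), sprintf("m%d", 1:15)),
                 a2 = sprintf("s%d", 1:10))
  rm_ <- representation_metrics(subs, events)
  expect_false(any(rm_$analysed[rm_$subset == "small"]))
  ## big: 6/100 = 6% > 5% -> displayed in the percentage panel
  expect_true(all(rm_$display[rm_$subset == "big"]))
  expect_equal(rm_$pct[rm_$subset == "big" & rm_$analysis == "a1"], 6)
  ## mid: 15 genes > 10 -> displayed via the absolute panel
  expect_true(all(rm_$display[rm_$subset == "mid"]))
  ## events = subset -> 100%
  rm2 <- representation_metrics(list(x = subs$big), list(all = subs$big))
  expect_equal(rm2$pct, 100)
})

test_that("OBO round trips and cyclic ontologies are rejected", {
  g <- simulate_go_annotations(go_config(n_terms = 40, n_genes = 100),
                               seed = 2)
  tf <- tempfile(fileext = ".obo")
  writeLines(g$obo_text, tf)
  o2 <- read_obo(tf)
  expect_identical(o2$terms, g$obo$terms)
  expect_setequal(paste(o2$edges$child, o2$edges$parent),
                  paste(g$obo$edges$child, g$obo$edges$parent))
  cyc <- c("format-version: 1.2", "", "[Term]", "id: GO:1", "name: a",
           "is_a: GO:2", "", "[Term]", "id: GO:2", "name: b",
           "is_a: GO:1", "")
  tf2 <- tempfile(fileext = ".obo")
  writeLines(cyc, tf2)
  expect_error(read_obo(tf2), "cycle")
})

test_that("a single-term ontology yields a single-set partition", {
  obo <- list(terms = data.frame(id = "GO:1", name = "only",
                                 namespace = "biological_process"),
              edges = data.frame(child = character(),
                                 parent = character()))
  gg <- go_graph(obo, data.frame(gene_id = c("g1", "g2"), term = "GO:1"))
  part <- louvain_partition(gg, seed = 1)
  expect_equal(nrow(part$membership), 1)
  expect_equal(length(unique(part$membership$set)), 1)
})
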