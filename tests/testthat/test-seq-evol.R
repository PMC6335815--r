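test_that("4-fold degenerate columns match a brute-force degeneracy scan", {
  ## ATG (Met, 1-fold) excluded; GGx (Gly, 4-fold) included
  aln <- c(x = "ATGGGA", y = "ATGGGC")
  expect_identical(fourfold_degenerate_columns(aln), 6L)

  ## 20-codon toy alignment vs an independent lookup-table scan
  set.seed(4)
  s <- aridEvol:::random_root_seq(20)
  s2 <- aridEvol:::evolve_codon_seq(s, 0.3, 0.5)
  aln <- c(a = paste(c("A", "C", "G", "T")[s], collapse = ""),
           b = paste(c("A", "C", "G", "T")[s2], collapse = ""))
  got <- fourfold_degenerate_columns(aln)
  want <- integer()
  for (k in 1:20) {
    cods <- substring(aln, 3 * k - 2, 3 * k)
    if (all(vapply(cods, oracle_is_fourfold, TRUE))) {
      want <- c(want, 3L * k)
    }
  }
  expect_identical(got, want)
})

test_that("internal stop codons are reported with sequence and position", {
  expect_error(fourfold_degenerate_columns(c(ok = "ATGGGA", bad = "TAAGGA")),
               "stop codon in 'bad' at codon 1")
})

test_that("JC silent distance matches the closed form and flags saturation", {
  ## identical sequences -> 0
  aln <- c(a = strrep("GGA", 20), b = strrep("GGA", 20))
  cols <- fourfold_degenerate_columns(aln)
  expect_equal(jc_silent_distance(aln, cols)["a", "b"], 0)

  ## p = 0.1: two mismatches among 20 4-fold columns
  b <- paste0(strrep("GGA", 18), "GGC", "GGG")
  aln2 <- c(a = strrep("GGA", 20), b = b)
  d <- jc_silent_distance(aln2, fourfold_degenerate_columns(aln2))
  expect_equal(d["a", "b"], -0.75 * log(1 - 4 * 0.1 / 3), tolerance = 1e-12)
  expect_equal(round(d["a", "b"], 5), 0.10733)

  ## p = 0.75: saturated, excluded
  a <- strrep("GGA", 4)
  b <- paste0("GGC", "GGG", "GGT", "GGA")
  d2 <- jc_silent_distance(c(a = a, b = b),
                           fourfold_degenerate_columns(c(a = a, b = b)))
  expect_true(is.na(d2["a", "b"]))
  expect_true(attr(d2, "saturated")["a", "b"])
})

test_that("least-squares branch lengths solve the 3-taxon star exactly", {
  tr <- ape::read.tree(text = "(A:1,B:1,C:1)root;")
  d <- matrix(c(0, .2, .3, .2, 0, .4, .3, .4, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  bl <- ls_branch_lengths(tr, d)
  expect_equal(unname(bl[c("A", "B", "C")]), c(0.05, 0.15, 0.25),
               tolerance = 1e-9)
  expect_lt(attr(bl, "residual"), 1e-9)
})

test_that("additive distances are reproduced with zero residual", {
  tr <- repleta_tree()
  d <- ape::cophenetic.phylo(tr)
  bl <- ls_branch_lengths(tr, d)
  expect_lt(attr(bl, "residual"), 1e-8)
  true <- setNames(branch_table(tr)$length, branch_table(tr)$branch)
  ident <- setdiff(names(bl), attr(bl, "root_spanning"))
  expect_equal(bl[ident], true[ident], tolerance = 1e-8)
  ## the root-spanning pair is only identifiable as a sum
  rs <- attr(bl, "root_spanning")
  expect_equal(sum(bl[rs]), sum(true[rs]), tolerance = 1e-8)
  expect_error(ls_branch_lengths(tr, d[1:2, 1:2]), ">= 3 taxa")
})

test_that("NG86 handles the trivial codon-pair cases", {
  s <- strrep("GGA", 10)
  kk <- ng86_kaks(s, s)
  expect_equal(kk$Ka, 0)
  expect_equal(kk$Ks, 0)
  expect_true(is.na(kk$ratio))

  ## GGA -> GGG is synonymous
  kk2 <- ng86_kaks(paste0(strrep("GGA", 9), "GGA"),
                   paste0(strrep("GGA", 9), "GGG"))
  expect_equal(kk2$Ka, 0)
  expect_gt(kk2$Ks, 0)
  expect_error(ng86_kaks("GGA", "GGAGGA"), "mismatch")
})

test_that("NG86 difference counts agree with explicit pathway enumeration", {
  ## spot-check a 10-codon pair with 2 differing codons against the
  ## brute-force oracle (the exhaustive sweep lives in the acceptance
  ## suite)
  s1 <- "ATGAAACCCGGGTTTCTGATCGATCGAGGG"
  s2 <- "ATGAAGCCCGGATTTCTGATCGATCGAGGG"
  got <- ng86_kaks(s1, s2)
  want <- oracle_ng86(s1, s2)
  expect_equal(got$Sd, want$Sd, tolerance = 1e-9)
  expect_equal(got$Nd, want$Nd, tolerance = 1e-9)
  expect_equal(got$S, want$S, tolerance = 1e-9)
  expect_equal(got$Ka, want$Ka, tolerance = 1e-9)
  expect_equal(got$Ks, want$Ks, tolerance = 1e-9)
})

test_that("the four-criterion phylogeny filter applies its rules in order", {
  aln_long <- function() {
    s <- strrep("GGACTT", 110)            # 220 codons
    c(Dmel = s, Dvir = s, Drep = s, Dhyd = s, Dbuz = s, Dald = s,
      Dmoj = s)
  }
  alns <- list(og1 = aln_long(), og2 = aln_long(), og3 = aln_long())
  has_inp <- c(og1 = TRUE, og2 = FALSE, og3 = FALSE)
  ## og3: short members (150 aa) but all within five residues
  res <- filter_orthogroups_for_phylogeny(
    alns, has_inp,
    lengths_aa = list(og1 = rep(220, 7), og2 = c(300, 300, 301, 299,
                                                 300, 300, 300),
                      og3 = c(150, 151, 152, 153, 148, 150, 150)))
  expect_equal(res$rejected_by[res$orthogroup_id == "og1"], "duplications")
  expect_true(res$retained[res$orthogroup_id == "og2"])
  ## og3 clears criterion 3 via the within-five-residues exception
  ## (its 5-residue spread still has to face the MAD criterion)
  expect_false(identical(res$rejected_by[res$orthogroup_id == "og3"],
                         "length"))

  ## a fast-evolving member (all nonsynonymous differences) fails Ka/Ks
  fast <- aln_long()
  base <- fast[["Dmel"]]
  mut <- gsub("GGA", "AGA", base)          # Gly -> Arg, nonsynonymous
  fast[["Dmoj"]] <- mut
  res2 <- filter_orthogroups_for_phylogeny(list(fast_og = fast),
                                           c(fast_og = FALSE))
  expect_equal(res2$rejected_by, "kaks")

  ## length spread beyond the MAD bound fails criterion 4
  res3 <- filter_orthogroups_for_phylogeny(
    list(og = aln_long()), c(og = FALSE),
    lengths_aa = list(og = c(300, 300, 300, 300, 300, 300, 380)))
  expect_equal(res3$rejected_by, "mad")
})

test_that("supermatrix export concatenates with 1-based partitions", {
  alns <- list(og2 = c(A = strrep("C", 60), B = strrep("G", 60)),
               og1 = c(A = strrep("A", 30), B = strrep("T", 30)))
  sm <- export_supermatrix(alns)
  expect_equal(sm$partitions$start, c(1, 31))
  expect_equal(sm$partitions$end, c(30, 90))
  expect_equal(sm$partitions$orthogroup_id, c("og1", "og2"))
  expect_equal(unname(nchar(sm$matrix)), c(90, 90))
  expect_equal(substr(sm$matrix[["A"]], 1, 30), strrep("A", 30))
  expect_equal(sm$partition_text, c("DNA, og1 = 1-30", "DNA, og2 = 31-90"))
  expect_error(export_supermatrix(list()), "no retained")
  expect_error(export_supermatrix(
    list(og1 = c(A = "AAA"), og2 = c(B = "CCC"))), "mismatch")
})

test_that("silent distances are symmetric, zero iff identical, monotone in p", {
  ps <- c(0.05, 0.1, 0.2, 0.4, 0.6)
  ds <- -0.75 * log(1 - 4 * ps / 3)
  expect_true(all(diff(ds) > 0))
  set.seed(2)
  s <- aridEvol:::random_root_seq(100)
  s2 <- aridEvol:::evolve_codon_seq(s, 0.2, 0.1)
  aln <- c(a = paste(c("A", "C", "G", "T")[s], collapse = ""),
           b = paste(c("A", "C", "G", "T")[s2], collapse = ""))
  d <- jc_silent_distance(aln, fourfold_degenerate_columns(aln))
  expect_equal(d["a", "b"], d["b", "a"])
  expect_equal(d["a", "a"], 0)
})
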