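sample_cols <- function() {
  paste0("T", rep(0:7, each = 3), "_rep", rep(1:3, 8))
}

test_that("the low-expression filter is strict at the 50-read threshold", {
  m <- matrix(0L, 5, 24, dimnames = list(paste0("g", 1:5), sample_cols()))
  m[1, 1] <- 0L; m[2, 1] <- 50L; m[3, 1] <- 51L; m[4, 1] <- 500L
  m[5, 1] <- 49L
  kept <- filter_low_expression(m)
  expect_identical(rownames(kept), c("g3", "g4"))
})

test_that("TMM factors are 1 for identical or proportional libraries", {
  set.seed(1)
  base <- matrix(rnbinom(200 * 4, mu = 100, size = 10), 200, 4,
                 dimnames = list(NULL, paste0("s", 1:4)))
  same <- base[, c(1, 1, 1, 1)]
  colnames(same) <- paste0("s", 1:4)
  expect_equal(unname(tmm_factors(same)), rep(1, 4))
  ## doubling a library changes the M ratios by a constant -> equal
  ## factors after the geometric-mean rescaling
  two <- cbind(s1 = base[, 1], s2 = 2L * base[, 1])
  f <- tmm_factors(two)
  expect_equal(unname(f[1]), unname(f[2]), tolerance = 1e-9)
  ## geometric mean is always 1
  f2 <- tmm_factors(base)
  expect_equal(exp(mean(log(f2))), 1, tolerance = 1e-9)
  expect_error(tmm_factors(cbind(base[, 1])), "2 samples")
  expect_error(tmm_factors(cbind(s1 = base[, 1], s2 = 0L * base[, 1])),
               "all-zero")
})

test_that("the DE criterion needs two qualifying post-control time points", {
  set.seed(7)
  ng <- 400
  mu <- matrix(100, ng, 24, dimnames = list(sprintf("g%03d", 1:ng),
                                            sample_cols()))
  ## g001: 4-fold up at T2, T3, T4 -> DE
  mu[1, 7:15] <- 400
  ## g002: 4-fold up at exactly one time point -> not DE
  mu[2, 7:9] <- 400
  cnt <- matrix(rnbinom(length(mu), mu = mu, size = 20), ng,
                dimnames = dimnames(mu))
  res <- de_call(cnt)
  expect_true(res$de[["g001"]])
  expect_false(res$de[["g002"]])
  ## DE monotonicity: raising the fold-change threshold never adds genes
  res_hi <- de_call(cnt, lfc = 2)
  expect_true(all(names(res_hi$de)[res_hi$de] %in%
                    names(res$de)[res$de]))
  ## missing control or single replicate are rejected
  expect_error(de_call(cnt[, -(1:3)]), "T0")
  expect_error(de_call(cnt[, -(2:3)]), "replicates")
})

test_that("profile standardisation yields exact z-scores", {
  m <- rbind(lin = 1:8, const = rep(3, 8))
  expect_warning(z <- standardize_profiles(m), "constant")
  expect_equal(nrow(z), 1)
  expect_equal(unname(z["lin", ]), (1:8 - 4.5) / sd(1:8))
  expect_equal(mean(z["lin", ]), 0, tolerance = 1e-12)
  expect_equal(sd(z["lin", ]), 1, tolerance = 1e-12)
})

test_that("fuzzy c-means memberships are normalised and symmetric cases split", {
  set.seed(3)
  x <- rbind(matrix(rnorm(40, -3, .2), 20), matrix(rnorm(40, 3, .2), 20))
  x <- cbind(x, x)                      # 4-dim, two tight groups
  fit <- fuzzy_cmeans(x, 2, seed = 5)
  expect_equal(unname(rowSums(fit$membership)), rep(1, 40),
               tolerance = 1e-9)
  ## objective non-increasing across iterations
  expect_true(all(diff(fit$trace) <= 1e-8))
  ## a point equidistant from two symmetric centroids gets (0.5, 0.5)
  x2 <- rbind(x, 0)
  fit2 <- fuzzy_cmeans(x2, 2, seed = 5)
  expect_equal(unname(fit2$membership[41, ]), c(0.5, 0.5),
               tolerance = 5e-3)
  expect_error(fuzzy_cmeans(x, 1, seed = 1), "c <")
  expect_error(fuzzy_cmeans(x, 40, seed = 1), "c <")
})

test_that("two planted shapes are recovered with ARI >= 0.95", {
  set.seed(11)
  tmpl <- expression_templates()
  truth <- rep(1:2, each = 60)
  prof <- tmpl[c(2, 7), ][truth, ] + matrix(rnorm(120 * 8, 0, 0.3), 120)
  prof <- standardize_profiles(prof)
  fit <- fuzzy_cmeans(prof, 2, seed = 9)
  hard <- apply(fit$membership, 1, which.max)
  expect_gte(mclust::adjustedRandIndex(hard, truth), 0.95)
})

test_that("our fuzzy c-means agrees with an independent implementation", {
  set.seed(21)
  x <- rbind(matrix(rnorm(60, -2, .4), 30), matrix(rnorm(60, 2, .4), 30))
  ours <- fuzzy_cmeans(x, 2, seed = 2)
  set.seed(2)
  ref <- e1071::cmeans(x, 2, m = 2, iter.max = 500)
  perm <- if (sum((ours$centers[1, ] - ref$centers[1, ])^2) <
              sum((ours$centers[1, ] - ref$centers[2, ])^2)) 1:2 else 2:1
  expect_equal(unname(ours$centers), unname(ref$centers[perm, ]),
               tolerance = 1e-2)
  ## same converged objective when evaluated on the reference fit
  d2 <- outer(rowSums(x^2), rowSums(ref$centers^2), "+") -
    2 * x %*% t(ref$centers)
  obj_ref <- sum(ref$membership^2 * d2)
  expect_equal(ours$objective, obj_ref, tolerance = 1e-3)
})

test_that("the partition coefficient is 1 when crisp and 1/c when uniform", {
  crisp <- diag(4)[rep(1:4, 5), ]
  expect_equal(partition_coefficient(crisp), 1)
  unif <- matrix(1 / 6, 30, 6)
  expect_equal(partition_coefficient(unif), 1 / 6)
})

test_that("the cluster report finds planted excesses and discriminating genes", {
  ## synthetic membership matrix (3 clusters): cluster 1 has 8 A-core
  ## genes (5 of them A-only), 3 B-core genes; one gene never clears
  ## the 0.5 core cut (max membership 0.49) and is left unclustered
  genes_a <- sprintf("A%02d", 1:9)
  genes_b <- sprintf("B%02d", 1:3)
  meta <- data.frame(gene_id = c(genes_a, genes_b),
                     species = rep(c("spA", "spB"), c(9, 3)),
                     stringsAsFactors = FALSE)
  u <- matrix(0, 12, 3)
  u[1:8, ] <- rep(c(0.9, 0.05, 0.05), each = 8)
  u[9, ] <- c(0.49, 0.26, 0.25)
  u[10:12, ] <- rep(c(0.8, 0.1, 0.1), each = 3)
  fit <- structure(list(membership = u, centers = matrix(0, 3, 8), c = 3),
                   class = "fcm")
  rownames(fit$membership) <- meta$gene_id
  ## orthologue map: A01..A03 <-> B01..B03; A04.. have no orthologue
  orth <- data.frame(gene_a = sprintf("A%02d", 1:3),
                     gene_b = sprintf("B%02d", 1:3))
  expect_warning(rep_ <- cluster_report(fit, meta, orth), "orthologue")
  s1 <- rep_$summary[rep_$summary$cluster == 1, ]
  expect_equal(s1$excess_species, "spA")
  expect_equal(s1$excess, 5)
  ## A01..A03 have core orthologues in cluster 1 -> not discriminating
  expect_setequal(rep_$discriminating[["1"]], sprintf("A%02d", 4:8))
  ## the max-membership-0.49 gene is reported unclustered
  expect_true("A09" %in% rep_$unclustered$gene_id)
  ## top members are the highest-membership discriminating genes
  t1 <- rep_$top_members[rep_$top_members$cluster == 1, ]
  expect_true(all(t1$gene_id %in% sprintf("A%02d", 4:8)))
})

test_that("identical core sets give zero discriminating genes", {
  meta <- data.frame(gene_id = c(sprintf("A%d", 1:6), sprintf("B%d", 1:6)),
                     species = rep(c("spA", "spB"), each = 6))
  u <- matrix(0.05, 12, 2)
  u[c(1:3, 7:9), 1] <- 0.95; u[c(1:3, 7:9), 2] <- 0.05
  u[c(4:6, 10:12), 2] <- 0.95; u[c(4:6, 10:12), 1] <- 0.05
  fit <- structure(list(membership = u, centers = matrix(0, 2, 8), c = 2),
                   class = "fcm")
  rownames(fit$membership) <- meta$gene_id
  orth <- data.frame(gene_a = sprintf("A%d", 1:6),
                     gene_b = sprintf("B%d", 1:6))
  rep_ <- cluster_report(fit, meta, orth)
  expect_true(all(vapply(rep_$discriminating, length, 0L) == 0))
})
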