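test_that("branch-event tabulation matches the simulated truth exactly", {
  cfg <- sim_config(n_families = 200, seed = 17,
                    birth_rate = c(ancestral_repleta = 150,
                                   cactus_use = 400,
                                   cactus_specialisation = 300,
                                   mulleri_complex = 60),
                    duplication_rate = c(Dald = 150, Dmoj = 80,
                                         Dbuz = 120, Dhyd = 100,
                                         Drep = 70),
                    loss_prob = 0)
  sim <- simulate_gene_families(cfg)
  om <- orthology_from_truth(sim)
  tab <- tabulate_branch_events(om, sim$selection, cfg$tree)
  ## origination counts per internal branch equal the truth
  for (b in c("ancestral_repleta", "cactus_use", "cactus_specialisation",
              "mulleri_complex")) {
    expect_equal(tab$n_orthogroups_arising[tab$branch == b],
                 sum(sim$families$origin_branch == b))
  }
  ## inparalogue counts per terminal branch equal the truth
  inp <- sim$genes[sim$genes$class == "inparalogue", ]
  for (sp in c("Dald", "Dmoj", "Dbuz", "Dhyd", "Drep")) {
    expect_equal(tab$n_inparalogues[tab$branch == sp],
                 sum(inp$species == sp))
    expect_equal(tab$n_og_inparalogues[tab$branch == sp],
                 length(unique(inp$family[inp$species == sp])))
  }
  ## selection counts per branch equal the truth
  for (b in unique(sim$selection$branch)) {
    expect_equal(tab$n_selected[tab$branch == b],
                 sum(sim$selection$selected[sim$selection$branch == b]))
  }
  expect_error(
    tabulate_branch_events(om, data.frame(gene_id = "g", branch = "nope",
                                          selected = 1L), cfg$tree),
    "unknown branch")
})

test_that("duplication-rate zero zeroes the inparalogue columns", {
  cfg <- sim_config(n_families = 80, seed = 2,
                    duplication_rate = numeric(0))
  sim <- simulate_gene_families(cfg)
  tab <- tabulate_branch_events(orthology_from_truth(sim), sim$selection,
                                cfg$tree)
  expect_true(all(tab$n_inparalogues[tab$terminal] == 0))
  expect_true(all(tab$n_og_inparalogues[tab$terminal] == 0))
})

test_that("expected counts and excesses follow the global-rate formula", {
  ee <- expected_and_excess(c(10, 20, 30), c(1, 2, 3))
  expect_equal(ee$excess, c(0, 0, 0))
  ee2 <- expected_and_excess(c(30, 20, 10), c(1, 2, 3))
  expect_equal(ee2$excess, c(20, 0, -20))
  expect_equal(ee2$expected, c(10, 20, 30))
  expect_error(expected_and_excess(c(1, 2), c(0, 0)), "positive")
  ## excess conservation at tight tolerance, random cases
  set.seed(5)
  for (i in 1:20) {
    cnt <- rpois(6, 50)
    len <- runif(6, 0.01, 1)
    expect_lt(abs(sum(expected_and_excess(cnt, len)$excess)), 1e-9)
  }
})

test_that("a planted 3x rate yields the largest positive excess", {
  ## single-seed spot check; the 20-seed study is in the acceptance suite
  cfg <- sim_config(n_families = 10, seed = 23,
                    tree = repleta_tree(c(ancestral_repleta = 0.1,
                                          cactus_use = 0.1,
                                          cactus_specialisation = 0.1,
                                          mulleri_complex = 0.1)),
                    birth_rate = c(ancestral_repleta = 1000,
                                   cactus_use = 3000,
                                   cactus_specialisation = 1000,
                                   mulleri_complex = 1000),
                    duplication_rate = numeric(0))
  sim <- simulate_gene_families(cfg)
  cnt <- table(factor(sim$families$origin_branch,
                      levels = c("ancestral_repleta", "cactus_use",
                                 "cactus_specialisation",
                                 "mulleri_complex")))
  ee <- expected_and_excess(as.numeric(cnt), rep(0.1, 4))
  expect_equal(which.max(ee$excess), 2L)
})

test_that("Clopper-Pearson intervals reproduce the published cells", {
  expect_equal(round(100 * clopper_pearson(95, 1237), 2),
               c(lower = 6.26, upper = 9.31))
  expect_equal(round(100 * 95 / 1237, 2), 7.68)
  expect_equal(round(100 * 31 / 456, 2), 6.80)
  expect_equal(clopper_pearson(0, 10)[["lower"]], 0)
  expect_equal(clopper_pearson(10, 10)[["upper"]], 1)
  expect_error(clopper_pearson(11, 10))
})

test_that("Clopper-Pearson equals tail-inversion bisection to 1e-10", {
  for (xn in list(c(7, 20), c(0, 10), c(1, 1), c(95, 1237))) {
    got <- clopper_pearson(xn[1], xn[2])
    want <- oracle_cp(xn[1], xn[2])
    expect_equal(got[["lower"]], want[["lower"]], tolerance = 1e-10)
    expect_equal(got[["upper"]], want[["upper"]], tolerance = 1e-10)
  }
})

test_that("CP interval contains x/n and narrows with n", {
  set.seed(9)
  for (i in 1:25) {
    n <- sample(5:500, 1); x <- sample(0:n, 1)
    ci <- clopper_pearson(x, n)
    expect_lte(ci[["lower"]], x / n)
    expect_gte(ci[["upper"]], x / n)
  }
  w <- vapply(c(10, 40, 160, 640), function(n) {
    diff(clopper_pearson(n / 5, n))
  }, 0)
  expect_true(all(diff(w) < 0))
})

test_that("the association table computes strata, intervals and Fisher p", {
  flags <- rbind(
    data.frame(species = "Dald",
               has_inparalogue = rep(c(FALSE, TRUE), c(9615, 1237)),
               is_selected = c(rep(c(TRUE, FALSE), c(429, 9615 - 429)),
                               rep(c(TRUE, FALSE), c(95, 1237 - 95)))),
    data.frame(species = "Drep",
               has_inparalogue = rep(c(FALSE, TRUE), c(10480, 456)),
               is_selected = c(rep(c(TRUE, FALSE), c(371, 10480 - 371)),
                               rep(c(TRUE, FALSE), c(31, 456 - 31)))))
  at <- association_table(flags)
  ald <- at[at$species == "Dald", ]
  expect_equal(ald$pct_inp, 7.68)
  expect_equal(c(ald$ci_lo_inp, ald$ci_hi_inp), c(6.26, 9.31))
  expect_equal(ald$pct_noInp, round(100 * 429 / 9615, 2))
  rep_ <- at[at$species == "Drep", ]
  expect_equal(rep_$pct_inp, 6.80)
  expect_equal(c(rep_$ci_lo_inp, rep_$ci_hi_inp), c(4.67, 9.51))
  expect_true(all(at$p_fisher >= 0 & at$p_fisher <= 1))
  ## x = 0 stratum: pct 0, lower CI 0
  f0 <- data.frame(species = "X", has_inparalogue = rep(c(FALSE, TRUE),
                                                        c(50, 20)),
                   is_selected = FALSE)
  a0 <- association_table(f0)
  expect_equal(a0$pct_inp, 0)
  expect_equal(a0$ci_lo_inp, 0)
})

test_that("Fisher p-values are near-uniform under an independence null", {
  ## study-scale tables (~10,000 genes/species) so the exact test's
  ## discreteness does not dominate the p distribution
  set.seed(31)
  p <- vapply(1:1000, function(i) {
    inp <- runif(10000) < 0.3
    sel <- runif(10000) < 0.2
    m <- table(inp, sel)
    fisher.test(m)$p.value
  }, 0)
  ks <- suppressWarnings(stats::ks.test(p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("the shared-DE overlap statistic reproduces the published expectation", {
  ov <- overlap_independence(123, 702, 681, 10443)
  expect_equal(round(ov$expected_both, 1), 63.5)
  expect_equal(ov$fold, 123 / ov$expected_both)
  expect_lt(abs(ov$fold - 2), 0.1)
  expect_equal(ov$df, 1L)

  ov0 <- overlap_independence(0, 0, 0, 100)
  expect_equal(ov0$expected_both, 0)
  expect_true(is.na(ov0$fold))

  ov1 <- overlap_independence(25, 25, 25, 100)
  expect_equal(ov1$expected_both, 25)
  expect_equal(ov1$fold, 1)
  expect_lt(ov1$chi2, 1e-9)
  expect_error(overlap_independence(1, 1, 1, 0), "positive")
  expect_error(overlap_independence(50, 40, 30, 100), "exceed")
})
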