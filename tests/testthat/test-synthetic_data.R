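test_that("simulation is deterministic under a seed and distinct across seeds", {
  a <- simulate_two_way(n_per_category = 3, I = 2, J = 2, m = 2, seed = 5)
  b <- simulate_two_way(n_per_category = 3, I = 2, J = 2, m = 2, seed = 5)
  c <- simulate_two_way(n_per_category = 3, I = 2, J = 2, m = 2, seed = 6)
  expect_identical(a$pseudobulk$values, b$pseudobulk$values)
  expect_identical(a$truth$category, b$truth$category)
  expect_false(identical(a$pseudobulk$values, c$pseudobulk$values))
})

test_that("planted offsets are sum-to-zero and consistent with the category", {
  sim <- simulate_two_way(n_per_category = 5, I = 4, J = 3, m = 2, seed = 8)
  eff <- attr(sim$truth, "effects")
  for (g in sim$truth$gene_id) {
    e <- eff[[g]]
    expect_lt(abs(sum(e$alpha)), 1e-9)
    expect_lt(abs(sum(e$beta)), 1e-9)
    expect_true(all(abs(rowSums(e$ab)) < 1e-9))
    expect_true(all(abs(colSums(e$ab)) < 1e-9))
  }
  f1_genes <- sim$truth$gene_id[sim$truth$category == "F1"]
  for (g in f1_genes) {
    expect_true(all(attr(sim$truth, "effects")[[g]]$beta == 0))
    expect_true(all(attr(sim$truth, "effects")[[g]]$ab == 0))
  }
})

test_that("near-noiseless F1 genes vary only across f1 levels", {
  sim <- simulate_two_way(n_per_category = 3, I = 3, J = 2, m = 3,
                          effect_sd = 2, noise_sd = 1e-6, seed = 13)
  pb <- sim$pseudobulk
  g <- sim$truth$gene_id[sim$truth$category == "F1"][1]
  y <- pb$values[g, ]
  by_f1 <- tapply(y, pb$design$f1, function(v) diff(range(v)))
  expect_true(all(by_f1 < 1e-4))
  expect_gt(diff(range(tapply(y, pb$design$f1, mean))), 0.5)
})

test_that("null interaction F averages near 1 for planted additive genes", {
  sim <- simulate_two_way(n_per_category = 200, I = 3, J = 2, m = 4,
                          seed = 17)
  pb <- sim$pseudobulk
  add_genes <- sim$truth$category == "F1+F2"
  mods <- two_way_models()
  ff <- idas:::fit_fixed_matrix(pb$values[add_genes, ], pb$design, mods$m1)
  fr <- idas:::fit_fixed_matrix(pb$values[add_genes, ], pb$design, mods$m2)
  df1 <- fr$df_resid - ff$df_resid
  Fstat <- ((fr$rss - ff$rss) / df1) / (ff$rss / ff$df_resid)
  expect_gte(mean(Fstat), 0.8)
  expect_lte(mean(Fstat), 1.25)
})

test_that("refitting each category under its own model recovers the noise variance", {
  sim <- simulate_two_way(n_per_category = 200, I = 3, J = 2, m = 4,
                          noise_sd = 0.5, seed = 18)
  pb <- sim$pseudobulk
  own_spec <- c("F1" = "m3", "F2" = "m4", "F1xF2" = "m1", "F1+F2" = "m2",
                "non-sig" = "m5")
  mods <- two_way_models()
  for (cat in names(own_spec)) {
    rows <- sim$truth$category == cat
    f <- idas:::fit_fixed_matrix(pb$values[rows, ], pb$design,
                                 mods[[own_spec[[cat]]]])
    ratio <- mean(f$rss / f$df_resid) / 0.5^2
    expect_gte(ratio, 0.8); expect_lte(ratio, 1.25)
  }
})

test_that("single-cell simulation reproduces planted means through aggregation", {
  means <- matrix(c(3, 3, 8, 2), nrow = 1,
                  dimnames = list("g1", NULL))
  # constant gene at c with zero noise: pseudobulk exactly log2(c + 1)
  const <- simulate_single_cell(c("sA", "sB"), c("x", "y"),
                                c(sA = "R", sB = "NR"),
                                cells_per_group = 10,
                                group_means = matrix(c(3, 3), 1,
                                                     dimnames = list("g1",
                                                                     NULL)),
                                sigma_log = 0, seed = 1)
  pbc <- pseudobulk_aggregate(const)
  expect_true(all(abs(pbc$values - log2(4)) < 1e-12))

  big <- simulate_single_cell("sA", "x", c(sA = "R"),
                              cells_per_group = 1000,
                              group_means = matrix(8, 1,
                                                   dimnames = list("g1",
                                                                   NULL)),
                              sigma_log = 0.5, seed = 2)
  agg_mean <- 2^pseudobulk_aggregate(big)$values[1, 1] - 1
  expect_lt(abs(agg_mean - 8) / 8, 0.05)
})

test_that("single-cell generator refuses conflicting sample phenotypes", {
  map <- data.frame(sample_id = c("sA", "sA"), phenotype = c("R", "NR"))
  expect_error(
    simulate_single_cell("sA", "x", map, 5,
                         matrix(1, 1, dimnames = list("g1", NULL))),
    "conflict")
})

test_that("spatial simulation plants recoverable neighbor correlation", {
  labels <- data.frame(sample_id = "s1", f1 = "A", f2 = "early")
  for (seed in c(1, 2)) {
    ds <- simulate_spatial(labels, grid_n = 30,
                           rho = matrix(0.9, 1, dimnames = list("g1", NULL)),
                           seed = seed)
    r <- nn_correlation(as.matrix(ds$values), ds$cell_meta[, c("x", "y")])
    expect_gte(r[["g1"]], 0.8); expect_lte(r[["g1"]], 0.95)
    ds0 <- simulate_spatial(labels, grid_n = 30,
                            rho = matrix(0, 1, dimnames = list("g1", NULL)),
                            seed = seed)
    r0 <- nn_correlation(as.matrix(ds0$values), ds0$cell_meta[, c("x", "y")])
    expect_lt(abs(r0[["g1"]]), 0.15)
  }
  # perfect correlation with no independent noise component
  ds1 <- simulate_spatial(labels, grid_n = 10,
                          rho = matrix(1, 1, dimnames = list("g1", NULL)),
                          seed = 3)
  r1 <- nn_correlation(as.matrix(ds1$values), ds1$cell_meta[, c("x", "y")])
  expect_equal(unname(r1), 1, tolerance = 1e-12)
  expect_error(simulate_spatial(labels, grid_n = 5,
                                rho = matrix(1.4, 1)), "\\[-1, 1\\]")
})

test_that("recovery metrics report identity for a perfect classification", {
  sim <- simulate_two_way(n_per_category = 4, I = 2, J = 2, m = 3, seed = 20)
  fake <- sim$truth
  policy <- threshold_policy("alpha", 0.05)
  tab <- data.frame(gene_id = fake$gene_id, category = fake$category,
                    reason = NA_character_, stringsAsFactors = FALSE)
  gc <- idas:::new_gene_classification(tab, "two_way", policy, 0.05)
  rec <- recovery_metrics(sim$truth, gc)
  expect_true(all(diag(rec$confusion) == 4))
  expect_true(all(rec$recall == 1))
  expect_equal(rec$fdr_sig, 0)
  bad <- gc; bad$gene_id[1] <- "nope"
  expect_error(recovery_metrics(sim$truth, bad), "different gene sets")
})
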