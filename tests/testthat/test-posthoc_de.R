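test_that("group-contrast fits reproduce pooled two-sample formulas", {
  vals <- rbind(g1 = c(0, 0, 0, 1, 1, 1),
                g2 = c(1, 2, 3, 4, 5, 6))
  grp <- factor(rep(c("A", "B"), each = 3))
  fit <- fit_contrast(vals, grp, c(B = 1, A = -1))
  expect_equal(fit$beta, c(1, 3))
  expect_equal(fit$s2, c(0, 1))
  expect_equal(fit$df, c(4, 4))
  expect_equal(fit$v, rep(2 / 3, 2))
  expect_error(contrast_one_vs_rest(factor(rep("A", 3)), "A"),
               "at least two")
})

test_that("moderation prior estimation handles limit and error cases", {
  expect_error(estimate_moderation(runif(5), 4), "insufficient")
  same <- estimate_moderation(rep(2.5, 60), 6)
  expect_identical(same$d0, Inf)
  expect_equal(same$s0_sq, 2.5, tolerance = 1e-6)
})

test_that("moments estimator recovers a planted scaled-inv-chi-square prior", {
  d0_true <- 4; s0_true <- 1; d_g <- 6
  for (seed in c(1, 2)) {
    set.seed(seed)
    n <- 5000
    s2 <- d0_true * s0_true / rchisq(n, df = d0_true) *
      rchisq(n, df = d_g) / d_g
    est <- estimate_moderation(s2, d_g)
    expect_gte(est$d0, 2.5); expect_lte(est$d0, 6.5)
    expect_gte(est$s0_sq, 0.8); expect_lte(est$s0_sq, 1.25)
  }
})

test_that("moderated t has the right limits and plug-in arithmetic", {
  set.seed(8)
  n <- 50
  beta <- rnorm(n); s2 <- rchisq(n, 4) / 4; d <- 5; v <- 0.4
  # d0 = 0: ordinary t exactly
  mt0 <- moderated_t(beta, s2, d, v, list(d0 = 0, s0_sq = 1))
  t_ord <- beta / sqrt(s2 * v)
  expect_equal(mt0$t, t_ord, tolerance = 1e-12)
  expect_equal(mt0$p, 2 * pt(-abs(t_ord), df = d), tolerance = 1e-12)
  # d0 = Inf: common variance s0^2
  mtI <- moderated_t(beta, s2, d, v, list(d0 = Inf, s0_sq = 2))
  expect_true(all(mtI$s2_post == 2))
  expect_equal(mtI$p, 2 * pnorm(-abs(beta / sqrt(2 * v))), tolerance = 1e-12)
  # plug-in: d0 = 4, s0 = 1, s2 = 4, d = 4 -> s2_post = 2.5
  expect_equal(moderated_t(1, 4, 4, 1, list(d0 = 4, s0_sq = 1))$s2_post, 2.5)
})

test_that("variance shrinkage is contractive", {
  set.seed(15)
  s2 <- rchisq(200, 3)
  prm <- estimate_moderation(s2, 6)
  mt <- moderated_t(rnorm(200), s2, 6, 0.5, prm)
  expect_true(all(mt$s2_post >= pmin(s2, prm$s0_sq) - 1e-12))
  expect_true(all(mt$s2_post <= pmax(s2, prm$s0_sq) + 1e-12))
})

test_that("moderation agrees with the established empirical-Bayes implementation", {
  set.seed(23)
  n <- 400; d <- 6
  s2 <- 4 / rchisq(n, 4) * rchisq(n, d) / d
  ours <- estimate_moderation(s2, d)
  ref <- limma::squeezeVar(s2, df = d)
  expect_equal(ours$d0, ref$df.prior, tolerance = 1e-6)
  expect_equal(ours$s0_sq, ref$var.prior, tolerance = 1e-6)
  post <- moderated_t(rnorm(n), s2, d, 1, ours)
  expect_equal(post$s2_post, ref$var.post, tolerance = 1e-6)
})

test_that("DE p-values are invariant to permutation and constant shifts", {
  set.seed(19)
  vals <- matrix(rnorm(20 * 12), 20,
                 dimnames = list(sprintf("g%02d", 1:20), NULL))
  grp <- factor(rep(c("A", "B"), each = 6))
  base <- fit_contrast(vals, grp, c(B = 1, A = -1))
  perm <- sample(12)
  permd <- fit_contrast(vals[, perm], grp[perm], c(B = 1, A = -1))
  expect_equal(base$beta, permd$beta, tolerance = 1e-12)
  expect_equal(base$s2, permd$s2, tolerance = 1e-12)
  shifted <- fit_contrast(vals + 100, grp, c(B = 1, A = -1))
  expect_equal(base$beta, shifted$beta, tolerance = 1e-9)
  expect_equal(base$s2, shifted$s2, tolerance = 1e-9)
})

# pseudobulk with a planted state marker, a phenotype gene, an interaction
# gene and flat filler genes
marker_fixture <- function(seed = 77, n_filler = 30) {
  set.seed(seed)
  d <- observation_design(
    sprintf("o%d", 1:36),
    f1 = rep(c("mitotic", "stress", "antigen"), each = 12),
    f2 = rep(rep(c("NR", "R"), each = 6), 3))
  n <- 36
  Y <- matrix(rnorm(n_filler * n, sd = 0.2), n_filler, n)
  rownames(Y) <- sprintf("flat%02d", seq_len(n_filler))
  state_marker <- rnorm(n, sd = 0.2) + ifelse(d$f1 == "stress", 2, 0)
  pheno_gene <- rnorm(n, sd = 0.2) + ifelse(d$f2 == "R", 1, 0)
  inter_gene <- rnorm(n, sd = 0.2) +
    ifelse(d$f1 == "mitotic" & d$f2 == "R", 2, 0)
  Y <- rbind(Y, state_marker = state_marker, pheno_gene = pheno_gene,
             inter_gene = inter_gene)
  pseudobulk_matrix(Y + 5, d)
}

test_that("cell-state markers single out the planted state gene", {
  pb <- marker_fixture()
  res <- cellstate_markers(pb)
  stress <- res[res$state == "stress", ]
  top <- stress$gene_id[which.min(stress$p)]
  expect_identical(top, "state_marker")
  expect_equal(stress$log2FC[stress$gene_id == "state_marker"], 2,
               tolerance = 0.15)
  expect_true(stress$positive_marker[stress$gene_id == "state_marker"])
  flat <- res[res$gene_id == "flat01", ]
  expect_true(all(flat$padj > 0.05))
})

test_that("phenotype signature labels planted up-regulation and nulls", {
  pb <- marker_fixture()
  res <- phenotype_signature(pb, p_cut = 0.001, fc_cut = log2(1.5))
  expect_identical(res$label[res$gene_id == "pheno_gene"], "up-in-R")
  expect_lt(res$p[res$gene_id == "pheno_gene"], 0.001)
  expect_identical(res$label[res$gene_id == "flat01"], "below-threshold")
  # degenerate thresholds: every gene labeled by sign
  res2 <- phenotype_signature(pb, p_cut = 1.0000, fc_cut = 0)
  expect_true(all(res2$label[res2$log2FC > 0] == "up-in-R"))
})

test_that("interaction markers find state-specific phenotype genes", {
  pb <- marker_fixture()
  genes <- c("inter_gene", "state_marker", sprintf("flat%02d", 1:8))
  out <- interaction_markers(pb, genes, top_k = 3)
  mito <- out$state_markers[out$state_markers$state == "mitotic", ]
  expect_true("inter_gene" %in% mito$gene_id)
  hits <- out$markers[out$markers$selected, ]
  expect_true(any(hits$gene_id == "inter_gene" & hits$state == "mitotic" &
                    hits$phenotype == "R"))
  # a pure state marker survives step 1 for its state but not step 2
  stress_rows <- out$markers[out$markers$gene_id == "state_marker" &
                               out$markers$state == "stress", ]
  expect_true(nrow(stress_rows) == 0 || !any(stress_rows$selected))
})

test_that("top_k larger than the gene set keeps everything", {
  pb <- marker_fixture(n_filler = 10)
  out <- interaction_markers(pb, c("inter_gene", "flat01"), top_k = 50)
  expect_true(all(table(out$state_markers$state) == 2))
})

test_that("states covering a single phenotype are skipped with a warning", {
  d <- observation_design(sprintf("o%d", 1:10),
                          f1 = rep(c("x", "y"), each = 5),
                          f2 = c(rep("R", 5), rep(c("R", "NR"), length.out = 5)))
  set.seed(4)
  Y <- matrix(rnorm(12 * 10), 12, 10,
              dimnames = list(sprintf("g%02d", 1:12), NULL))
  pb <- pseudobulk_matrix(Y, d)
  expect_warning(out <- interaction_markers(pb, top_k = 2), "single phenotype")
  expect_false("x" %in% out$markers$state)
})
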