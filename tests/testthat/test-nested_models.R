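test_that("model specifications enforce term hierarchy", {
  expect_error(model_spec("f1:f2"), "requires")
  expect_error(model_spec(c("f1", "f2", "f1:f2:f3")), "requires")
  expect_silent(model_spec(c("f1", "f2", "f1:f2")))
  expect_length(two_way_models(), 5)
  expect_length(three_way_models(), 10)
  expect_true(all(vapply(three_way_models(), function(s) s$random_intercept,
                         logical(1))))
})

test_that("hand-derived 2x2 fixture reproduces exact RSS, df, F and p", {
  fx <- fixture_2x2()
  mods <- two_way_models()
  full <- fit_fixed(fx$y, fx$design, mods$m1)
  addv <- fit_fixed(fx$y, fx$design, mods$m2)
  aonly <- fit_fixed(fx$y, fx$design, mods$m3)
  expect_equal(full$rss, 8)
  expect_equal(full$df_resid, 4)
  expect_equal(addv$rss, 8)       # cell means exactly additive
  expect_equal(addv$df_resid, 5)
  expect_equal(aonly$rss, 10)
  expect_equal(aonly$df_resid, 6)

  t_int <- f_test_nested(full, addv)
  expect_equal(t_int$statistic, 0)
  expect_equal(t_int$p, 1)

  t_beta <- f_test_nested(addv, aonly)
  expect_equal(t_beta$statistic, 1.25)
  expect_equal(t_beta$df1, 1)
  expect_equal(t_beta$df2, 5)
  expect_equal(t_beta$p, pf(1.25, 1, 5, lower.tail = FALSE))
})

test_that("degenerate nested comparisons follow the declared conventions", {
  fx <- fixture_2x2()
  mods <- two_way_models()
  full <- fit_fixed(fx$y, fx$design, mods$m1)
  expect_equal(f_test_nested(full, full)$p, 1)    # reduced = full
  # constant response: zero RSS under every spec, comparison yields p = 1
  const <- lapply(mods, function(s) fit_fixed(rep(3, 8), fx$design, s))
  expect_true(all(vapply(const, function(f) f$rss, numeric(1)) < 1e-20))
  expect_equal(f_test_nested(const$m1, const$m5)$p, 1)
  # exact full fit with imperfect reduced fit: p = 0
  y_exact <- c(1, 1, 2, 2, 5, 5, 9, 9)  # interaction pattern, no noise
  f1 <- fit_fixed(y_exact, fx$design, mods$m1)
  f2 <- fit_fixed(y_exact, fx$design, mods$m2)
  expect_equal(f1$rss, 0)
  expect_gt(f2$rss, 0)
  expect_equal(f_test_nested(f1, f2)$p, 0)
})

test_that("F-tests match the pseudo-inverse brute-force oracle on random designs", {
  set.seed(42)
  mods <- two_way_models()
  for (rep in 1:20) {
    I <- sample(2:4, 1); J <- sample(2:4, 1)
    n <- sample((I * J + 2):40, 1)
    d <- random_design(I, J, n)
    y <- rnorm(n)
    full <- fit_fixed(y, d, mods$m1)
    red <- fit_fixed(y, d, mods$m2)
    if (red$df_resid <= full$df_resid || full$df_resid <= 0) next
    got <- f_test_nested(full, red)
    want <- oracle_f_test(idas:::spec_model_matrix(d, mods$m1),
                          idas:::spec_model_matrix(d, mods$m2), y)
    expect_equal(got$statistic, want$statistic, tolerance = 1e-8)
    expect_equal(got$p, want$p, tolerance = 1e-8)
  }
})

test_that("adding terms never increases RSS and relabeling never changes p", {
  set.seed(7)
  mods <- two_way_models()
  d <- random_design(3, 2, 24)
  y <- rnorm(24)
  rss <- vapply(mods, function(s) fit_fixed(y, d, s)$rss, numeric(1))
  expect_true(rss[["m1"]] <= rss[["m2"]] + 1e-9)
  expect_true(rss[["m2"]] <= rss[["m3"]] + 1e-9)
  expect_true(rss[["m2"]] <= rss[["m4"]] + 1e-9)
  expect_true(rss[["m3"]] <= rss[["m5"]] + 1e-9)

  p0 <- f_test_nested(fit_fixed(y, d, mods$m1),
                      fit_fixed(y, d, mods$m2))$p
  # relabel factor levels and permute observations
  perm <- sample(24)
  d2 <- observation_design(d$obs_id[perm],
                           f1 = paste0("Z", as.integer(d$f1))[perm],
                           f2 = paste0("Q", as.integer(d$f2))[perm])
  p1 <- f_test_nested(fit_fixed(y[perm], d2, mods$m1),
                      fit_fixed(y[perm], d2, mods$m2))$p
  expect_equal(p0, p1, tolerance = 1e-10)
})

test_that("rank-deficient designs drop inestimable columns", {
  # missing (b, v) combination
  d <- observation_design(sprintf("o%d", 1:9),
                          f1 = c("a", "a", "a", "a", "a", "a", "b", "b", "b"),
                          f2 = c("u", "u", "u", "v", "v", "v", "u", "u", "u"))
  mods <- two_way_models()
  set.seed(3)
  y <- rnorm(9)
  full <- fit_fixed(y, d, mods$m1)
  expect_identical(full$n_fixed_params, 3L)      # 3 non-empty cells
  expect_identical(full$df_resid, 6L)
})

test_that("ML mixed fits agree with the closed-form Gaussian likelihood when sigma_u = 0", {
  set.seed(11)
  d <- small_three_way_design(I = 3, J = 2, K = 2, n_subjects = 6)
  mods <- three_way_models()
  y <- rnorm(nrow(d))                  # no subject effect at all
  mf <- fit_mixed(y, d, mods$m6)
  expect_true(mf$converged)
  of <- fit_fixed(y, d, model_spec(c("f1", "f2", "f3")))
  ll_fixed <- gaussian_ml_loglik(of$rss, of$n_obs)
  expect_gte(mf$loglik, ll_fixed - 1e-6)
  expect_lt(mf$loglik - ll_fixed, 2)   # sigma_u estimate ~ 0

  # strong subject effect: random intercept must improve the likelihood
  u <- rnorm(6, sd = 3)
  y2 <- y + u[as.integer(d$subject)]
  mf2 <- fit_mixed(y2, d, mods$m6)
  of2 <- fit_fixed(y2, d, model_spec(c("f1", "f2", "f3")))
  expect_gt(mf2$loglik, gaussian_ml_loglik(of2$rss, of2$n_obs) + 2)
})

test_that("ML log-likelihoods are monotone under nesting", {
  set.seed(13)
  d <- small_three_way_design(I = 2, J = 2, K = 2, n_subjects = 4)
  y <- rnorm(nrow(d)) + rep(c(0, 1), each = nrow(d) / 2)
  mods <- three_way_models()
  ll <- vapply(mods, function(s) fit_mixed(y, d, s)$loglik, numeric(1))
  nested_pairs <- list(c("m1", "m2"), c("m2", "m3"), c("m2", "m4"),
                       c("m2", "m5"), c("m3", "m6"), c("m6", "m7"),
                       c("m6", "m8"), c("m6", "m9"), c("m7", "m10"))
  for (pr in nested_pairs) {
    expect_gte(ll[[pr[1]]], ll[[pr[2]]] - 1e-6)
  }
})

test_that("likelihood-ratio tests follow the chi-square reference", {
  f_full <- structure(list(loglik = -10, n_fixed_params = 2L, n_obs = 30L),
                      class = "idas_fit")
  f_red <- structure(list(loglik = -10 - 3.84 / 2, n_fixed_params = 1L,
                          n_obs = 30L), class = "idas_fit")
  out <- lrt_nested(f_full, f_red)
  expect_equal(out$deviance, 3.84)
  expect_equal(out$df, 1)
  expect_equal(out$p, pchisq(3.84, 1, lower.tail = FALSE))
  expect_lt(abs(out$p - 0.05), 1e-3)
  expect_equal(lrt_nested(f_full, f_full)$p, 1)
  # reduced fitting better than full only by numerical noise: clipped to 0
  f_red2 <- structure(list(loglik = -10 + 1e-9, n_fixed_params = 1L,
                           n_obs = 30L), class = "idas_fit")
  expect_equal(lrt_nested(f_full, f_red2)$deviance, 0)
})

test_that("a planted interaction is detected by the mixed LRT", {
  mods <- three_way_models()
  hits <- 0L
  for (seed in 1:10) {
    set.seed(seed)
    d <- small_three_way_design(I = 2, J = 2, K = 2, n_subjects = 6)
    abc <- idas:::draw_threeway(2, 2, 2, 1.5)   # effect/noise = 3
    y <- abc[cbind(as.integer(d$f1), as.integer(d$f2), as.integer(d$f3))] +
      rnorm(nrow(d), sd = 0.5) + rnorm(6, sd = 0.5)[as.integer(d$subject)]
    p <- lrt_nested(fit_mixed(y, d, mods$m1), fit_mixed(y, d, mods$m2))$p
    if (p < 0.01) hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})

test_that("fixed F and mixed LRT agree in decision under sigma_u = 0", {
  set.seed(21)
  d <- small_three_way_design(I = 2, J = 2, K = 2, n_subjects = 8)
  mods <- three_way_models()
  fixed_add <- model_spec(c("f1", "f2", "f3"))
  fixed_f1 <- model_spec("f1")
  agree <- 0L
  n_genes <- 40L
  for (g in seq_len(n_genes)) {
    beta <- if (g %% 2 == 0) c(0, 1.2) else c(0, 0)
    y <- beta[as.integer(d$f2)] + rnorm(nrow(d), sd = 1)
    p_f <- f_test_nested(fit_fixed(y, d, fixed_add),
                         fit_fixed(y, d, fixed_f1))$p
    p_l <- lrt_nested(fit_mixed(y, d, mods$m6), fit_mixed(y, d, mods$m7))$p
    if ((p_f <= 0.05) == (p_l <= 0.05)) agree <- agree + 1L
  }
  expect_gte(agree / n_genes, 0.9)
})

test_that("Satterthwaite block tests match the nested-pair hypotheses", {
  set.seed(31)
  d <- small_three_way_design(I = 3, J = 2, K = 2, n_subjects = 6)
  mods <- three_way_models()
  # planted f1 effect only: the f2/f3 block test (m6 vs m7) must not fire,
  # the blocks containing the missing factors must fire
  a <- c(-2, 0, 2)
  Y <- t(vapply(1:8, function(g) {
    a[as.integer(d$f1)] + rnorm(nrow(d), sd = 0.5) +
      rnorm(6, sd = 0.5)[as.integer(d$subject)]
  }, numeric(nrow(d))))
  rownames(Y) <- paste0("g", 1:8)
  p <- idas:::sat_stage_tests(Y, d, mods$m6,
                              list(main_f1 = mods$m7, main_f2 = mods$m8,
                                   main_f3 = mods$m9))
  expect_gte(mean(p[, "main_f1"] > 0.05), 6 / 8)  # f2+f3 block truly null
  expect_true(all(p[, "main_f2"] < 0.01))   # block includes f1
  expect_true(all(p[, "main_f3"] < 0.01))
})
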