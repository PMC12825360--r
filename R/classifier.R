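# Staged classification of genes by nested ANOVA model comparison.
#
# Two-way (fixed effects, F-tests), five categories:
#   stage 1  no-effect test      intercept-only vs full         -> non-sig
#   stage 2  interaction test    additive vs full               -> F1xF2
#   stage 3  main-effect tests   f2-only vs additive (f1 test),
#                                f1-only vs additive (f2 test)  -> F1 / F2
#   stage 4  remainder of the significant set                   -> F1+F2
#
# Three-way (random intercept, ML likelihood-ratio tests), ten categories:
#   stage 1  no-effect test      null vs full                   -> non-sig
#   stage 2  interaction test    additive vs full               -> Int/NotInt
#   stage 3  single-factor tests on NotInt: a gene is F1 when the f1-only
#            model is NOT contradicted (its test against the additive model
#            is not significant) while the f2-only and f3-only models ARE
#            contradicted; symmetrically F2, F3
#   stage 4  remaining NotInt                                   -> additive
#   stage 5  three-way test on Int: all-two-way vs full         -> F1xF2xF3
#   stage 6  two-way tests on the rest: dropping f1:f2 (or f2:f3, f1:f3)
#            from the all-two-way model; exactly one significant drop
#            -> F1xF2 / F2xF3 / F1xF3, otherwise two-way-combine
#
# Benjamini-Hochberg adjustment is computed within each stage across
# exactly the genes entering that stage; mixing stages would mix null
# distributions.

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment (wraps `stats::p.adjust`), with
#' input validation. `NA` entries are preserved and excluded from the
#' effective test count.
#'
#' @param pvals numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values, clipped at 1, order-consistent with the input.
#' @export
adjust_bh <- function(pvals) {
  p <- as.numeric(pvals)
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Significance-threshold policy
#'
#' `alpha` mode selects genes with (adjusted) p at or below `level`.
#' `quantile` mode — applicable to the stage-1 no-effect test only — selects
#' the `floor(level * m)` genes with the smallest (adjusted) p-values, with
#' boundary ties broken by lexicographic gene id for determinism.
#'
#' @param mode `"alpha"` or `"quantile"`.
#' @param level significance level or quantile fraction, in (0, 1).
#' @param use_adjusted apply the threshold to BH-adjusted (default) or raw
#'   p-values.
#' @return an object of class `idas_threshold_policy`.
#' @export
threshold_policy <- function(mode = c("alpha", "quantile"), level = 0.05,
                             use_adjusted = TRUE) {
  mode <- match.arg(mode)
  level <- as.numeric(level)
  if (!is.finite(level) || level <= 0 || level >= 1) {
    stop("level must lie strictly between 0 and 1")
  }
  structure(list(mode = mode, level = level,
                 use_adjusted = isTRUE(use_adjusted)),
            class = "idas_threshold_policy")
}

#' Select significant genes under a threshold policy
#'
#' @param pvals numeric vector (raw or adjusted, per the caller); `NA`
#'   entries are never selected.
#' @param policy a [threshold_policy()].
#' @param ids gene identifiers, required in quantile mode for the tie-break.
#' @return logical vector, `TRUE` where selected.
#' @export
select_significant <- function(pvals, policy, ids = NULL) {
  stopifnot(inherits(policy, "idas_threshold_policy"))
  p <- as.numeric(pvals)
  if (!length(p)) stop("empty p-value vector")
  if (policy$mode == "alpha") {
    out <- !is.na(p) & p <= policy$level
    return(out)
  }
  k <- floor(policy$level * length(p))
  out <- rep(FALSE, length(p))
  if (k == 0) return(out)
  if (is.null(ids)) ids <- sprintf("g%08d", seq_along(p))
  ord <- order(p, ids, na.last = TRUE)
  out[ord[seq_len(min(k, sum(!is.na(p))))]] <- TRUE
  out
}

# Decide significance at stages 2+ (always fixed-alpha) honouring the
# raw/adjusted choice of the policy.
stage_significant <- function(p_raw, p_adj, alpha, use_adjusted) {
  p <- if (use_adjusted) p_adj else p_raw
  !is.na(p) & p <= alpha
}

# Two-way per-stage p-values: F-test of reduced vs full over a gene subset.
# The fast path QR-factors each design once; genes with NA observations are
# fit individually on their complete cases. Untestable genes (residual df
# of the full model collapses to zero, or the df difference collapses)
# return NA.
fixed_stage_p <- function(Y, design, spec_full, spec_reduced) {
  n_genes <- nrow(Y)
  p <- rep(NA_real_, n_genes)
  complete <- !apply(is.na(Y), 1, any)
  if (any(complete)) {
    ff <- fit_fixed_matrix(Y[complete, , drop = FALSE], design, spec_full)
    fr <- fit_fixed_matrix(Y[complete, , drop = FALSE], design, spec_reduced)
    df1 <- fr$df_resid - ff$df_resid
    if (ff$df_resid > 0 && df1 > 0) {
      p[complete] <- f_test_p(ff$rss, ff$df_resid, fr$rss, df1)
    }
  }
  for (g in which(!complete)) {
    y <- Y[g, ]
    ok <- !is.na(y)
    if (sum(ok) < 3) next
    sub <- design[ok, , drop = FALSE]
    full <- fit_fixed(y[ok], sub, spec_full)
    red <- fit_fixed(y[ok], sub, spec_reduced)
    df1 <- red$df_resid - full$df_resid
    if (full$df_resid > 0 && df1 > 0) {
      p[g] <- f_test_p(full$rss, full$df_resid, red$rss, df1)
    }
  }
  p
}

row_var_zero <- function(Y) {
  apply(Y, 1, function(y) {
    y <- y[!is.na(y)]
    length(y) == 0 || max(y) - min(y) <= 1e-12 * max(1, abs(y[1]))
  })
}

#' Two-way gene classification
#'
#' Runs the staged two-way procedure (see the module header) on a
#' pseudobulk matrix whose design has factors `f1` and `f2`. Constant genes
#' are routed to `non-sig` with all stage p-values set to 1; genes that
#' become untestable at a stage (degrees of freedom collapse under missing
#' observations) are routed to `non-sig` with a reason code, preserving the
#' partition of the gene set.
#'
#' @param pb a `PseudobulkMatrix` (no `f3`, no random effect needed).
#' @param policy a [threshold_policy()]; quantile mode applies to stage 1
#'   only.
#' @param stage_alpha fixed significance level for stages 2+; defaults to
#'   `policy$level` in alpha mode and 0.05 in quantile mode.
#' @param verbose log per-stage gene counts via `message()`.
#' @return a `GeneClassification` with stage tests `no_effect`,
#'   `interaction`, `main_f1`, `main_f2`.
#' @export
classify_two_way <- function(pb, policy = threshold_policy("alpha", 0.05),
                             stage_alpha = NULL, verbose = FALSE) {
  stopifnot(inherits(pb, "PseudobulkMatrix"),
            inherits(policy, "idas_threshold_policy"))
  design <- pb$design
  if (has_f3(design)) {
    stop("design has an f3 factor; use classify_three_way")
  }
  if (nlevels(design$f1) < 2 || nlevels(design$f2) < 2) {
    stop("classification requires at least two levels of f1 and of f2")
  }
  if (is.null(stage_alpha)) {
    stage_alpha <- if (policy$mode == "alpha") policy$level else 0.05
  }
  mods <- two_way_models()
  Y <- pb$values
  ids <- pb$gene_ids
  n <- length(ids)
  tests <- c("no_effect", "interaction", "main_f1", "main_f2")
  p_raw <- matrix(NA_real_, n, length(tests), dimnames = list(ids, tests))
  p_adj <- p_raw
  category <- rep(NA_character_, n)
  reason <- rep(NA_character_, n)

  constant <- row_var_zero(Y)
  category[constant] <- "non-sig"
  reason[constant] <- "zero-variance"
  p_raw[constant, ] <- 1
  p_adj[constant, ] <- 1

  # stage 1: no-effect test, intercept-only vs full
  test1 <- !constant
  if (any(test1)) {
    p1 <- fixed_stage_p(Y[test1, , drop = FALSE], design, mods$m1, mods$m5)
    p_raw[test1, "no_effect"] <- p1
    p_adj[test1, "no_effect"] <- adjust_bh(p1)
    untestable1 <- test1 & is.na(p_raw[, "no_effect"])
    category[untestable1] <- "non-sig"
    reason[untestable1] <- "untestable-stage1"
  }
  pool <- if (policy$use_adjusted) p_adj[, "no_effect"] else
    p_raw[, "no_effect"]
  sig <- select_significant(pool, policy, ids = ids) & is.na(category)
  category[!sig & is.na(category)] <- "non-sig"
  if (verbose) message("stage 1: ", sum(sig), " / ", n, " genes significant")

  # stage 2: interaction test on the significant set
  if (any(sig)) {
    p2 <- fixed_stage_p(Y[sig, , drop = FALSE], design, mods$m1, mods$m2)
    p_raw[sig, "interaction"] <- p2
    p_adj[sig, "interaction"] <- adjust_bh(p2)
    int <- sig & stage_significant(p_raw[, "interaction"],
                                   p_adj[, "interaction"],
                                   stage_alpha, policy$use_adjusted)
    category[int] <- "F1xF2"
    untestable2 <- sig & is.na(p_raw[, "interaction"])
    category[untestable2] <- "non-sig"
    reason[untestable2] <- "untestable-stage2"
  } else int <- rep(FALSE, n)
  if (verbose) message("stage 2: ", sum(int), " interaction genes")

  # stage 3: main-effect tests on significant, non-interaction genes
  s3 <- sig & is.na(category)
  if (any(s3)) {
    pa <- fixed_stage_p(Y[s3, , drop = FALSE], design, mods$m2, mods$m4)
    pb_ <- fixed_stage_p(Y[s3, , drop = FALSE], design, mods$m2, mods$m3)
    p_raw[s3, "main_f1"] <- pa
    p_adj[s3, "main_f1"] <- adjust_bh(pa)
    p_raw[s3, "main_f2"] <- pb_
    p_adj[s3, "main_f2"] <- adjust_bh(pb_)
    c_alpha <- s3 & stage_significant(p_raw[, "main_f1"], p_adj[, "main_f1"],
                                      stage_alpha, policy$use_adjusted)
    c_beta <- s3 & stage_significant(p_raw[, "main_f2"], p_adj[, "main_f2"],
                                     stage_alpha, policy$use_adjusted)
    category[c_alpha & !c_beta] <- "F1"
    category[c_beta & !c_alpha] <- "F2"
    untestable3 <- s3 & (is.na(p_raw[, "main_f1"]) | is.na(p_raw[, "main_f2"]))
    category[untestable3] <- "non-sig"
    reason[untestable3] <- "untestable-stage3"
  }

  # stage 4: everything significant not yet assigned is additive
  category[is.na(category)] <- "F1+F2"
  if (verbose) {
    message("categories: ", paste(names(table(category)),
                                  table(category), sep = "=",
                                  collapse = " "))
  }
  finish_classification(ids, category, reason, p_raw, p_adj, "two_way",
                        policy, stage_alpha)
}

finish_classification <- function(ids, category, reason, p_raw, p_adj,
                                  design_type, policy, stage_alpha) {
  stopifnot(!anyNA(category))
  tab <- data.frame(gene_id = ids, category = category, reason = reason,
                    stringsAsFactors = FALSE)
  for (tn in colnames(p_raw)) {
    tab[[paste0("p_", tn)]] <- p_raw[, tn]
    tab[[paste0("padj_", tn)]] <- p_adj[, tn]
  }
  new_gene_classification(tab, design_type, policy, stage_alpha)
}

# Likelihood-ratio p-values for one stage of the three-way procedure over a
# gene subset (rows of Y). Both specs are fit by refitting a shared lmer
# template per gene.
mixed_stage_p <- function(Y, design, spec_full, spec_reduced) {
  ff <- fit_mixed_matrix(Y, design, spec_full)
  fr <- fit_mixed_matrix(Y, design, spec_reduced)
  p <- lrt_p(ff$loglik, ff$n_fixed_params, fr$loglik, fr$n_fixed_params)
  p[!(ff$ok & fr$ok)] <- NA_real_
  p
}

#' Three-way gene classification with a per-subject random intercept
#'
#' Runs the staged three-way procedure (see the module header) on a
#' pseudobulk matrix whose design has factors `f1`, `f2`, `f3` and a
#' `subject` grouping. Every stage compares two nested random-intercept
#' models. Two references for that comparison are offered:
#' `"satterthwaite"` (default) tests the dropped coefficient block of the
#' full model with an F-statistic on Satterthwaite-approximated denominator
#' degrees of freedom (per-gene REML fits via lmerTest), which stays
#' calibrated at small subject counts; `"lrt"` uses the maximum-likelihood
#' chi-square likelihood-ratio test, which is asymptotically equivalent but
#' anticonservative when observations and subjects are few. Genes whose
#' mixed fit fails at a stage are routed to `non-sig` with a reason code.
#'
#' Stage-3 note: a gene may fail (i.e. not reject) more than one
#' single-factor test; no unique single-factor model is then contradicted
#' and the gene is routed to `additive` with reason `ambiguous-main`.
#'
#' @inheritParams classify_two_way
#' @param pb a `PseudobulkMatrix` whose design includes `f3` and `subject`.
#' @param test `"satterthwaite"` or `"lrt"` (see above).
#' @return a `GeneClassification` with stage tests `no_effect`,
#'   `interaction`, `main_f1`, `main_f2`, `main_f3`, `threeway`,
#'   `int_f1f2`, `int_f2f3`, `int_f1f3`.
#' @export
classify_three_way <- function(pb, policy = threshold_policy("alpha", 0.05),
                               stage_alpha = NULL,
                               test = c("satterthwaite", "lrt"),
                               verbose = FALSE) {
  stopifnot(inherits(pb, "PseudobulkMatrix"),
            inherits(policy, "idas_threshold_policy"))
  test <- match.arg(test)
  design <- pb$design
  if (!has_f3(design)) stop("three-way classification requires an f3 factor")
  if (!has_subject(design)) {
    stop("three-way classification requires a subject grouping")
  }
  if (nlevels(design$f1) < 2 || nlevels(design$f2) < 2 ||
      nlevels(design$f3) < 2) {
    stop("classification requires at least two levels of f1, f2 and f3")
  }
  if (is.null(stage_alpha)) {
    stage_alpha <- if (policy$mode == "alpha") policy$level else 0.05
  }
  mods <- three_way_models()
  Y <- pb$values
  if (any(is.na(Y))) {
    stop("three-way classification does not support missing observations")
  }
  ids <- pb$gene_ids
  n <- length(ids)
  tests <- c("no_effect", "interaction", "main_f1", "main_f2", "main_f3",
             "threeway", "int_f1f2", "int_f2f3", "int_f1f3")
  p_raw <- matrix(NA_real_, n, length(tests), dimnames = list(ids, tests))
  p_adj <- p_raw
  category <- rep(NA_character_, n)
  reason <- rep(NA_character_, n)

  constant <- row_var_zero(Y)
  category[constant] <- "non-sig"
  reason[constant] <- "zero-variance"
  p_raw[constant, ] <- 1
  p_adj[constant, ] <- 1

  # Raw stage p-values for a batch of tests sharing one full model. The
  # Satterthwaite path fits the full model once per gene and tests each
  # dropped block on that fit; the LRT path fits full and reduced by ML.
  batch_p <- function(mask, full, drops) {
    if (!any(mask)) return(invisible(NULL))
    Ysub <- Y[mask, , drop = FALSE]
    p <- if (test == "satterthwaite") {
      sat_stage_tests(Ysub, design, full, drops)
    } else {
      vapply(drops, function(red) {
        mixed_stage_p(Ysub, design, full, red)
      }, numeric(sum(mask)))
    }
    p <- matrix(p, nrow = sum(mask), dimnames = list(NULL, names(drops)))
    for (name in names(drops)) {
      p_raw[mask, name] <<- p[, name]
      p_adj[mask, name] <<- adjust_bh(p[, name])
    }
    invisible(NULL)
  }
  sig_at <- function(name) {
    stage_significant(p_raw[, name], p_adj[, name], stage_alpha,
                      policy$use_adjusted)
  }
  route_failures <- function(mask, names, code) {
    bad <- mask & apply(is.na(p_raw[, names, drop = FALSE]), 1, any)
    category[bad] <<- "non-sig"
    reason[bad] <<- code
    invisible(NULL)
  }
  # stage-2/5 tests reuse the stage-1 full-model (m1) comparisons: p-values
  # computed for genes that never entered the stage are discarded, and the
  # BH adjustment is recomputed within the stage's entrants only
  restrict_stage <- function(entrants, name) {
    universe <- test1
    p_raw[universe & !entrants, name] <<- NA_real_
    p_adj[universe, name] <<- NA_real_
    p_adj[entrants, name] <<- adjust_bh(p_raw[entrants, name])
    invisible(NULL)
  }

  # stage 1: no-effect test (null vs full), plus the other m1-based blocks
  test1 <- !constant
  batch_p(test1, mods$m1, list(no_effect = mods$m10,
                               interaction = mods$m6,
                               threeway = mods$m2))
  route_failures(test1, "no_effect", "untestable-stage1")
  pool <- if (policy$use_adjusted) p_adj[, "no_effect"] else
    p_raw[, "no_effect"]
  sig <- select_significant(pool, policy, ids = ids) & is.na(category)
  category[!sig & is.na(category)] <- "non-sig"
  if (verbose) message("stage 1: ", sum(sig), " / ", n, " genes significant")

  # stage 2: any-interaction test (additive vs full) on the significant set
  keep_int <- sig & !is.na(p_raw[, "interaction"])
  restrict_stage(keep_int, "interaction")
  route_failures(sig, "interaction", "untestable-stage2")
  sig <- sig & is.na(category)
  int <- sig & sig_at("interaction")
  notint <- sig & !int
  if (verbose) message("stage 2: ", sum(int), " interaction / ",
                       sum(notint), " non-interaction genes")

  # stages 3-4: single-factor tests on the non-interaction set
  batch_p(notint, mods$m6, list(main_f1 = mods$m7,
                                main_f2 = mods$m8,
                                main_f3 = mods$m9))
  route_failures(notint, c("main_f1", "main_f2", "main_f3"),
                 "untestable-stage3")
  notint <- notint & is.na(category)
  r1 <- sig_at("main_f1"); r2 <- sig_at("main_f2"); r3 <- sig_at("main_f3")
  category[notint & !r1 & r2 & r3] <- "F1"
  category[notint & r1 & !r2 & r3] <- "F2"
  category[notint & r1 & r2 & !r3] <- "F3"
  n_fail <- as.integer(!r1) + as.integer(!r2) + as.integer(!r3)
  amb <- notint & is.na(category) & n_fail >= 2
  reason[amb] <- "ambiguous-main"
  category[notint & is.na(category)] <- "additive"

  # stage 5: three-way interaction test on the interaction set
  keep_three <- int & !is.na(p_raw[, "threeway"])
  restrict_stage(keep_three, "threeway")
  route_failures(int, "threeway", "untestable-stage5")
  int <- int & is.na(category)
  three <- int & sig_at("threeway")
  category[three] <- "F1xF2xF3"
  twoway <- int & !three

  # stage 6: which two-way interaction(s) are needed
  batch_p(twoway, mods$m2, list(int_f1f2 = mods$m3,
                                int_f2f3 = mods$m4,
                                int_f1f3 = mods$m5))
  route_failures(twoway, c("int_f1f2", "int_f2f3", "int_f1f3"),
                 "untestable-stage6")
  twoway <- twoway & is.na(category)
  iab <- sig_at("int_f1f2"); ibc <- sig_at("int_f2f3"); iac <- sig_at("int_f1f3")
  category[twoway & iab & !ibc & !iac] <- "F1xF2"
  category[twoway & ibc & !iab & !iac] <- "F2xF3"
  category[twoway & iac & !iab & !ibc] <- "F1xF3"
  category[twoway & is.na(category)] <- "two-way-combine"

  if (verbose) {
    message("categories: ", paste(names(table(category)),
                                  table(category), sep = "=",
                                  collapse = " "))
  }
  finish_classification(ids, category, reason, p_raw, p_adj, "three_way",
                        policy, stage_alpha)
}
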