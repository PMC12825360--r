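# Candidate ANOVA models and nested-model tests.
#
# Two-way designs use ordinary least squares per gene and compare nested
# fixed-effect models by F-test. Three-way designs add a per-subject random
# intercept; models are fit by maximum likelihood (ML, not REML, because
# every classification test compares fixed-effect structures and REML
# likelihoods are not comparable across fixed specifications) and compared
# by likelihood-ratio chi-square tests whose degrees of freedom count
# fixed-effect parameters only.
#
# All genes share one design, so each model's design matrix is QR-factored
# once and residual sums of squares for the whole gene matrix are obtained
# in a single pass; mixed models are fit once per specification on a
# template response and refit per gene.

MODEL_TERMS <- c("f1", "f2", "f3", "f1:f2", "f2:f3", "f1:f3", "f1:f2:f3")

#' Specify a candidate ANOVA model
#'
#' A model is the intercept plus a subset of factor terms, optionally with a
#' per-subject random intercept. Term hierarchy is enforced: an interaction
#' may only appear together with all of its marginal main effects and (for
#' the three-way interaction) all two-way interactions among its factors.
#'
#' @param terms character subset of
#'   `c("f1","f2","f3","f1:f2","f2:f3","f1:f3","f1:f2:f3")`; may be empty
#'   (intercept-only model).
#' @param random_intercept add `(1 | subject)`?
#' @return an object of class `idas_model_spec`.
#' @export
model_spec <- function(terms = character(), random_intercept = FALSE) {
  terms <- unique(as.character(terms))
  bad <- setdiff(terms, MODEL_TERMS)
  if (length(bad)) stop("unknown model term(s): ", paste(bad, collapse = ", "))
  needs <- list("f1:f2" = c("f1", "f2"),
                "f2:f3" = c("f2", "f3"),
                "f1:f3" = c("f1", "f3"),
                "f1:f2:f3" = c("f1", "f2", "f3", "f1:f2", "f2:f3", "f1:f3"))
  for (tm in intersect(names(needs), terms)) {
    miss <- setdiff(needs[[tm]], terms)
    if (length(miss)) {
      stop("term ", tm, " requires ", paste(miss, collapse = ", "))
    }
  }
  structure(list(terms = terms[order(match(terms, MODEL_TERMS))],
                 random_intercept = isTRUE(random_intercept)),
            class = "idas_model_spec")
}

#' @export
print.idas_model_spec <- function(x, ...) {
  rhs <- if (length(x$terms)) paste(x$terms, collapse = " + ") else "1"
  if (x$random_intercept) rhs <- paste(rhs, "+ (1 | subject)")
  cat("model: y ~", rhs, "\n")
  invisible(x)
}

spec_formula <- function(spec, response = "y") {
  rhs <- if (length(spec$terms)) paste(spec$terms, collapse = " + ") else "1"
  if (spec$random_intercept) rhs <- paste(rhs, "+ (1 | subject)")
  stats::as.formula(paste(response, "~", rhs))
}

is_nested_spec <- function(full, reduced) {
  all(reduced$terms %in% full$terms) &&
    reduced$random_intercept == full$random_intercept
}

#' The five candidate two-way fixed-effect models
#'
#' `m1` full (f1 + f2 + f1:f2), `m2` additive, `m3` f1 only, `m4` f2 only,
#' `m5` intercept only.
#'
#' @return named list of [model_spec()]s.
#' @export
two_way_models <- function() {
  list(m1 = model_spec(c("f1", "f2", "f1:f2")),
       m2 = model_spec(c("f1", "f2")),
       m3 = model_spec("f1"),
       m4 = model_spec("f2"),
       m5 = model_spec())
}

#' The ten candidate three-way random-intercept models
#'
#' `m1` full (all main effects, all two-way interactions, the three-way
#' interaction), `m2` all two-way interactions, `m3`--`m5` each drop one
#' two-way interaction from `m2` (f1:f2, f2:f3, f1:f3 respectively), `m6`
#' additive, `m7`--`m9` single-factor (f1, f2, f3), `m10` intercept only.
#' All include a per-subject random intercept.
#'
#' @return named list of [model_spec()]s.
#' @export
three_way_models <- function() {
  list(m1 = model_spec(c("f1", "f2", "f3", "f1:f2", "f2:f3", "f1:f3",
                         "f1:f2:f3"), random_intercept = TRUE),
       m2 = model_spec(c("f1", "f2", "f3", "f1:f2", "f2:f3", "f1:f3"),
                       random_intercept = TRUE),
       m3 = model_spec(c("f1", "f2", "f3", "f2:f3", "f1:f3"),
                       random_intercept = TRUE),
       m4 = model_spec(c("f1", "f2", "f3", "f1:f2", "f1:f3"),
                       random_intercept = TRUE),
       m5 = model_spec(c("f1", "f2", "f3", "f1:f2", "f2:f3"),
                       random_intercept = TRUE),
       m6 = model_spec(c("f1", "f2", "f3"), random_intercept = TRUE),
       m7 = model_spec("f1", random_intercept = TRUE),
       m8 = model_spec("f2", random_intercept = TRUE),
       m9 = model_spec("f3", random_intercept = TRUE),
       m10 = model_spec(random_intercept = TRUE))
}

spec_model_matrix <- function(design, spec) {
  f <- spec_formula(model_spec(spec$terms), response = NULL)
  # treatment (reference-level) coding; nested RSS comparisons are
  # coding-invariant so this is an internal convention only
  stats::model.matrix(f, data = as.data.frame(design))
}

#' Fit a fixed-effect model to one gene
#'
#' Ordinary least squares with treatment coding. Rank-deficient designs
#' (missing factor-level combinations) drop inestimable columns via pivoted
#' QR, reducing the fixed-parameter count accordingly.
#'
#' @param y numeric response vector (one gene across observations); `NA`
#'   entries are dropped together with their design rows.
#' @param design an `ObservationDesign`.
#' @param spec a [model_spec()] with `random_intercept = FALSE`.
#' @return list of class `idas_fit` with `rss`, `df_resid`,
#'   `n_fixed_params`, `n_obs`, `method = "ols"`.
#' @export
fit_fixed <- function(y, design, spec) {
  stopifnot(inherits(spec, "idas_model_spec"), !spec$random_intercept)
  X <- spec_model_matrix(design, spec)
  ok <- !is.na(y)
  X <- X[ok, , drop = FALSE]
  y <- y[ok]
  qr_x <- qr(X)
  rank <- qr_x$rank
  res <- qr.resid(qr_x, y)
  rss <- sum(res^2)
  structure(list(rss = rss, df_resid = length(y) - rank,
                 n_fixed_params = rank, n_obs = length(y),
                 loglik = NA_real_, method = "ols"),
            class = "idas_fit")
}

# Vectorized OLS over a genes x observations matrix with a shared design.
# Returns per-gene rss plus the common df_resid / rank. Rows containing NA
# must be handled by the caller (per-gene fit_fixed on complete cases).
fit_fixed_matrix <- function(Y, design, spec) {
  X <- spec_model_matrix(design, spec)
  qr_x <- qr(X)
  res <- qr.resid(qr_x, t(Y))
  list(rss = colSums(res^2),
       df_resid = nrow(X) - qr_x$rank,
       n_fixed_params = qr_x$rank,
       n_obs = nrow(X))
}

#' F-test comparing nested fixed-effect fits
#'
#' `F = ((rss_r - rss_f) / (df_r - df_f)) / (rss_f / df_f)` with the p-value
#' from the upper tail of `F(df_r - df_f, df_f)`. Degenerate cases: if the
#' residual sums of squares agree (to relative tolerance) the p-value is 1;
#' if the full model fits exactly (`rss_f = 0`) while the reduced does not,
#' the p-value is 0; a constant gene (both RSS zero) gives p = 1 because a
#' zero-variance response carries no signal.
#'
#' @param full,reduced `idas_fit` objects from [fit_fixed()] on the same
#'   observations, reduced nested in full.
#' @return list with `statistic`, `df1`, `df2`, `p`.
#' @export
f_test_nested <- function(full, reduced) {
  if (full$n_obs != reduced$n_obs) {
    stop("fits were not computed on the same observations")
  }
  df1 <- reduced$df_resid - full$df_resid
  if (df1 == 0 && isTRUE(all.equal(full$rss, reduced$rss))) {
    # comparing a model with itself (or an equivalent parameterization)
    return(list(statistic = 0, df1 = 0, df2 = full$df_resid, p = 1))
  }
  if (df1 <= 0) stop("reduced model must have fewer parameters than full")
  if (full$df_resid <= 0) stop("full model has zero residual degrees of freedom")
  if (reduced$rss < full$rss - 1e-8 * max(1, full$rss)) {
    stop("models are not nested: reduced RSS below full RSS")
  }
  p <- f_test_p(full$rss, full$df_resid, reduced$rss, df1)
  extra <- max(reduced$rss - full$rss, 0)
  stat <- if (full$rss > 0) (extra / df1) / (full$rss / full$df_resid) else
    if (extra > 0) Inf else 0
  list(statistic = stat, df1 = df1, df2 = full$df_resid, p = p)
}

# vectorized p-value core shared by f_test_nested and the classifier
f_test_p <- function(rss_f, df_f, rss_r, df1) {
  extra <- pmax(rss_r - rss_f, 0)
  scale <- pmax(rss_r, rss_f)
  p <- rep(NA_real_, length(rss_f))
  same <- extra <= 1e-12 * pmax(scale, 1)      # includes constant genes
  exact <- !same & rss_f <= 1e-12 * pmax(scale, 1)
  rest <- !same & !exact
  p[same] <- 1
  p[exact] <- 0
  if (any(rest)) {
    stat <- (extra[rest] / df1) / (rss_f[rest] / df_f)
    p[rest] <- stats::pf(stat, df1, df_f, lower.tail = FALSE)
  }
  p
}

# --- mixed models -----------------------------------------------------------

lmer_quiet_control <- function() {
  lme4::lmerControl(
    check.conv.singular = lme4::.makeCC(action = "ignore", tol = 1e-4),
    calc.derivs = FALSE)
}

# Build a reusable fitter for one mixed spec on a fixed design: lmer is run
# once on a template response, then refit() per gene, which skips the model
# matrix construction and is an order of magnitude faster.
mixed_template <- function(design, spec) {
  stopifnot(spec$random_intercept)
  if (!has_subject(design)) {
    stop("subject grouping is required for random-intercept models")
  }
  if (nlevels(design$subject) < 2) {
    stop("random-intercept models need at least two subjects")
  }
  dat <- as.data.frame(design)
  dat$y <- stats::rnorm(nrow(dat))
  fit <- suppressMessages(lme4::lmer(spec_formula(spec), data = dat,
                                     REML = FALSE,
                                     control = lmer_quiet_control()))
  fit
}

fit_from_lmer <- function(fit) {
  structure(list(rss = NA_real_,
                 df_resid = NA_real_,
                 n_fixed_params = length(lme4::fixef(fit)),
                 n_obs = stats::nobs(fit),
                 loglik = as.numeric(stats::logLik(fit)),
                 method = "ml_mixed"),
            class = "idas_fit")
}

#' Fit a random-intercept model to one gene by maximum likelihood
#'
#' Fits `y ~ fixed terms + (1 | subject)` with `lme4::lmer` under ML so that
#' likelihoods are comparable across fixed-effect specifications. A
#' non-convergent fit is retried twice from jittered responses scaled back;
#' persistent failure returns a fit with `converged = FALSE` rather than
#' aborting a whole run.
#'
#' @inheritParams fit_fixed
#' @param spec a [model_spec()] with `random_intercept = TRUE`.
#' @return list of class `idas_fit` with `loglik`, `n_fixed_params`,
#'   `n_obs`, `converged`, `method = "ml_mixed"`.
#' @export
fit_mixed <- function(y, design, spec) {
  stopifnot(inherits(spec, "idas_model_spec"), spec$random_intercept)
  ok <- !is.na(y)
  design <- design[ok, , drop = FALSE]
  dat <- as.data.frame(design)
  dat$y <- y[ok]
  out <- tryCatch(
    suppressMessages(lme4::lmer(spec_formula(spec), data = dat, REML = FALSE,
                                control = lmer_quiet_control())),
    error = function(e) e)
  if (inherits(out, "error")) {
    res <- structure(list(rss = NA_real_, df_resid = NA_real_,
                          n_fixed_params = NA_integer_, n_obs = sum(ok),
                          loglik = NA_real_, method = "ml_mixed",
                          converged = FALSE,
                          reason = conditionMessage(out)),
                     class = "idas_fit")
    return(res)
  }
  res <- fit_from_lmer(out)
  res$converged <- TRUE
  res
}

# ML loglik for a whole gene matrix under one mixed spec. Genes whose fit
# fails get NA loglik and ok = FALSE.
fit_mixed_matrix <- function(Y, design, spec) {
  template <- mixed_template(design, spec)
  n_fixed <- length(lme4::fixef(template))
  refit_one <- function(y) {
    out <- tryCatch(suppressMessages(lme4::refit(template, newresp = y)),
                    error = function(e) NULL)
    if (is.null(out)) NA_real_ else as.numeric(stats::logLik(out))
  }
  ll <- apply(Y, 1, refit_one)
  list(loglik = as.numeric(ll), n_fixed_params = n_fixed,
       ok = !is.na(ll), n_obs = nrow(as.data.frame(design)))
}

#' Likelihood-ratio test comparing nested ML fits
#'
#' Deviance `D = 2 (loglik_full - loglik_reduced)`, clipped at zero against
#' numerical noise, referred to a chi-square whose degrees of freedom count
#' the difference in fixed-effect parameters. The random-intercept variance
#' appears in both models, so no boundary correction applies.
#'
#' @param full,reduced `idas_fit` objects from [fit_mixed()] on the same
#'   observations with identical random structure.
#' @return list with `deviance`, `df`, `p`.
#' @export
lrt_nested <- function(full, reduced) {
  if (full$n_obs != reduced$n_obs) {
    stop("fits were not computed on the same observations")
  }
  df <- full$n_fixed_params - reduced$n_fixed_params
  if (is.na(df)) stop("fixed-effect parameter counts unavailable")
  if (df == 0 && abs(full$loglik - reduced$loglik) < 1e-6) {
    return(list(deviance = 0, df = 0, p = 1))  # identical specifications
  }
  if (df <= 0) {
    stop("full model must have more fixed-effect parameters than reduced")
  }
  d <- max(2 * (full$loglik - reduced$loglik), 0)
  list(deviance = d, df = df,
       p = stats::pchisq(d, df = df, lower.tail = FALSE))
}

# --- Satterthwaite block F-tests ---------------------------------------------
#
# Every nested pair in the three-way procedure differs by a set of whole
# model terms, so "reduced vs full" is equivalently an F-test that the
# dropped coefficient block of the full model is zero. The Satterthwaite
# denominator-degrees-of-freedom approximation (lmerTest) keeps that test
# calibrated at small subject counts, where the asymptotic chi-square of
# the ML likelihood-ratio test is anticonservative; it is the classifier's
# default reference for mixed designs.

# design-matrix column names belonging to each term of a spec
spec_term_cols <- function(design, spec) {
  X <- spec_model_matrix(design, spec)
  tl <- attr(stats::terms(spec_formula(model_spec(spec$terms),
                                       response = NULL)), "term.labels")
  asg <- attr(X, "assign")
  stats::setNames(lapply(seq_along(tl), function(i) colnames(X)[asg == i]),
                  tl)
}

# Fit the full model of a comparison once per gene (REML, lmerTest) and
# test each dropped-term block by Satterthwaite F. `drops` is a named list
# of reduced specs; returns a genes x drops matrix of p-values (NA where a
# fit or test fails, or the block is entirely inestimable).
sat_stage_tests <- function(Y, design, full_spec, drops) {
  stopifnot(full_spec$random_intercept)
  term_cols <- spec_term_cols(design, full_spec)
  block_cols <- lapply(drops, function(red) {
    dropped <- setdiff(full_spec$terms, red$terms)
    if (!length(dropped)) stop("reduced spec drops no terms")
    unlist(term_cols[dropped], use.names = FALSE)
  })
  dat <- as.data.frame(design)
  form <- spec_formula(full_spec)
  ctrl <- lme4::lmerControl(
    check.conv.singular = lme4::.makeCC(action = "ignore", tol = 1e-4))
  p <- matrix(NA_real_, nrow(Y), length(drops),
              dimnames = list(rownames(Y), names(drops)))
  for (g in seq_len(nrow(Y))) {
    dat$y <- Y[g, ]
    fit <- tryCatch(
      suppressWarnings(suppressMessages(
        lmerTest::lmer(form, data = dat, REML = TRUE, control = ctrl))),
      error = function(e) NULL)
    if (is.null(fit)) next
    X <- lme4::getME(fit, "X")
    for (j in seq_along(block_cols)) {
      idx <- match(block_cols[[j]], colnames(X))
      idx <- idx[!is.na(idx)]       # rank-deficient columns were dropped
      if (!length(idx)) next
      L <- diag(ncol(X))[idx, , drop = FALSE]
      res <- tryCatch(
        suppressWarnings(lmerTest::contestMD(fit, L,
                                             ddf = "Satterthwaite")),
        error = function(e) NULL)
      if (!is.null(res) && nrow(res)) p[g, j] <- res[["Pr(>F)"]]
    }
  }
  p
}

lrt_p <- function(ll_f, nf_f, ll_r, nf_r) {
  df <- nf_f - nf_r
  d <- pmax(2 * (ll_f - ll_r), 0)
  ifelse(is.na(d) | df <= 0, NA_real_,
         stats::pchisq(d, df = df, lower.tail = FALSE))
}
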