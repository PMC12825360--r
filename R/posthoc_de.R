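# Post-hoc differential expression per classified category, with
# empirical-Bayes variance moderation.
#
# The moderated t-statistic borrows strength across genes through a scaled
# inverse-chi-square prior on the residual variances: the prior (d0, s0^2)
# is estimated by method of moments on the log variances, the per-gene
# variance is shrunk to s~^2 = (d0 s0^2 + d s^2) / (d0 + d), and the
# t-statistic gains d0 extra degrees of freedom. d0 = 0 recovers the
# ordinary t; d0 = Inf pools all genes to a common variance.

#' Group-contrast OLS fit per gene
#'
#' Fits a cell-means model (one coefficient per group level) to every gene
#' and evaluates a linear contrast of the group means. This is the shared
#' engine behind cell-state markers, phenotype signatures and interaction
#' markers.
#'
#' @param values genes x observations matrix (log2 scale).
#' @param group factor of length `ncol(values)`.
#' @param contrast named numeric vector over (a subset of) group levels;
#'   unnamed levels get weight zero. The usual conventions: `c(A = 1, B =
#'   -1)` for a level-vs-level log2 fold change, or one-vs-rest weights
#'   `c(S = 1, rest = -1/(L-1))` built by [contrast_one_vs_rest()].
#' @return data.frame with one row per gene: `beta` (contrast estimate,
#'   log2FC), `s2` (residual variance), `df` (residual degrees of freedom,
#'   identical across genes), `v` (unscaled contrast variance
#'   `c' (X'X)^-1 c`, identical across genes).
#' @export
fit_contrast <- function(values, group, contrast) {
  values <- as.matrix(values)
  group <- droplevels(as.factor(group))
  if (length(group) != ncol(values)) {
    stop("group length must match the number of observations")
  }
  if (nlevels(group) < 2) {
    stop("contrast requires at least two group levels")
  }
  bad <- setdiff(names(contrast), levels(group))
  if (length(bad)) {
    stop("contrast names absent from the group levels: ",
         paste(bad, collapse = ", "))
  }
  cvec <- stats::setNames(rep(0, nlevels(group)), levels(group))
  cvec[names(contrast)] <- contrast
  if (all(cvec == 0)) stop("contrast is identically zero")
  n_per <- table(group)
  if (any(n_per[names(cvec)[cvec != 0]] == 0)) {
    stop("contrast involves an empty group level")
  }
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("gene%d", seq_len(nrow(values)))
  }
  means <- t(apply(values, 1, function(y) tapply(y, group, mean)))
  beta <- as.numeric(means %*% cvec)
  df <- ncol(values) - nlevels(group)
  if (df < 1) stop("no residual degrees of freedom for the contrast fit")
  fitted <- means[, as.integer(group), drop = FALSE]
  s2 <- rowSums((values - fitted)^2) / df
  v <- sum(cvec^2 / as.numeric(n_per))
  data.frame(gene_id = rownames(values), beta = beta, s2 = as.numeric(s2),
             df = df, v = v, stringsAsFactors = FALSE, row.names = NULL)
}

#' One-vs-rest contrast weights
#'
#' @param group factor of group labels.
#' @param level the focal level.
#' @return named contrast vector: +1 on `level`, `-1/(L-1)` on each other
#'   level, so `beta` is the focal mean minus the average of the other
#'   group means.
#' @export
contrast_one_vs_rest <- function(group, level) {
  lv <- levels(droplevels(as.factor(group)))
  if (!level %in% lv) stop("unknown group level: ", level)
  if (length(lv) < 2) {
    stop("one-vs-rest contrast needs at least two group levels")
  }
  w <- stats::setNames(rep(-1 / (length(lv) - 1), length(lv)), lv)
  w[level] <- 1
  w
}

#' Estimate the variance prior by method of moments
#'
#' Fits a scaled inverse-chi-square prior to the ensemble of per-gene
#' residual variances, working on log variances: with
#' `e_g = log(s2_g) - digamma(d_g/2) + log(d_g/2)`, the excess of `var(e)`
#' over `mean(trigamma(d_g/2))` identifies the prior degrees of freedom
#' `d0` through the inverse trigamma, and the adjusted mean of `e`
#' identifies `s0^2`. Zero excess (or less) yields `d0 = Inf` with
#' `s0^2 = exp(mean(e))`, i.e. no evidence of variance heterogeneity beyond
#' sampling noise.
#'
#' @param s2 per-gene residual variances; zeros are excluded from
#'   estimation.
#' @param df per-gene residual degrees of freedom (recycled if scalar).
#' @return list of class `idas_moderation` with `d0` and `s0_sq`.
#' @export
estimate_moderation <- function(s2, df) {
  s2 <- as.numeric(s2)
  df <- rep_len(as.numeric(df), length(s2))
  keep <- is.finite(s2) & s2 > 0 & df >= 1
  if (sum(keep) < 10) {
    stop("insufficient genes for moderation (need >= 10 with positive ",
         "variance and df >= 1)")
  }
  s2 <- s2[keep]; df <- df[keep]
  e <- log(s2) - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  evar <- stats::var(e) - mean(trigamma(df / 2))
  if (is.finite(evar) && evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s0_sq <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    # no dispersion beyond sampling noise: infinite prior df, and the prior
    # variance is simply the mean observed variance
    d0 <- Inf
    s0_sq <- mean(s2)
  }
  structure(list(d0 = d0, s0_sq = s0_sq), class = "idas_moderation")
}

# Newton solve of trigamma(y) = x on y > 0 (monotone decreasing).
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2L)
    y <- y + dif
    if (-dif / y < 1e-8) break
  }
  y
}

#' Moderated t-statistics and p-values
#'
#' @param beta contrast estimates (log2FC).
#' @param s2 per-gene residual variances.
#' @param df per-gene residual degrees of freedom.
#' @param v unscaled contrast variance.
#' @param params an `idas_moderation` prior from [estimate_moderation()],
#'   or a list with `d0`, `s0_sq` (use `d0 = 0` for ordinary t-tests).
#' @return data.frame with `s2_post` (shrunken variance), `t` (moderated
#'   t), `df_total` (`df + d0`), `p` (two-sided; normal reference when
#'   `d0 = Inf`). A gene with zero shrunken variance and nonzero `beta`
#'   gets `p = 0` and `t = +-Inf` (arises in noiseless fixtures).
#' @export
moderated_t <- function(beta, s2, df, v, params) {
  d0 <- params$d0
  s0 <- params$s0_sq
  if (is.null(d0) || is.null(s0) || d0 < 0 || s0 < 0) {
    stop("invalid moderation parameters")
  }
  n <- length(beta)
  s2 <- rep_len(as.numeric(s2), n)
  df <- rep_len(as.numeric(df), n)
  v <- rep_len(as.numeric(v), n)
  s2_post <- if (is.infinite(d0)) rep_len(s0, n) else
    (d0 * s0 + df * s2) / (d0 + df)
  se <- sqrt(s2_post * v)
  t <- ifelse(se > 0, beta / se, ifelse(beta == 0, 0, sign(beta) * Inf))
  df_total <- df + d0
  p <- ifelse(is.infinite(df_total),
              2 * stats::pnorm(-abs(t)),
              2 * stats::pt(-abs(t), df = df_total))
  p[is.infinite(t)] <- 0
  p[se == 0 & beta == 0] <- 1
  data.frame(s2_post = s2_post, t = t, df_total = df_total, p = p)
}

# Shared path: contrast fit + moderation + BH. Falls back to ordinary t
# (d0 = 0) with a warning when too few genes support prior estimation.
de_table <- function(values, group, contrast, contrast_label,
                     params = NULL) {
  fit <- fit_contrast(values, group, contrast)
  if (is.null(params)) {
    params <- tryCatch(estimate_moderation(fit$s2, fit$df),
                       error = function(e) {
                         warning("falling back to ordinary t-tests: ",
                                 conditionMessage(e), call. = FALSE)
                         list(d0 = 0, s0_sq = mean(fit$s2))
                       })
  }
  mt <- moderated_t(fit$beta, fit$s2, fit$df, fit$v, params)
  data.frame(gene_id = fit$gene_id, contrast = contrast_label,
             log2FC = fit$beta, s2 = fit$s2, df = fit$df,
             s2_post = mt$s2_post, t = mt$t, df_total = mt$df_total,
             p = mt$p, padj = adjust_bh(mt$p),
             stringsAsFactors = FALSE)
}

#' Cell-state markers from main-effect (F1) genes
#'
#' One-vs-rest moderated-t contrast of every `f1` (cell-state) level,
#' restricted to the supplied genes (typically the `F1` category of a
#' classification). BH adjustment is applied within each state; positive
#' markers (`log2FC > 0`) are flagged, matching the convention used for
#' downstream enrichment input.
#'
#' @param pb a `PseudobulkMatrix`.
#' @param genes gene ids to test (default: all genes in `pb`).
#' @return data.frame of `DEResult` rows per (gene, state) with columns
#'   `gene_id`, `state`, `log2FC`, `s2`, `df`, `s2_post`, `t`, `df_total`,
#'   `p`, `padj`, `positive_marker`. States with fewer than two
#'   observations are excluded with a warning.
#' @export
cellstate_markers <- function(pb, genes = NULL) {
  stopifnot(inherits(pb, "PseudobulkMatrix"))
  values <- subset_genes(pb, genes)
  group <- droplevels(pb$design$f1)
  if (nlevels(group) < 2) stop("cell-state markers need at least two states")
  out <- list()
  for (st in levels(group)) {
    if (sum(group == st) < 2) {
      warning("state '", st, "' has fewer than two observations; excluded")
      next
    }
    tab <- de_table(values, group, contrast_one_vs_rest(group, st),
                    paste0(st, "_vs_rest"))
    tab$state <- st
    out[[st]] <- tab
  }
  if (!length(out)) stop("no state has enough observations")
  res <- do.call(rbind, out)
  res$positive_marker <- res$log2FC > 0
  rownames(res) <- NULL
  res
}

#' Phenotype signature from main-effect (F2) genes
#'
#' Level-vs-level moderated-t contrast of the phenotype factor across all
#' observations, restricted to the supplied genes (typically the `F2`
#' category). With two phenotype levels each gene is labeled
#' `up-in-<level2>`, `up-in-<level1>` or `below-threshold` using a raw
#' p-value cutoff and an absolute log2 fold-change cutoff.
#'
#' @param pb a `PseudobulkMatrix`.
#' @param genes gene ids to test (default all).
#' @param p_cut raw p-value threshold (default 0.001).
#' @param fc_cut absolute log2FC threshold (default `log2(1.5)`).
#' @return data.frame per gene with the contrast columns plus `label`.
#' @export
phenotype_signature <- function(pb, genes = NULL, p_cut = 0.001,
                                fc_cut = log2(1.5)) {
  stopifnot(inherits(pb, "PseudobulkMatrix"))
  values <- subset_genes(pb, genes)
  group <- droplevels(pb$design$f2)
  if (nlevels(group) != 2) {
    stop("the signed phenotype signature requires exactly two phenotype ",
         "levels")
  }
  lv <- levels(group)
  tab <- de_table(values, group,
                  stats::setNames(c(-1, 1), lv),
                  paste0(lv[2], "_vs_", lv[1]))
  tab$label <- ifelse(tab$p < p_cut & tab$log2FC > fc_cut,
                      paste0("up-in-", lv[2]),
                      ifelse(tab$p < p_cut & tab$log2FC < -fc_cut,
                             paste0("up-in-", lv[1]), "below-threshold"))
  tab
}

#' Cell-state-specific phenotype markers from interaction genes
#'
#' Two-step interpretation of the interaction category: (1) within the
#' interaction gene set, rank genes per cell state by their one-vs-rest
#' moderated-t p-value (ties by decreasing `|log2FC|`, then gene id) and
#' keep the top `top_k` marker genes of each state; (2) for each kept
#' (gene, state), contrast the two phenotype levels within that state's
#' observations; (3) report the (gene, state, phenotype) triples passing
#' the thresholds as state-specific phenotype markers.
#'
#' @param pb a `PseudobulkMatrix` with two `f2` levels.
#' @param genes interaction-category gene ids (default all).
#' @param top_k markers retained per state in step 1 (default 10).
#' @param p_cut,fc_cut step-2 thresholds on raw p and absolute log2FC
#'   (defaults 0.001 and `log2(1.5)`).
#' @return list with `state_markers` (step-1 table with `rank` per state)
#'   and `markers` (step-2 table with `phenotype`, the level the gene is up
#'   in, and `selected` flagging triples passing both thresholds). States
#'   whose observations cover only one phenotype are skipped with a
#'   warning.
#' @export
interaction_markers <- function(pb, genes = NULL, top_k = 10,
                                p_cut = 0.001, fc_cut = log2(1.5)) {
  stopifnot(inherits(pb, "PseudobulkMatrix"), top_k >= 1)
  values <- subset_genes(pb, genes)
  design <- pb$design
  states <- droplevels(design$f1)
  phen <- droplevels(design$f2)
  if (nlevels(phen) != 2) {
    stop("interaction markers require exactly two phenotype levels")
  }
  step1 <- cellstate_markers(pb, genes)
  keep <- list()
  for (st in unique(step1$state)) {
    sub <- step1[step1$state == st, ]
    ord <- order(sub$p, -abs(sub$log2FC), sub$gene_id)
    sub <- sub[ord[seq_len(min(top_k, nrow(sub)))], ]
    sub$rank <- seq_len(nrow(sub))
    keep[[st]] <- sub
  }
  step1_kept <- do.call(rbind, keep)
  rownames(step1_kept) <- NULL

  lv <- levels(phen)
  out <- list()
  for (st in unique(step1_kept$state)) {
    in_state <- states == st
    ph <- droplevels(phen[in_state])
    if (nlevels(ph) < 2) {
      warning("state '", st, "' has observations from a single phenotype; ",
              "skipped")
      next
    }
    if (sum(in_state) - 2 < 1) {
      warning("state '", st, "' lacks residual degrees of freedom for the ",
              "within-state contrast; skipped")
      next
    }
    gsel <- step1_kept$gene_id[step1_kept$state == st]
    tab <- de_table(values[gsel, , drop = FALSE][, in_state, drop = FALSE],
                    ph, stats::setNames(c(-1, 1), lv),
                    paste0(st, ":", lv[2], "_vs_", lv[1]))
    tab$state <- st
    tab$phenotype <- ifelse(tab$log2FC > 0, lv[2], lv[1])
    tab$selected <- tab$p < p_cut & abs(tab$log2FC) > fc_cut
    out[[st]] <- tab
  }
  markers <- if (length(out)) do.call(rbind, out) else
    data.frame()
  rownames(markers) <- NULL
  list(state_markers = step1_kept, markers = markers)
}

subset_genes <- function(pb, genes) {
  if (is.null(genes)) return(pb$values)
  genes <- as.character(genes)
  missing <- setdiff(genes, pb$gene_ids)
  if (length(missing)) {
    stop("gene id(s) absent from the pseudobulk matrix: ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  pb$values[genes, , drop = FALSE]
}

#' Write a differential-expression table
#'
#' @param de data.frame from [cellstate_markers()], [phenotype_signature()]
#'   or the `markers` element of [interaction_markers()].
#' @param path output path (TSV).
#' @export
write_de <- function(de, path) {
  utils::write.table(de, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}
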