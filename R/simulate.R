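# Synthetic data with known per-gene ground truth.
#
# Each planted category is generated from its own generative ANOVA model:
# factor offsets are drawn from centered normals, recentered to sum to zero
# within every margin (so the categories are identifiable) and rescaled to
# root-mean-square `effect_sd` (so "effect size" means the same thing for
# every gene and factor); Gaussian noise (and, for three-way designs, a
# Gaussian subject intercept) is added on top. Everything is deterministic
# under a seed.

#' Per-gene simulation ground truth
#'
#' data.frame of class `SimTruth` with columns `gene_id` and `category`;
#' the per-gene effect parameters (offset vectors/tables, `noise_sd`,
#' `sigma_u`, `seed`) are stored in the `effects` attribute, a named list.
#'
#' @name SimTruth
NULL

new_sim_truth <- function(gene_ids, categories, effects, noise_sd,
                          sigma_u = 0, seed = NA_integer_) {
  structure(data.frame(gene_id = gene_ids, category = categories,
                       stringsAsFactors = FALSE),
            class = c("SimTruth", "data.frame"),
            effects = effects, noise_sd = noise_sd, sigma_u = sigma_u,
            seed = seed)
}

# centered, RMS-normalized offset vector
draw_offsets <- function(k, sd) {
  repeat {
    v <- stats::rnorm(k)
    v <- v - mean(v)
    rms <- sqrt(mean(v^2))
    if (rms > 1e-8) return(v * sd / rms)
  }
}

# doubly-centered, RMS-normalized interaction table
draw_interaction <- function(k1, k2, sd) {
  repeat {
    m <- matrix(stats::rnorm(k1 * k2), k1, k2)
    m <- m - rowMeans(m)[row(m)] - colMeans(m)[col(m)] + mean(m)
    rms <- sqrt(mean(m^2))
    if (rms > 1e-8) return(m * sd / rms)
  }
}

# triply-centered three-way interaction array: apply the centering operator
# along each dimension so every margin sums to zero, then RMS-normalize
draw_threeway <- function(k1, k2, k3, sd) {
  center_dim <- function(a, d) sweep(a, setdiff(1:3, d), apply(a, setdiff(1:3, d), mean))
  repeat {
    a <- array(stats::rnorm(k1 * k2 * k3), dim = c(k1, k2, k3))
    for (d in 1:3) a <- center_dim(a, d)
    rms <- sqrt(mean(a^2))
    if (rms > 1e-8) return(a * sd / rms)
  }
}

#' Simulate a two-way pseudobulk dataset with planted categories
#'
#' Generates a balanced I x J design with m replicates per cell and
#' `n_per_category` genes for each of the five two-way categories. A gene's
#' category determines which terms are nonzero: `F1` genes carry only f1
#' offsets, `F1+F2` genes carry both main effects without interaction,
#' `F1xF2` genes carry main effects plus a doubly-centered interaction
#' table, `non-sig` genes are pure noise around the baseline.
#'
#' @param n_per_category genes per category (default 200).
#' @param I,J,m factor-level counts and replicates (defaults 5, 2, 6).
#' @param effect_sd root-mean-square size of every planted offset vector
#'   (default 2).
#' @param noise_sd residual standard deviation (default 0.5).
#' @param mu baseline log2 expression (default 5).
#' @param seed integer seed; identical inputs give byte-identical output.
#' @param categories subset of category labels to plant (default all five);
#'   e.g. `"non-sig"` alone yields a global-null dataset.
#' @return list with `pseudobulk` (a `PseudobulkMatrix`) and `truth` (a
#'   `SimTruth`).
#' @export
simulate_two_way <- function(n_per_category = 200, I = 5, J = 2, m = 6,
                             effect_sd = 2, noise_sd = 0.5, mu = 5,
                             seed = 1, categories = two_way_categories()) {
  if (I < 2 || J < 2 || m < 2) stop("need I >= 2, J >= 2, m >= 2")
  if (effect_sd <= 0 || noise_sd <= 0) {
    stop("effect_sd and noise_sd must be positive")
  }
  if (!all(categories %in% two_way_categories())) {
    stop("unknown category label(s)")
  }
  set.seed(seed)
  grid <- expand.grid(rep = seq_len(m), f2 = seq_len(J), f1 = seq_len(I))
  obs_ids <- sprintf("i%d.j%d.r%d", grid$f1, grid$f2, grid$rep)
  design <- observation_design(obs_ids,
                               f1 = paste0("s", grid$f1),
                               f2 = paste0("p", grid$f2))
  cats <- categories
  n_genes <- n_per_category * length(cats)
  gene_ids <- sprintf("gene%04d", seq_len(n_genes))
  categories <- rep(cats, each = n_per_category)
  Y <- matrix(NA_real_, n_genes, nrow(grid),
              dimnames = list(gene_ids, obs_ids))
  effects <- vector("list", n_genes)
  names(effects) <- gene_ids
  for (g in seq_len(n_genes)) {
    cat_g <- categories[g]
    a <- if (cat_g %in% c("F1", "F1+F2", "F1xF2")) draw_offsets(I, effect_sd)
         else numeric(I)
    b <- if (cat_g %in% c("F2", "F1+F2", "F1xF2")) draw_offsets(J, effect_sd)
         else numeric(J)
    ab <- if (cat_g == "F1xF2") draw_interaction(I, J, effect_sd)
          else matrix(0, I, J)
    mu_cell <- mu + a[grid$f1] + b[grid$f2] + ab[cbind(grid$f1, grid$f2)]
    Y[g, ] <- mu_cell + stats::rnorm(nrow(grid), sd = noise_sd)
    effects[[g]] <- list(alpha = a, beta = b, ab = ab)
  }
  list(pseudobulk = pseudobulk_matrix(Y, design),
       truth = new_sim_truth(gene_ids, categories, effects, noise_sd,
                             seed = seed))
}

#' Simulate a three-way pseudobulk dataset with a subject random intercept
#'
#' Balanced design: `n_subjects` subjects are split evenly over the J
#' levels of the between-subject factor `f2`; each subject contributes `m`
#' replicate observations for every (f1, f3) combination. Gene categories
#' span the ten three-way labels; `two-way-combine` genes carry two of the
#' three two-way interactions (f1:f2 and f2:f3), `F1xF2xF3` genes carry a
#' triply-centered three-way interaction on top of the main effects.
#'
#' @inheritParams simulate_two_way
#' @param K number of f3 levels (default 2).
#' @param n_subjects number of subjects (default 8; must be >= J).
#' @param m replicates per subject per (f1, f3) combination (default 1).
#' @param sigma_u subject random-intercept standard deviation (default 0.5).
#' @return list with `pseudobulk` and `truth`, as [simulate_two_way()].
#' @export
simulate_three_way <- function(n_per_category = 200, I = 5, J = 2, K = 2,
                               n_subjects = 8, m = 1, effect_sd = 2,
                               noise_sd = 0.5, sigma_u = 0.5, mu = 5,
                               seed = 1) {
  if (I < 2 || J < 2 || K < 2) stop("need I, J, K >= 2")
  if (n_subjects < max(2, J)) stop("need at least max(2, J) subjects")
  if (sigma_u < 0) stop("sigma_u must be non-negative")
  set.seed(seed)
  subj_pheno <- rep_len(seq_len(J), n_subjects)  # balanced when J | N
  grid <- expand.grid(rep = seq_len(m), f3 = seq_len(K), f1 = seq_len(I),
                      subject = seq_len(n_subjects))
  grid$f2 <- subj_pheno[grid$subject]
  obs_ids <- sprintf("n%d.i%d.k%d.r%d", grid$subject, grid$f1, grid$f3,
                     grid$rep)
  design <- observation_design(obs_ids,
                               f1 = paste0("s", grid$f1),
                               f2 = paste0("p", grid$f2),
                               f3 = paste0("t", grid$f3),
                               subject = paste0("n", grid$subject))
  cats <- three_way_categories()
  terms_for <- list(
    "F1" = "a", "F2" = "b", "F3" = "c",
    "additive" = c("a", "b", "c"),
    "F1xF2" = c("a", "b", "ab"),
    "F2xF3" = c("b", "c", "bc"),
    "F1xF3" = c("a", "c", "ac"),
    "two-way-combine" = c("a", "b", "c", "ab", "bc"),
    "F1xF2xF3" = c("a", "b", "c", "abc"),
    "non-sig" = character())
  n_genes <- n_per_category * length(cats)
  gene_ids <- sprintf("gene%04d", seq_len(n_genes))
  categories <- rep(cats, each = n_per_category)
  Y <- matrix(NA_real_, n_genes, nrow(grid),
              dimnames = list(gene_ids, obs_ids))
  effects <- vector("list", n_genes)
  names(effects) <- gene_ids
  for (g in seq_len(n_genes)) {
    tm <- terms_for[[categories[g]]]
    a <- if ("a" %in% tm) draw_offsets(I, effect_sd) else numeric(I)
    b <- if ("b" %in% tm) draw_offsets(J, effect_sd) else numeric(J)
    cc <- if ("c" %in% tm) draw_offsets(K, effect_sd) else numeric(K)
    ab <- if ("ab" %in% tm) draw_interaction(I, J, effect_sd) else
      matrix(0, I, J)
    bc <- if ("bc" %in% tm) draw_interaction(J, K, effect_sd) else
      matrix(0, J, K)
    ac <- if ("ac" %in% tm) draw_interaction(I, K, effect_sd) else
      matrix(0, I, K)
    abc <- if ("abc" %in% tm) draw_threeway(I, J, K, effect_sd) else
      array(0, dim = c(I, J, K))
    u <- stats::rnorm(n_subjects, sd = sigma_u)
    mu_cell <- mu + a[grid$f1] + b[grid$f2] + cc[grid$f3] +
      ab[cbind(grid$f1, grid$f2)] + bc[cbind(grid$f2, grid$f3)] +
      ac[cbind(grid$f1, grid$f3)] + abc[cbind(grid$f1, grid$f2, grid$f3)] +
      u[grid$subject]
    Y[g, ] <- mu_cell + stats::rnorm(nrow(grid), sd = noise_sd)
    effects[[g]] <- list(alpha = a, beta = b, gamma = cc, ab = ab, bc = bc,
                         ac = ac, abc = abc, u = u)
  }
  list(pseudobulk = pseudobulk_matrix(Y, design),
       truth = new_sim_truth(gene_ids, categories, effects, noise_sd,
                             sigma_u = sigma_u, seed = seed))
}

#' Simulate a single-cell dataset around planted group means
#'
#' Per-cell expression is lognormal noise around the planted group mean,
#' scaled so the expectation equals the mean
#' (`x = mean * exp(rnorm(0, sigma_log) - sigma_log^2 / 2)`); with
#' `sigma_log = 0` every cell equals its group mean exactly. Pseudobulk
#' aggregation of the result therefore reproduces the planted means within
#' Monte-Carlo error.
#'
#' @param sample_ids character vector of sample identifiers.
#' @param states character vector of cell-state labels.
#' @param phenotype_map named character vector (`sample_id -> phenotype`)
#'   or a data.frame with `sample_id`, `phenotype`; a sample mapped to two
#'   phenotypes is refused.
#' @param cells_per_group cells per (sample, state) group.
#' @param group_means genes x states matrix of expected expression
#'   (recycled across samples), or genes x (sample.state) matrix with
#'   columns named `paste(sample_id, state, sep = ".")`. Non-negative.
#' @param sigma_log lognormal noise sd on the log scale (default 0.5).
#' @param seed integer seed.
#' @return a [single_cell_dataset()].
#' @export
simulate_single_cell <- function(sample_ids, states, phenotype_map,
                                 cells_per_group, group_means,
                                 sigma_log = 0.5, seed = 1) {
  if (cells_per_group < 1) stop("cells_per_group must be at least 1")
  if (is.data.frame(phenotype_map)) {
    agg <- tapply(as.character(phenotype_map$phenotype),
                  as.character(phenotype_map$sample_id),
                  function(p) unique(p))
    if (any(lengths(agg) > 1)) {
      stop("phenotype conflict: sample(s) mapped to multiple phenotypes: ",
           paste(names(agg)[lengths(agg) > 1], collapse = ", "))
    }
    phenotype_map <- vapply(agg, `[[`, character(1), 1L)
  }
  missing_samples <- setdiff(sample_ids, names(phenotype_map))
  if (length(missing_samples)) {
    stop("phenotype_map lacks sample(s): ",
         paste(missing_samples, collapse = ", "))
  }
  group_means <- as.matrix(group_means)
  if (any(group_means < 0)) stop("group means must be non-negative")
  gene_ids <- rownames(group_means)
  if (is.null(gene_ids)) gene_ids <- sprintf("gene%03d", seq_len(nrow(group_means)))
  by_sample_state <- !is.null(colnames(group_means)) &&
    all(as.vector(outer(sample_ids, states, paste, sep = ".")) %in%
          colnames(group_means))
  if (!by_sample_state && !identical(ncol(group_means), length(states))) {
    stop("group_means must have one column per state or per sample.state")
  }
  if (!by_sample_state && is.null(colnames(group_means))) {
    colnames(group_means) <- states
  }
  set.seed(seed)
  blocks <- list(); meta <- list()
  for (s in sample_ids) for (st in states) {
    mcol <- if (by_sample_state) paste(s, st, sep = ".") else st
    mn <- group_means[, mcol]
    noise <- matrix(stats::rnorm(length(mn) * cells_per_group,
                                 sd = sigma_log),
                    length(mn), cells_per_group)
    x <- mn * exp(noise - sigma_log^2 / 2)
    key <- paste(s, st, sep = ".")
    blocks[[key]] <- x
    meta[[key]] <- data.frame(
      sample_id = s, state = st, phenotype = unname(phenotype_map[s]),
      n = cells_per_group, stringsAsFactors = FALSE)
  }
  values <- do.call(cbind, blocks)
  meta <- do.call(rbind, meta)
  cell_meta <- meta[rep(seq_len(nrow(meta)), meta$n),
                    c("sample_id", "state", "phenotype")]
  cell_ids <- sprintf("cell%05d", seq_len(ncol(values)))
  single_cell_dataset(values, cell_meta, gene_ids = gene_ids,
                      cell_ids = cell_ids)
}

#' Simulate spatially resolved expression with planted neighbor correlation
#'
#' Cells are laid out as tight pairs on a jittered grid, so each cell's
#' nearest neighbor is its pair mate. For each gene and sample, pair
#' expression is drawn from a bivariate normal (sd 1 around a baseline of
#' 10, floored at zero) with the planted correlation, so the realized
#' nnCorrelation converges to the planted value as the grid grows.
#'
#' @param design_labels data.frame with `sample_id`, `f1`, `f2` (one row
#'   per sample).
#' @param grid_n cells are laid out on a `grid_n x grid_n` arrangement
#'   (one cell dropped when the count is odd); `grid_n >= 2`.
#' @param rho genes x samples matrix of planted correlations in `[-1, 1]`
#'   (rownames = gene ids, columns ordered as `design_labels$sample_id`),
#'   or a function `(gene_id, f1, f2) -> rho`.
#' @param gene_ids required when `rho` is a function.
#' @param seed integer seed.
#' @return a [single_cell_dataset()] covering all samples, with `x`/`y`
#'   coordinates, `state = "cell"`, `phenotype = f1` and `timepoint = f2`
#'   in the metadata (ready for [nn_feature_matrix()]).
#' @export
simulate_spatial <- function(design_labels, grid_n = 10, rho,
                             gene_ids = NULL, seed = 1) {
  stopifnot(is.data.frame(design_labels),
            all(c("sample_id", "f1", "f2") %in% names(design_labels)))
  if (grid_n < 2) stop("grid_n must be at least 2")
  samples <- as.character(design_labels$sample_id)
  if (anyDuplicated(samples)) stop("duplicate sample ids in design_labels")
  if (is.function(rho)) {
    if (is.null(gene_ids)) stop("gene_ids required when rho is a function")
    rho_mat <- outer(seq_along(gene_ids), seq_along(samples),
                     Vectorize(function(g, s) {
                       rho(gene_ids[g], design_labels$f1[s],
                           design_labels$f2[s])
                     }))
    dimnames(rho_mat) <- list(gene_ids, samples)
  } else {
    rho_mat <- as.matrix(rho)
    if (is.null(rownames(rho_mat))) {
      rownames(rho_mat) <- sprintf("gene%03d", seq_len(nrow(rho_mat)))
    }
    colnames(rho_mat) <- samples
    gene_ids <- rownames(rho_mat)
  }
  if (any(abs(rho_mat) > 1)) stop("correlations must lie in [-1, 1]")
  n_cells <- grid_n^2 - (grid_n^2 %% 2)
  n_pairs <- n_cells / 2
  set.seed(seed)
  vals <- list(); metas <- list()
  for (si in seq_along(samples)) {
    pc <- expand.grid(cx = seq_len(ceiling(n_pairs / grid_n)),
                      cy = seq_len(grid_n))[seq_len(n_pairs), ]
    x <- as.numeric(rbind(pc$cx - 0.15, pc$cx + 0.15)) +
      stats::runif(n_cells, -0.05, 0.05)
    y <- as.numeric(rbind(pc$cy, pc$cy)) + stats::runif(n_cells, -0.05, 0.05)
    v <- matrix(NA_real_, length(gene_ids), n_cells)
    for (g in seq_along(gene_ids)) {
      r <- rho_mat[g, si]
      z1 <- stats::rnorm(n_pairs)
      z2 <- r * z1 + sqrt(1 - r^2) * stats::rnorm(n_pairs)
      v[g, ] <- pmax(10 + as.numeric(rbind(z1, z2)), 0)
    }
    vals[[si]] <- v
    metas[[si]] <- data.frame(
      sample_id = samples[si], state = "cell",
      phenotype = as.character(design_labels$f1[si]),
      timepoint = as.character(design_labels$f2[si]),
      x = x, y = y, stringsAsFactors = FALSE)
  }
  values <- do.call(cbind, vals)
  meta <- do.call(rbind, metas)
  single_cell_dataset(values, meta, gene_ids = gene_ids,
                      cell_ids = sprintf("cell%05d", seq_len(ncol(values))))
}

#' Score a classification against simulation ground truth
#'
#' @param truth a `SimTruth`.
#' @param gc a `GeneClassification` over the same genes.
#' @return list with `confusion` (truth x predicted contingency table over
#'   the union of category labels), `recall` and `precision` (named vectors
#'   over truth / predicted categories), and `fdr_sig` (fraction of genes
#'   classified as significant whose truth is `non-sig`).
#' @export
recovery_metrics <- function(truth, gc) {
  stopifnot(inherits(truth, "SimTruth"), inherits(gc, "GeneClassification"))
  if (!setequal(truth$gene_id, gc$gene_id)) {
    stop("truth and classification cover different gene sets")
  }
  pred <- gc$category[match(truth$gene_id, gc$gene_id)]
  lv <- union(unique(truth$category), unique(pred))
  lv <- c(setdiff(lv, "non-sig"), intersect("non-sig", lv))
  confusion <- table(truth = factor(truth$category, levels = lv),
                     predicted = factor(pred, levels = lv))
  recall <- diag(confusion) / pmax(rowSums(confusion), 1)
  precision <- diag(confusion) / pmax(colSums(confusion), 1)
  pred_sig <- pred != "non-sig"
  fdr_sig <- if (any(pred_sig)) {
    mean(truth$category[pred_sig] == "non-sig")
  } else 0
  list(confusion = confusion, recall = recall, precision = precision,
       fdr_sig = fdr_sig)
}
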