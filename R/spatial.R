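# Spatial front end: per-sample, per-gene nearest-neighbor correlation
# (nnCorrelation). For each cell the single nearest other cell by Euclidean
# distance is found, and for each gene the Pearson correlation between each
# cell's expression and its neighbor's expression is computed over the
# directed pairs (i, nn(i)). The resulting genes x samples feature matrix
# is a drop-in response for the two-way classifier: a gene whose spatial
# coherence varies with a sample-level factor lands in that factor's
# category.

#' Nearest spatial neighbor per cell
#'
#' @param coords numeric matrix or data.frame with columns `x`, `y` (or two
#'   unnamed columns), one row per cell; coordinates must be finite.
#' @return integer vector: for each cell, the index of the closest other
#'   cell (self excluded); exact distance ties resolve to the smallest cell
#'   index. Duplicate coordinates are legal (distance zero to another cell).
#' @export
nearest_neighbor <- function(coords) {
  coords <- as.matrix(coords)
  if (ncol(coords) >= 2 && all(c("x", "y") %in% colnames(coords))) {
    coords <- coords[, c("x", "y"), drop = FALSE]
  }
  if (ncol(coords) != 2) stop("coords must have two columns (x, y)")
  if (nrow(coords) < 2) stop("need at least two cells to define neighbors")
  if (!all(is.finite(coords))) stop("coordinates must be finite")
  d <- as.matrix(stats::dist(coords))
  diag(d) <- Inf
  # ties (within floating-point tolerance) resolve to the smallest index
  vapply(seq_len(nrow(d)), function(i) {
    m <- min(d[i, ])
    which(d[i, ] <= m + (m + 1) * 1e-9)[1]
  }, integer(1))
}

#' Nearest-neighbor correlation for one sample
#'
#' @param values genes x cells expression matrix for one sample.
#' @param coords per-cell coordinates (see [nearest_neighbor()]); at least
#'   three cells.
#' @return named numeric vector per gene: Pearson correlation between own
#'   and nearest-neighbor expression over all directed pairs, in `[-1, 1]`;
#'   `NA` (explicitly undefined, never zeroed) when either vector has zero
#'   variance.
#' @export
nn_correlation <- function(values, coords) {
  values <- as.matrix(values)
  if (nrow(as.matrix(coords)) < 3) {
    stop("nnCorrelation requires at least three cells per sample")
  }
  if (ncol(values) != nrow(as.matrix(coords))) {
    stop("values columns must match coords rows")
  }
  nn <- nearest_neighbor(coords)
  own <- values
  nbr <- values[, nn, drop = FALSE]
  r <- vapply(seq_len(nrow(values)), function(g) {
    x <- own[g, ]; y <- nbr[g, ]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) NA_real_ else
      stats::cor(x, y)
  }, numeric(1))
  names(r) <- rownames(values)
  r
}

#' Nearest-neighbor correlation feature matrix across samples
#'
#' Splits a spatially resolved `SingleCellDataset` (metadata columns `x`,
#' `y` required) by sample and computes [nn_correlation()] per sample,
#' assembling a genes x samples feature matrix plus a per-sample design.
#' The sample-level factors default to `phenotype` (f1) and `timepoint`
#' (f2) when present; pass `f1_col` / `f2_col` to choose other metadata
#' columns (they must be constant within each sample).
#'
#' @param ds a `SingleCellDataset` with `x`, `y` metadata.
#' @param f1_col,f2_col cell-metadata columns providing the two sample-level
#'   factors.
#' @param min_cells samples with fewer cells are dropped (default 3).
#' @return a `PseudobulkMatrix` whose "observations" are samples and whose
#'   values are nnCorrelation features (undefined entries `NA`).
#' @export
nn_feature_matrix <- function(ds, f1_col = "phenotype", f2_col = "timepoint",
                              min_cells = 3) {
  stopifnot(inherits(ds, "SingleCellDataset"))
  meta <- ds$cell_meta
  if (!all(c("x", "y") %in% names(meta))) {
    stop("spatial features require x and y cell coordinates")
  }
  for (col in c(f1_col, f2_col)) {
    if (!col %in% names(meta)) {
      stop("metadata lacks sample-level factor column: ", col)
    }
  }
  samples <- split(seq_along(ds$cell_ids), as.character(meta$sample_id))
  samples <- samples[lengths(samples) >= min_cells]
  if (length(samples) < 2) stop("need at least two samples with enough cells")
  samples <- samples[order(names(samples))]
  sample_factor <- function(col) {
    vapply(samples, function(ix) {
      u <- unique(as.character(meta[[col]][ix]))
      if (length(u) > 1) {
        stop("metadata column '", col, "' is not constant within a sample")
      }
      u
    }, character(1))
  }
  vals <- vapply(samples, function(ix) {
    nn_correlation(as.matrix(ds$values[, ix, drop = FALSE]),
                   meta[ix, c("x", "y")])
  }, numeric(length(ds$gene_ids)))
  vals <- matrix(vals, nrow = length(ds$gene_ids),
                 dimnames = list(ds$gene_ids, names(samples)))
  design <- observation_design(names(samples),
                               f1 = sample_factor(f1_col),
                               f2 = sample_factor(f2_col))
  pseudobulk_matrix(vals, design, gene_ids = ds$gene_ids)
}

#' Two-way classification of spatial nnCorrelation features
#'
#' Treats the nnCorrelation value as the per-sample response and delegates
#' to [classify_two_way()]. Genes whose feature is undefined in at least
#' `max_missing` of the samples are excluded up front (with a message);
#' remaining undefined entries are dropped per gene during fitting, never
#' imputed.
#'
#' @param features a genes x samples `PseudobulkMatrix` of nnCorrelation
#'   values, e.g. from [nn_feature_matrix()].
#' @param policy a [threshold_policy()].
#' @param max_missing maximum tolerated fraction of undefined entries per
#'   gene (default 0.2).
#' @param ... passed to [classify_two_way()].
#' @return list with `classification` (a `GeneClassification` over the
#'   retained genes) and `excluded` (data.frame of dropped genes with their
#'   missing fraction).
#' @export
spatial_idas <- function(features, policy = threshold_policy("alpha", 0.05),
                         max_missing = 0.2, ...) {
  stopifnot(inherits(features, "PseudobulkMatrix"))
  frac_na <- rowMeans(is.na(features$values))
  drop <- frac_na >= max_missing & frac_na > 0
  excluded <- data.frame(gene_id = features$gene_ids[drop],
                         missing_fraction = unname(frac_na[drop]),
                         reason = rep("undefined-nnCorrelation", sum(drop)),
                         stringsAsFactors = FALSE, row.names = NULL)
  if (any(drop)) {
    message("excluding ", sum(drop), " gene(s) with >= ",
            round(100 * max_missing), "% undefined nnCorrelation entries")
  }
  if (all(drop)) stop("no genes left after the missingness filter")
  kept <- pseudobulk_matrix(features$values[!drop, , drop = FALSE],
                            features$design,
                            gene_ids = features$gene_ids[!drop])
  list(classification = classify_two_way(kept, policy, ...),
       excluded = excluded)
}
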