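# Pseudobulk aggregation: collapse single cells into one observation per
# sample x cell-state (x timepoint) group on the log2 scale. Working on
# group means rather than individual cells avoids the inflated false
# discovery rates of cell-level testing (pseudo-replication) and brings the
# residuals close enough to Gaussian for the linear-model machinery.

#' Aggregate single cells into pseudobulk observations
#'
#' For each group defined by `group_keys`, the per-gene mean expression over
#' the group's cells is computed on the input value scale and transformed as
#' `log2(mean + pseudocount)`. Each surviving group becomes one observation;
#' the design records `f1 = state`, `f2 = phenotype` (inherited from the
#' sample), `f3 = timepoint` when grouped by it, and `subject` (from
#' `subject_id` when present, otherwise the sample id).
#'
#' @param ds a `SingleCellDataset`.
#' @param group_keys metadata columns defining groups; must include
#'   `sample_id` and `state`, may add `timepoint`.
#' @param pseudocount positive offset added before the log2 transform
#'   (default 1, so all-zero genes map to 0).
#' @param min_cells groups with fewer cells are dropped (default 1); drops
#'   are reported via `message()`.
#' @return a [pseudobulk_matrix()].
#' @export
pseudobulk_aggregate <- function(ds, group_keys = c("sample_id", "state"),
                                 pseudocount = 1, min_cells = 1) {
  stopifnot(inherits(ds, "SingleCellDataset"))
  if (!all(c("sample_id", "state") %in% group_keys)) {
    stop("group_keys must include sample_id and state")
  }
  extra <- setdiff(group_keys, c("sample_id", "state", "timepoint"))
  if (length(extra)) stop("unsupported group key(s): ",
                          paste(extra, collapse = ", "))
  if (!all(group_keys %in% names(ds$cell_meta))) {
    stop("cell metadata lacks group key column(s): ",
         paste(setdiff(group_keys, names(ds$cell_meta)), collapse = ", "))
  }
  if (pseudocount <= 0) stop("pseudocount must be positive")
  if (min_cells < 1) stop("min_cells must be at least 1")

  meta <- ds$cell_meta
  # phenotype is a sample-level attribute: cells of one sample must agree
  pheno_by_sample <- tapply(as.character(meta$phenotype),
                            as.character(meta$sample_id),
                            function(p) unique(p))
  conflicted <- names(pheno_by_sample)[lengths(pheno_by_sample) > 1]
  if (length(conflicted)) {
    stop("cells disagree on sample-level phenotype within sample(s): ",
         paste(conflicted, collapse = ", "))
  }
  if ("timepoint" %in% group_keys && anyNA(meta$timepoint)) {
    stop("timepoint grouping requested but timepoint has missing values")
  }

  key_cols <- lapply(group_keys, function(k) as.character(meta[[k]]))
  key <- do.call(paste, c(key_cols, sep = "."))
  groups <- split(seq_along(key), key)
  sizes <- lengths(groups)
  dropped <- names(groups)[sizes < min_cells]
  if (length(dropped)) {
    message("dropping ", length(dropped), " group(s) below min_cells = ",
            min_cells, ": ", paste(dropped, collapse = ", "))
    groups <- groups[sizes >= min_cells]
  }
  if (!length(groups)) stop("no groups survive the min_cells filter")
  groups <- groups[order(names(groups))]

  vals <- vapply(groups, function(ix) {
    m <- Matrix::rowMeans(ds$values[, ix, drop = FALSE])
    log2(as.numeric(m) + pseudocount)
  }, numeric(length(ds$gene_ids)))
  vals <- matrix(vals, nrow = length(ds$gene_ids),
                 dimnames = list(ds$gene_ids, names(groups)))

  first_ix <- vapply(groups, `[[`, integer(1), 1L)
  samples <- as.character(meta$sample_id)[first_ix]
  states <- as.character(meta$state)[first_ix]
  phenos <- vapply(pheno_by_sample[samples], `[[`, character(1), 1L)
  f3 <- if ("timepoint" %in% group_keys) {
    as.character(meta$timepoint)[first_ix]
  }
  subject <- if ("subject_id" %in% names(meta)) {
    as.character(meta$subject_id)[first_ix]
  } else samples
  design <- observation_design(names(groups), f1 = states, f2 = phenos,
                               f3 = f3, subject = subject)
  pseudobulk_matrix(vals, design, gene_ids = ds$gene_ids)
}

#' Summarize replication of a pseudobulk design
#'
#' Counts observations per factor-level combination, flagging combinations
#' with zero observations (rank-deficient full model) and combinations with
#' a single observation. When every combination has exactly one observation
#' the full fixed-effect model is saturated (zero residual degrees of
#' freedom) and a warning is issued.
#'
#' @param pb a `PseudobulkMatrix` (or an `ObservationDesign`).
#' @return a list with `counts` (data.frame of factor combinations and
#'   observation counts, including empty combinations), `missing` and
#'   `single_replicate` (character vectors of combination labels), and
#'   `saturated` (logical: residual df of the full model is zero).
#' @export
design_summary <- function(pb) {
  design <- if (inherits(pb, "PseudobulkMatrix")) pb$design else pb
  stopifnot(inherits(design, "ObservationDesign"))
  fcols <- intersect(c("f1", "f2", "f3"), names(design))
  tab <- as.data.frame(table(design[fcols]), stringsAsFactors = FALSE)
  names(tab)[ncol(tab)] <- "n_obs"
  lab <- do.call(paste, c(tab[fcols], sep = ":"))
  missing <- lab[tab$n_obs == 0]
  single <- lab[tab$n_obs == 1]
  # residual df of the cell-means full model = n - (#non-empty combinations)
  saturated <- all(tab$n_obs <= 1)
  if (saturated) {
    warning("full model saturated: every factor-level combination has at ",
            "most one observation (zero residual degrees of freedom)")
  }
  list(counts = tab, missing = missing, single_replicate = single,
       saturated = saturated)
}
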