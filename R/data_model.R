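# Domain containers shared by every stage of the workflow.
#
# All containers are plain S3 lists validated on construction, in the style
# of lightweight analysis packages: a SingleCellDataset holds expression
# values plus per-cell metadata, an ObservationDesign describes the factorial
# structure of pseudobulk observations, and a PseudobulkMatrix couples a
# genes x observations log2 matrix with its design.

#' Single-cell expression dataset
#'
#' Couples a genes x cells expression matrix (raw counts or normalized,
#' non-negative) with a per-cell metadata table. The metadata must provide
#' `sample_id`, `state` (cell-state label, factor F1 of the downstream
#' design) and `phenotype` (sample-level phenotype, factor F2); it may also
#' carry `timepoint` (factor F3), `subject_id`, spatial coordinates `x`/`y`
#' and a `da_selected` flag produced by an upstream differential-abundance
#' tool (Milo, DA-seq, Scissor or similar).
#'
#' @param values numeric matrix (base or `Matrix` sparse), genes in rows,
#'   cells in columns; non-negative.
#' @param cell_meta data.frame with one row per cell, in column order of
#'   `values`; must contain `sample_id`, `state`, `phenotype`.
#' @param gene_ids,cell_ids optional character vectors overriding the
#'   dimnames of `values`.
#' @return an object of class `SingleCellDataset` with elements `values`,
#'   `gene_ids`, `cell_ids`, `cell_meta`.
#' @export
single_cell_dataset <- function(values, cell_meta, gene_ids = NULL,
                                cell_ids = NULL) {
  if (is.null(gene_ids)) gene_ids <- rownames(values)
  if (is.null(cell_ids)) cell_ids <- colnames(values)
  if (is.null(gene_ids) || is.null(cell_ids)) {
    stop("gene and cell identifiers are required (dimnames or explicit args)")
  }
  gene_ids <- as.character(gene_ids)
  cell_ids <- as.character(cell_ids)
  if (length(gene_ids) != nrow(values) || length(cell_ids) != ncol(values)) {
    stop("identifier lengths do not match matrix dimensions")
  }
  if (anyDuplicated(gene_ids)) stop("duplicate gene identifiers")
  if (anyDuplicated(cell_ids)) stop("duplicate cell identifiers")
  mn <- suppressWarnings(min(values))  # S4 Summary method covers Matrix
  if (is.finite(mn) && mn < 0) stop("expression values must be non-negative")
  if (!is.data.frame(cell_meta)) stop("cell_meta must be a data.frame")
  if (nrow(cell_meta) != length(cell_ids)) {
    stop("cell_meta must have one row per cell")
  }
  required <- c("sample_id", "state", "phenotype")
  missing_cols <- setdiff(required, names(cell_meta))
  if (length(missing_cols)) {
    stop("cell_meta is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  for (col in required) {
    if (anyNA(cell_meta[[col]])) {
      stop("cell_meta column '", col, "' contains missing values")
    }
  }
  rownames(values) <- gene_ids
  colnames(values) <- cell_ids
  rownames(cell_meta) <- cell_ids
  structure(
    list(values = values, gene_ids = gene_ids, cell_ids = cell_ids,
         cell_meta = cell_meta),
    class = "SingleCellDataset"
  )
}

#' @export
print.SingleCellDataset <- function(x, ...) {
  cat("SingleCellDataset:", length(x$gene_ids), "genes x",
      length(x$cell_ids), "cells\n")
  cat("  samples:", length(unique(x$cell_meta$sample_id)),
      " states:", length(unique(x$cell_meta$state)),
      " phenotypes:", length(unique(x$cell_meta$phenotype)), "\n")
  extras <- intersect(c("timepoint", "subject_id", "x", "y", "da_selected"),
                      names(x$cell_meta))
  if (length(extras)) cat("  optional metadata:",
                          paste(extras, collapse = ", "), "\n")
  invisible(x)
}

#' Observation design for pseudobulk models
#'
#' Describes the factorial structure of a set of pseudobulk observations:
#' factor `f1` (I >= 2 levels, typically cell state), factor `f2` (J >= 2
#' levels, typically phenotype), optional factor `f3` (K >= 2 levels,
#' typically a pre/on-treatment timepoint) and an optional `subject`
#' grouping used as the random-intercept term of the three-way models.
#'
#' @param obs_ids unique observation identifiers.
#' @param f1,f2 factors (or coercible); classification requires at least
#'   two levels of each, aggregation alone does not.
#' @param f3 optional third factor.
#' @param subject optional subject/patient grouping label per observation.
#' @return data.frame of class `ObservationDesign` with columns `obs_id`,
#'   `f1`, `f2` and optionally `f3`, `subject`.
#' @export
observation_design <- function(obs_ids, f1, f2, f3 = NULL, subject = NULL) {
  obs_ids <- as.character(obs_ids)
  if (anyDuplicated(obs_ids)) stop("duplicate observation identifiers")
  n <- length(obs_ids)
  d <- data.frame(obs_id = obs_ids,
                  f1 = droplevels(as.factor(f1)),
                  f2 = droplevels(as.factor(f2)),
                  stringsAsFactors = FALSE)
  if (!is.null(f3)) d$f3 <- droplevels(as.factor(f3))
  if (!is.null(subject)) d$subject <- droplevels(as.factor(subject))
  if (any(vapply(d, length, 1L) != n)) {
    stop("all design columns must have one entry per observation")
  }
  # single-level factors are tolerated here (aggregation of a one-state or
  # one-phenotype dataset is legal); the classifiers require >= 2 levels
  rownames(d) <- obs_ids
  class(d) <- c("ObservationDesign", "data.frame")
  d
}

has_f3 <- function(design) "f3" %in% names(design)
has_subject <- function(design) "subject" %in% names(design)

#' Pseudobulk expression matrix
#'
#' A genes x observations matrix of log2-scale expression values paired with
#' its [observation_design()]. Columns correspond to design rows in order.
#' `NA` entries are permitted (an observation undefined for a particular
#' gene, e.g. a spatial feature with zero variance); per-gene model fits
#' drop them.
#'
#' @param values numeric matrix, genes x observations, log2 scale.
#' @param design an `ObservationDesign` with one row per column of `values`.
#' @param gene_ids optional character vector overriding rownames.
#' @return an object of class `PseudobulkMatrix`.
#' @export
pseudobulk_matrix <- function(values, design, gene_ids = NULL) {
  values <- as.matrix(values)
  if (is.null(gene_ids)) gene_ids <- rownames(values)
  if (is.null(gene_ids)) stop("gene identifiers are required")
  gene_ids <- as.character(gene_ids)
  if (anyDuplicated(gene_ids)) stop("duplicate gene identifiers")
  if (!inherits(design, "ObservationDesign")) {
    stop("design must be an ObservationDesign")
  }
  if (ncol(values) != nrow(design)) {
    stop("number of matrix columns (", ncol(values),
         ") does not match number of design observations (", nrow(design), ")")
  }
  if (any(is.infinite(values))) stop("pseudobulk values must be finite or NA")
  rownames(values) <- gene_ids
  colnames(values) <- design$obs_id
  structure(list(values = values, gene_ids = gene_ids, design = design),
            class = "PseudobulkMatrix")
}

#' @export
print.PseudobulkMatrix <- function(x, ...) {
  d <- x$design
  cat("PseudobulkMatrix:", nrow(x$values), "genes x", ncol(x$values),
      "observations\n")
  cat("  f1 levels:", nlevels(d$f1), " f2 levels:", nlevels(d$f2))
  if (has_f3(d)) cat(" f3 levels:", nlevels(d$f3))
  if (has_subject(d)) cat("  subjects:", nlevels(d$subject))
  cat("\n")
  invisible(x)
}

#' Gene classification table
#'
#' One row per gene with the assigned category and the raw/BH-adjusted
#' p-value of every staged test the gene entered (`NA` where a stage was not
#' evaluated for that gene). Categories partition the input gene set.
#'
#' @format data.frame of class `GeneClassification` with columns `gene_id`,
#'   `category`, `reason` and paired `p_*` / `padj_*` columns per stage
#'   test; attributes `design_type` ("two_way"/"three_way"),
#'   `threshold_mode`, `threshold_level`, `use_adjusted`, `stage_alpha`.
#' @name GeneClassification
NULL

two_way_categories <- function() c("F1", "F2", "F1xF2", "F1+F2", "non-sig")

three_way_categories <- function() {
  c("F1", "F2", "F3", "F1xF2", "F2xF3", "F1xF3", "two-way-combine",
    "additive", "F1xF2xF3", "non-sig")
}

new_gene_classification <- function(tab, design_type, policy, stage_alpha) {
  stopifnot(is.data.frame(tab), all(c("gene_id", "category") %in% names(tab)))
  valid <- switch(design_type,
                  two_way = two_way_categories(),
                  three_way = three_way_categories(),
                  stop("unknown design type"))
  bad <- setdiff(unique(tab$category), valid)
  if (length(bad)) stop("invalid categories: ", paste(bad, collapse = ", "))
  rownames(tab) <- NULL
  structure(tab,
            class = c("GeneClassification", "data.frame"),
            design_type = design_type,
            threshold_mode = policy$mode,
            threshold_level = policy$level,
            use_adjusted = policy$use_adjusted,
            stage_alpha = stage_alpha)
}

#' @export
print.GeneClassification <- function(x, ...) {
  cat("GeneClassification (", attr(x, "design_type"), " design, ",
      nrow(x), " genes)\n", sep = "")
  cat("  threshold: ", attr(x, "threshold_mode"), " ",
      attr(x, "threshold_level"),
      if (isTRUE(attr(x, "use_adjusted"))) " on BH-adjusted p" else
        " on raw p", "\n", sep = "")
  print(table(factor(x$category,
                     levels = switch(attr(x, "design_type"),
                                     two_way = two_way_categories(),
                                     three_way = three_way_categories()))))
  invisible(x)
}

#' Summarize category counts of a classification
#'
#' @param gc a `GeneClassification`.
#' @return named integer vector of per-category gene counts (all categories,
#'   including empty ones).
#' @export
category_counts <- function(gc) {
  stopifnot(inherits(gc, "GeneClassification"))
  lv <- switch(attr(gc, "design_type"),
               two_way = two_way_categories(),
               three_way = three_way_categories())
  table(factor(gc$category, levels = lv))
}
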