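# Readers and writers for the plain-text formats the tool touches:
# MatrixMarket + features/barcodes sidecars, dense CSV/TSV expression,
# metadata tables, and the classification / DE / pseudobulk output tables.

read_table_auto <- function(path, sep = NULL) {
  if (is.null(sep)) {
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  }
  utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                    stringsAsFactors = FALSE, quote = "\"", comment.char = "")
}

#' Read a single-cell expression dataset
#'
#' Reads expression values either from a MatrixMarket triplet file with
#' `features.tsv` / `barcodes.tsv` sidecars, or from a dense CSV/TSV whose
#' first column holds gene identifiers and whose header row holds cell
#' identifiers. Cell metadata is read from a separate CSV/TSV keyed by a
#' `cell_id` column.
#'
#' Orientation is declared, never guessed: the default `genes_by_cells`
#' follows the MatrixMarket single-cell convention; pass
#' `orientation = "cells_by_genes"` for a transposed input.
#'
#' @param matrix_path path to the `.mtx` or dense expression table.
#' @param meta_path path to the cell metadata table; must contain `cell_id`,
#'   `sample_id`, `state`, `phenotype`. Every matrix cell must appear in the
#'   metadata.
#' @param format one of `"auto"`, `"mtx"`, `"csv"`, `"tsv"`.
#' @param orientation `"genes_by_cells"` (default) or `"cells_by_genes"`.
#' @param features_path,barcodes_path sidecar paths for `mtx` input;
#'   default to `features.tsv` / `barcodes.tsv` next to the matrix.
#' @return a [single_cell_dataset()].
#' @export
read_single_cell <- function(matrix_path, meta_path,
                             format = c("auto", "mtx", "csv", "tsv"),
                             orientation = c("genes_by_cells",
                                             "cells_by_genes"),
                             features_path = NULL, barcodes_path = NULL) {
  format <- match.arg(format)
  orientation <- match.arg(orientation)
  if (!file.exists(matrix_path)) stop("matrix file not found: ", matrix_path)
  if (!file.exists(meta_path)) stop("metadata file not found: ", meta_path)
  if (format == "auto") {
    format <- if (grepl("\\.mtx$", matrix_path, ignore.case = TRUE)) "mtx"
              else if (grepl("\\.csv$", matrix_path, ignore.case = TRUE)) "csv"
              else "tsv"
  }
  if (format == "mtx") {
    dir <- dirname(matrix_path)
    if (is.null(features_path)) features_path <- file.path(dir, "features.tsv")
    if (is.null(barcodes_path)) barcodes_path <- file.path(dir, "barcodes.tsv")
    if (!file.exists(features_path)) {
      stop("features file not found: ", features_path)
    }
    if (!file.exists(barcodes_path)) {
      stop("barcodes file not found: ", barcodes_path)
    }
    values <- Matrix::readMM(matrix_path)
    genes <- utils::read.table(features_path, header = FALSE, sep = "\t",
                               stringsAsFactors = FALSE)[[1]]
    cells <- utils::read.table(barcodes_path, header = FALSE, sep = "\t",
                               stringsAsFactors = FALSE)[[1]]
  } else {
    tab <- read_table_auto(matrix_path, if (format == "csv") "," else "\t")
    genes <- as.character(tab[[1]])
    values <- as.matrix(tab[, -1, drop = FALSE])
    cells <- colnames(values)
  }
  if (orientation == "cells_by_genes") {
    values <- Matrix::t(values)
    tmp <- genes; genes <- cells; cells <- tmp
  }
  if (nrow(values) != length(genes) || ncol(values) != length(cells)) {
    stop("identifier counts do not match matrix dimensions ",
         "(check --orientation)")
  }
  meta <- read_table_auto(meta_path)
  if (!"cell_id" %in% names(meta)) {
    stop("metadata is missing required column(s): cell_id")
  }
  required <- c("sample_id", "state", "phenotype")
  missing_cols <- setdiff(required, names(meta))
  if (length(missing_cols)) {
    stop("metadata is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  idx <- match(cells, meta$cell_id)
  if (anyNA(idx)) {
    stop("cells present in the matrix but absent from metadata: ",
         paste(utils::head(cells[is.na(idx)], 5), collapse = ", "))
  }
  meta <- meta[idx, , drop = FALSE]
  single_cell_dataset(values, meta, gene_ids = genes, cell_ids = cells)
}

#' Subset to the differential-abundance-selected cells
#'
#' The classifier consumes the output of any upstream differential-abundance
#' method as a per-cell selection flag. `da_selected` may be logical or a
#' signed group label (e.g. "responding"/"non-responding"); any non-missing,
#' non-false, non-empty label retains the cell. The label itself is never
#' used as a model factor.
#'
#' @param ds a `SingleCellDataset`.
#' @param mode `"flag"` (keep flagged cells) or `"all"` (identity).
#' @return the subset `SingleCellDataset`; the gene set is unchanged.
#' @export
filter_da_cells <- function(ds, mode = c("flag", "all")) {
  stopifnot(inherits(ds, "SingleCellDataset"))
  mode <- match.arg(mode)
  if (mode == "all") return(ds)
  if (!"da_selected" %in% names(ds$cell_meta)) {
    stop("da_selected column absent from cell metadata; ",
         "run an upstream differential-abundance tool or use mode = 'all'")
  }
  flag <- ds$cell_meta$da_selected
  keep <- if (is.logical(flag)) {
    !is.na(flag) & flag
  } else {
    lab <- trimws(as.character(flag))
    !is.na(flag) & !(tolower(lab) %in% c("", "na", "none", "false", "0"))
  }
  if (!any(keep)) stop("no cells selected by the differential-abundance flag")
  single_cell_dataset(ds$values[, keep, drop = FALSE],
                      ds$cell_meta[keep, , drop = FALSE],
                      gene_ids = ds$gene_ids,
                      cell_ids = ds$cell_ids[keep])
}

#' Write / read a gene classification table
#'
#' Tab-separated, one row per gene ordered by `gene_id`, with the category,
#' a reason code for genes routed without testing, and one raw-p plus one
#' BH-adjusted-p column per stage test (empty where the gene did not enter
#' that stage).
#'
#' @param gc a `GeneClassification`.
#' @param path output path.
#' @return `write_classification` invisibly returns `path`;
#'   `read_classification` returns the table as a data.frame with the
#'   classification attributes restored from the header comment.
#' @export
write_classification <- function(gc, path) {
  stopifnot(inherits(gc, "GeneClassification"))
  tab <- as.data.frame(gc)
  tab <- tab[order(tab$gene_id), , drop = FALSE]
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf(
    "# design_type=%s threshold_mode=%s threshold_level=%s use_adjusted=%s stage_alpha=%s",
    attr(gc, "design_type"), attr(gc, "threshold_mode"),
    format(attr(gc, "threshold_level")), attr(gc, "use_adjusted"),
    format(attr(gc, "stage_alpha"))), con)
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' @rdname write_classification
#' @export
read_classification <- function(path) {
  header <- readLines(path, n = 1)
  tab <- utils::read.table(path, header = TRUE, sep = "\t", skip = 1,
                           check.names = FALSE, stringsAsFactors = FALSE,
                           na.strings = "")
  kv <- regmatches(header, gregexpr("[a-z_]+=[^ ]+", header))[[1]]
  meta <- stats::setNames(sub("^[a-z_]+=", "", kv), sub("=.*$", "", kv))
  policy <- threshold_policy(mode = meta[["threshold_mode"]],
                             level = as.numeric(meta[["threshold_level"]]),
                             use_adjusted = as.logical(meta[["use_adjusted"]]))
  new_gene_classification(tab, meta[["design_type"]], policy,
                          as.numeric(meta[["stage_alpha"]]))
}

#' Write / read a pseudobulk matrix with its design sidecar
#'
#' The values table is genes x observations TSV with a leading `gene_id`
#' column; the design sidecar is one row per observation. Missing values are
#' written as `NA`.
#'
#' @param pb a `PseudobulkMatrix`.
#' @param values_path,design_path output paths.
#' @export
write_pseudobulk <- function(pb, values_path, design_path) {
  stopifnot(inherits(pb, "PseudobulkMatrix"))
  tab <- data.frame(gene_id = pb$gene_ids, pb$values, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(tab, values_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(as.data.frame(pb$design), design_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(values_path)
}

#' @rdname write_pseudobulk
#' @export
read_pseudobulk <- function(values_path, design_path) {
  tab <- utils::read.table(values_path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  d <- utils::read.table(design_path, header = TRUE, sep = "\t",
                         check.names = FALSE, stringsAsFactors = FALSE)
  if (!"obs_id" %in% names(d)) stop("design file lacks an obs_id column")
  design <- observation_design(d$obs_id, d$f1, d$f2,
                               f3 = if ("f3" %in% names(d)) d$f3,
                               subject = if ("subject" %in% names(d))
                                 d$subject)
  values <- as.matrix(tab[, -1, drop = FALSE])
  pseudobulk_matrix(values, design, gene_ids = as.character(tab$gene_id))
}
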