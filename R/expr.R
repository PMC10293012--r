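#' Expression matrix with sample metadata
#'
#' Light container for a genes x samples (or genes x cells) count matrix and
#' its per-column metadata, the common currency of the bulk-processing and
#' classification functions. Counts may be a base matrix or a sparse
#' [Matrix::dgCMatrix-class].
#'
#' @param counts non-negative count matrix with unique rownames (gene IDs) and
#'   unique colnames (sample or cell IDs).
#' @param meta data.frame with one row per column of `counts`; typically
#'   carries `patient`, `compartment` (`"blood"`/`"tumor"`), `population`
#'   (`"CD4"`, `"CD8"`, `"CD45neg"`, `"MG"`, `"MDM"`) and `disease`
#'   (`"glioma"`, `"BrM-pTRT-low"`, `"BrM-pTRT-high"`, `"unknown"`).
#'
#' @return An object of class `"expr_matrix"`: a list with elements `counts`
#'   and `meta`.
#' @export
expression_matrix <- function(counts, meta) {
  stop_if(is.null(rownames(counts)) || anyDuplicated(rownames(counts)) > 0,
          "counts must have unique rownames (gene IDs)")
  stop_if(ncol(counts) > 0 &&
            (is.null(colnames(counts)) || anyDuplicated(colnames(counts)) > 0),
          "counts must have unique colnames (sample IDs)")
  stop_if(length(counts) > 0 && min(counts) < 0, "counts must be non-negative")
  stop_if(!is.data.frame(meta) || nrow(meta) != ncol(counts),
          "meta must be a data.frame with one row per sample")
  rownames(meta) <- colnames(counts)
  structure(list(counts = counts, meta = meta), class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d genes x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  if (ncol(x$counts) > 0 && "population" %in% names(x$meta))
    print(table(x$meta$population, x$meta$compartment))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$counts)

#' Subset an expression matrix
#'
#' @param x an [expression_matrix()].
#' @param genes,samples index vectors (names, logical or integer) applied to
#'   rows and columns respectively; `NULL` keeps everything.
#' @return the subsetted `expr_matrix`.
#' @export
subset_expr <- function(x, genes = NULL, samples = NULL) {
  counts <- x$counts
  meta <- x$meta
  if (!is.null(genes)) counts <- counts[genes, , drop = FALSE]
  if (!is.null(samples)) {
    counts <- counts[, samples, drop = FALSE]
    meta <- meta[samples, , drop = FALSE]
  }
  expression_matrix(counts, meta)
}
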