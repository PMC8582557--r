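#' Annotated single-cell count matrix
#'
#' Bundles a gene-by-cell count matrix with the per-cell annotations the
#' pipeline needs: cell type, subject (biopsy donor) and disease stage
#' (e.g. NAG/CAG/IM/EGC for the gastritis-to-early-cancer cascade).
#'
#' @param counts gene x cell matrix of non-negative integer counts; dense or
#'   a \code{Matrix} sparse matrix. Row names are gene ids, column names cell
#'   ids (generated when absent).
#' @param cell_type,subject,stage character vectors, one entry per cell.
#' @return An object of class \code{annotated_counts}: a list with elements
#'   \code{counts}, \code{cell_type}, \code{subject}, \code{stage}.
#' @export
annotated_counts <- function(counts, cell_type, subject, stage) {
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("gene", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("cell", seq_len(ncol(counts)))
  n <- ncol(counts)
  cell_type <- as.character(cell_type)
  subject <- as.character(subject)
  stage <- as.character(stage)
  if (length(cell_type) != n || length(subject) != n || length(stage) != n)
    stop("per-cell annotation length must equal the number of cells (",
         n, ")")
  if (any(counts < 0)) stop("counts must be non-negative")
  structure(
    list(counts = counts, cell_type = cell_type,
         subject = subject, stage = stage),
    class = "annotated_counts")
}

#' @export
print.annotated_counts <- function(x, ...) {
  cat(sprintf(
    "annotated_counts: %d genes x %d cells; %d cell types, %d subjects, %d stages\n",
    nrow(x$counts), ncol(x$counts), length(unique(x$cell_type)),
    length(unique(x$subject)), length(unique(x$stage))))
  invisible(x)
}

#' @export
dim.annotated_counts <- function(x) dim(x$counts)

#' Subset an annotated_counts object by cells and/or genes
#'
#' @param x an \code{annotated_counts} object.
#' @param genes,cells logical, integer or character index vectors.
#' @return The subsetted \code{annotated_counts}.
#' @export
subset_cells <- function(x, cells = NULL, genes = NULL) {
  stopifnot(inherits(x, "annotated_counts"))
  if (is.null(cells)) cells <- seq_len(ncol(x$counts))
  if (is.character(cells)) cells <- match(cells, colnames(x$counts))
  if (is.logical(cells)) cells <- which(cells)
  if (is.null(genes)) genes <- seq_len(nrow(x$counts))
  annotated_counts(x$counts[genes, cells, drop = FALSE],
                   x$cell_type[cells], x$subject[cells], x$stage[cells])
}

#' Write an annotated_counts object as MatrixMarket + TSV sidecar
#'
#' The counts go to \code{<prefix>.mtx} with gene ids in
#' \code{<prefix>.genes.tsv}; the cell annotations go to
#' \code{<prefix>.cells.tsv} with columns cell_id, cell_type, subject, stage.
#'
#' @param x an \code{annotated_counts} object.
#' @param prefix path prefix for the three output files.
#' @return Invisibly, the paths written.
#' @export
write_annotated_counts <- function(x, prefix) {
  stopifnot(inherits(x, "annotated_counts"))
  m <- methods::as(methods::as(x$counts, "dMatrix"), "sparseMatrix")
  paths <- paste0(prefix, c(".mtx", ".genes.tsv", ".cells.tsv"))
  Matrix::writeMM(m, paths[1])
  utils::write.table(data.frame(gene = rownames(x$counts)), paths[2],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(cell_id = colnames(x$counts), cell_type = x$cell_type,
               subject = x$subject, stage = x$stage),
    paths[3], sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}

#' Read an annotated_counts object written by write_annotated_counts
#'
#' @param prefix path prefix used when writing.
#' @return An \code{annotated_counts} object (sparse counts).
#' @export
read_annotated_counts <- function(prefix) {
  m <- Matrix::readMM(paste0(prefix, ".mtx"))
  genes <- utils::read.delim(paste0(prefix, ".genes.tsv"),
                             stringsAsFactors = FALSE)$gene
  ann <- utils::read.delim(paste0(prefix, ".cells.tsv"),
                           stringsAsFactors = FALSE)
  rownames(m) <- genes
  colnames(m) <- ann$cell_id
  annotated_counts(m, ann$cell_type, ann$subject, ann$stage)
}
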