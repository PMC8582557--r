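# Quality control and pseudobulk summarisation of the single-cell reference.

#' Quality-control configuration
#'
#' Thresholds follow the literal reading of the filters applied to the
#' gastric single-cell reference: cell types are kept when they have more
#' than \code{min_cells_per_type} cells spanning at least
#' \code{min_stages_per_type} stages; cells with fewer than
#' \code{min_genes_per_cell} expressed genes are dropped; genes detected in
#' less than \code{min_gene_cell_fraction} of the remaining cells are
#' dropped. The filter order is fixed: type-level, then cell-level, then
#' gene-level.
#'
#' @param min_genes_per_cell keep cells with at least this many expressed
#'   genes (default 500).
#' @param min_gene_cell_fraction keep genes detected in at least this
#'   fraction of cells (default 0.02).
#' @param min_cells_per_type strict lower bound on cells per kept type
#'   (default 20, i.e. keep types with > 20 cells).
#' @param min_stages_per_type minimum number of stages a kept type must span
#'   (default 2).
#' @return A list of class \code{qc_config}.
#' @export
qc_config <- function(min_genes_per_cell = 500,
                      min_gene_cell_fraction = 0.02,
                      min_cells_per_type = 20,
                      min_stages_per_type = 2) {
  if (min_genes_per_cell <= 0 || min_gene_cell_fraction <= 0 ||
      min_cells_per_type <= 0 || min_stages_per_type <= 0)
    stop("all QC thresholds must be positive")
  structure(as.list(environment()), class = "qc_config")
}

#' Apply the reference QC filters
#'
#' @param data an \code{\link{annotated_counts}} object.
#' @param cfg a \code{\link{qc_config}}.
#' @return The filtered \code{annotated_counts}.
#' @export
qc_filter <- function(data, cfg = qc_config()) {
  stopifnot(inherits(data, "annotated_counts"), inherits(cfg, "qc_config"))
  if (ncol(data$counts) == 0) stop("data is empty")

  # 1. type level: > min_cells_per_type cells at >= min_stages_per_type stages
  tab <- table(data$cell_type)
  stages_per_type <- tapply(data$stage, data$cell_type,
                            function(s) length(unique(s)))
  keep_types <- names(tab)[tab > cfg$min_cells_per_type &
                           stages_per_type[names(tab)] >= cfg$min_stages_per_type]
  keep_cell <- data$cell_type %in% keep_types

  # 2. cell level: "fewer than K expressed genes" removed, so keep >= K
  genes_per_cell <- Matrix::colSums(data$counts > 0)
  keep_cell <- keep_cell & genes_per_cell >= cfg$min_genes_per_cell
  if (!any(keep_cell)) stop("all cells filtered out")

  sub <- subset_cells(data, cells = keep_cell)

  # 3. gene level: "detected in less than f of cells" removed, so keep >= f
  det_frac <- Matrix::rowSums(sub$counts > 0) / ncol(sub$counts)
  keep_gene <- det_frac >= cfg$min_gene_cell_fraction
  if (!any(keep_gene)) stop("all genes filtered out")
  subset_cells(sub, genes = keep_gene)
}

#' Pseudobulk summarisation
#'
#' Sums counts over all cells sharing a grouping key, producing one profile
#' per group. Grouping keys are built from any combination of the annotation
#' fields (plus an optional per-cell \code{population} vector).
#'
#' @param data an \code{\link{annotated_counts}} object.
#' @param group_by character vector naming annotation fields to group by,
#'   e.g. \code{c("cell_type", "subject")}.
#' @param population optional per-cell population labels usable in
#'   \code{group_by} as \code{"population"}.
#' @return A list of class \code{pseudobulk}: \code{values} (gene x group
#'   matrix of summed counts), \code{groups} (data.frame of key columns,
#'   one row per output column) and \code{normalized = FALSE}.
#' @export
pseudobulk_summarize <- function(data, group_by = c("cell_type", "subject"),
                                 population = NULL) {
  stopifnot(inherits(data, "annotated_counts"))
  fields <- list(cell_type = data$cell_type, subject = data$subject,
                 stage = data$stage)
  if (!is.null(population)) fields$population <- as.character(population)
  bad <- setdiff(group_by, names(fields))
  if (length(bad)) stop("unknown grouping label(s): ",
                        paste(bad, collapse = ", "))
  keyvars <- fields[group_by]
  key <- do.call(paste, c(keyvars, sep = "\r"))
  lev <- unique(key)
  idx <- split(seq_along(key), factor(key, levels = lev))
  vals <- vapply(idx, function(i)
    as.numeric(Matrix::rowSums(data$counts[, i, drop = FALSE])),
    numeric(nrow(data$counts)))
  rownames(vals) <- rownames(data$counts)
  parts <- do.call(rbind, strsplit(lev, "\r", fixed = TRUE))
  groups <- as.data.frame(parts, stringsAsFactors = FALSE)
  names(groups) <- group_by
  colnames(vals) <- do.call(paste, c(groups, sep = "|"))
  structure(list(values = vals, groups = groups, normalized = FALSE),
            class = "pseudobulk")
}

#' @export
print.pseudobulk <- function(x, ...) {
  cat(sprintf("pseudobulk: %d genes x %d groups (%s)%s\n",
              nrow(x$values), ncol(x$values),
              paste(names(x$groups), collapse = " x "),
              if (x$normalized) ", TPM-normalized" else ""))
  invisible(x)
}

#' TPM normalisation of pseudobulk profiles
#'
#' Scales each column to sum to one million. For 3'-tag single-cell data no
#' gene-length term applies; for full-length data supply \code{gene_lengths}
#' (in any consistent unit) to divide counts by length before scaling.
#'
#' @param pb a \code{\link{pseudobulk_summarize}} result, or a plain gene x
#'   sample matrix.
#' @param gene_lengths optional named numeric vector of gene lengths.
#' @return Same shape as the input, with columns summing to 1e6 and, for
#'   pseudobulk input, \code{normalized = TRUE}.
#' @export
tpm_normalize <- function(pb, gene_lengths = NULL) {
  v <- if (inherits(pb, "pseudobulk")) pb$values else as.matrix(pb)
  if (!is.null(gene_lengths)) {
    len <- gene_lengths[rownames(v)]
    if (any(is.na(len)) || any(len <= 0))
      stop("gene_lengths must cover all genes with positive values")
    v <- v / len
  }
  tot <- colSums(v)
  if (any(tot <= 0)) {
    bad <- colnames(v)[tot <= 0]
    stop("all-zero profile(s): ", paste(bad, collapse = ", "))
  }
  v <- sweep(v, 2, tot, "/") * 1e6
  if (inherits(pb, "pseudobulk")) {
    pb$values <- v
    pb$normalized <- TRUE
    pb
  } else v
}
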