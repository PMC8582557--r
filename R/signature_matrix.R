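# Marker selection and signature-matrix construction (the GC10 analogue),
# artificial-bulk construction and the marker-depth (M) sweep.

#' Marker-selection configuration
#'
#' @param min_fold_change minimum fold change of a marker in its population
#'   versus the rest (default 2).
#' @param max_p one-way ANOVA significance threshold (default 0.01).
#' @param M_per_population markers kept per population (default 150).
#' @param M_grid candidate depths for \code{\link{choose_M}} (default
#'   seq(50, 250, 50)).
#' @param pseudocount added to fold-change numerator and denominator
#'   (default 1).
#' @return A list of class \code{marker_config}.
#' @export
marker_config <- function(min_fold_change = 2, max_p = 0.01,
                          M_per_population = 150,
                          M_grid = seq(50, 250, by = 50),
                          pseudocount = 1) {
  if (!length(M_grid) || is.unsorted(M_grid))
    stop("M_grid must be non-empty and sorted")
  structure(as.list(environment()), class = "marker_config")
}

# two-group one-way ANOVA F and p, vectorised over the rows of x
# (population columns `in_pop` vs the rest); equivalent to
# oneway.test(var.equal = TRUE) per gene.
.anova2_rows <- function(x, in_pop) {
  n1 <- sum(in_pop); n2 <- sum(!in_pop); n <- n1 + n2
  m1 <- rowMeans(x[, in_pop, drop = FALSE])
  m2 <- rowMeans(x[, !in_pop, drop = FALSE])
  gm <- (n1 * m1 + n2 * m2) / n
  ssb <- n1 * (m1 - gm)^2 + n2 * (m2 - gm)^2
  ssw <- rowSums((x[, in_pop, drop = FALSE] - m1)^2) +
         rowSums((x[, !in_pop, drop = FALSE] - m2)^2)
  df1 <- 1; df2 <- n - 2
  f <- (ssb / df1) / (ssw / df2)
  p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  p[ssw == 0 & ssb == 0] <- 1        # flat gene: no evidence
  p[ssw == 0 & ssb > 0] <- 0         # perfectly separated gene
  list(F = f, p = p)
}

#' Select population-specific marker genes
#'
#' For each population, genes at least \code{min_fold_change}-fold higher
#' (mean TPM, pseudocount-stabilised) in that population than in all other
#' populations and significant at \code{max_p} (one-way ANOVA of the
#' population's per-subject profiles versus the rest) are ranked by
#' descending fold change and the top \code{M_per_population} retained. Ties
#' are broken by smaller p, then gene id.
#'
#' @param pb a TPM-normalised \code{pseudobulk} grouped by population and
#'   subject (first grouping column is taken as the population label).
#' @param cfg a \code{\link{marker_config}}.
#' @return A list of class \code{marker_selection}: \code{markers} (named
#'   list of ordered gene ids per population) and \code{stats} (data.frame
#'   gene, population, fold_change, p_value, selected).
#' @export
select_markers <- function(pb, cfg = marker_config()) {
  stopifnot(inherits(pb, "pseudobulk"))
  pop <- pb$groups[[1]]
  pops <- unique(pop)
  if (length(pops) < 2) stop("need >= 2 populations")
  x <- pb$values
  stats_list <- list()
  markers <- list()
  for (p in pops) {
    in_pop <- pop == p
    fc <- (rowMeans(x[, in_pop, drop = FALSE]) + cfg$pseudocount) /
          (rowMeans(x[, !in_pop, drop = FALSE]) + cfg$pseudocount)
    an <- .anova2_rows(x, in_pop)
    ok <- fc >= cfg$min_fold_change & an$p <= cfg$max_p
    ord <- order(-fc, an$p, rownames(x))
    ord <- ord[ok[ord]]
    sel <- utils::head(ord, cfg$M_per_population)
    if (!length(sel))
      warning("population '", p, "' has no surviving marker genes")
    markers[[p]] <- rownames(x)[sel]
    stats_list[[p]] <- data.frame(
      gene = rownames(x), population = p, fold_change = fc,
      p_value = an$p, selected = seq_len(nrow(x)) %in% sel,
      row.names = NULL, stringsAsFactors = FALSE)
  }
  structure(list(markers = markers,
                 stats = do.call(rbind, stats_list)),
            class = "marker_selection")
}

#' Build a signature matrix from pseudobulk profiles and marker lists
#'
#' The signature is the per-population mean TPM profile restricted to the
#' union of the marker genes; a gene marking several populations appears
#' once.
#'
#' @param pb TPM-normalised \code{pseudobulk} grouped by population (and
#'   subject).
#' @param markers a \code{marker_selection} or a named list of gene id
#'   vectors per population.
#' @param name label for the matrix (e.g. "GC10").
#' @return A list of class \code{signature_matrix}: \code{values}
#'   (marker-gene x population mean-TPM matrix), \code{markers}, \code{name}.
#' @export
build_signature <- function(pb, markers, name = "signature") {
  stopifnot(inherits(pb, "pseudobulk"))
  if (inherits(markers, "marker_selection")) markers <- markers$markers
  genes <- unique(unlist(markers, use.names = FALSE))
  if (!length(genes)) stop("empty marker union")
  pop <- pb$groups[[1]]
  pops <- unique(pop)
  vals <- vapply(pops, function(p)
    rowMeans(pb$values[genes, pop == p, drop = FALSE]),
    numeric(length(genes)))
  rownames(vals) <- genes
  colnames(vals) <- pops
  structure(list(values = vals, markers = markers, name = name),
            class = "signature_matrix")
}

#' @export
print.signature_matrix <- function(x, ...) {
  cat(sprintf("signature_matrix '%s': %d genes x %d populations\n",
              x$name, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Construct artificial bulk profiles from a single-cell reference
#'
#' Sums counts across all cells of each biopsy (subject), yielding bulk-like
#' profiles whose true cell-population composition is known.
#'
#' @param data an \code{\link{annotated_counts}} object.
#' @param population per-cell population labels (defaults to cell types).
#' @param weight \code{"cells"} (true fractions = cell-count proportions,
#'   default) or \code{"umi"} (UMI-mass proportions).
#' @return A list: \code{bulk} (gene x biopsy summed counts) and
#'   \code{fractions} (biopsy x population true proportions, rows sum to 1).
#' @export
make_artificial_bulk <- function(data, population = NULL,
                                 weight = c("cells", "umi")) {
  stopifnot(inherits(data, "annotated_counts"))
  weight <- match.arg(weight)
  if (is.null(population)) population <- data$cell_type
  population <- as.character(population)
  subj <- unique(data$subject)
  pops <- unique(population)
  bulk <- vapply(subj, function(s)
    as.numeric(Matrix::rowSums(data$counts[, data$subject == s, drop = FALSE])),
    numeric(nrow(data$counts)))
  rownames(bulk) <- rownames(data$counts)
  w <- if (weight == "cells") rep(1, ncol(data$counts))
       else as.numeric(Matrix::colSums(data$counts))
  fr <- t(vapply(subj, function(s) {
    in_s <- data$subject == s
    tot <- tapply(w[in_s], factor(population[in_s], levels = pops), sum)
    tot[is.na(tot)] <- 0
    tot / sum(tot)
  }, numeric(length(pops))))
  colnames(fr) <- pops
  rownames(fr) <- subj
  list(bulk = bulk, fractions = fr)
}

#' Choose the marker depth M by deconvolution accuracy on artificial bulk
#'
#' For each M in the grid, marker lists are truncated to depth M, a
#' signature is built, the artificial bulk is deconvolved, and accuracy is
#' scored as the mean per-biopsy RMSE between estimated and true fractions
#' (Pearson r reported alongside). The arg-min M wins; ties go to the
#' smallest M.
#'
#' @param artificial a \code{\link{make_artificial_bulk}} result.
#' @param pb TPM-normalised population pseudobulk (for signature building).
#' @param markers a \code{marker_selection} (full-depth lists).
#' @param cfg a \code{\link{marker_config}} supplying \code{M_grid}.
#' @param deconv_cfg a \code{\link{deconv_config}}.
#' @return A list: \code{best_M} and \code{table} (data.frame M, rmse, r,
#'   truncated flag for grid values exceeding available markers).
#' @export
choose_M <- function(artificial, pb, markers, cfg = marker_config(),
                     deconv_cfg = deconv_config()) {
  if (inherits(markers, "marker_selection")) markers <- markers$markers
  truth <- artificial$fractions
  rows <- lapply(cfg$M_grid, function(M) {
    trunc_flag <- any(vapply(markers, length, 1L) < M)
    mk <- lapply(markers, utils::head, M)
    sig <- build_signature(pb, mk, name = paste0("M", M))
    fr <- deconvolve(sig, artificial$bulk, deconv_cfg)$fractions
    fr <- fr[rownames(truth), colnames(truth), drop = FALSE]
    rmse <- mean(sqrt(rowMeans((fr - truth)^2)))
    r <- if (stats::sd(truth) > 0 && stats::sd(fr) > 0)
      stats::cor(as.vector(fr), as.vector(truth)) else NA_real_
    data.frame(M = M, rmse = rmse, r = r, truncated = trunc_flag)
  })
  tab <- do.call(rbind, rows)
  list(best_M = tab$M[which.min(tab$rmse)], table = tab)
}

#' Merge fine-grained fractions into major lineages
#'
#' Sums fraction columns by a fine-type to lineage map (e.g. 17 immune cell
#' types into 7 lineages: adaptive T, innate T, adaptive B, NK, monocytes,
#' dendritic cells, granulocytes). Total mass per sample is conserved.
#'
#' @param fractions samples x fine-type matrix (or data.frame).
#' @param map named character vector: fine type -> lineage label; must cover
#'   every column of \code{fractions}.
#' @return samples x lineage matrix with the same row sums.
#' @export
merge_lineages <- function(fractions, map) {
  fractions <- as.matrix(fractions)
  miss <- setdiff(colnames(fractions), names(map))
  if (length(miss)) stop("unmapped fine type(s): ",
                         paste(miss, collapse = ", "))
  lin <- unname(map[colnames(fractions)])
  lev <- unique(lin)
  out <- vapply(lev, function(l)
    rowSums(fractions[, lin == l, drop = FALSE]),
    numeric(nrow(fractions)))
  if (nrow(fractions) == 1) out <- matrix(out, 1, dimnames = list(rownames(fractions), lev))
  colnames(out) <- lev
  rownames(out) <- rownames(fractions)
  out
}

#' Write a signature matrix as TSV (genes x populations)
#'
#' @param sig a \code{signature_matrix}.
#' @param path output file; gene ids in the first column, population names
#'   in the header — the shape CIBERSORT-style tools consume.
#' @return Invisibly, \code{path}.
#' @export
write_signature_tsv <- function(sig, path) {
  stopifnot(inherits(sig, "signature_matrix"))
  df <- data.frame(gene = rownames(sig$values), sig$values,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a signature matrix from TSV
#'
#' @param path TSV with gene ids in column 1 and one column per population.
#' @param name label for the matrix.
#' @return A \code{signature_matrix} (marker lists set to all genes per
#'   population).
#' @export
read_signature_tsv <- function(path, name = "signature") {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  vals <- as.matrix(df[, -1, drop = FALSE])
  rownames(vals) <- df[[1]]
  structure(list(values = vals,
                 markers = stats::setNames(
                   rep(list(rownames(vals)), ncol(vals)), colnames(vals)),
                 name = name),
            class = "signature_matrix")
}
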