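# Cell-type-specific gene ranking by two-way ANOVA and discovery of cell
# populations from a hierarchical tree over (cell type, stage) mean profiles.

#' Clustering configuration for population discovery
#'
#' @param N_top_genes number of top-ranked genes used to build the tree
#'   (default 100).
#' @param pseudocount added before the log2 transform (default 1).
#' @param distance \code{"one_minus_r2"} (default, 1 - Pearson r squared) or
#'   \code{"one_minus_r"}. The default treats strong anti-correlation as
#'   similarity; it is retained as the reference behaviour.
#' @return A list of class \code{cluster_config}. Linkage is fixed to Ward.
#' @export
cluster_config <- function(N_top_genes = 100, pseudocount = 1,
                           distance = c("one_minus_r2", "one_minus_r")) {
  if (N_top_genes < 2) stop("N_top_genes must be >= 2")
  if (pseudocount <= 0) stop("pseudocount must be positive")
  distance <- match.arg(distance)
  structure(list(N_top_genes = N_top_genes, pseudocount = pseudocount,
                 distance = distance, linkage = "ward"),
            class = "cluster_config")
}

#' Rank genes by the two-way ANOVA cell-type versus subject criterion
#'
#' Fits, per gene, an additive two-way ANOVA of log2(TPM + pseudocount) on
#' cell type and subject (type-II sums of squares for unbalanced designs) on
#' the (cell type, subject) pseudobulk profiles, and ranks genes by the ratio
#' of the cell-type F statistic to the subject F statistic. Genes with zero
#' subject F are ranked by cell-type F above all finite ratios; zero-variance
#' genes are excluded.
#'
#' @param pb a TPM-normalised \code{pseudobulk} grouped by cell_type and
#'   subject (columns \code{cell_type}, \code{subject} in \code{pb$groups}).
#' @param cfg a \code{\link{cluster_config}}.
#' @param n_top number of top genes returned; defaults to
#'   \code{cfg$N_top_genes}. Use \code{Inf} for the full ranking.
#' @return A data.frame with columns gene, F_celltype, F_subject, ratio,
#'   rank, ordered by rank; attribute \code{n_excluded} counts zero-variance
#'   genes.
#' @export
rank_genes_anova <- function(pb, cfg = cluster_config(), n_top = cfg$N_top_genes) {
  stopifnot(inherits(pb, "pseudobulk"))
  if (!all(c("cell_type", "subject") %in% names(pb$groups)))
    stop("pseudobulk must be grouped by cell_type and subject")
  ct <- factor(pb$groups$cell_type)
  sb <- factor(pb$groups$subject)
  if (nlevels(ct) < 2 || nlevels(sb) < 2)
    stop("need >= 2 cell types and >= 2 subjects")
  x <- log2(pb$values + cfg$pseudocount)

  res <- apply(x, 1, function(y) {
    if (stats::var(y) == 0) return(c(NA_real_, NA_real_))
    fit <- stats::lm(y ~ ct + sb)
    a <- tryCatch(car::Anova(fit, type = 2),
                  error = function(e) NULL)
    if (is.null(a)) return(c(NA_real_, NA_real_))
    c(a["ct", "F value"], a["sb", "F value"])
  })
  F_ct <- res[1, ]
  F_sb <- res[2, ]
  keep <- is.finite(F_ct)
  n_excluded <- sum(!keep)
  F_ct <- F_ct[keep]; F_sb <- F_sb[keep]
  ratio <- ifelse(F_sb > 0, F_ct / F_sb, Inf)
  # infinite ratios (F_subject = 0) rank first, ordered by F_celltype
  ord <- order(-is.infinite(ratio), ifelse(is.infinite(ratio), -F_ct, -ratio))
  out <- data.frame(gene = rownames(pb$values)[keep][ord],
                    F_celltype = F_ct[ord], F_subject = F_sb[ord],
                    ratio = ratio[ord], rank = seq_along(ord),
                    stringsAsFactors = FALSE)
  if (is.finite(n_top)) out <- out[seq_len(min(n_top, nrow(out))), ]
  attr(out, "n_excluded") <- n_excluded
  out
}

#' Mean expression profiles per (cell type, stage)
#'
#' Builds per-(cell type, stage) mean profiles from annotated counts by
#' pseudobulking on (cell_type, stage, subject), TPM-normalising, then
#' averaging over subjects within each (cell type, stage). These are the
#' leaves the cluster tree is grown on.
#'
#' @param data a QC-filtered \code{\link{annotated_counts}} object.
#' @param genes optional gene subset (e.g. the top-ranked genes).
#' @return A gene x "celltype|stage" matrix of mean TPM.
#' @export
mean_profiles_by_type_stage <- function(data, genes = NULL) {
  pb <- pseudobulk_summarize(data, c("cell_type", "stage", "subject"))
  pb <- tpm_normalize(pb)
  key <- paste(pb$groups$cell_type, pb$groups$stage, sep = "|")
  lev <- unique(key)
  m <- vapply(lev, function(k)
    rowMeans(pb$values[, key == k, drop = FALSE]),
    numeric(nrow(pb$values)))
  colnames(m) <- lev
  if (!is.null(genes)) m <- m[intersect(genes, rownames(m)), , drop = FALSE]
  m
}

#' Build the hierarchical cluster tree over mean profiles
#'
#' Profiles are log2(x + pseudocount) transformed; the pairwise distance is
#' 1 - r^2 (Pearson) and agglomeration uses Ward's linkage.
#'
#' @param mean_profiles gene x leaf matrix (leaves are "celltype|stage"
#'   labels), typically restricted to the top-N ranked genes.
#' @param cfg a \code{\link{cluster_config}}.
#' @return A list of class \code{cluster_tree}: \code{hclust} (the tree) and
#'   \code{leaves} (leaf labels).
#' @export
build_cluster_tree <- function(mean_profiles, cfg = cluster_config()) {
  m <- log2(as.matrix(mean_profiles) + cfg$pseudocount)
  if (ncol(m) < 2) stop("need >= 2 leaves")
  r <- stats::cor(m)
  d <- if (cfg$distance == "one_minus_r2") 1 - r^2 else 1 - r
  hc <- stats::hclust(stats::as.dist(d), method = "ward.D2")
  structure(list(hclust = hc, leaves = colnames(m), distance = cfg$distance),
            class = "cluster_tree")
}

#' Cut the tree into k populations and propagate labels to cells
#'
#' Each (cell type, stage) leaf is assigned to one of \code{k} clusters;
#' single cells inherit the population of their leaf. Cluster numbers can be
#' renamed via \code{label_map} (e.g. to EMEC, PMEC, stromal, ...).
#'
#' @param tree a \code{\link{build_cluster_tree}} result.
#' @param k number of populations (default 10).
#' @param data optional \code{annotated_counts}; when given, per-cell
#'   population labels are returned as well.
#' @param label_map optional named vector renaming cluster ids ("1".."k").
#' @return A list: \code{leaf_population} (named vector leaf -> population)
#'   and, when \code{data} is supplied, \code{cell_population}.
#' @export
assign_populations <- function(tree, k = 10, data = NULL, label_map = NULL) {
  stopifnot(inherits(tree, "cluster_tree"))
  if (k > length(tree$leaves)) stop("fewer leaves than requested clusters")
  cl <- stats::cutree(tree$hclust, k = k)
  lab <- as.character(cl)
  if (!is.null(label_map)) {
    miss <- setdiff(unique(lab), names(label_map))
    if (length(miss)) stop("label_map missing cluster(s): ",
                           paste(miss, collapse = ", "))
    lab <- unname(label_map[lab])
  }
  leaf_pop <- stats::setNames(lab, tree$leaves)
  out <- list(leaf_population = leaf_pop)
  if (!is.null(data)) {
    stopifnot(inherits(data, "annotated_counts"))
    key <- paste(data$cell_type, data$stage, sep = "|")
    miss <- setdiff(unique(key), names(leaf_pop))
    if (length(miss)) stop("leaf missing from tree: ",
                           paste(miss, collapse = ", "))
    out$cell_population <- unname(leaf_pop[key])
  }
  out
}

#' Report population-assignment stability across top-N choices
#'
#' Rebuilds the tree for each N in \code{N_grid} and reports the adjusted
#' agreement of each cut with the reference N (first grid element), as a
#' diagnostic for sensitivity of the population structure to N.
#'
#' @param data QC-filtered \code{annotated_counts}.
#' @param pb (cell_type, subject) TPM pseudobulk for ranking.
#' @param k cluster count.
#' @param N_grid candidate top-N values.
#' @param cfg a \code{\link{cluster_config}}.
#' @return data.frame with columns N and agreement (fraction of leaves whose
#'   co-membership pattern matches the reference cut).
#' @export
population_stability <- function(data, pb, k = 10,
                                 N_grid = c(50, 100, 150, 200),
                                 cfg = cluster_config()) {
  cuts <- lapply(N_grid, function(N) {
    rk <- rank_genes_anova(pb, cfg, n_top = N)
    mp <- mean_profiles_by_type_stage(data, rk$gene)
    assign_populations(build_cluster_tree(mp, cfg), k = k)$leaf_population
  })
  ref <- cuts[[1]]
  pair_agree <- function(a, b) {
    a <- a[names(ref)]; b <- b[names(ref)]
    pa <- outer(a, a, "=="); pb2 <- outer(b, b, "==")
    mean(pa[upper.tri(pa)] == pb2[upper.tri(pb2)])
  }
  data.frame(N = N_grid,
             agreement = vapply(cuts, pair_agree, numeric(1), b = ref))
}

#' Write a cluster tree in Newick format
#'
#' @param tree a \code{\link{build_cluster_tree}} result.
#' @param path output file.
#' @return Invisibly, \code{path}.
#' @export
write_tree_newick <- function(tree, path) {
  stopifnot(inherits(tree, "cluster_tree"))
  phy <- ape::as.phylo(tree$hclust)
  ape::write.tree(phy, file = path)
  invisible(path)
}
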