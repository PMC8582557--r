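# Two-way ANOVA gene ranking and hierarchical population discovery.

# pseudobulk object wrapping a gene x (cell type x subject) TPM matrix
pb_from_matrix <- function(vals, cell_type, subject) {
  structure(list(values = vals,
                 groups = data.frame(cell_type = cell_type,
                                     subject = subject,
                                     stringsAsFactors = FALSE),
                 normalized = TRUE),
            class = "pseudobulk")
}

test_that("ANOVA F values match a from-scratch balanced oracle", {
  set.seed(21)
  ct <- rep(c("A", "B", "C"), each = 3)
  sb <- rep(c("s1", "s2", "s3"), times = 3)
  vals <- matrix(rexp(5 * 9, 1 / 50), 5, 9,
                 dimnames = list(paste0("g", 1:5), NULL))
  pb <- pb_from_matrix(vals, ct, sb)
  rk <- rank_genes_anova(pb, cluster_config(), n_top = Inf)
  for (g in rownames(vals)) {
    y <- log2(vals[g, ] + 1)
    oracle <- balanced_anova_F(y, ct, sb)
    row <- rk[rk$gene == g, ]
    expect_equal(row$F_celltype, unname(oracle["F_a"]), tolerance = 1e-8)
    expect_equal(row$F_subject, unname(oracle["F_b"]), tolerance = 1e-8)
  }
})

test_that("ranking excludes flat genes and demotes subject-driven genes", {
  set.seed(22)
  ct <- rep(c("A", "B", "C"), each = 4)
  sb <- rep(paste0("s", 1:4), times = 3)
  n_genes <- 40
  vals <- matrix(rexp(n_genes * 12, 1 / 20), n_genes, 12,
                 dimnames = list(sprintf("g%02d", 1:n_genes), NULL))
  vals["g01", ] <- 7                                  # flat
  subj_eff <- c(s1 = 1, s2 = 8, s3 = 20, s4 = 50)
  vals["g02", ] <- subj_eff[sb] * exp(rnorm(12, 0, 0.01))  # subject only
  vals["g03", ] <- c(A = 1, B = 40, C = 120)[ct] *
    exp(rnorm(12, 0, 0.01))                           # cell type only
  pb <- pb_from_matrix(vals, ct, sb)
  rk <- rank_genes_anova(pb, cluster_config(), n_top = Inf)
  expect_false("g01" %in% rk$gene)
  expect_equal(attr(rk, "n_excluded"), 1)
  expect_equal(rk$gene[1], "g03")
  top10 <- rank_genes_anova(pb, cluster_config(), n_top = 10)$gene
  expect_false("g02" %in% top10)
})

test_that("ranking is invariant to column permutation", {
  set.seed(23)
  ct <- rep(c("A", "B"), each = 4)
  sb <- rep(paste0("s", 1:4), 2)
  vals <- matrix(rexp(30 * 8, 1 / 30), 30, 8,
                 dimnames = list(paste0("g", 1:30), NULL))
  pb <- pb_from_matrix(vals, ct, sb)
  perm <- sample(8)
  pb2 <- pb_from_matrix(vals[, perm], ct[perm], sb[perm])
  r1 <- rank_genes_anova(pb, n_top = Inf)
  r2 <- rank_genes_anova(pb2, n_top = Inf)
  expect_identical(r1$gene, r2$gene)
  expect_equal(r1$ratio, r2$ratio, tolerance = 1e-10)
})

test_that("the 1 - r^2 metric merges identical and anti-correlated leaves first", {
  base <- c(1, 2, 3, 4, 5, 6)
  m <- cbind(leafA = base, leafB = base,               # r = 1
             leafC = rev(base),                        # r = -1 with A on log scale? use raw
             leafD = c(2, 9, 4, 1, 7, 3))
  # use pseudocount 1; correlations computed on log2(m+1)
  tr <- build_cluster_tree(m, cluster_config())
  h <- tr$hclust
  first <- sort(h$merge[1, ])
  # identical profiles must merge at height ~0 first
  expect_equal(sort(h$labels[-first]), c("leafA", "leafB"))
  expect_lt(h$height[1], 1e-12)

  # an exactly anti-correlated pair also has distance 0 under 1 - r^2
  l <- log2(m + 1)
  x <- l[, 1]; y <- max(x) + min(x) - x                # r = -1 on log scale
  m2 <- cbind(P = 2^x - 1, Q = 2^y - 1, R = m[, 4])
  tr2 <- build_cluster_tree(m2, cluster_config())
  expect_lt(tr2$hclust$height[1], 1e-12)
  expect_setequal(tr2$hclust$labels[sort(tr2$hclust$merge[1, ]) * -1],
                  c("P", "Q"))

  # the 1 - r alternative keeps the anti-correlated pair far apart
  tr3 <- build_cluster_tree(m2, cluster_config(distance = "one_minus_r"))
  expect_gt(tr3$hclust$height[1], 1e-12)
})

test_that("planted block structure is recovered by the tree cut", {
  set.seed(24)
  G <- 60
  blocks <- rep(1:3, each = 4)
  profiles <- sapply(blocks, function(b) {
    base <- rep(1, G)
    base[((b - 1) * 20 + 1):(b * 20)] <- 50
    base * exp(rnorm(G, 0, 0.1))
  })
  colnames(profiles) <- paste0("leaf", seq_along(blocks))
  tr <- build_cluster_tree(profiles)
  cut <- assign_populations(tr, k = 3)$leaf_population
  expect_equal(mclust::adjustedRandIndex(cut, blocks), 1.0)

  # k = 1 and k = number of leaves are the degenerate cuts
  expect_length(unique(assign_populations(tr, k = 1)$leaf_population), 1)
  expect_length(unique(assign_populations(tr, k = 12)$leaf_population), 12)
  expect_error(assign_populations(tr, k = 13), "fewer leaves")
})

test_that("tree is invariant to uniform rescaling of profiles", {
  set.seed(25)
  m <- matrix(rexp(40 * 6, 1 / 10), 40, 6,
              dimnames = list(NULL, paste0("L", 1:6)))
  # Pearson r is scale-invariant; the log transform is not, so compare
  # trees built on the same log-scale profiles shifted by a constant factor
  cfg <- cluster_config(pseudocount = 0.001)
  t1 <- build_cluster_tree(m, cfg)
  t2 <- build_cluster_tree(m * 1000, cfg)
  expect_equal(stats::cutree(t1$hclust, 3)[t1$leaves],
               stats::cutree(t2$hclust, 3)[t2$leaves])
})

test_that("cells inherit their leaf's population and maps are checked", {
  sim <- small_sc(seed = 26, n_genes = 300)
  d <- qc_filter(sim$data, qc_config(min_genes_per_cell = 20))
  pb <- tpm_normalize(pseudobulk_summarize(d, c("cell_type", "subject")))
  rk <- rank_genes_anova(pb, n_top = 50)
  mp <- mean_profiles_by_type_stage(d, rk$gene)
  tr <- build_cluster_tree(mp)
  asg <- assign_populations(tr, k = 3, data = d)
  expect_length(asg$cell_population, ncol(d$counts))
  key <- paste(d$cell_type, d$stage, sep = "|")
  expect_identical(asg$cell_population, unname(asg$leaf_population[key]))
  expect_error(assign_populations(tr, k = 3, data = d,
                                  label_map = c(`1` = "x")),
               "label_map missing")
  # newick export round-trips leaf labels
  path <- file.path(tempdir(), "tree.nwk")
  write_tree_newick(tr, path)
  phy <- ape::read.tree(path)
  expect_setequal(phy$tip.label, tr$leaves)
})
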