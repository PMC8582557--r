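# Marker selection, signature construction, artificial bulk and the
# marker-depth sweep.

pb_pop <- function(vals, population, subject) {
  structure(list(values = vals,
                 groups = data.frame(population = population,
                                     subject = subject,
                                     stringsAsFactors = FALSE),
                 normalized = TRUE),
            class = "pseudobulk")
}

test_that("marker selection ranks exclusive genes first and enforces both filters", {
  set.seed(31)
  pop <- rep(c("A", "B"), each = 4)
  sb <- rep(paste0("s", 1:4), 2)
  vals <- matrix(rexp(20 * 8, 1 / 10), 20, 8,
                 dimnames = list(sprintf("g%02d", 1:20), NULL))
  vals["g01", ] <- ifelse(pop == "A", 5000, 0)      # exclusive to A
  # fold change ~3 but noisy within groups -> non-significant
  vals["g02", ] <- ifelse(pop == "A", 30, 10) * exp(rnorm(8, 0, 2))
  pb <- pb_pop(vals, pop, sb)
  sel <- select_markers(pb, marker_config(M_per_population = 5))
  expect_equal(sel$markers$A[1], "g01")
  st2 <- sel$stats[sel$stats$gene == "g02" & sel$stats$population == "A", ]
  if (st2$fold_change >= 2 && st2$p_value > 0.01)
    expect_false(st2$selected)
  # every selected gene satisfies both thresholds
  ok <- sel$stats[sel$stats$selected, ]
  expect_true(all(ok$fold_change >= 2 & ok$p_value <= 0.01))
})

test_that("the vectorised one-way ANOVA matches oneway.test", {
  set.seed(32)
  pop <- rep(c("A", "B", "C"), each = 3)
  vals <- matrix(rexp(6 * 9, 1 / 10), 6, 9,
                 dimnames = list(paste0("g", 1:6), NULL))
  an <- tmescore:::.anova2_rows(log2(vals + 1), pop == "A")
  for (g in 1:6) {
    ref <- stats::oneway.test(log2(vals[g, ] + 1) ~ (pop == "A"),
                              var.equal = TRUE)
    expect_equal(unname(an$F[g]), unname(ref$statistic), tolerance = 1e-10)
    expect_equal(unname(an$p[g]), ref$p.value, tolerance = 1e-10)
  }
})

test_that("planted markers are recovered with high precision", {
  precisions <- sapply(1:3, function(seed) {
    sim <- small_sc(seed = seed)
    d <- sim$data
    pb <- tpm_normalize(pseudobulk_summarize(d, c("cell_type", "subject")))
    sel <- select_markers(pb, marker_config(M_per_population = 50))
    mean(sapply(names(sel$markers), function(tp)
      mean(sel$markers[[tp]] %in% sim$markers[[tp]])))
  })
  expect_gte(mean(precisions), 0.9)
})

test_that("signature rows are the union of marker lists", {
  set.seed(33)
  pop <- rep(c("A", "B"), each = 2)
  vals <- matrix(rexp(10 * 4, 1 / 10), 10, 4,
                 dimnames = list(paste0("g", 1:10), NULL))
  pb <- pb_pop(vals, pop, rep(c("s1", "s2"), 2))
  sig <- build_signature(pb, list(A = c("g1", "g2", "g3"),
                                  B = c("g2", "g3", "g4")))
  expect_equal(nrow(sig$values), 4)            # union with overlap
  sig2 <- build_signature(pb, list(A = paste0("g", 1:3),
                                   B = paste0("g", 6:8)))
  expect_equal(nrow(sig2$values), 6)           # disjoint union
  # per-population mean restricted to markers
  expect_equal(unname(sig$values["g1", "A"]),
               mean(vals["g1", pop == "A"]))
  expect_error(build_signature(pb, list(A = character(0))), "empty")
})

test_that("artificial bulk equals a column-sum oracle with cell-count truths", {
  sim <- small_sc(seed = 34, n_genes = 200)
  d <- sim$data
  ab <- make_artificial_bulk(d)
  for (s in unique(d$subject)) {
    expect_equal(unname(ab$bulk[, s]),
                 unname(rowSums(as.matrix(d$counts[, d$subject == s]))))
    tab <- table(factor(d$cell_type[d$subject == s],
                        levels = colnames(ab$fractions)))
    expect_equal(unname(ab$fractions[s, ]),
                 unname(as.numeric(tab / sum(tab))))
  }
  expect_equal(unname(rowSums(ab$fractions)),
               rep(1, nrow(ab$fractions)))

  # single-population biopsy gives a unit basis vector
  one <- subset_cells(d, cells = d$cell_type == "typeA" & d$subject == "P1")
  ab1 <- make_artificial_bulk(one)
  expect_equal(as.numeric(ab1$fractions), 1)

  # UMI weighting reweights by per-cell totals
  ab_umi <- make_artificial_bulk(d, weight = "umi")
  expect_equal(unname(rowSums(ab_umi$fractions)),
               rep(1, nrow(ab_umi$fractions)))
})

test_that("choose_M scores the grid and breaks ties toward the smallest M", {
  sim <- small_sc(seed = 35)
  d <- sim$data
  pb <- tpm_normalize(pseudobulk_summarize(d, c("cell_type", "subject")))
  sel <- select_markers(pb, marker_config(M_per_population = 50))
  ab <- make_artificial_bulk(d)
  res <- choose_M(ab, pb, sel,
                  marker_config(M_grid = c(20, 40)),
                  deconv_config(min_overlap_genes = 20))
  expect_true(res$best_M %in% c(20, 40))
  expect_equal(res$table$M, c(20, 40))
  expect_true(all(is.finite(res$table$rmse)))
  # singleton grid returns its element; depths beyond the lists are flagged
  res1 <- choose_M(ab, pb, sel, marker_config(M_grid = 40),
                   deconv_config(min_overlap_genes = 20))
  expect_equal(res1$best_M, 40)
  res2 <- choose_M(ab, pb, sel, marker_config(M_grid = c(40, 500)),
                   deconv_config(min_overlap_genes = 20))
  expect_true(res2$table$truncated[res2$table$M == 500])
})

test_that("lineage merging conserves fraction mass", {
  fr <- random_simplex(6, 4)
  colnames(fr) <- c("cd4_naive", "cd4_memory", "cd8_naive", "nk")
  map <- c(cd4_naive = "Tadaptive", cd4_memory = "Tadaptive",
           cd8_naive = "Tadaptive", nk = "NK")
  out <- merge_lineages(fr, map)
  expect_equal(unname(rowSums(out)), unname(rowSums(fr)))
  expect_equal(unname(out[, "Tadaptive"]),
               unname(rowSums(fr[, 1:3])))
  # identity map leaves fractions unchanged
  idm <- stats::setNames(colnames(fr), colnames(fr))
  expect_equal(merge_lineages(fr, idm)[, colnames(fr)], fr)
  expect_error(merge_lineages(fr, map[-1]), "unmapped")
  # the worked four-subset example: adaptive lineage 0.1+0.2+0.1+0.2
  fr2 <- matrix(c(0.1, 0.2, 0.1, 0.2, 0.4), 1,
                dimnames = list("s1", c("cd4n", "cd4m", "cd8n", "cd8m",
                                        "mono")))
  m2 <- c(cd4n = "Tadaptive", cd4m = "Tadaptive", cd8n = "Tadaptive",
          cd8m = "Tadaptive", mono = "Monocytes")
  expect_equal(unname(merge_lineages(fr2, m2)[, "Tadaptive"]), 0.6)
})

test_that("signature matrices round-trip through TSV", {
  sig <- toy_signature(K = 3, G = 50)
  path <- file.path(tempdir(), "sig.tsv")
  write_signature_tsv(sig, path)
  back <- read_signature_tsv(path)
  expect_equal(back$values, sig$values, tolerance = 1e-9)
})
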