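# Kaplan-Meier/log-rank, Cox models, FDR, fixed-effects meta-analysis and
# the prognostic gene screen.

test_that("log-rank matches the hand-worked observed-minus-expected table", {
  # group A dies at 1,2,3; group B at 4,5,6 (all events, no ties)
  d <- data.frame(os_time = 1:6, os_event = 1L)
  g <- rep(c("A", "B"), each = 3)
  res <- km_logrank(g, d)
  expect_equal(res$chisq, logrank_chisq_oracle(d$os_time, d$os_event, g),
               tolerance = 1e-10)
  expect_equal(res$p, pchisq(res$chisq, 1, lower.tail = FALSE))
  # duplicated groups are exchangeable: statistic 0, p = 1
  dup <- data.frame(os_time = rep(1:4, 2), os_event = 1L)
  res_dup <- km_logrank(rep(c("A", "B"), each = 4), dup)
  expect_equal(res_dup$p, 1, tolerance = 1e-12)
  # KM estimates are non-increasing within each group's curve
  strata_id <- rep(seq_along(res$fit$strata), res$fit$strata)
  for (s in unique(strata_id))
    expect_true(all(diff(res$fit$surv[strata_id == s]) <= 1e-12))
  # label swap leaves p unchanged
  res_swap <- km_logrank(rev(g), d)
  expect_equal(res_swap$p, res$p, tolerance = 1e-12)
  expect_error(km_logrank(rep("A", 6), d), "groups")
})

test_that("log-rank has power against a strong planted effect", {
  set.seed(51)
  hits <- sapply(1:20, function(i) {
    n <- 400
    grp <- rep(c("lo", "hi"), each = n / 2)
    lam <- ifelse(grp == "lo", 0.3, 0.1)
    d <- data.frame(os_time = rexp(n, lam), os_event = 1L)
    km_logrank(grp, d)$p < 0.001
  })
  expect_gte(mean(hits), 0.95)
})

test_that("Cox partial likelihood matches a brute-force 1-D scan", {
  d <- data.frame(os_time = c(2, 5, 9), os_event = 1L,
                  x = c(1.2, -0.4, 0.3))
  fit <- cox_fit(d, "x", fdr = FALSE)
  grid <- seq(-4, 4, by = 1e-4)
  ll <- vapply(grid, cox_loglik_oracle, numeric(1),
               time = d$os_time, event = d$os_event, x = d$x)
  expect_equal(fit$beta, grid[which.max(ll)], tolerance = 1e-3)
})

test_that("Cox results carry the standard structure and symmetries", {
  set.seed(52)
  n <- 300
  x <- rnorm(n)
  sv <- simulate_survival(x, sim_survival_config(beta_stem = -0.4,
                                                 censor_rate = 0.02,
                                                 seed = 53))
  sv$x <- x
  sv$y <- -x
  res <- cox_fit(sv, c("x", "y"), type = "univariate")
  expect_equal(res$HR[res$term == "x"], 1 / res$HR[res$term == "y"],
               tolerance = 1e-8)
  expect_true(all(res$CI_low <= res$HR & res$HR <= res$CI_high))
  expect_true(all(res$HR > 0))
  expect_true(all(res$fdr_adjusted_p >= res$p - 1e-15))

  # multivariate layout with a stage factor referenced at its first level
  sv$stage <- sample(c("I", "II", "III", "IV"), n, replace = TRUE)
  sv$age <- rnorm(n, 60, 8)
  mv <- cox_fit(sv, c("x", "age", "stage"), type = "multivariate")
  expect_true(any(grepl("stageII", mv$term)))
  expect_false(any(grepl("stageI$", mv$term)))   # level I is the reference
  expect_error(cox_fit(sv, "nope"), "missing covariate")
})

test_that("planted continuous effects are recovered at cohort scale", {
  set.seed(54)
  score <- rnorm(1000)
  sv <- simulate_survival(score, sim_survival_config(
    beta_stem = -0.105, censor_rate = 0.02, seed = 55))
  res <- cox_fit(sv, "stem_score", fdr = FALSE)
  expect_gte(res$HR, 0.85)
  expect_lte(res$HR, 0.95)
})

test_that("BH adjustment matches hand computation and is monotone", {
  expect_equal(fdr_adjust(0.2), 0.2)
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(fdr_adjust(rep(1, 5)), rep(1, 5))
  set.seed(56)
  p <- runif(30)
  adj <- fdr_adjust(p)
  expect_true(all(adj >= p - 1e-15))
  expect_true(all(diff(adj[order(p)]) >= -1e-15))
  expect_error(fdr_adjust(c(0.5, 1.2)), "\\[0,1\\]")
})

test_that("fixed-effects pooling matches closed forms and metafor", {
  # two identical studies: beta unchanged, se / sqrt(2)
  m <- meta_fixed(c(-0.3, -0.3), c(0.1, 0.1))
  expect_equal(m$pooled_beta, -0.3)
  expect_equal(m$pooled_se, 0.1 / sqrt(2))
  # worked example: w = {100, 25} -> beta = -0.12, se = 1/sqrt(125)
  m2 <- meta_fixed(c(-0.1, -0.2), c(0.1, 0.2))
  expect_equal(m2$pooled_beta, -0.12, tolerance = 1e-12)
  expect_equal(m2$pooled_se, 0.0894, tolerance = 1e-3)
  # equal-se pooling is the plain mean
  m3 <- meta_fixed(c(0.1, 0.5, 0.9), rep(0.2, 3))
  expect_equal(m3$pooled_beta, 0.5)
  # a dominant tiny-se study pins the pooled estimate
  m4 <- meta_fixed(c(0.4, -1), c(1e-4, 1))
  expect_lt(abs(m4$pooled_beta - 0.4), 1e-3)
  # weights sum to one, pooled se below every input se
  expect_equal(sum(m2$studies$weight), 1)
  expect_lt(m2$pooled_se, min(c(0.1, 0.2)))
  # independent oracle
  ref <- metafor::rma(yi = c(-0.1, -0.2), sei = c(0.1, 0.2), method = "FE")
  expect_equal(m2$pooled_beta, as.numeric(ref$beta), tolerance = 1e-10)
  expect_equal(m2$pooled_se, as.numeric(ref$se), tolerance = 1e-10)
  expect_equal(m2$p, as.numeric(ref$pval), tolerance = 1e-10)
  # single study passes through with a note
  m5 <- meta_fixed(-0.2, 0.1)
  expect_equal(m5$pooled_beta, -0.2)
  expect_false(is.null(m5$note))
  expect_error(meta_fixed(c(1, 2), 0.1), "match")
  expect_error(meta_fixed(0.1, -1), "> 0")
})

# four synthetic cohorts with expression-driven hazards for a planted gene
make_screen_cohorts <- function(beta_planted = 0.4, n = 300, n_null = 6,
                                seed = 60) {
  set.seed(seed)
  genes <- c("PLANTED", paste0("NULL", seq_len(n_null)))
  lapply(stats::setNames(1:4, paste0("cohort", 1:4)), function(i) {
    expr <- matrix(rnorm(length(genes) * n), length(genes), n,
                   dimnames = list(genes, paste0("s", 1:n)))
    lp <- beta_planted * expr["PLANTED", ]
    t_event <- rexp(n, 0.1 * exp(lp))
    t_cens <- rexp(n, 0.01)
    clinical <- data.frame(
      os_time = pmin(t_event, t_cens),
      os_event = as.integer(t_event <= t_cens),
      age = rnorm(n, 60, 10),
      sex = sample(c("M", "F"), n, replace = TRUE))
    list(expression = expr, clinical = clinical)
  })
}

test_that("the gene screen selects planted effects and rejects the rest", {
  cohorts <- make_screen_cohorts()
  res <- suppressMessages(prognostic_gene_screen(
    cohorts, rownames(cohorts[[1]]$expression), direction = "risk",
    covariates = c("age", "sex", "stage")))
  expect_true(res$selected[res$gene == "PLANTED"])
  expect_false(any(res$selected[res$gene != "PLANTED"]))
  expect_equal(res$n_cohorts_significant[res$gene == "PLANTED"], 4)
  # a protective-direction screen must not pick a risk gene
  res_prot <- suppressMessages(prognostic_gene_screen(
    cohorts, "PLANTED", direction = "protective",
    covariates = c("age", "sex")))
  expect_false(res_prot$selected[1])
})

test_that("the cohort-count rule excludes genes significant in too few cohorts", {
  cohorts <- make_screen_cohorts(seed = 61)
  # kill the planted effect in cohorts 3 and 4 by shuffling expression
  for (i in 3:4) {
    set.seed(100 + i)
    cohorts[[i]]$expression["PLANTED", ] <-
      sample(cohorts[[i]]$expression["PLANTED", ])
  }
  res <- suppressMessages(prognostic_gene_screen(
    cohorts, "PLANTED", direction = "risk",
    covariates = c("age", "sex"), min_cohorts = 3))
  expect_equal(res$n_cohorts_significant[1], 2)
  expect_false(res$selected[1])
})
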