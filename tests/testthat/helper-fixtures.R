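# Fixtures built in code: small planted-signal datasets and independent
# oracles used across the suite.

# small synthetic single-cell reference (3 types, planted markers)
small_sc <- function(seed = 1, n_genes = 600, n_markers = 50,
                     marker_fold = 8, cells_per_type = 60) {
  cfg <- sim_sc_config(
    n_genes = n_genes,
    cell_types = stats::setNames(rep(cells_per_type, 3),
                                 c("typeA", "typeB", "typeC")),
    subjects = paste0("P", 1:6),
    subject_stage = stats::setNames(
      rep(c("NAG", "CAG", "IM"), 2), paste0("P", 1:6)),
    n_markers_per_type = n_markers,
    marker_fold = marker_fold,
    baseline_dispersion = 0.5,
    subject_effect_sd = 0.2,
    seed = seed)
  simulate_sc_dataset(cfg)
}

# random gene x K signature with well-separated population profiles
toy_signature <- function(K = 4, G = 400, seed = 1) {
  set.seed(seed)
  vals <- matrix(stats::rexp(G * K, rate = 1 / 100), G, K)
  # give each population a block of elevated genes so columns are separable
  block <- floor(G / K)
  for (k in seq_len(K))
    vals[((k - 1) * block + 1):(k * block), k] <-
      vals[((k - 1) * block + 1):(k * block), k] * 8
  rownames(vals) <- sprintf("g%04d", seq_len(G))
  colnames(vals) <- paste0("pop", seq_len(K))
  structure(list(values = vals,
                 markers = stats::setNames(
                   rep(list(rownames(vals)), K), colnames(vals)),
                 name = "toy"),
            class = "signature_matrix")
}

# random points on the probability simplex
random_simplex <- function(n, k) {
  x <- matrix(stats::rexp(n * k), n, k)
  x / rowSums(x)
}

# constrained least-squares oracle: non-negative LS then renormalise to the
# simplex; mirrors the deconvolution contract on noiseless/noisy input but
# shares no code with deconvolve()
nnls_fractions <- function(S, y) {
  w <- pracma::lsqnonneg(as.matrix(S), as.numeric(y))$x
  w / sum(w)
}

# textbook balanced two-way ANOVA (one observation per cell, main effects):
# from-scratch sums of squares
balanced_anova_F <- function(y, a_fac, b_fac) {
  a <- factor(a_fac); b <- factor(b_fac)
  A <- nlevels(a); B <- nlevels(b)
  gm <- mean(y)
  ssa <- B * sum((tapply(y, a, mean) - gm)^2)
  ssb <- A * sum((tapply(y, b, mean) - gm)^2)
  sst <- sum((y - gm)^2)
  sse <- sst - ssa - ssb
  dfe <- (A - 1) * (B - 1)
  c(F_a = (ssa / (A - 1)) / (sse / dfe),
    F_b = (ssb / (B - 1)) / (sse / dfe))
}

# hand log-rank statistic from the standard observed-minus-expected table
logrank_chisq_oracle <- function(time, event, group) {
  g <- factor(group)
  stopifnot(nlevels(g) == 2)
  tms <- sort(unique(time[event == 1]))
  O1 <- E1 <- V <- 0
  for (t in tms) {
    at_risk <- time >= t
    d <- sum(event == 1 & time == t)
    n <- sum(at_risk)
    n1 <- sum(at_risk & g == levels(g)[1])
    d1 <- sum(event == 1 & time == t & g == levels(g)[1])
    O1 <- O1 + d1
    E1 <- E1 + d * n1 / n
    if (n > 1)
      V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O1 - E1)^2 / V
}

# brute-force 1-D Cox partial likelihood (no ties) for a single covariate
cox_loglik_oracle <- function(beta, time, event, x) {
  ord <- order(time)
  time <- time[ord]; event <- event[ord]; x <- x[ord]
  ll <- 0
  for (i in which(event == 1)) {
    risk <- time >= time[i]
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}

# three well-separated blobs in the 4-D STEM feature space; blob 1 is
# stromal/monocyte-high, blob 3 EMEC/T-high
stem_blobs <- function(n_per = 40, seed = 1, sd = 0.02) {
  set.seed(seed)
  centers <- rbind(c(0.15, 0.50, 0.40, 0.30),   # H-like
                   c(0.25, 0.25, 0.50, 0.20),   # M-like
                   c(0.45, 0.12, 0.60, 0.15))   # L-like
  colnames(centers) <- c("EMEC", "Stromal", "Tadaptive", "Monocytes")
  x <- do.call(rbind, lapply(1:3, function(b)
    sweep(matrix(rnorm(n_per * 4, 0, sd), n_per, 4), 2, centers[b, ], "+")))
  colnames(x) <- colnames(centers)
  rownames(x) <- paste0("s", seq_len(nrow(x)))
  list(x = abs(x), truth = rep(1:3, each = n_per))
}

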