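# Patient stratification: survival-optimal score cutoff over a quantile
# grid, and TME subtyping by spectral clustering on the four STEM
# populations.

#' Cutoff-search configuration
#'
#' @param q_min,q_max,q_step quantile grid (defaults 0.10 to 0.90 step
#'   0.01).
#' @param test "cox" (univariate Cox Wald p, default) or "logrank".
#' @return A list of class \code{cutoff_config}.
#' @export
cutoff_config <- function(q_min = 0.10, q_max = 0.90, q_step = 0.01,
                          test = c("cox", "logrank")) {
  if (q_min <= 0 || q_max >= 1 || q_min > q_max || q_step <= 0)
    stop("quantile grid must lie within (0,1) and be non-empty")
  structure(list(q_min = q_min, q_max = q_max, q_step = q_step,
                 test = match.arg(test)),
            class = "cutoff_config")
}

#' Survival-optimal score cutoff over a quantile grid
#'
#' Dichotomises the score at each grid quantile, tests the two groups
#' (univariate Cox by default, log-rank optionally) and returns the cutoff
#' minimising the p-value. Grid points where either group has zero events
#' are skipped with a warning; ties go to the smaller quantile.
#'
#' @param scores per-sample numeric scores.
#' @param survival data.frame with columns \code{os_time}, \code{os_event}
#'   aligned with \code{scores}.
#' @param cfg a \code{\link{cutoff_config}}.
#' @return A list of class \code{cutoff_result}: \code{cutoff_value},
#'   \code{cutoff_quantile}, \code{p_value}, \code{grid} (data.frame q,
#'   cutoff, p).
#' @export
optimal_cutoff <- function(scores, survival, cfg = cutoff_config()) {
  if (length(scores) != nrow(survival))
    stop("scores and survival rows must align")
  if (sum(survival$os_event) < 2) stop("need >= 2 events")
  if (stats::var(scores) == 0)
    stop("constant score vector: all cutoffs give degenerate groups")
  qs <- seq(cfg$q_min, cfg$q_max, by = cfg$q_step)
  srv <- survival::Surv(survival$os_time, survival$os_event)
  rows <- lapply(qs, function(q) {
    cut <- stats::quantile(scores, q, names = FALSE)
    grp <- scores > cut
    if (length(unique(grp)) < 2) return(NULL)
    ev <- tapply(survival$os_event, grp, sum)
    if (any(ev == 0)) {
      warning(sprintf("quantile %.2f skipped: a group has zero events", q))
      return(NULL)
    }
    p <- if (cfg$test == "cox") {
      fit <- survival::coxph(srv ~ grp)
      summary(fit)$coefficients[1, "Pr(>|z|)"]
    } else {
      sd <- survival::survdiff(srv ~ grp)
      stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE)
    }
    data.frame(q = q, cutoff = cut, p = p)
  })
  grid <- do.call(rbind, rows)
  if (is.null(grid) || !nrow(grid))
    stop("no evaluable grid point (every split degenerate)")
  best <- grid[which.min(grid$p), ]   # which.min takes the first = smaller q
  structure(list(cutoff_value = best$cutoff, cutoff_quantile = best$q,
                 p_value = best$p, grid = grid),
            class = "cutoff_result")
}

#' @export
print.cutoff_result <- function(x, ...) {
  cat(sprintf("optimal cutoff %.4g at quantile %.2f (p = %.3g)\n",
              x$cutoff_value, x$cutoff_quantile, x$p_value))
  invisible(x)
}

# --- spectral clustering ---------------------------------------------------

# RBF affinity with median-pairwise-distance bandwidth
.rbf_affinity <- function(x, sigma = NULL) {
  d <- as.matrix(stats::dist(x))
  if (is.null(sigma)) sigma <- stats::median(d[upper.tri(d)])
  if (sigma <= 0) sigma <- 1
  A <- exp(-d^2 / (2 * sigma^2))
  diag(A) <- 0
  A
}

# normalised spectral clustering (symmetric Laplacian, row-normalised
# eigenvector embedding, k-means); deterministic given the RNG state
.spectral_cluster <- function(x, k, sigma = NULL) {
  A <- .rbf_affinity(x, sigma)
  dinv <- 1 / sqrt(pmax(rowSums(A), .Machine$double.eps))
  L <- diag(nrow(A)) - (dinv * A) %*% diag(dinv)
  ev <- eigen(L, symmetric = TRUE)
  U <- ev$vectors[, ncol(L) - seq_len(k) + 1, drop = FALSE]
  nrm <- sqrt(rowSums(U^2))
  U <- U / pmax(nrm, .Machine$double.eps)
  stats::kmeans(U, centers = k, nstart = 25, iter.max = 100)$cluster
}

# --- cluster-count selection panel -----------------------------------------

.index_ch <- function(x, cl) {
  n <- nrow(x); k <- length(unique(cl))
  gm <- colMeans(x)
  ssb <- 0; ssw <- 0
  for (g in unique(cl)) {
    xg <- x[cl == g, , drop = FALSE]
    cg <- colMeans(xg)
    ssb <- ssb + nrow(xg) * sum((cg - gm)^2)
    ssw <- ssw + sum(sweep(xg, 2, cg)^2)
  }
  (ssb / (k - 1)) / (ssw / (n - k))
}

.index_db <- function(x, cl) {
  ks <- sort(unique(cl))
  cent <- t(vapply(ks, function(g) colMeans(x[cl == g, , drop = FALSE]),
                   numeric(ncol(x))))
  s <- vapply(seq_along(ks), function(i) {
    xg <- x[cl == ks[i], , drop = FALSE]
    mean(sqrt(rowSums(sweep(xg, 2, cent[i, ])^2)))
  }, numeric(1))
  db <- vapply(seq_along(ks), function(i) {
    max(vapply(seq_along(ks)[-i], function(j)
      (s[i] + s[j]) / sqrt(sum((cent[i, ] - cent[j, ])^2)), numeric(1)))
  }, numeric(1))
  mean(db)
}

#' Choose the cluster count by a validity-index panel
#'
#' Evaluates k in \code{k_range} with Ward hierarchical clustering on
#' Euclidean distance and takes a majority vote over four indices:
#' silhouette width (max), Calinski-Harabasz (max), Davies-Bouldin (min)
#' and the gap statistic (firstSEmax rule). Without a majority the fallback
#' k is returned.
#'
#' @param x samples x features matrix.
#' @param k_range candidate counts (default 2:6).
#' @param fallback_k returned when the vote has no majority (default 3).
#' @param B gap-statistic bootstrap references (default 50).
#' @return A list: \code{k}, \code{votes} (per-index best k), \code{table}
#'   (index values per k).
#' @export
choose_k_panel <- function(x, k_range = 2:6, fallback_k = 3, B = 50) {
  x <- as.matrix(x)
  d <- stats::dist(x)
  hc <- stats::hclust(d, method = "ward.D2")
  cuts <- lapply(k_range, function(k) stats::cutree(hc, k))
  sil <- vapply(seq_along(k_range), function(i)
    mean(cluster::silhouette(cuts[[i]], d)[, 3]), numeric(1))
  ch <- vapply(seq_along(k_range), function(i)
    .index_ch(x, cuts[[i]]), numeric(1))
  db <- vapply(seq_along(k_range), function(i)
    .index_db(x, cuts[[i]]), numeric(1))
  gap <- cluster::clusGap(
    x, FUNcluster = function(xx, k)
      list(cluster = stats::cutree(
        stats::hclust(stats::dist(xx), "ward.D2"), k)),
    K.max = max(k_range), B = B, verbose = FALSE)
  gt <- gap$Tab[k_range, , drop = FALSE]
  gap_k <- k_range[cluster::maxSE(gt[, "gap"], gt[, "SE.sim"],
                                  method = "firstSEmax")]
  votes <- c(silhouette = k_range[which.max(sil)],
             calinski_harabasz = k_range[which.max(ch)],
             davies_bouldin = k_range[which.min(db)],
             gap = gap_k)
  tab <- table(votes)
  k <- if (max(tab) > length(votes) / 2)
    as.integer(names(tab)[which.max(tab)]) else fallback_k
  list(k = k, votes = votes,
       table = data.frame(k = k_range, silhouette = sil,
                          calinski_harabasz = ch, davies_bouldin = db,
                          gap = gt[, "gap"]))
}

#' Subtype configuration
#'
#' @param k fixed cluster count, or NULL to choose by
#'   \code{\link{choose_k_panel}} (fallback 3, the reproduction default).
#' @param sigma RBF bandwidth; NULL (default) uses the median
#'   pairwise-distance heuristic.
#' @param k_range candidate counts for the panel.
#' @param seed integer seed controlling k-means initialisation.
#' @return A list of class \code{subtype_config}.
#' @export
subtype_config <- function(k = NULL, sigma = NULL, k_range = 2:6,
                           seed = 1L) {
  if (!is.null(k) && k < 2) stop("k must be >= 2")
  structure(list(k = k, sigma = sigma, k_range = k_range, seed = seed),
            class = "subtype_config")
}

#' TME subtyping by spectral clustering on the four STEM populations
#'
#' Clusters samples on the fractions of the four STEM populations (EMEC and
#' stromal from the non-immune compartment; adaptive T and monocytes from
#' the immune compartment) with an RBF-affinity spectral method, then names
#' clusters by composition: H = highest mean stromal + monocyte (worst
#' prognosis in the source cohorts), L = highest mean EMEC + adaptive T,
#' M = the remainder.
#'
#' @param features samples x 4 matrix/data.frame with columns EMEC,
#'   Stromal, Tadaptive, Monocytes (name matching is case-sensitive).
#' @param cfg a \code{\link{subtype_config}}.
#' @return A list of class \code{subtype_assignment}: \code{subtype}
#'   (factor H/M/L per sample), \code{cluster} (raw cluster ids), \code{k},
#'   \code{panel} (index panel output when k was chosen automatically).
#' @export
tme_subtype <- function(features, cfg = subtype_config()) {
  x <- as.matrix(features)
  need <- c("EMEC", "Stromal", "Tadaptive", "Monocytes")
  miss <- setdiff(need, colnames(x))
  if (length(miss)) stop("features lack column(s): ",
                         paste(miss, collapse = ", "))
  x <- x[, need]
  if (anyNA(x)) stop("missing feature values")
  if (!is.null(cfg$k) && cfg$k > nrow(x))
    stop("k exceeds the sample count")
  set.seed(cfg$seed)
  panel <- NULL
  k <- cfg$k
  if (is.null(k)) {
    panel <- choose_k_panel(x, cfg$k_range)
    k <- panel$k
  }
  cl <- .spectral_cluster(x, k, cfg$sigma)

  # composition-based naming
  ks <- sort(unique(cl))
  hm <- vapply(ks, function(g)
    mean(x[cl == g, "Stromal"]) + mean(x[cl == g, "Monocytes"]), numeric(1))
  lm_ <- vapply(ks, function(g)
    mean(x[cl == g, "EMEC"]) + mean(x[cl == g, "Tadaptive"]), numeric(1))
  name <- rep("TMEsubtype-M", length(ks))
  h_i <- which.max(hm)
  name[h_i] <- "TMEsubtype-H"
  l_cand <- setdiff(order(-lm_), h_i)
  if (length(l_cand)) name[l_cand[1]] <- "TMEsubtype-L"
  subtype <- factor(name[match(cl, ks)],
                    levels = c("TMEsubtype-H", "TMEsubtype-M",
                               "TMEsubtype-L"))
  names(subtype) <- rownames(x)
  structure(list(subtype = subtype, cluster = cl, k = k, panel = panel),
            class = "subtype_assignment")
}

#' Cross-tabulate subtype assignments against an external classification
#'
#' @param subtype a \code{subtype_assignment} or factor.
#' @param external vector of external class labels, same length/order.
#' @return A contingency table.
#' @export
subtype_crosstab <- function(subtype, external) {
  if (inherits(subtype, "subtype_assignment")) subtype <- subtype$subtype
  table(subtype = subtype, external = external)
}
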