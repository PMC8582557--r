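# Synthetic-data generators: an annotated single-cell reference with planted
# cell-type markers, bulk mixtures with known proportions, and survival
# outcomes with a planted log-linear score effect. These define the study
# conditions every downstream stage is tested under.

#' Configuration for the synthetic single-cell reference
#'
#' Counts are negative binomial around a gene baseline; each cell type gets a
#' disjoint block of marker genes whose mean is multiplied by
#' \code{marker_fold} in that type; each (subject, gene) pair carries a
#' log-normal multiplicative effect so the subject factor of the two-way
#' ANOVA stage is non-trivial. Subjects are assigned to stages by
#' \code{subject_stage}, mimicking a biopsy cohort spanning the
#' gastritis-to-early-cancer cascade.
#'
#' @param n_genes number of genes.
#' @param cell_types named integer vector: cells per type.
#' @param subjects character vector of subject (biopsy) ids.
#' @param subject_stage named character vector mapping each subject to one
#'   stage label.
#' @param n_markers_per_type planted marker genes per cell type (disjoint
#'   blocks).
#' @param marker_fold fold-elevation of a marker gene's mean in its own type
#'   (> 1 plants signal; 1 plants none).
#' @param baseline_dispersion negative-binomial dispersion (\code{size =
#'   1/dispersion}).
#' @param subject_effect_sd sd of per-(subject, gene) log-scale effects.
#' @param base_mean_meanlog,base_mean_sdlog log-normal parameters of the gene
#'   baseline means.
#' @param seed integer seed.
#' @return A list of class \code{sim_sc_config}.
#' @export
sim_sc_config <- function(n_genes = 2000,
                          cell_types = c(EMEC = 220, Stromal = 200,
                                         Endothelial = 180, Goblet = 160,
                                         PC = 160, GMC = 160),
                          subjects = paste0("P", 1:9),
                          subject_stage = stats::setNames(
                            c("NAG", "NAG", "CAG", "CAG", "IM", "IM", "IM",
                              "EGC", "EGC"), paste0("P", 1:9)),
                          n_markers_per_type = 50,
                          marker_fold = 8,
                          baseline_dispersion = 0.5,
                          subject_effect_sd = 0.2,
                          base_mean_meanlog = log(0.5),
                          base_mean_sdlog = 1,
                          seed = 1L) {
  if (n_genes < 1) stop("n_genes must be positive")
  if (is.null(names(cell_types)) || any(cell_types < 1))
    stop("cell_types must be a named vector of positive counts")
  if (!all(subjects %in% names(subject_stage)))
    stop("every subject must map to exactly one stage")
  if (marker_fold < 1) stop("marker_fold must be >= 1")
  if (n_markers_per_type * length(cell_types) > n_genes)
    stop("marker blocks for distinct cell types must be disjoint: ",
         "n_markers_per_type * n_types exceeds n_genes")
  structure(as.list(environment()), class = "sim_sc_config")
}

#' Simulate an annotated single-cell reference with planted markers
#'
#' @param cfg a \code{\link{sim_sc_config}}.
#' @return A list: \code{data} (\code{annotated_counts}) and \code{markers}
#'   (named list of planted marker gene ids per cell type).
#' @export
simulate_sc_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "sim_sc_config"))
  set.seed(cfg$seed)
  G <- cfg$n_genes
  types <- names(cfg$cell_types)
  genes <- sprintf("gene%04d", seq_len(G))

  base_mu <- stats::rlnorm(G, cfg$base_mean_meanlog, cfg$base_mean_sdlog)

  # disjoint marker blocks, one per type
  markers <- list()
  for (i in seq_along(types)) {
    idx <- ((i - 1) * cfg$n_markers_per_type + 1):(i * cfg$n_markers_per_type)
    markers[[types[i]]] <- genes[idx]
  }
  if (anyDuplicated(unlist(markers)))
    stop("overlapping marker assignments between cell types")

  cell_type <- rep(types, cfg$cell_types)
  n_cells <- length(cell_type)
  # biopsies differ in composition: per type, subjects are sampled with
  # Dirichlet-distributed weights (guaranteeing >= 1 cell per subject so
  # every (type, subject) pseudobulk group exists)
  n_subj <- length(cfg$subjects)
  subject <- unlist(lapply(cfg$cell_types, function(k) {
    w <- stats::rgamma(n_subj, shape = 5)
    s <- c(cfg$subjects,
           sample(cfg$subjects, max(0, k - n_subj), replace = TRUE,
                  prob = w / sum(w)))
    s[seq_len(k)]
  }), use.names = FALSE)
  stage <- unname(cfg$subject_stage[subject])

  # per-(subject, gene) multiplicative effects
  subj_eff <- matrix(
    stats::rlnorm(G * length(cfg$subjects), 0, cfg$subject_effect_sd),
    nrow = G, dimnames = list(genes, cfg$subjects))

  fold <- matrix(1, G, length(types), dimnames = list(genes, types))
  for (tp in types) fold[markers[[tp]], tp] <- cfg$marker_fold

  size <- 1 / cfg$baseline_dispersion
  counts <- matrix(0L, G, n_cells,
                   dimnames = list(genes, sprintf("cell%05d", seq_len(n_cells))))
  for (j in seq_len(n_cells)) {
    mu <- base_mu * fold[, cell_type[j]] * subj_eff[, subject[j]]
    counts[, j] <- stats::rnbinom(G, size = size, mu = mu)
  }
  list(data = annotated_counts(counts, cell_type, subject, stage),
       markers = markers)
}

#' Configuration for bulk mixture simulation
#'
#' @param proportions samples x populations matrix; non-negative rows summing
#'   to 1 (within 1e-9). Column names must match signature populations.
#' @param noise_sd sd of additive Gaussian noise on log-scale expression.
#' @param seed integer seed.
#' @return A list of class \code{sim_mixture_config}.
#' @export
sim_mixture_config <- function(proportions, noise_sd = 0, seed = 1L) {
  proportions <- as.matrix(proportions)
  if (any(proportions < 0)) stop("all proportions must be >= 0")
  if (any(abs(rowSums(proportions) - 1) > 1e-9))
    stop("each proportions row must sum to 1")
  structure(list(proportions = proportions, noise_sd = noise_sd, seed = seed),
            class = "sim_mixture_config")
}

#' Simulate bulk mixtures from a signature matrix with known proportions
#'
#' Each sample is the signature-weighted combination of population profiles;
#' noise is applied multiplicatively as \code{exp(N(0, noise_sd))} so the
#' noiseless case is exactly linear.
#'
#' @param signature a \code{\link{signature_matrix}} object or a plain
#'   gene x population matrix.
#' @param cfg a \code{\link{sim_mixture_config}}.
#' @return A list: \code{bulk} (gene x sample matrix) and \code{fractions}
#'   (the true samples x populations proportions).
#' @export
simulate_mixtures <- function(signature, cfg) {
  stopifnot(inherits(cfg, "sim_mixture_config"))
  S <- if (inherits(signature, "signature_matrix")) signature$values
       else as.matrix(signature)
  if (ncol(S) < 2) stop("signature must have >= 2 populations")
  P <- cfg$proportions
  if (is.null(colnames(P))) colnames(P) <- colnames(S)
  if (!identical(sort(colnames(P)), sort(colnames(S))))
    stop("proportion columns must match signature populations")
  P <- P[, colnames(S), drop = FALSE]
  set.seed(cfg$seed)
  bulk <- S %*% t(P)
  if (cfg$noise_sd > 0)
    bulk <- bulk * exp(matrix(stats::rnorm(length(bulk), 0, cfg$noise_sd),
                              nrow(bulk)))
  colnames(bulk) <- if (!is.null(rownames(P))) rownames(P)
                    else paste0("S", seq_len(nrow(P)))
  list(bulk = bulk, fractions = P)
}

#' Configuration for survival simulation
#'
#' @param beta_stem log-hazard coefficient per unit of (centred) STEM score.
#' @param baseline_hazard events per time unit (> 0).
#' @param censor_rate rate of independent exponential censoring (>= 0; 0
#'   means no censoring).
#' @param shape Weibull shape; 1 (default) gives the exponential baseline.
#' @param seed integer seed.
#' @return A list of class \code{sim_survival_config}.
#' @export
sim_survival_config <- function(beta_stem = 0, baseline_hazard = 0.1,
                                censor_rate = 0.02, shape = 1, seed = 1L) {
  if (baseline_hazard <= 0) stop("baseline_hazard must be > 0")
  if (censor_rate < 0) stop("censor_rate must be >= 0")
  structure(list(beta_stem = beta_stem, baseline_hazard = baseline_hazard,
                 censor_rate = censor_rate, shape = shape, seed = seed),
            class = "sim_survival_config")
}

#' Simulate overall-survival outcomes from STEM scores
#'
#' Event times are Weibull (exponential when \code{shape = 1}) with hazard
#' proportional to \code{exp(beta_stem * (score - mean(score)))}; censoring
#' is independent exponential.
#'
#' @param stem_scores numeric vector of per-sample scores (finite).
#' @param cfg a \code{\link{sim_survival_config}}.
#' @return A data.frame: sample, os_time, os_event (1 = death observed),
#'   stem_score.
#' @export
simulate_survival <- function(stem_scores, cfg) {
  stopifnot(inherits(cfg, "sim_survival_config"))
  if (!all(is.finite(stem_scores))) stop("stem_scores must be finite")
  set.seed(cfg$seed)
  n <- length(stem_scores)
  lp <- cfg$beta_stem * (stem_scores - mean(stem_scores))
  # inverse-transform sampling for Weibull PH: S(t) = exp(-h0 t^shape e^lp)
  u <- stats::runif(n)
  t_event <- (-log(u) / (cfg$baseline_hazard * exp(lp)))^(1 / cfg$shape)
  t_cens <- if (cfg$censor_rate > 0) stats::rexp(n, cfg$censor_rate)
            else rep(Inf, n)
  data.frame(
    sample = if (!is.null(names(stem_scores))) names(stem_scores)
             else paste0("S", seq_len(n)),
    os_time = pmin(t_event, t_cens),
    os_event = as.integer(t_event <= t_cens),
    stem_score = as.numeric(stem_scores),
    stringsAsFactors = FALSE)
}
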