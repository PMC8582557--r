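# Ratio scores among non-rare populations and the STEM score.

#' Scoring configuration
#'
#' @param rare_threshold populations whose cohort-mean fraction is at or
#'   below this are excluded from ratio scoring (default 0.05).
#' @param ratio_epsilon small stabiliser added to every ratio denominator so
#'   clipped-to-zero fractions stay finite (default 1e-6).
#' @return A list of class \code{score_config}.
#' @export
score_config <- function(rare_threshold = 0.05, ratio_epsilon = 1e-6) {
  if (rare_threshold <= 0 || rare_threshold >= 1)
    stop("rare_threshold must be in (0,1)")
  if (ratio_epsilon <= 0) stop("ratio_epsilon must be positive")
  structure(list(rare_threshold = rare_threshold,
                 ratio_epsilon = ratio_epsilon),
            class = "score_config")
}

.as_fraction_matrix <- function(fractions) {
  if (inherits(fractions, "fraction_table")) fractions$fractions
  else as.matrix(fractions)
}

#' Populations exceeding the rarity threshold
#'
#' A population is non-rare when its mean fraction across the cohort
#' exceeds \code{rare_threshold} of the compartment total.
#'
#' @param fractions samples x populations matrix or \code{fraction_table}.
#' @param cfg a \code{\link{score_config}}.
#' @return Character vector of non-rare population names.
#' @export
nonrare_populations <- function(fractions, cfg = score_config()) {
  fr <- .as_fraction_matrix(fractions)
  colnames(fr)[colMeans(fr) > cfg$rare_threshold]
}

#' Pairwise ratio scores among populations
#'
#' For every ordered pair (A, B) of the given populations, the score
#' \code{f_A / (f_B + epsilon)} is emitted (both A/B and B/A, as both
#' directions can carry distinct prognostic value).
#'
#' @param fractions samples x populations matrix or \code{fraction_table}.
#' @param populations populations to score; defaults to
#'   \code{\link{nonrare_populations}}.
#' @param cfg a \code{\link{score_config}}.
#' @return data.frame of scores, one column per "A/B" pair, rownames =
#'   samples.
#' @export
ratio_scores <- function(fractions, populations = NULL,
                         cfg = score_config()) {
  fr <- .as_fraction_matrix(fractions)
  if (is.null(populations)) populations <- nonrare_populations(fr, cfg)
  miss <- setdiff(populations, colnames(fr))
  if (length(miss)) stop("unknown population(s): ",
                         paste(miss, collapse = ", "))
  out <- list()
  for (a in populations) for (b in populations) {
    if (a == b) next
    out[[paste0(a, "/", b)]] <- fr[, a] / (fr[, b] + cfg$ratio_epsilon)
  }
  as.data.frame(out, row.names = rownames(fr), check.names = FALSE,
                optional = TRUE)
}

#' The STEM score
#'
#' Per sample, the sum of the two most prognostic compartment ratios:
#' the early-malignant-epithelial to stromal fraction ratio (non-immune
#' compartment) plus the adaptive-T to monocyte fraction ratio (immune
#' compartment):
#' \deqn{STEM = f_{EMEC}/f_{Stromal} + f_{Tadaptive}/f_{Monocytes}}
#'
#' @param fractions_nonimmune samples x populations fractions containing the
#'   columns named by \code{emec} and \code{stromal}.
#' @param fractions_immune samples x populations fractions containing the
#'   columns named by \code{t_adaptive} and \code{monocytes}.
#' @param cfg a \code{\link{score_config}}.
#' @param emec,stromal,t_adaptive,monocytes column names of the four STEM
#'   populations.
#' @return Named numeric vector of per-sample STEM scores (samples taken
#'   from the non-immune table; the immune table must cover them).
#' @export
stem_score <- function(fractions_nonimmune, fractions_immune,
                       cfg = score_config(),
                       emec = "EMEC", stromal = "Stromal",
                       t_adaptive = "Tadaptive", monocytes = "Monocytes") {
  ni <- .as_fraction_matrix(fractions_nonimmune)
  im <- .as_fraction_matrix(fractions_immune)
  for (col in c(emec, stromal))
    if (!col %in% colnames(ni)) stop("non-immune fractions lack column '",
                                     col, "'")
  for (col in c(t_adaptive, monocytes))
    if (!col %in% colnames(im)) stop("immune fractions lack column '",
                                     col, "'")
  if (!is.null(rownames(ni)) && !is.null(rownames(im))) {
    miss <- setdiff(rownames(ni), rownames(im))
    if (length(miss)) stop("immune fractions missing sample(s): ",
                           paste(utils::head(miss), collapse = ", "))
    im <- im[rownames(ni), , drop = FALSE]
  }
  eps <- cfg$ratio_epsilon
  s <- ni[, emec] / (ni[, stromal] + eps) +
       im[, t_adaptive] / (im[, monocytes] + eps)
  stats::setNames(as.numeric(s), rownames(ni))
}
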