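# Survival statistics: Kaplan-Meier / log-rank, Cox models with FDR
# adjustment, fixed-effects meta-analysis and the prognostic marker-gene
# screen.

#' Kaplan-Meier curves and log-rank test between groups
#'
#' @param groups per-sample group labels (>= 2 non-empty groups).
#' @param survival data.frame with \code{os_time}, \code{os_event}.
#' @return A list: \code{fit} (a \code{survfit} object with the
#'   product-limit estimates), \code{chisq}, \code{df}, \code{p}.
#' @export
km_logrank <- function(groups, survival) {
  groups <- factor(groups)
  if (nlevels(droplevels(groups)) < 2)
    stop("need >= 2 non-empty groups")
  if (sum(survival$os_event) < 1) stop("need >= 1 event")
  srv <- survival::Surv(survival$os_time, survival$os_event)
  fit <- survival::survfit(srv ~ groups)
  sd <- survival::survdiff(srv ~ groups)
  df <- length(sd$n) - 1
  list(fit = fit, chisq = unname(sd$chisq), df = df,
       p = stats::pchisq(sd$chisq, df, lower.tail = FALSE))
}

# term-level tidy summary of a coxph fit
.cox_table <- function(fit) {
  s <- summary(fit)
  co <- s$coefficients
  data.frame(term = rownames(co),
             beta = co[, "coef"],
             HR = exp(co[, "coef"]),
             se = co[, "se(coef)"],
             z = co[, "z"],
             CI_low = exp(co[, "coef"] - 1.96 * co[, "se(coef)"]),
             CI_high = exp(co[, "coef"] + 1.96 * co[, "se(coef)"]),
             p = co[, "Pr(>|z|)"],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Univariate or multivariate Cox proportional-hazards fits
#'
#' Partial-likelihood fits with Efron tie handling. In univariate mode each
#' term is fitted alone; in multivariate mode all terms are fitted jointly
#' (the covariate layout used throughout: age, sex, stage with level I as
#' reference, Lauren histology, treatment flags — whatever subset the table
#' carries). Stage columns are coerced to factors so level I is the
#' reference. Non-converged fits are flagged, not dropped silently.
#'
#' @param survival data.frame with \code{os_time}, \code{os_event} and the
#'   covariate columns named in \code{terms}.
#' @param terms character vector of covariate column names.
#' @param type "univariate" (default) or "multivariate".
#' @param fdr apply Benjamini-Hochberg adjustment across the returned
#'   p-values (default TRUE).
#' @return data.frame with columns term, beta, HR, se, z, CI_low, CI_high,
#'   p, fdr_adjusted_p, converged.
#' @export
cox_fit <- function(survival, terms,
                    type = c("univariate", "multivariate"), fdr = TRUE) {
  type <- match.arg(type)
  miss <- setdiff(terms, names(survival))
  if (length(miss)) stop("missing covariate column(s): ",
                         paste(miss, collapse = ", "))
  dat <- survival
  if ("stage" %in% terms)
    dat$stage <- stats::relevel(factor(dat$stage),
                                ref = sort(unique(as.character(dat$stage)))[1])
  if (sum(dat$os_event) < length(terms) + 1)
    stop("too few events for ", length(terms), " term(s)")
  srv <- survival::Surv(dat$os_time, dat$os_event)
  fit_one <- function(tms) {
    f <- stats::as.formula(paste("srv ~", paste(tms, collapse = " + ")))
    fit <- tryCatch(survival::coxph(f, data = dat, ties = "efron"),
                    warning = function(w) {
                      fit <- suppressWarnings(
                        survival::coxph(f, data = dat, ties = "efron"))
                      attr(fit, "flagged") <- conditionMessage(w)
                      fit
                    })
    out <- .cox_table(fit)
    out$converged <- is.null(attr(fit, "flagged"))
    out
  }
  res <- if (type == "univariate")
    do.call(rbind, lapply(terms, fit_one))
  else fit_one(terms)
  if (fdr) res$fdr_adjusted_p <- fdr_adjust(res$p)
  res
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' @param p vector of p-values in [0, 1].
#' @return The step-up adjusted p-values (monotone, >= raw p).
#' @export
fdr_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must be in [0,1]")
  stats::p.adjust(p, method = "BH")
}

#' Fixed-effects (inverse-variance) meta-analysis of log hazard ratios
#'
#' Pools per-study log-HRs with weights 1/se^2; the pooled standard error
#' is (sum of weights)^(-1/2) and the overall effect is tested by z.
#'
#' @param betas per-study log hazard ratios.
#' @param ses per-study standard errors (> 0).
#' @param labels optional study labels.
#' @return A list of class \code{meta_result}: pooled_beta, pooled_se,
#'   pooled_HR, CI_low, CI_high, z, p, and \code{studies} (the inputs with
#'   normalised weights). A single study passes through with a note.
#' @export
meta_fixed <- function(betas, ses, labels = NULL) {
  if (length(betas) != length(ses)) stop("betas and ses must match")
  if (any(ses <= 0)) stop("all ses must be > 0")
  if (is.null(labels)) labels <- paste0("study", seq_along(betas))
  w <- 1 / ses^2
  pooled_beta <- sum(w * betas) / sum(w)
  pooled_se <- 1 / sqrt(sum(w))
  z <- pooled_beta / pooled_se
  res <- list(pooled_beta = pooled_beta, pooled_se = pooled_se,
              pooled_HR = exp(pooled_beta),
              CI_low = exp(pooled_beta - 1.96 * pooled_se),
              CI_high = exp(pooled_beta + 1.96 * pooled_se),
              z = z, p = 2 * stats::pnorm(-abs(z)),
              studies = data.frame(label = labels, beta = betas, se = ses,
                                   weight = w / sum(w),
                                   stringsAsFactors = FALSE),
              note = if (length(betas) == 1)
                "single study: pooled result equals the input" else NULL)
  structure(res, class = "meta_result")
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf(
    "fixed-effects meta: HR %.3f (95%% CI %.3f-%.3f), z = %.2f, p = %.3g (%d studies)\n",
    x$pooled_HR, x$CI_low, x$CI_high, x$z, x$p, nrow(x$studies)))
  invisible(x)
}

#' Screen marker genes for prognostic value across cohorts
#'
#' For each gene: a multivariate Cox model per cohort (the gene's expression
#' as a continuous term, z-standardised per cohort by default, plus whatever
#' covariates that cohort carries); genes significant (p < \code{per_cohort_p})
#' with the population's expected hazard direction (HR > 1 for stromal
#' markers, HR < 1 for EMEC markers) in at least \code{min_cohorts} cohorts
#' are pooled by fixed-effects meta-analysis; the gene is selected when the
#' overall p is below \code{meta_p}. When requiring all cohorts yields no
#' gene, the rule relaxes to all-but-one (the "three of four" fallback).
#'
#' @param cohorts named list; each element a list with \code{expression}
#'   (gene x sample matrix) and \code{clinical} (data.frame with os_time,
#'   os_event and covariates).
#' @param genes marker genes to screen.
#' @param direction "risk" (HR > 1 expected; stromal) or "protective"
#'   (HR < 1 expected; EMEC).
#' @param covariates covariate columns used when present in a cohort;
#'   absent ones are dropped per cohort.
#' @param per_cohort_p per-cohort significance threshold (default 0.05).
#' @param meta_p overall-effect threshold (default 1e-5).
#' @param min_cohorts cohorts that must pass; NULL (default) = all, with
#'   the all-but-one fallback.
#' @param standardize z-score expression per cohort (default TRUE).
#' @return data.frame: gene, n_cohorts_significant, meta_beta, meta_se,
#'   meta_HR, meta_p, direction_ok, selected; attribute
#'   \code{per_cohort} holds the full per-cohort results.
#' @export
prognostic_gene_screen <- function(cohorts, genes,
                                   direction = c("risk", "protective"),
                                   covariates = c("age", "sex", "stage",
                                                  "lauren", "chemotherapy",
                                                  "radiation"),
                                   per_cohort_p = 0.05, meta_p = 1e-5,
                                   min_cohorts = NULL, standardize = TRUE) {
  direction <- match.arg(direction)
  n_coh <- length(cohorts)
  if (is.null(names(cohorts))) names(cohorts) <- paste0("cohort", seq_len(n_coh))

  per <- list()
  for (cn in names(cohorts)) {
    co <- cohorts[[cn]]
    cl <- co$clinical
    covs <- intersect(covariates, names(cl))
    if (length(setdiff(covariates, covs)))
      message(cn, ": covariate(s) absent, dropped: ",
              paste(setdiff(covariates, covs), collapse = ", "))
    if ("stage" %in% covs)
      cl$stage <- stats::relevel(
        factor(cl$stage), ref = sort(unique(as.character(cl$stage)))[1])
    srv <- survival::Surv(cl$os_time, cl$os_event)
    for (g in genes) {
      expr <- co$expression[g, ]
      x <- if (standardize) as.numeric(scale(expr)) else as.numeric(expr)
      dat <- cbind(data.frame(.expr = x), cl[covs])
      f <- stats::as.formula(
        paste("srv ~ .expr", if (length(covs))
          paste("+", paste(covs, collapse = " + ")) else ""))
      fit <- tryCatch(
        suppressWarnings(survival::coxph(f, data = dat, ties = "efron")),
        error = function(e) NULL)
      if (is.null(fit)) next
      co_row <- summary(fit)$coefficients[".expr", , drop = FALSE]
      per[[length(per) + 1]] <- data.frame(
        cohort = cn, gene = g, beta = co_row[, "coef"],
        se = co_row[, "se(coef)"], p = co_row[, "Pr(>|z|)"],
        row.names = NULL, stringsAsFactors = FALSE)
    }
  }
  per <- do.call(rbind, per)

  dir_ok <- function(beta) if (direction == "risk") beta > 0 else beta < 0
  summarise <- function(k_required) {
    out <- lapply(genes, function(g) {
      pg <- per[per$gene == g, ]
      n_sig <- sum(pg$p < per_cohort_p & dir_ok(pg$beta))
      m <- meta_fixed(pg$beta, pg$se, pg$cohort)
      data.frame(gene = g, n_cohorts_significant = n_sig,
                 meta_beta = m$pooled_beta, meta_se = m$pooled_se,
                 meta_HR = m$pooled_HR, meta_p = m$p,
                 direction_ok = dir_ok(m$pooled_beta),
                 selected = n_sig >= k_required & dir_ok(m$pooled_beta) &
                   m$p < meta_p,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  }
  k_all <- if (is.null(min_cohorts)) n_coh else min_cohorts
  res <- summarise(k_all)
  if (is.null(min_cohorts) && !any(res$selected) && n_coh > 1) {
    res <- summarise(n_coh - 1)   # "significant in three of the four"
    attr(res, "fallback") <- n_coh - 1
  }
  attr(res, "per_cohort") <- per
  res
}
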