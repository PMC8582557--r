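# nu-SVR deconvolution of bulk mixtures against a signature matrix, with
# non-negativity and sum-to-one constraints (the CIBERSORT recipe).

#' Deconvolution configuration
#'
#' Reproduces the published support-vector-regression recipe: the mixture
#' and the signature are z-standardised, a linear-kernel nu-SVR is fitted
#' for each nu in \code{nu_grid}, the nu minimising the reconstruction RMSE
#' on the signature genes wins, negative coefficients are clipped to zero
#' and the rest renormalised to sum to one.
#'
#' @param nu_grid candidate nu values in (0, 1) (default 0.25, 0.5, 0.75).
#' @param scaling z-score standardisation of mixture and signature
#'   (default TRUE); guarantees scale invariance of the fractions.
#' @param min_overlap_genes minimum genes shared between signature and bulk
#'   (default 100).
#' @param cost SVR cost parameter (libsvm default 1).
#' @return A list of class \code{deconv_config}.
#' @export
deconv_config <- function(nu_grid = c(0.25, 0.5, 0.75), scaling = TRUE,
                          min_overlap_genes = 100, cost = 1) {
  if (any(nu_grid <= 0 | nu_grid >= 1)) stop("nu values must be in (0,1)")
  structure(list(nu_grid = nu_grid, scaling = scaling,
                 min_overlap_genes = min_overlap_genes, cost = cost),
            class = "deconv_config")
}

# fit one sample: returns list(fractions, rmse, r, nu)
.deconvolve_one <- function(X, y, cfg) {
  if (cfg$scaling) {
    Xs <- (X - mean(X)) / stats::sd(as.vector(X))
    ys <- (y - mean(y)) / stats::sd(y)
  } else {
    Xs <- X; ys <- y
  }
  best <- NULL
  for (nu in cfg$nu_grid) {
    fit <- e1071::svm(Xs, ys, type = "nu-regression", kernel = "linear",
                      nu = nu, cost = cfg$cost, scale = FALSE)
    w <- as.numeric(t(fit$coefs) %*% fit$SV)
    w_pos <- pmax(w, 0)
    if (sum(w_pos) == 0) next
    f <- w_pos / sum(w_pos)
    recon <- as.numeric(Xs %*% f)
    # compare on the standardised scale used in fitting
    rs <- if (stats::sd(recon) > 0) scale(recon)[, 1] else recon
    rmse <- sqrt(mean((rs - ys)^2))
    r <- suppressWarnings(stats::cor(recon, ys))
    if (is.null(best) || rmse < best$rmse)
      best <- list(fractions = f, rmse = rmse, r = r, nu = nu)
  }
  if (is.null(best))
    best <- list(fractions = rep(1 / ncol(X), ncol(X)), rmse = NA_real_,
                 r = NA_real_, nu = NA_real_)
  best
}

#' Deconvolve bulk samples into relative cell-population fractions
#'
#' Estimates, per sample, relative (not absolute) population fractions by
#' nu-SVR of the mixture on the signature columns over the genes shared by
#' both matrices. Fractions are non-negative and sum to one.
#'
#' @param signature a \code{signature_matrix} or gene x population matrix.
#' @param bulk gene x sample expression matrix (row names are gene ids).
#' @param cfg a \code{\link{deconv_config}}.
#' @param compartment optional tag ("nonimmune" or "immune") carried in the
#'   result.
#' @return A list of class \code{fraction_table}: \code{fractions} (samples
#'   x populations, rows on the probability simplex), \code{diagnostics}
#'   (per-sample rmse, r, nu), \code{compartment}.
#' @export
deconvolve <- function(signature, bulk, cfg = deconv_config(),
                       compartment = NULL) {
  S <- if (inherits(signature, "signature_matrix")) signature$values
       else as.matrix(signature)
  bulk <- as.matrix(bulk)
  if (any(bulk < 0)) stop("bulk expression must be non-negative")
  shared <- intersect(rownames(S), rownames(bulk))
  if (length(shared) < cfg$min_overlap_genes)
    stop("only ", length(shared), " genes shared between signature (",
         nrow(S), ") and bulk (", nrow(bulk), "); need >= ",
         cfg$min_overlap_genes)
  X <- S[shared, , drop = FALSE]
  B <- bulk[shared, , drop = FALSE]
  if (any(colSums(B) == 0))
    stop("all-zero mixture(s): ",
         paste(colnames(B)[colSums(B) == 0], collapse = ", "))
  fits <- lapply(seq_len(ncol(B)), function(j)
    .deconvolve_one(X, B[, j], cfg))
  fr <- do.call(rbind, lapply(fits, `[[`, "fractions"))
  rownames(fr) <- colnames(B)
  colnames(fr) <- colnames(S)
  diag <- data.frame(
    sample = colnames(B),
    rmse = vapply(fits, `[[`, numeric(1), "rmse"),
    r = vapply(fits, `[[`, numeric(1), "r"),
    nu = vapply(fits, `[[`, numeric(1), "nu"),
    stringsAsFactors = FALSE)
  structure(list(fractions = fr, diagnostics = diag,
                 compartment = compartment),
            class = "fraction_table")
}

#' @export
print.fraction_table <- function(x, ...) {
  cat(sprintf("fraction_table%s: %d samples x %d populations\n",
              if (!is.null(x$compartment)) paste0(" (", x$compartment, ")")
              else "",
              nrow(x$fractions), ncol(x$fractions)))
  invisible(x)
}

#' Reconstruction goodness of fit for estimated fractions
#'
#' Rebuilds each mixture as signature times fractions on the shared genes and
#' scores it against the observed mixture on the standardised scale used in
#' fitting.
#'
#' @param signature a \code{signature_matrix} or gene x population matrix.
#' @param fractions samples x populations matrix (or a
#'   \code{fraction_table}).
#' @param bulk gene x sample matrix.
#' @return data.frame: sample, rmse, r.
#' @export
reconstruct_and_score <- function(signature, fractions, bulk) {
  S <- if (inherits(signature, "signature_matrix")) signature$values
       else as.matrix(signature)
  if (inherits(fractions, "fraction_table")) fractions <- fractions$fractions
  fractions <- as.matrix(fractions)
  bulk <- as.matrix(bulk)
  shared <- intersect(rownames(S), rownames(bulk))
  X <- if (is.null(colnames(fractions))) S[shared, , drop = FALSE]
       else S[shared, colnames(fractions), drop = FALSE]
  Xs <- (X - mean(X)) / stats::sd(as.vector(X))
  out <- lapply(seq_len(ncol(bulk)), function(j) {
    y <- bulk[shared, j]
    ys <- (y - mean(y)) / stats::sd(y)
    recon <- as.numeric(Xs %*% fractions[j, ])
    rs <- if (stats::sd(recon) > 0) scale(recon)[, 1] else recon
    data.frame(sample = colnames(bulk)[j],
               rmse = sqrt(mean((rs - ys)^2)),
               r = suppressWarnings(stats::cor(recon, ys)))
  })
  do.call(rbind, out)
}

#' Write a fraction table (with diagnostics) as TSV
#'
#' @param ft a \code{fraction_table}.
#' @param path output file.
#' @return Invisibly, \code{path}.
#' @export
write_fractions_tsv <- function(ft, path) {
  stopifnot(inherits(ft, "fraction_table"))
  df <- data.frame(sample = rownames(ft$fractions), ft$fractions,
                   ft$diagnostics[, c("rmse", "r", "nu")],
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
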