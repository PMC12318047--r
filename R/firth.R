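#' @title Gene-set burden enrichment by Firth penalized logistic regression
#' @name geneset_firth
#' @description
#' Case-control status is regressed on the per-sample count of qualifying
#' variants inside a gene set, adjusting for principal components, sex and
#' the exome-wide rare-coding burden. The likelihood is penalized by the
#' Jeffreys prior (half the log determinant of the Fisher information), which
#' keeps estimates finite under complete or quasi-complete separation — the
#' usual state of affairs for sparse rare-variant burdens. The burden p-value
#' is a penalized likelihood-ratio test by default.
NULL

#' Define a gene-set burden test
#'
#' @param name label.
#' @param gene_ids non-empty character vector of member genes.
#' @param variant_class test class, see [variant_classes()].
#' @param filter `"singleton"` (cohort MAC 1, absent from the reference
#'   panel) or `"mac_cap"` with the given cap.
#' @param mac_cap cap used when `filter = "mac_cap"` (default 5).
#' @return List of class `geneset_spec`.
#' @export
geneset_spec <- function(name, gene_ids, variant_class = "PTV_only",
                         filter = c("mac_cap", "singleton"), mac_cap = 5L) {
  filter <- match.arg(filter)
  if (!length(gene_ids)) stop("gene_ids must be non-empty")
  variant_class <- match.arg(variant_class, variant_classes())
  structure(list(name = name, gene_ids = unique(gene_ids),
                 variant_class = variant_class, filter = filter,
                 mac_cap = as.integer(mac_cap)),
            class = "geneset_spec")
}

#' Per-sample burden of qualifying variants within a gene set
#'
#' @param samples sample table.
#' @param variants variant table.
#' @param spec a [geneset_spec()].
#' @param panel optional gene annotation table; when supplied, set members
#'   absent from the panel raise a configuration error.
#' @return Named integer vector over all samples.
#' @export
set_burden_vector <- function(samples, variants, spec, panel = NULL) {
  if (!is.null(panel)) {
    unknown <- setdiff(spec$gene_ids, panel$gene_id)
    if (length(unknown))
      stop("gene set '", spec$name, "' names gene(s) not in the panel: ",
           paste(unknown, collapse = ", "))
  }
  keep <- variants$gene_id %in% spec$gene_ids &
    class_membership(variants, spec$variant_class)
  keep <- keep & if (spec$filter == "singleton") is_singleton(variants) else
    passes_rare_filter(variants, mac_cap = spec$mac_cap)
  exome_wide_burden(samples, variants, filter = keep)
}

# Penalized log-likelihood, score and information for logistic y ~ X b.
.firth_pieces <- function(y, X, beta) {
  eta <- drop(X %*% beta)
  p <- stats::plogis(eta)
  w <- p * (1 - p)
  XW <- X * w
  I <- crossprod(X, XW)                    # Fisher information
  ch <- tryCatch(chol(I), error = function(e) NULL)
  if (is.null(ch)) return(NULL)
  logdet <- 2 * sum(log(diag(ch)))
  # hat values h_i = w_i x_i' I^{-1} x_i via one triangular solve
  B <- forwardsolve(t(ch), t(X * sqrt(w)))
  h <- colSums(B^2)
  log1pe <- ifelse(eta > 30, eta, log1p(exp(eta)))  # overflow guard
  ll <- sum(y * eta - log1pe) + 0.5 * logdet
  U <- drop(crossprod(X, y - p + h * (0.5 - p)))
  list(ll = ll, U = U, I = I, ch = ch)
}

#' Fit a Firth-penalized logistic regression
#'
#' Maximizes the Jeffreys-penalized log-likelihood
#' `l(beta) + 1/2 log det I(beta)` by Newton iterations with step-halving.
#' Convergence: relative penalized log-likelihood change `<= 1e-8` or score
#' max-norm `<= 1e-6`, at most `max_iter` iterations with up to 10 halvings
#' per step.
#'
#' @param y 0/1 response vector (not constant).
#' @param X design matrix including the intercept; full column rank.
#' @param test_col column (index or name) whose coefficient is tested
#'   (default 2, the column after the intercept).
#' @param p_method `"plrt"` (penalized likelihood-ratio test, default) or
#'   `"wald"`.
#' @param max_iter maximum Newton iterations (default 50).
#' @return List of class `firth_fit`: `beta`, `se`, `or_burden`, `ci95`
#'   (Wald on the log-odds scale, exponentiated), `p_burden`, `loglik`
#'   (penalized), `converged`, `n_iter`.
#' @export
firth_fit <- function(y, X, test_col = 2L, p_method = c("plrt", "wald"),
                      max_iter = 50L) {
  p_method <- match.arg(p_method)
  y <- as.numeric(y)
  X <- as.matrix(X)
  if (length(unique(y)) < 2L) stop("response is constant")
  if (qr(X)$rank < ncol(X)) stop("design matrix is rank-deficient")
  if (is.character(test_col)) test_col <- match(test_col, colnames(X))
  fit <- .firth_newton(y, X, max_iter = max_iter)
  se <- sqrt(diag(chol2inv(fit$ch)))
  b <- fit$beta[test_col]
  hw <- stats::qnorm(0.975) * se[test_col]
  p_burden <- if (p_method == "wald") {
    stats::pchisq((b / se[test_col])^2, df = 1, lower.tail = FALSE)
  } else {
    # constrained fit: tested coefficient fixed at 0, penalty still from the
    # full-model information (the standard penalized LRT construction)
    fit0 <- .firth_newton(y, X, max_iter = max_iter,
                          free = setdiff(seq_len(ncol(X)), test_col))
    stats::pchisq(max(0, 2 * (fit$ll - fit0$ll)), df = 1, lower.tail = FALSE)
  }
  structure(list(beta = stats::setNames(fit$beta, colnames(X)),
                 se = stats::setNames(se, colnames(X)),
                 or_burden = exp(b), ci95 = exp(b + c(-hw, hw)),
                 p_burden = p_burden, loglik = fit$ll,
                 converged = fit$converged, n_iter = fit$n_iter),
            class = "firth_fit")
}

# Newton ascent of the penalized log-likelihood. `free` restricts the update
# to a coordinate subset (others pinned at 0) for constrained/LRT fits; the
# penalty always uses the full design.
.firth_newton <- function(y, X, max_iter = 50L, tol_grad = 1e-6,
                          tol_ll = 1e-8, free = seq_len(ncol(X))) {
  beta <- rep(0, ncol(X))
  cur <- .firth_pieces(y, X, beta)
  if (is.null(cur)) stop("Fisher information is singular at the start")
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    I_free <- crossprod(cur$ch)[free, free, drop = FALSE]
    step <- rep(0, ncol(X))
    step[free] <- solve(I_free, cur$U[free])
    cand <- NULL
    for (h in 0:10) {
      b2 <- beta + step / 2^h
      cand <- .firth_pieces(y, X, b2)
      if (!is.null(cand) && is.finite(cand$ll) && cand$ll >= cur$ll - 1e-12)
        break
      cand <- NULL
    }
    if (is.null(cand)) break  # no admissible step
    rel <- abs(cand$ll - cur$ll) / (abs(cur$ll) + 1e-10)
    beta <- b2
    cur <- cand
    if (max(abs(cur$U[free])) <= tol_grad || rel <= tol_ll) {
      converged <- TRUE
      break
    }
  }
  list(beta = beta, ll = cur$ll, U = cur$U, ch = cur$ch,
       converged = converged, n_iter = it)
}

#' @export
print.firth_fit <- function(x, ...) {
  cat(sprintf(
    "Firth fit: OR = %.4g (95%% CI %.4g-%.4g), p = %.4g, %sconverged in %d iterations\n",
    x$or_burden, x$ci95[1], x$ci95[2], x$p_burden,
    if (x$converged) "" else "NOT ", x$n_iter))
  invisible(x)
}

#' Gene-set enrichment test on a study
#'
#' Builds the design `[intercept, set burden, PCs, sex, exome-wide burden]`
#' and fits [firth_fit()], returning the burden effect on the odds-ratio
#' scale.
#'
#' @param study list with `variants`, `samples` and (optionally) `genes`.
#' @param spec a [geneset_spec()].
#' @param covariate_names columns of the sample table used as covariates;
#'   default: every `pc*` column, `sex`, `exome_burden`.
#' @param p_method passed to [firth_fit()].
#' @return List: `set_name`, `or_burden`, `ci95`, `p_burden`, `converged`,
#'   `n_carriers`, `fit`.
#' @export
geneset_test <- function(study, spec, covariate_names = NULL,
                         p_method = "plrt") {
  samples <- study$samples
  if (is.null(covariate_names))
    covariate_names <- c(grep("^pc[0-9]+$", names(samples), value = TRUE),
                         intersect(c("sex", "exome_burden"), names(samples)))
  missing_cov <- setdiff(covariate_names, names(samples))
  if (length(missing_cov))
    stop("covariate(s) missing from samples: ",
         paste(missing_cov, collapse = ", "))
  burden <- set_burden_vector(samples, study$variants, spec,
                              panel = study$genes)
  y <- as.numeric(samples$phenotype == "case")
  covs <- lapply(covariate_names, function(nm) {
    x <- samples[[nm]]
    if (nm == "sex") as.numeric(x == "male") else as.numeric(x)
  })
  X <- cbind(intercept = 1, burden = as.numeric(burden[samples$sample_id]),
             do.call(cbind, stats::setNames(covs, covariate_names)))
  fit <- firth_fit(y, X, test_col = "burden", p_method = p_method)
  list(set_name = spec$name, or_burden = fit$or_burden, ci95 = fit$ci95,
       p_burden = fit$p_burden, converged = fit$converged,
       n_carriers = sum(burden > 0), fit = fit)
}
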