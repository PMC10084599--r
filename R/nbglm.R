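#' Method-of-moments NB dispersion estimates
#'
#' Per-gene dispersion on the variance scale `var = mean + alpha * mean^2`.
#' Within every replicate group with at least two observations the normalized
#' counts give a moment estimate `(var_k - mean_k) / mean_k^2`; estimates are
#' combined across groups weighted by their degrees of freedom. With
#' `method = "trended"` (default) a mean-dispersion trend
#' `alpha(mu) = a0 + a1/mu` is fitted across genes and each gene-wise
#' estimate is shrunk toward the trend, which stabilizes the noisy per-gene
#' moments at small replicate numbers; `method = "moments"` returns the raw
#' (floored) gene-wise values.
#'
#' @param mat gene x observation matrix of counts.
#' @param groups factor/character of replicate-group membership per column.
#' @param norm_factors positive per-column scaling (size factors); counts are
#'   divided by these before taking moments. Default all 1.
#' @param method `"trended"` or `"moments"`.
#' @param floor smallest admissible dispersion.
#' @param shrink weight of the trend in the shrunk estimate (0..1).
#' @return numeric vector of dispersions (one per row of `mat`), with the
#'   method recorded in `attr(, "method")`.
#' @export
estimate_dispersions <- function(mat, groups, norm_factors = NULL,
                                 method = c("trended", "moments"),
                                 floor = 1e-8, shrink = 0.7) {
  method <- match.arg(method)
  mat <- as.matrix(mat)
  groups <- as.character(groups)
  if (length(groups) != ncol(mat)) stop("groups must match columns of mat")
  if (is.null(norm_factors)) norm_factors <- rep(1, ncol(mat))
  nc <- sweep(mat, 2, norm_factors, "/")

  tab <- table(groups)
  use <- names(tab)[tab >= 2]
  if (!length(use)) stop("need at least one group with >= 2 replicates")

  num <- numeric(nrow(mat))   # sum of df-weighted moment estimates
  den <- numeric(nrow(mat))
  mean_all <- numeric(nrow(mat))
  n_all <- 0
  for (g in use) {
    cols <- which(groups == g)
    m <- rowMeans(nc[, cols, drop = FALSE])
    v <- apply(nc[, cols, drop = FALSE], 1, var)
    df <- length(cols) - 1
    ok <- m > 0
    a <- ifelse(ok, (v - m) / m^2, NA_real_)
    num <- num + ifelse(ok, df * a, 0)
    den <- den + ifelse(ok, df, 0)
    mean_all <- mean_all + rowSums(nc[, cols, drop = FALSE])
    n_all <- n_all + length(cols)
  }
  mean_all <- mean_all / n_all
  raw <- ifelse(den > 0, num / pmax(den, 1), NA_real_)
  genewise <- pmax(raw, floor)
  genewise[is.na(genewise)] <- floor    # all-zero/degenerate genes

  if (method == "moments") {
    return(structure(genewise, method = "moments", raw = raw))
  }

  # mean-dispersion trend alpha(mu) = a0 + a1/mu, fitted on the raw moments
  fit_ok <- is.finite(raw) & mean_all > 0
  trend <- rep(floor, nrow(mat))
  if (sum(fit_ok) >= 10) {
    co <- tryCatch(coef(lm(raw[fit_ok] ~ I(1 / mean_all[fit_ok]))),
                   error = function(e) c(NA, NA))
    a0 <- max(co[1], floor, na.rm = TRUE)
    a1 <- max(co[2], 0, na.rm = TRUE)
    trend <- pmax(a0 + a1 / pmax(mean_all, 1e-8), floor)
  } else if (sum(fit_ok) > 0) {
    trend <- rep(max(median(raw[fit_ok]), floor), nrow(mat))
  }
  out <- pmax((1 - shrink) * genewise + shrink * trend, floor)
  structure(out, method = "trended", raw = raw, trend = trend)
}

#' Fit a negative-binomial GLM with log link and known dispersion
#'
#' Iteratively reweighted least squares with working weights
#' `mu / (1 + alpha mu)` (the inverse variance of the log-scale score for NB
#' with `var = mu + alpha mu^2`). The coefficient covariance is the inverse
#' Fisher information `(X' W X)^{-1}` at convergence.
#'
#' @param y response counts (non-negative; non-integer values are accepted,
#'   which permits fitting expected counts).
#' @param X design matrix (full rank).
#' @param offset log-scale offset per observation (e.g. log size factors).
#' @param alpha NB dispersion (>= 0; 0 is the Poisson limit). Either a
#'   scalar or one value per observation — the latter supports models mixing
#'   observation types with different variance structure (e.g. total counts
#'   and within-sample allele counts).
#' @param tol relative deviance convergence tolerance.
#' @param maxit maximum IRLS iterations.
#' @return list of class `nb_fit`: `coefficients`, `cov`, `converged`,
#'   `deviance`, `iterations`, `fitted`, `df_residual`.
#' @export
fit_nb_glm <- function(y, X, offset = 0, alpha, tol = 1e-10, maxit = 100) {
  X <- as.matrix(X)
  n <- length(y)
  if (nrow(X) != n) stop("design rows must match length(y)")
  offset <- rep_len(offset, n)
  if (any(y < 0) || any(!is.finite(y))) stop("y must be finite and non-negative")
  if (qr(X)$rank < ncol(X)) {
    return(structure(list(coefficients = rep(NA_real_, ncol(X)), cov = NULL,
                          converged = FALSE, status = "failed_fit",
                          deviance = NA_real_, iterations = 0L),
                     class = "nb_fit"))
  }

  alpha <- rep_len(alpha, n)
  if (any(alpha < 0)) stop("alpha must be non-negative")

  nb_dev <- function(y, mu) {
    t1 <- ifelse(y > 0, y * log(y / mu), 0)
    # log1p keeps the Poisson limit (alpha -> 0) numerically stable
    t2 <- ifelse(alpha > 0,
                 (y + 1 / pmax(alpha, 1e-300)) *
                   (log1p(alpha * y) - log1p(alpha * mu)),
                 y - mu)
    2 * sum(t1 - t2)
  }

  mu <- pmax(y, 1 / 6) + mean(y) / 10
  eta <- log(mu) - offset
  dev <- nb_dev(y, mu)
  beta <- NULL
  converged <- FALSE
  it <- 0L
  while (it < maxit) {
    it <- it + 1L
    w <- mu / (1 + alpha * mu)
    z <- eta + (y - mu) / mu
    sw <- sqrt(w)
    fit <- tryCatch(qr(sw * X), error = function(e) NULL)
    if (is.null(fit) || fit$rank < ncol(X)) {
      return(structure(list(coefficients = rep(NA_real_, ncol(X)), cov = NULL,
                            converged = FALSE, status = "failed_fit",
                            deviance = NA_real_, iterations = it),
                       class = "nb_fit"))
    }
    beta <- qr.coef(fit, sw * z)
    eta <- pmin(pmax(drop(X %*% beta), -30), 30)
    mu <- exp(eta + offset)
    dev_new <- nb_dev(y, mu)
    if (!is.finite(dev_new)) break
    if (abs(dev_new - dev) / (abs(dev_new) + 0.1) < tol) {
      dev <- dev_new
      converged <- TRUE
      break
    }
    dev <- dev_new
  }
  if (!converged || is.null(beta) || any(!is.finite(beta))) {
    return(structure(list(coefficients = if (is.null(beta)) rep(NA_real_, ncol(X)) else beta,
                          cov = NULL, converged = FALSE, status = "failed_fit",
                          deviance = dev, iterations = it),
                     class = "nb_fit"))
  }
  w <- mu / (1 + alpha * mu)
  info <- crossprod(X * w, X)
  cov <- tryCatch(solve(info), error = function(e) NULL)
  if (is.null(cov)) {
    return(structure(list(coefficients = beta, cov = NULL, converged = FALSE,
                          status = "failed_fit", deviance = dev,
                          iterations = it),
                     class = "nb_fit"))
  }
  dimnames(cov) <- list(colnames(X), colnames(X))
  names(beta) <- colnames(X)
  structure(list(coefficients = beta, cov = cov, converged = TRUE,
                 status = "tested", deviance = dev, iterations = it,
                 fitted = mu, df_residual = n - ncol(X)),
            class = "nb_fit")
}

#' Wald test of a linear contrast of NB GLM coefficients
#'
#' The estimate is reported in log2 units; the z statistic is the natural-log
#' estimate over its standard error and the p-value is two-sided normal,
#' `p = 2 (1 - Phi(|z|))`.
#'
#' @param fit an `nb_fit`.
#' @param contrast numeric contrast vector over the coefficients.
#' @return list: `log2fc`, `se` (log2 scale), `wald`, `p`, `status`.
#' @export
wald_contrast <- function(fit, contrast) {
  stopifnot(inherits(fit, "nb_fit"))
  if (!isTRUE(fit$converged)) {
    return(list(log2fc = NA_real_, se = NA_real_, wald = NA_real_,
                p = NA_real_, status = fit$status))
  }
  if (length(contrast) != length(fit$coefficients)) {
    stop("contrast length must match the number of coefficients")
  }
  est <- sum(contrast * fit$coefficients)
  v <- drop(t(contrast) %*% fit$cov %*% contrast)
  if (!is.finite(v) || v <= 0) {
    return(list(log2fc = est / log(2), se = NA_real_, wald = NA_real_,
                p = NA_real_, status = "failed_fit"))
  }
  z <- est / sqrt(v)
  list(log2fc = est / log(2), se = sqrt(v) / log(2), wald = z,
       p = 2 * pnorm(-abs(z)), status = "tested")
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment over the non-missing entries; `NA` entries (genes
#' that were not tested) are excluded from the number of tests and stay `NA`.
#'
#' @param p numeric vector of p-values in `[0, 1]` (NA allowed).
#' @return vector of adjusted p-values, same length and order.
#' @export
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
bh_adjust <- function(p) {
  if (!is.numeric(p)) stop("p must be numeric")
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
  out <- rep(NA_real_, length(p))
  out[ok] <- p.adjust(p[ok], method = "BH")
  out
}
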