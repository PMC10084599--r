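#' Fit the per-gene NB group model once for a dataset
#'
#' Fits every gene with a cell-means design (one coefficient per sample
#' group) so that any pairwise group contrast can be extracted afterwards
#' without refitting. Library depth enters as a `log(size factor)` offset;
#' when a [estimate_batch_factor()] object is supplied the housekeeping-based
#' batch shift is folded into the offsets as well (`batch_method = "offset"`,
#' the default) or the unit-norm factor `w1` is added as a per-gene covariate
#' (`batch_method = "covariate"`). Dispersions are estimated once from this
#' design (see [estimate_dispersions()]) and shared by all contrasts.
#'
#' @param counts gene x sample count matrix.
#' @param samples sample table with `sample_id` and `group` columns matching
#'   the columns of `counts`.
#' @param sf size factors; estimated from `counts` when `NULL`.
#' @param batch optional `batch_factor`.
#' @param batch_method how the batch factor enters the model.
#' @param dispersions optional per-gene dispersions; estimated when `NULL`.
#' @param min_count genes whose total count is below this are flagged
#'   `low_count` and not fitted.
#' @return object of class `nb_group_fit` with per-gene coefficients,
#'   covariances, status, normalized group means, and the inputs needed by
#'   [run_contrast()].
#' @export
nb_fit_groups <- function(counts, samples, sf = NULL, batch = NULL,
                          batch_method = c("offset", "covariate"),
                          dispersions = NULL, min_count = 1) {
  batch_method <- match.arg(batch_method)
  counts <- as.matrix(counts)
  if (!all(samples$sample_id %in% colnames(counts))) {
    stop("sample ids missing from the count matrix")
  }
  counts <- counts[, samples$sample_id, drop = FALSE]
  if (is.null(sf)) sf <- estimate_size_factors(counts)
  sf <- sf[samples$sample_id]

  eff_sf <- if (!is.null(batch) && batch_method == "offset") {
    effective_size_factors(sf, batch, counts)
  } else sf
  offset <- log(eff_sf)

  group <- factor(samples$group, levels = intersect(EGG_GROUPS, samples$group))
  X <- model.matrix(~ 0 + group)
  colnames(X) <- levels(group)
  if (!is.null(batch) && batch_method == "covariate") {
    X <- cbind(X, W1 = batch$w1[samples$sample_id])
  }

  if (is.null(dispersions)) {
    dispersions <- estimate_dispersions(counts, samples$group,
                                        norm_factors = eff_sf)
  }

  ngene <- nrow(counts)
  p <- ncol(X)
  beta <- matrix(NA_real_, ngene, p, dimnames = list(rownames(counts), colnames(X)))
  covs <- array(NA_real_, c(p, p, ngene))
  status <- rep("tested", ngene)

  for (i in seq_len(ngene)) {
    y <- counts[i, ]
    if (sum(y) < min_count) {
      status[i] <- "low_count"
      next
    }
    fit <- fit_nb_glm(y, X, offset = offset, alpha = dispersions[i])
    if (!isTRUE(fit$converged)) {
      status[i] <- "failed_fit"
      next
    }
    beta[i, ] <- fit$coefficients
    covs[, , i] <- fit$cov
  }

  norm <- normalize_counts(counts, eff_sf)
  group_means <- vapply(levels(group), function(g) {
    rowMeans(norm[, samples$group == g, drop = FALSE])
  }, numeric(ngene))

  structure(list(beta = beta, cov = covs, status = status,
                 group_means = group_means, groups = levels(group),
                 coef_names = colnames(X), dispersions = dispersions,
                 sf = sf, eff_sf = eff_sf, samples = samples,
                 batch_method = if (is.null(batch)) "none" else batch_method),
            class = "nb_group_fit")
}

#' @export
print.nb_group_fit <- function(x, ...) {
  cat("NB group model:", nrow(x$beta), "genes,",
      paste(x$groups, collapse = "/"), "groups\n")
  cat("  status:", paste(names(table(x$status)), table(x$status),
                         sep = "=", collapse = " "), "\n")
  cat("  batch handling:", x$batch_method, "\n")
  invisible(x)
}

#' Wald contrast between two sample groups
#'
#' Extracts `log2(groupA / groupB)` with its Wald test from a fitted
#' [nb_fit_groups()] model and applies Benjamini-Hochberg correction across
#' the tested genes of this contrast.
#'
#' @param fit an `nb_group_fit`.
#' @param groupA,groupB group labels; `groupA` is the numerator.
#' @param alpha significance level recorded with the result (0.05 for the
#'   parental contrast, 0.10 for contrasts involving F1 samples).
#' @return data.frame of class `de_result`: gene, mean_A, mean_B (normalized
#'   group means), log2fc, se, wald, p, padj, status.
#' @export
run_contrast <- function(fit, groupA, groupB, alpha = 0.05) {
  stopifnot(inherits(fit, "nb_group_fit"))
  for (g in c(groupA, groupB)) {
    if (!g %in% fit$groups) stop("unknown group: ", g)
  }
  p <- length(fit$coef_names)
  contrast <- numeric(p)
  names(contrast) <- fit$coef_names
  contrast[groupA] <- contrast[groupA] + 1
  contrast[groupB] <- contrast[groupB] - 1
  degenerate <- groupA == groupB
  if (degenerate) warning("contrast of a group with itself is degenerate")

  ngene <- nrow(fit$beta)
  est <- drop(fit$beta %*% contrast)
  v <- vapply(seq_len(ngene), function(i) {
    if (is.na(est[i])) return(NA_real_)
    drop(t(contrast) %*% fit$cov[, , i] %*% contrast)
  }, numeric(1))

  log2fc <- est / log(2)
  se <- sqrt(v) / log(2)
  wald <- ifelse(degenerate | se == 0, 0, est / sqrt(v))
  pval <- ifelse(is.na(wald), NA_real_, 2 * pnorm(-abs(wald)))
  status <- fit$status
  out <- data.frame(gene = rownames(fit$beta),
                    mean_A = fit$group_means[, groupA],
                    mean_B = fit$group_means[, groupB],
                    log2fc = log2fc, se = se, wald = wald, p = pval,
                    padj = bh_adjust(ifelse(status == "tested", pval, NA_real_)),
                    status = status,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "groupA") <- groupA
  attr(out, "groupB") <- groupB
  attr(out, "alpha") <- alpha
  attr(out, "degenerate") <- degenerate
  class(out) <- c("de_result", "data.frame")
  out
}

#' All six pairwise contrasts used by the classifiers
#'
#' Runs PP:LL at the parental significance level and the five contrasts that
#' involve F1 samples at the relaxed F1 level.
#'
#' @param fit an `nb_group_fit` containing all four groups.
#' @param alpha_parental,alpha_f1 significance levels.
#' @return named list of `de_result` tables: `PP_LL`, `PL_PP`, `PL_LL`,
#'   `LP_PP`, `LP_LL`, `PL_LP`.
#' @export
run_all_contrasts <- function(fit, alpha_parental = 0.05, alpha_f1 = 0.10) {
  need <- EGG_GROUPS
  if (!all(need %in% fit$groups)) {
    stop("all four groups are required; missing: ",
         paste(setdiff(need, fit$groups), collapse = ", "))
  }
  list(PP_LL = run_contrast(fit, "PP", "LL", alpha = alpha_parental),
       PL_PP = run_contrast(fit, "PL", "PP", alpha = alpha_f1),
       PL_LL = run_contrast(fit, "PL", "LL", alpha = alpha_f1),
       LP_PP = run_contrast(fit, "LP", "PP", alpha = alpha_f1),
       LP_LL = run_contrast(fit, "LP", "LL", alpha = alpha_f1),
       PL_LP = run_contrast(fit, "PL", "LP", alpha = alpha_f1))
}
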