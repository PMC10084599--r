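#' Median-of-ratios size factors
#'
#' For each gene with strictly positive counts in every sample, the reference
#' is the geometric mean of that gene across samples; a sample's size factor
#' is the median over those genes of `count / reference`.
#'
#' @param counts non-negative gene x sample matrix.
#' @return named positive numeric vector, one size factor per sample.
#' @export
#' @examples
#' m <- matrix(c(10, 20, 40, 20, 40, 80), ncol = 2,
#'             dimnames = list(paste0("g", 1:3), c("a", "b")))
#' estimate_size_factors(m)  # (1/sqrt(2), sqrt(2))
estimate_size_factors <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(pos)) {
    stop("size factors undefined: no gene has positive counts in every sample")
  }
  ref <- exp(rowMeans(log(counts[pos, , drop = FALSE])))
  sf <- apply(counts[pos, , drop = FALSE], 2, function(col) median(col / ref))
  if (any(!is.finite(sf)) || any(sf <= 0)) {
    stop("non-positive size factor estimated; check the count matrix")
  }
  stats::setNames(sf, colnames(counts))
}

#' Divide counts by their size factors
#'
#' @param counts gene x sample matrix.
#' @param sf named size factors covering every column of `counts`.
#' @return real-valued matrix `counts[, j] / sf[j]`.
#' @export
normalize_counts <- function(counts, sf) {
  counts <- as.matrix(counts)
  if (is.null(names(sf))) {
    if (length(sf) != ncol(counts)) stop("size factor length mismatch")
  } else {
    missing <- setdiff(colnames(counts), names(sf))
    if (length(missing)) {
      stop("no size factor for samples: ", paste(missing, collapse = ", "))
    }
    sf <- sf[colnames(counts)]
  }
  if (any(sf <= 0)) stop("size factors must be positive")
  sweep(counts, 2, sf, "/")
}

#' Housekeeping-gene batch factor
#'
#' Estimates one unwanted-variation covariate from a priori control genes,
#' absorbing the shift between sequencing batches. The log2(normalized + 1)
#' submatrix of the housekeeping genes is centered per gene across samples;
#' `w1` is its first right-singular vector (zero-sum by construction, unit
#' norm, sign fixed so the first coordinate above 1e-8 in magnitude is
#' positive). `gamma` is the per-sample log2 expression shift fitted by the
#' single factor — the rank-1 reconstruction `sigma1 * mean(u1) * w1`,
#' averaging the factor's loadings over the control genes — and is the
#' log-scale correction applied when models span both batches. Restricting
#' the correction to the leading factor keeps it one-dimensional and
#' discards control-gene measurement noise orthogonal to it.
#'
#' @param counts gene x sample count matrix.
#' @param sf size factors from [estimate_size_factors()].
#' @param housekeeping character vector of control gene ids (>= 2, all
#'   present in `counts`).
#' @return list of class `batch_factor`: `w1` (unit-norm, zero-centered),
#'   `gamma` (per-sample log2 shift), `sigma1` (leading singular value),
#'   `negligible` (TRUE when the control genes carry no sample structure),
#'   `housekeeping`.
#' @export
estimate_batch_factor <- function(counts, sf, housekeeping) {
  counts <- as.matrix(counts)
  missing <- setdiff(housekeeping, rownames(counts))
  if (length(missing)) {
    stop("housekeeping genes absent from the count matrix: ",
         paste(missing, collapse = ", "))
  }
  if (length(housekeeping) < 2) stop("need at least 2 housekeeping genes")
  norm <- normalize_counts(counts[housekeeping, , drop = FALSE], sf)
  l2 <- log2(norm + 1)
  centered <- l2 - rowMeans(l2)
  sv <- svd(centered)
  w1 <- sv$v[, 1]
  u1 <- sv$u[, 1]
  sigma1 <- sv$d[1]
  negligible <- sigma1 < 1e-8
  i <- which(abs(w1) > 1e-8)[1]
  if (!is.na(i) && w1[i] < 0) {
    w1 <- -w1
    u1 <- -u1
  }
  gamma <- if (negligible) rep(0, ncol(counts)) else sigma1 * mean(u1) * w1
  structure(list(w1 = stats::setNames(w1, colnames(counts)),
                 gamma = stats::setNames(gamma, colnames(counts)),
                 sigma1 = sigma1,
                 negligible = negligible,
                 housekeeping = housekeeping),
            class = "batch_factor")
}

#' @export
print.batch_factor <- function(x, ...) {
  cat("Housekeeping batch factor (", length(x$housekeeping), " control genes)\n",
      sep = "")
  cat("  leading singular value:", format(x$sigma1, digits = 4),
      if (x$negligible) "(negligible)" else "", "\n")
  cat("  gamma range (log2):",
      paste(format(range(x$gamma), digits = 3), collapse = " .. "), "\n")
  invisible(x)
}

# effective per-sample scaling: size factors, then the housekeeping-based
# batch shift (gamma, log2), then — when counts are supplied — a second
# joint median-of-ratios pass on the corrected scale. The second pass
# absorbs any global residual of the housekeeping bridge, mirroring the
# two-step normalization (batch factor for cross-batch comparability,
# median-of-ratios across all samples for depth).
effective_size_factors <- function(sf, batch = NULL, counts = NULL) {
  if (is.null(batch)) return(sf)
  stopifnot(inherits(batch, "batch_factor"))
  g <- batch$gamma[names(sf)]
  eff <- sf * 2 ^ g
  if (!is.null(counts)) {
    r <- estimate_size_factors(sweep(counts[, names(sf), drop = FALSE], 2, eff, "/"))
    eff <- eff * r
  }
  eff
}
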