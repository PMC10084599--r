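#' Filter genes with informative allele assignment
#'
#' A gene is informative when, summing over all F1 samples, more than
#' `min_frac` of its reads could be assigned to a parental allele and at
#' least `min_reads` reads were assigned.
#'
#' @param allele allele count table.
#' @param min_frac minimum assigned fraction (strict inequality; default 0.20).
#' @param min_reads minimum total assigned reads (default 10).
#' @return character vector of informative gene ids.
#' @export
#' @examples
#' tab <- data.frame(gene = c("a", "b"), sample_id = "PL_1",
#'                   reads_P = c(15, 5), reads_L = c(10, 4),
#'                   reads_unassigned = c(75, 21))
#' filter_informative(tab)  # "a"
filter_informative <- function(allele, min_frac = 0.20, min_reads = 10) {
  assigned <- tapply(allele$reads_P + allele$reads_L, allele$gene, sum)
  total <- tapply(allele$reads_P + allele$reads_L + allele$reads_unassigned,
                  allele$gene, sum)
  keep <- total > 0 & assigned / total > min_frac & assigned >= min_reads
  names(keep)[keep]
}

#' Allele-level dispersion from extra-binomial variation
#'
#' The two allele counts of a sample share that sample's total-count noise,
#' which cancels in the within-sample allele comparison; estimating an NB
#' dispersion from the marginal across-sample variance of allele counts
#' would therefore overstate the uncertainty of allelic contrasts. This
#' estimator targets only allele-level noise: per gene (and per cross
#' direction, pooled by degrees of freedom) it computes the binomial Pearson
#' overdispersion of the L-allele fractions across samples,
#' `phi = mean[(L_j - a_j f)^2 / (a_j f (1 - f))]` with `a_j` the assigned
#' total, and converts the excess `phi - 1` into the NB dispersion that
#' inflates the log allelic-ratio variance by the same amount:
#' `alpha = (phi - 1) / (2 abar f (1 - f))`. Pure binomial thinning gives
#' `phi ~ 1` and hence a near-Poisson allele model, whose independent
#' log-ratio variance `1/m_P + 1/m_L` equals the binomial log-odds variance.
#'
#' @param P,L gene x F1-sample matrices of allele-assigned counts.
#' @param direction optional per-column cross-direction labels (PL/LP);
#'   fractions are centered within direction so a direction-dependent
#'   allelic shift is not counted as noise.
#' @param floor smallest admissible dispersion.
#' @return numeric vector of per-gene dispersions.
#' @export
allele_dispersions <- function(P, L, direction = NULL, floor = 1e-8) {
  P <- as.matrix(P); L <- as.matrix(L)
  stopifnot(identical(dim(P), dim(L)))
  if (is.null(direction)) direction <- rep("all", ncol(P))
  out <- rep(floor, nrow(P))
  for (i in seq_len(nrow(P))) {
    num <- 0; df <- 0; afw <- 0
    for (dir in unique(direction)) {
      cols <- which(direction == dir)
      a <- P[i, cols] + L[i, cols]
      use <- a > 0
      if (sum(use) < 2) next
      a <- a[use]; l <- L[i, cols][use]
      f <- sum(l) / sum(a)
      if (f <= 0 || f >= 1) next
      d <- sum(use) - 1
      num <- num + sum((l - a * f)^2 / (a * f * (1 - f)))
      df <- df + d
      afw <- afw + d * mean(a) * f * (1 - f)
    }
    if (df == 0 || afw == 0) next
    phi <- num / df
    out[i] <- max((phi - 1) / (2 * afw / df), floor)
  }
  out
}

# internal: reshape an allele count table into genes x sample matrices for
# the P and L alleles, restricted to the given samples
allele_matrices <- function(allele, sample_ids, genes = NULL) {
  sub <- allele[allele$sample_id %in% sample_ids, , drop = FALSE]
  if (!nrow(sub)) stop("no allele counts for the requested samples")
  if (is.null(genes)) genes <- sort(unique(sub$gene))
  gi <- match(sub$gene, genes)
  si <- match(sub$sample_id, sample_ids)
  ok <- !is.na(gi)
  P <- matrix(0L, length(genes), length(sample_ids),
              dimnames = list(genes, sample_ids))
  L <- P
  P[cbind(gi[ok], si[ok])] <- sub$reads_P[ok]
  L[cbind(gi[ok], si[ok])] <- sub$reads_L[ok]
  list(P = P, L = L)
}

#' Test allelic imbalance in F1 samples
#'
#' Each F1 sample contributes two observations per gene (P-allele and
#' L-allele read counts). A per-gene NB GLM with a Geno (allele) coefficient
#' is fitted with an offset equal to the log of the sample's assigned-read
#' scale — both alleles of a sample share that offset, so allele
#' assignability and any sample-level batch shift cancel in the comparison.
#' The reported `log2fc` is the allelic log2 ratio L over P.
#'
#' @param allele allele count table.
#' @param samples sample table (only its F1 rows are used).
#' @param genes genes to test (e.g. [filter_informative()] output); default
#'   all genes in `allele`.
#' @param alpha significance level recorded with the result (default 0.10).
#' @param dispersions optional per-gene dispersions for the allele counts;
#'   by default estimated with [allele_dispersions()] (extra-binomial
#'   variation only, since total-count noise cancels within samples).
#' @return data.frame of class `de_result`: gene, mean_P, mean_L, log2fc,
#'   se, wald, p, padj, status.
#' @export
test_allelic_imbalance <- function(allele, samples, genes = NULL,
                                   alpha = 0.10, dispersions = NULL) {
  f1 <- samples[samples$group %in% F1_GROUPS, , drop = FALSE]
  if (!nrow(f1)) stop("no F1 (PL/LP) samples supplied")
  am <- allele_matrices(allele, f1$sample_id, genes)
  P <- am$P; L <- am$L
  ngene <- nrow(P); ns <- ncol(P)

  tot <- colSums(P + L)
  if (all(tot == 0)) stop("no assigned reads in any sample")
  scale <- tot / exp(mean(log(pmax(tot, 1))))
  scale[scale <= 0] <- 1

  # observation layout: all P columns then all L columns
  obs <- cbind(P, L)
  geno <- rep(c("P", "L"), each = ns)
  if (is.null(dispersions)) {
    dispersions <- allele_dispersions(P, L, direction = f1$group)
  }

  X <- cbind(intercept = 1, genoL = as.numeric(geno == "L"))
  offset <- log(rep(scale, 2))
  contrast <- c(0, 1)

  res <- data.frame(gene = rownames(P),
                    mean_P = rowMeans(sweep(P, 2, scale, "/")),
                    mean_L = rowMeans(sweep(L, 2, scale, "/")),
                    log2fc = NA_real_, se = NA_real_, wald = NA_real_,
                    p = NA_real_, status = "tested",
                    stringsAsFactors = FALSE, row.names = NULL)
  for (i in seq_len(ngene)) {
    y <- obs[i, ]
    if (sum(y) == 0) {
      res$status[i] <- "low_count"
      next
    }
    fit <- fit_nb_glm(y, X, offset = offset, alpha = dispersions[i])
    w <- wald_contrast(fit, contrast)
    if (w$status != "tested") {
      res$status[i] <- w$status
      next
    }
    res$log2fc[i] <- w$log2fc; res$se[i] <- w$se
    res$wald[i] <- w$wald; res$p[i] <- w$p
  }
  res$padj <- bh_adjust(ifelse(res$status == "tested", res$p, NA_real_))
  attr(res, "alpha") <- alpha
  class(res) <- c("de_result", "data.frame")
  res
}

#' Genotype-by-origin interaction test
#'
#' Compares the parental expression ratio to the F1 allelic ratio. Each
#' parental sample contributes one observation (Geno = its morph,
#' Ori = parental, count = total reads); each F1 sample contributes two
#' (Geno = allele, Ori = F1, count = allele reads). A per-gene NB GLM with
#' design `~ Geno * Ori` is fitted; the reported estimate is
#' `log2(LL/PP ratio) - log2(F1 L/P allelic ratio)` — the trans component of
#' the expression divergence, zero for a purely cis-driven gene.
#'
#' @param counts gene x sample count matrix (parental totals).
#' @param samples sample table covering parental and F1 samples.
#' @param sf size factors for `counts`.
#' @param allele allele count table for the F1 samples.
#' @param batch optional `batch_factor`; folded into the parental offsets
#'   (the Ori main effect absorbs any remaining between-batch level shift).
#' @param genes genes to test; default all genes in `allele`.
#' @param alpha significance level recorded with the result (default 0.10).
#' @return data.frame of class `de_result`: gene, log2fc (the interaction,
#'   log2), se, wald, p, padj, status.
#' @export
test_interaction <- function(counts, samples, sf, allele, batch = NULL,
                             genes = NULL, alpha = 0.10) {
  par <- samples[samples$group %in% c("PP", "LL"), , drop = FALSE]
  f1 <- samples[samples$group %in% F1_GROUPS, , drop = FALSE]
  if (!nrow(par)) stop("no parental (PP/LL) samples supplied")
  if (!nrow(f1)) stop("no F1 (PL/LP) samples supplied")
  am <- allele_matrices(allele, f1$sample_id, genes)
  genes <- rownames(am$P)
  counts <- as.matrix(counts)[genes, par$sample_id, drop = FALSE]

  eff <- effective_size_factors(sf[par$sample_id], batch)
  tot <- colSums(am$P + am$L)
  scale <- tot / exp(mean(log(pmax(tot, 1))))
  scale[scale <= 0] <- 1

  obs <- cbind(counts, am$P, am$L)
  ns <- ncol(am$P)
  geno <- c(ifelse(par$group == "PP", "P", "L"), rep(c("P", "L"), each = ns))
  ori <- c(rep("parental", nrow(par)), rep("F1", 2 * ns))
  offset <- c(log(eff), log(rep(scale, 2)))

  # parental totals carry the count-level NB dispersion; F1 allele
  # observations carry only allele-level (extra-binomial) dispersion
  disp_par <- estimate_dispersions(counts, par$group, norm_factors = eff)
  disp_all <- allele_dispersions(am$P, am$L, direction = f1$group)

  genoL <- as.numeric(geno == "L")
  oriF1 <- as.numeric(ori == "F1")
  X <- cbind(intercept = 1, genoL = genoL, oriF1 = oriF1,
             genoL_oriF1 = genoL * oriF1)
  # parental log-ratio minus allelic log-ratio = -(interaction coefficient)
  contrast <- c(0, 0, 0, -1)

  res <- data.frame(gene = genes, log2fc = NA_real_, se = NA_real_,
                    wald = NA_real_, p = NA_real_, status = "tested",
                    stringsAsFactors = FALSE, row.names = NULL)
  for (i in seq_along(genes)) {
    y <- obs[i, ]
    if (sum(y[ori == "F1"]) == 0 || sum(y[ori == "parental"]) == 0) {
      res$status[i] <- "low_count"
      next
    }
    alpha_obs <- c(rep(disp_par[i], nrow(par)), rep(disp_all[i], 2 * ns))
    fit <- fit_nb_glm(y, X, offset = offset, alpha = alpha_obs)
    w <- wald_contrast(fit, contrast)
    if (w$status != "tested") {
      res$status[i] <- w$status
      next
    }
    res$log2fc[i] <- w$log2fc; res$se[i] <- w$se
    res$wald[i] <- w$wald; res$p[i] <- w$p
  }
  res$padj <- bh_adjust(ifelse(res$status == "tested", res$p, NA_real_))
  attr(res, "alpha") <- alpha
  class(res) <- c("de_result", "data.frame")
  res
}

#' Assign the mode of regulatory change
#'
#' Combines three comparisons per gene — A: parental differential expression
#' (PP vs LL totals), B: F1 allelic imbalance, C: genotype-by-origin
#' interaction — into one category by their significance pattern:
#' \tabular{llll}{
#'   A \tab B \tab C \tab category \cr
#'   sig \tab sig \tab ns  \tab cis \cr
#'   sig \tab ns  \tab sig \tab trans \cr
#'   sig \tab sig \tab sig \tab cis_plus_trans (allelic and residual-trans
#'     components same sign) or cis_x_trans (opposite) \cr
#'   ns  \tab sig \tab sig \tab compensatory \cr
#'   ns  \tab ns  \tab any \tab conserved \cr
#'   other \tab \tab \tab ambiguous
#' }
#' The residual trans component is `A - B` on the log2 scale with both
#' oriented as L over P.
#'
#' @param parental a `de_call` for the parental contrast; if its recorded
#'   numerator group is PP the fold change is flipped so that positive
#'   values mean higher in LL.
#' @param allelic result of [test_allelic_imbalance()].
#' @param interaction result of [test_interaction()].
#' @param alpha significance level applied to B and C (default 0.10).
#' @return data.frame of class `regulatory_call`: gene, category, a_log2,
#'   a_sig, b_log2, b_padj, c_log2, c_padj. Genes lacking a tested B or C
#'   comparison are reported `unclassified`.
#' @export
classify_regulatory_mode <- function(parental, allelic, interaction,
                                     alpha = 0.10) {
  genes <- intersect(intersect(parental$gene, allelic$gene), interaction$gene)
  if (!length(genes)) stop("no genes shared by the three comparisons")
  pa <- parental[match(genes, parental$gene), ]
  b <- allelic[match(genes, allelic$gene), ]
  cc <- interaction[match(genes, interaction$gene), ]

  flip <- identical(attr(parental, "groupA"), "PP")
  a_log2 <- if (flip) -pa$log2fc else pa$log2fc
  a_sig <- pa$is_de
  b_sig <- !is.na(b$padj) & b$padj <= alpha
  c_sig <- !is.na(cc$padj) & cc$padj <= alpha
  untested <- b$status != "tested" | cc$status != "tested" | is.na(a_sig)

  trans_comp <- a_log2 - b$log2fc
  cat <- rep("ambiguous", length(genes))
  cat[a_sig & b_sig & !c_sig] <- "cis"
  cat[a_sig & !b_sig & c_sig] <- "trans"
  both <- a_sig & b_sig & c_sig
  cat[both & sign(b$log2fc) == sign(trans_comp)] <- "cis_plus_trans"
  cat[both & sign(b$log2fc) != sign(trans_comp)] <- "cis_x_trans"
  cat[!a_sig & b_sig & c_sig] <- "compensatory"
  cat[!a_sig & !b_sig] <- "conserved"
  cat[untested] <- "unclassified"

  out <- data.frame(gene = genes, category = cat,
                    a_log2 = a_log2, a_sig = a_sig,
                    b_log2 = b$log2fc, b_padj = b$padj,
                    c_log2 = cc$log2fc, c_padj = cc$padj,
                    stringsAsFactors = FALSE)
  class(out) <- c("regulatory_call", "data.frame")
  out
}
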