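#' Call differential expression from a contrast result
#'
#' A gene is differentially expressed when its BH-adjusted p-value is at or
#' below the contrast's significance level and the absolute fold change
#' exceeds `fold_threshold` (i.e. `|log2fc| > log2(fold_threshold)`).
#'
#' @param de a `de_result` from [run_contrast()].
#' @param alpha significance level; defaults to the level recorded with `de`.
#' @param fold_threshold minimum fold change (default 1.5).
#' @return data.frame of class `de_call`: gene, is_de, direction (the group
#'   expressed higher, or "none"), log2fc, padj, mean_A, mean_B.
#' @export
call_de <- function(de, alpha = NULL, fold_threshold = 1.5) {
  stopifnot(inherits(de, "de_result") || all(c("gene", "log2fc", "padj") %in% names(de)))
  if (is.null(alpha)) alpha <- attr(de, "alpha")
  if (is.null(alpha)) stop("alpha not supplied and not recorded on the result")
  ga <- attr(de, "groupA"); gb <- attr(de, "groupB")
  if (is.null(ga)) { ga <- "A"; gb <- "B" }
  is_de <- !is.na(de$padj) & de$padj <= alpha &
    abs(de$log2fc) > log2(fold_threshold)
  direction <- ifelse(!is_de, "none", ifelse(de$log2fc > 0, ga, gb))
  out <- data.frame(gene = de$gene, is_de = is_de, direction = direction,
                    log2fc = de$log2fc, padj = de$padj,
                    mean_A = de$mean_A, mean_B = de$mean_B,
                    stringsAsFactors = FALSE)
  attr(out, "groupA") <- ga
  attr(out, "groupB") <- gb
  attr(out, "alpha") <- alpha
  attr(out, "fold_threshold") <- fold_threshold
  class(out) <- c("de_call", "data.frame")
  out
}

#' Qualitative (exclusive) expression call
#'
#' A gene is exclusive to one group when the other group's mean normalized
#' count is below `low` while its own exceeds `high`.
#'
#' @param mean_a,mean_b mean normalized counts of the two groups.
#' @param low,high thresholds (defaults 10 and 150).
#' @return character vector: "A_only", "B_only" or "none".
#' @export
#' @examples
#' call_exclusive(c(5, 5, 0), c(200, 100, 151))  # B_only, none, B_only
call_exclusive <- function(mean_a, mean_b, low = 10, high = 150) {
  ifelse(mean_b < low & mean_a > high, "A_only",
         ifelse(mean_a < low & mean_b > high, "B_only", "none"))
}

# internal: pull the is_de flags and fold-change signs of the six contrasts
# into plain matrices aligned on gene order
de_flag_table <- function(calls) {
  need <- c("PP_LL", "PL_PP", "PL_LL", "LP_PP", "LP_LL", "PL_LP")
  missing <- setdiff(need, names(calls))
  if (length(missing)) {
    stop("missing contrast call tables: ", paste(missing, collapse = ", "))
  }
  gene <- calls[[1]]$gene
  for (nm in need) {
    if (!identical(calls[[nm]]$gene, gene)) {
      stop("contrast tables must cover the same genes in the same order")
    }
  }
  list(gene = gene,
       de = vapply(need, function(nm) calls[[nm]]$is_de, logical(length(gene))),
       up = vapply(need, function(nm) calls[[nm]]$log2fc > 0, logical(length(gene))))
}

#' Classify the mode of inheritance of every gene
#'
#' Applies the decision list, in order, to the six pairwise contrasts:
#' \enumerate{
#'   \item \strong{uninformative}: mean normalized count below `low_count` in
#'     both F1 groups (insufficiently sequenced in F1 samples);
#'   \item \strong{parent_of_origin}: PL:LP differentially expressed;
#'   \item \strong{conserved}: no remaining contrast differentially expressed;
#'   \item \strong{dominant_P}: PP:LL DE, neither F1 differs from PP, both
#'     differ from LL (expressed at the PP level); \strong{dominant_L}
#'     mirrored;
#'   \item \strong{additive}: both F1 groups differ from both parents with F1
#'     means strictly between the parental means (intermediate expression);
#'   \item \strong{overdominant} / \strong{underdominant}: both F1 groups
#'     differ from both parents in the same outward direction (above /
#'     below both);
#'   \item \strong{ambiguous}: any other pattern.
#' }
#' Steps 2-7 are mutually exclusive by construction, so every gene receives
#' exactly one mode.
#'
#' @param calls named list of `de_call` tables for contrasts `PP_LL`,
#'   `PL_PP`, `PL_LL`, `LP_PP`, `LP_LL`, `PL_LP` (see [run_all_contrasts()]
#'   and [call_de()]), all covering the same genes in the same order.
#' @param group_means gene x group matrix of mean normalized counts with
#'   columns PP, LL, PL, LP (as in `nb_fit_groups()$group_means`).
#' @param low_count F1 informativeness threshold on normalized means.
#' @return data.frame of class `inheritance_call`: gene, mode.
#' @export
classify_inheritance <- function(calls, group_means, low_count = 10) {
  ft <- de_flag_table(calls)
  gene <- ft$gene
  de <- ft$de; up <- ft$up
  gm <- group_means[gene, , drop = FALSE]

  uninformative <- gm[, "PL"] < low_count & gm[, "LP"] < low_count
  poe <- de[, "PL_LP"]
  any_de5 <- de[, "PP_LL"] | de[, "PL_PP"] | de[, "PL_LL"] |
    de[, "LP_PP"] | de[, "LP_LL"]
  dom_P <- de[, "PP_LL"] & !de[, "PL_PP"] & !de[, "LP_PP"] &
    de[, "PL_LL"] & de[, "LP_LL"]
  dom_L <- de[, "PP_LL"] & !de[, "PL_LL"] & !de[, "LP_LL"] &
    de[, "PL_PP"] & de[, "LP_PP"]
  all4 <- de[, "PL_PP"] & de[, "PL_LL"] & de[, "LP_PP"] & de[, "LP_LL"]
  lo <- pmin(gm[, "PP"], gm[, "LL"]); hi <- pmax(gm[, "PP"], gm[, "LL"])
  between <- gm[, "PL"] > lo & gm[, "PL"] < hi & gm[, "LP"] > lo & gm[, "LP"] < hi
  additive <- de[, "PP_LL"] & all4 & between
  over <- all4 & up[, "PL_PP"] & up[, "PL_LL"] & up[, "LP_PP"] & up[, "LP_LL"]
  under <- all4 & !up[, "PL_PP"] & !up[, "PL_LL"] & !up[, "LP_PP"] & !up[, "LP_LL"]

  mode <- rep("ambiguous", length(gene))
  mode[under] <- "underdominant"
  mode[over] <- "overdominant"
  mode[additive] <- "additive"
  mode[dom_L] <- "dominant_L"
  mode[dom_P] <- "dominant_P"
  mode[!any_de5] <- "conserved"
  mode[poe] <- "parent_of_origin"
  mode[uninformative] <- "uninformative"

  out <- data.frame(gene = gene, mode = mode, stringsAsFactors = FALSE)
  class(out) <- c("inheritance_call", "data.frame")
  out
}

#' Classify parent-of-origin effect direction
#'
#' For genes differentially expressed between the reciprocal F1s, each cross
#' direction is classified against the parentals independently. A gene is
#' \strong{maternal} when it looks P-dominant in PL eggs but not in LP eggs,
#' or L-dominant in LP eggs but not in PL eggs (each F1 matches its mother's
#' morph); \strong{paternal} is the mirror image. Genes matching neither or
#' both patterns stay unclassified.
#'
#' @param calls the same contrast call list used by [classify_inheritance()].
#' @param genes optional subset of gene ids to classify (typically the
#'   parent_of_origin genes); default: genes with PL:LP DE.
#' @return data.frame of class `poe_call`: gene, call_PL, call_LP
#'   ("P_dominant" / "L_dominant" / "other") and effect
#'   ("maternal" / "paternal" / "unclassified").
#' @export
classify_parent_of_origin <- function(calls, genes = NULL) {
  ft <- de_flag_table(calls)
  de <- ft$de
  if (is.null(genes)) genes <- ft$gene[de[, "PL_LP"]]
  idx <- match(genes, ft$gene)
  if (anyNA(idx)) stop("genes absent from the contrast tables")

  p_in_PL <- !de[idx, "PL_PP"] & de[idx, "PL_LL"]
  l_in_PL <- de[idx, "PL_PP"] & !de[idx, "PL_LL"]
  p_in_LP <- !de[idx, "LP_PP"] & de[idx, "LP_LL"]
  l_in_LP <- de[idx, "LP_PP"] & !de[idx, "LP_LL"]

  maternal <- (p_in_PL & !p_in_LP) | (l_in_LP & !l_in_PL)
  paternal <- (l_in_PL & !l_in_LP) | (p_in_LP & !p_in_PL)
  effect <- ifelse(maternal & !paternal, "maternal",
                   ifelse(paternal & !maternal, "paternal", "unclassified"))

  lab <- function(p, l) ifelse(p, "P_dominant", ifelse(l, "L_dominant", "other"))
  out <- data.frame(gene = genes,
                    call_PL = lab(p_in_PL, l_in_PL),
                    call_LP = lab(p_in_LP, l_in_LP),
                    effect = effect, stringsAsFactors = FALSE)
  class(out) <- c("poe_call", "data.frame")
  out
}

#' Detect preferential expression of one parent's allele
#'
#' Tests allelic imbalance separately in each F1 cross direction and flags
#' genes where the favored allele switches with the cross while total
#' expression does not differ between PL and LP: \strong{maternal}
#' preference favors the P allele in PL eggs and the L allele in LP eggs;
#' \strong{paternal} preference is the mirror image.
#'
#' @param allele allele count table (gene, sample_id, reads_P, reads_L,
#'   reads_unassigned).
#' @param samples sample table.
#' @param total_de `de_call` for the PL:LP total-count contrast.
#' @param genes genes to test (typically [filter_informative()] output).
#' @param alpha significance level for the per-direction imbalance tests.
#' @return data.frame: gene, log2_ratio_PL, padj_PL, log2_ratio_LP, padj_LP,
#'   preference ("maternal" / "paternal" / "none").
#' @export
detect_allele_preference <- function(allele, samples, total_de, genes = NULL,
                                     alpha = 0.10) {
  per_dir <- lapply(c("PL", "LP"), function(g) {
    smp <- samples[samples$group == g, , drop = FALSE]
    test_allelic_imbalance(allele, smp, genes = genes, alpha = alpha)
  })
  names(per_dir) <- c("PL", "LP")
  common <- intersect(per_dir$PL$gene, per_dir$LP$gene)
  if (!length(common)) {
    return(data.frame(gene = character(0), log2_ratio_PL = numeric(0),
                      padj_PL = numeric(0), log2_ratio_LP = numeric(0),
                      padj_LP = numeric(0), preference = character(0),
                      stringsAsFactors = FALSE))
  }
  a <- per_dir$PL[match(common, per_dir$PL$gene), ]
  b <- per_dir$LP[match(common, per_dir$LP$gene), ]
  no_total_de <- !total_de$is_de[match(common, total_de$gene)]
  no_total_de[is.na(no_total_de)] <- FALSE

  sig_a <- !is.na(a$padj) & a$padj <= alpha
  sig_b <- !is.na(b$padj) & b$padj <= alpha
  # log2 ratio is L over P: maternal preference = P favored in PL (< 0)
  # and L favored in LP (> 0)
  maternal <- sig_a & sig_b & a$log2fc < 0 & b$log2fc > 0 & no_total_de
  paternal <- sig_a & sig_b & a$log2fc > 0 & b$log2fc < 0 & no_total_de
  data.frame(gene = common,
             log2_ratio_PL = a$log2fc, padj_PL = a$padj,
             log2_ratio_LP = b$log2fc, padj_LP = b$padj,
             preference = ifelse(maternal, "maternal",
                                 ifelse(paternal, "paternal", "none")),
             stringsAsFactors = FALSE)
}
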