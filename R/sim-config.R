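#' Configuration for a simulated reciprocal-cross oocyte experiment
#'
#' Builds and validates the configuration of the synthetic-data generator.
#' The defaults emulate the study geometry the package targets: pooled-oocyte
#' RNA-seq libraries from 7 PP and 7 LL mothers plus 5 PL and 5 LP reciprocal
#' F1 mothers, sequenced in two batches (parentals vs F1s), with SNP-limited
#' allele assignability averaging 21.6\% of F1 reads.
#'
#' Each gene belongs to one true architecture class. Classes control the
#' cis (`c`), trans (`t`), dominance (`w`) and parent-of-origin parameters of
#' the generative model (see [expected_group_means()]):
#' \describe{
#'   \item{conserved}{`c = t = 0`, `w = 0.5`: identical expectation everywhere.}
#'   \item{cis / trans / cis_plus_trans / cis_x_trans}{regulatory divergence
#'     with additive inheritance (`w = 0.5`).}
#'   \item{compensatory}{`t = -c`: parents equal, F1 alleles imbalanced.}
#'   \item{dominant_P / dominant_L}{trans divergence with the F1 total pinned
#'     to one parent (`w = 0` or `1`).}
#'   \item{overdominant / underdominant}{F1 total outside the parental range.}
#'   \item{parent_of_origin}{the two F1 directions each track one parent
#'     (maternal or paternal orientation, drawn equally).}
#'   \item{preferential}{no total-count effect, but the maternal (or paternal)
#'     allele is preferentially expressed in both F1 directions.}
#' }
#'
#' @param n_genes number of genes to simulate.
#' @param reps named integer vector of replicate counts for PP, LL, PL, LP.
#' @param baseline_log2_mean location/scale of the per-gene normal draw of the
#'   log2 baseline expression `log2(mu)`.
#' @param dispersion_log_mean,dispersion_log_sd meanlog/sdlog of the log-normal
#'   draw of the per-gene NB dispersion `alpha` (variance = mean + alpha mean^2).
#' @param class_proportions named numeric vector over the architecture classes;
#'   must sum to 1.
#' @param effect_size_log2 length-2 range of absolute effect magnitudes (log2
#'   units) for cis/trans/dominance architectures.
#' @param poe_log2 absolute log2 difference between the two F1 directions for
#'   parent-of-origin genes.
#' @param pref_log2 absolute log2 shift of the allelic ratio (per direction)
#'   for preferential-allele genes.
#' @param library_size_range range of the uniform per-sample library scaling.
#' @param batch_log2_offset global log2 shift applied to every gene of the F1
#'   sequencing batch (the simulated batch effect).
#' @param n_housekeeping number of designated control genes, always drawn from
#'   the conserved class.
#' @param assignability_mean target mean of the per-gene allele-assignable
#'   read fraction `pi` in F1 samples.
#' @param assignability_shape1 first shape parameter of the Beta distribution
#'   of `pi`; the second is derived so the mean equals `assignability_mean`.
#' @param seed integer seed used by [simulate_experiment()].
#'
#' @return An object of class `sim_config` (a validated list).
#' @seealso [simulate_experiment()], [simulate_truth()]
#' @export
#' @examples
#' cfg <- sim_config(n_genes = 500, seed = 1)
#' cfg$reps
sim_config <- function(n_genes = 2000,
                       reps = c(PP = 7, LL = 7, PL = 5, LP = 5),
                       baseline_log2_mean = c(location = 7, scale = 1.5),
                       dispersion_log_mean = log(0.05),
                       dispersion_log_sd = 0.5,
                       class_proportions = c(conserved = 0.40,
                                             cis = 0.08,
                                             trans = 0.08,
                                             cis_plus_trans = 0.04,
                                             cis_x_trans = 0.04,
                                             compensatory = 0.06,
                                             dominant_P = 0.08,
                                             dominant_L = 0.08,
                                             overdominant = 0.05,
                                             underdominant = 0.05,
                                             parent_of_origin = 0.04,
                                             preferential = 0.00),
                       effect_size_log2 = c(1.5, 3),
                       poe_log2 = 1,
                       pref_log2 = 2,
                       library_size_range = c(0.7, 1.3),
                       batch_log2_offset = 1,
                       n_housekeeping = 50,
                       assignability_mean = 0.216,
                       assignability_shape1 = 2,
                       seed = NULL) {
  cfg <- list(n_genes = as.integer(n_genes),
              reps = reps,
              baseline_log2_mean = baseline_log2_mean,
              dispersion_log_mean = dispersion_log_mean,
              dispersion_log_sd = dispersion_log_sd,
              class_proportions = class_proportions,
              effect_size_log2 = effect_size_log2,
              poe_log2 = poe_log2,
              pref_log2 = pref_log2,
              library_size_range = library_size_range,
              batch_log2_offset = batch_log2_offset,
              n_housekeeping = as.integer(n_housekeeping),
              assignability_mean = assignability_mean,
              assignability_shape1 = assignability_shape1,
              seed = if (is.null(seed)) NULL else as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

SIM_CLASSES <- c("conserved", "cis", "trans", "cis_plus_trans", "cis_x_trans",
                 "compensatory", "dominant_P", "dominant_L", "overdominant",
                 "underdominant", "parent_of_origin", "preferential")

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_genes < 1) stop("n_genes must be positive")
  if (!all(EGG_GROUPS %in% names(cfg$reps))) {
    stop("reps must name all of ", paste(EGG_GROUPS, collapse = ", "))
  }
  if (any(cfg$reps < 0)) stop("replicate counts must be non-negative")
  cp <- cfg$class_proportions
  unknown <- setdiff(names(cp), SIM_CLASSES)
  if (length(unknown)) {
    stop("unknown architecture classes: ", paste(unknown, collapse = ", "))
  }
  if (any(cp < 0)) stop("class proportions must be non-negative")
  if (abs(sum(cp) - 1) > 1e-9) {
    stop("class_proportions must sum to 1 (got ", format(sum(cp)), ")")
  }
  alloc <- allocate_classes(cfg$n_genes, cp)
  if (any(cp > 0 & alloc == 0)) {
    stop("class proportions cannot be realized with n_genes = ", cfg$n_genes,
         ": classes ",
         paste(names(cp)[cp > 0 & alloc == 0], collapse = ", "),
         " would receive no genes")
  }
  if (cfg$n_housekeeping >= cfg$n_genes) {
    stop("n_housekeeping must be smaller than n_genes")
  }
  n_cons <- alloc[match("conserved", names(cp))]
  if (is.na(n_cons)) n_cons <- 0
  if (cfg$n_housekeeping > n_cons) {
    stop("n_housekeeping (", cfg$n_housekeeping, ") exceeds the number of ",
         "conserved genes (", n_cons, "); housekeeping genes must be ",
         "zero-effect genes")
  }
  if (cfg$assignability_mean <= 0 || cfg$assignability_mean > 1) {
    stop("assignability_mean must lie in (0, 1]")
  }
  if (length(cfg$library_size_range) != 2 ||
      any(cfg$library_size_range <= 0) ||
      diff(cfg$library_size_range) < 0) {
    stop("library_size_range must be an increasing positive pair")
  }
  if (length(cfg$effect_size_log2) != 2 || any(cfg$effect_size_log2 <= 0) ||
      diff(cfg$effect_size_log2) < 0) {
    stop("effect_size_log2 must be an increasing positive pair")
  }
  invisible(cfg)
}

# largest-remainder allocation of n genes over class proportions
allocate_classes <- function(n, props) {
  raw <- props * n
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    ord <- order(raw - base, decreasing = TRUE)
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  stats::setNames(as.integer(base), names(props))
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Reciprocal-cross simulation config\n")
  cat("  genes:", x$n_genes, " (", x$n_housekeeping, "housekeeping )\n")
  cat("  replicates:", paste(names(x$reps), x$reps, sep = "=", collapse = " "), "\n")
  cat("  batch log2 offset (F1 batch):", x$batch_log2_offset, "\n")
  cat("  mean allele assignability:", x$assignability_mean, "\n")
  nz <- x$class_proportions[x$class_proportions > 0]
  cat("  classes:", paste(names(nz), format(nz), sep = "=", collapse = " "), "\n")
  invisible(x)
}
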