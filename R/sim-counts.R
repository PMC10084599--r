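#' Simulate the raw count matrix and sample table
#'
#' Emits `count ~ NB(mean, dispersion)` with
#' `mean = s_j * 2^(batch offset if F1 batch) * group mean`, where the group
#' mean comes from [expected_group_means()], `s_j` is a per-sample library
#' scaling drawn uniformly from `library_size_range`, and the batch offset is
#' a global log2 shift applied to every gene (housekeeping genes included) of
#' the F1 sequencing batch. The NB dispersion is the per-gene `alpha` of the
#' truth table (variance = mean + alpha * mean^2); `alpha` below 1e-10 is
#' emitted as Poisson.
#'
#' @param truth a `truth_table` from [simulate_truth()].
#' @param config the [sim_config()] used to generate `truth`.
#' @return list with `counts` (integer gene x sample matrix), `samples`
#'   (data.frame: sample_id, group, batch, replicate) and `lib_size` (the
#'   drawn scalings, for reference).
#' @export
simulate_counts <- function(truth, config) {
  validate_sim_config(config)
  stopifnot(nrow(truth) == config$n_genes)
  reps <- config$reps[EGG_GROUPS]
  groups <- rep(EGG_GROUPS, times = reps)
  if (length(groups) == 0L) stop("no samples requested in reps")
  sample_id <- unlist(lapply(EGG_GROUPS, function(g) {
    if (reps[[g]] == 0L) character(0) else paste0(g, "_", seq_len(reps[[g]]))
  }))
  batch <- ifelse(groups %in% F1_GROUPS, "b2_F1", "b1_parental")
  samples <- data.frame(sample_id = sample_id, group = groups, batch = batch,
                        replicate = unlist(lapply(reps, seq_len), use.names = FALSE),
                        stringsAsFactors = FALSE)

  em <- expected_group_means(truth)
  base <- as.matrix(em[, c("PP", "LL", "PL", "LP")])[, groups, drop = FALSE]
  s <- runif(nrow(samples), config$library_size_range[1], config$library_size_range[2])
  bfac <- ifelse(batch == "b2_F1", 2 ^ config$batch_log2_offset, 1)
  mean_mat <- sweep(base, 2, s * bfac, "*")

  n <- length(mean_mat)
  size <- rep(1 / pmax(truth$alpha, 1e-12), times = ncol(mean_mat))
  pois <- rep(truth$alpha < 1e-10, times = ncol(mean_mat))
  draws <- numeric(n)
  mu_vec <- as.vector(mean_mat)
  if (any(pois)) draws[pois] <- rpois(sum(pois), mu_vec[pois])
  if (any(!pois)) draws[!pois] <- rnbinom(sum(!pois), mu = mu_vec[!pois], size = size[!pois])
  counts <- matrix(as.integer(draws), nrow = nrow(truth),
                   dimnames = list(truth$gene, samples$sample_id))
  list(counts = counts, samples = samples, lib_size = stats::setNames(s, sample_id))
}

#' Simulate allele-assigned read counts for the F1 samples
#'
#' Binomial thinning of the simulated totals: for each (gene, F1 sample) cell
#' the number of allele-assignable reads is `Binomial(total, pi_g)` and, of
#' those, the L-allele reads are `Binomial(assigned, f_L)` with the expected
#' L fraction of that cross direction (see [expected_group_means()]). The sum
#' `reads_P + reads_L + reads_unassigned` reproduces the count-matrix entry
#' exactly.
#'
#' @param truth the `truth_table`.
#' @param counts,samples output of [simulate_counts()].
#' @return data.frame: gene, sample_id, reads_P, reads_L, reads_unassigned.
#' @export
simulate_allele_counts <- function(truth, counts, samples) {
  f1 <- samples[samples$group %in% F1_GROUPS, , drop = FALSE]
  if (nrow(f1) == 0L) stop("no F1 (PL/LP) samples in the sample table")
  em <- expected_group_means(truth)
  ng <- nrow(truth)

  out <- vector("list", nrow(f1))
  for (j in seq_len(nrow(f1))) {
    tot <- counts[, f1$sample_id[j]]
    assigned <- rbinom(ng, size = tot, prob = truth$pi)
    fL <- if (f1$group[j] == "PL") em$f_L_PL else em$f_L_LP
    reads_L <- rbinom(ng, size = assigned, prob = fL)
    out[[j]] <- data.frame(gene = truth$gene,
                           sample_id = f1$sample_id[j],
                           reads_P = assigned - reads_L,
                           reads_L = reads_L,
                           reads_unassigned = tot - assigned,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  res <- res[order(res$gene, res$sample_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Simulate a complete reciprocal-cross experiment
#'
#' Seeds the RNG from `config$seed` (when set) and runs [simulate_truth()],
#' [simulate_counts()] and [simulate_allele_counts()] in sequence, so a given
#' config + seed always yields byte-identical outputs.
#'
#' @param config a [sim_config()].
#' @return list of class `eggcross_sim`: `truth`, `counts`, `samples`,
#'   `allele`, `housekeeping` (ids), `config`.
#' @export
#' @examples
#' sim <- simulate_experiment(sim_config(n_genes = 200, seed = 7))
#' dim(sim$counts)
simulate_experiment <- function(config) {
  validate_sim_config(config)
  if (!is.null(config$seed)) set.seed(config$seed)
  truth <- simulate_truth(config)
  cs <- simulate_counts(truth, config)
  allele <- if (any(cs$samples$group %in% F1_GROUPS)) {
    simulate_allele_counts(truth, cs$counts, cs$samples)
  } else NULL
  out <- list(truth = truth, counts = cs$counts, samples = cs$samples,
              allele = allele,
              housekeeping = truth$gene[truth$is_housekeeping],
              config = config)
  class(out) <- "eggcross_sim"
  out
}

#' @export
print.eggcross_sim <- function(x, ...) {
  cat("Simulated reciprocal-cross experiment:",
      nrow(x$counts), "genes x", ncol(x$counts), "samples\n")
  cat("  groups:", paste(names(table(x$samples$group)),
                         table(x$samples$group), sep = "=", collapse = " "), "\n")
  cat("  housekeeping genes:", length(x$housekeeping), "\n")
  invisible(x)
}
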