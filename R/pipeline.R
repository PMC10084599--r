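#' Pipeline run configuration
#'
#' Collects every threshold the pipeline applies, the input paths (or an
#' inline simulation config), and the output directory. Thresholds default
#' to the study's printed values: parental FDR 0.05, F1 FDR 0.10, 1.5-fold
#' change, exclusive-expression bounds 10/150, informative-read bounds
#' 20\% / 10 reads.
#'
#' @param simulate optional [sim_config()]; when set the pipeline simulates
#'   its input instead of reading files.
#' @param counts,samples,allele,housekeeping input file paths (ignored when
#'   `simulate` is given).
#' @param alpha_parental,alpha_f1 FDR levels for parental / F1 contrasts.
#' @param fold_threshold minimum fold change for a DE call.
#' @param exclusive_low,exclusive_high exclusive-expression thresholds on
#'   mean normalized counts.
#' @param informative_frac,informative_reads allele-assignment filter.
#' @param batch_method how the housekeeping batch factor enters the models.
#' @param outdir optional output directory for result tables.
#' @param seed integer seed for a simulated run.
#' @return list of class `run_config`.
#' @export
run_config <- function(simulate = NULL, counts = NULL, samples = NULL,
                       allele = NULL, housekeeping = NULL,
                       alpha_parental = 0.05, alpha_f1 = 0.10,
                       fold_threshold = 1.5,
                       exclusive_low = 10, exclusive_high = 150,
                       informative_frac = 0.20, informative_reads = 10,
                       batch_method = c("offset", "covariate"),
                       outdir = NULL, seed = NULL) {
  batch_method <- match.arg(batch_method)
  cfg <- list(simulate = simulate, counts = counts, samples = samples,
              allele = allele, housekeeping = housekeeping,
              alpha_parental = alpha_parental, alpha_f1 = alpha_f1,
              fold_threshold = fold_threshold,
              exclusive_low = exclusive_low, exclusive_high = exclusive_high,
              informative_frac = informative_frac,
              informative_reads = informative_reads,
              batch_method = batch_method,
              outdir = outdir, seed = if (is.null(seed)) NULL else as.integer(seed))
  stopifnot(cfg$alpha_parental > 0, cfg$alpha_parental < 1,
            cfg$alpha_f1 > 0, cfg$alpha_f1 < 1,
            cfg$fold_threshold > 0, cfg$exclusive_low > 0,
            cfg$exclusive_high > 0, cfg$informative_frac >= 0,
            cfg$informative_reads > 0)
  if (is.null(simulate) && (is.null(counts) || is.null(samples))) {
    stop("either a simulation config or counts + samples paths are required")
  }
  if (!is.null(simulate)) validate_sim_config(simulate)
  class(cfg) <- "run_config"
  cfg
}

#' Write / read a run configuration as YAML
#'
#' The round trip `read_run_config(write_run_config(cfg, f))` reproduces an
#' equivalent configuration.
#'
#' @param cfg a `run_config`.
#' @param path YAML file path.
#' @return `write_run_config`: `path` invisibly; `read_run_config`: a
#'   `run_config`.
#' @export
write_run_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  x <- unclass(cfg)
  if (!is.null(x$simulate)) {
    sim <- unclass(x$simulate)
    sim$reps <- as.list(sim$reps)
    sim$baseline_log2_mean <- as.list(sim$baseline_log2_mean)
    sim$class_proportions <- as.list(sim$class_proportions)
    x$simulate <- sim
  }
  yaml::write_yaml(x[!vapply(x, is.null, logical(1))], path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  if (!is.null(x$simulate)) {
    sim <- x$simulate
    sim$reps <- unlist(sim$reps)
    sim$baseline_log2_mean <- unlist(sim$baseline_log2_mean)
    sim$class_proportions <- unlist(sim$class_proportions)
    x$simulate <- do.call(sim_config, sim)
  }
  do.call(run_config, x)
}

#' PCA report of the samples
#'
#' Principal components of the samples on log2(normalized + 1) expression,
#' centered per gene. Used for reporting group separation.
#'
#' @param norm_mat gene x sample matrix of normalized counts.
#' @param samples sample table.
#' @param n_components number of components to return (default 2).
#' @return list: `coordinates` (samples x components, with group labels),
#'   `variance_fraction` per returned component.
#' @export
pca_report <- function(norm_mat, samples, n_components = 2) {
  if (ncol(norm_mat) < 3) stop("PCA report needs at least 3 samples")
  if (n_components >= ncol(norm_mat)) {
    stop("fewer samples than requested components")
  }
  pc <- prcomp(t(log2(as.matrix(norm_mat) + 1)), center = TRUE, scale. = FALSE)
  k <- seq_len(n_components)
  coords <- data.frame(sample_id = colnames(norm_mat),
                       group = samples$group[match(colnames(norm_mat),
                                                   samples$sample_id)],
                       pc$x[, k, drop = FALSE],
                       stringsAsFactors = FALSE, row.names = NULL)
  vf <- pc$sdev^2 / sum(pc$sdev^2)
  list(coordinates = coords, variance_fraction = vf[k])
}

#' Score classifier calls against simulated truth
#'
#' @param calls data.frame with `gene` and a call column (second column or
#'   `call_column`).
#' @param truth the `truth_table`, or any data.frame with `gene` and a truth
#'   column (`truth_column`).
#' @param call_column,truth_column column names holding the labels.
#' @return list: `confusion` (truth x called table), `recall` and
#'   `precision` per true class, `accuracy`.
#' @export
score_against_truth <- function(calls, truth,
                                call_column = names(calls)[2],
                                truth_column = "true_inheritance") {
  idx <- match(calls$gene, truth$gene)
  if (anyNA(idx)) stop("called genes absent from the truth table")
  tl <- truth[[truth_column]][idx]
  cl <- calls[[call_column]]
  confusion <- table(truth = tl, called = cl)
  classes <- rownames(confusion)
  recall <- vapply(classes, function(k) {
    n <- sum(confusion[k, ])
    if (n == 0) NA_real_ else {
      hit <- if (k %in% colnames(confusion)) confusion[k, k] else 0
      hit / n
    }
  }, numeric(1))
  precision <- vapply(classes, function(k) {
    if (!k %in% colnames(confusion)) return(NA_real_)
    n <- sum(confusion[, k])
    if (n == 0) NA_real_ else confusion[k, k] / n
  }, numeric(1))
  accuracy <- sum(tl == cl) / length(cl)
  list(confusion = confusion, recall = recall, precision = precision,
       accuracy = accuracy)
}

#' Run the full reciprocal-cross analysis pipeline
#'
#' simulate (or load) -> size factors -> housekeeping batch factor -> NB
#' group model -> six contrasts -> DE / exclusive / inheritance /
#' parent-of-origin / preferential-allele calls -> informative-gene filter ->
#' allelic, interaction tests -> regulatory modes -> PCA -> tallies (and,
#' for simulated runs, confusion matrices against truth). Deterministic for
#' a given config and seed. When `cfg$outdir` is set every result table is
#' written there as TSV.
#'
#' @param cfg a [run_config()].
#' @return list of class `eggcross_run` with the fitted objects, per-stage
#'   call tables, and a `summary` of tallies.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  if (!is.null(cfg$simulate)) {
    sim_cfg <- cfg$simulate
    if (!is.null(cfg$seed)) sim_cfg$seed <- cfg$seed
    sim <- simulate_experiment(sim_cfg)
    counts <- sim$counts; samples <- sim$samples
    allele <- sim$allele; housekeeping <- sim$housekeeping
    truth <- sim$truth
  } else {
    counts <- read_counts(cfg$counts)
    samples <- read_samples(cfg$samples)
    allele <- if (!is.null(cfg$allele)) read_allele_counts(cfg$allele) else NULL
    housekeeping <- if (!is.null(cfg$housekeeping)) {
      read_housekeeping(cfg$housekeeping)
    } else character(0)
    truth <- NULL
  }

  sf <- estimate_size_factors(counts)
  batch <- if (length(housekeeping) >= 2) {
    estimate_batch_factor(counts, sf, housekeeping)
  } else NULL

  fit <- nb_fit_groups(counts, samples, sf = sf, batch = batch,
                       batch_method = cfg$batch_method)
  contrasts <- run_all_contrasts(fit, alpha_parental = cfg$alpha_parental,
                                 alpha_f1 = cfg$alpha_f1)
  calls <- lapply(contrasts, call_de, fold_threshold = cfg$fold_threshold)

  exclusive <- call_exclusive(fit$group_means[, "PP"], fit$group_means[, "LL"],
                              low = cfg$exclusive_low, high = cfg$exclusive_high)
  exclusive <- data.frame(gene = rownames(fit$group_means),
                          exclusive = ifelse(exclusive == "A_only", "PP_only",
                                             ifelse(exclusive == "B_only",
                                                    "LL_only", "none")),
                          stringsAsFactors = FALSE)

  inheritance <- classify_inheritance(calls, fit$group_means,
                                      low_count = cfg$exclusive_low)
  poe <- classify_parent_of_origin(calls)

  informative <- character(0)
  allelic <- interaction <- regulatory <- preference <- NULL
  if (!is.null(allele)) {
    informative <- filter_informative(allele, min_frac = cfg$informative_frac,
                                      min_reads = cfg$informative_reads)
    if (length(informative)) {
      allelic <- test_allelic_imbalance(allele, samples, genes = informative,
                                        alpha = cfg$alpha_f1)
      interaction <- test_interaction(counts, samples, sf, allele,
                                      batch = batch, genes = informative,
                                      alpha = cfg$alpha_f1)
      regulatory <- classify_regulatory_mode(calls$PP_LL, allelic, interaction,
                                             alpha = cfg$alpha_f1)
      preference <- detect_allele_preference(allele, samples, calls$PL_LP,
                                             genes = informative,
                                             alpha = cfg$alpha_f1)
    }
  }

  norm <- normalize_counts(counts, fit$eff_sf)
  pca <- pca_report(norm, samples)

  summary <- list(
    n_genes = nrow(counts),
    n_samples = ncol(counts),
    n_de_parental = sum(calls$PP_LL$is_de),
    n_exclusive = table(exclusive$exclusive),
    inheritance_tally = table(factor(inheritance$mode,
                                     levels = INHERITANCE_MODES)),
    n_poe = nrow(poe),
    poe_tally = if (nrow(poe)) table(poe$effect) else table(character(0)),
    n_informative = length(informative),
    regulatory_tally = if (!is.null(regulatory)) {
      table(factor(regulatory$category,
                   levels = c(REGULATORY_MODES, "unclassified")))
    } else NULL,
    n_preference = if (!is.null(preference)) {
      sum(preference$preference != "none")
    } else NA_integer_,
    pca_variance = pca$variance_fraction)

  scores <- NULL
  if (!is.null(truth)) {
    scores <- list(
      inheritance = score_against_truth(inheritance, truth,
                                        call_column = "mode",
                                        truth_column = "true_inheritance"),
      regulatory = if (!is.null(regulatory)) {
        score_against_truth(regulatory, truth, call_column = "category",
                            truth_column = "true_regulatory")
      } else NULL)
  }

  run <- list(config = cfg, counts = counts, samples = samples,
              allele = allele, truth = truth, sf = sf, batch = batch, fit = fit,
              contrasts = contrasts, calls = calls, exclusive = exclusive,
              inheritance = inheritance, poe = poe,
              informative = informative, allelic = allelic,
              interaction = interaction, regulatory = regulatory,
              preference = preference, pca = pca,
              summary = summary, scores = scores)
  class(run) <- "eggcross_run"

  if (!is.null(cfg$outdir)) write_run(run, cfg$outdir)
  run
}

write_run <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(x, f) write.table(x, file.path(dir, f), sep = "\t",
                                   quote = FALSE, row.names = FALSE)
  wt(data.frame(sample_id = names(run$sf), size_factor = run$sf), "size_factors.tsv")
  if (!is.null(run$batch)) {
    wt(data.frame(sample_id = names(run$batch$w1), w1 = run$batch$w1,
                  gamma_log2 = run$batch$gamma), "w1.tsv")
  }
  for (nm in names(run$contrasts)) wt(run$contrasts[[nm]], paste0("de_", nm, ".tsv"))
  wt(run$inheritance, "inheritance.tsv")
  wt(run$poe, "poe.tsv")
  wt(run$exclusive, "exclusive.tsv")
  if (!is.null(run$regulatory)) wt(run$regulatory, "regmode.tsv")
  if (!is.null(run$preference)) wt(run$preference, "allele_preference.tsv")
  wt(run$pca$coordinates, "pca.tsv")
  invisible(dir)
}

#' @export
print.eggcross_run <- function(x, ...) {
  s <- x$summary
  cat("Reciprocal-cross pipeline run:", s$n_genes, "genes,",
      s$n_samples, "samples\n")
  cat("  DE between PP and LL:", s$n_de_parental, "\n")
  cat("  inheritance modes:\n")
  print(s$inheritance_tally)
  cat("  PL:LP differential genes:", s$n_poe, "\n")
  if (!is.null(s$regulatory_tally)) {
    cat("  informative for allele analysis:", s$n_informative, "\n")
    cat("  regulatory modes:\n")
    print(s$regulatory_tally)
  }
  if (!is.null(x$scores)) {
    cat("  inheritance label accuracy vs truth:",
        format(x$scores$inheritance$accuracy, digits = 3), "\n")
  }
  invisible(x)
}
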