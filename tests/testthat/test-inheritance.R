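test_that("DE calls require both the FDR and the fold-change criterion", {
  de <- data.frame(gene = paste0("g", 1:4),
                   mean_A = 100, mean_B = 100,
                   log2fc = c(1.0, 0.5, 2.0, -1.0),
                   se = 0.1, wald = 1, p = 0.01,
                   padj = c(0.01, 0.001, 0.2, 0.04),
                   status = "tested", stringsAsFactors = FALSE)
  attr(de, "groupA") <- "PP"; attr(de, "groupB") <- "LL"
  class(de) <- c("de_result", "data.frame")
  calls <- call_de(de, alpha = 0.05)
  # g1: both criteria met; g2 fails 1.5x (0.5 < log2 1.5); g3 fails FDR
  expect_equal(calls$is_de, c(TRUE, FALSE, FALSE, TRUE))
  expect_equal(calls$direction, c("PP", "none", "none", "LL"))
})

test_that("exclusive expression uses the 10/150 rule with strict bounds", {
  expect_equal(call_exclusive(5, 200), "B_only")
  expect_equal(call_exclusive(5, 100), "none")
  expect_equal(call_exclusive(0, 151), "B_only")
  expect_equal(call_exclusive(200, 5), "A_only")
  expect_equal(call_exclusive(10, 200), "none")   # not strictly below 10
  expect_equal(call_exclusive(5, 150), "none")    # not strictly above 150
})

test_that("the inheritance decision table labels canonical patterns", {
  genes <- c("cons", "domP", "domL", "addi", "over", "under", "poe", "ambi")
  F <- rep(FALSE, 8); names(F) <- genes
  de <- list(PP_LL = F, PL_PP = F, PL_LL = F, LP_PP = F, LP_LL = F, PL_LP = F)
  fc <- lapply(de, function(x) stats::setNames(rep(0, 8), genes))

  set_gene <- function(g, contrast, val) {
    de[[contrast]][g] <<- val != 0
    fc[[contrast]][g] <<- val
  }
  # P-dominant: PP:LL DE, F1s match PP, differ from LL
  set_gene("domP", "PP_LL", 2)
  set_gene("domP", "PL_LL", 2); set_gene("domP", "LP_LL", 2)
  # L-dominant mirrored
  set_gene("domL", "PP_LL", 2)
  set_gene("domL", "PL_PP", -2); set_gene("domL", "LP_PP", -2)
  # additive: F1s differ from both parents, means intermediate
  set_gene("addi", "PP_LL", 2)
  set_gene("addi", "PL_PP", -1); set_gene("addi", "PL_LL", 1)
  set_gene("addi", "LP_PP", -1); set_gene("addi", "LP_LL", 1)
  # overdominant: F1s above both parents
  set_gene("over", "PL_PP", 1); set_gene("over", "PL_LL", 1)
  set_gene("over", "LP_PP", 1); set_gene("over", "LP_LL", 1)
  # underdominant: below both parents
  set_gene("under", "PL_PP", -1); set_gene("under", "PL_LL", -1)
  set_gene("under", "LP_PP", -1); set_gene("under", "LP_LL", -1)
  # parent-of-origin: reciprocal F1s differ (takes precedence)
  set_gene("poe", "PL_LP", 2); set_gene("poe", "PP_LL", 2)
  # ambiguous: PP:LL DE but an inconsistent F1 pattern
  set_gene("ambi", "PP_LL", 2); set_gene("ambi", "PL_PP", -1)

  calls <- fake_call_set(genes, de, fc)
  gm <- cbind(PP = rep(200, 8), LL = rep(50, 8),
              PL = rep(100, 8), LP = rep(100, 8))
  rownames(gm) <- genes
  gm["over", ] <- c(100, 200, 400, 400)
  gm["under", ] <- c(100, 200, 50, 50)

  out <- classify_inheritance(calls, gm)
  expect_equal(out$mode[match(genes, out$gene)],
               c("conserved", "dominant_P", "dominant_L", "additive",
                 "overdominant", "underdominant", "parent_of_origin",
                 "ambiguous"))

  # uninformative takes precedence over everything
  gm["poe", c("PL", "LP")] <- c(4, 6)
  out2 <- classify_inheritance(calls, gm)
  expect_equal(out2$mode[out2$gene == "poe"], "uninformative")

  # additivity requires intermediate means
  gm2 <- gm; gm2["addi", "PL"] <- 300
  out3 <- classify_inheritance(calls, gm2)
  expect_equal(out3$mode[out3$gene == "addi"], "ambiguous")

  expect_error(classify_inheritance(calls[-1], gm), "missing contrast")
})

test_that("every tested gene gets exactly one inheritance mode (partition)", {
  cfg <- sim_config(n_genes = 600, seed = 55)
  run <- run_pipeline(run_config(simulate = cfg, seed = 55))
  modes <- run$inheritance$mode
  expect_equal(length(modes), 600)
  expect_true(all(modes %in% c("conserved", "additive", "dominant_P",
                               "dominant_L", "overdominant", "underdominant",
                               "parent_of_origin", "uninformative",
                               "ambiguous")))
  expect_equal(sum(run$summary$inheritance_tally), 600)
})

test_that("parent-of-origin orientation follows the per-direction rule", {
  genes <- c("mat1", "mat2", "pat1", "pat2", "same", "none")
  F <- rep(FALSE, 6); names(F) <- genes
  de <- list(PP_LL = !F, PL_PP = F, PL_LL = F, LP_PP = F, LP_LL = F,
             PL_LP = !F)
  fc <- lapply(de, function(x) ifelse(x, 2, 0))
  set_gene <- function(g, contrast, val) {
    de[[contrast]][g] <<- val != 0
    fc[[contrast]][g] <<- val
  }
  # maternal: P-dominant in PL only (PL=PP, PL!=LL; LP differs from both)
  set_gene("mat1", "PL_LL", 2)
  set_gene("mat1", "LP_PP", -1); set_gene("mat1", "LP_LL", 1)
  # maternal via the mirrored clause: L-dominant in LP only
  set_gene("mat2", "LP_PP", -2)
  set_gene("mat2", "PL_PP", -1); set_gene("mat2", "PL_LL", 1)
  # paternal: L-dominant in PL only
  set_gene("pat1", "PL_PP", -2)
  set_gene("pat1", "LP_PP", -1); set_gene("pat1", "LP_LL", 1)
  # paternal: P-dominant in LP only
  set_gene("pat2", "LP_LL", 2)
  set_gene("pat2", "PL_PP", -1); set_gene("pat2", "PL_LL", 1)
  # same sub-class in both directions: not a parental effect
  set_gene("same", "PL_LL", 2); set_gene("same", "LP_LL", 2)
  # no dominance pattern in either direction
  set_gene("none", "PL_PP", -1); set_gene("none", "PL_LL", 1)
  set_gene("none", "LP_PP", -1); set_gene("none", "LP_LL", 1)

  calls <- fake_call_set(genes, de, fc)
  out <- classify_parent_of_origin(calls)
  expect_equal(out$effect[match(genes, out$gene)],
               c("maternal", "maternal", "paternal", "paternal",
                 "unclassified", "unclassified"))
  expect_equal(out$call_PL[out$gene == "mat1"], "P_dominant")
  expect_equal(out$call_LP[out$gene == "mat2"], "L_dominant")
})

test_that("preferential-allele detection needs a reciprocal allele switch", {
  cfg <- sim_config(n_genes = 500,
                    class_proportions = c(conserved = 0.6, cis = 0.2,
                                          preferential = 0.2),
                    n_housekeeping = 20, seed = 61)
  sim <- simulate_experiment(cfg)
  inf <- filter_informative(sim$allele)
  sf <- estimate_size_factors(sim$counts)
  fit <- nb_fit_groups(sim$counts, sim$samples, sf = sf)
  plp <- call_de(run_contrast(fit, "PL", "LP", alpha = 0.10))
  pr <- detect_allele_preference(sim$allele, sim$samples, plp, genes = inf)
  truth <- sim$truth[match(pr$gene, sim$truth$gene), ]

  # cis-like imbalance (same allele favored in both directions) and balanced
  # conserved genes yield at most stray FDR-level preference calls
  false_calls <- sum(pr$preference != "none" &
                       truth$class %in% c("cis", "conserved"))
  expect_lte(false_calls, max(2, 0.01 * nrow(pr)))
  # most informative preferential genes are recovered with the right label
  hit <- pr$preference[truth$class == "preferential"] ==
    truth$allele_pref[truth$class == "preferential"]
  expect_gt(mean(hit), 0.8)
})

test_that("relabeling the morphs mirrors the classification", {
  cfg <- sim_config(n_genes = 400, n_housekeeping = 20,
                    batch_log2_offset = 0, seed = 71)
  sim <- simulate_experiment(cfg)

  classify <- function(counts, samples) {
    fit <- nb_fit_groups(counts, samples)
    classify_inheritance(lapply(run_all_contrasts(fit), call_de),
                         fit$group_means)
  }
  out1 <- classify(sim$counts, sim$samples)

  # swap morph labels: PP<->LL and PL<->LP (a pure relabeling of the data)
  swapped <- sim$samples
  swapped$group <- c(PP = "LL", LL = "PP", PL = "LP", LP = "PL")[swapped$group]
  out2 <- classify(sim$counts, swapped)

  map <- c(conserved = "conserved", additive = "additive",
           dominant_P = "dominant_L", dominant_L = "dominant_P",
           overdominant = "overdominant", underdominant = "underdominant",
           parent_of_origin = "parent_of_origin",
           uninformative = "uninformative", ambiguous = "ambiguous")
  expect_equal(unname(map[out1$mode]), out2$mode)
})
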