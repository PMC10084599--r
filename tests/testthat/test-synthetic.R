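test_that("expected group means follow the closed-form generative model", {
  base <- data.frame(gene = "g1", mu = 100, c = 0, t = 0, w_PL = 0.5,
                     w_LP = 0.5, d = 0, pref = 0, allele_pref = "none")

  # zero effects: identical means everywhere, balanced alleles
  em <- expected_group_means(base)
  expect_equal(unlist(em[, c("PP", "LL", "PL", "LP")]),
               c(PP = 100, LL = 100, PL = 100, LP = 100))
  expect_equal(em$f_L, 0.5)

  # pure cis, c = 2: parents 100 vs 400, L allele fraction 2^2/(1+2^2)
  cis <- transform(base, c = 2)
  em <- expected_group_means(cis)
  expect_equal(em$PP, 100)
  expect_equal(em$LL, 400)
  expect_equal(em$PL, 100 * 2 ^ (2 * 0.5))
  expect_equal(em$f_L, 0.8)

  # P-dominance under a trans effect: F1 totals pinned to PP
  dom <- transform(base, t = 1, w_PL = 0, w_LP = 0)
  em <- expected_group_means(dom)
  expect_equal(em$PP, 100)
  expect_equal(em$LL, 200)
  expect_equal(em$PL, 100)
  expect_equal(em$LP, 100)
  expect_equal(em$f_L, 0.5)

  # symmetric parent-of-origin offset: PL raised, LP lowered
  poe <- transform(base, d = 1)
  em <- expected_group_means(poe)
  expect_equal(em$PL / em$LP, 2)
  expect_equal(em$PP, em$LL)

  # expected log ratios: parental gap is c + t, allelic gap is c
  set.seed(1)
  tt <- data.frame(gene = paste0("g", 1:20), mu = 100,
                   c = runif(20, -2, 2), t = runif(20, -2, 2),
                   w_PL = 0.5, w_LP = 0.5, d = 0, pref = 0,
                   allele_pref = "none")
  em <- expected_group_means(tt)
  expect_equal(log2(em$LL / em$PP), tt$c + tt$t)
  expect_equal(log2(em$f_L / (1 - em$f_L)), tt$c)
})

test_that("simulate_truth realizes class proportions exactly and is seeded", {
  cfg <- sim_config(n_genes = 100, n_housekeeping = 10,
                    class_proportions = c(conserved = 0.5, cis = 0.25,
                                          trans = 0.25),
                    seed = 4)
  set.seed(4); tr1 <- simulate_truth(cfg)
  set.seed(4); tr2 <- simulate_truth(cfg)
  expect_identical(tr1, tr2)
  expect_equal(sum(tr1$class == "conserved"), 50)
  expect_equal(sum(tr1$class == "cis"), 25)
  expect_equal(sum(tr1$class == "trans"), 25)
  expect_true(all(tr1$c[tr1$class == "cis"] != 0))
  expect_true(all(tr1$t[tr1$class == "cis"] == 0))
  expect_true(all(tr1$c[tr1$class == "trans"] == 0))
  expect_true(all(tr1$t[tr1$class == "trans"] != 0))
  expect_true(all(tr1$pi >= 0 & tr1$pi <= 1))

  # housekeeping genes are zero-effect genes
  hk <- tr1[tr1$is_housekeeping, ]
  expect_equal(nrow(hk), 10)
  expect_true(all(hk$c == 0 & hk$t == 0 & hk$d == 0 &
                    hk$w_PL == 0.5 & hk$w_LP == 0.5))

  # all-conserved config: every gene zero-effect
  cfg0 <- sim_config(n_genes = 60, n_housekeeping = 5,
                     class_proportions = c(conserved = 1), seed = 1)
  tr0 <- simulate_truth(cfg0)
  expect_true(all(tr0$c == 0 & tr0$t == 0 & tr0$d == 0 & tr0$w_PL == 0.5))
  expect_true(all(tr0$true_inheritance == "conserved"))

  # unrealizable proportions are rejected
  expect_error(sim_config(n_genes = 3, n_housekeeping = 1,
                          class_proportions = c(conserved = 0.9, cis = 0.05,
                                                trans = 0.05)),
               "realized")
  expect_error(sim_config(n_genes = 100, n_housekeeping = 99,
                          class_proportions = c(conserved = 0.5, cis = 0.5)),
               "housekeeping")
  expect_error(sim_config(class_proportions = c(conserved = 0.7, cis = 0.2)),
               "sum to 1")
})

test_that("simulated counts match the closed-form expectations (MC oracle)", {
  # 3000 replicate genes with identical parameters; empirical group means of
  # normalized counts must sit within 3 Monte-Carlo SEs of the expectation
  n <- 3000
  truth <- data.frame(gene = sprintf("g%05d", 1:n), mu = 100, alpha = 0.05,
                      c = 2, t = -1, w_PL = 0.25, w_LP = 0.75, d = 0,
                      pref = 0, pi = 0.5, allele_pref = "none")
  cfg <- sim_config(n_genes = n, reps = c(PP = 2, LL = 2, PL = 2, LP = 2),
                    library_size_range = c(1, 1), batch_log2_offset = 0,
                    n_housekeeping = 1,
                    class_proportions = c(conserved = 1))
  set.seed(8)
  cs <- simulate_counts(truth, cfg)
  em <- expected_group_means(truth[1, ])
  for (g in c("PP", "LL", "PL", "LP")) {
    cols <- cs$samples$sample_id[cs$samples$group == g]
    x <- as.vector(cs$counts[, cols])
    mc_se <- sd(x) / sqrt(length(x))
    expect_lt(abs(mean(x) - em[[g]]), 3 * mc_se)
  }
})

test_that("zero dispersion reduces the emission to Poisson", {
  n <- 10000
  truth <- data.frame(gene = sprintf("g%05d", 1:n), mu = 100, alpha = 0,
                      c = 0, t = 0, w_PL = 0.5, w_LP = 0.5, d = 0,
                      pref = 0, pi = 0.5, allele_pref = "none")
  cfg <- sim_config(n_genes = n, reps = c(PP = 1, LL = 0, PL = 0, LP = 0),
                    library_size_range = c(1, 1), batch_log2_offset = 0,
                    n_housekeeping = 1, class_proportions = c(conserved = 1))
  set.seed(9)
  cs <- simulate_counts(truth, cfg)
  x <- cs$counts[, 1]
  expect_lt(abs(var(x) / mean(x) - 1), 0.05)
})

test_that("allele counts conserve totals and follow the thinning model", {
  cfg <- sim_config(n_genes = 400, seed = 12)
  sim <- simulate_experiment(cfg)
  # conservation, exactly, for every (gene, F1 sample)
  tot <- sim$allele$reads_P + sim$allele$reads_L + sim$allele$reads_unassigned
  expect_identical(tot,
                   as.integer(sim$counts[cbind(sim$allele$gene,
                                               sim$allele$sample_id)]))
  expect_true(all(sim$allele$sample_id %in%
                    sim$samples$sample_id[sim$samples$group %in% c("PL", "LP")]))
  # degenerate assignability
  tr1 <- sim$truth; tr1$pi <- 0
  a0 <- simulate_allele_counts(tr1, sim$counts, sim$samples)
  expect_true(all(a0$reads_P == 0 & a0$reads_L == 0))
  tr1$pi <- 1
  a1 <- simulate_allele_counts(tr1, sim$counts, sim$samples)
  expect_true(all(a1$reads_unassigned == 0))

  # no F1 samples -> error
  par_only <- sim$samples[sim$samples$group %in% c("PP", "LL"), ]
  expect_error(simulate_allele_counts(sim$truth, sim$counts, par_only), "F1")
})

test_that("assigned fraction and allelic fraction obey the law of large numbers", {
  n <- 10000
  truth <- data.frame(gene = sprintf("g%05d", 1:n), mu = 200, alpha = 0.05,
                      c = 2, t = 0, w_PL = 0.5, w_LP = 0.5, d = 0,
                      pref = 0, pi = 0.216, allele_pref = "none")
  cfg <- sim_config(n_genes = n, reps = c(PP = 0, LL = 0, PL = 3, LP = 3),
                    library_size_range = c(1, 1), batch_log2_offset = 0,
                    n_housekeeping = 0, class_proportions = c(conserved = 1))
  set.seed(13)
  cs <- simulate_counts(truth, cfg)
  al <- simulate_allele_counts(truth, cs$counts, cs$samples)
  assigned <- tapply(al$reads_P + al$reads_L, al$gene, sum)
  total <- tapply(al$reads_P + al$reads_L + al$reads_unassigned, al$gene, sum)
  expect_lt(abs(mean(assigned / total) - 0.216), 0.01)
  fL <- tapply(al$reads_L, al$gene, sum) / assigned
  expect_lt(abs(mean(fL) - 0.8), 0.01)
})

test_that("a fixed seed makes the whole experiment byte-identical", {
  cfg <- sim_config(n_genes = 150, seed = 77)
  s1 <- simulate_experiment(cfg)
  s2 <- simulate_experiment(cfg)
  expect_identical(s1$counts, s2$counts)
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$allele, s2$allele)
})

test_that("experiment tables survive a disk round trip", {
  cfg <- sim_config(n_genes = 60, n_housekeeping = 5, seed = 3)
  sim <- simulate_experiment(cfg)
  dir <- withr::local_tempdir()
  write_experiment(sim, dir)
  expect_identical(read_counts(file.path(dir, "counts.tsv")), sim$counts)
  expect_equal(read_samples(file.path(dir, "samples.tsv")), sim$samples)
  al <- read_allele_counts(file.path(dir, "allele_counts.tsv"))
  expect_equal(al, sim$allele)
  expect_identical(read_housekeeping(file.path(dir, "housekeeping.txt")),
                   sim$housekeeping)
})
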