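# Independent brute-force oracles, written deliberately close to the plain
# definitions (loops, no reuse of package internals).

# median-of-ratios: reference = geometric mean per gene over samples for
# genes positive everywhere; size factor = median of count/reference
brute_force_size_factors <- function(m) {
  keep <- c()
  for (g in seq_len(nrow(m))) {
    if (all(m[g, ] > 0)) keep <- c(keep, g)
  }
  ref <- numeric(length(keep))
  for (k in seq_along(keep)) {
    ref[k] <- prod(m[keep[k], ]) ^ (1 / ncol(m))
  }
  sf <- numeric(ncol(m))
  for (j in seq_len(ncol(m))) {
    ratios <- numeric(length(keep))
    for (k in seq_along(keep)) ratios[k] <- m[keep[k], j] / ref[k]
    sf[j] <- median(ratios)
  }
  sf
}

# BH step-up by definition: padj_i = min over {j : p_j >= p_i} of
# m * p_j / rank_j, capped at 1
brute_force_bh <- function(p) {
  m <- length(p)
  r <- rank(p, ties.method = "max")
  out <- numeric(m)
  for (i in seq_len(m)) {
    cand <- m * p[p >= p[i]] / r[p >= p[i]]
    out[i] <- min(1, min(cand))
  }
  out
}

# small random count matrix, all entries positive unless zeros requested
random_count_matrix <- function(ngene = 6, nsample = 4, with_zeros = FALSE) {
  m <- matrix(rpois(ngene * nsample, lambda = 50) + 1, ngene, nsample,
              dimnames = list(paste0("g", seq_len(ngene)),
                              paste0("s", seq_len(nsample))))
  if (with_zeros) m[sample(length(m), 2)] <- 0
  m
}

# a de_call table built directly from flags, for classifier decision tests
fake_call <- function(genes, is_de, log2fc, groupA = "A", groupB = "B") {
  out <- data.frame(gene = genes, is_de = is_de,
                    direction = ifelse(!is_de, "none",
                                       ifelse(log2fc > 0, groupA, groupB)),
                    log2fc = log2fc, padj = ifelse(is_de, 0.01, 0.9),
                    mean_A = 100, mean_B = 100, stringsAsFactors = FALSE)
  attr(out, "groupA") <- groupA
  attr(out, "groupB") <- groupB
  class(out) <- c("de_call", "data.frame")
  out
}

# the six-contrast call list for hand-specified DE patterns; `de` is a list
# with logical vectors named PP_LL, PL_PP, PL_LL, LP_PP, LP_LL, PL_LP and
# `fc` matching signed log2 fold changes
fake_call_set <- function(genes, de, fc) {
  nm <- c("PP_LL", "PL_PP", "PL_LL", "LP_PP", "LP_LL", "PL_LP")
  grp <- list(c("PP", "LL"), c("PL", "PP"), c("PL", "LL"),
              c("LP", "PP"), c("LP", "LL"), c("PL", "LP"))
  out <- lapply(seq_along(nm), function(i) {
    fake_call(genes, de[[nm[i]]], fc[[nm[i]]], grp[[i]][1], grp[[i]][2])
  })
  names(out) <- nm
  out
}

# expected-count (noise-free) reciprocal-cross dataset from a truth table
expected_dataset <- function(truth, reps = c(PP = 7, LL = 7, PL = 5, LP = 5),
                             pi = 0.5) {
  em <- expected_group_means(truth)
  groups <- rep(names(reps), reps)
  samples <- data.frame(
    sample_id = paste0(groups, "_", unlist(lapply(reps, seq_len))),
    group = groups,
    batch = ifelse(groups %in% c("PL", "LP"), "b2_F1", "b1_parental"),
    replicate = unlist(lapply(reps, seq_len)), stringsAsFactors = FALSE)
  counts <- as.matrix(em[, groups])
  dimnames(counts) <- list(truth$gene, samples$sample_id)
  f1 <- samples[samples$group %in% c("PL", "LP"), ]
  allele <- do.call(rbind, lapply(seq_len(nrow(f1)), function(j) {
    tot <- counts[, f1$sample_id[j]]
    fL <- if (f1$group[j] == "PL") em$f_L_PL else em$f_L_LP
    a <- tot * pi
    data.frame(gene = truth$gene, sample_id = f1$sample_id[j],
               reads_P = a * (1 - fL), reads_L = a * fL,
               reads_unassigned = tot - a, stringsAsFactors = FALSE)
  }))
  sf <- stats::setNames(rep(1, ncol(counts)), colnames(counts))
  list(counts = counts, samples = samples, allele = allele, sf = sf)
}
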