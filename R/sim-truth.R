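#' Draw the per-gene ground truth of a simulated experiment
#'
#' Assigns every gene an architecture class (exact largest-remainder counts
#' from `class_proportions`), then draws its generative parameters:
#' baseline mean `mu`, NB dispersion `alpha`, cis effect `c`, trans effect
#' `t`, dominance weights (`w_PL`, `w_LP`), symmetric parent-of-origin offset
#' `d`, allelic-preference shift, and allele assignability `pi`. Housekeeping
#' genes are the first `n_housekeeping` conserved genes; their baselines are
#' drawn from the upper part of the expression range, mirroring the practice
#' of picking well-expressed control genes.
#'
#' @param config a [sim_config()] object.
#' @return A `data.frame` of class `truth_table`, one row per gene, with the
#'   generative parameters and the true inheritance / regulatory / parent-of-
#'   origin / allele-preference labels.
#' @export
simulate_truth <- function(config) {
  validate_sim_config(config)
  n <- config$n_genes
  alloc <- allocate_classes(n, config$class_proportions)
  cls <- rep(names(alloc), times = alloc)

  gene <- sprintf("g%05d", seq_len(n))
  mu <- 2 ^ rnorm(n, config$baseline_log2_mean[["location"]],
                  config$baseline_log2_mean[["scale"]])
  alpha <- rlnorm(n, config$dispersion_log_mean, config$dispersion_log_sd)
  m <- config$assignability_mean
  pi <- if (m >= 1) rep(1, n) else {
    rbeta(n, config$assignability_shape1,
          config$assignability_shape1 * (1 - m) / m)
  }

  eff <- runif(n, config$effect_size_log2[1], config$effect_size_log2[2])
  sgn <- sample(c(-1, 1), n, replace = TRUE)

  c_eff <- numeric(n)
  t_eff <- numeric(n)
  w_PL <- rep(0.5, n)
  w_LP <- rep(0.5, n)
  d <- numeric(n)
  pref <- numeric(n)
  poe_effect <- rep("none", n)
  allele_pref <- rep("none", n)

  for (k in seq_len(n)) {
    e <- sgn[k] * eff[k]
    switch(cls[k],
      conserved = NULL,
      cis = { c_eff[k] <- e },
      trans = { t_eff[k] <- e },
      cis_plus_trans = { c_eff[k] <- 0.6 * e; t_eff[k] <- 0.4 * e },
      cis_x_trans = {
        # opposite signs, unequal magnitude so the net parental effect
        # stays detectable: |c + t| = (2/3)|c|
        e2 <- sgn[k] * max(abs(e), 2.25)
        c_eff[k] <- e2; t_eff[k] <- -e2 / 3
      },
      compensatory = { c_eff[k] <- e; t_eff[k] <- -e },
      dominant_P = { t_eff[k] <- e; w_PL[k] <- 0; w_LP[k] <- 0 },
      dominant_L = { t_eff[k] <- e; w_PL[k] <- 1; w_LP[k] <- 1 },
      overdominant = {
        t_eff[k] <- e
        w <- if (e > 0) runif(1, 1.4, 1.8) else -runif(1, 0.4, 0.8)
        w_PL[k] <- w; w_LP[k] <- w
      },
      underdominant = {
        t_eff[k] <- e
        w <- if (e > 0) -runif(1, 0.4, 0.8) else runif(1, 1.4, 1.8)
        w_PL[k] <- w; w_LP[k] <- w
      },
      parent_of_origin = {
        t_eff[k] <- sgn[k] * config$poe_log2
        if (runif(1) < 0.5) {          # each F1 direction tracks one parent
          poe_effect[k] <- "maternal"  # PL follows PP, LP follows LL
          w_PL[k] <- 0; w_LP[k] <- 1
        } else {
          poe_effect[k] <- "paternal"  # PL follows LL, LP follows PP
          w_PL[k] <- 1; w_LP[k] <- 0
        }
      },
      preferential = {
        pref[k] <- config$pref_log2
        allele_pref[k] <- if (runif(1) < 0.5) "maternal" else "paternal"
      },
      stop("unhandled class ", cls[k]))
  }

  is_hk <- rep(FALSE, n)
  hk_idx <- which(cls == "conserved")[seq_len(config$n_housekeeping)]
  is_hk[hk_idx] <- TRUE
  # control genes are picked among well-expressed genes
  mu[hk_idx] <- 2 ^ runif(length(hk_idx), 6.5, 10)

  true_inheritance <- vapply(cls, function(x) switch(x,
    conserved = , compensatory = , preferential = "conserved",
    cis = , trans = , cis_plus_trans = , cis_x_trans = "additive",
    dominant_P = "dominant_P",
    dominant_L = "dominant_L",
    overdominant = "overdominant",
    underdominant = "underdominant",
    parent_of_origin = "parent_of_origin"), character(1))
  true_regulatory <- vapply(cls, function(x) switch(x,
    conserved = , preferential = "conserved",
    cis = "cis",
    cis_plus_trans = "cis_plus_trans",
    cis_x_trans = "cis_x_trans",
    compensatory = "compensatory",
    trans = , dominant_P = , dominant_L = , overdominant = ,
    underdominant = , parent_of_origin = "trans"), character(1))

  truth <- data.frame(gene = gene, class = cls, mu = mu, alpha = alpha,
                      c = c_eff, t = t_eff, w_PL = w_PL, w_LP = w_LP,
                      d = d, pref = pref, pi = pi,
                      is_housekeeping = is_hk,
                      true_inheritance = unname(true_inheritance),
                      true_regulatory = unname(true_regulatory),
                      poe_effect = poe_effect,
                      allele_pref = allele_pref,
                      stringsAsFactors = FALSE)
  class(truth) <- c("truth_table", "data.frame")
  truth
}

#' Expected group means and F1 allelic fractions under the generative model
#'
#' Closed-form expectations for each gene: per-allele-copy means are
#' `x(P|PP) = mu/2`, `x(L|LL) = (mu/2) 2^(c+t)`, and in the heterozygous F1
#' background `x(P|F1) = (mu/2) 2^(t/2)`, `x(L|F1) = (mu/2) 2^(c+t/2)` (the
#' trans environment of a heterozygote is the midpoint of the parental
#' environments). Totals are `PP = mu`, `LL = mu 2^(c+t)`; the F1 total is
#' re-targeted by the dominance weight to `mu 2^((c+t) w)` per cross
#' direction, then shifted by `+d/2` (PL) / `-d/2` (LP) log2 units for a
#' symmetric parent-of-origin offset. The expected fraction of assignable F1
#' reads carrying the L allele is `2^c / (1 + 2^c)`, independent of dominance
#' and trans effects; preferential-allele genes shift it by `pref` log2 units
#' toward the maternal (or paternal) allele of each cross direction.
#'
#' @param truth a `truth_table` (or any data.frame with its parameter columns).
#' @return A data.frame with one row per gene: expected normalized totals
#'   `PP`, `LL`, `PL`, `LP`, the pooled expected L-allele fraction `f_L`, and
#'   the per-direction fractions `f_L_PL`, `f_L_LP`.
#' @export
#' @examples
#' t1 <- data.frame(gene = "g1", mu = 100, c = 2, t = 0, w_PL = 0.5,
#'                  w_LP = 0.5, d = 0, pref = 0, allele_pref = "none")
#' expected_group_means(t1)  # PP = 100, LL = 400, f_L = 0.8
expected_group_means <- function(truth) {
  stopifnot(all(c("mu", "c", "t") %in% names(truth)))
  n <- nrow(truth)
  w_PL <- if ("w_PL" %in% names(truth)) truth$w_PL else rep(0.5, n)
  w_LP <- if ("w_LP" %in% names(truth)) truth$w_LP else rep(0.5, n)
  d <- if ("d" %in% names(truth)) truth$d else numeric(n)
  pref <- if ("pref" %in% names(truth)) truth$pref else numeric(n)
  ap <- if ("allele_pref" %in% names(truth)) truth$allele_pref else rep("none", n)

  e <- truth$c + truth$t
  PP <- truth$mu
  LL <- truth$mu * 2 ^ e
  PL <- truth$mu * 2 ^ (e * w_PL + d / 2)
  LP <- truth$mu * 2 ^ (e * w_LP - d / 2)

  frac <- function(l2) 2 ^ l2 / (1 + 2 ^ l2)
  f_L <- frac(truth$c)
  # preferential expression of the maternal allele: P in PL eggs, L in LP eggs
  shift_PL <- ifelse(ap == "maternal", -pref, ifelse(ap == "paternal", pref, 0))
  shift_LP <- -shift_PL
  f_L_PL <- frac(truth$c + shift_PL)
  f_L_LP <- frac(truth$c + shift_LP)

  out <- data.frame(PP = PP, LL = LL, PL = PL, LP = LP,
                    f_L = f_L, f_L_PL = f_L_PL, f_L_LP = f_L_LP)
  if ("gene" %in% names(truth)) out <- cbind(gene = truth$gene, out)
  stopifnot(all(out$PP > 0), all(out$LL > 0), all(out$PL > 0), all(out$LP > 0))
  out
}
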