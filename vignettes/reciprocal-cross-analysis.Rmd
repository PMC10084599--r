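---
title: "Classifying inheritance and regulatory modes in reciprocal-cross egg transcriptomes"
author: "eggcross"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying inheritance and regulatory modes in reciprocal-cross egg transcriptomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eggcross)
```

## The design

Two parental morphs — a small-egg planktotrophic type (P) and a large-egg
lecithotrophic type (L) — are crossed reciprocally. Four kinds of mothers
contribute pooled-oocyte RNA-seq libraries: the parentals PP and LL and the
two reciprocal F1s, PL (P mother × L father) and LP (L mother × P father).
The F1 mothers are genetically equivalent heterozygotes; any expression
difference between PL and LP eggs is a parent-of-origin effect, while
differences shared by both F1 directions reflect allele-specific
(genotype-driven) effects. Within F1 samples, reads that overlap
morph-distinguishing variants can be assigned to the P or the L allele,
which separates cis-acting from trans-acting regulatory divergence.

The package implements this analysis as a pipeline of small, individually
testable stages — normalization, a negative-binomial Wald engine, and three
classifiers — plus a generative simulator whose every parameter corresponds
to a quantity one of the stages is supposed to recover.

## The generative model

Each gene has a baseline expected normalized count $\mu$, an NB dispersion
$\alpha$ (variance $= m + \alpha m^2$), a cis effect $c$ and a trans effect
$t$ (both log2 units), dominance weights, and optional parent-of-origin and
allele-preference parameters. Per allele copy,

- $x(P \mid PP) = \mu/2$, and $x(L \mid LL) = (\mu/2)\,2^{c+t}$;
- in the F1 background the trans environment is the midpoint of the
  parental environments, so $x(P \mid F1) = (\mu/2)\,2^{t/2}$ and
  $x(L \mid F1) = (\mu/2)\,2^{c+t/2}$.

Totals are $PP = \mu$ and $LL = \mu\,2^{c+t}$. The F1 total is re-targeted
by a dominance weight $w$ to $\mu\,2^{(c+t)w}$: $w = 1/2$ is additive
(intermediate), $w = 0$ pins the F1 to the PP level (P-dominant), $w = 1$
to the LL level (L-dominant), and $w$ outside $[0,1]$ produces
mis-expression (over-/underdominance). Because dominance re-targets the
total rather than perturbing the alleles, the expected fraction of
assignable F1 reads carrying the L allele stays $2^c/(1+2^c)$ regardless of
$t$ and $w$ — the property that makes the allelic ratio a clean estimator
of $c$. Two consequences worth noting, both of which the tests assert
exactly: the expected parental log2 ratio (LL:PP) is $c+t$, and the
expected F1 allelic log2 ratio is $c$.

Parent-of-origin genes carry per-direction dominance weights
$(w_{PL}, w_{LP})$: a *maternal*-oriented gene has $w_{PL}=0, w_{LP}=1$
(each F1 matches its mother's morph), a *paternal* one the reverse. This is
exactly the pattern the orientation classifier is defined to detect; a
symmetric offset $d$ (PL raised by $d/2$ log2, LP lowered) is also
available for total-level shifts without a dominance asymmetry.
Preferential-allele genes shift the allelic ratio toward the maternal (or
paternal) allele of each cross direction while leaving all totals equal.

Counts are emitted as $\mathrm{NB}(s_j \cdot b_j \cdot m_{g,\mathrm{group}(j)},
\alpha_g)$ with $s_j$ a uniform library scaling and $b_j = 2^{\delta}$ for
samples of the F1 sequencing batch ($\delta$ = `batch_log2_offset`,
default 1, applied to every gene including the controls). Allele counts are
binomial thinnings: assigned $\sim \mathrm{Bin}(\mathrm{total}, \pi_g)$,
then L-reads $\sim \mathrm{Bin}(\mathrm{assigned}, f_L)$, so
`reads_P + reads_L + reads_unassigned` reproduces the count matrix exactly.
The study the defaults emulate could assign 21.6% of F1 reads, so
$\pi_g \sim \mathrm{Beta}$ with mean 0.216; the within-study distribution of
$\pi_g$ is not published, so its shape (`assignability_shape1 = 2`) is a
configurable choice, not an asserted fact.

### Default parameter choices

Chosen once, as plausible bulk pooled-oocyte RNA-seq values: baseline
$\log_2 \mu \sim N(7, 1.5^2)$ (median ≈ 128 normalized reads); dispersion
$\alpha \sim \mathrm{lognormal}(\log 0.05, 0.5)$, typical of low-noise bulk
libraries from pooled material; library scalings uniform on $[0.7, 1.3]$;
replicate geometry 7/7/5/5 with the parentals and F1s in separate
sequencing batches; 50 housekeeping genes drawn from the well-expressed end
of the conserved class (control lists are curated from stably, decently
expressed genes — near-zero controls would make the batch factor ill-
conditioned); effect magnitudes uniform on $[1.5, 3]$ log2 so that true
effects sit clearly above the 1.5-fold call threshold; parent-of-origin
magnitude 1 log2.

## Normalization and the batch factor

Size factors are plain median-of-ratios: the reference is the geometric
mean of each all-positive gene across samples, and $s_j$ is the median of
$\mathrm{count}_{gj}/\mathrm{ref}_g$. The estimator assumes most genes are
not differentially expressed; the simulator's default mix (40% conserved
plus effects balanced in sign) respects that, and an all-DE configuration
demonstrably biases it (one unit test constructs exactly this failure).

The batch factor is estimated from a priori housekeeping genes: take
$\log_2(\mathrm{normalized}+1)$ of the control genes, center each gene,
and compute the first right-singular vector $W_1$ (unit norm, zero sum,
sign fixed deterministically). The per-sample correction `gamma` is the
rank-1 reconstruction of the samples' shared log2 shift,
$\sigma_1 \bar u_1 W_1$ — restricting to the leading factor keeps the
correction one-dimensional and drops control-gene noise orthogonal to it.

Two design points deserve an explanation:

1. **The correction enters as an offset, not a free covariate.** In this
   design the batch split coincides with the parental-vs-F1 split, so a
   per-gene coefficient on $W_1$ is collinear with the group means and
   unidentifiable; models would either drop it or inflate every cross-batch
   contrast. A per-sample offset derived from the control genes uses the
   one assumption that breaks the confounding — housekeeping genes do not
   differ biologically between the groups — and leaves genuine F1-specific
   biology (dominance, mis-expression) untouched. A `covariate` mode is
   still available for designs where batch and biology are not aliased.
2. **A second joint median-of-ratios pass follows the bridge.** Size
   factors computed jointly across batches already absorb any *global*
   between-batch scale — including the simulator's global offset — so the
   housekeeping bridge matters precisely when the two sequencing runs are
   depth-anchored separately (counts normalized per run, the situation a
   batch-split dataset naturally arrives in). The pipeline therefore
   applies `gamma` and then re-estimates ratios jointly on the corrected
   scale; the second pass removes the residual shared error of the
   housekeeping estimate (which is $O(1/\sqrt{n_{hk}})$ per sample and
   would otherwise wobble cross-batch contrasts).

## The NB Wald engine

Each gene is fitted once per dataset with a cell-means design (one
coefficient per group, log link, `log` size-factor offsets) by IRLS with
working weights $m/(1+\alpha m)$; the covariance is the inverse Fisher
information at convergence, and any pairwise contrast is then a linear
function of the stored coefficients. Convergence is declared at a relative
deviance change below 1e-10 (100 iterations maximum); non-convergent or
rank-deficient fits are reported as `failed_fit` statuses, never as errors
escaping the per-gene loop, and all-zero genes are `low_count`. The
deviance uses `log1p` so the Poisson limit ($\alpha \to 0$) is numerically
exact — saturated fits at the dispersion floor otherwise fail to converge.

Wald statistics use the normal reference; p-values are two-sided;
Benjamini–Hochberg correction is applied per contrast over the tested
genes. Significance is 0.05 for the parental contrast and 0.10 for every
contrast involving F1 samples (compensating the F1s' higher biological
variability), and a DE call additionally requires a fold change above 1.5×
(|log2 FC| > log2 1.5 ≈ 0.585) on the unshrunken estimate. The relaxed F1
level applies to the significance only; the fold threshold is kept at 1.5×
everywhere.

Dispersions are method-of-moments within replicate groups, pooled by
degrees of freedom, and by default shrunk (weight 0.7) toward a fitted
mean–dispersion trend $a_0 + a_1/\mu$. The shrinkage matters for
calibration: raw gene-wise moments at 7+7 replicates leave the plug-in
Wald test rejecting ~7–8% of null genes at $p<0.05$, while the trended
estimator brings it to ~5% (measured across seeds in the test suite).

### Allele-level dispersion

Within an F1 sample the two allele counts share that sample's total-count
noise, which cancels in the P-vs-L comparison. An NB dispersion estimated
from the *marginal* across-sample variance of allele counts would therefore
overstate the allelic-contrast uncertainty (empirically: interaction-test
null rejection 0.018 instead of 0.05). The allelic models instead use a
binomial-Pearson estimator: per gene, the overdispersion $\phi$ of the
L-fractions across samples (within cross direction), converted to the NB
dispersion that inflates the log allelic-ratio variance by the same
factor, $\alpha = (\phi-1)/(2\,\bar a f(1-f))$, floored at zero excess.
Pure binomial thinning gives $\phi \approx 1$, i.e. a near-Poisson allele
model, whose independent log-ratio variance $1/m_P + 1/m_L$ equals the
binomial log-odds variance — so treating the two alleles as independent
observations is exact at the ratio level. The genotype-by-origin
interaction model mixes observation types and so carries per-observation
dispersions: count-level for parental rows, allele-level for F1 rows.

## The classifiers

**Mode of inheritance** applies a fixed decision order to the six pairwise
contrasts (PP:LL at 0.05; PL:PP, PL:LL, LP:PP, LP:LL, PL:LP at 0.10):
uninformative (mean normalized F1 count below 10 in both directions) →
parent-of-origin (PL:LP differs) → conserved (nothing differs) → dominant
(F1s at one parent's level, differing from the other) → additive (F1s
differ from both parents with strictly intermediate means) →
over-/underdominant (F1s outside the parental range, same outward
direction) → ambiguous. The order makes the partition deterministic, and
"same level" is operationalized as not-DE at the F1 criteria — absence of
evidence, as in the criteria tables such analyses conventionally use. The
low-count cutoff reuses the 10-normalized-read constant rather than
introducing a new threshold. Additivity demands intermediate point
estimates on top of significance because intermediate expression is its
defining feature; with only 5 F1 replicates per direction this stage has
the least power, and additive recovery is reported separately for that
reason.

**Parent-of-origin orientation** re-applies the dominance calls per cross
direction: maternal means P-dominant in PL but not LP, or L-dominant in LP
but not PL (each F1 matching its mother); paternal is the mirror. Genes
matching neither or both patterns stay unclassified. The maternal/paternal
axis is invariant to swapping the morph labels, which the suite checks by
relabeling an entire simulated experiment.

**Preferential-allele detection** looks for genes whose favored allele
switches with the cross direction (significant imbalance both ways,
opposite signs, maternal or paternal consistently) while PL:LP totals do
not differ — allele switching without a total-level reciprocal difference.

**Regulatory mode** combines three comparisons, all oriented L over P:
A (parental totals, DE call at 0.05 with the fold threshold), B (F1 allelic
imbalance, 0.10), C (genotype × origin interaction, 0.10, estimating
A − B). Significant patterns map to: A,B only → *cis*; A,C only → *trans*;
A,B,C with the allelic and residual-trans components ($B$ and $A-B$)
sharing a sign → *cis + trans*, opposite signs → *cis × trans*; B,C
without A → *compensatory*; neither A nor B → conserved; anything else
ambiguous. Only genes with informative allele assignment enter — more than
20% of F1 reads assigned and at least 10 assigned reads, summed over F1
samples. On expected (noise-free) counts the three estimates satisfy
$A - B = C$ to machine precision, which the acceptance suite asserts at
1e-6.

## What the simulator does and does not emulate

It reproduces the features the statistics depend on: NB counts with
gene-specific dispersion, the replicate geometry, a batch split aligned
with parentals-vs-F1s, SNP-limited allele assignability with exact read
conservation, and architectures whose expectations realize each class
definition. It does not emulate read-level artifacts (mapping bias toward
the reference morph, positional SNP effects), correlated gene modules,
outlier samples, or assignability that correlates with regulatory class.
Passing recovery tests therefore certifies the inferential machinery, not
robustness to upstream artifacts; on real data the allele-assignment step
and its biases live upstream of this package's inputs.

Label recovery is quoted among genes with informative F1 coverage: genes
whose F1 expectation the simulation itself pushes below the 10-read rule
(a fifth of underdominant genes at the default baseline distribution) are
flagged uninformative by design and cannot carry a label — the same
category the motivating study reports.

## Problem sizes and runtime

The test suite simulates 200–2000 genes per scenario (2000 for the
calibration, batch-correction and recovery checks, matching the study-scale
gene counts entering each stage) and completes in well under a minute; the
acceptance script re-runs every stage from scratch in ~10 s. Per-gene IRLS
over 24 samples costs ~2 ms, so runtime scales linearly and comfortably to
full transcriptomes (~20k genes in a few minutes).

## Known limitations

- The housekeeping bridge assumes control genes are biologically stable
  across all four groups; if they are not, the correction absorbs real
  signal. With batch aliased to the parental/F1 axis this is an assumption,
  not something the data can check.
- Dispersion shrinkage uses a two-parameter trend; datasets with strongly
  non-monotone mean–dispersion relations would prefer a nonparametric
  trend.
- The additive/ambiguous boundary is power-limited at 5 replicates per F1
  direction; simulated additive recovery around 80% is expected, not a
  defect.
- The interaction model treats the two alleles of a sample as independent
  observations (exact for ratios under binomial thinning, approximate
  beyond it) and assumes symmetric SNP ascertainment between alleles.
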