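---
title: "Designing multi-sample single-cell studies with powersc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing multi-sample single-cell studies with powersc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(powersc)
```

## The problem

A multi-sample single-cell RNA-seq study that aims to find differentially
expressed (DE) genes or eQTL genes in a specific cell type has three cost
levers: the number of samples $n_s$, the number of cells captured per
sample $n_c$, and the reads sequenced per cell $r$. Under a fixed budget
these trade off against each other, and the power to *detect* a gene
factorizes into two conditionally independent pieces given its mean
expression:

$$P_i \;=\; P(i \in E)\, \cdot\, P(i \in S),$$

the probability that gene $i$ passes the expressed-gene filter in the
planned experiment, times the power of the statistical test. The overall
power of a design is the average $P_i$ over a ranked prior of target
genes, and `optimize_design()` searches the $(n_c, r)$ grid with $n_s$
pinned by the budget.

## The expression model

Per-cell UMI counts of gene $i$ in one cell type are negative binomial
with mean $\mu_i$ and dispersion $\phi_i$. Pseudobulk aggregation over
the $n_{cs}$ cells of the type in one individual is exact in this model:
the per-individual sum is NB with mean $n_{cs}\mu_i$ and dispersion
$\phi_i / n_{cs}$ (a property the test suite verifies empirically). A
gene is called expressed when its pseudobulk sum exceeds a count
threshold $n$ in more than a fraction $k$ of individuals; both pieces are
closed-form CDF evaluations (NB tail, then a binomial tail across
individuals). An alternative "nonzero cells" criterion and a
counts-per-kilobase variant for full-length protocols are provided by
`expression_threshold()`.

To extrapolate to unseen designs, the distribution of gene means in a
cell type is modeled as a zero-inflated mixture of two gamma components
(the second capturing a small set of highly expressed genes), fitted by
EM with left-censoring at $1/n_c$ — the smallest observable mean — so
that observed zeros are shared between structural zeros and
censored-gamma mass. The gamma density is parameterized by shape and
rate; component means are shape/rate. Sequencing depth enters through
linear curves of the mixture parameters versus the mean UMI count per
cell (the zero weight $p_1$ declining with depth, floored at 0.01; the
outlier weight $p_3$ held constant at the median of the fits), and a
saturation curve `mapped reads` $= b_0 + b_1 \ln(\text{mean UMI})$ links
read depth to UMI yield. Dispersion follows the trend
$\phi(\mu) = a_0 + a_1/\mu$, fitted across genes with
variance-proportional weights and 5% residual trimming.

Expression ranks map to means through the mixture quantiles with a
half-rank correction, $q = 1 - (i - 0.5)/G$ with $G = 21{,}000$ genes by
default; rank 1 is the most expressed gene. The half-rank correction
avoids the degenerate $q = 1$ at rank 1; the descending orientation makes
reference studies' "top genes" land on high means. Quantiles inside the
zero mass return $\mu = 0$ and short-circuit to $P_i = 0$.

## Significance power

**DE.** The two-group pseudobulk comparison uses the analytic power of
the Wald test for a negative-binomial rate ratio $\rho = 2^{\mathrm{lfc}}$:
$V_1 = (1/\mu_0 + \phi) + (1/(\rho\mu_0) + \phi)/\theta$ per control
sample under the alternative, and a null variance evaluated at (variant
1) the control mean, (variant 2) the unweighted average of the two
means, or (variant 3, default) the constrained-ML common mean. Both
rejection tails are summed, so the size is exactly $\alpha$ at
$\rho = 1$. For a balanced design and a unit null ratio, variants 2 and
3 coincide; the Monte-Carlo oracle confirms variant 3 as the most
accurate (mean absolute deviation 0.013 over the validation grid). The
approximation degrades for group sizes of ~5 or pseudobulk means of ~2,
where deviations up to ~0.05 remain against any finite-sample Wald
implementation; this limitation is inherited from the asymptotic
two-rate framework and documented rather than patched.

**eQTL.** For well-expressed genes, genotype-on-expression power is the
noncentral-F power of a single-regressor test: $f^2 = R^2/(1 - R^2)$,
numerator df 1, denominator df $n_s - 2$, noncentrality $f^2 n_s$. Below
a pseudobulk mean of 5 (the `mean_switch`), where log-transformed counts
are too discrete for normal theory, a count-level simulation takes over:
allele frequencies are drawn uniformly from 0.1–0.9, genotypes are the
deterministic Hardy–Weinberg expected counts (largest-remainder
rounding), counts are NB with per-genotype means
$e^{\ln\mu_c + \beta g}$, $\beta = \sqrt{R^2 / (2 f_a (1-f_a))}$, and a
dispersion chosen by root-finding so that the sd of $\log(x+1)$ equals
the residual sd $\sqrt{1 - R^2}$. That sd is *unimodal* in $\phi$ (at
extreme overdispersion zeros dominate and the log-scale spread falls
again), so the root is sought on the increasing branch and the closest
achievable value is used when the target is unattainable — which is
itself the mechanism by which low-mean genes lose power. A precomputed
lookup grid (bilinear in $\log \mu$ and $\sigma$) caches the
root-finding.

**Multiple testing.** Bonferroni divides $\alpha$ by the expected number
of expressed genes (times 10 assumed independent SNPs per gene for eQTL
scans). The FDR alternative inverts the expected-discovery identity
$\mathrm{FDR}(\alpha') = m_0\alpha' / (m_0\alpha' + r_1(\alpha'))$ by
bisection on $\ln \alpha'$, with $m_0$ the expected expressed non-prior
genes and $r_1$ the sum over prior genes of expression probability times
power at $\alpha'$.

## A refinement for strongly regulated genes

The single-mean filter model evaluates $P(i \in E)$ at one mean for all
individuals. In a faithful two-group simulation, the treated group's
mean carries the fold change, and for a strongly regulated gene whose
control mean sits near the count threshold the two calculations diverge
badly (a 6-fold down-regulated gene may be filtered out almost always
while the single-mean model says never). `overall_detection_power()`
therefore computes DE-prior expression probabilities as the tail of a
sum of two binomials — control individuals passing at $\mu$, treated at
$\rho\mu$ — which reduces exactly to the single-mean form at $\rho = 1$.
The expected number of expressed genes over all ranks (where no effect
is assumed) keeps the single-mean form. With this refinement the
composed power tracks an end-to-end simulation (counts → pseudobulk →
filter → NB Wald at the adjusted threshold) within Monte-Carlo error.

## Study design under a budget

The cost model prices kits (one kit covers `lanes_per_kit` lanes,
`cells_loaded_per_lane` cells each) and flow cells:
$C_t = \lceil n_s/(6\,n_{sl})\rceil C_k + \lceil n_s n_c r / r_f \rceil C_f$,
and its ceiling-free inversion pins $n_s$ for any $(n_c, r)$ grid point.
Overloading a lane raises the doublet rate $d = 7.67\times10^{-6}\, n_c
n_{sl}$ (at most 15.34% when 20,000 cells are loaded per lane); doublets
are assumed detected and discarded, leaving $n_u = (1-d) n_c$ usable
cells, and because a doublet absorbs $f_d = 1.8$ times a singlet's
reads, the singlet depth shrinks to $r_s = r n_c / (n_u + f_d(n_c -
n_u))$, of which 80% maps to the transcriptome. Non-overloading
technologies (Drop-seq, Smart-seq2) use a constant doublet rate and
per-cell library pricing. Rare-cell-type capture is the negative
binomial tail $F_{NB}(n_c - n_{cs};\, n_{cs}, f_c)^{n_s}$, with
`min_cells_for_detection()` inverting it for the smallest adequate
$n_c$.

Grid ties are broken toward larger $n_s$ (robustness to
inter-individual variance), then lower read depth; the expected cells of
the target type per sample, $\lfloor f_c n_u \rfloor$, must be at least
1 or the design is declared infeasible.

## The synthetic world

The generators state the world the tests live in. Effect-size priors
follow the stated scenarios: 250 DE genes with log2 fold-change
magnitudes $\sim N(2, 1)$ (the "high" scenario; signs randomized since
the magnitude distribution is what is specified), 2,000 eQTL genes with
$R = \tanh(Z)$, $Z \sim N(0.5, 0.2)$ truncated below its mean via
rejection sampling, ranks uniform without replacement over the first
10,000 genes. The synthetic expression prior uses a gamma-1 mean of 0.3
UMI, a gamma-2 mean of 8 UMI ($p_3 = 0.05$), a zero weight of 0.25, the
dispersion trend $\phi = 0.2 + 1.5/\mu$ and a saturation curve
calibrated so ~10,000 mapped reads yield ~1,500 UMI — values typical of
a droplet experiment at moderate depth. Pilot-count simulation draws
gene means from the mixture (censoring means below $1/n_c$ to zero),
dispersions from the trend, and i.i.d. NB counts per cell.

What a green test establishes: internal consistency of the analytic
pipeline against honest simulation from its own generative model. What
it does not establish: robustness to batch effects, inter-individual
overdispersion beyond the NB model, cell-type misassignment, or
mismatch between pilot and study populations — none of which the
generative model emulates.

## Numerical choices

* EM for the censored mixture runs three deterministic initializations
  (positive means split at the 90th/80th/95th percentile; moment
  estimates per side) rather than random restarts, so fits are pure
  functions of their inputs; the generalized M-step accepts a numerical
  gamma update only when it improves the objective, keeping the
  likelihood monotone on any input.
* NB CDFs are evaluated through `pnbinom` (regularized incomplete
  beta), with a Poisson fallback below dispersion 1e-12; dispersions
  are clamped at 1e-8.
* The mixture quantile inverts the CDF on a 2,048-point log-spaced grid
  with four Newton polishing steps.
* The FDR bisection runs to interval exhaustion (~1e-13 on the log
  scale) so the returned threshold, not only the achieved FDR, is
  accurate; degenerate cases ($m_0 = 0$, all-zero power) return flagged
  results instead of roots.
* The Monte-Carlo DE oracle uses a Cox–Reid-adjusted profile dispersion
  in its NB Wald test: plain ML dispersion at 10 samples per group is
  biased low and inflates rejection by several points, which would
  miscalibrate the oracle itself.

## Known limitations

* The analytic DE power is asymptotic; at ~5 samples per group or
  pseudobulk means of ~2 it can deviate from any finite-sample NB Wald
  implementation by up to ~0.05 in either direction.
* The eQTL low-mean branch treats the rank-mapped pseudobulk mean as
  the lower-expressed genotype's mean; how pilot ranks map to
  genotype-conditional means is not identified by pilot bulk data.
* Cost constants are illustrative placeholders; users should supply
  their own `cost_model()`.
* Batch effects are handled only at fitting time (per-batch NB and
  mixture fits feeding the same depth curves); studies expecting strong
  batch structure should adjust via covariates in the eventual analysis,
  which this power model does not represent.
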