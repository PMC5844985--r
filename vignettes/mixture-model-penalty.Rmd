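---
title: "The spike-and-slab mixture penalty: model, optimizer and simulation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The spike-and-slab mixture penalty: model, optimizer and simulation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mixpen)
```

## The model

For $N$ individuals genotyped at $n$ SNPs, the phenotype vector $y$ follows
the standard polygenic linear model

$$ y = X\beta + \varepsilon, \qquad \varepsilon \sim N(0, \Sigma_\varepsilon), $$

where $X$ is the $N \times n$ dosage matrix (0/1/2 minor-allele counts,
column-standardized before fitting) and $\beta$ the per-SNP effect sizes.
Most SNPs are null; a small fraction are causal with appreciable effects.
The classical way to encode this belief is a spike-and-slab mixture prior on
each effect,

$$ \beta_j \sim \tilde\pi_{1j}\, p_{1j}(\beta_j) + (1 - \tilde\pi_{1j})\, p_{0j}(\beta_j), $$

with a diffuse "slab" $p_{1j}$ (here a zero-mean normal with standard
deviation `slab_sd`) for causal effects and a concentrated "spike" $p_{0j}$
(a narrow normal, or a Laplace density) for null ones. Rather than running
an MCMC over this prior, the package uses it *explicitly as a penalty*: the
objective minimized is

$$ F(\beta) = L(\beta) + w\,C(\beta), \qquad
   C(\beta) = \sum_j c_j(\beta_j) = -\sum_j \log\!\big[\tilde\pi_{1j} p_{1j}(\beta_j) + (1-\tilde\pi_{1j}) p_{0j}(\beta_j)\big], $$

where $L$ is the Gaussian negative log-likelihood with diagonal residual
covariance and $w$ (default 1, `weight` in `optimizer_config()`) balances
likelihood and penalty. Because $\tilde\pi_{1j}$ is per-SNP, any external
information — functional-annotation enrichment, posterior inclusion
probabilities from fine-mapping tools — plugs in directly as a prior
probability vector ([read_priors()], [enriched_priors()]).

Two limits recover familiar estimators: $\tilde\pi_{1j} = 1$ for all $j$
(all SNPs causal, normal effects) is the infinitesimal model, whose
penalized fit is exactly ridge regression; $\tilde\pi_{1j} \in (0,1)$ with a
narrow spike behaves like a probabilistic, soft best-subset penalty.
Alongside the mixture fit the package implements the comparison estimators:
per-SNP univariate regression, the generalized-ridge closed form
$\hat\beta = (X^\top\Sigma^{-1}X + D)^{-1}X^\top\Sigma^{-1}y$ (the
"regularized pseudo-inverse", equivalent to the all-slab mixture fit when
$D_{jj} = 1/(\pi_{1j}\sigma_{1j}^2)$), and the elastic net / LASSO by
coordinate descent on the unscaled objective
$\lVert X\beta - y\rVert^2 + \lambda\sum_j[\tfrac{1-\alpha}{2}\beta_j^2 + \alpha|\beta_j|]$
with two-fold cross-validated $\lambda$.

The per-SNP *responsibility*
$r_j = \tilde\pi_{1j} p_{1j}(\hat\beta_j)/m_j(\hat\beta_j)$ — the
posterior-style weight that SNP $j$'s fitted effect came from the slab —
is the default variant-selection statistic (`selected` is $r_j > 0.5$).

## Optimization

$F$ is minimized by nonlinear conjugate gradient (Polak–Ribière+ by
default; Fletcher–Reeves, Dai–Yuan and Hager–Zhang are available) with a
Newton–Raphson line search on $\phi(t) = F(\beta + t d)$. The curvature
$\phi''(t) = d^\top H d$ is obtained from a Hessian–vector product

$$ Hv = X^\top \Sigma_\varepsilon^{-1} (X v) + w\,(c'' \circ v), $$

two matrix–vector products plus an elementwise product, so the $n \times n$
Hessian is never materialized and the per-iteration cost is $O(Nn)$.
Because the spike makes $C$ non-convex, the line search is safeguarded:
whenever the local curvature is non-positive or a Newton step fails the
Armijo decrease test ($c_1 = 10^{-4}$), it falls back to backtracking
halving, which guarantees a non-increasing objective trace on every fit.
Inside `fit_mixture_model()` the likelihood part of $\phi$ is expanded as
an explicit quadratic in $t$ (one mat-vec per search direction), which is
mathematically identical to evaluating $F$ afresh but makes each Newton
step $O(N + n)$.

Numerical choices worth knowing:

* All mixture arithmetic is in log space (log-sum-exp); responsibilities
  come from the log-odds, so the penalty, gradient and curvature are finite
  for $|\beta|$ up to $10^3$ and $\tilde\pi_1$ down to $10^{-300}$, and
  $\tilde\pi_{1j} \in \{0, 1\}$ are handled exactly as single-component
  costs.
* The Laplace null's $|\beta|$ is smoothed to $\sqrt{\beta^2 +
  \varepsilon_s}$ ($\varepsilon_s = 10^{-8}$) so the objective stays twice
  differentiable — NCG's assumptions hold and no subgradient machinery is
  needed. Derivative oracles (finite differences) are invalid inside the
  smoothing region $|\beta| \lesssim \sqrt{\varepsilon_s}$; tests avoid it.
* The likelihood's normalizing constant uses the residual dimension $N$ in
  the $(2\pi)^{-\cdot/2}$ exponent. It is a constant in $\beta$ and does
  not affect the minimizer.
* Convergence: $\lVert g\rVert_\infty < 10^{-6}$ or relative objective
  decrease below $10^{-10}$, `max_iter = min(10n, 5000)`; restarts to
  steepest descent every $n$ iterations or whenever conjugacy degrades.
  Oracle-equivalence tests tighten these to $10^{-9}/10^{-15}$.
* Initialization is $\beta = 0$; a warm start can be supplied.
* Annealing (default): the null scale is multiplied by $\{10, 3.16, 1\}$
  across three stages, each warm-starting from the last — a homotopy from a
  near-ridge problem to the target spike that reduces the risk of poor
  local minima. Only local minimization is claimed; grid-search tests use
  instances whose landscape the oracle itself verifies.

## Prior specification and defaults

| parameter | default | meaning / rationale |
|---|---|---|
| `pi1` | 0.01 | prior causal probability per SNP; 0.01 is the constant-prior (MM-CP) headline configuration, matching ~1% causal SNPs in the simulation design |
| `slab_sd` | 1 | causal-effect scale, matching the $N(0,1)$ simulated effects |
| `null_family` | `laplace` | null (spike) family used in the headline results; a normal spike is available |
| `null_scale` | 0.05 | spike width. No value is stated in the reference design, so it was fixed once: well below the unit slab, comparable to the per-SNP sampling noise $\sqrt{\sigma^2_\varepsilon/N}\approx 0.07$ at the desk scale $N = 2000$, $h^2=0.5$ |
| `weight` | 1 | equal weighting of likelihood and penalty; lower it for strongly polygenic traits |
| threshold | 0.5 | responsibility cut for calling a variant causal |

Configurations by name: **MM-CP** `constant_priors(g, 0.01)` (Laplace
null); **MM-EP** `enriched_priors(g, ann, 0.5)` — enriched-category SNPs at
the true causal share, others at 0; **MM-DAP-style** `read_priors()` on any
per-variant probability table; **infinitesimal** `infinitesimal_priors(g)`.
In benchmarks MM-EP and MM-CP share the same null family by default so the
contrast isolates the prior probabilities.

## What the simulator emulates — and what it does not

`simulate_gwas()` replaces resampling-based genotype simulation from
reference haplotypes with a parametric emulator: per-SNP MAF uniform in
`maf_range` (default $(0.01, 0.5]$, i.e. already MAF-filtered), two
haplotypes per sample generated by thresholding a latent Gaussian AR(1)
chain along each chromosome (`ld_rho`, default 0.5) — a Gaussian copula
giving exact marginal frequencies and local LD. Causal variants are
concentrated in enriched annotation categories (Exon/3'UTR/5'UTR;
`enriched_fraction` default 0.02 of SNPs) with `causal_param` (default 0.5)
of the enriched class causal, hence ~1% of all SNPs causal, with effects
$N(0,1)$. Phenotypes are built by the linear model at `heritability` 0.5;
the noise variance is calibrated against the *realized* genetic variance,
so the in-sample heritability is tight even at moderate $N$. The default
desk scale ($N = 2000$, $n = 2000$ over 4 pseudo-chromosomes) mirrors the
reference design's ratios at roughly 1/100 size. `ld_rho = 0.5` was chosen
once as a realistic mid-range adjacent-SNP correlation for common variants
within a locus.

Not emulated: recombination-map-aware LD structure, population
stratification and relatedness, allele-frequency/effect-size coupling,
case-control liability traits, and genome-scale $n$. Columns that come out
monomorphic in the finite sample are redrawn independently (the stated
design conditions on polymorphic SNPs), which slightly breaks the LD chain
at those columns. Consequently a green benchmark here establishes
*orderings and trends* among methods under clean polygenic architecture —
not the absolute correlation/PPV/NPV levels reported on
reference-panel-based simulations, which depend on data not shipped with
this package.

Window handling follows the per-chromosome design: each chromosome is one
window, the total heritability budget is split evenly (`0.5/22` $\approx$
`0.0227` per window in the genome-wide design), each window is fitted
independently with residual variance $(1 - h^2_w)\,\mathrm{Var}(y)$.
Standardization is per column, so per-window and genome-wide
standardization coincide.

## Design choices where the design was open

* **Detection rules.** No selection rule is stated for the reference
  PPV/NPV results. Defaults here: responsibility $> 0.5$ for mixture fits,
  nonzero support for the LASSO, Bonferroni-corrected $|z|$ for univariate,
  all recorded in benchmark output.
* **NMSE.** Defined on effect sizes in benchmark rows; the λ
  cross-validation separately uses held-out *phenotype* NMSE
  $\lVert y - X\hat\beta\rVert^2/\lVert y\rVert^2$. Both appear because the
  term is ambiguous in the source material.
* **Elastic-net scaling.** The objective is implemented exactly as printed,
  with an unscaled residual sum of squares; relative to the common
  $1/(2N)$ parameterization, $\lambda$ here is $2N\lambda_{\text{glmnet}}$.
  The printed constraint $0 < \alpha \le 1$ contradicts the accompanying
  text, which names $\alpha = 0$ as ridge; $\alpha = 0$ is allowed.
* **CV ties** break toward the larger (sparser) $\lambda$.
* **Missing genotypes** are mean-imputed per column with a logged count.
* **Windows** are non-overlapping per-chromosome blocks; the "sliding"
  phrasing in the source reduces to this under one-window-per-chromosome.

## Limitations

Non-convexity means convergence is to a local minimum; annealing mitigates
but does not remove this. The diagonal residual covariance ignores sample
relatedness. Windows are fitted independently, so cross-window LD leakage
is not modeled. The Laplace-null smoothing constant trades a tiny bias near
zero for smoothness. PPV/NPV at desk scale frequently saturate at 1, so
method contrasts there lean on NPV and correlation.
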