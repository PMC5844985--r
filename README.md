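# mixpen

Multivariate regression for GWAS-style data in which a spike-and-slab
mixture prior on SNP effect sizes is used **explicitly as a penalty**. The
package is for statistical geneticists who want fine-mapping-aware effect
size estimation: per-SNP prior causal probabilities — constant,
annotation-enrichment based, or imported from fine-mapping tools (DAP,
CAVIAR, PAINTOR, ...) — flow directly into a penalized multivariate fit,
without MCMC.

## The model

With phenotype $y$ ($N$ samples), standardized dosage matrix $X$
($N \times n$) and effects $\beta$,

$$ y = X\beta + \varepsilon,\qquad \varepsilon \sim N(0, \Sigma_\varepsilon), $$

the estimate minimizes $F = L + C$, where $L$ is the Gaussian negative
log-likelihood and

$$ C = -\sum_{j=1}^n \log\left[\tilde\pi_{1j}\,p_{1j}(\beta_j) + (1-\tilde\pi_{1j})\,p_{0j}(\beta_j)\right] $$

penalizes each effect by minus the log of its spike-and-slab mixture prior:
a diffuse normal slab $p_{1j}$ for causal effects, a narrow spike $p_{0j}$
(normal or Laplace) for null ones, and $\tilde\pi_{1j}$ the prior
probability that SNP $j$ is causal. $F$ is minimized by nonlinear
conjugate gradient with a Hessian-free Newton–Raphson line search
($\phi'' = d^\top H d$ via $Hv = X^\top\Sigma^{-1}Xv + c''\circ v$; the
$n\times n$ Hessian is never formed). Per-SNP *responsibilities*
$r_j = \tilde\pi_{1j}p_{1j}/m_j$ at the optimum drive variant selection.
Setting $\tilde\pi_{1j}=1$ recovers ridge regression (the infinitesimal
model). Baselines included: univariate regression, generalized-ridge
closed form (RegPI), coordinate-descent elastic net / LASSO with
cross-validated $\lambda$, plus a genotype/phenotype simulator and
PPV/NPV benchmarking.

## Worked example

Simulate a 2000-sample, 500-SNP panel where 4% of SNPs are in enriched
annotation categories, half of those (10 SNPs) are causal with $N(0,1)$
effects, and heritability is 0.5; then fit the constant-prior mixture
(`pi1 = 0.01`, Laplace null):

```r
library(mixpen)
library(dplyr)

sim <- simulate_gwas(sim_config(n_samples = 2000, n_snps = 500,
                                n_chromosomes = 1, enriched_fraction = 0.04,
                                causal_param = 0.5, heritability = 0.5,
                                seed = 42))
fit <- fit_mixture_model(sim$genotypes_std, sim$phenotype,
                         constant_priors(sim$genotypes_std, pi1 = 0.01),
                         sim$noise)
glance(fit)
#> # A tibble: 1 × 7
#>   n_windows n_snps objective n_iter converged max_grad_norm n_selected
#>       <int>  <int>     <dbl>  <int> <lgl>             <dbl>      <int>
#> 1         1    500     3945.    207 TRUE             0.0758          7

tidy(fit) |> filter(selected) |> left_join(sim$truth, by = "variant_id") |>
  select(variant_id, beta_hat, responsibility, beta_true, causal)
#> # A tibble: 7 × 5
#>   variant_id beta_hat responsibility beta_true causal
#>   <chr>         <dbl>          <dbl>     <dbl> <lgl>
#> 1 1:snp00149    0.497          0.881     0.424 TRUE
#> 2 1:snp00196    1.21           1.000     1.22  TRUE
#> 3 1:snp00216   -1.80           1.000    -1.84  TRUE
#> 4 1:snp00225   -0.616          0.987    -0.708 TRUE
#> 5 1:snp00311   -1.28           1.000    -1.29  TRUE
#> 6 1:snp00440   -1.05           1.000    -1.18  TRUE
#> 7 1:snp00470    0.624          0.989     0.536 TRUE

effect_metrics(tidy(fit)$beta_hat, sim$truth$beta_true)
#> # A tibble: 1 × 3
#>   correlation correlation_defined   nmse
#>         <dbl> <lgl>                <dbl>
#> 1       0.990 TRUE                0.0200

ppv_npv(tidy(fit)$selected, sim$truth)
#> # A tibble: 1 × 8
#>     ppv   npv ppv_defined npv_defined    tp    fp    tn    fn
#>   <dbl> <dbl> <lgl>       <lgl>       <int> <int> <int> <int>
#> 1     1 0.994 TRUE        TRUE            7     0   490     3
```

All seven selected variants are truly causal (PPV 1), their estimates track
the true effects closely (correlation 0.99, NMSE 0.02), and three weak
causal SNPs are missed (NPV 0.994). A univariate scan on the same data
reaches correlation ≈ 0.78: multivariate fitting with the mixture penalty
resolves LD that marginal tests cannot.

External priors slot in the same way:

```r
pr  <- read_priors("dap_scores.tsv", sim$genotypes_std, default_pi1 = 0.01)
fit <- fit_mixture_model(sim$genotypes_std, sim$phenotype, pr, sim$noise)
```

and `benchmark_compare()` + `autoplot()` reproduce multi-method
correlation/PPV/NPV comparisons over seeded replicates.

## Command line

A thin CLI over the same functions lives at `inst/cli/mixpen.R`:

```sh
Rscript inst/cli/mixpen.R simulate --out sim/ --n-samples 2000 --n-snps 500 --seed 7
Rscript inst/cli/mixpen.R fit --genotypes sim/genotypes.tsv \
    --phenotype sim/phenotype.tsv --method mmp --pi1 0.01 --null laplace --out fit/
Rscript inst/cli/mixpen.R evaluate --estimates fit/estimates.tsv \
    --truth sim/truth.tsv --out eval/
```

Every run writes a `manifest.json` sufficient to reproduce it
bit-identically.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

re-runs the package's main computation from scratch against the installed
package: it simulates seeded desk-scale replicates of the enrichment
design, fits the enriched-prior and constant-prior mixture configurations
alongside the LASSO and univariate baselines, logs their mean effect-size
correlation, NMSE, PPV and NPV, and writes the machine-readable report to
`--out`.
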