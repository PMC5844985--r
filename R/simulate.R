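#' Simulation scenario configuration
#'
#' Desk-scale emulation of a Hapgen2-style genotype/phenotype design:
#' uniform MAF spectrum, local LD through a latent Gaussian first-order
#' chain on haplotypes, causal variants concentrated in enriched
#' functional-annotation categories (exon and UTRs), causal effects drawn
#' `N(0, effect_sd^2)`, and phenotype noise calibrated to a target
#' heritability. The defaults mirror the reference design's ratios at
#' desk scale: about 1% of SNPs causal, arising as 50% of a 2% enriched
#' class, heritability 0.5.
#'
#' @param n_samples,n_snps,n_chromosomes Dimensions of the genotype panel.
#' @param maf_range Minor-allele-frequency range; variants are drawn
#'   uniformly within it (default `(0.01, 0.5]`, matching a MAF > 0.01
#'   inclusion filter).
#' @param ld_rho Latent adjacent-haplotype correlation in `[0, 1)`;
#'   0 gives independent SNPs.
#' @param enriched_fraction Fraction of SNPs in enriched categories.
#' @param causal_rule `"fraction_of_enriched"` (causal SNPs are a
#'   `causal_param` share of the enriched class) or `"global_fraction"`
#'   (a `causal_param` share of all SNPs).
#' @param causal_param Share used by `causal_rule`.
#' @param effect_sd Standard deviation of causal effects.
#' @param heritability Target `Var(X beta) / Var(y)` in `[0, 1]`.
#' @param seed Integer seed; the whole scenario is reproducible from it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_samples = 2000L, n_snps = 2000L, n_chromosomes = 4L,
                       maf_range = c(0.01, 0.5), ld_rho = 0.5,
                       enriched_fraction = 0.02,
                       causal_rule = c("fraction_of_enriched", "global_fraction"),
                       causal_param = 0.5, effect_sd = 1,
                       heritability = 0.5, seed = 1L) {
  causal_rule <- match.arg(causal_rule)
  stopifnot(
    n_samples >= 2L, n_snps >= 1L, n_chromosomes >= 1L,
    length(maf_range) == 2L, maf_range[1] > 0, maf_range[2] <= 0.5,
    maf_range[1] <= maf_range[2],
    ld_rho >= 0, ld_rho < 1,
    enriched_fraction >= 0, enriched_fraction <= 1,
    causal_param >= 0, causal_param <= 1,
    effect_sd > 0, heritability >= 0, heritability <= 1
  )
  structure(
    list(n_samples = as.integer(n_samples), n_snps = as.integer(n_snps),
         n_chromosomes = as.integer(n_chromosomes), maf_range = maf_range,
         ld_rho = ld_rho, enriched_fraction = enriched_fraction,
         causal_rule = causal_rule, causal_param = causal_param,
         effect_sd = effect_sd, heritability = heritability,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Simulate genotype dosages
#'
#' Each SNP gets a MAF drawn uniformly in `maf_range`. The two haplotypes
#' of every sample are generated along each chromosome by thresholding a
#' latent Gaussian AR(1) chain with parameter `ld_rho` (a Gaussian-copula
#' construction), so adjacent SNPs are correlated while marginal allele
#' frequencies are exact. Dosage is the haplotype sum in `{0, 1, 2}`.
#' Columns that come out monomorphic in the finite sample are redrawn with
#' independent alleles (the design conditions on polymorphic SNPs).
#'
#' @param config A [sim_config()].
#' @return A raw [geno_matrix()] with chromosome labels and MAFs.
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_snps < config$n_chromosomes) {
    stop("need at least one SNP per chromosome", call. = FALSE)
  }
  with_local_seed(config$seed, {
    N <- config$n_samples
    n <- config$n_snps
    maf <- stats::runif(n, config$maf_range[1], config$maf_range[2])
    chrom <- sort(rep_len(seq_len(config$n_chromosomes), n))
    dos <- matrix(0, N, n)
    rho <- config$ld_rho
    for (ch in seq_len(config$n_chromosomes)) {
      idx <- which(chrom == ch)
      nc <- length(idx)
      hap_sum <- matrix(0L, N, nc)
      for (h in 1:2) {
        z <- matrix(stats::rnorm(N * nc), N, nc)
        if (rho > 0 && nc > 1L) {
          for (j in 2:nc) z[, j] <- rho * z[, j - 1] + sqrt(1 - rho^2) * z[, j]
        }
        thr <- stats::qnorm(maf[idx])
        hap_sum <- hap_sum + (sweep(z, 2L, thr, "<") * 1L)
      }
      dos[, idx] <- hap_sum
    }
    # condition on polymorphism: redraw degenerate columns independently
    for (j in which(apply(dos, 2L, stats::var) == 0)) {
      repeat {
        col <- stats::rbinom(N, 2L, maf[j])
        if (stats::var(col) > 0) break
      }
      dos[, j] <- col
    }
    rownames(dos) <- sprintf("s%05d", seq_len(N))
    geno_matrix(
      dosages = dos,
      variant_ids = sprintf("%d:snp%05d", chrom, seq_len(n)),
      chromosome = as.character(chrom),
      maf = maf
    )
  })
}

#' Simulate annotations, causal assignment and true effect sizes
#'
#' An `enriched_fraction` share of SNPs is labelled with enriched
#' categories (Exon/UTR3/UTR5, assigned at random); the rest are
#' Intron/Intergenic. Under the `fraction_of_enriched` rule a
#' `causal_param` share of the enriched SNPs is causal (drawn uniformly);
#' causal effects are independent `N(0, effect_sd^2)` and null effects are
#' exactly zero.
#'
#' @param g A [geno_matrix()].
#' @param config A [sim_config()].
#' @return A `sim_truth` tibble with columns `variant_id`, `beta_true`,
#'   `causal`, `category`, `enriched`.
#' @export
simulate_effects <- function(g, config) {
  stopifnot(inherits(g, "geno_matrix"), inherits(config, "sim_config"))
  n <- ncol(g$dosages)
  with_local_seed(config$seed + 1L, {
    n_enr <- round(config$enriched_fraction * n)
    enr_idx <- if (n_enr > 0) sample(n, n_enr) else integer()
    category <- sample(c("Intron", "Intergenic"), n, replace = TRUE)
    if (n_enr > 0) {
      category[enr_idx] <- sample(enriched_categories(), n_enr, replace = TRUE)
    }
    if (config$causal_rule == "fraction_of_enriched") {
      if (n_enr == 0 && config$causal_param > 0) {
        stop("no enriched SNPs to draw causal variants from", call. = FALSE)
      }
      n_causal <- round(config$causal_param * n_enr)
      causal_idx <- if (n_causal > 0) sample(enr_idx, n_causal) else integer()
    } else {
      n_causal <- round(config$causal_param * n)
      causal_idx <- if (n_causal > 0) sample(n, n_causal) else integer()
    }
    beta <- numeric(n)
    beta[causal_idx] <- stats::rnorm(length(causal_idx), 0, config$effect_sd)
    # a causal SNP must carry a nonzero effect, exactly
    while (any(beta[causal_idx] == 0)) {
      zero <- causal_idx[beta[causal_idx] == 0]
      beta[zero] <- stats::rnorm(length(zero), 0, config$effect_sd)
    }
    out <- tibble::tibble(
      variant_id = g$variants$variant_id,
      beta_true = beta,
      causal = beta != 0,
      category = category,
      enriched = category %in% enriched_categories()
    )
    class(out) <- c("sim_truth", class(out))
    out
  })
}

#' Simulate a phenotype at a target heritability
#'
#' Builds the genetic value `u = X beta_true` on standardized genotypes
#' and adds i.i.d. normal noise with variance `Var(u) (1 - h2) / h2`, so
#' the realized in-sample heritability `Var(u) / Var(y)` is tightly
#' controlled even at modest sample sizes. `h2 = 1` gives `y = u` exactly;
#' `h2 = 0` requires an all-null truth and yields pure `N(0, 1)` noise.
#'
#' @param g A standardized [geno_matrix()].
#' @param truth A `sim_truth` from [simulate_effects()].
#' @param config A [sim_config()].
#' @return Tibble with `sample_id`, `value`; attribute `realized_h2`.
#' @export
simulate_phenotype <- function(g, truth, config) {
  stopifnot(inherits(g, "geno_matrix"), inherits(config, "sim_config"))
  if (!g$standardized) stop("standardize genotypes before simulating phenotypes",
                            call. = FALSE)
  h2 <- config$heritability
  u <- unname(drop(g$dosages %*% truth$beta_true))
  with_local_seed(config$seed + 2L, {
    N <- nrow(g$dosages)
    if (all(truth$beta_true == 0)) {
      if (h2 > 0) stop("heritability undefined: all true effects are zero", call. = FALSE)
      y <- stats::rnorm(N)
    } else if (h2 == 1) {
      y <- u
    } else {
      if (h2 == 0) stop("h2 = 0 with nonzero effects is contradictory", call. = FALSE)
      noise_var <- stats::var(u) * (1 - h2) / h2
      y <- u + stats::rnorm(N, 0, sqrt(noise_var))
    }
    out <- tibble::tibble(
      sample_id = rownames(g$dosages) %||% sprintf("s%05d", seq_len(N)),
      value = y
    )
    attr(out, "realized_h2") <- if (stats::var(y) > 0) stats::var(u) / stats::var(y) else NA_real_
    out
  })
}

#' Run the full simulation pipeline
#'
#' Convenience wrapper: genotypes, effects, standardization, phenotype and
#' per-chromosome windows from one scenario config.
#'
#' @param config A [sim_config()].
#' @param total_h2 Heritability budget passed to [make_windows()]
#'   (defaults to the scenario heritability).
#' @return List with `genotypes` (raw), `genotypes_std` (standardized,
#'   windowed), `phenotype`, `truth` (with `realized_h2` attribute copied
#'   on), `noise` and `annotations`.
#' @export
simulate_gwas <- function(config = sim_config(), total_h2 = config$heritability) {
  g <- simulate_genotypes(config)
  truth <- simulate_effects(g, config)
  gs <- standardize_genotypes(g)
  y <- simulate_phenotype(gs, truth, config)
  win <- make_windows(gs, "per_chromosome", total_h2 = total_h2)
  attr(truth, "realized_h2") <- attr(y, "realized_h2")
  list(
    genotypes = g,
    genotypes_std = win$genotypes,
    phenotype = y,
    truth = truth,
    noise = win$noise,
    annotations = truth[c("variant_id", "category", "enriched")]
  )
}

#' Write a simulated scenario to TSV fixtures
#'
#' @param sim Output of [simulate_gwas()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly; writes `genotypes.tsv`, `phenotype.tsv`,
#'   `truth.tsv`, `annotations.tsv`.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_genotypes(sim$genotypes, file.path(dir, "genotypes.tsv"))
  write_phenotype(sim$phenotype, file.path(dir, "phenotype.tsv"))
  readr::write_tsv(sim$truth, file.path(dir, "truth.tsv"), progress = FALSE)
  readr::write_tsv(sim$annotations, file.path(dir, "annotations.tsv"), progress = FALSE)
  invisible(dir)
}
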