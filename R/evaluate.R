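#' Classify variants as selected (putatively causal)
#'
#' Detection rules: `"responsibility"` selects SNPs whose causal-component
#' responsibility exceeds a threshold (default 0.5, the natural posterior
#' cut for mixture fits); `"magnitude"` selects SNPs with `|beta_hat|`
#' above a threshold — with threshold 0 this is nonzero-support selection,
#' the natural rule for exactly sparse estimators such as the LASSO.
#'
#' @param beta_hat Estimated effects.
#' @param responsibilities Per-SNP causal responsibilities (required for
#'   the responsibility rule).
#' @param rule `"responsibility"` or `"magnitude"`.
#' @param threshold Cut point; in `(0, 1)` for responsibilities, `>= 0`
#'   for magnitudes.
#' @return Logical vector of selections.
#' @export
classify_variants <- function(beta_hat, responsibilities = NULL,
                              rule = c("responsibility", "magnitude"),
                              threshold = if (rule[1] == "responsibility") 0.5 else 0) {
  rule <- match.arg(rule)
  if (rule == "responsibility") {
    if (is.null(responsibilities)) {
      stop("responsibility rule needs responsibilities", call. = FALSE)
    }
    if (threshold <= 0 || threshold >= 1) {
      stop("responsibility threshold must lie in (0, 1)", call. = FALSE)
    }
    responsibilities > threshold
  } else {
    if (threshold < 0) stop("magnitude threshold must be >= 0", call. = FALSE)
    abs(beta_hat) > threshold
  }
}

#' Positive and negative predictive value of a variant selection
#'
#' PPV is the share of selected variants that are truly causal; NPV is the
#' share of unselected variants that are truly null. A predictive value
#' whose denominator is empty is returned as `NA` with its `*_defined`
#' flag set to `FALSE` (never silently propagated).
#'
#' @param selected Logical selection vector.
#' @param truth Logical causal-indicator vector, or a `sim_truth` tibble.
#' @return Tibble with `ppv`, `npv`, `ppv_defined`, `npv_defined`, and the
#'   confusion counts `tp`, `fp`, `tn`, `fn`.
#' @export
ppv_npv <- function(selected, truth) {
  causal <- if (is.data.frame(truth)) truth$causal else as.logical(truth)
  stopifnot(length(selected) == length(causal))
  tp <- sum(selected & causal)
  fp <- sum(selected & !causal)
  fn <- sum(!selected & causal)
  tn <- sum(!selected & !causal)
  tibble::tibble(
    ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_,
    ppv_defined = tp + fp > 0,
    npv_defined = tn + fn > 0,
    tp = tp, fp = fp, tn = tn, fn = fn
  )
}

#' Effect-size accuracy metrics
#'
#' Pearson correlation between estimated and true effects (scale- and
#' shift-invariant, so it rewards correct ordering even when magnitudes
#' are shrunken, as under the infinitesimal model) and normalized mean
#' squared error `||beta_hat - beta_true||^2 / ||beta_true||^2` (which is
#' not).
#'
#' @param beta_hat,beta_true Effect vectors of equal length.
#' @return Tibble with `correlation` (NA with `correlation_defined =
#'   FALSE` when `beta_hat` has zero variance) and `nmse`.
#' @export
effect_metrics <- function(beta_hat, beta_true) {
  stopifnot(length(beta_hat) == length(beta_true))
  if (all(beta_true == 0)) stop("nmse undefined: beta_true is all zero", call. = FALSE)
  defined <- stats::sd(beta_hat) > 0
  tibble::tibble(
    correlation = if (defined) stats::cor(beta_hat, beta_true) else NA_real_,
    correlation_defined = defined,
    nmse = sum((beta_hat - beta_true)^2) / sum(beta_true^2)
  )
}

#' Method specification for benchmarking
#'
#' @param method One of `"mmp"`, `"lasso"`, `"ridge"`, `"regpi"`,
#'   `"univariate"`, `"infinitesimal"`.
#' @param label Row label (defaults to `method`).
#' @param ... Method options: `pi1`, `slab_sd`, `null_family`,
#'   `null_scale`, `prior` (`"constant"` or `"enriched"`), `lambda`,
#'   `alpha`, `ridge_precision`, `z_threshold`, `config` (an
#'   [optimizer_config()]).
#' @return A `method_spec` list.
#' @export
method_spec <- function(method = c("mmp", "lasso", "ridge", "regpi",
                                   "univariate", "infinitesimal"),
                        label = NULL, ...) {
  method <- match.arg(method)
  structure(list(method = method, label = label %||% method, opts = list(...)),
            class = "method_spec")
}

# fit one method on one simulated replicate; returns beta_hat + selection
run_method <- function(spec, sim) {
  g <- sim$genotypes_std
  y <- sim$phenotype$value
  opts <- spec$opts
  n <- ncol(g$dosages)
  sigma2_flat <- (1 - sim$noise$h2_per_window) * stats::var(y)
  switch(spec$method,
    mmp = {
      prior <- if (identical(opts$prior, "enriched")) {
        # same null family as the constant-prior configuration by default, so
        # benchmark contrasts isolate the prior probabilities
        enriched_priors(g, sim$annotations,
                        pi1_enriched = opts$pi1 %||% 0.5,
                        pi1_background = opts$pi1_background %||% 0,
                        null_family = opts$null_family %||% "laplace",
                        null_scale = opts$null_scale %||% 0.05)
      } else {
        constant_priors(g, pi1 = opts$pi1 %||% 0.01,
                        null_family = opts$null_family %||% "laplace",
                        null_scale = opts$null_scale %||% 0.05)
      }
      cfg <- opts$config %||% optimizer_config()
      fit <- fit_mixture_model(g, y, prior, sim$noise, cfg)
      est <- tidy(fit)
      list(beta_hat = est$beta_hat,
           selected = classify_variants(est$beta_hat, est$responsibility,
                                        "responsibility",
                                        opts$threshold %||% 0.5),
           sparsity_param = mean(prior$pi1))
    },
    infinitesimal = {
      fit <- fit_mixture_model(g, y, infinitesimal_priors(g, opts$slab_sd %||% 1),
                               sim$noise, opts$config %||% optimizer_config())
      est <- tidy(fit)
      list(beta_hat = est$beta_hat,
           selected = rep(TRUE, n),  # every SNP is causal under this prior
           sparsity_param = 1)
    },
    lasso = {
      lam <- opts$lambda
      if (is.null(lam)) {
        # standard practice: 2-fold CV over a log grid below the smallest
        # lambda that zeroes every coefficient (lambda_max = 2 max|X'y|)
        lam_max <- 2 * max(abs(crossprod(g$dosages, y)))
        grid <- exp(seq(log(1e-3 * lam_max), log(lam_max), length.out = 8))
        lam <- cv_select_lambda(g, y, lambda_grid = grid, folds = 2L,
                                seed = 1L)$best_lambda
      }
      fit <- elastic_net_cd(g, y, lambda = lam, alpha = 1)
      list(beta_hat = fit$estimate,
           selected = classify_variants(fit$estimate, rule = "magnitude",
                                        threshold = 0),
           sparsity_param = lam)
    },
    ridge = {
      prec <- opts$ridge_precision %||% (sigma2_flat / (opts$slab_sd %||% 1)^2)
      fit <- regpi_closed_form(g, y, sigma2 = sigma2_flat, prior_precision = prec)
      list(beta_hat = fit$estimate, selected = rep(TRUE, n), sparsity_param = prec)
    },
    regpi = {
      # per-SNP precision 1 / (pi1_j slab_sd_j^2) from the enrichment truth
      pi1 <- ifelse(sim$annotations$enriched, opts$pi1 %||% 0.5,
                    opts$pi1_background %||% 1e-4)
      prec <- sigma2_flat / (pi1 * (opts$slab_sd %||% 1)^2)
      fit <- regpi_closed_form(g, y, sigma2 = sigma2_flat, prior_precision = prec)
      list(beta_hat = fit$estimate,
           selected = abs(fit$estimate) > (opts$threshold %||% 0.05),
           sparsity_param = NA_real_)
    },
    univariate = {
      fit <- univariate_regression(g, y)
      zthr <- opts$z_threshold %||% stats::qnorm(1 - 0.025 / n)  # Bonferroni 5%
      list(beta_hat = fit$estimate,
           selected = abs(fit$statistic) > zthr,
           sparsity_param = zthr)
    }
  )
}

#' Multi-method benchmark over simulated replicates
#'
#' For each replicate: simulate one dataset, fit every method on the same
#' data, and record effect-size correlation, NMSE, PPV, NPV and the
#' selection count. Sweeping a sparsity parameter (`pi1` for the mixture,
#' `lambda` for the LASSO) across method specs reproduces the
#' dense-to-sparse trade-off curves.
#'
#' @param scenario A [sim_config()]; its seed is replaced per replicate.
#' @param methods List of [method_spec()]s.
#' @param n_replicates Number of simulated datasets.
#' @param seeds Integer seeds, one per replicate.
#' @return A tibble of class `mixpen_benchmark`: one row per
#'   (replicate, method) with columns `method`, `seed`, `sparsity_param`,
#'   `correlation`, `nmse`, `ppv`, `npv`, `n_selected`, `runtime_s`,
#'   `failed`. A method failure flags the row and the run continues.
#' @export
benchmark_compare <- function(scenario, methods, n_replicates = 1L,
                              seeds = seq_len(n_replicates)) {
  stopifnot(length(methods) >= 1L, length(seeds) == n_replicates)
  rows <- purrr::map(seq_len(n_replicates), function(r) {
    cfg <- scenario
    cfg$seed <- as.integer(seeds[r])
    sim <- simulate_gwas(cfg)
    purrr::map(methods, function(spec) {
      t0 <- proc.time()[["elapsed"]]
      res <- tryCatch(run_method(spec, sim), error = function(e) e)
      dt <- proc.time()[["elapsed"]] - t0
      if (inherits(res, "error")) {
        return(tibble::tibble(
          method = spec$label, seed = seeds[r], sparsity_param = NA_real_,
          correlation = NA_real_, nmse = NA_real_, ppv = NA_real_,
          npv = NA_real_, n_selected = NA_integer_, runtime_s = dt,
          failed = TRUE
        ))
      }
      em <- effect_metrics(res$beta_hat, sim$truth$beta_true)
      pv <- ppv_npv(res$selected, sim$truth)
      tibble::tibble(
        method = spec$label, seed = seeds[r],
        sparsity_param = res$sparsity_param,
        correlation = em$correlation, nmse = em$nmse,
        ppv = pv$ppv, npv = pv$npv,
        n_selected = sum(res$selected), runtime_s = dt, failed = FALSE
      )
    }) |> purrr::list_rbind()
  }) |> purrr::list_rbind()
  class(rows) <- c("mixpen_benchmark", class(rows))
  rows
}

#' Write benchmark rows as tidy TSV
#'
#' Undefined metrics are serialized as the sentinel string `"undefined"`
#' rather than blanks.
#'
#' @param bench A `mixpen_benchmark` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_benchmark <- function(bench, path) {
  out <- dplyr::mutate(
    bench,
    dplyr::across(c("correlation", "nmse", "ppv", "npv"),
                  \(x) ifelse(is.na(x), "undefined", format(x, digits = 10)))
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
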