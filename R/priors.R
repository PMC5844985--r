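#' Per-SNP spike-and-slab prior specification
#'
#' The mixture prior on each effect size is
#' `pi1[j] * N(0, slab_sd[j]^2) + (1 - pi1[j]) * p0`, where the null
#' component `p0` is either a narrow normal spike with standard deviation
#' `null_scale` or a Laplace density with scale `null_scale`. Minus the log
#' of this mixture is the per-SNP penalty added to the negative
#' log-likelihood.
#'
#' @param pi1 Numeric vector (or scalar, recycled) of prior causal
#'   probabilities in `[0, 1]`.
#' @param slab_sd Slab standard deviation(s), positive.
#' @param null_family `"normal_spike"` or `"laplace"`.
#' @param null_scale Null-component scale: sd of the spike, or the Laplace
#'   scale `b`. Default 0.05, narrow relative to the unit slab.
#' @param smoothing_eps Smoothing constant for the Laplace `|beta|`
#'   (replaced by `sqrt(beta^2 + smoothing_eps)` so the penalty stays twice
#'   differentiable). Default `1e-8`.
#' @param variant_id Optional variant IDs carried through to fit output.
#' @param n Length when `pi1`/`slab_sd` are scalars.
#' @return An object of class `prior_spec`.
#' @export
prior_spec <- function(pi1 = 0.01, slab_sd = 1,
                       null_family = c("laplace", "normal_spike"),
                       null_scale = 0.05, smoothing_eps = 1e-8,
                       variant_id = NULL, n = NULL) {
  null_family <- match.arg(null_family)
  if (is.null(n)) n <- max(length(pi1), length(slab_sd), length(variant_id))
  pi1 <- rep_len(as.numeric(pi1), n)
  slab_sd <- rep_len(as.numeric(slab_sd), n)
  if (any(pi1 < 0 | pi1 > 1)) stop("pi1 must lie in [0, 1]", call. = FALSE)
  if (any(slab_sd <= 0) || null_scale <= 0) stop("scales must be > 0", call. = FALSE)
  if (smoothing_eps < 0) stop("smoothing_eps must be >= 0", call. = FALSE)
  structure(
    list(pi1 = pi1, slab_sd = slab_sd, null_family = null_family,
         null_scale = null_scale, smoothing_eps = smoothing_eps,
         variant_id = variant_id),
    class = "prior_spec"
  )
}

#' @export
print.prior_spec <- function(x, ...) {
  cat(sprintf(
    "<prior_spec> %d SNPs, pi1 in [%.3g, %.3g], slab sd %.3g, %s null (scale %.3g)\n",
    length(x$pi1), min(x$pi1), max(x$pi1), x$slab_sd[1], x$null_family, x$null_scale
  ))
  invisible(x)
}

#' Constant-prior (MM-CP) specification
#'
#' Every SNP receives the same prior causal probability; the headline
#' configuration uses `pi1 = 0.01` with a Laplace null.
#'
#' @inheritParams prior_spec
#' @param g A [geno_matrix()] giving the SNP set.
#' @return A [prior_spec()].
#' @export
constant_priors <- function(g, pi1 = 0.01, slab_sd = 1, ...) {
  prior_spec(pi1 = pi1, slab_sd = slab_sd,
             variant_id = g$variants$variant_id,
             n = ncol(g$dosages), ...)
}

#' Enrichment-informed (MM-EP) specification
#'
#' SNPs in enriched annotation categories (exon and UTRs by default) get
#' an elevated prior causal probability; everything else gets a background
#' value. Setting `pi1_enriched` to the true causal share of the enriched
#' class reproduces the "priors equal truth" upper-bound configuration.
#'
#' @param g A [geno_matrix()].
#' @param annotations Tibble with `variant_id` and `enriched` (see
#'   [read_annotations()]).
#' @param pi1_enriched Prior causal probability for enriched SNPs.
#' @param pi1_background Probability for the rest (default 0).
#' @inheritParams prior_spec
#' @return A [prior_spec()].
#' @export
enriched_priors <- function(g, annotations, pi1_enriched = 0.5,
                            pi1_background = 0, slab_sd = 1, ...) {
  ann <- dplyr::left_join(g$variants["variant_id"],
                          annotations[c("variant_id", "enriched")],
                          by = "variant_id")
  enr <- dplyr::coalesce(ann$enriched, FALSE)
  prior_spec(pi1 = ifelse(enr, pi1_enriched, pi1_background),
             slab_sd = slab_sd, variant_id = g$variants$variant_id, ...)
}

#' Infinitesimal specification
#'
#' `pi1 = 1` for every SNP: all effects are drawn from the normal slab, so
#' the penalized fit coincides with ridge regression (generalized ridge
#' when `slab_sd` varies by SNP).
#'
#' @param g A [geno_matrix()].
#' @param slab_sd Slab standard deviation.
#' @return A [prior_spec()].
#' @export
infinitesimal_priors <- function(g, slab_sd = 1) {
  prior_spec(pi1 = 1, slab_sd = slab_sd, null_family = "normal_spike",
             variant_id = g$variants$variant_id, n = ncol(g$dosages))
}
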