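#' Mixture-component density
#'
#' Density of a single prior component at effect size `beta_j`: a
#' zero-mean normal with standard deviation `scale`, or a Laplace with
#' scale `b = scale` whose `|beta|` is smoothed to
#' `sqrt(beta^2 + smoothing_eps)` so the penalty remains differentiable.
#'
#' @param beta_j Effect size(s).
#' @param family `"normal"` or `"laplace"`.
#' @param scale Positive scale parameter.
#' @param smoothing_eps Non-negative smoothing constant for the Laplace.
#' @return Density value(s), strictly positive.
#' @export
component_pdf <- function(beta_j, family = c("normal", "laplace"),
                          scale, smoothing_eps = 0) {
  family <- match.arg(family)
  if (scale <= 0) stop("scale must be > 0", call. = FALSE)
  exp(component_logpdf(beta_j, family, scale, smoothing_eps)$logp)
}

# log density plus first two derivatives of the log density; everything the
# penalty needs is expressible through these (stable for extreme beta).
component_logpdf <- function(beta, family, scale, smoothing_eps = 0) {
  if (family == "normal") {
    s2 <- scale^2
    list(
      logp = -0.5 * log(2 * pi * s2) - beta^2 / (2 * s2),
      g = -beta / s2,        # d log p / d beta
      gp = rep(-1 / s2, length(beta))  # second derivative of log p
    )
  } else {
    s <- sqrt(beta^2 + smoothing_eps)
    if (smoothing_eps == 0) {
      g <- ifelse(beta == 0, 0, -sign(beta) / scale)
      gp <- rep(0, length(beta))
    } else {
      g <- -beta / (s * scale)
      gp <- -smoothing_eps / (s^3 * scale)
    }
    list(logp = -log(2 * scale) - s / scale, g = g, gp = gp)
  }
}

#' Spike-and-slab penalty: cost, gradient, curvature, responsibilities
#'
#' For each SNP the penalty is `c_j = -log m_j` with mixture density
#' `m_j = pi1_j p1_j(beta_j) + (1 - pi1_j) p0_j(beta_j)`. All arithmetic is
#' done in log space via log-sum-exp. The gradient is `-m'/m`, the
#' curvature `(m'/m)^2 - m''/m`, and the responsibility
#' `r_j = pi1_j p1_j / m_j` is the posterior-style weight that the effect
#' came from the causal (slab) component.
#'
#' @param beta Effect-size vector.
#' @param prior A [prior_spec()] of matching length.
#' @return List with `cost` (scalar), `grad`, `curvature` and
#'   `responsibilities` (vectors).
#' @export
penalty_terms <- function(beta, prior) {
  stopifnot(inherits(prior, "prior_spec"), length(beta) == length(prior$pi1))
  # slab: zero-mean normal, sd varying per SNP
  s2 <- prior$slab_sd^2
  lp1 <- -0.5 * log(2 * pi * s2) - beta^2 / (2 * s2)
  g1 <- -beta / s2
  gp1 <- -1 / s2
  null_fam <- if (prior$null_family == "normal_spike") "normal" else "laplace"
  p0 <- component_logpdf(beta, null_fam, prior$null_scale, prior$smoothing_eps)
  lp0 <- p0$logp
  g0 <- p0$g
  gp0 <- p0$gp

  pi1 <- prior$pi1
  # responsibilities from log odds; exact at pi1 = 0 or 1
  r <- numeric(length(beta))
  mid <- pi1 > 0 & pi1 < 1
  r[pi1 == 1] <- 1
  r[pi1 == 0] <- 0
  if (any(mid)) {
    lo <- log(pi1[mid]) + lp1[mid] - log1p(-pi1[mid]) - lp0[mid]
    r[mid] <- stats::plogis(lo)
  }
  # log mixture via log-sum-exp
  logm <- numeric(length(beta))
  logm[pi1 == 1] <- lp1[pi1 == 1]
  logm[pi1 == 0] <- lp0[pi1 == 0]
  if (any(mid)) {
    a <- log(pi1[mid]) + lp1[mid]
    b <- log1p(-pi1[mid]) + lp0[mid]
    mx <- pmax(a, b)
    logm[mid] <- mx + log(exp(a - mx) + exp(b - mx))
  }
  # m'/m and m''/m through component log-derivatives and responsibilities:
  # p' = g p and p'' = (g^2 + g') p for each component
  mp_over_m <- r * g1 + (1 - r) * g0
  mpp_over_m <- r * (g1^2 + gp1) + (1 - r) * (g0^2 + gp0)
  list(
    cost = -sum(logm),
    grad = -mp_over_m,
    curvature = mp_over_m^2 - mpp_over_m,
    responsibilities = r
  )
}

#' Gaussian negative log-likelihood and its gradient
#'
#' `L = (d/2) log(2*pi) + (1/2) log|Sigma| + (1/2) r' Sigma^-1 r` with
#' residual `r = y - X beta` and diagonal residual covariance
#' `Sigma = diag(sigma2)`. The normalizing exponent uses the residual
#' dimension `d = length(y)`.
#'
#' @param beta Effect-size vector.
#' @param X Standardized dosage matrix (`N x n`).
#' @param y Phenotype vector of length `N`.
#' @param sigma2 Residual variance: scalar or length-`N` vector.
#' @return List with `L` (scalar) and `grad` (length-`n` vector).
#' @export
neg_log_likelihood <- function(beta, X, y, sigma2) {
  if (!all(is.finite(beta))) stop("non-finite beta", call. = FALSE)
  stopifnot(length(beta) == ncol(X), length(y) == nrow(X), all(sigma2 > 0))
  d <- length(y)
  s2 <- rep_len(sigma2, d)
  r <- y - drop(X %*% beta)
  L <- 0.5 * d * log(2 * pi) + 0.5 * sum(log(s2)) + 0.5 * sum(r^2 / s2)
  list(L = L, grad = -unname(drop(crossprod(X, r / s2))))
}

#' Hessian-vector product of the penalized objective
#'
#' Computes `H v = X' Sigma^-1 (X v) + weight * curvature * v` with two
#' matrix-vector products and one elementwise product; the `n x n` Hessian
#' is never formed. `curvature` is the per-SNP second derivative of the
#' penalty from [penalty_terms()].
#'
#' @param v Direction vector (length `n`).
#' @param X Standardized dosage matrix.
#' @param sigma2 Residual variance (scalar or length-`N`).
#' @param curvature Per-SNP penalty curvature.
#' @param weight Penalty weight (default 1).
#' @return Length-`n` vector `H v`.
#' @export
hessian_vector_product <- function(v, X, sigma2, curvature, weight = 1) {
  stopifnot(length(v) == ncol(X), length(curvature) == length(v))
  s2 <- rep_len(sigma2, nrow(X))
  unname(drop(crossprod(X, drop(X %*% v) / s2))) + weight * curvature * v
}

#' Evaluate the penalized objective F = L + weight * C
#'
#' @inheritParams neg_log_likelihood
#' @param prior A [prior_spec()].
#' @param weight Positive weight on the penalty (equal weighting of
#'   likelihood and cost, `weight = 1`, is the default; a polygenic trait
#'   may warrant down-weighting the penalty).
#' @return List with `F`, `L`, `C`, `gradient`, `curvature` and
#'   `responsibilities`.
#' @export
evaluate_objective <- function(beta, X, y, sigma2, prior, weight = 1) {
  if (weight <= 0) stop("weight must be > 0", call. = FALSE)
  lik <- neg_log_likelihood(beta, X, y, sigma2)
  pen <- penalty_terms(beta, prior)
  list(
    F = lik$L + weight * pen$cost,
    L = lik$L,
    C = pen$cost,
    gradient = lik$grad + weight * pen$grad,
    curvature = pen$curvature,
    responsibilities = pen$responsibilities
  )
}
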