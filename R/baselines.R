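#' Univariate (single-SNP) regression
#'
#' The marginal least-squares slope of the phenotype on each standardized
#' dosage column, with its standard error and t statistic — the
#' conventional GWAS per-SNP scan used as the simplest comparison
#' estimator.
#'
#' @param genotypes A standardized [geno_matrix()].
#' @param phenotype Numeric vector or tibble with `value`.
#' @return Tibble with `variant_id`, `estimate`, `std_error`, `statistic`,
#'   `p_value`.
#' @export
univariate_regression <- function(genotypes, phenotype) {
  stopifnot(inherits(genotypes, "geno_matrix"))
  if (!genotypes$standardized) stop("standardize genotypes first", call. = FALSE)
  y <- if (is.data.frame(phenotype)) phenotype$value else as.numeric(phenotype)
  X <- genotypes$dosages
  stopifnot(length(y) == nrow(X))
  N <- nrow(X)
  # columns are centred (standardized), so fitting with an intercept is the
  # same as regressing the centred phenotype on each column
  yc <- y - mean(y)
  xtx <- unname(colSums(X^2))
  xty <- unname(drop(crossprod(X, yc)))
  slope <- xty / xtx
  rss <- pmax(sum(yc^2) - slope^2 * xtx, 0)
  s2 <- rss / (N - 2)
  se <- sqrt(s2 / xtx)
  tstat <- slope / se
  tibble::tibble(
    variant_id = genotypes$variants$variant_id,
    estimate = slope,
    std_error = se,
    statistic = tstat,
    p_value = 2 * stats::pt(abs(tstat), df = N - 2, lower.tail = FALSE)
  )
}

#' Regularized pseudo-inverse (generalized-ridge) closed form
#'
#' The analytic MAP estimator under independent zero-mean normal priors
#' with per-SNP precision `d_j`:
#' `beta_hat = (X' Sigma^-1 X + D)^-1 X' Sigma^-1 y`, `D = diag(d)`. With a
#' uniform precision and scalar residual variance this is ridge
#' regression; with precisions `1 / (pi1_j * slab_sd_j^2)` it is the
#' enriched-prior analytic reference that the mixture optimizer should
#' match when every prior is pure slab.
#'
#' @param genotypes A standardized [geno_matrix()].
#' @param phenotype Numeric vector or tibble with `value`.
#' @param sigma2 Residual variance (scalar or per-sample vector).
#' @param prior_precision Positive per-SNP prior precision, recycled.
#' @return Tibble with `variant_id`, `estimate`.
#' @export
regpi_closed_form <- function(genotypes, phenotype, sigma2 = 1, prior_precision = 1) {
  stopifnot(inherits(genotypes, "geno_matrix"))
  y <- if (is.data.frame(phenotype)) phenotype$value else as.numeric(phenotype)
  X <- genotypes$dosages
  n <- ncol(X)
  d <- rep_len(prior_precision, n)
  if (any(d <= 0)) stop("prior_precision must be > 0", call. = FALSE)
  s2 <- rep_len(sigma2, nrow(X))
  Xs <- X / sqrt(s2)
  A <- crossprod(Xs)
  diag(A) <- diag(A) + d
  b <- drop(crossprod(X, y / s2))
  est <- tryCatch(
    unname(drop(chol2inv(chol(A)) %*% b)),
    error = function(e) stop("regularized system not positive definite: ",
                             conditionMessage(e), call. = FALSE)
  )
  tibble::tibble(variant_id = genotypes$variants$variant_id, estimate = est)
}

#' Elastic net / LASSO by cyclic coordinate descent
#'
#' Minimizes the elastic-net objective in its unscaled form
#' `||X b - y||^2 + lambda * sum_j [ (1 - alpha)/2 * b_j^2 + alpha |b_j| ]`,
#' with `alpha = 1` the LASSO and `alpha = 0` ridge. Each coordinate
#' update is the soft-threshold closed form
#' `b_j = S(x_j' r_j, lambda * alpha / 2) / (x_j' x_j + lambda (1-alpha)/2)`.
#' Note the residual sum of squares carries no `1/(2N)` factor, so lambda
#' here is `2 N lambda_glmnet` relative to the usual glmnet scaling.
#'
#' @param genotypes A standardized [geno_matrix()] (or bare matrix).
#' @param phenotype Numeric vector or tibble with `value`.
#' @param lambda Positive regularization strength.
#' @param alpha Mixing parameter in `[0, 1]`.
#' @param max_sweeps Full-cycle cap.
#' @param tol Convergence: max absolute coordinate change per sweep.
#' @return Tibble with `variant_id`, `estimate`; attribute `sweeps`.
#' @export
elastic_net_cd <- function(genotypes, phenotype, lambda, alpha = 1,
                           max_sweeps = 1000L, tol = 1e-8) {
  if (inherits(genotypes, "geno_matrix")) {
    X <- genotypes$dosages
    vids <- genotypes$variants$variant_id
  } else {
    X <- as.matrix(genotypes)
    vids <- colnames(X) %||% sprintf("snp%05d", seq_len(ncol(X)))
  }
  y <- if (is.data.frame(phenotype)) phenotype$value else as.numeric(phenotype)
  if (lambda <= 0) stop("lambda must be > 0", call. = FALSE)
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]", call. = FALSE)
  n <- ncol(X)
  xtx <- colSums(X^2)
  beta <- numeric(n)
  r <- y
  thr <- lambda * alpha / 2
  denom <- xtx + lambda * (1 - alpha) / 2
  converged <- FALSE
  sweeps <- 0L
  for (s in seq_len(max_sweeps)) {
    sweeps <- s
    delta <- 0
    for (j in seq_len(n)) {
      bj <- beta[j]
      z <- sum(X[, j] * r) + xtx[j] * bj
      bj_new <- soft_threshold(z, thr) / denom[j]
      if (bj_new != bj) {
        r <- r - X[, j] * (bj_new - bj)
        delta <- max(delta, abs(bj_new - bj))
        beta[j] <- bj_new
      }
    }
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged) warning("coordinate descent hit max_sweeps without converging",
                          call. = FALSE)
  out <- tibble::tibble(variant_id = vids, estimate = beta)
  attr(out, "sweeps") <- sweeps
  attr(out, "converged") <- converged
  out
}

soft_threshold <- function(z, t) sign(z) * pmax(abs(z) - t, 0)

#' Select lambda by k-fold cross-validation
#'
#' Splits samples into folds by a seeded permutation, fits the elastic net
#' on each training split over a lambda grid, and scores held-out
#' phenotype NMSE `||y_val - X_val b||^2 / ||y_val||^2`. Ties are broken
#' toward the larger (sparser) lambda. The default grid spans
#' `[0.45, 0.70]` with two folds, the protocol used for the per-chromosome
#' LASSO comparison.
#'
#' @param genotypes A standardized [geno_matrix()].
#' @param phenotype Numeric vector or tibble with `value`.
#' @param lambda_grid Candidate lambdas.
#' @param folds Number of folds (>= 2).
#' @param alpha Elastic-net mixing parameter.
#' @param seed Seed for the fold permutation.
#' @return List with `best_lambda` and `nmse`, a tibble of
#'   `(lambda, nmse)`.
#' @export
cv_select_lambda <- function(genotypes, phenotype,
                             lambda_grid = seq(0.45, 0.70, by = 0.05),
                             folds = 2L, alpha = 1, seed = 1L) {
  stopifnot(inherits(genotypes, "geno_matrix"))
  y <- if (is.data.frame(phenotype)) phenotype$value else as.numeric(phenotype)
  X <- genotypes$dosages
  N <- nrow(X)
  if (folds < 2L) stop("folds must be >= 2", call. = FALSE)
  if (length(lambda_grid) < 1L) stop("empty lambda grid", call. = FALSE)
  fold_id <- with_local_seed(seed, sample(rep_len(seq_len(folds), N)))
  nmse <- vapply(lambda_grid, function(lam) {
    errs <- vapply(seq_len(folds), function(f) {
      tr <- fold_id != f
      if (stats::var(y[!tr]) == 0) stop("validation fold has zero-variance response",
                                        call. = FALSE)
      fit <- elastic_net_cd(X[tr, , drop = FALSE], y[tr], lambda = lam, alpha = alpha)
      pred <- drop(X[!tr, , drop = FALSE] %*% fit$estimate)
      sum((y[!tr] - pred)^2) / sum(y[!tr]^2)
    }, numeric(1))
    mean(errs)
  }, numeric(1))
  # ties toward larger lambda (sparser model)
  best <- max(lambda_grid[nmse <= min(nmse) + 1e-12])
  list(best_lambda = best,
       nmse = tibble::tibble(lambda = lambda_grid, nmse = nmse))
}

# run expr under a fixed seed without disturbing the caller's RNG stream
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}
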