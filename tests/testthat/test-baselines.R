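test_that("univariate slopes match per-column least squares", {
  g <- standardize_genotypes(rand_geno(50, 10, seed = 51))
  X <- g$dosages
  y <- 2 * X[, 1]
  res <- univariate_regression(g, y)
  expect_equal(res$estimate[1], 2)

  yo <- y - X[, 3] * sum(y * X[, 3]) / sum(X[, 3]^2)  # orthogonalized against x3
  expect_equal(univariate_regression(g, yo)$estimate[3], 0, tolerance = 1e-12)

  set.seed(52)
  yr <- rnorm(50)
  res2 <- univariate_regression(g, yr)
  for (j in 1:10) {
    lmfit <- lm(yr ~ X[, j])
    expect_equal(res2$estimate[j], unname(coef(lmfit)[2]), tolerance = 1e-10)
    expect_equal(res2$std_error[j], summary(lmfit)$coefficients[2, 2],
                 tolerance = 1e-10)
  }
})

test_that("regularized pseudo-inverse spans the OLS and full-shrinkage limits", {
  g <- standardize_genotypes(rand_geno(80, 10, seed = 53))
  set.seed(54)
  y <- rnorm(80)
  ols <- solve(crossprod(g$dosages), crossprod(g$dosages, y))
  near0 <- regpi_closed_form(g, y, sigma2 = 1, prior_precision = 1e-10)
  expect_equal(near0$estimate, unname(drop(ols)), tolerance = 1e-6)
  huge <- regpi_closed_form(g, y, sigma2 = 1, prior_precision = 1e12)
  expect_lt(max(abs(huge$estimate)), 1e-6)
})

test_that("RegPI equals the all-slab mixture fit with matching variances", {
  g <- standardize_genotypes(rand_geno(100, 30, seed = 55))
  set.seed(56)
  beta_true <- numeric(30); beta_true[sample(30, 5)] <- rnorm(5)
  y <- drop(g$dosages %*% beta_true) + rnorm(100)
  s2 <- 0.5 * var(y)
  pi1 <- rep(c(0.5, 0.1), 15)
  slab <- rep(1, 30)
  # slab-only fit with per-SNP variances pi1_j * slab^2 matches RegPI with
  # precisions 1 / (pi1_j slab^2): the two parameterizations are equivalent
  pr <- prior_spec(pi1 = 1, slab_sd = sqrt(pi1) * slab,
                   null_family = "normal_spike", n = 30)
  fit <- fit_mixture_model(g, y, pr, noise_model(1, 0.5),
                           optimizer_config(grad_tol = 1e-9, f_rel_tol = 1e-15,
                                            max_iter = 4000, anneal = NULL))
  rp <- regpi_closed_form(g, y, sigma2 = s2, prior_precision = 1 / (pi1 * slab^2))
  expect_equal(tidy(fit)$beta_hat, rp$estimate, tolerance = 1e-5)
  # residual identity X' S^-1 (y - X b) = D b
  resid <- unname(drop(crossprod(g$dosages, (y - g$dosages %*% rp$estimate) / s2)))
  expect_equal(resid, rp$estimate / (pi1 * slab^2), tolerance = 1e-8)
})

test_that("coordinate descent solves the unscaled elastic-net objective", {
  # scalar case: min (b - 1)^2 + 0.8 |b| has solution 1 - 0.4 = 0.6;
  # orthonormal columns decouple the coordinates, so each is soft-thresholded
  set.seed(570)
  X <- qr.Q(qr(matrix(rnorm(16), 4, 4)))
  y <- drop(X %*% c(1, 0.2, -0.5, 0))
  fit <- elastic_net_cd(X, y, lambda = 0.8, alpha = 1)
  expect_equal(fit$estimate, c(0.6, 0, -0.1, 0), tolerance = 1e-10)

  # alpha = 0 equals ridge closed form with penalty lambda/2 * I
  g <- standardize_genotypes(rand_geno(60, 8, seed = 57))
  set.seed(58)
  yr <- rnorm(60)
  lam <- 3
  ridge <- solve(crossprod(g$dosages) + (lam / 2) * diag(8),
                 crossprod(g$dosages, yr))
  fr <- elastic_net_cd(g, yr, lambda = lam, alpha = 0)
  expect_equal(fr$estimate, unname(drop(ridge)), tolerance = 1e-8)

  # full shrinkage when lambda * alpha / 2 >= max |x_j' y|
  lam_max <- 2 * max(abs(crossprod(X, y)))
  f0 <- elastic_net_cd(X, y, lambda = lam_max * 1.01, alpha = 1)
  expect_equal(f0$estimate, rep(0, 4))
})

test_that("LASSO solutions satisfy the KKT subgradient conditions", {
  g <- standardize_genotypes(rand_geno(70, 15, seed = 59))
  set.seed(60)
  beta_true <- numeric(15); beta_true[1:3] <- c(0.5, -0.4, 0.3)
  y <- drop(g$dosages %*% beta_true) + rnorm(70)
  lam <- 40
  fit <- elastic_net_cd(g, y, lambda = lam, alpha = 1, tol = 1e-12)
  gradL <- 2 * drop(crossprod(g$dosages, g$dosages %*% fit$estimate - y))
  active <- fit$estimate != 0
  expect_true(any(active) && any(!active))
  expect_lt(max(abs(gradL[active] + lam * sign(fit$estimate[active]))), 1e-6)
  expect_lt(max(abs(gradL[!active])), lam + 1e-6)
})

test_that("coordinate descent agrees with glmnet under the lambda mapping", {
  skip_if_not_installed("glmnet")
  g <- standardize_genotypes(rand_geno(100, 12, seed = 61))
  set.seed(62)
  y <- drop(g$dosages[, 1] * 0.5) + rnorm(100)
  N <- 100
  for (lam in c(20, 80)) {
    ours <- elastic_net_cd(g, y, lambda = lam, alpha = 1, tol = 1e-12)
    gfit <- glmnet::glmnet(g$dosages, y, alpha = 1, lambda = lam / (2 * N),
                           standardize = FALSE, intercept = FALSE,
                           thresh = 1e-14)
    expect_equal(ours$estimate, unname(as.vector(gfit$beta)), tolerance = 1e-5)
  }
})

test_that("cross-validated lambda selection follows the fold protocol", {
  g <- standardize_genotypes(rand_geno(60, 10, seed = 63))
  set.seed(64)
  y <- rnorm(60)
  single <- cv_select_lambda(g, y, lambda_grid = 0.55, folds = 2)
  expect_equal(single$best_lambda, 0.55)

  # default grid mirrors the 2-fold protocol over [0.45, 0.70]
  res <- cv_select_lambda(g, y)
  expect_equal(range(res$nmse$lambda), c(0.45, 0.70))
  expect_equal(nrow(res$nmse), 6L)
  # pure-noise response: small lambdas cannot beat chance by much
  expect_true(all(res$nmse$nmse > 0.5))

  # ties break toward the sparser (larger) lambda: replicate exact ties by
  # a grid of lambdas all large enough to zero every coefficient
  lam_max <- 2 * max(abs(crossprod(g$dosages, y))) * 4
  tied <- cv_select_lambda(g, y, lambda_grid = lam_max * c(1, 1.5, 2), folds = 2)
  expect_equal(tied$best_lambda, lam_max * 2)

  expect_error(cv_select_lambda(g, y, folds = 1), "folds")
})

test_that("baselines are permutation-equivariant in SNP order", {
  g <- standardize_genotypes(rand_geno(50, 6, seed = 65))
  set.seed(66)
  y <- rnorm(50)
  perm <- c(4, 1, 6, 3, 2, 5)
  gp <- g
  gp$dosages <- gp$dosages[, perm]
  gp$variants <- gp$variants[perm, ]
  expect_equal(univariate_regression(gp, y)$estimate,
               univariate_regression(g, y)$estimate[perm])
  expect_equal(regpi_closed_form(gp, y, 1, 2)$estimate,
               regpi_closed_form(g, y, 1, 2)$estimate[perm], tolerance = 1e-10)
  expect_equal(elastic_net_cd(gp, y, lambda = 30)$estimate,
               elastic_net_cd(g, y, lambda = 30)$estimate[perm], tolerance = 1e-7)
})
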