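# scalar quadratic (t - 2)^2 along direction 1: Newton is exact
test_that("Newton line search is exact on a quadratic", {
  fgrad <- function(b) list(F = (b - 2)^2, grad = 2 * (b - 2))
  fhvp <- function(b, v) 2 * v
  ls <- newton_line_search(0, 1, fgrad, fhvp, t0 = 1, max_newton = 1L)
  expect_equal(ls$t, 2, tolerance = 1e-12)
  expect_equal(ls$F_new, 0, tolerance = 1e-12)
  expect_error(newton_line_search(0, -1, fgrad, fhvp), "descent direction")
})

test_that("line search matches a dense grid argmin on a ridge objective", {
  inst <- rand_instance(40, 8, seed = 31)
  lam <- 2
  fgrad <- function(b) {
    r <- inst$y - drop(inst$X %*% b)
    list(F = 0.5 * sum(r^2) + 0.5 * lam * sum(b^2),
         grad = -drop(crossprod(inst$X, r)) + lam * b)
  }
  fhvp <- function(b, v) drop(crossprod(inst$X, inst$X %*% v)) + lam * v
  set.seed(32)
  beta <- rnorm(8, 0, 0.2)
  g <- fgrad(beta)$grad
  d <- -g
  ls <- newton_line_search(beta, d, fgrad, fhvp)
  tgrid <- seq(0, 4 * ls$t, length.out = 1e5)
  fvals <- vapply(tgrid, function(t) fgrad(beta + t * d)$F, numeric(1))
  tstar <- tgrid[which.min(fvals)]
  expect_equal(ls$t, tstar, tolerance = 2 * diff(tgrid[1:2]) / tstar)
})

test_that("non-convex spike region falls back to backtracking with descent", {
  # concave phi at the start: spike/slab penalty ridge between modes
  pr <- prior_spec(pi1 = 0.5, slab_sd = 2, null_family = "normal_spike",
                   null_scale = 0.02, n = 1)
  fgrad <- function(b) {
    pt <- penalty_terms(b, pr)
    list(F = 0.05 * (b - 1)^2 + pt$cost, grad = 0.1 * (b - 1) + pt$grad)
  }
  fhvp <- function(b, v) (0.1 + penalty_terms(b, pr)$curvature) * v
  # pick a point in the spike-to-slab transition where curvature is negative
  bgrid <- seq(0.02, 0.5, by = 0.005)
  curv <- vapply(bgrid, function(b) penalty_terms(b, pr)$curvature, numeric(1))
  b0 <- bgrid[which.min(curv)]
  expect_lt(fhvp(b0, 1), 0)
  g0 <- fgrad(b0)$grad
  ls <- newton_line_search(b0, -sign(g0), fgrad, fhvp)
  expect_gt(ls$t, 0)
  expect_lt(ls$F_new, fgrad(b0)$F)
})

test_that("NCG solves an SPD quadratic to high accuracy", {
  set.seed(33)
  M <- matrix(rnorm(100), 10, 10)
  A <- crossprod(M) + diag(10)
  b <- rnorm(10)
  sol <- solve(A, b)
  fgrad <- function(x) list(F = 0.5 * sum(x * (A %*% x)) - sum(b * x),
                            grad = drop(A %*% x) - b)
  fhvp <- function(x, v) drop(A %*% v)
  for (upd in c("fletcher_reeves", "polak_ribiere_plus", "dai_yuan", "hager_zhang")) {
    res <- ncg_minimize(numeric(10), fgrad, fhvp,
                        optimizer_config(beta_update = upd, grad_tol = 1e-10,
                                         f_rel_tol = 1e-16, anneal = NULL))
    expect_equal(res$beta_hat, sol, tolerance = 1e-8)
    expect_true(all(diff(res$objective_trace) <= 1e-12))
  }
})

tight_cfg <- function(...) {
  optimizer_config(grad_tol = 1e-9, f_rel_tol = 1e-15, max_iter = 3000, ...)
}

test_that("all-slab fits reproduce the generalized-ridge closed form", {
  inst <- rand_instance(60, 12, seed = 34)
  pr <- prior_spec(pi1 = 1, slab_sd = runif(12, 0.5, 2),
                   null_family = "normal_spike", n = 12)
  fit <- fit_mixture_model(inst$g, inst$y, pr, noise_model(1, 0.5),
                           tight_cfg(anneal = NULL))
  A <- crossprod(inst$X) / inst$sigma2 + diag(1 / pr$slab_sd^2)
  closed <- solve(A, crossprod(inst$X, inst$y) / inst$sigma2)
  expect_equal(tidy(fit)$beta_hat, unname(drop(closed)), tolerance = 1e-6)
})

test_that("1- and 2-SNP spike/slab fits match exhaustive grid search", {
  set.seed(35)
  # 1 SNP, strong signal so the objective is unimodal
  g1 <- standardize_genotypes(rand_geno(60, 1, seed = 36))
  y1 <- drop(g1$dosages) * 0.8 + rnorm(60, 0, 0.5)
  pr1 <- prior_spec(pi1 = 0.1, slab_sd = 1, null_family = "normal_spike",
                    null_scale = 0.05, n = 1)
  s2 <- 0.5 * var(y1)
  grid <- seq(-1.5, 1.5, by = 1e-3)
  fg <- vapply(grid, function(b) {
    evaluate_objective(b, g1$dosages, y1, s2, pr1)$F
  }, numeric(1))
  fit1 <- fit_mixture_model(g1, y1, pr1, noise_model(1, 0.5), tight_cfg())
  expect_equal(tidy(fit1)$beta_hat, grid[which.min(fg)], tolerance = 2e-3)

  # 2 SNPs: vectorized grid oracle over the plane
  g2 <- standardize_genotypes(rand_geno(80, 2, seed = 37))
  beta_true <- c(0.9, 0)
  y2 <- drop(g2$dosages %*% beta_true) + rnorm(80, 0, 0.5)
  pr2 <- prior_spec(pi1 = 0.1, slab_sd = 1, null_family = "normal_spike",
                    null_scale = 0.05, n = 2)
  s2b <- 0.5 * var(y2)
  X <- g2$dosages
  G <- crossprod(X)
  xty <- drop(crossprod(X, y2))
  yty <- sum(y2^2)
  b1 <- seq(-1.5, 1.5, by = 1e-3)
  b2 <- b1
  # per-coordinate penalties (independent across SNPs), direct arithmetic
  c1 <- vapply(b1, function(b) -log(0.1 * dnorm(b, 0, 1) + 0.9 * dnorm(b, 0, 0.05)),
               numeric(1))
  c2 <- c1
  Q <- outer(b1^2 * G[1, 1], b2^2 * G[2, 2], "+") / 2 +
    outer(b1, b2) * G[1, 2] -
    outer(b1 * xty[1], b2 * xty[2], "+")
  Fgrid <- (Q + yty / 2) / s2b + outer(c1, c2, "+")
  idx <- arrayInd(which.min(Fgrid), dim(Fgrid))
  oracle <- c(b1[idx[1]], b2[idx[2]])
  fit2 <- fit_mixture_model(g2, y2, pr2, noise_model(1, 0.5), tight_cfg())
  expect_equal(tidy(fit2)$beta_hat, oracle, tolerance = 2e-3)
})

test_that("fits are permutation-equivariant and deterministic", {
  inst <- rand_instance(50, 8, seed = 38)
  pr <- rand_prior(8, seed = 39, null_family = "laplace")
  fit <- fit_mixture_model(inst$g, inst$y, pr, noise_model(1, 0.5))
  fit_again <- fit_mixture_model(inst$g, inst$y, pr, noise_model(1, 0.5))
  expect_identical(fit$windows[[1]]$objective_trace,
                   fit_again$windows[[1]]$objective_trace)
  expect_identical(tidy(fit)$beta_hat, tidy(fit_again)$beta_hat)

  perm <- c(3, 1, 8, 5, 2, 7, 4, 6)
  gp <- inst$g
  gp$dosages <- gp$dosages[, perm]
  gp$variants <- gp$variants[perm, ]
  prp <- prior_spec(pi1 = pr$pi1[perm], slab_sd = pr$slab_sd[perm],
                    null_family = pr$null_family, null_scale = pr$null_scale,
                    smoothing_eps = pr$smoothing_eps)
  fitp <- fit_mixture_model(gp, inst$y, prp, noise_model(1, 0.5))
  # identical mathematics; floating-point drift from BLAS summation order only
  expect_lt(max(abs(tidy(fitp)$beta_hat - tidy(fit)$beta_hat[perm])), 1e-6)
})

test_that("objective traces never increase, across priors and stages", {
  for (seed in 1:5) {
    inst <- rand_instance(60, 15, seed = 400 + seed)
    fam <- if (seed %% 2) "laplace" else "normal_spike"
    pr <- prior_spec(pi1 = 0.05, slab_sd = 1, null_family = fam,
                     null_scale = 0.05, n = 15)
    fit <- fit_mixture_model(inst$g, inst$y, pr, noise_model(1, 0.5))
    for (tr in fit$windows[[1]]$stage_traces) {
      expect_true(all(diff(tr) <= 1e-9 * pmax(1, abs(tr[-length(tr)]))))
    }
  }
})

test_that("annealing improves or preserves the final objective on most instances", {
  better <- 0L
  n_inst <- 20L
  for (seed in seq_len(n_inst)) {
    g <- standardize_genotypes(rand_geno(80, 10, seed = 500 + seed))
    set.seed(600 + seed)
    beta_true <- numeric(10)
    beta_true[sample(10, 2)] <- rnorm(2)
    y <- drop(g$dosages %*% beta_true) + rnorm(80, 0, 1)
    pr <- prior_spec(pi1 = 0.1, slab_sd = 1, null_family = "normal_spike",
                     null_scale = 0.02, n = 10)
    warm <- fit_mixture_model(g, y, pr, noise_model(1, 0.5), optimizer_config())
    cold <- fit_mixture_model(g, y, pr, noise_model(1, 0.5),
                              optimizer_config(anneal = NULL))
    if (warm$windows[[1]]$objective <= cold$windows[[1]]$objective + 1e-8) {
      better <- better + 1L
    }
  }
  expect_gte(better, 0.8 * n_inst)
})

test_that("multi-window fits run per window and a window cap is enforced", {
  g <- rand_geno(60, 12, seed = 40)
  g$variants$chromosome <- as.character(rep(1:3, each = 4))
  w <- make_windows(g, "per_chromosome", total_h2 = 0.3)
  gs <- standardize_genotypes(w$genotypes)
  set.seed(41)
  y <- rnorm(60)
  fit <- fit_mixture_model(gs, y, constant_priors(gs, 0.1), w$noise)
  expect_length(fit$windows, 3L)
  td <- tidy(fit)
  expect_equal(td$variant_id, gs$variants$variant_id)
  expect_true(all(td$responsibility >= 0 & td$responsibility <= 1))
  expect_error(
    fit_mixture_model(gs, y, constant_priors(gs, 0.1), w$noise,
                      optimizer_config(max_window_snps = 3L)),
    "smaller windows"
  )
  expect_equal(unname(coef(fit)), td$beta_hat)
  gl <- glance(fit)
  expect_equal(gl$n_windows, 3L)
  expect_true(gl$converged)
})
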