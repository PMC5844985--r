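#' Optimizer configuration
#'
#' Controls the nonlinear conjugate gradient (NCG) minimizer. Direction
#' updates: Fletcher-Reeves, Polak-Ribiere+ (default; robust on non-convex
#' objectives), Dai-Yuan, and Hager-Zhang, all with periodic steepest-
#' descent restarts. The line search runs a few Newton-Raphson steps on
#' `phi(t) = F(beta + t d)` using Hessian-vector products for `phi''`,
#' safeguarded by Armijo backtracking so descent is guaranteed even in the
#' non-convex spike region.
#'
#' @param beta_update One of `"polak_ribiere_plus"`, `"fletcher_reeves"`,
#'   `"dai_yuan"`, `"hager_zhang"`.
#' @param max_iter Iteration cap; default `min(10 * n, 5000)` chosen at fit
#'   time when `NULL`.
#' @param grad_tol Stop when the max-norm of the gradient falls below this.
#' @param f_rel_tol Stop when the relative objective decrease falls below
#'   this.
#' @param line_search_max_newton Newton steps per line search.
#' @param restart_every Steepest-descent restart period; `NULL` means `n`.
#' @param weight Penalty weight passed to the objective.
#' @param anneal Annealing schedule: list of stages, each a list with
#'   `pi1_mult` and `null_scale_mult` applied to the target prior; stages
#'   run sequentially with warm starts. `NULL` disables annealing. The
#'   default homotopy widens the null scale by x10 and x3.16 before the
#'   target fit.
#' @param max_window_snps Refuse windows larger than this.
#' @return An `optimizer_config` list.
#' @export
optimizer_config <- function(beta_update = c("polak_ribiere_plus", "fletcher_reeves",
                                             "dai_yuan", "hager_zhang"),
                             max_iter = NULL, grad_tol = 1e-6, f_rel_tol = 1e-10,
                             line_search_max_newton = 5L, restart_every = NULL,
                             weight = 1,
                             anneal = default_anneal_schedule(),
                             max_window_snps = 20000L) {
  beta_update <- match.arg(beta_update)
  stopifnot(grad_tol > 0, f_rel_tol > 0, line_search_max_newton >= 1L, weight > 0)
  if (!is.null(max_iter) && max_iter < 1L) stop("max_iter must be >= 1", call. = FALSE)
  structure(
    list(beta_update = beta_update, max_iter = max_iter, grad_tol = grad_tol,
         f_rel_tol = f_rel_tol, line_search_max_newton = as.integer(line_search_max_newton),
         restart_every = restart_every, weight = weight, anneal = anneal,
         max_window_snps = as.integer(max_window_snps)),
    class = "optimizer_config"
  )
}

#' @rdname optimizer_config
#' @export
default_anneal_schedule <- function() {
  list(list(pi1_mult = 1, null_scale_mult = 10),
       list(pi1_mult = 1, null_scale_mult = 3.16),
       list(pi1_mult = 1, null_scale_mult = 1))
}

# One-dimensional Newton-Raphson minimization of phi(t) with Armijo
# backtracking safeguard. phi/dphi/d2phi are functions of t; f0 = phi(0),
# dphi0 = phi'(0) < 0. Returns t = 0 on stall.
newton_ls_1d <- function(phi, dphi, d2phi, t0, max_newton, f0, dphi0) {
  n_eval <- 0L
  t <- if (is.finite(t0) && t0 > 0) t0 else 1
  newton_ok <- TRUE
  for (k in seq_len(max_newton)) {
    dp <- dphi(t)
    n_eval <- n_eval + 1L
    if (!is.finite(dp)) { newton_ok <- FALSE; break }
    if (abs(dp) <= 1e-14 * max(1, abs(dphi0))) break
    d2p <- d2phi(t)
    if (!is.finite(d2p) || d2p <= 0) { newton_ok <- FALSE; break }
    t_new <- t - dp / d2p
    if (!is.finite(t_new) || t_new <= 0) { newton_ok <- FALSE; break }
    if (abs(t_new - t) <= 1e-12 * max(1, t)) { t <- t_new; break }
    t <- t_new
  }
  c1 <- 1e-4
  armijo <- function(t, Ft) is.finite(Ft) && Ft <= f0 + c1 * t * dphi0
  if (newton_ok) {
    Ft <- phi(t)
    n_eval <- n_eval + 1L
    if (armijo(t, Ft)) return(list(t = t, F_new = Ft, n_eval = n_eval))
  }
  # safeguard: backtracking halving from the Newton point (or t0)
  t <- if (is.finite(t) && t > 0) t else max(t0, 1)
  for (h in seq_len(50L)) {
    Ft <- phi(t)
    n_eval <- n_eval + 1L
    if (armijo(t, Ft)) return(list(t = t, F_new = Ft, n_eval = n_eval))
    t <- t / 2
  }
  list(t = 0, F_new = f0, n_eval = n_eval)
}

#' Newton-Raphson line search with Armijo safeguard
#'
#' Minimizes `phi(t) = F(beta + t d)` along a descent direction by Newton
#' iterations `t <- t - phi'(t) / phi''(t)`, with `phi''` obtained from a
#' Hessian-vector product (never a full Hessian). Whenever the local
#' curvature is non-positive, a Newton step leaves the feasible region, or
#' the Newton point fails the Armijo decrease test (`c1 = 1e-4`), the
#' search falls back to backtracking halving; a step of 0 is returned only
#' after 50 failed halvings (stall).
#'
#' @param beta Current point.
#' @param direction Descent direction (`grad' d < 0`).
#' @param fgrad Function `beta -> list(F, grad)`.
#' @param fhvp Function `(beta, v) -> H v`.
#' @param t0 Initial step (previous accepted step is a good choice).
#' @param max_newton Newton iteration cap.
#' @param f0,g0 Optional objective/gradient at `beta` (recomputed if missing).
#' @return List with `t` (accepted step, 0 on stall), `F_new`, and `n_eval`,
#'   the number of one-dimensional evaluations used.
#' @export
newton_line_search <- function(beta, direction, fgrad, fhvp, t0 = 1,
                               max_newton = 5L, f0 = NULL, g0 = NULL) {
  if (is.null(f0) || is.null(g0)) {
    e0 <- fgrad(beta)
    f0 <- e0$F
    g0 <- e0$grad
  }
  dphi0 <- sum(g0 * direction)
  if (!is.finite(dphi0) || dphi0 >= 0) {
    stop("line search requires a descent direction", call. = FALSE)
  }
  # cache the last full evaluation so phi/dphi at the same t cost one call
  cache <- new.env(parent = emptyenv())
  full_eval <- function(t) {
    if (!is.null(cache$t) && identical(cache$t, t)) return(cache$ev)
    ev <- fgrad(beta + t * direction)
    cache$t <- t
    cache$ev <- ev
    ev
  }
  newton_ls_1d(
    phi = function(t) full_eval(t)$F,
    dphi = function(t) sum(full_eval(t)$grad * direction),
    d2phi = function(t) sum(direction * fhvp(beta + t * direction, direction)),
    t0 = t0, max_newton = max_newton, f0 = f0, dphi0 = dphi0
  )
}

#' Nonlinear conjugate gradient minimization
#'
#' Minimizes a smooth objective from `beta0` using conjugate directions
#' with the configured update formula, Hessian-free Newton line searches,
#' and steepest-descent restarts whenever the restart period elapses, the
#' conjugacy coefficient vanishes, or the candidate direction loses
#' descent. The trace of objective values is non-increasing by
#' construction.
#'
#' @param beta0 Start point.
#' @param fgrad Function `beta -> list(F, grad)`.
#' @param fhvp Function `(beta, v) -> H v`.
#' @param config An [optimizer_config()].
#' @return List with `beta_hat`, `objective_trace`, `n_iter`, `converged`,
#'   and `grad_norm` (final max-norm).
#' @export
ncg_minimize <- function(beta0, fgrad, fhvp, config = optimizer_config()) {
  e <- fgrad(beta0)
  if (!is.finite(e$F) || !all(is.finite(e$grad))) {
    stop("objective not finite at the start point", call. = FALSE)
  }
  ncg_loop(
    beta0 = beta0, f0 = e$F, g0 = e$grad, config = config,
    line_search = function(beta, d, f0, g0, t0) {
      newton_line_search(beta, d, fgrad, fhvp, t0 = t0,
                         max_newton = config$line_search_max_newton,
                         f0 = f0, g0 = g0)
    },
    grad_at = function(beta, ls) fgrad(beta)$grad
  )
}

# shared NCG iteration: line_search(beta, d, f0, g0, t0) -> list(t, F_new),
# grad_at(beta_new, ls) -> gradient at the accepted point.
ncg_loop <- function(beta0, f0, g0, config, line_search, grad_at) {
  n <- length(beta0)
  max_iter <- config$max_iter %||% min(10L * n, 5000L)
  restart_every <- config$restart_every %||% max(n, 10L)
  beta <- beta0
  g <- g0
  d <- -g
  trace <- f0
  t_prev <- 1
  converged <- FALSE
  since_restart <- 0L
  for (k in seq_len(max_iter)) {
    if (max(abs(g)) < config$grad_tol) { converged <- TRUE; break }
    if (sum(g * d) >= 0) { d <- -g; since_restart <- 0L }
    f_prev <- trace[length(trace)]
    ls <- line_search(beta, d, f_prev, g, t_prev)
    if (ls$t == 0) { converged <- max(abs(g)) < sqrt(config$grad_tol); break }
    beta <- beta + ls$t * d
    if (!is.finite(ls$F_new)) {
      stop(sprintf("objective became non-finite at iteration %d", k), call. = FALSE)
    }
    g_new <- grad_at(beta, ls)
    trace <- c(trace, ls$F_new)
    rel_drop <- (f_prev - ls$F_new) / max(1, abs(f_prev))
    since_restart <- since_restart + 1L
    if (since_restart >= restart_every) {
      bk <- 0
      since_restart <- 0L
    } else {
      bk <- conjugacy_coefficient(config$beta_update, g, g_new, d)
      if (!is.finite(bk) || bk == 0) since_restart <- 0L
      if (!is.finite(bk)) bk <- 0
    }
    d <- -g_new + bk * d
    if (sum(g_new * d) >= 0) { d <- -g_new; since_restart <- 0L }
    g <- g_new
    t_prev <- ls$t
    if (rel_drop >= 0 && rel_drop < config$f_rel_tol) { converged <- TRUE; break }
  }
  if (max(abs(g)) < config$grad_tol) converged <- TRUE
  list(beta_hat = beta, objective_trace = trace, n_iter = length(trace) - 1L,
       converged = converged, grad_norm = max(abs(g)))
}

conjugacy_coefficient <- function(update, g, g_new, d) {
  yk <- g_new - g
  switch(update,
    fletcher_reeves = sum(g_new^2) / sum(g^2),
    polak_ribiere_plus = max(0, sum(g_new * yk) / sum(g^2)),
    dai_yuan = sum(g_new^2) / sum(d * yk),
    hager_zhang = {
      dy <- sum(d * yk)
      bn <- sum((yk - 2 * d * sum(yk^2) / dy) * g_new) / dy
      eta <- -1 / (sqrt(sum(d^2)) * min(0.01, sqrt(sum(g^2))))
      max(bn, eta)
    }
  )
}

# NCG specialized to F = L(y - X beta; sigma2) + weight * C(beta).
# Along a direction the likelihood part of phi(t) is an explicit quadratic
# (one mat-vec X d per iteration), so every Newton step of the line search
# costs O(N + n) instead of a full objective evaluation. The full gradient
# at the accepted point costs one more mat-vec. Identical mathematics to
# ncg_minimize on evaluate_objective, exploited structure only.
ncg_gauss_mixture <- function(X, y, sigma2, prior, weight, config, beta0) {
  N <- nrow(X)
  s2 <- rep_len(sigma2, N)
  const_L <- 0.5 * N * log(2 * pi) + 0.5 * sum(log(s2))
  beta_env <- new.env(parent = emptyenv())
  beta_env$r <- y - if (all(beta0 == 0)) 0 else drop(X %*% beta0)
  pen0 <- penalty_terms(beta0, prior)
  f0 <- const_L + 0.5 * sum(beta_env$r^2 / s2) + weight * pen0$cost
  g0 <- -drop(crossprod(X, beta_env$r / s2)) + weight * pen0$grad
  if (!is.finite(f0) || !all(is.finite(g0))) {
    stop("objective not finite at the start point", call. = FALSE)
  }
  line_search <- function(beta, d, f0, g0, t0) {
    Xd <- drop(X %*% d)
    a <- sum(Xd^2 / s2)
    b0 <- sum(beta_env$r * Xd / s2)
    rr0 <- sum(beta_env$r^2 / s2)
    dphi0 <- sum(g0 * d)
    ls <- newton_ls_1d(
      phi = function(t) {
        const_L + 0.5 * (rr0 - 2 * t * b0 + t^2 * a) +
          weight * penalty_terms(beta + t * d, prior)$cost
      },
      dphi = function(t) {
        -b0 + t * a + weight * sum(penalty_terms(beta + t * d, prior)$grad * d)
      },
      d2phi = function(t) {
        a + weight * sum(penalty_terms(beta + t * d, prior)$curvature * d^2)
      },
      t0 = t0, max_newton = config$line_search_max_newton,
      f0 = f0, dphi0 = dphi0
    )
    ls$Xd <- Xd
    ls
  }
  grad_at <- function(beta, ls) {
    beta_env$r <- beta_env$r - ls$t * ls$Xd
    -drop(crossprod(X, beta_env$r / s2)) + weight * penalty_terms(beta, prior)$grad
  }
  ncg_loop(beta0, f0, g0, config, line_search, grad_at)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fit the mixture-model-penalized regression
#'
#' Minimizes `F = L + weight * C` window by window: each window is fitted
#' independently against its own residual variance
#' `(1 - h2_window) * var(y)`. When an annealing schedule is configured the
#' stages are fitted sequentially (wide null first), each warm-starting
#' from the previous solution — a homotopy from a near-ridge problem to the
#' target spike that helps NCG avoid poor local minima of the non-convex
#' penalty.
#'
#' @param genotypes A standardized [geno_matrix()] with window assignments
#'   (see [make_windows()]); a single window is assumed when `window_id`
#'   is absent.
#' @param phenotype Numeric vector or tibble with a `value` column.
#' @param prior A [prior_spec()] aligned to the variants.
#' @param noise A [noise_model()]; defaults to a single window at
#'   heritability 0.5.
#' @param config An [optimizer_config()].
#' @param beta_init Optional warm-start vector (default zero).
#' @return An object of class `mmp_fit`; see [tidy.mmp_fit()] and
#'   [glance.mmp_fit()] for tibble views.
#' @export
fit_mixture_model <- function(genotypes, phenotype, prior = NULL, noise = NULL,
                              config = optimizer_config(), beta_init = NULL) {
  stopifnot(inherits(genotypes, "geno_matrix"))
  if (!genotypes$standardized) {
    stop("genotypes must be standardized before fitting", call. = FALSE)
  }
  y <- if (is.data.frame(phenotype)) phenotype$value else as.numeric(phenotype)
  X <- genotypes$dosages
  if (length(y) != nrow(X)) stop("phenotype length does not match genotypes", call. = FALSE)
  n <- ncol(X)
  prior <- prior %||% constant_priors(genotypes)
  if (length(prior$pi1) != n) stop("prior length does not match variants", call. = FALSE)
  wid <- genotypes$variants$window_id
  if (all(is.na(wid))) wid <- rep(1L, n)
  noise <- noise %||% noise_model(n_windows = dplyr::n_distinct(wid), h2_per_window = 0.5)
  beta_init <- beta_init %||% numeric(n)
  windows <- unique(wid)
  fits <- vector("list", length(windows))
  for (i in seq_along(windows)) {
    w <- windows[i]
    idx <- which(wid == w)
    if (length(idx) > config$max_window_snps) {
      stop(sprintf("window %s has %d SNPs (cap %d); use smaller windows",
                   w, length(idx), config$max_window_snps), call. = FALSE)
    }
    fits[[i]] <- fit_one_window(
      X[, idx, drop = FALSE], y, subset_prior(prior, idx),
      sigma2 = bind_sigma2(noise, y), config = config,
      beta_init = beta_init[idx], window_id = w,
      variant_id = genotypes$variants$variant_id[idx]
    )
  }
  structure(
    list(windows = fits, prior = prior, config = config,
         variant_id = genotypes$variants$variant_id, window_id = wid),
    class = "mmp_fit"
  )
}

subset_prior <- function(prior, idx) {
  prior_spec(pi1 = prior$pi1[idx], slab_sd = prior$slab_sd[idx],
             null_family = prior$null_family, null_scale = prior$null_scale,
             smoothing_eps = prior$smoothing_eps,
             variant_id = prior$variant_id[idx])
}

fit_one_window <- function(X, y, prior, sigma2, config, beta_init, window_id,
                           variant_id) {
  stages <- config$anneal %||% list(list(pi1_mult = 1, null_scale_mult = 1))
  beta <- beta_init
  traces <- list()
  res <- NULL
  for (s in seq_along(stages)) {
    st <- stages[[s]]
    pr <- prior_spec(
      pi1 = pmin(1, prior$pi1 * st$pi1_mult),
      slab_sd = prior$slab_sd,
      null_family = prior$null_family,
      null_scale = prior$null_scale * st$null_scale_mult,
      smoothing_eps = prior$smoothing_eps,
      variant_id = prior$variant_id
    )
    res <- ncg_gauss_mixture(X, y, sigma2, pr, config$weight, config, beta)
    beta <- res$beta_hat
    traces[[s]] <- res$objective_trace
  }
  final <- evaluate_objective(beta, X, y, sigma2, prior, weight = config$weight)
  list(
    window_id = window_id,
    variant_id = variant_id,
    beta_hat = unname(beta),
    responsibilities = unname(final$responsibilities),
    objective = final$F,
    objective_trace = res$objective_trace,
    stage_traces = traces,
    n_iter = res$n_iter,
    converged = res$converged,
    grad_norm = res$grad_norm,
    sigma2 = sigma2
  )
}

#' @export
print.mmp_fit <- function(x, ...) {
  gl <- glance(x)
  cat(sprintf("<mmp_fit> %d window(s), %d SNPs, total objective %.6g, %s\n",
              gl$n_windows, gl$n_snps, gl$objective,
              if (gl$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Extract the full effect-size vector from a fit
#' @param object An `mmp_fit`.
#' @param ... Unused.
#' @return Named numeric vector in variant order.
#' @export
coef.mmp_fit <- function(object, ...) {
  out <- numeric(length(object$variant_id))
  names(out) <- object$variant_id
  for (w in object$windows) out[w$variant_id] <- w$beta_hat
  out
}
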