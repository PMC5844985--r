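#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a mixture-model fit into per-SNP rows
#'
#' @param x An `mmp_fit` from [fit_mixture_model()].
#' @param ... Unused.
#' @return Tibble with `variant_id`, `window_id`, `beta_hat`,
#'   `responsibility`, `selected` (responsibility > 0.5), in the original
#'   variant order.
#' @method tidy mmp_fit
#' @export
tidy.mmp_fit <- function(x, ...) {
  rows <- purrr::map(x$windows, function(w) {
    tibble::tibble(
      variant_id = w$variant_id,
      window_id = w$window_id,
      beta_hat = w$beta_hat,
      responsibility = w$responsibilities
    )
  }) |> purrr::list_rbind()
  rows <- rows[match(x$variant_id, rows$variant_id), ]
  rows$selected <- rows$responsibility > 0.5
  rows
}

#' One-row fit summary
#'
#' @param x An `mmp_fit`.
#' @param ... Unused.
#' @return Tibble with `n_windows`, `n_snps`, `objective` (sum over
#'   windows), `n_iter` (total NCG iterations of the final annealing
#'   stage), `converged` (all windows), `max_grad_norm`, `n_selected`.
#' @method glance mmp_fit
#' @export
glance.mmp_fit <- function(x, ...) {
  tibble::tibble(
    n_windows = length(x$windows),
    n_snps = length(x$variant_id),
    objective = sum(purrr::map_dbl(x$windows, "objective")),
    n_iter = sum(purrr::map_int(x$windows, "n_iter")),
    converged = all(purrr::map_lgl(x$windows, "converged")),
    max_grad_norm = max(purrr::map_dbl(x$windows, "grad_norm")),
    n_selected = sum(tidy(x)$selected)
  )
}

#' Plot a benchmark: accuracy metrics by method
#'
#' One panel per metric (correlation, NMSE, PPV, NPV), points per
#' replicate with a crossbar at the method mean.
#'
#' @param object A `mixpen_benchmark` tibble from [benchmark_compare()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mixpen_benchmark
#' @export
autoplot.mixpen_benchmark <- function(object, ...) {
  long <- tidyr::pivot_longer(
    dplyr::filter(object, !.data$failed),
    cols = c("correlation", "nmse", "ppv", "npv"),
    names_to = "metric", values_to = "value"
  ) |>
    dplyr::filter(!is.na(.data$value))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$method, y = .data$value)) +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.5, size = 1) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.5,
                          linewidth = 0.3, colour = "firebrick") +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Method comparison on simulated replicates") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Sparsity-sweep curves
#'
#' Plots a metric against the sparsity parameter for sweep-style
#' benchmarks. For mixture sweeps the x axis (prior causal probability)
#' is reversed so that moving right always means a sparser fit, matching
#' the direction of a LASSO lambda sweep.
#'
#' @param bench A `mixpen_benchmark` with a swept `sparsity_param`.
#' @param metric Column to plot (default `"correlation"`).
#' @param reverse_x Reverse the x axis (use for pi1 sweeps).
#' @return A ggplot object.
#' @export
plot_sweep <- function(bench, metric = "correlation", reverse_x = FALSE) {
  df <- dplyr::filter(bench, !.data$failed, !is.na(.data[[metric]]))
  df$x <- if (reverse_x) -log10(df$sparsity_param) else log10(df$sparsity_param)
  xlab <- if (reverse_x) "-log10(sparsity parameter), sparser to the right"
          else "log10(sparsity parameter)"
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data[[metric]],
                                   colour = .data$method)) +
    ggplot2::stat_summary(fun = mean, geom = "line") +
    ggplot2::stat_summary(fun = mean, geom = "point") +
    ggplot2::labs(x = xlab, y = metric) +
    ggplot2::theme_minimal()
}
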