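#' Construct a genotype matrix object
#'
#' Bundles an `N x n` dosage matrix with per-variant metadata. Raw dosages
#' are additively coded (0/1/2 copies of the minor allele); after
#' [standardize_genotypes()] every column has mean 0 and unit sample
#' variance.
#'
#' @param dosages Numeric `N x n` matrix, one row per sample, one column per
#'   variant. Column names, if present, are used as variant IDs.
#' @param variant_ids Character vector of `n` variant identifiers.
#' @param chromosome Character/integer vector of `n` chromosome labels.
#' @param maf Optional numeric vector of minor allele frequencies; computed
#'   from the dosages when missing (only valid for raw dosages).
#' @param standardized Logical flag; `TRUE` when columns are centred/scaled.
#' @param window_id Optional integer vector of window assignments (see
#'   [make_windows()]).
#'
#' @return An object of class `geno_matrix`: a list with elements `dosages`
#'   (matrix) and `variants` (tibble with columns `variant_id`,
#'   `chromosome`, `maf`, `window_id`), plus a `standardized` flag.
#' @export
geno_matrix <- function(dosages, variant_ids = colnames(dosages),
                        chromosome = rep("1", ncol(dosages)),
                        maf = NULL, standardized = FALSE,
                        window_id = rep(NA_integer_, ncol(dosages))) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  n <- ncol(dosages)
  if (nrow(dosages) < 2L || n < 1L) {
    stop("genotype matrix needs at least 2 samples and 1 variant", call. = FALSE)
  }
  if (is.null(variant_ids)) variant_ids <- sprintf("snp%05d", seq_len(n))
  stopifnot(length(variant_ids) == n, length(chromosome) == n)
  if (!standardized) {
    bad <- dosages[!is.na(dosages)]
    if (!all(bad %in% c(0, 1, 2))) {
      stop("raw dosages must be coded 0/1/2 (standardize explicitly)", call. = FALSE)
    }
  }
  if (is.null(maf)) {
    if (standardized) stop("maf must be supplied for standardized dosages", call. = FALSE)
    maf <- compute_maf(dosages)
  }
  colnames(dosages) <- variant_ids
  structure(
    list(
      dosages = dosages,
      variants = tibble::tibble(
        variant_id = as.character(variant_ids),
        chromosome = as.character(chromosome),
        maf = as.numeric(maf),
        window_id = as.integer(window_id)
      ),
      standardized = isTRUE(standardized)
    ),
    class = "geno_matrix"
  )
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf(
    "<geno_matrix> %d samples x %d variants (%s), %d chromosome(s)\n",
    nrow(x$dosages), ncol(x$dosages),
    if (x$standardized) "standardized" else "raw 0/1/2",
    dplyr::n_distinct(x$variants$chromosome)
  ))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$dosages)

# minor allele frequency from raw 0/1/2 dosages (NAs ignored)
compute_maf <- function(dosages) {
  p <- colMeans(dosages, na.rm = TRUE) / 2
  pmin(p, 1 - p)
}

#' Standardize genotype dosages
#'
#' Centres each dosage column to mean zero and scales it to unit sample
#' variance (denominator `N - 1`), the usual normalization applied before
#' multivariate effect-size estimation so that effect sizes are per
#' standardized-genotype units.
#'
#' @param g A [geno_matrix()] with raw dosages.
#' @return A `geno_matrix` with standardized columns and the
#'   `standardized` flag set; variant metadata (including raw MAF) retained.
#' @export
standardize_genotypes <- function(g) {
  stopifnot(inherits(g, "geno_matrix"))
  if (g$standardized) {
    stop("genotypes are already standardized", call. = FALSE)
  }
  x <- g$dosages
  mu <- colMeans(x)
  sdv <- apply(x, 2L, stats::sd)
  if (any(sdv <= 0 | !is.finite(sdv))) {
    bad <- g$variants$variant_id[sdv <= 0 | !is.finite(sdv)]
    stop("zero-variance column(s): ", paste(utils::head(bad, 5L), collapse = ", "),
         " (filter monomorphic variants first)", call. = FALSE)
  }
  x <- sweep(sweep(x, 2L, mu, "-"), 2L, sdv, "/")
  out <- g
  out$dosages <- x
  out$standardized <- TRUE
  out
}

#' Partition variants into fitting windows
#'
#' Assigns every variant to a window and spreads a total narrow-sense
#' heritability budget evenly across windows, yielding the per-window
#' residual-variance model used by the likelihood. With one window per
#' chromosome and `total_h2 = 0.5` over 22 chromosomes the per-window
#' heritability is 0.5/22 (about 0.0227).
#'
#' @param g A [geno_matrix()].
#' @param scheme `"per_chromosome"` (one window per chromosome label, in
#'   order of first appearance) or `"fixed_size"` (consecutive blocks of
#'   `size` variants).
#' @param size Window size for the `fixed_size` scheme.
#' @param total_h2 Total heritability to divide across windows.
#' @return A list with `genotypes` (the input with `window_id` filled in)
#'   and `noise`, a [noise_model()] holding per-window heritability. The
#'   residual variance is bound to a phenotype at fit time.
#' @export
make_windows <- function(g, scheme = c("per_chromosome", "fixed_size"),
                         size = NULL, total_h2 = 0.5) {
  stopifnot(inherits(g, "geno_matrix"))
  scheme <- match.arg(scheme)
  n <- ncol(g$dosages)
  if (scheme == "per_chromosome") {
    chr <- g$variants$chromosome
    wid <- as.integer(factor(chr, levels = unique(chr)))
  } else {
    if (is.null(size) || size <= 0) stop("size must be a positive integer", call. = FALSE)
    wid <- as.integer((seq_len(n) - 1L) %/% size + 1L)
  }
  g$variants$window_id <- wid
  n_windows <- max(wid)
  g$variants$window_id <- wid
  list(
    genotypes = g,
    noise = noise_model(
      n_windows = n_windows,
      h2_per_window = total_h2 / n_windows
    )
  )
}

#' Residual-noise model
#'
#' Diagonal residual covariance specified through a per-window heritability:
#' when bound to a phenotype `y`, each window's residual variance is
#' `(1 - h2_per_window) * var(y)`.
#'
#' @param n_windows Number of windows.
#' @param h2_per_window Heritability attributed to each window, in `[0, 1)`.
#' @param sigma2 Optional explicit per-window residual variance (overrides
#'   the heritability binding).
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(n_windows = 1L, h2_per_window = 0.5, sigma2 = NULL) {
  stopifnot(n_windows >= 1L, h2_per_window >= 0, h2_per_window < 1)
  if (!is.null(sigma2) && any(sigma2 <= 0)) stop("sigma2 must be > 0", call. = FALSE)
  structure(
    list(n_windows = as.integer(n_windows),
         h2_per_window = h2_per_window,
         sigma2 = sigma2),
    class = "noise_model"
  )
}

# residual variance for one window given the phenotype it is fitted against
bind_sigma2 <- function(noise, y) {
  if (!is.null(noise$sigma2)) return(noise$sigma2)
  s2 <- (1 - noise$h2_per_window) * stats::var(y)
  if (s2 <= 0) stop("bound residual variance is not positive", call. = FALSE)
  s2
}

#' @export
print.noise_model <- function(x, ...) {
  cat(sprintf("<noise_model> %d window(s), h2/window = %.4g%s\n",
              x$n_windows, x$h2_per_window,
              if (is.null(x$sigma2)) " (sigma2 bound at fit time)"
              else sprintf(", sigma2 = %.4g", x$sigma2[1])))
  invisible(x)
}
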