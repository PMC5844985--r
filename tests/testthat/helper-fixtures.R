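# fixtures built in code: small genotype panels, random regression
# instances, finite-difference oracles

rand_geno <- function(N, n, seed, maf = NULL) {
  set.seed(seed)
  if (is.null(maf)) maf <- runif(n, 0.1, 0.5)
  dos <- vapply(maf, function(p) rbinom(N, 2L, p), numeric(N))
  # guard against monomorphic draws at small N
  for (j in which(apply(dos, 2L, var) == 0)) {
    repeat {
      col <- rbinom(N, 2L, maf[j])
      if (var(col) > 0) break
    }
    dos[, j] <- col
  }
  geno_matrix(dos, variant_ids = sprintf("v%03d", seq_len(n)))
}

rand_instance <- function(N, n, seed, h2 = 0.5) {
  g <- standardize_genotypes(rand_geno(N, n, seed))
  set.seed(seed + 1000L)
  y <- rnorm(N)
  list(g = g, X = g$dosages, y = y, sigma2 = (1 - h2) * var(y))
}

# central finite differences of a scalar function of beta
fd_gradient <- function(f, beta, h = 1e-6) {
  vapply(seq_along(beta), function(j) {
    e <- numeric(length(beta)); e[j] <- h
    (f(beta + e) - f(beta - e)) / (2 * h)
  }, numeric(1))
}

fd_second <- function(f, x, h = 1e-4) {
  (f(x + h) - 2 * f(x) + f(x - h)) / h^2
}

rand_prior <- function(n, seed, null_family = "normal_spike") {
  set.seed(seed)
  prior_spec(
    pi1 = runif(n, 0.05, 0.95), slab_sd = runif(n, 0.5, 2),
    null_family = null_family,
    null_scale = 0.05, smoothing_eps = 1e-8, n = n
  )
}

# write a minimal VCF 4.2 text fixture; gts is variants x samples matrix of
# GT strings
write_vcf_fixture <- function(path, gts, chrom = rep("1", nrow(gts)),
                              alt = rep("T", nrow(gts))) {
  samples <- sprintf("S%d", seq_len(ncol(gts)))
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  body <- vapply(seq_len(nrow(gts)), function(i) {
    paste(c(chrom[i], i * 100L, sprintf("rs%d", i), "A", alt[i], ".", "PASS",
            ".", "GT", gts[i, ]), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  path
}
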