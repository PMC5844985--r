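#' Read genotype dosages from VCF or TSV
#'
#' Reads biallelic genotypes as additive dosages (0/1/2 copies of the
#' alternate allele), drops monomorphic variants and variants at or below a
#' minor-allele-frequency cutoff, and mean-imputes missing calls. Input
#' order of the retained variants is preserved.
#'
#' The TSV dialect has a header row of variant IDs and one row of dosages
#' per sample (first column `sample_id`). VCF reading uses the GT field
#' only and requires the \pkg{VariantAnnotation} package; multiallelic
#' records are skipped with a warning.
#'
#' @param path File path.
#' @param format `"tsv"` or `"vcf"`; guessed from the extension by default.
#' @param maf_min Variants with MAF `<= maf_min` are removed (default 0.01,
#'   the usual GWAS inclusion threshold).
#' @return A raw (unstandardized) [geno_matrix()].
#' @export
read_genotypes <- function(path, format = c("auto", "tsv", "vcf"), maf_min = 0.01) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) "vcf" else "tsv"
  }
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  parsed <- if (format == "vcf") read_vcf_dosages(path) else read_tsv_dosages(path)
  x <- parsed$dosages
  n_miss <- sum(is.na(x))
  if (n_miss > 0L) {
    message(sprintf("imputing %d missing genotype call(s) to column means", n_miss))
    for (j in which(colSums(is.na(x)) > 0L)) {
      m <- mean(x[, j], na.rm = TRUE)
      if (is.nan(m)) m <- 0
      x[is.na(x[, j]), j] <- m
    }
  }
  p <- colMeans(x) / 2
  maf <- pmin(p, 1 - p)
  varying <- apply(x, 2L, function(col) stats::var(col) > 0)
  keep <- maf > maf_min & varying
  if (!any(keep)) stop("all variants removed by the MAF/monomorphic filter", call. = FALSE)
  n_drop <- sum(!keep)
  if (n_drop > 0L) {
    message(sprintf("removed %d variant(s) with MAF <= %g or zero variance", n_drop, maf_min))
  }
  geno_matrix(
    dosages = x[, keep, drop = FALSE],
    variant_ids = parsed$variant_ids[keep],
    chromosome = parsed$chromosome[keep],
    maf = maf[keep]
  )
}

read_tsv_dosages <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (ncol(tab) < 2L) stop("malformed genotype TSV (need sample_id + variants): ", path, call. = FALSE)
  first <- names(tab)[1L]
  ids <- if (identical(tolower(first), "sample_id")) tab[[1L]] else NULL
  cols <- if (is.null(ids)) tab else tab[-1L]
  x <- as.matrix(cols)
  if (!is.numeric(x)) {
    bad <- which(!vapply(cols, is.numeric, logical(1)))[1L]
    stop(sprintf("malformed genotype TSV: non-numeric dosages in column '%s'", names(cols)[bad]),
         call. = FALSE)
  }
  if (!is.null(ids)) rownames(x) <- ids
  # chromosome label embedded as "chr_id" prefix when present ("1:rs42" or plain id)
  vids <- colnames(x)
  chrom <- ifelse(grepl(":", vids, fixed = TRUE), sub(":.*$", "", vids), "1")
  list(dosages = x, variant_ids = vids, chromosome = chrom)
}

read_vcf_dosages <- function(path) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE)) {
    stop("VCF input requires the VariantAnnotation package", call. = FALSE)
  }
  vcf <- VariantAnnotation::readVcf(path)
  alt <- VariantAnnotation::alt(vcf)
  multi <- lengths(alt) > 1L
  if (any(multi)) {
    warning(sprintf("skipping %d multiallelic record(s)", sum(multi)), call. = FALSE)
    vcf <- vcf[!multi]
  }
  gt <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gt)) stop("VCF has no GT field: ", path, call. = FALSE)
  dos <- apply(gt, c(1, 2), gt_to_dosage)
  rr <- SummarizedExperiment::rowRanges(vcf)
  list(
    dosages = t(dos),
    variant_ids = rownames(gt),
    chromosome = as.character(GenomicRanges::seqnames(rr))
  )
}

gt_to_dosage <- function(gt) {
  if (is.na(gt) || gt %in% c(".", "./.", ".|.")) return(NA_real_)
  alleles <- strsplit(gt, "[/|]")[[1L]]
  if (any(alleles == ".")) return(NA_real_)
  sum(alleles != "0")
}

#' Write genotype dosages to the package TSV dialect
#'
#' @param g A [geno_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(g, path) {
  stopifnot(inherits(g, "geno_matrix"))
  ids <- rownames(g$dosages)
  if (is.null(ids)) ids <- sprintf("s%05d", seq_len(nrow(g$dosages)))
  # chromosome is encoded in the header as "chrom:variant" so round-trips keep it
  vids <- ifelse(
    grepl(":", g$variants$variant_id, fixed = TRUE),
    g$variants$variant_id,
    paste0(g$variants$chromosome, ":", g$variants$variant_id)
  )
  tab <- tibble::as_tibble(g$dosages, .name_repair = "minimal")
  names(tab) <- vids
  readr::write_tsv(dplyr::bind_cols(tibble::tibble(sample_id = ids), tab), path,
                   progress = FALSE)
  invisible(path)
}

#' Read a phenotype vector
#'
#' Expects a TSV with columns `sample_id` and `value`.
#'
#' @param path File path.
#' @param g Optional [geno_matrix()]; when given, length (and, if sample IDs
#'   are available, order) is checked against the genotype rows.
#' @return A tibble with columns `sample_id`, `value`.
#' @export
read_phenotype <- function(path, g = NULL) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("sample_id", "value") %in% names(tab))) {
    stop("phenotype TSV needs columns sample_id, value: ", path, call. = FALSE)
  }
  if (!all(is.finite(tab$value))) stop("phenotype contains non-finite values", call. = FALSE)
  if (!is.null(g) && nrow(tab) != nrow(g$dosages)) {
    stop(sprintf("phenotype has %d samples but genotypes have %d",
                 nrow(tab), nrow(g$dosages)), call. = FALSE)
  }
  tibble::as_tibble(tab[c("sample_id", "value")])
}

#' Write a phenotype vector
#' @param y Numeric vector or tibble with `sample_id`, `value`.
#' @param path Output path.
#' @param sample_ids Sample IDs when `y` is a bare vector.
#' @return `path`, invisibly.
#' @export
write_phenotype <- function(y, path, sample_ids = NULL) {
  if (!is.data.frame(y)) {
    if (is.null(sample_ids)) sample_ids <- sprintf("s%05d", seq_along(y))
    y <- tibble::tibble(sample_id = sample_ids, value = as.numeric(y))
  }
  readr::write_tsv(y, path, progress = FALSE)
  invisible(path)
}

#' Read per-SNP mixture priors from a TSV
#'
#' Joins an external table of prior causal probabilities (e.g. posterior
#' inclusion probabilities exported from a fine-mapping tool such as DAP,
#' CAVIAR or PAINTOR) onto the variants of a genotype matrix. Variants not
#' present in the file receive the defaults, so an empty file yields the
#' constant-prior (MM-CP) configuration.
#'
#' @param path TSV with columns `variant_id`, `pi1` and optionally
#'   `slab_sd`.
#' @param g The [geno_matrix()] whose variant order the result follows.
#' @param default_pi1,default_slab_sd Defaults for absent variants.
#' @param ... Passed to [prior_spec()] (null family and scale).
#' @return A [prior_spec()] aligned to `g`.
#' @export
read_priors <- function(path, g, default_pi1 = 0.01, default_slab_sd = 1, ...) {
  stopifnot(inherits(g, "geno_matrix"))
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (nrow(tab) > 0L && !all(c("variant_id", "pi1") %in% names(tab))) {
    stop("prior TSV needs columns variant_id, pi1: ", path, call. = FALSE)
  }
  if (nrow(tab) == 0L) {
    tab <- tibble::tibble(variant_id = character(), pi1 = numeric())
  }
  if (any(tab$pi1 < -0.1 | tab$pi1 > 1.1)) {
    stop("pi1 values far outside [0, 1]; wrong column?", call. = FALSE)
  }
  if (any(tab$pi1 < 0 | tab$pi1 > 1)) {
    warning("clipping pi1 values to [0, 1]", call. = FALSE)
    tab$pi1 <- pmin(pmax(tab$pi1, 0), 1)
  }
  if (!"slab_sd" %in% names(tab)) tab$slab_sd <- default_slab_sd
  joined <- dplyr::left_join(
    g$variants["variant_id"],
    tab[c("variant_id", "pi1", "slab_sd")],
    by = "variant_id"
  ) |>
    dplyr::mutate(
      pi1 = dplyr::coalesce(.data$pi1, default_pi1),
      slab_sd = dplyr::coalesce(.data$slab_sd, default_slab_sd)
    )
  prior_spec(pi1 = joined$pi1, slab_sd = joined$slab_sd,
             variant_id = joined$variant_id, ...)
}

#' Read a functional-annotation table
#'
#' @param path TSV with columns `variant_id`, `category`; categories in
#'   `Exon`, `UTR3`, `UTR5` are flagged as enriched.
#' @param g Optional [geno_matrix()] to align/validate against.
#' @return Tibble with `variant_id`, `category`, `enriched`.
#' @export
read_annotations <- function(path, g = NULL) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("variant_id", "category") %in% names(tab))) {
    stop("annotation TSV needs columns variant_id, category: ", path, call. = FALSE)
  }
  if (anyDuplicated(tab$variant_id)) {
    stop("annotation table assigns multiple categories to one variant", call. = FALSE)
  }
  out <- tibble::tibble(
    variant_id = as.character(tab$variant_id),
    category = as.character(tab$category),
    enriched = tab$category %in% enriched_categories()
  )
  if (!is.null(g)) {
    out <- dplyr::left_join(g$variants["variant_id"], out, by = "variant_id") |>
      dplyr::mutate(
        category = dplyr::coalesce(.data$category, "Intergenic"),
        enriched = dplyr::coalesce(.data$enriched, FALSE)
      )
  }
  out
}

enriched_categories <- function() c("Exon", "UTR3", "UTR5")
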