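#' Genomic inflation factor
#'
#' `lambda = median(chi2_obs) / median(chi2_null)` where each p-value is
#' transformed to its 1-df chi-square quantile; the null median is
#' `qchisq(0.5, 1) = 0.4549`. Values near 1 indicate a calibrated test.
#'
#' @param pvalues numeric vector of p-values in (0, 1].
#' @return lambda (positive scalar).
#' @export
genomic_inflation <- function(pvalues) {
  if (!length(pvalues)) stop("empty p-value vector")
  if (any(is.na(pvalues)) || any(pvalues <= 0) || any(pvalues > 1))
    stop("p-values must lie in (0, 1]")
  chi <- qchisq(pvalues, df = 1, lower.tail = FALSE)
  median(chi) / qchisq(0.5, df = 1)
}

#' End-to-end multi-trait genome scan
#'
#' Pipeline: read each trait's summary file, harmonize alleles and intersect
#' SNPs, obtain the between-trait correlation matrix (estimated from the
#' panel or loaded from a file), run the four tests on every SNP, and
#' assemble results with per-trait two-sided p-values, significance flags
#' keyed to the OMNI p-value, and per-test genomic inflation factors.
#' Deterministic given inputs and configuration.
#'
#' @param trait_files character vector (>= 2) of summary file paths.
#' @param config list with elements:
#'   \describe{
#'     \item{column_map}{a single column map (see [read_trait_summary()]) or
#'       a list of one per file.}
#'     \item{trait_names}{optional labels.}
#'     \item{sigma}{path to a correlation matrix file, a matrix, or `NULL`
#'       to estimate from the panel.}
#'     \item{whitelist}{optional independent-SNP id vector or file (one id
#'       per line) used when estimating sigma.}
#'     \item{null_z_cap}{optional cap on `max|z|` for sigma estimation.}
#'     \item{threshold}{significance threshold (default `5e-8`).}
#'     \item{drop_palindromic}{default `TRUE`.}
#'     \item{method}{p-value path, `"exact"` (default) or `"interpolate"`.}
#'   }
#' @return a `scan_result`: data.frame of per-SNP results with attributes
#'   `lambda_gc` (named per-test vector), `threshold`, `sigma` and
#'   `flip_log`.
#' @export
run_scan <- function(trait_files, config = list()) {
  if (length(trait_files) < 2L) stop("need at least two trait files")
  cmap <- config$column_map %||% stop("config$column_map is required")
  if (!is.null(names(cmap)) && "snp" %in% names(cmap))
    cmap <- rep(list(cmap), length(trait_files))
  tnames <- config$trait_names %||% rep(NA_character_, length(trait_files))
  traits <- lapply(seq_along(trait_files), function(i)
    read_trait_summary(trait_files[i], cmap[[i]],
                       trait_name = if (is.na(tnames[i])) NULL else tnames[i]))
  panel <- harmonize(traits,
                     drop_palindromic = config$drop_palindromic %||% TRUE)
  sigma <- config$sigma
  if (is.null(sigma)) {
    wl <- config$whitelist
    if (is.character(wl) && length(wl) == 1L && file.exists(wl))
      wl <- readLines(wl)
    sigma <- estimate_trait_correlation(panel, null_z_cap = config$null_z_cap,
                                        snp_whitelist = wl)
  } else if (is.character(sigma)) {
    sigma <- read_correlation(sigma)
  } else {
    sigma <- trait_correlation(as.matrix(sigma))
  }
  if (nrow(sigma) != ncol(panel$z))
    stop("sigma dimension does not match the number of traits")
  threshold <- config$threshold %||% 5e-8
  method <- config$method %||% "exact"
  P <- multi_trait_pvalues(panel$z, sigma, method = method)
  # p-value underflow guard: report below-representation values at the floor
  floored <- P < 1e-300
  P[floored] <- 1e-300
  trait_p <- 2 * norm_sf(abs(panel$z))
  colnames(trait_p) <- paste0("p_", panel$trait_names)
  res <- data.frame(panel$snps[, c("snp", "chrom", "pos")], trait_p, P,
                    significant = P[, "p_omni"] < threshold,
                    p_floored = rowSums(floored) > 0,
                    stringsAsFactors = FALSE)
  lambda <- vapply(c(p_gbj = "p_gbj", p_ghc = "p_ghc", p_minp = "p_minp",
                     p_omni = "p_omni"),
                   function(cn) genomic_inflation(res[[cn]]), 0)
  attr(res, "lambda_gc") <- lambda
  attr(res, "threshold") <- threshold
  attr(res, "sigma") <- sigma
  attr(res, "flip_log") <- panel$flip_log
  class(res) <- c("scan_result", "data.frame")
  res
}

#' Select significant hits from a scan
#'
#' Filters to rows with `p_omni` below the scan threshold, optionally
#' restricts to a supplied list of approximately independent SNPs (LD
#' pruning itself needs genotype data and is delegated to the caller), and
#' sorts by ascending OMNI p-value.
#'
#' @param result a `scan_result`.
#' @param independent_snps optional character vector of SNP ids.
#' @param threshold override the scan threshold.
#' @return data.frame of hits sorted by `p_omni`.
#' @export
select_hits <- function(result, independent_snps = NULL, threshold = NULL) {
  thr <- threshold %||% attr(result, "threshold") %||% 5e-8
  hits <- result[result$p_omni < thr, , drop = FALSE]
  if (!is.null(independent_snps))
    hits <- hits[hits$snp %in% independent_snps, , drop = FALSE]
  hits[order(hits$p_omni), , drop = FALSE]
}

#' @export
print.scan_result <- function(x, ...) {
  cat("scan_result:", nrow(x), "SNPs;", sum(x$significant),
      "significant at", format(attr(x, "threshold")), "\n")
  l <- attr(x, "lambda_gc")
  cat("lambda_gc:", paste(sprintf("%s=%.3f", sub("^p_", "", names(l)), l),
                          collapse = "  "), "\n")
  invisible(x)
}
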