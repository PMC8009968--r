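#' Read one trait's GWAS summary statistics
#'
#' Parses a whitespace/tab-delimited summary file (optionally gzipped) into a
#' per-trait table of SNP records with a single Z-score per SNP. The score
#' can be supplied directly (`z`), as `beta` and `se` (then `z = beta/se`),
#' or as a two-sided p-value plus effect direction (then
#' `z = direction * qnorm(1 - p/2)`). Malformed rows (non-positive `se`,
#' p-values outside `(0, 1]`, missing fields, invalid alleles) are skipped
#' and counted, not fatal.
#'
#' @param path file path.
#' @param column_map named list mapping the roles `snp`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele` and exactly one score encoding — `z`, or
#'   `beta` + `se`, or `p` + `direction` — to column names in the file.
#' @param trait_name label for the trait (default: file name).
#' @return a `trait_summary`: `data.table` with columns `snp`, `chrom`,
#'   `pos`, `ea`, `oa`, `z`; attributes `trait_name` and `n_skipped`.
#' @export
read_trait_summary <- function(path, column_map, trait_name = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  need <- c("snp", "chrom", "pos", "effect_allele", "other_allele")
  enc <- if (!is.null(column_map$z)) "z"
         else if (!is.null(column_map$beta) && !is.null(column_map$se)) "beta"
         else if (!is.null(column_map$p) && !is.null(column_map$direction)) "p"
         else stop("column_map must declare one of: z, beta+se, p+direction")
  dt <- if (grepl("\\.b?gz$", path)) {
    # base R decompresses transparently through a gzfile connection
    data.table::fread(text = readLines(gzfile(path)), header = TRUE)
  } else {
    data.table::fread(path, header = TRUE, data.table = TRUE)
  }
  cols <- unlist(column_map)
  miss <- setdiff(cols, names(dt))
  if (length(miss))
    stop("columns not found in ", path, ": ", paste(miss, collapse = ", "))
  if (length(setdiff(need, names(column_map))))
    stop("column_map must name: ", paste(need, collapse = ", "))
  out <- data.table::data.table(
    snp = as.character(dt[[column_map$snp]]),
    chrom = as.character(dt[[column_map$chrom]]),
    pos = suppressWarnings(as.integer(dt[[column_map$pos]])),
    ea = toupper(as.character(dt[[column_map$effect_allele]])),
    oa = toupper(as.character(dt[[column_map$other_allele]])))
  z <- switch(enc,
    z = suppressWarnings(as.numeric(dt[[column_map$z]])),
    beta = {
      b <- suppressWarnings(as.numeric(dt[[column_map$beta]]))
      s <- suppressWarnings(as.numeric(dt[[column_map$se]]))
      s[!is.na(s) & s <= 0] <- NA_real_
      b / s
    },
    p = {
      p <- suppressWarnings(as.numeric(dt[[column_map$p]]))
      d <- sign(suppressWarnings(as.numeric(dt[[column_map$direction]])))
      p[!is.na(p) & (p <= 0 | p > 1)] <- NA_real_
      d[d == 0] <- NA_real_
      d * qnorm(p / 2, lower.tail = FALSE)
    })
  out[, z := z]
  bad <- !is.finite(out$z) | is.na(out$pos) | out$snp == "" |
    !(out$ea %in% c("A", "C", "G", "T")) | !(out$oa %in% c("A", "C", "G", "T"))
  n_skipped <- sum(bad)
  out <- out[!bad]
  if (anyDuplicated(out$snp))
    stop("duplicate SNP ids within trait file ", path)
  data.table::setattr(out, "trait_name",
                      trait_name %||% sub("\\.(txt|tsv|gz)+$", "", basename(path)))
  data.table::setattr(out, "n_skipped", n_skipped)
  data.table::setattr(out, "class", c("trait_summary", class(out)))
  out[]
}

complement <- c(A = "T", C = "G", G = "C", T = "A")
is_palindromic <- function(ea, oa) complement[ea] == oa

#' Harmonize several trait summaries into a Z-score panel
#'
#' Intersects SNPs across traits and aligns effect alleles to a reference
#' trait: where a trait reports the swapped allele pair its Z-score is
#' negated; strand flips (complementary coding) are resolved the same way.
#' Strand-ambiguous palindromic SNPs (A/T, C/G) are dropped by default, as
#' are SNPs with irreconcilable allele pairs. All flips and drops are logged.
#'
#' @param traits list of `trait_summary` objects (>= 2).
#' @param reference_trait index of the trait whose allele coding defines the
#'   panel (default 1).
#' @param drop_palindromic drop A/T and C/G SNPs (default `TRUE`).
#' @return a `harmonized_panel`: list with `snps` (data.table `snp`, `chrom`,
#'   `pos`, `ea`, `oa`), `z` (M x K matrix), `trait_names`, and `flip_log`
#'   (data.table `snp`, `trait`, `action`).
#' @export
harmonize <- function(traits, reference_trait = 1L, drop_palindromic = TRUE) {
  if (length(traits) < 2L) stop("need at least two traits")
  names <- vapply(traits, function(x) attr(x, "trait_name") %||% "", "")
  names[names == ""] <- paste0("trait", seq_along(traits))[names == ""]
  shared <- Reduce(intersect, lapply(traits, function(x) x$snp))
  if (!length(shared)) stop("no SNPs shared by all traits")
  ref <- traits[[reference_trait]]
  ref <- ref[match(shared, ref$snp)]
  log <- list()
  keep <- rep(TRUE, length(shared))
  if (drop_palindromic) {
    pal <- is_palindromic(ref$ea, ref$oa)
    if (any(pal)) {
      log[[length(log) + 1L]] <- data.table::data.table(
        snp = ref$snp[pal], trait = names[reference_trait], action = "drop_palindromic")
      keep <- keep & !pal
    }
  }
  zmat <- matrix(NA_real_, length(shared), length(traits))
  for (j in seq_along(traits)) {
    tj <- traits[[j]][match(shared, traits[[j]]$snp)]
    if (j == reference_trait) {
      zmat[, j] <- tj$z
      next
    }
    same <- tj$ea == ref$ea & tj$oa == ref$oa
    swap <- tj$ea == ref$oa & tj$oa == ref$ea
    flip <- complement[tj$ea] == ref$ea & complement[tj$oa] == ref$oa
    flipswap <- complement[tj$ea] == ref$oa & complement[tj$oa] == ref$ea
    direct <- same | (flip & !swap & !flipswap)
    swapped <- (swap | flipswap) & !direct
    bad <- !(direct | swapped)
    zmat[, j] <- ifelse(swapped, -tj$z, tj$z)
    if (any(swapped & keep))
      log[[length(log) + 1L]] <- data.table::data.table(
        snp = shared[swapped & keep], trait = names[j], action = "flip_sign")
    if (any(bad & keep))
      log[[length(log) + 1L]] <- data.table::data.table(
        snp = shared[bad & keep], trait = names[j], action = "drop_allele_mismatch")
    keep <- keep & !bad
  }
  snps <- data.table::data.table(snp = ref$snp, chrom = ref$chrom,
                                 pos = ref$pos, ea = ref$ea, oa = ref$oa)[keep]
  panel <- list(snps = snps,
                z = zmat[keep, , drop = FALSE],
                trait_names = names,
                flip_log = if (length(log)) data.table::rbindlist(log)
                           else data.table::data.table(snp = character(),
                                                       trait = character(),
                                                       action = character()))
  colnames(panel$z) <- names
  class(panel) <- "harmonized_panel"
  panel
}

#' @export
print.harmonized_panel <- function(x, ...) {
  cat("harmonized_panel:", nrow(x$z), "SNPs x", ncol(x$z), "traits (",
      paste(x$trait_names, collapse = ", "), ")\n")
  cat("  actions logged:", nrow(x$flip_log), "\n")
  invisible(x)
}

#' Estimate the between-trait correlation matrix from a Z-score panel
#'
#' Under the null, per-SNP Z-vectors are MVN(0, sigma), so sigma is estimated
#' by the Pearson sample correlation of the Z-score columns over
#' (approximately) independent SNPs. LD pruning itself requires genotype
#' data; callers supply a precomputed whitelist of independent SNPs instead.
#' Optionally, SNPs with `max_k |z| > null_z_cap` can be excluded so strong
#' signals do not inflate the estimate (the default keeps all SNPs). The
#' result is symmetrized, given an exact unit diagonal, and projected to the
#' nearest positive semi-definite correlation matrix if sampling noise makes
#' it indefinite.
#'
#' @param panel a `harmonized_panel`.
#' @param null_z_cap optional cap on `max|z|` per SNP (default `NULL`: none).
#' @param snp_whitelist optional character vector of independent SNP ids.
#' @return a `trait_correlation` matrix with trait names.
#' @export
estimate_trait_correlation <- function(panel, null_z_cap = NULL,
                                       snp_whitelist = NULL) {
  Z <- panel$z
  keep <- rep(TRUE, nrow(Z))
  if (!is.null(snp_whitelist)) keep <- keep & panel$snps$snp %in% snp_whitelist
  if (!is.null(null_z_cap)) keep <- keep & apply(abs(Z), 1L, max) <= null_z_cap
  Z <- Z[keep, , drop = FALSE]
  if (nrow(Z) < 2L) stop("fewer than 2 usable SNPs for correlation estimation")
  if (nrow(Z) < 1000L)
    warning("correlation estimated from only ", nrow(Z),
            " SNPs; estimates may be unstable")
  m <- cor(Z)
  m <- (m + t(m)) / 2
  diag(m) <- 1
  m <- nearest_psd_correlation(m)
  sig <- trait_correlation(m)
  dimnames(sig) <- list(panel$trait_names, panel$trait_names)
  sig
}

#' Write a harmonized panel as TSV
#'
#' @param panel a `harmonized_panel`.
#' @param path output path.
#' @export
write_panel <- function(panel, path) {
  out <- cbind(panel$snps[, c("snp", "chrom", "pos")],
               data.table::as.data.table(panel$z))
  data.table::setnames(out, c("snp", "chrom", "pos",
                              paste0("z_", panel$trait_names)))
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}
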