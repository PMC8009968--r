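#' Between-trait correlation matrix
#'
#' Validates (and lightly repairs) a K x K between-trait correlation matrix:
#' symmetric, unit diagonal, off-diagonal entries in \[-1, 1\], positive
#' semi-definite up to a small eigenvalue tolerance. Trait Z-scores are
#' asymptotically MVN(0, sigma) under the null, so every test in this package
#' is parameterized by this matrix.
#'
#' @param x square numeric matrix.
#' @param tol tolerance for symmetry, unit diagonal and the smallest
#'   eigenvalue (default `1e-8`).
#' @return the validated matrix with class `"trait_correlation"`.
#' @export
#' @examples
#' trait_correlation(diag(3))
#' exchangeable_correlation(4, 0.3)
trait_correlation <- function(x, tol = 1e-8) {
  x <- as.matrix(x)
  if (nrow(x) != ncol(x) || !is.numeric(x))
    stop("`x` must be a square numeric matrix")
  if (any(!is.finite(x))) stop("correlation matrix has non-finite entries")
  if (max(abs(x - t(x))) > tol) stop("correlation matrix is not symmetric")
  x <- (x + t(x)) / 2
  if (max(abs(diag(x) - 1)) > tol) stop("correlation matrix diagonal must be 1")
  diag(x) <- 1
  if (max(abs(x)) > 1 + tol) stop("correlation entries must lie in [-1, 1]")
  x[x > 1] <- 1; x[x < -1] <- -1
  if (nrow(x) > 1) {
    ev <- eigen(x, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -tol)
      stop("correlation matrix is not positive semi-definite (min eigenvalue ",
           format(min(ev)), ")")
  }
  structure(x, class = c("trait_correlation", class(matrix())))
}

#' @rdname trait_correlation
#' @param K number of traits.
#' @param rho common off-diagonal correlation; must satisfy
#'   `rho >= -1/(K-1)` for positive semi-definiteness.
#' @export
exchangeable_correlation <- function(K, rho) {
  if (K < 1) stop("K must be >= 1")
  if (K > 1 && (rho < -1 / (K - 1) - 1e-12 || rho > 1))
    stop("exchangeable rho must lie in [-1/(K-1), 1]")
  m <- matrix(rho, K, K)
  diag(m) <- 1
  trait_correlation(m)
}

# project a symmetric matrix to the nearest correlation matrix with
# non-negative eigenvalues (clip, then rescale the diagonal back to 1)
nearest_psd_correlation <- function(x) {
  x <- (x + t(x)) / 2
  e <- eigen(x, symmetric = TRUE)
  if (min(e$values) >= 0) {
    diag(x) <- 1
    return(x)
  }
  v <- pmax(e$values, 0)
  y <- e$vectors %*% (v * t(e$vectors))
  d <- sqrt(pmax(diag(y), .Machine$double.eps))
  y <- y / tcrossprod(d)
  diag(y) <- 1
  (y + t(y)) / 2
}

#' Read or write a correlation matrix as plain text
#'
#' The on-disk format is a whitespace-delimited K x K square matrix with an
#' optional single header row of trait names.
#'
#' @param path file path.
#' @return `read_correlation()` returns a `trait_correlation` matrix (with
#'   trait names as dimnames when a header is present).
#' @export
read_correlation <- function(path) {
  first <- readLines(path, n = 1L)
  toks <- strsplit(trimws(first), "[ \t,]+")[[1]]
  has_header <- any(is.na(suppressWarnings(as.numeric(toks))))
  m <- as.matrix(read.table(path, header = has_header))
  rownames(m) <- NULL
  sig <- trait_correlation(unname(m))
  if (has_header) dimnames(sig) <- list(colnames(m), colnames(m))
  sig
}

#' @rdname read_correlation
#' @param sigma correlation matrix to write.
#' @export
write_correlation <- function(sigma, path) {
  header <- !is.null(colnames(sigma))
  write.table(format(sigma, digits = 10), path, quote = FALSE,
              row.names = FALSE, col.names = header, sep = "\t")
  invisible(path)
}
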