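# shared small helpers

.datatable.aware <- TRUE

# standard normal survival function
norm_sf <- function(x) pnorm(x, lower.tail = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

# run code with a locally fixed RNG state, restoring the caller's stream
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# validate a K-vector of Z-scores
check_z <- function(z) {
  if (!is.numeric(z) || length(z) < 1L)
    stop("`z` must be a numeric vector of length >= 1")
  if (!all(is.finite(z)))
    stop("`z` must contain only finite values")
  invisible(z)
}
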