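#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded at `seed`, then restores the
#' previous RNG state, so generators are bit-reproducible without clobbering
#' the caller's random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
check_finite <- function(x, what) {
  if (!all(is.finite(x)))
    stop(sprintf("non-finite values in %s", what), call. = FALSE)
  invisible(x)
}

# largest eigenvalue of a symmetric PSD matrix by power iteration
power_lambda_max <- function(A, iter = 100L, tol = 1e-10) {
  d <- nrow(A)
  if (d == 0L) return(0)
  v <- rep(1 / sqrt(d), d)
  lam <- 0
  for (i in seq_len(iter)) {
    w <- A %*% v
    nw <- sqrt(sum(w^2))
    if (nw == 0) return(0)
    v_new <- as.numeric(w / nw)
    lam_new <- nw
    if (abs(lam_new - lam) <= tol * max(1, lam_new) && i > 3L) {
      lam <- lam_new
      break
    }
    v <- v_new
    lam <- lam_new
  }
  lam
}
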