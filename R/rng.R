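#' Derive a reproducible substream seed
#'
#' All simulator randomness flows from one explicit seed. Per-well (and
#' per-field) random streams are derived from the master seed and an integer
#' counter, so that adding, removing or reordering wells never perturbs the
#' draws of any other well.
#'
#' @param seed master integer seed.
#' @param counter non-negative integer stream index.
#' @return an integer seed, always in `[1, 2^31 - 2]`.
#' @keywords internal
substream_seed <- function(seed, counter) {
  # multiplicative hash on doubles; operands stay far below 2^53 so the
  # arithmetic is exact
  s <- (abs(as.double(seed)) %% 2147483647) + 1
  v <- (s * 48271 + as.double(counter) * 9973 + 12345) %% 2147483647
  as.integer(v + 1)
}

#' Evaluate an expression under a local RNG state
#'
#' Saves and restores `.Random.seed` so simulator internals do not disturb
#' the caller's random stream.
#'
#' @param seed integer seed for the local stream.
#' @param expr expression to evaluate.
#' @keywords internal
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# lognormal multiplicative noise with mean exactly 1 and the requested
# coefficient of variation; cv = 0 degenerates to the constant 1
rlnorm1 <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  s2 <- log(1 + cv^2)
  stats::rlnorm(n, meanlog = -s2 / 2, sdlog = sqrt(s2))
}
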