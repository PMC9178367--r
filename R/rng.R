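#' Derive a reproducible child seed from a root seed
#'
#' Deterministic Lehmer-style mixing so that independent random streams
#' (per habitat, per run) can be derived from one root seed without
#' consuming the global RNG. Growing an ensemble or a sweep extends the
#' stream without perturbing earlier draws.
#'
#' @param seed integer root seed.
#' @param index nonnegative integer stream index.
#' @return an integer in `[1, 2^31 - 2]`, usable with [set.seed()].
#' @export
derive_seed <- function(seed, index = 0L) {
  m <- 2147483647  # 2^31 - 1, Mersenne prime
  s <- as.numeric(seed) %% m
  # two multiplicative rounds keep products below 2^53 (exact in doubles)
  s <- (48271 * s + 16807 * (as.numeric(index) %% m)) %% m
  s <- (69621 * s + 1) %% m
  as.integer(s + (s == 0))
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG state afterwards. seed = NULL uses the
# current global stream (and advances it).
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
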