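#' Community parameters for a GLV metacommunity
#'
#' Bundles the species-pool size and the statistical and demographic
#' parameters shared by all habitats: connectance `c` (proportion of
#' nonzero off-diagonal interactions), the mean `mu` and standard
#' deviation `sigma` of the nonzero interaction strengths, intrinsic
#' growth rates `r`, carrying capacities `K`, per-species dispersal
#' rates `D`, and the extinction threshold below which a species is
#' counted as globally extinct.
#'
#' Defaults follow the standard convention for this model class:
#' `r = K = 1` for every species, a common scalar dispersal rate, and an
#' extinction cutoff of `1e-5` biomass-density units.
#'
#' @param N species-pool size (positive integer).
#' @param c connectance in `(0, 1]`.
#' @param mu mean of nonzero interaction strengths.
#' @param sigma standard deviation (>= 0) of nonzero interaction strengths.
#' @param r intrinsic growth rates; scalar or length-`N`, all > 0.
#' @param K carrying capacities; scalar or length-`N`, all > 0.
#' @param D dispersal rates; scalar or length-`N`, all >= 0.
#' @param extinction_threshold positive density below which a species is
#'   considered extinct (strictly below: a density exactly at the
#'   threshold counts as extant).
#' @return an object of class `community_params`.
#' @examples
#' p <- community_params(N = 50, c = 1, mu = 0, sigma = 1.25 / sqrt(50))
#' p
#' @export
community_params <- function(N, c = 1, mu = 0, sigma = 0.1,
                             r = 1, K = 1, D = 1,
                             extinction_threshold = 1e-5) {
  N <- as.integer(N)
  stopifnot(length(N) == 1L, N >= 1L)
  if (!(length(c) == 1L && c > 0 && c <= 1))
    stop("connectance `c` must lie in (0, 1]")
  stopifnot(length(mu) == 1L, is.finite(mu))
  if (!(length(sigma) == 1L && sigma >= 0))
    stop("`sigma` must be a nonnegative scalar")
  r <- rep_len(as.numeric(r), N)
  K <- rep_len(as.numeric(K), N)
  D <- rep_len(as.numeric(D), N)
  if (any(r <= 0)) stop("all growth rates `r` must be strictly positive")
  if (any(K <= 0)) stop("all carrying capacities `K` must be strictly positive")
  if (any(D < 0)) stop("dispersal rates `D` must be nonnegative")
  if (!(length(extinction_threshold) == 1L && extinction_threshold > 0))
    stop("`extinction_threshold` must be a positive scalar")
  structure(
    list(N = N, c = as.numeric(c), mu = as.numeric(mu),
         sigma = as.numeric(sigma), r = r, K = K, D = D,
         extinction_threshold = as.numeric(extinction_threshold)),
    class = "community_params"
  )
}

#' @export
print.community_params <- function(x, ...) {
  cat(sprintf("GLV community parameters: N = %d, c = %g, mu = %g, sigma = %g\n",
              x$N, x$c, x$mu, x$sigma))
  cat(sprintf("  complexity sigma*sqrt(cN) = %.4g\n",
              complexity_proxy(x$sigma, x$c, x$N)))
  cat(sprintf("  r in [%g, %g], K in [%g, %g], D in [%g, %g], extinction < %g\n",
              min(x$r), max(x$r), min(x$K), max(x$K), min(x$D), max(x$D),
              x$extinction_threshold))
  invisible(x)
}

# replace dispersal rates, keeping everything else
set_dispersal <- function(params, D) {
  params$D <- rep_len(as.numeric(D), params$N)
  if (any(params$D < 0)) stop("dispersal rates `D` must be nonnegative")
  params
}
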