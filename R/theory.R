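#' Closed-form moments of the effective interaction matrix
#'
#' The coherent-limit effective matrix is the average of `G` habitat
#' matrices, so its entries have smaller variance than the local ones —
#' heterogeneity reduces effective complexity. These functions give the
#' closed forms for the three correlation structures.
#'
#' `moments_independent()`: habitats are independent draws with
#' independent Bernoulli(`c`) presence, so over all off-diagonal
#' positions
#' \deqn{\bar\mu = c\mu, \qquad \bar\sigma^2 = \frac{c}{G}\left(\sigma^2 +
#'   \mu^2 (1 - c)\right).}
#'
#' `variance_equicorrelated()`: a shared mask and pairwise entry
#' correlation `rho` between any two habitats give, over present
#' positions,
#' \deqn{\bar\sigma^2_\rho = \frac{\sigma^2}{G}\left(1 + (G-1)\rho\right),}
#' which saturates at `rho * sigma^2` as `G` grows.
#'
#' `variance_nn_chain()`: habitats on a chain with nearest-neighbor
#' correlation `rho_nn` (decaying as `rho_nn^lag`) give
#' \deqn{\bar\sigma^2_{nn} = \sigma^2 \frac{G + 2\sum_{\eta=1}^{G-1}
#'   \rho_{nn}^\eta (G - \eta)}{G^2},}
#' which tends to 0 as `G` grows for any `rho_nn < 1`.
#'
#' @param c connectance in `(0, 1]`.
#' @param mu mean of nonzero local interaction strengths.
#' @param sigma standard deviation of nonzero local interaction strengths.
#' @param G number of habitats (>= 1).
#' @param rho pairwise correlation in `[0, 1]`.
#' @param rho_nn nearest-neighbor correlation in `[0, 1)`.
#' @return an object of class `theory_prediction`: list with `mu_bar`,
#'   `var_bar`, `sigma_bar = sqrt(var_bar)`, `regime` and `G`.
#' @examples
#' moments_independent(c = 1, mu = 0, sigma = 0.5, G = 4)   # var_bar 0.0625
#' variance_equicorrelated(sigma = 1, G = 4, rho = 0.5)     # var_bar 0.625
#' @export
moments_independent <- function(c, mu, sigma, G) {
  check_theory_args(c = c, sigma = sigma, G = G)
  var_bar <- (c / G) * (sigma^2 + mu^2 * (1 - c))
  new_theory_prediction(mu_bar = c * mu, var_bar = var_bar,
                        regime = "independent", G = G)
}

#' @rdname moments_independent
#' @export
variance_equicorrelated <- function(sigma, G, rho) {
  check_theory_args(sigma = sigma, G = G)
  if (rho < 0 || rho > 1) stop("`rho` must lie in [0, 1]")
  var_bar <- (sigma^2 / G) * (1 + (G - 1) * rho)
  new_theory_prediction(mu_bar = NA_real_, var_bar = var_bar,
                        regime = "equicorrelated", G = G, rho = rho)
}

#' @rdname moments_independent
#' @export
variance_nn_chain <- function(sigma, G, rho_nn) {
  check_theory_args(sigma = sigma, G = G)
  if (rho_nn < 0 || rho_nn >= 1) stop("`rho_nn` must lie in [0, 1)")
  eta <- seq_len(G - 1)  # empty when G = 1
  var_bar <- sigma^2 * (G + 2 * sum(rho_nn^eta * (G - eta))) / G^2
  new_theory_prediction(mu_bar = NA_real_, var_bar = var_bar,
                        regime = "nn_chain", G = G, rho_nn = rho_nn)
}

check_theory_args <- function(c = NULL, sigma = NULL, G = NULL) {
  if (!is.null(c) && !(c > 0 && c <= 1)) stop("connectance `c` must lie in (0, 1]")
  if (!is.null(sigma) && sigma < 0) stop("`sigma` must be nonnegative")
  if (!is.null(G) && G < 1) stop("`G` must be at least 1")
  invisible(NULL)
}

new_theory_prediction <- function(mu_bar, var_bar, regime, G,
                                  rho = NULL, rho_nn = NULL) {
  structure(list(mu_bar = mu_bar, var_bar = var_bar,
                 sigma_bar = sqrt(var_bar), regime = regime,
                 G = as.integer(G), rho = rho, rho_nn = rho_nn),
            class = "theory_prediction")
}

#' @export
print.theory_prediction <- function(x, ...) {
  cat(sprintf("effective-matrix moments (%s, G = %d):\n", x$regime, x$G))
  cat(sprintf("  mu_bar = %s, var_bar = %.6g, sigma_bar = %.6g\n",
              if (is.na(x$mu_bar)) "-" else format(x$mu_bar), x$var_bar,
              x$sigma_bar))
  invisible(x)
}

#' Infinite-habitat limit of the effective variance
#'
#' As the number of habitats grows, the effective variance tends to 0 for
#' independent habitats (so a large enough heterogeneous landscape can
#' support arbitrarily high local complexity), to `rho * sigma^2` for
#' equicorrelated habitats (an upper bound on the achievable richness at
#' a given correlation), and to 0 again for the nearest-neighbor chain
#' (distant habitats decorrelate).
#'
#' @param spec a [correlation_spec()].
#' @param sigma local interaction standard deviation.
#' @param c connectance (unused beyond validation; the limit is 0 for
#'   independent habitats regardless).
#' @param mu local interaction mean (unused; kept for interface symmetry).
#' @return the limiting `var_bar` (a variance scale).
#' @export
large_G_limit <- function(spec, sigma, c = 1, mu = 0) {
  stopifnot(inherits(spec, "correlation_spec"))
  check_theory_args(c = c, sigma = sigma)
  switch(spec$kind,
         independent = 0,
         equicorrelated = spec$rho * sigma^2,
         nn_chain = 0)
}

#' May-scaling complexity proxy
#'
#' `sigma * sqrt(c * N)`: the random-matrix complexity scale that governs
#' stability and feasibility of a large community; with `N` and `c`
#' fixed, `sigma` tunes complexity, and halving `c` while doubling `N`
#' leaves the proxy unchanged.
#'
#' @param sigma interaction standard deviation (>= 0).
#' @param c connectance in `(0, 1]`.
#' @param N species-pool size.
#' @return the scalar complexity `sigma * sqrt(c * N)`.
#' @export
complexity_proxy <- function(sigma, c, N) {
  check_theory_args(c = c, sigma = sigma, G = 1)
  if (N < 1) stop("`N` must be at least 1")
  sigma * sqrt(c * N)
}

#' Interaction standard deviation realizing a target complexity
#'
#' Inverse of [complexity_proxy()]: the `sigma` for which
#' `sigma * sqrt(c * N)` equals `complexity`.
#'
#' @param complexity target May-scaling complexity (>= 0).
#' @inheritParams complexity_proxy
#' @return the scalar `complexity / sqrt(c * N)`.
#' @export
sigma_for_complexity <- function(complexity, c, N) {
  if (complexity < 0) stop("`complexity` must be nonnegative")
  check_theory_args(c = c, G = 1)
  if (N < 1) stop("`N` must be at least 1")
  complexity / sqrt(c * N)
}

#' Tabulate effective-matrix moments for a parameter set
#'
#' Convenience table of `mu_bar`, `var_bar`, `sigma_bar` and the large-G
#' limit across the requested habitat counts, for one correlation
#' structure.
#'
#' @param spec a [correlation_spec()].
#' @param c,mu,sigma local interaction statistics.
#' @param G_list habitat counts to tabulate.
#' @return a data frame, one row per `G`.
#' @export
theory_table <- function(spec, c, mu, sigma, G_list) {
  stopifnot(inherits(spec, "correlation_spec"))
  rows <- lapply(G_list, function(G) {
    pred <- switch(spec$kind,
      independent = moments_independent(c, mu, sigma, G),
      equicorrelated = variance_equicorrelated(sigma, G, spec$rho),
      nn_chain = variance_nn_chain(sigma, G, spec$rho_nn))
    data.frame(kind = spec$kind, G = G,
               mu_bar = if (is.na(pred$mu_bar)) c * mu else pred$mu_bar,
               var_bar = pred$var_bar, sigma_bar = pred$sigma_bar,
               var_limit = large_G_limit(spec, sigma, c, mu))
  })
  do.call(rbind, rows)
}
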