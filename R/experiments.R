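#' Reproducible heterogeneity-richness experiment drivers
#'
#' Each driver sweeps a heterogeneity axis, simulates the spatial GLV
#' metacommunity to a coherent stationary state for several seeded
#' replicate runs, and returns a tidy richness table: one row per run,
#' every row traceable to its seed. Non-convergent runs are retained and
#' flagged (`converged = FALSE`); [summarize_richness()] excludes them
#' from fixed-point summaries.
#'
#' `run_independent_sweep()` is the extreme-heterogeneity experiment:
#' every habitat an independent interaction matrix, one habitat per patch
#' on a near-square grid (or a chain), richness recorded as the habitat
#' count `G` grows. With local complexity held above the full-coexistence
#' limit, mean relative richness rises with `G` and saturates at 1.
#'
#' @param G_list habitat counts to sweep.
#' @param n_runs replicate runs per sweep point.
#' @param params a [community_params()]; default `N = 50`, `c = 1`,
#'   `mu = 0` and `sigma` set so the May complexity `sigma * sqrt(cN)`
#'   is 1.25.
#' @param topology `"grid"` (near-square factorization of `G`) or
#'   `"chain"`.
#' @param dispersal `"adaptive"` (escalate `D` by decades until the
#'   coherence spread is below `coherence_tol`) or `"fixed"` (use `D`).
#' @param D fixed dispersal rate, or the starting rate for the adaptive
#'   policy.
#' @param coherence_tol coherence-spread target for the adaptive policy.
#' @param seed root seed; every run derives its own stream from it.
#' @param t_max,residual_tol integrator controls, see
#'   [integrate_to_equilibrium()].
#' @param verbose print one line per run.
#' @return a `richness_table` data frame with columns `experiment`, `G`,
#'   `rho`, `mu`, `run`, `seed`, `n`, `relative_richness`,
#'   `sigma_bar_emp`, `sigma_bar_theory`, `converged`, `coherent`,
#'   `D_used`.
#' @export
run_independent_sweep <- function(G_list = c(1, 2, 4, 8, 16, 32),
                                  n_runs = 5,
                                  params = NULL,
                                  topology = c("grid", "chain"),
                                  dispersal = c("adaptive", "fixed"),
                                  D = 1, coherence_tol = 1e-3,
                                  seed = 1, t_max = 1e4,
                                  residual_tol = 1e-9, verbose = FALSE) {
  topology <- match.arg(topology)
  dispersal <- match.arg(dispersal)
  if (is.null(params))
    params <- community_params(N = 50, c = 1, mu = 0,
                               sigma = sigma_for_complexity(1.25, 1, 50))
  spec <- correlation_spec("independent")
  rows <- list(); k <- 0L
  for (G in G_list) {
    land <- build_landscape(
      if (topology == "grid") near_square_grid(G) else chain1d(G),
      assignment = seq_len(G))
    theo <- sqrt(moments_independent(params$c, params$mu, params$sigma, G)$var_bar)
    for (run in seq_len(n_runs)) {
      k <- k + 1L
      run_seed <- derive_seed(seed, k)
      ens <- sample_ensemble(G, spec, params, seed = run_seed)
      res <- run_one(land, ens, params, dispersal, D, coherence_tol,
                     run_seed, t_max, residual_tol)
      eff <- effective_matrix(ens, land)
      rows[[k]] <- data.frame(
        experiment = "independent_sweep", G = G, rho = NA_real_,
        mu = params$mu, run = run, seed = run_seed,
        n = res$rich$n, relative_richness = res$rich$relative,
        sigma_bar_emp = eff$sigma_bar, sigma_bar_theory = theo,
        converged = res$eq$converged, coherent = res$coherent,
        D_used = res$D_used)
      if (verbose)
        message(sprintf("G = %d run %d: n = %d (D = %g, coherent = %s)",
                        G, run, res$rich$n, res$D_used, res$coherent))
    }
  }
  as_richness_table(do.call(rbind, rows),
                    list(experiment = "independent_sweep", params = params,
                         topology = topology, dispersal = dispersal,
                         seed = seed))
}

# integrate one landscape under the chosen dispersal policy
run_one <- function(land, ens, params, dispersal, D, coherence_tol,
                    run_seed, t_max, residual_tol) {
  init_seed <- derive_seed(run_seed, 999L)
  if (dispersal == "adaptive" && land$P > 1L) {
    ad <- find_coherent_dispersal(land, ens, params, D_init = D,
                                  coherence_tol = coherence_tol,
                                  seed = init_seed, t_max = t_max,
                                  residual_tol = residual_tol)
    eq <- ad$equilibrium; D_used <- ad$D_used; coherent <- ad$coherent
  } else {
    p <- set_dispersal(params, D * (if (all(params$D == 0)) 1 else params$D))
    eq <- integrate_to_equilibrium(land, ens, p, seed = init_seed,
                                   t_max = t_max, residual_tol = residual_tol)
    D_used <- D
    coherent <- eq$spread_max < coherence_tol
  }
  list(eq = eq, rich = global_richness(eq, params), D_used = D_used,
       coherent = coherent)
}

#' Nine-patch habitat-number sweep with correlated habitats
#'
#' The fixed-area experiment: `P` patches (a 3-by-3 grid by default)
#' hosting `H` equicorrelated habitats assigned by a uniformly random
#' surjective map (every habitat occupies at least one patch). Richness
#' is recorded as `H`, the pairwise correlation `rho`, and the
#' interaction mean `mu` vary. Low `rho` yields a strongly positive
#' habitat-richness relationship; at `rho = 1` all habitats coincide and
#' the curve is flat.
#'
#' @param H_list habitat counts (each between 1 and the patch count).
#' @param rho_list pairwise correlations to sweep.
#' @param mu_list interaction means to sweep (e.g. `c(0, -0.5)` for a
#'   mixture community and a competitive community).
#' @param rows,cols grid dimensions (default 3 x 3).
#' @param N,c_,sigma community settings; `sigma = NULL` keeps May
#'   complexity at 1.25 for the given `N` and `c_`.
#' @inheritParams run_independent_sweep
#' @return a `richness_table` data frame (columns as in
#'   [run_independent_sweep()], with `G` holding the habitat count `H`).
#' @export
run_habitat_sweep <- function(H_list = 1:9,
                              rho_list = c(0.2, 0.5, 0.8),
                              mu_list = c(0, -0.5),
                              n_runs = 50,
                              rows = 3, cols = 3,
                              N = 100, c_ = 1, sigma = NULL,
                              dispersal = c("adaptive", "fixed"),
                              D = 1, coherence_tol = 1e-3,
                              seed = 1, t_max = 1e4,
                              residual_tol = 1e-9, verbose = FALSE) {
  dispersal <- match.arg(dispersal)
  if (is.null(sigma)) sigma <- sigma_for_complexity(1.25, c_, N)
  P <- rows * cols
  if (any(H_list < 1 | H_list > P))
    stop("every H must lie between 1 and the patch count ", P)
  out <- list(); k <- 0L
  for (mu in mu_list) {
    params <- community_params(N = N, c = c_, mu = mu, sigma = sigma)
    for (rho in rho_list) {
      spec <- correlation_spec("equicorrelated", rho = rho)
      for (H in H_list) {
        theo <- sqrt(variance_equicorrelated(sigma, H, rho)$var_bar)
        for (run in seq_len(n_runs)) {
          k <- k + 1L
          run_seed <- derive_seed(seed, k)
          ens <- sample_ensemble(H, spec, params, seed = run_seed)
          assignment <- with_seed(derive_seed(run_seed, 1L),
                                  sample_surjection(H, P))
          land <- build_landscape(grid2d(rows, cols), assignment = assignment)
          res <- run_one(land, ens, params, dispersal, D, coherence_tol,
                         run_seed, t_max, residual_tol)
          eff <- effective_matrix(ens, land)
          out[[k]] <- data.frame(
            experiment = "habitat_sweep", G = H, rho = rho, mu = mu,
            run = run, seed = run_seed,
            n = res$rich$n, relative_richness = res$rich$relative,
            sigma_bar_emp = eff$sigma_bar, sigma_bar_theory = theo,
            converged = res$eq$converged, coherent = res$coherent,
            D_used = res$D_used)
          if (verbose)
            message(sprintf("mu = %g rho = %g H = %d run %d: n = %d",
                            mu, rho, H, run, res$rich$n))
        }
      }
    }
  }
  as_richness_table(do.call(rbind, out),
                    list(experiment = "habitat_sweep", N = N, c = c_,
                         sigma = sigma, rows = rows, cols = cols,
                         dispersal = dispersal, seed = seed))
}

# uniformly random surjection of P patches onto H habitats, by exact
# rejection sampling (acceptance >= H!/H^H, fast for H <= 9)
sample_surjection <- function(H, P) {
  if (H > P) stop("cannot place ", H, " habitats surjectively on ", P, " patches")
  if (H == 1L) return(rep(1L, P))
  if (H == P) return(sample.int(P))
  for (i in seq_len(100000L)) {
    a <- sample.int(H, P, replace = TRUE)
    if (length(unique(a)) == H) return(a)
  }
  stop("surjection rejection sampling failed")  # unreachable for P <= 9
}

#' One-dimensional nearest-neighbor-correlated chain sweep
#'
#' Habitats arranged along a chain, one per patch, with interaction
#' strengths correlated as `rho_nn^distance`. Records richness and the
#' empirical effective-matrix standard deviation next to its closed-form
#' prediction, as the chain length `G` and `rho_nn` vary.
#'
#' @param G_list chain lengths to sweep.
#' @param rho_nn_list nearest-neighbor correlations.
#' @inheritParams run_habitat_sweep
#' @export
run_nn_chain_sweep <- function(G_list = c(2, 4, 8, 16),
                               rho_nn_list = c(0, 0.5, 0.9),
                               n_runs = 10,
                               N = 50, c_ = 1, mu = 0, sigma = NULL,
                               dispersal = c("adaptive", "fixed"),
                               D = 1, coherence_tol = 1e-3,
                               seed = 1, t_max = 1e4,
                               residual_tol = 1e-9, verbose = FALSE) {
  dispersal <- match.arg(dispersal)
  if (is.null(sigma)) sigma <- sigma_for_complexity(1.25, c_, N)
  params <- community_params(N = N, c = c_, mu = mu, sigma = sigma)
  out <- list(); k <- 0L
  for (rho_nn in rho_nn_list) {
    spec <- correlation_spec("nn_chain", rho_nn = rho_nn)
    for (G in G_list) {
      land <- build_landscape(chain1d(G), assignment = seq_len(G))
      theo <- sqrt(variance_nn_chain(sigma, G, rho_nn)$var_bar)
      for (run in seq_len(n_runs)) {
        k <- k + 1L
        run_seed <- derive_seed(seed, k)
        ens <- sample_ensemble(G, spec, params, seed = run_seed)
        res <- run_one(land, ens, params, dispersal, D, coherence_tol,
                       run_seed, t_max, residual_tol)
        eff <- effective_matrix(ens, land)
        out[[k]] <- data.frame(
          experiment = "nn_chain_sweep", G = G, rho = rho_nn, mu = mu,
          run = run, seed = run_seed,
          n = res$rich$n, relative_richness = res$rich$relative,
          sigma_bar_emp = eff$sigma_bar, sigma_bar_theory = theo,
          converged = res$eq$converged, coherent = res$coherent,
          D_used = res$D_used)
        if (verbose)
          message(sprintf("rho_nn = %g G = %d run %d: n = %d",
                          rho_nn, G, run, res$rich$n))
      }
    }
  }
  as_richness_table(do.call(rbind, out),
                    list(experiment = "nn_chain_sweep", N = N, c = c_,
                         mu = mu, sigma = sigma, dispersal = dispersal,
                         seed = seed))
}

#' Coherence scan: spread and reduction error across dispersal rates
#'
#' For one fixed heterogeneous ensemble on one landscape, integrates the
#' spatial system at each dispersal rate in `D_list`, simulates the
#' effective well-mixed system once, and records the coherence spread and
#' the full-vs-effective discrepancy per `D`. As dispersal grows the
#' spread shrinks and the effective reduction becomes accurate.
#'
#' @param D_list dispersal rates (default three decades, 1 to 1000).
#' @param rows,cols grid dimensions of the landscape.
#' @param N,c_,mu,sigma community settings (`sigma = NULL`: May
#'   complexity 1.25).
#' @param seed seed fixing the ensemble and initial conditions.
#' @inheritParams run_independent_sweep
#' @return a data frame with one row per `D`: `D`, `spread`,
#'   `max_relative_density_error`, `richness_spatial`,
#'   `richness_effective`, `converged`.
#' @export
run_coherence_scan <- function(D_list = 10^(0:3),
                               rows = 3, cols = 3,
                               N = 50, c_ = 1, mu = 0, sigma = NULL,
                               seed = 1, t_max = 1e4,
                               residual_tol = 1e-9, verbose = FALSE) {
  if (is.null(sigma)) sigma <- sigma_for_complexity(1.25, c_, N)
  params <- community_params(N = N, c = c_, mu = mu, sigma = sigma)
  P <- rows * cols
  ens <- sample_ensemble(P, correlation_spec("independent"), params,
                         seed = derive_seed(seed, 1L))
  land <- build_landscape(grid2d(rows, cols), assignment = seq_len(P))
  eff <- effective_matrix(ens, land)
  eff_eq <- simulate_effective(eff, params, seed = derive_seed(seed, 2L),
                               t_max = t_max, residual_tol = residual_tol)
  rows_out <- lapply(D_list, function(D) {
    p <- set_dispersal(params, D)
    eq <- integrate_to_equilibrium(land, ens, p,
                                   seed = derive_seed(seed, 3L),
                                   t_max = t_max,
                                   residual_tol = residual_tol)
    disc <- full_vs_effective_discrepancy(eq, eff_eq, params)
    if (verbose)
      message(sprintf("D = %g: spread = %.3g, error = %.3g",
                      D, eq$spread_max, disc$max_relative_density_error))
    data.frame(D = D, spread = eq$spread_max,
               max_relative_density_error = disc$max_relative_density_error,
               richness_spatial = global_richness(eq, params)$n,
               richness_effective = eff_eq$richness,
               converged = eq$converged && eff_eq$converged)
  })
  out <- do.call(rbind, rows_out)
  attr(out, "config") <- list(experiment = "coherence_scan", N = N, c = c_,
                              mu = mu, sigma = sigma, seed = seed)
  out
}

as_richness_table <- function(df, config) {
  attr(df, "config") <- config
  class(df) <- c("richness_table", class(df))
  df
}

#' Aggregate a richness table
#'
#' Mean and standard deviation of richness per sweep cell, computed from
#' the raw rows. Non-convergent runs are excluded from the summaries; the
#' number excluded is reported per cell.
#'
#' @param tbl a `richness_table` from one of the experiment drivers.
#' @param by grouping columns (default the sweep axes present).
#' @return a data frame with per-cell `n_runs`, `n_excluded`,
#'   `mean_richness`, `sd_richness`, `mean_relative`,
#'   `mean_sigma_bar_emp`, `mean_sigma_bar_theory`.
#' @export
summarize_richness <- function(tbl, by = intersect(c("experiment", "G", "rho", "mu"),
                                                   names(tbl))) {
  stopifnot(is.data.frame(tbl), all(by %in% names(tbl)))
  # sweep axes may hold NA (e.g. rho in the independent sweep): keep them
  keycols <- lapply(tbl[by], function(v) {
    v <- as.character(v); v[is.na(v)] <- "<NA>"; v
  })
  key <- interaction(keycols, drop = TRUE, lex.order = TRUE)
  parts <- split(as.data.frame(tbl), key)
  out <- lapply(parts, function(d) {
    ok <- d[d$converged, , drop = FALSE]
    cbind(d[1L, by, drop = FALSE],
          data.frame(n_runs = nrow(d), n_excluded = nrow(d) - nrow(ok),
                     mean_richness = mean(ok$n),
                     sd_richness = stats::sd(ok$n),
                     mean_relative = mean(ok$relative_richness),
                     mean_sigma_bar_emp = mean(ok$sigma_bar_emp),
                     mean_sigma_bar_theory = mean(ok$sigma_bar_theory)))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[do.call(order, res[by]), , drop = FALSE]
}

#' Write a richness table (or its summary) as CSV
#'
#' @param tbl a data frame from an experiment driver.
#' @param file output path.
#' @export
write_richness_table <- function(tbl, file) {
  utils::write.csv(as.data.frame(tbl), file, row.names = FALSE)
  invisible(file)
}

# near-square factorization of G: rows * cols = G with rows <= cols and
# rows as large as possible (primes fall back to a 1 x G chain-like grid)
near_square_grid <- function(G) {
  G <- as.integer(G)
  rows <- as.integer(floor(sqrt(G)))
  while (rows > 1L && G %% rows != 0L) rows <- rows - 1L
  grid2d(rows, G %/% rows)
}

#' Quick-look plot of a richness sweep
#'
#' Mean richness with one-standard-deviation error bars against the
#' heterogeneity axis, one line per `(rho, mu)` cell. Base graphics.
#'
#' @param x a `richness_table`.
#' @param relative plot relative richness `n/N` instead of counts.
#' @param ... passed to [plot()].
#' @export
plot.richness_table <- function(x, relative = TRUE, ...) {
  s <- summarize_richness(x)
  yv <- if (relative) s$mean_relative else s$mean_richness
  ok <- x$relative_richness > 0
  pool <- if (any(ok)) max(x$n[ok] / x$relative_richness[ok]) else 1
  sdv <- s$sd_richness / (if (relative) pool else 1)
  cells <- unique(s[, intersect(c("rho", "mu"), names(s)), drop = FALSE])
  plot(range(s$G), range(c(yv - sdv, yv + sdv), na.rm = TRUE), type = "n",
       xlab = "number of habitats",
       ylab = if (relative) "relative richness n/N" else "richness n", ...)
  for (i in seq_len(nrow(cells))) {
    sel <- rep(TRUE, nrow(s))
    for (col in names(cells)) {
      v <- cells[i, col]
      sel <- sel & (is.na(s[[col]]) == is.na(v)) &
        (is.na(v) | s[[col]] == v)
    }
    d <- s[sel, , drop = FALSE]
    graphics::lines(d$G, yv[sel], type = "b", pch = 19, col = i)
    graphics::arrows(d$G, yv[sel] - sdv[sel], d$G, yv[sel] + sdv[sel],
                     angle = 90, code = 3, length = 0.03, col = i)
  }
  invisible(x)
}
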