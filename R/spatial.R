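#' Right-hand side of the spatial GLV system
#'
#' For species `i` at patch `p` with habitat matrix `A^(p)`:
#' `d(phi)/dt = r_i phi (1 - phi / K_i) + phi * sum_j A^(p)_ij phi_j +
#' D_i * Laplacian(phi) / h^2`. Exposed mainly for testing and for users
#' who want to drive their own integrator; [integrate_to_equilibrium()]
#' is the standard entry point.
#'
#' @param densities `P x N` matrix of abundance densities.
#' @param landscape a [build_landscape()] object whose assignment indexes
#'   into `ensemble`.
#' @param ensemble a [sample_ensemble()] object.
#' @param params a [community_params()] object (supplies `r`, `K`, `D`).
#' @return a `P x N` matrix of time derivatives.
#' @export
glv_rhs <- function(densities, landscape, ensemble, params) {
  stopifnot(inherits(landscape, "landscape"),
            inherits(ensemble, "habitat_ensemble"),
            inherits(params, "community_params"))
  if (max(landscape$assignment) > ensemble$G)
    stop("landscape assignment refers to habitats beyond the ensemble")
  densities <- as.matrix(densities)
  if (nrow(densities) != landscape$P || ncol(densities) != params$N)
    stop("`densities` must be patches x N")
  A <- lapply(ensemble$matrices[landscape$assignment], `[[`, "entries")
  interaction <- matrix(0, landscape$P, params$N)
  for (p in seq_len(landscape$P))
    interaction[p, ] <- A[[p]] %*% densities[p, ]
  growth <- sweep(1 - sweep(densities, 2L, params$K, "/"), 2L, params$r, "*")
  densities * (growth + interaction) +
    dispersal_term(densities, landscape, params$D)
}

# internal fast RHS on the species-fastest state vector y (length N*P);
# pre: ctx holds A (list over patches), L (Laplacian), r, K, D, h2, N, P.
# The field is NOT clamped here: the smooth GLV flow keeps phi = 0
# invariant, numerical undershoots are atol-sized and decay back to zero,
# and a kink at zero would wreck the stiff solver's Newton iteration
glv_rhs_vec <- function(t, y, ctx) {
  Phi <- matrix(y, ctx$N, ctx$P)
  interaction <- matrix(0, ctx$N, ctx$P)
  for (p in seq_len(ctx$P))
    interaction[, p] <- ctx$A[[p]] %*% Phi[, p]
  dPhi <- Phi * (ctx$r * (1 - Phi / ctx$K) + interaction) +
    (ctx$D * (Phi %*% ctx$tL)) / ctx$h2
  list(as.vector(dPhi))
}

#' Integrate the spatial GLV system to a stationary state
#'
#' Adaptive-step integration (lsodar, which switches automatically
#' between stiff and non-stiff methods) until the residual
#' `max |d(phi)/dt|` falls below
#' `residual_tol`, or `t_max` is reached. The stopping conditions are
#' posed as solver root functions, so one solver call runs to the exact
#' stopping time. Numerically negative densities (tiny undershoots of
#' the absorbing zero state) are clamped to zero in the reported
#' equilibrium. Trajectories that blow up (a known GLV regime at
#' high complexity and weak coupling: abundances diverge in finite time)
#' are intercepted by a root function at `|phi| = phi_max` and reported
#' as `diverged`, never as an error. When the patch graph keeps coupled
#' state entries close together (grids and chains), a banded Jacobian is
#' used, which is substantially faster for stiff high-dispersal runs.
#'
#' The final approach to a fixed point can be very slow (per-capita
#' rates scale with the equilibrium densities, which are small in
#' strongly competitive communities), so by default the integration
#' stops at a coarse residual (`coarse_tol`) and the equilibrium is
#' polished by Newton iteration on the stationarity equations, using the
#' analytic Jacobian. The polished point is accepted only if Newton
#' converges below `residual_tol` near the coarse state and no
#' below-threshold species could invade it (all their local per-capita
#' growth rates are negative — a sufficient non-invasibility condition,
#' since the dispersal operator cannot create growth); otherwise the
#' integration simply resumes to the strict tolerance.
#'
#' @inheritParams glv_rhs
#' @param initial `P x N` matrix of strictly positive starting densities,
#'   or `NULL` to draw i.i.d. uniform on `[0.1, 1]` from `seed`.
#' @param seed integer seed for the default initial condition.
#' @param t_max integration horizon (default `1e4` time units).
#' @param rtol,atol relative/absolute integration tolerances.
#' @param residual_tol stationarity criterion on `max |d(phi)/dt|`.
#' @param phi_max divergence guard: integration stops if any density
#'   exceeds this value.
#' @param polish use Newton polishing from the coarse residual (default
#'   `TRUE`).
#' @param coarse_tol residual at which integration hands over to Newton.
#' @return an object of class `spatial_equilibrium`: list with
#'   `densities` (`P x N`, clamped nonnegative), `converged`, `diverged`,
#'   `residual`, `t_final`, `coherence_spread` (per extant species) and
#'   `spread_max`.
#' @export
integrate_to_equilibrium <- function(landscape, ensemble, params,
                                     initial = NULL, seed = NULL,
                                     t_max = 1e4, rtol = 1e-6, atol = 1e-9,
                                     residual_tol = 1e-9, phi_max = 1e8,
                                     polish = TRUE, coarse_tol = 1e-5) {
  stopifnot(inherits(landscape, "landscape"),
            inherits(ensemble, "habitat_ensemble"),
            inherits(params, "community_params"))
  if (max(landscape$assignment) > ensemble$G)
    stop("landscape assignment refers to habitats beyond the ensemble")
  P <- landscape$P; N <- params$N
  if (is.null(initial)) {
    initial <- matrix(with_seed(seed, stats::runif(P * N, 0.1, 1)), P, N)
  } else {
    initial <- as.matrix(initial)
    if (nrow(initial) != P || ncol(initial) != N)
      stop("`initial` must be patches x N")
    if (any(initial <= 0)) stop("`initial` densities must be strictly positive")
  }
  ctx <- list(
    N = N, P = P,
    A = lapply(ensemble$matrices[landscape$assignment], `[[`, "entries"),
    tL = t(landscape$laplacian),
    r = params$r, K = params$K, D = params$D, h2 = landscape$h^2
  )
  n <- N * P
  # banded Jacobian pays off when the band is well below the full width
  bw <- N * landscape$band_offset + N - 1L
  use_band <- P > 1L && bw < 0.5 * n
  # stage the model in the compiled backend; the derivative and the two
  # stopping events (divergence: any density reaching phi_max;
  # stationarity: residual crossing the staged threshold) run as C
  # callbacks, so one solver call integrates straight to the stopping time
  neg_floor <- 1e-8
  pack <- c(P, N, landscape$h^2, phi_max, residual_tol, neg_floor,
            params$r, params$K, params$D, as.vector(landscape$laplacian),
            unlist(lapply(ctx$A, as.vector), use.names = FALSE))
  run_to_residual <- function(y, t_now, target_tol) {
    pack[5] <- target_tol
    .Call(C_glv_set_model, pack)
    converged <- FALSE; diverged <- FALSE
    repeat {
      out <- tryCatch(
        suppressWarnings(deSolve::lsodar(
          y = y, times = c(t_now, t_max), func = "C_glv_deriv",
          parms = NULL, dllname = "glvmeta", initfunc = NULL, nroot = 3L,
          rootfunc = "C_glv_root",
          rtol = rtol, atol = atol,
          jactype = if (use_band) "bandint" else "fullint",
          bandup = if (use_band) bw else NULL,
          banddown = if (use_band) bw else NULL,
          maxsteps = 20000L)),
        error = function(e) e)
      if (inherits(out, "error")) { diverged <- TRUE; break }
      yy <- out[nrow(out), -1L]
      t_reached <- out[nrow(out), 1L]
      if (any(!is.finite(yy))) { y <- yy; t_now <- t_reached; diverged <- TRUE; break }
      y <- yy
      root_id <- if (is.null(attr(out, "troot"))) integer(0)
                 else which(attr(out, "iroot") != 0)
      if (1L %in% root_id) { t_now <- t_reached; diverged <- TRUE; break }
      if (2L %in% root_id) { t_now <- t_reached; converged <- TRUE; break }
      if (3L %in% root_id) {
        # a density undershot the negative floor: zero is invariant in
        # the exact dynamics, so clamp and resume from the event time
        y[y < 0] <- 0
        if (t_reached <= t_now) { diverged <- TRUE; break }
        t_now <- t_reached
        next
      }
      if (t_reached >= t_max - 1e-8) { t_now <- t_reached; break }
      if (t_reached <= t_now) { diverged <- TRUE; break }
      t_now <- t_reached  # maxsteps exhausted mid-way: resume
    }
    list(y = y, t_now = t_now, converged = converged, diverged = diverged)
  }
  first_tol <- if (polish) max(coarse_tol, residual_tol) else residual_tol
  st <- run_to_residual(as.vector(t(initial)), 0, first_tol)
  if (polish && st$converged && !st$diverged && first_tol > residual_tol) {
    pol <- newton_polish(st$y, ctx, residual_tol, phi_max)
    if (pol$ok) {
      st$y <- pol$y
    } else {
      # Newton declined (slow saddle passage or invasible species):
      # resume the dynamics to the strict tolerance
      st <- run_to_residual(st$y, st$t_now, residual_tol)
    }
  }
  y <- st$y; t_now <- st$t_now
  converged <- st$converged; diverged <- st$diverged
  densities <- t(matrix(pmax(y, 0), N, P))
  residual <- if (diverged) Inf else max(abs(glv_rhs_vec(t_now, as.vector(t(densities)), ctx)[[1L]]))
  eq <- structure(list(densities = densities,
                       converged = converged && !diverged,
                       diverged = diverged,
                       residual = residual, t_final = t_now,
                       extinction_threshold = params$extinction_threshold),
                  class = "spatial_equilibrium")
  cs <- coherence_spread(eq)
  eq$coherence_spread <- cs$per_species
  eq$spread_max <- cs$max
  eq
}

# analytic Jacobian of the spatial GLV right-hand side at state y
# (species-fastest layout). Within-patch block: diag of per-capita rates
# plus density-row-scaled interactions; dispersal adds D_i * L[p,q] / h^2
# on the same-species cross-patch diagonal.
glv_jacobian <- function(y, ctx) {
  N <- ctx$N; P <- ctx$P; n <- N * P
  Phi <- matrix(y, N, P)
  J <- matrix(0, n, n)
  for (p in seq_len(P)) {
    idx <- (p - 1L) * N + seq_len(N)
    phi <- Phi[, p]
    Ap <- ctx$A[[p]]
    block <- phi * Ap  # row i scaled by phi_i
    diag(block) <- ctx$r * (1 - 2 * phi / ctx$K) + as.vector(Ap %*% phi)
    J[idx, idx] <- block
  }
  L <- t(ctx$tL)
  for (p in seq_len(P)) for (q in seq_len(P)) {
    if (L[p, q] != 0)
      J[cbind((p - 1L) * N + seq_len(N), (q - 1L) * N + seq_len(N))] <-
        J[cbind((p - 1L) * N + seq_len(N), (q - 1L) * N + seq_len(N))] +
        ctx$D * L[p, q] / ctx$h2
  }
  J
}

# Newton iteration on 0 = f(phi) from a near-stationary state. Accepts
# only if it converges below `tol` while staying close to the start, and
# the result is non-invasible: for every species with patch-mean density
# below `floor_density`, the linearized invasion operator
# diag(per-capita growth over patches) + D_i L / h^2 has only negative
# eigenvalues (a per-species P x P symmetric eigenproblem — the exact
# criterion; at high dispersal a species can grow locally yet still be
# drained away by dispersal).
newton_polish <- function(y, ctx, tol, phi_max,
                          max_iter = 30L, floor_density = 1e-7) {
  scale0 <- max(abs(y), 1)
  y0 <- y
  f <- glv_rhs_vec(0, y, ctx)[[1L]]
  for (it in seq_len(max_iter)) {
    if (max(abs(f)) < 0.01 * tol) break
    step <- tryCatch(solve(glv_jacobian(y, ctx), f), error = function(e) NULL)
    if (is.null(step)) return(list(ok = FALSE))
    y_new <- y - step
    if (any(!is.finite(y_new)) || max(abs(y_new)) > phi_max)
      return(list(ok = FALSE))
    f_new <- glv_rhs_vec(0, y_new, ctx)[[1L]]
    if (it > 3L && max(abs(f_new)) > 0.5 * max(abs(f)))
      return(list(ok = FALSE))  # not in the quadratic basin
    y <- y_new; f <- f_new
  }
  if (max(abs(f)) >= tol) return(list(ok = FALSE))
  if (max(abs(y - y0)) > 0.1 * scale0) return(list(ok = FALSE))
  Phi <- matrix(y, ctx$N, ctx$P)
  extinct <- which(rowMeans(Phi) < floor_density)
  if (length(extinct)) {
    growth <- vapply(seq_len(ctx$P), function(p)
      ctx$r * (1 - pmax(Phi[, p], 0) / ctx$K) +
        as.vector(ctx$A[[p]] %*% pmax(Phi[, p], 0)),
      numeric(ctx$N))
    L <- t(ctx$tL)
    for (i in extinct) {
      M <- diag(growth[i, ], ctx$P) + ctx$D[i] * L / ctx$h2
      lam <- max(eigen(M, symmetric = TRUE, only.values = TRUE)$values)
      if (lam >= 0) return(list(ok = FALSE))
    }
  }
  list(ok = TRUE, y = y, iterations = it)
}

#' @export
print.spatial_equilibrium <- function(x, ...) {
  cat(sprintf(
    "spatial equilibrium: %d patches x %d species; converged = %s%s\n",
    nrow(x$densities), ncol(x$densities), x$converged,
    if (x$diverged) " (diverged)" else ""))
  cat(sprintf("  t_final = %g, residual = %.3g, max coherence spread = %.3g\n",
              x$t_final, x$residual, x$max_spread %||% x$spread_max))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write an equilibrium as tidy CSV, with an optional run log
#'
#' One row per (patch, species) with the equilibrium density. The run
#' log is a small plain-text key-value file (seed, dispersal, residual,
#' t_final, convergence flags) for provenance.
#'
#' @param equilibrium a `spatial_equilibrium`.
#' @param file CSV output path.
#' @param log_file optional path for the run log.
#' @param meta optional named list folded into the run log (e.g. seed,
#'   D_used).
#' @export
write_equilibrium <- function(equilibrium, file, log_file = NULL, meta = list()) {
  stopifnot(inherits(equilibrium, "spatial_equilibrium"))
  d <- equilibrium$densities
  tidy <- data.frame(patch = rep(seq_len(nrow(d)), times = ncol(d)),
                     species = rep(seq_len(ncol(d)), each = nrow(d)),
                     density = as.vector(d))
  utils::write.csv(tidy, file, row.names = FALSE)
  if (!is.null(log_file)) {
    log <- c(list(converged = equilibrium$converged,
                  diverged = equilibrium$diverged,
                  residual = equilibrium$residual,
                  t_final = equilibrium$t_final,
                  spread_max = equilibrium$spread_max), meta)
    writeLines(paste(names(log), vapply(log, format, character(1)),
                     sep = ": "), log_file)
  }
  invisible(file)
}

#' Spatial coherence spread of an equilibrium
#'
#' For each species whose patch-mean density is at or above the
#' extinction threshold: `(max over patches - min over patches) /
#' patch-mean`. Species below threshold are excluded; a single-patch
#' landscape has spread 0 by convention. The scalar summary is the
#' maximum over included species (0 if none). Small values diagnose the
#' high-dispersal coherent regime in which densities are (nearly) equal
#' across patches.
#'
#' @param equilibrium a `spatial_equilibrium`, or a bare `P x N` density
#'   matrix.
#' @param threshold extinction threshold (taken from the equilibrium
#'   object when available).
#' @return list with `per_species` (NA for excluded species) and `max`.
#' @export
coherence_spread <- function(equilibrium, threshold = 1e-5) {
  densities <- if (inherits(equilibrium, "spatial_equilibrium")) {
    threshold <- equilibrium$extinction_threshold %||% threshold
    equilibrium$densities
  } else as.matrix(equilibrium)
  N <- ncol(densities)
  per <- rep(NA_real_, N)
  pm <- colMeans(densities)
  if (nrow(densities) == 1L) {
    per[pm >= threshold] <- 0
    return(list(per_species = per, max = 0))
  }
  keep <- pm >= threshold
  if (any(keep)) {
    hi <- apply(densities[, keep, drop = FALSE], 2L, max)
    lo <- apply(densities[, keep, drop = FALSE], 2L, min)
    per[keep] <- (hi - lo) / pm[keep]
  }
  list(per_species = per, max = if (any(keep)) max(per[keep]) else 0)
}

#' Global species richness of an equilibrium
#'
#' A species is extant iff its patch-mean equilibrium density is at or
#' above the extinction threshold (a density exactly at the threshold
#' counts as extant; extinction is strictly below).
#'
#' @param equilibrium a `spatial_equilibrium`, an effective-system
#'   equilibrium (length-`N` vector), or a `P x N` matrix.
#' @param params a [community_params()] supplying the threshold (or pass
#'   `threshold` directly).
#' @param threshold overrides the params threshold if given.
#' @return list with `n` (count) and `relative` (`n / N`).
#' @export
global_richness <- function(equilibrium, params = NULL, threshold = NULL) {
  if (is.null(threshold))
    threshold <- if (!is.null(params)) params$extinction_threshold
                 else if (inherits(equilibrium, "spatial_equilibrium"))
                   equilibrium$extinction_threshold
                 else 1e-5
  pm <- if (inherits(equilibrium, "spatial_equilibrium"))
    colMeans(equilibrium$densities)
  else if (is.matrix(equilibrium)) colMeans(equilibrium)
  else as.numeric(equilibrium)
  n <- sum(pm >= threshold)
  list(n = n, relative = n / length(pm))
}

#' Find a dispersal rate that makes the metacommunity spatially coherent
#'
#' The coherent (high-dispersal) regime is defined by its outcome — the
#' per-species density spread across patches — rather than by a
#' particular dispersal value. Starting from `D_init`, the dispersal rate
#' is escalated in powers of `factor` (fresh seeded initial conditions
#' each time) until the coherence spread of the equilibrium drops below
#' `coherence_tol` or the rate reaches `D_init * factor^max_decades`.
#' Because the spread scales roughly as `1/D`, a measured spread is used
#' to jump directly to the decade predicted to satisfy the tolerance
#' (then verified); runs that diverge at weak coupling escalate one
#' decade at a time.
#'
#' @inheritParams integrate_to_equilibrium
#' @param D_init starting dispersal rate (applied to all species,
#'   multiplying the relative profile in `params$D`).
#' @param factor escalation factor per decade (default 10).
#' @param max_decades maximum number of decades above `D_init`.
#' @param coherence_tol target maximum coherence spread (default `1e-3`).
#' @return list with `equilibrium` (the accepted run), `D_used` (scalar
#'   multiplier), `coherent` (logical), and `trace` (data frame of the
#'   escalation path: D, spread, converged, diverged).
#' @export
find_coherent_dispersal <- function(landscape, ensemble, params,
                                    D_init = 1, factor = 10, max_decades = 4,
                                    coherence_tol = 1e-3, seed = NULL, ...) {
  D_rel <- params$D
  if (all(D_rel == 0)) D_rel <- rep(1, params$N)
  D_cap <- D_init * factor^max_decades
  trace <- NULL
  Dmult <- D_init
  best <- NULL
  repeat {
    p_k <- set_dispersal(params, Dmult * D_rel)
    eq <- integrate_to_equilibrium(landscape, ensemble, p_k, seed = seed, ...)
    trace <- rbind(trace, data.frame(D = Dmult, spread = eq$spread_max,
                                     converged = eq$converged,
                                     diverged = eq$diverged))
    if (!eq$diverged && (is.null(best) || eq$spread_max < best$spread))
      best <- list(eq = eq, D = Dmult, spread = eq$spread_max)
    done <- !eq$diverged && eq$converged && eq$spread_max < coherence_tol
    if (done || Dmult >= D_cap) break
    step <- if (eq$diverged || !is.finite(eq$spread_max) || eq$spread_max <= 0)
      1
    else  # spread ~ 1/D: jump to the decade predicted to reach the tolerance
      max(1, ceiling(log(eq$spread_max / coherence_tol, base = factor)))
    Dmult <- min(Dmult * factor^step, D_cap)
  }
  if (is.null(best))
    stop("all dispersal escalations diverged; the ensemble may be beyond the collapse regime")
  list(equilibrium = best$eq, D_used = best$D,
       coherent = best$spread < coherence_tol, trace = trace)
}
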