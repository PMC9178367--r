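# a one-habitat ensemble around a fixed matrix
fixed_ensemble <- function(A, params) {
  mask <- A != 0; diag(mask) <- FALSE
  structure(list(G = 1L,
                 matrices = list(glvmeta:::new_interaction_matrix(A, mask)),
                 spec = correlation_spec("independent"),
                 params = params, seed = NA_integer_),
            class = "habitat_ensemble")
}

test_that("GLV right-hand side vanishes at known fixed points", {
  p <- community_params(N = 1, sigma = 0)
  land <- build_landscape(grid2d(1, 1))
  ens <- fixed_ensemble(matrix(0, 1, 1), p)
  # logistic fixed point and the absorbing extinct state
  expect_equal(glv_rhs(matrix(1, 1, 1), land, ens, p), matrix(0, 1, 1))
  expect_equal(glv_rhs(matrix(0, 1, 1), land, ens, p), matrix(0, 1, 1))

  # two identical patches with equal densities: dispersal term drops out
  p2 <- community_params(N = 6, c = 1, mu = -0.1, sigma = 0.2, D = 5)
  A <- sample_interaction_matrix(p2, seed = 21)$entries
  ens2 <- fixed_ensemble(A, p2)
  land2 <- build_landscape(chain1d(2), assignment = c(1, 1))
  land1 <- build_landscape(grid2d(1, 1))
  phi <- runif(6, 0.2, 0.8)
  two <- glv_rhs(rbind(phi, phi), land2, ens2, p2)
  one <- glv_rhs(matrix(phi, 1), land1, ens2, p2)
  expect_equal(two[1, ], one[1, ], tolerance = 1e-12)
  expect_equal(two[2, ], one[1, ], tolerance = 1e-12)
})

test_that("integration reaches analytically known equilibria", {
  # logistic with symmetric diffusion: both patches converge to K = 1
  p <- community_params(N = 1, sigma = 0, D = 3)
  ens <- fixed_ensemble(matrix(0, 1, 1), p)
  land <- build_landscape(chain1d(2), assignment = c(1, 1))
  eq <- integrate_to_equilibrium(land, ens, p, seed = 1)
  expect_true(eq$converged)
  expect_equal(as.vector(eq$densities), c(1, 1), tolerance = 1e-6)

  # symmetric two-species competition: 1 - phi - 0.5 phi = 0 => phi = 2/3
  p2 <- community_params(N = 2, sigma = 0)
  A <- matrix(c(0, -0.5, -0.5, 0), 2, 2)
  eq2 <- integrate_to_equilibrium(build_landscape(grid2d(1, 1)),
                                  fixed_ensemble(A, p2), p2, seed = 2)
  expect_true(eq2$converged)
  expect_equal(as.vector(eq2$densities), c(2 / 3, 2 / 3), tolerance = 1e-6)
})

test_that("identical habitats reproduce the single-patch equilibrium everywhere", {
  p <- community_params(N = 10, c = 1, mu = 0,
                        sigma = sigma_for_complexity(0.8, 1, 10), D = 10)
  A <- sample_interaction_matrix(p, seed = 23)$entries
  ens <- fixed_ensemble(A, p)
  single <- integrate_to_equilibrium(build_landscape(grid2d(1, 1)),
                                     ens, p, seed = 3)
  spatial <- integrate_to_equilibrium(
    build_landscape(grid2d(2, 2), assignment = rep(1, 4)), ens, p, seed = 4)
  expect_true(single$converged && spatial$converged)
  ref <- as.vector(single$densities)
  for (patch in 1:4) {
    rel <- abs(spatial$densities[patch, ] - ref) / pmax(ref, 1e-8)
    expect_lt(max(rel[ref >= p$extinction_threshold]), 1e-6)
  }
  expect_lt(spatial$spread_max, 1e-6)
})

test_that("coherence spread shrinks as dispersal grows", {
  p <- community_params(N = 10, c = 1, mu = 0,
                        sigma = sigma_for_complexity(1.25, 1, 10))
  ens <- sample_ensemble(9, correlation_spec("independent"), p, seed = 25)
  land <- build_landscape(grid2d(3, 3), assignment = 1:9)
  spreads <- vapply(c(1, 10, 100, 1000), function(D) {
    eq <- integrate_to_equilibrium(land, ens, set_dispersal(p, D), seed = 5)
    eq$spread_max
  }, numeric(1))
  expect_true(all(diff(spreads) <= 0))
  expect_lt(spreads[4], spreads[1])
})

test_that("richness counting applies the threshold as a strict lower cutoff", {
  dens <- matrix(c(0.5, 2e-5, 1e-6), 1, 3)
  expect_equal(global_richness(dens, threshold = 1e-5)$n, 2)
  expect_equal(global_richness(matrix(0, 2, 4), threshold = 1e-5)$n, 0)
  # a density exactly at the threshold is extant
  expect_equal(global_richness(c(1e-5, 0.1), threshold = 1e-5)$n, 2)
  expect_equal(global_richness(c(1e-5, 0.1), threshold = 1e-5)$relative, 1)
})

test_that("coherence spread handles degenerate and uniform fields", {
  uniform <- matrix(rep(c(0.4, 0.9, 2e-6), each = 5), 5, 3)
  cs <- coherence_spread(uniform, threshold = 1e-5)
  expect_equal(cs$per_species[1:2], c(0, 0))
  expect_true(is.na(cs$per_species[3]))  # below threshold: excluded
  expect_equal(cs$max, 0)
  expect_equal(coherence_spread(matrix(c(1, 2), 1, 2), threshold = 1e-5)$max, 0)
})

test_that("equilibria are nonnegative and reproducible; divergence is flagged", {
  p <- community_params(N = 12, c = 1, mu = 0,
                        sigma = sigma_for_complexity(1.25, 1, 12), D = 2)
  ens <- sample_ensemble(4, correlation_spec("independent"), p, seed = 26)
  land <- build_landscape(grid2d(2, 2), assignment = 1:4)
  a <- integrate_to_equilibrium(land, ens, p, seed = 6)
  b <- integrate_to_equilibrium(land, ens, p, seed = 6)
  expect_true(all(a$densities >= 0))
  expect_equal(a$densities, b$densities, tolerance = 1e-8)

  # a single mutualistic pair with strong interaction diverges: flagged,
  # not raised
  pm <- community_params(N = 2, sigma = 0)
  Am <- matrix(c(0, 2, 2, 0), 2, 2)
  dv <- integrate_to_equilibrium(build_landscape(grid2d(1, 1)),
                                 fixed_ensemble(Am, pm), pm, seed = 7)
  expect_true(dv$diverged)
  expect_false(dv$converged)

  expect_error(integrate_to_equilibrium(land, ens, p,
                                        initial = matrix(0, 4, 12)),
               "strictly positive")
})

test_that("equilibria export as tidy CSV with a provenance log", {
  p <- community_params(N = 3, sigma = 0, D = 1)
  A <- matrix(0, 3, 3)
  ens <- fixed_ensemble(A, p)
  land <- build_landscape(chain1d(2), assignment = c(1, 1))
  eq <- integrate_to_equilibrium(land, ens, p, seed = 14)
  f <- tempfile(fileext = ".csv"); lg <- tempfile(fileext = ".log")
  write_equilibrium(eq, f, log_file = lg, meta = list(seed = 14))
  tidy <- utils::read.csv(f)
  expect_equal(nrow(tidy), 6)           # 2 patches x 3 species
  expect_equal(tidy$density, as.vector(eq$densities), tolerance = 1e-12)
  log <- readLines(lg)
  expect_true(any(grepl("^converged: TRUE", log)))
  expect_true(any(grepl("^seed: 14", log)))
})

test_that("adaptive dispersal search reaches the coherent regime", {
  p <- community_params(N = 8, c = 1, mu = 0,
                        sigma = sigma_for_complexity(1.0, 1, 8))
  ens <- sample_ensemble(4, correlation_spec("independent"), p, seed = 27)
  land <- build_landscape(grid2d(2, 2), assignment = 1:4)
  ad <- find_coherent_dispersal(land, ens, p, seed = 8)
  expect_true(ad$coherent)
  expect_lt(ad$equilibrium$spread_max, 1e-3)
  expect_true(all(diff(ad$trace$D) > 0))
})
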