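test_that("independent-habitat moments follow the averaging formula", {
  pred <- moments_independent(c = 1, mu = 0, sigma = 0.5, G = 4)
  expect_equal(pred$mu_bar, 0)
  expect_equal(pred$var_bar, 0.0625)
  expect_equal(pred$sigma_bar, 0.25)

  # single habitat: no averaging
  expect_equal(moments_independent(1, -0.3, 0.7, 1)$var_bar, 0.49)

  # partial connectance adds the mu^2 (1 - c) presence-variance term
  pred2 <- moments_independent(c = 0.5, mu = 1, sigma = 1, G = 2)
  expect_equal(pred2$mu_bar, 0.5)
  expect_equal(pred2$var_bar, 0.375)

  # brute-force sampling oracle: 1e5 simulated entry-averages
  set.seed(42)
  n_mc <- 1e5
  avgs <- (matrix(rbinom(n_mc * 2, 1, 0.5), n_mc) *
             matrix(rnorm(n_mc * 2, 1, 1), n_mc)) |> rowMeans()
  se <- stats::sd((avgs - mean(avgs))^2) / sqrt(n_mc)
  expect_lt(abs(stats::var(avgs) - 0.375), 3 * se)

  expect_error(moments_independent(0, 0, 1, 4), "connectance")
  expect_error(moments_independent(1, 0, -1, 4), "sigma")
})

test_that("equicorrelated variance interpolates independence and identity", {
  expect_equal(variance_equicorrelated(1, 4, 0.5)$var_bar, 0.625)

  # rho = 0 coincides with independent habitats at full connectance
  for (sigma in c(0.2, 1, 3)) for (G in c(1, 2, 7))
    expect_equal(variance_equicorrelated(sigma, G, 0)$var_bar,
                 moments_independent(1, 0.4, sigma, G)$var_bar,
                 tolerance = 1e-14)

  # saturation at rho * sigma^2 for very many habitats
  expect_lt(abs(variance_equicorrelated(1, 1e6, 0.3)$var_bar - 0.3), 1e-5)

  expect_error(variance_equicorrelated(1, 4, -0.1), "rho")
})

test_that("nearest-neighbor chain variance has the right limits", {
  expect_equal(variance_nn_chain(1, 1, 0.7)$var_bar, 1)       # empty sum
  for (G in c(2, 5, 10))
    expect_equal(variance_nn_chain(1.5, G, 0)$var_bar, 1.5^2 / G)

  # two habitats have only one pair: chain and equicorrelated coincide
  for (r in seq(0, 0.95, by = 0.05)) for (sigma in c(0.5, 2))
    expect_equal(variance_nn_chain(sigma, 2, r)$var_bar,
                 variance_equicorrelated(sigma, 2, r)$var_bar,
                 tolerance = 1e-15)

  expect_error(variance_nn_chain(1, 4, 1), "rho_nn")
})

test_that("effective variance responds monotonically to G, rho, rho_nn", {
  G_grid <- 2^(0:8)
  v_ind <- vapply(G_grid, function(G)
    moments_independent(0.7, -0.2, 1.2, G)$var_bar, numeric(1))
  expect_true(all(diff(v_ind) < 0))          # strictly decreasing in G
  expect_lt(v_ind[length(v_ind)], 0.02)      # heading to 0

  rho_grid <- seq(0, 1, by = 0.1)
  v_eq <- vapply(rho_grid, function(r)
    variance_equicorrelated(1, 5, r)$var_bar, numeric(1))
  expect_true(all(diff(v_eq) > 0))           # strictly increasing in rho

  for (r in c(0.1, 0.5, 0.9)) {
    v <- variance_nn_chain(1, 8, r)$var_bar
    expect_gte(v, 1 / 8)                     # at least the rho_nn = 0 floor
    expect_lte(v, 1)                         # at most a single habitat
  }
  v_nn <- vapply(G_grid, function(G)
    variance_nn_chain(1, G, 0.9)$var_bar, numeric(1))
  expect_true(all(diff(v_nn) < 0))
  expect_lt(v_nn[length(v_nn)], 0.1)
})

test_that("infinite-habitat limits match each correlation structure", {
  expect_equal(large_G_limit(correlation_spec("independent"), 5), 0)
  expect_equal(
    large_G_limit(correlation_spec("equicorrelated", rho = 0.25), 2), 1.0)
  expect_equal(
    large_G_limit(correlation_spec("nn_chain", rho_nn = 0.99), 3), 0)
})

test_that("May complexity proxy scales as sigma * sqrt(cN)", {
  expect_equal(complexity_proxy(1.25 / sqrt(50), 1, 50), 1.25)
  expect_equal(complexity_proxy(0, 0.3, 100), 0)
  # halving c and doubling N leaves the proxy unchanged
  expect_equal(complexity_proxy(0.2, 0.5, 100), complexity_proxy(0.2, 1, 50))
  # inverse round-trips
  expect_equal(complexity_proxy(sigma_for_complexity(1.25, 0.5, 80), 0.5, 80),
               1.25)
})

test_that("theory_table assembles consistent rows", {
  tab <- theory_table(correlation_spec("equicorrelated", rho = 0.4),
                      c = 1, mu = 0, sigma = 1, G_list = c(1, 4, 16))
  expect_equal(nrow(tab), 3)
  expect_equal(tab$sigma_bar, sqrt(tab$var_bar))
  expect_equal(tab$var_limit, rep(0.4, 3))
  expect_true(all(diff(tab$var_bar) < 0))
})
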