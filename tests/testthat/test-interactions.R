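test_that("mask sampling realizes the requested connectance", {
  # full connectance forces every off-diagonal slot
  m <- sample_mask(2, 1, seed = 1)
  expect_identical(diag(m), c(FALSE, FALSE))
  expect_true(all(m[row(m) != col(m)]))
  expect_equal(sum(sample_mask(3, 1, seed = 2)), 6L)

  # pooled Bernoulli fraction over many seeds: 3 binomial SEs around c
  N <- 50; c <- 0.5; n_seeds <- 200
  hits <- vapply(seq_len(n_seeds),
                 function(s) sum(sample_mask(N, c, seed = s)), numeric(1))
  n_slots <- n_seeds * N * (N - 1)
  frac <- sum(hits) / n_slots
  se <- sqrt(c * (1 - c) / n_slots)
  expect_lt(abs(frac - c), 3 * se)

  expect_error(sample_mask(3, 0), "connectance")
  expect_error(sample_mask(3, 1.2), "connectance")
  expect_error(sample_mask(0, 0.5), "at least 1")
})

test_that("interaction matrices have the requested entry distribution", {
  # zero-variance draw pins every present entry at mu
  p <- community_params(N = 4, c = 1, mu = -0.5, sigma = 0)
  A <- sample_interaction_matrix(p, seed = 3)
  off <- row(A$entries) != col(A$entries)
  expect_true(all(A$entries[off] == -0.5))
  expect_true(all(diag(A$entries) == 0))

  # pooled moments of nonzero entries across seeds: 3 standard errors
  p <- community_params(N = 50, c = 1, mu = 0, sigma = 0.3)
  vals <- unlist(lapply(1:100, function(s) {
    A <- sample_interaction_matrix(p, seed = s)
    A$entries[A$mask]
  }))
  n <- length(vals)
  expect_lt(abs(mean(vals) - 0), 3 * 0.3 / sqrt(n))
  expect_lt(abs(stats::sd(vals) - 0.3), 3 * 0.3 / sqrt(2 * n))

  # masked-out positions stay exactly zero
  p2 <- community_params(N = 30, c = 0.3, mu = 1, sigma = 0.5)
  A2 <- sample_interaction_matrix(p2, seed = 4)
  expect_true(all(A2$entries[!A2$mask] == 0))

  bad_mask <- matrix(TRUE, 3, 3)
  expect_error(sample_interaction_matrix(tiny_params(3), mask = bad_mask),
               "diagonal")
  expect_error(sample_interaction_matrix(tiny_params(4),
                                         mask = sample_mask(3, 1, 1)),
               "logical matrix")
})

test_that("correlation specs validate their parameters", {
  expect_error(correlation_spec("equicorrelated"), "rho")
  expect_error(correlation_spec("equicorrelated", rho = 1.5), "rho")
  expect_error(correlation_spec("nn_chain", rho_nn = 1), "rho_nn")
  expect_error(correlation_spec("independent", rho = 0.5), "only meaningful")
  expect_silent(correlation_spec("nn_chain", rho_nn = 0))
})

test_that("ensembles realize their cross-habitat correlation structure", {
  p <- community_params(N = 102, c = 1, mu = 0, sigma = 1)

  # rho = 1 collapses every habitat onto one draw
  ens1 <- sample_ensemble(3, correlation_spec("equicorrelated", rho = 1),
                          p, seed = 5)
  expect_equal(ens1$matrices[[2]]$entries, ens1$matrices[[1]]$entries)
  expect_equal(ens1$matrices[[3]]$entries, ens1$matrices[[1]]$entries)

  # rho_nn = 0 is independence: pooled correlation within 3 SE of 0
  ens0 <- sample_ensemble(2, correlation_spec("nn_chain", rho_nn = 0),
                          p, seed = 6)
  n_pos <- sum(ens0$matrices[[1]]$mask)
  expect_gte(n_pos, 1e4)
  expect_lt(abs(lag_correlation(ens0, 1)), 3 / sqrt(n_pos))

  # AR chain: correlation falls off as rho_nn^lag
  pn <- community_params(N = 100, c = 1, mu = 0, sigma = 1)
  ensn <- sample_ensemble(4, correlation_spec("nn_chain", rho_nn = 0.6),
                          pn, seed = 7)
  m <- sum(ensn$matrices[[1]]$mask)
  for (lag in 1:2) {
    target <- 0.6^lag
    n_pool <- m * (4 - lag)
    se <- (1 - target^2) / sqrt(n_pool)
    expect_lt(abs(lag_correlation(ensn, lag) - target), 3 * se)
  }

  # equicorrelated: every habitat pair near rho
  ense <- sample_ensemble(4, correlation_spec("equicorrelated", rho = 0.5),
                          pn, seed = 8)
  corr <- empirical_ensemble_moments(ense)$pairwise_correlations
  off <- corr[row(corr) != col(corr)]
  expect_true(all(abs(off - 0.5) < 3 * (1 - 0.25) / sqrt(m)))

  # shared vs independent masks
  expect_identical(ense$matrices[[1]]$mask, ense$matrices[[4]]$mask)
  pi2 <- community_params(N = 40, c = 0.5, mu = 0, sigma = 1)
  ensi <- sample_ensemble(2, correlation_spec("independent"), pi2, seed = 9)
  expect_false(identical(ensi$matrices[[1]]$mask, ensi$matrices[[2]]$mask))
})

test_that("seeds make ensembles reproducible and extendable", {
  p <- tiny_params(12)
  spec <- correlation_spec("equicorrelated", rho = 0.3)
  a <- sample_ensemble(3, spec, p, seed = 10)
  b <- sample_ensemble(3, spec, p, seed = 10)
  expect_identical(a$matrices, b$matrices)
  d <- sample_ensemble(3, spec, p, seed = 11)
  expect_false(identical(a$matrices[[1]]$entries, d$matrices[[1]]$entries))

  # growing G leaves earlier habitats untouched
  big <- sample_ensemble(5, spec, p, seed = 10)
  expect_identical(big$matrices[1:3], a$matrices)
  ii <- sample_ensemble(2, correlation_spec("independent"), p, seed = 12)
  jj <- sample_ensemble(4, correlation_spec("independent"), p, seed = 12)
  expect_identical(jj$matrices[1:2], ii$matrices)
})

test_that("empirical moments of the averaged matrix match the closed forms", {
  # identical habitats: pairwise correlations exactly 1
  p <- community_params(N = 30, c = 1, mu = 0, sigma = 1)
  ens <- sample_ensemble(3, correlation_spec("equicorrelated", rho = 1),
                         p, seed = 13)
  corr <- empirical_ensemble_moments(ens)$pairwise_correlations
  expect_equal(max(abs(corr - 1)), 0, tolerance = 1e-12)

  # independent, c = 1: var of averaged entries ~ sigma^2 / G
  p2 <- community_params(N = 200, c = 1, mu = 0, sigma = 0.5)
  em <- empirical_ensemble_moments(
    sample_ensemble(4, correlation_spec("independent"), p2, seed = 14))
  n <- 200 * 199
  se <- 0.0625 * sqrt(2 / (n - 1))
  expect_lt(abs(em$entry_variance_of_average - 0.0625), 3 * se)

  # equicorrelated: var ~ (sigma^2/G)(1 + (G-1) rho)
  p3 <- community_params(N = 200, c = 1, mu = 0, sigma = 1)
  em3 <- empirical_ensemble_moments(
    sample_ensemble(4, correlation_spec("equicorrelated", rho = 0.5),
                    p3, seed = 15))
  se3 <- 0.625 * sqrt(2 / (n - 1))
  expect_lt(abs(em3$entry_variance_of_average - 0.625), 3 * se3)
})

test_that("matrices and ensembles round-trip through delimited text", {
  p <- community_params(N = 8, c = 0.6, mu = -0.2, sigma = 0.4)
  A <- sample_interaction_matrix(p, seed = 16)
  f <- tempfile(fileext = ".tsv")
  write_interaction_matrix(A, f)
  B <- read_interaction_matrix(f)
  expect_equal(B$entries, A$entries, tolerance = 1e-12)
  expect_identical(B$mask, A$mask)

  ens <- sample_ensemble(3, correlation_spec("nn_chain", rho_nn = 0.4),
                         p, seed = 17)
  d <- tempfile()
  write_ensemble(ens, d)
  ens2 <- read_ensemble(d)
  expect_equal(ens2$G, 3L)
  expect_equal(ens2$spec$rho_nn, 0.4)
  expect_equal(ens2$params$sigma, p$sigma)
  for (g in 1:3)
    expect_equal(ens2$matrices[[g]]$entries, ens$matrices[[g]]$entries,
                 tolerance = 1e-12)
  unlink(d, recursive = TRUE)
})
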