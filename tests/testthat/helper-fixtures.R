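# small parameter sets reused across tests
tiny_params <- function(N = 10, c = 1, mu = 0, sigma = NULL, ...) {
  if (is.null(sigma)) sigma <- sigma_for_complexity(1.25, c, N)
  community_params(N = N, c = c, mu = mu, sigma = sigma, ...)
}

# pooled entry correlation between habitat pairs at a given lag of a
# shared-mask ensemble
lag_correlation <- function(ensemble, lag) {
  mask <- ensemble$matrices[[1L]]$mask
  pairs <- cbind(seq_len(ensemble$G - lag), seq_len(ensemble$G - lag) + lag)
  xs <- ys <- NULL
  for (k in seq_len(nrow(pairs))) {
    xs <- c(xs, ensemble$matrices[[pairs[k, 1]]]$entries[mask])
    ys <- c(ys, ensemble$matrices[[pairs[k, 2]]]$entries[mask])
  }
  stats::cor(xs, ys)
}
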