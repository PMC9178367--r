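#' Sample a random interaction mask
#'
#' Draws the structural skeleton of an interaction web: each off-diagonal
#' entry is independently present with probability `c` (i.i.d. Bernoulli,
#' not an exact count), and the diagonal is always absent.
#'
#' @param N species-pool size.
#' @param c connectance in `(0, 1]`.
#' @param seed optional integer seed for reproducibility.
#' @return an `N x N` logical matrix with all-`FALSE` diagonal.
#' @export
sample_mask <- function(N, c, seed = NULL) {
  N <- as.integer(N)
  if (N < 1L) stop("`N` must be at least 1")
  if (!(c > 0 && c <= 1)) stop("connectance `c` must lie in (0, 1]")
  mask <- with_seed(seed, matrix(stats::runif(N * N) < c, N, N))
  diag(mask) <- FALSE
  mask
}

#' Sample one habitat interaction matrix
#'
#' Nonzero entries (where the mask is `TRUE`) are i.i.d. Normal(mu, sigma^2);
#' structurally absent entries and the diagonal are exactly zero. `A[i, j]`
#' and `A[j, i]` are sampled independently, so all interaction types
#' (trophic, mutualistic, competitive, commensal, amensal) occur as a
#' mixture when `mu = 0`.
#'
#' @param params a [community_params()] object.
#' @param mask optional `N x N` logical mask with `FALSE` diagonal; if
#'   absent one is drawn via [sample_mask()].
#' @param seed optional integer seed.
#' @return an object of class `interaction_matrix`: a list with `entries`
#'   (numeric matrix) and `mask` (logical matrix).
#' @export
sample_interaction_matrix <- function(params, mask = NULL, seed = NULL) {
  stopifnot(inherits(params, "community_params"))
  N <- params$N
  with_seed(seed, {
    if (is.null(mask)) mask <- sample_mask(N, params$c)
    check_mask(mask, N)
    entries <- matrix(0, N, N)
    entries[mask] <- stats::rnorm(sum(mask), params$mu, params$sigma)
    new_interaction_matrix(entries, mask)
  })
}

new_interaction_matrix <- function(entries, mask) {
  structure(list(entries = entries, mask = mask), class = "interaction_matrix")
}

check_mask <- function(mask, N) {
  if (!is.logical(mask) || !is.matrix(mask) || any(dim(mask) != N))
    stop("`mask` must be an ", N, " x ", N, " logical matrix")
  if (any(diag(mask))) stop("`mask` must have an all-FALSE diagonal")
  invisible(mask)
}

#' @export
print.interaction_matrix <- function(x, ...) {
  N <- nrow(x$entries)
  nz <- sum(x$mask)
  cat(sprintf("interaction matrix: N = %d, %d nonzero entries (connectance %.3f)\n",
              N, nz, nz / (N * (N - 1))))
  invisible(x)
}

#' Cross-habitat correlation structure
#'
#' Describes how interaction strengths co-vary between habitats:
#' `"independent"` (each habitat is a fresh draw, independent masks),
#' `"equicorrelated"` (a shared mask; every habitat pair has entry
#' correlation `rho`), or `"nn_chain"` (a shared mask; habitats ordered
#' along a chain with nearest-neighbor correlation `rho_nn` decaying as
#' `rho_nn^lag` with distance).
#'
#' @param kind one of `"independent"`, `"equicorrelated"`, `"nn_chain"`.
#' @param rho pairwise correlation in `[0, 1]` (equicorrelated only).
#' @param rho_nn nearest-neighbor correlation in `[0, 1)` (nn_chain only).
#' @return an object of class `correlation_spec`.
#' @export
correlation_spec <- function(kind = c("independent", "equicorrelated", "nn_chain"),
                             rho = NULL, rho_nn = NULL) {
  kind <- match.arg(kind)
  if (kind == "equicorrelated") {
    if (is.null(rho) || length(rho) != 1L || rho < 0 || rho > 1)
      stop("equicorrelated structure needs `rho` in [0, 1]")
    rho <- as.numeric(rho)
  } else if (!is.null(rho)) {
    stop("`rho` is only meaningful for kind = \"equicorrelated\"")
  }
  if (kind == "nn_chain") {
    if (is.null(rho_nn) || length(rho_nn) != 1L || rho_nn < 0 || rho_nn >= 1)
      stop("nn_chain structure needs `rho_nn` in [0, 1)")
    rho_nn <- as.numeric(rho_nn)
  } else if (!is.null(rho_nn)) {
    stop("`rho_nn` is only meaningful for kind = \"nn_chain\"")
  }
  structure(list(kind = kind, rho = rho, rho_nn = rho_nn),
            class = "correlation_spec")
}

#' @export
print.correlation_spec <- function(x, ...) {
  extra <- switch(x$kind,
    independent = "",
    equicorrelated = sprintf(" (rho = %g)", x$rho),
    nn_chain = sprintf(" (rho_nn = %g)", x$rho_nn))
  cat("habitat correlation structure: ", x$kind, extra, "\n", sep = "")
  invisible(x)
}

#' Sample an ensemble of habitat interaction matrices
#'
#' Generates `G` habitat matrices under a given cross-habitat correlation
#' structure:
#' \describe{
#'   \item{independent}{`G` independent draws, each with its own mask.}
#'   \item{equicorrelated}{one shared mask; on each present position the
#'     habitat-`g` entry is `mu + sigma * (sqrt(rho) z0 + sqrt(1 - rho) z_g)`
#'     with `z0, z_g` independent standard normals, so any two habitats
#'     have entry correlation exactly `rho`.}
#'   \item{nn_chain}{one shared mask; per position a first-order
#'     autoregressive chain `x[g+1] = rho_nn x[g] + sqrt(1 - rho_nn^2) e[g]`
#'     with standard-normal marginals, so habitats `g` and `g'` have
#'     correlation `rho_nn^|g - g'|`.}
#' }
#' Entry streams are derived per habitat from the root seed, so extending
#' `G` does not perturb the matrices of earlier habitats.
#'
#' @param G number of habitats (>= 1).
#' @param spec a [correlation_spec()].
#' @param params a [community_params()].
#' @param seed optional integer root seed.
#' @return an object of class `habitat_ensemble`.
#' @export
sample_ensemble <- function(G, spec, params, seed = NULL) {
  G <- as.integer(G)
  if (G < 1L) stop("`G` must be at least 1")
  stopifnot(inherits(spec, "correlation_spec"), inherits(params, "community_params"))
  if (is.null(seed)) seed <- with_seed(NULL, sample.int(2147483646L, 1L))
  N <- params$N
  if (spec$kind == "independent") {
    matrices <- lapply(seq_len(G), function(g)
      sample_interaction_matrix(params, seed = derive_seed(seed, g)))
  } else {
    mask <- sample_mask(N, params$c, seed = derive_seed(seed, 0L))
    m <- sum(mask)
    if (spec$kind == "equicorrelated") {
      z0 <- with_seed(derive_seed(seed, 1L), stats::rnorm(m))
      matrices <- lapply(seq_len(G), function(g) {
        zg <- with_seed(derive_seed(seed, g + 1L), stats::rnorm(m))
        x <- sqrt(spec$rho) * z0 + sqrt(1 - spec$rho) * zg
        entries <- matrix(0, N, N)
        entries[mask] <- params$mu + params$sigma * x
        new_interaction_matrix(entries, mask)
      })
    } else {  # nn_chain: AR(1) across the habitat index, per position
      matrices <- vector("list", G)
      x <- with_seed(derive_seed(seed, 2L), stats::rnorm(m))
      for (g in seq_len(G)) {
        if (g > 1L) {
          eps <- with_seed(derive_seed(seed, g + 1L), stats::rnorm(m))
          x <- spec$rho_nn * x + sqrt(1 - spec$rho_nn^2) * eps
        }
        entries <- matrix(0, N, N)
        entries[mask] <- params$mu + params$sigma * x
        matrices[[g]] <- new_interaction_matrix(entries, mask)
      }
    }
  }
  structure(list(G = G, matrices = matrices, spec = spec, params = params,
                 seed = as.integer(seed)),
            class = "habitat_ensemble")
}

#' @export
print.habitat_ensemble <- function(x, ...) {
  cat(sprintf("habitat ensemble: G = %d habitats, N = %d species, kind = %s, seed = %d\n",
              x$G, x$params$N, x$spec$kind, x$seed))
  invisible(x)
}

# off-diagonal positions over which the moments of the averaged matrix are
# defined: all off-diagonal slots for independent-mask ensembles (structural
# zeros belong to the ensemble's entry distribution), present positions only
# for shared-mask ensembles (an interaction present anywhere is present
# everywhere, and absent positions are deterministic zeros).
moment_positions <- function(ensemble) {
  N <- ensemble$params$N
  offdiag <- !diag(TRUE, N)
  if (ensemble$spec$kind == "independent") offdiag
  else ensemble$matrices[[1L]]$mask
}

#' Empirical moments of an ensemble's averaged matrix
#'
#' Verification harness for the closed-form moment theory: computes, from
#' a generated ensemble, the sample mean and sample variance of the
#' entries of the habitat-averaged matrix, and the matrix of habitat-pair
#' entry correlations. For independent-mask ensembles the moments run over
#' all off-diagonal positions (structural zeros included); for shared-mask
#' ensembles over the present positions only — matching the populations
#' the respective closed forms describe.
#'
#' @param ensemble a [sample_ensemble()] result.
#' @return a list with `entry_mean`, `entry_variance_of_average`, and
#'   `pairwise_correlations` (a `G x G` matrix).
#' @export
empirical_ensemble_moments <- function(ensemble) {
  stopifnot(inherits(ensemble, "habitat_ensemble"))
  pos <- moment_positions(ensemble)
  vals <- vapply(ensemble$matrices, function(m) m$entries[pos], numeric(sum(pos)))
  avg <- rowMeans(vals)
  corr <- if (ensemble$G == 1L) matrix(1, 1, 1) else suppressWarnings(stats::cor(vals))
  list(entry_mean = mean(avg),
       entry_variance_of_average = stats::var(avg),
       pairwise_correlations = corr)
}

#' Write / read an interaction matrix as delimited text
#'
#' Plain tab-separated reals, one matrix row per line, no headers.
#'
#' @param x an `interaction_matrix` or bare numeric matrix.
#' @param file path to write to / read from.
#' @param sep field separator (tab by default; comma also common).
#' @return `read_interaction_matrix()` returns an `interaction_matrix`
#'   whose mask marks the nonzero entries.
#' @export
write_interaction_matrix <- function(x, file, sep = "\t") {
  m <- if (inherits(x, "interaction_matrix")) x$entries else as.matrix(x)
  utils::write.table(m, file = file, sep = sep,
                     row.names = FALSE, col.names = FALSE)
  invisible(file)
}

#' @rdname write_interaction_matrix
#' @export
read_interaction_matrix <- function(file, sep = "\t") {
  m <- as.matrix(utils::read.table(file, sep = sep, header = FALSE))
  dimnames(m) <- NULL
  if (nrow(m) != ncol(m)) stop("matrix in ", file, " is not square")
  mask <- m != 0
  diag(mask) <- FALSE
  new_interaction_matrix(m, mask)
}

#' Write / read a habitat ensemble as plain text
#'
#' One delimited matrix file per habitat (`habitat_01.tsv`, ...) plus a
#' `metadata.dcf` sidecar in Debian-control key-value format recording
#' N, c, mu, sigma, the correlation structure, G and the seed.
#'
#' @param ensemble a `habitat_ensemble`.
#' @param dir directory to populate (created if needed).
#' @return `read_ensemble()` returns a `habitat_ensemble` (masks are
#'   reconstructed from nonzero entries).
#' @export
write_ensemble <- function(ensemble, dir) {
  stopifnot(inherits(ensemble, "habitat_ensemble"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (g in seq_len(ensemble$G))
    write_interaction_matrix(ensemble$matrices[[g]],
                             file.path(dir, sprintf("habitat_%02d.tsv", g)))
  p <- ensemble$params; s <- ensemble$spec
  meta <- data.frame(N = p$N, c = p$c, mu = p$mu, sigma = p$sigma,
                     kind = s$kind,
                     rho = if (is.null(s$rho)) NA else s$rho,
                     rho_nn = if (is.null(s$rho_nn)) NA else s$rho_nn,
                     G = ensemble$G, seed = ensemble$seed,
                     extinction_threshold = p$extinction_threshold)
  write.dcf(meta, file.path(dir, "metadata.dcf"))
  invisible(dir)
}

#' @rdname write_ensemble
#' @export
read_ensemble <- function(dir) {
  meta <- as.data.frame(read.dcf(file.path(dir, "metadata.dcf")),
                        stringsAsFactors = FALSE)
  num <- function(k) as.numeric(meta[[k]])
  params <- community_params(N = num("N"), c = num("c"), mu = num("mu"),
                             sigma = num("sigma"),
                             extinction_threshold = num("extinction_threshold"))
  spec <- switch(meta$kind,
    independent = correlation_spec("independent"),
    equicorrelated = correlation_spec("equicorrelated", rho = num("rho")),
    nn_chain = correlation_spec("nn_chain", rho_nn = num("rho_nn")))
  G <- as.integer(num("G"))
  matrices <- lapply(seq_len(G), function(g)
    read_interaction_matrix(file.path(dir, sprintf("habitat_%02d.tsv", g))))
  structure(list(G = G, matrices = matrices, spec = spec, params = params,
                 seed = as.integer(num("seed"))),
            class = "habitat_ensemble")
}
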