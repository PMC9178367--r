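#' Patch topologies
#'
#' Constructors for the spatial arrangement of patches: a two-dimensional
#' grid with 4-neighbor coupling, a one-dimensional chain, or an arbitrary
#' connected graph given by a symmetric adjacency matrix.
#'
#' Grid patches are numbered with the smaller grid dimension varying
#' fastest (see the `coords` element of the built landscape), which keeps
#' the coupling structure of the resulting ODE system close to the
#' diagonal and lets the integrator use a banded Jacobian.
#'
#' @param rows,cols grid dimensions (positive integers).
#' @param length number of patches in the chain.
#' @param adjacency symmetric logical (or 0/1) matrix with empty diagonal.
#' @return an object of class `patch_topology`.
#' @export
grid2d <- function(rows, cols) {
  rows <- as.integer(rows); cols <- as.integer(cols)
  stopifnot(rows >= 1L, cols >= 1L)
  structure(list(type = "grid2d", rows = rows, cols = cols),
            class = "patch_topology")
}

#' @rdname grid2d
#' @export
chain1d <- function(length) {
  length <- as.integer(length)
  stopifnot(length >= 1L)
  structure(list(type = "chain1d", length = length), class = "patch_topology")
}

#' @rdname grid2d
#' @export
graph_topology <- function(adjacency) {
  adjacency <- as.matrix(adjacency) != 0
  if (nrow(adjacency) != ncol(adjacency))
    stop("`adjacency` must be square")
  if (!isTRUE(all(adjacency == t(adjacency))))
    stop("`adjacency` must be symmetric")
  if (any(diag(adjacency))) stop("`adjacency` must have an empty diagonal")
  structure(list(type = "graph", adjacency = adjacency),
            class = "patch_topology")
}

#' Build a landscape: patch graph plus habitat assignment
#'
#' Validates and precomputes everything the spatial simulator needs: the
#' (connected) patch adjacency, patch degrees, the graph Laplacian used
#' for dispersal, and the patch-to-habitat assignment. Grids and chains
#' use zero-flux (reflecting) boundaries by default — boundary patches
#' simply have fewer neighbors, so pure dispersal conserves total
#' abundance — or periodic (wrap-around) boundaries if requested.
#'
#' @param topology a [grid2d()], [chain1d()] or [graph_topology()] object.
#' @param assignment integer vector, one habitat index per patch (into the
#'   ensemble used for simulation). Defaults to all patches sharing
#'   habitat 1.
#' @param h patch spacing (the discrete-Laplacian denominator is `h^2`);
#'   default 1.
#' @param periodic logical; wrap grid/chain boundaries (ignored for
#'   `graph` topologies).
#' @return an object of class `landscape` with elements `P` (patch
#'   count), `adjacency`, `degree`, `laplacian`, `assignment`, `h`,
#'   `coords` (for grids/chains) and `band_offset` (maximum patch-index
#'   distance between neighbors).
#' @export
build_landscape <- function(topology, assignment = NULL, h = 1,
                            periodic = FALSE) {
  stopifnot(inherits(topology, "patch_topology"))
  if (!(length(h) == 1L && h > 0)) stop("`h` must be a positive scalar")
  coords <- NULL
  if (topology$type == "grid2d") {
    r <- topology$rows; cc <- topology$cols
    # number patches with the smaller dimension fastest
    if (r <= cc) grid <- expand.grid(row = seq_len(r), col = seq_len(cc))
    else grid <- expand.grid(col = seq_len(cc), row = seq_len(r))[, c("row", "col")]
    P <- r * cc
    idx <- integer(P)
    if (r <= cc) idx_of <- function(row, col) (col - 1L) * r + row
    else idx_of <- function(row, col) (row - 1L) * cc + col
    adj <- matrix(FALSE, P, P)
    link <- function(a, b) adj[a, b] <<- adj[b, a] <<- TRUE
    for (row in seq_len(r)) for (col in seq_len(cc)) {
      p <- idx_of(row, col)
      if (row < r) link(p, idx_of(row + 1L, col))
      else if (periodic && r > 2L) link(p, idx_of(1L, col))
      if (col < cc) link(p, idx_of(row, col + 1L))
      else if (periodic && cc > 2L) link(p, idx_of(row, 1L))
    }
    coords <- data.frame(patch = seq_len(P),
                         row = grid$row, col = grid$col)
  } else if (topology$type == "chain1d") {
    P <- topology$length
    adj <- matrix(FALSE, P, P)
    if (P > 1L) {
      for (p in seq_len(P - 1L)) adj[p, p + 1L] <- adj[p + 1L, p] <- TRUE
      if (periodic && P > 2L) adj[1L, P] <- adj[P, 1L] <- TRUE
    }
    coords <- data.frame(patch = seq_len(P), position = seq_len(P))
  } else {
    adj <- topology$adjacency
    P <- nrow(adj)
  }
  if (!is_connected(adj)) stop("the patch graph must be connected")
  if (is.null(assignment)) assignment <- rep(1L, P)
  assignment <- as.integer(assignment)
  if (length(assignment) != P)
    stop("`assignment` must give one habitat index per patch (", P, ")")
  if (any(assignment < 1L)) stop("habitat indices must be >= 1")
  degree <- rowSums(adj)
  lap <- adj * 1; diag(lap) <- -degree
  band <- if (P > 1L) {
    e <- which(adj, arr.ind = TRUE)
    max(abs(e[, 1L] - e[, 2L]))
  } else 0L
  structure(list(type = topology$type, P = P, adjacency = adj,
                 degree = degree, laplacian = lap,
                 assignment = assignment, h = as.numeric(h),
                 coords = coords, periodic = periodic,
                 band_offset = as.integer(band)),
            class = "landscape")
}

is_connected <- function(adj) {
  P <- nrow(adj)
  if (P == 1L) return(TRUE)
  seen <- logical(P)
  frontier <- 1L
  seen[1L] <- TRUE
  while (length(frontier)) {
    nxt <- which(colSums(adj[frontier, , drop = FALSE]) > 0 & !seen)
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  all(seen)
}

#' @export
print.landscape <- function(x, ...) {
  cat(sprintf("landscape: %s, %d patches, %d habitats in use, h = %g%s\n",
              x$type, x$P, length(unique(x$assignment)), x$h,
              if (isTRUE(x$periodic)) ", periodic" else ""))
  invisible(x)
}

#' Diffusive dispersal term on a landscape
#'
#' The discrete-Laplacian dispersal flux: for species `i` at patch `p`,
#' `D_i * (sum of neighbor densities - degree(p) * density at p) / h^2`.
#' On interior grid patches this is the classic 5-point stencil; boundary
#' patches use their actual neighbor count (zero-flux), so every column
#' of the result sums to zero and dispersal alone conserves abundance.
#'
#' @param densities `P x N` matrix of densities.
#' @param landscape a [build_landscape()] object.
#' @param D per-species dispersal rates (scalar or length `N`, >= 0).
#' @return a `P x N` matrix of dispersal contributions to `d(phi)/dt`.
#' @export
dispersal_term <- function(densities, landscape, D) {
  stopifnot(inherits(landscape, "landscape"))
  densities <- as.matrix(densities)
  if (nrow(densities) != landscape$P)
    stop("`densities` must have one row per patch")
  N <- ncol(densities)
  D <- rep_len(as.numeric(D), N)
  if (any(D < 0)) stop("dispersal rates must be nonnegative")
  (landscape$laplacian %*% densities) %*% diag(D, N) / landscape$h^2
}
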