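# Spatial graph, Laplacian penalty and simplex projection.

#' Build the spot adjacency graph
#'
#' Spots are neighbours iff their centre distance is at most `neighbor_factor`
#' times the minimal nonzero inter-spot distance. The default factor 1.2
#' captures the 4-neighbourhood of a square array and the 6-neighbourhood of a
#' hexagonal array while excluding diagonals.
#'
#' @param coords data.frame with columns x, y (rownames = spot ids).
#' @param neighbor_factor multiple of the minimal spacing defining adjacency.
#' @return list of class `spatial_graph` with the 0/1 adjacency `A`, `degree`
#'   vector and Laplacian `L = D - A`.
#' @export
build_spatial_graph <- function(coords, neighbor_factor = 1.2) {
  stopifnot(nrow(coords) >= 1)
  d <- as.matrix(dist(coords[, c("x", "y")]))
  if (nrow(coords) > 1 && any(d[upper.tri(d)] == 0))
    warning("duplicate spot coordinates")
  nz <- d[d > 0]
  A <- if (length(nz)) (d > 0 & d <= neighbor_factor * min(nz)) * 1 else d * 0
  dimnames(A) <- list(rownames(coords), rownames(coords))
  deg <- rowSums(A)
  L <- diag(deg, nrow = nrow(A)) - A
  dimnames(L) <- dimnames(A)
  structure(list(A = A, degree = deg, L = L), class = "spatial_graph")
}

#' Graph-Laplacian smoothness penalty
#'
#' `tr(theta^T L theta)`, equal to half the adjacency-weighted sum of squared
#' differences between neighbouring rows of theta.
#'
#' @param theta spots x K proportion matrix.
#' @param L spot Laplacian (or a `spatial_graph`).
#' @return scalar penalty, >= 0.
#' @export
laplacian_penalty <- function(theta, L) {
  if (inherits(L, "spatial_graph")) L <- L$L
  if (!isSymmetric(unname(L), tol = 1e-8)) stop("Laplacian must be symmetric")
  sum(theta * (L %*% theta))
}

#' Euclidean projection onto the probability simplex
#'
#' @param v numeric vector.
#' @return the closest point to `v` with non-negative entries summing to one.
#' @export
project_simplex <- function(v) {
  u <- sort(v, decreasing = TRUE)
  css <- cumsum(u)
  rho <- max(which(u + (1 - css) / seq_along(u) > 0))
  tau <- (1 - css[rho]) / rho
  pmax(v + tau, 0)
}
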