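# Enhanced-resolution imputation: classify edge vs inner spots, build a finer
# grid inside the tissue, initialize compositions from nearest original spots
# and take a one-step random walk on a Gaussian-kernel graph. Expression is
# imputed through the Moore-Penrose inverse of the composition matrix.

#' Classify spots as edge or inner and locate in-tissue holes
#'
#' Spot occupancy is rasterized onto the spot lattice; background pixels
#' connected to the raster border (flood fill) are outside the tissue, the
#' remaining background pixels are holes. Spots 8-adjacent to outside or hole
#' pixels are edge spots; the in-hole lattice positions are returned as
#' missing spots.
#'
#' @param coords spot coordinate data.frame (columns x, y).
#' @param spacing lattice spacing D; default the minimal nonzero inter-spot
#'   distance.
#' @return list with logical `edge` (per spot), data.frame `holes` of missing
#'   in-hole lattice positions, and `spacing`.
#' @export
label_edge_spots <- function(coords, spacing = NULL) {
  n <- nrow(coords)
  if (n < 3) return(list(edge = rep(TRUE, n), holes = coords[0, ], spacing = spacing))
  if (is.null(spacing)) {
    d <- dist(coords[, c("x", "y")])
    spacing <- min(d[d > 0])
  }
  ix <- round((coords$x - min(coords$x)) / spacing) + 1L
  iy <- round((coords$y - min(coords$y)) / spacing) + 1L
  nx <- max(ix); ny <- max(iy)
  if (nx == 1 || ny == 1)                       # single row/column: all edge
    return(list(edge = rep(TRUE, n), holes = coords[0, ], spacing = spacing))
  occ <- matrix(FALSE, nx, ny)
  occ[cbind(ix, iy)] <- TRUE
  outside <- .flood_from_border(occ)
  hole <- !occ & !outside
  # edge = occupied cell with an 8-neighbour that is outside or a hole
  edge <- logical(n)
  for (s in seq_len(n)) {
    for (dx in -1:1) for (dy in -1:1) {
      if (dx == 0 && dy == 0) next
      px <- ix[s] + dx; py <- iy[s] + dy
      if (px < 1 || px > nx || py < 1 || py > ny || outside[px, py] || hole[px, py]) {
        edge[s] <- TRUE
      }
    }
  }
  hidx <- which(hole, arr.ind = TRUE)
  holes <- data.frame(x = min(coords$x) + (hidx[, 1] - 1) * spacing,
                      y = min(coords$y) + (hidx[, 2] - 1) * spacing)
  list(edge = edge, holes = holes, spacing = spacing)
}

# BFS flood fill of FALSE cells reachable from the matrix border (4-adjacency
# padded by one ring so any border background is a seed).
.flood_from_border <- function(occ) {
  nx <- nrow(occ); ny <- ncol(occ)
  pad <- matrix(FALSE, nx + 2, ny + 2)
  pad[2:(nx + 1), 2:(ny + 1)] <- occ
  outside <- matrix(FALSE, nx + 2, ny + 2)
  queue <- which(!pad & (row(pad) == 1 | row(pad) == nx + 2 |
                           col(pad) == 1 | col(pad) == ny + 2))
  outside[queue] <- TRUE
  while (length(queue)) {
    cur <- queue[1]; queue <- queue[-1]
    i <- (cur - 1) %% (nx + 2) + 1
    j <- (cur - 1) %/% (nx + 2) + 1
    for (nb in list(c(i - 1, j), c(i + 1, j), c(i, j - 1), c(i, j + 1))) {
      if (nb[1] < 1 || nb[1] > nx + 2 || nb[2] < 1 || nb[2] > ny + 2) next
      k <- nb[1] + (nb[2] - 1) * (nx + 2)
      if (!pad[k] && !outside[k]) { outside[k] <- TRUE; queue <- c(queue, k) }
    }
  }
  outside[2:(nx + 1), 2:(ny + 1), drop = FALSE]
}

#' Build the enhanced-resolution grid
#'
#' The bounding rectangle of the original spot centres is gridded into squares
#' of side `d < D`; a square centre is retained iff it lies within `D` of an
#' inner spot or within `(D - d) / 2` of an edge spot, filtering out locations
#' outside the tissue or in holes.
#'
#' @param coords original spot coordinates.
#' @param D original centre-to-centre spacing.
#' @param d new side length (0 < d < D).
#' @param edge logical per-spot edge labels; default from
#'   [label_edge_spots()].
#' @return data.frame of retained new centres (columns x, y) with attributes
#'   `d` and `D`.
#' @export
build_highres_grid <- function(coords, D, d, edge = NULL) {
  if (d >= D || d <= 0) stop("need 0 < d < D")
  if (is.null(edge)) edge <- label_edge_spots(coords, spacing = D)$edge
  gx <- seq(min(coords$x), max(coords$x), by = d)
  gy <- seq(min(coords$y), max(coords$y), by = d)
  cand <- expand.grid(x = gx, y = gy)
  inner <- coords[!edge, , drop = FALSE]
  edge_c <- coords[edge, , drop = FALSE]
  d_inner <- if (nrow(inner)) .min_dist(cand, inner) else rep(Inf, nrow(cand))
  d_edge <- if (nrow(edge_c)) .min_dist(cand, edge_c) else rep(Inf, nrow(cand))
  keep <- d_inner <= D | d_edge <= (D - d) / 2
  out <- cand[keep, , drop = FALSE]
  rownames(out) <- paste0("hr", seq_len(nrow(out)))
  attr(out, "d") <- d; attr(out, "D") <- D
  out
}

# minimal Euclidean distance from each row of a to the rows of b
.min_dist <- function(a, b) {
  d2 <- outer(a$x, b$x, "-")^2 + outer(a$y, b$y, "-")^2
  sqrt(apply(d2, 1, min))
}

#' Initialize compositions on the new grid
#'
#' Each new centre copies the average proportion row of the original spot(s)
#' at minimal distance (ties within 1e-9 are averaged), so rows stay on the
#' simplex.
#'
#' @param grid new centres from [build_highres_grid()].
#' @param theta spots x K proportions on the original spots.
#' @param coords original spot coordinates (rows aligned with `theta`).
#' @return new-centres x K matrix.
#' @export
init_theta <- function(grid, theta, coords) {
  d2 <- outer(grid$x, coords$x, "-")^2 + outer(grid$y, coords$y, "-")^2
  t(apply(d2, 1, function(row) {
    nearest <- which(row <= min(row) + 1e-9)
    colMeans(theta[nearest, , drop = FALSE])
  }))
}

#' Gaussian random-walk kernel over grid centres
#'
#' `W_ij = exp(-r_ij^2 / 2 tau^2)` for centre distance `r_ij <= phi`, zero
#' beyond the cutoff; `M = D^-1 W` is the row-stochastic one-step walk matrix.
#' Isolated centres (all-zero row) get self-weight 1.
#'
#' @param centers data.frame of centres (columns x, y).
#' @param phi neighbourhood cutoff (> 0), same length unit as the coordinates.
#' @param tau kernel bandwidth (> 0).
#' @return list of class `imputation_kernel` with `W` and `M`.
#' @export
gaussian_kernel <- function(centers, phi, tau) {
  stopifnot(phi > 0, tau > 0)
  r2 <- outer(centers$x, centers$x, "-")^2 + outer(centers$y, centers$y, "-")^2
  W <- exp(-r2 / (2 * tau^2))
  W[sqrt(r2) > phi] <- 0
  iso <- rowSums(W) == 0
  if (any(iso)) W[cbind(which(iso), which(iso))] <- 1
  M <- W / rowSums(W)
  structure(list(W = W, M = M, phi = phi, tau = tau),
            class = "imputation_kernel")
}

#' One-step random-walk imputation of compositions
#'
#' @param kernel an `imputation_kernel`.
#' @param theta0 initial compositions on the new centres (simplex rows).
#' @return imputed compositions `M theta0`; rows remain on the simplex.
#' @export
impute_theta <- function(kernel, theta0) {
  kernel$M %*% theta0
}

#' Impute gene expression on the new grid
#'
#' `X_imputed = theta_imputed theta^+ X` with `theta^+` the Moore-Penrose
#' inverse of the original-spot composition matrix ((theta^T theta)^-1
#' theta^T when theta has full column rank, SVD pseudoinverse otherwise, with
#' a warning) and `X` the depth-normalized observed expression.
#'
#' @param theta_imputed new-centres x K compositions.
#' @param theta original spots x K compositions.
#' @param X spots x genes depth-normalized expression.
#' @return new-centres x genes imputed expression.
#' @export
impute_expression <- function(theta_imputed, theta, X) {
  gram <- crossprod(theta)
  pinv <- tryCatch(solve(gram, t(theta)), error = function(e) {
    warning("rank-deficient composition matrix; using SVD pseudoinverse")
    s <- svd(theta)
    pos <- s$d > max(s$d) * 1e-12
    s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
  })
  theta_imputed %*% pinv %*% X
}

#' Impute a deconvolution result at a set of target resolutions
#'
#' Convenience wrapper running the full imputation for each target side
#' length: edge labelling, grid construction, nearest-spot initialization,
#' random-walk smoothing, and (optionally) expression imputation.
#'
#' @param fit a `spot_deconv` (or a list with `theta` and `coords`).
#' @param resolutions target side lengths d, each < the original spacing.
#' @param phi,tau kernel hyperparameters (see [tune_imputation()]).
#' @param expression optional spots x genes depth-normalized matrix to impute.
#' @return named list (one element per resolution) with `centers`, `theta`
#'   and optionally `expression`.
#' @export
impute <- function(fit, resolutions, phi, tau, expression = NULL) {
  coords <- fit$coords
  theta <- fit$theta
  lab <- label_edge_spots(coords)
  out <- list()
  for (d in resolutions) {
    grid <- build_highres_grid(coords, lab$spacing, d, edge = lab$edge)
    th0 <- init_theta(grid, theta, coords)
    kern <- gaussian_kernel(grid, phi, tau)
    thi <- impute_theta(kern, th0)
    res <- list(centers = grid, theta = thi)
    if (!is.null(expression))
      res$expression <- impute_expression(thi, theta, expression)
    out[[as.character(d)]] <- res
  }
  out
}

#' Tune the kernel hyperparameters on coarse-grained data
#'
#' Coarse-grains a single-cell-resolution spatial dataset at a ladder of spot
#' sizes, imputes from the coarsest map to each finer one for every candidate
#' `(phi, tau)`, and returns the pair minimizing the mean RMSE against the
#' finer maps' ground truth. Search ranges default to 1-200 length units for
#' both.
#'
#' @param sc a single-cell spatial dataset (list with `counts`, `coords`,
#'   `cell_type`), e.g. from [make_fixture()].
#' @param phi_grid,tau_grid candidate values.
#' @param sizes coarse-graining spot sizes; the largest is the source map.
#' @return list with `phi`, `tau` and the score `table`.
#' @export
tune_imputation <- function(sc, phi_grid, tau_grid,
                            sizes = seq(100, 1000, by = 100)) {
  if (!length(phi_grid) || !length(tau_grid)) stop("empty grid")
  sizes <- sort(sizes)
  maps <- lapply(sizes, function(s) coarse_grain(sc, s))
  src <- maps[[length(maps)]]
  targets <- maps[-length(maps)]
  lab <- label_edge_spots(src$coords)
  grid <- expand.grid(phi = phi_grid, tau = tau_grid)
  scores <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    errs <- numeric(0)
    for (tg in targets) {
      d <- attr(tg, "grid_size")
      hr <- build_highres_grid(src$coords, lab$spacing, d, edge = lab$edge)
      th0 <- init_theta(hr, src$theta, src$coords)
      thi <- impute_theta(gaussian_kernel(hr, grid$phi[g], grid$tau[g]), th0)
      # match imputed centres to ground-truth spots of this resolution
      d2 <- outer(hr$x, tg$coords$x, "-")^2 + outer(hr$y, tg$coords$y, "-")^2
      nearest <- apply(d2, 2, which.min)
      truth <- tg$theta[, colnames(thi), drop = FALSE]
      errs <- c(errs, mean(vapply(seq_len(nrow(truth)), function(i)
        rmse(thi[nearest[i], ], truth[i, ]), numeric(1))))
    }
    scores[g] <- mean(errs)
  }
  best <- which.min(scores)
  list(phi = grid$phi[best], tau = grid$tau[best],
       table = cbind(grid, rmse = scores))
}
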