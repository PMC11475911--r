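# Two-stage ADMM optimization of the penalized deconvolution objective
#   F(theta, alpha) = sum_i [ l_i(theta_i, alpha_i) + lambda_r r(theta_i) ]
#                     + lambda_l tr(theta^T L theta)
# Stage 1 (cell-type selection): per-spot adaptive-LASSO problem. Stage 2
# (spatial smoothing): joint problem on the selected supports with the
# graph-Laplacian penalty. Both stages use consensus ADMM. On the feasible
# set theta >= 0 the weighted L1 penalty is linear, so it joins the smooth
# block (likelihood + penalties, box-constrained warm-started L-BFGS-B with
# an exact zero lower bound); the constraint block is a per-row simplex
# projection, which yields exact zeros. Over-relaxation and
# residual-balancing adaptation of the penalty parameter rho are standard
# accelerations.

.admm_control <- function(maxit = 200, tol = 1e-5, rho = 1, inner_maxit = 30,
                          relax = 1.6, warn = TRUE) {
  list(maxit = maxit, tol = tol, rho = rho, inner_maxit = inner_maxit,
       relax = relax, warn = warn)
}

# Shared ADMM driver. mask: logical I x K of free coordinates (support);
# lin_w: I x K matrix of linear penalty weights (lambda_r * q, zero in stage
# 2); lap_l: lambda_l (0 in stage 1); L: Laplacian or NULL.
.admm_fit <- function(Y, N, mu, quad, theta0, alpha0, mask, lin_w,
                      lap_l = 0, L = NULL, control = .admm_control()) {
  I <- nrow(Y); K <- nrow(mu)
  theta <- theta0 * mask
  theta <- theta / pmax(rowSums(theta), 1e-12)
  v <- theta
  u <- matrix(0, I, K)
  alpha <- alpha0
  rho <- control$rho
  free <- which(mask)                     # indices into I x K matrices
  trace <- numeric(0)
  best <- list(obj = Inf, v = v, alpha = alpha)
  objective <- function(th, al) {
    .negloglik_all(th, al, Y, N, mu, quad, grad = FALSE)$value +
      sum(lin_w * abs(th)) +
      (if (lap_l > 0) lap_l * sum(th * (L %*% th)) else 0)
  }
  nf <- length(free)
  for (it in seq_len(control$maxit)) {
    # -- theta/alpha update: smooth subproblem on the free coordinates.
    # The likelihood term needs strictly positive predicted rates; the exact
    # zero lower bound is safe because mu is floored to be positive and the
    # v/u shift keeps iterates off the all-zero row.
    par0 <- c(theta[free], alpha)
    fn <- function(par) {
      th <- matrix(0, I, K); th[free] <- par[seq_len(nf)]
      al <- par[-seq_len(nf)]
      s <- th %*% mu
      if (any(s <= 0)) return(1e12)
      val <- .negloglik_all(th, al, Y, N, mu, quad, grad = FALSE)$value +
        sum(lin_w * th) + (rho / 2) * sum((th - v + u)^2) +
        (if (lap_l > 0) lap_l * sum(th * (L %*% th)) else 0)
      if (!is.finite(val)) 1e12 else val
    }
    gr <- function(par) {
      th <- matrix(0, I, K); th[free] <- par[seq_len(nf)]
      al <- par[-seq_len(nf)]
      g <- .negloglik_all(th, al, Y, N, mu, quad)
      dth <- g$dtheta + lin_w + rho * (th - v + u)
      if (lap_l > 0) dth <- dth + 2 * lap_l * (L %*% th)
      c(dth[free], g$dalpha)
    }
    o <- optim(par0, fn, gr, method = "L-BFGS-B",
               lower = c(rep(0, nf), rep(-Inf, I)),
               upper = c(rep(1, nf), rep(Inf, I)),
               control = list(maxit = control$inner_maxit, factr = 1e6))
    theta <- matrix(0, I, K, dimnames = dimnames(theta0))
    theta[free] <- o$par[seq_len(nf)]
    alpha <- o$par[-seq_len(nf)]
    # -- v update (with over-relaxation): simplex projection per row
    v_old <- v
    th_rel <- control$relax * theta + (1 - control$relax) * v_old
    v <- matrix(0, I, K, dimnames = dimnames(theta0))
    for (i in seq_len(I)) {
      ki <- which(mask[i, ])
      v[i, ki] <- project_simplex(th_rel[i, ki] + u[i, ki])
    }
    # -- dual update and residuals
    u <- u + th_rel - v
    r_pri <- sqrt(sum((theta - v)^2))
    r_dua <- rho * sqrt(sum((v - v_old)^2))
    obj <- objective(v, alpha)
    trace <- c(trace, obj)
    if (obj < best$obj) best <- list(obj = obj, v = v, alpha = alpha)
    # scaled feasibility thresholds (absolute tol plus relative part)
    eps_pri <- sqrt(nf) * control$tol + 1e-3 * max(sqrt(sum(theta^2)), sqrt(sum(v^2)))
    eps_dua <- sqrt(nf) * control$tol + 1e-3 * rho * sqrt(sum(u^2))
    if (r_pri < eps_pri && r_dua < eps_dua) break
    # residual balancing only during the first half; freezing rho afterwards
    # stabilizes the tail of the iteration
    if (it <= control$maxit / 2) {
      if (r_pri > 10 * r_dua) { rho <- rho * 2; u <- u / 2 }
      else if (r_dua > 10 * r_pri) { rho <- rho / 2; u <- u * 2 }
    }
  }
  if (isTRUE(control$warn) && it == control$maxit &&
      (r_pri >= eps_pri || r_dua >= eps_dua))
    warning("ADMM reached the iteration cap; returning the best iterate")
  # return the best feasible iterate; cummin of the trace is the sequence of
  # accepted objectives
  list(theta = best$v, alpha = best$alpha, objective = best$obj,
       iterations = it, trace = trace, accepted = cummin(trace),
       primal = r_pri, dual = r_dua)
}

#' Stage 1: per-spot cell-type selection by adaptive LASSO
#'
#' Minimizes `sum_i [l_i + lambda_r r(theta_i)]` by ADMM with simplex
#' projection; cell type k is called present in spot i iff the estimate is at
#' least `cutoff` (default 0.001).
#'
#' @param Y spots x genes count matrix.
#' @param N spot total UMI counts.
#' @param mu K x G signature matrix.
#' @param quad quadrature grid from [eps_quadrature()] at the profiled sigma.
#' @param theta0,alpha0 initial values (base-model MLE).
#' @param q adaptive weights from [weights_from_mle()].
#' @param lambda_r sparsity hyperparameter (>= 0).
#' @param cutoff presence threshold on the estimates.
#' @param control ADMM controls.
#' @return list with `theta`, `alpha`, logical `selected` (I x K), and the
#'   objective `trace`.
#' @export
stage1_select <- function(Y, N, mu, quad, theta0, alpha0, q, lambda_r,
                          cutoff = 0.001, control = .admm_control()) {
  mask <- matrix(TRUE, nrow(Y), nrow(mu))
  fit <- .admm_fit(Y, N, mu, quad, theta0, alpha0, mask,
                   lin_w = lambda_r * q, control = control)
  selected <- fit$theta >= cutoff
  dimnames(selected) <- dimnames(fit$theta)
  c(fit, list(selected = selected))
}

#' Stage 2: spatially smoothed refit on the selected supports
#'
#' Minimizes `sum_i l_i + lambda_l tr(theta^T L theta)` jointly over all spots
#' with theta fixed to zero outside each spot's selected cell types. Spots
#' with an empty selection fall back to the full cell-type set with a warning.
#'
#' @inheritParams stage1_select
#' @param selected logical I x K support matrix from stage 1.
#' @param L spot Laplacian (a `spatial_graph` or matrix).
#' @param lambda_l smoothing hyperparameter (>= 0; 0 decouples the spots).
#' @return list with the final `theta` (rows on the simplex, zeros preserved
#'   off-support), `alpha` and the objective `trace`.
#' @export
stage2_smooth <- function(Y, N, mu, quad, theta0, alpha0, selected, L,
                          lambda_l, control = .admm_control()) {
  if (inherits(L, "spatial_graph")) L <- L$L
  empty <- rowSums(selected) == 0
  if (any(empty)) {
    warning("empty cell-type selection for ", sum(empty),
            " spot(s); falling back to the full set")
    selected[empty, ] <- TRUE
  }
  .admm_fit(Y, N, mu, quad, theta0, alpha0, selected,
            lin_w = matrix(0, nrow(Y), nrow(mu)),
            lap_l = lambda_l, L = L, control = control)
}

#' Gene-wise cross-validation of the two hyperparameters
#'
#' Marker genes are split into `folds` seeded equal-size groups. For each
#' candidate `(lambda_r, lambda_l)` the two-stage fit is run on the training
#' genes of each fold and the base-model log-likelihood of the held-out genes
#' is computed at the fitted (theta, alpha); the candidate with the largest
#' mean validation log-likelihood wins, ties going to the lexicographically
#' smallest pair (weaker regularization).
#'
#' @inheritParams stage1_select
#' @param L spot Laplacian.
#' @param lambda_r_grid,lambda_l_grid candidate values.
#' @param folds number of folds (default 5).
#' @param seed seed for the fold assignment.
#' @param control ADMM controls (a reduced iteration budget is typical here).
#' @return list with `lambda_r`, `lambda_l`, the score `table` (one row per
#'   candidate with the mean validation log-likelihood) and `fold_id`.
#' @export
cross_validate <- function(Y, N, mu, quad, lambda_r_grid, lambda_l_grid, L,
                           folds = 5, seed = 1, cutoff = 0.001,
                           control = .admm_control(maxit = 50)) {
  control$warn <- FALSE   # CV refits run a reduced budget by design
  G <- ncol(Y)
  if (G < folds) stop("need at least as many genes as folds")
  if (!length(lambda_r_grid) || !length(lambda_l_grid)) stop("empty grid")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  fold_id <- sample(rep_len(seq_len(folds), G))
  # per-fold MLE (shared across candidates)
  fold_fit <- lapply(seq_len(folds), function(f) {
    tr <- fold_id != f
    mle <- fit_base_mle(Y[, tr, drop = FALSE], N, mu[, tr, drop = FALSE],
                        sigma_grid = quad$sigma)
    mle$q <- weights_from_mle(mle$theta)
    mle
  })
  grid <- expand.grid(lambda_r = lambda_r_grid, lambda_l = lambda_l_grid)
  grid <- grid[order(grid$lambda_r, grid$lambda_l), ]
  scores <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    ll <- numeric(folds)
    for (f in seq_len(folds)) {
      tr <- fold_id != f
      mle <- fold_fit[[f]]
      s1 <- stage1_select(Y[, tr, drop = FALSE], N, mu[, tr, drop = FALSE],
                          quad, mle$theta, mle$alpha, mle$q,
                          grid$lambda_r[g], cutoff, control)
      s2 <- stage2_smooth(Y[, tr, drop = FALSE], N, mu[, tr, drop = FALSE],
                          quad, s1$theta, s1$alpha, s1$selected, L,
                          grid$lambda_l[g], control)
      th <- pmax(s2$theta, 1e-12)
      th <- th / rowSums(th)              # keep predicted rates positive
      ll[f] <- -.negloglik_all(th, s2$alpha, Y[, !tr, drop = FALSE], N,
                               mu[, !tr, drop = FALSE], quad,
                               grad = FALSE)$value
    }
    scores[g] <- mean(ll)
  }
  best <- which.max(scores)               # first max = lexicographically smallest
  list(lambda_r = grid$lambda_r[best], lambda_l = grid$lambda_l[best],
       table = cbind(grid, score = scores), fold_id = fold_id)
}
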