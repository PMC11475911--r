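# Base model of the deconvolution regression: per spot i and gene j the
# (transformed) count Y_ij ~ Poisson(N_i * lambda_ij) with
#   log(lambda_ij) = alpha_i + log(sum_k theta_ik mu_kj) + eps_ij,
# where eps_ij follows a heavy-tailed (Cauchy-Gaussian mixture approximation)
# error distribution. The random effect eps is marginalized on a fixed
# quadrature grid.

#' Heavy-tailed error density
#'
#' Gaussian body for |eps| <= 3 sigma and a slowly decaying 1/|eps| tail
#' beyond, approximating a Cauchy-Gaussian mixture for robustness to outlier
#' genes:
#' \deqn{p(\epsilon) = C/(\sqrt{2\pi}\sigma) e^{-\epsilon^2/2\sigma^2}
#'   \quad |\epsilon| \le 3\sigma}
#' \deqn{p(\epsilon) = \frac{2\sqrt{2}C}{9(|\epsilon|\sigma - \frac{7}{3}\sigma^2)\sqrt{\pi}}
#'   e^{-9/2} \quad 3\sigma < |\epsilon| \le 8\sigma}
#' The tail is truncated at `trunc_mult * sigma` (default 8) because the
#' 1/|eps| tail is not integrable on an unbounded range; C normalizes the
#' truncated density to integrate to 1 (closed form).
#'
#' @param eps numeric vector of error values.
#' @param sigma positive scale parameter.
#' @param trunc_mult truncation point in units of sigma (> 3).
#' @return density values, zero beyond the truncation point.
#' @export
heavy_tail_density <- function(eps, sigma, trunc_mult = 8) {
  if (sigma <= 0) stop("sigma must be positive")
  stopifnot(trunc_mult > 3)
  C <- .heavy_tail_C(sigma, trunc_mult)
  a <- abs(eps)
  out <- numeric(length(eps))
  body <- a <= 3 * sigma
  tail <- a > 3 * sigma & a <= trunc_mult * sigma
  out[body] <- C / (sqrt(2 * pi) * sigma) * exp(-eps[body]^2 / (2 * sigma^2))
  out[tail] <- 2 * sqrt(2) * C * exp(-9 / 2) /
    (9 * (a[tail] * sigma - 7 / 3 * sigma^2) * sqrt(pi))
  out
}

# Normalizing constant: integral of the unnormalized density is
#   (2 Phi(3) - 1) + 4 sqrt(2) e^{-9/2} log((T - 7/3)/(3 - 7/3)) / (9 sqrt(pi) sigma)
# with T the truncation multiple.
.heavy_tail_C <- function(sigma, trunc_mult = 8) {
  body <- 2 * pnorm(3) - 1
  tail <- 4 * sqrt(2) * exp(-9 / 2) *
    log((trunc_mult - 7 / 3) / (3 - 7 / 3)) / (9 * sqrt(pi) * sigma)
  1 / (body + tail)
}

#' Quadrature grid for marginalizing the heavy-tailed random effect
#'
#' 25 equally spaced nodes on [-5 sigma, 5 sigma] plus 8 tail nodes out to the
#' truncation point. Trapezoid weights under [heavy_tail_density()] are
#' renormalized to sum to one, so the marginal likelihood is an exact finite
#' mixture over the grid.
#'
#' @param sigma positive scale.
#' @param n_body nodes in the central range (default 25).
#' @return list with `nodes`, `log_w` (log weights) and `sigma`.
#' @export
eps_quadrature <- function(sigma, n_body = 25) {
  body <- seq(-5 * sigma, 5 * sigma, length.out = n_body)
  tails <- c(-8, -7.25, -6.5, -5.75, 5.75, 6.5, 7.25, 8) * sigma
  nodes <- sort(unique(c(body, tails)))
  dens <- heavy_tail_density(nodes, sigma)
  h <- diff(nodes)
  w <- dens * c(h[1], (h[-1] + h[-length(h)]) / 2, h[length(h)]) / 1
  w <- w / sum(w)
  list(nodes = nodes, log_w = log(w), sigma = sigma)
}

# log(sum(exp(x))) rows of a matrix, stably.
.logsumexp_rows <- function(m) {
  mx <- apply(m, 1, max)
  mx + log(rowSums(exp(m - mx)))
}

#' Negative log-likelihood of the base model for one spot
#'
#' Marginalizes the heavy-tailed random effect over the quadrature grid:
#' `-sum_j log sum_m w_m Poisson(Y_j | N e^{alpha + eps_m} s_j)` with
#' `s_j = sum_k theta_k mu_kj`.
#'
#' @param theta length-K proportion vector (simplex).
#' @param alpha spot fixed effect.
#' @param Y length-G count vector for the spot.
#' @param N total UMI count of the spot.
#' @param mu K x G signature matrix.
#' @param quad quadrature grid from [eps_quadrature()].
#' @return scalar negative log-likelihood.
#' @export
base_negloglik <- function(theta, alpha, Y, N, mu, quad) {
  if (any(theta < -1e-8)) stop("negative proportions")
  s <- drop(theta %*% mu)
  if (any(s <= 0)) stop("zero predicted rate for some gene")
  lograte <- log(N) + alpha + log(s)            # length G
  ll <- outer(lograte, quad$nodes, "+")          # G x M log rates
  lp <- dpois(Y, exp(ll), log = TRUE)            # recycles Y down columns
  -sum(.logsumexp_rows(sweep(lp, 2, quad$log_w, "+")))
}

# Vectorized negative log-likelihood and gradient across all spots (compiled
# kernel). theta: I x K (rows need not be on the simplex during ADMM
# iterates, but must be >= 0 with positive predicted rates), alpha: length I,
# Y: I x G, N: length I. Returns value, d/dtheta (I x K), d/dalpha (length I).
.negloglik_all <- function(theta, alpha, Y, N, mu, quad, grad = TRUE) {
  out <- glrm_negloglik_cpp(theta, alpha, Y, N, mu, quad$nodes, quad$log_w,
                            grad)
  if (grad) dimnames(out$dtheta) <- dimnames(theta)
  out
}

#' Total negative log-likelihood of the base model across spots
#'
#' Convenience wrapper around the compiled kernel, summing [base_negloglik()]
#' over all spots; used e.g. to score held-out genes in cross-validation.
#'
#' @param theta I x K proportion matrix.
#' @param alpha length-I fixed effects.
#' @param Y I x G counts; `N` length-I totals; `mu` K x G signatures.
#' @inheritParams base_negloglik
#' @return scalar total negative log-likelihood.
#' @export
base_negloglik_total <- function(theta, alpha, Y, N, mu, quad) {
  .negloglik_all(theta, alpha, Y, N, mu, quad, grad = FALSE)$value
}

#' Fit the base model by maximum likelihood
#'
#' Per-spot maximization over (theta_i, alpha_i) with the simplex constraint
#' handled by a softmax reparameterization (BFGS with analytic gradients);
#' sigma^2 is profiled on a shared grid across spots. These estimates seed the
#' two penalized ADMM stages and their reciprocals form the adaptive-LASSO
#' weights.
#'
#' @param Y spots x genes count matrix.
#' @param N length-I vector of spot total UMI counts.
#' @param mu K x G signature matrix.
#' @param sigma_grid candidate values of sigma profiled by total likelihood.
#' @param maxit BFGS iteration cap per spot.
#' @return list with `theta` (I x K, simplex rows), `alpha`, `sigma`, `quad`
#'   and the total negative log-likelihood `negll`.
#' @export
fit_base_mle <- function(Y, N, mu,
                         sigma_grid = c(0.05, 0.1, 0.15, 0.25, 0.35, 0.5, 0.75, 1),
                         maxit = 100) {
  I <- nrow(Y); K <- nrow(mu)
  fit_all <- function(quad, init = NULL) {
    theta <- matrix(0, I, K, dimnames = list(rownames(Y), rownames(mu)))
    alpha <- numeric(I)
    total <- 0
    for (i in seq_len(I)) {
      par0 <- if (is.null(init)) rep(0, K + 1) else init[[i]]
      fn <- function(par) {
        th <- .softmax(par[seq_len(K)])
        .negloglik_all(matrix(th, 1), par[K + 1], Y[i, , drop = FALSE],
                       N[i], mu, quad, grad = FALSE)$value
      }
      gr <- function(par) {
        th <- .softmax(par[seq_len(K)])
        g <- .negloglik_all(matrix(th, 1), par[K + 1], Y[i, , drop = FALSE],
                            N[i], mu, quad)
        dth <- drop(g$dtheta)
        # softmax Jacobian
        deta <- th * (dth - sum(th * dth))
        c(deta, g$dalpha)
      }
      o <- optim(par0, fn, gr, method = "BFGS", control = list(maxit = maxit))
      if (o$convergence != 0 && o$convergence != 1)
        warning("base-model MLE did not converge for spot ", i)
      theta[i, ] <- .softmax(o$par[seq_len(K)])
      alpha[i] <- o$par[K + 1]
      total <- total + o$value
    }
    list(theta = theta, alpha = alpha, negll = total)
  }
  # profile sigma: fit at a mid-grid value, score all sigmas at the fitted
  # parameters, then refit at the winner
  quad0 <- eps_quadrature(sigma_grid[ceiling(length(sigma_grid) / 2)])
  f0 <- fit_all(quad0)
  score <- vapply(sigma_grid, function(s)
    .negloglik_all(f0$theta, f0$alpha, Y, N, mu, eps_quadrature(s),
                   grad = FALSE)$value, numeric(1))
  sigma <- sigma_grid[which.min(score)]
  quad <- eps_quadrature(sigma)
  f <- if (sigma == quad0$sigma) f0 else fit_all(quad)
  list(theta = f$theta, alpha = f$alpha, sigma = sigma, quad = quad,
       negll = f$negll)
}

.softmax <- function(eta) {
  e <- exp(eta - max(eta))
  e / sum(e)
}

#' Adaptive-LASSO weights from the base-model MLE
#'
#' Reciprocal MLE proportions, floored at `floor_val` so absent types get a
#' large but finite weight.
#'
#' @param theta_hat I x K MLE proportions.
#' @param floor_val lower bound applied before inversion (default 1e-4).
#' @return I x K positive weight matrix.
#' @export
weights_from_mle <- function(theta_hat, floor_val = 1e-4) {
  1 / pmax(theta_hat, floor_val)
}

#' Adaptive-LASSO penalty for one spot
#'
#' `r(theta_i) = sum_k q_ik |theta_ik|`.
#'
#' @param theta length-K proportions.
#' @param q length-K positive weights.
#' @return scalar penalty.
#' @export
adaptive_lasso_penalty <- function(theta, q) {
  if (any(q < 0)) stop("negative adaptive-LASSO weights")
  sum(q * abs(theta))
}
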