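# Heavy-tailed error model, marginalized likelihood, penalties and the
# two-stage ADMM fits.

test_that("heavy-tail density is symmetric, normalized and Gaussian-bodied", {
  for (sigma in c(0.1, 0.5, 1)) {
    eps <- seq(-8 * sigma, 8 * sigma, length.out = 41)
    expect_equal(heavy_tail_density(eps, sigma),
                 heavy_tail_density(-eps, sigma))
    # quadrature oracle for the normalization
    total <- integrate(heavy_tail_density, -8 * sigma, 8 * sigma,
                       sigma = sigma, rel.tol = 1e-10,
                       subdivisions = 2000L)$value
    expect_equal(total, 1, tolerance = 1e-6)
    # in the body the ratio to the mode cancels the normalizing constant
    e <- 1.7 * sigma
    expect_equal(heavy_tail_density(e, sigma) / heavy_tail_density(0, sigma),
                 exp(-e^2 / (2 * sigma^2)), tolerance = 1e-12)
    # positive, and positive just beyond the body/tail break
    expect_gt(heavy_tail_density(3.0001 * sigma, sigma), 0)
  }
  expect_error(heavy_tail_density(0, -1), "positive")
})

test_that("quadrature weights are a normalized mixture over the grid", {
  quad <- eps_quadrature(0.3)
  expect_equal(sum(exp(quad$log_w)), 1, tolerance = 1e-12)
  expect_equal(length(quad$nodes), 33)  # 25 body + 8 tail nodes
})

test_that("marginalized negative log-likelihood matches a dense oracle", {
  set.seed(10)
  K <- 3; G <- 8
  mu <- matrix(rexp(K * G) / G, K, G)
  theta <- c(0.2, 0.5, 0.3)
  alpha <- 0.1; N <- 500; sigma <- 0.3
  Y <- rpois(G, N * exp(alpha) * drop(theta %*% mu))
  quad <- eps_quadrature(sigma)
  got <- base_negloglik(theta, alpha, Y, N, mu, quad)
  # oracle: same finite mixture evaluated gene-by-gene with direct sums
  w <- exp(quad$log_w)
  oracle <- -sum(vapply(seq_len(G), function(j) {
    rate <- N * exp(alpha + quad$nodes) * drop(theta %*% mu)[j]
    log(sum(w * dpois(Y[j], rate)))
  }, numeric(1)))
  expect_equal(got, oracle, tolerance = 1e-6)
  # near-degenerate error: reduces to the plain Poisson likelihood
  quad0 <- eps_quadrature(1e-4)
  plain <- -sum(dpois(Y, N * exp(alpha) * drop(theta %*% mu), log = TRUE))
  expect_equal(base_negloglik(theta, alpha, Y, N, mu, quad0), plain,
               tolerance = 1e-3)
  # K = 1, theta = 1, alpha = 0, Y = 0, N = 1, mu = 1: one nat per gene
  expect_equal(base_negloglik(1, 0, rep(0, 2), 1, matrix(1, 1, 2), quad0), 2,
               tolerance = 1e-4)
})

test_that("compiled likelihood gradient matches finite differences", {
  set.seed(11)
  I <- 3; K <- 3; G <- 10
  mu <- matrix(rexp(K * G) / G, K, G)
  theta <- random_theta(I, K, 11)
  alpha <- rnorm(I, 0, 0.1)
  N <- rep(300, I)
  Y <- matrix(rpois(I * G, 300 * (theta %*% mu)), I, G)
  quad <- eps_quadrature(0.3)
  g <- spotdecon:::.negloglik_all(theta, alpha, Y, N, mu, quad)
  h <- 1e-6
  for (probe in list(c(1, 2), c(3, 1))) {
    th2 <- theta; th2[probe[1], probe[2]] <- th2[probe[1], probe[2]] + h
    fd <- (spotdecon:::.negloglik_all(th2, alpha, Y, N, mu, quad,
                                      grad = FALSE)$value - g$value) / h
    expect_equal(g$dtheta[probe[1], probe[2]], fd, tolerance = 1e-3)
  }
  a2 <- alpha; a2[2] <- a2[2] + h
  fd <- (spotdecon:::.negloglik_all(theta, a2, Y, N, mu, quad,
                                    grad = FALSE)$value - g$value) / h
  expect_equal(g$dalpha[2], fd, tolerance = 1e-3)
})

test_that("base-model MLE recovers pure and mixed compositions", {
  set.seed(12)
  K <- 3; G <- 30
  mu <- matrix(rexp(K * G), K, G)
  mu[1, 1:8] <- mu[1, 1:8] * 10
  mu[2, 9:16] <- mu[2, 9:16] * 10
  mu[3, 17:24] <- mu[3, 17:24] * 10
  mu <- mu / rowSums(mu)
  N <- rep(2000, 4)
  truth <- rbind(c(1, 0, 0), c(0, 1, 0), c(0.5, 0.5, 0), c(1/3, 1/3, 1/3))
  Y <- t(sapply(1:4, function(i) rpois(G, N[i] * drop(truth[i, ] %*% mu))))
  fit <- fit_base_mle(Y, N, mu)
  expect_gt(fit$theta[1, 1], 0.95)
  expect_gt(fit$theta[2, 2], 0.95)
  expect_equal(fit$theta[3, ], truth[3, ], tolerance = 0.05,
               ignore_attr = TRUE)
  expect_equal(unname(rowSums(fit$theta)), rep(1, 4), tolerance = 1e-8)
})

test_that("adaptive-LASSO penalty and weights follow their formulas", {
  expect_equal(adaptive_lasso_penalty(c(0.5, 0.25), c(2, 4)), 2)
  expect_equal(adaptive_lasso_penalty(c(0, 0), c(2, 4)), 0)
  th <- c(0.3, 0.7)
  expect_equal(adaptive_lasso_penalty(3 * th, c(1, 2)),
               3 * adaptive_lasso_penalty(th, c(1, 2)))
  expect_error(adaptive_lasso_penalty(th, c(-1, 1)), "negative")
  q <- weights_from_mle(rbind(c(0.5, 0, 0.5)))
  expect_equal(unname(q[1, ]), c(2, 1e4, 2))
})

test_that("spatial graph captures lattice neighbourhoods", {
  two <- data.frame(x = c(0, 1), y = c(0, 0), row.names = c("a", "b"))
  g <- build_spatial_graph(two)
  expect_equal(unname(g$A), rbind(c(0, 1), c(1, 0)))
  expect_equal(unname(rowSums(g$L)), c(0, 0))
  # 3x3 unit grid: interior spot has degree 4; far-away spot is isolated
  gr <- expand.grid(x = 0:2, y = 0:2)
  gr <- rbind(gr, data.frame(x = 50, y = 50))
  g2 <- build_spatial_graph(gr)
  expect_equal(unname(g2$degree[5]), 4)
  expect_equal(unname(g2$degree[10]), 0)
  expect_warning(build_spatial_graph(data.frame(x = c(0, 0), y = c(0, 0))),
                 "duplicate")
})

test_that("laplacian penalty equals the pairwise-sum identity", {
  g <- build_spatial_graph(data.frame(x = c(0, 1), y = c(0, 0)))
  expect_equal(laplacian_penalty(rbind(c(1, 0), c(0, 1)), g), 2)
  expect_equal(laplacian_penalty(rbind(c(0.3, 0.7), c(0.3, 0.7)), g), 0)
  # random inputs vs the explicit half-sum over adjacent pairs
  set.seed(13)
  gr <- expand.grid(x = 0:3, y = 0:3)
  g2 <- build_spatial_graph(gr)
  th <- random_theta(16, 4, 13)
  pairwise <- 0
  for (s in 1:16) for (t in 1:16)
    pairwise <- pairwise + 0.5 * g2$A[s, t] * sum((th[s, ] - th[t, ])^2)
  expect_equal(laplacian_penalty(th, g2), pairwise, tolerance = 1e-10)
  expect_error(laplacian_penalty(th, matrix(c(0, 1, 0, 0), 2)), "symmetric")
})

test_that("simplex projection returns feasible closest points", {
  set.seed(14)
  for (r in 1:20) {
    v <- rnorm(5, sd = 2)
    p <- project_simplex(v)
    expect_equal(sum(p), 1, tolerance = 1e-12)
    expect_true(all(p >= 0))
  }
  expect_equal(project_simplex(c(0.2, 0.3, 0.5)), c(0.2, 0.3, 0.5))
})

test_that("stage 1 selects supports that shrink as lambda_r grows", {
  inp <- tiny_glrm_inputs()
  sub <- 1:12
  Y <- inp$Y[sub, ]; N <- inp$N[sub]
  mle <- fit_base_mle(Y, N, inp$mu)
  q <- weights_from_mle(mle$theta)
  sizes <- numeric(0)
  sel_prev <- NULL
  for (lam in c(0.1, 3, 30)) {
    s1 <- suppressWarnings(
      stage1_select(Y, N, inp$mu, mle$quad, mle$theta, mle$alpha, q, lam,
                    control = spotdecon:::.admm_control(maxit = 80, tol = 1e-4)))
    expect_equal(unname(rowSums(s1$theta)), rep(1, length(sub)), tolerance = 1e-6)
    sizes <- c(sizes, sum(s1$selected))
    sel_prev <- s1$selected
  }
  # selected sets shrink (solver noise tolerance: allow equality)
  expect_true(all(diff(sizes) <= 0))
  # strongly regularized pure-type spots keep a single type
  pure <- which(apply(inp$sim$theta[rownames(Y), ], 1, max) == 1)
  if (length(pure)) expect_true(all(rowSums(sel_prev)[pure] == 1))
})

test_that("stage 2 smooths towards a common composition as lambda_l grows", {
  inp <- tiny_glrm_inputs()
  sub <- 1:12
  Y <- inp$Y[sub, ]; N <- inp$N[sub]
  L <- inp$graph$L[rownames(Y), rownames(Y)]
  mle <- fit_base_mle(Y, N, inp$mu)
  selected <- matrix(TRUE, nrow(Y), nrow(inp$mu))
  vars <- numeric(0)
  for (lam in c(0, 5, 500)) {
    s2 <- suppressWarnings(
      stage2_smooth(Y, N, inp$mu, mle$quad, mle$theta, mle$alpha, selected,
                    L, lam,
                    control = spotdecon:::.admm_control(maxit = 80, tol = 1e-4)))
    expect_equal(unname(rowSums(s2$theta)), rep(1, length(sub)), tolerance = 1e-6)
    vars <- c(vars, mean(apply(s2$theta, 2, var)))
  }
  expect_true(all(diff(vars) < 0))   # across-spot variance decreases
})

test_that("stage 2 preserves zeros off the selected support", {
  inp <- tiny_glrm_inputs()
  sub <- 1:8
  Y <- inp$Y[sub, ]; N <- inp$N[sub]
  L <- inp$graph$L[rownames(Y), rownames(Y)]
  mle <- fit_base_mle(Y, N, inp$mu)
  selected <- mle$theta >= 0.05
  selected[1, ] <- c(TRUE, FALSE, FALSE)
  s2 <- suppressWarnings(
    stage2_smooth(Y, N, inp$mu, mle$quad, mle$theta, mle$alpha, selected, L, 1,
                  control = spotdecon:::.admm_control(maxit = 60, tol = 1e-4)))
  expect_true(all(s2$theta[!selected] == 0))
  expect_equal(unname(s2$theta[1, ]), c(1, 0, 0))
  # empty selection falls back to the full set with a warning
  selected[2, ] <- FALSE
  expect_warning(
    stage2_smooth(Y, N, inp$mu, mle$quad, mle$theta, mle$alpha, selected, L, 0,
                  control = spotdecon:::.admm_control(maxit = 5, tol = 1e-2)),
    "empty")
})

test_that("ADMM accepts a non-increasing objective sequence and returns its best iterate", {
  inp <- tiny_glrm_inputs()
  sub <- 1:10
  Y <- inp$Y[sub, ]; N <- inp$N[sub]
  mle <- fit_base_mle(Y, N, inp$mu)
  q <- weights_from_mle(mle$theta)
  s1 <- suppressWarnings(
    stage1_select(Y, N, inp$mu, mle$quad, mle$theta, mle$alpha, q, 1,
                  control = spotdecon:::.admm_control(maxit = 80, tol = 0)))
  expect_true(all(diff(s1$accepted) <= 0))
  expect_equal(s1$objective, min(s1$trace))
  expect_lt(s1$objective, s1$trace[1])
  # tail oscillation stays within solver tolerance of the optimum
  tail_tr <- tail(s1$trace, 20)
  expect_lt(max(tail_tr) - s1$objective, 0.02 * abs(s1$objective))
})

test_that("cross-validation picks the exhaustive argmax with seeded folds", {
  inp <- tiny_glrm_inputs()
  sub <- 1:10
  Y <- inp$Y[sub, ]; N <- inp$N[sub]
  L <- inp$graph$L[rownames(Y), rownames(Y)]
  mle <- fit_base_mle(Y, N, inp$mu)
  ctrl <- spotdecon:::.admm_control(maxit = 15, tol = 1e-3)
  grid_r <- c(0.5, 5); grid_l <- c(0.5, 5)
  cv <- cross_validate(Y, N, inp$mu, mle$quad, grid_r, grid_l, L,
                       folds = 3, seed = 21, control = ctrl)
  expect_identical(cv, cross_validate(Y, N, inp$mu, mle$quad, grid_r, grid_l,
                                      L, folds = 3, seed = 21, control = ctrl))
  best <- cv$table[which.max(cv$table$score), ]
  expect_equal(cv$lambda_r, best$lambda_r)
  expect_equal(cv$lambda_l, best$lambda_l)
  # single-candidate grid returns that candidate
  one <- cross_validate(Y, N, inp$mu, mle$quad, 2, 3, L, folds = 3,
                        seed = 21, control = ctrl)
  expect_equal(c(one$lambda_r, one$lambda_l), c(2, 3))
  expect_error(cross_validate(Y, N, inp$mu, mle$quad, numeric(0), 1, L),
               "empty grid")
})

test_that("signatures average normalized profiles per type", {
  counts <- cbind(a = c(2, 2, 0), b = c(0, 5, 5), c = c(1, 1, 2))
  rownames(counts) <- paste0("g", 1:3)
  annot <- setNames(factor(c("T1", "T1", "T2")), c("a", "b", "c"))
  mu <- compute_signatures(counts, annot)
  # hand-computed: normalize each cell to total 1, average within type
  expect_equal(unname(mu["T1", ]), c((0.5 + 0) / 2, (0.5 + 0.5) / 2, 0.5 / 2))
  expect_equal(unname(mu["T2", ]), c(0.25, 0.25, 0.5))
  # duplicating every cell leaves the means unchanged
  dup <- cbind(counts, counts)
  colnames(dup) <- c("a", "b", "c", "a2", "b2", "c2")
  mu2 <- compute_signatures(dup, setNames(factor(c("T1", "T1", "T2",
                                                   "T1", "T1", "T2")),
                                          colnames(dup)))
  expect_equal(unname(mu2), unname(mu))
})
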