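# Edge labelling, grid construction, kernel random walk and expression
# imputation.

test_that("edge labelling separates perimeter, interior and holes", {
  # single row: everything is edge
  row <- data.frame(x = 0:4, y = rep(0, 5))
  expect_true(all(label_edge_spots(row)$edge))
  # filled 5x5 grid: 16 perimeter spots edge, 9 interior inner
  g <- expand.grid(x = 0:4, y = 0:4)
  lab <- label_edge_spots(g)
  interior <- g$x >= 1 & g$x <= 3 & g$y >= 1 & g$y <= 3
  expect_equal(sum(lab$edge), 16)
  expect_true(all(!lab$edge[interior]))
  expect_equal(nrow(lab$holes), 0)
  # remove the centre: its 8 ring neighbours become edge, hole reported
  g2 <- g[!(g$x == 2 & g$y == 2), ]
  lab2 <- label_edge_spots(g2)
  ring <- abs(g2$x - 2) <= 1 & abs(g2$y - 2) <= 1
  expect_true(all(lab2$edge[ring]))
  expect_equal(nrow(lab2$holes), 1)
  expect_equal(unlist(lab2$holes), c(x = 2, y = 2))
})

test_that("high-resolution grid retains centres per the distance criteria", {
  # 2x2 unit-spaced spots, all edge; d = 0.5 keeps centres within (D-d)/2
  co <- expand.grid(x = c(0, 1), y = c(0, 1))
  grid <- build_highres_grid(co, D = 1, d = 0.5)
  # brute-force criterion check over the same candidate lattice
  gx <- seq(0, 1, by = 0.5); cand <- expand.grid(x = gx, y = gx)
  dmin <- apply(cand, 1, function(p)
    min(sqrt((p[1] - co$x)^2 + (p[2] - co$y)^2)))
  expect_equal(nrow(grid), sum(dmin <= 0.25))
  expect_true(all(apply(grid, 1, function(p)
    min(sqrt((p[1] - co$x)^2 + (p[2] - co$y)^2))) <= 0.25 + 1e-12))
  expect_error(build_highres_grid(co, D = 1, d = 1), "d < D")
  # with an interior, every inner spot lies within D of a retained centre
  big <- expand.grid(x = 0:5, y = 0:5)
  lab <- label_edge_spots(big)
  hr <- build_highres_grid(big, D = 1, d = 0.6)
  inner <- big[!lab$edge, ]
  dmin2 <- apply(inner, 1, function(p)
    min(sqrt((p[1] - hr$x)^2 + (p[2] - hr$y)^2)))
  expect_true(all(dmin2 <= 1))
})

test_that("theta initialization copies or averages nearest original spots", {
  co <- data.frame(x = c(0, 2), y = c(0, 0))
  th <- rbind(c(1, 0), c(0, 1))
  grid <- data.frame(x = c(0, 1), y = c(0, 0))
  th0 <- init_theta(grid, th, co)
  expect_equal(unname(th0[1, ]), c(1, 0))        # coincident: copies
  expect_equal(unname(th0[2, ]), c(0.5, 0.5))    # equidistant: averages
  expect_equal(unname(rowSums(th0)), c(1, 1))
})

test_that("gaussian kernel respects the cutoff and is row-stochastic", {
  centers <- data.frame(x = c(0, 1, 10), y = c(0, 0, 0))
  k <- gaussian_kernel(centers, phi = 2, tau = 1)
  expect_equal(k$W[1, 1], 1)                     # r = 0
  expect_equal(k$W[1, 2], exp(-0.5))             # r = tau
  expect_equal(k$W[1, 3], 0)                     # beyond phi
  expect_equal(unname(rowSums(k$M)), rep(1, 3))
  # isolated centre keeps itself
  k2 <- gaussian_kernel(data.frame(x = c(0, 10), y = c(0, 0)), 1, 1)
  expect_equal(unname(k2$M[2, ]), c(0, 1))
})

test_that("one-step walk preserves the simplex and matches direct product", {
  M <- rbind(c(0.5, 0.5), c(0.5, 0.5))
  th0 <- rbind(c(1, 0), c(0, 1))
  out <- impute_theta(list(M = M), th0)
  expect_equal(unname(out), rbind(c(0.5, 0.5), c(0.5, 0.5)))
  # constant compositions are a fixed point of any stochastic matrix
  set.seed(30)
  centers <- data.frame(x = runif(15), y = runif(15))
  k <- gaussian_kernel(centers, phi = 0.5, tau = 0.2)
  flat <- matrix(rep(c(0.2, 0.3, 0.5), each = 15), 15, 3)
  expect_equal(impute_theta(k, flat), k$M %*% flat)  # direct product oracle
  expect_equal(unname(impute_theta(k, flat)), unname(flat), tolerance = 1e-12)
  th <- random_theta(15, 3, 30)
  expect_equal(unname(rowSums(impute_theta(k, th))), rep(1, 15),
               tolerance = 1e-12)
})

test_that("expression imputation matches the pseudoinverse identities", {
  set.seed(31)
  th <- diag(3)
  thi <- random_theta(4, 3, 31)
  X <- matrix(runif(3 * 6), 3, 6)
  expect_equal(impute_expression(thi, th, X), thi %*% X)
  # theta_imputed = theta, invertible theta: reproduces X
  th2 <- random_theta(3, 3, 32)
  expect_equal(impute_expression(th2, th2, X), X, tolerance = 1e-8)
  # tall full-rank instance vs an independent SVD pseudoinverse
  th3 <- random_theta(8, 3, 33)
  X3 <- matrix(runif(8 * 5), 8, 5)
  s <- svd(th3)
  pinv <- s$v %*% diag(1 / s$d) %*% t(s$u)
  expect_equal(impute_expression(thi, th3, X3), thi %*% pinv %*% X3,
               tolerance = 1e-8)
})

test_that("kernel tuning returns the exhaustive argmin", {
  fx <- make_fixture(K = 3, n_cells = 500, n_genes = 40, seed = 8,
                     extent = 1000, markers_per_type = 5, platform_sd = 0)
  phi_grid <- c(120, 200); tau_grid <- c(40, 120)
  tuned <- tune_imputation(fx$sc, phi_grid, tau_grid,
                           sizes = c(250, 333, 500))
  best <- tuned$table[which.min(tuned$table$rmse), ]
  expect_equal(tuned$phi, best$phi)
  expect_equal(tuned$tau, best$tau)
  one <- tune_imputation(fx$sc, 100, 50, sizes = c(250, 500))
  expect_equal(c(one$phi, one$tau), c(100, 50))
  expect_error(tune_imputation(fx$sc, numeric(0), 1), "empty grid")
})

test_that("full imputation keeps simplex rows and covers the tissue", {
  fx <- make_fixture(K = 3, n_cells = 500, n_genes = 40, seed = 9,
                     extent = 600, markers_per_type = 5, platform_sd = 0)
  sim <- coarse_grain(fx$sc, 150)
  fit <- list(theta = sim$theta, coords = sim$coords)
  out <- impute(fit, resolutions = c(100, 75), phi = 150, tau = 60,
                expression = t(library_normalize(sim$counts, 1)))
  for (res in out) {
    expect_equal(unname(rowSums(res$theta)), rep(1, nrow(res$theta)),
                 tolerance = 1e-9)
    expect_gt(nrow(res$centers), nrow(sim$coords) * 0.8)
    expect_equal(nrow(res$expression), nrow(res$theta))
  }
})
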