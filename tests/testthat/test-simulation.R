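# Coarse-graining, density/replacement manipulations and the fixture
# generator.

test_that("coarse-graining follows the ceiling formula and conserves cells", {
  # two cells in one spot: gene1 relative expression (10/100 + 0/50)/2 = 0.05
  counts <- cbind(A = c(10, 90), B = c(0, 50))
  rownames(counts) <- c("g1", "g2")
  sc <- list(counts = counts,
             coords = data.frame(x = c(1, 2), y = c(1, 2),
                                 row.names = c("A", "B")),
             cell_type = setNames(factor(c("T1", "T2")), c("A", "B")))
  sim <- coarse_grain(sc, grid_size = 10, scale_N = 1000)
  expect_equal(ncol(sim$counts), 1)
  expect_equal(unname(sim$counts["g1", 1]), 50)
  expect_equal(unname(sim$theta[1, ]), c(0.5, 0.5))
  # ceiling never drops a non-zero gene to zero
  counts2 <- cbind(A = c(1, 9999))
  rownames(counts2) <- c("g1", "g2")
  sc2 <- list(counts = counts2,
              coords = data.frame(x = 1, y = 1, row.names = "A"),
              cell_type = setNames(factor("T1"), "A"))
  sim2 <- coarse_grain(sc2, 10)
  expect_equal(unname(sim2$counts["g1", 1]), 1)  # ceil(1e-4 * 1000) = 1
  expect_equal(unname(sim2$theta[1, ]), 1)       # one-hot
  # cell conservation and exact rational ground truth on a larger fixture
  fx <- tiny_fixture()
  sim3 <- coarse_grain(fx$sc, 80)
  expect_equal(sum(sim3$cells_per_spot), ncol(fx$sc$counts))
  expect_equal(unname(rowSums(sim3$theta)), rep(1, nrow(sim3$theta)))
  expect_error(coarse_grain(fx$sc, -1), "positive")
})

test_that("sequencing replacement keeps geometry and labels", {
  fx <- tiny_fixture()
  rep1 <- sequencing_replace(fx$sc, fx$ref, fx$ref_annot, seed = 4)
  expect_identical(rep1$coords, fx$sc$coords)
  expect_identical(as.character(rep1$cell_type), as.character(fx$sc$cell_type))
  expect_identical(rep1, sequencing_replace(fx$sc, fx$ref, fx$ref_annot,
                                            seed = 4))
  # every replaced profile is an actual reference column of the same type
  k <- levels(fx$sc$cell_type)[1]
  cell <- which(fx$sc$cell_type == k)[1]
  pool <- fx$ref[, fx$ref_annot == k, drop = FALSE]
  match_any <- any(apply(pool, 2, function(cl) all(cl == rep1$counts[, cell])))
  expect_true(match_any)
  bad_annot <- fx$ref_annot
  levels(bad_annot) <- c("X", "Y", "Z")
  expect_error(sequencing_replace(fx$sc, fx$ref, bad_annot), "absent")
})

test_that("densify multiplies cell counts and preserves the ground truth", {
  fx <- make_fixture(K = 3, n_cells = 150, n_genes = 40, seed = 5,
                     extent = 300, markers_per_type = 5, n_ref_cells = 900,
                     platform_sd = 0)
  dense <- densify(fx$sc, fx$ref, fx$ref_annot, factor = 3, seed = 6)
  expect_equal(ncol(dense$counts), 3 * ncol(fx$sc$counts))
  th1 <- coarse_grain(fx$sc, 100)$theta
  th3 <- coarse_grain(dense, 100)$theta
  expect_equal(th3[rownames(th1), colnames(th1)], th1)
})

test_that("down-sampling and mismatch scenarios edit only what they claim", {
  fx <- tiny_fixture()
  k <- levels(fx$ref_annot)[2]
  n_k <- sum(fx$ref_annot == k)
  ds <- downsample_celltype(fx$ref, fx$ref_annot, k, 5, seed = 7)
  expect_equal(sum(ds$annot == k), 5)
  expect_equal(sum(ds$annot != k), sum(fx$ref_annot != k))
  full <- downsample_celltype(fx$ref, fx$ref_annot, k, n_k, seed = 7)
  expect_equal(ncol(full$counts), ncol(fx$ref))
  expect_error(downsample_celltype(fx$ref, fx$ref_annot, k, n_k + 1), "exceeds")

  drop1 <- mismatch_scenarios(fx$ref, fx$ref_annot, drop = k)
  expect_equal(nlevels(drop1$annot), 2)
  novel <- fx$ref[, 1:10]
  colnames(novel) <- paste0("x", 1:10)
  add1 <- mismatch_scenarios(fx$ref, fx$ref_annot, add_counts = novel,
                             add_annot = rep("novel", 10))
  expect_equal(nlevels(add1$annot), 4)
  ident <- mismatch_scenarios(fx$ref, fx$ref_annot)
  expect_equal(ident$counts, fx$ref)
  expect_error(mismatch_scenarios(fx$ref, fx$ref_annot,
                                  drop = levels(fx$ref_annot)[1:2]),
               "fewer than 2")
})

test_that("the fixture generator is seeded and marker blocks are recoverable", {
  fx1 <- tiny_fixture(seed = 9)
  fx2 <- tiny_fixture(seed = 9)
  expect_identical(fx1, fx2)
  expect_false(identical(fx1$sc$counts, tiny_fixture(seed = 10)$sc$counts))
  # without distortion, reference type means track the spatial type means
  fx <- tiny_fixture(seed = 9)
  mu_sc <- compute_signatures(fx$sc$counts, fx$sc$cell_type)
  mu_ref <- compute_signatures(fx$ref, fx$ref_annot)
  expect_gt(cor(as.vector(mu_sc), as.vector(mu_ref[rownames(mu_sc), ])), 0.98)
  # marker blocks recovered by the selection procedure at default criteria
  got <- select_marker_genes(library_normalize(fx$ref, 1), fx$ref_annot,
                             marker_criteria(), raw = fx$ref)
  expect_true(all(unlist(fx$marker_genes) %in% got))
  # layered geometry: types segregate along y
  med_y <- tapply(fx$sc$coords$y, fx$sc$cell_type, median)
  expect_true(all(diff(med_y) > 0))
})

test_that("merging experiments keeps them spatially disjoint", {
  fx <- tiny_fixture()
  both <- merge_experiments(fx$sc, fx$sc)
  expect_equal(ncol(both$counts), 2 * ncol(fx$sc$counts))
  gap <- min(both$coords$x[-(1:ncol(fx$sc$counts))]) -
    max(both$coords$x[1:ncol(fx$sc$counts)])
  expect_gt(gap, 5 * (max(fx$sc$coords$x) - min(fx$sc$coords$x)))
})
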