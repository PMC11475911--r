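# Ground-truthed simulation: coarse-graining of single-cell-resolution
# spatial data into capture spots, sequencing-based profile replacement,
# density scaling, rare-type down-sampling, reference-mismatch scenarios and
# a fully synthetic fixture generator.
#
# A single-cell spatial dataset is a list with
#   counts    genes x cells count matrix
#   coords    data.frame (rownames = cell ids, columns x, y)
#   cell_type named factor of per-cell labels

.validate_sc <- function(sc) {
  stopifnot(is.list(sc), all(c("counts", "coords", "cell_type") %in% names(sc)))
  stopifnot(identical(colnames(sc$counts), rownames(sc$coords)))
  sc$cell_type <- droplevels(factor(sc$cell_type[colnames(sc$counts)]))
  sc
}

#' Coarse-grain single-cell spatial data into capture spots
#'
#' Grids the tissue into half-open squares of side `grid_size` anchored at
#' (min x, min y). For every non-empty square the ground-truth composition is
#' the cell-count fraction per type, and the simulated expression is
#' `nUMI_j = ceil(mean_i(U_ij / sum_j U_ij) * scale_N)` over the cells in the
#' square — the ceiling never drops a non-zero gene to zero.
#'
#' @param sc single-cell spatial dataset.
#' @param grid_size square side length (same unit as the coordinates).
#' @param scale_N scaling factor applied to the mean relative expression
#'   (default 1000).
#' @return list of class `simulated_st` with `counts` (genes x spots),
#'   `coords` (spot centres), `theta` (spots x K ground truth, exact
#'   cell-count fractions) and `cells_per_spot`; `grid_size` kept as an
#'   attribute.
#' @export
coarse_grain <- function(sc, grid_size, scale_N = 1000) {
  sc <- .validate_sc(sc)
  if (grid_size <= 0) stop("grid_size must be positive")
  if (ncol(sc$counts) == 0) stop("empty tissue")
  gx <- floor((sc$coords$x - min(sc$coords$x)) / grid_size)
  gy <- floor((sc$coords$y - min(sc$coords$y)) / grid_size)
  cell_spot <- paste0("s", gx, "_", gy)
  spots <- unique(cell_spot)
  rel <- library_normalize(sc$counts, 1)      # U_ij / sum_j U_ij per cell
  types <- levels(sc$cell_type)
  counts <- matrix(0, nrow(sc$counts), length(spots),
                   dimnames = list(rownames(sc$counts), spots))
  theta <- matrix(0, length(spots), length(types),
                  dimnames = list(spots, types))
  centers <- data.frame(x = numeric(length(spots)), y = numeric(length(spots)),
                        row.names = spots)
  n_cells <- integer(length(spots))
  for (s in seq_along(spots)) {
    cells <- which(cell_spot == spots[s])
    n_cells[s] <- length(cells)
    counts[, s] <- ceiling(rowMeans(rel[, cells, drop = FALSE]) * scale_N)
    tab <- table(sc$cell_type[cells])
    theta[s, names(tab)] <- as.numeric(tab) / length(cells)
    g0 <- unique(gx[cells]); g1 <- unique(gy[cells])
    centers[s, ] <- c(min(sc$coords$x) + (g0 + 0.5) * grid_size,
                      min(sc$coords$y) + (g1 + 0.5) * grid_size)
  }
  structure(list(counts = counts, coords = centers, theta = theta,
                 cells_per_spot = setNames(n_cells, spots)),
            class = "simulated_st", grid_size = grid_size)
}

#' Replace cell profiles with same-type reference cells
#'
#' Keeps every cell's location and label but swaps its expression for that of
#' a randomly chosen reference cell of the same type (without replacement
#' while reference cells of the type remain, then with replacement).
#'
#' @param sc single-cell spatial dataset.
#' @param ref genes x cells reference count matrix.
#' @param annot named factor of reference cell types.
#' @param seed integer seed.
#' @return the modified single-cell spatial dataset (same genes as `ref`).
#' @export
sequencing_replace <- function(sc, ref, annot, seed = 1) {
  sc <- .validate_sc(sc)
  annot <- factor(annot[colnames(ref)])
  missing <- setdiff(levels(sc$cell_type), levels(annot))
  if (length(missing)) stop("cell types absent from reference: ",
                            paste(missing, collapse = ", "))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  new_counts <- matrix(0, nrow(ref), ncol(sc$counts),
                       dimnames = list(rownames(ref), colnames(sc$counts)))
  for (k in levels(sc$cell_type)) {
    cells <- which(sc$cell_type == k)
    pool <- which(annot == k)
    take <- if (length(cells) <= length(pool))
      sample(pool, length(cells)) else
        c(sample(pool), sample(pool, length(cells) - length(pool), replace = TRUE))
    new_counts[, cells] <- ref[, take]
  }
  list(counts = new_counts, coords = sc$coords, cell_type = sc$cell_type)
}

#' Increase cell density while preserving compositions
#'
#' For every spot (lattice square) and every cell type present in it, adds
#' `(factor - 1)` times as many same-type reference cells at the location of
#' one of the spot's cells, so the ground-truth composition is unchanged while
#' the cell count scales by `factor`. Reference cells are drawn without
#' replacement until exhausted, then with replacement (with a warning).
#'
#' @param sc single-cell spatial dataset (genes must match `ref`).
#' @param ref genes x cells reference counts.
#' @param annot reference cell types.
#' @param factor density multiple (the spec's arms use 3 or 6).
#' @param seed integer seed.
#' @return the densified single-cell spatial dataset.
#' @export
densify <- function(sc, ref, annot, factor = 3, seed = 1) {
  sc <- .validate_sc(sc)
  stopifnot(factor >= 2)
  annot <- factor(annot[colnames(ref)])
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  used <- integer(0)
  add_counts <- list(); add_xy <- list(); add_type <- list()
  for (k in levels(droplevels(sc$cell_type))) {
    cells <- which(sc$cell_type == k)
    n_new <- (factor - 1) * length(cells)
    pool <- setdiff(which(annot == k), used)
    if (n_new > length(pool)) {
      warning("reference exhausted for type ", k, "; sampling with replacement")
      take <- c(pool, sample(which(annot == k), n_new - length(pool), replace = TRUE))
    } else take <- sample(pool, n_new)
    used <- c(used, take)
    src <- rep(cells, factor - 1)              # duplicate at existing locations
    add_counts[[k]] <- ref[rownames(sc$counts), take, drop = FALSE]
    add_xy[[k]] <- sc$coords[src, , drop = FALSE]
    add_type[[k]] <- rep(k, n_new)
  }
  counts <- cbind(sc$counts, do.call(cbind, add_counts))
  colnames(counts) <- paste0("cell", seq_len(ncol(counts)))
  coords <- rbind(sc$coords, do.call(rbind, add_xy))
  rownames(coords) <- colnames(counts)
  ct <- factor(c(as.character(sc$cell_type), unlist(add_type)))
  names(ct) <- colnames(counts)
  list(counts = counts, coords = coords, cell_type = ct)
}

#' Down-sample one cell type in the reference
#'
#' @param ref genes x cells reference counts.
#' @param annot reference cell types.
#' @param celltype the type to down-sample.
#' @param n cells of that type to keep.
#' @param seed integer seed.
#' @return list with the subset `counts` and `annot`.
#' @export
downsample_celltype <- function(ref, annot, celltype, n, seed = 1) {
  annot <- factor(annot[colnames(ref)])
  idx <- which(annot == celltype)
  if (n > length(idx)) stop("n exceeds the available cells of type ", celltype)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  keep <- sort(c(setdiff(seq_along(annot), idx), sample(idx, n)))
  list(counts = ref[, keep, drop = FALSE], annot = droplevels(annot[keep]))
}

#' Build mismatching-reference scenarios
#'
#' Drops the named cell types from the reference (missing-type scenario)
#' and/or appends external cells carrying novel labels (added-type scenario).
#'
#' @param ref genes x cells reference counts.
#' @param annot reference cell types.
#' @param drop character vector of types to remove (default none).
#' @param add_counts,add_annot optional external cells to append; their labels
#'   must not collide with retained reference types.
#' @return list with modified `counts` and `annot`.
#' @export
mismatch_scenarios <- function(ref, annot, drop = character(0),
                               add_counts = NULL, add_annot = NULL) {
  annot <- factor(annot[colnames(ref)])
  if (length(drop)) {
    if (!all(drop %in% levels(annot))) stop("unknown cell type in drop")
    if (nlevels(annot) - length(drop) < 2)
      stop("dropping would leave fewer than 2 cell types")
    keep <- !(annot %in% drop)
    ref <- ref[, keep, drop = FALSE]
    annot <- droplevels(annot[keep])
  }
  if (!is.null(add_counts)) {
    stopifnot(!is.null(add_annot), ncol(add_counts) == length(add_annot))
    ref <- cbind(ref, add_counts[rownames(ref), , drop = FALSE])
    annot <- factor(c(as.character(annot), as.character(add_annot)))
    names(annot) <- colnames(ref)
  }
  list(counts = ref, annot = annot)
}

#' Generate a synthetic single-cell spatial dataset with paired reference
#'
#' Emulates a cortical-layer-like tissue: K cell types with log-normal mean
#' profiles and type-specific marker blocks; cells placed uniformly in a
#' square tissue, with type membership biased towards one horizontal layer
#' per type (`layered`) or independent of position (`random`); per-cell
#' counts Poisson around depth-scaled type means. A paired external reference
#' is drawn from the same type means with an independent per-gene log-normal
#' multiplicative platform distortion.
#'
#' @param K cell types (>= 2).
#' @param n_cells cells in the spatial dataset.
#' @param n_genes genes.
#' @param geometry `"layered"` (default) or `"random"`.
#' @param seed integer seed; the generator is a pure function of its
#'   arguments and the seed.
#' @param n_ref_cells cells in the paired reference (default `n_cells`).
#' @param extent tissue side length in coordinate units (default 1000).
#' @param markers_per_type marker-block size (default 10).
#' @param marker_fold marker over-expression fold (default 8).
#' @param marker_dropout factor damping marker-block expression in the
#'   non-marker types (default 5e-4), mimicking the near-zero background
#'   expression of real marker genes.
#' @param marker_leak multiplier for the partial expression of each marker
#'   block in the adjacent layer's type (default 1, i.e. baseline-level
#'   leak); markers are enriched, not exclusive.
#' @param depth_range per-cell total-count range (default 800-1500).
#' @param platform_sd standard deviation of the log-normal per-gene scale
#'   component of the platform distortion applied to the reference (default
#'   0.5; 0 disables the whole distortion).
#' @param platform_gamma_sd standard deviation of the per-gene response
#'   exponent around 1 (default 0.4); makes the distortion depend on
#'   expression level, so it cannot be absorbed by a per-gene random effect.
#' @param layer_purity probability that a cell takes its layer's dominant
#'   type (default 0.8).
#' @return list with `sc` (single-cell spatial dataset), `ref` (genes x cells
#'   reference counts), `ref_annot`, the true `profiles` (K x genes relative
#'   expression) and the `marker_genes` blocks.
#' @export
make_fixture <- function(K = 5, n_cells = 2000, n_genes = 200,
                         geometry = c("layered", "random"), seed = 1,
                         n_ref_cells = n_cells, extent = 1000,
                         markers_per_type = 10, marker_fold = 8,
                         marker_dropout = 5e-4, marker_leak = 1,
                         depth_range = c(800, 1500), platform_sd = 0.5,
                         platform_gamma_sd = 0.4, layer_purity = 0.8) {
  geometry <- match.arg(geometry)
  stopifnot(K >= 2, n_genes >= K * markers_per_type, n_cells >= K)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  genes <- sprintf("gene%03d", seq_len(n_genes))
  types <- paste0("type", seq_len(K))
  # base profile shared across types, marker blocks boosted per type
  base <- rlnorm(n_genes, meanlog = 0, sdlog = 1)
  profiles <- matrix(rep(base, each = K), K, n_genes,
                     dimnames = list(types, genes))
  marker_genes <- list()
  for (k in seq_len(K)) {
    block <- seq((k - 1) * markers_per_type + 1, k * markers_per_type)
    base_block <- profiles[k, block]
    # near-silent in other types (as real markers passing pct thresholds are),
    # except a partial leak into the adjacent layer's type: real markers are
    # enriched rather than exclusive, and shared expression is what makes
    # cross-platform contrast distortion hurt downstream regression
    profiles[-k, block] <- profiles[-k, block] * marker_dropout
    adj <- if (k < K) k + 1 else k - 1
    profiles[adj, block] <- base_block * marker_leak
    profiles[k, block] <- base_block * marker_fold
    marker_genes[[types[k]]] <- genes[block]
  }
  profiles <- profiles / rowSums(profiles)    # relative expression
  # spatial layout
  xy <- data.frame(x = runif(n_cells, 0, extent), y = runif(n_cells, 0, extent))
  if (geometry == "layered") {
    layer <- pmin(floor(xy$y / extent * K) + 1, K)
    dominant <- runif(n_cells) < layer_purity
    type_idx <- ifelse(dominant, layer, sample.int(K, n_cells, replace = TRUE))
  } else {
    type_idx <- sample.int(K, n_cells, replace = TRUE)
  }
  cell_type <- factor(types[type_idx], levels = types)
  depth <- runif(n_cells, depth_range[1], depth_range[2])
  counts <- matrix(rpois(n_genes * n_cells,
                         t(profiles[type_idx, , drop = FALSE]) *
                           rep(depth, each = n_genes)),
                   n_genes, n_cells,
                   dimnames = list(genes, sprintf("cell%04d", seq_len(n_cells))))
  rownames(xy) <- colnames(counts)
  names(cell_type) <- colnames(counts)
  # paired reference: same type means under a platform distortion. A purely
  # per-gene multiplicative factor is absorbed by the per-gene random effect
  # of the downstream regression, so besides a per-gene scale f_j the
  # distortion compresses/expands each gene's across-type contrast around its
  # geometric-mean level m_j:  mu'_kj = f_j m_j (mu_kj / m_j)^gamma_j.
  # This level-dependent component is what per-gene effects cannot absorb.
  if (platform_sd > 0) {
    f <- rlnorm(n_genes, 0, platform_sd)
    gamma <- rnorm(n_genes, 1, platform_gamma_sd)
    m <- exp(colMeans(log(profiles)))
    prof_ref <- t(f * m * (t(profiles) / m)^gamma)
  } else {
    prof_ref <- profiles
  }
  ref_type_idx <- sample.int(K, n_ref_cells, replace = TRUE)
  ref_depth <- runif(n_ref_cells, depth_range[1], depth_range[2])
  ref_mean <- t(prof_ref[ref_type_idx, , drop = FALSE])
  ref_mean <- sweep(ref_mean, 2, colSums(ref_mean), "/")   # renormalize profiles
  ref <- matrix(rpois(n_genes * n_ref_cells,
                      ref_mean * rep(ref_depth, each = n_genes)),
                n_genes, n_ref_cells,
                dimnames = list(genes, sprintf("ref%04d", seq_len(n_ref_cells))))
  ref_annot <- setNames(factor(types[ref_type_idx], levels = types), colnames(ref))
  list(sc = list(counts = counts, coords = xy, cell_type = cell_type),
       ref = ref, ref_annot = ref_annot, profiles = profiles,
       marker_genes = marker_genes,
       platform_factors = if (platform_sd > 0)
         list(scale = f, gamma = gamma) else NULL)
}

#' Offset two experiments so they are never spatial neighbours
#'
#' Shifts the second dataset in x by ten times the combined tissue width, so
#' grids and spot graphs never link cells or spots across experiments.
#'
#' @param sc1,sc2 single-cell spatial datasets with identical genes.
#' @return merged single-cell spatial dataset.
#' @export
merge_experiments <- function(sc1, sc2) {
  sc1 <- .validate_sc(sc1); sc2 <- .validate_sc(sc2)
  stopifnot(identical(rownames(sc1$counts), rownames(sc2$counts)))
  width <- max(sc1$coords$x, sc2$coords$x) - min(sc1$coords$x, sc2$coords$x)
  sc2$coords$x <- sc2$coords$x + 10 * width
  counts <- cbind(sc1$counts, sc2$counts)
  colnames(counts) <- paste0("cell", seq_len(ncol(counts)))
  coords <- rbind(sc1$coords, sc2$coords)
  rownames(coords) <- colnames(counts)
  ct <- factor(c(as.character(sc1$cell_type), as.character(sc2$cell_type)))
  names(ct) <- colnames(counts)
  list(counts = counts, coords = coords, cell_type = ct)
}
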