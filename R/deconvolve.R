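# Pipeline orchestration: preprocessing -> pseudo-spots -> CVAE -> signatures
# -> MLE initialization -> cross-validation -> selection -> spatial smoothing.

#' Cell-type signature matrix
#'
#' Mean library-size-normalized expression of each cell type across its cells,
#' restricted to the marker genes. Computed from the (CVAE-transformed, when
#' the platform correction is on) reference.
#'
#' @param ref genes x cells (transformed) reference expression.
#' @param annot named factor of cell types.
#' @param marker_genes genes to keep (default all).
#' @return K x genes matrix, one row per cell type.
#' @export
compute_signatures <- function(ref, annot, marker_genes = rownames(ref)) {
  annot <- droplevels(factor(annot[colnames(ref)]))
  if (any(table(annot) < 1)) stop("empty cell type")
  norm <- library_normalize(ref, 1)
  norm <- norm[marker_genes, , drop = FALSE]
  types <- levels(annot)
  mu <- t(vapply(types, function(k)
    rowMeans(norm[, annot == k, drop = FALSE]), numeric(nrow(norm))))
  dimnames(mu) <- list(types, marker_genes)
  mu
}

#' Deconvolution configuration
#'
#' @param n_hvg number of highly variable genes in the CVAE gene panel.
#' @param marker [marker_criteria()] applied to both marker-selection passes
#'   (before the CVAE for the gene panel, and on the transformed reference for
#'   the regression).
#' @param cells_min,cells_max cells per pseudo-spot, chosen to match the cell
#'   density of the ST data.
#' @param n_pseudospots pseudo-spot count; NULL uses
#'   [plan_pseudospot_count()] = min(100 N K, 500000).
#' @param use_cvae,use_pseudospots,use_lasso,use_laplacian ablation switches.
#'   With `use_cvae = FALSE` the raw ST data and raw reference are used (the
#'   regression-only arm).
#' @param lambda_r,lambda_l fixed hyperparameters; NULL triggers gene-wise
#'   cross-validation over the grids.
#' @param lambda_r_grid,lambda_l_grid CV candidate grids (default 7-point
#'   logarithmic grids over [0.1, 100]).
#' @param cv_folds CV folds (default 5).
#' @param sigma_grid profiling grid for the error scale sigma.
#' @param cvae_epochs,cvae_batch CVAE training budget.
#' @param neighbor_factor spot-graph neighbourhood multiple.
#' @param theta_cutoff presence cutoff on stage-1 estimates (default 0.001).
#' @param admm,admm_cv ADMM controls for the final fit and for CV refits.
#' @param seed integer seed for every stochastic step.
#' @return list of class `deconv_config`.
#' @export
deconv_config <- function(n_hvg = 250, marker = marker_criteria(),
                          cells_min = 5, cells_max = 20,
                          n_pseudospots = NULL,
                          use_cvae = TRUE, use_pseudospots = TRUE,
                          use_lasso = TRUE, use_laplacian = TRUE,
                          lambda_r = NULL, lambda_l = NULL,
                          lambda_r_grid = 10^seq(-1, 2, length.out = 7),
                          lambda_l_grid = 10^seq(-1, 2, length.out = 7),
                          cv_folds = 5,
                          sigma_grid = c(0.05, 0.1, 0.15, 0.25, 0.35, 0.5, 0.75, 1),
                          cvae_epochs = 300, cvae_batch = 128,
                          neighbor_factor = 1.2, theta_cutoff = 0.001,
                          admm = .admm_control(),
                          admm_cv = .admm_control(maxit = 30, tol = 1e-4,
                                                  warn = FALSE),
                          seed = 1) {
  structure(as.list(environment()), class = "deconv_config")
}

#' Deconvolve spot-level ST data against a scRNA-seq reference
#'
#' Runs the full pipeline: gene-panel selection, pseudo-spot generation,
#' CVAE platform correction, signature computation, base-model MLE,
#' hyperparameter cross-validation, adaptive-LASSO cell-type selection and
#' graph-Laplacian smoothing. Ablation switches in `config` disable
#' individual components.
#'
#' @param st genes x spots ST count matrix.
#' @param coords spot coordinate data.frame (rownames = spot ids, columns x,
#'   y).
#' @param ref genes x cells reference count matrix.
#' @param annot named factor of reference cell types.
#' @param config a [deconv_config()].
#' @return object of class `spot_deconv`; see [tidy.spot_deconv()].
#' @export
deconvolve <- function(st, coords, ref, annot, config = deconv_config()) {
  stopifnot(inherits(config, "deconv_config"))
  st <- count_matrix(st); ref <- count_matrix(ref)
  annot <- droplevels(factor(annot[colnames(ref)]))
  K <- nlevels(annot)
  coords <- coords[colnames(st), , drop = FALSE]
  common <- intersect(rownames(st), rownames(ref))
  if (length(common) < 10) stop("too few genes shared between ST and reference")
  st <- st[common, , drop = FALSE]; ref <- ref[common, , drop = FALSE]

  ref_norm <- library_normalize(ref, 1)
  markers1 <- select_marker_genes(ref_norm, annot, config$marker, raw = ref)
  hvgs <- select_hvgs(ref, min(config$n_hvg, nrow(ref)))
  panel <- rownames(st)[rownames(st) %in% union(hvgs, markers1)]

  cvae_fit <- NULL
  if (config$use_cvae) {
    st_norm <- library_normalize(st, 1)[panel, , drop = FALSE]
    ref_p <- ref_norm[panel, , drop = FALSE]
    pseudo <- NULL
    if (config$use_pseudospots) {
      n_ps <- if (is.null(config$n_pseudospots))
        plan_pseudospot_count(ncol(st), K) else config$n_pseudospots
      pseudo <- generate_pseudospots(ref_p, annot, n_ps, config$cells_min,
                                     config$cells_max, seed = config$seed)
    }
    sc_data <- cbind(ref_p, if (!is.null(pseudo)) t(pseudo$expression))
    sc_sc <- minmax_scale(sc_data)
    st_sc <- minmax_scale(st_norm)
    ref_scaled <- minmax_scale(ref_p, sc_sc$factors)$scaled
    pseudo_scaled <- if (!is.null(pseudo))
      t(minmax_scale(t(pseudo$expression), sc_sc$factors)$scaled)
    cc <- cvae_config(latent_dim = 3 * K, epochs = config$cvae_epochs,
                      batch_size = config$cvae_batch, seed = config$seed)
    cvae_fit <- train_cvae(st_sc$scaled, ref_scaled, pseudo_scaled, cc)
    st_adj <- transform_st(cvae_fit, st_sc$scaled, sc_sc$factors)
    ref_adj <- denoise_reference(cvae_fit, ref_scaled, sc_sc$factors)
    # transformed expression is continuous: "expressing" needs a floor of
    # one count per 10k rather than > 0
    markers <- select_marker_genes(library_normalize(ref_adj, 1), annot,
                                   config$marker, expressed_min = 1e-4)
    if (length(markers) < max(5, K)) markers <- markers1[markers1 %in% panel]
  } else {
    st_adj <- st[panel, , drop = FALSE]
    ref_adj <- ref[panel, , drop = FALSE]
    markers <- markers1[markers1 %in% panel]
  }

  if (length(markers) < max(2, K))
    stop("too few marker genes selected (", length(markers),
         "); relax the marker criteria")
  mu <- compute_signatures(ref_adj, annot, markers)
  Y <- t(st_adj[markers, , drop = FALSE])
  keep_g <- colSums(Y) > 0
  Y <- Y[, keep_g, drop = FALSE]; mu <- mu[, keep_g, drop = FALSE]
  mu <- pmax(mu, 1e-8)                      # strictly positive predicted rates
  N <- colSums(st_adj)
  if (any(N == 0)) stop("spot(s) with zero total count after transformation")

  mle <- fit_base_mle(Y, N, mu, sigma_grid = config$sigma_grid)
  quad <- mle$quad
  q <- weights_from_mle(mle$theta)
  graph <- build_spatial_graph(coords, config$neighbor_factor)

  cv <- NULL
  lambda_r <- config$lambda_r; lambda_l <- config$lambda_l
  if (!config$use_lasso) lambda_r <- 0
  if (!config$use_laplacian) lambda_l <- 0
  if (is.null(lambda_r) || is.null(lambda_l)) {
    cv <- cross_validate(Y, N, mu, quad,
                         if (is.null(lambda_r)) config$lambda_r_grid else lambda_r,
                         if (is.null(lambda_l)) config$lambda_l_grid else lambda_l,
                         graph$L, folds = config$cv_folds, seed = config$seed,
                         cutoff = config$theta_cutoff, control = config$admm_cv)
    lambda_r <- cv$lambda_r; lambda_l <- cv$lambda_l
  }

  if (config$use_lasso) {
    s1 <- stage1_select(Y, N, mu, quad, mle$theta, mle$alpha, q, lambda_r,
                        cutoff = config$theta_cutoff, control = config$admm)
    selected <- s1$selected
    theta1 <- s1$theta; alpha1 <- s1$alpha; trace1 <- s1$trace
  } else {
    selected <- mle$theta >= config$theta_cutoff
    theta1 <- mle$theta; alpha1 <- mle$alpha; trace1 <- numeric(0)
  }
  s2 <- stage2_smooth(Y, N, mu, quad, theta1, alpha1, selected, graph$L,
                      lambda_l, control = config$admm)

  structure(list(theta = s2$theta, alpha = s2$alpha, sigma = mle$sigma,
                 lambda_r = lambda_r, lambda_l = lambda_l, cv = cv,
                 selected = selected, mle_theta = mle$theta,
                 markers = colnames(Y), gene_panel = panel,
                 cell_types = rownames(mu), coords = coords, graph = graph,
                 cvae = cvae_fit, config = config,
                 traces = list(stage1 = trace1, stage2 = s2$trace)),
            class = "spot_deconv")
}

#' @export
print.spot_deconv <- function(x, ...) {
  cat("Spot deconvolution:", nrow(x$theta), "spots x", length(x$cell_types),
      "cell types;", length(x$markers), "marker genes\n")
  cat("  sigma =", x$sigma, "; lambda_r =", format(x$lambda_r, digits = 4),
      "; lambda_l =", format(x$lambda_l, digits = 4),
      if (is.null(x$cvae)) "(platform correction off)" else "(platform correction on)",
      "\n")
  invisible(x)
}

#' Tidy a deconvolution result
#'
#' One row per spot and cell type with the estimated proportion, the spot
#' coordinates and the presence call.
#'
#' @param x a `spot_deconv` object.
#' @param ... unused.
#' @return data.frame with columns spot, x, y, cell_type, proportion,
#'   selected.
#' @export
tidy.spot_deconv <- function(x, ...) {
  I <- nrow(x$theta); K <- ncol(x$theta)
  data.frame(
    spot = rep(rownames(x$theta), K),
    x = rep(x$coords$x, K),
    y = rep(x$coords$y, K),
    cell_type = rep(colnames(x$theta), each = I),
    proportion = as.vector(x$theta),
    selected = as.vector(x$selected),
    row.names = NULL
  )
}

#' One-row summary of a deconvolution fit
#' @param x a `spot_deconv` object.
#' @param ... unused.
#' @return one-row data.frame with fit dimensions and hyperparameters.
#' @export
glance.spot_deconv <- function(x, ...) {
  data.frame(n_spots = nrow(x$theta), n_cell_types = ncol(x$theta),
             n_markers = length(x$markers), sigma = x$sigma,
             lambda_r = x$lambda_r, lambda_l = x$lambda_l,
             cvae = !is.null(x$cvae),
             mean_types_per_spot = mean(rowSums(x$selected)))
}

#' Write estimated proportions and run metadata
#'
#' Writes the spots x K proportion CSV (header = cell-type names) and a JSON
#' sidecar with the resolved configuration and chosen hyperparameters.
#'
#' @param fit a `spot_deconv`.
#' @param path CSV output path; the sidecar is `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_theta <- function(fit, path) {
  write.csv(as.data.frame(fit$theta), path, row.names = TRUE)
  meta <- list(sigma = fit$sigma, lambda_r = fit$lambda_r,
               lambda_l = fit$lambda_l, markers = fit$markers,
               cell_types = fit$cell_types, seed = fit$config$seed,
               switches = fit$config[c("use_cvae", "use_pseudospots",
                                       "use_lasso", "use_laplacian")])
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a proportion matrix written by [write_theta()]
#' @param path CSV path.
#' @return spots x K numeric matrix.
#' @export
read_theta <- function(path) {
  as.matrix(read.csv(path, row.names = 1, check.names = FALSE))
}
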