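# Small shared fixtures, generated in code at test time.

# tiny synthetic tissue + paired reference (no platform distortion)
tiny_fixture <- function(seed = 2, platform_sd = 0) {
  make_fixture(K = 3, n_cells = 300, n_genes = 60, seed = seed, extent = 400,
               markers_per_type = 6, platform_sd = platform_sd)
}

# deconvolution-ready inputs derived from the tiny fixture
tiny_glrm_inputs <- function(seed = 2) {
  fx <- tiny_fixture(seed)
  sim <- coarse_grain(fx$sc, 100)
  ref <- fx$sc$counts
  annot <- fx$sc$cell_type
  markers <- select_marker_genes(library_normalize(ref, 1), annot,
                                 marker_criteria(), raw = ref)
  mu <- pmax(compute_signatures(ref, annot, markers), 1e-8)
  Y <- t(sim$counts[markers, , drop = FALSE])
  list(fx = fx, sim = sim, Y = Y, N = colSums(sim$counts), mu = mu,
       markers = markers, graph = build_spatial_graph(sim$coords))
}

# random simplex matrix
random_theta <- function(I, K, seed = 1) {
  set.seed(seed)
  th <- matrix(rexp(I * K), I, K)
  th / rowSums(th)
}
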