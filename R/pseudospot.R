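# Pseudo-spots: artificial cell mixtures sampled from the reference so the
# scRNA-seq condition of the CVAE sees a spectrum of compositions comparable
# to real spots.

#' Number of pseudo-spots to generate
#'
#' `min(100 * N * K, 500000)` for `N` real spots and `K` cell types.
#'
#' @param N number of spots in the real ST data.
#' @param K number of cell types in the reference.
#' @return integer pseudo-spot count.
#' @export
plan_pseudospot_count <- function(N, K) {
  stopifnot(N >= 1, K >= 1)
  as.integer(min(100 * N * K, 500000))
}

#' Generate pseudo-spots from reference cells
#'
#' Each pseudo-spot draws its cell count uniformly in `[cells_min, cells_max]`,
#' samples that many reference cells uniformly without replacement, and
#' averages their library-normalized profiles. The true composition is the
#' sampled cell-count fraction per type.
#'
#' @param ref_norm genes x cells library-normalized expression.
#' @param annot named factor of cell types for the reference cells.
#' @param n_spots number of pseudo-spots.
#' @param cells_min,cells_max range of cells per pseudo-spot.
#' @param seed integer seed; the generator is a pure function of its inputs
#'   and the seed.
#' @return list with `expression` (pseudo-spots x genes), `composition`
#'   (pseudo-spots x K, rows on the simplex) and `cells_per_spot`.
#' @export
generate_pseudospots <- function(ref_norm, annot, n_spots,
                                 cells_min, cells_max, seed = 1) {
  if (cells_min > cells_max || cells_max > ncol(ref_norm) || cells_min < 1)
    stop("invalid cells-per-spot range")
  annot <- droplevels(factor(annot[colnames(ref_norm)]))
  types <- levels(annot)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  sizes <- sample(cells_min:cells_max, n_spots, replace = TRUE)
  expr <- matrix(0, n_spots, nrow(ref_norm),
                 dimnames = list(paste0("pseudo", seq_len(n_spots)),
                                 rownames(ref_norm)))
  comp <- matrix(0, n_spots, length(types),
                 dimnames = list(rownames(expr), types))
  for (s in seq_len(n_spots)) {
    idx <- sample.int(ncol(ref_norm), sizes[s], replace = FALSE)
    expr[s, ] <- rowMeans(ref_norm[, idx, drop = FALSE])
    tab <- table(annot[idx])
    comp[s, names(tab)] <- as.numeric(tab) / sizes[s]
  }
  list(expression = expr, composition = comp, cells_per_spot = sizes)
}

#' Split pseudo-spots into training and validation sets
#'
#' Seeded random permutation; the last `val_frac` of the permutation is held
#' out for learning-rate decay and early stopping during CVAE training.
#'
#' @param n_spots total pseudo-spots.
#' @param val_frac validation fraction (default 0.2).
#' @param seed integer seed.
#' @return list with integer index vectors `train` and `val`.
#' @export
split_pseudospots <- function(n_spots, val_frac = 0.2, seed = 1) {
  stopifnot(n_spots >= 2, val_frac > 0, val_frac < 1)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  perm <- sample.int(n_spots)
  n_val <- max(1, round(val_frac * n_spots))
  list(train = sort(perm[seq_len(n_spots - n_val)]),
       val = sort(perm[seq(n_spots - n_val + 1, n_spots)]))
}

# Save/restore the global RNG state so seeded helpers do not disturb the
# caller's random stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
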