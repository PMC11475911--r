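# Evaluation metrics: per-spot RMSE, Jensen-Shannon divergence, Pearson
# correlation and FDR against ground-truth compositions; ARI and purity of
# dominant-cell-type maps against region annotations.

#' Root-mean-square error between two composition vectors
#'
#' `sqrt(mean((est - truth)^2))` over the K cell types.
#'
#' @param est,truth length-K numeric vectors.
#' @return scalar >= 0.
#' @export
rmse <- function(est, truth) {
  if (length(est) != length(truth)) stop("length mismatch")
  sqrt(mean((est - truth)^2))
}

#' Jensen-Shannon divergence (base-2, bounded in [0, 1])
#'
#' `0.5 KL(p || m) + 0.5 KL(q || m)` with `m = (p + q)/2`, using the
#' convention 0 log 0 = 0. Symmetric in its arguments.
#'
#' @param est,truth length-K probability vectors (simplex rows).
#' @return scalar in [0, 1].
#' @export
jsd <- function(est, truth) {
  if (any(est < 0) || any(truth < 0)) stop("negative entries")
  m <- (est + truth) / 2
  kl <- function(p, q) {
    i <- p > 0
    sum(p[i] * (log2(p[i]) - log2(q[i])))
  }
  (kl(est, m) + kl(truth, m)) / 2
}

#' Pearson correlation between estimated and true compositions
#'
#' Standard sample correlation over the K proportions; NA when either vector
#' is constant (reported as missing and excluded from aggregates).
#'
#' @param est,truth length-K numeric vectors (K >= 2).
#' @return scalar in [-1, 1], or NA for constant input.
#' @export
pearson <- function(est, truth) {
  if (length(est) < 2) stop("need K >= 2")
  if (sd(est) == 0 || sd(truth) == 0) return(NA_real_)
  cor(est, truth)
}

#' Per-spot false discovery rate of presence calls
#'
#' Fraction of predicted-present cell types (estimate strictly > 0) that are
#' truly absent. NA when nothing is predicted present.
#'
#' @param est,truth length-K vectors; presence = strictly positive entry.
#' @return scalar in [0, 1], or NA.
#' @export
fdr <- function(est, truth) {
  pred <- est > 0
  if (!any(pred)) return(NA_real_)
  sum(pred & truth == 0) / sum(pred)
}

#' Evaluate estimated compositions against ground truth
#'
#' @param est,truth spots x K matrices with matching rows and columns (truth
#'   columns are reordered to `est`'s).
#' @return list with `per_spot` (data.frame of rmse/jsd/pearson/fdr per spot)
#'   and `summary` (median and IQR per metric, plus the count of spots with
#'   undefined correlation).
#' @export
evaluate_theta <- function(est, truth) {
  if (!is.null(rownames(est)) && !is.null(rownames(truth)))
    truth <- truth[rownames(est), , drop = FALSE]
  if (!is.null(colnames(est)) && !is.null(colnames(truth)))
    truth <- truth[, colnames(est), drop = FALSE]
  per_spot <- data.frame(
    spot = rownames(est),
    rmse = vapply(seq_len(nrow(est)), function(i) rmse(est[i, ], truth[i, ]), 1),
    jsd = vapply(seq_len(nrow(est)), function(i) jsd(est[i, ], truth[i, ]), 1),
    pearson = vapply(seq_len(nrow(est)), function(i) pearson(est[i, ], truth[i, ]), 1),
    fdr = vapply(seq_len(nrow(est)), function(i) fdr(est[i, ], truth[i, ]), 1),
    row.names = NULL)
  agg <- function(v) c(median = median(v, na.rm = TRUE),
                       q25 = unname(quantile(v, 0.25, na.rm = TRUE)),
                       q75 = unname(quantile(v, 0.75, na.rm = TRUE)))
  summary <- as.data.frame(rbind(rmse = agg(per_spot$rmse),
                                 jsd = agg(per_spot$jsd),
                                 pearson = agg(per_spot$pearson),
                                 fdr = agg(per_spot$fdr)))
  summary$n_undefined <- c(0, 0, sum(is.na(per_spot$pearson)),
                           sum(is.na(per_spot$fdr)))
  list(per_spot = per_spot, summary = summary)
}

#' Dominant cell type per spot
#'
#' Argmax of each proportion row; ties broken by the first cell-type index
#' (with a message noting how many rows were tied).
#'
#' @param theta spots x K proportion matrix.
#' @return character vector of cell-type names.
#' @export
dominant_type <- function(theta) {
  ties <- sum(apply(theta, 1, function(r) sum(r == max(r)) > 1))
  if (ties > 0) message(ties, " spot(s) had tied dominant types; first index used")
  colnames(theta)[apply(theta, 1, which.max)]
}

#' ARI and purity of a predicted labelling against region annotations
#'
#' Adjusted Rand index of the two labelings plus cluster purity (each
#' predicted class mapped to its majority region).
#'
#' @param dominant per-spot predicted labels (e.g. [dominant_type()]).
#' @param regions per-spot region annotations, same spots.
#' @return named numeric vector c(ari, purity).
#' @export
ari_purity <- function(dominant, regions) {
  if (length(dominant) != length(regions) || !length(dominant))
    stop("labelings must cover the same non-empty spot set")
  tab <- table(dominant, regions)
  purity <- sum(apply(tab, 1, max)) / length(dominant)
  ari <- if (requireNamespace("mclust", quietly = TRUE)) {
    mclust::adjustedRandIndex(dominant, regions)
  } else .ari_contingency(tab)
  c(ari = ari, purity = purity)
}

# ARI from the contingency table (used when mclust is unavailable, and as the
# independent cross-check in the tests).
.ari_contingency <- function(tab) {
  n <- sum(tab)
  sum_comb <- function(x) sum(choose(x, 2))
  index <- sum_comb(tab)
  a <- sum_comb(rowSums(tab)); b <- sum_comb(colSums(tab))
  expected <- a * b / choose(n, 2)
  maxind <- (a + b) / 2
  if (maxind == expected) return(0)
  (index - expected) / (maxind - expected)
}

#' Relative absolute error for one cell type
#'
#' `|est - truth| / truth` for spots where the type is truly present.
#'
#' @param est,truth per-spot proportion vectors of a single cell type.
#' @return numeric vector (NA where the type is absent in truth).
#' @export
relative_abs_error <- function(est, truth) {
  ifelse(truth > 0, abs(est - truth) / truth, NA_real_)
}

#' False negative rate of presence calls for one cell type
#'
#' Fraction of spots truly containing the type where it is predicted absent.
#'
#' @param est,truth per-spot proportion vectors of a single cell type.
#' @return scalar in [0, 1], or NA if the type is never truly present.
#' @export
false_negative_rate <- function(est, truth) {
  pres <- truth > 0
  if (!any(pres)) return(NA_real_)
  sum(est[pres] == 0) / sum(pres)
}
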