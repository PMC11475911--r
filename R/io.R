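# Count-matrix I/O and preprocessing: loading, library-size normalization,
# highly-variable-gene and marker-gene selection.

#' Validate a genes x samples count matrix
#'
#' A count matrix is a base matrix of non-negative integers with unique
#' row (gene) and column (sample) names.
#'
#' @param values numeric matrix, genes in rows.
#' @param gene_ids,sample_ids optional identifier vectors overriding dimnames.
#' @return the validated matrix with dimnames set.
#' @export
count_matrix <- function(values, gene_ids = rownames(values),
                         sample_ids = colnames(values)) {
  values <- as.matrix(values)
  if (is.null(gene_ids) || is.null(sample_ids))
    stop("count_matrix requires gene and sample identifiers")
  if (anyDuplicated(gene_ids)) stop("duplicate gene identifiers")
  if (anyDuplicated(sample_ids)) stop("duplicate sample identifiers")
  if (length(gene_ids) != nrow(values) || length(sample_ids) != ncol(values))
    stop("identifier lengths do not match matrix dimensions")
  if (!is.numeric(values) || anyNA(values)) stop("non-numeric entries in count matrix")
  if (any(values < 0)) stop("negative entries in count matrix")
  storage.mode(values) <- "double"
  dimnames(values) <- list(as.character(gene_ids), as.character(sample_ids))
  values
}

#' Load a count matrix from CSV/TSV or MatrixMarket files
#'
#' CSV/TSV files must carry a header row of sample ids and a first column of
#' gene ids. MatrixMarket input takes the `.mtx` triplet file plus two sidecar
#' text files with one gene / sample identifier per line.
#'
#' @param path file path (`.csv`, `.tsv`/`.txt`, or `.mtx`).
#' @param orientation `"genes"` if rows of the file are genes (default),
#'   `"samples"` if rows are samples (the matrix is transposed on load).
#' @param gene_file,sample_file sidecar identifier files, required for MTX.
#' @return genes x samples count matrix.
#' @export
load_count_matrix <- function(path, orientation = c("genes", "samples"),
                              gene_file = NULL, sample_file = NULL) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.mtx$", path)) {
    if (is.null(gene_file) || is.null(sample_file))
      stop("MTX input requires gene_file and sample_file sidecars")
    m <- as.matrix(Matrix::readMM(path))
    rn <- readLines(gene_file)
    cn <- readLines(sample_file)
  } else {
    sep <- if (grepl("\\.csv$", path)) "," else "\t"
    df <- read.csv(path, sep = sep, check.names = FALSE, row.names = 1)
    m <- as.matrix(df)
    rn <- rownames(df)
    cn <- colnames(df)
  }
  rownames(m) <- rn
  colnames(m) <- cn
  if (orientation == "samples") m <- t(m)
  count_matrix(m)
}

#' Write a count matrix to CSV or MatrixMarket
#'
#' @param m genes x samples count matrix.
#' @param path output path; `.mtx` triggers MatrixMarket output with
#'   `<path>.genes.txt` / `<path>.samples.txt` sidecars.
#' @return invisibly, the path written.
#' @export
write_count_matrix <- function(m, path) {
  if (grepl("\\.mtx$", path)) {
    Matrix::writeMM(Matrix::Matrix(m, sparse = TRUE), path)
    writeLines(rownames(m), paste0(path, ".genes.txt"))
    writeLines(colnames(m), paste0(path, ".samples.txt"))
  } else {
    write.csv(as.data.frame(m), path, row.names = TRUE)
  }
  invisible(path)
}

#' Load spot coordinates (columns id, x, y)
#' @param path CSV file with columns `id`, `x`, `y`.
#' @return data.frame with rownames = spot ids and numeric columns x, y.
#' @export
load_coordinates <- function(path) {
  df <- read.csv(path)
  stopifnot(all(c("id", "x", "y") %in% names(df)))
  if (anyDuplicated(df$id)) stop("duplicate spot identifiers")
  if (!all(is.finite(df$x)) || !all(is.finite(df$y))) stop("non-finite coordinates")
  out <- data.frame(x = df$x, y = df$y, row.names = as.character(df$id))
  out
}

#' Load cell annotations (columns id, cell_type)
#' @param path CSV file with columns `id`, `cell_type`.
#' @return named factor of cell types, names = cell ids.
#' @export
load_annotations <- function(path) {
  df <- read.csv(path)
  stopifnot(all(c("id", "cell_type") %in% names(df)))
  if (anyDuplicated(df$id)) stop("duplicate cell identifiers")
  setNames(factor(df$cell_type), as.character(df$id))
}

#' Library-size normalization
#'
#' Rescales every sample (column) to a common total, `scale * U_ij / sum_j
#' U_ij`. Samples with zero total count are dropped with a warning naming them.
#'
#' @param m genes x samples matrix of non-negative values.
#' @param scale positive total each column is scaled to.
#' @return genes x samples matrix of non-negative reals; columns sum to `scale`.
#' @export
library_normalize <- function(m, scale = 1) {
  if (scale <= 0) stop("scale must be positive")
  tot <- colSums(m)
  if (any(tot == 0)) {
    warning("dropping zero-total samples: ",
            paste(colnames(m)[tot == 0], collapse = ", "))
    m <- m[, tot > 0, drop = FALSE]
    tot <- tot[tot > 0]
  }
  sweep(m, 2, tot / scale, "/")
}

#' Select highly variable genes
#'
#' Ranks genes by normalized dispersion of log1p counts-per-10k expression:
#' per-gene dispersion (variance / mean) is z-scored within 20 equal-frequency
#' bins of mean expression, so variability is judged relative to genes of
#' similar abundance. Deterministic; ties broken by gene name.
#'
#' @param ref genes x cells count matrix.
#' @param n number of genes to return.
#' @return character vector of `n` gene ids, most variable first.
#' @export
select_hvgs <- function(ref, n) {
  if (n < 1) stop("n must be >= 1")
  if (n > nrow(ref)) stop("n exceeds the number of genes")
  x <- log1p(library_normalize(ref, 1e4))
  mu <- rowMeans(x)
  v <- apply(x, 1, var)
  disp <- ifelse(mu > 0, v / mu, 0)
  n_bins <- max(1, min(20, floor(nrow(ref) / 5)))  # >= 5 genes per bin
  bins <- cut(rank(mu, ties.method = "first"), breaks = n_bins, labels = FALSE)
  z <- disp
  for (b in unique(bins)) {
    i <- bins == b
    s <- sd(disp[i])
    z[i] <- if (is.na(s) || s == 0) 0 else (disp[i] - mean(disp[i])) / s
  }
  ord <- order(-z, rownames(ref))
  rownames(ref)[ord][seq_len(n)]
}

#' Marker selection criteria
#'
#' Thresholds applied per ordered pair of cell types: BH-adjusted Wilcoxon
#' FDR, fold change of mean normalized expression, and the fractions of cells
#' expressing the gene (raw count > 0) in the foreground (`pct1_min`) and
#' background (`pct2_max`) type.
#'
#' @param fdr_max,fc_min,pct1_min,pct2_max,top_n thresholds; defaults follow
#'   the standard FDR < 0.05, FC >= 1.2, pct.1 >= 0.3, pct.2 <= 0.1, top 20
#'   genes per comparison.
#' @return list of class `marker_criteria`.
#' @export
marker_criteria <- function(fdr_max = 0.05, fc_min = 1.2, pct1_min = 0.3,
                            pct2_max = 0.1, top_n = 20) {
  stopifnot(fdr_max > 0, fdr_max <= 1, fc_min > 0,
            pct1_min >= 0, pct1_min <= 1, pct2_max >= 0, pct2_max <= 1,
            top_n >= 1)
  structure(list(fdr_max = fdr_max, fc_min = fc_min, pct1_min = pct1_min,
                 pct2_max = pct2_max, top_n = top_n),
            class = "marker_criteria")
}

#' Select cell-type marker genes
#'
#' For every ordered pair of cell types (a, b), genes are tested with a
#' two-sided Wilcoxon rank-sum test on library-normalized expression (cells of
#' a vs b), adjusted by Benjamini-Hochberg across genes within the comparison.
#' Genes passing all thresholds of `crit` are sorted by fold change (ratio of
#' means, foreground over background, with a 1e-9 pseudo-count) and the top
#' `top_n` per comparison are unioned.
#'
#' @param ref_norm genes x cells library-normalized expression matrix.
#' @param annot named factor of cell types (names = cell ids matching
#'   `colnames(ref_norm)`).
#' @param crit a [marker_criteria()] object.
#' @param raw optional genes x cells raw count matrix used for the
#'   expressing-cell fractions (`raw > 0`); when absent, a cell expresses a
#'   gene if its normalized expression exceeds `expressed_min`.
#' @param expressed_min expression floor defining "expressing" when no raw
#'   counts are given; 0 for count-like input, around 1e-4 (one count per
#'   10,000) for continuous autoencoder-transformed expression on the unit
#'   library scale.
#' @return character vector of marker gene ids (union over comparisons,
#'   in gene order of `ref_norm`).
#' @export
select_marker_genes <- function(ref_norm, annot, crit = marker_criteria(),
                                raw = NULL, expressed_min = 0) {
  annot <- annot[colnames(ref_norm)]
  types <- levels(droplevels(factor(annot)))
  if (length(types) < 2) stop("marker selection needs at least 2 cell types")
  expressed <- if (is.null(raw)) ref_norm > expressed_min else
    raw[rownames(ref_norm), colnames(ref_norm)] > 0
  counts_per_type <- table(annot)
  usable <- names(counts_per_type)[counts_per_type >= 2]
  skipped <- setdiff(types, usable)
  if (length(skipped))
    warning("skipping comparisons for cell types with < 2 cells: ",
            paste(skipped, collapse = ", "))
  selected <- character(0)
  for (a in usable) for (b in usable) {
    if (a == b) next
    ia <- which(annot == a); ib <- which(annot == b)
    xa <- ref_norm[, ia, drop = FALSE]
    xb <- ref_norm[, ib, drop = FALSE]
    pct1 <- rowMeans(expressed[, ia, drop = FALSE])
    pct2 <- rowMeans(expressed[, ib, drop = FALSE])
    fc <- (rowMeans(xa) + 1e-9) / (rowMeans(xb) + 1e-9)
    p <- vapply(seq_len(nrow(ref_norm)), function(g)
      wilcox.test(xa[g, ], xb[g, ], exact = FALSE)$p.value,
      numeric(1))
    p[!is.finite(p)] <- 1  # zero-variance genes: no evidence
    fdr <- p.adjust(p, method = "BH")
    keep <- which(fdr < crit$fdr_max & fc >= crit$fc_min &
                    pct1 >= crit$pct1_min & pct2 <= crit$pct2_max)
    if (!length(keep)) next
    keep <- keep[order(-fc[keep])]
    selected <- c(selected, rownames(ref_norm)[head(keep, crit$top_n)])
  }
  rownames(ref_norm)[rownames(ref_norm) %in% selected]
}
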