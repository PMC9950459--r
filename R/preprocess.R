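#' Log2-transform a raw abundance matrix
#'
#' @param mat raw-scale [proteome_matrix()] with strictly positive values.
#' @return the matrix on the log2 scale.
#' @export
log2_transform <- function(mat) {
  validate_proteome_matrix(mat)
  if (mat$scale != "raw")
    stop("matrix is already on the ", mat$scale, " scale")
  if (any(mat$values <= 0)) {
    bad <- rownames(mat$values)[apply(mat$values <= 0, 1L, any)]
    stop("non-positive values; offending analytes: ",
         paste(utils::head(bad, 5L), collapse = ", "))
  }
  proteome_matrix(log2(mat$values), gene_symbols = mat$gene_symbols,
                  scale = "log2")
}

#' Undo the log2 transform
#' @param mat log2-scale [proteome_matrix()].
#' @return raw-scale matrix.
#' @export
inverse_log2_transform <- function(mat) {
  validate_proteome_matrix(mat)
  if (mat$scale != "log2") stop("matrix is not on the log2 scale")
  proteome_matrix(2^mat$values, gene_symbols = mat$gene_symbols, scale = "raw")
}

#' Median signal normalization
#'
#' Scales each sample so all sample medians equal the grand median of the
#' per-sample medians (factor = grand median / sample median). Stands in for
#' the vendor's median signal normalization step; idempotent.
#'
#' @param mat raw-scale [proteome_matrix()].
#' @return normalized raw-scale matrix, with the scale factors attached as
#'   attribute `"scale_factors"`.
#' @export
median_normalize <- function(mat) {
  validate_proteome_matrix(mat)
  if (mat$scale != "raw") stop("median normalization applies to raw-scale data")
  med <- apply(mat$values, 2L, stats::median)
  if (any(med == 0)) stop("sample(s) with zero median: ",
                          paste(colnames(mat$values)[med == 0], collapse = ", "))
  f <- stats::median(med) / med
  out <- proteome_matrix(sweep(mat$values, 2L, f, "*"),
                         gene_symbols = mat$gene_symbols, scale = "raw")
  attr(out, "scale_factors") <- stats::setNames(f, colnames(mat$values))
  out
}

#' Cross-platform concordance by Spearman correlation
#'
#' Tie-corrected Spearman rank correlation between paired measurements of
#' the same analytes on two platforms, with a two-sided p-value: exact
#' permutation enumeration via [stats::cor.test()] for n <= 10 without ties,
#' t-approximation otherwise (standard in the n ~ 19-30 regime of
#' immunoassay validation subsets).
#'
#' @param x,y equal-length paired numeric vectors (log2-transform upstream;
#'   rank-based, so any monotone transform gives the same rho).
#' @return list with `n`, `rho`, `p_value`.
#' @export
crossplatform_concordance <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 5L) stop("need at least 5 pairs")
  if (anyNA(x) || anyNA(y)) stop("missing values not allowed")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant vector: Spearman correlation undefined")
  rho <- stats::cor(rank(x), rank(y))  # tie-corrected: Pearson on average ranks
  has_ties <- anyDuplicated(x) || anyDuplicated(y)
  if (n <= 10L && !has_ties) {
    p <- stats::cor.test(x, y, method = "spearman", exact = TRUE)$p.value
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(n = n, rho = rho, p_value = min(p, 1))
}

#' Principal component analysis of the meta-proteome
#'
#' PCA of the samples on analyte-centered log2 data (no variance scaling by
#' default; `scale.` exposes the scaled variant). Variance fractions come
#' from the eigenvalues and sum to one over the returned components.
#'
#' @param mat log2-scale [proteome_matrix()] with at least 3 samples.
#' @param scale. logical; scale analytes to unit variance before PCA.
#' @return list of class `pca_metaproteome` with `scores` (samples x
#'   components), `variance_fraction`, `n_components`.
#' @export
pca_metaproteome <- function(mat, scale. = FALSE) {
  validate_proteome_matrix(mat)
  if (mat$scale != "log2") stop("PCA expects log2-scale data")
  if (ncol(mat$values) < 3L) stop("need at least 3 samples")
  if (scale.) {
    sds <- apply(mat$values, 1L, stats::sd)
    if (any(sds == 0)) stop("constant analyte(s) cannot be variance-scaled")
  }
  pc <- stats::prcomp(t(mat$values), center = TRUE, scale. = scale.)
  vf <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(scores = pc$x, variance_fraction = vf,
                 n_components = length(vf)),
            class = "pca_metaproteome")
}

#' @export
print.pca_metaproteome <- function(x, ...) {
  cat(sprintf("PCA meta-proteome: %d samples, %d components\n",
              nrow(x$scores), x$n_components))
  vf <- round(100 * x$variance_fraction[seq_len(min(5, x$n_components))], 1)
  cat("  variance explained (%):", paste(vf, collapse = ", "), "...\n")
  invisible(x)
}

#' Test a principal component for association with labor status
#'
#' Two-sided Welch t-test of the component scores between the TNL and TIL
#' groups.
#'
#' @param pca a [pca_metaproteome()] result.
#' @param annotation sample annotation table.
#' @param component component index.
#' @return two-sided p-value.
#' @export
associate_pc_with_group <- function(pca, annotation, component = 1L) {
  if (component > pca$n_components) stop("component out of range")
  sc <- pca$scores[, component]
  grp <- annotation$group[match(rownames(pca$scores), annotation$sample_id)]
  if (anyNA(grp)) stop("samples without annotation")
  if (any(table(grp) < 2L)) stop("each group needs at least 2 samples")
  stats::t.test(sc[grp == "TIL"], sc[grp == "TNL"])$p.value
}

#' Correlate a principal component with a per-sample covariate
#'
#' Pearson correlation (with two-sided p) of component scores against a
#' covariate such as gestational age at sampling.
#'
#' @param pca a [pca_metaproteome()] result.
#' @param covariate numeric vector, one value per sample in score order; no
#'   missing values.
#' @param component component index.
#' @return list with `r` and `p_value`.
#' @export
correlate_pc_with_covariate <- function(pca, covariate, component = 1L) {
  if (component > pca$n_components) stop("component out of range")
  if (length(covariate) != nrow(pca$scores))
    stop("covariate length must match number of samples")
  if (anyNA(covariate)) stop("missing covariate values not allowed")
  if (stats::sd(covariate) == 0) stop("constant covariate")
  ct <- stats::cor.test(pca$scores[, component], covariate, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value)
}
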