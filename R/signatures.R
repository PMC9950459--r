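#' Reference-standardized Z-scores
#'
#' Standardizes each analyte's log2 abundance by subtracting the mean and
#' dividing by the standard deviation computed from the reference (TNL)
#' group only, so reference samples have mean 0 / SD 1 per analyte and the
#' scores of other samples are expressed in reference SD units. Analytes
#' with zero reference SD are excluded with a warning.
#'
#' @param mat log2-scale [proteome_matrix()].
#' @param annotation sample annotation; reference group needs >= 2 samples.
#' @param reference_group `"TNL"` (default) or `"TIL"`.
#' @return z-scale [proteome_matrix()] (excluded analytes dropped, their
#'   ids in attribute `"excluded"`).
#' @export
zscore_by_reference <- function(mat, annotation, reference_group = "TNL") {
  validate_proteome_matrix(mat)
  if (mat$scale != "log2") stop("Z-scoring expects log2-scale data")
  reference_group <- match.arg(reference_group, c("TNL", "TIL"))
  ann <- match_annotation(mat, annotation)
  ref <- ann$sample_id[ann$group == reference_group]
  if (length(ref) < 2L) stop("reference group needs at least 2 samples")
  mu <- rowMeans(mat$values[, ref, drop = FALSE])
  sd <- apply(mat$values[, ref, drop = FALSE], 1L, stats::sd)
  drop <- sd == 0
  if (any(drop)) {
    warning(sum(drop), " analyte(s) with zero reference SD excluded: ",
            paste(utils::head(rownames(mat$values)[drop], 5L), collapse = ", "))
  }
  keep <- !drop
  z <- (mat$values[keep, , drop = FALSE] - mu[keep]) / sd[keep]
  out <- proteome_matrix(z, gene_symbols = mat$gene_symbols[keep],
                         scale = "zscore")
  attr(out, "excluded") <- rownames(mat$values)[drop]
  out
}

#' Select the measured analytes of an ordered signature
#'
#' Walks the signature's members in preferential-expression order (most
#' specific first), keeps each gene that has a measured analyte, and stops
#' after `max_genes` genes. A gene measured by several analytes contributes
#' a single analyte: the one with the highest mean abundance (ties broken by
#' analyte id).
#'
#' @param signature a gene set (list with `members`, see
#'   [read_signature_lists()]).
#' @param mat a [proteome_matrix()].
#' @param max_genes cap on genes used (default 20).
#' @return character vector of analyte ids in signature order (possibly
#'   empty).
#' @export
select_signature_analytes <- function(signature, mat, max_genes = 20L) {
  validate_proteome_matrix(mat)
  members <- signature$members
  out <- character(0)
  for (g in members) {
    if (length(out) >= max_genes) break
    hits <- which(mat$gene_symbols == g & nzchar(g))
    if (!length(hits)) next
    if (length(hits) > 1L) {
      means <- rowMeans(mat$values[hits, , drop = FALSE])
      ids <- rownames(mat$values)[hits]
      hits <- hits[order(-means, ids)][1]
    }
    out <- c(out, rownames(mat$values)[hits])
  }
  out
}

#' Aggregate a signature into a per-sample score
#'
#' Per-sample arithmetic mean of the listed analytes' Z-scores: the
#' meta-protein signature score.
#'
#' @param z_mat z-scale [proteome_matrix()] from [zscore_by_reference()].
#' @param analytes non-empty character vector of analyte ids.
#' @return named numeric vector, one score per sample.
#' @export
aggregate_signature <- function(z_mat, analytes) {
  validate_proteome_matrix(z_mat)
  if (z_mat$scale != "zscore") stop("aggregation expects a z-scale matrix")
  if (!length(analytes)) stop("empty analyte list")
  missing <- setdiff(analytes, rownames(z_mat$values))
  if (length(missing))
    stop("analytes not in matrix: ", paste(utils::head(missing, 5L), collapse = ", "))
  colMeans(z_mat$values[analytes, , drop = FALSE])
}

#' Score and compare cell-type signatures between groups
#'
#' For each ordered signature: selects up to `max_genes` measured analytes,
#' drops signatures with fewer than `min_genes`, aggregates
#' reference-standardized Z-scores per sample, compares TIL vs TNL scores
#' with the two-sided Wilcoxon rank-sum test (exact distribution when the
#' smaller group has <= `exact_limit` samples and there are no ties, normal
#' approximation with continuity and tie correction otherwise), and applies
#' BH adjustment across all tested signatures as one family. Direction is
#' the sign of the TIL-minus-TNL median score difference for significant
#' signatures.
#'
#' @param mat log2-scale [proteome_matrix()].
#' @param annotation sample annotation.
#' @param signatures named list of ordered gene sets.
#' @param min_genes minimum measured signature genes (default 5).
#' @param max_genes cap on genes used (default 20).
#' @param q_threshold FDR threshold (default 0.1).
#' @param exact_limit exact rank-sum distribution below this smaller-group
#'   size (default 12).
#' @return list of class `signature_scores` with `table` (one row per
#'   tested signature: name, n_genes_used, median score per group, p, q,
#'   direction, significant) and `scores` (samples x signatures matrix).
#' @export
compare_signatures <- function(mat, annotation, signatures, min_genes = 5L,
                               max_genes = 20L, q_threshold = 0.1,
                               exact_limit = 12L) {
  validate_proteome_matrix(mat)
  ann <- match_annotation(mat, annotation)
  if (any(table(ann$group) < 1L)) stop("both groups must be present")
  z <- suppressWarnings(zscore_by_reference(mat, annotation))
  sel <- lapply(signatures, select_signature_analytes, mat = z,
                max_genes = max_genes)
  n_used <- lengths(sel)
  keep <- n_used >= min_genes
  if (!any(keep)) stop("no signature has enough measured genes")
  sel <- sel[keep]
  sigs <- signatures[keep]
  til <- ann$sample_id[ann$group == "TIL"]
  tnl <- ann$sample_id[ann$group == "TNL"]
  scores <- vapply(sel, function(a) aggregate_signature(z, a),
                   numeric(ncol(z$values)))
  rownames(scores) <- colnames(z$values)
  p <- numeric(length(sel)); med_diff <- numeric(length(sel))
  for (i in seq_along(sel)) {
    s_til <- scores[til, i]; s_tnl <- scores[tnl, i]
    exact <- min(length(s_til), length(s_tnl)) <= exact_limit &&
      !anyDuplicated(c(s_til, s_tnl))
    p[i] <- stats::wilcox.test(s_til, s_tnl, exact = exact,
                               correct = !exact)$p.value
    med_diff[i] <- stats::median(s_til) - stats::median(s_tnl)
  }
  q <- bh_adjust(p)
  tab <- data.frame(signature_name = vapply(sigs, `[[`, "", "name"),
                    n_genes_used = n_used[keep],
                    median_tnl = apply(scores[tnl, , drop = FALSE], 2L, stats::median),
                    median_til = apply(scores[til, , drop = FALSE], 2L, stats::median),
                    wilcoxon_p = p, q_value = q,
                    significant = q < q_threshold,
                    direction = ifelse(q < q_threshold,
                                       ifelse(med_diff > 0, "up", "down"),
                                       "none"),
                    stringsAsFactors = FALSE, row.names = NULL)
  structure(list(table = tab, scores = scores), class = "signature_scores")
}

#' @export
print.signature_scores <- function(x, ...) {
  cat(sprintf("signature_scores: %d signatures tested, %d significant\n",
              nrow(x$table), sum(x$table$significant)))
  print.data.frame(x$table, digits = 3)
  invisible(x)
}
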