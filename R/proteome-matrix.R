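#' Proteome abundance matrix
#'
#' The container every pipeline stage consumes: an analytes x samples matrix
#' of aptamer abundance values together with per-analyte gene annotations and
#' a scale flag. Raw values are relative fluorescence units (RFU) and must be
#' strictly positive so that the log2 transform is defined; `scale = "log2"`
#' marks already-transformed data and `scale = "zscore"` marks
#' reference-standardized data produced by [zscore_by_reference()].
#'
#' @param values numeric matrix, analytes in rows, samples in columns.
#'   Row names are taken as analyte ids and column names as sample ids when
#'   `analyte_ids`/`sample_ids` are not given.
#' @param gene_symbols character vector, one per analyte; `""` means the
#'   analyte has no gene annotation (it still participates in differential
#'   analysis but is excluded from gene-level steps).
#' @param scale one of `"raw"`, `"log2"`, `"zscore"`.
#' @param analyte_ids,sample_ids optional explicit id vectors; must be unique.
#'
#' @return An object of class `proteome_matrix`: a list with elements
#'   `values`, `gene_symbols`, `scale`.
#' @export
proteome_matrix <- function(values, gene_symbols = NULL,
                            scale = c("raw", "log2", "zscore"),
                            analyte_ids = NULL, sample_ids = NULL) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix (analytes x samples)")
  if (!is.null(analyte_ids)) rownames(values) <- analyte_ids
  if (!is.null(sample_ids)) colnames(values) <- sample_ids
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("analyte and sample ids are required (as dimnames or arguments)")
  if (is.null(gene_symbols)) gene_symbols <- rep("", nrow(values))
  gene_symbols <- as.character(gene_symbols)
  if (length(gene_symbols) != nrow(values))
    stop("'gene_symbols' must have one entry per analyte")
  obj <- structure(
    list(values = values, gene_symbols = gene_symbols, scale = scale),
    class = "proteome_matrix"
  )
  validate_proteome_matrix(obj)
  obj
}

#' @rdname proteome_matrix
#' @param x a `proteome_matrix`.
#' @export
validate_proteome_matrix <- function(x) {
  stopifnot(inherits(x, "proteome_matrix"))
  ids <- rownames(x$values)
  sids <- colnames(x$values)
  if (anyDuplicated(ids))
    stop("duplicate analyte ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (anyDuplicated(sids))
    stop("duplicate sample ids: ", paste(unique(sids[duplicated(sids)]), collapse = ", "))
  if (ncol(x$values) < 1L) stop("matrix has no samples")
  if (nrow(x$values) < 1L) stop("matrix has no analytes")
  if (anyNA(x$values)) stop("missing values are not supported")
  if (x$scale == "raw" && any(x$values <= 0)) {
    bad <- ids[apply(x$values <= 0, 1L, any)]
    stop("raw-scale values must be strictly positive; offending analytes: ",
         paste(utils::head(bad, 5L), collapse = ", "))
  }
  invisible(x)
}

#' @export
print.proteome_matrix <- function(x, ...) {
  cat(sprintf("proteome_matrix: %d analytes x %d samples [%s scale]\n",
              nrow(x$values), ncol(x$values), x$scale))
  n_annot <- sum(nzchar(x$gene_symbols))
  cat(sprintf("  %d analytes with gene annotation\n", n_annot))
  invisible(x)
}

#' @export
dim.proteome_matrix <- function(x) dim(x$values)

#' Analyte and sample accessors
#' @param x a `proteome_matrix`.
#' @return character vector of ids.
#' @export
analyte_ids <- function(x) rownames(x$values)

#' @rdname analyte_ids
#' @export
sample_ids <- function(x) colnames(x$values)

#' Subset a proteome matrix by analyte and/or sample ids
#'
#' @param x a `proteome_matrix`.
#' @param analytes,samples character vectors of ids to keep (NULL keeps all).
#' @return a `proteome_matrix`.
#' @export
subset_matrix <- function(x, analytes = NULL, samples = NULL) {
  stopifnot(inherits(x, "proteome_matrix"))
  ai <- if (is.null(analytes)) rownames(x$values) else analytes
  si <- if (is.null(samples)) colnames(x$values) else samples
  missing_a <- setdiff(ai, rownames(x$values))
  if (length(missing_a))
    stop("unknown analyte ids: ", paste(utils::head(missing_a, 5L), collapse = ", "))
  missing_s <- setdiff(si, colnames(x$values))
  if (length(missing_s))
    stop("unknown sample ids: ", paste(utils::head(missing_s, 5L), collapse = ", "))
  proteome_matrix(x$values[ai, si, drop = FALSE],
                  gene_symbols = x$gene_symbols[match(ai, rownames(x$values))],
                  scale = x$scale)
}

#' Build a sample annotation table
#'
#' @param sample_id character vector of unique sample ids.
#' @param group character/factor with levels `TNL` (reference, not in labor)
#'   and `TIL` (in labor).
#' @param ga_weeks gestational age at sampling in weeks (may be `NA`).
#' @return a `data.frame` with columns `sample_id`, `group` (factor
#'   TNL/TIL), `ga_weeks`.
#' @export
sample_annotation <- function(sample_id, group, ga_weeks = NA_real_) {
  sample_id <- as.character(sample_id)
  if (anyDuplicated(sample_id)) stop("duplicate sample ids in annotation")
  group <- as.character(group)
  bad <- setdiff(unique(group), c("TNL", "TIL"))
  if (length(bad)) stop("unknown group label(s): ", paste(bad, collapse = ", "))
  ga_weeks <- rep_len(as.numeric(ga_weeks), length(sample_id))
  if (any(!is.na(ga_weeks) & ga_weeks <= 0)) stop("ga_weeks must be positive")
  data.frame(sample_id = sample_id,
             group = factor(group, levels = c("TNL", "TIL")),
             ga_weeks = ga_weeks,
             stringsAsFactors = FALSE)
}

# Align an annotation table to a matrix's samples; every sample must have
# exactly one annotation row.
match_annotation <- function(mat, annotation) {
  stopifnot(inherits(mat, "proteome_matrix"))
  sid <- colnames(mat$values)
  idx <- match(sid, annotation$sample_id)
  if (anyNA(idx)) {
    stop("samples without annotation: ",
         paste(utils::head(sid[is.na(idx)], 5L), collapse = ", "))
  }
  annotation[idx, , drop = FALSE]
}
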