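#' Read a protein abundance table
#'
#' Reads a UTF-8, tab-delimited abundance table with one header row of sample
#' ids and the annotation columns `analyte_id` and `gene_symbol` followed by
#' one numeric column per sample. Extra annotation columns are tolerated and
#' ignored by name-based selection. A `# scale: log2` sidecar comment line
#' (written by [write_abundance_table()]) restores the scale flag; otherwise
#' the table is taken as raw RFU.
#'
#' @param path file path.
#' @param orientation `"analytes_in_rows"` (the only supported layout;
#'   argument kept for explicitness at call sites).
#' @param extra_annotation_cols column names treated as additional analyte
#'   annotations rather than samples (name-based selection; defaults cover
#'   common vendor export columns).
#' @return a [proteome_matrix()].
#' @export
read_abundance_table <- function(path, orientation = "analytes_in_rows",
                                 extra_annotation_cols = c(
                                   "uniprot", "uniprot_id", "entrez",
                                   "entrez_id", "entrez_gene_id", "target",
                                   "target_name", "somamer_id", "seq_id",
                                   "dilution", "description")) {
  orientation <- match.arg(orientation, "analytes_in_rows")
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  scale <- "raw"
  skip <- 0L
  if (startsWith(first, "#")) {
    skip <- 1L
    m <- regmatches(first, regexec("^#\\s*scale:\\s*(\\w+)", first))[[1]]
    if (length(m) == 2L) scale <- m[2]
  }
  df <- utils::read.delim(path, header = TRUE, sep = "\t", skip = skip,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character", na.strings = character())
  required <- c("analyte_id", "gene_symbol")
  if (!all(required %in% names(df)))
    stop("abundance table must have 'analyte_id' and 'gene_symbol' columns")
  sample_cols <- setdiff(names(df),
                         c(required,
                           names(df)[tolower(names(df)) %in% extra_annotation_cols]))
  if (length(sample_cols) == 0L) stop("abundance table has no sample columns")
  if (anyDuplicated(df$analyte_id))
    stop("duplicate analyte id(s): ",
         paste(unique(df$analyte_id[duplicated(df$analyte_id)]), collapse = ", "))
  vals <- matrix(NA_real_, nrow(df), length(sample_cols),
                 dimnames = list(df$analyte_id, sample_cols))
  for (j in seq_along(sample_cols)) {
    raw <- df[[sample_cols[j]]]
    v <- suppressWarnings(as.numeric(raw))
    if (anyNA(v)) {
      i <- which(is.na(v))[1]
      stop(sprintf("non-numeric value '%s' at row %d (analyte %s), column '%s'",
                   raw[i], i, df$analyte_id[i], sample_cols[j]))
    }
    vals[, j] <- v
  }
  proteome_matrix(vals, gene_symbols = df$gene_symbol, scale = scale)
}

#' Write a protein abundance table
#'
#' Inverse of [read_abundance_table()]: tab-delimited, UTF-8, `.` decimal,
#' full double precision (17 significant digits) so that read/write is the
#' identity and write/read/write is byte-identical. Non-raw scales are
#' recorded in a `# scale:` sidecar line.
#'
#' @param mat a [proteome_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_abundance_table <- function(mat, path) {
  validate_proteome_matrix(mat)
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (mat$scale != "raw") writeLines(sprintf("# scale: %s", mat$scale), con)
  header <- c("analyte_id", "gene_symbol", colnames(mat$values))
  writeLines(paste(header, collapse = "\t"), con)
  body <- format_full(mat$values)
  lines <- paste(rownames(mat$values), mat$gene_symbols,
                 apply(body, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(lines, con)
  invisible(path)
}

# %.17g formatting: shortest representation that round-trips a double
format_full <- function(m) {
  out <- sprintf("%.17g", m)
  dim(out) <- dim(m)
  out
}

#' Read / write sample annotation tables
#'
#' Tab-delimited with columns `sample_id`, `group` (TNL/TIL), `ga_weeks`
#' (empty for missing).
#'
#' @param path file path.
#' @return [read_annotation_table()]: annotation `data.frame` as built by
#'   [sample_annotation()].
#' @export
read_annotation_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  req <- c("sample_id", "group", "ga_weeks")
  if (!all(req %in% names(df)))
    stop("annotation table must have columns: ", paste(req, collapse = ", "))
  sample_annotation(df$sample_id, df$group, df$ga_weeks)
}

#' @rdname read_annotation_table
#' @param annotation annotation `data.frame`.
#' @export
write_annotation_table <- function(annotation, path) {
  df <- annotation[, c("sample_id", "group", "ga_weeks")]
  df$group <- as.character(df$group)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a GMT gene-set file
#'
#' Standard GMT dialect: one set per line, `name TAB description TAB member
#' members...`. Duplicate members within a set are removed preserving first
#' occurrence; member order is otherwise preserved (for cell-type signature
#' files it encodes the preferential-expression ranking, most specific
#' first).
#'
#' @param path file path.
#' @return a named list of gene sets; each element is a list with fields
#'   `name`, `description`, `members` (character vector, non-empty, unique).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  keep <- which(nzchar(trimws(lines)))
  sets <- vector("list", length(keep))
  names_seen <- character(0)
  for (k in seq_along(keep)) {
    i <- keep[k]
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    fields <- fields[nzchar(fields)]
    if (length(fields) < 3L)
      stop(sprintf("GMT line %d has fewer than 3 fields", i))
    nm <- fields[1]
    if (nm %in% names_seen) stop("duplicate gene-set name: ", nm)
    names_seen <- c(names_seen, nm)
    members <- fields[-(1:2)]
    members <- members[!duplicated(members)]
    sets[[k]] <- list(name = nm, description = fields[2], members = members)
  }
  names(sets) <- names_seen
  sets
}

#' @rdname read_gmt
#' @param sets list of gene sets (as returned by [read_gmt()]).
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(sets, function(s) {
    paste(c(s$name, s$description, s$members), collapse = "\t")
  }, character(1))
  writeLines(lines, file(path, encoding = "UTF-8"))
  invisible(path)
}

#' Read ordered cell-type signature lists
#'
#' GMT dialect where member order encodes preferential-expression rank
#' (most cell-type-specific gene first), suitable for
#' [select_signature_analytes()]. An empty file yields an empty list.
#'
#' @param path file path.
#' @return named list of ordered gene sets.
#' @export
read_signature_lists <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (length(readLines(path, n = 1L)) == 0L) return(structure(list(), names = character(0)))
  read_gmt(path)
}
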