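#' Per-analyte two-group summary statistics
#'
#' For each analyte on the log2 scale: the difference of group means
#' (TIL minus TNL, i.e. the log2 fold change as a ratio of geometric means),
#' the pooled residual variance, the residual degrees of freedom
#' `n_TIL + n_TNL - 2`, and the standard-error factor
#' `sqrt(1/n_TIL + 1/n_TNL)`.
#'
#' @param mat log2-scale [proteome_matrix()].
#' @param annotation sample annotation; both groups need >= 2 samples and
#'   every sample must be annotated.
#' @return list of class `group_stats` with per-analyte vectors `log2fc`,
#'   `s2`, scalars `df_residual`, `stderr_factor`, plus `analyte_id`,
#'   `gene_symbol`, group sizes.
#' @export
fit_group_stats <- function(mat, annotation) {
  validate_proteome_matrix(mat)
  if (mat$scale != "log2") stop("group statistics expect log2-scale data")
  ann <- match_annotation(mat, annotation)
  til <- ann$sample_id[ann$group == "TIL"]
  tnl <- ann$sample_id[ann$group == "TNL"]
  n1 <- length(tnl); n2 <- length(til)
  if (n1 < 2L || n2 < 2L) stop("each group needs at least 2 samples")
  v <- mat$values
  m_til <- rowMeans(v[, til, drop = FALSE])
  m_tnl <- rowMeans(v[, tnl, drop = FALSE])
  ss <- rowSums((v[, til, drop = FALSE] - m_til)^2) +
        rowSums((v[, tnl, drop = FALSE] - m_tnl)^2)
  df <- n1 + n2 - 2L
  structure(list(analyte_id = rownames(v),
                 gene_symbol = mat$gene_symbols,
                 log2fc = unname(m_til - m_tnl),
                 s2 = unname(ss / df),
                 df_residual = df,
                 stderr_factor = sqrt(1 / n1 + 1 / n2),
                 n_tnl = n1, n_til = n2),
            class = "group_stats")
}

# Newton solve of trigamma(y) = x, y > 0 (monotone decreasing, convex).
trigamma_inverse <- function(x) {
  if (x <= 0) return(Inf)
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:60) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2L)
    y <- y + dif
    if (abs(dif / y) < 1e-10) break
  }
  y
}

#' Method-of-moments empirical-Bayes hyperparameter fit
#'
#' Fits the prior degrees of freedom `d0` and prior variance `s0^2` of the
#' hierarchical variance model (per-analyte variances ~ scaled
#' inverse-chi-square) by moment matching on
#' `e_g = log(s_g^2) - digamma(d_g/2) + log(d_g/2)`:
#' `trigamma(d0/2) = var(e) - trigamma(d_g/2)` (with `d0 = Inf` when the
#' right-hand side is non-positive) and
#' `s0^2 = exp(mean(e) + digamma(d0/2) - log(d0/2))`; in the infinite-d0
#' limit `s0^2` is the arithmetic mean of the sample variances.
#'
#' @param stats a [fit_group_stats()] result (>= 50 analytes recommended; a
#'   warning is emitted below that).
#' @return list of class `ebayes_params` with `d0` (possibly `Inf`) and
#'   `s0_sq`.
#' @export
estimate_ebayes <- function(stats) {
  stopifnot(inherits(stats, "group_stats"))
  s2 <- stats$s2
  m <- length(s2)
  if (m < 2L) stop("need at least 2 analytes to estimate hyperparameters")
  if (m < 50L)
    warning("fewer than 50 analytes: hyperparameter estimates are unstable")
  if (any(s2 <= 0)) {
    warning("zero sample variances detected, offset away from zero")
    s2 <- pmax(s2, 1e-5 * stats::median(s2[s2 > 0]))
  }
  dg <- stats$df_residual
  e <- log(s2) - digamma(dg / 2) + log(dg / 2)
  evar <- stats::var(e) - trigamma(dg / 2)
  if (evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s0_sq <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s0_sq <- mean(s2)
  }
  structure(list(d0 = d0, s0_sq = s0_sq), class = "ebayes_params")
}

#' Moderated t-statistics
#'
#' Shrinks each analyte's variance toward the prior,
#' `s_tilde^2 = (d0 s0^2 + d_g s_g^2) / (d0 + d_g)`, forms
#' `t = log2fc / (stderr_factor * sqrt(s_tilde^2))`, and computes two-sided
#' p-values from a t-distribution with `d0 + d_g` degrees of freedom
#' (Gaussian when `d0 = Inf`). `d0 = 0` disables moderation and reproduces
#' the ordinary pooled two-sample t-test.
#'
#' @param stats a [fit_group_stats()] result.
#' @param params an [estimate_ebayes()] result, or a list with `d0`,
#'   `s0_sq` (`d0 = 0` for no moderation).
#' @return a `data.frame` of class `differential_table` with columns
#'   `analyte_id`, `gene_symbol`, `log2fc`, `t`, `p_value` and (unfilled)
#'   `q_value`, `significant`, `direction`.
#' @export
moderated_t <- function(stats, params) {
  stopifnot(inherits(stats, "group_stats"))
  d0 <- params$d0; s0 <- params$s0_sq
  dg <- stats$df_residual
  if (d0 == 0) {
    s_tilde <- stats$s2
    df_total <- dg
  } else if (is.infinite(d0)) {
    s_tilde <- rep(s0, length(stats$s2))
    df_total <- Inf
  } else {
    s_tilde <- (d0 * s0 + dg * stats$s2) / (d0 + dg)
    df_total <- d0 + dg
  }
  tval <- stats$log2fc / (stats$stderr_factor * sqrt(s_tilde))
  p <- if (is.infinite(df_total)) 2 * stats::pnorm(-abs(tval))
       else 2 * stats::pt(-abs(tval), df = df_total)
  structure(data.frame(analyte_id = stats$analyte_id,
                       gene_symbol = stats$gene_symbol,
                       log2fc = stats$log2fc,
                       t = tval, p_value = p,
                       q_value = NA_real_,
                       significant = NA,
                       direction = NA_character_,
                       stringsAsFactors = FALSE),
            class = c("differential_table", "data.frame"))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values (q-values): `q_(i) = min_{j>=i} p_(j) * m / j`,
#' capped at 1 and mapped back to input order (delegates to
#' [stats::p.adjust()]).
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return q-values in input order.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (anyNA(p) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Joint q-value / fold-change significance call
#'
#' Fills `q_value` (BH across all analytes) if absent, then calls an analyte
#' significant iff `q < q_threshold` (strict) and
#' `|log2fc| >= log2(fc_threshold)` (fold change taken two-sided on the
#' ratio scale), with `direction` from the sign of the log2 fold change.
#'
#' @param table a [moderated_t()] result.
#' @param q_threshold FDR threshold (default 0.1).
#' @param fc_threshold fold-change threshold on the ratio scale
#'   (default 1.25).
#' @return the completed `differential_table`.
#' @export
call_differential <- function(table, q_threshold = 0.1, fc_threshold = 1.25) {
  stopifnot(inherits(table, "differential_table"))
  if (all(is.na(table$q_value))) table$q_value <- bh_adjust(table$p_value)
  table$significant <- table$q_value < q_threshold &
    abs(table$log2fc) >= log2(fc_threshold)
  table$direction <- ifelse(!table$significant, "none",
                            ifelse(table$log2fc > 0, "up", "down"))
  attr(table, "q_threshold") <- q_threshold
  attr(table, "fc_threshold") <- fc_threshold
  table
}

#' One-call differential abundance analysis
#'
#' Convenience wrapper: group statistics, empirical-Bayes moderation,
#' moderated t, BH adjustment, and the joint significance call.
#'
#' @inheritParams fit_group_stats
#' @inheritParams call_differential
#' @param moderate logical; `FALSE` uses the ordinary pooled t-test.
#' @return a completed `differential_table` with the fitted
#'   `ebayes_params` attached as attribute `"ebayes"`.
#' @export
diff_abundance <- function(mat, annotation, q_threshold = 0.1,
                           fc_threshold = 1.25, moderate = TRUE) {
  gs <- fit_group_stats(mat, annotation)
  params <- if (moderate) estimate_ebayes(gs) else list(d0 = 0, s0_sq = NA_real_)
  tab <- call_differential(moderated_t(gs, params),
                           q_threshold = q_threshold,
                           fc_threshold = fc_threshold)
  attr(tab, "ebayes") <- params
  tab
}

#' @export
print.differential_table <- function(x, ...) {
  n <- nrow(x)
  if (!all(is.na(x$significant))) {
    ns <- sum(x$significant)
    cat(sprintf("differential_table: %d analytes, %d significant (%d up, %d down)\n",
                n, ns, sum(x$direction == "up"), sum(x$direction == "down")))
  } else {
    cat(sprintf("differential_table: %d analytes (significance not yet called)\n", n))
  }
  print.data.frame(utils::head(as.data.frame(x), 6L), digits = 4)
  if (n > 6L) cat("...\n")
  invisible(x)
}

#' @export
summary.differential_table <- function(object, ...) {
  list(n_analytes = nrow(object),
       n_significant = sum(object$significant, na.rm = TRUE),
       n_up = sum(object$direction == "up", na.rm = TRUE),
       n_down = sum(object$direction == "down", na.rm = TRUE))
}

#' Write / read a differential table
#' @param table a `differential_table`.
#' @param path file path.
#' @export
write_differential_table <- function(table, path) {
  df <- as.data.frame(table)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_differential_table
#' @export
read_differential_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                          na.strings = "NA")
  df$gene_symbol[is.na(df$gene_symbol)] <- ""
  structure(df, class = c("differential_table", "data.frame"))
}
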