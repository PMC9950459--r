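#' Build a ranked gene list from a differential table
#'
#' Genes are ranked by the signed moderated t-statistic, best (most
#' increased in labor) first. Analytes without a gene symbol are dropped;
#' multiple analytes mapping to one gene are collapsed to the analyte with
#' the largest |t|. Ties in the score are broken by gene symbol (stable,
#' reproducible ordering).
#'
#' @param table a `differential_table` with `t` filled.
#' @return list of class `ranked_list` with parallel vectors `gene_symbols`
#'   (unique, ordered best to worst) and `scores` (non-increasing).
#' @export
rank_proteins <- function(table) {
  stopifnot(inherits(table, "differential_table"))
  keep <- nzchar(table$gene_symbol) & !is.na(table$t)
  if (!any(keep)) stop("no analytes with gene annotation to rank")
  g <- table$gene_symbol[keep]
  t <- table$t[keep]
  # collapse to max |t| per gene; deterministic tie-break by analyte id order
  ord <- order(-abs(t))
  first <- !duplicated(g[ord])
  g <- g[ord][first]; t <- t[ord][first]
  o <- order(-t, g)
  structure(list(gene_symbols = g[o], scores = t[o]), class = "ranked_list")
}

#' Weighted running-sum enrichment score
#'
#' Walks the ranked list: member genes ("hits") increment the running sum by
#' `|score|^weight_p` normalized by the sum of those weights over members in
#' the list; non-members decrement by `1/(N - n_members)`. The enrichment
#' score (ES) is the signed maximum-magnitude deviation of the walk, and the
#' leading edge is the member genes at or before the extremum (at or after,
#' for negative ES).
#'
#' @param ranked a [rank_proteins()] result.
#' @param members character vector of gene symbols.
#' @param weight_p hit-weight exponent (1 = classic weighted statistic).
#' @return list with `es`, `leading_edge`, `n_hits`.
#' @export
enrichment_score <- function(ranked, members, weight_p = 1) {
  stopifnot(inherits(ranked, "ranked_list"))
  hit <- ranked$gene_symbols %in% members
  nh <- sum(hit)
  N <- length(ranked$gene_symbols)
  if (nh == 0L) stop("gene set has no members in the ranked list")
  if (nh == N) stop("gene set covers the entire ranked list")
  w <- abs(ranked$scores)^weight_p
  inc <- numeric(N)
  wh <- w[hit]
  if (sum(wh) == 0) wh <- rep(1, nh)  # all-zero scores: unweighted hits
  inc[hit] <- wh / sum(wh)
  inc[!hit] <- -1 / (N - nh)
  walk <- cumsum(inc)
  i_ext <- which.max(abs(walk))
  es <- walk[i_ext]
  le <- if (es >= 0) ranked$gene_symbols[seq_len(i_ext)][hit[seq_len(i_ext)]]
        else ranked$gene_symbols[i_ext:N][hit[i_ext:N]]
  list(es = es, leading_edge = le, n_hits = nh)
}

#' Gene-set permutation null for the enrichment score
#'
#' Samples member sets of the given size uniformly at random from the ranked
#' list and records their enrichment scores. When `exhaustive = TRUE` (only
#' sensible for tiny lists) all `choose(N, set_size)` sets are enumerated,
#' making downstream permutation p-values exact.
#'
#' @param ranked a [rank_proteins()] result.
#' @param set_size number of member genes (< N).
#' @param n_perm number of permutations (a warning below 100).
#' @param seed RNG seed; same seed gives an identical null sample.
#' @param weight_p hit-weight exponent, as in [enrichment_score()].
#' @param exhaustive enumerate all subsets instead of sampling.
#' @return numeric vector of null enrichment scores.
#' @export
permutation_null <- function(ranked, set_size, n_perm = 1000L, seed = 1L,
                             weight_p = 1, exhaustive = FALSE) {
  stopifnot(inherits(ranked, "ranked_list"))
  N <- length(ranked$gene_symbols)
  if (set_size >= N) stop("set_size must be smaller than the ranked list")
  if (exhaustive) {
    combos <- utils::combn(N, set_size)
    return(apply(combos, 2L, function(ix)
      enrichment_score(ranked, ranked$gene_symbols[ix], weight_p)$es))
  }
  if (n_perm < 100L) warning("fewer than 100 permutations: p-values are coarse")
  set.seed(seed %% 2147483647)
  vapply(seq_len(n_perm), function(i) {
    ix <- sample.int(N, set_size)
    enrichment_score(ranked, ranked$gene_symbols[ix], weight_p)$es
  }, numeric(1))
}

# sign-stratified permutation p for one observed es against its null sample
perm_pvalue <- function(es, null_es) {
  if (es >= 0) {
    denom <- sum(null_es >= 0)
    if (denom == 0L) return(1 / (length(null_es) + 1))
    sum(null_es >= es) / denom
  } else {
    denom <- sum(null_es < 0)
    if (denom == 0L) return(1 / (length(null_es) + 1))
    sum(null_es <= es) / denom
  }
}

# normalize es by the mean |null es| of matching sign
normalize_es <- function(es, null_es) {
  pos <- null_es[null_es >= 0]; neg <- null_es[null_es < 0]
  if (es >= 0) {
    if (!length(pos)) return(NA_real_)
    es / mean(pos)
  } else {
    if (!length(neg)) return(NA_real_)
    -es / mean(neg)  # neg mean is negative: result keeps the sign of es
  }
}

#' Preranked gene-set enrichment analysis
#'
#' For each gene set with at least `min_size` members measured in the ranked
#' list: weighted running-sum ES, gene-set permutation p-value, NES
#' (ES normalized by the mean |null ES| of matching sign), and an FDR q by
#' the sign-stratified pooled-null procedure (ratio of the pooled-null to
#' the observed NES exceedance fractions, capped at 1 and monotonized from
#' the most extreme NES inward).
#'
#' @param ranked a [rank_proteins()] result.
#' @param sets named list of gene sets (see [read_gmt()]).
#' @param min_size minimum measured members for a set to be tested
#'   (default 5).
#' @param n_perm permutations per set size (default 1000).
#' @param q_threshold significance threshold reported in the summary
#'   (default 0.25).
#' @param seed RNG seed.
#' @param weight_p hit-weight exponent.
#' @return `data.frame` of class `enrichment_result`, one row per tested
#'   set: `set_name`, `size_used`, `es`, `nes`, `p_perm`, `q_value`,
#'   `significant`, `leading_edge` (semicolon-joined).
#' @export
run_gsea <- function(ranked, sets, min_size = 5L, n_perm = 1000L,
                     q_threshold = 0.25, seed = 1L, weight_p = 1) {
  stopifnot(inherits(ranked, "ranked_list"))
  if (!length(sets)) stop("no gene sets supplied")
  present <- lapply(sets, function(s) intersect(s$members, ranked$gene_symbols))
  sizes <- lengths(present)
  keep <- sizes >= min_size & sizes < length(ranked$gene_symbols)
  if (!any(keep)) stop("no gene set passes the minimum-size filter")
  sets <- sets[keep]; present <- present[keep]; sizes <- sizes[keep]

  # one shared null per distinct measured size; seed derived from size so the
  # result is invariant to the order in which sets are supplied
  nulls <- lapply(sort(unique(sizes)), function(sz)
    permutation_null(ranked, sz, n_perm = n_perm,
                     seed = sub_seed(seed, paste0("gsea_size_", sz)),
                     weight_p = weight_p))
  names(nulls) <- as.character(sort(unique(sizes)))

  es <- numeric(length(sets)); nes <- numeric(length(sets))
  pp <- numeric(length(sets)); le <- character(length(sets))
  null_nes <- vector("list", length(sets))
  for (i in seq_along(sets)) {
    r <- enrichment_score(ranked, present[[i]], weight_p)
    nl <- nulls[[as.character(sizes[i])]]
    es[i] <- r$es
    pp[i] <- perm_pvalue(r$es, nl)
    nes[i] <- normalize_es(r$es, nl)
    le[i] <- paste(r$leading_edge, collapse = ";")
    null_nes[[i]] <- vapply(nl, normalize_es, numeric(1), null_es = nl)
  }
  q <- gsea_fdr(nes, unlist(null_nes))
  out <- data.frame(set_name = vapply(sets, `[[`, "", "name"),
                    size_used = as.integer(sizes),
                    es = es, nes = nes, p_perm = pp, q_value = q,
                    significant = q < q_threshold,
                    leading_edge = le,
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[order(-abs(out$nes), out$set_name), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("enrichment_result", "data.frame"),
            q_threshold = q_threshold)
}

# Sign-stratified GSEA FDR: for each observed NES*, q = (fraction of pooled
# null NES of the same sign at least as extreme) / (fraction of observed NES
# of the same sign at least as extreme), capped at 1, then monotonized so q
# is non-decreasing from the most extreme NES inward.
gsea_fdr <- function(obs_nes, pooled_null_nes) {
  q <- vapply(obs_nes, function(v) {
    if (is.na(v)) return(NA_real_)
    if (v >= 0) {
      null_pos <- pooled_null_nes[pooled_null_nes >= 0]
      obs_pos <- obs_nes[obs_nes >= 0]
      num <- if (length(null_pos)) mean(null_pos >= v) else 0
      den <- mean(obs_pos >= v)
    } else {
      null_neg <- pooled_null_nes[pooled_null_nes < 0]
      obs_neg <- obs_nes[obs_nes < 0]
      num <- if (length(null_neg)) mean(null_neg <= v) else 0
      den <- mean(obs_neg <= v)
    }
    min(1, num / den)
  }, numeric(1))
  # monotonize within each sign: a less extreme NES cannot have smaller q
  for (positive in c(TRUE, FALSE)) {
    ix <- which(!is.na(obs_nes) & if (positive) obs_nes >= 0 else obs_nes < 0)
    ix <- ix[order(-abs(obs_nes[ix]))]
    if (length(ix) > 1L) q[ix] <- cummax(q[ix])
  }
  q
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("enrichment_result: %d gene sets tested, %d significant (q < %.2g)\n",
              nrow(x), sum(x$significant, na.rm = TRUE), attr(x, "q_threshold")))
  print.data.frame(utils::head(as.data.frame(x)[, c("set_name", "size_used",
                                                    "es", "nes", "p_perm",
                                                    "q_value")], 8L), digits = 3)
  invisible(x)
}

#' Write an enrichment result table
#' @param result an `enrichment_result`.
#' @param path file path.
#' @export
write_enrichment_result <- function(result, path) {
  utils::write.table(as.data.frame(result), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
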