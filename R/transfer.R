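#' Define the amniotic fluid labor signature
#'
#' Among analytes called significant with direction "up" (increased in
#' labor), takes the `top_n` with the largest log2 fold change; exact
#' fold-change ties are broken by smaller q-value, then analyte id.
#' Only the increased-in-labor direction is pursued: the decreased proteins
#' do not transfer into plasma as a discriminating aggregate.
#'
#' @param table a completed `differential_table`.
#' @param top_n signature length cap (default 20).
#' @return list of class `labor_signature` with `analyte_id`,
#'   `gene_symbol`, `log2fc` (the selection metric, descending) and an
#'   empty `mapped_plasma_ids` slot filled by [map_signature_to_panel()].
#' @export
define_labor_signature <- function(table, top_n = 20L) {
  stopifnot(inherits(table, "differential_table"))
  if (all(is.na(table$significant))) stop("significance calls missing: run call_differential first")
  up <- table[table$significant & table$direction == "up", , drop = FALSE]
  if (nrow(up) == 0L) stop("no significantly increased analytes to build a signature from")
  ord <- order(-up$log2fc, up$q_value, up$analyte_id)
  up <- up[utils::head(ord, top_n), , drop = FALSE]
  structure(list(analyte_id = up$analyte_id,
                 gene_symbol = up$gene_symbol,
                 log2fc = up$log2fc,
                 q_value = up$q_value,
                 mapped_plasma_ids = character(0),
                 mapped_gene_symbols = character(0)),
            class = "labor_signature")
}

#' Map a labor signature onto a plasma panel
#'
#' Matches signature members to plasma analytes by gene symbol, preserving
#' signature order. A gene measured by several plasma analytes contributes
#' the analyte with the highest mean abundance.
#'
#' @param signature a [define_labor_signature()] result.
#' @param plasma plasma [proteome_matrix()].
#' @return the signature with `mapped_plasma_ids` /
#'   `mapped_gene_symbols` filled.
#' @export
map_signature_to_panel <- function(signature, plasma) {
  stopifnot(inherits(signature, "labor_signature"))
  validate_proteome_matrix(plasma)
  fake_set <- list(members = signature$gene_symbol)
  ids <- select_signature_analytes(fake_set, plasma,
                                   max_genes = length(signature$gene_symbol))
  if (!length(ids)) stop("no signature gene is measured on the plasma panel")
  signature$mapped_plasma_ids <- ids
  signature$mapped_gene_symbols <-
    plasma$gene_symbols[match(ids, rownames(plasma$values))]
  signature
}

#' @export
print.labor_signature <- function(x, ...) {
  cat(sprintf("labor_signature: %d proteins (most increased in labor first)\n",
              length(x$analyte_id)))
  cat("  ", paste(utils::head(x$gene_symbol, 10L), collapse = ", "),
      if (length(x$gene_symbol) > 10L) "..." else "", "\n")
  if (length(x$mapped_plasma_ids))
    cat(sprintf("  %d mapped to the plasma panel\n", length(x$mapped_plasma_ids)))
  invisible(x)
}

#' Aggregated plasma signature score
#'
#' Z-scores each mapped analyte against the plasma TNL reference and
#' averages per sample (delegating to [zscore_by_reference()] and
#' [aggregate_signature()]): the AF-derived labor signature evaluated in
#' maternal plasma. The AF cohort informs only the feature list — no AF
#' sample data enters this computation.
#'
#' @param plasma raw- or log2-scale plasma [proteome_matrix()].
#' @param signature a mapped [map_signature_to_panel()] result.
#' @param annotation plasma sample annotation.
#' @return named per-sample score vector.
#' @export
score_plasma_signature <- function(plasma, signature, annotation) {
  stopifnot(inherits(signature, "labor_signature"))
  if (!length(signature$mapped_plasma_ids))
    stop("signature not mapped to the plasma panel")
  if (plasma$scale == "raw") plasma <- log2_transform(plasma)
  z <- zscore_by_reference(plasma, annotation, reference_group = "TNL")
  ids <- intersect(signature$mapped_plasma_ids, rownames(z$values))
  if (!length(ids)) stop("no mapped analyte survived Z-scoring")
  aggregate_signature(z, ids)
}

#' ROC AUC with DeLong confidence interval
#'
#' AUC as the tie-corrected Mann-Whitney statistic `U/(n1*n0)` (ties count
#' one half), with a 95% CI from the DeLong placement-variance estimate,
#' truncated to \[0, 1\]. Degenerate perfect separation gives a zero-width
#' variance; the CI then collapses onto the AUC.
#'
#' @param scores numeric per-sample scores (higher = more labor-like).
#' @param annotation sample annotation aligned by names of `scores`.
#' @param positive positive class label (default `"TIL"`).
#' @param conf_level confidence level (default 0.95).
#' @return list with `auc`, `ci_low`, `ci_high`, `n_positive`,
#'   `n_negative`.
#' @export
roc_auc <- function(scores, annotation, positive = "TIL", conf_level = 0.95) {
  grp <- annotation$group[match(names(scores), annotation$sample_id)]
  if (anyNA(grp)) stop("scores with unknown sample ids")
  pos <- scores[grp == positive]
  neg <- scores[grp != positive]
  n1 <- length(pos); n0 <- length(neg)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  # placements: psi(x, y) = 1[x > y] + 0.5 * 1[x == y]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  auc <- mean(cmp)
  v10 <- rowMeans(cmp)   # per-positive placement
  v01 <- colMeans(cmp)   # per-negative placement
  var_auc <- if (n1 > 1L && n0 > 1L)
    stats::var(v10) / n1 + stats::var(v01) / n0 else 0
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  half <- zq * sqrt(max(var_auc, 0))
  list(auc = auc,
       ci_low = max(0, auc - half), ci_high = min(1, auc + half),
       n_positive = n1, n_negative = n0)
}

# per-fold RNG seed derived from the global seed and the held-out sample id,
# so out-of-fold predictions are invariant to sample order
fold_seed <- function(seed, sample_id) {
  sub_seed(seed, paste0("fold_", sample_id))
}

#' Leave-one-out cross-validated random forest with in-fold selection
#'
#' The plasma classification protocol: for each sample in turn, a
#' probability random forest is fit on all remaining samples over the full
#' candidate pool (AF-significant-up analytes present on the plasma panel),
#' features are ranked by impurity importance, the top `n_select` are used
#' to refit a final forest, and the held-out sample's predicted probability
#' of the positive class is recorded. Feature selection happens inside
#' every fold, so the held-out sample never influences which features its
#' model uses. AUC over the out-of-fold scores is reported with both the
#' DeLong CI and a stratified-bootstrap CI (out-of-fold scores violate
#' DeLong's independence assumption mildly).
#'
#' @param plasma raw- or log2-scale plasma [proteome_matrix()].
#' @param candidate_analytes character vector of candidate analyte ids
#'   (>= `n_select` recommended; fewer triggers a warning and all are
#'   used).
#' @param annotation plasma sample annotation (>= 3 samples per class).
#' @param n_select features in the final per-fold model (default 10).
#' @param n_trees trees per forest (default 500).
#' @param seed global seed; per-fold seeds are derived from it and the
#'   held-out sample id.
#' @param n_boot stratified bootstrap resamples for the second CI
#'   (default 2000).
#' @param importance `"impurity"` (default) or `"permutation"`.
#' @return list of class `classifier_evaluation`: `oof_scores` (named,
#'   out-of-fold), `auc`, `ci_low`, `ci_high` (DeLong),
#'   `ci_boot_low`, `ci_boot_high`, `feature_rank` (data.frame: analyte,
#'   mean per-fold importance rank, selection frequency), `n_folds`,
#'   `fold_log` (held-out id, training size, selected features per fold).
#' @export
loocv_random_forest <- function(plasma, candidate_analytes, annotation,
                                n_select = 10L, n_trees = 500L, seed = 1L,
                                n_boot = 2000L,
                                importance = c("impurity", "permutation")) {
  importance <- match.arg(importance)
  if (plasma$scale == "raw") plasma <- log2_transform(plasma)
  missing <- setdiff(candidate_analytes, rownames(plasma$values))
  if (length(missing))
    stop("candidate analytes not on the plasma panel: ",
         paste(utils::head(missing, 5L), collapse = ", "))
  if (length(candidate_analytes) < n_select) {
    warning("fewer candidates than n_select: using all ",
            length(candidate_analytes))
    n_select <- length(candidate_analytes)
  }
  ann <- match_annotation(plasma, annotation)
  if (any(table(ann$group) < 3L)) stop("each class needs at least 3 samples")
  X <- t(plasma$values[candidate_analytes, , drop = FALSE])
  colnames(X) <- make.names(candidate_analytes)  # ranger-safe names
  y <- factor(ann$group, levels = c("TNL", "TIL"))
  sids <- colnames(plasma$values)
  n <- length(sids)
  oof <- stats::setNames(numeric(n), sids)
  rank_mat <- matrix(NA_real_, n, length(candidate_analytes),
                     dimnames = list(sids, candidate_analytes))
  fold_log <- vector("list", n)
  for (i in seq_len(n)) {
    tr <- setdiff(seq_len(n), i)
    tr <- tr[order(sids[tr])]  # canonical row order: invariance to input order
    fs <- fold_seed(seed, sids[i])
    d_tr <- data.frame(.y = y[tr], X[tr, , drop = FALSE], check.names = FALSE)
    rf0 <- ranger::ranger(dependent.variable.name = ".y", data = d_tr,
                          num.trees = n_trees, importance = importance,
                          probability = TRUE, num.threads = 1L, seed = fs)
    imp <- rf0$variable.importance[colnames(X)]
    rk <- rank(-imp, ties.method = "first")
    rank_mat[i, ] <- rk
    top <- colnames(X)[order(rk)][seq_len(n_select)]
    d_sel <- data.frame(.y = y[tr], X[tr, top, drop = FALSE], check.names = FALSE)
    rf1 <- ranger::ranger(dependent.variable.name = ".y", data = d_sel,
                          num.trees = n_trees, importance = "none",
                          probability = TRUE, num.threads = 1L, seed = fs + 1)
    pred <- stats::predict(rf1, data.frame(X[i, top, drop = FALSE],
                                           check.names = FALSE))$predictions
    oof[i] <- pred[1, "TIL"]
    fold_log[[i]] <- list(held_out = sids[i], n_train = length(tr),
                          selected = candidate_analytes[match(top, colnames(X))])
  }
  roc <- roc_auc(oof, annotation)
  boot <- boot_auc_ci(oof, ann$group, n_boot = n_boot,
                      seed = sub_seed(seed, "boot_ci"))
  mean_rank <- colMeans(rank_mat)
  sel_freq <- vapply(candidate_analytes, function(a)
    mean(vapply(fold_log, function(f) a %in% f$selected, logical(1))),
    numeric(1))
  fr <- data.frame(analyte_id = candidate_analytes,
                   mean_rank = mean_rank,
                   selection_frequency = sel_freq,
                   stringsAsFactors = FALSE, row.names = NULL)
  fr <- fr[order(fr$mean_rank), , drop = FALSE]
  rownames(fr) <- NULL
  structure(list(oof_scores = oof, auc = roc$auc,
                 ci_low = roc$ci_low, ci_high = roc$ci_high,
                 ci_boot_low = boot[1], ci_boot_high = boot[2],
                 feature_rank = fr, n_folds = n, fold_log = fold_log),
            class = "classifier_evaluation")
}

# stratified bootstrap percentile CI for the AUC of a score vector
boot_auc_ci <- function(scores, groups, n_boot = 2000L, seed = 1L,
                        conf_level = 0.95) {
  set.seed(seed %% 2147483647)
  pos <- which(groups == "TIL"); neg <- which(groups == "TNL")
  aucs <- vapply(seq_len(n_boot), function(b) {
    ip <- sample(pos, replace = TRUE); ineg <- sample(neg, replace = TRUE)
    mean(outer(scores[ip], scores[ineg],
               function(a, bb) (a > bb) + 0.5 * (a == bb)))
  }, numeric(1))
  alpha <- (1 - conf_level) / 2
  unname(stats::quantile(aucs, c(alpha, 1 - alpha), type = 7))
}

#' @export
print.classifier_evaluation <- function(x, ...) {
  cat(sprintf("LOOCV random forest: %d folds\n", x$n_folds))
  cat(sprintf("  out-of-fold AUC = %.3f (DeLong 95%% CI %.3f-%.3f; bootstrap %.3f-%.3f)\n",
              x$auc, x$ci_low, x$ci_high, x$ci_boot_low, x$ci_boot_high))
  cat("  top features by mean in-fold importance rank:\n")
  print.data.frame(utils::head(x$feature_rank, 10L), digits = 3)
  invisible(x)
}
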