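# Shared fixtures and independent oracles, built in code at test time.

# small proteome matrix with explicit values
make_pm <- function(values, genes = NULL, scale = "raw",
                    analytes = NULL, samples = NULL) {
  if (is.null(analytes)) analytes <- sprintf("A%02d", seq_len(nrow(values)))
  if (is.null(samples)) samples <- sprintf("S%02d", seq_len(ncol(values)))
  dimnames(values) <- list(analytes, samples)
  proteome_matrix(values, gene_symbols = genes, scale = scale)
}

# annotation for a TNL-then-TIL sample layout
make_ann <- function(n_tnl, n_til, ids = NULL) {
  if (is.null(ids)) ids <- sprintf("S%02d", seq_len(n_tnl + n_til))
  sample_annotation(ids, rep(c("TNL", "TIL"), c(n_tnl, n_til)))
}

# Brute-force BH step-up: q_(i) = min_{j >= i} p_(j) * m / j, capped at 1.
# Independent of stats::p.adjust.
bh_bruteforce <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[i] <- min(1, min(ps[i:m] * m / (i:m)))
  }
  out <- numeric(m)
  out[o] <- q
  out
}

# Brute-force AUC: mean over all (positive, negative) pairs of
# 1[pos > neg] + 0.5 * 1[pos == neg].
auc_bruteforce <- function(pos, neg) {
  total <- 0
  for (a in pos) for (b in neg) {
    total <- total + (a > b) + 0.5 * (a == b)
  }
  total / (length(pos) * length(neg))
}

# Direct evaluation of the weighted running sum for one gene set; written
# as an explicit loop, independent of enrichment_score's vectorized path.
es_bruteforce <- function(genes, scores, members, p = 1) {
  N <- length(genes)
  hits <- genes %in% members
  wsum <- sum(abs(scores[hits])^p)
  run <- 0; best <- 0
  for (i in seq_len(N)) {
    run <- run + if (hits[i]) abs(scores[i])^p / wsum else -1 / (N - sum(hits))
    if (abs(run) > abs(best)) best <- run
  }
  best
}

# ranked list built directly (bypassing rank_proteins)
make_ranked <- function(genes, scores) {
  structure(list(gene_symbols = genes, scores = scores),
            class = "ranked_list")
}
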