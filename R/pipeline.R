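#' Default pipeline run configuration
#'
#' Thresholds mirror the analysis protocol: differential calls at q < 0.1
#' and fold change >= 1.25; GSEA on sets with >= 5 measured genes at
#' q < 0.25; signatures on >= 5 measured genes at q < 0.1 with up to 20
#' genes used; a top-20 labor signature; 10 features selected per LOOCV
#' fold.
#'
#' @param out_dir output directory.
#' @param seed global seed (drives simulation and all permutation /
#'   resampling steps).
#' @param stages character vector of stages to run, a subset of
#'   `c("simulate", "qc", "differential", "gsea", "signatures",
#'   "transfer")`.
#' @param ... overrides for any config entry (thresholds, [sim_config()]
#'   fields under `sim`, `n_perm`, `n_trees`, ...).
#' @return a named list (class `run_config`).
#' @export
default_run_config <- function(out_dir = tempfile("laborproteome_run_"),
                               seed = 1L,
                               stages = c("simulate", "qc", "differential",
                                          "gsea", "signatures", "transfer"),
                               ...) {
  cfg <- list(out_dir = out_dir, seed = as.integer(seed), stages = stages,
              q_diff = 0.1, fc = 1.25, gsea_q = 0.25, sig_q = 0.1,
              min_set = 5L, max_sig_genes = 20L, top_n = 20L,
              n_select = 10L, n_perm = 1000L, n_trees = 500L,
              sim = list())
  dots <- list(...)
  for (nm in names(dots)) cfg[[nm]] <- dots[[nm]]
  stopifnot(cfg$q_diff > 0, cfg$q_diff <= 1, cfg$gsea_q > 0, cfg$gsea_q <= 1,
            cfg$sig_q > 0, cfg$sig_q <= 1, cfg$fc >= 1)
  unknown <- setdiff(cfg$stages, c("simulate", "qc", "differential", "gsea",
                                   "signatures", "transfer"))
  if (length(unknown)) stop("unknown stage(s): ", paste(unknown, collapse = ", "))
  class(cfg) <- "run_config"
  cfg
}

#' Read a run configuration from YAML
#' @param path YAML file with any subset of the [default_run_config()]
#'   fields.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(default_run_config, y)
}

#' Run the pipeline end to end
#'
#' Executes the enabled stages in order
#' simulate -> qc -> differential -> gsea -> signatures -> transfer,
#' writing each stage's artifacts under `config$out_dir` and a JSON run
#' manifest recording the config hash, seed, per-stage elapsed time and
#' output checksums. A failing stage aborts with a stage-named error;
#' outputs written so far are renamed with a `.partial` suffix. Two runs
#' with the same config and seed produce identical manifests (equal
#' checksums).
#'
#' @param config a `run_config` (see [default_run_config()]), or a path to
#'   a YAML file.
#' @return the manifest (list), invisibly; also written to
#'   `manifest.json`.
#' @export
run_pipeline <- function(config = default_run_config()) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(config_hash = config_hash(config), seed = config$seed,
                   r_version = paste(R.version$major, R.version$minor, sep = "."),
                   stages = list())
  scfg <- do.call(sim_config, c(config$sim, list(seed = config$seed)))
  state <- new.env(parent = emptyenv())

  run_stage <- function(name, fun) {
    if (!(name %in% config$stages)) {
      manifest$stages[[name]] <<- list(status = "skipped")
      return(invisible(NULL))
    }
    t0 <- proc.time()[["elapsed"]]
    outputs <- tryCatch(fun(), error = function(e) {
      mark_partial(config$out_dir)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
    manifest$stages[[name]] <<- list(
      status = "ok",
      elapsed_sec = round(proc.time()[["elapsed"]] - t0, 3),
      outputs = file_checksums(outputs))
    message(sprintf("[%s] ok (%.1fs): %s", name,
                    manifest$stages[[name]]$elapsed_sec,
                    paste(basename(outputs), collapse = ", ")))
  }

  run_stage("simulate", function() {
    af <- simulate_af_cohort(scfg)
    pl <- simulate_plasma_cohort(scfg, af$truth)
    sig <- simulate_signature_genesets(scfg, af$truth)
    state$af <- af; state$plasma <- pl; state$signatures <- sig
    p <- file.path(config$out_dir,
                   c("af_abundance.tsv", "af_annotation.tsv", "af_truth.tsv",
                     "plasma_abundance.tsv", "plasma_annotation.tsv",
                     "plasma_truth.tsv", "celltype_signatures.gmt"))
    write_abundance_table(af$matrix, p[1])
    write_annotation_table(af$annotation, p[2])
    utils::write.table(af$truth, p[3], sep = "\t", quote = FALSE, row.names = FALSE)
    write_abundance_table(pl$matrix, p[4])
    write_annotation_table(pl$annotation, p[5])
    utils::write.table(pl$truth, p[6], sep = "\t", quote = FALSE, row.names = FALSE)
    write_gmt(sig$sets, p[7])
    p
  })

  need_af <- function() {
    if (is.null(state$af)) stop("simulate stage disabled and no AF inputs in state")
    state$af
  }

  run_stage("qc", function() {
    af <- need_af()
    norm <- median_normalize(af$matrix)
    lg <- log2_transform(norm)
    state$af_log2 <- lg
    pca <- pca_metaproteome(lg)
    pairs <- simulate_crossplatform_pairs(19L, 0.76,
                                          seed = sub_seed(config$seed, "qc_pairs"))
    conc <- crossplatform_concordance(log2(pairs$platform_a),
                                      log2(pairs$platform_b))
    p <- file.path(config$out_dir, c("pca_scores.tsv", "pca_variance.json",
                                     "concordance.json"))
    utils::write.table(data.frame(sample_id = rownames(pca$scores),
                                  pca$scores[, 1:min(5, pca$n_components)]),
                       p[1], sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(list(
      variance_fraction = pca$variance_fraction,
      pc1_group_p = associate_pc_with_group(pca, af$annotation, 1L),
      pc2_group_p = associate_pc_with_group(pca, af$annotation, 2L),
      pc1_ga = correlate_pc_with_covariate(
        pca, af$annotation$ga_weeks[match(rownames(pca$scores),
                                          af$annotation$sample_id)], 1L)),
      p[2], auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(conc, p[3], auto_unbox = TRUE, digits = NA)
    p
  })

  run_stage("differential", function() {
    af <- need_af()
    if (is.null(state$af_log2))
      state$af_log2 <- log2_transform(median_normalize(af$matrix))
    tab <- diff_abundance(state$af_log2, af$annotation,
                          q_threshold = config$q_diff,
                          fc_threshold = config$fc)
    state$diff <- tab
    p <- file.path(config$out_dir, c("differential_table.tsv",
                                     "differential_summary.json"))
    write_differential_table(tab, p[1])
    jsonlite::write_json(summary(tab), p[2], auto_unbox = TRUE, digits = NA)
    p
  })

  run_stage("gsea", function() {
    if (is.null(state$diff)) stop("differential stage output required")
    ranked <- rank_proteins(state$diff)
    sets <- state$signatures$sets
    if (is.null(sets)) stop("no gene sets available (simulate stage disabled)")
    res <- run_gsea(ranked, sets, min_size = config$min_set,
                    n_perm = config$n_perm, q_threshold = config$gsea_q,
                    seed = sub_seed(config$seed, "gsea"))
    state$gsea <- res
    p <- file.path(config$out_dir, "enrichment_result.tsv")
    write_enrichment_result(res, p)
    p
  })

  run_stage("signatures", function() {
    af <- need_af()
    if (is.null(state$af_log2))
      state$af_log2 <- log2_transform(median_normalize(af$matrix))
    if (is.null(state$signatures)) stop("no signature sets available")
    sc <- compare_signatures(state$af_log2, af$annotation,
                             state$signatures$sets,
                             min_genes = config$min_set,
                             max_genes = config$max_sig_genes,
                             q_threshold = config$sig_q)
    state$sig_scores <- sc
    p <- file.path(config$out_dir, c("signature_table.tsv",
                                     "signature_scores.tsv"))
    utils::write.table(sc$table, p[1], sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(data.frame(sample_id = rownames(sc$scores), sc$scores),
                       p[2], sep = "\t", quote = FALSE, row.names = FALSE)
    p
  })

  run_stage("transfer", function() {
    if (is.null(state$diff)) stop("differential stage output required")
    if (is.null(state$plasma)) stop("plasma cohort required")
    pl <- state$plasma
    sig <- define_labor_signature(state$diff, top_n = config$top_n)
    sig <- map_signature_to_panel(sig, pl$matrix)
    scores <- score_plasma_signature(pl$matrix, sig, pl$annotation)
    roc <- roc_auc(scores, pl$annotation)
    cand <- candidate_plasma_analytes(state$diff, pl$matrix)
    ev <- loocv_random_forest(pl$matrix, cand, pl$annotation,
                              n_select = config$n_select,
                              n_trees = config$n_trees,
                              seed = sub_seed(config$seed, "loocv"))
    state$transfer <- list(signature = sig, scores = scores, roc = roc,
                           evaluation = ev)
    p <- file.path(config$out_dir, c("labor_signature.json",
                                     "plasma_scores.tsv",
                                     "transfer_evaluation.json"))
    jsonlite::write_json(list(analyte_id = sig$analyte_id,
                              gene_symbol = sig$gene_symbol,
                              log2fc = sig$log2fc,
                              mapped_plasma_ids = sig$mapped_plasma_ids),
                         p[1], digits = NA)
    utils::write.table(data.frame(sample_id = names(scores), score = scores,
                                  oof_rf_score = ev$oof_scores[names(scores)]),
                       p[2], sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(list(aggregated_auc = roc$auc,
                              aggregated_ci = c(roc$ci_low, roc$ci_high),
                              loocv_auc = ev$auc,
                              loocv_ci_delong = c(ev$ci_low, ev$ci_high),
                              loocv_ci_boot = c(ev$ci_boot_low, ev$ci_boot_high),
                              n_candidates = length(cand),
                              feature_rank = ev$feature_rank),
                         p[3], auto_unbox = TRUE, digits = NA)
    p
  })

  manifest_path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(manifest, list(path = manifest_path, state = state)))
}

#' Candidate pool for the plasma classifier
#'
#' All analytes significant-up in the AF differential table whose gene is
#' measured on the plasma panel (one plasma analyte per gene, highest mean
#' abundance on ties).
#'
#' @param table AF `differential_table`.
#' @param plasma plasma [proteome_matrix()].
#' @return character vector of plasma analyte ids.
#' @export
candidate_plasma_analytes <- function(table, plasma) {
  up <- table[!is.na(table$significant) & table$significant &
                table$direction == "up", , drop = FALSE]
  genes <- unique(up$gene_symbol[nzchar(up$gene_symbol)])
  if (!length(genes)) stop("no significant-up annotated analytes")
  select_signature_analytes(list(members = genes), plasma,
                            max_genes = length(genes))
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  clean <- unclass(config)
  clean$out_dir <- NULL  # location must not change the scientific identity
  yaml::write_yaml(clean, tmp)
  unname(tools::md5sum(tmp))
}

file_checksums <- function(paths) {
  as.list(stats::setNames(unname(tools::md5sum(paths)), basename(paths)))
}

mark_partial <- function(out_dir) {
  fs <- list.files(out_dir, full.names = TRUE)
  fs <- fs[!grepl("\\.partial$", fs)]
  for (f in fs) file.rename(f, paste0(f, ".partial"))
}

#' Summarize a pipeline run from its manifest
#'
#' Reads the manifest and the stage outputs next to it and reports the
#' significant-protein counts (total/up/down), significant signatures, and
#' the plasma AUCs. Missing outputs are listed, not fatal. The JSON-ready
#' list and the printed text report are numerically identical.
#'
#' @param manifest_path path to `manifest.json`.
#' @return list of class `run_summary` with `counts`, `missing`,
#'   `stages`.
#' @export
summarize_run <- function(manifest_path) {
  if (!file.exists(manifest_path)) stop("manifest not found: ", manifest_path)
  man <- jsonlite::read_json(manifest_path)
  out_dir <- dirname(manifest_path)
  counts <- list(); missing <- character(0)
  grab <- function(file, fn) {
    p <- file.path(out_dir, file)
    if (!file.exists(p)) { missing <<- c(missing, file); return(NULL) }
    fn(p)
  }
  ds <- grab("differential_summary.json", jsonlite::read_json)
  if (!is.null(ds)) counts[c("n_analytes", "n_significant", "n_up", "n_down")] <-
    ds[c("n_analytes", "n_significant", "n_up", "n_down")]
  st <- grab("signature_table.tsv", function(p) utils::read.delim(p))
  if (!is.null(st)) {
    counts$n_signatures_tested <- nrow(st)
    counts$n_signatures_significant <- sum(st$significant)
  }
  ev <- grab("transfer_evaluation.json", jsonlite::read_json)
  if (!is.null(ev)) {
    counts$aggregated_auc <- ev$aggregated_auc
    counts$loocv_auc <- ev$loocv_auc
  }
  stages <- vapply(man$stages, function(s) s$status, character(1))
  structure(list(counts = counts, missing = missing, stages = stages),
            class = "run_summary")
}

#' @export
print.run_summary <- function(x, ...) {
  cat("pipeline run summary\n")
  for (nm in names(x$stages)) cat(sprintf("  stage %-12s %s\n", nm, x$stages[[nm]]))
  for (nm in names(x$counts)) {
    v <- x$counts[[nm]]
    cat(sprintf("  %-26s %s\n", nm,
                if (is.numeric(v) && v %% 1 != 0) sprintf("%.4f", v) else v))
  }
  if (length(x$missing))
    cat("  missing outputs:", paste(x$missing, collapse = ", "), "\n")
  invisible(x)
}

#' Reproduce the published amniotic fluid analysis on real tables
#'
#' Runs the full AF differential call (q < 0.1, fold change >= 1.25) and
#' the PCA meta-proteome on a user-supplied abundance + annotation table
#' (the published supplementary proteomics tables, once downloaded, are in
#' exactly this layout), and optionally the plasma transfer evaluation.
#' Reports the significant counts, the PC1/PC2 variance fractions and the
#' three largest positive log2 fold changes — the headline quantities of
#' the published analysis.
#'
#' @param af_abundance_path,af_annotation_path AF cohort TSVs (see
#'   [read_abundance_table()] / [read_annotation_table()]).
#' @param plasma_abundance_path,plasma_annotation_path optional plasma
#'   cohort TSVs; when given, the aggregated-Z AUC and LOOCV AUC are also
#'   computed.
#' @param normalize apply [median_normalize()] before log2 (set `FALSE`
#'   for tables already standardized by the vendor pipeline).
#' @param seed seed for the LOOCV forest.
#' @return list with `n_significant`, `n_up`, `n_down`,
#'   `variance_fraction_pc1/2`, `top3_up_genes`, `differential` (full
#'   table) and, if plasma data were given, `aggregated_auc`,
#'   `loocv_auc`.
#' @export
reproduce_af_analysis <- function(af_abundance_path, af_annotation_path,
                                  plasma_abundance_path = NULL,
                                  plasma_annotation_path = NULL,
                                  normalize = TRUE, seed = 1L) {
  mat <- read_abundance_table(af_abundance_path)
  ann <- read_annotation_table(af_annotation_path)
  if (normalize && mat$scale == "raw") mat <- median_normalize(mat)
  if (mat$scale == "raw") mat <- log2_transform(mat)
  tab <- diff_abundance(mat, ann)
  pca <- pca_metaproteome(mat)
  s <- summary(tab)
  top3 <- tab$gene_symbol[order(-tab$log2fc)][1:3]
  out <- list(n_significant = s$n_significant, n_up = s$n_up,
              n_down = s$n_down,
              variance_fraction_pc1 = pca$variance_fraction[1],
              variance_fraction_pc2 = pca$variance_fraction[2],
              top3_up_genes = top3, differential = tab)
  if (!is.null(plasma_abundance_path)) {
    pl <- read_abundance_table(plasma_abundance_path)
    pann <- read_annotation_table(plasma_annotation_path)
    sig <- map_signature_to_panel(define_labor_signature(tab), pl)
    scores <- score_plasma_signature(pl, sig, pann)
    out$aggregated_auc <- roc_auc(scores, pann)$auc
    cand <- candidate_plasma_analytes(tab, pl)
    out$loocv_auc <- loocv_random_forest(pl, cand, pann, seed = seed)$auc
  }
  out
}
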