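#' Simulation configuration for synthetic labor cohorts
#'
#' Defaults emulate the study conditions the pipeline targets: a
#' 1310-analyte x 35-sample amniotic fluid (AF) cohort (11 TNL, 24 TIL), a
#' 1125-analyte x 80-sample maternal plasma cohort (21 TNL, 59 TIL), about
#' 19% of AF analytes truly differential with ~40% of those increased in
#' labor, fold changes between 1.25 and 4, partial analyte overlap between
#' the AF and plasma panels, and attenuated transfer of AF effects into
#' plasma. Per-analyte variances are drawn from a scaled inverse-chi-square
#' distribution so the empirical-Bayes estimator in [estimate_ebayes()] has
#' a correctly specified target.
#'
#' @param n_analytes_af,n_analytes_plasma panel sizes.
#' @param panel_overlap_fraction fraction of AF analytes also measured on the
#'   plasma panel, in (0, 1].
#' @param n_tnl_af,n_til_af,n_tnl_plasma,n_til_plasma group sizes.
#' @param frac_differential fraction of AF analytes with a true labor effect.
#' @param frac_up_among_differential fraction of differential analytes with
#'   increased abundance in labor.
#' @param log2fc_magnitude_range range of |true log2 fold change| for
#'   differential analytes (uniform draw); default c(0.33, 2) spans fold
#'   changes ~1.25-4.
#' @param baseline_log2_mean_range range of per-analyte baseline log2 RFU
#'   means (uniform draw).
#' @param var_prior_df,var_prior_scale d0 and s0^2 of the scaled
#'   inverse-chi-square from which per-analyte log2 variances are drawn.
#' @param plasma_attenuation multiplier in [0, 1] applied to AF log2 fold
#'   changes when planting them in plasma.
#' @param crossplatform_noise_sd reserved for cross-platform pairing noise.
#' @param n_celltypes,signature_size number and size of synthetic cell-type
#'   signature gene sets.
#' @param frac_unannotated fraction of analytes without a gene symbol.
#' @param seed integer RNG seed; all generators are pure functions of
#'   (config, seed).
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_analytes_af = 1310L,
                       n_analytes_plasma = 1125L,
                       panel_overlap_fraction = 0.75,
                       n_tnl_af = 11L, n_til_af = 24L,
                       n_tnl_plasma = 21L, n_til_plasma = 59L,
                       frac_differential = 0.19,
                       frac_up_among_differential = 0.40,
                       log2fc_magnitude_range = c(0.33, 2.0),
                       baseline_log2_mean_range = c(6, 14),
                       var_prior_df = 4,
                       var_prior_scale = 0.05,
                       plasma_attenuation = 0.5,
                       crossplatform_noise_sd = 0.5,
                       n_celltypes = 8L,
                       signature_size = 25L,
                       frac_unannotated = 0.02,
                       seed = 1L) {
  cfg <- list(n_analytes_af = as.integer(n_analytes_af),
              n_analytes_plasma = as.integer(n_analytes_plasma),
              panel_overlap_fraction = panel_overlap_fraction,
              n_tnl_af = as.integer(n_tnl_af), n_til_af = as.integer(n_til_af),
              n_tnl_plasma = as.integer(n_tnl_plasma),
              n_til_plasma = as.integer(n_til_plasma),
              frac_differential = frac_differential,
              frac_up_among_differential = frac_up_among_differential,
              log2fc_magnitude_range = log2fc_magnitude_range,
              baseline_log2_mean_range = baseline_log2_mean_range,
              var_prior_df = var_prior_df,
              var_prior_scale = var_prior_scale,
              plasma_attenuation = plasma_attenuation,
              crossplatform_noise_sd = crossplatform_noise_sd,
              n_celltypes = as.integer(n_celltypes),
              signature_size = as.integer(signature_size),
              frac_unannotated = frac_unannotated,
              seed = as.integer(seed))
  with(cfg, {
    stopifnot(n_analytes_af > 0, n_analytes_plasma > 0,
              panel_overlap_fraction > 0, panel_overlap_fraction <= 1,
              frac_differential >= 0, frac_differential <= 1,
              frac_up_among_differential >= 0, frac_up_among_differential <= 1,
              length(log2fc_magnitude_range) == 2,
              log2fc_magnitude_range[1] > 0,
              diff(log2fc_magnitude_range) >= 0,
              var_prior_df > 0, var_prior_scale > 0,
              plasma_attenuation >= 0, plasma_attenuation <= 1,
              crossplatform_noise_sd > 0,
              frac_unannotated >= 0, frac_unannotated < 1)
  })
  class(cfg) <- "sim_config"
  cfg
}

# deterministic sub-seed derived from the config seed and a stream label,
# kept below 2^31
sub_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  (as.numeric(seed) * 7919 + h) %% 2147483647
}

#' Simulate an amniotic fluid cohort
#'
#' Draws, per analyte, a baseline log2 mean, a true log2 fold change
#' (0 for null analytes; for differential analytes a uniform magnitude in
#' `log2fc_magnitude_range` with sign set by `frac_up_among_differential`),
#' and a variance from a scaled inverse-chi-square(d0, s0^2). Sample values
#' are Gaussian on the log2 scale around the group mean and exponentiated to
#' raw RFU. Deterministic under a fixed config seed.
#'
#' @param config a [sim_config()].
#' @return list with elements `matrix` (raw-scale [proteome_matrix()]),
#'   `annotation` (see [sample_annotation()]), and `truth`, a data.frame
#'   with per-analyte `analyte_id`, `gene_symbol`, `true_log2fc`,
#'   `true_var`.
#' @export
simulate_af_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_tnl_af < 2L || config$n_til_af < 2L)
    stop("each group needs at least 2 samples (variance undefined otherwise)")
  set.seed(sub_seed(config$seed, "af_cohort"))
  m <- config$n_analytes_af
  ids <- sprintf("AF%04d", seq_len(m))
  genes <- sprintf("G%04d", seq_len(m))
  n_blank <- round(config$frac_unannotated * m)
  if (n_blank > 0) genes[sample.int(m, n_blank)] <- ""

  n_diff <- round(config$frac_differential * m)
  lfc <- numeric(m)
  if (n_diff > 0) {
    idx <- sample.int(m, n_diff)
    mag <- stats::runif(n_diff, config$log2fc_magnitude_range[1],
                        config$log2fc_magnitude_range[2])
    n_up <- round(config$frac_up_among_differential * n_diff)
    sgn <- rep(-1, n_diff)
    if (n_up > 0) sgn[seq_len(n_up)] <- 1
    lfc[idx] <- mag * sgn
  }
  mu <- stats::runif(m, config$baseline_log2_mean_range[1],
                     config$baseline_log2_mean_range[2])
  s2 <- config$var_prior_df * config$var_prior_scale /
    stats::rchisq(m, df = config$var_prior_df)

  n1 <- config$n_tnl_af; n2 <- config$n_til_af
  sids <- c(sprintf("TNL_%02d", seq_len(n1)), sprintf("TIL_%02d", seq_len(n2)))
  grp <- rep(c("TNL", "TIL"), c(n1, n2))
  group_mean <- outer(lfc, as.numeric(grp == "TIL")) + mu
  log2vals <- group_mean + matrix(stats::rnorm(m * (n1 + n2), sd = sqrt(s2)),
                                  m, n1 + n2)
  vals <- 2^log2vals
  dimnames(vals) <- list(ids, sids)
  annotation <- sample_annotation(sids, grp,
                                  ga_weeks = round(stats::runif(n1 + n2, 37, 41), 1))
  list(matrix = proteome_matrix(vals, gene_symbols = genes, scale = "raw"),
       annotation = annotation,
       truth = data.frame(analyte_id = ids, gene_symbol = genes,
                          true_log2fc = lfc, true_var = s2,
                          stringsAsFactors = FALSE))
}

#' Simulate a maternal plasma cohort carrying attenuated AF effects
#'
#' A `panel_overlap_fraction` share of the AF analytes (chosen uniformly at
#' random) is placed on the plasma panel, carrying
#' `plasma_attenuation * true AF log2fc` as its planted plasma effect;
#' plasma-only analytes are nulls. Baselines and variances are re-drawn
#' (the platforms differ), sharing only the effect structure.
#'
#' @param config a [sim_config()].
#' @param truth the `truth` component returned by [simulate_af_cohort()].
#' @return list with `matrix` (raw-scale), `annotation`, and `truth`
#'   (per-plasma-analyte `true_log2fc`, plus `af_analyte_id` for shared
#'   analytes, `NA` for plasma-only).
#' @export
simulate_plasma_cohort <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"), is.data.frame(truth))
  set.seed(sub_seed(config$seed, "plasma_cohort"))
  n_shared <- round(config$panel_overlap_fraction * nrow(truth))
  if (n_shared < 1L) stop("panel overlap yields zero shared analytes")
  if (n_shared > config$n_analytes_plasma)
    stop("plasma panel smaller than the shared-analyte count implied by overlap")
  shared_idx <- sort(sample.int(nrow(truth), n_shared))
  m <- config$n_analytes_plasma
  ids <- sprintf("PL%04d", seq_len(m))
  genes <- c(truth$gene_symbol[shared_idx],
             sprintf("P%04d", seq_len(m - n_shared)))
  af_ids <- c(truth$analyte_id[shared_idx], rep(NA_character_, m - n_shared))
  lfc <- c(config$plasma_attenuation * truth$true_log2fc[shared_idx],
           rep(0, m - n_shared))

  mu <- stats::runif(m, config$baseline_log2_mean_range[1],
                     config$baseline_log2_mean_range[2])
  s2 <- config$var_prior_df * config$var_prior_scale /
    stats::rchisq(m, df = config$var_prior_df)
  n1 <- config$n_tnl_plasma; n2 <- config$n_til_plasma
  sids <- c(sprintf("PTNL_%02d", seq_len(n1)), sprintf("PTIL_%02d", seq_len(n2)))
  grp <- rep(c("TNL", "TIL"), c(n1, n2))
  group_mean <- outer(lfc, as.numeric(grp == "TIL")) + mu
  vals <- 2^(group_mean + matrix(stats::rnorm(m * (n1 + n2), sd = sqrt(s2)),
                                 m, n1 + n2))
  dimnames(vals) <- list(ids, sids)
  list(matrix = proteome_matrix(vals, gene_symbols = genes, scale = "raw"),
       annotation = sample_annotation(sids, grp,
                                      ga_weeks = round(stats::runif(n1 + n2, 37, 41), 1)),
       truth = data.frame(analyte_id = ids, gene_symbol = genes,
                          af_analyte_id = af_ids, true_log2fc = lfc,
                          true_var = s2, stringsAsFactors = FALSE))
}

#' Simulate paired cross-platform measurements
#'
#' Gaussian-copula construction: a bivariate normal with Pearson correlation
#' `2*sin(pi*rho/6)` has population Spearman correlation `rho`; monotone
#' exponentiation to positive values preserves it. Emulates paired
#' aptamer-vs-immunoassay measurements of the same analyte.
#'
#' @param n number of pairs (>= 5).
#' @param rho_target population Spearman correlation, strictly inside (-1, 1).
#' @param seed RNG seed.
#' @return data.frame with positive-valued columns `platform_a`,
#'   `platform_b`.
#' @export
simulate_crossplatform_pairs <- function(n, rho_target, seed = 1L) {
  if (n < 5L) stop("need at least 5 pairs")
  if (abs(rho_target) >= 1) stop("rho_target must lie strictly inside (-1, 1)")
  set.seed(seed %% 2147483647)
  r <- 2 * sin(pi * rho_target / 6)
  z1 <- stats::rnorm(n)
  z2 <- r * z1 + sqrt(1 - r^2) * stats::rnorm(n)
  data.frame(platform_a = exp(z1 + 8), platform_b = exp(z2 + 4))
}

#' Simulate ordered cell-type signature gene sets
#'
#' Builds `n_celltypes` ordered gene sets over the AF cohort's annotated
#' analytes. Cell types are assigned directions cyclically (up / down /
#' null): "up" sets draw members from analytes with positive true log2 fold
#' change, "down" sets from negative, "null" sets from analytes with exactly
#' zero true effect. Members are ordered by |true log2fc| descending
#' (a proxy for preferential expression; ties broken by gene symbol), so the
#' first member of each set is its strongest planted marker.
#'
#' @param config a [sim_config()].
#' @param truth `truth` from [simulate_af_cohort()].
#' @return list with `sets` (named list of ordered gene sets, GMT-ready) and
#'   `directions` (named character vector: up/down/null per set).
#' @export
simulate_signature_genesets <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"), is.data.frame(truth))
  set.seed(sub_seed(config$seed, "signatures"))
  annotated <- truth[nzchar(truth$gene_symbol), , drop = FALSE]
  pools <- list(up = annotated[annotated$true_log2fc > 0, , drop = FALSE],
                down = annotated[annotated$true_log2fc < 0, , drop = FALSE],
                null = annotated[annotated$true_log2fc == 0, , drop = FALSE])
  dirs <- rep(c("up", "down", "null"), length.out = config$n_celltypes)
  sets <- vector("list", config$n_celltypes)
  nm <- sprintf("celltype_%02d_%s", seq_len(config$n_celltypes), dirs)
  for (k in seq_len(config$n_celltypes)) {
    pool <- pools[[dirs[k]]]
    if (nrow(pool) < config$signature_size)
      stop(sprintf("not enough %s-effect analytes (%d) for signature size %d",
                   dirs[k], nrow(pool), config$signature_size))
    pick <- pool[sample.int(nrow(pool), config$signature_size), , drop = FALSE]
    ord <- order(-abs(pick$true_log2fc), pick$gene_symbol)
    sets[[k]] <- list(name = nm[k],
                      description = sprintf("synthetic %s cell-type signature", dirs[k]),
                      members = pick$gene_symbol[ord])
  }
  names(sets) <- nm
  names(dirs) <- nm
  list(sets = sets, directions = dirs)
}
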