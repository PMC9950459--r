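test_that("gene ranking collapses analytes by max |t| with stable ties", {
  tab <- structure(data.frame(analyte_id = c("A1", "A2", "A3", "A4"),
                              gene_symbol = c("GX", "GX", "GY", ""),
                              log2fc = 0, t = c(3, -1, 2, 9),
                              p_value = 0.5, q_value = NA_real_,
                              significant = NA, direction = NA_character_),
                   class = c("differential_table", "data.frame"))
  r <- rank_proteins(tab)
  # GX kept at t = 3 (max |t| of its two analytes); unannotated A4 dropped
  expect_identical(r$gene_symbols, c("GX", "GY"))
  expect_identical(r$scores, c(3, 2))

  # all-distinct genes: length preserved, scores non-increasing
  set.seed(20)
  tab2 <- structure(data.frame(analyte_id = sprintf("A%03d", 1:50),
                               gene_symbol = sprintf("G%03d", 1:50),
                               log2fc = 0, t = rnorm(50), p_value = 0.5,
                               q_value = NA_real_, significant = NA,
                               direction = NA_character_),
                    class = c("differential_table", "data.frame"))
  r2 <- rank_proteins(tab2)
  expect_length(r2$gene_symbols, 50L)
  expect_true(all(diff(r2$scores) <= 0))

  # brute-force group-by-max-|t| oracle on a 100-analyte fixture
  genes <- sample(sprintf("G%02d", 1:40), 100, replace = TRUE)
  tvals <- rnorm(100)
  tab3 <- structure(data.frame(analyte_id = sprintf("A%03d", 1:100),
                               gene_symbol = genes, log2fc = 0, t = tvals,
                               p_value = 0.5, q_value = NA_real_,
                               significant = NA, direction = NA_character_),
                    class = c("differential_table", "data.frame"))
  r3 <- rank_proteins(tab3)
  oracle <- sapply(split(tvals, genes), function(v) v[which.max(abs(v))])
  expect_identical(sort(names(oracle)), sort(r3$gene_symbols))
  expect_equal(r3$scores, unname(oracle[r3$gene_symbols]), tolerance = 1e-15)

  tab_empty <- tab; tab_empty$gene_symbol <- ""
  expect_error(rank_proteins(tab_empty), "no analytes")
})

test_that("enrichment score equals the hand-computed running-sum extremum", {
  ranked <- make_ranked(paste0("g", 1:6), c(3, 2, 1, -1, -2, -3))

  # top-ranked singleton: walk hits +1 at position 1
  top <- enrichment_score(ranked, "g1")
  expect_identical(top$es, 1)
  expect_identical(top$leading_edge, "g1")

  # bottom-ranked singleton: maximal negative deviation at position N-1
  bot <- enrichment_score(ranked, "g6")
  expect_identical(bot$es, -1)
  expect_identical(bot$leading_edge, "g6")

  # {g1, g4}: hits weight 3 and 1 (sum 4), misses -1/4;
  # walk = 0.75, 0.5, 0.25, 0.5, 0.25, 0 -> ES = 0.75, leading edge g1
  r <- enrichment_score(ranked, c("g1", "g4"))
  expect_equal(r$es, 0.75, tolerance = 1e-15)
  expect_identical(r$leading_edge, "g1")

  expect_error(enrichment_score(ranked, "nope"), "no members")
})

test_that("ES stays in [-1, 1] and negates under list reversal", {
  set.seed(21)
  for (i in 1:30) {
    N <- sample(6:40, 1)
    sc <- sort(rnorm(N), decreasing = TRUE)
    genes <- paste0("g", 1:N)
    members <- sample(genes, sample(1:(N - 1), 1))
    es <- enrichment_score(make_ranked(genes, sc), members)$es
    expect_true(es >= -1 && es <= 1)
    expect_equal(es, es_bruteforce(genes, sc, members), tolerance = 1e-12)
    es_rev <- enrichment_score(make_ranked(rev(genes), rev(sc)), members)$es
    expect_equal(es_rev, -es, tolerance = 1e-12)
  }
})

test_that("permutation null is exact in exhaustive mode and seed-stable", {
  ranked <- make_ranked(paste0("g", 1:6), c(3, 2, 1, -1, -2, -3))
  null_ex <- permutation_null(ranked, 2L, exhaustive = TRUE)
  expect_length(null_ex, choose(6, 2))
  # exhaustive permutation p agrees with a brute-force enumeration of all
  # C(6,2) subsets via the independent running-sum oracle
  all_es <- apply(combn(6, 2), 2, function(ix)
    es_bruteforce(ranked$gene_symbols, ranked$scores, ranked$gene_symbols[ix]))
  obs <- enrichment_score(ranked, c("g1", "g2"))$es
  p_manual <- sum(all_es >= obs) / sum(all_es >= 0)
  expect_equal(laborproteome:::perm_pvalue(obs, null_ex), p_manual,
               tolerance = 1e-12)

  n1 <- permutation_null(ranked, 2L, n_perm = 500, seed = 77)
  n2 <- permutation_null(ranked, 2L, n_perm = 500, seed = 77)
  expect_identical(n1, n2)
  expect_warning(permutation_null(ranked, 2L, n_perm = 50, seed = 1),
                 "fewer than 100")
  expect_error(permutation_null(ranked, 6L), "smaller")

  # sampled null mean of signed es near 0 for a symmetric score vector
  big <- make_ranked(paste0("g", 1:20), seq(2, -2, length.out = 20))
  ns <- permutation_null(big, 4L, n_perm = 10000, seed = 3)
  expect_lt(abs(mean(ns)), 3 * sd(ns) / sqrt(length(ns)))
})

test_that("GSEA applies the size filter, finds planted sets, and is order-invariant", {
  set.seed(22)
  N <- 60
  genes <- sprintf("g%02d", 1:N)
  scores <- sort(rnorm(N, sd = 2), decreasing = TRUE)
  ranked <- make_ranked(genes, scores)
  sets <- list(
    planted = list(name = "planted", description = "", members = genes[1:10]),
    tiny = list(name = "tiny", description = "", members = genes[c(3, 9, 15, 21)]),
    random1 = list(name = "random1", description = "", members = sample(genes, 12)),
    random2 = list(name = "random2", description = "", members = sample(genes, 8)),
    dup_a = list(name = "dup_a", description = "", members = genes[seq(5, 45, 5)]),
    dup_b = list(name = "dup_b", description = "", members = genes[seq(5, 45, 5)])
  )
  res <- run_gsea(ranked, sets, min_size = 5L, n_perm = 1000L, seed = 9)
  # the 4-member set is excluded
  expect_false("tiny" %in% res$set_name)
  # planted top-10 set: extreme tail
  pl <- res[res$set_name == "planted", ]
  expect_lte(pl$p_perm, 0.001)
  expect_lt(pl$q_value, 0.25)
  expect_true(pl$significant)
  # identical duplicate sets get identical es and nes
  expect_identical(res$es[res$set_name == "dup_a"],
                   res$es[res$set_name == "dup_b"])
  expect_identical(res$nes[res$set_name == "dup_a"],
                   res$nes[res$set_name == "dup_b"])
  # supplying the sets in another order changes nothing
  res2 <- run_gsea(ranked, rev(sets), min_size = 5L, n_perm = 1000L, seed = 9)
  res2 <- res2[match(res$set_name, res2$set_name), ]
  expect_equal(res$es, res2$es, tolerance = 1e-15)
  expect_equal(res$q_value, res2$q_value, tolerance = 1e-15)
  # sign(nes) = sign(es); leading edge is a subset of the set's members
  expect_true(all(sign(res$nes) == sign(res$es) | res$es == 0))
  for (i in seq_len(nrow(res))) {
    le <- strsplit(res$leading_edge[i], ";")[[1]]
    expect_true(all(le %in% sets[[res$set_name[i]]]$members))
  }
  expect_error(run_gsea(ranked, list(list(name = "x", description = "",
                                          members = genes[1:2]))),
               "minimum-size")
})

test_that("sampled permutation p agrees with exhaustive enumeration", {
  set.seed(23)
  genes <- paste0("g", 1:8)
  scores <- sort(rnorm(8), decreasing = TRUE)
  ranked <- make_ranked(genes, scores)
  for (size in c(2L, 3L)) {
    null_ex <- permutation_null(ranked, size, exhaustive = TRUE)
    null_s <- permutation_null(ranked, size, n_perm = 50000L, seed = 31)
    for (members in list(genes[1:size], genes[(9 - size):8],
                         genes[seq_len(size) * 2])) {
      es <- enrichment_score(ranked, members)$es
      p_ex <- laborproteome:::perm_pvalue(es, null_ex)
      p_s <- laborproteome:::perm_pvalue(es, null_s)
      se <- sqrt(p_ex * (1 - p_ex) / 50000) + 1e-9
      expect_lt(abs(p_s - p_ex), 3 * se + 2e-4)
    }
  }
})

test_that("fgsea agrees with the in-package enrichment scores", {
  suppressPackageStartupMessages(library(fgsea))
  set.seed(24)
  N <- 100
  genes <- sprintf("g%03d", 1:N)
  scores <- sort(rnorm(N, sd = 1.5), decreasing = TRUE)
  ranked <- make_ranked(genes, scores)
  pathways <- list(p1 = genes[1:15], p2 = sample(genes, 20),
                   p3 = genes[85:100])
  stats <- setNames(scores, genes)
  fg <- fgsea(pathways, stats, minSize = 5, maxSize = 50, nPermSimple = 1000,
              scoreType = "std")
  for (nm in fg$pathway) {
    mine <- enrichment_score(ranked, pathways[[nm]])$es
    expect_equal(mine, fg$ES[fg$pathway == nm], tolerance = 1e-6)
  }
})
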