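test_that("pairwise correlations match the covariance-formula oracle", {
  set.seed(61)
  M <- matrix(rnorm(50 * 80), 50, 80,
              dimnames = list(sprintf("g%02d", 1:50), NULL))
  C <- pairwise_corr(M)
  expect_equal(diag(C), setNames(rep(1, 50), rownames(M)))
  expect_equal(unclass(C), t(unclass(C)), ignore_attr = TRUE)
  for (pair in list(c(1, 2), c(3, 40), c(17, 50))) {
    expect_equal(C[pair[1], pair[2]],
                 oracle_pearson(M[pair[1], ], M[pair[2], ]),
                 tolerance = 1e-12)
  }
  # perfect anti-correlation
  M2 <- rbind(a = rnorm(30), b = 0)
  M2["b", ] <- -M2["a", ]
  expect_equal(pairwise_corr(M2)["a", "b"], -1, tolerance = 1e-12)

  # constant rows are flagged and zeroed, diagonal stays 1
  M3 <- rbind(a = rnorm(30), b = rep(2, 30))
  C3 <- pairwise_corr(M3)
  expect_equal(C3["a", "b"], 0)
  expect_equal(C3["b", "b"], 1)
  expect_true(attr(C3, "constant")["b"])
  expect_error(pairwise_corr(M2[, 1:2]), ">= 3")
})

test_that("forcing the null sets to the responsive set collapses the null", {
  set.seed(62)
  M <- matrix(rnorm(60 * 100), 60, 100,
              dimnames = list(sprintf("g%02d", 1:60), NULL))
  degs <- rownames(M)[1:20]
  sets <- matrix(rep(1:20, 5), nrow = 20)    # every set IS the DEG set
  nl <- matched_null(M, M, degs, sets = sets)
  expect_true(all(abs(nl$null_sds - nl$observed_sd) < 1e-12))
  expect_lt(nl$ks_stat, 1e-12)
  expect_gt(nl$ks_p, 0.999)
})

test_that("null sets match the responsive expression-decile profile exactly", {
  cfg <- sim_config(n_genes = 500, frac_deg = 0.1, cells_per_timepoint = 60,
                    timepoints = c("0h", "18h"), time_hours = c(0, 18),
                    responder_prob = c(0, 0.4), seed = 44)
  tr <- build_truth(cfg)
  sim <- simulate_counts(tr, cfg)
  nm <- normalize_log(sim)
  sc <- regress_scale(nm)
  degs <- tr$genes$gene_id[tr$genes$is_deg]
  nl <- matched_null(sc, nm, degs, n_sets = 50, set_size = 50, seed = 9)
  expect_equal(length(nl$null_sds), 50)
  expect_equal(colSums(nl$set_profiles), rep(50, 50))
  for (s in seq_len(ncol(nl$set_profiles))) {
    expect_equal(nl$set_profiles[, s], nl$target_profile)
  }
  # no responsive gene ever enters a null set
  expect_false(any(rownames(sc$mat)[nl$sets] %in% degs))
  # determinism
  nl2 <- matched_null(sc, nm, degs, n_sets = 50, set_size = 50, seed = 9)
  expect_identical(nl$sets, nl2$sets)
  expect_equal(nl$null_sds, nl2$null_sds)
})

test_that("correlation clustering recovers planted block structure", {
  set.seed(71)
  # two perfectly anti-correlated blocks
  base <- rnorm(60)
  M <- rbind(matrix(rep(base, 6), 6, byrow = TRUE) +
               matrix(rnorm(360, 0, 0.05), 6),
             matrix(rep(-base, 6), 6, byrow = TRUE) +
               matrix(rnorm(360, 0, 0.05), 6))
  rownames(M) <- sprintf("g%02d", 1:12)
  C <- pairwise_corr(M)
  cl <- cluster_corr(C, k = 2, seed = 5)
  expect_equal(length(unique(cl[1:6])), 1)
  expect_equal(length(unique(cl[7:12])), 1)
  expect_true(cl[1] != cl[12])

  # k equal to the number of genes -> singletons
  cl_n <- cluster_corr(C, k = 12, seed = 5)
  expect_equal(sort(unname(cl_n)), 1:12)
  expect_error(cluster_corr(C, k = 13), "k must be")

  # planted 3-block structure recovered with high adjusted Rand index
  lat <- matrix(rnorm(3 * 200), 3, 200)
  truth_lab <- rep(1:3, each = 15)
  M3 <- lat[truth_lab, ] + matrix(rnorm(45 * 200, 0, 0.4), 45, 200)
  rownames(M3) <- sprintf("g%02d", 1:45)
  cl3 <- cluster_corr(pairwise_corr(M3), k = 3, seed = 5)
  expect_gt(adjusted_rand(cl3, truth_lab), 0.9)
  # deterministic given the seed
  expect_identical(cl3, cluster_corr(pairwise_corr(M3), k = 3, seed = 5))
})

test_that("variable-gene selection prefers dispersed genes within bins", {
  cfg <- tiny_config(seed = 29)
  sim <- simulate_counts(build_truth(cfg))
  nm <- normalize_log(sim)
  # n = gene count returns everything
  expect_setequal(select_hvg(nm, n = nrow(nm$mat)), rownames(nm$mat))
  # a zero-variance gene is never selected while positive-variance remain
  nm2 <- nm
  nm2$mat <- rbind(nm$mat, flat = rep(1.5, ncol(nm$mat)))
  sel <- select_hvg(nm2, n = nrow(nm2$mat) - 1)
  expect_false("flat" %in% sel)

  # responsive genes (extra induced variance) are enriched among the top
  cfg2 <- sim_config(n_genes = 800, frac_deg = 0.1, cells_per_timepoint = 150,
                     timepoints = c("0h", "18h"), time_hours = c(0, 18),
                     responder_prob = c(0, 0.5),
                     fold_change_range = c(3, 10), seed = 55)
  tr2 <- build_truth(cfg2)
  sim2 <- simulate_counts(tr2, cfg2)
  nm2b <- normalize_log(sim2)
  top <- select_hvg(nm2b, n = 200)
  degs <- tr2$genes$gene_id[tr2$genes$is_deg]
  k <- sum(top %in% degs)
  pval <- phyper(k - 1, length(degs), 800 - length(degs), 200,
                 lower.tail = FALSE)
  expect_lt(pval, 1e-6)
})

test_that("PCA embedding is exact, sign-stable and reconstructive", {
  # points on one line: first component explains ~100% of variance
  set.seed(81)
  t_par <- rnorm(40)
  M <- rbind(g1 = 2 * t_par, g2 = -t_par, g3 = 0.5 * t_par)
  sc <- structure(list(mat = M, clip = 10,
                       cell_meta = data.frame(cell = sprintf("c%02d", 1:40),
                                              timepoint = "0h")),
                  class = "dex_scaled")
  colnames(sc$mat) <- sprintf("c%02d", 1:40)
  em <- suppressWarnings(pca_embed(sc, n_components = 3))
  expect_gt(em$explained_var_ratio[1], 1 - 1e-10)

  # full-rank reconstruction reproduces the input
  set.seed(82)
  M2 <- matrix(rnorm(8 * 30), 8, 30,
               dimnames = list(paste0("g", 1:8), paste0("c", 1:30)))
  sc2 <- structure(list(mat = M2, clip = 10,
                        cell_meta = data.frame(cell = colnames(M2),
                                               timepoint = "0h")),
                   class = "dex_scaled")
  em2 <- pca_embed(sc2, n_components = 8)
  centers <- rowMeans(M2)
  rec <- em2$coords %*% t(em2$loadings) + matrix(centers, 30, 8, byrow = TRUE)
  expect_lt(max(abs(t(rec) - M2)), 1e-8)
  # sign convention: the largest-magnitude loading of each PC is positive
  for (j in seq_len(ncol(em2$loadings))) {
    expect_gt(em2$loadings[which.max(abs(em2$loadings[, j])), j], 0)
  }
})

test_that("de novo clusters recover separated groups and count compositions", {
  set.seed(91)
  centers <- matrix(rnorm(6 * 2, sd = 20), 6, 2)
  tps <- c("0h", "1h", "2h", "4h", "8h", "18h")
  coords <- centers[rep(1:6, each = 50), ] + matrix(rnorm(600, 0, 0.5), 300, 2)
  rownames(coords) <- sprintf("c%03d", 1:300)
  em <- structure(list(coords = coords,
                       cell_meta = data.frame(cell = rownames(coords),
                                              timepoint = rep(tps, each = 50))),
                  class = "dex_embedding")
  cl <- denovo_clusters(em, k = 6, seed = 2)
  expect_gt(adjusted_rand(cl$cluster, rep(1:6, each = 50)), 0.99)
  expect_equal(sum(cl$composition), 300)
  # composition rows sum to cluster sizes
  expect_equal(as.vector(rowSums(cl$composition)),
               as.vector(table(cl$cluster)))
  # same seed -> identical labels
  expect_identical(cl$cluster, denovo_clusters(em, k = 6, seed = 2)$cluster)
  expect_error(denovo_clusters(em, k = 301), "exceeds")
})
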