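#' Pairwise Pearson correlations between responsive genes
#'
#' Standard Pearson correlation of scaled expression profiles across all
#' cells of the time course (zeros enter as their scaled values). Constant
#' gene rows have undefined correlations; these are set to 0 and flagged.
#'
#' @param scaled a [regress_scale()] object (or plain genes x cells
#'   matrix).
#' @param degs genes to correlate; default all rows.
#' @return An object of class `dex_corr`: the symmetric unit-diagonal
#'   correlation matrix with attribute `constant` (logical per gene).
#' @export
pairwise_corr <- function(scaled, degs = NULL) {
  M <- if (inherits(scaled, "dex_scaled")) scaled$mat else scaled
  if (!is.null(degs)) M <- M[degs, , drop = FALSE]
  if (ncol(M) < 3) stop("need >= 3 cells", call. = FALSE)
  sds <- apply(M, 1L, stats::sd)
  constant <- sds == 0 | !is.finite(sds)
  C <- suppressWarnings(stats::cor(t(M)))
  C[constant, ] <- 0
  C[, constant] <- 0
  diag(C) <- 1
  attr(C, "constant") <- constant
  class(C) <- c("dex_corr", class(C))
  C
}

upper_tri_values <- function(C) C[upper.tri(C)]

#' Expression-matched resampling null for correlation spread
#'
#' Calibrates the spread (SD) of pairwise correlations among the
#' responsive genes against random gene sets expressed at similar levels.
#' The distribution of mean log-normalized expression of the responsive
#' set is split into deciles; each null set draws non-responsive genes to
#' match that decile profile exactly (without replacement within a set).
#' Per set, the SD of all pairwise correlations is recorded; a two-sample
#' Kolmogorov-Smirnov test compares the responsive-set correlation
#' distribution with the pooled null correlations.
#'
#' @param scaled a [regress_scale()] object (correlation scale).
#' @param norm the matching [normalize_log()] object (expression-matching
#'   scale).
#' @param degs character vector: the responsive gene set.
#' @param n_sets number of null sets.
#' @param set_size genes per null set.
#' @param seed RNG seed.
#' @param sets optional integer matrix (`set_size` x `n_sets`) of
#'   pre-specified row indices into the gene universe, overriding sampling
#'   (used for calibration checks).
#' @param max_pool cap on the number of pooled null correlations entering
#'   the KS test (deterministic per-set subsampling beyond it).
#' @return An object of class `dex_null`: list with `null_sds`,
#'   `observed_sd`, `ks_stat`, `ks_p`, `observed_corrs`, `decile_breaks`,
#'   `target_profile` (genes per decile in a null set), `set_profiles`
#'   (decile profile of every set) and `sets`.
#' @export
matched_null <- function(scaled, norm, degs, n_sets = 1000, set_size = 400,
                         seed = 1L, sets = NULL, max_pool = 200000) {
  M <- if (inherits(scaled, "dex_scaled")) scaled$mat else scaled
  genes <- rownames(M)
  stopifnot(all(degs %in% genes))
  expr <- rowMeans(if (inherits(norm, "dex_norm")) norm$mat else norm)[genes]

  # decile profile of the responsive set, allocated to set_size seats
  breaks <- stats::quantile(expr[degs], probs = 0:10 / 10, names = FALSE)
  breaks[1] <- -Inf; breaks[11] <- Inf
  deg_bin <- findInterval(expr[degs], breaks, rightmost.closed = TRUE,
                          all.inside = TRUE)
  prof <- tabulate(deg_bin, nbins = 10L)
  target <- floor(prof / sum(prof) * set_size)
  rem <- set_size - sum(target)
  if (rem > 0) {
    frac <- prof / sum(prof) * set_size - target
    target[order(-frac)[seq_len(rem)]] <- target[order(-frac)[seq_len(rem)]] + 1L
  }

  pool_bin <- findInterval(expr, breaks, rightmost.closed = TRUE,
                           all.inside = TRUE)
  eligible <- setdiff(genes, degs)
  sds_all <- apply(M, 1L, stats::sd)
  eligible <- eligible[sds_all[eligible] > 0]
  elig_by_bin <- split(match(eligible, genes), pool_bin[match(eligible, genes)])

  if (is.null(sets)) {
    for (b in which(target > 0)) {
      have <- length(elig_by_bin[[as.character(b)]])
      if (is.null(elig_by_bin[[as.character(b)]]) || have < target[b]) {
        stop(sprintf(
          "expression decile %d has %d eligible genes but %d are required",
          b, have, target[b]), call. = FALSE)
      }
    }
    set.seed(seed)
    sets <- vapply(seq_len(n_sets), function(s) {
      unlist(lapply(which(target > 0), function(b) {
        sample(elig_by_bin[[as.character(b)]], target[b])
      }), use.names = FALSE)
    }, integer(set_size))
  } else {
    sets <- as.matrix(sets)
    n_sets <- ncol(sets)
    set_size <- nrow(sets)
    set.seed(seed)
  }

  # one full correlation matrix over every gene any set can touch
  used <- sort(unique(c(match(degs, genes), as.vector(sets))))
  C <- pairwise_corr(M[used, , drop = FALSE])
  pos_of <- integer(length(genes)); pos_of[used] <- seq_along(used)

  obs_idx <- pos_of[match(degs, genes)]
  observed_corrs <- upper_tri_values(C[obs_idx, obs_idx, drop = FALSE])
  observed_sd <- stats::sd(observed_corrs)

  per_set_keep <- max(1L, ceiling(max_pool / n_sets))
  null_sds <- numeric(n_sets)
  pooled <- vector("list", n_sets)
  set_profiles <- matrix(0L, 10L, n_sets)
  for (s in seq_len(n_sets)) {
    idx <- pos_of[sets[, s]]
    v <- upper_tri_values(C[idx, idx, drop = FALSE])
    null_sds[s] <- stats::sd(v)
    pooled[[s]] <- if (length(v) > per_set_keep) v[sample.int(length(v), per_set_keep)] else v
    set_profiles[, s] <- tabulate(pool_bin[sets[, s]], nbins = 10L)
  }
  pooled <- unlist(pooled, use.names = FALSE)
  ks <- suppressWarnings(stats::ks.test(observed_corrs, pooled))

  structure(list(null_sds = null_sds, observed_sd = observed_sd,
                 ks_stat = unname(ks$statistic), ks_p = ks$p.value,
                 observed_corrs = observed_corrs,
                 decile_breaks = breaks, target_profile = target,
                 set_profiles = set_profiles, sets = sets),
            class = "dex_null")
}

#' @export
print.dex_null <- function(x, ...) {
  cat(sprintf(
    "Expression-matched correlation null: %d sets\n  observed SD %.4f; null SD range [%.4f, %.4f]; KS D = %.3f (p = %.3g)\n",
    length(x$null_sds), x$observed_sd, min(x$null_sds), max(x$null_sds),
    x$ks_stat, x$ks_p))
  invisible(x)
}

#' Cluster responsive genes on their correlation profiles
#'
#' k-means on the rows of the correlation matrix (best of `nstart`
#' initializations), with cluster labels relabeled in decreasing size
#' order so the output is deterministic for a given seed.
#'
#' @param corr a [pairwise_corr()] matrix.
#' @param k number of clusters.
#' @param seed RNG seed.
#' @param nstart k-means restarts.
#' @return named integer vector of cluster labels (1 = largest cluster).
#' @export
cluster_corr <- function(corr, k = 6, seed = 1L, nstart = 10) {
  n <- nrow(corr)
  if (k < 2 || k > n) stop("k must be in [2, n_genes]", call. = FALSE)
  if (k == n) {                         # every gene its own cluster
    out <- seq_len(n)
    names(out) <- rownames(corr)
    return(out)
  }
  set.seed(seed)
  km <- stats::kmeans(unclass(corr), centers = k, nstart = nstart,
                      iter.max = 100)
  sizes <- table(km$cluster)
  relabel <- integer(k)
  relabel[order(-as.integer(sizes), as.integer(names(sizes)))] <- seq_len(k)
  out <- relabel[km$cluster]
  names(out) <- rownames(corr)
  out
}

#' Select highly variable genes
#'
#' Genes are ranked by dispersion (variance / mean of `expm1(normalized)`
#' expression) standardized within 20 mean-expression bins, and the top
#' `n` are returned. Deterministic; ties broken by gene order.
#'
#' @param norm a [normalize_log()] object.
#' @param n number of genes to select.
#' @param n_bins number of mean-expression bins.
#' @return character vector of gene names.
#' @export
select_hvg <- function(norm, n = 500, n_bins = 20) {
  M <- expm1(norm$mat)
  mu <- rowMeans(M)
  v <- apply(M, 1L, stats::var)
  disp <- ifelse(mu > 0, v / mu, 0)
  n <- min(n, nrow(M))
  br <- unique(stats::quantile(mu, probs = seq(0, 1, length.out = n_bins + 1)))
  bin <- findInterval(mu, br, rightmost.closed = TRUE, all.inside = TRUE)
  z <- numeric(length(disp))
  for (b in unique(bin)) {
    i <- bin == b
    m <- mean(disp[i]); s <- stats::sd(disp[i])
    z[i] <- if (is.na(s) || s == 0) 0 else (disp[i] - m) / s
  }
  z[v == 0] <- -Inf                       # zero-variance genes are never selected
  rownames(norm$mat)[order(-z)[seq_len(n)]]
}

#' PCA embedding of cells
#'
#' Exact principal component analysis of the cells-by-genes scaled matrix
#' restricted to the supplied genes. Component signs are fixed by making
#' the loading of largest magnitude positive. Explained-variance ratios
#' are reported; if the matrix rank is lower than requested, fewer
#' components are returned with a warning.
#'
#' @param scaled a [regress_scale()] object.
#' @param genes genes to use (e.g. from [select_hvg()]).
#' @param n_components number of components.
#' @return An object of class `dex_embedding`: list with `coords` (cells x
#'   components), `loadings`, `explained_var_ratio` and `cell_meta`.
#' @export
pca_embed <- function(scaled, genes = rownames(scaled$mat), n_components = 15) {
  M <- t(scaled$mat[genes, , drop = FALSE])   # cells x genes
  n_components <- min(n_components, ncol(M), nrow(M))
  pc <- stats::prcomp(M, center = TRUE, scale. = FALSE)
  evr <- pc$sdev^2 / sum(pc$sdev^2)
  rank_eff <- sum(pc$sdev > pc$sdev[1] * 1e-10)
  if (rank_eff < n_components) {
    warning(sprintf("matrix rank %d < %d requested components", rank_eff,
                    n_components))
    n_components <- rank_eff
  }
  coords <- pc$x[, seq_len(n_components), drop = FALSE]
  loadings <- pc$rotation[, seq_len(n_components), drop = FALSE]
  for (j in seq_len(n_components)) {
    if (loadings[which.max(abs(loadings[, j])), j] < 0) {
      loadings[, j] <- -loadings[, j]
      coords[, j] <- -coords[, j]
    }
  }
  structure(list(coords = coords, loadings = loadings,
                 explained_var_ratio = evr[seq_len(n_components)],
                 cell_meta = scaled$cell_meta),
            class = "dex_embedding")
}

#' De novo cell clusters on the PCA embedding
#'
#' k-means on the leading principal components (by default the first 15 or
#' all available, whichever is smaller), with a per-(cluster, timepoint)
#' composition table. Labels are relabeled by decreasing cluster size.
#'
#' @param embedding a [pca_embed()] object.
#' @param k number of clusters.
#' @param seed RNG seed.
#' @param n_components components used for clustering.
#' @param nstart k-means restarts.
#' @return list with `cluster` (named integer per cell) and `composition`
#'   (cluster x timepoint count matrix, if timepoints are available).
#' @export
denovo_clusters <- function(embedding, k = 6, seed = 1L,
                            n_components = 15, nstart = 10) {
  X <- embedding$coords[, seq_len(min(n_components, ncol(embedding$coords))),
                        drop = FALSE]
  if (k > nrow(X)) stop("k exceeds the number of cells", call. = FALSE)
  set.seed(seed)
  km <- stats::kmeans(X, centers = k, nstart = nstart, iter.max = 100)
  sizes <- table(km$cluster)
  relabel <- integer(k)
  relabel[order(-as.integer(sizes), as.integer(names(sizes)))] <- seq_len(k)
  cl <- relabel[km$cluster]
  names(cl) <- rownames(X)
  comp <- NULL
  if (!is.null(embedding$cell_meta)) {
    tp <- embedding$cell_meta$timepoint[match(names(cl), embedding$cell_meta$cell)]
    comp <- table(cluster = cl, timepoint = tp)
  }
  list(cluster = cl, composition = comp)
}

#' Two-gene co-expression overlay values
#'
#' For a pair of genes, returns per-cell blended intensities in the style
#' of a two-channel co-localization image: each gene's scaled expression is
#' mapped to `[0, 1]` and reported per cell together with their product
#' (co-expression intensity).
#'
#' @param scaled a [regress_scale()] object.
#' @param gene_x,gene_y the two genes.
#' @return data frame: cell, x, y, blend.
#' @export
coexpression_overlay <- function(scaled, gene_x, gene_y) {
  rescale01 <- function(v) {
    r <- range(v)
    if (diff(r) == 0) return(rep(0, length(v)))
    (v - r[1]) / diff(r)
  }
  x <- rescale01(scaled$mat[gene_x, ])
  y <- rescale01(scaled$mat[gene_y, ])
  data.frame(cell = colnames(scaled$mat), x = x, y = y, blend = x * y,
             stringsAsFactors = FALSE)
}
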