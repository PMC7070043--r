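#' Remove cells with high mitochondrial fraction
#'
#' Cells with a mitochondrial gene percentage strictly greater than
#' `mito_max` are removed; cells exactly at the boundary are retained. The
#' gene universe is unchanged.
#'
#' @param sim a `dex_sim` object (list with `counts` and `cell_meta`).
#' @param mito_max maximum allowed mitochondrial fraction (default 5%).
#' @return the filtered `dex_sim` object.
#' @export
qc_filter <- function(sim, mito_max = 0.05) {
  stopifnot(!is.null(sim$cell_meta$mito_fraction))
  keep <- sim$cell_meta$mito_fraction <= mito_max
  if (!any(keep)) stop("QC filter removed every cell", call. = FALSE)
  subset_cells(sim, which(keep))
}

subset_cells <- function(sim, idx) {
  sim$counts <- sim$counts[, idx, drop = FALSE]
  sim$cell_meta <- sim$cell_meta[idx, , drop = FALSE]
  rownames(sim$cell_meta) <- NULL
  if (!is.null(sim$responders)) {
    sim$responders <- sim$responders[, idx, drop = FALSE]
  }
  sim
}

#' Balance cell numbers across timepoints
#'
#' Randomly subsets each timepoint to exactly `n_per_timepoint` cells,
#' without replacement, deterministically for a given seed.
#'
#' @param sim a `dex_sim` object.
#' @param n_per_timepoint cells to retain per timepoint.
#' @param seed RNG seed.
#' @return the downsampled `dex_sim` object; cell order follows timepoint
#'   order.
#' @export
balance_downsample <- function(sim, n_per_timepoint = 400, seed = 1L) {
  tp <- sim$cell_meta$timepoint
  set.seed(seed)
  keep <- integer(0)
  for (t in unique(tp)) {
    idx <- which(tp == t)
    if (length(idx) < n_per_timepoint) {
      stop(sprintf("timepoint %s has only %d cells (< %d requested)",
                   t, length(idx), n_per_timepoint), call. = FALSE)
    }
    keep <- c(keep, sort(sample(idx, n_per_timepoint)))
  }
  subset_cells(sim, keep)
}

#' Log-normalize a count matrix
#'
#' Per cell, counts are scaled to a common library size and
#' log-transformed: `value = log1p(count / cell_total * scale)` (natural
#' log). Zeros map to zeros and the transform is monotone within a cell.
#'
#' @param sim a `dex_sim` object.
#' @param scale target library size (default 10,000).
#' @return An object of class `dex_norm`: list with `mat` (genes x cells),
#'   `scale`, `log_base` and `cell_meta`.
#' @export
normalize_log <- function(sim, scale = 10000) {
  totals <- colSums(sim$counts)
  if (any(totals == 0)) stop("all-zero cell; cannot normalize", call. = FALSE)
  mat <- log1p(sweep(sim$counts, 2L, totals, "/") * scale)
  structure(list(mat = mat, scale = scale, log_base = "e",
                 cell_meta = sim$cell_meta),
            class = "dex_norm")
}

#' @export
print.dex_norm <- function(x, ...) {
  cat(sprintf("Log-normalized matrix: %d genes x %d cells (scale %g, natural log)\n",
              nrow(x$mat), ncol(x$mat), x$scale))
  invisible(x)
}

#' Regress out cell-level covariates and scale
#'
#' Per gene, ordinary least squares of log-normalized expression on the
#' cell-level covariates (with intercept); residuals are standardized to
#' unit variance and clipped. This removes the impact of transcript counts,
#' mitochondrial percent and cell-cycle scores before PCA and correlation
#' analysis. Collinear covariate columns are dropped with a warning;
#' constant genes yield an all-zero row.
#'
#' @param norm a [normalize_log()] object.
#' @param covariates character vector of `cell_meta` columns, or a numeric
#'   matrix with one row per cell.
#' @param clip residual z-values are clipped to `c(-clip, clip)`.
#' @return An object of class `dex_scaled`: list with `mat` (genes x cells
#'   residual z-values), `clip` and `cell_meta`.
#' @export
regress_scale <- function(norm,
                          covariates = c("total_transcripts", "mito_fraction",
                                         "cell_cycle_score"),
                          clip = 10) {
  Y <- t(norm$mat)                    # cells x genes
  if (nrow(Y) < 2) stop("need at least 2 cells", call. = FALSE)
  X <- if (is.character(covariates)) {
    stopifnot(all(covariates %in% names(norm$cell_meta)))
    as.matrix(norm$cell_meta[, covariates, drop = FALSE])
  } else {
    as.matrix(covariates)
  }
  stopifnot(nrow(X) == nrow(Y))
  X <- cbind(`(Intercept)` = 1, X)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    drop <- setdiff(seq_len(ncol(X)), qx$pivot[seq_len(qx$rank)])
    warning(sprintf("dropping collinear covariate column(s): %s",
                    paste(colnames(X)[drop], collapse = ", ")))
    X <- X[, qx$pivot[seq_len(qx$rank)], drop = FALSE]
    qx <- qr(X)
  }
  res <- qr.resid(qx, Y)
  sds <- sqrt(colSums(res^2) / (nrow(res) - 1))
  z <- res
  nz <- sds > 1e-12
  z[, nz] <- sweep(res[, nz, drop = FALSE], 2L, sds[nz], "/")
  z[, !nz] <- 0
  z[z > clip] <- clip
  z[z < -clip] <- -clip
  structure(list(mat = t(z), clip = clip, cell_meta = norm$cell_meta),
            class = "dex_scaled")
}

#' Bulk-vs-single-cell detection by expression quintile
#'
#' Genes with positive bulk mean in the vehicle (EtOH) condition are ranked
#' by that mean and split into five equal-size bins (quintile 1 = highest
#' expression; ties broken by stable gene order). Per quintile, the
#' fraction of genes detected in the single-cell data (>= 1 count in >= 1
#' cell) is reported, along with summaries of the per-gene cell-detection
#' rate, plus the overall detected fraction.
#'
#' @param bulk a [simulate_bulk()] object, or a matrix of bulk counts with
#'   columns named `<timepoint>_rep<i>`.
#' @param sim a `dex_sim` object sharing gene identifiers with `bulk`.
#' @param etoh the vehicle condition label used for ranking.
#' @return list with `table` (data frame per quintile: n_genes,
#'   frac_detected, median/q1/q3 of per-gene detection rate) and
#'   `overall_detected_frac`.
#' @export
detection_quintiles <- function(bulk, sim, etoh = "0h") {
  bc <- if (inherits(bulk, "dex_bulk")) bulk$counts else bulk
  cond <- if (inherits(bulk, "dex_bulk")) bulk$condition
          else sub("_rep[0-9]+$", "", colnames(bc))
  shared <- intersect(rownames(bc), rownames(sim$counts))
  etoh_mean <- rowMeans(bc[shared, cond == etoh, drop = FALSE])
  expressed <- shared[etoh_mean > 0]
  if (length(expressed) < 5) stop("fewer than 5 bulk-detected genes", call. = FALSE)
  ord <- expressed[order(-etoh_mean[expressed])]    # stable: ties keep gene order
  n <- length(ord)
  sizes <- rep(n %/% 5L, 5L)
  sizes[seq_len(n %% 5L)] <- sizes[seq_len(n %% 5L)] + 1L
  quintile <- rep(1:5, times = sizes)

  det_rate <- rowMeans(sim$counts[ord, , drop = FALSE] > 0)
  detected <- det_rate > 0
  tab <- do.call(rbind, lapply(1:5, function(q) {
    i <- quintile == q
    data.frame(quintile = q, n_genes = sum(i),
               frac_detected = mean(detected[i]),
               median_det_rate = stats::median(det_rate[i]),
               q1_det_rate = unname(stats::quantile(det_rate[i], 0.25)),
               q3_det_rate = unname(stats::quantile(det_rate[i], 0.75)))
  }))
  list(table = tab, overall_detected_frac = mean(detected),
       gene_order = ord, quintile = quintile, detection_rate = det_rate)
}
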