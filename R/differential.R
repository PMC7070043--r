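#' Two-part (hurdle) differential expression test, all genes at once
#'
#' For each gene, compares cells in group B (treated) against group A
#' (vehicle) with a two-part model: a discrete component (detection
#' modelled on group, a binomial likelihood-ratio test equivalent to
#' logistic regression on the two-level factor) and a continuous component
#' (positive log-expression modelled as Gaussian with a group mean shift, a
#' likelihood-ratio test with pooled variance). The test statistic is the
#' sum of the two deviance drops, chi-square with df = 2 (df = 1 when a
#' group has fewer than 2 expressing cells and the continuous part is
#' dropped). The fold change is computed on the mean of `expm1(normalized)`
#' per group with a small pseudocount.
#'
#' @param norm a [normalize_log()] object.
#' @param cells_a,cells_b column indices (or names) of the two cell groups;
#'   A is the reference (vehicle) group.
#' @param genes genes to test; default all.
#' @return An object of class `dex_de`: data frame with one row per gene —
#'   gene, log2fc, detection_a, detection_b, lrt, df, p, direction,
#'   untestable.
#' @export
hurdle_test_all <- function(norm, cells_a, cells_b, genes = rownames(norm$mat)) {
  A <- norm$mat[genes, cells_a, drop = FALSE]
  B <- norm$mat[genes, cells_b, drop = FALSE]
  if (ncol(A) < 2 || ncol(B) < 2) stop("both groups need >= 2 cells", call. = FALSE)
  nA <- ncol(A); nB <- ncol(B)
  kA <- rowSums(A > 0); kB <- rowSums(B > 0)

  # discrete component: binomial LRT on detection
  binll <- function(k, n) {
    p <- k / n
    ifelse(k > 0, k * log(p), 0) + ifelse(n - k > 0, (n - k) * log(1 - p), 0)
  }
  lrt_d <- 2 * (binll(kA, nA) + binll(kB, nB) - binll(kA + kB, nA + nB))

  # continuous component: Gaussian LRT on positive values, pooled variance
  posA <- A > 0; posB <- B > 0
  sumA <- rowSums(A * posA); sumB <- rowSums(B * posB)
  sqA <- rowSums(A^2 * posA); sqB <- rowSums(B^2 * posB)
  mA <- ifelse(kA > 0, sumA / kA, 0)
  mB <- ifelse(kB > 0, sumB / kB, 0)
  rss1 <- (sqA - kA * mA^2) + (sqB - kB * mB^2)
  npos <- kA + kB
  mPool <- ifelse(npos > 0, (sumA + sumB) / npos, 0)
  rss0 <- (sqA + sqB) - npos * mPool^2
  cont_ok <- kA >= 2 & kB >= 2
  lrt_c <- numeric(length(genes))
  w <- cont_ok & rss1 > 0
  lrt_c[w] <- npos[w] * log(pmax(rss0[w], rss1[w]) / rss1[w])
  # identical positive values within each group but different between them
  sep <- cont_ok & rss1 <= 0 & rss0 > 1e-12
  lrt_c[sep] <- Inf

  df <- ifelse(cont_ok, 2L, 1L)
  lrt <- pmax(lrt_d, 0) + ifelse(cont_ok, lrt_c, 0)
  p <- stats::pchisq(lrt, df, lower.tail = FALSE)

  eps <- 1e-9
  meanA <- rowMeans(expm1(A)); meanB <- rowMeans(expm1(B))
  log2fc <- log2((meanB + eps) / (meanA + eps))
  untestable <- kA + kB == 0
  p[untestable] <- 1
  log2fc[untestable] <- 0

  structure(data.frame(
    gene = genes,
    log2fc = log2fc,
    detection_a = kA / nA,
    detection_b = kB / nB,
    n_a = nA, n_b = nB,
    lrt = lrt, df = df, p = p,
    direction = ifelse(log2fc >= 0, 1L, -1L),
    untestable = untestable,
    row.names = NULL, stringsAsFactors = FALSE
  ), class = c("dex_de", "data.frame"))
}

#' Hurdle test for a single gene
#'
#' @inheritParams hurdle_test_all
#' @param gene the gene to test.
#' @return a one-row `dex_de` data frame.
#' @export
hurdle_test <- function(norm, cells_a, cells_b, gene) {
  hurdle_test_all(norm, cells_a, cells_b, genes = gene)
}

#' Call differentially expressed genes for one comparison
#'
#' Applies the detection filter (genes detected in fewer than
#' `min_detection` of cells in both groups are excluded before testing),
#' Benjamini-Hochberg adjustment across the tested genes, and the
#' fold-change and adjusted-p cutoffs. A fold change exactly at the cutoff
#' is retained.
#'
#' @param results a `dex_de` data frame from one timepoint-vs-vehicle
#'   comparison.
#' @param fc_cutoff minimum absolute fold change (linear scale).
#' @param alpha adjusted p-value cutoff (strict `<`).
#' @param min_detection minimum detection fraction.
#' @param detection_scope `"either"`: the filter passes if detection is
#'   >= `min_detection` in at least one group; `"pooled"`: in the pooled
#'   detection fraction.
#' @return list with `degs` (character vector), `table` (tested genes with
#'   `padj` and `deg` columns) and `n_tested`.
#' @export
call_degs <- function(results, fc_cutoff = 1.25, alpha = 0.01,
                      min_detection = 0.10,
                      detection_scope = c("either", "pooled")) {
  detection_scope <- match.arg(detection_scope)
  if (nrow(results) == 0) {
    return(list(degs = character(0), table = results, n_tested = 0L))
  }
  pass <- if (detection_scope == "either") {
    results$detection_a >= min_detection | results$detection_b >= min_detection
  } else {
    (results$detection_a * results$n_a + results$detection_b * results$n_b) /
      (results$n_a + results$n_b) >= min_detection
  }
  tested <- results[pass & !results$untestable, , drop = FALSE]
  if (nrow(tested) == 0) {
    return(list(degs = character(0), table = tested, n_tested = 0L))
  }
  tested$padj <- stats::p.adjust(tested$p, method = "BH")
  tested$deg <- abs(tested$log2fc) >= log2(fc_cutoff) & tested$padj < alpha
  list(degs = tested$gene[tested$deg], table = tested,
       n_tested = nrow(tested))
}

#' Run the per-timepoint DE analysis against the vehicle condition
#'
#' @param norm a [normalize_log()] object whose `cell_meta` carries the
#'   `timepoint` column.
#' @param etoh vehicle condition label.
#' @param ... passed to [call_degs()].
#' @return named list (per treated timepoint) of [call_degs()] results.
#' @export
de_by_timepoint <- function(norm, etoh = "0h", ...) {
  tp <- norm$cell_meta$timepoint
  treated <- setdiff(unique(tp), etoh)
  cells_a <- which(tp == etoh)
  out <- lapply(treated, function(t) {
    res <- hurdle_test_all(norm, cells_a, which(tp == t))
    call_degs(res, ...)
  })
  names(out) <- treated
  out
}

#' Merge per-timepoint DEG lists into a superset
#'
#' The union of the per-timepoint DEG lists, with provenance (which
#' timepoints called each gene) and a consensus direction taken from the
#' timepoint with the largest absolute log fold change.
#'
#' @param per_timepoint named list of [call_degs()] results (or of
#'   character vectors, in which case directions are unavailable).
#' @return An object of class `dex_superset`: data frame with gene,
#'   direction, n_timepoints, timepoints (comma-separated), max_abs_log2fc.
#' @export
merge_supersets <- function(per_timepoint) {
  rows <- list()
  for (t in names(per_timepoint)) {
    x <- per_timepoint[[t]]
    if (is.character(x)) {
      rows[[t]] <- data.frame(gene = x, timepoint = rep(t, length(x)),
                              log2fc = rep(NA_real_, length(x)),
                              direction = rep(NA_integer_, length(x)),
                              stringsAsFactors = FALSE)
    } else {
      tab <- x$table[x$table$deg, , drop = FALSE]
      rows[[t]] <- data.frame(gene = tab$gene,
                              timepoint = rep(t, nrow(tab)),
                              log2fc = tab$log2fc, direction = tab$direction,
                              stringsAsFactors = FALSE)
    }
  }
  all <- do.call(rbind, rows)
  if (is.null(all) || nrow(all) == 0) {
    return(structure(data.frame(gene = character(0), direction = integer(0),
                                n_timepoints = integer(0),
                                timepoints = character(0),
                                max_abs_log2fc = numeric(0)),
                     class = c("dex_superset", "data.frame")))
  }
  genes <- unique(all$gene)
  out <- do.call(rbind, lapply(genes, function(g) {
    sub <- all[all$gene == g, , drop = FALSE]
    best <- if (all(is.na(sub$log2fc))) 1L else which.max(abs(sub$log2fc))
    data.frame(gene = g,
               direction = sub$direction[best],
               n_timepoints = nrow(sub),
               timepoints = paste(sub$timepoint, collapse = ","),
               max_abs_log2fc = if (all(is.na(sub$log2fc))) NA_real_
                                else max(abs(sub$log2fc)),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  structure(out, class = c("dex_superset", "data.frame"))
}

#' Overlap of two gene sets (Venn counts)
#'
#' @param set_a,set_b character vectors (or `dex_superset` objects).
#' @return list with `shared`, `unique_a`, `unique_b` counts and the
#'   corresponding gene vectors.
#' @export
deg_overlap <- function(set_a, set_b) {
  a <- if (is.data.frame(set_a)) set_a$gene else set_a
  b <- if (is.data.frame(set_b)) set_b$gene else set_b
  a <- unique(a); b <- unique(b)
  list(shared = length(intersect(a, b)),
       unique_a = length(setdiff(a, b)),
       unique_b = length(setdiff(b, a)),
       shared_genes = intersect(a, b),
       unique_a_genes = setdiff(a, b),
       unique_b_genes = setdiff(b, a))
}

#' Classify genes by the number of proximal peaks
#'
#' A peak is proximal to a gene when the minimum distance from the gene's
#' TSS point to the peak interval is at most `window` bp (distance 0 if the
#' TSS falls inside the peak; the boundary is inclusive). Peaks are 0-based
#' half-open intervals (BED convention). Classification is strand
#' independent: class 0, 1 or 2+ proximal peaks.
#'
#' @param tss data frame with columns `chrom`, `pos`, `gene_id`.
#' @param peaks data frame with columns `chrom`, `start`, `end`.
#' @param window proximity window in bp.
#' @return named integer vector per gene: 0, 1 or 2 (meaning 2+).
#' @export
peak_proximity <- function(tss, peaks, window = 50000) {
  if (nrow(peaks) > 0 && any(peaks$end <= peaks$start)) {
    stop("malformed peak interval: end <= start", call. = FALSE)
  }
  out <- integer(nrow(tss))
  names(out) <- tss$gene_id
  for (ch in unique(tss$chrom)) {
    gi <- which(tss$chrom == ch)
    pk <- peaks[peaks$chrom == ch, , drop = FALSE]
    if (nrow(pk) == 0) { out[gi] <- 0L; next }
    starts <- sort(pk$start)
    lasts <- sort(pk$end - 1L)           # last covered base
    pos <- tss$pos[gi]
    # proximal iff start <= pos + window AND last >= pos - window
    n_left_ok <- findInterval(pos + window, starts)
    n_gone <- findInterval(pos - window - 1L, lasts)
    cnt <- n_left_ok - n_gone
    out[gi] <- pmin(pmax(cnt, 0L), 2L)
  }
  out
}
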