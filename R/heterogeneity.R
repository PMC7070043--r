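#' Vehicle-condition baseline statistics per responsive gene
#'
#' For each gene of interest, computes the mean and sample standard
#' deviation (n - 1 denominator) of log-normalized expression over
#' vehicle-treated (EtOH) cells in which the gene was detected: undetected
#' zero values are excluded so that the baseline is not underestimated
#' (which would overestimate the hormone response). Genes expressed in
#' fewer than 2 vehicle cells are flagged degenerate and carry
#' mean = SD = 0, so genes never seen at baseline can still be called
#' responsive once induced.
#'
#' @param norm a [normalize_log()] object.
#' @param etoh_cells column indices or names of the vehicle cells (>= 2).
#' @param degs genes to characterize.
#' @return data frame: gene, mean, sd, n_expressing, degenerate.
#' @export
baseline_stats <- function(norm, etoh_cells, degs) {
  if (length(etoh_cells) < 2) stop("need >= 2 vehicle cells", call. = FALSE)
  missing <- setdiff(degs, rownames(norm$mat))
  if (length(missing)) {
    stop(sprintf("gene(s) not in matrix: %s",
                 paste(utils::head(missing, 5), collapse = ", ")), call. = FALSE)
  }
  E <- norm$mat[degs, etoh_cells, drop = FALSE]
  pos <- E > 0
  n_exp <- rowSums(pos)
  s <- rowSums(E * pos)
  m <- ifelse(n_exp > 0, s / n_exp, 0)
  ss <- rowSums(E^2 * pos) - n_exp * m^2
  sdv <- ifelse(n_exp >= 2, sqrt(pmax(ss, 0) / (n_exp - 1)), 0)
  degenerate <- n_exp < 2
  m[degenerate] <- 0
  sdv[degenerate] <- 0
  data.frame(gene = degs, mean = m, sd = sdv, n_expressing = n_exp,
             degenerate = degenerate, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Call per-cell responder status for every responsive gene
#'
#' A cell responds at an induced gene when its log-normalized expression is
#' strictly greater than one SD above the vehicle baseline mean; at a
#' repressed gene, strictly more than one SD below it. Undetected values
#' are evaluated at 0, so an undetected induced gene never responds, while
#' an undetected repressed gene responds whenever `mean - sd > 0`. For
#' genes with a degenerate baseline (mean = SD = 0), an induced gene
#' responds whenever it is expressed at all.
#'
#' @param norm a [normalize_log()] object.
#' @param baseline a [baseline_stats()] data frame.
#' @param directions named integer vector (+1 induced / -1 repressed) per
#'   gene, e.g. from a [merge_supersets()] object.
#' @param cells cells to evaluate (default all, vehicle included so the
#'   baseline false-call rate is observable).
#' @return An object of class `dex_responders`: logical gene x cell matrix
#'   with the per-gene `direction` attached as an attribute.
#' @export
call_responders <- function(norm, baseline, directions,
                            cells = colnames(norm$mat)) {
  genes <- baseline$gene
  if (!all(genes %in% names(directions))) {
    stop("unknown direction for some gene(s)", call. = FALSE)
  }
  dirv <- directions[genes]
  if (!all(dirv %in% c(-1L, 1L))) stop("directions must be +1 or -1", call. = FALSE)
  V <- norm$mat[genes, cells, drop = FALSE]
  up <- dirv == 1L
  thr_up <- baseline$mean + baseline$sd
  thr_dn <- baseline$mean - baseline$sd
  resp <- matrix(FALSE, nrow(V), ncol(V), dimnames = dimnames(V))
  resp[up, ] <- V[up, , drop = FALSE] > thr_up[up]
  resp[!up, ] <- V[!up, , drop = FALSE] < thr_dn[!up]
  structure(resp, direction = dirv, class = c("dex_responders", "matrix"))
}

#' Ratio of Responding Genes (RRG) per cell
#'
#' The per-cell fraction of the full responsive-gene superset at which the
#' cell passes the SD threshold. The denominator is the superset size for
#' every cell (optionally, only the genes detected in that cell). Vehicle
#' cells are included: their nonzero RRG measures the baseline
#' false-call rate implied by thresholding at one SD.
#'
#' @param resp a [call_responders()] matrix.
#' @param cell_meta data frame with `cell` and `timepoint` columns matching
#'   the matrix columns (optional; adds the timepoint to the output).
#' @param denominator `"superset"` (fixed, default) or `"detected"`
#'   (per-cell detected genes only, requires `norm`).
#' @param norm the [normalize_log()] object (only for
#'   `denominator = "detected"`).
#' @return data frame: cell, timepoint (if available), rrg.
#' @export
rrg <- function(resp, cell_meta = NULL,
                denominator = c("superset", "detected"), norm = NULL) {
  denominator <- match.arg(denominator)
  if (nrow(resp) == 0) stop("empty responsive-gene set", call. = FALSE)
  if (denominator == "superset") {
    v <- colMeans(resp)
  } else {
    stopifnot(!is.null(norm))
    det <- norm$mat[rownames(resp), colnames(resp), drop = FALSE] > 0
    nd <- colSums(det)
    v <- ifelse(nd > 0, colSums(resp & det) / nd, 0)
  }
  out <- data.frame(cell = colnames(resp), rrg = unname(v),
                    stringsAsFactors = FALSE)
  if (!is.null(cell_meta)) {
    out$timepoint <- cell_meta$timepoint[match(out$cell, cell_meta$cell)]
    out <- out[, c("cell", "timepoint", "rrg")]
  }
  out
}

#' Responding-cell percentage (RC%) per gene and timepoint
#'
#' Per (gene, timepoint), the fraction of that timepoint's cells passing
#' the SD threshold. Genes undetected at a timepoint can yield 0%. By
#' construction, the mean RC% over genes at a timepoint equals the mean RRG
#' over that timepoint's cells: both are means of the same indicator
#' matrix.
#'
#' @param resp a [call_responders()] matrix.
#' @param cell_meta data frame with `cell` and `timepoint` for each column.
#' @return data frame: gene, timepoint, rc_pct (fraction in `[0, 1]`).
#' @export
rc_pct <- function(resp, cell_meta) {
  tp <- cell_meta$timepoint[match(colnames(resp), cell_meta$cell)]
  out <- do.call(rbind, lapply(unique(tp), function(t) {
    data.frame(gene = rownames(resp), timepoint = t,
               rc_pct = rowMeans(resp[, tp == t, drop = FALSE]),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
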