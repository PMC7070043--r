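#' Draw the generative ground truth for a simulation
#'
#' Samples per-gene baselines, dispersions, responsiveness flags, directions,
#' kinetic classes and fold changes, plus the per-timepoint responder
#' probabilities. The result is the ground truth against which downstream
#' recovery is tested.
#'
#' Kinetic classes modulate when a responsive gene's fold change reaches full
#' size across the time course: "early" genes are at full effect from 1 h,
#' "progressive" genes ramp linearly in log-time, and "late" genes reach half
#' effect at 4 h and full effect from 8 h.
#'
#' @param config a [sim_config()] object.
#' @return An object of class `dex_truth`: a list with `genes` (data frame:
#'   gene_id, mu, phi, is_deg, direction, kinetic, fold_change), `timepoints`
#'   (data frame: timepoint, hours, responder_prob) and the config.
#' @export
build_truth <- function(config) {
  validate_config(config)
  set.seed(config$seed)
  n <- config$n_genes
  n_deg <- round(n * config$frac_deg)
  n_down <- round(n_deg * config$frac_down)

  gene_id <- sprintf("g%05d", seq_len(n))
  mu <- 10^stats::runif(n, config$baseline_logmean_range[1],
                        config$baseline_logmean_range[2])
  phi <- stats::runif(n, config$nb_dispersion_range[1],
                      config$nb_dispersion_range[2])
  is_deg <- rep(FALSE, n)
  is_deg[sample.int(n, n_deg)] <- TRUE
  direction <- rep(1L, n)
  deg_idx <- which(is_deg)
  if (n_down > 0) direction[sample(deg_idx, n_down)] <- -1L
  kinetic <- rep(NA_character_, n)
  kinetic[deg_idx] <- sample(c("early", "progressive", "late"),
                             n_deg, replace = TRUE)
  fold_change <- rep(1, n)
  # right-skewed on the log scale: most effects sit near the minimum, with
  # a thin tail reaching the strongest inductions, as hormone-response
  # fold-change distributions do
  fr <- log10(config$fold_change_range)
  fold_change[deg_idx] <- 10^(fr[1] + (fr[2] - fr[1]) *
                                stats::rbeta(n_deg, 1, 3))

  structure(list(
    genes = data.frame(gene_id = gene_id, mu = mu, phi = phi,
                       is_deg = is_deg, direction = direction,
                       kinetic = kinetic, fold_change = fold_change,
                       stringsAsFactors = FALSE),
    timepoints = data.frame(timepoint = config$timepoints,
                            hours = config$time_hours,
                            responder_prob = config$responder_prob,
                            stringsAsFactors = FALSE),
    config = config
  ), class = "dex_truth")
}

#' @export
print.dex_truth <- function(x, ...) {
  cat(sprintf("Simulation truth: %d genes (%d responsive, %d repressed)\n",
              nrow(x$genes), sum(x$genes$is_deg),
              sum(x$genes$is_deg & x$genes$direction < 0)))
  print(x$timepoints)
  invisible(x)
}

# fraction of the full (log-scale) effect realized at `hours` for each class
kinetic_fraction <- function(kinetic, hours, max_hours) {
  frac <- numeric(length(kinetic))
  early <- !is.na(kinetic) & kinetic == "early"
  prog <- !is.na(kinetic) & kinetic == "progressive"
  late <- !is.na(kinetic) & kinetic == "late"
  frac[early] <- as.numeric(hours >= 1)
  frac[prog] <- log1p(hours) / log1p(max_hours)
  frac[late] <- if (hours >= 8) 1 else if (hours >= 4) 0.5 else 0
  frac
}

#' Simulate a single-cell UMI count matrix with responder structure
#'
#' For each cell at timepoint t and each responsive gene g, a responder
#' indicator is drawn Bernoulli(p_t); responders have their negative-binomial
#' mean multiplied by the gene's effective fold change (divided, for
#' repressed genes). Counts are drawn NB(mean, phi) and then zeroed by an
#' expression-dependent logistic dropout applied to the underlying mean,
#' reproducing the detection-vs-expression bias of shallow single-cell data.
#'
#' @param truth a [build_truth()] object.
#' @param config the matching [sim_config()]; defaults to the one stored in
#'   `truth`.
#' @param cells_per_timepoint optional override of the configured number of
#'   cells per timepoint (e.g. to simulate a pre-QC excess of cells).
#' @return An object of class `dex_sim`: list with `counts` (integer genes x
#'   cells matrix), `cell_meta` (data frame: cell, timepoint,
#'   total_transcripts, mito_fraction, cell_cycle_score), `responders`
#'   (logical DEG x cells ground-truth matrix) and `truth`.
#' @export
simulate_counts <- function(truth, config = truth$config,
                            cells_per_timepoint = config$cells_per_timepoint) {
  stopifnot(inherits(truth, "dex_truth"))
  set.seed(config$seed + 1L)
  g <- truth$genes
  tp <- truth$timepoints
  n_genes <- nrow(g)
  n_tp <- nrow(tp)
  n_cells <- n_tp * cells_per_timepoint
  max_hours <- max(tp$hours)

  cell_tp <- rep(tp$timepoint, each = cells_per_timepoint)
  cell_id <- sprintf("c_%s_%03d", cell_tp,
                     rep(seq_len(cells_per_timepoint), times = n_tp))
  lib <- exp(stats::rnorm(n_cells, 0, config$libsize_sd))
  mito <- stats::rbeta(n_cells, config$mito_beta[1], config$mito_beta[2])
  cc_score <- stats::rnorm(n_cells, 0, 1)

  deg_idx <- which(g$is_deg)
  counts <- matrix(0L, n_genes, n_cells,
                   dimnames = list(g$gene_id, cell_id))
  responders <- matrix(FALSE, length(deg_idx), n_cells,
                       dimnames = list(g$gene_id[deg_idx], cell_id))

  for (ti in seq_len(n_tp)) {
    cols <- which(cell_tp == tp$timepoint[ti])
    p_t <- tp$responder_prob[ti]
    kf <- kinetic_fraction(g$kinetic, tp$hours[ti], max_hours)
    # effective multiplicative effect for a responder at this timepoint
    eff <- g$fold_change^(kf * g$direction)
    eff[!g$is_deg] <- 1

    if (length(deg_idx)) {
      resp <- if (config$responder_mode == "shared") {
        matrix(rep(stats::rbinom(length(cols), 1L, p_t) == 1L,
                   each = length(deg_idx)),
               nrow = length(deg_idx))
      } else {
        matrix(stats::rbinom(length(deg_idx) * length(cols), 1L, p_t) == 1L,
               nrow = length(deg_idx))
      }
      responders[, cols] <- resp
    }

    mu_mat <- outer(g$mu, lib[cols])       # genes x cells baseline means
    if (length(deg_idx)) {
      fac <- matrix(1, length(deg_idx), length(cols))
      fac[responders[, cols, drop = FALSE]] <-
        rep(eff[deg_idx], length(cols))[as.vector(responders[, cols, drop = FALSE])]
      mu_mat[deg_idx, ] <- mu_mat[deg_idx, , drop = FALSE] * fac
    }
    cnt <- stats::rnbinom(length(mu_mat), size = rep(1 / g$phi, length(cols)),
                          mu = as.vector(mu_mat))
    p_det <- stats::plogis(config$dropout_slope *
                             (log10(as.vector(mu_mat)) - config$dropout_midpoint))
    cnt[stats::runif(length(cnt)) > p_det] <- 0
    counts[, cols] <- as.integer(cnt)
  }

  cell_meta <- data.frame(
    cell = cell_id,
    timepoint = cell_tp,
    total_transcripts = colSums(counts),
    mito_fraction = mito,
    cell_cycle_score = cc_score,
    stringsAsFactors = FALSE
  )
  structure(list(counts = counts, cell_meta = cell_meta,
                 responders = responders, truth = truth),
            class = "dex_sim")
}

#' @export
print.dex_sim <- function(x, ...) {
  cat(sprintf("Simulated count matrix: %d genes x %d cells (%s)\n",
              nrow(x$counts), ncol(x$counts),
              paste(unique(x$cell_meta$timepoint), collapse = ", ")))
  cat(sprintf("  median transcripts/cell: %d; median genes/cell: %d\n",
              as.integer(stats::median(x$cell_meta$total_transcripts)),
              as.integer(stats::median(colSums(x$counts > 0)))))
  invisible(x)
}

#' Simulate bulk RNA-seq replicate counts
#'
#' Bulk expression at timepoint t is the population mixture of responding
#' and non-responding cells, so the per-condition mean is
#' `mu_g * (1 + p_t * (f_eff^direction - 1))`. Replicates are drawn
#' negative-binomially around that mean.
#'
#' @param truth a [build_truth()] object.
#' @param n_reps replicates per condition (>= 2).
#' @param depth multiplicative sequencing-depth factor applied to all bulk
#'   means, so bulk counts are much larger than per-cell UMI counts.
#' @param config the matching config.
#' @return An object of class `dex_bulk`: list with `counts` (genes x
#'   condition:replicate matrix), `condition` (per-column timepoint labels)
#'   and `means` (genes x timepoint expected-mean matrix).
#' @export
simulate_bulk <- function(truth, n_reps = 3, depth = 100,
                          config = truth$config) {
  stopifnot(inherits(truth, "dex_truth"))
  if (n_reps < 2) stop("n_reps must be >= 2", call. = FALSE)
  set.seed(config$seed + 2L)
  g <- truth$genes
  tp <- truth$timepoints
  max_hours <- max(tp$hours)

  means <- vapply(seq_len(nrow(tp)), function(ti) {
    kf <- kinetic_fraction(g$kinetic, tp$hours[ti], max_hours)
    eff <- g$fold_change^(kf * g$direction)
    eff[!g$is_deg] <- 1
    depth * g$mu * (1 + tp$responder_prob[ti] * (eff - 1))
  }, numeric(nrow(g)))
  means <- matrix(means, nrow = nrow(g))
  dimnames(means) <- list(g$gene_id, tp$timepoint)

  cols <- paste(rep(tp$timepoint, each = n_reps),
                rep(seq_len(n_reps), times = nrow(tp)), sep = "_rep")
  mu_rep <- means[, rep(seq_len(ncol(means)), each = n_reps), drop = FALSE]
  counts <- matrix(stats::rnbinom(length(mu_rep),
                                  size = rep(1 / g$phi, ncol(mu_rep)),
                                  mu = as.vector(mu_rep)),
                   nrow = nrow(g), dimnames = list(g$gene_id, cols))
  structure(list(counts = counts,
                 condition = rep(tp$timepoint, each = n_reps),
                 means = means),
            class = "dex_bulk")
}

#' Simulate synthetic TSS annotations and binding-site peaks
#'
#' Places gene TSSs on synthetic chromosomes far enough apart that windows
#' never overlap between genes, then places peaks so that the number of
#' peaks within `window` bp of each TSS equals the requested class
#' (0, 1 or 2+). Some class-0 genes receive a decoy peak just beyond the
#' window and some class-1 peaks sit exactly at the window boundary, so the
#' inclusive <= window rule is exercised.
#'
#' @param truth a [build_truth()] object (supplies the gene universe).
#' @param classes integer vector (values 0, 1, 2) per gene: the target
#'   proximal-peak class, 2 meaning "2 or more". Default samples classes.
#' @param window proximity window in bp.
#' @param config the matching config.
#' @return list with `tss` (data frame: chrom, pos, strand, gene_id),
#'   `peaks` (data frame: chrom, start, end; 0-based half-open) and
#'   `classes` (named integer vector of target classes).
#' @export
simulate_features <- function(truth, classes = NULL, window = 50000L,
                              config = truth$config) {
  stopifnot(inherits(truth, "dex_truth"))
  set.seed(config$seed + 4L)
  g <- truth$genes
  n <- nrow(g)
  if (is.null(classes)) {
    classes <- sample(0:2, n, replace = TRUE, prob = c(0.25, 0.3, 0.45))
  }
  stopifnot(length(classes) == n, all(classes %in% 0:2))
  names(classes) <- g$gene_id

  spacing <- 2L * window + 100000L
  chrom <- paste0("chrS", 1 + (seq_len(n) - 1) %% 4)
  pos <- window + 10000L + spacing * ((seq_len(n) - 1) %/% 4)
  strand <- sample(c("+", "-"), n, replace = TRUE)
  tss <- data.frame(chrom = chrom, pos = pos, strand = strand,
                    gene_id = g$gene_id, stringsAsFactors = FALSE)

  peak_list <- vector("list", n)
  width <- 300L
  for (i in seq_len(n)) {
    k <- classes[i]
    ps <- integer(0)
    if (k >= 1) {
      # one peak whose nearest edge is at a random distance <= window;
      # occasionally exactly at the boundary
      d1 <- if (stats::runif(1) < 0.1) window else sample.int(window, 1L) - 1L
      ps <- c(ps, pos[i] + d1)
      if (k >= 2) {
        extra <- 1L + stats::rbinom(1, 1, 0.5)
        for (e in seq_len(extra)) {
          de <- sample.int(window - width, 1L) - 1L
          ps <- c(ps, pos[i] - de - width)  # upstream, fully inside window
        }
      }
    } else if (stats::runif(1) < 0.5) {
      # decoy just beyond the window (nearest edge at window + 1 .. window + 20kb)
      ps <- pos[i] + window + sample.int(20000L, 1L)
    }
    if (length(ps)) {
      peak_list[[i]] <- data.frame(chrom = chrom[i], start = ps,
                                   end = ps + width, stringsAsFactors = FALSE)
    }
  }
  peaks <- do.call(rbind, peak_list[!vapply(peak_list, is.null, logical(1))])
  if (is.null(peaks)) {
    peaks <- data.frame(chrom = character(0), start = integer(0),
                        end = integer(0), stringsAsFactors = FALSE)
  }
  rownames(peaks) <- NULL
  list(tss = tss, peaks = peaks, classes = classes)
}
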