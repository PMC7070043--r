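#' Simulation configuration
#'
#' Builds and validates the configuration object that parameterizes every
#' generator in the package. The defaults emulate the design of a
#' dexamethasone (Dex) treatment time course in a hormone-responsive breast
#' cancer line: six treatment conditions (vehicle/EtOH "0h" plus 1, 2, 4, 8
#' and 18 h of 100 nM Dex), 400 cells per condition, baseline expression
#' spanning roughly five orders of magnitude with expression-dependent
#' dropout, and a subset of Dex-responsive genes whose per-cell response is
#' stochastic.
#'
#' @param n_genes number of genes to simulate.
#' @param frac_deg fraction of genes that are hormone-responsive (DEGs).
#' @param frac_down fraction of the DEGs that are repressed rather than
#'   induced.
#' @param timepoints ordered character labels of the treatment conditions;
#'   the vehicle condition `"0h"` must be present and first.
#' @param time_hours numeric treatment duration (hours) for each timepoint;
#'   drives the kinetic-class effect schedule.
#' @param cells_per_timepoint cells simulated per timepoint.
#' @param responder_prob per-timepoint probability that a given cell mounts a
#'   response at a given DEG; the vehicle entry must be 0.
#' @param responder_mode `"independent"` draws one Bernoulli indicator per
#'   (gene, cell); `"shared"` draws one indicator per cell applied to every
#'   DEG, giving co-ordinated (correlated) responses.
#' @param fold_change_range multiplicative effect range for responders;
#'   minimum must exceed 1. Fold changes are drawn right-skewed on the log
#'   scale (a Beta(1, 3)-distributed fraction of the log range), so most
#'   responsive genes have modest effects while a thin tail reaches the
#'   strongest inductions, with the default upper bound of 40 admitting
#'   FKBP5-like genes.
#' @param baseline_logmean_range range of log10 baseline mean counts per
#'   cell.
#' @param nb_dispersion_range range of the per-gene negative-binomial
#'   dispersion (`phi`, variance `mu + phi * mu^2`).
#' @param dropout_midpoint,dropout_slope logistic detection model: a count is
#'   retained with probability `plogis(dropout_slope * (log10(mu) -
#'   dropout_midpoint))` where `mu` is the underlying per-cell mean.
#' @param mito_beta shape parameters of the Beta distribution for per-cell
#'   mitochondrial fraction; the default puts a tail above the 5% QC cutoff.
#' @param libsize_sd standard deviation (natural-log scale) of the
#'   log-normal per-cell library-size factor.
#' @param seed integer seed; every generator is a pure function of
#'   (config, seed).
#'
#' @return An object of class `dex_config` (a validated list).
#' @export
#' @examples
#' cfg <- sim_config(n_genes = 200, cells_per_timepoint = 50)
#' cfg$timepoints
sim_config <- function(n_genes = 2000,
                       frac_deg = 0.05,
                       frac_down = 0.25,
                       timepoints = c("0h", "1h", "2h", "4h", "8h", "18h"),
                       time_hours = c(0, 1, 2, 4, 8, 18),
                       cells_per_timepoint = 400,
                       responder_prob = c(0, 0.12, 0.18, 0.22, 0.26, 0.30),
                       responder_mode = c("independent", "shared"),
                       fold_change_range = c(1.5, 40),
                       baseline_logmean_range = c(-2.5, 2.5),
                       nb_dispersion_range = c(0.3, 2),
                       dropout_midpoint = -0.5,
                       dropout_slope = 1.5,
                       mito_beta = c(2, 70),
                       libsize_sd = 0.3,
                       seed = 1L) {
  responder_mode <- match.arg(responder_mode)
  cfg <- list(
    n_genes = as.integer(n_genes),
    frac_deg = frac_deg,
    frac_down = frac_down,
    timepoints = as.character(timepoints),
    time_hours = as.numeric(time_hours),
    cells_per_timepoint = as.integer(cells_per_timepoint),
    responder_prob = as.numeric(responder_prob),
    responder_mode = responder_mode,
    fold_change_range = as.numeric(fold_change_range),
    baseline_logmean_range = as.numeric(baseline_logmean_range),
    nb_dispersion_range = as.numeric(nb_dispersion_range),
    dropout_midpoint = dropout_midpoint,
    dropout_slope = dropout_slope,
    mito_beta = as.numeric(mito_beta),
    libsize_sd = libsize_sd,
    seed = as.integer(seed)
  )
  validate_config(cfg)
  structure(cfg, class = "dex_config")
}

validate_config <- function(cfg) {
  chk_frac <- function(x, nm) {
    if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
      stop(sprintf("configuration error: '%s' must lie in [0, 1]", nm),
           call. = FALSE)
    }
  }
  if (cfg$n_genes < 1) stop("configuration error: n_genes must be >= 1", call. = FALSE)
  chk_frac(cfg$frac_deg, "frac_deg")
  chk_frac(cfg$frac_down, "frac_down")
  chk_frac(cfg$responder_prob, "responder_prob")
  if (length(cfg$timepoints) < 1 || cfg$timepoints[1] != "0h") {
    stop("configuration error: timepoint \"0h\" must be present and first",
         call. = FALSE)
  }
  if (anyDuplicated(cfg$timepoints)) {
    stop("configuration error: duplicated timepoint labels", call. = FALSE)
  }
  nt <- length(cfg$timepoints)
  if (length(cfg$time_hours) != nt || length(cfg$responder_prob) != nt) {
    stop("configuration error: time_hours and responder_prob must match timepoints",
         call. = FALSE)
  }
  if (cfg$responder_prob[1] != 0) {
    stop("configuration error: responder probability at \"0h\" must be 0",
         call. = FALSE)
  }
  if (cfg$fold_change_range[1] <= 1 || diff(cfg$fold_change_range) < 0) {
    stop("configuration error: fold_change_range minimum must exceed 1",
         call. = FALSE)
  }
  if (cfg$libsize_sd < 0) stop("configuration error: libsize_sd must be >= 0", call. = FALSE)
  if (any(cfg$mito_beta <= 0)) stop("configuration error: mito_beta shapes must be > 0", call. = FALSE)
  invisible(cfg)
}

#' @export
print.dex_config <- function(x, ...) {
  cat("Simulation configuration\n")
  cat(sprintf("  genes: %d (%.0f%% responsive, %.0f%% of those repressed)\n",
              x$n_genes, 100 * x$frac_deg, 100 * x$frac_down))
  cat(sprintf("  timepoints: %s (%d cells each)\n",
              paste(x$timepoints, collapse = ", "), x$cells_per_timepoint))
  cat(sprintf("  responder probabilities: %s (%s)\n",
              paste(format(x$responder_prob), collapse = ", "), x$responder_mode))
  cat(sprintf("  fold change range: %.2g-%.2g; baseline log10 mean range: %g..%g\n",
              x$fold_change_range[1], x$fold_change_range[2],
              x$baseline_logmean_range[1], x$baseline_logmean_range[2]))
  invisible(x)
}
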