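#' Run the full single-cell heterogeneity analysis on simulated data
#'
#' Convenience driver wiring the stages together the way the study design
#' prescribes: simulate counts (optionally with a pre-QC excess of cells),
#' remove cells above the mitochondrial cutoff, balance timepoints by
#' random downsampling, log-normalize, regress out cell-level covariates,
#' call differentially expressed genes per timepoint with the hurdle test,
#' merge them into a superset with consensus directions, compute the
#' vehicle baseline with zero-exclusion, call per-cell responders, and
#' derive RRG and RC%.
#'
#' @param config a [sim_config()] object.
#' @param raw_cells_per_timepoint cells to simulate before QC; defaults to
#'   25% more than the configured analysis size so the mito filter and the
#'   balanced downsampling are both exercised.
#' @param seed seed for the downsampling step.
#' @return list with the intermediate and final objects: `sim`, `norm`,
#'   `scaled`, `de`, `superset`, `baseline`, `responders`, `rrg_table`,
#'   `rc_table`.
#' @export
run_dex_pipeline <- function(config = sim_config(),
                             raw_cells_per_timepoint =
                               ceiling(config$cells_per_timepoint * 1.25),
                             seed = config$seed) {
  truth <- build_truth(config)
  sim <- simulate_counts(truth, config,
                         cells_per_timepoint = raw_cells_per_timepoint)
  sim <- qc_filter(sim)
  sim <- balance_downsample(sim, config$cells_per_timepoint, seed = seed)
  norm <- normalize_log(sim)
  scaled <- regress_scale(norm)

  de <- de_by_timepoint(norm, etoh = config$timepoints[1])
  superset <- merge_supersets(de)

  out <- list(truth = truth, sim = sim, norm = norm, scaled = scaled,
              de = de, superset = superset)
  if (nrow(superset) > 0) {
    etoh_cells <- which(sim$cell_meta$timepoint == config$timepoints[1])
    baseline <- baseline_stats(norm, etoh_cells, superset$gene)
    dirs <- stats::setNames(superset$direction, superset$gene)
    resp <- call_responders(norm, baseline, dirs)
    out$baseline <- baseline
    out$responders <- resp
    out$rrg_table <- rrg(resp, sim$cell_meta)
    out$rc_table <- rc_pct(resp, sim$cell_meta)
  }
  out
}
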