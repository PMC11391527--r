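# Orchestration: run whole analyses and write data-first outputs (CSV/JSON).
# Figures are optional; every artefact is reproducible from the written data
# plus the manifest (which records inputs, seed and package version).

# Internal: write the run manifest next to a command's outputs.
write_manifest <- function(out_dir, subcommand, config, lifetable, seed = NA) {
  manifest <- list(
    subcommand = subcommand,
    config = if (is.character(config)) config else "(inline)",
    lifetable = if (is.character(lifetable)) lifetable else "(inline)",
    seed = seed,
    package_version = as.character(utils::packageVersion("hipcea")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

# Internal: resolve config / life-table arguments that may be paths or objects.
resolve_inputs <- function(config, lifetable) {
  params <- if (inherits(config, "cea_params")) config else load_params(config)
  table <- if (inherits(lifetable, "life_table")) {
    lifetable
  } else if (is.null(lifetable)) {
    example_lifetable()
  } else {
    read_life_table(lifetable)
  }
  list(params = params, table = table)
}

#' Write a cohort trace to CSV
#'
#' One row per cycle with the state occupancies and the discounted cost and
#' QALY increments accrued in that cycle.
#'
#' @param arm_result A `cea_arm` from [run_cohort()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(arm_result, path) {
  d <- data.frame(cycle = seq_len(nrow(arm_result$trace)) - 1L,
                  arm_result$trace,
                  cost_increment = arm_result$cost_by_cycle,
                  qaly_increment = arm_result$qaly_by_cycle,
                  check.names = FALSE)
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Run the base-case analysis and write its report
#'
#' Runs both strategy arms, computes the ICER, and writes `base_case.json`
#' (arm results and ICER record), per-arm traces (`trace_IF.csv`,
#' `trace_HA.csv`) and `manifest.json` to `out_dir`.
#'
#' @param config Path to a YAML/JSON config, a named list of overrides, a
#'   `cea_params` object, or `NULL` for the base case.
#' @param lifetable Path to a life-table CSV, a [life_table()], or `NULL` for
#'   the bundled fixture.
#' @param out_dir Output directory (created if needed).
#' @param ... Passed to [run_cohort()] (accrual conventions).
#' @return Invisibly, a list with both `cea_arm` objects and the `cea_icer`.
#' @export
cea_run <- function(config = NULL, lifetable = NULL, out_dir, ...) {
  inp <- resolve_inputs(config, lifetable)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  arm_if <- run_cohort("IF", inp$params, inp$table, ...)
  arm_ha <- run_cohort("HA", inp$params, inp$table, ...)
  icer <- compute_icer(arm_if, arm_ha, inp$params$wtp)

  arm_record <- function(a) {
    list(strategy = a$strategy, discounted_cost = a$discounted_cost,
         discounted_qaly = a$discounted_qaly,
         well_state_share = a$well_state_share, alive_at_end = a$alive_at_end,
         accrual = a$accrual, half_cycle_correction = a$half_cycle_correction)
  }
  jsonlite::write_json(
    list(IF = arm_record(arm_if), HA = arm_record(arm_ha),
         icer = icer[c("delta_cost", "delta_qaly", "icer", "classification", "wtp")]),
    file.path(out_dir, "base_case.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  write_trace(arm_if, file.path(out_dir, "trace_IF.csv"))
  write_trace(arm_ha, file.path(out_dir, "trace_HA.csv"))
  write_manifest(out_dir, "run", config, lifetable)

  message(sprintf("base case: IF $%.0f / %.3f QALYs; HA $%.0f / %.3f QALYs; %s",
                  arm_if$discounted_cost, arm_if$discounted_qaly,
                  arm_ha$discounted_cost, arm_ha$discounted_qaly,
                  if (is.na(icer$icer)) icer$classification
                  else sprintf("ICER $%.2f/QALY (%s)", icer$icer, icer$classification)))
  invisible(list(IF = arm_if, HA = arm_ha, icer = icer))
}

#' Run the tornado analysis and write it as tidy CSV
#'
#' @inheritParams cea_run
#' @param rel_range Relative variation for [tornado()] (default 0.2).
#' @return Invisibly, the tornado `data.frame`.
#' @export
cea_tornado <- function(config = NULL, lifetable = NULL, out_dir, rel_range = 0.2, ...) {
  inp <- resolve_inputs(config, lifetable)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tor <- tornado(inp$params, inp$table, rel_range = rel_range, ...)
  utils::write.csv(tor, file.path(out_dir, "tornado.csv"), row.names = FALSE)
  write_manifest(out_dir, "tornado", config, lifetable)
  invisible(tor)
}

#' Run a two-way sensitivity grid and write it as tidy CSV
#'
#' @inheritParams cea_run
#' @param param_x,param_y Parameter names (defaults: the two procedure costs).
#' @param x_values,y_values Numeric grids; default 41-point grids spanning
#'   0 to twice the base value.
#' @return Invisibly, the classified grid `data.frame`.
#' @export
cea_twoway <- function(config = NULL, lifetable = NULL, out_dir,
                       param_x = "c_if", param_y = "c_ha",
                       x_values = NULL, y_values = NULL, ...) {
  inp <- resolve_inputs(config, lifetable)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(x_values)) x_values <- seq(0, 2 * inp$params[[param_x]], length.out = 41)
  if (is.null(y_values)) y_values <- seq(0, 2 * inp$params[[param_y]], length.out = 41)
  grid <- two_way_region(param_x, x_values, param_y, y_values,
                         inp$params, inp$table, ...)
  utils::write.csv(grid, file.path(out_dir, "twoway.csv"), row.names = FALSE)
  write_manifest(out_dir, "twoway", config, lifetable)
  invisible(grid)
}

#' Run the threshold analysis and write it as CSV
#'
#' @inheritParams cea_run
#' @return Invisibly, the [threshold_table()] `data.frame`.
#' @export
cea_thresholds <- function(config = NULL, lifetable = NULL, out_dir, ...) {
  inp <- resolve_inputs(config, lifetable)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  thr <- threshold_table(inp$params, inp$table, ...)
  utils::write.csv(thr, file.path(out_dir, "thresholds.csv"), row.names = FALSE)
  write_manifest(out_dir, "thresholds", config, lifetable)
  invisible(thr)
}

#' Run the probabilistic sensitivity analysis and write its outputs
#'
#' Writes per-iteration results (`psa.csv`), the acceptability curve
#' (`ceac.csv`), plane summaries with the 95% ellipse (`psa_summary.json`),
#' and `manifest.json`.
#'
#' @inheritParams cea_run
#' @param n_iter Number of Monte Carlo iterations.
#' @param seed Integer seed (required for reproducibility).
#' @param wtp_grid Willingness-to-pay grid for the acceptability curve.
#' @return Invisibly, a list with the `cea_psa`, the summaries and the curve.
#' @export
cea_psa <- function(config = NULL, lifetable = NULL, out_dir,
                    n_iter = 10000, seed,
                    wtp_grid = seq(0, 40000, by = 1000), ...) {
  inp <- resolve_inputs(config, lifetable)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  psa <- sample_psa(inp$params, inp$table, n_iter = n_iter, seed = seed, ...)
  summaries <- ce_summaries(psa, inp$params$wtp)
  curve <- acceptability_curve(psa, wtp_grid)

  utils::write.csv(
    data.frame(cost_if = psa$cost_if, qaly_if = psa$qaly_if,
               cost_ha = psa$cost_ha, qaly_ha = psa$qaly_ha,
               delta_cost = psa$delta_cost, delta_qaly = psa$delta_qaly),
    file.path(out_dir, "psa.csv"), row.names = FALSE
  )
  utils::write.csv(curve, file.path(out_dir, "ceac.csv"), row.names = FALSE)
  ell <- summaries$ellipse_95
  jsonlite::write_json(
    list(share_more_costly = summaries$share_more_costly,
         share_more_effective = summaries$share_more_effective,
         share_acceptable_at_wtp = summaries$share_acceptable_at_wtp,
         icer_of_means = summaries$icer_of_means,
         ellipse_95 = if (is.null(ell)) NULL else
           list(center = as.list(ell$center), radii = ell$radii, angle = ell$angle)),
    file.path(out_dir, "psa_summary.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE
  )
  write_manifest(out_dir, "psa", config, lifetable, seed = seed)

  message(sprintf(
    "PSA (%d iterations): HA costlier in %.1f%%, more effective in %.1f%%, acceptable at WTP in %.1f%%",
    psa$n_iter, 100 * summaries$share_more_costly,
    100 * summaries$share_more_effective, 100 * summaries$share_acceptable_at_wtp))
  invisible(list(psa = psa, summaries = summaries, ceac = curve))
}

#' Plot the cost-effectiveness plane of a PSA
#'
#' Scatter of incremental QALYs vs incremental cost with the WTP line.
#' Requires ggplot2 (suggested); the underlying data are always available via
#' [cea_psa()]'s CSV output.
#'
#' @param psa A [psa_result()] object.
#' @param wtp Willingness-to-pay threshold drawn as a line.
#' @return A ggplot object.
#' @export
plot_ce_plane <- function(psa, wtp) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting", call. = FALSE)
  }
  d <- data.frame(delta_qaly = psa$delta_qaly, delta_cost = psa$delta_cost)
  ggplot2::ggplot(d, ggplot2::aes(x = delta_qaly, y = delta_cost)) +
    ggplot2::geom_point(alpha = 0.25, size = 0.6) +
    ggplot2::geom_abline(slope = wtp, intercept = 0, linetype = "dashed") +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.3) +
    ggplot2::labs(x = "Incremental QALYs (HA - IF)",
                  y = "Incremental cost, USD (HA - IF)")
}

#' Plot a cost-effectiveness acceptability curve
#'
#' @param curve Output of [acceptability_curve()].
#' @return A ggplot object.
#' @export
plot_ceac <- function(curve) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting", call. = FALSE)
  }
  ggplot2::ggplot(curve, ggplot2::aes(x = wtp, y = fraction)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Willingness to pay, USD/QALY",
                  y = "Probability HA is cost-effective")
}
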