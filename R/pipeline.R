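#' Batch-analyze a folder of curve files
#'
#' Scans `folder` for ccfs-txt curve files, analyses every parseable curve
#' with [analyze_curve()], exports the per-curve results CSV, and writes a
#' QC report (counts of skipped files and of flagged curves by reason) plus
#' a JSON run-record (all parameters and the package version) beside the
#' output.
#'
#' @param folder Input folder of curve files.
#' @param params [analysis_params()].
#' @param out Output CSV path.
#' @return Invisibly a list: `results` (list of `ccfs_result`), `table`
#'   (data.frame incl. `flagged`/`flag_reason`), `qc` (list), `status`
#'   (0 if at least one curve analysed successfully, 1 otherwise).
#' @export
ccfs_analyze <- function(folder, params = analysis_params(),
                         out = file.path(folder, "results.csv")) {
  curves <- scan_folder(folder)
  if (!length(curves)) {
    message("no parseable curves in ", folder)
    return(invisible(list(results = list(), table = NULL, qc = NULL,
                          status = 1L)))
  }
  results <- lapply(curves, analyze_curve, params = params)
  tab <- results_to_df(results)
  export_results_csv(tab, out)
  reasons <- table(tab$flag_reason[tab$flagged])
  qc <- list(n_files = length(curves) + attr(curves, "skipped"),
             n_parsed = length(curves),
             n_skipped = attr(curves, "skipped"),
             skipped_files = attr(curves, "skipped_files"),
             n_analyzed = sum(!tab$flagged),
             n_flagged = sum(tab$flagged),
             flag_reasons = as.list(reasons))
  .write_run_record(out, list(subcommand = "analyze", folder = folder,
                              out = out, params = unclass(params), qc = qc))
  status <- if (qc$n_analyzed >= 1) 0L else 1L
  invisible(list(results = results, table = tab, qc = qc, status = status))
}

#' Run a simulated CCFS sweep from a configuration
#'
#' Thin orchestration over [generate_experiment()]: builds the
#' [simulation_config()] from overrides, draws a seed if none is given, and
#' writes the run-record beside the output folder.
#'
#' @param variable,values,n_per_condition,out_dir,master_seed Passed to
#'   [generate_experiment()]; `master_seed = NULL` draws one at random and
#'   records it.
#' @param cfg A [simulation_config()].
#' @return Invisibly the manifest data.frame with attribute `master_seed`.
#' @export
ccfs_simulate <- function(variable, values, n_per_condition, out_dir,
                          master_seed = NULL, cfg = simulation_config()) {
  if (is.null(master_seed))
    master_seed <- sample.int(.Machine$integer.max %/% 10000L, 1L)
  manifest <- generate_experiment(cfg, variable, values, n_per_condition,
                                  out_dir, master_seed = master_seed)
  .write_run_record(file.path(out_dir, "manifest.csv"),
                    list(subcommand = "simulate", variable = variable,
                         values = values,
                         n_per_condition = n_per_condition,
                         out_dir = out_dir, master_seed = master_seed))
  attr(manifest, "master_seed") <- master_seed
  invisible(manifest)
}

#' Aggregate a results CSV and fit one work model
#'
#' Reads the per-curve results CSV written by [ccfs_analyze()], aggregates
#' the unflagged works over the model's condition variable, fits the model
#' to the condition means, prints the fitted parameters with standard
#' errors, and writes the per-condition summary and fit CSVs.
#'
#' @param results_csv Path to a results CSV.
#' @param model_id `"delay"`, `"setpoint"`, `"approach"` or `"retract"`.
#' @param out Output path for the fit CSV; the condition summary goes to
#'   `sub(".csv", "_summary.csv", out)`.
#' @param weighting Passed to [fit_model()].
#' @return Invisibly a list: `summary` (ccfs_summary), `fit` (ccfs_fit),
#'   `status` (0).
#' @export
ccfs_fit <- function(results_csv, model_id, out = "fits.csv",
                     weighting = "none") {
  ms <- model_spec(model_id)
  df <- read.csv(results_csv, stringsAsFactors = FALSE)
  if (!ms$variable %in% names(df))
    stop("results CSV lacks column '", ms$variable,
         "' required by model '", ms$model_id, "'")
  summ <- aggregate_by_condition(df, ms$variable)
  fit <- fit_model(summ, model_id, weighting = weighting)
  message(sprintf("model %s: A = %.6g +/- %.3g, B = %.6g +/- %.3g (n = %d)",
                  fit$model_id, fit$A, fit$se_A, fit$B, fit$se_B,
                  fit$n_points))
  write.csv(fits_to_df(fit), out, row.names = FALSE)
  summary_out <- sub("\\.csv$", "_summary.csv", out)
  write.csv(summ[setdiff(names(summ), "values")], summary_out,
            row.names = FALSE)
  .write_run_record(out, list(subcommand = "fit",
                              results_csv = results_csv,
                              model_id = model_id, weighting = weighting,
                              out = out))
  invisible(list(summary = summ, fit = fit, status = 0L))
}

# JSON run-record next to an output file: parameters + package version
.write_run_record <- function(out_path, fields) {
  rec <- c(fields, list(
    package_version = as.character(utils::packageVersion("ccfs")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")))
  path <- paste0(sub("\\.[A-Za-z]+$", "", out_path), "_run_record.json")
  jsonlite::write_json(rec, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, force = TRUE)
  invisible(path)
}
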