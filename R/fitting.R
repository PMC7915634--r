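#' Aggregate per-curve detachment work by acquisition condition
#'
#' Groups unflagged per-curve results by one acquisition variable and
#' summarises the work distribution per condition value, mirroring how
#' per-condition averages are formed before model fitting.
#'
#' @param results A results data.frame ([results_to_df()] / the exported
#'   CSV read back) or a list of `ccfs_result` objects.
#' @param variable One of `"retract_speed_um_s"`, `"approach_speed_um_s"`,
#'   `"delay_time_s"`, `"setpoint_nN"`, `"delay_mode"` (short aliases
#'   `"v_r"`, `"v_a"`, `"tau"`, `"F0"`, `"delay_mode"` accepted).
#' @return A data.frame of class `ccfs_summary`, one row per distinct
#'   condition value sorted ascending: `variable`, `value`, `n_curves`,
#'   `mean_W`, `sd_W`, `median_W`, `degenerate` (single-curve group), and a
#'   list column `values` with the per-curve works.
#' @export
aggregate_by_condition <- function(results, variable) {
  alias <- c(v_r = "retract_speed_um_s", v_a = "approach_speed_um_s",
             tau = "delay_time_s", F0 = "setpoint_nN",
             delay_mode = "delay_mode")
  if (variable %in% names(alias)) variable <- alias[[variable]]
  valid <- unname(alias)
  if (!variable %in% valid)
    stop("unknown condition variable '", variable, "'; valid: ",
         paste(valid, collapse = ", "))
  df <- if (is.data.frame(results)) results else results_to_df(results)
  if (!variable %in% names(df))
    stop("results lack required column '", variable, "'")
  df <- df[!is.na(df$work_fJ), , drop = FALSE]
  if ("flagged" %in% names(df)) df <- df[!df$flagged, , drop = FALSE]
  if (!nrow(df)) {
    warning("no unflagged results to aggregate", call. = FALSE)
    out <- data.frame(variable = character(), value = numeric(),
                      n_curves = integer(), mean_W = numeric(),
                      sd_W = numeric(), median_W = numeric(),
                      degenerate = logical())
    out$values <- list()
    class(out) <- c("ccfs_summary", "data.frame")
    return(out)
  }
  groups <- split(df$work_fJ, df[[variable]])
  vals <- names(groups)
  num_vals <- suppressWarnings(as.numeric(vals))
  ord <- if (all(!is.na(num_vals))) order(num_vals) else order(vals)
  groups <- groups[ord]
  out <- data.frame(
    variable = variable,
    value = if (all(!is.na(num_vals))) num_vals[ord] else vals[ord],
    n_curves = vapply(groups, length, integer(1)),
    mean_W = vapply(groups, mean, numeric(1)),
    sd_W = vapply(groups, function(v) if (length(v) > 1) sd(v) else 0,
                  numeric(1)),
    median_W = vapply(groups, median, numeric(1)),
    degenerate = vapply(groups, function(v) length(v) < 2, logical(1)),
    row.names = NULL
  )
  out$values <- unname(groups)
  class(out) <- c("ccfs_summary", "data.frame")
  out
}

#' Fit one detachment-work model to condition means
#'
#' Nonlinear least squares (Levenberg-Marquardt) of per-condition mean work
#' against the condition value under one of the four registered models.
#' Initialisation is deterministic per model (linear-model heuristics, see
#' [model_spec()]); B is bounded below by 0 for the delay and setpoint
#' models. Parameter standard errors come from the Jacobian at the
#' solution.
#'
#' @param summaries A `ccfs_summary` from [aggregate_by_condition()], or any
#'   data.frame with `value` and `mean_W` (plus `sd_W`, `n_curves` if
#'   inverse-variance weighting is requested).
#' @param model_id `"delay"`, `"setpoint"`, `"approach"` or `"retract"`.
#' @param weighting `"none"` (default; condition means enter unweighted, as
#'   when fitting displayed averages) or `"inverse_variance"` (weights
#'   n/sd^2, i.e. inverse squared standard error of each mean; degenerate
#'   groups are dropped with a warning).
#' @return A `ccfs_fit` list: `model_id`, `A`, `B`, `se_A`, `se_B`, `rss`,
#'   `n_points`, and the underlying `nls` object as `fit`.
#' @export
fit_model <- function(summaries, model_id, weighting = c("none",
                                                         "inverse_variance")) {
  weighting <- match.arg(weighting)
  ms <- model_spec(model_id)
  x <- summaries$value
  y <- summaries$mean_W
  if (!is.numeric(x))
    stop("model '", ms$model_id, "' needs a numeric condition variable")
  keep <- is.finite(x) & is.finite(y)
  w <- rep(1, length(x))
  if (weighting == "inverse_variance") {
    se2 <- summaries$sd_W^2 / summaries$n_curves
    bad <- !is.finite(se2) | se2 <= 0
    if (any(bad)) {
      warning(sum(bad), " degenerate group(s) dropped from weighted fit",
              call. = FALSE)
      keep <- keep & !bad
    }
    w[!bad] <- 1 / se2[!bad]
  }
  x <- x[keep]; y <- y[keep]; w <- w[keep]
  if (length(x) < 3)
    stop("need at least 3 condition points to fit a 2-parameter model, got ",
         length(x))
  start <- ms$init(x, y)
  fun <- ms$fun
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ fun(x, A, B),
      start = list(A = start[["A"]], B = start[["B"]]),
      lower = ms$lower, weights = w,
      control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-14,
                                           ptol = 1e-14)),
    error = function(e) stop("fit of model '", ms$model_id, "' failed: ",
                             conditionMessage(e)))
  cf <- summary(fit)$coefficients
  structure(list(model_id = ms$model_id,
                 A = cf["A", "Estimate"], B = cf["B", "Estimate"],
                 se_A = cf["A", "Std. Error"], se_B = cf["B", "Std. Error"],
                 rss = stats::deviance(fit),
                 n_points = length(x), fit = fit),
            class = "ccfs_fit")
}

#' @export
print.ccfs_fit <- function(x, ...) {
  cat(sprintf("<ccfs_fit:%s> A = %.6g (se %.2g), B = %.6g (se %.2g), rss = %.4g, n = %d\n",
              x$model_id, x$A, x$se_A, x$B, x$se_B, x$rss, x$n_points))
  invisible(x)
}

#' Free-exponent power-law fit W = C x^p
#'
#' Used to check that the mean work versus setpoint force follows the Hertz
#' area scaling (exponent 2/3) without assuming it. Initialised from the
#' log-log regression slope.
#'
#' @param x Positive predictor values.
#' @param y Positive responses.
#' @return List with `C`, `p`, `se_p`, `rss`.
#' @export
fit_power_law <- function(x, y) {
  stopifnot(all(x > 0), all(y > 0), length(x) == length(y), length(x) >= 2)
  b <- coef(lm(log(y) ~ log(x)))
  fit <- minpack.lm::nlsLM(y ~ C * x^p,
                           start = list(C = exp(unname(b[1])),
                                        p = unname(b[2])),
                           control = minpack.lm::nls.lm.control(
                             maxiter = 200, ftol = 1e-14, ptol = 1e-14))
  cf <- summary(fit)$coefficients
  list(C = cf["C", "Estimate"], p = cf["p", "Estimate"],
       se_p = cf["p", "Std. Error"], rss = sum(stats::residuals(fit)^2))
}

#' Percentile bootstrap confidence interval for a condition mean
#'
#' @param values Per-curve works of one condition group (fJ).
#' @param n_boot Number of bootstrap resamples (default 2000).
#' @param seed Integer seed; the interval is reproducible for a fixed seed.
#' @param level Confidence level (default 0.95).
#' @return Numeric c(low, high) in fJ. With fewer than 3 values a degenerate
#'   interval (min, max) is returned with a warning.
#' @export
bootstrap_condition_ci <- function(values, n_boot = 2000, seed = 1,
                                   level = 0.95) {
  values <- values[is.finite(values)]
  if (length(values) < 3) {
    warning("fewer than 3 values: degenerate CI (min, max)", call. = FALSE)
    return(c(low = min(values), high = max(values)))
  }
  a <- (1 - level) / 2
  means <- withr::with_seed(seed, {
    vapply(seq_len(n_boot),
           function(i) mean(sample(values, replace = TRUE)), numeric(1))
  })
  q <- quantile(means, c(a, 1 - a), names = FALSE)
  c(low = q[1], high = q[2])
}

#' Fit results table for one or more fitted models
#'
#' @param fits A `ccfs_fit` or list of them.
#' @return data.frame with columns model_id, A, se_A, B, se_B, rss,
#'   n_points.
#' @export
fits_to_df <- function(fits) {
  if (inherits(fits, "ccfs_fit")) fits <- list(fits)
  do.call(rbind, lapply(fits, function(f)
    data.frame(model_id = f$model_id, A = f$A, se_A = f$se_A, B = f$B,
               se_B = f$se_B, rss = f$rss, n_points = f$n_points)))
}
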