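#' Acquisition metadata for one CCFS curve
#'
#' Constructs the metadata record attached to every force curve: the
#' acquisition parameters that the work models act on, plus the cantilever
#' spring constant needed for the bending correction.
#'
#' @param approach_speed Approach speed v_a in um/s (> 0).
#' @param retract_speed Retract speed v_r in um/s (> 0).
#' @param delay_time Contact (dwell) time tau in s (>= 0).
#' @param setpoint Setpoint force F0 in nN (> 0), the maximum compressive
#'   force before the dwell phase.
#' @param delay_mode Feedback during the dwell: `"constant_height"` (piezo
#'   fixed, force relaxes) or `"constant_force"` (piezo compensates).
#' @param spring_constant Cantilever spring constant k in N/m (> 0).
#' @param curve_length Length of the retract ramp in um.
#' @param source_id Identifier of the originating file or simulation.
#' @param extra Named list of additional header key/value pairs (kept on
#'   round trip through the ccfs-txt dialect, e.g. simulation seeds).
#'
#' @return An object of class `ccfs_metadata` (a named list).
#' @export
curve_metadata <- function(approach_speed = 10, retract_speed = 10,
                           delay_time = 45, setpoint = 1,
                           delay_mode = c("constant_height", "constant_force"),
                           spring_constant = 0.03, curve_length = 80,
                           source_id = "", extra = list()) {
  delay_mode <- match.arg(delay_mode)
  stopifnot(
    "approach_speed must be > 0" = is.numeric(approach_speed) && approach_speed > 0,
    "retract_speed must be > 0" = is.numeric(retract_speed) && retract_speed > 0,
    "delay_time must be >= 0" = is.numeric(delay_time) && delay_time >= 0,
    "setpoint must be > 0" = is.numeric(setpoint) && setpoint > 0,
    "spring_constant must be > 0" = is.numeric(spring_constant) && spring_constant > 0,
    "curve_length must be > 0" = is.numeric(curve_length) && curve_length > 0
  )
  structure(list(
    approach_speed = as.numeric(approach_speed),
    retract_speed = as.numeric(retract_speed),
    delay_time = as.numeric(delay_time),
    setpoint = as.numeric(setpoint),
    delay_mode = delay_mode,
    spring_constant = as.numeric(spring_constant),
    curve_length = as.numeric(curve_length),
    source_id = as.character(source_id),
    extra = extra
  ), class = "ccfs_metadata")
}

#' A sampled CCFS retract curve
#'
#' The pipeline's input record: the retract trace as (z, force) samples with
#' z the tip-sample separation (or raw piezo position if `corrected` is
#' FALSE) in um, strictly increasing, and force in nN under the sign
#' convention that adhesion is negative.
#'
#' @param z Numeric vector of positions in um, strictly increasing.
#' @param force Numeric vector of forces in nN, same length as `z`.
#' @param metadata A [curve_metadata()] object.
#' @param approach Optional two-column matrix/data.frame (z, force) holding
#'   the approach segment.
#' @param corrected Logical; TRUE if the cantilever-bending and baseline
#'   corrections have been applied so that `z` is tip-sample separation.
#'
#' @return An object of class `ccfs_curve`.
#' @export
force_curve <- function(z, force, metadata = curve_metadata(),
                        approach = NULL, corrected = TRUE) {
  z <- as.numeric(z); force <- as.numeric(force)
  if (length(z) != length(force))
    stop("z and force must have equal length")
  if (length(z) < 64)
    stop("a force curve needs at least 64 samples, got ", length(z))
  if (!all(is.finite(z)) || !all(is.finite(force)))
    stop("force curve samples must be finite (no NA/NaN/Inf)")
  if (any(diff(z) <= 0))
    stop("z must be strictly increasing")
  if (!inherits(metadata, "ccfs_metadata"))
    stop("metadata must be a ccfs_metadata object")
  structure(list(z = z, force = force, metadata = metadata,
                 approach = approach, corrected = isTRUE(corrected)),
            class = "ccfs_curve")
}

#' @export
print.ccfs_curve <- function(x, ...) {
  m <- x$metadata
  cat(sprintf(
    "<ccfs_curve> %d samples, z [%.3g, %.3g] um, F [%.3g, %.3g] nN\n",
    length(x$z), min(x$z), max(x$z), min(x$force), max(x$force)))
  cat(sprintf("  v_a=%g um/s  v_r=%g um/s  tau=%g s  F0=%g nN  %s  k=%g N/m\n",
              m$approach_speed, m$retract_speed, m$delay_time, m$setpoint,
              m$delay_mode, m$spring_constant))
  invisible(x)
}

# header key <-> metadata field map of the ccfs-txt dialect
.ccfs_header_keys <- c(
  approachSpeed_um_s = "approach_speed",
  retractSpeed_um_s = "retract_speed",
  delayTime_s = "delay_time",
  setpoint_nN = "setpoint",
  delayMode = "delay_mode",
  springConstant_N_m = "spring_constant",
  curveLength_um = "curve_length"
)

#' Write a force curve in the ccfs-txt dialect
#'
#' The dialect is UTF-8 text: header lines start with `"# "` and carry
#' `key: value` pairs; data rows are tab-separated `z_um<TAB>force_nN`.
#' One file holds one retract segment; an optional approach segment follows
#' in a second block introduced by `# segment: approach`. Values are written
#' at full double precision so that [read_curve_file()] reproduces the curve
#' exactly.
#'
#' @param curve A [force_curve()] object.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_curve_file <- function(curve, path) {
  if (!inherits(curve, "ccfs_curve")) stop("curve must be a ccfs_curve")
  if (!all(is.finite(curve$z)) || !all(is.finite(curve$force)))
    stop("refusing to write curve with non-finite samples")
  m <- curve$metadata
  hdr <- c(
    sprintf("# approachSpeed_um_s: %.17g", m$approach_speed),
    sprintf("# retractSpeed_um_s: %.17g", m$retract_speed),
    sprintf("# delayTime_s: %.17g", m$delay_time),
    sprintf("# setpoint_nN: %.17g", m$setpoint),
    sprintf("# delayMode: %s", m$delay_mode),
    sprintf("# springConstant_N_m: %.17g", m$spring_constant),
    sprintf("# curveLength_um: %.17g", m$curve_length),
    sprintf("# corrected: %s", if (curve$corrected) "true" else "false")
  )
  if (length(m$extra))
    hdr <- c(hdr, sprintf("# %s: %s", names(m$extra),
                          vapply(m$extra, format, "", digits = 17)))
  lines <- c(hdr, "# segment: retract",
             sprintf("%.17g\t%.17g", curve$z, curve$force))
  if (!is.null(curve$approach)) {
    ap <- as.matrix(curve$approach)
    lines <- c(lines, "# segment: approach",
               sprintf("%.17g\t%.17g", ap[, 1], ap[, 2]))
  }
  con <- tryCatch(file(path, "w", encoding = "UTF-8"),
                  error = function(e) stop("cannot open '", path,
                                           "' for writing: ",
                                           conditionMessage(e)))
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Read a force curve from a ccfs-txt file
#'
#' Parses the dialect written by [write_curve_file()]. Missing header keys
#' do not abort parsing: the baseline acquisition condition (v_a = v_r =
#' 10 um/s, tau = 45 s, F0 = 1 nN, constant height, k = 0.03 N/m, 80 um
#' ramp) is filled in with a warning and the applied defaults are recorded
#' in `metadata$extra$defaults_applied`.
#'
#' @param path Path to a ccfs-txt file.
#' @return A [force_curve()] object; `metadata$source_id` is the file name.
#' @export
read_curve_file <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  is_hdr <- startsWith(lines, "# ")
  blank <- !nzchar(trimws(lines))
  kv <- sub("^# ", "", lines[is_hdr])
  keys <- sub(":.*$", "", kv)
  vals <- trimws(sub("^[^:]*:", "", kv))
  hdr <- as.list(setNames(vals, keys)[keys != "segment"])

  data_idx <- which(!is_hdr & !blank)
  if (!length(data_idx))
    stop("format error in '", path, "': no data rows")
  seg_lines <- which(is_hdr)[keys == "segment"]
  appr_start <- seg_lines[vals[keys == "segment"] == "approach"]
  in_approach <- if (length(appr_start)) data_idx > appr_start[1] else
    rep(FALSE, length(data_idx))

  cols <- strsplit(lines[data_idx], "\t", fixed = TRUE)
  nc <- lengths(cols)
  if (any(nc < 2))
    stop("format error in '", path, "' line ", data_idx[which(nc < 2)[1]],
         ": expected 2 tab-separated columns")
  zv <- suppressWarnings(as.numeric(vapply(cols, `[`, "", 1L)))
  fv <- suppressWarnings(as.numeric(vapply(cols, `[`, "", 2L)))
  bad <- which(is.na(zv) | is.na(fv))
  if (length(bad))
    stop("format error in '", path, "' line ", data_idx[bad[1]],
         ": non-numeric data '", lines[data_idx[bad[1]]], "'")
  retract <- cbind(zv[!in_approach], fv[!in_approach])
  approach <- if (any(in_approach)) cbind(zv[in_approach], fv[in_approach])
  if (!nrow(retract))
    stop("format error in '", path, "': no retract data rows")

  md_args <- list()
  missing_keys <- character()
  for (hk in names(.ccfs_header_keys)) {
    fld <- .ccfs_header_keys[[hk]]
    if (!is.null(hdr[[hk]])) {
      v <- hdr[[hk]]
      md_args[[fld]] <- if (fld == "delay_mode") v else {
        nv <- suppressWarnings(as.numeric(v))
        if (is.na(nv)) stop("format error in '", path,
                            "': non-numeric header value for ", hk)
        nv
      }
    } else missing_keys <- c(missing_keys, hk)
  }
  known <- c(names(.ccfs_header_keys), "corrected", "segment")
  extra <- hdr[setdiff(names(hdr), known)]
  if (length(missing_keys)) {
    warning("'", basename(path), "': missing header key(s) ",
            paste(missing_keys, collapse = ", "),
            "; baseline-condition defaults applied", call. = FALSE)
    extra$defaults_applied <- paste(missing_keys, collapse = ",")
  }
  md_args$source_id <- basename(path)
  md_args$extra <- extra
  md <- do.call(curve_metadata, md_args)

  ap <- if (!is.null(approach)) {
    colnames(approach) <- c("z", "force"); approach
  }
  corrected <- !identical(tolower(hdr[["corrected"]] %||% "true"), "false")
  force_curve(retract[, 1], retract[, 2], metadata = md, approach = ap,
              corrected = corrected)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Cantilever-bending correction
#'
#' Converts raw piezo positions to tip-sample separation by subtracting the
#' cantilever deflection F/k: `z_tss = z_piezo - F/k`, with the nN/(N/m)
#' quotient (nm) converted to um.
#'
#' @param z_piezo Raw piezo positions in um.
#' @param force Forces in nN, same length.
#' @param k Cantilever spring constant in N/m (> 0).
#' @return Tip-sample separations in um.
#' @export
correct_bending <- function(z_piezo, force, k) {
  if (length(z_piezo) != length(force))
    stop("z_piezo and force must have equal length")
  if (!is.numeric(k) || length(k) != 1L || k <= 0)
    stop("spring constant k must be a single positive number")
  sep <- z_piezo - (force / k) * 1e-3  # nN / (N/m) = nm -> um
  if (any(diff(sep) <= 0))
    warning("separation no longer strictly monotonic after bending correction",
            call. = FALSE)
  sep
}

#' Load every parseable curve file in a folder
#'
#' Reads all `*.txt` files in `folder` with [read_curve_file()]; files that
#' fail to parse are skipped with a warning, and the number of skips is
#' reported in the `skipped` attribute of the returned list.
#'
#' @param folder Directory to scan.
#' @param pattern Filename regexp, default `"\\.txt$"`.
#' @return List of [force_curve()] objects; attributes `skipped` (count)
#'   and `skipped_files` (names).
#' @export
scan_folder <- function(folder, pattern = "\\.txt$") {
  if (!dir.exists(folder)) stop("folder not found: ", folder)
  files <- sort(list.files(folder, pattern = pattern, full.names = TRUE))
  files <- files[basename(files) != "manifest.csv"]
  if (!length(files)) {
    warning("no curve files found in ", folder, call. = FALSE)
    out <- list()
    attr(out, "skipped") <- 0L
    attr(out, "skipped_files") <- character()
    return(out)
  }
  curves <- list(); skipped <- character()
  for (f in files) {
    c_or_err <- tryCatch(read_curve_file(f), error = function(e) e)
    if (inherits(c_or_err, "error")) {
      warning("skipping unparseable file '", basename(f), "': ",
              conditionMessage(c_or_err), call. = FALSE)
      skipped <- c(skipped, basename(f))
    } else curves[[length(curves) + 1L]] <- c_or_err
  }
  attr(curves, "skipped") <- length(skipped)
  attr(curves, "skipped_files") <- skipped
  curves
}

#' Export per-curve detachment results as CSV
#'
#' One row per analysed curve, ordered by `source_id`, with the fixed
#' column schema: source_id, approach_speed_um_s, retract_speed_um_s,
#' delay_time_s, setpoint_nN, delay_mode, work_fJ, z_det_um, f_det_nN,
#' n_events, max_adhesion_nN. Flagged (failed) curves appear with NA
#' numeric fields. Numeric fields are written at full double precision.
#'
#' @param results List of detachment results from [analyze_curve()], or a
#'   data.frame already in the schema (via [results_to_df()]).
#' @param path Output CSV path.
#' @return Invisibly, the exported data.frame.
#' @export
export_results_csv <- function(results, path) {
  df <- if (is.data.frame(results)) results else results_to_df(results)
  df <- df[order(df$source_id),
           setdiff(names(df), c("flagged", "flag_reason")), drop = FALSE]
  ok <- tryCatch({
    write.csv(format(df, digits = 15, trim = TRUE, scientific = FALSE),
              path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) stop("cannot write '", path, "': ",
                              conditionMessage(e)))
  invisible(df)
}

#' Flatten detachment results to the CSV schema
#'
#' @param results List of `ccfs_result` objects from [analyze_curve()].
#' @return A data.frame in the [export_results_csv()] column schema, plus a
#'   `flagged` / `flag_reason` pair used for QC (dropped on export).
#' @export
results_to_df <- function(results) {
  if (inherits(results, "ccfs_result")) results <- list(results)
  if (!length(results))
    return(data.frame(source_id = character(),
                      approach_speed_um_s = numeric(),
                      retract_speed_um_s = numeric(),
                      delay_time_s = numeric(), setpoint_nN = numeric(),
                      delay_mode = character(), work_fJ = numeric(),
                      z_det_um = numeric(), f_det_nN = numeric(),
                      n_events = integer(), max_adhesion_nN = numeric(),
                      flagged = logical(), flag_reason = character()))
  row1 <- function(r) {
    m <- r$metadata
    data.frame(
      source_id = m$source_id,
      approach_speed_um_s = m$approach_speed,
      retract_speed_um_s = m$retract_speed,
      delay_time_s = m$delay_time,
      setpoint_nN = m$setpoint,
      delay_mode = m$delay_mode,
      work_fJ = if (r$flagged) NA_real_ else r$work,
      z_det_um = if (r$flagged) NA_real_ else r$z_det,
      f_det_nN = if (r$flagged) NA_real_ else r$f_det,
      n_events = if (r$flagged) NA_integer_ else length(r$events),
      max_adhesion_nN = if (r$flagged) NA_real_ else r$max_adhesion,
      flagged = r$flagged,
      flag_reason = if (r$flagged) r$flag_reason else "",
      stringsAsFactors = FALSE
    )
  }
  df <- do.call(rbind, lapply(results, row1))
  df
}
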