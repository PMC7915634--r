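#' Analysis parameters for the retract-segment pipeline
#'
#' @param tail_fraction Fraction (0, 0.5] of samples furthest from the
#'   sample used for the baseline estimate. Default 0.2.
#' @param sg_window Savitzky-Golay window length in samples (odd). Default
#'   21, common practice for AFM step detection.
#' @param sg_order Savitzky-Golay polynomial order (>= 1, < window).
#'   Default 3.
#' @param prominence_factor Multiple of the baseline noise SD (scaled by the
#'   SG window span) a derivative peak must exceed to count as a rupture,
#'   and the multiple of the flank-median standard error the estimated force
#'   jump must exceed. Default 5.
#' @param distance `"separation"` (default) analyses tip-sample separation,
#'   applying [correct_bending()] to uncorrected curves; `"piezo"` analyses
#'   the raw piezo coordinate.
#' @param derivative `"signed"` (default) detects upward force steps only
#'   (ruptures under the adhesion-negative sign convention); `"absolute"`
#'   detects steps of either sign.
#' @return An `ccfs_params` list.
#' @export
analysis_params <- function(tail_fraction = 0.2, sg_window = 21,
                            sg_order = 3, prominence_factor = 5,
                            distance = c("separation", "piezo"),
                            derivative = c("signed", "absolute")) {
  distance <- match.arg(distance)
  derivative <- match.arg(derivative)
  if (!(tail_fraction > 0 && tail_fraction <= 0.5))
    stop("tail_fraction must be in (0, 0.5]")
  sg_window <- as.integer(sg_window); sg_order <- as.integer(sg_order)
  if (sg_window %% 2L == 0L) stop("sg_window must be odd")
  if (!(sg_order >= 1L && sg_window > sg_order))
    stop("need sg_window > sg_order >= 1")
  structure(list(tail_fraction = tail_fraction, sg_window = sg_window,
                 sg_order = sg_order, prominence_factor = prominence_factor,
                 distance = distance, derivative = derivative),
            class = "ccfs_params")
}

#' Baseline level and noise of a retract curve
#'
#' Robust estimate from the part of the curve far from the sample: the
#' median force and the MAD-scaled spread over the furthest `tail_fraction`
#' of samples by z.
#'
#' @param curve A [force_curve()].
#' @param tail_fraction Fraction (0, 0.5] of samples in the window.
#' @return List with `level` (nN) and `noise_sd` (nN).
#' @export
estimate_baseline <- function(curve, tail_fraction = 0.2) {
  if (!(tail_fraction > 0 && tail_fraction <= 0.5))
    stop("tail_fraction must be in (0, 0.5]")
  n <- length(curve$z)
  m <- max(1L, floor(n * tail_fraction))
  if (m < 16L)
    stop("insufficient baseline: window has ", m, " samples (< 16)")
  w <- curve$force[(n - m + 1L):n]  # z increasing: tail = far from sample
  list(level = median(w), noise_sd = mad(w))
}

#' Z origin: first baseline crossing of the retract trace
#'
#' Scanning from the contact (minimum separation) end in retraction order,
#' returns the z of the first crossing of `baseline_level`, linearly
#' interpolated between the bracketing samples. All downstream Z values are
#' reported relative to this origin.
#'
#' @param curve A [force_curve()].
#' @param baseline_level Baseline force level in nN.
#' @return Origin z in the curve's raw coordinates (um).
#' @export
find_origin <- function(curve, baseline_level = 0) {
  f <- curve$force - baseline_level
  z <- curve$z
  hit <- which(f == 0)
  cross <- which(f[-length(f)] * f[-1] < 0)
  cand_z <- c(z[hit],
              if (length(cross)) {
                i <- cross
                z[i] - f[i] * (z[i + 1L] - z[i]) / (f[i + 1L] - f[i])
              })
  if (!length(cand_z))
    stop("no crossing: retract trace never crosses the baseline")
  min(cand_z)
}

#' Savitzky-Golay first derivative of force with respect to z
#'
#' Smoothed dF/dz from a Savitzky-Golay first-derivative filter, exact for
#' polynomials up to `polyorder`. Non-uniform sampling is handled via mean
#' spacing normalisation; output length equals input length (edges use the
#' filter's transient fits).
#'
#' @param curve A [force_curve()].
#' @param window Odd window length in samples, `polyorder < window <= n`.
#' @param polyorder Polynomial order (>= 1).
#' @return Numeric vector dF/dz in nN/um, same length as the curve.
#' @export
smooth_derivative <- function(curve, window = 21, polyorder = 3) {
  n <- length(curve$z)
  window <- as.integer(window); polyorder <- as.integer(polyorder)
  if (window %% 2L == 0L) stop("window must be odd")
  if (!(polyorder >= 1L && window > polyorder)) stop("need window > polyorder >= 1")
  if (window > n) stop("window (", window, ") exceeds curve length (", n, ")")
  dz <- mean(diff(curve$z))
  as.numeric(signal::sgolayfilt(curve$force, p = polyorder, n = window,
                                m = 1, ts = dz))
}

#' Detect rupture events from derivative peaks
#'
#' Rupture events are discontinuities where force steps up toward the
#' baseline during retraction. Candidates are local maxima of the (signed)
#' Savitzky-Golay derivative whose local prominence exceeds
#' `prominence_factor * noise_sd / (window * mean(dz))`; candidates within
#' one window of each other are merged (highest peak kept, leftmost on
#' ties). For each candidate the force jump is estimated as the difference
#' of flank medians over half-window windows on either side of the step;
#' events are kept only if the jump is positive and exceeds
#' `prominence_factor` times the standard error of that median difference,
#' which suppresses noise-induced derivative peaks on long curves.
#'
#' @param curve A [force_curve()].
#' @param deriv dF/dz from [smooth_derivative()] (recomputed if NULL).
#' @param prominence_factor Detection stringency (default 5).
#' @param noise_sd Baseline noise SD in nN from [estimate_baseline()].
#' @param window SG window used for `deriv` (sets the merge span and flank
#'   width).
#' @param derivative `"signed"` or `"absolute"` (see [analysis_params()]).
#' @return data.frame with one row per event: `z_position`, `force_jump`,
#'   `pre_force`, `post_force` (forces in raw, not baseline-subtracted, nN),
#'   ordered by z. Zero rows if no events.
#' @export
detect_discontinuities <- function(curve, deriv = NULL, prominence_factor = 5,
                                   noise_sd = 0, window = 21,
                                   derivative = c("signed", "absolute")) {
  derivative <- match.arg(derivative)
  if (is.null(deriv)) deriv <- smooth_derivative(curve, window = window)
  d <- if (derivative == "absolute") abs(deriv) else deriv
  n <- length(d)
  dz <- mean(diff(curve$z))
  hw <- window %/% 2L
  thr <- prominence_factor * noise_sd / (window * dz)

  empty <- data.frame(z_position = numeric(), force_jump = numeric(),
                      pre_force = numeric(), post_force = numeric())
  # local maxima (leftmost sample of plateaus), excluding filter edges
  lo <- hw + 1L; hi <- n - hw
  if (hi <= lo) return(empty)
  i <- lo:hi
  is_max <- d[i] > d[i - 1L] & d[i] >= d[i + 1L]
  cand <- i[is_max & d[i] > 0]
  if (!length(cand)) return(empty)

  # local prominence: peak minus the higher of the flanking minima
  prom <- vapply(cand, function(j) {
    l <- max(1L, j - window); r <- min(n, j + window)
    d[j] - max(min(d[l:j]), min(d[j:r]))
  }, numeric(1))
  cand <- cand[prom > thr & d[cand] > thr]
  if (!length(cand)) return(empty)

  # merge candidates within one window: keep the highest (leftmost on ties)
  ord <- order(cand)
  cand <- cand[ord]
  keep <- logical(length(cand))
  grp_start <- 1L
  for (k in seq_along(cand)) {
    if (k == length(cand) || cand[k + 1L] - cand[k] > window) {
      g <- grp_start:k
      best <- g[which.max(d[cand[g]])]
      keep[best] <- TRUE
      grp_start <- k + 1L
    }
  }
  cand <- cand[keep]

  # force jump from flank medians; significance gate
  pre <- post <- jump <- se <- numeric(length(cand))
  for (k in seq_along(cand)) {
    j <- cand[k]
    pre_idx <- max(1L, j - 2L * hw):max(1L, j - hw)
    post_idx <- min(n, j + hw):min(n, j + 2L * hw)
    pre[k] <- median(curve$force[pre_idx])
    post[k] <- median(curve$force[post_idx])
    jump[k] <- post[k] - pre[k]
    # var of a median of m Gaussians ~ (pi/2) sd^2 / m
    m_eff <- min(length(pre_idx), length(post_idx))
    se[k] <- noise_sd * sqrt(pi / (2 * m_eff)) * sqrt(2)
  }
  ok <- jump > 0 & jump > prominence_factor * se
  if (!any(ok)) return(empty)
  data.frame(z_position = curve$z[cand[ok]], force_jump = jump[ok],
             pre_force = pre[ok], post_force = post[ok])
}

#' Final detachment point
#'
#' The last rupture event marks full separation of the cells: returns its z
#' and the pre-rupture force relative to the baseline.
#'
#' @param events Event table from [detect_discontinuities()].
#' @param baseline_level Baseline level in nN.
#' @return List with `z_det` (raw um) and `f_det` (nN, baseline-relative,
#'   negative for adhesive curves).
#' @export
find_detachment_point <- function(events, baseline_level = 0) {
  if (!NROW(events))
    stop("no detachment detected: empty rupture-event list")
  last <- which.max(events$z_position)
  list(z_det = events$z_position[last],
       f_det = events$pre_force[last] - baseline_level)
}

#' Detachment work by trapezoidal integration
#'
#' W = -integral from Z = 0 to Z = Z_det of the baseline-subtracted force
#' over distance, in fJ (nN um). Adhesive (negative) force contributes
#' positively; repulsive excursions subtract; no floor at zero is applied.
#' Both integration limits are handled with sub-sample linear
#' interpolation.
#'
#' @param curve A [force_curve()].
#' @param z_det Detachment position relative to the origin (um, > 0).
#' @param origin_z Origin in raw coordinates (um), from [find_origin()].
#' @param baseline_level Baseline level (nN).
#' @return Work in fJ.
#' @export
compute_detachment_work <- function(curve, z_det, origin_z = 0,
                                    baseline_level = 0) {
  if (!is.numeric(z_det) || z_det <= 0) stop("z_det must be > 0")
  z_hi <- origin_z + z_det
  if (z_hi > max(curve$z) + 1e-12)
    stop("z_det lies beyond the last sample of the curve")
  z <- curve$z
  f <- curve$force - baseline_level
  inside <- z > origin_z & z < z_hi
  zi <- z[inside]; fi <- f[inside]
  f_lo <- approx(z, f, xout = origin_z, rule = 2)$y
  f_hi <- approx(z, f, xout = z_hi, rule = 2)$y
  zz <- c(origin_z, zi, z_hi)
  ff <- c(f_lo, fi, f_hi)
  -sum(diff(zz) * (head(ff, -1) + tail(ff, -1)) / 2)
}

#' Full retract-segment analysis of one curve
#'
#' Runs the pipeline baseline -> origin -> Savitzky-Golay derivative ->
#' rupture events -> detachment point -> detachment work -> maximum
#' adhesion. Deterministic for fixed inputs. Curves failing a stage
#' (insufficient baseline window, no baseline crossing, no detected
#' detachment) are returned flagged with the failure reason, never dropped.
#'
#' @param curve A [force_curve()].
#' @param params An [analysis_params()] object.
#' @return A `ccfs_result` list: `work` (fJ), `z_det` (um, origin-relative),
#'   `f_det` (nN), `events` (data.frame, z origin-relative), `max_adhesion`
#'   (nN, positive magnitude), `baseline_level`, `noise_sd`, `origin_z`
#'   (raw um), `metadata`, `flagged`, `flag_reason`, `params`.
#' @export
analyze_curve <- function(curve, params = analysis_params()) {
  stopifnot(inherits(curve, "ccfs_curve"), inherits(params, "ccfs_params"))
  md <- curve$metadata
  flag <- function(reason, bl = NULL, org = NA_real_) {
    structure(list(work = NA_real_, z_det = NA_real_, f_det = NA_real_,
                   events = NULL, max_adhesion = NA_real_,
                   baseline_level = if (is.null(bl)) NA_real_ else bl$level,
                   noise_sd = if (is.null(bl)) NA_real_ else bl$noise_sd,
                   origin_z = org, metadata = md, flagged = TRUE,
                   flag_reason = reason, params = params),
              class = "ccfs_result")
  }

  if (params$distance == "separation" && !curve$corrected) {
    sep <- correct_bending(curve$z, curve$force, md$spring_constant)
    if (any(diff(sep) <= 0)) return(flag("non-monotonic after correction"))
    curve <- force_curve(sep, curve$force, metadata = md,
                         approach = curve$approach, corrected = TRUE)
  }

  bl <- tryCatch(estimate_baseline(curve, params$tail_fraction),
                 error = function(e) e)
  if (inherits(bl, "error")) return(flag(conditionMessage(bl)))

  org <- tryCatch(find_origin(curve, bl$level), error = function(e) e)
  if (inherits(org, "error")) return(flag(conditionMessage(org), bl))

  deriv <- smooth_derivative(curve, params$sg_window, params$sg_order)
  ev <- detect_discontinuities(curve, deriv,
                               prominence_factor = params$prominence_factor,
                               noise_sd = bl$noise_sd,
                               window = params$sg_window,
                               derivative = params$derivative)
  ev <- ev[ev$z_position > org, , drop = FALSE]
  if (!NROW(ev)) return(flag("no detachment detected", bl, org))

  det <- find_detachment_point(ev, bl$level)
  z_det_rel <- det$z_det - org
  W <- compute_detachment_work(curve, z_det_rel, origin_z = org,
                               baseline_level = bl$level)
  win <- curve$z >= org & curve$z <= det$z_det
  max_adh <- max(bl$level - curve$force[win])

  ev$z_position <- ev$z_position - org
  structure(list(work = W, z_det = z_det_rel, f_det = det$f_det,
                 events = ev, max_adhesion = max_adh,
                 baseline_level = bl$level, noise_sd = bl$noise_sd,
                 origin_z = org, metadata = md, flagged = FALSE,
                 flag_reason = "", params = params),
            class = "ccfs_result")
}

#' @export
print.ccfs_result <- function(x, ...) {
  if (x$flagged) {
    cat("<ccfs_result> FLAGGED:", x$flag_reason, "\n")
  } else {
    cat(sprintf(
      "<ccfs_result> W = %.4g fJ, Z_det = %.4g um, F_det = %.4g nN, %d events, max adhesion %.4g nN\n",
      x$work, x$z_det, x$f_det, NROW(x$events), x$max_adhesion))
  }
  invisible(x)
}
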