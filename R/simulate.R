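#' Simulation configuration for synthetic CCFS experiments
#'
#' Collects everything the generator needs: the acquisition metadata
#' template, the Hertz contact parameters that shape the contact-area
#' trajectory, the stochastic bond model (Poisson formation proportional to
#' the time-integrated contact area; truncated-normal rupture forces;
#' shifted-exponential rupture extensions), the viscous drag, measurement
#' noise, and the constant-height dwell relaxation.
#'
#' The default bond formation rate (0.218 bonds/(um^2 s)) is calibrated so
#' that, at the baseline acquisition condition (v_a = v_r = 10 um/s,
#' F0 = 1 nN, constant height), the expected detachment work grows with the
#' dwell time at 1.72 fJ/s — the published linear delay-time response.
#'
#' @param metadata [curve_metadata()] template (condition values).
#' @param hertz [hertz_params()].
#' @param k_on Bond formation rate in bonds/(um^2 s).
#' @param mean_rupture_force Mean single-bond rupture force in nN.
#' @param rupture_force_sd SD of the rupture force in nN.
#' @param min_rupture_force Lower truncation of the rupture force in nN.
#' @param mean_rupture_extension Mean rupture position in um (shifted
#'   exponential with this mean).
#' @param extension_spread SD (and exponential scale) of the rupture
#'   position in um; must be < `mean_rupture_extension` so the shift is
#'   positive.
#' @param drag_coefficient Viscous drag coefficient in nN s/um (drag force
#'   = coefficient * v_r near contact).
#' @param drag_decay_length Decay length of the drag force in um.
#' @param noise_sd Gaussian measurement noise SD in nN.
#' @param relaxation_time Time constant (s) of the constant-height dwell
#'   force relaxation.
#' @param relaxation_floor Fraction of the setpoint the constant-height
#'   dwell force relaxes to (default 0.4).
#' @param sampling_rate Samples per um of the retract ramp.
#' @param min_rupture_spacing Optional minimum spacing (um) between rupture
#'   positions; NULL (default) leaves positions independent. Useful when a
#'   test requires every rupture to be resolvable by the detector.
#' @param bell_coefficient Optional Bell-kinetics coefficient: the mean
#'   rupture force is scaled by (1 + bell_coefficient * log(v_r /
#'   bell_v_ref)). Default 0 (off).
#' @param bell_v_ref Reference speed (um/s) for the Bell scaling.
#' @return A `ccfs_simconfig` list.
#' @export
simulation_config <- function(metadata = curve_metadata(),
                              hertz = hertz_params(),
                              k_on = 0.218,
                              mean_rupture_force = 0.3,
                              rupture_force_sd = 0.1,
                              min_rupture_force = 0.05,
                              mean_rupture_extension = 8,
                              extension_spread = 6,
                              drag_coefficient = 0.005,
                              drag_decay_length = 2,
                              noise_sd = 0.01,
                              relaxation_time = 5,
                              relaxation_floor = 0.4,
                              sampling_rate = 100,
                              min_rupture_spacing = NULL,
                              bell_coefficient = 0,
                              bell_v_ref = 1) {
  stopifnot(
    inherits(metadata, "ccfs_metadata"), inherits(hertz, "ccfs_hertz"),
    k_on >= 0, mean_rupture_force > 0, rupture_force_sd > 0,
    min_rupture_force > 0, mean_rupture_extension > 0,
    extension_spread > 0, extension_spread < mean_rupture_extension,
    drag_coefficient >= 0, drag_decay_length > 0, noise_sd >= 0,
    relaxation_time > 0, relaxation_floor > 0, relaxation_floor <= 1,
    sampling_rate > 0, bell_v_ref > 0
  )
  structure(list(metadata = metadata, hertz = hertz, k_on = k_on,
                 mean_rupture_force = mean_rupture_force,
                 rupture_force_sd = rupture_force_sd,
                 min_rupture_force = min_rupture_force,
                 mean_rupture_extension = mean_rupture_extension,
                 extension_spread = extension_spread,
                 drag_coefficient = drag_coefficient,
                 drag_decay_length = drag_decay_length,
                 noise_sd = noise_sd, relaxation_time = relaxation_time,
                 relaxation_floor = relaxation_floor,
                 sampling_rate = sampling_rate,
                 min_rupture_spacing = min_rupture_spacing,
                 bell_coefficient = bell_coefficient,
                 bell_v_ref = bell_v_ref),
            class = "ccfs_simconfig")
}

# dwell force fraction of setpoint at dwell time t (constant height)
.dwell_relax <- function(t, cfg) {
  cfg$relaxation_floor + (1 - cfg$relaxation_floor) *
    exp(-t / cfg$relaxation_time)
}

#' Contact-area trajectory of one simulated contact
#'
#' Piecewise trajectory of the instantaneous interaction surface S(t):
#' approach at v_a from first contact to the Hertz indentation delta0 at
#' the setpoint (S = pi R v_a t), a dwell of duration tau (S constant at
#' pi R delta0 in constant-force mode; relaxing with the dwell force as
#' S = A0 (F(t)/F0)^(2/3) in constant-height mode), and the in-contact part
#' of the retraction back to zero indentation at v_r.
#'
#' @param cfg A [simulation_config()].
#' @return A [contact_trajectory()].
#' @export
simulate_contact_phase <- function(cfg) {
  md <- cfg$metadata
  d0 <- hertz_indentation(md$setpoint, cfg$hertz)
  A0 <- hertz_contact_area(d0, cfg$hertz)
  piR <- pi * cfg$hertz$R

  t_app <- d0 / md$approach_speed
  tt <- seq(0, t_app, length.out = 64)
  times <- tt
  S <- piR * md$approach_speed * tt
  phase <- rep("approach", length(tt))

  tau <- md$delay_time
  if (tau > 0) {
    td <- seq(0, tau, length.out = 256)[-1]
    Sd <- if (md$delay_mode == "constant_force") rep(A0, length(td))
          else A0 * .dwell_relax(td, cfg)^(2 / 3)
    times <- c(times, t_app + td)
    S <- c(S, Sd)
    phase <- c(phase, rep("dwell", length(td)))
  }

  t_ret <- d0 / md$retract_speed
  tr <- seq(0, t_ret, length.out = 64)[-1]
  times <- c(times, t_app + tau + tr)
  S <- c(S, piR * (d0 - md$retract_speed * tr))
  phase <- c(phase, rep("retract", length(tr)))

  contact_trajectory(times, pmax(S, 0), phase)
}

#' Draw the number of bonds formed during one contact
#'
#' N ~ Poisson(k_on * integral S(t) dt).
#'
#' @param traj A [contact_trajectory()].
#' @param k_on Bond formation rate in bonds/(um^2 s).
#' @param seed Optional integer seed (scoped; does not disturb the global
#'   RNG stream).
#' @return Integer bond count.
#' @export
draw_bond_count <- function(traj, k_on, seed = NULL) {
  lambda <- bond_number_integral(traj, k_on)
  if (lambda == 0) return(0L)
  draw <- function() rpois(1L, lambda)
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

# truncated normal draws via inverse-CDF, lower truncation only
.rtnorm <- function(n, mean, sd, lower) {
  p0 <- pnorm(lower, mean, sd)
  qnorm(p0 + runif(n) * (1 - p0), mean, sd)
}

# mean of the lower-truncated normal
.etnorm <- function(mean, sd, lower) {
  a <- (lower - mean) / sd
  mean + sd * dnorm(a) / (1 - pnorm(a))
}

# effective mean rupture force, optionally Bell-scaled with retract speed
.rupture_force_mean <- function(cfg, v_r) {
  cfg$mean_rupture_force *
    (1 + cfg$bell_coefficient * log(v_r / cfg$bell_v_ref))
}

# noiseless retract force at separations z for given bonds
# bonds: list(f = rupture forces, x = rupture positions)
.noiseless_force <- function(z, cfg, bonds, F_start, d0) {
  f_rep <- ifelse(z < d0, F_start * pmax(1 - z / d0, 0)^(3 / 2), 0)
  f_drag <- -cfg$drag_coefficient * cfg$metadata$retract_speed *
    exp(-z / cfg$drag_decay_length)
  if (length(bonds$x)) {
    ord <- order(bonds$x)
    xs <- bonds$x[ord]
    slopes <- bonds$f[ord] / xs           # per-bond loading slope f/x
    csum <- c(0, cumsum(slopes))
    n_broken <- findInterval(z, xs)       # bonds with x <= z have ruptured
    f_bond <- -z * (csum[length(csum)] - csum[n_broken + 1L])
  } else f_bond <- 0
  f_rep + f_bond + f_drag
}

#' Synthesize one CCFS retract curve with ground truth
#'
#' Builds the retract trace on a uniform separation grid: a repulsive
#' contact region decaying from the end-of-dwell force over the Hertz
#' indentation, one linear loading ramp per bond that breaks with a discrete
#' upward force step at its rupture position, a smooth viscous drag near
#' contact, and Gaussian measurement noise. The ground truth records every
#' rupture and the exact detachment work of the noiseless trace (10x
#' oversampled trapezoidal integral from its baseline crossing to the last
#' rupture).
#'
#' @param cfg A [simulation_config()].
#' @param n_bonds Number of bonds (e.g. from [draw_bond_count()]).
#' @param seed Optional integer seed (scoped).
#' @return List with `curve` (a [force_curve()]) and `truth` (list:
#'   `n_bonds`, `rupture_z`, `rupture_force`, `origin_z`, `z_det` (um,
#'   origin-relative), `W` (fJ; NA when no bonds), `dwell_force` (data.frame
#'   t, force of the dwell phase)).
#' @export
synthesize_retract_curve <- function(cfg, n_bonds, seed = NULL) {
  run <- function() {
    md <- cfg$metadata
    d0 <- hertz_indentation(md$setpoint, cfg$hertz)
    F_start <- if (md$delay_mode == "constant_height")
      md$setpoint * .dwell_relax(md$delay_time, cfg) else md$setpoint

    mu_f <- .rupture_force_mean(cfg, md$retract_speed)
    shift <- cfg$mean_rupture_extension - cfg$extension_spread
    draw_x <- function(n) shift + rexp(n, rate = 1 / cfg$extension_spread)
    f <- if (n_bonds > 0)
      .rtnorm(n_bonds, mu_f, cfg$rupture_force_sd, cfg$min_rupture_force)
      else numeric()
    x <- if (n_bonds > 0) draw_x(n_bonds) else numeric()
    if (!is.null(cfg$min_rupture_spacing) && n_bonds > 1) {
      for (it in 1:200) {
        xs <- sort(x)
        if (min(diff(xs)) >= cfg$min_rupture_spacing &&
            min(xs) >= cfg$min_rupture_spacing) break
        bad <- which(x %in% xs[c(FALSE, diff(xs) < cfg$min_rupture_spacing)] |
                       x < cfg$min_rupture_spacing)
        x[bad] <- draw_x(length(bad))
      }
    }
    x <- pmin(x, md$curve_length * 0.95)  # ruptures stay inside the ramp
    bonds <- list(f = f, x = x)

    z <- seq(0, md$curve_length, by = 1 / cfg$sampling_rate)
    f_clean <- .noiseless_force(z, cfg, bonds, F_start, d0)
    force <- f_clean + if (cfg$noise_sd > 0)
      rnorm(length(z), 0, cfg$noise_sd) else 0

    # ground truth from the noiseless trace on a 10x finer grid
    truth <- list(n_bonds = as.integer(n_bonds), rupture_z = x,
                  rupture_force = f, origin_z = NA_real_, z_det = NA_real_,
                  W = NA_real_)
    if (n_bonds > 0) {
      z_last <- max(x)
      zf <- seq(0, z_last, by = 1 / (10 * cfg$sampling_rate))
      ff <- .noiseless_force(zf, cfg, bonds, F_start, d0)
      cross <- which(ff[-length(ff)] > 0 & ff[-1] <= 0)
      org <- if (length(cross)) {
        i <- cross[1]
        zf[i] - ff[i] * (zf[i + 1] - zf[i]) / (ff[i + 1] - ff[i])
      } else 0
      sel <- zf > org
      zz <- c(org, zf[sel])
      yy <- c(0, ff[sel])
      truth$origin_z <- org
      truth$z_det <- z_last - org
      truth$W <- -sum(diff(zz) * (head(yy, -1) + tail(yy, -1)) / 2)
    }
    tdw <- seq(0, md$delay_time, length.out = 128)
    truth$dwell_force <- data.frame(
      t = tdw,
      force = if (md$delay_mode == "constant_height")
        md$setpoint * .dwell_relax(tdw, cfg) else rep(md$setpoint, 128))

    list(curve = force_curve(z, force, metadata = md, corrected = TRUE),
         truth = truth)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Generate a synthetic CCFS experiment sweep on disk
#'
#' Writes `n_per_condition` ccfs-txt curve files per condition value of one
#' acquisition variable, each simulated end to end (contact trajectory ->
#' Poisson bond count -> retract trace), plus a `manifest.csv` linking every
#' file to its ground truth. Deterministic under a fixed master seed:
#' per-curve seeds are derived by (condition index, curve index), so adding
#' conditions never reshuffles existing curves.
#'
#' @param cfg A [simulation_config()] (its metadata supplies all
#'   non-swept condition values).
#' @param variable One of `"delay_time"`, `"setpoint"`, `"approach_speed"`,
#'   `"retract_speed"`, `"delay_mode"`.
#' @param values Vector of condition values to sweep.
#' @param n_per_condition Curves per condition.
#' @param out_dir Output folder (created if missing).
#' @param master_seed Integer master seed.
#' @return Invisibly, the manifest data.frame (`file`, `variable`, `value`,
#'   `seed`, `true_n_bonds`, `true_W_fJ`).
#' @export
generate_experiment <- function(cfg, variable, values, n_per_condition,
                                out_dir, master_seed = 1) {
  variable <- match.arg(variable, c("delay_time", "setpoint",
                                    "approach_speed", "retract_speed",
                                    "delay_mode"))
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output folder: ", out_dir)
  }
  rows <- vector("list", length(values) * n_per_condition)
  r <- 0L
  for (i in seq_along(values)) {
    md <- cfg$metadata
    md[[variable]] <- values[i]
    md <- do.call(curve_metadata, md[setdiff(names(md), "extra")])
    cfg_i <- cfg; cfg_i$metadata <- md
    traj <- simulate_contact_phase(cfg_i)
    for (j in seq_len(n_per_condition)) {
      seed_ij <- as.integer(master_seed + 9973L * i + j)
      n_bonds <- draw_bond_count(traj, cfg$k_on, seed = seed_ij)
      sim <- synthesize_retract_curve(cfg_i, n_bonds, seed = seed_ij + 1L)
      fname <- sprintf("cond%02d_%s_curve%03d.txt", i,
                       gsub("[^0-9A-Za-z._-]", "", as.character(values[i])),
                       j)
      sim$curve$metadata$source_id <- fname
      sim$curve$metadata$extra$seed <- seed_ij
      write_curve_file(sim$curve, file.path(out_dir, fname))
      r <- r + 1L
      rows[[r]] <- data.frame(file = fname, variable = variable,
                              value = as.character(values[i]),
                              seed = seed_ij,
                              true_n_bonds = sim$truth$n_bonds,
                              true_W_fJ = sim$truth$W,
                              stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Analytic expected detachment work of the simulator
#'
#' E[W] = k_on * integral(S(t) dt) * (E[f_rupture] E[x_rupture] / 2)
#' + drag work, where the contact-area integral is evaluated in closed form
#' for the approach and retract phases and by quadrature for the
#' constant-height dwell relaxation, E[f] is the truncated-normal mean and
#' E[x] the shifted-exponential mean, and the drag work is the asymptotic
#' integral of the drag force (coefficient * v_r * decay length). The small
#' repulsive-region and pre-origin corrections are neglected.
#'
#' @param cfg A [simulation_config()].
#' @return Expected work in fJ.
#' @export
expected_detachment_work <- function(cfg) {
  md <- cfg$metadata
  d0 <- hertz_indentation(md$setpoint, cfg$hertz)
  A0 <- hertz_contact_area(d0, cfg$hertz)
  piR <- pi * cfg$hertz$R
  I_app <- piR * d0^2 / (2 * md$approach_speed)
  I_ret <- piR * d0^2 / (2 * md$retract_speed)
  I_dwell <- if (md$delay_time == 0) 0
  else if (md$delay_mode == "constant_force") A0 * md$delay_time
  else A0 * integrate(function(t) .dwell_relax(t, cfg)^(2 / 3),
                      0, md$delay_time, rel.tol = 1e-10)$value
  Ef <- .etnorm(.rupture_force_mean(cfg, md$retract_speed),
                cfg$rupture_force_sd, cfg$min_rupture_force)
  Ex <- cfg$mean_rupture_extension
  w_bond <- Ef * Ex / 2
  cfg$k_on * (I_app + I_dwell + I_ret) * w_bond +
    cfg$drag_coefficient * md$retract_speed * cfg$drag_decay_length
}

#' Noisy staircase fixture for the rupture-event detector
#'
#' Deterministic-geometry staircase: the force starts at minus the sum of
#' the step heights and steps up to zero at each step position, with
#' optional Gaussian noise — the idealised multi-rupture trace the detector
#' must segment. Step positions are drawn uniformly with a guaranteed
#' minimum spacing so every step is resolvable.
#'
#' @param n_steps Number of steps (>= 1).
#' @param step_height Step height(s) in nN, recycled to `n_steps`.
#' @param length_um Curve length in um (default 20).
#' @param sampling_rate Samples per um (default 100).
#' @param noise_sd Gaussian noise SD in nN (default 0).
#' @param min_spacing Minimum spacing between steps in um (default 1).
#' @param seed Optional integer seed (scoped).
#' @return List with `curve` ([force_curve()]) and `truth` (list `n_steps`,
#'   `z_steps`, `heights`).
#' @export
simulate_staircase <- function(n_steps, step_height = 0.4, length_um = 20,
                               sampling_rate = 100, noise_sd = 0,
                               min_spacing = 1, seed = NULL) {
  stopifnot(n_steps >= 1)
  run <- function() {
    h <- rep_len(step_height, n_steps)
    lo <- min_spacing
    hi <- length_um * 0.8
    if (hi - lo < (n_steps - 1) * min_spacing)
      stop("cannot place ", n_steps, " steps with spacing ", min_spacing)
    repeat {
      zs <- sort(runif(n_steps, lo, hi))
      if (n_steps == 1 || min(diff(zs)) >= min_spacing) break
    }
    z <- seq(0, length_um, by = 1 / sampling_rate)
    force <- -vapply(z, function(zz) sum(h[zs > zz]), numeric(1))
    if (noise_sd > 0) force <- force + rnorm(length(z), 0, noise_sd)
    list(curve = force_curve(z, force, metadata = curve_metadata(
           source_id = "staircase"), corrected = TRUE),
         truth = list(n_steps = as.integer(n_steps), z_steps = zs,
                      heights = h))
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
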