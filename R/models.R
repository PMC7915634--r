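#' Hertz contact parameters
#'
#' @param R Effective radius of the contacting cells in um (> 0).
#' @param E_eff Effective elastic modulus in nN/um^2 (numerically equal to
#'   kPa; > 0). Soft cells are of order 1 kPa.
#' @return A `ccfs_hertz` list.
#' @export
hertz_params <- function(R = 10, E_eff = 1) {
  stopifnot("R must be > 0" = R > 0, "E_eff must be > 0" = E_eff > 0)
  structure(list(R = as.numeric(R), E_eff = as.numeric(E_eff)),
            class = "ccfs_hertz")
}

# Hertz prefactor C in F = C * delta^(3/2); standard sphere contact form.
.hertz_prefactor <- function(hp) (4 / 3) * hp$E_eff * sqrt(hp$R)

#' Hertz indentation at a given setpoint force
#'
#' Inverts the sphere-contact law F0 = C delta^(3/2) with
#' C = (4/3) E_eff sqrt(R), giving delta0 = (F0 / C)^(2/3). Only the 2/3
#' exponent matters for the work models; the prefactor sets the scale.
#'
#' @param F0 Setpoint force(s) in nN (> 0).
#' @param hp [hertz_params()].
#' @return Indentation(s) delta0 in um.
#' @export
hertz_indentation <- function(F0, hp = hertz_params()) {
  if (any(F0 <= 0)) stop("F0 must be > 0")
  (F0 / .hertz_prefactor(hp))^(2 / 3)
}

#' Hertz force at a given indentation (inverse of [hertz_indentation()])
#'
#' @param delta Indentation(s) in um (>= 0).
#' @param hp [hertz_params()].
#' @return Force(s) in nN.
#' @export
hertz_force <- function(delta, hp = hertz_params()) {
  if (any(delta < 0)) stop("delta must be >= 0")
  .hertz_prefactor(hp) * delta^(3 / 2)
}

#' Hertz contact area
#'
#' A = pi a^2 = pi R delta0, with contact radius a = sqrt(R delta0).
#' Composed with [hertz_indentation()], A is proportional to F0^(2/3).
#'
#' @param delta0 Indentation(s) in um (>= 0).
#' @param hp [hertz_params()].
#' @param radius If TRUE return the contact radius a (um) instead of A.
#' @return Contact area(s) in um^2 (or radius in um).
#' @export
hertz_contact_area <- function(delta0, hp = hertz_params(), radius = FALSE) {
  if (any(delta0 < 0)) stop("delta0 must be >= 0")
  if (radius) sqrt(hp$R * delta0) else pi * hp$R * delta0
}

#' Contact trajectory container
#'
#' Time course of the instantaneous cell-cell interaction surface S(t) over
#' the interaction time, with per-sample phase labels.
#'
#' @param times Strictly increasing times in s.
#' @param S Contact areas in um^2 (>= 0), same length.
#' @param phase Character vector of `"approach"`, `"dwell"`, `"retract"`.
#' @return A `ccfs_trajectory` list.
#' @export
contact_trajectory <- function(times, S, phase) {
  stopifnot(length(times) == length(S), length(times) == length(phase))
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (any(S < 0)) stop("contact area must be >= 0")
  if (!all(phase %in% c("approach", "dwell", "retract")))
    stop("phase labels must be approach/dwell/retract")
  structure(list(times = as.numeric(times), S = as.numeric(S),
                 phase = as.character(phase)), class = "ccfs_trajectory")
}

#' Expected number of bonds from the contact-area integral
#'
#' The bond-number model: the expected number of cell-cell bonds formed
#' during contact is proportional to the time integral of the instantaneous
#' interaction surface, N = rate * integral S(t) dt (trapezoidal rule over
#' all in-contact samples).
#'
#' @param traj A [contact_trajectory()].
#' @param rate_constant Bond formation rate in bonds/(um^2 s) (>= 0).
#' @return Expected bond count (dimensionless).
#' @export
bond_number_integral <- function(traj, rate_constant) {
  stopifnot(inherits(traj, "ccfs_trajectory"))
  if (rate_constant < 0) stop("rate_constant must be >= 0")
  rate_constant * .trapz(traj$times, traj$S)
}

.trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)

#' Detachment work versus delay time: W = A + B tau
#'
#' Linear model: bond number (hence work) grows in proportion to the time
#' spent in contact, plus a small offset from the indentation phase.
#'
#' @param tau Delay time(s) in s (>= 0).
#' @param A Offset in fJ.
#' @param B Slope in fJ/s.
#' @return Work in fJ.
#' @export
model_W_delay <- function(tau, A, B) {
  if (any(tau < 0)) stop("tau must be >= 0")
  A + B * tau
}

#' Detachment work versus setpoint force: W = A + B F0^(2/3)
#'
#' The Hertz contact area, and with it the bond number, scales as F0^(2/3).
#'
#' @param F0 Setpoint force(s) in nN (>= 0).
#' @param A Offset in fJ.
#' @param B Coefficient in fJ per nN^(2/3).
#' @return Work in fJ.
#' @export
model_W_setpoint <- function(F0, A, B) {
  if (any(F0 < 0)) stop("F0 must be >= 0")
  A + B * F0^(2 / 3)
}

#' Detachment work versus approach speed: W = A tau B / (B + v_a)
#'
#' The effective contact time shrinks inversely with the approach speed (the
#' hold position is the same for every speed), saturating at the full dwell
#' time tau as v_a -> 0: W = A * tau_eff with tau_eff = tau B / (B + v_a).
#' B is the half-saturation speed.
#'
#' @param v_a Approach speed(s) in um/s (> 0).
#' @param A Energy rate in fJ/s.
#' @param B Half-saturation speed in um/s.
#' @param tau Dwell time in s (default 45, the baseline condition).
#' @return Work in fJ.
#' @export
model_W_approach <- function(v_a, A, B, tau = 45) {
  if (any(v_a <= 0)) stop("v_a must be > 0")
  A * tau * B / (B + v_a)
}

#' Detachment work versus retract speed: W = A g v_r + B log(1 + v_r/v_ref)
#'
#' Viscous drag linear in the pulling speed dominates at high speed; a
#' kinetic (force-assisted bond dissociation) term gives the logarithmic
#' dependence at low speed. The geometry factor g (default 6 pi R with
#' R = 10 um) and the reference speed v_ref (default 1 um/s) are fixed
#' constants so that only A and B are free fit parameters.
#'
#' @param v_r Retract speed(s) in um/s (> 0).
#' @param A Drag coefficient (viscosity-like, fJ s/um^2 once multiplied by
#'   the geometry factor and speed).
#' @param B Kinetic term amplitude in fJ.
#' @param geometry Dimensionless-by-convention geometry factor, default
#'   6 pi 10.
#' @param v_ref Reference speed in um/s, default 1.
#' @return Work in fJ.
#' @export
model_W_retract <- function(v_r, A, B, geometry = 6 * pi * 10, v_ref = 1) {
  if (any(v_r <= 0)) stop("v_r must be > 0")
  A * geometry * v_r + B * log(1 + v_r / v_ref)
}

#' Registry of the four detachment-work models
#'
#' Maps a model id to its functional form, the results-CSV column holding
#' its condition variable, and the initialisation heuristic used by
#' [fit_model()].
#'
#' @param model_id One of `"delay"`, `"setpoint"`, `"approach"`,
#'   `"retract"`.
#' @return A `ccfs_model` list with `model_id`, `fun(x, A, B, ...)`,
#'   `variable` (condition column), `init(x, y)` returning c(A, B), and
#'   `lower` bounds for (A, B).
#' @export
model_spec <- function(model_id = c("delay", "setpoint", "approach",
                                    "retract")) {
  model_id <- match.arg(model_id)
  spec <- switch(model_id,
    delay = list(
      fun = function(x, A, B) model_W_delay(x, A, B),
      variable = "delay_time_s",
      init = function(x, y) {
        b <- coef(lm(y ~ x)); c(A = unname(b[1]), B = max(unname(b[2]), 1e-8))
      },
      lower = c(A = -Inf, B = 0)),
    setpoint = list(
      fun = function(x, A, B) model_W_setpoint(x, A, B),
      variable = "setpoint_nN",
      init = function(x, y) {
        b <- coef(lm(y ~ I(x^(2 / 3))))
        c(A = unname(b[1]), B = max(unname(b[2]), 1e-8))
      },
      lower = c(A = -Inf, B = 0)),
    approach = list(
      fun = function(x, A, B) model_W_approach(x, A, B),
      variable = "approach_speed_um_s",
      init = function(x, y) {
        c(A = max(y) / 45, B = unname(median(x)))
      },
      lower = c(A = 0, B = 1e-8)),
    retract = list(
      fun = function(x, A, B) model_W_retract(x, A, B),
      variable = "retract_speed_um_s",
      init = function(x, y) {
        g <- 6 * pi * 10
        b <- coef(lm(y ~ 0 + I(g * x) + log1p(x)))
        c(A = max(unname(b[1]), 1e-10), B = max(unname(b[2]), 1e-8))
      },
      lower = c(A = 0, B = 0))
  )
  structure(c(list(model_id = model_id), spec), class = "ccfs_model")
}
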