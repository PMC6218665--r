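# Modified Aliev-Panfilov reaction kinetics, voltage normalization and the
# explicit gating update.
#
# The kinetic functions f and g below are the phenomenological two-variable
# model in its dimensionless form. Physical (millisecond) time enters
# through the conversion constant tau carried by the parameter set: the
# monodomain solver uses f/tau as the per-ms reaction rate and advances the
# recovery variable with model-time increments dt/tau. tau = 12.9 ms is the
# standard Aliev-Panfilov time normalization; with it the model reproduces
# physiological upstroke slopes, action-potential durations of ~200 ms and,
# together with D = 0.0952 mm^2/ms, plane-wave conduction velocities near
# 37 cm/s.

#' Modified Aliev-Panfilov parameter set
#'
#' Defaults are the standard constants of the modified model:
#' `alpha = 0.05` (excitation threshold), `c1 = 52`, `c2 = 8` (excitation
#' and repolarization strengths), `mu1 = 0.1`, `mu2 = 0.3`, `b = 0.25`,
#' `gamma = 0.002` (recovery kinetics), resting and peak transmembrane
#' voltages `V_r = -85` mV, `V_p = 15` mV. `tau` (ms per model time unit)
#' couples the dimensionless kinetics to millisecond-valued simulations and
#' `r0 = 0.1146` is the initial recovery value representing the resting
#' steady-state regime.
#'
#' @param alpha,c1,c2,mu1,mu2,b,gamma dimensionless kinetic constants.
#' @param V_r,V_p resting and peak voltages (mV), `V_p > V_r`.
#' @param tau time-scale conversion (ms per model time unit).
#' @param r0 initial recovery value.
#' @return An `ionic_params` list.
#' @export
aliev_panfilov_params <- function(alpha = 0.05, c1 = 52, c2 = 8,
                                  mu1 = 0.1, mu2 = 0.3, b = 0.25,
                                  gamma = 0.002, V_r = -85, V_p = 15,
                                  tau = 12.9, r0 = 0.1146) {
  if (V_p <= V_r) stop("V_p must exceed V_r")
  if (tau <= 0) stop("tau must be positive")
  structure(list(alpha = alpha, c1 = c1, c2 = c2, mu1 = mu1, mu2 = mu2,
                 b = b, gamma = gamma, V_r = V_r, V_p = V_p,
                 tau = tau, r0 = r0),
            class = "ionic_params")
}

as_ionic_params <- function(params) {
  if (inherits(params, "ionic_params")) return(params)
  if (is.list(params)) return(do.call(aliev_panfilov_params, params))
  stop("params must be an ionic_params object or a named list")
}

#' Normalized ionic current f(phi, r)
#'
#' \eqn{f(\phi, r) = c_1\phi(\phi-\alpha)(1-\phi) - c_2 r \phi}, the cubic
#' excitation term minus the recovery-gated repolarizing current.
#' Vectorizes over `phi` and `r` of any common shape; the rate is per model
#' time unit (divide by `params$tau` for per-ms).
#'
#' @param phi normalized potential (may transiently leave `[0,1]`).
#' @param r recovery variable.
#' @param params an [aliev_panfilov_params()] set.
#' @export
ionic_current <- function(phi, r, params = aliev_panfilov_params()) {
  params$c1 * phi * (phi - params$alpha) * (1 - phi) - params$c2 * r * phi
}

#' Recovery kinetics g(phi, r)
#'
#' \eqn{g(\phi, r) = (\gamma + \mu_1 r/(\mu_2+\phi))(-r - c_2\phi(\phi-b-1))}.
#' Rate per model time unit, vectorized like [ionic_current()].
#'
#' @inheritParams ionic_current
#' @export
gating_rate <- function(phi, r, params = aliev_panfilov_params()) {
  den <- params$mu2 + phi
  if (any(den == 0)) stop("gating_rate: mu2 + phi vanished")
  (params$gamma + params$mu1 * r / den) *
    (-r - params$c2 * phi * (phi - params$b - 1))
}

#' Normalize a transmembrane voltage
#'
#' Affine map \eqn{\phi = (V_m - V_r)/(V_p - V_r)}; with default
#' parameters, -85 mV maps to 0 and 15 mV to 1.
#' @param Vm voltage in mV.
#' @inheritParams ionic_current
#' @export
normalize_potential <- function(Vm, params = aliev_panfilov_params()) {
  (Vm - params$V_r) / (params$V_p - params$V_r)
}

#' @rdname normalize_potential
#' @param phi normalized potential.
#' @export
denormalize_potential <- function(phi, params = aliev_panfilov_params()) {
  params$V_r + phi * (params$V_p - params$V_r)
}

#' Forward-Euler gating update
#'
#' \eqn{r_{n+1} = r_n + \Delta t\, g(\phi_n, r_n)} applied independently at
#' each point; `dt` is an increment in model time units (the solver passes
#' physical dt divided by `params$tau`).
#'
#' @inheritParams ionic_current
#' @param dt time increment (model units), `>= 0`.
#' @export
gating_step <- function(phi, r, dt, params = aliev_panfilov_params()) {
  if (any(dt < 0)) stop("dt must be non-negative")
  r + dt * gating_rate(phi, r, params)
}

# Backward-Euler gating solve (per point, vectorized scalar Newton); used
# by the fully-implicit comparator. Converges quadratically from r_n.
solve_gating_be <- function(phi, r_n, dt_model, params) {
  k <- params$c2 * phi * (phi - params$b - 1)
  A <- params$mu1 / (params$mu2 + phi)
  r <- r_n
  for (it in 1:6) {
    h <- r - r_n + dt_model * (params$gamma + A * r) * (r + k)
    hp <- 1 + dt_model * (A * (r + k) + params$gamma + A * r)
    r <- r - h / hp
  }
  r
}
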