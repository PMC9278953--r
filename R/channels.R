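## Voltage-gated channel mechanisms as pure gating mathematics, decoupled
## from any integrator.  All voltages are mV, times ms.
##
## Shift convention (public API): `delta_shift` is the change of the
## half-activation voltage, negative = hyperpolarizing.  The underlying
## model equations add a `vshift` term inside the exponent with the
## opposite sense; the mapping vshift = -delta_shift is applied internally
## so that e.g. delta_shift = -10 moves the Kv3 half-activation from
## -5 mV to -15 mV, matching how voltage shifts are reported for the
## measured conductances.

#' Kv3 steady-state activation
#'
#' Steady-state activation of the fast-spiking-interneuron delayed
#' rectifier (Kv3) conductance, \eqn{m_\infty(v) = 1 - 1/(1 +
#' \exp((v + 5 - \Delta)/12))}, where \eqn{\Delta} is `delta_shift`.
#' Half-activation sits at \eqn{-5 + \Delta} mV: \eqn{-5} mV for the
#' control channel, \eqn{-15} mV after a \eqn{-10} mV hyperpolarizing
#' shift.
#'
#' @param v Membrane potential (mV); vectorized.
#' @param delta_shift Shift of the half-activation voltage (mV), negative
#'   = hyperpolarizing. Default 0.
#' @return Activation fraction in \[0, 1\].
#' @export
#' @examples
#' kv3_minf(-5)              # 0.5
#' kv3_minf(-15, delta_shift = -10)  # 0.5
kv3_minf <- function(v, delta_shift = 0) {
  1 - 1 / (1 + exp((v + 5 - delta_shift) / 12))
}

#' Kv3 steady-state inactivation
#'
#' \eqn{h_\infty(v) = 1/(1 + \exp((v + 30 - \Delta)/10))}; half-inactivation
#' at \eqn{-30 + \Delta} mV, monotonically decreasing in `v`.
#'
#' @inheritParams kv3_minf
#' @return Inactivation fraction in \[0, 1\].
#' @export
kv3_hinf <- function(v, delta_shift = 0) {
  1 / (1 + exp((v + 30 - delta_shift) / 10))
}

#' Kv3 activation/deactivation time constant
#'
#' Bell-shaped voltage dependence \eqn{\tau_m(v) = 0.5 + 4\exp(-0.5((v -
#' \Delta + 25)/25)^2)\cdot s} (ms), peaking at \eqn{-25 + \Delta} mV with
#' a 0.5 ms floor.  `kin_scale` multiplies the Gaussian term only by
#' default (`parse = "gaussian"`); setting `parse = "whole"` multiplies
#' the entire expression including the floor.  Both parses coincide at
#' `kin_scale = 1`.  The 25 mV Gaussian width is the package's reading of
#' the mechanism; it is recorded in run metadata.
#'
#' @inheritParams kv3_minf
#' @param kin_scale Multiplier on the kinetics (> 0); values < 1 speed the
#'   channel up.
#' @param parse Where `kin_scale` applies: `"gaussian"` (default) or
#'   `"whole"`.
#' @return Time constant (ms), strictly positive.
#' @export
kv3_mtau <- function(v, delta_shift = 0, kin_scale = 1,
                     parse = c("gaussian", "whole")) {
  if (!is.numeric(kin_scale) || any(kin_scale <= 0))
    stop("kin_scale must be > 0")
  parse <- match.arg(parse)
  z <- (v - delta_shift + 25) / 25
  bell <- 4 * exp(-0.5 * z^2)
  if (parse == "whole") (0.5 + bell) * kin_scale else 0.5 + bell * kin_scale
}

#' Kv7 (M-current) steady-state activation
#'
#' Monotone sigmoid with half-activation at \eqn{-27 + \Delta} mV and a
#' 4 mV slope, the supplemented M-type potassium conductance used to
#' contrast slow- vs fast-gating K+ channel effects on firing.
#'
#' @inheritParams kv3_minf
#' @return Activation fraction in \[0, 1\].
#' @export
kv7_minf <- function(v, delta_shift = 0) {
  1 / (1 + exp(-(v + 27 - delta_shift) / 4))
}

#' Kv7 (M-current) activation time constant
#'
#' Very slow below spike threshold (~8 s) and two orders of magnitude
#' faster at spike voltages (150 ms above ~+8 mV): the gate integrates
#' spike activity over hundreds of milliseconds and is essentially frozen
#' between spikes.  The kinetic parameters are fixed; an
#' activation-voltage shift moves only the steady-state curve, so
#' `delta_shift` is accepted for interface symmetry but does not alter
#' the time constant.
#'
#' @inheritParams kv3_minf
#' @return Time constant (ms).
#' @export
kv7_mtau <- function(v, delta_shift = 0) {
  150 + 7850 / (1 + exp((v - 8) / 2))
}

#' Hodgkin-Huxley sodium channel rates
#'
#' Classic squid-axon Na+ rate functions with a rigid voltage shift of
#' both activation and inactivation curves (`v_shift`, positive =
#' depolarizing) and a multiplicative `kin_scale` on both time constants.
#' The removable singularity of the alpha_m expression at \eqn{v -
#' v_{shift} = -40} mV is handled by its analytic limit.
#'
#' @param v Membrane potential (mV); vectorized.
#' @param v_shift Rigid voltage shift (mV) of the curves.
#' @param kin_scale Multiplier on both time constants (> 0).
#' @return A list with numeric vectors `minf`, `hinf`, `mtau`, `htau`.
#' @export
nav_hh_rates <- function(v, v_shift = 0, kin_scale = 1) {
  if (any(kin_scale <= 0)) stop("kin_scale must be > 0")
  vv <- v - v_shift
  x <- -(vv + 40)
  am <- 0.1 * ifelse(abs(x / 10) < 1e-6,
                     10 * (1 - x / 20),
                     x / (exp(x / 10) - 1))
  bm <- 4 * exp(-(vv + 65) / 18)
  ah <- 0.07 * exp(-(vv + 65) / 20)
  bh <- 1 / (1 + exp(-(vv + 35) / 10))
  list(minf = am / (am + bm), hinf = ah / (ah + bh),
       mtau = kin_scale / (am + bm), htau = kin_scale / (ah + bh))
}

#' Gate parameter set
#'
#' Bundles the user-tunable knobs of a gating mechanism: the shift of its
#' half-activation voltage, the kinetic scale, and the (slow) inactivation
#' time constant.
#'
#' @param mechanism One of `"kv3"`, `"nav_hh"`, `"kv7"`.
#' @param delta_shift Shift of the half-activation voltage (mV).
#' @param kin_scale Kinetics multiplier (> 0).
#' @param tau_inact Kv3 inactivation time constant (ms), default 1000.
#' @param mtau_parse See [kv3_mtau()].
#' @return An object of class `gate_params`.
#' @export
gate_params <- function(mechanism = c("kv3", "nav_hh", "kv7"),
                        delta_shift = 0, kin_scale = 1, tau_inact = 1000,
                        mtau_parse = c("gaussian", "whole")) {
  mechanism <- match.arg(mechanism)
  mtau_parse <- match.arg(mtau_parse)
  if (kin_scale <= 0) stop("kin_scale must be > 0")
  if (tau_inact <= 0) stop("tau_inact must be > 0")
  structure(list(mechanism = mechanism, delta_shift = delta_shift,
                 kin_scale = kin_scale, tau_inact = tau_inact,
                 mtau_parse = mtau_parse),
            class = "gate_params")
}

#' Channel specification
#'
#' @param mechanism_id One of `"kv3"`, `"nav_hh"`, `"kv7"`, `"leak"`.
#' @param gbar Maximal conductance: density (S/cm2) when
#'   `gbar_mode = "density"`, absolute nS when `gbar_mode = "absolute"`.
#' @param e_rev Reversal potential (mV).
#' @param gates A [gate_params()] object (ignored for leak).
#' @param gate_exponents Integer powers `c(m, h)` applied to the activation
#'   and inactivation gates.  Defaults: Kv3 m^1 h^1, Nav m^3 h^1, Kv7 m^1.
#' @param gbar_mode `"density"` or `"absolute"`.
#' @return An object of class `channel_spec`.
#' @export
channel_spec <- function(mechanism_id = c("kv3", "nav_hh", "kv7", "leak"),
                         gbar, e_rev, gates = NULL, gate_exponents = NULL,
                         gbar_mode = c("density", "absolute")) {
  mechanism_id <- match.arg(mechanism_id)
  gbar_mode <- match.arg(gbar_mode)
  if (gbar < 0) stop("gbar must be >= 0")
  if (is.null(gate_exponents)) {
    gate_exponents <- switch(mechanism_id,
      kv3 = c(1L, 1L), nav_hh = c(3L, 1L), kv7 = c(1L, 0L),
      leak = c(0L, 0L))
  }
  if (any(gate_exponents < 0)) stop("gate_exponents must be >= 0")
  if (is.null(gates) && mechanism_id != "leak")
    gates <- gate_params(mechanism_id)
  structure(list(mechanism_id = mechanism_id, gbar = gbar, e_rev = e_rev,
                 gates = gates, gate_exponents = as.integer(gate_exponents),
                 gbar_mode = gbar_mode),
            class = "channel_spec")
}

## Steady states and time constants for a mechanism at voltage v.
gate_targets <- function(params, v) {
  switch(params$mechanism,
    kv3 = list(minf = kv3_minf(v, params$delta_shift),
               hinf = kv3_hinf(v, params$delta_shift),
               mtau = kv3_mtau(v, params$delta_shift, params$kin_scale,
                               params$mtau_parse),
               htau = params$tau_inact),
    nav_hh = {
      r <- nav_hh_rates(v, params$delta_shift, params$kin_scale)
      list(minf = r$minf, hinf = r$hinf, mtau = r$mtau, htau = r$htau)
    },
    kv7 = list(minf = kv7_minf(v, params$delta_shift), hinf = 1,
               mtau = kv7_mtau(v, params$delta_shift) * params$kin_scale,
               htau = Inf))
}

#' Advance a gate state by one time step
#'
#' Exact exponential relaxation toward the steady state at fixed voltage:
#' \eqn{m' = m_\infty + (m - m_\infty) e^{-dt/\tau_m}}, likewise for the
#' inactivation gate with its own time constant.  Exact for constant `v`,
#' hence composable: k substeps of dt equal one step of k dt.
#'
#' @param state List with elements `m` and `h` (fractions in \[0, 1\]).
#' @param v Membrane potential (mV).
#' @param dt Time step (ms), > 0.
#' @param params A [gate_params()] object.
#' @return Updated state list.
#' @export
gate_step <- function(state, v, dt, params) {
  if (dt <= 0) stop("dt must be > 0")
  tg <- gate_targets(params, v)
  m <- tg$minf + (state$m - tg$minf) * exp(-dt / tg$mtau)
  h <- if (is.finite(tg$htau))
    tg$hinf + (state$h - tg$hinf) * exp(-dt / tg$htau)
  else state$h
  list(m = m, h = h)
}

#' Ohmic channel current
#'
#' \eqn{I = \bar g m^a h^b (v - E_{rev})}; positive = outward.  Units
#' follow `gbar_mode`: nA for absolute nS conductances, mA/cm2 for
#' densities.
#'
#' @param spec A [channel_spec()].
#' @param state List with gate fractions `m`, `h`.
#' @param v Membrane potential (mV).
#' @return Current (positive outward).
#' @export
channel_current <- function(spec, state, v) {
  a <- spec$gate_exponents[1]
  b <- spec$gate_exponents[2]
  open <- (if (a > 0) state$m^a else 1) * (if (b > 0) state$h^b else 1)
  g <- spec$gbar * open
  drive <- v - spec$e_rev
  # nS * mV = pA, hence 1e-3 nA; S/cm2 * mV = mA/cm2 numerically as-is
  if (spec$gbar_mode == "absolute") g * drive * 1e-3 else g * drive
}
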