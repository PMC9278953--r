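## Single-compartment cell models and the fixed-step integrator wrapper.
##
## The PV model is a 20 um x 20 um cylinder (lateral area, the convention
## of compartmental simulators; a flat-square interpretation is selectable)
## carrying HH-type Nav, the Kv3 delayed rectifier, an optional Kv7
## M-current, and leak.  The pyramidal cell is a single-compartment
## burster: HH-type Na/K plus a persistent Na current with slow
## inactivation that paces bursts.
##
## Integration: exact-exponential gate updates and an exponential
## (linearly implicit) voltage update with conductances frozen over the
## step.  The voltage update is exact for a passive membrane and remains
## stable at dt = 0.025 ms even at spike-peak sodium conductances, where a
## fully explicit update would not be.

pv_defaults <- function() {
  list(
    # geometry: cylinder 20 um long, 20 um diameter, lateral area
    length_um = 20, diam_um = 20, geometry = "cylinder",
    cm_uF_cm2 = 1.0,
    gna_S_cm2 = 0.3, ena = 50, na_vshift = 0, na_kin_scale = 0.10,
    gkv3_S_cm2 = 0.04, ek = -90,
    kv3_delta_shift = 0, kv3_kin_scale = 1, kv3_tau_inact = 1000,
    kv3_mtau_parse = "gaussian",
    gkv7_S_cm2 = 0, kv7_delta_shift = 0, kv7_kin_scale = 1,
    gl_S_cm2 = 8.0e-4, el = -68,
    # in-silico dynamic clamp (Kv3 gating at the live membrane potential)
    dc_g_nS = 0, dc_delta_shift = 0, dc_kin_scale = 1, dc_tau_inact = 1000,
    dc_e_rev = -90
  )
}

pc_defaults <- function() {
  list(
    c_pF = 21, gna_nS = 28, gk_nS = 11.2, gnap_nS = 2.8, gl_nS = 5,
    ena = 50, ek = -85, el = -62, taun_bar_ms = 10, tauh_bar_ms = 1500
  )
}

compartment_area_cm2 <- function(cfg) {
  if (identical(cfg$geometry, "square"))
    return(cfg$length_um * cfg$diam_um * 1e-8)
  pi * cfg$diam_um * cfg$length_um * 1e-8
}

#' Create a fast-spiking PV interneuron model
#'
#' Single-compartment conductance-based model calibrated to fire
#' high-frequency, non-adapting spike trains with sub-millisecond action
#' potentials, a stable -70 mV resting potential, and an input resistance
#' near 100 MOhm.  All channel densities, reversals, and the Kv3
#' shift/kinetics knobs can be overridden through `config`.
#'
#' @param config Named list of overrides of the default parameters
#'   (unknown names are an error).  Key entries: `gna_S_cm2`, `gkv3_S_cm2`,
#'   `gkv7_S_cm2`, `gl_S_cm2` (densities, S/cm2), `kv3_delta_shift` (mV),
#'   `kv3_kin_scale`, `kv3_tau_inact` (ms), `el`, `ek`, `ena` (mV).
#' @return An object of class `c("pv_cell", "cell_model")`.
#' @export
#' @examples
#' cell <- make_pv_cell()
#' cell_capacitance_pF(cell)
make_pv_cell <- function(config = list()) {
  cfg <- merge_config(pv_defaults(), config, "pv cell")
  if (cfg$kv3_kin_scale <= 0 || cfg$kv3_tau_inact <= 0)
    stop("kv3 kinetic parameters must be positive")
  cfg$area_cm2 <- compartment_area_cm2(cfg)
  structure(list(type = "pv", params = cfg),
            class = c("pv_cell", "cell_model"))
}

#' Create a bursting pyramidal cell model
#'
#' Single-compartment burster: fast Na (instantaneous activation,
#' inactivation slaved to the delayed-rectifier gate), delayed-rectifier
#' K, leak, and a persistent Na current whose slow inactivation
#' terminates bursts.  Depolarizing bias moves the cell from silence
#' through rhythmic bursting to tonic spiking; the default constants put
#' the burst regime at the bias range used for the network's baseline.
#'
#' @param config Named list of overrides (absolute conductances in nS,
#'   capacitance in pF, reversals in mV, gate time-constant ceilings in
#'   ms).  Unknown names are an error.
#' @return An object of class `c("pc_cell", "cell_model")`.
#' @export
make_pc_cell <- function(config = list()) {
  cfg <- merge_config(pc_defaults(), config, "pc cell")
  structure(list(type = "pc", params = cfg),
            class = c("pc_cell", "cell_model"))
}

merge_config <- function(defaults, config, what) {
  if (length(config) == 0) return(defaults)
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0)
    stop("unknown ", what, " config entries: ",
         paste(unknown, collapse = ", "))
  modifyList(defaults, config)
}

#' Membrane capacitance of a cell model in pF
#'
#' @param cell A `cell_model`.
#' @return Capacitance (pF).
#' @export
cell_capacitance_pF <- function(cell) {
  if (cell$type == "pv")
    cell$params$cm_uF_cm2 * cell$params$area_cm2 * 1e6
  else cell$params$c_pF
}

#' Attach an in-silico dynamic-clamp Kv3 conductance
#'
#' Adds a current \eqn{g_{total} m h (v - E_{rev})} at every integration
#' step, with `m` and `h` advanced by the same Kv3 gating equations as the
#' intrinsic channel, evaluated on the live membrane potential --- the
#' simulation analogue of dynamic-clamp conductance injection.
#'
#' @param cell A PV `cell_model`.
#' @param g_total Total clamp conductance (nS), e.g. 20.
#' @param delta_shift Shift of the clamp conductance's half-activation
#'   voltage (mV).
#' @param e_rev Reversal potential of the injected current (mV).
#' @param kin_scale,tau_inact Kinetics of the clamp conductance.
#' @return The cell with the clamp attached.
#' @export
attach_dynamic_clamp <- function(cell, g_total, delta_shift = 0,
                                 e_rev = -90, kin_scale = 1,
                                 tau_inact = 1000) {
  stopifnot(inherits(cell, "pv_cell"))
  if (g_total < 0) stop("g_total must be >= 0")
  cell$params$dc_g_nS <- g_total
  cell$params$dc_delta_shift <- delta_shift
  cell$params$dc_kin_scale <- kin_scale
  cell$params$dc_tau_inact <- tau_inact
  cell$params$dc_e_rev <- e_rev
  cell
}

#' Alpha-function synaptic conductance
#'
#' \eqn{g(t) = g_{max} \frac{t - t_0}{\tau} \exp(1 - (t - t_0)/\tau)} for
#' \eqn{t \ge t_0}, zero before; peaks at exactly `gmax` at
#' \eqn{t_0 + \tau}.
#'
#' @param t Time (ms); vectorized.
#' @param onset_time Event onset \eqn{t_0} (ms).
#' @param gmax Peak conductance (nS).
#' @param tau Rise time constant (ms), > 0.
#' @return Conductance (nS).
#' @export
alpha_conductance <- function(t, onset_time = 0, gmax = 10, tau = 0.5) {
  if (tau <= 0) stop("tau must be > 0")
  x <- (t - onset_time) / tau
  ifelse(x >= 0, gmax * x * exp(1 - x), 0)
}

## Sum alpha-function waveforms for a set of events into a conductance
## series sampled at dt over n steps.  Each waveform is truncated at
## 12 tau (< 1e-4 of peak).
alpha_series <- function(onsets, gmax, tau, n, dt) {
  g <- numeric(n)
  if (length(onsets) == 0) return(g)
  gmax <- rep_len(gmax, length(onsets))
  span <- ceiling(12 * tau / dt)
  for (k in seq_along(onsets)) {
    i0 <- max(1L, floor(onsets[k] / dt) + 1L)
    i1 <- min(n, i0 + span)
    if (i0 > n) next
    tt <- (seq.int(i0, i1) - 1) * dt
    g[i0:i1] <- g[i0:i1] + alpha_conductance(tt, onsets[k], gmax[k], tau)
  }
  g
}

#' Simulate a single cell
#'
#' Fixed-step integration of a PV or PC model under injected current and
#' optional synaptic conductance input.  Deterministic given identical
#' inputs.
#'
#' @param cell A `cell_model` from [make_pv_cell()] or [make_pc_cell()].
#' @param duration Simulation length (ms).
#' @param dt Time step (ms), default 0.025, must be in (0, 0.1\].
#' @param i_inj Injected current (nA): scalar, or vector of length
#'   `duration/dt`.
#' @param exc_events,inh_events Optional data frames of synaptic events
#'   with columns `onset` (ms), `gmax` (nS); summed as alpha conductances
#'   with time constants `tau_exc` / `tau_inh` and reversals 0 / -90 mV.
#' @param tau_exc,tau_inh Alpha-synapse time constants (ms).
#' @param v0 Initial voltage (mV); defaults to the leak reversal.
#' @param record_currents Also return the total ionic membrane current.
#' @return A data frame of class `sim_trace` with columns `time_ms`,
#'   `v_mV` (and `i_mem_nA` if requested); attributes `dt` and `params`.
#' @export
simulate_cell <- function(cell, duration, dt = 0.025, i_inj = 0,
                          exc_events = NULL, inh_events = NULL,
                          tau_exc = 0.5, tau_inh = 5.8, v0 = NULL,
                          record_currents = FALSE) {
  stopifnot(inherits(cell, "cell_model"))
  if (dt <= 0 || dt > 0.1) stop("dt must be in (0, 0.1] ms")
  n <- round(duration / dt)
  i_vec <- if (length(i_inj) == 1) rep(i_inj, n) else i_inj
  if (length(i_vec) != n) stop("i_inj length must be duration/dt")
  g_exc <- if (is.null(exc_events)) numeric(n) else
    alpha_series(exc_events$onset, exc_events$gmax, tau_exc, n, dt)
  g_inh <- if (is.null(inh_events)) numeric(n) else
    alpha_series(inh_events$onset, inh_events$gmax, tau_inh, n, dt)
  if (is.null(v0))
    v0 <- if (cell$type == "pv") cell$params$el else -65

  p <- cell$params
  res <- if (cell$type == "pv") {
    p$kv3_mtau_parse <- if (identical(p$kv3_mtau_parse, "whole")) 1L else 0L
    .simulate_pv_cpp(p, dt, v0, i_vec, g_exc, g_inh, 0, -90,
                     record_currents)
  } else {
    .simulate_pc_cpp(p, dt, v0, i_vec, g_exc, g_inh, 0, -90,
                     record_currents)
  }
  if (isTRUE(res$blowup))
    stop("numerical blow-up at t = ", format(res$t_fail), " ms")
  out <- data.frame(time_ms = seq(0, by = dt, length.out = n + 1),
                    v_mV = res$v)
  if (record_currents) out$i_mem_nA <- res$i_mem
  attr(out, "dt") <- dt
  attr(out, "params") <- cell$params
  class(out) <- c("sim_trace", "data.frame")
  out
}
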